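# Simulation configuration.

#' Simulation configuration
#'
#' Bundles the study conditions and agent-rule parameters of the hourly-tick
#' regeneration model. Defaults encode the typically developing (TD) milieu:
#' satellite-cell (SC) density 0.10 per fiber per 10 um slice thickness
#' (0.04 emulates the cerebral palsy milieu), 10% strain-selected damage
#' with necrosis expansion, and 672 one-hour ticks (28 days). Rule
#' parameters the source literature leaves open (lifespans, proliferation
#' and clearance probabilities, recruitment windows) are calibrated once so
#' the emergent census reproduces published post-injury time courses
#' (neutrophils peak ~20 h, macrophages ~40 h, damaged-fibril clearance
#' within 90 h, SC decline from ~120 h, repair complete by ~216 h); see the
#' package vignette.
#'
#' @param sc_per_fiber_per_10um SC density per fiber per 10 um thickness
#'   (0.10 TD, 0.04 CP).
#' @param sc_count Optional exact initial SC count override (used by the
#'   SC sensitivity sweep).
#' @param damage_fraction Fraction of fibril pixels seeded as damaged
#'   (before necrosis expansion).
#' @param ticks Simulation length in hours.
#' @param replicates Default replicate count for experiment drivers
#'   (150 standard; 20 in fast mode).
#' @param stretch Imposed eccentric fiber stretch for the strain surrogate.
#' @param damage_mode `"strain"` (highest-strain pixels) or `"random"`.
#' @param collagen_damaged Collagen density assigned to damaged ECM.
#' @param n_neutrophils,n_macrophages Initial resident counts on ECM.
#' @param fb_per_fiber_per_10um Fibroblast seeding density (same formula as
#'   SCs); `n_fibroblasts` overrides with an exact count.
#' @param n_fibroblasts Optional exact fibroblast count.
#' @param neutrophil_lifespan_h Mean exponential neutrophil lifespan, hours,
#'   clocked from damage detection.
#' @param neutrophil_spawn_p Per-contact proliferation probability.
#' @param neutrophil_window_h Recruitment window after damage during which
#'   neutrophils proliferate.
#' @param neutrophil_cap Max neutrophil count.
#' @param neutrophil_recruit_max Maximum neutrophil recruits per hour
#'   (vascular influx ceiling, as for macrophages).
#' @param neutrophil_clear_p Per-contact probability of breaking down a
#'   damaged object in a tick.
#' @param macrophage_delay_h Hours after damage before macrophages engage.
#' @param macrophage_spawn_p Per-phagocytosis proliferation probability.
#' @param macrophage_window_h Recruitment window for M1 proliferation.
#' @param macrophage_cap Max macrophage count.
#' @param macrophage_recruit_max Maximum monocyte-derived M1 recruits per
#'   hour (vascular influx ceiling; makes clearance time scale with damage
#'   burden instead of self-compensating).
#' @param macrophage_influx Baseline monocyte influx per hour while damage
#'   persists (within the recruitment window), independent of contacts.
#' @param macrophage_clear_p Per-contact phagocytosis probability.
#' @param m1_lifespan_h Mean exponential M1 lifespan, hours.
#' @param m2_lifespan_h Duration of the anti-inflammatory M2 phase after
#'   the phenotype switch, hours (fixed, with a small spread).
#' @param inflammation_resolution_h Hours after damage during which
#'   phagocytosis remains effective; residual damage beyond this window
#'   persists chronically (inflammatory cells linger but stop clearing).
#' @param chronic_debris Damage burden (pixels) below which clearing
#'   continues past the resolution window: isolated debris is eventually
#'   cleared, only bulk unresolved damage becomes chronic.
#' @param il6_deposit Local IL-6 amount deposited per damage contact.
#' @param il6_diffusion 4-neighbor smoothing weight for the IL-6 field.
#' @param cytokine_decay First-order pool decay per hour (0 = accumulate).
#' @param hgf_threshold HGF pool level above which quiescent SCs activate.
#' @param sc_division_base_p Base hourly division probability of an eligible
#'   active SC (calibration knob; the division-chain decay is fixed).
#' @param sc_division_min_age_h Active age before first division (18 h).
#' @param sc_division_probs Probabilities of symmetric-SC, symmetric-
#'   myoblast and asymmetric division (must sum to 1).
#' @param sc_exit_p Hourly probability that an active SC leaves the pool
#'   once the IGF-1 gradient is no longer positive in the post-acute phase.
#' @param sc_exit_post_p Gentler exit hazard applied once repair is
#'   complete (residual active SCs linger and remodel borders before
#'   returning to quiescence).
#' @param sc_exit_after_h Post-damage hour from which the exit hazard can
#'   apply.
#' @param sc_repair_p Per-tick probability an adjacent active SC repairs a
#'   cleared fibril pixel.
#' @param sc_repairs_per_tick Maximum pixels an active SC can restore per
#'   tick while adjacent to repair sites.
#' @param repair_requires_myoblast If `TRUE`, repair consumes a myoblast and
#'   stalls without one; if `FALSE` (default) SCs may act directly when no
#'   myoblast is available.
#' @param myoblast_lifespan_h Unfused myoblast lifespan, hours.
#' @param fb_deposit_p Per-tick probability an adjacent myofibroblast
#'   deposits collagen on a cleared ECM-owned pixel.
#' @param fb_claim_fibril_p Per-tick probability an activated myofibroblast
#'   claims a cleared fibril-owned pixel at an ECM edge while repair is
#'   ongoing (collagen competition with myoblast-mediated repair).
#' @param fb_fallback_rate Pixels per fibroblast per tick filled once no SCs
#'   remain in the muscle (fibrosis fallback).
#' @param hypertrophy_p Per-tick probability that an active SC adds a border
#'   fibril once repair is complete.
#' @param hypertrophy_sc_cap Saturation count: hypertrophy proceeds at a
#'   rate set by at most this many active SCs (border remodeling is
#'   spatially limited).
#' @param n_speed,m_speed,sc_speed,fb_speed Movement speeds, pixels per hour
#'   (1 px is ~2.5 um across; motile cells cover several pixels per hour).
#' @param target_cap Subsample size of target pixels used for movement
#'   direction finding.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(sc_per_fiber_per_10um = 0.10,
                       sc_count = NULL,
                       damage_fraction = 0.10,
                       ticks = 672L,
                       replicates = 150L,
                       stretch = 0.30,
                       damage_mode = c("strain", "random"),
                       collagen_damaged = 0.2,
                       n_neutrophils = 20L,
                       n_macrophages = 5L,
                       fb_per_fiber_per_10um = 0.09,
                       n_fibroblasts = NULL,
                       neutrophil_lifespan_h = 12,
                       neutrophil_spawn_p = 0.3,
                       neutrophil_window_h = 19,
                       neutrophil_cap = 200L,
                       neutrophil_recruit_max = 8L,
                       neutrophil_clear_p = 0.5,
                       macrophage_delay_h = 12,
                       macrophage_spawn_p = 0.45,
                       macrophage_window_h = 39,
                       macrophage_cap = 170L,
                       macrophage_recruit_max = 6L,
                       macrophage_influx = 2L,
                       macrophage_clear_p = 0.8,
                       m1_lifespan_h = 36,
                       m2_lifespan_h = 45,
                       inflammation_resolution_h = 85,
                       chronic_debris = 60L,
                       il6_deposit = 1,
                       il6_diffusion = 0.2,
                       cytokine_decay = 0,
                       hgf_threshold = 0,
                       sc_division_base_p = 0.32,
                       sc_division_min_age_h = 18L,
                       sc_division_probs = c(sym_sc = 1/3, sym_mb = 1/3, asym = 1/3),
                       sc_exit_p = 0.12,
                       sc_exit_post_p = 0.03,
                       sc_exit_after_h = 96,
                       sc_repair_p = 1.0,
                       sc_repairs_per_tick = 4L,
                       repair_requires_myoblast = FALSE,
                       myoblast_lifespan_h = 48,
                       fb_deposit_p = 0.25,
                       fb_claim_fibril_p = 0.015,
                       fb_fallback_rate = 2L,
                       hypertrophy_p = 0.1,
                       hypertrophy_sc_cap = 10L,
                       n_speed = 4L,
                       m_speed = 5L,
                       sc_speed = 4L,
                       fb_speed = 2L,
                       target_cap = 256L) {
  damage_mode <- match.arg(damage_mode)
  stopifnot(
    sc_per_fiber_per_10um >= 0, damage_fraction >= 0, damage_fraction <= 1,
    ticks >= 1, replicates >= 1, stretch > 0,
    abs(sum(sc_division_probs) - 1) < 1e-9,
    sc_division_base_p >= 0, sc_division_base_p <= 1
  )
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> SC density %.2f/fiber/10um%s, damage %.0f%% (%s), %d ticks, %d replicates\n",
    x$sc_per_fiber_per_10um,
    if (!is.null(x$sc_count)) sprintf(" (override: %d SCs)", x$sc_count) else "",
    100 * x$damage_fraction, x$damage_mode, x$ticks, x$replicates
  ))
  invisible(x)
}

#' Initial satellite-cell count for a grid and configuration
#'
#' `density x n_fibers x slice_thickness / 10`, with stochastic rounding of
#' a fractional part (floor plus a Bernoulli draw on the remainder) so that
#' the expected count equals the density formula even for small bundles.
#'
#' @param config A `sim_config`.
#' @param grid A `tissue_grid`.
#' @return Integer SC count (uses the current RNG stream for the rounding
#'   draw when the formula value is fractional).
#' @export
initial_sc_count <- function(config, grid) {
  if (!is.null(config$sc_count)) return(as.integer(config$sc_count))
  m <- config$sc_per_fiber_per_10um * grid$n_fibers * grid$slice_thickness / 10
  stochastic_round(m)
}

initial_fb_count <- function(config, grid) {
  if (!is.null(config$n_fibroblasts)) return(as.integer(config$n_fibroblasts))
  m <- config$fb_per_fiber_per_10um * grid$n_fibers * grid$slice_thickness / 10
  stochastic_round(m)
}

stochastic_round <- function(m) {
  base <- floor(m)
  frac <- m - base
  as.integer(base + (frac > 0 && runif(1) < frac))
}
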