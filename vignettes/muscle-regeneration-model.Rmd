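---
title: "A coupled mechanobiological model of muscle damage and regeneration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coupled mechanobiological model of muscle damage and regeneration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myoregen)
```

## The model

`myoregen` simulates damage and regeneration of a skeletal-muscle fiber
bundle on a 2D pixel lattice, and asks how the outcome changes when the
satellite-cell (SC) pool is reduced, as it is in cerebral palsy (CP)
muscle. The model has two coupled parts.

**Mechanics.** Fibers and extracellular matrix (ECM) are transversely
isotropic, nearly incompressible hyperelastic materials: a Mooney-Rivlin
ground substance, an along-fiber energy $F_2(\tilde\lambda)$ with an
exponential toe region and a linear region above a transition stretch
$\lambda_m$, and a dilatational term $\tfrac{K}{2}[\ln J]^2$. The fiber
stress response is

$$\tilde\lambda\,\frac{\partial F_2}{\partial\tilde\lambda} =
\begin{cases}
0, & \tilde\lambda \le 1\\
c_3\!\left(e^{c_4(\tilde\lambda-1)}-1\right), & 1 \le \tilde\lambda \le \lambda_m\\
c_5\tilde\lambda + c_6, & \tilde\lambda \ge \lambda_m,
\end{cases}$$

with $c_6$ fixed by continuity at $\lambda_m$. Active tension follows a
time-varying elastance model, $T_a = T_{max}\,
\mathrm{Ca}_0^2/(\mathrm{Ca}_0^2+\mathrm{ECa}_{50}^2)\,C(t)$, where the
calcium sensitivity $\mathrm{ECa}_{50}$ depends on sarcomere length and
diverges at the slack length $l_0$ so that tension vanishes there. The
printed rendering of $\mathrm{ECa}_{50}$ in the source constitutive
literature is typographically ambiguous; the package implements the
standard elastance form
$\mathrm{ECa}_{50} = (\mathrm{Ca}_0)_{max}/\sqrt{e^{B(l-l_0)}-1}$ by
default and exposes the literal reading behind `form = "literal"`,
without claiming either matches any particular solver.

A full nonlinear finite-element equilibrium solve is deliberately out of
scope: its only downstream role is to *rank* strain across the section
under a 30% eccentric stretch. The surrogate strain field reproduces the
robust features of that ranking — outer fibers, especially corner
fibers, carry the highest strain; within each fiber, strain concentrates
at the periphery where the compliant matrix interface is (so the damage
the ranking selects forms bands along fiber boundaries, as seen in
damaged cross-sections); and strain scales inversely with the tangent
stiffness at the working stretch (dominated by the along-fiber modulus
$c_5$ above $\lambda_m$; $c_3$, $c_4$ and density do not enter there,
and the ground substance and bulk modulus enter only weakly).
Externally computed per-element strain tables can be imported instead
(`strain_import()`), registered to pixels by nearest element center.

**Agent-based regeneration.** The highest-strain 10% of fibril pixels are
marked damaged, and their von Neumann neighborhoods (fibril and ECM) join
them as a necrosis halo. An hourly-tick scheduler then runs, in fixed
order: cytokine update, neutrophils, macrophages, satellite cells and
myoblasts, fibroblasts, border re-formation/hypertrophy, census. Five
secreted factors are tracked as global pools with per-hour census-driven
secretion rates (used exactly as printed in their source literature; their
absolute scales are incommensurate, and only signs, gradients, and
arg-max comparisons feed the rules):

$$\begin{aligned}
dIGF1/dt &= 2(8.8\times10^{-5}\,AM)\\
dTNF\alpha/dt &= 3.21\times10^{-12} + 5.8\times10^{-12}N +
 1.25\times10^{-9}PM + 4.9\times10^{-18}Fb\\
dTGF\beta/dt &= 8.75\times10^{-3}\,AM\\
dHGF/dt &= 1.49\times10^{-7}\,DE\\
dIL6/dt &= 2.91\times10^{-12} + 1.25\times10^{-12}N + 1.25\times10^{-12}PM
\end{aligned}$$

Global pools drive the temporal gates (HGF level activates quiescent SCs;
positive IGF-1 gradient licenses SC division; positive TGF-β gradient
activates myofibroblasts). IL-6 additionally has a per-pixel local field,
deposited by neutrophils at damage contacts and smoothed by a
mass-conserving 4-neighbor kernel, which macrophages climb by Moore
arg-max before they engage. The spatial representation of the factors is
not prescribed by the underlying biology we model, so this split —
global pools for timing, one local field for chemotaxis — is a design
choice that reconciles ODE-like secretion rates with neighborhood-search
rules.

The cellular rules, in brief:

* **Neutrophils** are seeded on ECM, move toward damage, and on contact
  release IL-6, mark the object as needing repair, and break it down
  (pixel cleared to EMPTY, keeping its `needs_repair` flag and its
  original owner). They recruit from the vasculature during an early
  window and die with exponential lifespans clocked from damage
  detection, so their census peaks at ~20 h.
* **Macrophages (M1)** engage after an infiltration delay, phagocytose
  damaged objects (fibril and ECM debris), and recruit under a per-hour
  influx ceiling during a window ending at 39 h, peaking at ~40 h. When
  the last damaged object is cleared they all switch to the
  anti-inflammatory M2 phenotype, which secretes TGF-β and IGF-1-driving
  signal for a fixed ~45 h resolution phase; the end of that phase is
  what collapses the IGF-1 gradient and closes the SC division window.
* **Satellite cells** activate when HGF is present, divide after 18 h of
  active age while the IGF-1 gradient is positive — with the division
  chance decaying 20% per division for three divisions and another 40%
  from the fourth (`sc_division_prob()`) and symmetric-SC,
  symmetric-myoblast and asymmetric division types — and restore cleared
  fibril pixels they touch (myoblast fusion consumes the myoblast pool
  first). Once the IGF-1 gradient collapses in the post-acute phase,
  active SCs leave the pool under a hazard; this is what turns the SC
  census downward at ~120 h and, eventually, empties the muscle of SCs.
* **Fibroblasts** activate to myofibroblasts on a positive TGF-β
  gradient, redeposit collagen on cleared ECM-owned pixels at matrix
  edges, occasionally claim cleared fibril territory at those edges
  (collagen competition), and — once no SCs remain — fill *any* cleared
  space with ECM. That fallback is the fibrosis mechanism: in the CP
  milieu the SC pool empties before repair is complete, and the
  unrepaired fiber territory becomes matrix.
* **Hypertrophy.** When no repairable pixels remain (or the count is
  restored) and all damage is cleared, fiber borders are re-formed and
  remaining active SCs may add border fibrils into adjacent ECM, capped
  so that one pixel of septum always separates distinct fibers.

## Geometry

`tg_generate()` builds the synthetic stand-in for a segmented histology
cross-section: 20 Lloyd-relaxed Voronoi fiber domains separated by ~2-px
endomysial septa and wrapped in a 1-px perimysial ring, on an occupied
region sized so that occupied pixels equal
`round(target_fibrils / (1 - ecm_fraction))` exactly (a near-square
canvas minus a small EMPTY strip). Deterministic boundary passes then
drive the fibril count to exactly 9,864 pixels, so the default bundle has
an ECM area fraction of 15.80% at 6.45 µm²/pixel and a mean fiber
cross-sectional area of 3,181 µm² — the study's initial conditions.
Pixel bookkeeping is zero-sum: the occupied region cannot grow, so
hypertrophy converts septal ECM into fiber and the TD endpoint ECM
fraction drifts slightly *down* rather than up; a geometry open to
outward growth would be needed to reproduce simultaneous fiber and ECM
growth.

```{r geometry}
g <- tg_generate(seed = 1)
tg_composition(g)
```

## Parameters that matter

Study conditions (all in `sim_config()`): SC density 0.10 per fiber per
10 µm slice for the typically developing (TD) milieu versus 0.04 for CP —
10 versus 4 SCs for 20 fibers at 50 µm; damage fraction 0.10 of fibril
pixels (seeds, before necrosis expansion; a config flag documents this
reading of "10% damage"); 672 one-hour ticks; 150 replicates as the
standard, 20 in fast/desk mode. Material constants: $c_1$ 15 (fiber) /
0.5 (ECM), $c_2$ 0, $c_3$ 2, $c_4$ 60, $c_5$ 600, $K$ 1000, and active
parameters $T_{max}$ 135.7 kPa, $(\mathrm{Ca}_0)_{max}$ 4.35 µM, $B$
4.75 µm⁻¹, $l_0$ 1.58 µm, refl 2.04 µm. $\lambda_m$ is not constrained
beyond continuity; the default 1.06 keeps the exponential toe inside the
working range, and $c_6$ follows from continuity.

Rule parameters the underlying biology leaves open — lifespans,
proliferation, clearance and deposition probabilities, recruitment
windows and influx ceilings, movement speeds, the SC division base rate
and exit hazards, the hypertrophy rate — were calibrated once against
the published post-injury time courses (neutrophils peak 6–24 h,
macrophages predominant by ~48 h, damage cleared within 90 h, SC decline
from ~120 h, repair complete by ~216 h, TD recovery ≈ +0.8% over
baseline) and then frozen as the `sim_config()` defaults. Two of these
deserve emphasis because they shape the headline results:

* the per-hour *recruitment ceilings* on immune influx make total
  clearance capacity roughly independent of damage burden, so clearance
  time scales with damage: 5–10% clears well within 90 h, while 20%
  outruns the 85 h resolution window and leaves chronic residual damage;
* the *post-acute SC exit hazard* bounds the repair window, so repair
  capacity is proportional to the initial SC count. Demand (cleared
  fibril pixels) sits just below the capacity of 5 SCs, which is what
  produces the threshold behavior: recovery is insensitive to SC count
  above ~5 and collapses sharply at 4.

## Numerical choices

Movement descends an exact city-block distance transform of the current
target set (two-pass chamfer), with sub-integer random tie-breaking so
crowds spread over a damage frontier instead of herding along identical
paths. Working agents claim pixels through a greedy one-to-one matching
(fixed self/N/E/S/W scan order), so a crowd works as many pixels in
parallel as are adjacent. Moore-neighborhood searches use the fixed
tie-break order N, E, S, W, NE, SE, SW, NW, then self. Damage selection
takes exactly `ceiling(fraction × fibril_count)` pixels, ties broken by
lexicographic pixel order. Agents may share pixels (cells in a 50 µm
slice are not volume-filling at 6.45 µm²/px) and traverse any canvas
pixel. All stochasticity flows through one seeded RNG stream stored in
the simulation state, so whole runs — and whole coupled experiments —
are bit-reproducible for a fixed master seed; replicates draw distinct
child seeds, and both strain noise and agent placement are re-sampled
per replicate. Sweeps reuse the same child-seed vector at every level
(common random numbers), a paired design that sharpens ordering
comparisons.

Degenerate inputs: a grid without fibril pixels rejects strain and
damage operations; a damage fraction of 0 runs the full scheduler and
provably leaves the grid untouched; a fiber lost to atrophy in a coupled
run warns and continues (atrophy is an expected outcome); infeasible
geometry targets error rather than silently clipping.

## What the generator emulates — and what it does not

The synthetic bundle matches the real section in composition (fibril
count, ECM fraction, fiber count, scale) and in gross architecture
(irregular convex fiber domains, thin septa, a wrapped boundary). It does
not reproduce the real section's fiber size distribution, its irregular
outer contour, or any capillary/neuromuscular structure, and the strain
surrogate reproduces only the outer/corner-fiber ranking of a true
equilibrium solve. Passing tests therefore demonstrate that the cellular
rules produce the published dynamics *on a faithful synthetic stand-in*,
not that they reproduce pixel-level outcomes of the original segmented
histology; reported endpoint counts that depend on that exact geometry
(e.g. absolute CP endpoints) are reproduced in direction and relative
magnitude only.

## A short run

A desk-scale example (a small bundle and a few replicates; the full
study conditions use the 20-fiber bundle and 150 replicates):

```{r run}
small <- tg_generate(n_fibers = 6, target_fibrils = 1600,
                     target_ecm_fraction = 0.22, seed = 3)
reps <- simulate_replicates(small, sim_config(ticks = 250L), n = 3, seed = 1)
glance(reps)
```

```{r plot, fig.width = 6, fig.height = 3.5}
plot_census(reps)
```

Coupled TD-versus-CP contrasts are run with `run_coupled()` and
summarised with `summarize_runs()`; `sweep_damage()`, `sweep_sc()` and
`material_sensitivity()` script the sensitivity experiments.

## Known limitations

* Zero-sum geometry (above): TD ECM fraction declines slightly instead
  of staying flat.
* Cytokine pools neither decay (by default) nor convert units; they are
  gates, not concentrations.
* The M1→M2 switch is global ("after clearing damage"); a finite sensing
  radius is configurable but untested against data.
* Myoblasts are consumed by fusion but do not migrate; with
  `repair_requires_myoblast = FALSE` (default) SCs may restore pixels
  directly when no myoblast is available.
* The random damage-placement mode (`damage_mode = "random"`) is provided
  as an exploratory alternative and is not validated.
* Runtimes quoted in the tests use 20 replicates (fast mode); the
  standard 150-replicate conditions give the same means with tighter
  standard errors.
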