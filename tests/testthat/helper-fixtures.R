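# Shared small fixtures, built in code.

# Small 6-fiber bundle used by simulation unit tests (fast to generate).
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- tg_generate(n_fibers = 6, target_fibrils = 1600,
                                              target_ecm_fraction = 0.22, seed = 3)
    cache
  }
})

# Hand-built symmetric 2 x 2 four-fiber bundle: 10x10 fiber blocks separated
# by 2-px septa and wrapped by a 1-px ECM ring (23 x 23 canvas).
symmetric_bundle <- function() {
  H <- 23L; W <- 23L
  label <- matrix(myoregen:::ECM_CODE, H, W)
  blocks <- list(c(2, 2), c(2, 13), c(13, 2), c(13, 13))
  for (i in seq_along(blocks)) {
    r0 <- blocks[[i]][1]; c0 <- blocks[[i]][2]
    label[r0:(r0 + 9), c0:(c0 + 9)] <- i
  }
  myoregen:::new_tissue_grid(
    label = label, owner = label,
    collagen = ifelse(label == myoregen:::ECM_CODE, 1, 0),
    damaged = matrix(FALSE, H, W), needs_repair = matrix(FALSE, H, W),
    n_fibers = 4L
  )
}

# A tiny grid with exact fibril/ECM counts for composition arithmetic:
# one column of pixels, first `fibril` rows are fiber pixels (spread over
# n_fibers ids), the next `ecm` rows ECM, remainder EMPTY.
counting_grid <- function(fibril, ecm, n_fibers = 20L, pixel_area = 6.45) {
  H <- fibril + ecm
  label <- matrix(0L, H, 1L)
  if (fibril > 0) label[seq_len(fibril), 1] <- rep(seq_len(n_fibers), length.out = fibril)
  if (ecm > 0) label[fibril + seq_len(ecm), 1] <- myoregen:::ECM_CODE
  myoregen:::new_tissue_grid(
    label = label, owner = label,
    collagen = ifelse(label == myoregen:::ECM_CODE, 1, 0),
    damaged = matrix(FALSE, H, 1L), needs_repair = matrix(FALSE, H, 1L),
    n_fibers = n_fibers, pixel_area = pixel_area
  )
}
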