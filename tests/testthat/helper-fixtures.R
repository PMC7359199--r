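# Small fixtures built in code; no binary data on disk.

micro_grid <- function(values = c(1, 1, 2, 2)) {
  # 1 x 1 x n line grid with unit spacing, discretized at bin width 1
  arr <- array(values, c(length(values), 1, 1))
  discretize_fixed_bin(arr, roi_mask(array(TRUE, dim(arr)), c(1, 1, 1)), 1)
}

random_grid <- function(dims, G, seed) {
  # random levels 1..G with a sprinkling of out-of-mask voxels
  set.seed(seed)
  lev <- array(sample.int(G, prod(dims), replace = TRUE), dims)
  drop <- array(stats::runif(prod(dims)) < 0.2, dims)
  if (all(drop)) drop[1] <- FALSE
  lev[drop] <- 0L
  structure(list(levels = lev, G = max(lev), bin_width = 1, anchor = 0,
                 spacing = c(1, 1, 1)),
            class = "discretized_grid")
}

sphere_mask <- function(radius_mm, spacing_mm, n) {
  co <- (seq_len(n) - (n + 1) / 2) * spacing_mm
  d2 <- outer(outer(co^2, co^2, "+"), co^2, "+")
  roi_mask(d2 <= radius_mm^2, rep(spacing_mm, 3))
}

ramp_volume <- function(n = 32, spacing = c(1, 1, 1), modality = "CT") {
  # intensity linear in the x world coordinate
  arr <- array(rep((seq_len(n) - 1) * spacing[1], n * n), c(n, n, n))
  image_volume(arr, spacing, modality = modality)
}

with_seed_acc <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
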