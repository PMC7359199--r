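# Coiflet-1 analysis filters, scaled so the low-pass sums to 1 (the
# stationary-transform convention), keeping sub-band coefficients on the
# intensity scale so the fixed bin width remains meaningful.
coif1_filters <- function() {
  h <- c(-0.015655728135465, -0.072732619512854, 0.384864846864203,
         0.852572020212255, 0.337897662457809, -0.072732619512854)
  g <- rev(h) * (-1)^(seq_along(h) - 1)  # quadrature mirror
  list(L = h / sqrt(2), H = g / sqrt(2))
}

# n x n convolution matrix for filter `f` with half-point symmetric
# (reflected) boundary handling, filter centred on each sample.
conv_matrix <- function(n, f) {
  L <- length(f)
  if (n < L) stop(sprintf("axis length %d shorter than filter length %d", n, L))
  offs <- seq_along(f) - (L %/% 2 + 1L)
  S <- matrix(0, n, n)
  for (k in seq_along(f)) {
    idx <- seq_len(n) + offs[k]
    # reflect: ... 2 1 | 1 2 ... n-1 n | n n-1 ...
    idx <- ifelse(idx < 1L, 1L - idx, idx)
    idx <- ifelse(idx > n, 2L * n + 1L - idx, idx)
    S[cbind(seq_len(n), idx)] <- S[cbind(seq_len(n), idx)] + f[k]
  }
  S
}

#' One-level undecimated 3D wavelet decomposition
#'
#' Separable stationary (undecimated) Coiflet-1 transform producing the
#' eight sub-band maps `LLL ... HHH`, each congruent with the input grid.
#' Band letters are ordered by axis (x, y, z): `L` = low-pass, `H` =
#' high-pass along that axis, so e.g. `HLH` enhances variation along x and z.
#' Each band is subsequently discretized and fed through the intensity and
#' texture evaluators under the original ROI mask.
#'
#' @param volume An [image_volume()] at isotropic spacing.
#' @return Named list of eight 3D arrays (class `wavelet_stack`), names
#'   `LLL, LLH, LHL, LHH, HLL, HLH, HHL, HHH`.
#' @export
wavelet_decompose <- function(volume) {
  vals <- if (inherits(volume, "image_volume")) volume$values else as.array(volume)
  d <- dim(vals)
  flt <- coif1_filters()
  mats <- lapply(1:3, function(a)
    list(L = conv_matrix(d[a], flt$L), H = conv_matrix(d[a], flt$H)))
  apply_axis <- function(arr, axis, M) {
    perm <- c(axis, setdiff(1:3, axis))
    x <- aperm(arr, perm)
    dd <- dim(x)
    x <- array(M %*% matrix(x, nrow = dd[1L]), dd)
    aperm(x, order(perm))
  }
  bands <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
  out <- lapply(bands, function(b) {
    tags <- strsplit(b, "")[[1]]
    arr <- vals
    for (a in 1:3) arr <- apply_axis(arr, a, mats[[a]][[tags[a]]])
    arr
  })
  names(out) <- bands
  structure(out, class = "wavelet_stack")
}
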