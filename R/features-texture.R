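# Texture features over the six 3D matrix families. Matrices are built by
# compiled counters (src/texture.cpp); all feature formulas live here.
# Conventions for degenerate inputs: with a single grey level the maximal
# correlation coefficient is 1 and correlation-type features are missing;
# directions without a single co-occurring pair are dropped from the
# direction average.

glcm_base_names <- c(
  "joint maximum", "joint average", "joint variance", "joint entropy",
  "difference average", "difference variance", "difference entropy",
  "sum average", "sum variance", "sum entropy",
  "angular second moment", "contrast", "dissimilarity",
  "inverse difference", "inverse difference normalized",
  "inverse difference moment", "inverse difference moment normalized",
  "inverse variance", "correlation", "autocorrelation",
  "cluster tendency", "cluster shade", "cluster prominence",
  "information measures of correlation 1",
  "information measures of correlation 2",
  "maximal correlation coefficient")

log2z <- function(p) {
  out <- numeric(length(p))
  pos <- p > 0
  out[pos] <- log2(p[pos])
  dim(out) <- dim(p)
  out
}

glcm_feature_values <- function(counts) {
  G <- nrow(counts)
  tot <- sum(counts)
  if (tot == 0) return(rep(NA_real_, 26))
  p <- counts / tot
  i <- matrix(seq_len(G), G, G)
  j <- t(i)
  px <- rowSums(p)                      # symmetric: px == py
  mu <- sum(seq_len(G) * px)
  sig2 <- sum((seq_len(G) - mu)^2 * px)
  dmat <- abs(i - j)
  pdiff <- numeric(G)
  rs <- rowsum(as.vector(p), as.vector(dmat))
  pdiff[as.integer(rownames(rs)) + 1L] <- rs[, 1]
  smat <- i + j
  psum <- numeric(2 * G - 1)                 # indices k = 2 .. 2G
  rs2 <- rowsum(as.vector(p), as.vector(smat))
  psum[as.integer(rownames(rs2)) - 1L] <- rs2[, 1]
  da <- sum((0:(G - 1)) * pdiff)
  sa <- sum((2:(2 * G)) * psum)
  hxy <- -sum(p * log2z(p))
  hx <- -sum(px * log2z(px))
  pxpy <- outer(px, px)
  hxy1 <- -sum(p * log2z(pxpy))
  hxy2 <- -sum(pxpy * log2z(pxpy))
  mcc <- if (G == 1L) 1 else {
    nz <- which(px > 0)
    if (length(nz) < 2L) 1 else {
      pp <- p[nz, nz, drop = FALSE]
      pxn <- px[nz]
      # Q[i,j] = sum_k p_ik p_jk/(p_i p_k) is similar to the symmetric
      # B^2 with B = D^{-1/2} P D^{-1/2}; its second eigenvalue is the
      # square of the second-largest |eigenvalue| of B
      B <- pp / sqrt(outer(pxn, pxn))
      ev <- abs(eigen(B, symmetric = TRUE, only.values = TRUE)$values)
      sort(ev, decreasing = TRUE)[2]
    }
  }
  vals <- c(
    max(p),
    sum(i * p),
    sum((i - mu)^2 * p),
    hxy,
    da,
    sum(((0:(G - 1)) - da)^2 * pdiff),
    -sum(pdiff * log2z(pdiff)),
    sa,
    sum(((2:(2 * G)) - sa)^2 * psum),
    -sum(psum * log2z(psum)),
    sum(p^2),
    sum((i - j)^2 * p),
    sum(dmat * p),
    sum(p / (1 + dmat)),
    sum(p / (1 + dmat / G)),
    sum(p / (1 + (i - j)^2)),
    sum(p / (1 + (i - j)^2 / G^2)),
    if (G > 1L) sum(p[dmat > 0] / dmat[dmat > 0]^2) else 0,
    if (sig2 > 0) (sum(i * j * p) - mu^2) / sig2 else NA_real_,
    sum(i * j * p),
    sum((i + j - 2 * mu)^2 * p),
    sum((i + j - 2 * mu)^3 * p),
    sum((i + j - 2 * mu)^4 * p),
    if (hx > 0) (hxy - hxy1) / hx else NA_real_,
    sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0)),
    mcc)
  vals
}

#' Grey-level co-occurrence features
#'
#' Symmetric distance-1 co-occurrence over the 13 unique 3D directions.
#' Each of the 26 base statistics is reported under two aggregations:
#' computed per direction then averaged, and computed once on the
#' direction-merged matrix (suffix `merged`).
#'
#' @param grid A [discretize_fixed_bin()] result.
#' @return Named numeric vector of length 52.
#' @export
glcm_features <- function(grid) {
  counts <- cpp_glcm(grid$levels, dim(grid$levels), grid$G)
  per_dir <- matrix(apply(counts, 3, glcm_feature_values), nrow = 26)
  valid <- apply(counts, 3, sum) > 0
  avg <- if (any(valid)) rowMeans(per_dir[, valid, drop = FALSE])
         else rep(NA_real_, 26)
  merged <- glcm_feature_values(apply(counts, c(1, 2), sum))
  stats::setNames(c(avg, merged),
                  c(paste("GLCM", glcm_base_names),
                    paste("GLCM", glcm_base_names, "merged")))
}

# Shared formulas for matrices indexed (grey level i, structural index j):
# run length, zone size, zone distance, dependence count. `jname` labels the
# structural axis; `pct_den` is the denominator of the percentage feature
# (NULL drops it); `extra` appends family-specific statistics.
ij_matrix_features <- function(M, jlab, prefix, pct_den = NULL) {
  G <- nrow(M); Jm <- ncol(M)
  Ns <- sum(M)
  if (Ns == 0) {
    nm <- ij_feature_names(prefix, jlab, !is.null(pct_den))
    return(stats::setNames(rep(NA_real_, length(nm)), nm))
  }
  p <- M / Ns
  i <- matrix(seq_len(G), G, Jm)
  j <- matrix(seq_len(Jm), G, Jm, byrow = TRUE)
  ri <- rowSums(M); cj <- colSums(M)
  mui <- sum(i * p); muj <- sum(j * p)
  vals <- c(
    sum(p / j^2), sum(p * j^2),
    sum(p / i^2), sum(p * i^2),
    sum(p / (i^2 * j^2)), sum(p * i^2 / j^2),
    sum(p * j^2 / i^2), sum(p * i^2 * j^2),
    sum(ri^2) / Ns, sum(ri^2) / Ns^2,
    sum(cj^2) / Ns, sum(cj^2) / Ns^2)
  if (!is.null(pct_den)) vals <- c(vals, Ns / pct_den)
  vals <- c(vals,
            sum(p * (i - mui)^2),
            sum(p * (j - muj)^2),
            -sum(p * log2z(p)))
  stats::setNames(vals, ij_feature_names(prefix, jlab, !is.null(pct_den)))
}

ij_feature_names <- function(prefix, jlab, with_pct) {
  short <- switch(jlab, run = c("short run", "long run"),
                  zone = c("small zone", "large zone"),
                  distance = c("small distance", "large distance"),
                  dependence = c("low dependence", "high dependence"))
  jn <- switch(jlab, run = "run length", zone = "zone size",
               distance = "zone distance", dependence = "dependence count")
  gl_lo <- if (jlab == "dependence") "low grey level count emphasis"
           else if (jlab == "run") "low grey level run emphasis"
           else "low grey level zone emphasis"
  gl_hi <- sub("low", "high", gl_lo)
  nm <- c(paste(short[1], "emphasis"), paste(short[2], "emphasis"),
          gl_lo, gl_hi,
          paste(short[1], "low grey level emphasis"),
          paste(short[1], "high grey level emphasis"),
          paste(short[2], "low grey level emphasis"),
          paste(short[2], "high grey level emphasis"),
          "grey level non-uniformity", "grey level non-uniformity normalized",
          paste(jn, "non-uniformity"),
          paste(jn, "non-uniformity normalized"))
  if (with_pct) nm <- c(nm, switch(jlab, run = "run percentage",
                                   "zone percentage"))
  nm <- c(nm, "grey level variance",
          paste(jn, "variance"),
          switch(jlab, run = "run entropy",
                 dependence = "dependence count entropy",
                 paste(jn, "entropy")))
  paste(prefix, nm)
}

#' Grey-level run-length features
#'
#' Run-length matrices over the 13 directions; the 16 base statistics under
#' the direction-averaged and direction-merged aggregations.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of length 32.
#' @export
glrlm_features <- function(grid) {
  counts <- cpp_glrlm(grid$levels, dim(grid$levels), grid$G)
  nv <- sum(grid$levels > 0)
  dims <- dim(counts)
  per_dir <- vapply(seq_len(dims[3]), function(d)
    ij_matrix_features(matrix(counts[, , d], nrow = dims[1]),
                       "run", "GLRLM", pct_den = nv),
    numeric(16))
  avg <- rowMeans(per_dir)
  merged <- ij_matrix_features(apply(counts, c(1, 2), sum), "run", "GLRLM",
                               pct_den = 13 * nv)
  out <- c(avg, merged)
  names(out) <- c(rownames(per_dir), paste(names(merged), "merged"))
  out
}

#' Grey-level size-zone and distance-zone features
#'
#' Zones are 26-connected components of equal grey level; the size-zone
#' matrix counts them by (level, size) and the distance-zone matrix by
#' (level, city-block distance of the zone to the ROI border, border
#' voxels having distance 1).
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of length 32 (16 GLSZM + 16 GLDZM).
#' @export
zone_features <- function(grid) {
  z <- cpp_zones(grid$levels, dim(grid$levels), grid$G)
  nv <- sum(grid$levels > 0)
  c(ij_matrix_features(z$glszm, "zone", "GLSZM", pct_den = nv),
    ij_matrix_features(z$gldzm, "distance", "GLDZM", pct_den = nv))
}

#' Neighbourhood grey-tone difference and grey-level dependence features
#'
#' NGTDM statistics (coarseness, contrast, busyness, complexity, strength)
#' from 26-neighbour mean differences, and the 16 NGLDM dependence-count
#' features with coarseness parameter alpha = 0 (dependence = number of
#' 26-neighbours sharing the voxel's level). Features whose defining sums
#' vanish (e.g. coarseness of a constant region) are missing.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of length 21 (5 NGTDM + 16 NGLDM).
#' @export
neighbourhood_features <- function(grid) {
  nt <- cpp_ngtdm(grid$levels, dim(grid$levels), grid$G)
  G <- grid$G
  N <- sum(nt[, 1])
  ngtdm <- if (N == 0) {
    rep(NA_real_, 5)
  } else {
    pi_ <- nt[, 1] / N
    s <- nt[, 2]
    nz <- which(pi_ > 0)
    ngp <- length(nz)
    lev <- seq_len(G)
    co <- if (sum(pi_ * s) > 0) 1 / sum(pi_ * s) else NA_real_
    con <- if (ngp > 1) {
      sum(outer(pi_[nz], pi_[nz]) * outer(lev[nz], lev[nz], "-")^2) /
        (ngp * (ngp - 1)) * sum(s) / N
    } else 0
    bdn <- sum(abs(outer(lev[nz] * pi_[nz], lev[nz] * pi_[nz], "-")))
    bus <- if (bdn > 0) sum(pi_ * s) / bdn else NA_real_
    cplx <- sum(abs(outer(lev[nz], lev[nz], "-")) *
                  (outer(pi_[nz] * s[nz], rep(1, ngp)) +
                   outer(rep(1, ngp), pi_[nz] * s[nz])) /
                  (outer(pi_[nz], rep(1, ngp)) + outer(rep(1, ngp), pi_[nz]))) / N
    str <- if (sum(s) > 0)
      sum((outer(pi_[nz], rep(1, ngp)) + outer(rep(1, ngp), pi_[nz])) *
            outer(lev[nz], lev[nz], "-")^2) / sum(s)
    else 0
    c(co, con, bus, cplx, str)
  }
  names(ngtdm) <- paste("NGTDM", c("coarseness", "contrast", "busyness",
                                   "complexity", "strength"))
  M <- cpp_ngldm(grid$levels, dim(grid$levels), grid$G)
  ngldm <- ij_matrix_features(M, "dependence", "NGLDM", pct_den = NULL)
  p <- M / sum(M)
  ngldm <- c(ngldm, "NGLDM dependence count energy" = sum(p^2))
  c(ngtdm, ngldm)
}

#' All 137 texture features of one discretized grid
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of length 137.
#' @export
texture_features <- function(grid) {
  c(glcm_features(grid), glrlm_features(grid), zone_features(grid),
    neighbourhood_features(grid))
}
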