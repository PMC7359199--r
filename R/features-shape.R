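# Iso-surface mesh of a binary mask by marching tetrahedra at level 0.5.
# The 0/1 field (zero-padded) is lightly smoothed (Gaussian, 0.8 voxels)
# before meshing so the surface approximates the underlying smooth boundary
# instead of the voxel staircase; crossings are linearly interpolated along
# tetrahedron edges. Each grid cube on the voxel-centre lattice is split
# into six tetrahedra around its main diagonal. Surface area is the summed
# triangle area; the enclosed volume comes from the divergence theorem over
# the outward-oriented closed triangle mesh.
mesh_area_volume <- function(mask_arr, spacing, smooth_vox = 0.8) {
  d <- dim(mask_arr)
  p <- array(0, d + 2L)
  p[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask_arr
  if (smooth_vox > 0) {
    ps <- smooth_gaussian(p, rep(smooth_vox, 3))
    # a structure thinner than the smoothing kernel must not vanish
    if (max(ps) >= 0.5) p <- ps
  }
  pd <- dim(p)
  offs <- cbind(x = bitwAnd(0:7, 1L),            # corner bit order (x, y, z)
                y = bitwAnd(bitwShiftR(0:7, 1L), 1L),
                z = bitwAnd(bitwShiftR(0:7, 2L), 1L))
  nx <- pd[1] - 1L; ny <- pd[2] - 1L; nz <- pd[3] - 1L
  base <- as.matrix(expand.grid(i = seq_len(nx), j = seq_len(ny),
                                k = seq_len(nz)))
  corner_val <- matrix(0, nrow(base), 8L)
  for (c in 1:8)
    corner_val[, c] <- p[cbind(base[, 1] + offs[c, 1], base[, 2] + offs[c, 2],
                               base[, 3] + offs[c, 3])]
  corner_in <- corner_val >= 0.5
  ns <- rowSums(corner_in)
  mixed <- which(ns > 0L & ns < 8L)
  if (length(mixed) == 0L) return(list(volume = 0, area = 0))
  base <- base[mixed, , drop = FALSE]
  corner_val <- corner_val[mixed, , drop = FALSE]
  corner_in <- corner_in[mixed, , drop = FALSE]
  tets <- rbind(c(0, 1, 3, 7), c(0, 1, 5, 7), c(0, 2, 3, 7),
                c(0, 2, 6, 7), c(0, 4, 5, 7), c(0, 4, 6, 7)) + 1L
  cross3 <- function(u, v)
    cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
          u[, 3] * v[, 1] - u[, 1] * v[, 3],
          u[, 1] * v[, 2] - u[, 2] * v[, 1])
  area <- 0; vol6 <- 0
  for (t in 1:6) {
    vin <- corner_in[, tets[t, ], drop = FALSE]
    vval <- corner_val[, tets[t, ], drop = FALSE]
    P <- lapply(1:4, function(v) {
      o <- offs[tets[t, v], ]
      cbind((base[, 1] - 1L + o[1]) * spacing[1],
            (base[, 2] - 1L + o[2]) * spacing[2],
            (base[, 3] - 1L + o[3]) * spacing[3])
    })
    crossing <- function(a, b, rows) {
      v0 <- vval[rows, a]; v1 <- vval[rows, b]
      tt <- (0.5 - v0) / (v1 - v0)
      P[[a]][rows, , drop = FALSE] * (1 - tt) +
        P[[b]][rows, , drop = FALSE] * tt
    }
    add_tris <- function(p1, p2, p3, ref, toward) {
      # orient the normal away from (toward = FALSE) or toward (TRUE) `ref`
      n <- cross3(p2 - p1, p3 - p1)
      cen <- (p1 + p2 + p3) / 3
      s <- rowSums(n * (cen - ref)) * (if (toward) -1 else 1)
      flip <- s < 0
      tmp <- p2[flip, , drop = FALSE]
      p2[flip, ] <- p3[flip, , drop = FALSE]
      p3[flip, ] <- tmp
      n <- cross3(p2 - p1, p3 - p1)
      area <<- area + 0.5 * sum(sqrt(rowSums(n^2)))
      vol6 <<- vol6 + sum(p1 * cross3(p2, p3))
    }
    for (pat in 1:14) { # vertex-inside patterns 0001..1110
      flags <- as.logical(bitwAnd(pat, c(1L, 2L, 4L, 8L)))
      rows <- which(vin[, 1] == flags[1] & vin[, 2] == flags[2] &
                    vin[, 3] == flags[3] & vin[, 4] == flags[4])
      if (length(rows) == 0L) next
      ins <- which(flags); outs <- which(!flags)
      if (length(ins) == 1L) {
        A <- ins
        add_tris(crossing(A, outs[1], rows), crossing(A, outs[2], rows),
                 crossing(A, outs[3], rows), P[[A]][rows, , drop = FALSE],
                 toward = FALSE)
      } else if (length(ins) == 3L) {
        D <- outs
        add_tris(crossing(ins[1], D, rows), crossing(ins[2], D, rows),
                 crossing(ins[3], D, rows), P[[D]][rows, , drop = FALSE],
                 toward = TRUE)
      } else {
        A <- ins[1]; B <- ins[2]; C <- outs[1]; D <- outs[2]
        ref <- (P[[A]][rows, , drop = FALSE] + P[[B]][rows, , drop = FALSE]) / 2
        pac <- crossing(A, C, rows); pad <- crossing(A, D, rows)
        pbd <- crossing(B, D, rows); pbc <- crossing(B, C, rows)
        add_tris(pac, pad, pbd, ref, toward = FALSE)
        add_tris(pac, pbd, pbc, ref, toward = FALSE)
      }
    }
  }
  list(volume = abs(vol6) / 6, area = area)
}

#' Morphological (shape) features of an ROI mask
#'
#' The 18 intensity-independent shape features of the catalogue: volumes,
#' mesh surface area, the sphericity family, principal-axis lengths and
#' bounding-box densities. Surface area and mesh volume come from a
#' marching-tetrahedra iso-surface of the binary mask; axis lengths are
#' `4 * sqrt(eigenvalue)` of the voxel-position covariance. The
#' centre-of-mass shift is the distance between the mask centroid and the
#' centre of its axis-aligned bounding box.
#'
#' @param mask A non-empty [roi_mask()] (or logical 3D array).
#' @param spacing Voxel spacing in mm (taken from the mask if omitted).
#' @return Named numeric vector of length 18 (names prefixed `shape`).
#' @export
shape_features <- function(mask, spacing = NULL) {
  if (inherits(mask, "roi_mask")) {
    if (is.null(spacing)) spacing <- mask$spacing
    m <- mask$values
  } else m <- as.array(mask)
  if (!any(m)) stop("mask is empty")
  n <- sum(m)
  voxvol <- prod(spacing)
  mesh <- mesh_area_volume(m, spacing)
  V <- mesh$volume; A <- mesh$area
  idx <- which(m, arr.ind = TRUE)
  X <- sweep(idx - 1, 2, spacing, "*")
  bb_lo <- apply(X, 2, min); bb_hi <- apply(X, 2, max)
  bb_ext <- bb_hi - bb_lo + spacing          # voxel-bound box extents
  com <- colMeans(X)
  com_shift <- sqrt(sum((com - (bb_lo + bb_hi) / 2)^2))
  # maximum 3D diameter over surface voxel centres, chunked
  surf <- m & !(shift_mask(m, 1L, 1L) & shift_mask(m, 1L, -1L) &
                shift_mask(m, 2L, 1L) & shift_mask(m, 2L, -1L) &
                shift_mask(m, 3L, 1L) & shift_mask(m, 3L, -1L))
  S <- sweep(which(surf, arr.ind = TRUE) - 1, 2, spacing, "*")
  ns <- nrow(S)
  maxd <- 0
  s2 <- rowSums(S^2)
  step <- max(1L, floor(2e6 / ns))
  for (s in seq(1L, ns, by = step)) {
    e <- min(s + step - 1L, ns)
    D2 <- outer(s2[s:e], s2, "+") - 2 * S[s:e, , drop = FALSE] %*% t(S)
    maxd <- max(maxd, max(D2))
  }
  maxd <- sqrt(max(maxd, 0))
  C <- crossprod(sweep(X, 2, com)) / n
  ev <- sort(eigen(C, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev <- pmax(ev, 0)
  sphericity <- (36 * pi * V^2)^(1 / 3) / A
  vals <- as.numeric(c(
    n * voxvol, V, A, A / V, sphericity,
    V / (sqrt(pi) * A^1.5),
    36 * pi * V^2 / A^3,
    1 / sphericity,
    (A^3 / (36 * pi * V^2))^(1 / 3) - 1,
    com_shift, maxd,
    4 * sqrt(ev[1]), 4 * sqrt(ev[2]), 4 * sqrt(ev[3]),
    if (ev[1] > 0) sqrt(ev[2] / ev[1]) else NA_real_,
    if (ev[1] > 0) sqrt(ev[3] / ev[1]) else NA_real_,
    V / prod(bb_ext),
    A / (2 * (bb_ext[1] * bb_ext[2] + bb_ext[2] * bb_ext[3] +
              bb_ext[1] * bb_ext[3]))))
  stats::setNames(vals, shape_names())
}
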