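# Literal brute-force oracles for the texture features: every matrix is
# built by explicit enumeration (nested loops over voxels, neighbours and
# paths) and every statistic by explicit loops over matrix cells. Nothing
# here shares code with the package implementation.

oracle_dirs <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1), c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

olev <- function(lev, p) {
  d <- dim(lev)
  if (any(p < 1L) || any(p > d)) return(0L)
  lev[p[1], p[2], p[3]]
}

oracle_glcm_matrix <- function(lev, G, dir) {
  M <- matrix(0, G, G)
  d <- dim(lev)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lev[x, y, z]
    if (a == 0) next
    for (sgn in c(1L, -1L)) {
      b <- olev(lev, c(x, y, z) + sgn * dir)
      if (b > 0) M[a, b] <- M[a, b] + 1
    }
  }
  M
}

oracle_glcm_stats <- function(M) {
  G <- nrow(M)
  tot <- sum(M)
  if (tot == 0) return(rep(NA_real_, 26))
  P <- M / tot
  px <- numeric(G)
  for (i in 1:G) for (j in 1:G) px[i] <- px[i] + P[i, j]
  mu <- 0; for (i in 1:G) mu <- mu + i * px[i]
  s2 <- 0; for (i in 1:G) s2 <- s2 + (i - mu)^2 * px[i]
  pd <- numeric(G); ps <- numeric(2 * G)    # pd index k+1, ps index k
  for (i in 1:G) for (j in 1:G) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + P[i, j]
    ps[i + j] <- ps[i + j] + P[i, j]
  }
  ent <- function(v) { s <- 0; for (q in v) if (q > 0) s <- s - q * log2(q); s }
  da <- 0; for (k in 0:(G - 1)) da <- da + k * pd[k + 1]
  dv <- 0; for (k in 0:(G - 1)) dv <- dv + (k - da)^2 * pd[k + 1]
  sa <- 0; for (k in 2:(2 * G)) sa <- sa + k * ps[k]
  sv <- 0; for (k in 2:(2 * G)) sv <- sv + (k - sa)^2 * ps[k]
  acc <- function(f) {
    s <- 0
    for (i in 1:G) for (j in 1:G) s <- s + f(i, j) * P[i, j]
    s
  }
  hxy <- ent(as.vector(P)); hx <- ent(px)
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:G) for (j in 1:G) {
    q <- px[i] * px[j]
    if (P[i, j] > 0 && q > 0) hxy1 <- hxy1 - P[i, j] * log2(q)
    if (q > 0) hxy2 <- hxy2 - q * log2(q)
  }
  mcc <- if (G == 1) 1 else {
    nz <- which(px > 0)
    if (length(nz) < 2) 1 else {
      Q <- matrix(0, length(nz), length(nz))
      for (ii in seq_along(nz)) for (jj in seq_along(nz)) {
        s <- 0
        for (kk in seq_along(nz))
          s <- s + P[nz[ii], nz[kk]] * P[nz[jj], nz[kk]] /
            (px[nz[ii]] * px[nz[kk]])
        Q[ii, jj] <- s
      }
      ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
      sqrt(max(ev[2], 0))
    }
  }
  c(max(P),
    acc(function(i, j) i),
    acc(function(i, j) (i - mu)^2),
    hxy, da, dv, ent(pd), sa, sv, ent(ps),
    acc(function(i, j) P[i, j]),
    acc(function(i, j) (i - j)^2),
    acc(function(i, j) abs(i - j)),
    acc(function(i, j) 1 / (1 + abs(i - j))),
    acc(function(i, j) 1 / (1 + abs(i - j) / G)),
    acc(function(i, j) 1 / (1 + (i - j)^2)),
    acc(function(i, j) 1 / (1 + (i - j)^2 / G^2)),
    acc(function(i, j) if (i == j) 0 else 1 / (i - j)^2),
    if (s2 > 0) (acc(function(i, j) i * j) - mu^2) / s2 else NA_real_,
    acc(function(i, j) i * j),
    acc(function(i, j) (i + j - 2 * mu)^2),
    acc(function(i, j) (i + j - 2 * mu)^3),
    acc(function(i, j) (i + j - 2 * mu)^4),
    if (hx > 0) (hxy - hxy1) / hx else NA_real_,
    sqrt(max(1 - exp(-2 * (hxy2 - hxy)), 0)),
    mcc)
}

oracle_glcm_features <- function(lev, G) {
  per <- matrix(NA_real_, 26, 13)
  Msum <- matrix(0, G, G)
  valid <- logical(13)
  for (d in 1:13) {
    M <- oracle_glcm_matrix(lev, G, oracle_dirs[d, ])
    Msum <- Msum + M
    valid[d] <- sum(M) > 0
    per[, d] <- oracle_glcm_stats(M)
  }
  avg <- if (any(valid)) rowMeans(per[, valid, drop = FALSE])
         else rep(NA_real_, 26)
  c(avg, oracle_glcm_stats(Msum))
}

# 16 statistics shared by the (level, structural-index) families.
oracle_ij_stats <- function(M, pct_den) {
  Ns <- sum(M)
  G <- nrow(M); Jm <- ncol(M)
  if (Ns == 0) return(rep(NA_real_, if (is.null(pct_den)) 15 else 16))
  sre <- lre <- lgl <- hgl <- slg <- shg <- llg <- lhg <- 0
  mui <- muj <- entv <- gv <- jv <- 0
  for (i in 1:G) for (j in 1:Jm) {
    p <- M[i, j] / Ns
    sre <- sre + p / j^2; lre <- lre + p * j^2
    lgl <- lgl + p / i^2; hgl <- hgl + p * i^2
    slg <- slg + p / (i^2 * j^2); shg <- shg + p * i^2 / j^2
    llg <- llg + p * j^2 / i^2; lhg <- lhg + p * i^2 * j^2
    mui <- mui + i * p; muj <- muj + j * p
    if (p > 0) entv <- entv - p * log2(p)
  }
  for (i in 1:G) for (j in 1:Jm) {
    p <- M[i, j] / Ns
    gv <- gv + p * (i - mui)^2; jv <- jv + p * (j - muj)^2
  }
  gn <- 0; for (i in 1:G) gn <- gn + sum(M[i, ])^2
  jn <- 0; for (j in 1:Jm) jn <- jn + sum(M[, j])^2
  out <- c(sre, lre, lgl, hgl, slg, shg, llg, lhg,
           gn / Ns, gn / Ns^2, jn / Ns, jn / Ns^2)
  if (!is.null(pct_den)) out <- c(out, Ns / pct_den)
  c(out, gv, jv, entv)
}

oracle_glrlm_matrix <- function(lev, G, dir) {
  d <- dim(lev)
  M <- matrix(0, G, max(d))
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lev[x, y, z]
    if (a == 0) next
    if (olev(lev, c(x, y, z) - dir) == a) next   # not a run start
    len <- 1
    p <- c(x, y, z) + dir
    while (olev(lev, p) == a) { len <- len + 1; p <- p + dir }
    M[a, len] <- M[a, len] + 1
  }
  M
}

oracle_glrlm_features <- function(lev, G) {
  nv <- sum(lev > 0)
  per <- matrix(0, 16, 13)
  Msum <- NULL
  for (d in 1:13) {
    M <- oracle_glrlm_matrix(lev, G, oracle_dirs[d, ])
    Msum <- if (is.null(Msum)) M else Msum + M
    per[, d] <- oracle_ij_stats(M, nv)
  }
  c(rowMeans(per), oracle_ij_stats(Msum, 13 * nv))
}

# Zones by literal stack-based flood fill over the 26-neighbourhood; zone
# distance via iterative 6-connected erosion (a voxel's distance is the
# erosion pass on which it is removed).
oracle_zone_list <- function(lev) {
  d <- dim(lev)
  inm <- lev > 0
  dist <- array(NA_real_, d)
  cur <- inm
  pass <- 0
  while (any(cur)) {
    pass <- pass + 1
    border <- array(FALSE, d)
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      if (!cur[x, y, z]) next
      for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                     c(0, 0, 1), c(0, 0, -1))) {
        p <- c(x, y, z) + s
        if (any(p < 1) || any(p > d) || !cur[p[1], p[2], p[3]]) {
          border[x, y, z] <- TRUE
          break
        }
      }
    }
    dist[border] <- pass
    cur <- cur & !border
  }
  seen <- array(FALSE, d)
  zones <- list()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (lev[x, y, z] == 0 || seen[x, y, z]) next
    a <- lev[x, y, z]
    stack <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    vox <- list()
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      vox[[length(vox) + 1]] <- p
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        q <- p + c(dx, dy, dz)
        if (any(q < 1) || any(q > d)) next
        if (!seen[q[1], q[2], q[3]] && lev[q[1], q[2], q[3]] == a) {
          seen[q[1], q[2], q[3]] <- TRUE
          stack[[length(stack) + 1]] <- q
        }
      }
    }
    dmin <- min(vapply(vox, function(p) dist[p[1], p[2], p[3]], 0))
    zones[[length(zones) + 1]] <- c(level = a, size = length(vox),
                                    dist = dmin)
  }
  zones
}

oracle_zone_features <- function(lev, G) {
  zl <- oracle_zone_list(lev)
  nv <- sum(lev > 0)
  sz <- vapply(zl, function(z) z[["size"]], 0)
  dz <- vapply(zl, function(z) z[["dist"]], 0)
  lv <- vapply(zl, function(z) z[["level"]], 0)
  szm <- matrix(0, G, max(sz))
  dzm <- matrix(0, G, max(dz))
  for (k in seq_along(zl)) {
    szm[lv[k], sz[k]] <- szm[lv[k], sz[k]] + 1
    dzm[lv[k], dz[k]] <- dzm[lv[k], dz[k]] + 1
  }
  c(oracle_ij_stats(szm, nv), oracle_ij_stats(dzm, nv))
}

oracle_neighbourhood_features <- function(lev, G) {
  d <- dim(lev)
  ni <- numeric(G); si <- numeric(G)
  dep <- matrix(0, G, 27)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lev[x, y, z]
    if (a == 0) next
    nb <- c(); k <- 0
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      b <- olev(lev, c(x + dx, y + dy, z + dz))
      if (b > 0) { nb <- c(nb, b); if (b == a) k <- k + 1 }
    }
    dep[a, k + 1] <- dep[a, k + 1] + 1
    if (length(nb) > 0) {
      ni[a] <- ni[a] + 1
      si[a] <- si[a] + abs(a - mean(nb))
    }
  }
  N <- sum(ni)
  ngtdm <- if (N == 0) rep(NA_real_, 5) else {
    p <- ni / N
    nz <- which(p > 0); ngp <- length(nz)
    co <- 0; for (i in 1:G) co <- co + p[i] * si[i]
    coarse <- if (co > 0) 1 / co else NA_real_
    con <- 0; bden <- 0; cplx <- 0; snum <- 0
    for (i in nz) for (j in nz) {
      con <- con + p[i] * p[j] * (i - j)^2
      bden <- bden + abs(i * p[i] - j * p[j])
      cplx <- cplx + abs(i - j) * (p[i] * si[i] + p[j] * si[j]) /
        (p[i] + p[j])
      snum <- snum + (p[i] + p[j]) * (i - j)^2
    }
    con <- if (ngp > 1) con / (ngp * (ngp - 1)) * sum(si) / N else 0
    c(coarse, con,
      if (bden > 0) co / bden else NA_real_,
      cplx / N,
      if (sum(si) > 0) snum / sum(si) else 0)
  }
  Ns <- sum(dep)
  en <- 0
  for (i in 1:G) for (j in 1:27) en <- en + (dep[i, j] / Ns)^2
  c(ngtdm, oracle_ij_stats(dep, NULL), en)
}

oracle_texture_features <- function(grid) {
  lev <- grid$levels
  G <- grid$G
  unname(c(oracle_glcm_features(lev, G), oracle_glrlm_features(lev, G),
           oracle_zone_features(lev, G),
           oracle_neighbourhood_features(lev, G)))
}

# Independent ICC(3,1) from an explicit two-way ANOVA via stats::aov.
oracle_icc31 <- function(m) {
  df <- data.frame(y = as.vector(m),
                   case = factor(rep(seq_len(nrow(m)), ncol(m))),
                   obs = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  tab <- summary(stats::aov(y ~ case + obs, data = df))[[1]]
  bms <- tab["case", "Mean Sq"]
  ems <- tab["Residuals", "Mean Sq"]
  (bms - ems) / (bms + (ncol(m) - 1) * ems)
}

# Brute-force Benjamini-Hochberg: sort, scale, enforce monotonicity.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (r in seq_len(n)) q[r] <- p[o[r]] * n / r
  for (r in (n - 1):1) q[r] <- min(q[r], q[r + 1])
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# Textbook log-rank: expected events per group from the risk sets at each
# distinct event time; chi-square from (O-E)^2 / V.
oracle_logrank <- function(time, event, group) {
  g <- as.integer(factor(group))
  ts <- sort(unique(time[event == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O1 - E1)^2 / V
  list(chisq = chisq, p = 1 - stats::pchisq(chisq, 1))
}
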