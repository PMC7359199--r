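test_that("co-occurrence features match the hand-enumerated micro-grid", {
  g <- micro_grid(c(1, 1, 2, 2))
  # single direction along the line: pairs (1,1), (1,2), (2,2)
  M <- pleuradiomics:::cpp_glcm(g$levels, dim(g$levels), g$G)[, , 1]
  expect_equal(M, rbind(c(2, 1), c(1, 2)))
  f1 <- pleuradiomics:::glcm_feature_values(M)
  base_names <- pleuradiomics:::glcm_base_names
  expect_equal(f1[which(base_names == "contrast")], 1 / 3)
  expect_equal(f1[which(base_names == "inverse difference")], 5 / 6)

  const <- micro_grid(rep(2, 5))
  fc <- glcm_features(const)
  expect_equal(unname(fc["GLCM contrast"]), 0)
  expect_equal(unname(fc["GLCM inverse difference"]), 1)
  expect_equal(unname(fc["GLCM maximal correlation coefficient"]), 1)
  expect_true(is.na(fc["GLCM correlation"]))
})

test_that("run-length features match hand-enumerated runs", {
  g <- micro_grid(c(1, 1, 2, 2))
  # along the line: runs (level 1, len 2), (level 2, len 2)
  M <- matrix(pleuradiomics:::cpp_glrlm(g$levels, dim(g$levels), g$G)[, , 1],
              nrow = 2)
  f <- pleuradiomics:::ij_matrix_features(M, "run", "GLRLM", pct_den = 4)
  expect_equal(unname(f["GLRLM long run emphasis"]), 4)
  expect_equal(unname(f["GLRLM grey level non-uniformity"]), 1)
  expect_equal(unname(f["GLRLM run percentage"]), 0.5)

  # constant line of N voxels: one run, run percentage 1/N per direction
  cg <- micro_grid(rep(1, 6))
  Mc <- matrix(pleuradiomics:::cpp_glrlm(cg$levels, dim(cg$levels), 1)[, , 1],
               nrow = 1)
  fc <- pleuradiomics:::ij_matrix_features(Mc, "run", "GLRLM", pct_den = 6)
  expect_equal(unname(fc["GLRLM run percentage"]), 1 / 6)

  # alternating levels: every run has length 1 in every direction
  alt <- micro_grid(rep(c(1, 2), 5))
  fa <- glrlm_features(alt)
  expect_equal(unname(fa["GLRLM short run emphasis"]), 1)
  expect_equal(unname(fa["GLRLM short run emphasis merged"]), 1)
})

test_that("zone features match hand-enumerated zones and closed forms", {
  g <- micro_grid(c(1, 1, 2, 2))
  z <- zone_features(g)
  expect_equal(unname(z["GLSZM high grey level zone emphasis"]), 2.5)
  expect_equal(unname(z["GLSZM zone percentage"]), 0.5)

  N <- 27
  const <- discretize_fixed_bin(array(1, c(3, 3, 3)),
                                roi_mask(array(TRUE, c(3, 3, 3)), c(1, 1, 1)),
                                1)
  zc <- zone_features(const)
  expect_equal(unname(zc["GLSZM small zone emphasis"]), 1 / N^2)

  # all-distinct levels: every zone has size 1
  dist <- micro_grid(1:5)
  zd <- zone_features(dist)
  expect_equal(unname(zd["GLSZM zone size non-uniformity normalized"]), 1)
})

test_that("neighbourhood features handle degenerate grids per convention", {
  const <- discretize_fixed_bin(array(2, c(3, 3, 3)),
                                roi_mask(array(TRUE, c(3, 3, 3)), c(1, 1, 1)),
                                1)
  nf <- neighbourhood_features(const)
  expect_equal(unname(nf["NGTDM contrast"]), 0)
  expect_true(is.na(nf["NGTDM coarseness"]))

  lone <- array(0L, c(3, 3, 3)); lone[2, 2, 2] <- 1L
  g1 <- structure(list(levels = lone, G = 1L, bin_width = 1, anchor = 0,
                       spacing = c(1, 1, 1)), class = "discretized_grid")
  n1 <- neighbourhood_features(g1)
  expect_true(all(is.na(n1[startsWith(names(n1), "NGTDM")])))
  expect_false(anyNA(n1["NGLDM dependence count energy"]))
})

test_that("texture matrices satisfy their normalization invariants", {
  for (s in 1:5) {
    g <- random_grid(c(4, 3, 4), G = 4, seed = 100 + s)
    nv <- sum(g$levels > 0)
    glcm <- pleuradiomics:::cpp_glcm(g$levels, dim(g$levels), g$G)
    merged <- apply(glcm, c(1, 2), sum)
    expect_equal(merged, t(merged))                 # symmetric
    expect_equal(sum(merged / sum(merged)), 1)      # normalizes to 1
    rlm <- pleuradiomics:::cpp_glrlm(g$levels, dim(g$levels), g$G)
    for (d in seq_len(dim(rlm)[3])) {
      M <- matrix(rlm[, , d], nrow = g$G)
      # run counts x run lengths account for every in-mask voxel
      expect_equal(sum(M %*% seq_len(ncol(M))), nv)
    }
    zones <- pleuradiomics:::cpp_zones(g$levels, dim(g$levels), g$G)
    expect_equal(sum(zones$glszm %*% seq_len(ncol(zones$glszm))), nv)
  }
})

test_that("direction-aggregated features are invariant to 90-degree rotations", {
  g <- random_grid(c(4, 4, 4), G = 4, seed = 42)
  base <- texture_features(g)
  rotations <- list(
    function(a) aperm(a, c(2, 1, 3))[dim(a)[2]:1, , , drop = FALSE],
    function(a) aperm(a, c(1, 3, 2))[, dim(a)[3]:1, , drop = FALSE],
    function(a) aperm(a, c(3, 2, 1))[, , dim(a)[1]:1, drop = FALSE])
  for (rot in rotations) {
    gr <- g
    gr$levels <- rot(g$levels)
    out <- texture_features(gr)
    expect_equal(out, base, tolerance = 1e-10)
  }
})

test_that("implementation matches the brute-force oracle on random grids", {
  for (s in 1:10) {
    dims <- sample(2:4, 3, replace = TRUE)
    g <- random_grid(dims, G = sample(2:4, 1), seed = 500 + s)
    expect_equal(unname(texture_features(g)), oracle_texture_features(g),
                 tolerance = 1e-10)
  }
})
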