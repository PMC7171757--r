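# Discretization, first-order/shape features, and the four texture families.

test_that("discretization follows the relative min-max formula", {
  arr <- array(0, dim = c(3, 1, 1))
  arr[, 1, 1] <- c(0, 50, 100)
  vol <- toy_volume(arr)
  msk <- toy_mask(array(TRUE, dim = c(3, 1, 1)))
  dro <- discretize_roi(vol, msk, 64)
  expect_identical(as.integer(dro$levels[, 1, 1]), c(1L, 33L, 64L))

  # boundary mapping: min -> 1, max -> Ngrey
  arr2 <- array(runif(64), dim = c(4, 4, 4))
  dro2 <- discretize_roi(toy_volume(arr2), toy_mask(array(TRUE, dim = c(4, 4, 4))), 32)
  expect_equal(dro2$levels[which.min(arr2)], 1L)
  expect_equal(dro2$levels[which.max(arr2)], 32L)
  expect_true(all(dro2$levels >= 1 & dro2$levels <= 32))

  # uniform ROI maps to level 1
  dro3 <- discretize_roi(toy_volume(array(5, dim = c(2, 2, 2))),
                         toy_mask(array(TRUE, dim = c(2, 2, 2))), 64)
  expect_true(all(dro3$levels == 1L))

  expect_error(discretize_roi(toy_volume(array(1, dim = c(2, 2, 2))),
                              toy_mask(array(FALSE, dim = c(2, 2, 2)))),
               "empty-ROI")
})

test_that("discretization is invariant under increasing affine transforms", {
  set.seed(42)
  arr <- array(rnorm(125), dim = c(5, 5, 5))
  msk <- toy_mask(array(runif(125) < 0.7, dim = c(5, 5, 5)))
  a <- discretize_roi(toy_volume(arr), msk, 64)
  b <- discretize_roi(toy_volume(3.7 * arr + 11), msk, 64)
  expect_identical(a$levels, b$levels)
  fa <- extract_features(toy_volume(arr), msk)
  fb <- extract_features(toy_volume(3.7 * arr + 11), msk)
  texture <- grep("firstorder_(min|max|mean|std)", names(fa), invert = TRUE)
  expect_equal(fa[texture], fb[texture], tolerance = 1e-12)
})

test_that("first-order features handle degenerate and hand-checkable ROIs", {
  # uniform ROI: std 0, entropy 0, uniformity 1, skew/kurt missing
  fo <- first_order_features(toy_volume(array(7, dim = c(2, 2, 2))),
                             toy_mask(array(TRUE, dim = c(2, 2, 2))))
  expect_equal(unname(fo[c("std", "entropy")]), c(0, 0))
  expect_equal(unname(fo["uniformity"]), 1)
  expect_true(all(is.na(fo[c("skewness", "kurtosis")])))

  # cube of 8 voxels at 1 mm spacing: volume 8 voxels = 0.008 ml
  msk <- array(FALSE, dim = c(4, 4, 4)); msk[2:3, 2:3, 2:3] <- TRUE
  set.seed(1)
  fo2 <- first_order_features(toy_volume(array(rnorm(64), dim = c(4, 4, 4))),
                              toy_mask(msk))
  expect_equal(unname(fo2["volume_voxels"]), 8)
  expect_equal(unname(fo2["volume_ml"]), 0.008)

  # a digital ball is more spherical than an equal-volume slab
  dim3 <- c(21, 21, 21)
  ctr <- c(11, 11, 11)
  ball <- array(FALSE, dim3)
  for (z in 1:21) for (y in 1:21) for (x in 1:21)
    ball[x, y, z] <- sum((c(x, y, z) - ctr)^2) <= 8^2
  nb <- sum(ball)
  # equal-volume two-slice slab, filled voxel by voxel up to the ball count
  slab <- array(FALSE, dim3)
  k <- 0
  for (z in 10:11) for (y in 1:21) for (x in 1:21) {
    if (k < nb) { slab[x, y, z] <- TRUE; k <- k + 1 }
  }
  vol <- toy_volume(array(rnorm(prod(dim3)), dim3))
  sp_ball <- first_order_features(vol, toy_mask(ball))["sphericity"]
  sp_slab <- first_order_features(vol, toy_mask(slab))["sphericity"]
  expect_gt(sp_ball, sp_slab)
})

test_that("GLCM features match hand enumeration and symmetry properties", {
  # uniform ROI: one matrix cell
  dro <- make_droi(array(1L, dim = c(2, 2, 2)), 64)
  g <- glcm_features(dro)
  expect_equal(unname(g[c("homogeneity", "energy", "contrast",
                          "dissimilarity", "entropy")]),
               c(1, 1, 0, 0, 0))
  expect_true(is.na(g["correlation"]))

  # 2x2x1 ROI, levels [[1,1],[2,2]]: exhaustive directed-pair enumeration
  lev <- array(0L, dim = c(2, 2, 1))
  lev[1, 1, 1] <- 1L; lev[2, 1, 1] <- 1L
  lev[1, 2, 1] <- 2L; lev[2, 2, 1] <- 2L
  dro2 <- make_droi(lev, 2)
  counts <- oracle_glcm_counts(lev, 2, all_directions_3d())
  p <- counts / sum(counts)
  i <- row(p); j <- col(p)
  mu <- sum(seq_len(2) * rowSums(p))
  s2 <- sum((seq_len(2) - mu)^2 * rowSums(p))
  expected <- c(homogeneity = sum(p / (1 + abs(i - j))),
                energy = sum(p^2),
                contrast = sum((i - j)^2 * p),
                correlation = sum((i - mu) * (j - mu) * p) / s2,
                entropy = -sum(p[p > 0] * log2(p[p > 0])),
                dissimilarity = sum(abs(i - j) * p))
  expect_equal(glcm_features(dro2), expected, tolerance = 1e-12)

  # grey-level inversion leaves all but correlation's sign structure intact
  set.seed(7)
  lev3 <- array(sample(1:4, 27, replace = TRUE), dim = c(3, 3, 3))
  inv <- array(5L - lev3, dim = dim(lev3))
  a <- glcm_features(make_droi(lev3, 4))
  b <- glcm_features(make_droi(inv, 4))
  keep <- c("homogeneity", "energy", "contrast", "entropy", "dissimilarity")
  expect_equal(a[keep], b[keep], tolerance = 1e-12)
})

test_that("GLRLM features follow the single-entry formulas and run scans", {
  # single run of length L under one direction
  L <- 5L
  lev <- array(1L, dim = c(L, 1, 1))
  dro <- make_droi(lev, 3)
  onedir <- matrix(c(1L, 0L, 0L), 1)
  g <- glrlm_features(dro, onedir)
  expect_equal(unname(g[c("SRE", "LRE", "RP")]), c(1 / L^2, L^2, 1 / L))

  # uniform 1x1xN ROI: one run along the long axis
  levN <- array(1L, dim = c(1, 1, 7))
  counts <- oracle_glrlm_counts(levN, 1, matrix(c(0L, 0L, 1L), 1))
  expect_equal(sum(counts), 1)
  expect_equal(counts[1, 7], 1)

  # alternating strip: every run has length 1 in every direction
  lev2 <- array(rep(c(1L, 2L), 4), dim = c(8, 1, 1))
  g2 <- glrlm_features(make_droi(lev2, 2))
  expect_equal(unname(g2["SRE"]), 1)
  expect_equal(unname(g2["RP"]), 1)
})

test_that("NGLDM features match hand enumeration and scaling laws", {
  # uniform ROI: all s = 0, coarseness hits the documented guard limit
  g <- ngldm_features(make_droi(array(1L, dim = c(3, 3, 3)), 4))
  expect_equal(unname(g["coarseness"]), 1e6)
  expect_true(is.na(g["busyness"]))

  # centre voxel level 2 in a level-1 surround
  lev <- array(1L, dim = c(3, 3, 3)); lev[2, 2, 2] <- 2L
  res <- cpp_ngldm_sums(lev, 2)
  ora <- oracle_ngldm_sums(lev, 2)
  expect_equal(res$s, ora$s, tolerance = 1e-12)
  expect_equal(res$count, ora$count)

  # two-level ROI: doubling the label distance scales contrast by 2^3
  base <- array(1L, dim = c(4, 4, 1))
  base[c(1, 3), , 1] <- 1L; base[c(2, 4), , 1] <- 2L
  wide <- base; wide[wide == 2L] <- 3L
  c1 <- ngldm_features(make_droi(base, 8))["contrast"]
  c2 <- ngldm_features(make_droi(wide, 8))["contrast"]
  expect_equal(unname(c2 / c1), 8, tolerance = 1e-10)
})

test_that("GLZLM features count connected zones correctly", {
  # uniform ROI of V voxels: one zone
  V <- 27
  g <- glzlm_features(make_droi(array(1L, dim = c(3, 3, 3)), 2))
  expect_equal(unname(g[c("ZP", "SZE", "LZE")]), c(1 / V, 1 / V^2, V^2))

  # two disjoint same-level blobs: two zones
  lev <- array(0L, dim = c(5, 1, 1))
  lev[1:2, 1, 1] <- 1L; lev[4:5, 1, 1] <- 1L
  g2 <- glzlm_features(make_droi(lev, 1))
  expect_equal(unname(g2["ZP"]), 2 / 4)

  # checkerboard: every voxel its own zone (26-connectivity joins diagonals,
  # so use a 1-D alternating strip where diagonal adjacency cannot merge)
  lev3 <- array(rep(c(1L, 2L), 4), dim = c(8, 1, 1))
  g3 <- glzlm_features(make_droi(lev3, 2))
  expect_equal(unname(g3["ZP"]), 1)
})

test_that("feature vectors have the full 43/86/172 catalogue structure", {
  spec <- small_cohort_spec(2, seed = 5)
  coh <- generate_cohort(spec)
  v43 <- extract_features(coh[[1]]$volumes$T1CE, coh[[1]]$masks$tumor)
  expect_length(v43, 43)
  fam_counts <- table(sub("_.*", "", names(v43)))
  expect_equal(as.integer(fam_counts[c("firstorder", "glcm", "glrlm",
                                       "ngldm", "glzlm")]),
               c(12, 6, 11, 3, 11))
  pv <- extract_patient(coh[[1]])
  expect_length(pv, 172)
  expect_length(grep("^tumor_", names(pv)), 86)
  expect_length(grep("^node_", names(pv)), 86)
  tab <- extract_cohort(coh)
  expect_equal(dim(tab), c(2, 173))
  # determinism: regenerating the cohort reproduces the table exactly
  tab2 <- extract_cohort(generate_cohort(spec))
  expect_identical(tab, tab2)
})

test_that("features are invariant under axis permutation", {
  set.seed(11)
  arr <- array(rnorm(210), dim = c(5, 6, 7))
  msk <- array(runif(210) < 0.6, dim = c(5, 6, 7))
  msk[3, 3, 3] <- TRUE
  sp <- c(1, 1.5, 5)
  perm <- c(3, 1, 2)
  f1 <- extract_features(image_volume(arr, sp), roi_mask(msk))
  f2 <- extract_features(image_volume(aperm(arr, perm), sp[perm]),
                         roi_mask(aperm(msk, perm)))
  expect_equal(f1, f2, tolerance = 1e-10)
})

test_that("texture normalizations hold on random ROIs", {
  set.seed(3)
  for (rep in 1:5) {
    lev <- array(sample(0:4, 64, replace = TRUE, prob = c(0.2, rep(0.2, 4))),
                 dim = c(4, 4, 4))
    if (!any(lev > 0)) lev[1, 1, 1] <- 1L
    storage.mode(lev) <- "integer"
    dro <- make_droi(lev, 4)
    counts <- cpp_glcm_counts(lev, 4, all_directions_3d())
    if (sum(counts) > 0) expect_equal(sum(counts / sum(counts)), 1)
    rl <- glrlm_features(dro)
    expect_true(rl["RP"] > 0 && rl["RP"] <= 1)
    zl <- glzlm_features(dro)
    expect_true(zl["ZP"] > 0 && zl["ZP"] <= 1)
  }
})
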