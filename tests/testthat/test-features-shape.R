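test_that("shape features approach analytic sphere limits", {
  mask <- generate_tumor_mask(10, c(1, 1, 1))
  f <- shape_features(mask, c(1, 1, 1))
  expect_equal(length(f), 14)
  # surface-to-volume ratio of a radius-10 ball: 3/r = 0.3 per mm
  expect_lt(abs(f[["SurfaceVolumeRatio"]] - 0.3) / 0.3, 0.05)
  expect_gt(f[["Sphericity"]], 0.95)
  expect_lte(f[["Sphericity"]], 1.0 + 1e-6)
  # uniform ball PCA: axis length 4 * sqrt(r^2 / 5)
  expect_equal(f[["MajorAxisLength"]], 4 * 10 / sqrt(5), tolerance = 0.05)
  expect_equal(f[["Elongation"]], 1, tolerance = 0.02)
  expect_equal(f[["Maximum3DDiameter"]], 20, tolerance = 0.05)
})

test_that("anisotropic stretch doubles the major axis", {
  mask <- generate_tumor_mask(8, c(1, 1, 1))
  f1 <- shape_features(mask, c(1, 1, 1))
  f2 <- shape_features(mask, c(2, 1, 1))   # same voxels, stretched grid
  # PCA oracle on the stretched point cloud
  pts <- arrayInd(which(mask), dim(mask))
  ev <- eigen(cov(sweep(pts, 2, c(2, 1, 1), `*`)))$values
  expect_equal(f2[["MajorAxisLength"]], 4 * sqrt(ev[1]), tolerance = 1e-8)
  expect_equal(f2[["MajorAxisLength"]], 2 * f1[["MajorAxisLength"]],
               tolerance = 0.02)
  expect_lt(f2[["Flatness"]], f1[["Flatness"]])
})

test_that("degenerate masks fall back to voxel-based estimates, flagged", {
  m <- array(FALSE, c(3, 3, 3)); m[2, 2, 2] <- TRUE
  f <- shape_features(m, c(1, 1, 1))
  expect_true(attr(f, "voxel_fallback"))
  expect_equal(f[["VoxelVolume"]], 1)
  expect_equal(f[["SurfaceArea"]], 6)
  expect_error(shape_features(array(FALSE, c(2, 2, 2))), "empty")
})

test_that("whole-tumor texture panels behave consistently", {
  set.seed(31)
  d <- c(5, 5, 4)
  roi <- array(TRUE, d)
  img <- array(runif(prod(d)), d)
  expect_warning(f0 <- whole_tumor_features(array(1, d), roi), "constant")
  expect_equal(f0[["glcm_Contrast"]], 0)
  # integer-labeled image with n_bins = label count matches the habitat path
  lab <- random_label_map(d, k = 4, seed = 32)
  f1 <- whole_tumor_features(lab + 0.0, roi, n_bins = 4)
  f2 <- glcm_features(lab)
  expect_equal(unname(f1), unname(f2), tolerance = 1e-10)
  # discretized continuous image matches the oracle on its own labels
  edges <- seq(min(img), max(img), length.out = 9)
  labd <- array(pmin(pmax(findInterval(img, edges, rightmost.closed = TRUE),
                          1L), 8L), d)
  got <- whole_tumor_features(img, roi, n_bins = 8, panel = "all")
  expect_equal(unname(got[paste0("glcm_", names(oracle_glcm(labd)))]),
               unname(oracle_glcm(labd)), tolerance = 1e-10)
  expect_equal(unname(got[paste0("glszm_", names(oracle_glszm(labd)))]),
               unname(oracle_glszm(labd)), tolerance = 1e-10)
})

test_that("the habitat feature vector has exactly 58 + k components", {
  spec <- cohort_spec(noise_sd = 0)
  mask <- generate_tumor_mask(6, c(1, 1, 1))
  lab <- assign_habitats(mask, spec$habitat_proportions, 0, seed = 33)
  hm <- structure(list(labels = lab, k = 5, pid = "p", spacing = c(1, 1, 1),
                       proportions = habitat_proportions(lab, 5)),
                  class = "habitat_map")
  fv <- habitat_feature_vector(hm, mask = mask)
  expect_equal(length(fv), 58 + 5)
  expect_equal(length(habitat_feature_vector(hm, mask = mask,
                                             include_proportions = FALSE)),
               58)
  expect_false(any(duplicated(names(fv))))
  expect_equal(sum(fv[paste0("habitat_", 1:5)]), 1, tolerance = 1e-9)
})

test_that("habitat proportions are permutation-equivariant", {
  lab <- random_label_map(c(6, 6, 4), k = 4, seed = 34, background = 0.3)
  p <- habitat_proportions(lab, 4)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  perm <- c(3, 1, 4, 2)
  relab <- array(0L, dim(lab))
  relab[lab > 0] <- perm[lab[lab > 0]]
  p2 <- habitat_proportions(relab, 4)
  expect_equal(unname(p2[perm]), unname(p))
  # single-label map concentrates all mass
  lab1 <- array(0L, c(3, 3, 3)); lab1[2, 2, 2] <- 1L
  expect_equal(unname(habitat_proportions(lab1, 5)), c(1, 0, 0, 0, 0))
})

test_that("z-score normalization uses development statistics throughout", {
  set.seed(35)
  dev <- matrix(rnorm(200, 5, 3), 20, 10,
                dimnames = list(NULL, paste0("f", 1:10)))
  z <- z_score_normalize(dev)
  expect_equal(unname(colMeans(z)), rep(0, 10), tolerance = 1e-10)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 10), tolerance = 1e-10)
  val <- matrix(rnorm(100, 9, 1), 10, 10,
                dimnames = list(NULL, paste0("f", 1:10)))
  zv <- z_score_normalize(val, z)
  st <- attr(z, "zstats")
  expect_equal(zv[, "f1"], (val[, "f1"] - st$mean["f1"]) / st$sd["f1"])
  # constant features are dropped with a warning
  dev2 <- cbind(dev, cst = 1)
  expect_warning(z2 <- z_score_normalize(dev2), "constant")
  expect_false("cst" %in% colnames(z2))
})
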