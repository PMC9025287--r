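test_that("quantizer builds a uniform grid with a right-closed last bin", {
  pf <- data.frame(ein = seq(0, 256, length.out = 1000),
                   eout = seq(-100, 100, length.out = 1000),
                   rwo = seq(0, 1, length.out = 1000))
  qz <- fit_quantizer(pf)
  b <- qz$bins$ein
  expect_equal(length(b$centers), 256)
  expect_equal(b$edges[2] - b$edges[1], 1)
  expect_equal(b$centers[1], 0.5)
  expect_equal(b$centers[256], 255.5)
  x <- apply_quantizer(qz, data.frame(ein = c(0, 256, 255.2),
                                      eout = 0, rwo = 0.5))
  expect_equal(unname(x[1, "ein"]), 0.5)   # min lands in the first bin
  expect_equal(unname(x[2, "ein"]), 255.5) # max lands in the last bin
  # quantization error bounded by half a bin width
  v <- runif(500, 0, 256)
  q <- apply_quantizer(qz, data.frame(ein = v, eout = 0, rwo = 0.5))
  expect_true(all(abs(q[, "ein"] - v) <= 0.5 + 1e-12))
  # out-of-range values clamp to the extreme bins
  xc <- apply_quantizer(qz, data.frame(ein = c(-50, 400), eout = 0,
                                       rwo = 0.5))
  expect_equal(unname(xc[, "ein"]), c(0.5, 255.5))
  expect_warning(fit_quantizer(data.frame(ein = rep(1, 5), eout = 1:5,
                                          rwo = 1:5)), "constant")
})

test_that("population k-means recovers separable structure", {
  set.seed(20)
  x <- rbind(matrix(rnorm(300, 0, 0.1), ncol = 3),
             matrix(rnorm(300, 10, 0.1), ncol = 3))
  truth <- rep(1:2, each = 100)
  fit <- population_kmeans(x, 2, n_reps = 3, seed = 1)
  expect_equal(fit$cluster, truth)
  expect_equal(fit$centers[1, ], colMeans(x[1:100, ]), tolerance = 1e-6)
  expect_equal(fit$centers[2, ], colMeans(x[101:200, ]), tolerance = 1e-6)
  # k = 1 degenerates to the grand mean
  f1 <- population_kmeans(x, 1, n_reps = 1, seed = 1)
  expect_equal(f1$centers[1, ], colMeans(x), tolerance = 1e-8)
  expect_error(population_kmeans(x[1:3, ], 5), "fewer rows")
  # canonical order: ascending wash-in
  expect_true(all(diff(fit$centers[, 1]) > 0))
})

test_that("partition scores match brute-force oracles", {
  set.seed(21)
  x <- rbind(matrix(rnorm(90, 0, 0.05), ncol = 3),
             matrix(rnorm(90, 5, 0.05), ncol = 3),
             cbind(rnorm(30, 0, 0.05), rnorm(30, 8, 0.05),
                   rnorm(30, 0, 0.05)))
  cl <- rep(1:3, each = 30)
  sc <- score_partition(x, cl)
  expect_equal(sc[["calinski_harabasz"]], oracle_ch(x, cl),
               tolerance = 1e-10)
  expect_equal(sc[["silhouette"]], oracle_silhouette(x, cl),
               tolerance = 1e-10)
  expect_gt(sc[["silhouette"]], 0.9)   # tight, far-apart planted clusters
  # two singleton clusters: silhouette 0 by convention, CH degenerate
  sc2 <- score_partition(matrix(c(0, 0, 0, 1, 1, 1), 2, byrow = TRUE),
                         c(1, 2))
  expect_equal(sc2[["silhouette"]], 0)
  expect_true(is.na(sc2[["calinski_harabasz"]]))
  expect_error(score_partition(x, rep(1, 90)), "two clusters")
})

test_that("cluster-number selection follows the CH knee and silhouette", {
  # strictly decreasing CH from k = 2 selects 2
  d <- data.frame(k = 2:8, mean_ch = seq(100, 40, by = -10),
                  mean_silhouette = seq(0.9, 0.3, by = -0.1))
  expect_equal(select_k(d), 2)
  # monotonically increasing scores return the largest k with a warning
  d2 <- data.frame(k = 2:8, mean_ch = 1:7,
                   mean_silhouette = seq(0.5, 0.8, length.out = 7))
  expect_warning(k2 <- select_k(d2), "still increasing")
  expect_equal(k2, 8)
  # CH knee outside the silhouette top-2: kept, with a warning
  d3 <- data.frame(k = 2:6, mean_ch = c(50, 70, 90, 60, 55),
                   mean_silhouette = c(0.9, 0.85, 0.6, 0.55, 0.5))
  expect_warning(k3 <- select_k(d3), "keeping the CH knee")
  expect_equal(k3, 4)
  # single Gaussian cloud: k = 2 with a weak-structure warning
  set.seed(22)
  cloud <- matrix(rnorm(3000), ncol = 3)
  sw <- habitat_diagnostics(cloud, k_range = 2:6, n_reps = 3, seed = 9,
                            silhouette_n = 400)
  expect_warning(kc <- select_k(sw$diagnostics), "weak cluster structure")
  expect_equal(kc, 2)
})

test_that("habitat maps assign every voxel to its nearest center", {
  spec <- cohort_spec(noise_sd = 0)
  mask <- generate_tumor_mask(6, c(1, 1, 1))
  lab <- assign_habitats(mask, spec$habitat_proportions, 0, seed = 23)
  st <- render_dce(lab, spec, seed = 24)
  maps <- compute_perfusion_maps(st)
  pool <- pfv_table(maps)
  qz <- fit_quantizer(pool)
  xq <- apply_quantizer(qz, pool)
  fit <- population_kmeans(xq, 5, n_reps = 5, seed = 3)
  fit$quantizer <- qz
  hm <- build_habitat_map(maps, fit)
  # exhaustive nearest-center check
  x <- apply_quantizer(qz, pool)
  labv <- hm$labels[pool$voxel]
  for (i in seq_len(nrow(x))) {
    dd <- colSums((t(fit$centers) - x[i, ])^2)
    expect_equal(dd[labv[i]], min(dd), tolerance = 1e-9)
  }
  # noise-free planted habitats are recovered up to a label permutation;
  # rendered washout derives from rwo, so match centers on (ein, rwo)
  rendered_centers <- cbind(spec$habitat_centers$ein,
                            spec$habitat_centers$rwo)
  got <- cbind(fit$centers[, 1], fit$centers[, 3])
  perm2 <- match_centers(got, rendered_centers)
  expect_equal(sort(perm2), 1:5)
  relabeled <- perm2[hm$labels[mask]]
  expect_equal(relabeled, lab[mask])
  # proportions sum to one and idempotent reassignment changes nothing
  expect_equal(sum(hm$proportions), 1, tolerance = 1e-9)
  hm2 <- build_habitat_map(maps, fit)
  expect_identical(hm$labels, hm2$labels)
})

test_that("best inertia never increases with k on a fixed sample", {
  set.seed(25)
  x <- rbind(matrix(rnorm(600, 0, 1), ncol = 3),
             matrix(rnorm(600, 6, 1), ncol = 3))
  inert <- vapply(2:8, function(k)
    population_kmeans(x, k, n_reps = 5, seed = 4)$inertia, 0)
  expect_true(all(diff(inert) <= 1e-8))
})

test_that("center matching resolves arbitrary habitat numbering", {
  ref <- archetype_centers()
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(match_centers(ref[perm, ], ref), perm)
  expect_equal(match_centers(ref, ref), 1:5)
})

test_that("habitat models serialize losslessly to JSON", {
  set.seed(26)
  x <- matrix(rnorm(300), ncol = 3,
              dimnames = list(NULL, c("ein", "eout", "rwo")))
  qz <- fit_quantizer(as.data.frame(x))
  fit <- population_kmeans(apply_quantizer(qz, as.data.frame(x)), 3,
                           n_reps = 2, seed = 5)
  fit$quantizer <- qz
  path <- withr::local_tempfile(fileext = ".json")
  write_habitat_model(fit, path)
  back <- read_habitat_model(path)
  expect_equal(back$centers, fit$centers, tolerance = 1e-12)
  expect_equal(back$quantizer$bins$ein$edges, qz$bins$ein$edges,
               tolerance = 1e-12)
})
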