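test_that("tumor masks rasterize at the requested size", {
  mask <- generate_tumor_mask(10, c(1, 1, 1))
  expect_lt(abs(sum(mask) - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.1)
  # degenerate sub-voxel tumor keeps a single voxel
  m1 <- generate_tumor_mask(0.4, c(1, 1, 1))
  expect_equal(sum(m1), 1)
  # one connected component
  z <- habitatmri:::glszm_zones(array(as.integer(mask), dim(mask)))
  expect_equal(nrow(z), 1)
  expect_error(generate_tumor_mask(50, c(1, 1, 1), dim = c(20, 20, 20)),
               "too large")
})

test_that("habitat assignment hits the target proportions", {
  p <- default_habitat_kinetics()$proportion
  mask <- array(TRUE, c(40, 40, 32))  # 51200 voxels
  lab <- assign_habitats(mask, p, spatial_clump = 0, seed = 3)
  emp <- tabulate(lab[lab > 0], 5) / sum(mask)
  expect_true(all(abs(emp - p) < 0.02))
  # iid case passes a multinomial goodness-of-fit test at alpha = 0.01
  gof <- chisq.test(tabulate(lab[lab > 0], 5), p = p)
  expect_gt(gof$p.value, 0.01)
  # degenerate simplex corner
  lab1 <- assign_habitats(mask, c(1, 0, 0, 0, 0), 0, seed = 4)
  expect_true(all(lab1[mask] == 1))
  expect_error(assign_habitats(mask, c(0.5, 0.2), 0, seed = 1), "simplex")
  # determinism
  expect_identical(assign_habitats(mask, p, 1.5, seed = 5),
                   assign_habitats(mask, p, 1.5, seed = 5))
})

test_that("spatial clumping produces contiguous patches at calibrated rates", {
  p <- c(0.4, 0.3, 0.2, 0.1)
  mask <- array(TRUE, c(30, 30, 24))
  lab0 <- assign_habitats(mask, p, 0, seed = 6)
  lab2 <- assign_habitats(mask, p, 2, seed = 6)
  z0 <- habitatmri:::glszm_zones(lab0)
  z2 <- habitatmri:::glszm_zones(lab2)
  expect_gt(mean(z2$size), 5 * mean(z0$size))
  emp <- tabulate(lab2[lab2 > 0], 4) / sum(mask)
  expect_true(all(abs(emp - p) < 0.06))
})

test_that("rendering inverts the perfusion equations exactly when noiseless", {
  spec <- cohort_spec(noise_sd = 0)
  mask <- generate_tumor_mask(8, spec$voxel_spacing)
  lab <- assign_habitats(mask, spec$habitat_proportions, 0, seed = 8)
  st <- render_dce(lab, spec, seed = 9)
  m <- compute_perfusion_maps(st)
  for (h in 1:5) {
    idx <- which(lab == h)
    expect_equal(unique(m$ein[idx]), spec$habitat_centers$ein[h],
                 tolerance = 1e-12)
    expect_equal(unique(m$rwo[idx]), spec$habitat_centers$rwo[h],
                 tolerance = 1e-12)
  }
  # noisy rendering: voxelwise wash-in mean within 3 SE of the planted center
  spec2 <- cohort_spec(noise_sd = 60)
  st2 <- render_dce(lab, spec2, seed = 10)
  m2 <- compute_perfusion_maps(st2)
  idx <- which(lab == 1)
  se <- 60 / sqrt(length(idx))
  expect_lt(abs(mean(m2$ein[idx]) - 825), 3 * se)
})

test_that("scanner transform is strictly monotone, preserving intensity ranks", {
  spec <- cohort_spec(cohort = "validation")
  tr <- spec$scanner_transform
  f <- function(v) tr$intercept + tr$slope * v + tr$quad * v^2
  v <- seq(0, 6000, by = 1)
  expect_true(all(diff(f(v)) > 0))
})

test_that("survival simulation matches its closed form", {
  set.seed(1)
  f <- matrix(rnorm(3000), 1500, 2, dimnames = list(NULL, c("a", "b")))
  # null coefficients: exponential times with rate h_base
  sv <- simulate_survival(f, c(a = 0, b = 0), h_base = 0.01,
                          censor_time = 1e9, seed = 2)
  km <- survival::survfit(survival::Surv(sv$time, sv$event) ~ 1)
  med <- summary(km)$table
  expect_gt(log(2) / 0.01, med["0.95LCL"])
  expect_lt(log(2) / 0.01, med["0.95UCL"])
  # monotone hazard: larger linear predictor gives shorter times
  sv2 <- simulate_survival(f, c(a = 1.5), h_base = 0.01, censor_time = 1e9,
                           seed = 3)
  expect_lt(cor(sv2$lp, sv2$time, method = "spearman"), -0.3)
  # near-zero censoring horizon censors nearly everything
  sv3 <- simulate_survival(f, c(a = 0), h_base = 0.01, censor_time = 1e-4,
                           seed = 4)
  expect_lt(mean(sv3$event), 0.01)
  expect_error(simulate_survival(f, c(a = 0), h_base = 0), "positive")
  expect_error(simulate_survival(f, c(zz = 1)), "unknown feature")
})

test_that("cohorts round-trip through disk bit-exactly", {
  spec <- cohort_spec(n_patients = 2, tumor_radius_range = c(5, 6),
                      survival = list(coefficients = c(hist_Entropy = 0.5),
                                      clinical_coefficients = NULL,
                                      h_base = 0.01, censor_time = 108),
                      seed = 3)
  coh <- simulate_cohort(spec)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$manifest$n_patients, 2)
  expect_equal(nrow(back$clinical), 2)
  expect_true(all(c("pid", "time_months", "event") %in%
                    colnames(back$clinical)))
  p1 <- coh$patients[[1]]
  expect_identical(back$studies[[p1$pid]]$early, p1$study$early)
  expect_identical(back$studies[[p1$pid]]$roi, p1$study$roi)
  expect_equal(back$studies[[p1$pid]]$spacing, p1$study$spacing,
               tolerance = 1e-6)
  expect_identical(back$truth[[p1$pid]], p1$true_habitat_map)
  # regenerating with the same spec reproduces the cohort bit-identically
  coh2 <- simulate_cohort(spec)
  expect_identical(coh2$patients[[2]]$study$delayed,
                   coh$patients[[2]]$study$delayed)
  expect_identical(coh2$surv, coh$surv)
})

test_that("clinical covariates carry the configured marginal frequencies", {
  clin <- simulate_clinical(4000, seed = 5)
  expect_equal(mean(clin$er_positive), 0.792, tolerance = 0.03)
  expect_equal(mean(clin$lvi_positive), 0.292, tolerance = 0.03)
  expect_equal(mean(clin$age), 51.2, tolerance = 0.5)
  cm <- encode_clinical(clin)
  expect_equal(ncol(cm), 18)
  expect_equal(unname(cm[, "lvi_absent"]), 1 - clin$lvi_positive)
})
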