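test_that("full shrinkage and the unpenalized limit both behave", {
  d <- sim_cox_data(60, c(0.8, -0.5), seed = 40)
  big <- fit_cox_lasso(d$x, d$time, d$event, lambda = 50)
  expect_equal(length(big$coefficients), 0)
  # lambda = 0 matches an independent Newton partial-likelihood solver
  m0 <- fit_cox_lasso(d$x, d$time, d$event, lambda = 0)
  bhat <- oracle_cox_newton(d$x, d$time, d$event)
  expect_equal(unname(m0$coefficients[c("f1", "f2")]), unname(bhat),
               tolerance = 1e-6)
  # ... and survival::coxph agrees as a second, independent route
  cph <- survival::coxph(survival::Surv(d$time, d$event) ~ d$x,
                         ties = "breslow")
  expect_equal(unname(bhat), unname(coef(cph)), tolerance = 1e-6)
  expect_error(fit_cox_lasso(d$x, d$time, rep(0, 60)), "two events")
})

test_that("the selection path and nested evaluation behave sensibly", {
  d <- sim_cox_data(120, c(0.9, -0.7, 0, 0), seed = 48)
  # non-zero coefficient count is non-increasing in the penalty
  grid <- exp(seq(log(0.5), log(0.001), length.out = 12))
  nnz <- vapply(grid, function(l)
    length(fit_cox_lasso(d$x, d$time, d$event, lambda = l)$coefficients),
    0L)
  expect_true(all(diff(nnz) >= 0))
  # nested mode reports a cross-validated concordance in [0, 1]
  m <- fit_cox_lasso(d$x, d$time, d$event, seed = 2, nested = TRUE)
  expect_true(is.numeric(m$cv_c_index))
  expect_gte(m$cv_c_index, 0)
  expect_lte(m$cv_c_index, 1)
  # informative design: cross-validated C clears chance level
  expect_gt(m$cv_c_index, 0.5)
})

test_that("risk scores follow the baseline-hazard relative-risk form", {
  d <- sim_cox_data(80, c(0.7, 0), seed = 41)
  m <- fit_cox_lasso(d$x, d$time, d$event, lambda = 0.05)
  sc <- compute_risk_score(m, d$x)
  # all-zero features score exactly h0
  x0 <- matrix(0, 1, 2, dimnames = list(NULL, c("f1", "f2")))
  expect_equal(unname(compute_risk_score(m, x0)), m$h0)
  # strictly increasing in the linear predictor
  lp <- drop(d$x[, names(m$coefficients), drop = FALSE] %*% m$coefficients)
  expect_equal(order(sc), order(lp))
  # h0 is the Breslow increment at the earliest event time
  t1 <- min(d$time[d$event == 1])
  expect_equal(m$h0, sum(d$event == 1 & d$time == t1) /
                 sum(exp(lp[d$time >= t1])), tolerance = 1e-12)
  # doubling h0 doubles every score but not the median split
  m2 <- m; m2$h0 <- 2 * m$h0; m2$cutoff <- 2 * m$cutoff
  sc2 <- compute_risk_score(m2, d$x)
  expect_equal(sc2, 2 * sc, tolerance = 1e-12)
  expect_identical(stratify(sc2, m2$cutoff), stratify(sc, m$cutoff))
  expect_error(compute_risk_score(m, d$x[, 1, drop = FALSE]), "missing")
})

test_that("median-cutoff stratification uses the documented tie convention", {
  expect_equal(as.character(stratify(1.258, 1.067)), "high")
  expect_equal(as.character(stratify(0.790, 1.067)), "low")
  expect_equal(as.character(stratify(1.067, 1.067)), "high")
  g <- stratify(c(0.5, 1.5, 1.067), 1.067)
  expect_equal(levels(g), c("low", "high"))
})

test_that("group hazard ratios recover planted effects and symmetries", {
  set.seed(42)
  n <- 400
  g <- factor(rep(c("low", "high"), each = n / 2),
              levels = c("low", "high"))
  tt <- rexp(n, 0.02 * exp(1.2 * (g == "high")))
  ev <- as.integer(tt <= quantile(tt, 0.5))  # ~50% administrative events
  tm <- pmin(tt, quantile(tt, 0.5))
  hr <- group_hazard_ratio(g, tm, ev)
  expect_lt(abs(hr$log_hr - 1.2), 3 * hr$se)
  expect_true(hr$ci[1] < hr$hr && hr$hr < hr$ci[2])
  # swapping group labels inverts the hazard ratio
  g2 <- factor(ifelse(g == "high", "low", "high"), levels = c("low", "high"))
  hr2 <- group_hazard_ratio(g2, tm, ev)
  expect_equal(hr2$hr, 1 / hr$hr, tolerance = 1e-8)
  # label-permuted identical survival: HR near 1, p large
  set.seed(43)
  tt0 <- rexp(n, 0.02); ev0 <- rep(1L, n)
  hr0 <- group_hazard_ratio(g, tt0, ev0)
  expect_lt(abs(hr0$log_hr), 3 * hr0$se)
  expect_gt(hr0$p, 0.01)
  # no events in one group flags monotone likelihood
  evm <- ev0; evm[g == "low"] <- 0L
  w <- capture_warnings(group_hazard_ratio(g, tt0, evm))
  expect_true(any(grepl("monotone", w)))
})

test_that("Harrell's C matches exhaustive pair enumeration", {
  # perfect concordance without censoring
  tt <- c(5, 3, 9, 1, 7); ev <- rep(1L, 5)
  expect_equal(harrell_c_index(-tt, tt, ev)$c_index, 1)
  # 5-patient worked instance with censoring and a score tie
  sc <- c(2, 2, 1, 5, 4)
  tt2 <- c(3, 6, 8, 2, 9); ev2 <- c(1L, 0L, 1L, 1L, 0L)
  got <- harrell_c_index(sc, tt2, ev2)
  expect_equal(got$c_index, oracle_c_index(sc, tt2, ev2))
  # random scores concentrate near 1/2
  set.seed(44)
  tt3 <- rexp(600); sc3 <- rnorm(600)
  expect_equal(harrell_c_index(sc3, tt3, rep(1L, 600))$c_index, 0.5,
               tolerance = 0.06)
  # invariance under strictly monotone transforms of the score
  expect_equal(harrell_c_index(exp(sc3), tt3, rep(1L, 600))$c_index,
               harrell_c_index(sc3, tt3, rep(1L, 600))$c_index)
})

test_that("bootstrap model comparison separates extreme models only", {
  set.seed(45)
  n <- 200
  tt <- rexp(n); ev <- rep(1L, n)
  perfect <- -tt; anti <- tt
  cmp <- compare_models(perfect, anti, tt, ev, n_boot = 100, seed = 7)
  expect_lt(cmp$p, 0.001)
  # identical models: p = 1
  expect_equal(compare_models(perfect, perfect, tt, ev, n_boot = 50,
                              seed = 7)$p, 1)
  # two-sided symmetry under relabeling
  cmp2 <- compare_models(anti, perfect, tt, ev, n_boot = 100, seed = 7)
  expect_equal(cmp2$p, cmp$p, tolerance = 1e-12)
  expect_error(compare_models(perfect, anti, tt, ev, n_boot = 5), "at least")
})

test_that("the five-model battery freezes development decisions", {
  set.seed(46)
  n <- 60; nv <- 40
  mk <- function(n, seed) {
    set.seed(seed)
    hab <- matrix(rnorm(n * 8), n, 8,
                  dimnames = list(NULL, paste0("h", 1:8)))
    clin <- matrix(rnorm(n * 5), n, 5,
                   dimnames = list(NULL, paste0("c", 1:5)))
    lp <- 0.9 * hab[, 1] - 0.7 * hab[, 2]
    tt <- rexp(n, 0.02 * exp(lp))
    list(habitat = hab, dce = matrix(rnorm(n * 6), n, 6,
                                     dimnames = list(NULL, paste0("d", 1:6))),
         perfusion = matrix(rnorm(n * 6), n, 6,
                            dimnames = list(NULL, paste0("p", 1:6))),
         clinical = clin, time = pmin(tt, 50),
         event = as.integer(tt <= 50))
  }
  dev <- mk(n, 1); val <- mk(nv, 2)
  res <- build_all_risk_models(dev, val, seed = 3, n_boot = 25)
  expect_equal(nrow(res$report), 10)  # 5 models x 2 cohorts
  expect_setequal(unique(res$report$model),
                  c("radiomics_DCE_MR", "radiomics_perfusion", "HRS_only",
                    "clinical", "combined_habitat"))
  # validation rows reuse the development cutoffs bit-exactly
  for (nm in unique(res$report$model)) {
    rows <- res$report[res$report$model == nm, ]
    expect_identical(rows$cutoff[1], rows$cutoff[2])
  }
  expect_true(all(res$report$c_index >= 0 & res$report$c_index <= 1))
  # on data where only habitat features drive hazard, the combined model
  # is at least as concordant as the clinical model in development
  cdev <- res$report[res$report$cohort == "development", ]
  expect_gte(cdev$c_index[cdev$model == "combined_habitat"] + 0.02,
             cdev$c_index[cdev$model == "clinical"])
})

test_that("Cox models serialize losslessly to JSON", {
  d <- sim_cox_data(50, c(0.9, 0), seed = 47)
  m <- fit_cox_lasso(d$x, d$time, d$event, lambda = 0.02)
  path <- withr::local_tempfile(fileext = ".json")
  write_cox_model(m, path)
  back <- read_cox_model(path)
  expect_equal(back$coefficients, m$coefficients, tolerance = 1e-12)
  expect_equal(back$h0, m$h0, tolerance = 1e-12)
  expect_equal(back$cutoff, m$cutoff, tolerance = 1e-12)
  expect_equal(unname(compute_risk_score(back, d$x)),
               unname(compute_risk_score(m, d$x)), tolerance = 1e-12)
})
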