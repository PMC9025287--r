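# Shared fixtures, built in code at test time.

random_label_map <- function(dim = c(4, 4, 4), k = 3, seed = 1,
                             background = 0) {
  set.seed(seed)
  lab <- array(sample.int(k, prod(dim), replace = TRUE), dim)
  if (background > 0) {
    out <- sample(prod(dim), round(background * prod(dim)))
    lab[out] <- 0L
  }
  lab
}

tiny_study <- function(dim = c(5, 5, 4), spacing = c(1, 1, 1), seed = 1) {
  set.seed(seed)
  n <- prod(dim)
  pre <- array(500 + rnorm(n, 0, 20), dim)
  early <- pre + array(800 + rnorm(n, 0, 20), dim)
  delayed <- early * 0.8 + array(rnorm(n, 0, 20), dim)
  roi <- array(FALSE, dim)
  roi[2:(dim[1] - 1), 2:(dim[2] - 1), 2:(dim[3] - 1)] <- TRUE
  dce_study(pre, early, delayed, roi, spacing)
}

sim_cox_data <- function(n, beta, seed, censor = 30, h = 0.05) {
  set.seed(seed)
  p <- length(beta)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  tt <- rexp(n, h * exp(drop(x %*% beta)))
  list(x = x, time = pmin(tt, censor), event = as.integer(tt <= censor))
}

archetype_centers <- function()
  as.matrix(default_habitat_kinetics()[, c("ein", "eout", "rwo")])

# Cached heavy cluster-recovery run shared by several acceptance checks.
.acc_cache <- new.env(parent = emptyenv())

acceptance_mixture <- function() {
  if (is.null(.acc_cache$pf)) {
    spec <- cohort_spec(seed = 11)
    .acc_cache$pf <- simulate_pfv_cohort(spec, n_voxels = 100000, seed = 11)
    qz <- fit_quantizer(.acc_cache$pf$pfv)
    .acc_cache$xq <- apply_quantizer(qz, .acc_cache$pf$pfv)
  }
  list(pf = .acc_cache$pf, xq = .acc_cache$xq)
}

acceptance_sweep <- function() {
  if (is.null(.acc_cache$sweep)) {
    mix <- acceptance_mixture()
    .acc_cache$sweep <- habitat_diagnostics(mix$xq, k_range = 2:32,
                                            n_reps = 20, seed = 42)
  }
  .acc_cache$sweep
}
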