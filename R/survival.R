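# Cox-LASSO habitat risk score (HRS) and the five risk models: fitting,
# scoring, median-cutoff stratification, hazard ratios, concordance and
# model comparison.

check_surv <- function(time, event) {
  if (any(!is.finite(time)) || any(time <= 0))
    stop("survival times must be finite and positive", call. = FALSE)
  if (!all(event %in% c(0, 1)))
    stop("event indicator must be 0/1", call. = FALSE)
  invisible(NULL)
}

stratified_folds <- function(event, nfolds, seed) {
  local_seed(seed, {
    fold <- integer(length(event))
    for (g in c(0, 1)) {
      idx <- sample(which(event == g))
      fold[idx] <- rep_len(seq_len(nfolds), length(idx))
    }
    fold
  })
}

#' Fit an L1-penalized Cox model with cross-validated penalty
#'
#' Coordinate-descent Cox-LASSO (via \pkg{glmnet}, Breslow tie handling)
#' with the penalty chosen by 10-fold cross-validated partial-likelihood
#' deviance over a log-spaced grid, folds stratified by event status, and a
#' final refit on all development data at the selected penalty.  The
#' returned model carries everything needed to score new patients: the
#' non-zero coefficients, the Breslow baseline-hazard increment at the
#' earliest development event time (\code{h0}), and the development median
#' risk cutoff.
#'
#' @param x z-scored feature matrix (patients x features, named columns).
#' @param time,event survival outcome (months, 0/1).
#' @param lambda optional penalty grid; a single value skips
#'   cross-validation (0 gives the unpenalized fit).  By default a
#'   50-point log grid is chosen by \pkg{glmnet}.
#' @param nfolds folds for cross-validation (default 10).
#' @param seed seed for fold assignment.
#' @param nested also run an outer \code{nfolds}-fold loop in which the
#'   whole selection procedure (inner CV for the penalty, refit) is
#'   repeated on each outer training set and the held-out patients are
#'   scored, giving an optimism-free cross-validated C-index stored as
#'   \code{cv_c_index}.  The returned coefficients are always the final
#'   whole-data refit.
#' @return an object of class \code{cox_lasso_model}: list with
#'   \code{coefficients} (non-zero only), \code{lambda}, \code{h0},
#'   \code{cutoff}, \code{features} (full design columns) and \code{zstats}
#'   if attached to \code{x}.
#' @export
fit_cox_lasso <- function(x, time, event, lambda = NULL, nfolds = 10,
                          seed = 1, nested = FALSE) {
  x <- as.matrix(x)
  check_surv(time, event)
  if (sum(event) < 2) stop("need at least two events", call. = FALSE)
  y <- survival::Surv(time, event)
  if (!is.null(lambda) && length(lambda) == 1L) {
    fit <- glmnet::glmnet(x, y, family = "cox", alpha = 1,
                          lambda = c(lambda + 1, lambda),
                          standardize = FALSE, thresh = 1e-14,
                          maxit = 1e6)
    lam <- lambda
  } else {
    foldid <- stratified_folds(event, nfolds, derive_seed(seed, 17))
    cv <- local_seed(derive_seed(seed, 23), {
      if (is.null(lambda))
        glmnet::cv.glmnet(x, y, family = "cox", alpha = 1, nlambda = 50,
                          foldid = foldid, standardize = FALSE)
      else
        glmnet::cv.glmnet(x, y, family = "cox", alpha = 1, lambda = lambda,
                          foldid = foldid, standardize = FALSE)
    })
    lam <- cv$lambda.min
    fit <- cv$glmnet.fit
  }
  beta <- drop(as.matrix(stats::coef(fit, s = lam)))
  lp <- drop(x %*% beta)
  h0 <- breslow_h0(lp, time, event)
  score <- h0 * exp(lp)
  nz <- beta[beta != 0]
  cv_c <- NULL
  if (nested) {
    outer <- stratified_folds(event, nfolds, derive_seed(seed, 91))
    held <- rep(NA_real_, length(time))
    for (f in seq_len(nfolds)) {
      tr <- outer != f
      if (sum(event[tr]) < 2) next
      sub <- fit_cox_lasso(x[tr, , drop = FALSE], time[tr], event[tr],
                           lambda = lambda, nfolds = nfolds,
                           seed = derive_seed(seed, 92 + f),
                           nested = FALSE)
      held[!tr] <- compute_risk_score(sub, x[!tr, , drop = FALSE])
    }
    ok <- !is.na(held)
    cv_c <- harrell_c_index(held[ok], time[ok], event[ok])$c_index
  }
  structure(list(coefficients = nz, lambda = lam, h0 = h0,
                 cv_c_index = cv_c,
                 cutoff = stats::median(score),
                 features = colnames(x),
                 zstats = attr(x, "zstats"),
                 dev_scores = score),
            class = "cox_lasso_model")
}

# Breslow baseline-hazard increment at the earliest event time.
breslow_h0 <- function(lp, time, event) {
  t1 <- min(time[event == 1])
  d1 <- sum(event == 1 & time == t1)
  d1 / sum(exp(lp[time >= t1]))
}

#' @export
print.cox_lasso_model <- function(x, ...) {
  cat(sprintf("Cox-LASSO risk model: lambda = %.5g, h0(0) = %.5g, %s\n",
              x$lambda, x$h0,
              sprintf("median cutoff = %.4g", x$cutoff)))
  if (length(x$coefficients) == 0) cat("  (no features selected)\n")
  else print(round(x$coefficients, 4))
  invisible(x)
}

#' Compute the habitat risk score for new patients
#'
#' \eqn{HRS_i = h_0(0) \exp(\sum_j \beta_j x_{ij})}: the relative hazard at
#' time zero under the fitted model.  Features must be z-scored with the
#' development statistics (done automatically when the model carries them
#' and \code{x} is raw).
#'
#' @param model a \code{cox_lasso_model}.
#' @param x feature matrix for the patients to score.
#' @param normalized set \code{TRUE} if \code{x} is already z-scored.
#' @return numeric score vector.
#' @export
compute_risk_score <- function(model, x, normalized = TRUE) {
  stopifnot(inherits(model, "cox_lasso_model"))
  x <- as.matrix(x)
  if (!normalized && !is.null(model$zstats))
    x <- z_score_normalize(x, model$zstats)
  need <- names(model$coefficients)
  miss <- setdiff(need, colnames(x))
  if (length(miss))
    stop("missing feature(s): ", paste(miss, collapse = ", "), call. = FALSE)
  lp <- if (length(need) == 0) rep(0, nrow(x))
        else drop(x[, need, drop = FALSE] %*% model$coefficients)
  model$h0 * exp(lp)
}

#' Split patients into risk groups at a development cutoff
#'
#' High risk when \code{score >= cutoff} (a score exactly at the cutoff is
#' high risk; the boundary convention is fixed for reproducibility).  The
#' cutoff must come from the development cohort and is reused verbatim for
#' validation.
#'
#' @param scores numeric risk scores.
#' @param cutoff development median (or other) cutoff.
#' @return factor with levels \code{low}, \code{high}.
#' @export
stratify <- function(scores, cutoff) {
  factor(ifelse(scores >= cutoff, "high", "low"), levels = c("low", "high"))
}

#' Hazard ratio between risk groups
#'
#' Single-covariate Cox proportional-hazards fit of the high-vs-low group
#' indicator with Wald confidence interval and p-value.
#'
#' @param groups factor from \code{\link{stratify}}.
#' @param time,event survival outcome.
#' @param conf_level confidence level (default 0.95).
#' @return list with \code{hr}, \code{ci} (length 2), \code{p},
#'   \code{log_hr}, \code{se} and \code{monotone} (TRUE when a group has no
#'   events and the estimate diverges).
#' @export
group_hazard_ratio <- function(groups, time, event, conf_level = 0.95) {
  check_surv(time, event)
  if (nlevels(droplevels(groups)) < 2)
    stop("both risk groups must be nonempty", call. = FALSE)
  if (sum(event) < 1) stop("need at least one event", call. = FALSE)
  mono <- any(tapply(event, groups, sum) == 0)
  if (mono)
    warning("a group has no events; hazard ratio is unstable (monotone ",
            "likelihood)", call. = FALSE)
  fit <- survival::coxph(survival::Surv(time, event) ~ groups)
  b <- unname(stats::coef(fit)[1])
  se <- sqrt(stats::vcov(fit)[1, 1])
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(hr = exp(b), ci = exp(b + c(-1, 1) * zq * se),
       p = 2 * stats::pnorm(-abs(b / se)),
       log_hr = b, se = se, monotone = mono)
}

#' Harrell's concordance index
#'
#' Probability that, among comparable pairs (both events, or an event and a
#' patient censored later), the patient with the higher risk score fails
#' earlier.  Tied scores count 1/2.  Computed through
#' \code{survival::concordance}; the standard error is the one reported by
#' that estimator.
#'
#' @param scores risk scores (higher = riskier).
#' @param time,event survival outcome.
#' @return list with \code{c_index} and \code{se}.
#' @export
harrell_c_index <- function(scores, time, event) {
  check_surv(time, event)
  fit <- survival::concordance(survival::Surv(time, event) ~ scores,
                               reverse = TRUE, timewt = "n")
  if (sum(unlist(fit$count[c("concordant", "discordant", "tied.x")])) == 0)
    stop("no comparable pairs", call. = FALSE)
  list(c_index = unname(fit$concordance), se = sqrt(unname(fit$var)))
}

#' Compare two risk models by bootstrapped C-index difference
#'
#' Patients are resampled with replacement \code{n_boot} times; both
#' models' C-indices are recomputed on each replicate and a paired t
#' statistic over the replicate differences gives a two-sided p-value.
#' Identical score vectors return p = 1.
#'
#' @param scores_a,scores_b risk scores of the two models over the same
#'   patients.
#' @param time,event survival outcome.
#' @param n_boot bootstrap replicates (minimum 20, default 200).
#' @param seed resampling seed.
#' @return list with \code{p}, \code{t}, \code{mean_diff}, \code{n_boot}.
#' @export
compare_models <- function(scores_a, scores_b, time, event, n_boot = 200,
                           seed = 1) {
  if (n_boot < 20) stop("n_boot must be at least 20", call. = FALSE)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(time))
    stop("models must score the same patients", call. = FALSE)
  n <- length(time)
  diffs <- local_seed(derive_seed(seed, 31), {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (sum(event[idx]) == 0) return(NA_real_)
      ca <- harrell_c_index(scores_a[idx], time[idx], event[idx])$c_index
      cb <- harrell_c_index(scores_b[idx], time[idx], event[idx])$c_index
      ca - cb
    }, 0)
  })
  diffs <- diffs[is.finite(diffs)]
  s <- stats::sd(diffs)
  if (!is.finite(s) || s == 0) {
    # degenerate bootstrap: every replicate difference identical
    p <- if (isTRUE(all.equal(mean(diffs), 0))) 1 else 0
    return(list(p = p, t = if (p == 1) 0 else Inf,
                mean_diff = mean(diffs), n_boot = n_boot))
  }
  tt <- mean(diffs) / (s / sqrt(length(diffs)))
  list(p = 2 * stats::pt(-abs(tt), df = length(diffs) - 1), t = tt,
       mean_diff = mean(diffs), n_boot = n_boot)
}

# ---- five-model battery ----------------------------------------------------

fit_one_risk_model <- function(xdev, xval, surv_dev, surv_val, seed,
                               lambda = NULL) {
  zdev <- z_score_normalize(xdev)
  zval <- z_score_normalize(xval, zdev)
  model <- fit_cox_lasso(zdev, surv_dev$time, surv_dev$event,
                         lambda = lambda, seed = seed)
  list(model = model,
       dev = compute_risk_score(model, zdev),
       val = compute_risk_score(model, zval))
}

#' Build and evaluate the five risk models
#'
#' Fits the two conventional whole-tumor radiomics models
#' (\code{radiomics_DCE_MR}, \code{radiomics_perfusion}), the HRS-only
#' model, the clinical model and the combined (clinical + HRS) model on the
#' development cohort; freezes coefficients, z-score statistics and median
#' cutoffs; applies them to the validation cohort; and reports per-model,
#' per-cohort hazard ratios (high vs low group), C-indices and a
#' bootstrap comparison p-value against the combined model.
#'
#' @param dev,val per-cohort lists with elements \code{habitat} (58 + k
#'   habitat feature matrix), \code{dce} and \code{perfusion} (whole-tumor
#'   feature matrices), \code{clinical} (numeric covariate matrix),
#'   \code{time}, \code{event}.
#' @param seed seed for cross-validation folds and bootstrap.
#' @param n_boot bootstrap replicates for model comparison.
#' @return list with \code{report} (data.frame, one row per model x
#'   cohort), \code{models}, and per-model risk \code{scores}.
#' @export
build_all_risk_models <- function(dev, val, seed = 1, n_boot = 100) {
  fits <- list(
    radiomics_DCE_MR = fit_one_risk_model(dev$dce, val$dce, dev, val,
                                          derive_seed(seed, 1)),
    radiomics_perfusion = fit_one_risk_model(dev$perfusion, val$perfusion,
                                             dev, val, derive_seed(seed, 2)),
    HRS_only = fit_one_risk_model(dev$habitat, val$habitat, dev, val,
                                  derive_seed(seed, 3)),
    clinical = fit_one_risk_model(dev$clinical, val$clinical, dev, val,
                                  derive_seed(seed, 4)))
  hrs_dev <- fits$HRS_only$dev; hrs_val <- fits$HRS_only$val
  comb_dev <- cbind(dev$clinical, HRS = hrs_dev)
  comb_val <- cbind(val$clinical, HRS = hrs_val)
  fits$combined_habitat <- fit_one_risk_model(comb_dev, comb_val, dev, val,
                                              derive_seed(seed, 5))
  rows <- list()
  for (nm in names(fits)) {
    f <- fits[[nm]]
    for (coh in c("development", "validation")) {
      sc <- if (coh == "development") f$dev else f$val
      sv <- if (coh == "development") dev else val
      grp <- stratify(sc, f$model$cutoff)
      hr <- tryCatch(group_hazard_ratio(grp, sv$time, sv$event),
                     warning = function(w)
                       suppressWarnings(group_hazard_ratio(grp, sv$time,
                                                           sv$event)),
                     error = function(e)
                       list(hr = NA, ci = c(NA, NA), p = NA))
      ci <- harrell_c_index(sc, sv$time, sv$event)
      cmp <- if (nm == "combined_habitat") NA_real_ else NA
      rows[[length(rows) + 1]] <-
        data.frame(model = nm, cohort = coh, cutoff = f$model$cutoff,
                   hr = hr$hr, hr_lo = hr$ci[1], hr_hi = hr$ci[2],
                   hr_p = hr$p, c_index = ci$c_index, c_se = ci$se,
                   comparison_p = NA_real_,
                   score_min = min(sc), score_max = max(sc),
                   score_q1 = unname(stats::quantile(sc, 0.25)),
                   score_q3 = unname(stats::quantile(sc, 0.75)))
    }
  }
  report <- do.call(rbind, rows)
  for (nm in setdiff(names(fits), "combined_habitat")) {
    for (coh in c("development", "validation")) {
      sv <- if (coh == "development") dev else val
      a <- if (coh == "development") fits[[nm]]$dev else fits[[nm]]$val
      b <- if (coh == "development") fits$combined_habitat$dev
           else fits$combined_habitat$val
      p <- compare_models(a, b, sv$time, sv$event, n_boot = n_boot,
                          seed = derive_seed(seed, 100 + match(coh, c(
                            "development", "validation"))))$p
      report$comparison_p[report$model == nm & report$cohort == coh] <- p
    }
  }
  list(report = report,
       models = lapply(fits, `[[`, "model"),
       scores = lapply(fits, function(f) list(development = f$dev,
                                              validation = f$val)))
}

#' Serialize / read a Cox-LASSO risk model as JSON
#' @param model a \code{cox_lasso_model}.
#' @param path JSON file path.
#' @return \code{path} (write) or the model (read).
#' @export
write_cox_model <- function(model, path) {
  jsonlite::write_json(
    list(coefficients = as.list(model$coefficients), lambda = model$lambda,
         h0 = model$h0, cutoff = model$cutoff, features = model$features,
         zstats = model$zstats),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cox_model
#' @export
read_cox_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  zs <- if (!is.null(x$zstats))
    list(mean = unlist(x$zstats$mean), sd = unlist(x$zstats$sd),
         features = x$zstats$features)
  structure(list(coefficients = unlist(x$coefficients), lambda = x$lambda,
                 h0 = x$h0, cutoff = x$cutoff, features = x$features,
                 zstats = zs),
            class = "cox_lasso_model")
}
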