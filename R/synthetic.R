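# Synthetic dual-cohort DCE-MRI generator: spherical-to-ellipsoidal tumors,
# planted perfusion habitats with controllable spatial clumping, three-phase
# volume rendering that inverts the perfusion-map equations, clinical
# covariates with planted log-hazard contributions, and exponential
# survival times driven by a Cox model on habitat-heterogeneity features.

#' Default perfusion-habitat archetypes
#'
#' The five kinetic archetypes used as generator defaults, one row per
#' habitat: persistent low enhancement, strong wash-in with washout,
#' strong wash-in with plateau, moderate wash-in with washout, and marked
#' washout.  Columns: wash-in (\code{ein}) and washout (\code{eout}) in
#' intensity units, washout ratio (\code{rwo}, dimensionless) and the
#' mixing \code{proportion} of each habitat among tumor voxels.
#'
#' @return data.frame with k = 5 rows.
#' @export
default_habitat_kinetics <- function() {
  data.frame(
    habitat = 1:5,
    ein = c(825, 2420, 2206, 1154, 1302),
    eout = c(-667, 864, -14, 362, 915),
    rwo = c(0.021, 0.361, 0.075, 0.338, 0.717),
    proportion = c(0.419, 0.068, 0.256, 0.235, 0.022))
}

default_clinical_marginals <- function() {
  list(age_mean = 51.2, age_sd = 10.5,
       t_stage = c(0.607, 0.364, 0.023, 0.007),
       n_stage = c(0.613, 0.318, 0.046, 0.023),
       grade = c(0.266, 0.497, 0.237),
       type = c(idc = 0.925, ilc = 0.039, other = 0.036),
       enhancement = c(homogeneous = 0.091, heterogeneous = 0.659,
                       rim = 0.250),
       shape = c(round = 0.078, oval = 0.081, irregular = 0.841),
       margin_circumscribed = 0.055,
       lvi_positive = 0.292, eic_positive = 0.263,
       er_positive = 0.792, pr_positive = 0.708,
       p53_positive = 0.312, her2_positive = 0.192,
       ki67_high = 0.468,
       adj_chemo = 0.643, adj_rt = 0.783, adj_endocrine = 0.796)
}

#' Specify a synthetic cohort
#'
#' Bundles every knob of the generator.  Defaults model the study
#' conditions the analysis targets: a development cohort at
#' 0.85 x 0.85 x 3 mm voxels and a validation cohort at 0.80 x 0.80 x 3 mm
#' whose intensities additionally pass through a strictly monotone scanner
#' transform, tumors of 6-14 mm radius, five perfusion habitats with the
#' archetype kinetics and mixing proportions of
#' \code{\link{default_habitat_kinetics}}, and survival driven by planted
#' coefficients on habitat-heterogeneity features plus clinical
#' covariates.
#'
#' @param n_patients cohort size.
#' @param cohort \code{"development"} or \code{"validation"}.
#' @param voxel_spacing mm triplet; default depends on \code{cohort}.
#' @param tumor_radius_range mm range from which tumor radii are drawn.
#' @param habitat_centers data.frame with columns \code{ein}, \code{eout},
#'   \code{rwo} (k rows).  \code{eout} is only used by the bare-PFV mode;
#'   rendered volumes derive washout from \code{rwo}.
#' @param habitat_proportions simplex weights (length k).
#' @param spatial_clump correlation length of the label field in voxels
#'   (0 = independent voxels).
#' @param noise_sd intensity noise SD for rendered phases.
#' @param pfv_sd per-feature SD used by the bare-PFV mode.
#' @param baseline mean pre-contrast intensity.
#' @param scanner_transform list(intercept, slope, quad) of the monotone
#'   intensity map applied to validation-cohort volumes, or \code{NULL}.
#' @param survival list with \code{coefficients} (named, on z-scored
#'   habitat features), \code{clinical_coefficients} (named, on encoded
#'   clinical covariates), \code{h_base} (baseline hazard per month) and
#'   \code{censor_time} (administrative censoring, months).
#' @param seed integer master seed.
#' @return an object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_patients = 20,
                        cohort = c("development", "validation"),
                        voxel_spacing = NULL,
                        tumor_radius_range = c(6, 14),
                        habitat_centers = default_habitat_kinetics(),
                        habitat_proportions =
                          default_habitat_kinetics()$proportion,
                        spatial_clump = 1.5,
                        noise_sd = 60,
                        pfv_sd = c(150, 150, 0.05),
                        baseline = 500,
                        scanner_transform = NULL,
                        survival = list(
                          coefficients = c(
                            shape_SurfaceVolumeRatio = -0.235,
                            glcm_Idmn = -0.032,
                            glcm_Imc1 = 0.017,
                            glszm_SmallAreaEmphasis = 0.123),
                          clinical_coefficients = c(
                            n_stage = 0.199, lvi_absent = -0.624,
                            er_negative = 0.398, pr_negative = 0.325,
                            ki67_low = -0.623),
                          h_base = 0.0014, censor_time = 108),
                        seed = 1) {
  cohort <- match.arg(cohort)
  voxel_spacing <- voxel_spacing %||%
    (if (cohort == "development") c(0.85, 0.85, 3) else c(0.80, 0.80, 3))
  if (is.null(scanner_transform) && cohort == "validation")
    scanner_transform <- list(intercept = 150, slope = 0.85, quad = 3e-5)
  p <- habitat_proportions
  if (abs(sum(p) - 1) > 1e-9) stop("habitat proportions must sum to 1",
                                   call. = FALSE)
  if (any(p < 0)) stop("habitat proportions must be non-negative",
                       call. = FALSE)
  if (nrow(habitat_centers) != length(p))
    stop("one proportion per habitat center required", call. = FALSE)
  if (any(noise_sd < 0) || any(pfv_sd < 0))
    stop("noise SDs must be non-negative", call. = FALSE)
  structure(list(n_patients = n_patients, cohort = cohort,
                 voxel_spacing = as.numeric(voxel_spacing),
                 tumor_radius_range = as.numeric(tumor_radius_range),
                 habitat_centers = habitat_centers,
                 habitat_proportions = p,
                 spatial_clump = spatial_clump,
                 noise_sd = noise_sd, pfv_sd = rep_len(pfv_sd, 3),
                 baseline = baseline,
                 scanner_transform = scanner_transform,
                 survival = survival, seed = seed),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Synthetic %s cohort: %d patients, %d habitats, spacing %s mm\n",
              x$cohort, x$n_patients, length(x$habitat_proportions),
              paste(signif(x$voxel_spacing, 3), collapse = " x ")))
  invisible(x)
}

# ---- tumor mask ------------------------------------------------------------

rasterize_ellipsoid <- function(radii_mm, spacing, dim, center_mm) {
  ax <- lapply(1:3, function(a) ((seq_len(dim[a]) - 1) * spacing[a] -
                                   center_mm[a]) / radii_mm[a])
  d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  d2 <= 1
}

#' Generate a tumor ROI mask
#'
#' Rasterizes an ellipsoid (default: sphere) on the cohort voxel grid.
#' With \code{dim = NULL} the field of view is sized to the tumor plus a
#' fixed background margin; an explicit \code{dim} too small for the
#' requested radius is an error.
#'
#' @param radius tumor radius in mm (the first semi-axis).
#' @param spacing voxel spacing in mm.
#' @param axis_ratios length-3 multipliers of \code{radius} per axis.
#' @param dim optional volume dimensions.
#' @param margin background margin in mm around the tumor (default 8).
#' @return 3D logical mask with the tumor centered in the volume.
#' @export
generate_tumor_mask <- function(radius, spacing, axis_ratios = c(1, 1, 1),
                                dim = NULL, margin = 8) {
  radii <- radius * rep_len(axis_ratios, 3)
  if (is.null(dim)) {
    dim <- pmax(3L, as.integer(ceiling((2 * radii + 2 * margin) / spacing)))
  } else {
    if (any(2 * radii > dim * spacing))
      stop("tumor radius too large for the field of view", call. = FALSE)
  }
  center <- (dim - 1) / 2 * spacing
  mask <- rasterize_ellipsoid(radii, spacing, dim, center)
  if (!any(mask)) {
    # degenerate sub-voxel tumor: keep the center voxel
    mask[ceiling(dim[1] / 2), ceiling(dim[2] / 2), ceiling(dim[3] / 2)] <- TRUE
  }
  mask
}

# ---- habitat label fields --------------------------------------------------

# Offsets alpha such that P(argmax_h N(alpha_h, 1)) hits the target simplex.
calibrate_offsets <- function(p, tol = 1e-5, max_iter = 200) {
  k <- length(p)
  alpha <- stats::qnorm(pmin(pmax(p, 1e-6), 1 - 1e-6))
  win_prob <- function(alpha) {
    vapply(seq_len(k), function(h) {
      stats::integrate(function(x) {
        f <- stats::dnorm(x)
        for (j in seq_len(k)[-h]) f <- f * stats::pnorm(x + alpha[h] - alpha[j])
        f
      }, -Inf, Inf, rel.tol = 1e-9)$value
    }, 0)
  }
  for (it in seq_len(max_iter)) {
    cur <- win_prob(alpha)
    if (max(abs(cur - p)) < tol) break
    alpha <- alpha + 0.8 * log(pmax(p, 1e-12) / pmax(cur, 1e-12))
    alpha <- alpha - mean(alpha)
  }
  alpha
}

gauss_kernel_matrix <- function(n, sd) {
  hw <- max(1L, ceiling(3 * sd))
  w <- stats::dnorm(-hw:hw, sd = sd)
  w <- w / sum(w)
  W <- matrix(0, n, n)
  for (o in -hw:hw) {
    idx <- seq_len(n)
    tgt <- idx + o
    ok <- tgt >= 1 & tgt <= n
    W[cbind(idx[ok], tgt[ok])] <- W[cbind(idx[ok], tgt[ok])] + w[o + hw + 1]
  }
  W
}

#' Assign habitat labels inside a tumor mask
#'
#' With \code{spatial_clump = 0} labels are i.i.d. multinomial draws at
#' the target proportions.  With \code{spatial_clump > 0}, one Gaussian
#' random field per habitat is smoothed to the requested correlation
#' length, standardized, shifted by a calibrated offset and the voxel
#' takes the argmax habitat; marginal win probabilities equal the target
#' proportions, and smoothing makes patches spatially contiguous.
#'
#' @param mask 3D logical tumor mask.
#' @param proportions simplex weights over habitats.
#' @param spatial_clump correlation length in voxels (0 = independent).
#' @param seed integer seed.
#' @return 3D integer label volume (0 outside the mask).
#' @export
assign_habitats <- function(mask, proportions, spatial_clump = 0, seed = 1) {
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  p <- proportions
  if (abs(sum(p) - 1) > 1e-9 || any(p < 0))
    stop("proportions must lie on the simplex", call. = FALSE)
  k <- length(p)
  d <- dim(mask)
  labels <- array(0L, d)
  idx <- which(mask)
  if (spatial_clump <= 0) {
    labels[idx] <- local_seed(seed,
      sample.int(k, length(idx), replace = TRUE, prob = p))
    return(labels)
  }
  alpha <- calibrate_offsets(p)
  Ws <- lapply(1:3, function(a) gauss_kernel_matrix(d[a], spatial_clump))
  hw <- max(1L, ceiling(3 * spatial_clump))
  w1 <- stats::dnorm(-hw:hw, sd = spatial_clump)
  w1 <- w1 / sum(w1)
  norm1 <- sqrt(sum(w1^2))
  fields <- local_seed(seed, lapply(seq_len(k), function(h) {
    f <- array(stats::rnorm(prod(d)), d)
    for (a in 1:3) f <- apply_axis(f, Ws[[a]], a)
    f / norm1^3 + alpha[h]
  }))
  fm <- vapply(fields, function(f) f[idx], numeric(length(idx)))
  if (length(idx) == 1L) fm <- matrix(fm, nrow = 1)
  labels[idx] <- max.col(fm, ties.method = "first")
  labels
}

# ---- rendering -------------------------------------------------------------

#' Render a three-phase DCE study from a planted habitat label volume
#'
#' Inverts the perfusion-map definitions: each tumor voxel of habitat h
#' receives the habitat's wash-in and washout-ratio, and the phases are
#' \eqn{I_{pre} = baseline + \epsilon}, \eqn{I_{early} = I_{pre} + E_{in}
#' + \epsilon}, \eqn{I_{delayed} = I_{early}(1 - R_{WO}) + \epsilon} with
#' independent Gaussian noise of SD \code{noise_sd} and clipping at 0.
#' Background (non-tumor) voxels get low, persistent enhancement so the
#' volume has realistic non-zero support for histogram matching.  For a
#' validation spec the scanner transform is applied to all three phases.
#'
#' @param labels 3D integer habitat volume (0 = background).
#' @param spec a \code{cohort_spec}.
#' @param seed integer seed.
#' @param pid patient id for the resulting study.
#' @return a \code{dce_study}.
#' @export
render_dce <- function(labels, spec, seed = 1, pid = "p1") {
  d <- dim(labels)
  n <- prod(d)
  k <- nrow(spec$habitat_centers)
  if (any(labels < 0 | labels > k)) stop("invalid habitat labels",
                                         call. = FALSE)
  local_seed(seed, {
    ein <- array(abs(stats::rnorm(n, 50, 30)), d)   # background enhancement
    rwo <- array(0, d)
    inroi <- labels > 0
    ein[inroi] <- spec$habitat_centers$ein[labels[inroi]]
    rwo[inroi] <- spec$habitat_centers$rwo[labels[inroi]]
    ns <- spec$noise_sd
    pre <- spec$baseline + array(stats::rnorm(n, 0, ns), d)
    early <- pre + ein + array(stats::rnorm(n, 0, ns), d)
    delayed <- early * (1 - rwo) + array(stats::rnorm(n, 0, ns), d)
    pre[pre < 0] <- 0; early[early < 0] <- 0; delayed[delayed < 0] <- 0
    if (!is.null(spec$scanner_transform)) {
      tr <- spec$scanner_transform
      f <- function(v) tr$intercept + tr$slope * v + tr$quad * v^2
      pre <- f(pre); early <- f(early); delayed <- f(delayed)
    }
    dce_study(pre, early, delayed, inroi, spacing = spec$voxel_spacing,
              pid = pid, cohort = spec$cohort)
  })
}

# ---- survival --------------------------------------------------------------

#' Simulate survival outcomes from planted Cox coefficients
#'
#' Exponential event times under a proportional-hazards model:
#' \eqn{T = -\log(U) / (h_{base} e^{LP})} with \eqn{LP} the planted linear
#' predictor on z-scored features, administratively censored at
#' \code{censor_time}.
#'
#' @param features numeric matrix (patients x named features).
#' @param coefficients named coefficient vector; every name must be a
#'   column of \code{features}.
#' @param h_base baseline hazard per month (> 0).
#' @param censor_time administrative censoring time in months.
#' @param seed integer seed.
#' @param lp_offset optional additional per-patient linear predictor
#'   (e.g. clinical contributions).
#' @return data.frame with \code{time}, \code{event}, \code{lp}.
#' @export
simulate_survival <- function(features, coefficients, h_base = 0.0014,
                              censor_time = 108, seed = 1, lp_offset = 0) {
  if (h_base <= 0) stop("baseline hazard must be positive", call. = FALSE)
  features <- as.matrix(features)
  miss <- setdiff(names(coefficients), colnames(features))
  if (length(miss))
    stop("planted coefficients name unknown feature(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  lp <- rep_len(lp_offset, nrow(features))
  if (length(coefficients)) {
    z <- scale(features[, names(coefficients), drop = FALSE])
    z[, attr(z, "scaled:scale") == 0] <- 0
    lp <- lp + drop(z %*% coefficients)
  }
  tt <- local_seed(seed, {
    u <- stats::runif(nrow(features))
    -log(u) / (h_base * exp(lp))
  })
  data.frame(time = pmin(tt, censor_time),
             event = as.integer(tt <= censor_time),
             lp = lp)
}

#' Simulate clinicopathological covariates
#'
#' Draws the standard breast-cancer covariate panel (stage, grade,
#' receptor status, adjuvant therapy, MRI reading categories) from fixed
#' marginal frequencies typical of a development cohort.
#'
#' @param n number of patients.
#' @param seed integer seed.
#' @param marginals marginal frequencies (see
#'   \code{habitatmri:::default_clinical_marginals}).
#' @return data.frame of raw covariates (one row per patient).
#' @export
simulate_clinical <- function(n, seed = 1,
                              marginals = default_clinical_marginals()) {
  m <- marginals
  local_seed(seed, {
    rcat <- function(p) sample.int(length(p), n, replace = TRUE,
                                   prob = p / sum(p))
    data.frame(
      age = stats::rnorm(n, m$age_mean, m$age_sd),
      t_stage = rcat(m$t_stage),
      n_stage = rcat(m$n_stage) - 1L,
      grade = rcat(m$grade),
      type = c("idc", "ilc", "other")[rcat(m$type)],
      enhancement = names(m$enhancement)[rcat(m$enhancement)],
      shape = names(m$shape)[rcat(m$shape)],
      margin_circumscribed = stats::rbinom(n, 1, m$margin_circumscribed),
      lvi_positive = stats::rbinom(n, 1, m$lvi_positive),
      eic_positive = stats::rbinom(n, 1, m$eic_positive),
      er_positive = stats::rbinom(n, 1, m$er_positive),
      pr_positive = stats::rbinom(n, 1, m$pr_positive),
      p53_positive = stats::rbinom(n, 1, m$p53_positive),
      her2_positive = stats::rbinom(n, 1, m$her2_positive),
      ki67_high = stats::rbinom(n, 1, m$ki67_high),
      adj_chemo = stats::rbinom(n, 1, m$adj_chemo),
      adj_rt = stats::rbinom(n, 1, m$adj_rt),
      adj_endocrine = stats::rbinom(n, 1, m$adj_endocrine),
      stringsAsFactors = FALSE)
  })
}

#' Encode clinical covariates as a numeric model matrix
#'
#' Binary indicators follow the risk-factor direction conventions of the
#' clinical model (absence of lymphovascular invasion, ER/PR negativity,
#' Ki-67 < 20 pct); N and T stage and grade enter as ordinal integers.
#'
#' @param clin data.frame from \code{\link{simulate_clinical}}.
#' @return numeric matrix with named columns.
#' @export
encode_clinical <- function(clin) {
  cbind(age = clin$age,
        t_stage = clin$t_stage,
        n_stage = clin$n_stage,
        grade = clin$grade,
        type_non_idc = as.numeric(clin$type != "idc"),
        enhancement_rim = as.numeric(clin$enhancement == "rim"),
        shape_irregular = as.numeric(clin$shape == "irregular"),
        margin_not_circumscribed = 1 - clin$margin_circumscribed,
        lvi_absent = 1 - clin$lvi_positive,
        eic_positive = clin$eic_positive,
        er_negative = 1 - clin$er_positive,
        pr_negative = 1 - clin$pr_positive,
        p53_positive = clin$p53_positive,
        her2_positive = clin$her2_positive,
        ki67_low = 1 - clin$ki67_high,
        adj_chemo = clin$adj_chemo,
        adj_rt = clin$adj_rt,
        adj_endocrine = clin$adj_endocrine)
}

# ---- cohort assembly -------------------------------------------------------

#' Sample bare perfusion feature vectors from the habitat mixture
#'
#' The bare-PFV mode of the generator: voxels are drawn from the habitat
#' mixture directly in (wash-in, washout, washout-ratio) space with
#' per-feature Gaussian dispersion \code{spec$pfv_sd}, giving exact
#' control of the planted centers for clustering experiments.
#'
#' @param spec a \code{cohort_spec}.
#' @param n_voxels number of voxels to draw.
#' @param seed integer seed (defaults to the seed stored in \code{spec}).
#' @return list with \code{pfv} (data.frame ein/eout/rwo) and
#'   \code{habitat} (true labels).
#' @export
simulate_pfv_cohort <- function(spec, n_voxels = 100000, seed = NULL) {
  seed <- seed %||% spec$seed
  ctr <- spec$habitat_centers
  k <- nrow(ctr)
  local_seed(seed, {
    lab <- sample.int(k, n_voxels, replace = TRUE,
                      prob = spec$habitat_proportions)
    pfv <- data.frame(
      ein = ctr$ein[lab] + stats::rnorm(n_voxels, 0, spec$pfv_sd[1]),
      eout = ctr$eout[lab] + stats::rnorm(n_voxels, 0, spec$pfv_sd[2]),
      rwo = pmin(pmax(
        ctr$rwo[lab] + stats::rnorm(n_voxels, 0, spec$pfv_sd[3]), 0), 1))
    list(pfv = pfv, habitat = lab)
  })
}

#' Simulate a full synthetic cohort
#'
#' Image mode of the generator: per patient, draws a tumor mask, plants a
#' clumped habitat label field, renders the three phases, computes the
#' true habitat-heterogeneity features from the planted label map, draws
#' clinical covariates, and simulates Cox survival from the planted
#' habitat and clinical coefficients.
#'
#' @param spec a \code{cohort_spec}.
#' @return list of class \code{synthetic_cohort} with \code{patients}
#'   (each: \code{study}, \code{true_habitat_map},
#'   \code{lp}, \code{time}, \code{event}), \code{clinical} (raw
#'   data.frame), \code{clinical_matrix}, \code{features} (true habitat
#'   features), \code{surv} (time/event data.frame) and the \code{spec}.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  pids <- sprintf("%s%03d", if (spec$cohort == "development") "dev" else
    "val", seq_len(n))
  patients <- vector("list", n)
  feats <- NULL
  for (i in seq_len(n)) {
    sp <- derive_seed(spec$seed, i)
    geom <- local_seed(sp, list(
      radius = stats::runif(1, spec$tumor_radius_range[1],
                            spec$tumor_radius_range[2]),
      ratios = c(1, stats::runif(2, 0.75, 1))))
    mask <- generate_tumor_mask(geom$radius, spec$voxel_spacing,
                                geom$ratios)
    labels <- assign_habitats(mask, spec$habitat_proportions,
                              spec$spatial_clump,
                              seed = derive_seed(sp, 2))
    study <- render_dce(labels, spec, seed = derive_seed(sp, 3),
                        pid = pids[i])
    fv <- habitat_feature_vector(labels, mask = mask,
                                 spacing = spec$voxel_spacing)
    feats <- rbind(feats, fv)
    patients[[i]] <- list(pid = pids[i], study = study,
                          true_habitat_map = labels)
  }
  rownames(feats) <- pids
  clin <- simulate_clinical(n, seed = derive_seed(spec$seed, 7001))
  cm <- encode_clinical(clin)
  cc <- spec$survival$clinical_coefficients %||% numeric(0)
  lp_clin <- if (length(cc)) drop(cm[, names(cc), drop = FALSE] %*% cc)
             else rep(0, n)
  sv <- simulate_survival(feats, spec$survival$coefficients,
                          h_base = spec$survival$h_base,
                          censor_time = spec$survival$censor_time,
                          seed = derive_seed(spec$seed, 7002),
                          lp_offset = lp_clin)
  for (i in seq_len(n)) {
    patients[[i]]$lp <- sv$lp[i]
    patients[[i]]$time <- sv$time[i]
    patients[[i]]$event <- sv$event[i]
  }
  structure(list(patients = patients, clinical = clin, clinical_matrix = cm,
                 features = feats,
                 surv = data.frame(pid = pids, time_months = sv$time,
                                   event = sv$event),
                 spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic %s cohort: %d patients, %d events\n",
              x$spec$cohort, length(x$patients), sum(x$surv$event)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Per patient: the four NIfTI volumes of \code{\link{write_study}} plus
#' the ground-truth habitat label volume; one clinical CSV for the cohort
#' (pid, time_months, event, covariates); and a JSON manifest listing
#' patients, files and the generating seed.  A round-trip through
#' \code{\link{read_cohort}} reproduces voxel arrays exactly.
#'
#' @param cohort a \code{synthetic_cohort}.
#' @param dir output directory.
#' @return invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir, call. = FALSE)
  files <- list()
  for (p in cohort$patients) {
    paths <- write_study(p$study, dir)
    tp <- file.path(dir, paste0(p$pid, "_truehabitat.nii.gz"))
    write_volume_nifti(p$true_habitat_map, p$study$spacing, tp)
    files[[p$pid]] <- basename(c(paths, tp))
  }
  clin <- cbind(pid = cohort$surv$pid,
                time_months = cohort$surv$time_months,
                event = cohort$surv$event, cohort$clinical)
  utils::write.csv(clin, file.path(dir, "clinical.csv"), row.names = FALSE)
  manifest <- list(cohort = cohort$spec$cohort,
                   n_patients = length(cohort$patients),
                   pids = vapply(cohort$patients, `[[`, "", "pid"),
                   seed = cohort$spec$seed,
                   spacing = cohort$spec$voxel_spacing,
                   files = files, clinical = "clinical.csv")
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, digits = NA, auto_unbox = TRUE)
  invisible(mp)
}

#' Read a cohort directory written by \code{write_cohort}
#'
#' @param dir cohort directory containing \code{manifest.json}.
#' @return list with \code{studies} (named list of \code{dce_study}),
#'   \code{truth} (named list of label volumes), \code{clinical}
#'   (data.frame), \code{manifest}.
#' @export
read_cohort <- function(dir) {
  mp <- file.path(dir, "manifest.json")
  if (!file.exists(mp)) stop("no manifest.json in ", dir, call. = FALSE)
  manifest <- jsonlite::read_json(mp, simplifyVector = TRUE)
  studies <- list(); truth <- list()
  for (pid in manifest$pids) {
    studies[[pid]] <- read_study(dir, pid, cohort = manifest$cohort)
    tp <- file.path(dir, paste0(pid, "_truehabitat.nii.gz"))
    if (file.exists(tp)) {
      v <- read_volume_nifti(tp)$data
      truth[[pid]] <- array(as.integer(round(v)), dim(v))
    }
  }
  clinical <- utils::read.csv(file.path(dir, manifest$clinical))
  list(studies = studies, truth = truth, clinical = clinical,
       manifest = manifest)
}
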