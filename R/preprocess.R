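# Conform studies to isotropic resolution and harmonize cohort intensities.

# ---- cubic B-spline interpolation ------------------------------------------
# Interpolating cubic B-splines need a prefilter turning samples into spline
# coefficients (recursive filter with pole sqrt(3) - 2, mirror boundaries);
# evaluation then combines the 4 nearest coefficients with the cubic kernel.

bspline_kernel <- function(x) {
  ax <- abs(x)
  ifelse(ax < 1, 2 / 3 - ax^2 + ax^3 / 2,
         ifelse(ax < 2, (2 - ax)^3 / 6, 0))
}

# Prefilter along the first margin of a matrix (columns are independent runs).
bspline_prefilter_mat <- function(x) {
  n <- nrow(x)
  if (n == 1L) return(x)
  z <- sqrt(3) - 2
  c_p <- x * 6
  # causal init: c+[1] = sum_k x6[k] z^(k-1) over the mirror-extended signal,
  # truncated at machine precision
  horizon <- ceiling(log(.Machine$double.eps) / log(abs(z)))
  pos <- (seq_len(horizon) - 1) %% (2 * n - 2)
  pos <- ifelse(pos >= n, 2 * n - 2 - pos, pos)
  w <- z^(seq_len(horizon) - 1)
  c_p[1, ] <- drop(w %*% x[pos + 1, , drop = FALSE]) * 6
  for (k in 2:n) c_p[k, ] <- c_p[k, ] + z * c_p[k - 1, ]
  c_m <- c_p
  c_m[n, ] <- (z / (z^2 - 1)) * (c_p[n, ] + z * c_p[n - 1, ])
  for (k in (n - 1):1) c_m[k, ] <- z * (c_m[k + 1, ] - c_p[k, ])
  c_m
}

bspline_prefilter_axis <- function(vol, axis) {
  d <- dim(vol)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  v <- aperm(vol, perm)
  dv <- dim(v)
  m <- bspline_prefilter_mat(matrix(v, nrow = dv[1]))
  aperm(array(m, dv), order(perm))
}

# Weight matrix mapping n_in spline coefficients to values at positions u
# (0-based input-index units); mirror boundary for out-of-range support.
bspline_weights <- function(u, n_in) {
  W <- matrix(0, length(u), n_in)
  base <- floor(u)
  for (off in -1:2) {
    idx <- base + off
    w <- bspline_kernel(u - idx)
    idx <- ifelse(idx < 0, -idx, idx)
    idx <- ifelse(idx > n_in - 1, 2 * (n_in - 1) - idx, idx)
    idx <- pmax(pmin(idx, n_in - 1), 0)
    W[cbind(seq_along(u), idx + 1)] <- W[cbind(seq_along(u), idx + 1)] + w
  }
  W
}

resample_grid <- function(n_in, sp_in, sp_out) {
  n_out <- max(1L, as.integer(round(n_in * sp_in / sp_out)))
  u <- (seq_len(n_out) - 1) * sp_out / sp_in
  list(n_out = n_out, u = u)
}

interp_bspline_3d <- function(vol, spacing, new_spacing) {
  co <- vol
  for (ax in 1:3) co <- bspline_prefilter_axis(co, ax)
  for (ax in 1:3) {
    g <- resample_grid(dim(co)[ax], spacing[ax], new_spacing[ax])
    co <- apply_axis(co, bspline_weights(g$u, dim(co)[ax]), ax)
  }
  co
}

interp_nearest_3d <- function(vol, spacing, new_spacing) {
  idx <- lapply(1:3, function(ax) {
    g <- resample_grid(dim(vol)[ax], spacing[ax], new_spacing[ax])
    pmin(pmax(round(g$u) + 1, 1), dim(vol)[ax])
  })
  vol[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Resample a DCE study to isotropic resolution
#'
#' Intensity volumes are interpolated with interpolating cubic B-splines
#' (recursive prefilter, mirror boundaries); the ROI mask uses
#' nearest-neighbor interpolation and stays binary.  The output grid keeps
#' the input origin and covers the same physical extent to within one
#' voxel.  B-spline overshoot near sharp edges is clipped at 0, since
#' negative MR magnitudes are non-physical.
#'
#' @param study a \code{dce_study}.
#' @param new_spacing target spacing in mm (default 1 mm isotropic).
#' @return a \code{dce_study} on the new grid.
#' @export
resample_isotropic <- function(study, new_spacing = c(1, 1, 1)) {
  stopifnot(inherits(study, "dce_study"))
  new_spacing <- rep_len(as.numeric(new_spacing), 3)
  if (any(new_spacing <= 0)) stop("target spacing must be positive",
                                  call. = FALSE)
  if (any(dim(study$pre) * study$spacing <= 0) ||
      prod(dim(study$pre)) == 0)
    stop("degenerate (zero-extent) volume", call. = FALSE)
  resI <- function(v) {
    out <- interp_bspline_3d(v, study$spacing, new_spacing)
    out[out < 0] <- 0
    out
  }
  roi <- interp_nearest_3d(study$roi + 0, study$spacing, new_spacing) > 0.5
  if (!any(roi))
    stop("ROI vanished during resampling (tumor smaller than target voxel)",
         call. = FALSE)
  dce_study(resI(study$pre), resI(study$early), resI(study$delayed),
            roi, spacing = new_spacing, pid = study$pid,
            cohort = study$cohort)
}

# ---- histogram matching ----------------------------------------------------

#' Build the development-cohort reference intensity histogram
#'
#' Pools ROI voxels of every development study per phase and stores an
#' \code{n_quantiles}-point quantile table.  The table is the fixed target
#' distribution to which validation-cohort intensities are matched; it is
#' computed from tumor (ROI) voxels only so that background air does not
#' dominate the mapping.
#'
#' @param studies list of \code{dce_study} objects (development cohort).
#' @param n_quantiles number of quantile anchors (default 256, mirroring
#'   the 256-level quantization used downstream).
#' @return an object of class \code{reference_histogram}: per-phase
#'   quantile tables on probabilities \code{seq(0, 1, length.out =
#'   n_quantiles)}.
#' @export
build_reference_histogram <- function(studies, n_quantiles = 256) {
  if (length(studies) < 1) stop("need at least one development study",
                                call. = FALSE)
  probs <- seq(0, 1, length.out = n_quantiles)
  phases <- c("pre", "early", "delayed")
  tab <- lapply(phases, function(ph) {
    pool <- unlist(lapply(studies, function(s) s[[ph]][s$roi]),
                   use.names = FALSE)
    if (length(pool) == 0) stop("empty ROI intensity pool", call. = FALSE)
    unname(stats::quantile(pool, probs, type = 7))
  })
  names(tab) <- phases
  structure(list(quantiles = tab, probs = probs, n_quantiles = n_quantiles),
            class = "reference_histogram")
}

match_one <- function(vol, roi, ref_q, probs) {
  src <- unname(stats::quantile(vol[roi], probs, type = 7))
  # collapse duplicated source quantiles so the mapping is a function
  keep <- !duplicated(src)
  if (sum(keep) == 1) return(array(ref_q[keep][1], dim(vol)))
  out <- stats::approx(src[keep], ref_q[keep], xout = as.vector(vol),
                       rule = 2, ties = "ordered")$y
  array(out, dim(vol))
}

#' Harmonize a study's intensities to the development-cohort reference
#'
#' Per phase, maps source quantiles (computed over the study's ROI voxels)
#' to the reference quantiles by monotone piecewise-linear interpolation.
#' The mapping is estimated on tumor voxels but applied to the whole
#' volume; values outside the source range clamp to the reference extremes.
#'
#' @param study a \code{dce_study} (typically validation cohort).
#' @param reference a \code{reference_histogram} built from the development
#'   cohort.
#' @return the harmonized \code{dce_study}.
#' @export
histogram_match <- function(study, reference) {
  stopifnot(inherits(study, "dce_study"),
            inherits(reference, "reference_histogram"))
  phases <- c("pre", "early", "delayed")
  if (!all(phases %in% names(reference$quantiles)))
    stop("reference is missing a phase", call. = FALSE)
  vols <- lapply(phases, function(ph)
    match_one(study[[ph]], study$roi,
              reference$quantiles[[ph]], reference$probs))
  dce_study(vols[[1]], vols[[2]], vols[[3]], study$roi,
            spacing = study$spacing, pid = study$pid, cohort = study$cohort)
}

#' Serialize / read a reference histogram as JSON
#' @param reference a \code{reference_histogram}.
#' @param path file path.
#' @return \code{path} (write) or the object (read).
#' @export
write_reference_histogram <- function(reference, path) {
  jsonlite::write_json(unclass(reference), path, digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_reference_histogram
#' @export
read_reference_histogram <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(quantiles = as.list(x$quantiles), probs = x$probs,
                 n_quantiles = x$n_quantiles),
            class = "reference_histogram")
}
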