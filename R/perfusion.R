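#' Compute voxelwise perfusion parametric maps
#'
#' Derives the three kinetic maps from a three-phase DCE-MRI study:
#' wash-in \eqn{E_{in} = I_{early} - I_{pre}}, washout
#' \eqn{E_{out} = I_{early} - I_{delayed}}, and the washout ratio
#' \eqn{R_{WO} = (I_{early} - I_{delayed}) / I_{early}} when
#' \eqn{I_{delayed} < I_{early}} and 0 otherwise (no washout).  A delayed
#' signal at or above the early signal therefore yields a negative or zero
#' washout but a washout ratio of exactly 0.  \eqn{R_{WO}} is also defined
#' as 0 where \eqn{I_{early} = 0} so the map is total on clipped
#' (non-negative) intensities.
#'
#' @param study a \code{dce_study} (see \code{\link{dce_study}}).
#' @param roi_only logical; if \code{TRUE} (default) the maps are \code{NA}
#'   outside the ROI, the form consumed by clustering and feature
#'   extraction.  Set \code{FALSE} for whole-volume maps (visualization).
#' @return an object of class \code{perfusion_maps}: list with 3D arrays
#'   \code{ein}, \code{eout}, \code{rwo}, the \code{roi} mask, the patient
#'   id \code{pid} and voxel \code{spacing}.
#' @examples
#' s <- dce_study(pre = array(500, c(2, 2, 2)), early = array(2000, c(2, 2, 2)),
#'                delayed = array(1000, c(2, 2, 2)),
#'                roi = array(TRUE, c(2, 2, 2)), spacing = c(1, 1, 1))
#' m <- compute_perfusion_maps(s)
#' m$ein[1]  # 1500
#' m$rwo[1]  # 0.5
#' @export
compute_perfusion_maps <- function(study, roi_only = TRUE) {
  stopifnot(inherits(study, "dce_study"))
  d <- dim(study$pre)
  if (!identical(d, dim(study$early)) || !identical(d, dim(study$delayed)) ||
      !identical(d, dim(study$roi)))
    stop("phase volumes and ROI must share a common grid", call. = FALSE)
  ein <- study$early - study$pre
  eout <- study$early - study$delayed
  rwo <- ifelse(study$delayed < study$early & study$early > 0,
                eout / study$early, 0)
  if (roi_only) {
    out <- !study$roi
    ein[out] <- NA_real_
    eout[out] <- NA_real_
    rwo[out] <- NA_real_
  }
  structure(list(ein = ein, eout = eout, rwo = rwo, roi = study$roi,
                 pid = study$pid, spacing = study$spacing),
            class = "perfusion_maps")
}

#' Extract the perfusion feature vectors (PFVs) of a study's ROI voxels
#'
#' One row per ROI voxel with columns \code{ein}, \code{eout}, \code{rwo}
#' plus back-pointers \code{pid} and linear \code{voxel} index, the unit
#' pooled across a cohort before population-level clustering.
#'
#' @param maps a \code{perfusion_maps} object.
#' @return a data.frame with columns pid, voxel, ein, eout, rwo.
#' @export
pfv_table <- function(maps) {
  stopifnot(inherits(maps, "perfusion_maps"))
  idx <- which(maps$roi)
  data.frame(pid = rep(maps$pid %||% NA_character_, length(idx)),
             voxel = idx,
             ein = maps$ein[idx], eout = maps$eout[idx], rwo = maps$rwo[idx],
             stringsAsFactors = FALSE)
}

#' @export
print.perfusion_maps <- function(x, ...) {
  cat("Perfusion maps", if (!is.null(x$pid)) paste0("for ", x$pid), "\n")
  cat("  grid: ", paste(dim(x$ein), collapse = " x "),
      " voxels, ROI ", sum(x$roi), " voxels\n", sep = "")
  r <- range(x$ein[x$roi])
  cat(sprintf("  wash-in range inside ROI: [%.1f, %.1f]\n", r[1], r[2]))
  invisible(x)
}
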