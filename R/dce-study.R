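#' Construct a three-phase DCE-MRI study
#'
#' Container for one patient's pre-contrast, early-phase and delayed-phase
#' T1-weighted volumes plus the tumor ROI mask, voxel spacing and cohort
#' label.  All downstream operations (resampling, harmonization, perfusion
#' maps, habitat assignment) consume this object.
#'
#' @param pre,early,delayed 3D numeric arrays on a common grid.
#' @param roi 3D logical (or 0/1) array, the tumor mask.
#' @param spacing numeric length-3 voxel spacing in mm.
#' @param pid patient identifier.
#' @param cohort \code{"development"} or \code{"validation"}.
#' @return an object of class \code{dce_study}.
#' @export
dce_study <- function(pre, early, delayed, roi, spacing,
                      pid = "p1", cohort = "development") {
  stopifnot_volume(pre); stopifnot_volume(early); stopifnot_volume(delayed)
  roi <- array(as.logical(roi), dim = dim(roi))
  d <- dim(pre)
  if (!identical(d, dim(early)) || !identical(d, dim(delayed)) ||
      !identical(d, dim(roi)))
    stop("all volumes and the ROI must share one grid", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three positive mm values", call. = FALSE)
  if (!any(roi)) stop("ROI mask is empty", call. = FALSE)
  cohort <- match.arg(cohort, c("development", "validation"))
  structure(list(pre = pre, early = early, delayed = delayed, roi = roi,
                 spacing = spacing, pid = as.character(pid), cohort = cohort),
            class = "dce_study")
}

#' @export
print.dce_study <- function(x, ...) {
  cat(sprintf("DCE-MRI study %s (%s cohort)\n", x$pid, x$cohort))
  cat("  grid: ", paste(dim(x$pre), collapse = " x "),
      " voxels at ", paste(signif(x$spacing, 3), collapse = " x "),
      " mm\n", sep = "")
  cat("  ROI: ", sum(x$roi), " voxels (",
      signif(sum(x$roi) * prod(x$spacing) / 1000, 3), " mL)\n", sep = "")
  invisible(x)
}

# ---- NIfTI I/O -------------------------------------------------------------

write_volume_nifti <- function(vol, spacing, path) {
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim = dim(img)),
       spacing = RNifti::pixdim(img)[seq_len(3)])
}

#' Write a DCE study to NIfTI files
#'
#' Emits \code{{pid}_pre.nii.gz}, \code{{pid}_early.nii.gz},
#' \code{{pid}_delayed.nii.gz} and \code{{pid}_mask.nii.gz} in \code{dir}.
#'
#' @param study a \code{dce_study}.
#' @param dir output directory (created if needed).
#' @return invisibly, the four file paths.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "dce_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir, call. = FALSE)
  paths <- file.path(dir, paste0(study$pid, "_",
                                 c("pre", "early", "delayed", "mask"),
                                 ".nii.gz"))
  write_volume_nifti(study$pre, study$spacing, paths[1])
  write_volume_nifti(study$early, study$spacing, paths[2])
  write_volume_nifti(study$delayed, study$spacing, paths[3])
  write_volume_nifti(study$roi + 0, study$spacing, paths[4])
  invisible(paths)
}

#' Read a DCE study written by \code{write_study}
#'
#' @param dir directory holding the four per-patient NIfTI files.
#' @param pid patient identifier (file-name prefix).
#' @param cohort cohort label to attach.
#' @return a \code{dce_study}.
#' @export
read_study <- function(dir, pid, cohort = "development") {
  rd <- function(part) read_volume_nifti(
    file.path(dir, paste0(pid, "_", part, ".nii.gz")))
  pre <- rd("pre"); early <- rd("early"); delayed <- rd("delayed")
  mask <- rd("mask")
  dce_study(pre$data, early$data, delayed$data, mask$data > 0.5,
            spacing = pre$spacing, pid = pid, cohort = cohort)
}
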