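# Reading, validating and writing 4D binary segmentation series.
#
# Geometry convention: voxel (i,j,k) (1-based in R) has world position
# origin + (i-1, j-1, k-1) * spacing, in mm (RAS). Only axis-aligned,
# positive-diagonal affines are supported; oblique acquisitions must be
# resampled upstream.

#' Construct a segmentation series
#'
#' Bundles a 4D binary voxel array (x, y, z, phase) with its world-coordinate
#' geometry. Phase indexing is 0-based in all reported curves ("cardiac phase
#' 1" of clinical convention is phase 0 here, the end-diastolic reference).
#'
#' @param voxels 4D array with values in \{0, 1\}; 4th axis is cardiac phase.
#' @param spacing numeric length-3, voxel size in mm (all > 0).
#' @param origin numeric length-3, world position (mm) of voxel (1,1,1).
#' @param phase_duration_ms optional scalar, duration of one phase in ms.
#' @return An object of class `seg_series`.
#' @export
seg_series <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       phase_duration_ms = NULL) {
  if (length(dim(voxels)) != 4L)
    abort_input("`voxels` must be a 4D array (x, y, z, phase)")
  if (any(spacing <= 0)) abort_input("all spacing components must be > 0")
  if (dim(voxels)[4] < 2L) abort_input("a series needs at least 2 phases")
  vr <- range(voxels)
  if (vr[1] < -1e-6 || vr[2] > 1 + 1e-6 ||
      any(abs(voxels - round(voxels)) > 1e-6))
    abort_input("voxel values must be binary {0,1} (tolerance 1e-6)")
  storage.mode(voxels) <- "integer"
  if (sum(voxels) == 0L) abort_input("empty foreground")
  structure(list(voxels = voxels,
                 spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 n_phases = dim(voxels)[4],
                 phase_duration_ms = phase_duration_ms),
            class = "seg_series")
}

#' @export
print.seg_series <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<seg_series> %d x %d x %d voxels, %d phases\n", d[1], d[2],
              d[3], x$n_phases))
  cat(sprintf("  spacing: %s mm, origin: %s mm\n",
              paste(signif(x$spacing, 6), collapse = " x "),
              paste(signif(x$origin, 6), collapse = ", ")))
  cat(sprintf("  foreground voxels (phase 0): %d\n", sum(x$voxels[, , , 1])))
  invisible(x)
}

# 4x4 voxel->world affine for the axis-aligned geometry (0-based indices)
series_affine <- function(series) {
  aff <- diag(4)
  diag(aff)[1:3] <- series$spacing
  aff[1:3, 4] <- series$origin
  aff
}

# check that a NIfTI affine is axis-aligned with positive scales and return
# list(spacing, origin)
parse_affine <- function(aff) {
  rot <- aff[1:3, 1:3]
  sp <- sqrt(colSums(rot^2))
  if (any(sp <= 0)) abort_input("degenerate affine in NIfTI header")
  dirs <- sweep(rot, 2, sp, "/")
  if (max(abs(dirs - diag(3))) > 1e-4)
    abort_input(paste0("only axis-aligned RAS affines are supported; ",
                       "resample oblique data upstream"))
  list(spacing = as.numeric(sp), origin = as.numeric(aff[1:3, 4]))
}

#' Read a segmentation series from NIfTI
#'
#' Accepts either a single 4D NIfTI-1 file or an ordered character vector of
#' 3D per-phase files sharing one geometry.
#'
#' @param path file path (4D) or character vector of per-phase 3D file paths.
#' @return A [seg_series()].
#' @export
read_series <- function(path) {
  if (length(path) == 1L) {
    img <- RNifti::readNifti(path)
    arr <- array(as.vector(img), dim(img))  # plain array, header attrs dropped
    if (length(dim(arr)) == 3L) abort_input("expected a 4D volume or a vector of 3D volumes")
    if (length(dim(arr)) != 4L) abort_input("expected 4D NIfTI data")
    geo <- parse_affine(RNifti::xform(img))
    pd <- attr(img, "pixdim")
    phase_ms <- if (length(pd) >= 4 && pd[4] > 0 && pd[4] < 10) pd[4] * 1000 else
      if (length(pd) >= 4 && pd[4] >= 10) pd[4] else NULL
    return(seg_series(arr, spacing = geo$spacing, origin = geo$origin,
                      phase_duration_ms = phase_ms))
  }
  vols <- lapply(path, RNifti::readNifti)
  geos <- lapply(vols, function(v) parse_affine(RNifti::xform(v)))
  g0 <- geos[[1]]
  for (g in geos)
    if (max(abs(g$spacing - g0$spacing)) > 1e-6 ||
        max(abs(g$origin - g0$origin)) > 1e-6)
      abort_input("per-phase volumes do not share one geometry")
  arrs <- lapply(vols, as.array)
  d0 <- dim(arrs[[1]])
  if (length(d0) != 3L) abort_input("per-phase files must be 3D volumes")
  for (a in arrs)
    if (!identical(dim(a), d0)) abort_input("per-phase volumes differ in size")
  arr <- array(0L, c(d0, length(arrs)))
  for (t in seq_along(arrs)) arr[, , , t] <- arrs[[t]]
  seg_series(arr, spacing = g0$spacing, origin = g0$origin)
}

#' Write a segmentation series as 4D NIfTI-1
#'
#' Data are written as uint8 with the series' axis-aligned RAS affine.
#'
#' @param series a [seg_series()].
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "seg_series"))
  aff <- structure(series_affine(series), code = 2L)
  arr <- series$voxels
  attr(arr, "pixdim") <- c(series$spacing, 1)
  img <- RNifti::asNifti(arr)
  img <- RNifti::`qform<-`(img, aff)
  img <- RNifti::`sform<-`(img, aff)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Validate a segmentation series
#'
#' Automated quality gate standing in for manual review of segmentations:
#' each phase must contain exactly one 26-connected foreground component and
#' the foreground must keep a 1-voxel margin from the array boundary.
#' Failures are reported, not repaired: silently keeping e.g. the largest
#' component would hide segmentation faults that should exclude the dataset.
#'
#' @param series a [seg_series()].
#' @return A `seg_validation` object: per-phase tibble plus overall verdict.
#' @export
validate_series <- function(series) {
  stopifnot(inherits(series, "seg_series"))
  d <- dim(series$voxels)
  rep <- lapply(seq_len(series$n_phases), function(t) {
    vox <- series$voxels[, , , t]
    lab <- cpp_label_components(as.integer(vox), dim(vox))
    ncomp <- attr(lab, "n_components")
    margin_bad <- any(vox[c(1, d[1]), , ] != 0) ||
      any(vox[, c(1, d[2]), ] != 0) || any(vox[, , c(1, d[3])] != 0)
    tibble(phase = t - 1L, n_components = ncomp,
           foreground_voxels = sum(vox), margin_violation = margin_bad,
           pass = ncomp == 1L && !margin_bad && sum(vox) > 0L)
  })
  rep <- dplyr::bind_rows(rep)
  structure(list(per_phase = rep, verdict = all(rep$pass)),
            class = "seg_validation")
}

#' @export
print.seg_validation <- function(x, ...) {
  cat(sprintf("<seg_validation> verdict: %s\n",
              if (x$verdict) "PASS" else "FAIL"))
  bad <- dplyr::filter(x$per_phase, !.data$pass)
  if (nrow(bad) > 0) {
    cat("  failing phases:\n")
    print(bad)
  }
  invisible(x)
}

#' Serialize a validation report to JSON
#' @param report a `seg_validation` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_validation <- function(report, path) {
  jsonlite::write_json(list(verdict = report$verdict,
                            per_phase = report$per_phase),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# internal: single-phase view with cached geometry
series_phase <- function(series, phase) {
  stopifnot(phase >= 0, phase < series$n_phases)
  vox <- series$voxels[, , , phase + 1L, drop = TRUE]
  list(vox = vox, dim = dim(vox), spacing = series$spacing,
       origin = series$origin, phase = phase)
}

world_to_voxel <- function(phase, pts) {
  pts <- rbind(pts)
  sweep(sweep(pts, 2, phase$origin, "-"), 2, phase$spacing, "/")
}

voxel_to_world <- function(phase, idx0) {
  idx0 <- rbind(idx0)
  sweep(sweep(idx0, 2, phase$spacing, "*"), 2, phase$origin, "+")
}
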