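# Lumen surface extraction and non-rigid registration (coherent point drift).

#' Extract the lumen iso-surface of one phase
#'
#' The binary mask is lightly Gaussian-smoothed (default sigma 0.8 voxel,
#' balancing staircase inflation against curvature shrinkage) and the 0.5
#' level set is triangulated by marching tetrahedra (watertight). Outward
#' normals come from the negated smoothed-field gradient.
#'
#' @param phase a single-phase view from [series_phase_view()].
#' @param sigma_vox Gaussian smoothing in voxel units.
#' @return An `aorta_surface`: vertices (world mm), outward unit normals,
#'   triangles, phase index and provenance.
#' @export
extract_surface <- function(phase, sigma_vox = 0.8) {
  if (sum(phase$vox) == 0) abort_input("empty mask")
  # crop to the foreground bounding box (padded) before smoothing
  idx <- which(phase$vox == 1L, arr.ind = TRUE)
  pad <- as.integer(ceiling(3 * sigma_vox)) + 1L
  lo <- pmax(apply(idx, 2, min) - pad, 1L)
  hi <- pmin(apply(idx, 2, max) + pad, phase$dim)
  sub <- phase$vox[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sub_origin <- phase$origin + (lo - 1) * phase$spacing
  sm <- cpp_gauss_smooth(as.numeric(sub), dim(sub), sigma_vox)
  surf <- cpp_march_tets(sm, dim(sub), sub_origin, phase$spacing, 0.5)
  if (nrow(surf$vertices) < 12)
    abort_input("degenerate surface (mask too small)")
  g <- cpp_gradient_at(sm, dim(sub), sub_origin, phase$spacing,
                       surf$vertices)
  nrm <- -g / pmax(sqrt(rowSums(g^2)), 1e-12)
  structure(list(vertices = surf$vertices, normals = nrm,
                 triangles = surf$triangles, phase = phase$phase,
                 provenance = list(sigma_vox = sigma_vox, level = 0.5)),
            class = "aorta_surface")
}

#' @export
print.aorta_surface <- function(x, ...) {
  cat(sprintf("<aorta_surface> phase %d: %d vertices, %d triangles, area %.0f mm^2\n",
              x$phase, nrow(x$vertices), nrow(x$triangles), surface_area(x)))
  invisible(x)
}

#' Total triangulated surface area
#' @param surface an `aorta_surface`.
#' @return Area in mm^2.
#' @export
surface_area <- function(surface) {
  V <- surface$vertices; Tm <- surface$triangles
  a <- V[Tm[, 1], , drop = FALSE]
  b <- V[Tm[, 2], , drop = FALSE] - a
  cc <- V[Tm[, 3], , drop = FALSE] - a
  cr <- cbind(b[, 2] * cc[, 3] - b[, 3] * cc[, 2],
              b[, 3] * cc[, 1] - b[, 1] * cc[, 3],
              b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Decimate a surface to a fixed point count
#'
#' Farthest-point sampling from vertex 1 (fixed start, hence deterministic
#' and uniformly covering).
#'
#' @param surface an `aorta_surface` (or a vertex matrix).
#' @param n target point count.
#' @return List with `points` (n x 3) and `index` into the vertices.
#' @export
decimate_surface <- function(surface, n = 1500) {
  V <- if (inherits(surface, "aorta_surface")) surface$vertices else surface
  idx <- cpp_fps(V, as.integer(n), 0L)
  list(points = V[idx, , drop = FALSE], index = idx)
}

#' Registration parameters
#'
#' Controls the two-stage non-rigid registration. Stage 1 is coherent point
#' drift (CPD) with a stiff Gaussian motion-coherence kernel (`beta_mm`):
#' wide coherence is what makes bulk motion such as root translation
#' recoverable on a locally cylindrical vessel, where point-wise
#' correspondence alone only sees the surface-normal component of motion
#' (the aperture problem). Stage 2 refines the residual along the reference
#' surface normals only (`refine_beta_mm` kernel): dilation of the lumen is
#' a normal motion, and restricting the fine scale to the normal direction
#' removes tangential correspondence jitter between the two decimated point
#' sets. `lambda` trades data fit against deformation smoothness; `w` is the
#' expected outlier fraction (0 for clean segmentation surfaces). Fields are
#' expanded in the leading `rank` eigenmodes of the coherence kernel
#' (low-rank CPD). `interp_h_mm` is the kernel width for interpolating
#' displacements off the decimated points (landmark/seed transport).
#'
#' @param beta_mm stage-1 coherence kernel width (mm).
#' @param lambda stage-1 regularization weight.
#' @param w outlier weight in `[0, 1)`.
#' @param max_iter maximum EM iterations per stage.
#' @param tol relative sigma^2 convergence tolerance.
#' @param decimate target decimated point count per surface.
#' @param rank number of kernel eigenmodes per stage.
#' @param refine logical: run the normal-constrained refinement stage
#'   (requires surface normals on the reference).
#' @param refine_beta_mm stage-2 kernel width (mm).
#' @param refine_lambda stage-2 regularization weight.
#' @param interp_h_mm interpolation kernel width (mm).
#' @return A `registration_params` object.
#' @export
registration_params <- function(beta_mm = 25, lambda = 2, w = 0,
                                max_iter = 150, tol = 1e-5, decimate = 1500,
                                rank = 300, refine = TRUE,
                                refine_beta_mm = 10, refine_lambda = 4,
                                refine_rank = 100, interp_h_mm = 2) {
  if (beta_mm <= 0 || lambda <= 0 || w < 0 || w >= 1 ||
      refine_beta_mm <= 0 || refine_lambda <= 0)
    abort_input("invalid registration parameters (need beta>0, lambda>0, 0<=w<1)")
  structure(list(beta_mm = beta_mm, lambda = lambda, w = w,
                 max_iter = max_iter, tol = tol, decimate = decimate,
                 rank = rank, refine = refine,
                 refine_beta_mm = refine_beta_mm,
                 refine_lambda = refine_lambda,
                 refine_rank = refine_rank,
                 interp_h_mm = interp_h_mm),
            class = "registration_params")
}

# kernel eigenbases for a fixed decimated reference (reused across phases)
reference_basis <- function(ref_points, params) {
  k1 <- as.integer(min(params$rank, nrow(ref_points)))
  k2 <- as.integer(min(params$refine_rank %||% params$rank,
                       nrow(ref_points)))
  list(stage1 = cpp_kernel_eig(ref_points, params$beta_mm, k1),
       stage2 = if (isTRUE(params$refine))
         cpp_kernel_eig(ref_points, params$refine_beta_mm, k2) else NULL)
}

# decimate an aorta_surface (or matrix) keeping normals when available
decimate_with_normals <- function(obj, n) {
  if (inherits(obj, "aorta_surface")) {
    d <- decimate_surface(obj, n)
    list(points = d$points, normals = obj$normals[d$index, , drop = FALSE])
  } else {
    pts <- rbind(obj)
    if (nrow(pts) > n) pts <- decimate_surface(pts, n)$points
    list(points = pts, normals = NULL)
  }
}

#' Non-rigid registration of two surface point sets
#'
#' Two-stage coherent point drift (see [registration_params()]): a stiff
#' vector-field stage capturing bulk motion, then a refinement stage along
#' the reference surface normals capturing dilation. Deterministic for fixed
#' inputs and parameters. If the reference carries no normals (plain point
#' matrix), only stage 1 is run.
#'
#' @param ref,target `aorta_surface` objects or point matrices.
#' @param params a [registration_params()].
#' @param basis optional precomputed kernel eigenbases (internal reuse).
#' @param normals optional reference normals for decimated-point input.
#' @param w_init optional warm start: list with stage-1 matrix `W1` and
#'   stage-2 vector `w2`.
#' @return List: `ref_points` (decimated), `normals`, `displacements`,
#'   warm-start state `W`, and `diagnostics` (per-stage iterations, final
#'   sigma2, residual, converged).
#' @export
register_nonrigid <- function(ref, target, params = registration_params(),
                              basis = NULL, normals = NULL, w_init = NULL) {
  dref <- decimate_with_normals(ref, params$decimate)
  Y <- dref$points
  if (is.null(normals)) normals <- dref$normals
  Xfull <- if (inherits(target, "aorta_surface")) target$vertices else
    rbind(target)
  if (nrow(Y) == 0 || nrow(Xfull) == 0) abort_input("empty point set")
  X <- if (nrow(Xfull) > params$decimate)
    decimate_surface(Xfull, params$decimate)$points else Xfull
  refine <- isTRUE(params$refine) && !is.null(normals)
  if (is.null(basis)) basis <- reference_basis(Y, params)
  W1 <- if (!is.null(w_init)) w_init$W1 else matrix(0, nrow(Y), 3)
  r1 <- cpp_cpd_nonrigid(X, Y, basis$stage1$Q, basis$stage1$lam,
                         params$lambda, params$w,
                         as.integer(params$max_iter), params$tol, W1, -1)
  V <- r1$V
  it2 <- 0L
  r2 <- NULL
  if (refine) {
    w2 <- if (!is.null(w_init) && !is.null(w_init$w2)) w_init$w2 else
      rep(0, nrow(Y))
    r2 <- cpp_cpd_normal(X, Y + r1$V, normals, basis$stage2$Q,
                         basis$stage2$lam, params$refine_lambda, params$w,
                         as.integer(params$max_iter), params$tol, w2, -1)
    V <- r1$V + r2$V
    it2 <- r2$iterations
  }
  conv <- r1$converged && (is.null(r2) || r2$converged)
  resid <- if (is.null(r2)) r1$residual else r2$residual
  if (!conv)
    warning(sprintf("registration did not converge in %d iterations (residual %.3g mm)",
                    params$max_iter, resid))
  list(ref_points = Y, normals = normals, displacements = V,
       W = list(W1 = r1$W, w2 = if (is.null(r2)) NULL else r2$w),
       diagnostics = tibble(iterations = r1$iterations + it2,
                            sigma2 = if (is.null(r2)) r1$sigma2 else r2$sigma2,
                            residual = resid, converged = conv))
}

#' Displacement field of a series
#'
#' Registers the end-diastolic (phase 0) lumen surface to every other phase
#' independently and stores per-point displacement vectors on the decimated
#' reference surface. Phases with bit-identical masks share one registration
#' (deterministic reuse); EM is warm-started from the previous phase, which
#' does not change the fixed-point problem, only convergence speed.
#'
#' @param series a validated [seg_series()].
#' @param params a [registration_params()].
#' @param sigma_vox surface-extraction smoothing.
#' @return An `aorta_displacement_field`: decimated reference points,
#'   displacement array (n_phases x n_points x 3, phase 0 identically zero),
#'   and per-phase diagnostics.
#' @export
displacement_field <- function(series, params = registration_params(),
                               sigma_vox = 1.0) {
  n <- series$n_phases
  ref_phase <- series_phase(series, 0)
  ref_surf <- extract_surface(ref_phase, sigma_vox)
  dec <- decimate_surface(ref_surf, params$decimate)
  Y <- dec$points
  Nrm <- ref_surf$normals[dec$index, , drop = FALSE]
  basis <- reference_basis(Y, params)

  disp <- array(0, c(n, nrow(Y), 3))
  diags <- vector("list", n)
  diags[[1]] <- tibble(phase = 0L, iterations = 0L, sigma2 = 0,
                       residual = 0, converged = TRUE, reused_from = NA_integer_)
  # group identical masks (cheap weak hash, verified with identical())
  keys <- vapply(seq_len(n) - 1L, function(t) {
    v <- series$voxels[, , , t + 1L]
    paste(sum(v), sum(v * seq(1, 7, length.out = length(v))))
  }, character(1))
  done <- list()  # key -> list(V, W, phase)
  done[[keys[1]]] <- list(V = matrix(0, nrow(Y), 3), W = NULL, phase = 0L)
  W_prev <- NULL
  for (t in seq_len(n - 1L)) {
    key <- keys[t + 1L]
    hit <- done[[key]]
    if (!is.null(hit) &&
        identical(series$voxels[, , , t + 1L],
                  series$voxels[, , , hit$phase + 1L])) {
      disp[t + 1L, , ] <- hit$V
      diags[[t + 1L]] <- tibble(phase = t, iterations = 0L, sigma2 = NA_real_,
                                residual = NA_real_, converged = TRUE,
                                reused_from = hit$phase)
      W_prev <- hit$W
      next
    }
    tgt_surf <- extract_surface(series_phase(series, t), sigma_vox)
    reg <- register_nonrigid(Y, tgt_surf$vertices, params, basis = basis,
                             normals = Nrm, w_init = W_prev)
    disp[t + 1L, , ] <- reg$displacements
    W_prev <- reg$W
    done[[key]] <- list(V = reg$displacements, W = reg$W, phase = t)
    diags[[t + 1L]] <- dplyr::mutate(reg$diagnostics, phase = t,
                                     reused_from = NA_integer_,
                                     .before = 1)
  }
  structure(list(ref_points = Y, ref_index = dec$index,
                 ref_surface = ref_surf, ref_normals = Nrm,
                 displacements = disp, params = params,
                 diagnostics = dplyr::bind_rows(diags)),
            class = "aorta_displacement_field")
}

#' @export
print.aorta_displacement_field <- function(x, ...) {
  mags <- sqrt(apply(x$displacements^2, 1, function(m)
    max(rowSums(matrix(m, ncol = 3)^2))))
  cat(sprintf("<aorta_displacement_field> %d phases x %d points; peak |u| %.2f mm\n",
              dim(x$displacements)[1], dim(x$displacements)[2], max(mags)))
  invisible(x)
}

#' Interpolate the displacement field at arbitrary points
#'
#' Normalized Gaussian-kernel interpolation from the decimated reference
#' points (bandwidth `interp_h_mm`).
#'
#' @param field an `aorta_displacement_field`.
#' @param points matrix (or length-3 vector) of world-mm query points.
#' @param phase 0-based phase.
#' @return Displacement matrix (n x 3).
#' @export
interp_displacement <- function(field, points, phase) {
  pts <- rbind(points)
  V <- field$displacements[phase + 1L, , , drop = TRUE]
  if (is.null(dim(V))) V <- matrix(V, ncol = 3)
  cpp_kernel_interp(pts, field$ref_points, V, field$params$interp_h_mm)
}

#' Transport a world point by the displacement field
#' @inheritParams interp_displacement
#' @return Transported point(s), same shape as `points`.
#' @export
transport_point <- function(field, points, phase) {
  rbind(points) + interp_displacement(field, points, phase)
}

#' Per-phase mean displacement magnitude in a plane band
#'
#' Mean Euclidean displacement of reference surface points within a band of
#' +-`band_mm` around the plane (and within the plane's in-plane extent).
#' The subject-level value is the maximum over phases (earliest phase wins
#' ties).
#'
#' @param field an `aorta_displacement_field`.
#' @param plane an `aorta_plane` (end-diastolic definition).
#' @param band_mm band half-width (mm).
#' @return List: `curve` tibble (phase, value) and `peak` (value, phase).
#' @export
mean_plane_displacement <- function(field, plane, band_mm = 2.5) {
  idx <- plane_band_index(plane, field$ref_points, band_mm)
  if (length(idx) < 10)
    abort_input(sprintf("only %d reference points in band of plane %s (need >= 10)",
                        length(idx), plane$label))
  n <- dim(field$displacements)[1]
  vals <- vapply(seq_len(n), function(t) {
    v <- field$displacements[t, idx, , drop = TRUE]
    if (length(idx) == 1L) v <- matrix(v, 1, 3)
    mean(sqrt(rowSums(v^2)))
  }, numeric(1))
  pk <- peak_value(vals)
  list(curve = tibble(phase = seq_len(n) - 1L, value = vals), peak = pk)
}

#' Export per-phase displacement point clouds as ASCII PLY
#'
#' One file per phase: reference points with displacement vector and
#' magnitude as per-vertex properties.
#'
#' @param field an `aorta_displacement_field`.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return Written file paths, invisibly.
#' @export
write_displacement_ply <- function(field, dir, prefix = "displacement") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- dim(field$displacements)[1]
  paths <- character(n)
  for (t in seq_len(n)) {
    V <- field$displacements[t, , , drop = TRUE]
    mag <- sqrt(rowSums(V^2))
    p <- file.path(dir, sprintf("%s_phase%02d.ply", prefix, t - 1L))
    hdr <- c("ply", "format ascii 1.0",
             sprintf("element vertex %d", nrow(field$ref_points)),
             "property float x", "property float y", "property float z",
             "property float ux", "property float uy", "property float uz",
             "property float magnitude", "end_header")
    body <- apply(cbind(field$ref_points, V, mag), 1, function(r)
      paste(formatC(r, format = "g", digits = 7), collapse = " "))
    writeLines(c(hdr, body), p)
    paths[t] <- p
  }
  invisible(paths)
}
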