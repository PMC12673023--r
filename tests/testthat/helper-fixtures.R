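# Shared fixtures, built once per test run and cached.
#
# The "small" phantom is a scaled-down aorta (coarser voxels, fewer phases)
# used by unit tests; acceptance tests build full-resolution phantoms
# themselves.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

small_spec <- function(a = 0.10, eps = 0, d = 0, n_phases = 6,
                       spacing = 1.5) {
  phantom_spec(arch_radius_mm = 30, asc_radius_mm = 10, desc_radius_mm = 8,
               root_length_mm = 18, desc_length_mm = 50,
               aao_length_mm = 55, spacing_mm = spacing,
               n_phases = n_phases, systole_fraction = 0.4,
               radial_amplitude_asc = a, radial_amplitude_desc = a,
               strain_amplitude = eps, root_displacement_mm = d)
}

# radial-only small phantom + series (most-used fixture)
small_radial <- function() fixture("small_radial", function() {
  spec <- small_spec(a = 0.10)
  c(build_phantom(spec), list(spec = spec, lm = phantom_landmarks(spec)))
})

# zero-deformation small phantom
small_null <- function() fixture("small_null", function() {
  spec <- small_spec(a = 0, eps = 0, d = 0, n_phases = 4)
  c(build_phantom(spec), list(spec = spec, lm = phantom_landmarks(spec)))
})

# axis-aligned voxelized cylinder (radius r, axis z, length ~ zlen);
# pass `pad` explicitly when several radii must share one grid
make_cylinder <- function(r, zlen = 60, spacing = 1, flat_ends = TRUE,
                          pad = ceiling(r + 4)) {
  dims <- as.integer(c(2 * pad + 2, 2 * pad + 2, zlen + 12))
  org <- c(-pad - 0.5, -pad - 0.5, -5.5)
  ctr <- cbind(0, 0, seq(0, zlen, by = spacing / 2))
  m <- aorta4d:::cpp_stamp_tube(dims, org, rep(spacing, 3), ctr,
                                rep(r, nrow(ctr)))
  if (flat_ends) {
    m <- aorta4d:::cpp_clip_halfspace(m, dims, org, rep(spacing, 3),
                                      c(0, 0, 0), c(0, 0, -1), 3 * r)
    m <- aorta4d:::cpp_clip_halfspace(m, dims, org, rep(spacing, 3),
                                      c(0, 0, zlen), c(0, 0, 1), 3 * r)
  }
  list(vox = array(m, dims), dim = dims, spacing = rep(spacing, 3),
       origin = org, phase = 0L)
}

# two-phase cylinder series (radius r0 -> r1) on one shared grid
cylinder_series <- function(r0, r1, zlen = 60) {
  pad <- ceiling(max(r0, r1) + 4)
  p0 <- make_cylinder(r0, zlen, pad = pad)
  p1 <- make_cylinder(r1, zlen, pad = pad)
  seg_series(array(c(p0$vox, p1$vox), c(p0$dim, 2)),
             spacing = p0$spacing, origin = p0$origin)
}

# full subject panel on the small radial phantom (reused across tests)
small_subject <- function() fixture("small_subject", function() {
  ph <- small_radial()
  suppressWarnings(compute_subject(
    ph$series, ph$lm, blood_pressure(128, 80),
    subject_params(reg = registration_params(decimate = 800),
                   plane_extent_mm = 20, rmax_mm = 25)))
})
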