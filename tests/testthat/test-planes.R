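# Anatomical planes: areas, volumes, diameters, tracking.

test_that("plane normals follow the centerline tangent", {
  cl <- smooth_centerline(cbind(0, 0, seq(0, 80, by = 0.5))) |>
    set_landmarks(list(mid_AAo = c(0, 0, 40), annulus = c(0, 0, 0)))
  pl <- define_plane(cl, "mid_AAo")
  expect_equal(abs(pl$normal), c(0, 0, 1), tolerance = 1e-6)
  expect_equal(pl$center, c(0, 0, 40), tolerance = 1e-9)
  expect_equal(sum(pl$e1 * pl$normal), 0, tolerance = 1e-12)
  expect_equal(sum(pl$e1 * pl$e2), 0, tolerance = 1e-12)
  expect_error(define_plane(cl, "LSA"), "landmark")
})

test_that("cylinder cross-section area matches pi r^2", {
  cyl <- make_cylinder(10, zlen = 60)
  pl <- aorta4d:::new_plane("t", c(0, 0, 30), c(0, 0, 1), 25)
  expect_equal(plane_area(cyl, pl), pi * 100, tolerance = 0.015)
})

test_that("tilted sections scale as 1/cos(theta)", {
  cyl <- make_cylinder(10, zlen = 60)
  n30 <- c(sin(pi / 6), 0, cos(pi / 6))
  pl <- aorta4d:::new_plane("t", c(0, 0, 30), n30, 25)
  expect_equal(plane_area(cyl, pl), pi * 100 / cos(pi / 6), tolerance = 0.02)
})

test_that("planes outside the lumen are an error", {
  cyl <- make_cylinder(10, zlen = 40)
  beyond <- aorta4d:::new_plane("t", c(0, 0, 55), c(0, 0, 1), 25)
  expect_error(plane_area(cyl, beyond), "outside")
})

test_that("a plane slicing both limbs keeps only the connected region", {
  ph <- small_radial()
  p0 <- series_phase_view(ph$series, 0)
  spec <- ph$spec
  # plane at the STJ: its infinite extension also crosses the descending
  # limb; with a wide extent the flood fill must still isolate the root
  stj_s <- spec$landmarks_s[["STJ"]]
  pl <- aorta4d:::new_plane("STJ",
                            as.numeric(aorta4d:::phantom_base_point(spec, stj_s)),
                            as.numeric(aorta4d:::phantom_base_tangent(spec, stj_s)),
                            extent_mm = 100)
  a <- plane_area(p0, pl)
  expect_equal(a, pi * spec$asc_radius_mm^2, tolerance = 0.03)
})

test_that("segment volumes are partition-additive", {
  cyl <- make_cylinder(11, zlen = 100)
  cl <- smooth_centerline(cbind(0, 0, seq(-4, 104, by = 1)))
  smap <- arc_length_map(cl, cyl, rmax_mm = 25)
  whole <- segment_volume_range(cyl, smap, c(4, 104), sigma_vox = 0)
  part1 <- segment_volume_range(cyl, smap, c(4, 52.2499), sigma_vox = 0)
  part2 <- segment_volume_range(cyl, smap, c(52.2501, 104), sigma_vox = 0)
  expect_equal(part1 + part2, whole, tolerance = 1e-12)
})

test_that("cylinder segment volume matches pi r^2 L", {
  cyl <- make_cylinder(11, zlen = 120)
  cl <- smooth_centerline(cbind(0, 0, seq(-4, 124, by = 1)))
  smap <- arc_length_map(cl, cyl, rmax_mm = 25)
  # 100 mm of tube well inside the ends (cl s=0 at z=-4)
  v <- segment_volume_range(cyl, smap, c(14, 114))
  expect_equal(v, pi * 121 * 100, tolerance = 0.02)
})

test_that("equivalent diameter inverts the circle area", {
  expect_equal(equivalent_diameter(pi * 225), 30)
  expect_equal(equivalent_diameter(0), 0)
  expect_equal(equivalent_diameter(c(pi, 4 * pi)), c(2, 4))
  expect_error(equivalent_diameter(-1), ">= 0")
})

test_that("aortic segments carry the conventional landmark bounds", {
  expect_equal(aortic_segment("AAo")$from, "annulus")
  expect_equal(aortic_segment("AAo")$to, "BCT")
  expect_equal(aortic_segment("DAo")$from, "LSA")
  expect_equal(aortic_segment("DAo")$to, "diaphragm")
})

test_that("track_plane is exact for identity and rigid translation", {
  ph <- small_radial()
  field <- suppressWarnings(displacement_field(ph$series,
                                               registration_params(decimate = 800)))
  p0 <- series_phase_view(ph$series, 0)
  cl <- extract_centerline(p0, ph$lm$STJ, ph$lm$diaphragm) |>
    extend_to_annulus(ph$lm$annulus) |>
    smooth_centerline() |>
    set_landmarks(ph$lm)
  pl <- define_plane(cl, "mid_DAo", extent_mm = 20)

  same <- track_plane(pl, field, 0)
  expect_equal(same$center, pl$center, tolerance = 1e-12)
  expect_equal(same$normal, pl$normal, tolerance = 1e-12)

  # synthetic uniform translation field
  fake <- field
  fake$displacements[2, , ] <- matrix(rep(c(0, 0, 4), each = dim(field$displacements)[2]),
                                      ncol = 3)
  moved <- track_plane(pl, fake, 1)
  expect_equal(moved$center, pl$center + c(0, 0, 4), tolerance = 1e-9)
  expect_equal(moved$normal, pl$normal, tolerance = 1e-6)
})
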