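# Centerline extraction, smoothing, landmarks, tortuosity.

test_that("extracted cylinder centerline stays near the true axis", {
  cyl <- make_cylinder(10, zlen = 100)
  path <- extract_centerline(cyl, c(0, 0, 5), c(0, 0, 95))
  off_axis <- sqrt(path[, 1]^2 + path[, 2]^2)
  expect_lt(max(off_axis), 0.75)
  expect_lt(path[1, 3], path[nrow(path), 3])
})

test_that("arch path stays within a voxel of the analytic arc", {
  ph <- small_radial()
  p0 <- series_phase_view(ph$series, 0)
  path <- extract_centerline(p0, ph$lm$STJ, ph$lm$diaphragm)
  spec <- ph$spec
  dense <- aorta4d:::phantom_base_point(spec, seq(0, spec$total_s, by = 0.2))
  d <- vapply(seq_len(nrow(path)), function(i)
    min(sqrt(colSums((t(dense) - path[i, ])^2))), numeric(1))
  expect_lt(mean(d), spec$spacing_mm)
})

test_that("disconnected seeds are rejected", {
  cyl <- make_cylinder(8, zlen = 40)
  # second lump far away
  two <- cyl
  two$vox[3:6, 3:6, 3:6] <- 1L
  expect_error(extract_centerline(two, c(0, 0, 20), c(-12, -12, -2.5)),
               "disconnected|foreground")
  expect_error(extract_centerline(cyl, c(100, 0, 0), c(0, 0, 20)),
               "outside")
})

test_that("annulus extension adds exactly the straight-line length", {
  path <- cbind(0, 0, seq(10, 60, by = 1))
  same <- extend_to_annulus(path, c(0, 0, 10))
  expect_equal(nrow(same), nrow(path))
  ext <- extend_to_annulus(path, c(0, 0, 0))
  len <- sum(sqrt(rowSums(diff(ext)^2)))
  expect_equal(len, 60, tolerance = 1e-9)
})

test_that("smoothing recovers lengths of straight and circular paths", {
  straight <- cbind(0, 0, seq(0, 80, by = 1))
  cl <- smooth_centerline(straight)
  expect_equal(max(cl$points$s), 80, tolerance = 80 * 0.001)
  tg <- as.matrix(cl$points[, c("tx", "ty", "tz")])
  expect_equal(max(abs(tg[, 1:2])), 0, tolerance = 1e-6)

  # semicircle of radius 40: length pi * 40
  th <- seq(0, pi, length.out = 200)
  semi <- cbind(40 * cos(th), 0, 40 * sin(th))
  cls <- smooth_centerline(semi)
  expect_equal(max(cls$points$s), pi * 40, tolerance = 0.005)

  # jagged path (+-0.5 voxel zig-zag) must not inflate the length
  set.seed(42)
  zig <- straight + cbind(rep(c(0.5, -0.5), length.out = nrow(straight)),
                          rep(c(-0.5, 0.5), length.out = nrow(straight)), 0)
  clz <- smooth_centerline(zig)
  raw_len <- sum(sqrt(rowSums(diff(zig)^2)))
  expect_gt(raw_len, 80 * 1.05)           # the raw path overestimates
  expect_equal(max(clz$points$s), 80, tolerance = 0.01)
})

test_that("degenerate paths are rejected", {
  expect_error(smooth_centerline(matrix(1, 3, 3)), "4 distinct")
  expect_error(smooth_centerline(matrix(rep(c(1, 2, 3), each = 6), 6, 3)),
               "degenerate|4 distinct")
})

test_that("arc lengths between landmarks are additive and exact", {
  pts <- cbind(0, 0, seq(0, 120, by = 0.5))
  cl <- smooth_centerline(pts) |>
    set_landmarks(list(annulus = c(0, 0, 0), STJ = c(0, 0, 20),
                       BCT = c(0, 0, 50), diaphragm = c(0, 0, 120)))
  expect_equal(arc_length_between(cl, "STJ", "STJ"), 0)
  ab <- arc_length_between(cl, "annulus", "STJ")
  bc <- arc_length_between(cl, "STJ", "BCT")
  cd <- arc_length_between(cl, "BCT", "diaphragm")
  expect_equal(ab + bc + cd, arc_length_between(cl, "annulus", "diaphragm"),
               tolerance = 1e-9)
  expect_error(arc_length_between(cl, "annulus", "LSA"), "landmark")
})

test_that("phantom annulus-BCT length matches the generated value", {
  ph <- small_radial()
  p0 <- series_phase_view(ph$series, 0)
  cl <- extract_centerline(p0, ph$lm$STJ, ph$lm$diaphragm) |>
    extend_to_annulus(ph$lm$annulus) |>
    smooth_centerline() |>
    recenter_centerline(p0, extent_mm = 20) |>
    set_landmarks(ph$lm)
  expect_equal(arc_length_between(cl, "annulus", "BCT"),
               ph$spec$aao_length_mm, tolerance = 0.02)
})

test_that("tortuosity index is 1 for a line and pi/2 for a semicircle", {
  line <- smooth_centerline(cbind(0, 0, seq(0, 100, by = 0.5))) |>
    set_landmarks(list(STJ = c(0, 0, 0), diaphragm = c(0, 0, 100)))
  expect_equal(tortuosity_index(line), 1, tolerance = 1e-4)

  th <- seq(0, pi, length.out = 400)
  semi <- smooth_centerline(cbind(40 * cos(th), 0, 40 * sin(th))) |>
    set_landmarks(list(STJ = c(40, 0, 0), diaphragm = c(-40, 0, 0)))
  expect_equal(tortuosity_index(semi), pi / 2, tolerance = 0.01)

  ph <- small_radial()
  p0 <- series_phase_view(ph$series, 0)
  cl <- extract_centerline(p0, ph$lm$STJ, ph$lm$diaphragm) |>
    extend_to_annulus(ph$lm$annulus) |>
    smooth_centerline() |>
    recenter_centerline(p0, extent_mm = 20) |>
    set_landmarks(ph$lm)
  expect_equal(tortuosity_index(cl), ph$truth$ati, tolerance = 0.01)
  expect_gte(tortuosity_index(cl), 1)
})

test_that("centerline length is invariant under rigid 90-degree rotation", {
  ph <- small_radial()
  p0 <- series_phase_view(ph$series, 0)
  len0 <- {
    cl <- extract_centerline(p0, ph$lm$STJ, ph$lm$diaphragm) |>
      smooth_centerline()
    max(cl$points$s)
  }
  # rotate the mask 90 degrees about z (exact on the voxel grid)
  v <- p0$vox
  vr <- aperm(v, c(2, 1, 3))[dim(v)[2]:1, , ] # (x,y,z) -> (-y,x,z)
  rot_phase <- list(vox = vr, dim = dim(vr), spacing = p0$spacing,
                    origin = c(-(p0$origin[2] + (dim(v)[2] - 1) *
                                   p0$spacing[2]), p0$origin[1],
                               p0$origin[3]),
                    phase = 0L)
  rot_pt <- function(p) c(-p[2], p[1], p[3])
  lenr <- {
    cl <- extract_centerline(rot_phase, rot_pt(ph$lm$STJ),
                             rot_pt(ph$lm$diaphragm)) |>
      smooth_centerline()
    max(cl$points$s)
  }
  expect_equal(lenr, len0, tolerance = 0.01)
})
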