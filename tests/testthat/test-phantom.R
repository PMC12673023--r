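# Phantom generator: waveform, voxelization vs analytic truth, cohorts.

test_that("waveform has the required shape", {
  expect_equal(waveform(0, 0.35), 0)
  expect_equal(waveform(0.35 / 2, 0.35), 1)         # peak at mid-systole
  expect_equal(waveform(c(0.35, 0.5, 0.99), 0.35), c(0, 0, 0))
  # smoothness at the systole end: values ramp to 0 continuously
  expect_lt(waveform(0.349, 0.35), 1e-3)
  # independent oracle: quadrature of sin^2 over the cycle equals T_sys / 2
  q <- stats::integrate(function(t) waveform(t, 0.35), 0, 0.999999)$value
  expect_equal(q, 0.35 / 2, tolerance = 1e-5)
  expect_error(waveform(1.2), "t_frac")
})

test_that("zero-deformation phantom is bit-identical across phases", {
  ph <- small_null()
  v <- ph$series$voxels
  for (t in 2:dim(v)[4]) expect_identical(v[, , , t], v[, , , 1])
  tr <- ph$truth
  curves <- tidyr::pivot_wider(tr$curves, names_from = "metric",
                               values_from = "value", id_cols = "phase")
  for (m in c("volume_aao", "volume_dao", "area_mid_aao", "length_aao"))
    expect_equal(diff(range(curves[[m]])), 0)
})

test_that("ground-truth curves start and end at the baseline", {
  ph <- small_radial()
  cv <- ph$truth$curves
  for (m in unique(cv$metric)) {
    v <- cv$value[cv$metric == m]
    expect_equal(v[length(v)], v[1], tolerance = 1e-9)
  }
})

test_that("voxelized phase-0 volumes match the analytic cylinder values", {
  ph <- small_radial()
  spec <- ph$spec
  p0 <- series_phase_view(ph$series, 0)
  lm <- ph$lm
  cl <- extract_centerline(p0, lm$STJ, lm$diaphragm) |>
    extend_to_annulus(lm$annulus) |>
    smooth_centerline() |>
    recenter_centerline(p0, extent_mm = 20) |>
    set_landmarks(lm)
  smap <- arc_length_map(cl, p0, rmax_mm = 25)
  v_dao <- segment_volume(p0, cl, aortic_segment("DAo"), smap = smap)
  dao_truth <- pi * spec$desc_radius_mm^2 *
    (spec$landmarks_s[["diaphragm"]] - spec$landmarks_s[["LSA"]])
  # coarse 1.5 mm fixture; the 2% bound at 1 mm is asserted in the
  # acceptance suite's geometry oracles
  expect_equal(v_dao, dao_truth, tolerance = 0.03)
  v_aao <- segment_volume(p0, cl, aortic_segment("AAo"), smap = smap)
  expect_equal(v_aao, pi * spec$asc_radius_mm^2 * spec$aao_length_mm,
               tolerance = 0.03)
})

test_that("voxelization error shrinks as spacing is refined", {
  vol_err <- function(spacing) {
    spec <- small_spec(a = 0, n_phases = 2, spacing = spacing)
    ph <- build_phantom(spec)
    p0 <- series_phase_view(ph$series, 0)
    lm <- phantom_landmarks(spec)
    cl <- extract_centerline(p0, lm$STJ, lm$diaphragm) |>
      extend_to_annulus(lm$annulus) |>
      smooth_centerline() |>
      recenter_centerline(p0, extent_mm = 20) |>
      set_landmarks(lm)
    v <- segment_volume(p0, cl, aortic_segment("DAo"), rmax_mm = 25)
    truth <- pi * spec$desc_radius_mm^2 *
      (spec$landmarks_s[["diaphragm"]] - spec$landmarks_s[["LSA"]])
    abs(v / truth - 1)
  }
  e_coarse <- vol_err(2.0)
  e_fine <- vol_err(1.0)
  expect_lt(e_fine, e_coarse + 1e-9)
  expect_lt(e_fine, 0.015)
})

test_that("pure root translation has the stated displacement ground truth", {
  spec <- small_spec(a = 0, d = 9)
  # annulus carries the full translation, apex weight is 0
  expect_equal(aorta4d:::phantom_ring_mean_disp(spec, 0, 1), 9,
               tolerance = 1e-9)
  expect_equal(aorta4d:::phantom_ring_mean_disp(spec, spec$apex_s, 1), 0,
               tolerance = 1e-9)
  an <- analytic_metrics(spec, 48)
  w_stj <- 1 - spec$landmarks_s[["STJ"]] / spec$apex_s
  expect_equal(an$disp_stj, 9 * w_stj, tolerance = 1e-9)
})

test_that("analytic metrics reproduce the closed forms", {
  s1 <- small_spec(a = 0.10, eps = 0)
  expect_equal(analytic_metrics(s1, 48)$dist3d_aao, 4.375, tolerance = 1e-9)
  s2 <- phantom_spec(radial_amplitude_asc = 0.05, strain_amplitude = 0.10,
                     n_phases = 4)
  expect_equal(analytic_metrics(s2, 50)$dist3d_aao, 4.255, tolerance = 1e-9)
  s0 <- small_spec(a = 0, eps = 0, d = 0)
  an0 <- analytic_metrics(s0, 48)
  expect_equal(an0$dist3d_aao + an0$dist3d_dao + an0$dist2d_mid_aao +
                 an0$strain_pct, 0)
})

test_that("phantom masks pass series validation across deformation modes", {
  expect_true(validate_series(small_radial()$series)$verdict)
  spec <- small_spec(a = 0.1, eps = 0.12, d = 6, n_phases = 4)
  expect_true(validate_series(build_phantom(spec)$series)$verdict)
})

test_that("self-intersecting specs are rejected", {
  expect_error(phantom_spec(asc_radius_mm = 39, arch_radius_mm = 40),
               "self-intersect")
  expect_error(phantom_spec(radial_amplitude_asc = 0.6), "amplitude")
  expect_error(small_spec(spacing = 5), "spacing")
})

test_that("cohort simulation is reproducible and calibrated", {
  spec <- cohort_spec(seed = 7L)
  c1 <- simulate_cohort(spec)
  c2 <- simulate_cohort(spec)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 47 + 51 + 33)
  expect_setequal(unique(c1$group), c("healthy", "native", "rr"))

  # zero SD collapses a metric onto the group mean
  mt <- default_metric_table()
  mt$sd[mt$metric == "disp_stj"] <- 0
  c3 <- simulate_cohort(cohort_spec(metrics = mt, seed = 1L))
  expect_equal(unique(c3$disp_stj[c3$group == "healthy"]), 10.3)

  # large-sample calibration: healthy AAo distensibility mean within 3 SE
  big <- cohort_spec(n_healthy = 10000, n_native = 2, n_rr = 2, seed = 11L)
  cb <- simulate_cohort(big)
  m <- mean(cb$dist3d_aao[cb$group == "healthy"])
  se <- 1.4 / sqrt(10000)
  expect_lt(abs(m - 5.1), 3 * se)
  # truncated draws stay positive
  expect_true(all(cb$dist3d_aao > 0))
})

test_that("cohort metric means are calibrated within 2% at n = 1e4", {
  big <- cohort_spec(n_healthy = 10000, n_native = 10000, n_rr = 10000,
                     seed = 3L)
  cb <- simulate_cohort(big)
  mt <- default_metric_table()
  for (grp in c("healthy", "rr")) {
    sub <- cb[cb$group == grp, ]
    for (m in c("dist3d_aao", "strain_pct", "disp_stj", "v_ed_aao_ml")) {
      target <- mt$mean[mt$metric == m & mt$group == grp]
      expect_lt(abs(mean(sub[[m]]) / target - 1), 0.02)
    }
  }
})
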