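# Distensibility, strain, peak detection, blood pressure.

test_that("blood pressure derives pulse pressure and MAP", {
  bp <- blood_pressure(128, 80)
  expect_equal(bp$pulse_pressure, 48)
  expect_equal(bp$map, 96)
  expect_error(blood_pressure(80, 80), "systolic")
  expect_error(blood_pressure(120, 0), "systolic|diastolic")
})

test_that("peak_value reports the earliest maximal change", {
  pk <- peak_value(c(0, 3, 7, 7, 2))
  expect_equal(pk$value, 7)
  expect_equal(pk$phase, 2L)
  mono <- peak_value(c(10, 8, 6, 4))
  expect_equal(mono$value, 0)
  expect_equal(mono$phase, 0L)
  expect_error(peak_value(numeric(0)), "empty")
})

test_that("distensibility implements the volume-ratio formula", {
  # arithmetic oracle on published healthy group means:
  # dV = 12.3 mL over V0 = 54.3 mL at PP 48 mmHg
  v <- c(54.3, 60, 54.3 + 12.3, 66)
  d <- distensibility_3d(v, blood_pressure(128, 80))
  expect_equal(d, 12.3 / (54.3 * 48) * 1e3, tolerance = 1e-12)
  expect_equal(round(d, 3), 4.719)
  expect_equal(distensibility_3d(rep(5, 8), 48), 0)
  expect_error(distensibility_3d(c(0, 1), 48), "baseline")
  expect_error(distensibility_3d(c(2, 3), 0), "pulse")
  # 2D contract is identical on area curves
  expect_equal(distensibility_2d(c(100, 121), 48),
               distensibility_3d(c(100, 121), 48))
})

test_that("halving pulse pressure exactly doubles distensibility", {
  ph <- small_radial()
  curves <- ph$truth$curves
  v <- curves$value[curves$metric == "volume_aao"]
  a <- curves$value[curves$metric == "area_mid_aao"]
  full <- blood_pressure(128, 80)   # PP 48
  half <- blood_pressure(104, 80)   # PP 24
  expect_identical(distensibility_3d(v, half), 2 * distensibility_3d(v, full))
  expect_identical(distensibility_2d(a, half), 2 * distensibility_2d(a, full))
})

test_that("longitudinal strain curve and peak follow the definition", {
  # arithmetic oracle on published healthy means: L0 79.5 mm, dL 12.4 mm
  lens <- c(79.5, 85, 79.5 + 12.4, 88)
  sc <- longitudinal_strain_curve(lens)
  expect_equal(max(sc$value), 100 * 12.4 / 79.5, tolerance = 1e-12)
  expect_equal(round(max(sc$value), 2), 15.60)
  expect_equal(sc$value[1], 0)
  peak <- attr(sc, "peak")
  expect_equal(peak$phase, 2L)
  zero <- longitudinal_strain_curve(rep(80, 6))
  expect_true(all(zero$value == 0))
  expect_error(longitudinal_strain_curve(c(80, NA)), "missing")
})

test_that("compute_subject runs end-to-end and is deterministic", {
  ph <- small_radial()
  bp <- blood_pressure(128, 80)
  params <- subject_params(reg = registration_params(decimate = 800),
                           plane_extent_mm = 20, rmax_mm = 25)
  s1 <- small_subject()
  s2 <- suppressWarnings(compute_subject(ph$series, ph$lm, bp, params))
  expect_identical(s1$metrics, s2$metrics)
  expect_identical(s1$curves, s2$curves)

  an <- analytic_metrics(ph$spec, bp)
  f_peak <- max(waveform((seq_len(ph$spec$n_phases) - 1) / ph$spec$n_phases,
                         ph$spec$systole_fraction))
  # coarse 1.5 mm phantom: generous 12% bracket, exact checks live in the
  # acceptance suite at full resolution
  expect_equal(s1$metrics$dist3d_aao, an$dist3d_aao * f_peak,
               tolerance = 0.12)
  expect_equal(s1$metrics$dist3d_dao, an$dist3d_dao * f_peak,
               tolerance = 0.12)
  expect_lt(abs(s1$metrics$strain_pct), 1)   # no stretch mode here
  expect_equal(s1$metrics$ati, ph$truth$ati, tolerance = 0.02)
  expect_equal(s1$metrics$pp_mmhg, 48)
  # curves tibble is complete
  expect_setequal(unique(s1$curves$metric),
                  c("volume_aao", "volume_dao", "area_stj", "area_mid_aao",
                    "area_mid_dao", "area_diaphragm", "length_aao",
                    "strain_aao", "disp_stj", "disp_mid_aao", "disp_mid_dao",
                    "disp_diaphragm"))
  expect_true(all(table(s1$curves$metric) == ph$series$n_phases))
})

test_that("compute_subject validates its inputs", {
  ph <- small_null()
  bp <- blood_pressure(128, 80)
  expect_error(compute_subject(ph$series, ph$lm[1:3], bp), "missing landmarks")
  expect_error(compute_subject(ph$series, ph$lm, 48), "blood_pressure")
})

test_that("tidy and glance return the metric panel", {
  subj <- small_subject()
  td <- tidy(subj)
  expect_true(all(c("metric", "value") %in% names(td)))
  expect_true("dist3d_aao" %in% td$metric)
  expect_identical(glance(subj), subj$metrics)
})
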