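# Simulated cohorts for the statistics stage.
#
# Per-group metric and covariate distributions are calibrated to published
# group summaries for healthy volunteers and Marfan patients with a native
# or replaced aortic root (group sizes 47 / 51 / 33). Metrics are drawn from
# mean-calibrated truncated normals (plain normal draws can go negative at
# these SDs); selected covariate->metric links and the 2D-3D distensibility
# correlation are built in so the regression and correlation stages have
# known ground truth.

default_metric_table <- function() {
  g <- c("healthy", "native", "rr")
  row <- function(metric, m, s)
    tibble(metric = metric, group = g, mean = m, sd = s)
  dplyr::bind_rows(
    row("dist3d_aao", c(5.1, 3.6, 1.4), c(1.4, 1.4, 0.7)),
    row("dist3d_dao", c(3.2, 2.5, 2.4), c(1.1, 0.9, 1.0)),
    row("dist2d_mid_aao", c(4.2, 3.5, 1.5), c(1.5, 1.5, 0.8)),
    row("dist2d_mid_dao", c(2.9, 2.1, 1.9), c(1.2, 1.0, 0.8)),
    row("v_ed_aao_ml", c(54.3, 77.0, 73.6), c(17.3, 23.6, 15.5)),
    row("v_ed_dao_ml", c(60.4, 69.9, 89.9), c(16.6, 18.1, 21.1)),
    row("dv_aao_ml", c(12.3, 12.2, 4.8), c(3.2, 4.1, 2.4)),
    row("dv_dao_ml", c(8.7, 8.0, 9.7), c(2.8, 3.2, 3.1)),
    row("l_ed_aao", c(79.5, 90.7, 83.5), c(9.7, 11.3, 13.3)),
    row("dl_aao", c(12.4, 12.0, 7.3), c(3.4, 4.5, 4.3)),
    row("strain_pct", c(15.7, 13.4, 8.7), c(4.4, 4.8, 4.8)),
    row("disp_stj", c(10.3, 8.7, 5.7), c(1.3, 2.1, 1.6)),
    row("disp_mid_aao", c(5.1, 5.1, 4.5), c(1.1, 1.3, 1.3)),
    row("disp_mid_dao", c(1.4, 1.3, 1.3), c(0.4, 0.4, 0.5)),
    row("disp_diaphragm", c(2.1, 2.1, 1.6), c(0.7, 0.7, 0.7)))
}

default_covariate_table <- function() {
  g <- c("healthy", "native", "rr")
  row <- function(cov, m, s)
    tibble(covariate = cov, group = g, mean = m, sd = s)
  dplyr::bind_rows(
    row("bsa", c(1.9, 2.0, 2.1), c(0.2, 0.2, 0.2)),
    row("map_mmhg", c(97, 96, 95), c(9, 8, 8)),
    row("pp_mmhg", c(48, 47, 48), c(8, 7, 6)),
    row("hr", c(65, 71, 67), c(9, 12, 9)),
    # replaced roots carry a fixed-size graft; a tight synthetic 32 +- 2 mm
    # stands in for the unreported graft dimension
    row("root_diameter", c(33, 43, 32), c(4, 5, 2)),
    row("ati", c(2.3, 2.5, 2.5), c(0.2, 0.2, 0.3)))
}

#' Cohort simulation specification
#'
#' @param n_healthy,n_native,n_rr group sizes.
#' @param metrics per-group metric means/SDs (tibble: metric, group, mean,
#'   sd); defaults are calibrated to published group summaries.
#' @param covariates per-group covariate means/SDs (same layout).
#' @param age_range named list of `c(lo, hi)` per group (ages are uniform).
#' @param female_frac named vector of female fractions per group.
#' @param links covariate effects on `dist3d_aao` per group: named list of
#'   named coefficient vectors (defaults: in the native group, age -0.06 and
#'   root diameter -0.10 per mm, matching the regression ground truth the
#'   statistics stage is tested against).
#' @param rho_2d3d named list per region (`aao`, `dao`) of per-group Pearson
#'   correlations between 2D and 3D distensibility.
#' @param seed integer RNG seed; simulation is reproducible given the spec.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_healthy = 47, n_native = 51, n_rr = 33,
                        metrics = default_metric_table(),
                        covariates = default_covariate_table(),
                        age_range = list(healthy = c(22, 50),
                                         native = c(19, 50),
                                         rr = c(24, 50)),
                        female_frac = c(healthy = 0.49, native = 0.51,
                                        rr = 0.33),
                        links = list(native = c(age = -0.06,
                                                root_diameter = -0.10)),
                        rho_2d3d = list(aao = c(healthy = 0.81,
                                                native = 0.68, rr = 0.39),
                                        dao = c(healthy = 0.76,
                                                native = 0.63, rr = 0.90)),
                        seed = 1L) {
  ns <- c(healthy = n_healthy, native = n_native, rr = n_rr)
  if (any(ns < 2)) abort_input("group sizes must be >= 2")
  if (any(metrics$sd < 0) || any(covariates$sd < 0))
    abort_input("SDs must be >= 0")
  structure(list(n = ns, metrics = metrics, covariates = covariates,
                 age_range = age_range, female_frac = female_frac,
                 links = links, rho_2d3d = rho_2d3d, seed = as.integer(seed)),
            class = "cohort_spec")
}

# mean-calibrated truncated normal: location shifted so the truncated mean
# hits `target_mean` (at these SDs the naive truncation bias can exceed 2%)
rtnorm_calibrated <- function(n, target_mean, sd, lower = 0) {
  if (sd == 0) return(rep(target_mean, n))
  mu <- tryCatch(
    stats::uniroot(function(m) {
      a <- (lower - m) / sd
      m + sd * stats::dnorm(a) / stats::pnorm(a, lower.tail = FALSE) -
        target_mean
    }, interval = c(target_mean - 4 * sd, target_mean + sd),
    extendInt = "yes")$root,
    error = function(e) target_mean)
  u <- runif(n, pnorm(lower, mu, sd), 1)
  qnorm(pmin(u, 1 - 1e-12), mu, sd)
}

# redraw residuals until metric > lower (keeps the systematic part intact)
draw_with_resid <- function(base, resid_sd, lower = 0, max_tries = 100) {
  out <- base + rnorm(length(base), 0, resid_sd)
  for (i in seq_len(max_tries)) {
    bad <- out <= lower
    if (!any(bad)) break
    out[bad] <- base[bad] + rnorm(sum(bad), 0, resid_sd)
  }
  pmax(out, lower + 1e-6)
}

#' Simulate a cohort table
#'
#' One row per subject with group label, covariates and the full metric
#' panel. Deterministic for a fixed spec (the spec's seed is used).
#'
#' @param spec a [cohort_spec()].
#' @return A tibble.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  mt <- spec$metrics
  ct <- spec$covariates
  get_ms <- function(tbl, key, keycol, grp)
    tbl[tbl[[keycol]] == key & tbl$group == grp, c("mean", "sd")]
  out <- lapply(names(spec$n), function(grp) {
    n <- spec$n[[grp]]
    age <- runif(n, spec$age_range[[grp]][1], spec$age_range[[grp]][2])
    sex_male <- rbinom(n, 1, 1 - spec$female_frac[[grp]])
    covs <- lapply(unique(ct$covariate), function(cv) {
      ms <- get_ms(ct, cv, "covariate", grp)
      rtnorm_calibrated(n, ms$mean, ms$sd, lower = 0)
    })
    names(covs) <- unique(ct$covariate)

    metrics <- list()
    link <- spec$links[[grp]]
    for (m in unique(mt$metric)) {
      ms <- get_ms(mt, m, "metric", grp)
      if (m == "dist3d_aao" && !is.null(link)) {
        # systematic covariate part + residual, total SD matching the target
        sys_part <- rep(0, n)
        sys_var <- 0
        for (cv in names(link)) {
          x <- if (cv == "age") age else covs[[cv]]
          vx <- if (cv == "age")
            diff(spec$age_range[[grp]])^2 / 12 else
              get_ms(ct, cv, "covariate", grp)$sd^2
          sys_part <- sys_part + link[[cv]] * (x - mean(x))
          sys_var <- sys_var + link[[cv]]^2 * vx
        }
        resid_sd <- sqrt(max(ms$sd^2 - sys_var, (0.3 * ms$sd)^2))
        metrics[[m]] <- draw_with_resid(ms$mean + sys_part, resid_sd)
      } else if (m %in% c("dist2d_mid_aao", "dist2d_mid_dao")) {
        next  # drawn conditionally below
      } else {
        metrics[[m]] <- rtnorm_calibrated(n, ms$mean, ms$sd, lower = 0)
      }
    }
    # conditionally correlated 2D distensibilities
    for (reg in c("aao", "dao")) {
      m2 <- paste0("dist2d_mid_", reg)
      m3 <- paste0("dist3d_", reg)
      rho <- spec$rho_2d3d[[reg]][[grp]]
      ms2 <- get_ms(mt, m2, "metric", grp)
      ms3 <- get_ms(mt, m3, "metric", grp)
      base <- ms2$mean + rho * ms2$sd / ms3$sd * (metrics[[m3]] - ms3$mean)
      metrics[[m2]] <- draw_with_resid(base, ms2$sd * sqrt(1 - rho^2))
    }
    dplyr::bind_cols(tibble(group = grp, age = age, sex_male = sex_male),
                     as_tibble(covs), as_tibble(metrics))
  })
  out <- dplyr::bind_rows(out)
  dplyr::mutate(out, subject_id = sprintf("S%03d", dplyr::row_number()),
                .before = 1)
}
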