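# Configuration-driven pipeline commands backing the `aorta4d` command-line
# front-end (exec/aorta4d): phantom generation, per-subject metrics, cohort
# statistics. Each command reads a YAML config, writes its outputs plus a
# manifest sufficient to reproduce the run, and logs stage progress to
# stderr via message().

read_run_config <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) abort_input("config must be a YAML mapping")
  cfg
}

require_fields <- function(cfg, fields, where = "config") {
  miss <- setdiff(fields, names(cfg))
  if (length(miss))
    abort_input(sprintf("missing %s fields: %s", where,
                        paste(miss, collapse = ", ")))
  invisible(cfg)
}

write_manifest <- function(out_dir, cfg, seed, extra = list()) {
  jsonlite::write_json(
    c(list(package = "aorta4d",
           version = as.character(utils::packageVersion("aorta4d")),
           seed = seed, config = cfg), extra),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
}

log_stage <- function(...) message("[aorta4d] ", sprintf(...))

phantom_spec_from_config <- function(cfg) {
  known <- names(formals(phantom_spec))
  args <- cfg[intersect(names(cfg), known)]
  do.call(phantom_spec, args)
}

#' Generate a phantom dataset from a config
#'
#' Writes the 4D mask series (NIfTI), analytic ground-truth curves (CSV),
#' scalar truth and landmarks (JSON), and a run manifest. Deterministic for
#' a fixed config and seed.
#'
#' @param config path to a YAML config or an equivalent list. Recognized
#'   fields: any [phantom_spec()] argument, plus `out` (output directory)
#'   and `seed`.
#' @param out output directory (overrides the config).
#' @param seed integer seed recorded in the outputs.
#' @return Invisibly, the list of written files.
#' @export
cmd_phantom <- function(config, out = NULL, seed = 1L) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  out_dir <- out %||% cfg$out
  if (is.null(out_dir)) abort_input("no output directory given")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg$seed <- seed <- as.integer(cfg$seed %||% seed)
  spec <- phantom_spec_from_config(cfg)
  log_stage("building phantom (%d phases, %.2g mm spacing)", spec$n_phases,
            spec$spacing_mm)
  ph <- build_phantom(spec)
  rep <- validate_series(ph$series)
  if (!rep$verdict) stop("phantom failed series validation [stage: phantom]")
  files <- c(series = file.path(out_dir, "phantom.nii.gz"),
             truth_curves = file.path(out_dir, "truth_curves.csv"),
             truth_disp = file.path(out_dir, "truth_plane_displacement.csv"),
             truth = file.path(out_dir, "truth.json"),
             landmarks = file.path(out_dir, "landmarks.json"),
             validation = file.path(out_dir, "validation.json"))
  write_series(ph$series, files["series"])
  write.csv(ph$truth$curves, files["truth_curves"], row.names = FALSE)
  write.csv(ph$truth$plane_displacement, files["truth_disp"],
            row.names = FALSE)
  jsonlite::write_json(list(ati = ph$truth$ati,
                            waveform = ph$truth$waveform,
                            analytic_peak =
                              as.list(analytic_metrics(spec, cfg$pp %||% 48))),
                       files["truth"], auto_unbox = TRUE, digits = NA)
  lm <- phantom_landmarks(spec)
  jsonlite::write_json(lapply(lm, as.numeric), files["landmarks"],
                       digits = NA)
  write_validation(rep, files["validation"])
  write_manifest(out_dir, cfg, seed)
  log_stage("phantom written to %s", out_dir)
  invisible(files)
}

read_landmarks_json <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("landmark file not found: %s", path))
  lapply(jsonlite::read_json(path), function(p) as.numeric(unlist(p)))
}

#' Compute the subject metric panel from a config
#'
#' Inputs: a 4D mask series, a landmark JSON (`{label: [x,y,z]}` in mm) and
#' brachial blood pressure. Writes the metric panel (CSV + JSON), per-phase
#' curves (long CSV), displacement point clouds (PLY), registration
#' diagnostics and a manifest.
#'
#' @param config path to a YAML config or an equivalent list with fields
#'   `series`, `landmarks`, `bp` (list with `systolic`/`diastolic`), and
#'   optionally registration parameters and `out`.
#' @param out output directory (overrides the config).
#' @param seed recorded in the manifest (the pipeline is deterministic).
#' @return Invisibly, the computed `aorta_subject`.
#' @export
cmd_metrics <- function(config, out = NULL, seed = 1L) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  require_fields(cfg, c("series", "landmarks", "bp"))
  out_dir <- out %||% cfg$out
  if (is.null(out_dir)) abort_input("no output directory given")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!file.exists(cfg$series))
    abort_input(sprintf("series file not found: %s", cfg$series))
  bp_cfg <- cfg$bp
  if (is.null(bp_cfg$systolic) || is.null(bp_cfg$diastolic))
    abort_input("bp must provide systolic and diastolic (mmHg)")
  bp <- blood_pressure(bp_cfg$systolic, bp_cfg$diastolic)

  log_stage("reading series %s", cfg$series)
  series <- read_series(cfg$series)
  landmarks <- read_landmarks_json(cfg$landmarks)
  reg_args <- cfg$registration %||% list()
  params <- subject_params(
    reg = do.call(registration_params, reg_args),
    band_mm = cfg$band_mm %||% 2.5,
    plane_extent_mm = cfg$plane_extent_mm %||% 25)
  t0 <- proc.time()[["elapsed"]]
  log_stage("computing subject metrics (%d phases)", series$n_phases)
  subj <- compute_subject(series, landmarks, bp, params)
  log_stage("metrics done in %.1f s", proc.time()[["elapsed"]] - t0)

  write.csv(subj$metrics, file.path(out_dir, "metrics.csv"),
            row.names = FALSE)
  jsonlite::write_json(as.list(subj$metrics),
                       file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(subj$curves, file.path(out_dir, "curves.csv"), row.names = FALSE)
  write.csv(subj$field_diagnostics,
            file.path(out_dir, "registration_diagnostics.csv"),
            row.names = FALSE)
  utils::write.csv(subj$centerline$points,
                   file.path(out_dir, "centerline.csv"), row.names = FALSE)
  write_manifest(out_dir, cfg, seed)
  log_stage("subject outputs written to %s", out_dir)
  invisible(subj)
}

#' Run the cohort statistics stage from a config
#'
#' Either simulates a cohort (field `simulate: true`, using [cohort_spec()]
#' fields) or reads one from `cohort` (CSV). Runs the one-way ANOVA with the
#' significance gate on every metric, Tukey HSD for gated metrics, the
#' regression analysis, and the 2D-3D distensibility correlations; writes
#' tidy CSV/JSON results.
#'
#' @param config path to YAML config or an equivalent list.
#' @param out output directory (overrides the config).
#' @param seed seed for cohort simulation.
#' @return Invisibly, a list of result tibbles.
#' @export
cmd_cohort <- function(config, out = NULL, seed = 1L) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  out_dir <- out %||% cfg$out
  if (is.null(out_dir)) abort_input("no output directory given")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed %||% seed)

  if (isTRUE(cfg$simulate)) {
    known <- names(formals(cohort_spec))
    spec <- do.call(cohort_spec, c(cfg[intersect(names(cfg), known)],
                                   list(seed = seed)))
    cohort <- simulate_cohort(spec)
    log_stage("simulated cohort: %d subjects", nrow(cohort))
  } else {
    if (is.null(cfg$cohort)) abort_input("need `cohort` CSV or `simulate: true`")
    if (!file.exists(cfg$cohort))
      abort_input(sprintf("cohort file not found: %s", cfg$cohort))
    cohort <- as_tibble(read.csv(cfg$cohort))
    log_stage("read cohort: %d subjects", nrow(cohort))
  }
  if (!"group" %in% names(cohort)) abort_input("cohort table needs a `group` column")

  metrics <- cfg$metrics %||%
    intersect(unique(default_metric_table()$metric), names(cohort))
  gate <- cfg$gate_threshold %||% 0.005

  anova_tbl <- dplyr::bind_rows(lapply(metrics, function(m)
    dplyr::mutate(anova_oneway(cohort, !!rlang::sym(m), group), metric = m,
                  .before = 1)))
  anova_tbl$significant <- bonferroni_gate(anova_tbl$p_value, gate)

  tukey_tbl <- dplyr::bind_rows(lapply(
    anova_tbl$metric[anova_tbl$significant], function(m)
      dplyr::mutate(tukey_hsd(cohort, !!rlang::sym(m), group), metric = m,
                    .before = 1)))

  pearson_tbl <- dplyr::bind_rows(lapply(c("aao", "dao"), function(reg) {
    m2 <- paste0("dist2d_mid_", reg); m3 <- paste0("dist3d_", reg)
    if (!all(c(m2, m3) %in% names(cohort))) return(NULL)
    dplyr::bind_rows(lapply(unique(cohort$group), function(g)
      dplyr::mutate(pearson_cor(dplyr::filter(cohort, .data$group == g),
                                !!rlang::sym(m2), !!rlang::sym(m3)),
                    region = reg, group = g, .before = 1)))
  }))

  reg_cfg <- cfg$regression %||%
    list(outcome = "dist3d_aao", group = "native",
         predictors = c("age", "sex_male", "bsa", "root_diameter", "ati"))
  reg_data <- dplyr::filter(cohort, .data$group == reg_cfg$group)
  regression <- regress(reg_data, reg_cfg$outcome,
                        unlist(reg_cfg$predictors))

  write.csv(anova_tbl, file.path(out_dir, "anova.csv"), row.names = FALSE)
  if (nrow(tukey_tbl))
    write.csv(tukey_tbl, file.path(out_dir, "tukey.csv"), row.names = FALSE)
  write.csv(pearson_tbl, file.path(out_dir, "pearson.csv"),
            row.names = FALSE)
  write.csv(tidy(regression), file.path(out_dir, "regression.csv"),
            row.names = FALSE)
  write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  jsonlite::write_json(list(anova = anova_tbl, tukey = tukey_tbl,
                            pearson = pearson_tbl,
                            regression = tidy(regression)),
                       file.path(out_dir, "statistics.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, cfg, seed)
  log_stage("cohort statistics written to %s", out_dir)
  invisible(list(cohort = cohort, anova = anova_tbl, tukey = tukey_tbl,
                 pearson = pearson_tbl, regression = regression))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
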