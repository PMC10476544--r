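#' Render the measurement table to CSV
#'
#' Writes the per-item measurement report with the standard column order:
#' item, ICC, within-level unstandardized loading and R2, between-level
#' loading and R2, the cross-level difference with its 95% interval, and a
#' flag column (`*`) marking rows whose interval excludes zero. The anchor
#' row shows loadings of 1.000 at both levels and an em-dash in the
#' difference cell. Numeric fields are written at full precision so the
#' rendered file parses back exactly.
#'
#' @param report a `dsem_measurement` data.frame ([item_psychometrics()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
render_measurement_table <- function(report, path) {
  stopifnot(inherits(report, "dsem_measurement"))
  fmt <- function(x) ifelse(is.na(x), "", formatC(x, digits = 17, format = "g"))
  df <- data.frame(
    item = report$item,
    icc = fmt(report$icc),
    within_unstd_lambda = fmt(report$loading_within),
    within_r2 = fmt(report$r2_within),
    between_unstd_lambda = fmt(report$loading_between),
    between_r2 = fmt(report$r2_between),
    difference = ifelse(report$anchor, "—", fmt(report$difference)),
    diff_ci_low = fmt(report$diff_ci_low),
    diff_ci_high = fmt(report$diff_ci_high),
    flag = ifelse(!report$anchor & !is.na(report$invariant) &
                    !report$invariant, "*", ""),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Parse a rendered measurement table
#'
#' Inverse of [render_measurement_table()] for the numeric fields.
#'
#' @param path CSV path written by [render_measurement_table()].
#' @return data.frame with numeric columns restored (anchor difference NA).
#' @export
parse_measurement_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                        colClasses = "character")
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == "—", NA, x)))
  for (col in setdiff(names(df), c("item", "flag"))) df[[col]] <- num(df[[col]])
  df
}

#' Read a pipeline run configuration from YAML
#'
#' The YAML names the mode (`simulate`, `fit`, or `simulate-and-recover`),
#' file locations, the model block (item columns, anchor, covariates) and
#' the MCMC block (chains, iterations, PSR threshold, seed, ...).
#'
#' @param path YAML file path.
#' @return config list (validated by [run_pipeline()]).
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  substr(unname(tools::md5sum(tmp)), 1, 8)
}

settings_from_config <- function(mcmc) {
  do.call(mcmc_settings, mcmc[intersect(names(mcmc),
    names(formals(mcmc_settings)))])
}

#' Run the full analysis pipeline
#'
#' Orchestrates, in order: data simulation or loading, panel validation,
#' optional data-driven anchor selection, the unconditional fit with its
#' measurement and structural tables, and (when covariates are configured)
#' the conditional fit with its covariate-effect table. Every artifact is
#' stamped with the configuration hash and seed via the run manifest. The
#' conditional fit only runs after the unconditional fit converged, unless
#' `config$allow_unconverged` is set.
#'
#' @param config configuration list (or a YAML path understood by
#'   [read_run_config()]): fields `mode` (`"simulate"`, `"fit"`,
#'   `"simulate-and-recover"`), `out_dir`, `paths` (input CSV for fit
#'   mode), `model` (item_ids, anchor_item, covariate_ids, select_anchor
#'   flag), `mcmc` (passed to [mcmc_settings()]), `simulate` (n,
#'   missing_rate, profile) for the simulation modes.
#' @return list with `status` (0 on success) and `manifest` (artifact
#'   paths and run metadata); the manifest is also written as JSON.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  mode <- match.arg(config$mode, c("simulate", "fit", "simulate-and-recover"))
  if (!is.null(config$model$n_factors) && config$model$n_factors > 1) {
    stop("config error: one factor per run; joint multi-factor dynamic ",
         "models are out of scope (see package non-goals)", call. = FALSE)
  }
  out_dir <- config$out_dir %||% stop("config error: out_dir required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  settings <- settings_from_config(config$mcmc %||% list())
  manifest <- list(mode = mode, seed = settings$seed,
                   config_hash = config_hash(config), artifacts = list())
  add_artifact <- function(name, path) {
    manifest$artifacts[[name]] <<- path
  }

  sim <- NULL
  if (mode %in% c("simulate", "simulate-and-recover")) {
    scfg <- config$simulate %||% list()
    params <- default_true_params(scfg$profile %||% "depression")
    sim <- simulate_panel(
      params, n = scfg$n %||% 333,
      missing_rate = scfg$missing_rate %||% 0,
      covariates = if (is.null(params$beta)) NULL else "bernoulli",
      seed = settings$seed)
    write_simulation(sim, out_dir)
    add_artifact("panel", file.path(out_dir, "panel.csv"))
    add_artifact("truth_sidecar", file.path(out_dir, "truth_params.yaml"))
    add_artifact("true_random_effects", file.path(out_dir, "random_effects.csv"))
    panel <- sim$panel
    item_ids <- params$item_ids
    anchor <- params$anchor_item
    covariate_ids <- if (is.null(params$beta)) character() else names(params$beta)
  } else {
    item_ids <- config$model$item_ids %||%
      stop("config error: model$item_ids required in fit mode")
    anchor <- config$model$anchor_item %||% item_ids[1]
    covariate_ids <- config$model$covariate_ids %||% character()
    input <- config$paths$input %||% stop("config error: paths$input required")
    if (!file.exists(input)) stop("config error: input file not found: ", input)
    header <- names(utils::read.csv(input, nrows = 1))
    absent <- setdiff(c(item_ids, covariate_ids), header)
    if (length(absent) > 0) {
      stop("config error: input panel lacks configured column(s): ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    panel <- read_panel(input, item_ids, covariate_ids)
  }

  vrep <- validate_panel(panel)
  vpath <- file.path(out_dir, "validation.json")
  jsonlite::write_json(list(
    n_persons = vrep$n_persons, n_rows = vrep$n_rows,
    series_length_summary = as.list(vrep$series_length_summary),
    missing_rate_per_item = as.list(vrep$missing_rate_per_item),
    dropped_persons = vrep$dropped_persons), vpath,
    auto_unbox = TRUE, digits = NA)
  add_artifact("validation", vpath)
  if (mode == "simulate") {
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
    return(list(status = 0L, manifest = manifest))
  }

  spec <- dsem_model_spec(item_ids, anchor_item = anchor)
  if (isTRUE(config$model$select_anchor)) {
    sel <- select_anchor(panel, spec, settings)
    spec <- dsem_model_spec(item_ids, anchor_item = sel$anchor)
    apath <- file.path(out_dir, "anchor_selection.json")
    jsonlite::write_json(list(anchor = sel$anchor,
                              invariant_set = sel$invariant_set),
                         apath, auto_unbox = TRUE, digits = NA)
    add_artifact("anchor_selection", apath)
  }

  fit <- converge_and_rerun(panel, spec, settings)
  add_artifact("unconditional_summary",
               file.path(out_dir, "unconditional_summary.csv"))
  utils::write.csv(fit$summary, manifest$artifacts$unconditional_summary,
                   row.names = FALSE)
  meas <- item_psychometrics(fit$samples)
  render_measurement_table(meas, file.path(out_dir, "measurement_table.csv"))
  add_artifact("measurement_table", file.path(out_dir, "measurement_table.csv"))
  struct <- structural_summary(fit$samples)
  utils::write.csv(struct, file.path(out_dir, "structural_table.csv"),
                   row.names = FALSE)
  add_artifact("structural_table", file.path(out_dir, "structural_table.csv"))

  status <- if (fit$converged) 0L else 1L
  cond_ok <- fit$converged || isTRUE(config$allow_unconverged)
  if (length(covariate_ids) > 0 && cond_ok) {
    cspec <- dsem_model_spec(item_ids, anchor_item = spec$anchor_item,
                             covariate_ids = covariate_ids)
    cfit <- converge_and_rerun(panel, cspec, settings)
    betas <- do.call(rbind, lapply(covariate_ids, function(cv) {
      ce <- conditional_effects(cfit$samples, cv)
      ce$covariate <- cv
      ce
    }))
    utils::write.csv(betas, file.path(out_dir, "conditional_effects.csv"),
                     row.names = FALSE)
    add_artifact("conditional_effects",
                 file.path(out_dir, "conditional_effects.csv"))
    if (!cfit$converged) status <- 1L
  }

  if (mode == "simulate-and-recover") {
    truth <- structural_truth(sim$params)
    rec <- merge(struct, truth, by = "parameter", sort = FALSE)
    rec$covered <- rec$ci_low <= rec$truth & rec$truth <= rec$ci_high
    utils::write.csv(rec, file.path(out_dir, "recovery_report.csv"),
                     row.names = FALSE)
    add_artifact("recovery_report", file.path(out_dir, "recovery_report.csv"))
  }

  manifest$converged <- fit$converged
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  add_artifact("manifest", manifest_path)
  list(status = status, manifest = manifest)
}

# structural truth table matching structural_summary() parameter labels
structural_truth <- function(params) {
  S <- params$Sigma_b
  data.frame(
    parameter = c("phi_mean", "phi_var", "zeta_mean", "zeta_var", "eta_b_var",
                  "r_phi_zeta", "r_phi_eta", "r_zeta_eta"),
    truth = c(params$gamma[2], S[2, 2], params$gamma[3], S[3, 3], S[1, 1],
              S[2, 3] / sqrt(S[2, 2] * S[3, 3]),
              S[1, 2] / sqrt(S[1, 1] * S[2, 2]),
              S[1, 3] / sqrt(S[1, 1] * S[3, 3])),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
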