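## Dataset I/O, min-max normalization and the configuration-driven entry
## points behind the command-line tool (inst/cli/sccr.R).
##
## CSV dialect is fixed (comma separator, '.' decimal, UTF-8, header
## required) to avoid locale drift.

SC_MODEL_COLS <- c("time1", "status1", "time2", "status2")

#' Read a semi-competing risks dataset from CSV
#'
#' Expects the header columns `time1, status1, time2, status2` followed by
#' zero or more covariate columns, one row per subject.  Rows with missing
#' values in any model column are excluded with a message reporting the
#' count; rows violating the semi-competing invariants (nonnegative times,
#' `time1 <= time2`, binary statuses, `status1 == 0` implying
#' `time1 == time2`) raise an error naming the offending rows.
#'
#' @param path CSV file path.
#' @param covariates optional character vector restricting/ordering the
#'   covariate columns; default: every non-model column.
#' @return a validated data frame.
#' @export
read_semicomp <- function(path, covariates = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(SC_MODEL_COLS, names(df))
  if (length(miss))
    stop("schema error: missing columns ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(covariates)) covariates <- setdiff(names(df), SC_MODEL_COLS)
  missc <- setdiff(covariates, names(df))
  if (length(missc))
    stop("schema error: missing covariate columns ",
         paste(missc, collapse = ", "), call. = FALSE)
  df <- df[, c(SC_MODEL_COLS, covariates), drop = FALSE]
  nac <- !stats::complete.cases(df)
  if (any(nac)) {
    message("read_semicomp: excluding ", sum(nac),
            " partially observed rows (missing model columns)")
    df <- df[!nac, , drop = FALSE]
  }
  bad <- which(df$time1 < 0 | df$time1 > df$time2)
  if (length(bad))
    stop("rows violate 0 <= time1 <= time2: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  bad <- which(!(df$status1 %in% c(0, 1)) | !(df$status2 %in% c(0, 1)))
  if (length(bad))
    stop("rows with non-binary status: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  bad <- which(df$status1 == 0 & df$time1 != df$time2)
  if (length(bad))
    stop("rows with status1 == 0 but time1 != time2: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  rownames(df) <- NULL
  df
}

#' Write a semi-competing risks dataset to CSV
#'
#' @param data data frame with the model columns and covariates.
#' @param path output file path.
#' @export
write_semicomp <- function(data, path) {
  miss <- setdiff(SC_MODEL_COLS, names(data))
  if (length(miss))
    stop("data is missing columns ", paste(miss, collapse = ", "),
         call. = FALSE)
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' Min-max normalization
#'
#' Affine rescaling `(v - min) / (max - min)` onto `[0, 1]`, as applied to
#' event times and continuous covariates before fitting, so that all
#' quantities share a common scale.  The affine map is stored in attributes
#' for back-transformation; hazard ratios are unaffected by time rescaling
#' under the exponential link, but intercepts and shapes are reported on
#' the normalized scale.
#'
#' @param values numeric vector with at least two distinct values.
#' @return rescaled vector with attributes `min` and `range`.
#' @export
minmax_normalize <- function(values) {
  r <- range(values, na.rm = TRUE)
  if (r[1] == r[2])
    stop("minmax_normalize: constant vector", call. = FALSE)
  structure((values - r[1]) / (r[2] - r[1]), min = r[1],
            range = r[2] - r[1])
}

#' Invert a min-max normalization
#'
#' @param values normalized vector (attributes of [minmax_normalize()]), or
#'   any numeric vector if `min`/`range` are given explicitly.
#' @param min,range the affine map; defaults to the attributes of `values`.
#' @export
minmax_denormalize <- function(values, min = attr(values, "min"),
                               range = attr(values, "range")) {
  if (is.null(min) || is.null(range))
    stop("no affine map available", call. = FALSE)
  as.numeric(values) * range + min
}

.read_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path",
                             call. = FALSE)
  config
}

.config_log <- function(path, config, extra = list()) {
  info <- c(list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                 package_version = as.character(
                   utils::packageVersion("sccr")),
                 r_version = as.character(getRversion()),
                 config = config), extra)
  jsonlite::write_json(info, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Configuration-driven model fit with artifacts on disk
#'
#' Reads a dataset, optionally min-max normalizes the event times and
#' selected covariates, fits the model and writes: a coefficient table and
#' hazard-ratio/copula-coefficient tables (CSV), a full JSON dump of the
#' fit, and a JSON log with the resolved configuration.  Non-converged fits
#' are written with explicit flags rather than raising.
#'
#' Config fields: `data` (CSV path), `covariates` (character), `copula`,
#' `margins`, `procedure`, `optimizer`, `normalize_times` (logical),
#' `normalize_covariates` (character subset), `seed`, `grid`, `bounds`,
#' `control`, `output_dir`.
#'
#' @param config a list or path to a YAML file.
#' @return the `"sccr"` fit, invisibly.
#' @export
sccr_cli_fit <- function(config) {
  cfg <- .read_config(config)
  if (is.null(cfg$data) || is.null(cfg$output_dir))
    stop("config requires 'data' and 'output_dir'", call. = FALSE)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  dat <- read_semicomp(cfg$data, cfg$covariates)
  covariates <- setdiff(names(dat), SC_MODEL_COLS)
  norm_map <- list()
  if (isTRUE(cfg$normalize_times)) {
    tall <- minmax_normalize(c(dat$time1, dat$time2))
    norm_map$time <- list(min = attr(tall, "min"),
                          range = attr(tall, "range"))
    dat$time1 <- (dat$time1 - norm_map$time$min) / norm_map$time$range
    dat$time2 <- (dat$time2 - norm_map$time$min) / norm_map$time$range
  }
  for (cv in intersect(cfg$normalize_covariates, covariates)) {
    v <- minmax_normalize(dat[[cv]])
    norm_map[[cv]] <- list(min = attr(v, "min"), range = attr(v, "range"))
    dat[[cv]] <- as.numeric(v)
  }
  spec <- sccr_spec(cfg$copula %||% "clayton",
                    (cfg$margins %||% c("exponential", "exponential"))[1],
                    (cfg$margins %||% c("exponential", "exponential"))[2],
                    covariates)
  fit <- sccr_fit(dat, spec,
                  procedure = cfg$procedure %||% "two_step",
                  optimizer = cfg$optimizer %||% "bobyqa",
                  grid = cfg$grid %||% list(),
                  bounds = cfg$bounds %||% list(),
                  control = cfg$control %||% list())
  coefs <- data.frame(parameter = spec$par_names,
                      estimate = unname(fit$coefficients),
                      se = unname(fit$se),
                      lower = unname(fit$ci[, 1]),
                      upper = unname(fit$ci[, 2]))
  utils::write.csv(coefs, file.path(cfg$output_dir, "coefficients.csv"),
                   row.names = FALSE)
  utils::write.csv(hazard_ratio_table(fit),
                   file.path(cfg$output_dir, "hazard_ratios.csv"),
                   row.names = FALSE)
  utils::write.csv(copula_coef_table(fit),
                   file.path(cfg$output_dir, "copula_coefficients.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(coefficients = as.list(fit$coefficients),
         se = as.list(fit$se), loglik = fit$loglik, aic = fit$aic,
         converged = fit$converged, inference_ok = fit$inference_ok,
         message = fit$message, procedure = fit$procedure,
         optimizer = fit$optimizer, n = fit$n,
         normalization = norm_map),
    file.path(cfg$output_dir, "fit.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  .config_log(file.path(cfg$output_dir, "run_log.json"), cfg,
              list(normalization = norm_map,
                   grid = fit$grid, bounds = fit$bounds))
  invisible(fit)
}

#' Configuration-driven simulation study with artifacts on disk
#'
#' Builds a design from the config, runs [sccr_sim_study()] and writes the
#' per-replicate estimates (CSV), the aggregate MSE/CP table (CSV, one row
#' per parameter with one MSE/CP column pair per procedure), and a JSON
#' metadata log including the resolved censoring bound, seeds and
#' exclusion counts.
#'
#' Config fields: `copula`, `margins`, `truth` (list: `beta_nt`, `beta_t`,
#' `b`, `alpha_nt`, `alpha_t`), `n`, `reps`, `procedures`, `optimizer`,
#' `seed`, `censoring_upper`, `output_dir`.
#'
#' @param config a list or path to a YAML file.
#' @return the `"sccr_sim_study"` result, invisibly.
#' @export
sccr_cli_simulate <- function(config) {
  cfg <- .read_config(config)
  if (is.null(cfg$output_dir))
    stop("config requires 'output_dir'", call. = FALSE)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  tr <- cfg$truth %||% list()
  design <- sccr_design(copula = cfg$copula %||% "clayton",
                        margins = cfg$margins %||%
                          c("exponential", "exponential"),
                        beta_nt = tr$beta_nt, beta_t = tr$beta_t, b = tr$b,
                        alpha_nt = tr$alpha_nt, alpha_t = tr$alpha_t,
                        n = cfg$n %||% 3000,
                        censoring_upper = cfg$censoring_upper)
  study <- sccr_sim_study(design, reps = cfg$reps %||% 500,
                          procedures = cfg$procedures %||%
                            c("two_stage", "two_step"),
                          optimizer = cfg$optimizer %||% "bobyqa",
                          seed = cfg$seed %||% 1,
                          grid = cfg$grid %||% list(),
                          bounds = cfg$bounds %||% list(),
                          control = cfg$control %||% list())
  for (pr in study$procedures) {
    df <- as.data.frame(study$estimates[[pr]])
    df$included <- study$included[, pr]
    utils::write.csv(df,
                     file.path(cfg$output_dir,
                               paste0("estimates_", pr, ".csv")),
                     row.names = FALSE)
  }
  agg <- data.frame(parameter = design$spec$par_names,
                    true_value = unname(design$truth))
  for (pr in study$procedures) {
    agg[[paste0(pr, "_mse")]] <- unname(study$mse[, pr])
    agg[[paste0(pr, "_cp")]] <- unname(study$cp[, pr])
  }
  utils::write.csv(agg, file.path(cfg$output_dir, "aggregate_mse_cp.csv"),
                   row.names = FALSE)
  .config_log(file.path(cfg$output_dir, "study_log.json"), cfg,
              list(censoring_upper = study$censoring_upper,
                   base_seed = study$seed,
                   n_excluded = as.list(study$n_excluded),
                   unreliable = as.list(study$unreliable),
                   elapsed_seconds = study$elapsed))
  invisible(study)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
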