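# Configuration, CSV I/O and the end-to-end pipeline.

plate_schema <- c("condition", "replicate", "ca_free_uM", "em480", "em535")

#' Write a plate-reader dataset to CSV
#'
#' @param dataset a `camnet_plate` data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(dataset, path) {
  if (!all(plate_schema %in% names(dataset)))
    stop("dataset must have columns: ", paste(plate_schema, collapse = ", "))
  utils::write.csv(as.data.frame(dataset)[, plate_schema], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a plate-reader dataset from CSV
#'
#' Expects the columns `condition`, `replicate`, `ca_free_uM`, `em480`,
#' `em535`. Malformed rows (nonnumeric or nonpositive intensities,
#' negative Ca2+) are dropped and reported with their line numbers.
#'
#' @param path CSV file path.
#' @return A `camnet_plate` data.frame of the valid records.
#' @export
read_plate_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(raw) == 0 && ncol(raw) <= 1)
    stop("empty or headerless file: ", path)
  missing <- setdiff(plate_schema, names(raw))
  if (length(missing) > 0)
    stop("missing column(s): ", paste(missing, collapse = ", "))
  num <- function(v) suppressWarnings(as.numeric(v))
  d <- data.frame(condition = raw$condition,
                  replicate = num(raw$replicate),
                  ca_free_uM = num(raw$ca_free_uM),
                  em480 = num(raw$em480), em535 = num(raw$em535),
                  stringsAsFactors = FALSE)
  bad <- is.na(d$replicate) | is.na(d$ca_free_uM) | is.na(d$em480) |
    is.na(d$em535) | d$ca_free_uM < 0 | d$em480 <= 0 | d$em535 <= 0
  if (any(bad))
    warning("rejected ", sum(bad), " malformed row(s) at line(s): ",
            paste(which(bad) + 1L, collapse = ", "))
  d <- d[!bad, , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("camnet_plate", "data.frame")
  d
}

config_defaults <- function() {
  list(
    K9_per_uM = 0.078, K_M_N_per_uM = 0.078, K4_per_uM = 16.7,
    K2_per_uM = 1000, ca_assoc_N_per_uMh = 0.01, ca_assoc_C_per_uMh = 0.25,
    hill_exp = 2L,
    cam_tot_uM = 0.713, mlck_tot_uM = 0.0237,
    generating_model = 2L,
    mutants = c("WT", "N", "C", "NC"),
    ladder_uM = default_ladder(),
    n_replicates = as.list(default_replicates()),
    r0 = 0.5, delta_r = 0.5, channel_cv = 0.02, baseline_535 = 10000,
    alpha = 0.05, low_auc_range_uM = c(0, 0.038),
    detection_limit = 0.09,
    seed = 1L,
    data_csv = NULL, output_dir = NULL
  )
}

#' Build or read a validated run configuration
#'
#' `run_config()` merges overrides into the defaults and validates
#' every field (unknown keys are rejected). `read_run_config()` reads
#' the same structure from a YAML file; `write_run_config()` writes
#' one. Key names carry explicit units (`*_uM`, `*_per_uM`).
#'
#' @param ... named overrides of the default fields (equilibrium
#'   constants, totals, ladder, replicate counts, noise and ratio-map
#'   settings, test thresholds, `seed`, optional `data_csv` to ingest a
#'   measured plate CSV instead of simulating, optional `output_dir`
#'   for artifacts).
#' @return A validated list of class `camnet_config`.
#' @examples
#' cfg <- run_config(seed = 7, channel_cv = 0)
#' @export
run_config <- function(...) {
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]]))
    over <- over[[1]]
  defaults <- config_defaults()
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over, keep.null = TRUE)
  # validation
  num1 <- function(key, lo = 0) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < lo)
      stop("config field ", key, " must be a single number >= ", lo)
  }
  for (k in c("K9_per_uM", "K_M_N_per_uM", "K4_per_uM", "K2_per_uM",
              "ca_assoc_N_per_uMh", "ca_assoc_C_per_uMh", "cam_tot_uM",
              "mlck_tot_uM", "r0", "delta_r", "channel_cv")) num1(k)
  num1("baseline_535", lo = 1e-12)
  if (!cfg$generating_model %in% 1:3) stop("generating_model must be 1, 2 or 3")
  if (!all(cfg$mutants %in% c("WT", "N", "C", "NC")))
    stop("mutants must be among WT, N, C, NC")
  if (any(diff(cfg$ladder_uM) <= 0) || any(cfg$ladder_uM < 0))
    stop("ladder_uM must be strictly increasing and >= 0")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)")
  if (cfg$detection_limit < 0 || cfg$detection_limit > 1)
    stop("detection_limit must be in [0, 1]")
  reps <- unlist(cfg$n_replicates)
  if (any(reps < 1)) stop("replicate counts must be >= 1")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "camnet_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  run_config(yaml::read_yaml(path))
}

#' @rdname run_config
#' @param config a `camnet_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "camnet_config"))
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

config_params <- function(cfg) {
  camnet_params(k_apo = cfg$K9_per_uM, k_nlobe = cfg$K_M_N_per_uM,
                k_clobe = cfg$K4_per_uM, k_both = cfg$K2_per_uM,
                ca_assoc_N = cfg$ca_assoc_N_per_uMh,
                ca_assoc_C = cfg$ca_assoc_C_per_uMh,
                hill_exp = cfg$hill_exp)
}

#' Run the full model-discrimination pipeline
#'
#' Simulates a plate-reader dataset under the configured generating
#' model (or ingests a measured CSV when `data_csv` is set), computes
#' emission ratios, applies the two-statistic decision rule per
#' condition and regime, scores all three mechanisms against the
#' observed calls, and optionally writes curves, the prediction table,
#' the dataset and the report to `output_dir`. Fully deterministic for
#' a fixed config seed.
#'
#' @param config a `camnet_config` from [run_config()] or
#'   [read_run_config()].
#' @return A list of class `camnet_run`: `config`, `dataset`, `ratios`,
#'   `observed` (calls with p-values), `predictions` (structural
#'   table), `report` (a `camnet_report`).
#' @examples
#' \donttest{
#' run <- run_pipeline(run_config(seed = 1))
#' run$report$summary
#' }
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "camnet_config"))
  params <- config_params(config)
  conc <- concentrations(config$cam_tot_uM, config$mlck_tot_uM)
  dataset <- if (!is.null(config$data_csv)) {
    read_plate_csv(config$data_csv)
  } else {
    simulate_fret(params = params, model = config$generating_model,
                  mutants = config$mutants, conc = conc,
                  ladder = config$ladder_uM,
                  n_replicates = unlist(config$n_replicates),
                  ratio_map = c(r0 = config$r0, delta_r = config$delta_r),
                  noise = noise_model(channel_cv = config$channel_cv,
                                      baseline_535 = config$baseline_535),
                  seed = config$seed)
  }
  ratios <- compute_ratios(dataset)
  observed <- observed_calls(ratios, alpha = config$alpha,
                             low_range = config$low_auc_range_uM)
  mutants <- setdiff(unique(ratios$condition), "baseline")
  predictions <- predict_table(params, models = 1:3, mutants = mutants,
                               conc = conc)
  report <- classify_models(observed[, c("mutant", "regime", "call")],
                            predictions)
  out <- list(config = config, dataset = dataset, ratios = ratios,
              observed = observed, predictions = predictions,
              report = report)
  class(out) <- "camnet_run"
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$output_dir
    write_plate_csv(dataset, file.path(od, "plate.csv"))
    write_predictions_csv(predictions, file.path(od, "predictions.csv"))
    utils::write.csv(observed, file.path(od, "observed_calls.csv"),
                     row.names = FALSE)
    utils::write.csv(report$summary, file.path(od, "report_summary.csv"),
                     row.names = FALSE)
    for (mu in mutants) {
      cur <- titration_curve(cam_mlck_model(config$generating_model, mu,
                                            params, conc$cam_tot,
                                            conc$mlck_tot),
                             config$ladder_uM)
      write_curve_csv(cur, file.path(od, paste0("curve_", mu, ".csv")))
    }
    writeLines(c(sprintf("seed: %d", config$seed),
                 sprintf("generating_model: %d", config$generating_model),
                 utils::capture.output(print(report))),
               file.path(od, "report.txt"))
  }
  out
}

#' @export
print.camnet_run <- function(x, ...) {
  cat(sprintf("Pipeline run (seed %d, generating model %d, %d wells)\n\n",
              x$config$seed, x$config$generating_model, nrow(x$dataset)))
  print(x$report)
  invisible(x)
}
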