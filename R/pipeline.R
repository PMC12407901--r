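# polynomial rolling hash (mod 2^31 - 1) of a character vector, for config
# provenance stamps
.config_hash <- function(lines) {
  bytes <- utf8ToInt(paste(lines, collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 257 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Read a flat key-value run configuration
#'
#' One `key = value` pair per line; blank lines and `#` comments ignored.
#' Values that parse as numbers are returned numeric. The raw lines are
#' kept so the configuration can be re-serialized (and hashed) into the
#' output directory.
#'
#' @param path Config file path.
#' @return Named list of class `"run_config"` with attributes `lines` and
#'   `hash`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- grepl("=", lines) & !grepl("^\\s*#", lines)
  kv <- strsplit(lines[keep], "=", fixed = TRUE)
  out <- list()
  for (p in kv) {
    key <- trimws(p[[1]])
    val <- trimws(paste(p[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  structure(out, lines = lines, hash = .config_hash(lines),
            class = "run_config")
}

.cfg_get <- function(config, key, default = NULL) {
  if (!is.null(config[[key]])) return(config[[key]])
  if (is.null(default)) stop("config key missing: ", key)
  default
}

.stamp <- function(config) {
  c(sprintf("package_version = %s",
            as.character(utils::packageVersion("ghkselect"))),
    sprintf("config_hash = %s", attr(config, "hash")),
    sprintf("run_time = %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
}

.write_run_provenance <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(attr(config, "lines"), file.path(out_dir, "run_config.txt"))
  writeLines(.stamp(config), file.path(out_dir, "provenance.txt"))
}

#' Run the full selectivity pipeline from a configuration
#'
#' Reads the per-replicate measurement table (`measurements_csv`: columns
#' `replicate_id`, `g_frt`, `g_total`, `v_frt_raw`, `v_t_raw`,
#' `v_junction`) and the two bath recipes, fits [fit_selectivity()], and
#' writes `per_replicate.csv`, `estimate.csv`, a human-readable
#' `summary.txt` (including per-replicate exclusion reasons), the
#' re-serialized configuration and a provenance stamp (package version +
#' config hash) into `output_dir`. Deterministic given inputs and
#' configuration.
#'
#' Config keys: `measurements_csv`, `high_recipe`, `low_recipe`,
#' `output_dir`; optional `slope` ("paper"/"exact"), `guard_mV`,
#' `shared_gamma` (0/1).
#'
#' @param config A `"run_config"` from [read_run_config()], or a path to
#'   one.
#' @return The `"ghk_fit"`, invisibly.
#' @export
run_selectivity <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  meas_path <- .cfg_get(config, "measurements_csv")
  if (!file.exists(meas_path)) stop("measurements file not found: ", meas_path)
  high <- read_solution(.cfg_get(config, "high_recipe"))
  low <- read_solution(.cfg_get(config, "low_recipe"))
  out_dir <- .cfg_get(config, "output_dir")
  meas <- utils::read.csv(meas_path, stringsAsFactors = FALSE)
  fit <- fit_selectivity(
    meas, high_solution = high, low_solution = low,
    slope = .cfg_get(config, "slope", "paper"),
    guard_mV = .cfg_get(config, "guard_mV", 0.1),
    shared_gamma = as.logical(.cfg_get(config, "shared_gamma", 0)))

  .write_run_provenance(config, out_dir)
  utils::write.csv(fit$replicates, file.path(out_dir, "per_replicate.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(p_cl_na_mean = fit$estimate$mean, sem = fit$estimate$sem,
               n_valid = fit$estimate$n, n_total = nrow(fit$replicates)),
    file.path(out_dir, "estimate.csv"), row.names = FALSE)
  con <- file(file.path(out_dir, "summary.txt"), "w")
  sink(con); on.exit({ sink(); close(con) })
  writeLines(.stamp(config))
  summary(fit)
  invisible(fit)
}

#' Run the supporting assay quantifications from a configuration
#'
#' Quantifies whichever assay inputs the configuration names and writes
#' tidy CSV outputs plus a provenance stamp into `output_dir`. Recognized
#' keys (all optional, but at least one input is required):
#' \describe{
#'   \item{`ise_csv`}{ISE trace (`time_min`, `chloride_ppm`) ->
#'     `efflux.csv` with the percent chloride efflux.}
#'   \item{`plate_csv`}{Plate table (`well`, `role`, `fluorescence`, ...)
#'     -> `viability.csv`.}
#'   \item{`growth_csv`}{Yeast growth table -> `rescue_by_dose.csv` and
#'     `rescue_max.csv`.}
#'   \item{`secretion_csv`}{Counts table (`treatment`, `counts`; vehicle
#'     rows labelled `vehicle`) -> `secretion_fold.csv`.}
#' }
#' Plus `output_dir`, and optionally `ise_compound_min`, `ise_triton_min`,
#' `rescue_mode`.
#'
#' @param config A `"run_config"` or path to one.
#' @return Named list of the computed results, invisibly.
#' @export
run_assays <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- .cfg_get(config, "output_dir")
  results <- list()

  if (!is.null(config[["ise_csv"]])) {
    df <- utils::read.csv(config[["ise_csv"]])
    tr <- ise_trace(df$time_min, df$chloride_ppm,
                    .cfg_get(config, "ise_compound_min", 2),
                    .cfg_get(config, "ise_triton_min", 12))
    pct <- chloride_efflux_percent(tr)
    results$efflux <- data.frame(efflux_percent = as.numeric(pct),
                                 flag = attr(pct, "flag"))
  }
  if (!is.null(config[["plate_csv"]])) {
    df <- utils::read.csv(config[["plate_csv"]], stringsAsFactors = FALSE)
    results$viability <- viability_percent(plate_readings(df))
  }
  if (!is.null(config[["growth_csv"]])) {
    df <- utils::read.csv(config[["growth_csv"]], stringsAsFactors = FALSE)
    rs <- rescue_percent(growth_table(df),
                         mode = .cfg_get(config, "rescue_mode", "vehicle_wt"))
    results$rescue_by_dose <- rs$by_dose
    results$rescue_max <- rs$max_rescue
  }
  if (!is.null(config[["secretion_csv"]])) {
    df <- utils::read.csv(config[["secretion_csv"]], stringsAsFactors = FALSE)
    veh <- df$counts[df$treatment == "vehicle"]
    trt <- df[df$treatment != "vehicle", , drop = FALSE]
    trt$fold_of_vehicle <- normalize_to_vehicle(trt$counts, veh)
    results$secretion <- trt
  }
  if (!length(results))
    stop("config names no assay inputs ",
         "(ise_csv / plate_csv / growth_csv / secretion_csv)")

  .write_run_provenance(config, out_dir)
  files <- c(efflux = "efflux.csv", viability = "viability.csv",
             rescue_by_dose = "rescue_by_dose.csv",
             rescue_max = "rescue_max.csv", secretion = "secretion_fold.csv")
  for (nm in names(results))
    utils::write.csv(results[[nm]], file.path(out_dir, files[[nm]]),
                     row.names = FALSE)
  invisible(results)
}
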