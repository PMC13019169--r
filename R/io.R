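# Configuration, CSV/JSON schema validation, seeded-run manifests and the
# end-to-end pipeline runner.

#' Write / read an activity or simulation trace CSV
#'
#' Traces are written as RFC-4180 CSV with header `time,activity[,mean_m]`;
#' simulation metadata goes to a JSON sidecar (`<path>.json`) with the full
#' resolved parameter record and seed for bit-exact replay.
#'
#' @param trace a `sim_trace` or data.frame with `time`, `activity`.
#' @param path output CSV path.
#' @param sidecar write the JSON sidecar (default TRUE for `sim_trace`).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, sidecar = inherits(trace, "sim_trace")) {
  df <- as.data.frame(trace)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    meta <- attr(trace, "meta")
    cfg <- list(params = unclass(meta$params),
                adapt = if (!is.null(meta$adapt)) unclass(meta$adapt),
                seed = meta$seed, sample_interval = meta$sample_interval,
                n_events = meta$n_events)
    jsonlite::write_json(cfg, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- read.csv(path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    attr(df, "meta") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  df
}

#' Write / read stimulus windows JSON
#'
#' @param windows a [stimulus_windows()] object.
#' @param path JSON path.
#' @export
write_windows <- function(windows, path) {
  jsonlite::write_json(
    list(attractant = unname(split(windows$attractant, seq_len(nrow(windows$attractant)))),
         repellent = unname(split(windows$repellent, seq_len(nrow(windows$repellent))))),
    path, digits = NA)
  invisible(path)
}

#' @rdname write_windows
#' @export
read_windows <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  stimulus_windows(attractant = x$attractant, repellent = x$repellent)
}

schema_defs <- list(
  trace = list(cols = c("time", "activity")),
  activity = list(cols = c("cell_id", "time", "activity")),
  traces = list(cols = c("cell_id", "time", "donor", "acceptor")),
  events = list(cols = c("t_event", "direction", "amplitude", "tau",
                         "residence")),
  summary = list(cols = c("cell_id", "bias", "delta_G", "n_events", "r")),
  sweep = list(cols = c("L", "J", "H_b", "n_events", "mean_dt", "mean_tau",
                        "r", "polarized", "seed")),
  isoline = list(cols = c("r_target", "L", "J_iso", "pct_dev")),
  responses = list(cols = c("J", "dH", "t_R", "amplitude", "speed")))

#' Validate a table or file against a named schema
#'
#' Checks required columns and basic invariants (monotone time within each
#' cell, positive donor, activity ranges sane) and returns a pass/fail
#' report with row-level diagnostics. Window JSON files are validated with
#' `schema = "windows"` (non-overlap, t1 > t0).
#'
#' @param x data.frame or path to a CSV/JSON file.
#' @param schema one of `"trace"`, `"activity"`, `"traces"`, `"events"`,
#'   `"summary"`, `"sweep"`, `"isoline"`, `"responses"`, `"windows"`.
#' @return list `ok` (logical) and `problems` (character vector).
#' @export
validate <- function(x, schema) {
  if (schema == "windows") {
    w <- tryCatch(if (is.character(x)) read_windows(x) else
      stimulus_windows(x$attractant, x$repellent),
      error = function(e) e)
    if (inherits(w, "error"))
      return(list(ok = FALSE, problems = conditionMessage(w)))
    return(list(ok = TRUE, problems = character(0)))
  }
  if (!schema %in% names(schema_defs)) stop("unknown schema: ", schema)
  if (is.character(x)) x <- read.csv(x)
  def <- schema_defs[[schema]]
  probs <- character(0)
  missing <- setdiff(def$cols, names(x))
  if (length(missing))
    probs <- c(probs, paste("missing columns:", paste(missing, collapse = ", ")))
  if (!length(missing) && "time" %in% def$cols) {
    split_by <- if ("cell_id" %in% names(x)) x$cell_id else rep(1, nrow(x))
    for (id in unique(split_by)) {
      tt <- x$time[split_by == id]
      bad <- which(diff(tt) <= 0)
      if (length(bad))
        probs <- c(probs, sprintf("non-monotone time for '%s' at row %d",
                                  as.character(id), bad[1]))
    }
  }
  if (!length(missing) && "donor" %in% def$cols && any(x$donor <= 0))
    probs <- c(probs, sprintf("non-positive donor at row %d",
                              which(x$donor <= 0)[1]))
  list(ok = length(probs) == 0, problems = probs)
}

#' Run the synthetic end-to-end pipeline
#'
#' Chains the stages `synth` (cohort generation), `fret` (preprocessing of
#' the fluorescence channels), `events`/`summary` (switching statistics)
#' with sub-seeds derived from `config$seed`, writing each stage's outputs
#' and a manifest (resolved config, seeds, file digests, package version)
#' under `out_dir`. Identical config and seed give byte-identical outputs.
#'
#' @param config list with `n_cells`, `seed`, and optional overrides
#'   (`bias_range`, `mean_dt`, `sigma`, `duration`, detector settings under
#'   `det`).
#' @param out_dir output directory (created).
#' @return list with the `summary` table, per-stage file paths and the
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("arraycrit_run_")) {
  stopifnot(is.list(config), !is.null(config$n_cells), !is.null(config$seed))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  # stage 1: synthetic cohort
  cohort <- gen_cohort(n_cells = config$n_cells,
                       bias_range = config$bias_range %||% c(0.2, 0.8),
                       mean_dt = config$mean_dt %||% 50,
                       seed = config$seed,
                       sigma = config$sigma %||% 0.15,
                       duration = config$duration %||% 1000,
                       intensity_sigma = config$intensity_sigma %||% 0.01)
  files$traces <- file.path(out_dir, "traces.csv")
  write.csv(cohort$traces, files$traces, row.names = FALSE, quote = FALSE)
  files$windows <- file.path(out_dir, "windows.json")
  write_windows(cohort$windows, files$windows)
  # stage 2: FRET preprocessing per cell
  acts <- lapply(unique(cohort$traces$cell_id), function(id) {
    tr <- cohort$traces[cohort$traces$cell_id == id, ]
    fret_activity(tr, cohort$windows)
  })
  activity <- do.call(rbind, lapply(acts, as.data.frame))
  files$activity <- file.path(out_dir, "activity.csv")
  write.csv(activity, files$activity, row.names = FALSE, quote = FALSE)
  # stage 3: switching statistics
  det <- do.call(event_params, config$det %||% list())
  summary <- if (config$n_cells > 0) analyze_cohort(activity, det) else
    data.frame()
  files$summary <- file.path(out_dir, "summary.csv")
  write.csv(summary, files$summary, row.names = FALSE, quote = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("arraycrit")),
    config = config,
    seed = config$seed,
    digests = vapply(unlist(files), function(f) unname(tools::md5sum(f)),
                     character(1)))
  files$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null")
  list(summary = summary, files = files, manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
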