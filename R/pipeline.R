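#' Build and validate a pipeline configuration
#'
#' Nests the simulation, filter and detection configurations together with
#' run-level settings. Unknown keys in any section are rejected with a
#' message naming the key, so config-file typos fail loudly.
#'
#' @param sim Named list of [sim_config()] arguments (used in simulate
#'   mode).
#' @param filter Named list of [filter_spec()] arguments.
#' @param detect Named list of [detect_config()] arguments.
#' @param out_dir Output directory for events CSV, report JSON and plots.
#' @param seed Integer seed applied to the simulation when `sim$seed` is
#'   absent.
#' @param plots Whether [run_pipeline()] writes diagnostic plots.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = list(), filter = list(), detect = list(),
                            out_dir = ".", seed = 1L, plots = FALSE) {
  check_keys <- function(given, allowed, section) {
    bad <- setdiff(names(given), allowed)
    if (length(bad)) {
      stop_arg("unknown %s config key(s): %s", section,
               paste(bad, collapse = ", "))
    }
  }
  check_keys(sim, names(formals(sim_config)), "sim")
  check_keys(filter, names(formals(filter_spec)), "filter")
  check_keys(detect, names(formals(detect_config)), "detect")
  if (is.null(sim$seed)) sim$seed <- as.integer(seed)
  structure(list(sim = sim, filter = filter, detect = detect,
                 out_dir = out_dir, seed = as.integer(seed), plots = plots),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file may contain `sim`, `filter`, `detect`, `out_dir`, `seed` and
#' `plots` keys, all optional; sections are validated by
#' [pipeline_config()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_arg("config file not found: %s", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  allowed <- c("sim", "filter", "detect", "out_dir", "seed", "plots")
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) {
    stop_arg("unknown top-level config key(s): %s", paste(bad, collapse = ", "))
  }
  if (!is.null(raw$sim$event_schedule)) {
    raw$sim$event_schedule <- lapply(raw$sim$event_schedule,
                                     function(e) do.call(vaso_event_spec, e))
  }
  if (!is.null(raw$sim$artifact_schedule)) {
    raw$sim$artifact_schedule <- lapply(raw$sim$artifact_schedule, unlist)
  }
  pipeline_config(sim = as.list(raw$sim %||% list()),
                  filter = as.list(raw$filter %||% list()),
                  detect = as.list(raw$detect %||% list()),
                  out_dir = raw$out_dir %||% ".",
                  seed = raw$seed %||% 1L,
                  plots = isTRUE(raw$plots))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the end-to-end detection pipeline
#'
#' Reads (or simulates) a recording, filters it, extracts the analytic
#' envelope and baseline, detects and gates beats, segments events, and
#' writes `events.csv` plus `report.json` (and plots if configured) to the
#' output directory. Deterministic given the config and seed.
#'
#' @param config A [pipeline_config()] (or a path to a YAML/JSON config
#'   file).
#' @param input Path to a recording CSV, or `NULL` to simulate from
#'   `config$sim`.
#' @param reference_events Optional path to a reference events CSV (columns
#'   `nadir_s`, `percent`); when given, the pipeline events are paired to it
#'   by nadir time and an [agreement_report()] is added to the report.
#' @return Invisibly, a list with `analysis` (a `ppg_analysis`), `events`,
#'   `report` and the output file paths.
#' @export
run_pipeline <- function(config, input = NULL, reference_events = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_arg("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  rec <- if (is.null(input)) {
    stage("simulate", {
      sim <- simulate_recording(do.call(sim_config, config$sim))
      sim$recording
    })
  } else {
    stage("read", read_recording_csv(input))
  }
  fspec <- stage("filter-spec", do.call(filter_spec, config$filter))
  dcfg <- stage("detect-config", do.call(detect_config, config$detect))
  an <- stage("analyse", process_recording(rec, fspec, dcfg))

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  events_path <- file.path(config$out_dir, "events.csv")
  utils::write.csv(an$events, events_path, row.names = FALSE, quote = FALSE)

  report <- list(
    n_samples = length(rec), rate_hz = rec$rate_hz,
    channel = dcfg$channel, seed = config$seed,
    n_beats = length(an$beats$peak_indices),
    n_beats_accepted = sum(an$beats$accepted),
    n_events = nrow(an$events),
    filter = unclass(fspec), detect = unclass(dcfg))
  if (!is.null(reference_events)) {
    ref <- utils::read.csv(reference_events)
    pairs <- stage("compare", pair_events_by_time(
      an$events$nadir_s, an$events$percent, ref$nadir_s, ref$percent))
    if (pairs$n >= 3L) {
      ag <- agreement_report(pairs)
      report$agreement <- list(
        n = ag$n, agreement_pct = ag$agreement_pct, bias = ag$bias,
        loa_low = ag$loa_low, loa_high = ag$loa_high,
        r_squared = ag$r_squared,
        confusion = as.data.frame(ag$confusion),
        unmatched = c(attr(pairs, "unmatched_a"), attr(pairs, "unmatched_b")))
    } else {
      report$agreement <- list(n = pairs$n,
                               note = "too few paired events for statistics")
    }
  }
  report_path <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  plot_paths <- character(0)
  if (isTRUE(config$plots)) {
    plot_paths <- stage("plots", pipeline_plots(an, rec, config$out_dir))
  }
  invisible(list(analysis = an, events = an$events, report = report,
                 events_path = events_path, report_path = report_path,
                 plot_paths = plot_paths))
}

# Diagnostic plots: envelope + baseline with events, and raw channels.
pipeline_plots <- function(an, rec, out_dir) {
  paths <- character(0)
  t <- rec$timestamp_s
  p1 <- file.path(out_dir, "envelope.png")
  grDevices::png(p1, width = 1000, height = 500)
  plot(t, an$envelope$values, type = "l", col = "grey40",
       xlab = "time (s)", ylab = "envelope (counts)",
       main = sprintf("analytic envelope, %s channel", an$channel))
  graphics::lines(t, an$envelope$baseline, col = "blue", lwd = 2)
  if (nrow(an$events)) {
    graphics::abline(v = an$events$nadir_s, col = "red", lty = 2)
  }
  grDevices::dev.off()
  paths <- c(paths, p1)
  p2 <- file.path(out_dir, "raw.png")
  grDevices::png(p2, width = 1000, height = 500)
  plot(t, rec$ir, type = "l", col = "darkred", xlab = "time (s)",
       ylab = "counts", main = "raw channels (IR dark red, red grey)")
  graphics::lines(t, rec$red, col = "grey50")
  grDevices::dev.off()
  c(paths, p2)
}

#' Bland-Altman plot for an agreement report
#'
#' @param pairs A [paired_events].
#' @param path Output image path (PNG).
#' @return `path`, invisibly.
#' @export
plot_bland_altman <- function(pairs, path) {
  ba <- bland_altman(pairs)
  grDevices::png(path, width = 700, height = 500)
  plot(ba$means, ba$differences, pch = 19,
       xlab = "mean percent constriction", ylab = "difference (A - B)",
       main = "Bland-Altman")
  graphics::abline(h = ba$bias, col = "blue")
  graphics::abline(h = c(ba$loa_low, ba$loa_high), col = "red", lty = 2)
  grDevices::dev.off()
  invisible(path)
}
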