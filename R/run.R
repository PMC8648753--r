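# Orchestration of a full analysis: parse DE tables, retrieve enrichment
# per comparison, store the per-comparison STRING-format files, aggregate
# across comparisons and write the per-kind results/summary tables.

#' Configure an analysis run
#'
#' Collects everything [run_analysis()] needs. Defaults mirror the
#' interactive tool's: mouse, latest STRING version, alpha 0.05, up- and
#' downregulated genes analyzed separately, log-ratio fold changes.
#'
#' @param input_paths Character vector of DE table files (one comparison
#'   each; the file name is the comparison label).
#' @param output_dir Output folder; created if missing.
#' @param settings [analysis_settings()].
#' @param fc_convention Fold-change convention for [split_directions()].
#' @param offline_fixture_dir Optional directory served by
#'   [string_transport_fixture()]; when `NULL` the live
#'   [string_transport_http()] transport is used.
#' @param transport Optional explicit transport overriding the above.
#' @return Object of class `run_config`.
#' @export
run_config <- function(input_paths, output_dir,
                       settings = analysis_settings(),
                       fc_convention = c("log-ratio", "linear-ratio"),
                       offline_fixture_dir = NULL,
                       transport = NULL) {
  if (length(input_paths) == 0L) {
    stop("no input files given", call. = FALSE)
  }
  missing <- input_paths[!file.exists(input_paths)]
  if (length(missing) > 0L) {
    stop("input files not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(input_paths = input_paths, output_dir = output_dir,
         settings = settings, fc_convention = match.arg(fc_convention),
         offline_fixture_dir = offline_fixture_dir, transport = transport),
    class = "run_config"
  )
}

run_transport <- function(config) {
  if (!is.null(config$transport)) return(config$transport)
  if (!is.null(config$offline_fixture_dir)) {
    string_transport_fixture(config$offline_fixture_dir)
  } else {
    string_transport_http()
  }
}

#' Run a full enrichment analysis
#'
#' For every input file: parses the DE table, splits genes by direction,
#' retrieves significance-filtered enrichment per applicable direction, and
#' stores the records as `<DIRECTION>_<kind>.tsv` files in a subfolder of
#' `output_dir` named after the input file. Afterwards directions are
#' merged per comparison and all comparisons are aggregated per knowledge
#' base into `results_<kind>.tsv` and `summary_<kind>.tsv` at the top
#' level. Every step is logged to the console and to `run.log` in the
#' output folder. A comparison that fails (unreadable table, transport
#' failure after retries) is reported and skipped; the remaining
#' comparisons still run.
#'
#' @param config A [run_config()].
#' @param quiet Suppress console logging.
#' @return Object of class `run_report`: list with `output_dir`, `labels`,
#'   `aggregates` ([aggregate_enrichment()] output), `failures` (named
#'   character vector of per-file error messages), `files_written`, and
#'   `status` (0 = success, 1 = partial failure).
#' @export
run_analysis <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$output_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  say <- function(...) {
    msg <- paste0(...)
    writeLines(msg, log_con)
    if (!quiet) message(msg)
  }

  transport <- run_transport(config)
  say("analysis started: ", length(config$input_paths), " input file(s), mode ",
      config$settings$mode, ", species ", config$settings$species,
      ", alpha ", config$settings$alpha)

  per_direction <- list()
  failures <- character(0)
  files_written <- character(0)
  labels <- character(0)

  for (path in config$input_paths) {
    result <- tryCatch({
      de <- parse_de_table(path)
      say("parsed ", basename(path), ": ", length(de$genes), " genes (",
          de$n_skipped, " rows skipped)")
      sets <- split_directions(de, config$fc_convention)
      enr <- fetch_enrichment(sets, config$settings, transport, de$label)
      cmp_dir <- file.path(config$output_dir, de$label)
      dir.create(cmp_dir, showWarnings = FALSE)
      for (ce in enr) {
        for (kind in names(ce$records)) {
          f <- file.path(cmp_dir, paste0(ce$direction, "_", kind, ".tsv"))
          write_enrichment_tsv(ce$records[[kind]], f)
          files_written <- c(files_written, f)
        }
        say("  ", de$label, " [", ce$direction, "]: ",
            sum(vapply(ce$records, nrow, integer(1))), " significant term(s)")
      }
      list(label = de$label, enr = enr)
    }, error = function(e) e)
    if (inherits(result, "error")) {
      failures[[basename(path)]] <- conditionMessage(result)
      say("FAILED ", basename(path), ": ", conditionMessage(result))
    } else {
      labels <- c(labels, result$label)
      per_direction <- c(per_direction, result$enr)
    }
  }

  if (length(per_direction) == 0L) {
    say("run aborted: every comparison failed")
    stop("all retrievals failed:\n",
         paste0("  ", names(failures), ": ", failures, collapse = "\n"),
         call. = FALSE)
  }

  aggregates <- aggregate_enrichment(per_direction)
  for (kind in names(aggregates)) {
    rf <- file.path(config$output_dir, paste0("results_", kind, ".tsv"))
    sf <- file.path(config$output_dir, paste0("summary_", kind, ".tsv"))
    write_results(aggregates[[kind]]$results, rf)
    write_summary(aggregates[[kind]]$summary, sf)
    files_written <- c(files_written, rf, sf)
    say("aggregated ", kind, ": ", nrow(aggregates[[kind]]$summary),
        " term(s) -> ", basename(rf), ", ", basename(sf))
  }
  say("analysis finished: ", length(labels), " comparison(s) aggregated, ",
      length(failures), " failure(s)")

  structure(
    list(output_dir = config$output_dir, labels = labels,
         aggregates = aggregates, failures = failures,
         files_written = files_written,
         status = if (length(failures) > 0L) 1L else 0L),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("Enrichment run in ", x$output_dir, "\n",
      "  comparisons: ", length(x$labels), "\n",
      "  kinds aggregated: ", paste(names(x$aggregates), collapse = ", "), "\n",
      "  failures: ", length(x$failures), "\n", sep = "")
  if (length(x$failures) > 0L) {
    for (f in names(x$failures)) cat("    ", f, ": ", x$failures[[f]], "\n",
                                     sep = "")
  }
  invisible(x)
}
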