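#' Assemble a pipeline run configuration
#'
#' @param freqs Path to the ancestry-stratified frequency table.
#' @param clinvar,hgmd,plof Optional paths to source candidate tables (at
#'   least one is required).
#' @param classifications Optional path to the curated classification file.
#' @param populations Optional path to a population-size table; when given,
#'   each population is projected with the overall conservative prevalence.
#' @param mode `"conservative"`, `"relaxed"` or `"both"`.
#' @param out_dir Output directory for reports and the run log.
#' @param freq_dialect `"tsv"` or `"vcf"`.
#' @return Validated configuration list for [run_pipeline()].
#' @export
run_config <- function(freqs, clinvar = NULL, hgmd = NULL, plof = NULL,
                       classifications = NULL, populations = NULL,
                       mode = c("both", "conservative", "relaxed"),
                       out_dir = tempfile("genoprev_run_"),
                       freq_dialect = "tsv") {
  mode <- match.arg(mode)
  paths <- list(freqs = freqs, clinvar = clinvar, hgmd = hgmd, plof = plof,
                classifications = classifications, populations = populations)
  for (nm in names(paths)) {
    p <- paths[[nm]]
    if (!is.null(p) && !file.exists(p)) {
      stop("input path for '", nm, "' does not exist: ", p, call. = FALSE)
    }
  }
  if (is.null(clinvar) && is.null(hgmd) && is.null(plof)) {
    stop("at least one source table (clinvar, hgmd, plof) is required",
         call. = FALSE)
  }
  c(paths, list(mode = mode, out_dir = out_dir, freq_dialect = freq_dialect))
}

#' Run the full prevalence pipeline
#'
#' Executes ingest, classification, inclusion filtering, per-group
#' estimation and population projection in order, writing a JSON report, a
#' Markdown table per mode and a structured run log (per-source skip
#' summaries, warning counts, configuration provenance) into
#' `config$out_dir`. Identical inputs and configuration yield
#' byte-identical JSON reports.
#'
#' @param config From [run_config()].
#' @return Invisibly, a list with `candidates`, `classified`, `estimates`
#'   (one tibble per requested mode), `projections` and `report_paths`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- character()
  logit <- function(stage, level, msg) {
    log_lines <<- c(log_lines, sprintf("[%s] %s: %s", stage, level, msg))
  }
  fail <- function(stage, e) {
    logit(stage, "ERROR", conditionMessage(e))
    writeLines(log_lines, log_path)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }

  n_warn <- 0L
  with_stage <- function(stage, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) fail(stage, e)),
      warning = function(w) {
        n_warn <<- n_warn + 1L
        logit(stage, "WARN", conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
  }

  freqs <- with_stage("ingest", read_frequency_table(
    config$freqs, dialect = config$freq_dialect))
  records <- list()
  for (src in c("clinvar", "hgmd", "plof")) {
    if (is.null(config[[src]])) next
    tbl <- with_stage("ingest", read_source_table(config[[src]], src))
    sk <- skip_summary(tbl)
    logit("ingest", "INFO", sprintf(
      "%s: %d rows read, %d records kept, %d skipped (%s)",
      src, attr(tbl, "n_rows"), nrow(tbl), sum(sk$n),
      if (nrow(sk)) paste(sk$reason, sk$n, sep = "=", collapse = ", ") else "none"
    ))
    records[[src]] <- tbl
  }
  candidates <- with_stage("dedupe",
                           dedupe_candidates(dplyr::bind_rows(records), freqs))
  logit("dedupe", "INFO", paste(nrow(candidates), "distinct candidates"))
  if (nrow(candidates) == 0L) {
    logit("dedupe", "WARN", "empty candidate table: all estimates will be zero")
    n_warn <- n_warn + 1L
  }

  cls_tbl <- if (!is.null(config$classifications)) {
    with_stage("classify", read_classification_file(config$classifications))
  }
  classified <- with_stage("classify", classify_candidates(candidates, cls_tbl))
  logit("classify", "INFO", paste0(
    "final classes: ",
    paste(names(table(classified$final_class)),
          table(classified$final_class), sep = "=", collapse = ", ")
  ))

  modes <- if (config$mode == "both") c("conservative", "relaxed") else config$mode
  estimates <- list()
  for (m in modes) {
    inc <- with_stage("estimate", inclusion_set(classified, m))
    logit("estimate", "INFO", paste(m, "inclusion set:", nrow(inc), "variants"))
    estimates[[m]] <- with_stage("estimate", estimate_all_groups(inc, mode = m))
  }

  projections <- NULL
  if (!is.null(config$populations)) {
    pops <- with_stage("project", read_population_table(config$populations))
    rate <- estimates[[modes[1]]]$prevalence[
      estimates[[modes[1]]]$group == "all"]
    projections <- with_stage("project", project_populations(pops, rate))
  }

  report_paths <- character()
  for (m in modes) {
    jp <- file.path(config$out_dir, paste0("report_", m, ".json"))
    mp <- file.path(config$out_dir, paste0("report_", m, ".md"))
    write_report(estimates[[m]], projections, jp, format = "json")
    write_report(estimates[[m]], projections, mp, format = "markdown")
    report_paths <- c(report_paths, jp, mp)
  }
  logit("report", "INFO", paste("warnings:", n_warn))
  logit("report", "INFO", paste("mode:", config$mode))
  logit("report", "INFO", paste("genoprev version:",
                                as.character(utils::packageVersion("genoprev"))))
  writeLines(log_lines, log_path)

  invisible(list(candidates = candidates, classified = classified,
                 estimates = estimates, projections = projections,
                 report_paths = report_paths, log = log_lines))
}

#' Write a prevalence report
#'
#' JSON reports serialize estimates at full precision with a deterministic
#' field order; Markdown reports mirror the published table layout
#' (groups in display order with "1 in N" strings). The report header
#' records the modeling convention: carrier frequency `2*sum_q`, genetic
#' prevalence `(sum_q)^2`.
#'
#' @param estimates Tibble from [estimate_all_groups()].
#' @param projections Optional tibble from [project_populations()].
#' @param path Output file path.
#' @param format `"json"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(estimates, projections = NULL, path,
                         format = c("json", "markdown")) {
  if (nrow(estimates) == 0L) stop("empty estimates", call. = FALSE)
  format <- match.arg(format)
  if (format == "json") {
    payload <- list(
      model = "carrier_freq = 2*sum_q; prevalence = sum_q^2 (Hardy-Weinberg)",
      mode = estimates$mode[1],
      estimates = estimates[c("group", "sum_q", "carrier_freq", "prevalence",
                              "n_variants", "carrier_one_in",
                              "prevalence_one_in", "carrier_percent")]
    )
    if (!is.null(projections)) payload$projections <- projections
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    hdr <- c(
      paste0("# Genetic prevalence report (", estimates$mode[1], ")"),
      "",
      "Model: carrier frequency = 2*sum_q, genetic prevalence = (sum_q)^2 (Hardy-Weinberg).",
      "",
      "| Group | Variants | Carrier frequency | Genetic prevalence | Carrier % |",
      "|---|---|---|---|---|"
    )
    rows <- sprintf("| %s | %d | %s | %s | %s |",
                    estimates$group, estimates$n_variants,
                    ifelse(is.na(estimates$carrier_one_in), "-",
                           estimates$carrier_one_in),
                    ifelse(is.na(estimates$prevalence_one_in), "-",
                           estimates$prevalence_one_in),
                    estimates$carrier_percent)
    lines <- c(hdr, rows)
    if (!is.null(projections)) {
      lines <- c(lines, "", "## Projections", "",
                 "| Population | Size | Expected affected (rounded) | Grain |",
                 "|---|---|---|---|",
                 sprintf("| %s | %s | %s | %d |",
                         projections$population_name,
                         format(projections$population_size, big.mark = ",",
                                scientific = FALSE),
                         format(projections$expected_count_rounded,
                                big.mark = ",", scientific = FALSE),
                         projections$grain))
    }
    writeLines(lines, path)
  }
  invisible(path)
}
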