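#' Export a study evaluation report
#'
#' Writes the evaluation summary a SciRAP user would export from the online
#' tool: the header (study label, catalog reference, evaluator, timestamp),
#' the per-criterion table (criterion text, rating, weight, removal,
#' comments), the RQ and MQ scores and the three colour profiles. JSON is
#' the canonical machine format; the CSV variant writes the per-criterion
#' table with the header and scores in `#`-prefixed comment lines.
#'
#' @param evaluation A `scirap_evaluation`.
#' @param path Output file (`.json` or `.csv`).
#' @param partial If `TRUE`, an incompletely rated evaluation may be
#'   exported; scores and profiles are then omitted. Default `FALSE`:
#'   exporting an incomplete evaluation is an error.
#' @return `path`, invisibly.
#' @export
export_report <- function(evaluation, path, partial = FALSE) {
  scores <- profiles <- NULL
  if (!partial) {
    scores <- list(RQ = unclass(compute_score(evaluation, "RQ")),
                   MQ = unclass(compute_score(evaluation, "MQ")))
    profiles <- list(RQ = unclass(compute_colour_profile(evaluation, "RQ")),
                     MQ = unclass(compute_colour_profile(evaluation, "MQ")),
                     REL = unclass(compute_colour_profile(evaluation, "REL")))
    profiles <- lapply(profiles, function(p) {
      p$bars <- lapply(p$bars, as.list); p$overall <- as.list(p$overall); p
    })
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- list(report_type = "scirap_evaluation_report",
                tool_version = as.character(utils::packageVersion("scirapr")),
                evaluation = .evaluation_to_list(evaluation),
                criterion_text = .criterion_text_map(evaluation$catalog),
                scores = scores, profiles = profiles)
    obj <- obj[!vapply(obj, is.null, TRUE)]
    ok <- tryCatch({
      jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                           na = "null", digits = NA)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) {
      .stop_scirap(sprintf("cannot write report to '%s': %s",
                           path, conditionMessage(ok)), "scirap_io_error")
    }
  } else if (ext == "csv") {
    .export_report_csv(evaluation, path, scores)
  } else {
    .stop_scirap(sprintf("unknown report format '.%s' (expected .json or .csv)",
                         ext), "scirap_format_error")
  }
  invisible(path)
}

.criterion_text_map <- function(catalog) {
  c(stats::setNames(as.list(catalog$criteria$text), catalog$criteria$id),
    stats::setNames(as.list(catalog$relevance_items$text),
                    catalog$relevance_items$id))
}

.export_report_csv <- function(evaluation, path, scores) {
  con <- try(file(path, open = "wt"), silent = TRUE)
  if (inherits(con, "try-error")) {
    .stop_scirap(sprintf("cannot write report to '%s'", path), "scirap_io_error")
  }
  on.exit(close(con))
  writeLines(sprintf("# scirap report | study=%s | catalog=%s | evaluator=%s",
                     evaluation$study_label, evaluation$catalog_ref,
                     evaluation$evaluator %||% ""), con)
  if (!is.null(scores)) {
    writeLines(sprintf("# score %s=%.15g", names(scores),
                       vapply(scores, `[[`, 0, "score")), con)
  }
  a <- evaluation$assessments
  rel <- evaluation$relevance
  tab <- rbind(
    data.frame(id = a$id, section = a$section, rating = a$rating,
               weight = a$weight, removed = a$removed,
               justification = a$justification, comment = a$comment,
               stringsAsFactors = FALSE),
    data.frame(id = rel$id, section = "REL", rating = rel$rating,
               weight = NA_real_, removed = NA, justification = NA_character_,
               comment = rel$comment, stringsAsFactors = FALSE))
  utils::write.csv(tab, con, row.names = FALSE, na = "")
}

#' Import a study evaluation report
#'
#' Reconstructs the evaluation from a report written by [export_report()].
#' Any scores embedded in the report are recomputed from the reconstructed
#' ratings and compared; a mismatch (e.g. a hand-edited score field) raises
#' a tamper warning quoting both values.
#'
#' @param path Report file (`.json` or `.csv`).
#' @param catalog Catalog to resolve criterion ids against; defaults to the
#'   bundled version 2.0 instrument.
#' @return A `scirap_evaluation`.
#' @export
import_report <- function(path, catalog = "scirap-invitro-2.0") {
  if (!file.exists(path)) {
    .stop_scirap(sprintf("cannot read '%s': no such file", path),
                 "scirap_io_error")
  }
  if (!inherits(catalog, "scirap_catalog")) catalog <- load_catalog(catalog)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    raw <- jsonlite::read_json(path)
    if (!is.null(raw$report_type) &&
        !identical(raw$report_type, "scirap_evaluation_report")) {
      .stop_scirap(sprintf("'%s' is not a SciRAP evaluation report", path),
                   "scirap_format_error")
    }
    ev <- .evaluation_from_json(raw$evaluation %||% raw, catalog)
    .check_embedded_scores(ev, lapply(raw$scores, function(s) s$score))
    ev
  } else if (ext == "csv") {
    lines <- readLines(path, warn = FALSE)
    meta <- grep("^# score ", lines, value = TRUE)
    ev <- .evaluation_from_csv(path, catalog)
    hdr <- grep("^# scirap report", lines, value = TRUE)
    if (length(hdr) == 1L) {
      fields <- regmatches(hdr, regexec("study=([^|]*) \\| catalog=", hdr))[[1]]
      if (length(fields) == 2L) ev$study_label <- trimws(fields[2])
    }
    embedded <- list()
    for (m in meta) {
      part <- regmatches(m, regexec("^# score (RQ|MQ)=([-0-9.eE+]+)", m))[[1]]
      if (length(part) == 3L) embedded[[part[2]]] <- as.numeric(part[3])
    }
    .check_embedded_scores(ev, embedded)
    ev
  } else {
    .stop_scirap(sprintf("unknown report format '.%s'", ext),
                 "scirap_format_error")
  }
}

.check_embedded_scores <- function(evaluation, embedded) {
  for (sec in intersect(names(embedded), c("RQ", "MQ"))) {
    stored <- embedded[[sec]]
    if (is.null(stored) || is.na(stored)) next
    recomputed <- compute_score(evaluation, sec)$score
    if (abs(recomputed - stored) > 1e-6) {
      warning(sprintf(
        "tamper check: stored %s score %.6g differs from recomputed %.6g",
        sec, stored, recomputed), call. = FALSE)
    }
  }
  invisible(NULL)
}

#' Render a colour profile to a vector image
#'
#' Draws the profile with the instrument's colour mapping: fulfilled /
#' directly relevant green, partially fulfilled / indirectly relevant
#' yellow, not fulfilled / not relevant red, not determined grey. For
#' reliability sections each evaluation domain is one stacked bar; the
#' relevance profile is a pie whose sector angles are proportional to the
#' item fractions. The device is chosen from the file extension (`.pdf` or
#' `.svg`).
#'
#' @param profile A `scirap_colour_profile`.
#' @param path Output image path.
#' @param kind `"bars"` or `"pie"`; defaults to bars for RQ/MQ and pie for
#'   REL.
#' @return `path`, invisibly.
#' @export
render_profile <- function(profile, path,
                           kind = if (identical(profile$section, "REL")) "pie" else "bars") {
  if (!inherits(profile, "scirap_colour_profile") || length(profile$bars) == 0L) {
    .stop_scirap("empty colour profile: nothing to render",
                 "scirap_degenerate_input_error")
  }
  kind <- match.arg(kind, c("bars", "pie"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") grDevices::svg(path, width = 8, height = 5)
  else grDevices::pdf(path, width = 8, height = 5)
  on.exit(grDevices::dev.off())
  cols <- .CATEGORY_COLOURS
  if (kind == "bars") {
    mat <- sapply(profile$bars, function(b) b)  # categories x domains
    graphics::par(mar = c(9, 4, 3, 1))
    graphics::barplot(100 * mat, col = cols[rownames(mat)], las = 2,
                      ylab = "% of retained criteria (weighted)",
                      main = sprintf("SciRAP colour profile (%s)", profile$section),
                      names.arg = names(profile$bars), cex.names = 0.8)
  } else {
    o <- profile$overall[profile$overall > 0]
    graphics::pie(o, labels = sprintf("%s (%.0f%%)", names(o), 100 * o),
                  col = cols[names(o)], clockwise = TRUE,
                  main = sprintf("SciRAP colour profile (%s)", profile$section))
  }
  invisible(path)
}
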