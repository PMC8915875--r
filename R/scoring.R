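#' Compute the SciRAP score for one reliability section
#'
#' The score summarises one section (reporting quality or methodological
#' quality) as
#' \deqn{\mathrm{score} = \frac{F + 0.5\,PF}{T} \times 100}
#' where, with per-criterion weights \eqn{w_i \in [1, 1.5]}, \eqn{F} is the
#' total weight of criteria judged fulfilled, \eqn{PF} the total weight of
#' criteria judged partially fulfilled, and \eqn{T} the total weight of all
#' retained (non-removed) criteria. Criteria judged not fulfilled and not
#' determined contribute nothing to the numerator but full weight to
#' \eqn{T}, so NF and ND have the same impact on the score. With all weights
#' at the default 1 the formula reduces to plain counts. The score ranges
#' from 0 (all criteria not fulfilled) to 100 (all criteria fulfilled).
#'
#' @param evaluation A `scirap_evaluation` whose retained criteria in
#'   `section` are all rated.
#' @param section `"RQ"` or `"MQ"`.
#' @param include_open_questions Whether the section's open-ended "Other"
#'   criterion (RQ24 / MQ16 in the bundled catalog) is score-eligible.
#'   Default `TRUE`, matching the instrument's count of 24/16 criteria; set
#'   `FALSE` to score the closed criteria only.
#' @return A `scirap_score` object with fields `section`, `F`, `PF`, `T` and
#'   `score`.
#' @export
#' @examples
#' ev <- new_evaluation("scirap-invitro-2.0")
#' for (id in ev$assessments$id) ev <- set_rating(ev, id, "F")
#' compute_score(ev, "RQ")$score # 100
compute_score <- function(evaluation, section,
                          include_open_questions = TRUE) {
  a <- .section_rows(evaluation, section, include_open_questions)
  retained <- a[!a$removed, ]
  if (nrow(retained) == 0L) {
    .stop_scirap(sprintf("all %s criteria have been removed; score undefined",
                         section), "scirap_degenerate_input_error")
  }
  unrated <- retained$id[is.na(retained$rating)]
  if (length(unrated) > 0L) {
    .stop_scirap(sprintf("incomplete evaluation: unrated %s criteria: %s",
                         section, paste(unrated, collapse = ", ")),
                 "scirap_incomplete_evaluation_error")
  }
  f <- sum(retained$weight[retained$rating == "F"])
  pf <- sum(retained$weight[retained$rating == "PF"])
  tt <- sum(retained$weight)
  structure(list(section = section, F = f, PF = pf, T = tt,
                 score = (f + 0.5 * pf) / tt * 100),
            class = "scirap_score")
}

.section_rows <- function(evaluation, section, include_open_questions = TRUE) {
  if (!.is_string(section) || !section %in% c("RQ", "MQ")) {
    .stop_scirap("section must be 'RQ' or 'MQ'", "scirap_domain_error")
  }
  a <- evaluation$assessments[evaluation$assessments$section == section, ]
  if (!include_open_questions) {
    open <- evaluation$catalog$criteria$id[
      evaluation$catalog$criteria$is_open_question]
    a <- a[!a$id %in% open, ]
  }
  a
}

#' @export
print.scirap_score <- function(x, ...) {
  cat(sprintf("SciRAP %s score: %.1f  (F = %g, PF = %g, T = %g)\n",
              x$section, x$score, x$F, x$PF, x$T))
  invisible(x)
}

#' Compute a colour profile
#'
#' The colour profile is the qualitative companion of the score: for each
#' evaluation domain of a reliability section, the weighted fraction of
#' retained criteria judged in each category (F green, PF yellow, NF red,
#' ND grey); an up-weighted criterion occupies a proportionally larger share
#' of its bar. Removed criteria are excluded; a domain whose criteria are
#' all removed is omitted from the bars with a notice. For `section = "REL"`
#' the profile is the four-item relevance pie (equal weights, DR green, IR
#' yellow, NR red, ND grey).
#'
#' @inheritParams compute_score
#' @param section `"RQ"`, `"MQ"` or `"REL"`.
#' @return A `scirap_colour_profile`: list with `section`, `bars` (named
#'   list, one category-fraction vector per domain) and `overall` (category
#'   fractions across all retained criteria).
#' @export
compute_colour_profile <- function(evaluation, section) {
  if (identical(section, "REL")) return(.relevance_profile(evaluation))
  a <- .section_rows(evaluation, section)
  retained <- a[!a$removed, ]
  if (nrow(retained) == 0L) {
    .stop_scirap(sprintf("all %s criteria have been removed; profile undefined",
                         section), "scirap_degenerate_input_error")
  }
  unrated <- retained$id[is.na(retained$rating)]
  if (length(unrated) > 0L) {
    .stop_scirap(sprintf("incomplete evaluation: unrated %s criteria: %s",
                         section, paste(unrated, collapse = ", ")),
                 "scirap_incomplete_evaluation_error")
  }
  cats <- names(.RELIABILITY_CODES)
  frac <- function(rows) {
    w <- vapply(cats, function(k) sum(rows$weight[rows$rating == k]), 0)
    w / sum(w)
  }
  bars <- list()
  for (dom in evaluation$catalog$domains[[section]]) {
    rows <- retained[retained$domain == dom, ]
    if (nrow(rows) == 0L) {
      if (any(a$domain == dom)) {
        message(sprintf("domain '%s': all criteria removed; omitted from profile",
                        dom))
      }
      next
    }
    bars[[dom]] <- frac(rows)
  }
  structure(list(section = section, bars = bars, overall = frac(retained)),
            class = "scirap_colour_profile")
}

.relevance_profile <- function(evaluation) {
  rel <- evaluation$relevance
  unrated <- rel$id[is.na(rel$rating)]
  if (length(unrated) > 0L) {
    .stop_scirap(sprintf("incomplete evaluation: unrated relevance items: %s",
                         paste(unrated, collapse = ", ")),
                 "scirap_incomplete_evaluation_error")
  }
  cats <- names(.RELEVANCE_CODES)
  overall <- vapply(cats, function(k) sum(rel$rating == k), 0) / nrow(rel)
  bars <- lapply(seq_len(nrow(rel)), function(i) {
    v <- as.numeric(cats == rel$rating[i]); names(v) <- cats; v
  })
  names(bars) <- rel$domain
  structure(list(section = "REL", bars = bars, overall = overall),
            class = "scirap_colour_profile")
}

#' @export
print.scirap_colour_profile <- function(x, ...) {
  cat(sprintf("SciRAP colour profile (%s)\n", x$section))
  for (dom in names(x$bars)) {
    b <- x$bars[[dom]]
    cat(sprintf("  %-34s %s\n", dom,
                paste(sprintf("%s %3.0f%%", names(b), 100 * b), collapse = "  ")))
  }
  o <- x$overall
  cat(sprintf("  %-34s %s\n", "overall",
              paste(sprintf("%s %3.0f%%", names(o), 100 * o), collapse = "  ")))
  invisible(x)
}
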