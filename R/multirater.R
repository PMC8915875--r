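#' Consolidate rater evaluations into a rating matrix
#'
#' Builds the rater-by-criterion matrix underlying the multi-rater analysis:
#' one row per evaluation, one column per criterion (or relevance item) of
#' the requested section. Criteria removed by a rater become `NA` ("not
#' applicable") and are excluded from agreement denominators downstream;
#' relevance items cannot be removed, so relevance matrices never contain
#' `NA`.
#'
#' @param evaluations List of `scirap_evaluation` objects of the same study
#'   against the same catalog.
#' @param section `"RQ"`, `"MQ"` or `"REL"`.
#' @return A `scirap_rating_matrix`: a character matrix with rater ids as
#'   row names, criterion ids as column names, and attributes
#'   `study_label` and `section`.
#' @export
consolidate <- function(evaluations, section) {
  if (length(evaluations) == 0L) {
    .stop_scirap("no evaluations supplied", "scirap_degenerate_input_error")
  }
  refs <- vapply(evaluations, function(e) e$catalog_ref, "")
  if (length(unique(refs)) > 1L) {
    .stop_scirap(sprintf("evaluations reference different catalogs: %s",
                         paste(unique(refs), collapse = " vs ")),
                 "scirap_incompatibility_error")
  }
  studies <- vapply(evaluations, function(e) e$study_label, "")
  if (length(unique(studies)) > 1L) {
    .stop_scirap(sprintf("evaluations cover different studies: %s",
                         paste(unique(studies), collapse = " vs ")),
                 "scirap_incompatibility_error")
  }
  raters <- vapply(seq_along(evaluations), function(k) {
    evaluations[[k]]$evaluator %||% sprintf("rater%02d", k)
  }, "")
  if (anyDuplicated(raters)) {
    .stop_scirap(sprintf("duplicate rater id(s): %s",
                         paste(unique(raters[duplicated(raters)]), collapse = ", ")),
                 "scirap_incompatibility_error")
  }
  rows <- lapply(evaluations, function(e) {
    if (identical(section, "REL")) {
      stats::setNames(e$relevance$rating, e$relevance$id)
    } else {
      a <- .section_rows(e, section)
      stats::setNames(a$rating, a$id)  # removed criteria are NA already
    }
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- raters
  structure(mat, study_label = studies[1], section = section,
            catalog_ref = refs[1], class = c("scirap_rating_matrix", "matrix"))
}

#' Rating matrix from raw cells
#'
#' Low-level constructor used when ratings arrive as a consolidated
#' rater-by-criterion table rather than as individual evaluations.
#'
#' @param cells Character matrix (raters in rows, criteria in columns);
#'   `NA` or the literal token `"NA"` marks a removed criterion.
#' @param section `"RQ"`, `"MQ"` or `"REL"`.
#' @param study_label Study the ratings refer to.
#' @return A `scirap_rating_matrix`.
#' @export
rating_matrix <- function(cells, section, study_label = "study") {
  cells <- as.matrix(cells)
  mode(cells) <- "character"
  cells[cells == "NA"] <- NA_character_
  valid <- if (identical(section, "REL")) names(.RELEVANCE_CODES)
           else names(.RELIABILITY_CODES)
  bad <- stats::na.omit(setdiff(unique(as.vector(cells)), valid))
  if (length(bad) > 0L) {
    .stop_scirap(sprintf("invalid rating token(s) for section %s: %s",
                         section, paste(bad, collapse = ", ")),
                 "scirap_format_error")
  }
  if (identical(section, "REL") && anyNA(cells)) {
    .stop_scirap("relevance matrices cannot contain NA (items cannot be removed)",
                 "scirap_format_error")
  }
  if (is.null(rownames(cells))) {
    rownames(cells) <- sprintf("rater%02d", seq_len(nrow(cells)))
  }
  structure(cells, study_label = study_label, section = section,
            class = c("scirap_rating_matrix", "matrix"))
}

#' Per-criterion agreement summary
#'
#' For one criterion of a rating matrix, tallies the retained (non-NA)
#' ratings: the fraction of raters in each category, the number of distinct
#' categories observed (`k_observed`), the largest category fraction
#' (`p_max`) and the modal category. "Not determined" is an ordinary
#' category; removed criteria are excluded from the denominator. Modal ties
#' are broken by the fixed category order F, PF, NF, ND (DR, IR, NR, ND for
#' relevance), which affects the modal label only.
#'
#' @param matrix A `scirap_rating_matrix`.
#' @param criterion_id Column to summarise.
#' @return A `scirap_agreement` list: `criterion_id`, `n_retained`,
#'   `proportions`, `k_observed`, `p_max`, `modal_category`. When every
#'   rating is NA, `n_retained` is 0 and the remaining fields are `NA`.
#' @export
agreement <- function(matrix, criterion_id) {
  if (!criterion_id %in% colnames(matrix)) {
    .stop_scirap(sprintf("criterion '%s' not present in matrix", criterion_id),
                 "scirap_lookup_error")
  }
  ratings <- matrix[, criterion_id]
  ratings <- ratings[!is.na(ratings)]
  cats <- if (identical(attr(matrix, "section"), "REL")) names(.RELEVANCE_CODES)
          else names(.RELIABILITY_CODES)
  n <- length(ratings)
  if (n == 0L) {
    return(structure(list(criterion_id = criterion_id, n_retained = 0L,
                          proportions = NULL, k_observed = NA_integer_,
                          p_max = NA_real_, modal_category = NA_character_),
                     class = "scirap_agreement"))
  }
  counts <- vapply(cats, function(k) sum(ratings == k), 0L)
  props <- counts / n
  structure(list(criterion_id = criterion_id, n_retained = n,
                 proportions = props,
                 k_observed = sum(counts > 0L),
                 p_max = max(props),
                 modal_category = cats[which.max(props)]),
            class = "scirap_agreement")
}

#' @export
print.scirap_agreement <- function(x, ...) {
  cat(sprintf("%s: n = %d, k = %s, p_max = %s (%s)\n", x$criterion_id,
              x$n_retained, x$k_observed, format(x$p_max), x$modal_category))
  invisible(x)
}

#' Decision-rule thresholds for variability classification
#'
#' The instrument's variability appraisal is semi-quantitative, driven by
#' two signals per criterion: the number of categories observed and the
#' largest category percentage. The published bands are consensus (no
#' variability, all retained raters agree) and low variability (agreement
#' at least 80% but below 100%); the high-variability branch thresholds
#' were left to the analyst, so they are configurable here. Defaults: high
#' when `p_max < 0.6`, or when three or more categories are observed and
#' `p_max < 0.8`; the remaining band is reported as moderate.
#'
#' @param low_lower Lower bound of the low-variability band (default 0.8).
#' @param high_pmax Agreement below this is high variability regardless of
#'   category count (default 0.6).
#' @param high_k Category count at or above which the second high branch
#'   applies (default 3).
#' @param high_k_pmax Agreement bound for the second high branch (default
#'   0.8).
#' @param min_raters Minimum retained raters for a criterion to be
#'   classifiable (default 2).
#' @return A validated `scirap_rules` list (consensus threshold fixed at 1).
#' @export
decision_rules <- function(low_lower = 0.8, high_pmax = 0.6, high_k = 3L,
                           high_k_pmax = 0.8, min_raters = 2L) {
  rules <- structure(list(consensus_threshold = 1.0, low_lower = low_lower,
                          high_pmax = high_pmax, high_k = as.integer(high_k),
                          high_k_pmax = high_k_pmax,
                          min_raters = as.integer(min_raters)),
                     class = "scirap_rules")
  with(rules, {
    if (!(0 < high_pmax && high_pmax <= high_k_pmax &&
          high_k_pmax <= low_lower && low_lower < 1.0)) {
      .stop_scirap(
        "thresholds must satisfy 0 < high_pmax <= high_k_pmax <= low_lower < 1",
        "scirap_domain_error")
    }
    if (min_raters < 1L) {
      .stop_scirap("min_raters must be >= 1", "scirap_domain_error")
    }
  })
  rules
}

#' Classify inter-rater variability for one criterion
#'
#' Applies the decision rules to an agreement summary. Classes, in the
#' order tested: `consensus` when every retained rater chose the same
#' category (`p_max == 1`); `low` when `low_lower <= p_max < 1`; `high`
#' when `p_max < high_pmax`, or when `k_observed >= high_k` and
#' `p_max < high_k_pmax`; otherwise `moderate`. The classes partition the
#' agreement space, so exactly one applies.
#'
#' @param summary A `scirap_agreement` (from [agreement()]).
#' @param rules A `scirap_rules` object; default [decision_rules()].
#' @return A `scirap_classification` list: `criterion_id`, `class`
#'   (`"consensus"`, `"low"`, `"moderate"`, `"high"`, or
#'   `"unclassifiable"` when fewer than `min_raters` ratings were
#'   retained) and `triggering_rule` naming the fired branch.
#' @export
classify_variability <- function(summary, rules = decision_rules()) {
  stopifnot(inherits(summary, "scirap_agreement"))
  p <- summary$p_max; k <- summary$k_observed
  if (summary$n_retained < rules$min_raters) {
    cls <- "unclassifiable"
    rule <- sprintf("n_retained %d < min_raters %d", summary$n_retained,
                    rules$min_raters)
  } else if (p >= rules$consensus_threshold) {
    cls <- "consensus"
    rule <- "p_max = 1 (no variability)"
  } else if (p >= rules$low_lower) {
    cls <- "low"
    rule <- sprintf("%.2g <= p_max < 1", rules$low_lower)
  } else if (p < rules$high_pmax) {
    cls <- "high"
    rule <- sprintf("p_max < %.2g", rules$high_pmax)
  } else if (k >= rules$high_k && p < rules$high_k_pmax) {
    cls <- "high"
    rule <- sprintf("k >= %d and p_max < %.2g", rules$high_k, rules$high_k_pmax)
  } else {
    cls <- "moderate"
    rule <- sprintf("%.2g <= p_max < %.2g with k < %d", rules$high_pmax,
                    rules$low_lower, rules$high_k)
  }
  structure(list(criterion_id = summary$criterion_id, class = cls,
                 triggering_rule = rule, p_max = p, k_observed = k,
                 n_retained = summary$n_retained,
                 modal_category = summary$modal_category),
            class = "scirap_classification")
}

#' Classify every criterion of a rating matrix
#'
#' Convenience wrapper running [agreement()] and [classify_variability()]
#' over all columns.
#'
#' @inheritParams agreement
#' @inheritParams classify_variability
#' @param matrix A `scirap_rating_matrix`.
#' @return Data frame with one row per criterion: `criterion_id`,
#'   `n_retained`, `k_observed`, `p_max`, `modal_category`, `class`,
#'   `triggering_rule`; carries the rules used as attribute `rules`.
#' @export
classify_matrix <- function(matrix, rules = decision_rules()) {
  rows <- lapply(colnames(matrix), function(id) {
    cl <- classify_variability(agreement(matrix, id), rules)
    data.frame(criterion_id = cl$criterion_id, n_retained = cl$n_retained,
               k_observed = cl$k_observed, p_max = cl$p_max,
               modal_category = cl$modal_category %||% NA_character_,
               class = cl$class, triggering_rule = cl$triggering_rule,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "rules") <- rules
  attr(out, "study_label") <- attr(matrix, "study_label")
  attr(out, "section") <- attr(matrix, "section")
  out
}

#' Cross-study prioritization of criteria for refinement
#'
#' A criterion or item is prioritized for potential refinement when it is
#' classified as high variability in at least one study; criteria showing
#' only consensus or low variability everywhere are not prioritized.
#'
#' @param classifications Named list of per-study classification tables
#'   (from [classify_matrix()]); names are study labels.
#' @return Data frame with `criterion_id`, one class column per study, and
#'   a logical `prioritized` flag.
#' @export
prioritize <- function(classifications) {
  if (length(classifications) == 0L) {
    .stop_scirap("at least one study's classifications are required",
                 "scirap_degenerate_input_error")
  }
  if (is.null(names(classifications)) || any(names(classifications) == "")) {
    names(classifications) <- sprintf("study%d", seq_along(classifications))
  }
  ids <- unique(unlist(lapply(classifications, `[[`, "criterion_id")))
  out <- data.frame(criterion_id = ids, stringsAsFactors = FALSE)
  for (study in names(classifications)) {
    cl <- classifications[[study]]
    out[[study]] <- cl$class[match(ids, cl$criterion_id)]
  }
  cls_mat <- as.matrix(out[, names(classifications), drop = FALSE])
  out$prioritized <- apply(cls_mat == "high", 1, any, na.rm = TRUE)
  out
}

#' Rounded percentage summary
#'
#' `round(100 * numerator / denominator)` with halves rounded away from
#' zero (exact integer arithmetic), the convention used for survey-style
#' "n (xx%)" summaries.
#'
#' @param numerator,denominator Non-negative integer counts,
#'   `numerator <= denominator`, `denominator > 0`.
#' @return Integer percent.
#' @export
#' @examples
#' percent_summary(26, 30) # 87
percent_summary <- function(numerator, denominator) {
  if (!is.numeric(numerator) || !is.numeric(denominator) ||
      any(is.na(numerator)) || any(is.na(denominator))) {
    .stop_scirap("counts must be numeric and non-missing", "scirap_domain_error")
  }
  if (any(denominator <= 0)) {
    .stop_scirap("denominator must be positive", "scirap_domain_error")
  }
  if (any(numerator < 0) || any(numerator > denominator)) {
    .stop_scirap("numerator must lie in [0, denominator]", "scirap_domain_error")
  }
  as.integer((200L * as.integer(numerator) + as.integer(denominator)) %/%
               (2L * as.integer(denominator)))
}

# ---- matrix CSV dialect ---------------------------------------------------

#' Write a rating matrix as CSV
#'
#' First column `rater`, one column per criterion id, cells in the fixed
#' token set with removed criteria written as the literal token `NA`. A
#' `#`-prefixed header line records the study, section and catalog.
#'
#' @param matrix A `scirap_rating_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# scirap matrix | study=%s | section=%s | catalog=%s",
                     attr(matrix, "study_label"), attr(matrix, "section"),
                     attr(matrix, "catalog_ref") %||% ""), con)
  tab <- data.frame(rater = rownames(matrix), unclass(matrix),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(tab, con, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a rating matrix from CSV
#'
#' @param path CSV written by [write_matrix()] or hand-assembled in the
#'   same dialect (first column rater ids).
#' @param section Section of the ratings; if `NULL`, taken from the file's
#'   `#` header line or inferred from the tokens present.
#' @return A `scirap_rating_matrix`.
#' @export
read_matrix <- function(path, section = NULL) {
  if (!file.exists(path)) {
    .stop_scirap(sprintf("cannot read '%s': no such file", path),
                 "scirap_io_error")
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  study <- "study"
  if (startsWith(first, "# scirap matrix")) {
    get <- function(key) {
      m <- regmatches(first, regexec(paste0(key, "=([^|]*)"), first))[[1]]
      if (length(m) == 2L) trimws(m[2]) else NULL
    }
    study <- get("study") %||% study
    section <- section %||% get("section")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                         check.names = FALSE,
                         colClasses = "character", na.strings = "NA")
  cells <- as.matrix(tab[, -1, drop = FALSE])
  rownames(cells) <- tab[[1]]
  if (is.null(section)) {
    toks <- stats::na.omit(unique(as.vector(cells)))
    section <- if (all(toks %in% names(.RELEVANCE_CODES)) &&
                   any(toks %in% c("DR", "IR", "NR"))) "REL" else "RQ"
  }
  rating_matrix(cells, section = section, study_label = study)
}
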