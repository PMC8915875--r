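#' Start a fresh study evaluation
#'
#' Creates the evaluation state for one study against one catalog: one
#' assessment slot per reliability criterion (unrated, weight 1, not
#' removed) and one slot per relevance item. Ratings, weights and removals
#' are then recorded with [set_rating()], [set_relevance_rating()],
#' [set_weight()] and [remove_criterion()].
#'
#' @param catalog A `scirap_catalog`, or a name/path accepted by
#'   [load_catalog()].
#' @param study_label Label of the study under evaluation.
#' @param evaluator Optional rater identifier.
#' @param timestamp Optional ISO-8601 timestamp string.
#' @return A `scirap_evaluation` object.
#' @export
#' @examples
#' ev <- new_evaluation("scirap-invitro-2.0", study_label = "Study 1")
#' ev <- set_rating(ev, "RQ01", "F")
new_evaluation <- function(catalog, study_label = "study",
                           evaluator = NULL, timestamp = NULL) {
  if (!inherits(catalog, "scirap_catalog")) catalog <- load_catalog(catalog)
  cr <- catalog$criteria
  assessments <- data.frame(
    id = cr$id, section = cr$section, domain = cr$domain,
    rating = NA_character_, weight = 1.0, removed = FALSE,
    justification = NA_character_, comment = NA_character_,
    stringsAsFactors = FALSE)
  relevance <- data.frame(
    id = catalog$relevance_items$id,
    domain = catalog$relevance_items$domain,
    rating = NA_character_, comment = NA_character_,
    stringsAsFactors = FALSE)
  structure(list(study_label = study_label,
                 catalog_ref = .catalog_ref(catalog),
                 catalog = catalog,
                 assessments = assessments,
                 relevance = relevance,
                 evaluator = evaluator,
                 timestamp = timestamp),
            class = "scirap_evaluation")
}

.criterion_row <- function(evaluation, criterion_id) {
  if (criterion_id %in% evaluation$relevance$id) {
    .stop_scirap(sprintf(
      "'%s' is a relevance item; use set_relevance_rating() (categories DR/IR/NR/ND)",
      criterion_id), "scirap_lookup_error")
  }
  i <- match(criterion_id, evaluation$assessments$id)
  if (is.na(i)) {
    .stop_scirap(sprintf("unknown criterion id '%s'", criterion_id),
                 "scirap_lookup_error")
  }
  i
}

#' Record a reliability rating
#'
#' @param evaluation A `scirap_evaluation`.
#' @param criterion_id Criterion id (e.g. `"RQ01"`, `"MQ05"`).
#' @param rating One of `"F"`, `"PF"`, `"NF"`, `"ND"`.
#' @param comment Optional free-text comment.
#' @return The updated evaluation. Rating a removed criterion is an error:
#'   removal and judgment are mutually exclusive.
#' @export
set_rating <- function(evaluation, criterion_id, rating, comment = NULL) {
  i <- .criterion_row(evaluation, criterion_id)
  if (!.is_string(rating) || !rating %in% names(.RELIABILITY_CODES)) {
    .stop_scirap(sprintf("rating must be one of %s",
                         paste(names(.RELIABILITY_CODES), collapse = "/")),
                 "scirap_domain_error")
  }
  if (evaluation$assessments$removed[i]) {
    .stop_scirap(sprintf("criterion '%s' has been removed and cannot be rated",
                         criterion_id), "scirap_state_error")
  }
  evaluation$assessments$rating[i] <- rating
  if (!is.null(comment)) evaluation$assessments$comment[i] <- comment
  evaluation
}

#' Record a relevance rating
#'
#' @inheritParams set_rating
#' @param item_id Relevance item id (e.g. `"REL1"`).
#' @param rating One of `"DR"`, `"IR"`, `"NR"`, `"ND"`.
#' @return The updated evaluation.
#' @export
set_relevance_rating <- function(evaluation, item_id, rating, comment = NULL) {
  i <- match(item_id, evaluation$relevance$id)
  if (is.na(i)) {
    .stop_scirap(sprintf("unknown relevance item id '%s'", item_id),
                 "scirap_lookup_error")
  }
  if (!.is_string(rating) || !rating %in% names(.RELEVANCE_CODES)) {
    .stop_scirap(sprintf("relevance rating must be one of %s",
                         paste(names(.RELEVANCE_CODES), collapse = "/")),
                 "scirap_domain_error")
  }
  evaluation$relevance$rating[i] <- rating
  if (!is.null(comment)) evaluation$relevance$comment[i] <- comment
  evaluation
}

#' Remove a criterion from an evaluation
#'
#' A criterion judged not applicable (e.g. cell-passage reporting for a study
#' not conducted in a cell line) can be removed; it then carries no rating
#' and is excluded from the score, the colour profile and any downstream
#' agreement analysis. Relevance items can never be removed. A justification
#' is strongly encouraged; omitting it emits a warning.
#'
#' @inheritParams set_rating
#' @param justification Optional reason for the removal.
#' @return The updated evaluation with the criterion flagged removed and its
#'   rating cleared.
#' @export
remove_criterion <- function(evaluation, criterion_id, justification = NULL) {
  if (criterion_id %in% evaluation$relevance$id) {
    .stop_scirap("relevance items cannot be weighed up or removed",
                 "scirap_not_permitted_error")
  }
  i <- .criterion_row(evaluation, criterion_id)
  if (is.null(justification)) {
    warning(sprintf("criterion '%s' removed without justification", criterion_id),
            call. = FALSE)
    justification <- NA_character_
  }
  evaluation$assessments$removed[i] <- TRUE
  evaluation$assessments$rating[i] <- NA_character_
  evaluation$assessments$justification[i] <- justification
  evaluation
}

#' Set a criterion weight
#'
#' Criteria deemed specifically critical to the evaluation at hand may be
#' up-weighted from the default 1 up to 1.5. The weight scales the
#' criterion's contribution to the SciRAP score and its area in the colour
#' profile. Relevance items cannot be weighed up.
#'
#' @inheritParams set_rating
#' @param weight Numeric weight in `[1, 1.5]`.
#' @return The updated evaluation.
#' @export
set_weight <- function(evaluation, criterion_id, weight) {
  if (criterion_id %in% evaluation$relevance$id) {
    .stop_scirap("relevance items cannot be weighed up or removed",
                 "scirap_not_permitted_error")
  }
  i <- .criterion_row(evaluation, criterion_id)
  if (!is.numeric(weight) || length(weight) != 1L || is.na(weight) ||
      weight < 1.0 || weight > 1.5) {
    .stop_scirap(sprintf("weight must lie in [1.0, 1.5], got %s",
                         format(weight)), "scirap_domain_error")
  }
  if (evaluation$assessments$removed[i]) {
    .stop_scirap(sprintf("criterion '%s' has been removed", criterion_id),
                 "scirap_state_error")
  }
  evaluation$assessments$weight[i] <- weight
  evaluation
}

#' @export
print.scirap_evaluation <- function(x, ...) {
  a <- x$assessments
  cat(sprintf("SciRAP evaluation of '%s' (catalog %s)\n",
              x$study_label, x$catalog_ref))
  if (!is.null(x$evaluator)) cat(sprintf("  evaluator: %s\n", x$evaluator))
  for (sec in c("RQ", "MQ")) {
    s <- a[a$section == sec, ]
    cat(sprintf("  %s: %d rated, %d removed, %d pending\n", sec,
                sum(!is.na(s$rating)), sum(s$removed),
                sum(is.na(s$rating) & !s$removed)))
  }
  cat(sprintf("  relevance: %d of %d items rated\n",
              sum(!is.na(x$relevance$rating)), nrow(x$relevance)))
  invisible(x)
}

# ---- evaluation file formats (ratings in, prior to report export) --------

#' Read a study evaluation from a ratings file
#'
#' Accepts the JSON evaluation format (fields `study_label`, `catalog_ref`,
#' `assessments`, `relevance`) or the flat CSV dialect with columns
#' `id, section, rating, weight, removed, justification, comment` where
#' relevance rows carry section `REL` and the rating tokens are exactly
#' `F/PF/NF/ND` and `DR/IR/NR/ND`.
#'
#' @param path Input file (`.json` or `.csv`).
#' @param catalog Catalog the ratings refer to; defaults to the bundled
#'   version 2.0 instrument.
#' @return A `scirap_evaluation`.
#' @export
read_evaluation <- function(path, catalog = "scirap-invitro-2.0") {
  if (!file.exists(path)) {
    .stop_scirap(sprintf("cannot read '%s': no such file", path),
                 "scirap_io_error")
  }
  if (!inherits(catalog, "scirap_catalog")) catalog <- load_catalog(catalog)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") .evaluation_from_json(jsonlite::read_json(path), catalog)
  else if (ext == "csv") .evaluation_from_csv(path, catalog)
  else .stop_scirap(sprintf("unknown evaluation format '.%s' (expected .json or .csv)",
                            ext), "scirap_format_error")
}

.evaluation_from_json <- function(raw, catalog) {
  if (!is.null(raw$catalog_ref) && raw$catalog_ref != .catalog_ref(catalog)) {
    .stop_scirap(sprintf("evaluation references catalog '%s' but '%s' was supplied",
                         raw$catalog_ref, .catalog_ref(catalog)),
                 "scirap_incompatibility_error")
  }
  as_string <- function(x) if (.is_string(x)) x else NULL
  ev <- new_evaluation(catalog, study_label = as_string(raw$study_label) %||% "study",
                       evaluator = as_string(raw$evaluator),
                       timestamp = as_string(raw$timestamp))
  for (a in raw$assessments) {
    id <- a$id
    if (isTRUE(a$removed)) {
      ev <- suppressWarnings(remove_criterion(ev, id, a$justification))
    } else if (!is.null(a$rating)) {
      ev <- set_rating(ev, id, a$rating, comment = a$comment)
    }
    if (!is.null(a$weight) && a$weight != 1) ev <- set_weight(ev, id, a$weight)
  }
  for (r in raw$relevance) {
    if (!is.null(r$rating)) {
      ev <- set_relevance_rating(ev, r$id, r$rating, comment = r$comment)
    }
  }
  ev
}

.evaluation_from_csv <- function(path, catalog) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                         na.strings = "")
  need <- c("id", "rating")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    .stop_scirap(sprintf("evaluation CSV is missing column(s): %s",
                         paste(miss, collapse = ", ")), "scirap_format_error")
  }
  ev <- new_evaluation(catalog)
  rel_ids <- catalog$relevance_items$id
  for (i in seq_len(nrow(tab))) {
    id <- tab$id[i]
    rating <- tab$rating[i]
    removed <- isTRUE(as.logical(tab$removed[i]))
    is_rel <- id %in% rel_ids
    valid <- if (is_rel) names(.RELEVANCE_CODES) else names(.RELIABILITY_CODES)
    if (!removed && !is.na(rating) && !rating %in% valid) {
      .stop_scirap(sprintf("row %d (id %s): rating token '%s' not in {%s}",
                           i, id, rating, paste(valid, collapse = ", ")),
                   "scirap_format_error")
    }
    if (is_rel) {
      if (!is.na(rating)) {
        ev <- set_relevance_rating(ev, id, rating, comment = tab$comment[i])
      }
    } else {
      if (removed) {
        just <- if ("justification" %in% names(tab)) tab$justification[i] else NA
        ev <- suppressWarnings(remove_criterion(
          ev, id, if (is.na(just)) NULL else just))
      } else if (!is.na(rating)) {
        cm <- if ("comment" %in% names(tab)) tab$comment[i] else NA
        ev <- set_rating(ev, id, rating,
                         comment = if (is.na(cm)) NULL else cm)
      }
      if ("weight" %in% names(tab) && !is.na(tab$weight[i]) && tab$weight[i] != 1) {
        ev <- set_weight(ev, id, as.numeric(tab$weight[i]))
      }
    }
  }
  ev
}

#' Write a study evaluation to a ratings file
#'
#' Inverse of [read_evaluation()]; `format` is inferred from the file
#' extension (`.json` or `.csv`).
#'
#' @param evaluation A `scirap_evaluation`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(evaluation, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(.evaluation_to_list(evaluation), path,
                         auto_unbox = TRUE, pretty = TRUE, na = "null")
  } else if (ext == "csv") {
    a <- evaluation$assessments
    rel <- evaluation$relevance
    tab <- rbind(
      data.frame(id = a$id, section = a$section, rating = a$rating,
                 weight = a$weight, removed = a$removed,
                 justification = a$justification, comment = a$comment,
                 stringsAsFactors = FALSE),
      data.frame(id = rel$id, section = "REL", rating = rel$rating,
                 weight = NA_real_, removed = NA,
                 justification = NA_character_, comment = rel$comment,
                 stringsAsFactors = FALSE))
    utils::write.csv(tab, path, row.names = FALSE, na = "")
  } else {
    .stop_scirap(sprintf("unknown evaluation format '.%s'", ext),
                 "scirap_format_error")
  }
  invisible(path)
}

.evaluation_to_list <- function(evaluation) {
  a <- evaluation$assessments
  assessments <- lapply(seq_len(nrow(a)), function(i) {
    out <- list(id = a$id[i])
    if (a$removed[i]) {
      out$removed <- TRUE
      if (!is.na(a$justification[i])) out$justification <- a$justification[i]
    } else if (!is.na(a$rating[i])) {
      out$rating <- a$rating[i]
    }
    if (a$weight[i] != 1) out$weight <- a$weight[i]
    if (!is.na(a$comment[i])) out$comment <- a$comment[i]
    out
  })
  rel <- evaluation$relevance
  relevance <- lapply(seq_len(nrow(rel)), function(i) {
    out <- list(id = rel$id[i])
    if (!is.na(rel$rating[i])) out$rating <- rel$rating[i]
    if (!is.na(rel$comment[i])) out$comment <- rel$comment[i]
    out
  })
  out <- list(study_label = evaluation$study_label,
              catalog_ref = evaluation$catalog_ref,
              evaluator = evaluation$evaluator,
              timestamp = evaluation$timestamp,
              assessments = assessments,
              relevance = relevance)
  out[!vapply(out, is.null, TRUE)]
}
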