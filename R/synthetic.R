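#' Specification of a synthetic rater panel
#'
#' Describes the generative model for a panel of independent raters: each
#' cell of the rater-by-criterion matrix is drawn independently, first
#' removing the criterion with `removal_probability` (reliability sections
#' only), else sampling a category from `category_probabilities`. An
#' optional per-rater `leniency` vector tilts each rater's distribution
#' towards the favourable end of the scale (exponential tilt on the
#' category credit F = 1, PF = 0.5, NF = ND = 0); zero leniency leaves the
#' probabilities untouched and is the default, matching the assumption of
#' exchangeable raters.
#'
#' @param n_raters Number of raters (rows).
#' @param category_probabilities Named probability vector over the section's
#'   categories (e.g. `c(F = .8, PF = .15, NF = .05, ND = 0)`), or a list of
#'   such vectors, one per criterion, for per-criterion agreement structure.
#' @param removal_probability Probability that a rater removes a criterion
#'   (in `[0, 1)`; must be 0 for relevance).
#' @param seed Integer seed; mandatory, so panels are reproducible.
#' @param leniency Optional numeric vector of per-rater tilts (length
#'   `n_raters`); `NULL` disables the hook.
#' @return A `scirap_panel_spec` list.
#' @export
panel_spec <- function(n_raters, category_probabilities,
                       removal_probability = 0, seed, leniency = NULL) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    .stop_scirap("an integer seed is required", "scirap_domain_error")
  }
  if (!is.numeric(n_raters) || n_raters < 1L) {
    .stop_scirap("n_raters must be a positive count", "scirap_domain_error")
  }
  if (!is.numeric(removal_probability) || removal_probability < 0 ||
      removal_probability >= 1) {
    .stop_scirap("removal_probability must lie in [0, 1)", "scirap_domain_error")
  }
  probs <- if (is.list(category_probabilities)) category_probabilities
           else list(category_probabilities)
  for (p in probs) {
    if (is.null(names(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      .stop_scirap(
        "category_probabilities must be named, non-negative and sum to 1",
        "scirap_domain_error")
    }
  }
  if (!is.null(leniency) && length(leniency) != n_raters) {
    .stop_scirap("leniency must have one entry per rater", "scirap_domain_error")
  }
  structure(list(n_raters = as.integer(n_raters),
                 category_probabilities = category_probabilities,
                 removal_probability = removal_probability,
                 seed = as.integer(seed), leniency = leniency),
            class = "scirap_panel_spec")
}

# Run code with a private RNG stream so generation never disturbs the
# caller's .Random.seed.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.panel_probs_for <- function(spec, criterion_ids, cats) {
  cp <- spec$category_probabilities
  if (is.list(cp)) {
    if (length(cp) != length(criterion_ids)) {
      .stop_scirap(sprintf(
        "per-criterion probabilities: %d vectors for %d criteria",
        length(cp), length(criterion_ids)), "scirap_domain_error")
    }
  } else {
    cp <- rep(list(cp), length(criterion_ids))
  }
  lapply(cp, function(p) {
    bad <- setdiff(names(p), cats)
    if (length(bad) > 0L) {
      .stop_scirap(sprintf("unknown category token(s): %s",
                           paste(bad, collapse = ", ")), "scirap_domain_error")
    }
    full <- stats::setNames(numeric(length(cats)), cats)
    full[names(p)] <- p
    full
  })
}

#' Generate a synthetic rating matrix
#'
#' Draws a reproducible rater-by-criterion panel under a [panel_spec()]:
#' identical seeds give identical matrices.
#'
#' @param catalog A `scirap_catalog` or name/path for [load_catalog()].
#' @param section `"RQ"`, `"MQ"` or `"REL"`.
#' @param spec A `scirap_panel_spec`.
#' @param study_label Study label attached to the matrix.
#' @return A `scirap_rating_matrix`.
#' @export
#' @examples
#' sp <- panel_spec(31, c(F = .8, PF = .15, NF = .05, ND = 0), seed = 7)
#' m <- generate_panel("scirap-invitro-2.0", "MQ", sp)
#' dim(m) # 31 x 16
generate_panel <- function(catalog, section, spec, study_label = "synthetic study") {
  stopifnot(inherits(spec, "scirap_panel_spec"))
  if (!inherits(catalog, "scirap_catalog")) catalog <- load_catalog(catalog)
  is_rel <- identical(section, "REL")
  if (is_rel && spec$removal_probability > 0) {
    .stop_scirap("relevance items cannot be removed; removal_probability must be 0",
                 "scirap_domain_error")
  }
  ids <- if (is_rel) catalog$relevance_items$id
         else catalog$criteria$id[catalog$criteria$section == section]
  if (length(ids) == 0L) {
    .stop_scirap(sprintf("catalog has no section '%s'", section),
                 "scirap_domain_error")
  }
  cats <- if (is_rel) names(.RELEVANCE_CODES) else names(.RELIABILITY_CODES)
  probs <- .panel_probs_for(spec, ids, cats)
  credit <- if (is_rel) c(DR = 1, IR = 0.5, NR = 0, ND = 0)
            else c(F = 1, PF = 0.5, NF = 0, ND = 0)
  n <- spec$n_raters
  cells <- .with_seed(spec$seed, {
    m <- matrix(NA_character_, nrow = n, ncol = length(ids))
    for (j in seq_along(ids)) {
      keep <- if (spec$removal_probability > 0) {
        stats::runif(n) >= spec$removal_probability
      } else rep(TRUE, n)
      if (is.null(spec$leniency)) {
        m[keep, j] <- sample(cats, sum(keep), replace = TRUE, prob = probs[[j]])
      } else {
        for (i in which(keep)) {
          p <- probs[[j]] * exp(spec$leniency[i] * credit[cats])
          m[i, j] <- sample(cats, 1L, prob = p / sum(p))
        }
      }
    }
    m
  })
  dimnames(cells) <- list(sprintf("rater%02d", seq_len(n)), ids)
  structure(cells, study_label = study_label, section = section,
            catalog_ref = .catalog_ref(catalog),
            class = c("scirap_rating_matrix", "matrix"))
}

# Preset rating distributions for single synthetic evaluations. The two
# extremes emulate a well-reported versus a poorly reported study; "mixed"
# sits between them.
.EVALUATION_PRESETS <- list(
  well_reported = list(
    reliability = c(F = 0.75, PF = 0.15, NF = 0.05, ND = 0.05),
    relevance = c(DR = 0.70, IR = 0.20, NR = 0.05, ND = 0.05)),
  poorly_reported = list(
    reliability = c(F = 0.05, PF = 0.15, NF = 0.40, ND = 0.40),
    relevance = c(DR = 0.20, IR = 0.30, NR = 0.30, ND = 0.20)),
  mixed = list(
    reliability = c(F = 0.35, PF = 0.30, NF = 0.20, ND = 0.15),
    relevance = c(DR = 0.40, IR = 0.30, NR = 0.15, ND = 0.15)))

#' Generate a complete synthetic study evaluation
#'
#' Draws one rater's complete evaluation under a named preset:
#' `"well_reported"` skews ratings towards fulfilled, `"poorly_reported"`
#' towards not fulfilled / not determined, `"mixed"` sits in between. All
#' criteria and relevance items are rated; nothing is removed or
#' up-weighted.
#'
#' @inheritParams generate_panel
#' @param preset `"well_reported"`, `"poorly_reported"` or `"mixed"`.
#' @param seed Integer seed (mandatory).
#' @param study_label,evaluator Labels attached to the evaluation.
#' @return A complete `scirap_evaluation`.
#' @export
generate_evaluation <- function(catalog, preset, seed,
                                study_label = "synthetic study",
                                evaluator = NULL) {
  if (!.is_string(preset) || !preset %in% names(.EVALUATION_PRESETS)) {
    .stop_scirap(sprintf("unknown preset '%s' (known: %s)", preset,
                         paste(names(.EVALUATION_PRESETS), collapse = ", ")),
                 "scirap_lookup_error")
  }
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    .stop_scirap("an integer seed is required", "scirap_domain_error")
  }
  if (!inherits(catalog, "scirap_catalog")) catalog <- load_catalog(catalog)
  dist <- .EVALUATION_PRESETS[[preset]]
  ev <- new_evaluation(catalog, study_label = study_label, evaluator = evaluator)
  cats <- names(.RELIABILITY_CODES); rcats <- names(.RELEVANCE_CODES)
  draws <- .with_seed(seed, {
    list(rel = sample(cats, nrow(ev$assessments), replace = TRUE,
                      prob = dist$reliability[cats]),
         item = sample(rcats, nrow(ev$relevance), replace = TRUE,
                       prob = dist$relevance[rcats]))
  })
  ev$assessments$rating <- draws$rel
  ev$relevance$rating <- draws$item
  ev
}
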