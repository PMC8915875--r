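# Independent brute-force oracles. These deliberately take a different route
# from the package internals: per-criterion credit accumulation in a loop for
# the score, table()-based tallies for agreement, and a literal transcription
# of the decision-rule branches for classification.

oracle_score <- function(ratings, weights = rep(1, length(ratings))) {
  num <- 0; tot <- 0
  for (i in seq_along(ratings)) {
    credit <- switch(ratings[i], F = 1, PF = 0.5, NF = 0, ND = 0)
    num <- num + credit * weights[i]
    tot <- tot + weights[i]
  }
  num / tot * 100
}

oracle_agreement <- function(tokens) {
  kept <- tokens[!is.na(tokens)]
  if (length(kept) == 0L) {
    return(list(n = 0L, k = NA_integer_, p_max = NA_real_, modal = NA_character_))
  }
  tab <- table(kept)
  props <- as.numeric(tab) / length(kept)
  list(n = length(kept), k = length(tab), p_max = max(props),
       modal = names(tab)[which.max(props)])
}

oracle_class <- function(p_max, k, low_lower = 0.8, high_pmax = 0.6,
                         high_k = 3, high_k_pmax = 0.8) {
  if (p_max == 1) return("consensus")
  if (p_max >= low_lower) return("low")
  if (p_max < high_pmax) return("high")
  if (k >= high_k && p_max < high_k_pmax) return("high")
  "moderate"
}

# A complete evaluation with every criterion rated from `pool` (recycled or
# sampled) and every relevance item rated DR.
complete_evaluation <- function(ratings = "F", catalog = test_catalog(),
                                relevance = "DR", ...) {
  ev <- new_evaluation(catalog, ...)
  n <- nrow(ev$assessments)
  ev$assessments$rating <- rep_len(ratings, n)
  ev$relevance$rating <- rep_len(relevance, nrow(ev$relevance))
  ev
}

# Load the bundled catalog once per test run.
test_catalog <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- load_catalog("scirap-invitro-2.0")
    cached
  }
})
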