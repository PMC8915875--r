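# Fixed category vocabularies. Order doubles as the modal tie-break order.
.RELIABILITY_CODES <- c(F = "fulfilled", PF = "partially fulfilled",
                        NF = "not fulfilled", ND = "not determined")
.RELEVANCE_CODES <- c(DR = "directly relevant", IR = "indirectly relevant",
                      NR = "not relevant", ND = "not determined")

# Colour mapping used by colour-profile rendering (hex values fixed by config).
.CATEGORY_COLOURS <- c(F = "#2ca02c", PF = "#ffd92f", NF = "#d62728",
                       ND = "#bfbfbf", DR = "#2ca02c", IR = "#ffd92f",
                       NR = "#d62728")

#' Rating categories for reliability criteria
#'
#' The four categories a reporting-quality or methodological-quality
#' criterion can be judged as.
#'
#' @return A data frame with columns `code` (`F`, `PF`, `NF`, `ND`) and
#'   `label` (the human-readable judgment).
#' @export
#' @examples
#' rating_categories()
rating_categories <- function() {
  data.frame(code = names(.RELIABILITY_CODES),
             label = unname(.RELIABILITY_CODES),
             stringsAsFactors = FALSE)
}

#' Rating categories for relevance items
#'
#' @return A data frame with columns `code` (`DR`, `IR`, `NR`, `ND`) and
#'   `label`.
#' @export
relevance_categories <- function() {
  data.frame(code = names(.RELEVANCE_CODES),
             label = unname(.RELEVANCE_CODES),
             stringsAsFactors = FALSE)
}

.is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

.stop_scirap <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "scirap_error")))
}

# %||% as in rlang, for optional fields coming out of JSON.
`%||%` <- function(a, b) if (is.null(a)) b else a
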