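#' Load a SciRAP criteria catalog
#'
#' Resolves either the bundled instrument or a user-supplied catalog file.
#' The bundled name `"scirap-invitro-2.0"` always resolves without any file
#' and yields the version 2.0 in vitro instrument: 24 reporting-quality (RQ)
#' criteria, 16 methodological-quality (MQ) criteria and 4 relevance items,
#' organised by evaluation domain. User catalogs are JSON (canonical) or YAML
#' following the same schema and are validated on load.
#'
#' @param source Bundled catalog name (currently `"scirap-invitro-2.0"`) or
#'   path to a catalog JSON/YAML file.
#' @return A `scirap_catalog` object: a list with `name`, `version`,
#'   `domains` (per-section character vectors), `criteria` (data frame with
#'   `id`, `section`, `domain`, `text`, `conditional_note`,
#'   `is_open_question`, `guidance`) and `relevance_items` (data frame with
#'   `id`, `domain`, `text`).
#' @export
#' @examples
#' cat2 <- load_catalog("scirap-invitro-2.0")
#' table(cat2$criteria$section)
load_catalog <- function(source) {
  if (!.is_string(source)) {
    .stop_scirap("`source` must be a single catalog name or file path",
                 "scirap_lookup_error")
  }
  if (source == "scirap-invitro-2.0") {
    path <- system.file("extdata", "scirap-invitro-2.0.json",
                        package = "scirapr", mustWork = TRUE)
    return(.catalog_from_file(path))
  }
  if (!file.exists(source)) {
    .stop_scirap(sprintf(
      "unknown bundled catalog or missing file: '%s' (bundled: 'scirap-invitro-2.0')",
      source), "scirap_lookup_error")
  }
  .catalog_from_file(source)
}

.catalog_from_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      .stop_scirap("the 'yaml' package is required to read YAML catalogs",
                   "scirap_format_error")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  catalog <- .catalog_from_list(raw)
  violations <- validate_catalog(catalog)
  if (length(violations) > 0L) {
    .stop_scirap(paste0("invalid catalog:\n  - ",
                        paste(violations, collapse = "\n  - ")),
                 "scirap_validation_error")
  }
  catalog
}

.catalog_from_list <- function(raw) {
  for (field in c("name", "version", "domains", "criteria", "relevance_items")) {
    if (is.null(raw[[field]])) {
      .stop_scirap(sprintf("catalog is missing required field '%s'", field),
                   "scirap_validation_error")
    }
  }
  chr1 <- function(x) if (is.null(x)) NA_character_ else as.character(x)[1]
  criteria <- do.call(rbind, lapply(raw$criteria, function(cr) {
    data.frame(id = chr1(cr$id), section = chr1(cr$section),
               domain = chr1(cr$domain), text = chr1(cr$text),
               conditional_note = chr1(cr$conditional_note),
               is_open_question = isTRUE(cr$is_open_question),
               guidance = chr1(cr$guidance),
               stringsAsFactors = FALSE)
  }))
  relevance <- do.call(rbind, lapply(raw$relevance_items, function(it) {
    data.frame(id = chr1(it$id), domain = chr1(it$domain), text = chr1(it$text),
               stringsAsFactors = FALSE)
  }))
  structure(list(
    name = as.character(raw$name)[1],
    version = as.character(raw$version)[1],
    domains = lapply(raw$domains, function(d) unlist(d, use.names = FALSE)),
    criteria = criteria,
    relevance_items = relevance
  ), class = "scirap_catalog")
}

#' Validate a catalog against the instrument's structural invariants
#'
#' Violations are returned as data, not raised, so a whole catalog can be
#' audited in one pass. Checked invariants: unique criterion and item ids;
#' sections restricted to RQ/MQ; domains drawn from the declared per-section
#' domain list; the "funding and competing interests" domain belongs to RQ
#' only; and, for catalogs declaring version 2.0, the fixed sizes of the
#' instrument (24 RQ criteria, 16 MQ criteria, 4 relevance items).
#'
#' @param catalog A `scirap_catalog`.
#' @return Character vector of human-readable violations; empty when the
#'   catalog is valid.
#' @export
validate_catalog <- function(catalog) {
  v <- character(0)
  cr <- catalog$criteria
  rel <- catalog$relevance_items
  all_ids <- c(cr$id, rel$id)
  dup <- unique(all_ids[duplicated(all_ids)])
  for (id in dup) v <- c(v, sprintf("%s: duplicated id", id))
  bad_sec <- cr$id[!cr$section %in% c("RQ", "MQ")]
  for (id in bad_sec) v <- c(v, sprintf("%s: section must be RQ or MQ", id))
  for (i in seq_len(nrow(cr))) {
    sec <- cr$section[i]
    declared <- catalog$domains[[sec]]
    if (!is.null(declared) && !cr$domain[i] %in% declared) {
      v <- c(v, sprintf("%s: domain '%s' not declared for section %s",
                        cr$id[i], cr$domain[i], sec))
    }
  }
  if ("funding and competing interests" %in% catalog$domains$MQ ||
      any(cr$section == "MQ" & cr$domain == "funding and competing interests")) {
    v <- c(v, "MQ: the 'funding and competing interests' domain is RQ-only")
  }
  if (any(is.na(rel$id)) || anyDuplicated(rel$id)) {
    v <- c(v, "relevance_items: ids must be present and unique")
  }
  if (identical(catalog$version, "2.0")) {
    n_rq <- sum(cr$section == "RQ"); n_mq <- sum(cr$section == "MQ")
    if (n_rq != 24L) v <- c(v, sprintf("version 2.0 requires 24 RQ criteria, found %d", n_rq))
    if (n_mq != 16L) v <- c(v, sprintf("version 2.0 requires 16 MQ criteria, found %d", n_mq))
    if (nrow(rel) != 4L) v <- c(v, sprintf("version 2.0 requires 4 relevance items, found %d", nrow(rel)))
  }
  v
}

#' Serialize a catalog to JSON
#'
#' Writes the schema read back by [load_catalog()]; `write_catalog()` then
#' `load_catalog()` round-trips to an equal catalog.
#'
#' @param catalog A `scirap_catalog`.
#' @param path Output file path (`.json`).
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  cr <- catalog$criteria
  criteria <- lapply(seq_len(nrow(cr)), function(i) {
    out <- list(id = cr$id[i], section = cr$section[i],
                domain = cr$domain[i], text = cr$text[i])
    if (!is.na(cr$conditional_note[i])) out$conditional_note <- cr$conditional_note[i]
    if (isTRUE(cr$is_open_question[i])) out$is_open_question <- TRUE
    if (!is.na(cr$guidance[i])) out$guidance <- cr$guidance[i]
    out
  })
  rel <- catalog$relevance_items
  items <- lapply(seq_len(nrow(rel)), function(i) {
    list(id = rel$id[i], domain = rel$domain[i], text = rel$text[i])
  })
  obj <- list(name = catalog$name, version = catalog$version,
              domains = catalog$domains, criteria = criteria,
              relevance_items = items)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

.catalog_ref <- function(catalog) paste0(catalog$name, "@", catalog$version)

#' @export
print.scirap_catalog <- function(x, ...) {
  cat(sprintf("SciRAP catalog '%s' version %s\n", x$name, x$version))
  cat(sprintf("  %d RQ criteria, %d MQ criteria, %d relevance items\n",
              sum(x$criteria$section == "RQ"), sum(x$criteria$section == "MQ"),
              nrow(x$relevance_items)))
  for (sec in names(x$domains)) {
    cat(sprintf("  %s domains: %s\n", sec, paste(x$domains[[sec]], collapse = "; ")))
  }
  invisible(x)
}
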