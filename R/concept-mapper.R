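# Lexical concept mapping.  Term-valued columns are mapped against a loaded
# vocabulary through a tiered, purely lexical scheme: exact label, normalized
# label, exact synonym, normalized synonym.  No stemming and no edit-distance
# matching — mapping is semi-automated, and uncertain matches stay with the
# curators in the unmapped report.

#' Load a vocabulary file
#'
#' Tab-delimited text with columns `term_id`, `label`, `synonyms`
#' (pipe-separated, may be empty) and `category`.
#'
#' @param path vocabulary file.
#' @return object of class `disco_vocabulary`.
#' @export
read_vocabulary <- function(path) {
  if (!file.exists(path)) disco_abort("not_found", paste0("no vocabulary at ", path))
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                          na.strings = character(0), quote = "",
                          stringsAsFactors = FALSE)
  needed <- c("term_id", "label")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    disco_abort("validation", paste0(
      "vocabulary is missing column(s): ", paste(missing, collapse = ", ")
    ))
  }
  if (anyDuplicated(df$term_id)) {
    disco_abort("validation", "vocabulary term_id values must be unique")
  }
  if (any(!nzchar(df$label))) {
    disco_abort("validation", "vocabulary labels must be non-empty")
  }
  if (!"synonyms" %in% names(df)) df$synonyms <- ""
  if (!"category" %in% names(df)) df$category <- ""
  syns <- lapply(strsplit(df$synonyms, "|", fixed = TRUE), function(s) {
    s[nzchar(s)]
  })
  structure(
    list(entries = data.frame(
      term_id = df$term_id, label = df$label, category = df$category,
      stringsAsFactors = FALSE
    ), synonyms = setNames(syns, df$term_id)),
    class = "disco_vocabulary"
  )
}

#' @export
print.disco_vocabulary <- function(x, ...) {
  cat(sprintf("<disco_vocabulary> %d term(s)\n", nrow(x$entries)))
  invisible(x)
}

# Normalization: lowercase, trim, collapse internal whitespace, strip
# surrounding punctuation.
normalize_term <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[[:space:]]+", " ", x)
  x <- sub("^[[:punct:]]+", "", x)
  x <- sub("[[:punct:]]+$", "", x)
  trimws(x)
}

#' Map one raw term against a vocabulary
#'
#' Tier order: exact label > normalized label > exact synonym > normalized
#' synonym.  All candidates at the best achieved tier are returned, ordered
#' by term id.  No fuzzy matching: an unmatched term is simply unmapped.
#'
#' @param raw the raw string value.
#' @param vocabulary a [read_vocabulary()] result.
#' @return list with `tier` (one of `exact`, `normalized`, `synonym`,
#'   `synonym_normalized`, `unmapped`) and `term_ids` (character, possibly
#'   empty).
#' @export
map_term <- function(raw, vocabulary) {
  entries <- vocabulary$entries
  hit <- function(ids) list(term_ids = radix_sort(unique(ids)))
  ids <- entries$term_id[entries$label == raw]
  if (length(ids)) return(c(hit(ids), tier = "exact"))
  norm <- normalize_term(raw)
  ids <- entries$term_id[normalize_term(entries$label) == norm]
  if (length(ids)) return(c(hit(ids), tier = "normalized"))
  syn_exact <- vapply(vocabulary$synonyms, function(s) raw %in% s, logical(1))
  if (any(syn_exact)) return(c(hit(names(vocabulary$synonyms)[syn_exact]), tier = "synonym"))
  syn_norm <- vapply(vocabulary$synonyms, function(s) {
    norm %in% normalize_term(s)
  }, logical(1))
  if (any(syn_norm)) {
    return(c(hit(names(vocabulary$synonyms)[syn_norm]), tier = "synonym_normalized"))
  }
  list(term_ids = character(), tier = "unmapped")
}

#' Map the term columns of a resource's production version
#'
#' Each distinct raw value per term-annotated column is mapped once; the
#' mappings are persisted keyed to the production version, and distinct
#' unmapped terms are reported for curators, most frequent first (ties by
#' term ascending).
#'
#' @param store a [disco_store()].
#' @param resource_id resource with a production version.
#' @param vocabulary a [read_vocabulary()] result.
#' @param script optional parsed script (defaults to the registered one).
#' @return list with `mappings` (data frame: `field`, `raw`, `term_id`,
#'   `tier`, `n`), `unmapped` (data frame: `field`, `raw`, `n`), `version`,
#'   and `notice` when the script declares no term columns.
#' @export
map_resource_terms <- function(store, resource_id, vocabulary, script = NULL) {
  res <- get_resource(store, resource_id)
  prod <- store$production[[resource_id]]
  if (is.null(prod)) {
    disco_abort("not_found", paste0(resource_id, " has no production version"))
  }
  if (is.null(script)) script <- parse_script(res$service_scripts[["interop"]])
  version <- store$history[[resource_id]]$version
  term_fields <- intersect(
    script$schema$name[script$schema$content_kind == "term"],
    names(prod$data)
  )
  if (!length(term_fields)) {
    return(list(
      mappings = data.frame(
        field = character(), raw = character(), term_id = character(),
        tier = character(), n = integer(), stringsAsFactors = FALSE
      ),
      unmapped = data.frame(field = character(), raw = character(),
                            n = integer(), stringsAsFactors = FALSE),
      version = version,
      notice = "script declares no term-valued columns"
    ))
  }
  map_rows <- list()
  unmapped_rows <- list()
  for (f in term_fields) {
    vals <- prod$data[[f]]
    vals <- vals[!is.na(vals) & vals != ""]
    if (!length(vals)) next
    counts <- table(vals)
    for (raw in radix_sort(names(counts))) {
      m <- map_term(raw, vocabulary)
      if (m$tier == "unmapped") {
        unmapped_rows[[length(unmapped_rows) + 1L]] <- data.frame(
          field = f, raw = raw, n = as.integer(counts[[raw]]),
          stringsAsFactors = FALSE
        )
      } else {
        map_rows[[length(map_rows) + 1L]] <- data.frame(
          field = f, raw = raw, term_id = m$term_ids, tier = m$tier,
          n = as.integer(counts[[raw]]), stringsAsFactors = FALSE
        )
      }
    }
  }
  mappings <- if (length(map_rows)) {
    do.call(rbind, c(map_rows, list(make.row.names = FALSE)))
  } else {
    data.frame(field = character(), raw = character(), term_id = character(),
               tier = character(), n = integer(), stringsAsFactors = FALSE)
  }
  unmapped <- if (length(unmapped_rows)) {
    df <- do.call(rbind, c(unmapped_rows, list(make.row.names = FALSE)))
    df[radix_order(-df$n, df$raw), , drop = FALSE]
  } else {
    data.frame(field = character(), raw = character(), n = integer(),
               stringsAsFactors = FALSE)
  }
  rownames(unmapped) <- NULL
  out <- list(mappings = mappings, unmapped = unmapped, version = version)
  store$mappings[[resource_id]] <- c(
    store$mappings[[resource_id]] %||% list(),
    setNames(list(out), as.character(version))
  )
  out
}
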