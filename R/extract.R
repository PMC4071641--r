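# Record extraction and type coercion.  Extraction yields raw, untrimmed
# strings; the only transformation applied is CSV/TSV dialect resolution
# (RFC 4180 quoting for CSV; TSV is tab-split with no quoting).  A structural
# mismatch — a selected column or path that is gone — is the "ingestion
# breaks" signal and raises an extraction error naming source and selector.

parse_csv_records <- function(text, sep) {
  df <- utils::read.csv(
    text = text, sep = sep, colClasses = "character",
    check.names = FALSE, stringsAsFactors = FALSE,
    na.strings = character(0), quote = if (sep == ",") "\"" else "",
    strip.white = FALSE, blank.lines.skip = TRUE
  )
  names(df) <- trimws_bom(names(df))
  df
}

trimws_bom <- function(x) sub("^﻿", "", x)

extract_from_tabular <- function(src, text, idx) {
  sep <- if (src$format == "csv") "," else "\t"
  df <- tryCatch(
    parse_csv_records(text, sep),
    error = function(e) disco_abort(
      "extraction",
      paste0("source ", idx, " (", src$locator, "): unreadable ",
             src$format, " document: ", conditionMessage(e)),
      source = src$locator, selector = src$record_selector
    )
  )
  out <- list()
  for (fname in names(src$extractors)) {
    col <- src$extractors[[fname]]
    if (!col %in% names(df)) {
      disco_abort(
        "extraction",
        paste0("source ", idx, " (", src$locator, "): column '", col,
               "' selected for field '", fname, "' is missing from the header"),
        source = src$locator, selector = col
      )
    }
    out[[fname]] <- df[[col]]
  }
  as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE,
                optional = TRUE)
}

extract_from_xml <- function(src, text, idx) {
  doc <- tryCatch(
    xml2::read_xml(text),
    error = function(e) disco_abort(
      "extraction",
      paste0("source ", idx, " (", src$locator, "): malformed XML: ",
             conditionMessage(e)),
      source = src$locator, selector = src$record_selector
    )
  )
  nodes <- xml2::xml_find_all(doc, paste0("./", src$record_selector))
  rows <- lapply(nodes, function(node) {
    vapply(src$extractors, function(path) {
      if (startsWith(path, "@")) {
        xml2::xml_attr(node, substring(path, 2L))
      } else {
        hit <- xml2::xml_find_first(node, paste0("./", path))
        if (inherits(hit, "xml_missing")) NA_character_ else xml2::xml_text(hit)
      }
    }, character(1))
  })
  rows_to_frame(rows, names(src$extractors))
}

extract_from_json <- function(src, text, idx) {
  obj <- tryCatch(
    jsonlite::fromJSON(text, simplifyVector = FALSE),
    error = function(e) disco_abort(
      "extraction",
      paste0("source ", idx, " (", src$locator, "): malformed JSON: ",
             conditionMessage(e)),
      source = src$locator, selector = src$record_selector
    )
  )
  node <- obj
  sel <- src$record_selector
  if (nzchar(sel)) {
    for (step in strsplit(sub("^/", "", sel), "/", fixed = TRUE)[[1]]) {
      node <- node[[step]]
      if (is.null(node)) {
        disco_abort(
          "extraction",
          paste0("source ", idx, " (", src$locator, "): selector '", sel,
                 "' does not resolve (missing member '", step, "')"),
          source = src$locator, selector = sel
        )
      }
    }
  }
  if (!is.list(node)) {
    disco_abort(
      "extraction",
      paste0("source ", idx, " (", src$locator, "): selector '", sel,
             "' does not point at a record array"),
      source = src$locator, selector = sel
    )
  }
  rows <- lapply(node, function(item) {
    vapply(src$extractors, function(ptr) {
      v <- item
      for (step in strsplit(sub("^/", "", ptr), "/", fixed = TRUE)[[1]]) {
        v <- v[[step]]
        if (is.null(v)) return(NA_character_)
      }
      if (is.null(v)) NA_character_ else as.character(v)
    }, character(1))
  })
  rows_to_frame(rows, names(src$extractors))
}

rows_to_frame <- function(rows, fields) {
  if (!length(rows)) {
    return(as.data.frame(
      setNames(rep(list(character()), length(fields)), fields),
      stringsAsFactors = FALSE, check.names = FALSE
    ))
  }
  mat <- do.call(rbind, rows)
  df <- as.data.frame(mat, stringsAsFactors = FALSE, check.names = FALSE,
                      optional = TRUE)
  names(df) <- fields
  rownames(df) <- NULL
  df
}

#' Extract records from a script's sources
#'
#' One record per selected record unit, concatenated across sources in source
#' order.  Fields a source does not extract are missing (`NA`).
#'
#' @param script a parsed [parse_script()] result.
#' @param documents optional list of pre-fetched documents (raw vectors or
#'   character), one per source, in source order; when `NULL` each source is
#'   fetched via [fetch_source()].
#' @param base_dir base directory for relative locators (defaults to the
#'   script's own directory).
#' @return data frame of raw string records, columns in declared field order
#'   (only declared fields present).
#' @export
extract_records <- function(script, documents = NULL, base_dir = script$dir) {
  parts <- lapply(seq_along(script$sources), function(i) {
    src <- script$sources[[i]]
    content <- if (is.null(documents)) {
      fetch_source(src, base_dir)$content
    } else {
      documents[[i]]
    }
    text <- source_text(content)
    switch(src$format,
      csv = , tsv = extract_from_tabular(src, text, i),
      xml = extract_from_xml(src, text, i),
      json = extract_from_json(src, text, i)
    )
  })
  all_fields <- script$schema$name
  parts <- lapply(parts, function(df) {
    for (f in setdiff(all_fields, names(df))) df[[f]] <- rep(NA_character_, nrow(df))
    present <- intersect(all_fields, names(df))
    df[, present, drop = FALSE][, order(match(present, all_fields)), drop = FALSE]
  })
  # Restrict to fields any source extracted; absent columns come back NA via
  # canonicalization downstream.
  out <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}

re_int <- "^[+-]?[0-9]+$"
re_real <- "^[+-]?([0-9]+(\\.[0-9]*)?|\\.[0-9]+)([eE][+-]?[0-9]+)?$"
re_iso_date <- "^[0-9]{4}-[0-9]{2}-[0-9]{2}$"
re_mdy_date <- "^[0-9]{1,2}/[0-9]{1,2}/[0-9]{2}$"
re_url <- "^[A-Za-z][A-Za-z0-9+.-]*://[^[:space:]]+$"

# Accepted date dialects: ISO-8601 calendar dates plus M/D/YY with pivot year
# 1970 (70-99 -> 1900s, 00-69 -> 2000s), so "4/4/13" reads as 2013-04-04.
parse_disco_date <- function(x) {
  if (grepl(re_iso_date, x)) {
    d <- as.Date(x, format = "%Y-%m-%d")
    if (!is.na(d) && format(d, "%Y-%m-%d") == x) return(d)
    return(as.Date(NA))
  }
  if (grepl(re_mdy_date, x)) {
    parts <- as.integer(strsplit(x, "/", fixed = TRUE)[[1]])
    yy <- parts[3]
    year <- if (yy >= 70) 1900L + yy else 2000L + yy
    iso <- sprintf("%04d-%02d-%02d", year, parts[1], parts[2])
    d <- as.Date(iso, format = "%Y-%m-%d")
    if (!is.na(d) && format(d, "%Y-%m-%d") != iso) d <- as.Date(NA)
    return(d)
  }
  as.Date(NA)
}

#' Validate records against declared field types
#'
#' Collects per-cell issues instead of throwing: unparseable integers, reals,
#' dates and urls become `data_type_error`; text longer than `max_length`
#' becomes `field_overflow` (the value is reported, never truncated).  Missing
#' fields and empty strings are not coercion failures.
#'
#' @param script a parsed harvest script.
#' @param records raw record data frame from [extract_records()].
#' @return list with `records` (unchanged raw values), `typed` (list-columns
#'   with parsed values where parsing succeeded) and `issues` (an issue data
#'   frame).
#' @export
coerce_records <- function(script, records) {
  issues <- list()
  typed <- records
  for (i in seq_len(nrow(script$schema))) {
    f <- script$schema[i, ]
    if (!f$name %in% names(records)) next
    v <- records[[f$name]]
    present <- !is.na(v) & v != ""
    idx <- which(present)
    if (f$type == "integer") {
      bad <- idx[!grepl(re_int, v[idx])]
      for (r in bad) {
        issues[[length(issues) + 1L]] <- new_issue(
          "data_type_error", paste0("row:", r), f$name,
          paste0("'", v[r], "' is not an integer")
        )
      }
    } else if (f$type == "real") {
      bad <- idx[!grepl(re_real, v[idx])]
      for (r in bad) {
        issues[[length(issues) + 1L]] <- new_issue(
          "data_type_error", paste0("row:", r), f$name,
          paste0("'", v[r], "' is not a number")
        )
      }
    } else if (f$type == "date") {
      parsed <- rep(as.Date(NA), length(v))
      for (r in idx) {
        d <- parse_disco_date(v[r])
        parsed[r] <- d
        if (is.na(d)) {
          issues[[length(issues) + 1L]] <- new_issue(
            "data_type_error", paste0("row:", r), f$name,
            paste0("'", v[r], "' is not an ISO-8601 or M/D/YY date")
          )
        }
      }
      typed[[f$name]] <- as.character(parsed)
    } else if (f$type == "url") {
      bad <- idx[!grepl(re_url, v[idx])]
      for (r in bad) {
        issues[[length(issues) + 1L]] <- new_issue(
          "data_type_error", paste0("row:", r), f$name,
          paste0("'", v[r], "' is not a URL")
        )
      }
    } else if (f$type == "text" && !is.na(f$max_length)) {
      over <- idx[nchar(v[idx], type = "chars") > f$max_length]
      for (r in over) {
        issues[[length(issues) + 1L]] <- new_issue(
          "field_overflow", paste0("row:", r), f$name,
          paste0(nchar(v[r], type = "chars"), " chars exceeds max_length ",
                 f$max_length)
        )
      }
    }
  }
  list(
    records = records,
    typed = typed,
    issues = do.call(bind_issues, issues)
  )
}

#' Render a record's drill-down link
#'
#' Substitutes `{field}` placeholders in the script's link template with the
#' record's raw values.
#'
#' @param script a parsed harvest script.
#' @param record named character vector (one record).
#' @return the URL string, or `NA` if the script has no template.
#' @export
drilldown_link <- function(script, record) {
  if (is.na(script$link_template)) return(NA_character_)
  out <- script$link_template
  for (f in names(record)) {
    out <- gsub(paste0("{", f, "}"), record[[f]] %||% "", out, fixed = TRUE)
  }
  out
}
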