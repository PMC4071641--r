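# Harvest scripts: the declarative templates that tell the crawler where a
# resource's data lives, how to pull each field out, what the primary key is,
# and how records link back into the source.  The script file is a JSON
# document with top-level keys `resource`, `table`, `sources`, `fields`,
# `primary_key`, `link_template`.

FIELD_TYPES <- c("integer", "real", "text", "date", "url")
SOURCE_FORMATS <- c("csv", "tsv", "xml", "json")
CONTENT_KINDS <- c("value", "term", "object")

#' Parse and validate a harvest script
#'
#' All structural invariants are enforced here: unique field names, primary
#' key and link-template placeholders naming declared fields, `max_length`
#' only on text fields, extractors only for declared fields, and a
#' syntactically valid record selector per source format.
#'
#' @param document path to the script file (JSON).
#' @return an object of class `disco_script`.
#' @export
parse_script <- function(document) {
  if (!file.exists(document)) {
    disco_abort("not_found", paste0("script not found: ", document))
  }
  raw <- tryCatch(
    jsonlite::fromJSON(document, simplifyVector = FALSE),
    error = function(e) disco_abort(
      "parse", paste0("script ", document, " is not valid JSON: ", conditionMessage(e))
    )
  )
  for (key in c("resource", "table", "sources", "fields")) {
    if (is.null(raw[[key]])) {
      disco_abort("validation", paste0(
        "script ", document, ": missing required element '", key, "'"
      ))
    }
  }

  fields <- lapply(raw$fields, function(f) {
    if (is.null(f$name) || !nzchar(f$name)) {
      disco_abort("validation", "script element 'fields': field with no name")
    }
    type <- f$type %||% "text"
    if (!type %in% FIELD_TYPES) {
      disco_abort("validation", paste0(
        "field '", f$name, "': unknown declared type '", type, "'"
      ))
    }
    kind <- f$content_kind %||% "value"
    if (!kind %in% CONTENT_KINDS) {
      disco_abort("validation", paste0(
        "field '", f$name, "': unknown content kind '", kind, "'"
      ))
    }
    if (!is.null(f$max_length) && type != "text") {
      disco_abort("validation", paste0(
        "field '", f$name, "': max_length is only valid for text fields"
      ))
    }
    list(
      name = f$name, type = type,
      max_length = if (is.null(f$max_length)) NA_integer_ else as.integer(f$max_length),
      content_kind = kind,
      relationship = f$relationship %||% NA_character_
    )
  })
  fnames <- vapply(fields, `[[`, character(1), "name")
  dup <- fnames[duplicated(fnames)]
  if (length(dup)) {
    disco_abort("validation", paste0(
      "script element 'fields': duplicate field name(s) ",
      paste(unique(dup), collapse = ", ")
    ))
  }
  schema <- data.frame(
    name = fnames,
    type = vapply(fields, `[[`, character(1), "type"),
    max_length = vapply(fields, `[[`, integer(1), "max_length"),
    content_kind = vapply(fields, `[[`, character(1), "content_kind"),
    relationship = vapply(fields, `[[`, character(1), "relationship"),
    stringsAsFactors = FALSE
  )

  pk <- vapply(raw$primary_key %||% list(), as.character, character(1))
  missing_pk <- setdiff(pk, fnames)
  if (length(missing_pk)) {
    disco_abort("validation", paste0(
      "script element 'primary_key' names undeclared field(s): ",
      paste(missing_pk, collapse = ", ")
    ))
  }

  link_template <- raw$link_template %||% NA_character_
  if (!is.na(link_template)) {
    ph <- regmatches(link_template, gregexpr("\\{([^}]*)\\}", link_template))[[1]]
    ph <- gsub("[{}]", "", ph)
    bad <- setdiff(ph, fnames)
    if (length(bad)) {
      disco_abort("validation", paste0(
        "script element 'link_template' references undeclared field(s): ",
        paste(bad, collapse = ", ")
      ))
    }
  }

  sources <- lapply(seq_along(raw$sources), function(i) {
    s <- raw$sources[[i]]
    loc <- paste0("sources[", i, "]")
    fmt <- s$format %||% ""
    if (!fmt %in% SOURCE_FORMATS) {
      disco_abort("validation", paste0(
        "script element '", loc, "': unknown format tag '", fmt, "'"
      ))
    }
    if (is.null(s$locator) || !nzchar(s$locator)) {
      disco_abort("validation", paste0("script element '", loc, "': missing locator"))
    }
    sel <- s$record_selector %||% if (fmt %in% c("csv", "tsv")) "header" else ""
    validate_selector(fmt, sel, loc)
    extract <- s$extractors %||% setNames(as.list(fnames), fnames)
    extract <- lapply(extract, as.character)
    bad <- setdiff(names(extract), fnames)
    if (length(bad)) {
      disco_abort("validation", paste0(
        "script element '", loc, "': extractor(s) for undeclared field(s) ",
        paste(bad, collapse = ", ")
      ))
    }
    structure(
      list(locator = s$locator, format = fmt, record_selector = sel,
           extractors = extract),
      class = "disco_source_spec"
    )
  })

  renames <- NULL
  if (!is.null(raw$renames)) {
    renames <- vapply(raw$renames, as.character, character(1))
    bad <- setdiff(unname(renames), fnames)
    if (length(bad)) {
      disco_abort("validation", paste0(
        "script element 'renames' targets undeclared field(s): ",
        paste(bad, collapse = ", ")
      ))
    }
  }

  structure(
    list(
      resource_id = raw$resource, table_name = raw$table,
      sources = sources, schema = schema, primary_key = pk,
      link_template = link_template, renames = renames,
      path = normalizePath(document), dir = dirname(normalizePath(document))
    ),
    class = "disco_script"
  )
}

# Restricted selector syntax per format: csv/tsv use the header row ("header");
# xml uses child steps only (a/b/c); json uses a slash path to the record
# array ("" for a root array).  Full query languages are deliberately out.
validate_selector <- function(format, selector, loc) {
  ok <- switch(format,
    csv = , tsv = identical(selector, "header") || identical(selector, ""),
    xml = nzchar(selector) && !grepl("^/|//|@|\\[", selector),
    json = identical(selector, "") ||
      grepl("^(/[^/]+)+$", selector) || grepl("^[^/@]+(/[^/]+)*$", selector)
  )
  if (!isTRUE(ok)) {
    disco_abort("validation", paste0(
      "script element '", loc, "': record selector '", selector,
      "' is not valid for format ", format
    ))
  }
}

#' @export
print.disco_script <- function(x, ...) {
  cat(sprintf(
    "<disco_script> %s/%s: %d field(s), %d source(s), pk = [%s]\n",
    x$resource_id, x$table_name, nrow(x$schema), length(x$sources),
    paste(x$primary_key, collapse = ", ")
  ))
  invisible(x)
}

#' Fetch one source document
#'
#' Returns the raw bytes untouched plus fetch metadata (byte size and
#' modification timestamp) used later for change probing.
#'
#' @param spec a source spec from a parsed script.
#' @param base_dir directory relative locators resolve against (usually the
#'   script's directory).
#' @return list with `content` (raw vector), `size`, `mtime`, `fetched_at`,
#'   `locator`.
#' @export
fetch_source <- function(spec, base_dir = ".") {
  loc <- spec$locator
  if (grepl("^[a-z][a-z0-9+.-]*://", loc)) {
    con <- tryCatch(url(loc, open = "rb"), error = function(e) NULL)
    if (is.null(con)) {
      disco_abort("fetch", paste0("unreachable locator: ", loc),
                  locator = loc, reason = "unreachable")
    }
    on.exit(close(con))
    content <- tryCatch(
      readBin(con, what = "raw", n = 64L * 1024L * 1024L),
      error = function(e) disco_abort(
        "fetch", paste0("fetch from ", loc, " failed: ", conditionMessage(e)),
        locator = loc, reason = "timeout"
      )
    )
    return(list(content = content, size = length(content),
                mtime = NA, fetched_at = Sys.time(), locator = loc))
  }
  path <- if (file.exists(loc)) loc else file.path(base_dir, loc)
  if (!file.exists(path)) {
    disco_abort("fetch", paste0("source not found: ", loc),
                locator = loc, reason = "not_found")
  }
  info <- file.info(path)
  content <- readBin(path, what = "raw", n = info$size)
  list(content = content, size = length(content), mtime = info$mtime,
       fetched_at = Sys.time(), locator = loc)
}

source_text <- function(content) {
  if (is.raw(content)) {
    txt <- rawToChar(content)
    Encoding(txt) <- "UTF-8"
    txt
  } else {
    as.character(content)
  }
}
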