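# Resource registry: the catalog behind the main dashboard.  A resource is
# described by an XML information file (id, name, contacts, services with
# their script locators, free-text description) and is the unit everything
# else — harvests, versions, schedules, views — hangs off.

VALID_SERVICES <- c("interop", "linkout", "news")

parse_info_file <- function(info_file) {
  if (!file.exists(info_file)) {
    disco_abort("not_found", paste0("info file not found: ", info_file))
  }
  doc <- tryCatch(
    xml2::read_xml(info_file),
    error = function(e) disco_abort(
      "parse", paste0("malformed resource XML in <document>: ", conditionMessage(e))
    )
  )
  root <- xml2::xml_name(doc)
  if (root != "resource") {
    disco_abort("parse", paste0("expected root element <resource>, found <", root, ">"))
  }
  nif_id <- xml2::xml_attr(doc, "id")
  if (is.na(nif_id) || !nzchar(nif_id)) {
    disco_abort("parse", "element <resource> is missing its id attribute")
  }
  name <- xml2::xml_attr(doc, "name")
  if (is.na(name) || !nzchar(name)) {
    disco_abort("parse", "element <resource> is missing its name attribute")
  }
  contacts <- lapply(xml2::xml_find_all(doc, "./contact"), function(c) {
    list(name = xml2::xml_attr(c, "name"), email = xml2::xml_attr(c, "email"))
  })
  services <- lapply(xml2::xml_find_all(doc, "./service"), function(sv) {
    type <- xml2::xml_attr(sv, "type")
    if (is.na(type) || !type %in% VALID_SERVICES) {
      disco_abort("parse", paste0(
        "element <service> has unknown type '", type, "' (expected ",
        paste(VALID_SERVICES, collapse = "/"), ")"
      ))
    }
    list(type = type, script = xml2::xml_attr(sv, "script"))
  })
  description <- xml2::xml_text(xml2::xml_find_first(doc, "./description"))
  if (is.na(description)) description <- ""
  list(
    nif_id = nif_id, name = name, contacts = contacts,
    services = services, description = trimws(description)
  )
}

resolve_locator <- function(locator, base_dir) {
  if (is.na(locator) || !nzchar(locator)) return(NA_character_)
  if (grepl("^[a-z][a-z0-9+.-]*://", locator)) return(locator) # remote URL
  if (file.exists(locator)) return(normalizePath(locator))
  cand <- file.path(base_dir, locator)
  if (file.exists(cand)) return(normalizePath(cand))
  locator
}

#' Register (or re-register) a resource
#'
#' Imports a resource-information XML file into the registry.  Re-registering
#' an existing `nif_id` updates the stored metadata in place and logs the
#' change; a conflicting name for the same id is rejected.
#'
#' @param store a [disco_store()].
#' @param info_file path to the resource-information XML document
#'   (`<resource id name>` with `<contact>`, `<service>`, `<description>`
#'   children).
#' @param script_locator optional override for the interop harvest-script
#'   location; defaults to the `script` attribute of the interop `<service>`
#'   element, resolved relative to `info_file`.
#' @param services optional character vector overriding the service set
#'   (subset of `interop`, `linkout`, `news`).
#' @param time registration timestamp (for reproducible tests).
#' @return the stored resource record, invisibly.
#' @export
register_resource <- function(store, info_file, script_locator = NULL,
                              services = NULL, time = Sys.time()) {
  info <- parse_info_file(info_file)
  base_dir <- dirname(normalizePath(info_file))

  svc_types <- vapply(info$services, `[[`, character(1), "type")
  if (!is.null(services)) {
    bad <- setdiff(services, VALID_SERVICES)
    if (length(bad)) {
      disco_abort("usage", paste0("unknown service(s): ", paste(bad, collapse = ", ")))
    }
    svc_types <- services
  }
  if (!length(svc_types)) {
    disco_abort("validation", paste0(
      "active resource ", info$nif_id, " must declare at least one service"
    ))
  }

  service_scripts <- list()
  for (sv in info$services) {
    if (sv$type %in% svc_types) {
      service_scripts[[sv$type]] <- resolve_locator(sv$script, base_dir)
    }
  }
  for (missing in setdiff(svc_types, names(service_scripts))) {
    service_scripts[missing] <- list(NA_character_)
  }
  if (!is.null(script_locator)) {
    service_scripts[["interop"]] <- resolve_locator(script_locator, base_dir)
  }

  interop_script <- service_scripts[["interop"]]
  if ("interop" %in% svc_types) {
    remote <- !is.na(interop_script) && grepl("^[a-z][a-z0-9+.-]*://", interop_script)
    if (is.na(interop_script) ||
        (!remote && !file.exists(interop_script))) {
      disco_abort("validation", paste0(
        "harvest script for ", info$nif_id, " is not readable: ",
        interop_script %||% "<none>"
      ))
    }
    location_kind <- if (remote) "remote" else "local"
  } else {
    location_kind <- NA_character_
  }

  if (!grepl("^[A-Za-z]+-[0-9]{4}-[0-9]+$", info$nif_id)) {
    warning(sprintf("resource id '%s' does not follow the usual nif-DDDD-DDDDD shape",
                    info$nif_id), call. = FALSE)
  }

  existing <- store$resources[[info$nif_id]]
  if (!is.null(existing) && !identical(existing$name, info$name)) {
    disco_abort("conflict", sprintf(
      "resource %s is already registered as '%s' (got '%s')",
      info$nif_id, existing$name, info$name
    ))
  }

  rec <- list(
    nif_id = info$nif_id, name = info$name,
    services = sort(unique(svc_types)),
    service_scripts = service_scripts,
    script_location = location_kind,
    info_file = normalizePath(info_file),
    contacts = info$contacts,
    description = info$description,
    active = TRUE,
    registered_at = fmt_time(time)
  )
  store$resources[[info$nif_id]] <- rec
  audit_log(store, info$nif_id,
            if (is.null(existing)) "registered" else "registration_updated",
            detail = info$name, time = time)
  invisible(rec)
}

registry_frame <- function(store) {
  res <- store$resources
  if (!length(res)) {
    return(data.frame(
      nif_id = character(), name = character(), services = character(),
      script_location = character(), active = logical(),
      stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, lapply(res, function(r) {
    data.frame(
      nif_id = r$nif_id, name = r$name,
      services = paste(r$services, collapse = ","),
      script_location = r$script_location, active = r$active,
      stringsAsFactors = FALSE
    )
  }))
}

#' List registered resources
#'
#' @param store a [disco_store()].
#' @param query optional case-insensitive substring matched against id and
#'   name.
#' @param sort_key resource field to order by (`nif_id`, `name`, `services`,
#'   `script_location`, `active`); ties always break by `nif_id` ascending.
#' @param offset,limit paging window (0-based offset).
#' @return list with `items` (data frame page), `total` (matches before
#'   paging), `offset`, `limit`.
#' @export
list_resources <- function(store, query = NULL, sort_key = "nif_id",
                           offset = 0, limit = Inf) {
  df <- registry_frame(store)
  if (!sort_key %in% names(df)) {
    disco_abort("usage", paste0(
      "unknown sort key '", sort_key, "'; expected one of ",
      paste(names(df), collapse = ", ")
    ))
  }
  if (!is.null(query) && nzchar(query)) {
    hit <- grepl(query, df$nif_id, ignore.case = TRUE, fixed = FALSE) |
      grepl(query, df$name, ignore.case = TRUE, fixed = FALSE)
    df <- df[hit, , drop = FALSE]
  }
  ord <- radix_order(df[[sort_key]], df$nif_id)
  df <- df[ord, , drop = FALSE]
  total <- nrow(df)
  if (is.finite(limit) || offset > 0) {
    idx <- seq_len(total)
    idx <- idx[idx > offset & idx <= offset + limit]
    df <- df[idx, , drop = FALSE]
  }
  rownames(df) <- NULL
  list(items = df, total = total, offset = offset, limit = limit)
}

get_resource <- function(store, nif_id) {
  r <- store$resources[[nif_id]]
  if (is.null(r)) disco_abort("not_found", paste0("unknown resource: ", nif_id))
  r
}

#' Detailed record for one resource
#'
#' Merges the registry entry with the parsed information file and per-service
#' script pointers.
#'
#' @param store a [disco_store()].
#' @param nif_id registered resource id.
#' @return a list with registry fields, `contacts`, `description`,
#'   `service_scripts`, and current production/staged version summaries.
#' @export
resource_detail <- function(store, nif_id) {
  r <- get_resource(store, nif_id)
  prod <- store$production[[nif_id]]
  hist <- store$history[[nif_id]]
  staged <- store$staged[[nif_id]]
  c(r, list(
    production_version = if (is.null(hist)) 0L else hist$version,
    production_records = if (is.null(prod)) 0L else nrow(prod$data),
    staged_status = if (is.null(staged)) NA_character_ else staged$status
  ))
}

#' Export / import the registry
#'
#' Round-trips the full registry (field by field) through a lossless JSON
#' serialization.
#'
#' @param store a [disco_store()].
#' @param path file path.
#' @return `registry_export()` returns `path` invisibly; `registry_import()`
#'   the store, with its registry replaced.
#' @export
registry_export <- function(store, path) {
  writeLines(jsonlite::serializeJSON(store$resources), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname registry_export
#' @export
registry_import <- function(store, path) {
  if (!file.exists(path)) disco_abort("not_found", paste0("no registry at ", path))
  store$resources <- jsonlite::unserializeJSON(
    paste(readLines(path, warn = FALSE), collapse = "\n")
  )
  invisible(store)
}
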