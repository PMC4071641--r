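# Materialized cross-resource views.  A view is a union-concatenation of
# per-member projections of production data onto a shared column list, with
# two provenance columns prepended (source resource id and source record
# key).  Each view has a beta channel (rebuilt on member promotions) and a
# production channel (only ever updated by approve_view).

#' Define a materialized view
#'
#' @param store a [disco_store()].
#' @param definition either a path to a JSON view-definition document
#'   (`name`, `columns[]`, `members[]` each with `resource` and `map{}`) or
#'   an equivalent list.  Map entries are either `list(field = "src_col")` or
#'   `list(const = "literal")`; every member must map every view column.
#' @return the stored view definition, invisibly.
#' @export
define_view <- function(store, definition) {
  def <- if (is.character(definition)) {
    if (!file.exists(definition)) {
      disco_abort("not_found", paste0("view definition not found: ", definition))
    }
    jsonlite::fromJSON(definition, simplifyVector = FALSE)
  } else {
    definition
  }
  if (is.null(def$name) || !nzchar(def$name)) {
    disco_abort("validation", "view definition needs a non-empty 'name'")
  }
  columns <- vapply(def$columns, function(cdef) {
    if (is.character(cdef)) cdef else cdef$name
  }, character(1))
  if (!length(columns) || anyDuplicated(columns)) {
    disco_abort("validation", paste0(
      "view '", def$name, "': columns must be non-empty and unique"
    ))
  }
  members <- lapply(def$members, function(m) {
    rid <- m$resource
    get_resource(store, rid)
    if (is.null(store$production[[rid]])) {
      disco_abort("validation", paste0(
        "view '", def$name, "': member ", rid, " has no production version"
      ))
    }
    prod_cols <- names(store$production[[rid]]$data)
    map <- lapply(m$map, function(entry) {
      if (is.character(entry)) entry <- list(field = entry)
      entry
    })
    for (col in columns) {
      entry <- map[[col]]
      if (is.null(entry) || (is.null(entry$field) && is.null(entry$const))) {
        disco_abort("validation", paste0(
          "view '", def$name, "': member ", rid,
          " has no mapping for column '", col, "'"
        ))
      }
      if (!is.null(entry$field) && !entry$field %in% prod_cols) {
        disco_abort("validation", paste0(
          "view '", def$name, "': member ", rid, " maps column '", col,
          "' to unknown source field '", entry$field, "'"
        ))
      }
    }
    list(resource = rid, map = map)
  })
  if (!length(members)) {
    disco_abort("validation", paste0("view '", def$name, "' has no members"))
  }
  view <- list(
    name = def$name, columns = columns, members = members,
    beta = NULL, production = NULL, status = "defined", last_error = NA_character_
  )
  store$views[[def$name]] <- view
  audit_log(store, NA_character_, "view_defined",
            sprintf("view '%s': %d column(s), %d member(s)",
                    def$name, length(columns), length(members)))
  invisible(view)
}

#' Materialize a view to a channel
#'
#' Concatenates member projections in member order; row count always equals
#' the sum of the members' production row counts.  Two provenance columns are
#' prepended: `.source` (member resource id) and `.key` (source record key).
#'
#' @param store a [disco_store()].
#' @param view_name a defined view.
#' @param channel `"beta"` (default) or `"production"`.
#' @param time timestamp.
#' @return the materialized data frame, invisibly.
#' @export
materialize_view <- function(store, view_name, channel = c("beta", "production"),
                             time = Sys.time()) {
  channel <- match.arg(channel)
  view <- store$views[[view_name]]
  if (is.null(view)) disco_abort("not_found", paste0("unknown view: ", view_name))
  parts <- lapply(view$members, function(m) {
    prod <- store$production[[m$resource]]
    if (is.null(prod)) {
      disco_abort("validation", paste0(
        "view '", view_name, "': member ", m$resource, " has no production version"
      ))
    }
    n <- nrow(prod$data)
    cols <- lapply(view$columns, function(col) {
      entry <- m$map[[col]]
      if (!is.null(entry$const)) {
        rep(as.character(entry$const), n)
      } else {
        if (!entry$field %in% names(prod$data)) {
          disco_abort("validation", paste0(
            "view '", view_name, "': member ", m$resource,
            " schema drifted; source field '", entry$field, "' is gone"
          ))
        }
        prod$data[[entry$field]]
      }
    })
    df <- as.data.frame(setNames(cols, view$columns), stringsAsFactors = FALSE,
                        check.names = FALSE, optional = TRUE)
    if (n == 0L) {
      df <- as.data.frame(
        setNames(rep(list(character()), length(view$columns)), view$columns),
        stringsAsFactors = FALSE, check.names = FALSE
      )
    }
    cbind(
      data.frame(.source = rep(m$resource, n), .key = prod$keys,
                 stringsAsFactors = FALSE),
      df
    )
  })
  mat <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  rownames(mat) <- NULL
  store$view_seq <- store$view_seq + 1L
  view <- store$views[[view_name]]
  view[[channel]] <- list(
    data = mat, seq = store$view_seq, time = fmt_time(time),
    member_versions = vapply(view$members, function(m) {
      store$history[[m$resource]]$version
    }, integer(1))
  )
  view$status <- "ok"
  store$views[[view_name]] <- view
  audit_log(store, NA_character_, "view_materialized",
            sprintf("view '%s' -> %s (%d row(s))", view_name, channel, nrow(mat)),
            time = time)
  invisible(mat)
}

#' Deploy the beta channel of a view to production
#'
#' Atomic copy of the beta relation; refused unless the beta channel is newer
#' than the production channel.
#'
#' @param store a [disco_store()].
#' @param view_name a materialized view.
#' @param time timestamp.
#' @export
approve_view <- function(store, view_name, time = Sys.time()) {
  view <- store$views[[view_name]]
  if (is.null(view)) disco_abort("not_found", paste0("unknown view: ", view_name))
  if (is.null(view$beta)) {
    disco_abort("usage", paste0("view '", view_name, "' has no beta materialization"))
  }
  if (!is.null(view$production) && view$production$seq >= view$beta$seq) {
    disco_abort("usage", paste0(
      "view '", view_name, "': beta channel is not newer than production"
    ))
  }
  view$production <- view$beta
  view$production$time <- fmt_time(time)
  store$views[[view_name]] <- view
  audit_log(store, NA_character_, "view_deployed",
            sprintf("view '%s' beta -> production", view_name), time = time)
  invisible(view)
}
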