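# The warehouse store.
#
# The reference back-end is an environment holding named relations plus the
# EAV bookkeeping tables (deltas, schema deltas, snapshots), the registry, the
# run/audit logs, schedules, views and term mappings.  The engine is pluggable
# in principle: everything round-trips losslessly through store_save() /
# store_load(), and all state mutations funnel through the functions in this
# package, never through direct field access in user code.

#' Create an empty warehouse store
#'
#' @param timezone IANA zone used for all timestamps (default `"UTC"`).
#' @return an object of class `disco_store` (an environment).
#' @examples
#' s <- disco_store()
#' @export
disco_store <- function(timezone = "UTC") {
  s <- new.env(parent = emptyenv())
  s$timezone <- timezone
  s$resources <- list()     # nif_id -> resource record
  s$production <- list()    # nif_id -> disco_relation (current version)
  s$history <- list()       # nif_id -> versions, deltas, snapshots, schema
  s$staged <- list()        # nif_id -> in-flight staged version (or NULL)
  s$views <- list()         # view_name -> view definition + channels
  s$schedules <- list()     # nif_id -> schedule
  s$runs <- list()          # append-only list of run records
  s$audit <- list()         # append-only list of audit entries
  s$notifications <- list() # append-only curator/contact notices
  s$mappings <- list()      # nif_id -> term mappings per version
  s$fetch_meta <- list()    # locator -> last fetch metadata (for probing)
  s$manual_queue <- character() # ad-hoc triggered resources
  s$in_progress <- character()  # resources currently being updated
  s$view_seq <- 0L          # monotone counter stamping view materializations
  class(s) <- "disco_store"
  s
}

#' @export
print.disco_store <- function(x, ...) {
  cat(sprintf(
    "<disco_store> %d resource(s), %d view(s), %d run(s) logged\n",
    length(x$resources), length(x$views), length(x$runs)
  ))
  invisible(x)
}

audit_log <- function(store, resource_id, event, detail = "",
                      time = Sys.time()) {
  store$audit[[length(store$audit) + 1L]] <- list(
    time = fmt_time(time), resource_id = resource_id,
    event = event, detail = detail
  )
  invisible(store)
}

notify <- function(store, audience, resource_id, message,
                   time = Sys.time()) {
  store$notifications[[length(store$notifications) + 1L]] <- list(
    time = fmt_time(time), audience = audience,
    resource_id = resource_id, message = message
  )
  invisible(store)
}

#' Audit trail as a data frame
#'
#' Every state transition in the store (registrations, runs, approvals,
#' promotions, view deployments) is appended here; the log is never rewritten.
#'
#' @param store a [disco_store()].
#' @return data frame with columns `time`, `resource_id`, `event`, `detail`.
#' @export
audit_trail <- function(store) {
  if (!length(store$audit)) {
    return(data.frame(
      time = character(), resource_id = character(),
      event = character(), detail = character(), stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, lapply(store$audit, function(e) {
    data.frame(
      time = e$time, resource_id = e$resource_id, event = e$event,
      detail = e$detail, stringsAsFactors = FALSE
    )
  }))
}

#' Notifications as a data frame
#' @param store a [disco_store()].
#' @return data frame with columns `time`, `audience`, `resource_id`, `message`.
#' @export
notifications <- function(store) {
  if (!length(store$notifications)) {
    return(data.frame(
      time = character(), audience = character(), resource_id = character(),
      message = character(), stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, lapply(store$notifications, function(e) {
    data.frame(
      time = e$time, audience = e$audience, resource_id = e$resource_id,
      message = e$message, stringsAsFactors = FALSE
    )
  }))
}

#' Persist a store to disk / restore it
#'
#' Serialization is lossless (type- and `NA`-preserving JSON); `store_load()`
#' reproduces the store field by field, which is what the CLI uses to carry
#' state across invocations.
#'
#' @param store a [disco_store()].
#' @param path file path for the serialized store.
#' @return `store_save()` returns `path` invisibly; `store_load()` a
#'   `disco_store`.
#' @export
store_save <- function(store, path) {
  fields <- mget(ls(store, all.names = TRUE), envir = store)
  json <- jsonlite::serializeJSON(fields)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname store_save
#' @export
store_load <- function(path) {
  if (!file.exists(path)) disco_abort("not_found", paste0("no store at ", path))
  fields <- jsonlite::unserializeJSON(paste(readLines(path, warn = FALSE), collapse = "\n"))
  s <- disco_store()
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = s)
  s
}

# A store checksum used by purity tests: digest of the serialized state.
store_checksum <- function(store) {
  fields <- mget(ls(store, all.names = TRUE), envir = store)
  sha256_hex(jsonlite::serializeJSON(fields))
}
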