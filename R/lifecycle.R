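# The data-source lifecycle: the formal state machine behind curation.
#
#   run_update: fetch -> extract -> coerce -> stage -> diff
#     unchanged  -> staged relation discarded, fact recorded
#     new data   -> held pending until a curator reviews it
#     any error  -> run recorded as failed, nothing promoted
#   pending -> approved (immediate promote, or scheduled for batch flush)
#   pending -> problem (note recorded, staged relation retained)
#
# At most one version per resource is ever in {pending, approved, scheduled};
# all four import-issue kinds block approval unless explicitly overridden.

BLOCKING_KINDS <- c("data_type_error", "duplicate_key", "field_overflow",
                    "incomplete_import")

append_run <- function(store, resource_id, started, finished, outcome,
                       version = NA_integer_, issues = empty_issues(),
                       error = NA_character_) {
  counts <- table(factor(issues$kind, levels = BLOCKING_KINDS))
  store$runs[[length(store$runs) + 1L]] <- list(
    resource_id = resource_id,
    started_at = fmt_time(started), finished_at = fmt_time(finished),
    outcome = outcome, version = version,
    issue_counts = as.list(counts), error = error
  )
  invisible(store)
}

#' Run history as a data frame
#'
#' @param store a [disco_store()].
#' @param resource_id optional filter.
#' @param n optional: only the `n` most recent runs (the per-resource
#'   dashboard shows six).
#' @return data frame, oldest first.
#' @export
run_history <- function(store, resource_id = NULL, n = NULL) {
  runs <- store$runs
  if (!is.null(resource_id)) {
    runs <- Filter(function(r) r$resource_id == resource_id, runs)
  }
  if (!length(runs)) {
    return(data.frame(
      resource_id = character(), started_at = character(),
      finished_at = character(), outcome = character(), version = integer(),
      n_issues = integer(), error = character(), stringsAsFactors = FALSE
    ))
  }
  df <- do.call(rbind, lapply(runs, function(r) {
    data.frame(
      resource_id = r$resource_id, started_at = r$started_at,
      finished_at = r$finished_at, outcome = r$outcome,
      version = r$version,
      n_issues = sum(unlist(r$issue_counts)),
      error = r$error, stringsAsFactors = FALSE
    )
  }))
  if (!is.null(n)) df <- utils::tail(df, n)
  rownames(df) <- NULL
  df
}

#' Execute one update run for a resource
#'
#' Runs the full ingestion pipeline.  An empty changeset is recorded as an
#' `unchanged` run and the staged relation is discarded; otherwise the staged
#' version is held pending with its change summary attached.  Fetch or
#' extraction failures produce a `failed` run record; nothing is ever
#' partially promoted.
#'
#' @param store a [disco_store()].
#' @param resource_id registered resource with the interop service.
#' @param time run timestamp.
#' @return the run record (list with `outcome` among `unchanged`,
#'   `new_pending`, `failed`), invisibly.
#' @export
run_update <- function(store, resource_id, time = Sys.time()) {
  res <- get_resource(store, resource_id)
  if (!"interop" %in% res$services) {
    disco_abort("usage", paste0(resource_id, " does not use the interop service"))
  }
  inflight <- store$staged[[resource_id]]
  if (!is.null(inflight) && inflight$status %in% c("pending", "approved", "scheduled")) {
    disco_abort("conflict", paste0(
      "resource ", resource_id, " has a version awaiting curation (",
      inflight$status, "); refusing a new run"
    ))
  }
  started <- time
  store$in_progress <- union(store$in_progress, resource_id)
  on.exit(store$in_progress <- setdiff(store$in_progress, resource_id))

  result <- tryCatch({
    script <- parse_script(res$service_scripts[["interop"]])
    docs <- lapply(script$sources, function(src) {
      f <- fetch_source(src, script$dir)
      store$fetch_meta[[paste0(resource_id, "::", src$locator)]] <- list(
        size = f$size, mtime = as.numeric(f$mtime), fetched_at = fmt_time(time)
      )
      f$content
    })
    records <- extract_records(script, documents = docs)
    coerced <- coerce_records(script, records)
    # A superseded problem version is replaced by the new run.
    if (!is.null(inflight)) {
      audit_log(store, resource_id, "superseded",
                sprintf("version %d (%s) superseded by a new run",
                        inflight$version_number, inflight$status), time = time)
      store$staged[[resource_id]] <- NULL
    }
    staged <- stage_ingest(store, resource_id, script, coerced$records,
                           coerced$issues, time = time)
    cs <- compute_changes(store, resource_id)
    if (changeset_empty(cs)) {
      store$staged[[resource_id]] <- NULL # discard the temporary relation
      if (!is.null(store$history[[resource_id]])) {
        h <- store$history[[resource_id]]
        h$last_unchanged_at <- fmt_time(time)
        store$history[[resource_id]] <- h
      }
      audit_log(store, resource_id, "run_unchanged",
                sprintf("data unchanged from production (%d record(s))",
                        cs$unchanged_count), time = time)
      list(outcome = "unchanged", version = NA_integer_, issues = staged$issues)
    } else {
      staged <- store$staged[[resource_id]]
      staged$summary <- summarize_changes(cs)
      store$staged[[resource_id]] <- staged
      audit_log(store, resource_id, "run_new_pending",
                staged$summary$text, time = time)
      list(outcome = "new_pending", version = staged$version_number,
           issues = staged$issues)
    }
  }, disco_error = function(e) {
    audit_log(store, resource_id, "run_failed", conditionMessage(e), time = time)
    list(outcome = "failed", version = NA_integer_, issues = empty_issues(),
         error = conditionMessage(e))
  })

  append_run(store, resource_id, started, time, result$outcome,
             result$version, result$issues, result$error %||% NA_character_)
  invisible(store$runs[[length(store$runs)]])
}

#' Review the pending version of a resource
#'
#' Read-only: returns the change summary, issue counts by kind, sample diffs
#' and any problem note.
#'
#' @param store a [disco_store()].
#' @param resource_id resource with a pending (or problem) version.
#' @return list with `version`, `status`, `summary`, `issue_counts`,
#'   `issues`, `note`.
#' @export
review <- function(store, resource_id) {
  staged <- store$staged[[resource_id]]
  if (is.null(staged)) {
    disco_abort("not_found", paste0("nothing pending for ", resource_id))
  }
  counts <- table(factor(staged$issues$kind, levels = BLOCKING_KINDS))
  list(
    resource_id = resource_id,
    version = staged$version_number,
    status = staged$status,
    record_count = staged$record_count,
    summary = staged$summary %||% summarize_changes(staged$changeset),
    issue_counts = as.list(counts),
    issues = staged$issues,
    note = staged$note %||% NA_character_
  )
}

#' Approve a pending version
#'
#' Immediate mode promotes right away and cascades dependent views; batch
#' mode marks the version `scheduled` for the next [flush_batch()].  Any
#' import issue (data type error, duplicate key, field overflow, incomplete
#' import) blocks approval unless `override = TRUE`, in which case the
#' override is logged.
#'
#' @param store a [disco_store()].
#' @param resource_id resource with a pending version.
#' @param mode `"immediate"` or `"batch"`.
#' @param override force approval past blocking issues (logged).
#' @param time timestamp.
#' @return for immediate mode the promotion result; for batch mode the staged
#'   version; invisibly.
#' @export
approve <- function(store, resource_id, mode = c("immediate", "batch"),
                    override = FALSE, time = Sys.time()) {
  mode <- match.arg(mode)
  staged <- store$staged[[resource_id]]
  if (is.null(staged) || staged$status != "pending") {
    disco_abort("not_found", paste0("no pending version for ", resource_id))
  }
  blocking <- staged$issues[staged$issues$kind %in% BLOCKING_KINDS, , drop = FALSE]
  if (nrow(blocking) && !override) {
    counts <- table(blocking$kind)
    disco_abort("validation", paste0(
      "approval refused for ", resource_id, ": unresolved import issue(s): ",
      paste(sprintf("%s x%d", names(counts), as.integer(counts)), collapse = ", "),
      " (use override to force)"
    ))
  }
  if (nrow(blocking) && override) {
    audit_log(store, resource_id, "override",
              sprintf("approval overrides %d issue(s)", nrow(blocking)),
              time = time)
  }
  if (mode == "batch") {
    staged$status <- "scheduled"
    store$staged[[resource_id]] <- staged
    audit_log(store, resource_id, "approved_batch",
              sprintf("version %d scheduled for batch promotion",
                      staged$version_number), time = time)
    return(invisible(staged))
  }
  staged$status <- "approved"
  store$staged[[resource_id]] <- staged
  audit_log(store, resource_id, "approved",
            sprintf("version %d approved", staged$version_number), time = time)
  out <- promote(store, resource_id, time = time)
  cascade_views(store, resource_id, time = time)
  invisible(out)
}

#' Promote all batch-scheduled versions
#'
#' Idempotent: versions are promoted exactly once; a second flush with
#' nothing scheduled is a no-op.
#'
#' @param store a [disco_store()].
#' @param time timestamp.
#' @return character vector of promoted resource ids, invisibly.
#' @export
flush_batch <- function(store, time = Sys.time()) {
  scheduled <- names(Filter(
    function(s) !is.null(s) && identical(s$status, "scheduled"),
    store$staged
  ))
  for (rid in radix_sort(scheduled)) {
    promote(store, rid, time = time)
    cascade_views(store, rid, time = time)
  }
  invisible(radix_sort(scheduled))
}

#' Flag the pending version as a problem
#'
#' The version stops being eligible for approval but its staged relation is
#' retained for debugging; a later [run_update()] supersedes it.
#'
#' @param store a [disco_store()].
#' @param resource_id resource with a pending version.
#' @param note curator note, persisted with the version.
#' @param time timestamp.
#' @export
mark_problem <- function(store, resource_id, note, time = Sys.time()) {
  staged <- store$staged[[resource_id]]
  if (is.null(staged) || staged$status != "pending") {
    disco_abort("not_found", paste0("no pending version for ", resource_id))
  }
  staged$status <- "problem"
  staged$note <- note
  store$staged[[resource_id]] <- staged
  audit_log(store, resource_id, "problem",
            sprintf("version %d flagged: %s", staged$version_number, note),
            time = time)
  invisible(staged)
}

#' Rebuild views depending on a freshly promoted resource
#'
#' Every view with the resource among its members is re-materialized to its
#' beta channel; curators and resource contacts are notified.  A failure in
#' one view does not affect the others.
#'
#' @param store a [disco_store()].
#' @param resource_id the promoted resource.
#' @param time timestamp.
#' @return character vector of regenerated view names, invisibly.
#' @export
cascade_views <- function(store, resource_id, time = Sys.time()) {
  touched <- character()
  for (vname in radix_sort(names(store$views))) {
    members <- vapply(store$views[[vname]]$members, `[[`, character(1), "resource")
    if (!resource_id %in% members) next
    ok <- tryCatch({
      materialize_view(store, vname, channel = "beta", time = time)
      TRUE
    }, disco_error = function(e) {
      v <- store$views[[vname]]
      v$status <- "failed"
      v$last_error <- conditionMessage(e)
      store$views[[vname]] <- v
      audit_log(store, resource_id, "view_failed",
                paste0(vname, ": ", conditionMessage(e)), time = time)
      FALSE
    })
    if (ok) {
      touched <- c(touched, vname)
      notify(store, "curators", resource_id,
             sprintf("view '%s' rebuilt on beta after %s promotion",
                     vname, resource_id), time = time)
      notify(store, "resource_contacts", resource_id,
             sprintf("your data now feeds a new beta version of view '%s'", vname),
             time = time)
    }
  }
  invisible(touched)
}
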