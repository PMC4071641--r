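# Dashboard reports.  All reports are pure reads over the store; rendering
# never mutates state.  Status icons become ASCII markers: [P] pending,
# [=] unchanged, [ok] production current, [!] problem.

status_marker <- function(status) {
  switch(status,
    pending = "[P]", unchanged = "[=]", problem = "[!]",
    failed = "[!]", "[ok]"
  )
}

#' Workflow-status dashboard (one row per resource and service)
#'
#' Shows, per resource and service, the production version number, date and
#' record count, plus the date and status marker of the most recent
#' ("current") version: `[P]` for a pending upload, `[=]` when the last run
#' found the data unchanged, `[!]` for problem/failed, `[ok]` otherwise.
#'
#' @param store a [disco_store()].
#' @return data frame ordered by `nif_id` then `service`.
#' @export
data_source_dashboard <- function(store) {
  rows <- list()
  for (rid in radix_sort(names(store$resources))) {
    res <- store$resources[[rid]]
    for (svc in res$services) {
      hist <- if (svc == "interop") store$history[[rid]] else NULL
      staged <- if (svc == "interop") store$staged[[rid]] else NULL
      prod_version <- if (is.null(hist)) 0L else hist$version
      last_promo <- if (!is.null(hist) && length(hist$promotions)) {
        hist$promotions[[length(hist$promotions)]]
      }
      runs <- if (svc == "interop") run_history(store, rid) else NULL
      last_run <- if (!is.null(runs) && nrow(runs)) runs[nrow(runs), ] else NULL
      status <- if (!is.null(staged)) {
        staged$status
      } else if (!is.null(last_run) && last_run$outcome == "unchanged") {
        "unchanged"
      } else if (!is.null(last_run) && last_run$outcome == "failed") {
        "failed"
      } else {
        "production"
      }
      current_date <- if (!is.null(staged)) {
        staged$created_at
      } else if (!is.null(last_run)) {
        last_run$finished_at
      } else if (!is.null(last_promo)) {
        last_promo$date
      } else {
        NA_character_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        nif_id = rid, name = res$name, service = svc,
        production_version = prod_version,
        production_date = if (is.null(last_promo)) NA_character_ else last_promo$date,
        production_records = if (is.null(last_promo)) NA_integer_ else
          as.integer(last_promo$record_count),
        current_date = current_date,
        status = status,
        marker = status_marker(status),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(
      nif_id = character(), name = character(), service = character(),
      production_version = integer(), production_date = character(),
      production_records = integer(), current_date = character(),
      status = character(), marker = character(), stringsAsFactors = FALSE
    ))
  }
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  df[radix_order(df$nif_id, df$service), , drop = FALSE]
}

#' Update-frequency report over interop resources
#'
#' Partitions interop resources by schedule frequency; resources without a
#' stored schedule count as ad hoc.  The total always equals the sum of the
#' four classes.
#'
#' @param store a [disco_store()].
#' @return list with `counts` (named: weekly, biweekly, monthly, adhoc) and
#'   `total`.
#' @export
update_frequency_report <- function(store) {
  counts <- c(weekly = 0L, biweekly = 0L, monthly = 0L, adhoc = 0L)
  for (rid in names(store$resources)) {
    if (!"interop" %in% store$resources[[rid]]$services) next
    sched <- store$schedules[[rid]]
    freq <- if (is.null(sched)) "adhoc" else sched$frequency
    counts[[freq]] <- counts[[freq]] + 1L
  }
  list(counts = as.list(counts), total = sum(counts))
}

#' Production growth series
#'
#' One point per promotion (unchanged runs contribute nothing): the
#' promotion date and the production record count at that point.
#'
#' @param store a [disco_store()].
#' @param resource_id a resource id, or `NULL` for all resources.
#' @return data frame `resource_id`, `date`, `version`, `record_count`,
#'   ordered by date.
#' @export
growth_report <- function(store, resource_id = NULL) {
  ids <- if (is.null(resource_id)) radix_sort(names(store$history)) else {
    if (is.null(store$history[[resource_id]])) {
      disco_abort("not_found", paste0("no promotions recorded for ", resource_id))
    }
    resource_id
  }
  rows <- list()
  for (rid in ids) {
    for (p in store$history[[rid]]$promotions) {
      rows[[length(rows) + 1L]] <- data.frame(
        resource_id = rid, date = p$date, version = p$version,
        record_count = as.integer(p$record_count), stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(resource_id = character(), date = character(),
                      version = integer(), record_count = integer(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  df[radix_order(df$date, df$resource_id), , drop = FALSE]
}

#' Views dashboard
#'
#' One row per defined view with member resources, channel stamps, and a flag
#' marking views whose beta channel is newer than production.
#'
#' @param store a [disco_store()].
#' @return data frame ordered by view name.
#' @export
views_dashboard <- function(store) {
  rows <- lapply(radix_sort(names(store$views)), function(vn) {
    v <- store$views[[vn]]
    data.frame(
      view = vn,
      members = paste(vapply(v$members, `[[`, character(1), "resource"),
                      collapse = ","),
      beta_seq = if (is.null(v$beta)) NA_integer_ else v$beta$seq,
      beta_time = if (is.null(v$beta)) NA_character_ else v$beta$time,
      production_seq = if (is.null(v$production)) NA_integer_ else v$production$seq,
      production_time = if (is.null(v$production)) NA_character_ else v$production$time,
      beta_newer = !is.null(v$beta) &&
        (is.null(v$production) || v$beta$seq > v$production$seq),
      status = v$status,
      stringsAsFactors = FALSE
    )
  })
  if (!length(rows)) {
    return(data.frame(
      view = character(), members = character(), beta_seq = integer(),
      beta_time = character(), production_seq = integer(),
      production_time = character(), beta_newer = logical(),
      status = character(), stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Render a report for the terminal
#'
#' Human table mode and machine (`json = TRUE`) mode carry identical data;
#' numbers in the human rendering use thousands separators (a production
#' count renders as e.g. `55,925`).
#'
#' @param report a data frame (or list) from one of the dashboard functions.
#' @param json emit JSON instead of an aligned table.
#' @return the rendered lines, invisibly (they are also `cat()`ed).
#' @export
render_report <- function(report, json = FALSE) {
  if (json) {
    out <- as.character(jsonlite::toJSON(report, dataframe = "rows",
                                         auto_unbox = TRUE, na = "null",
                                         pretty = TRUE))
    cat(out, "\n", sep = "")
    return(invisible(out))
  }
  if (is.data.frame(report)) {
    df <- report
    for (cn in names(df)) {
      if (is.numeric(df[[cn]])) {
        df[[cn]] <- ifelse(is.na(df[[cn]]), "",
                           format(df[[cn]], big.mark = ",", trim = TRUE,
                                  scientific = FALSE))
      }
      df[[cn]][is.na(df[[cn]])] <- ""
    }
    widths <- vapply(names(df), function(cn) {
      max(nchar(c(cn, df[[cn]]), type = "width"))
    }, numeric(1))
    pad <- function(x, w) formatC(x, width = w, flag = "-")
    lines <- c(
      paste(mapply(pad, names(df), widths), collapse = "  "),
      paste(mapply(pad, rep("-", length(widths)), widths), collapse = "  "),
      if (nrow(df)) {
        vapply(seq_len(nrow(df)), function(i) {
          paste(mapply(function(cn, w) pad(df[[cn]][i], w), names(df), widths),
                collapse = "  ")
        }, character(1))
      }
    )
  } else {
    lines <- utils::capture.output(utils::str(report, give.attr = FALSE))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
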