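# Calendar scheduling.  Frequencies follow the update-frequency classes used
# for participating resources: weekly (day-of-week anchor), bi-weekly (every
# 14 days from an anchor date), monthly (day-of-month anchor, days 29-31
# clamped to the month's last day) and ad hoc (not scheduled).  All
# timestamps are minute-resolution in one configured zone (UTC by default);
# the engine ticks on demand rather than as a daemon.

FREQUENCIES <- c("weekly", "biweekly", "monthly", "adhoc")

parse_hhmm <- function(at) {
  m <- regmatches(at, regexec("^([0-9]{1,2}):([0-9]{2})$", at))[[1]]
  if (!length(m)) disco_abort("usage", paste0("time_of_day '", at, "' is not HH:MM"))
  hh <- as.integer(m[2]); mm <- as.integer(m[3])
  if (hh > 23 || mm > 59) disco_abort("usage", paste0("time_of_day '", at, "' out of range"))
  c(hh, mm)
}

#' Create / store a harvest schedule
#'
#' @param store a [disco_store()] (optional for `new_schedule()`).
#' @param resource_id registered resource.
#' @param frequency one of `weekly`, `biweekly`, `monthly`, `adhoc`.
#' @param anchor day-of-week 1-7 (Monday = 1) for weekly, an anchor `Date`
#'   (or "YYYY-MM-DD") for biweekly, day-of-month 1-31 for monthly; must be
#'   absent for adhoc.
#' @param at time of day, `"HH:MM"`.
#' @return the schedule object (class `disco_schedule`).
#' @export
new_schedule <- function(resource_id, frequency, anchor = NULL, at = "00:00") {
  if (!frequency %in% FREQUENCIES) {
    disco_abort("usage", paste0("unknown frequency '", frequency, "'"))
  }
  hm <- parse_hhmm(at)
  if (frequency == "adhoc") {
    if (!is.null(anchor)) disco_abort("usage", "adhoc schedules take no anchor")
  } else if (frequency == "weekly") {
    anchor <- as.integer(anchor)
    if (is.na(anchor) || anchor < 1L || anchor > 7L) {
      disco_abort("usage", "weekly anchor must be a day-of-week 1 (Mon) .. 7 (Sun)")
    }
  } else if (frequency == "biweekly") {
    anchor <- as.Date(anchor)
    if (is.na(anchor)) disco_abort("usage", "biweekly anchor must be a date")
  } else if (frequency == "monthly") {
    anchor <- as.integer(anchor)
    if (is.na(anchor) || anchor < 1L || anchor > 31L) {
      disco_abort("usage", "monthly anchor must be a day-of-month 1 .. 31")
    }
  }
  structure(
    list(resource_id = resource_id, frequency = frequency, anchor = anchor,
         hour = hm[1], minute = hm[2]),
    class = "disco_schedule"
  )
}

#' @rdname new_schedule
#' @export
set_schedule <- function(store, resource_id, frequency, anchor = NULL,
                         at = "00:00") {
  get_resource(store, resource_id)
  sched <- new_schedule(resource_id, frequency, anchor, at)
  store$schedules[[resource_id]] <- sched
  audit_log(store, resource_id, "schedule_set",
            sprintf("%s anchor=%s at %02d:%02d", frequency,
                    paste(format(anchor), collapse = ""), sched$hour, sched$minute))
  invisible(sched)
}

#' @export
print.disco_schedule <- function(x, ...) {
  cat(sprintf("<disco_schedule> %s: %s anchor=%s at %02d:%02d\n",
              x$resource_id, x$frequency,
              paste(format(x$anchor), collapse = ""), x$hour, x$minute))
  invisible(x)
}

day_time <- function(date, hour, minute) {
  as.POSIXct(sprintf("%s %02d:%02d:00", format(date, "%Y-%m-%d"), hour, minute),
             tz = "UTC")
}

last_dom <- function(year, month) {
  first_next <- if (month == 12L) as.Date(sprintf("%d-01-01", year + 1L)) else
    as.Date(sprintf("%d-%02d-01", year, month + 1L))
  as.integer(format(first_next - 1L, "%d"))
}

#' Next scheduled run strictly after a timestamp
#'
#' Monthly anchors 29-31 clamp to the month's last day; biweekly fires every
#' 14 days from the anchor date (never before it); adhoc returns `NULL`.
#'
#' @param schedule a `disco_schedule`.
#' @param after a POSIXct (interpreted in UTC).
#' @return POSIXct of the next run, or `NULL` for adhoc.
#' @export
next_run <- function(schedule, after) {
  after <- disco_time(after)
  hh <- schedule$hour; mm <- schedule$minute
  switch(schedule$frequency,
    adhoc = NULL,
    weekly = {
      d0 <- as.Date(after, tz = "UTC")
      for (off in 0:7) {
        d <- d0 + off
        iso_dow <- as.integer(format(d, "%u"))
        if (iso_dow == schedule$anchor) {
          t <- day_time(d, hh, mm)
          if (t > after) return(t)
        }
      }
      stop("unreachable") # nocov
    },
    biweekly = {
      a <- schedule$anchor
      t0 <- day_time(a, hh, mm)
      if (t0 > after) return(t0)
      days <- as.integer(as.Date(after, tz = "UTC") - a)
      k <- days %/% 14L
      for (kk in c(k, k + 1L, k + 2L)) {
        t <- day_time(a + 14L * kk, hh, mm)
        if (t > after) return(t)
      }
      stop("unreachable") # nocov
    },
    monthly = {
      d0 <- as.Date(after, tz = "UTC")
      year <- as.integer(format(d0, "%Y"))
      month <- as.integer(format(d0, "%m"))
      for (i in 0:2) {
        m <- month + i
        y <- year + (m - 1L) %/% 12L
        m <- ((m - 1L) %% 12L) + 1L
        day <- min(schedule$anchor, last_dom(y, m))
        t <- day_time(as.Date(sprintf("%d-%02d-%02d", y, m, day)), hh, mm)
        if (t > after) return(t)
      }
      stop("unreachable") # nocov
    }
  )
}

#' Snapshot of the task queue
#'
#' All resources whose next scheduled run (relative to their last completed
#' run, or their registration when never run) is due at or before `now`, plus
#' manually triggered resources, ordered by due time then resource id.
#' Resources currently being updated are listed as in-progress, not
#' re-queued.
#'
#' @param store a [disco_store()].
#' @param now POSIXct.
#' @return data frame with `resource_id`, `due_at`, `state` (`due`,
#'   `manual`, `in_progress`).
#' @export
due_tasks <- function(store, now = Sys.time()) {
  now <- disco_time(now)
  rows <- list()
  for (rid in names(store$schedules)) {
    if (rid %in% store$in_progress) next
    sched <- store$schedules[[rid]]
    if (sched$frequency == "adhoc") next
    runs <- run_history(store, rid)
    baseline <- if (nrow(runs)) {
      disco_time(as.POSIXct(max(runs$finished_at), tz = "UTC"))
    } else {
      disco_time(as.POSIXct(get_resource(store, rid)$registered_at, tz = "UTC"))
    }
    due <- next_run(sched, baseline)
    if (!is.null(due) && due <= now) {
      rows[[length(rows) + 1L]] <- data.frame(
        resource_id = rid, due_at = fmt_time(due), state = "due",
        stringsAsFactors = FALSE
      )
    }
  }
  for (rid in setdiff(store$manual_queue, store$in_progress)) {
    rows[[length(rows) + 1L]] <- data.frame(
      resource_id = rid, due_at = fmt_time(now), state = "manual",
      stringsAsFactors = FALSE
    )
  }
  for (rid in store$in_progress) {
    rows[[length(rows) + 1L]] <- data.frame(
      resource_id = rid, due_at = NA_character_, state = "in_progress",
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(data.frame(resource_id = character(), due_at = character(),
                      state = character(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  df <- df[radix_order(df$state == "in_progress", df$due_at, df$resource_id), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Queue a manual (ad hoc) run
#'
#' @param store a [disco_store()].
#' @param resource_id registered resource.
#' @export
trigger_update <- function(store, resource_id) {
  get_resource(store, resource_id)
  store$manual_queue <- union(store$manual_queue, resource_id)
  invisible(store)
}

#' Probe a source for likely change
#'
#' Compares the source file's current size and timestamp against the metadata
#' of the last fetch.  Advisory only: a scheduled run is never suppressed by
#' the hint, but `trigger = TRUE` queues an early ad-hoc run when the source
#' looks changed.
#'
#' @param store a [disco_store()].
#' @param resource_id registered resource with a previous fetch.
#' @param trigger queue a manual run on `likely_changed`.
#' @return `"likely_changed"`, `"likely_unchanged"` or `"unknown"`.
#' @export
probe_source <- function(store, resource_id, trigger = FALSE) {
  res <- get_resource(store, resource_id)
  hint <- tryCatch({
    script <- parse_script(res$service_scripts[["interop"]])
    src <- script$sources[[1]]
    meta <- store$fetch_meta[[paste0(resource_id, "::", src$locator)]]
    if (is.null(meta)) {
      "unknown"
    } else {
      path <- if (file.exists(src$locator)) src$locator else
        file.path(script$dir, src$locator)
      if (!file.exists(path)) {
        "unknown"
      } else {
        info <- file.info(path)
        if (info$size == meta$size && as.numeric(info$mtime) == meta$mtime) {
          "likely_unchanged"
        } else {
          "likely_changed"
        }
      }
    }
  }, disco_error = function(e) "unknown")
  if (identical(hint, "likely_changed") && trigger) {
    trigger_update(store, resource_id)
  }
  hint
}

#' Execute all due tasks synchronously
#'
#' @param store a [disco_store()].
#' @param now POSIXct used both for due-ness and as the run timestamp.
#' @return list of run records, invisibly.
#' @export
scheduler_tick <- function(store, now = Sys.time()) {
  tasks <- due_tasks(store, now)
  tasks <- tasks[tasks$state != "in_progress", , drop = FALSE]
  out <- list()
  for (rid in tasks$resource_id) {
    store$manual_queue <- setdiff(store$manual_queue, rid)
    out[[rid]] <- tryCatch(
      run_update(store, rid, time = now),
      disco_error = function(e) list(outcome = "refused", error = conditionMessage(e))
    )
  }
  invisible(out)
}
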