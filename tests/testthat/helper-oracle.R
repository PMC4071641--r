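# Brute-force scheduling oracle: enumerate every minute of a window and keep
# those matching the schedule, entirely independently of next_run().

build_minute_grid <- function(start, end) {
  grid <- seq(start, end, by = "min")
  lt <- as.POSIXlt(grid, tz = "UTC")
  year <- lt$year + 1900L
  mon <- lt$mon + 1L
  ld <- vapply(seq_along(grid), function(i) {
    y <- year[i]; m <- mon[i]
    nxt <- if (m == 12L) as.Date(sprintf("%d-01-01", y + 1L)) else
      as.Date(sprintf("%d-%02d-01", y, m + 1L))
    as.integer(format(nxt - 1L, "%d"))
  }, integer(1))
  list(grid = grid, min = lt$min, hour = lt$hour, mday = lt$mday,
       mon = mon, year = year,
       wday = ifelse(lt$wday == 0L, 7L, lt$wday),
       date = as.Date(grid, tz = "UTC"), last_dom = ld)
}

# Cache: the 3-year acceptance grid is expensive; build at most once per run.
minute_grid_cache <- new.env(parent = emptyenv())
get_minute_grid <- function(start, end) {
  key <- paste(format(start), format(end))
  if (is.null(minute_grid_cache[[key]])) {
    minute_grid_cache[[key]] <- build_minute_grid(start, end)
  }
  minute_grid_cache[[key]]
}

oracle_next_run <- function(g, sched, after) {
  mask <- g$hour == sched$hour & g$min == sched$minute
  mask <- mask & switch(sched$frequency,
    weekly = g$wday == sched$anchor,
    biweekly = (as.integer(g$date - sched$anchor) %% 14L == 0L) &
      g$date >= sched$anchor,
    monthly = g$mday == pmin(sched$anchor, g$last_dom),
    adhoc = rep(FALSE, length(g$grid))
  )
  hits <- g$grid[mask & g$grid > after]
  if (!length(hits)) NULL else hits[1]
}

random_schedule <- function() {
  freq <- sample(c("weekly", "biweekly", "monthly", "adhoc"), 1)
  anchor <- switch(freq,
    weekly = sample(1:7, 1),
    biweekly = as.Date("2013-01-01") + sample(0:365, 1),
    monthly = sample(1:31, 1),
    adhoc = NULL
  )
  new_schedule("nif-0000-0001", freq, anchor,
               sprintf("%02d:%02d", sample(0:23, 1), sample(0:59, 1)))
}
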