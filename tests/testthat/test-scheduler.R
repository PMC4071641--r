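test_that("next_run handles the documented calendar cases", {
  # the 19th of each month at 14:00
  m19 <- new_schedule("r", "monthly", 19, "14:00")
  expect_equal(next_run(m19, fixed_time("2013-12-01", "00:00")),
               fixed_time("2013-12-19", "14:00"))
  # strictly after: at the exact firing minute the next month wins
  expect_equal(next_run(m19, fixed_time("2013-12-19", "14:00")),
               fixed_time("2014-01-19", "14:00"))
  # day-31 clamps to the month's last day
  m31 <- new_schedule("r", "monthly", 31, "09:30")
  expect_equal(next_run(m31, fixed_time("2014-02-01", "00:00")),
               fixed_time("2014-02-28", "09:30"))
  expect_equal(next_run(m31, fixed_time("2016-02-01", "00:00")),
               fixed_time("2016-02-29", "09:30")) # leap year
  # weekly: ISO day-of-week anchor
  w2 <- new_schedule("r", "weekly", 2, "08:00") # Tuesday
  expect_equal(next_run(w2, fixed_time("2013-12-04", "00:00")), # Wednesday
               fixed_time("2013-12-10", "08:00"))
  # biweekly counts 14-day strides from the anchor, never fires before it
  bw <- new_schedule("r", "biweekly", as.Date("2013-01-07"), "10:00")
  expect_equal(next_run(bw, fixed_time("2013-01-01", "00:00")),
               fixed_time("2013-01-07", "10:00"))
  expect_equal(next_run(bw, fixed_time("2013-01-07", "10:00")),
               fixed_time("2013-01-21", "10:00"))
  # adhoc never fires
  expect_null(next_run(new_schedule("r", "adhoc"), Sys.time()))
})

test_that("next_run matches the minute-enumeration oracle on a spot window", {
  g <- get_minute_grid(fixed_time("2013-01-01", "00:00"),
                       fixed_time("2013-07-01", "00:00"))
  set.seed(42)
  for (i in 1:25) {
    sched <- random_schedule()
    after <- fixed_time("2013-01-01") + sample(0:(150 * 86400), 1)
    got <- next_run(sched, after)
    want <- oracle_next_run(g, sched, after)
    if (is.null(want)) {
      # no occurrence inside the spot window: either truly never (adhoc) or
      # the next occurrence lies beyond the window end
      expect_true(is.null(got) || got > fixed_time("2013-07-01", "00:00"))
    } else {
      expect_equal(got, want)
    }
  }
})

test_that("next_run makes strict progress", {
  set.seed(7)
  for (i in 1:20) {
    sched <- random_schedule()
    if (sched$frequency == "adhoc") next
    t1 <- next_run(sched, fixed_time("2013-03-15", "11:11"))
    t2 <- next_run(sched, t1)
    expect_true(t2 > t1)
  }
})

test_that("due_tasks orders by due time then id and tracks in-progress runs", {
  s <- disco_store()
  for (i in 1:3) {
    fx <- toy_fixture(nif_id = sprintf("nif-0000-000%d", i), name = paste0("R", i))
    register_resource(s, fx$info, time = fixed_time("2013-01-01"))
  }
  set_schedule(s, "nif-0000-0001", "weekly", 1, at = "06:00")
  set_schedule(s, "nif-0000-0002", "monthly", 19, at = "06:00")
  set_schedule(s, "nif-0000-0003", "adhoc")

  q <- due_tasks(s, now = fixed_time("2013-01-10"))
  expect_equal(q$resource_id, c("nif-0000-0001")) # only the weekly is due yet
  q2 <- due_tasks(s, now = fixed_time("2013-02-20"))
  expect_equal(q2$resource_id, c("nif-0000-0001", "nif-0000-0002"))

  # ties on due time break by id
  set_schedule(s, "nif-0000-0002", "weekly", 1, at = "06:00")
  q3 <- due_tasks(s, now = fixed_time("2013-01-10"))
  expect_equal(q3$resource_id, c("nif-0000-0001", "nif-0000-0002"))

  # a running resource is in-progress, not re-queued
  s$in_progress <- "nif-0000-0001"
  q4 <- due_tasks(s, now = fixed_time("2013-01-10"))
  expect_equal(q4$state[q4$resource_id == "nif-0000-0001"], "in_progress")
  s$in_progress <- character()

  # manual trigger surfaces the adhoc resource
  trigger_update(s, "nif-0000-0003")
  q5 <- due_tasks(s, now = fixed_time("2013-01-10"))
  expect_true("nif-0000-0003" %in% q5$resource_id)
})

test_that("probing compares fetch metadata; first probe is unknown", {
  s <- disco_store()
  fx <- toy_fixture()
  register_resource(s, fx$info)
  expect_equal(probe_source(s, fx$nif_id), "unknown") # no baseline yet

  run_update(s, fx$nif_id, time = fixed_time("2013-01-01"))
  approve(s, fx$nif_id, time = fixed_time("2013-01-01"))
  expect_equal(probe_source(s, fx$nif_id), "likely_unchanged")

  writeLines(c(toy_csv_v1(), "9,extra,row"), fx$source)
  expect_equal(probe_source(s, fx$nif_id, trigger = TRUE), "likely_changed")
  expect_true(fx$nif_id %in% s$manual_queue)

  unlink(fx$source)
  expect_equal(probe_source(s, fx$nif_id), "unknown")
})

test_that("scheduler_tick executes due work and schedules stay on cadence", {
  s <- disco_store()
  fx <- toy_fixture()
  register_resource(s, fx$info, time = fixed_time("2013-01-01"))
  set_schedule(s, fx$nif_id, "monthly", 19, at = "14:00")
  runs <- scheduler_tick(s, now = fixed_time("2013-01-19", "14:00"))
  expect_equal(runs[[fx$nif_id]]$outcome, "new_pending")
  # still pending -> the next tick's run is refused, not duplicated
  runs2 <- scheduler_tick(s, now = fixed_time("2013-02-19", "14:00"))
  expect_equal(runs2[[fx$nif_id]]$outcome, "refused")
  approve(s, fx$nif_id, time = fixed_time("2013-02-19", "15:00"))
  expect_equal(nrow(run_history(s, fx$nif_id)), 1L)
})
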