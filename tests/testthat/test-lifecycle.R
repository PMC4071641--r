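test_that("run_update walks the pipeline and classifies outcomes", {
  s <- disco_store()
  fx <- toy_fixture()
  register_resource(s, fx$info)

  r1 <- run_update(s, fx$nif_id, time = fixed_time("2013-01-01"))
  expect_equal(r1$outcome, "new_pending")
  expect_equal(length(s$staged[[fx$nif_id]]$changeset$added), 3L)

  # re-running while pending is refused, not queued
  expect_error(run_update(s, fx$nif_id), class = "disco_conflict")
  approve(s, fx$nif_id, time = fixed_time("2013-01-01"))

  # identical source -> unchanged, no new version, no staged relation
  r2 <- run_update(s, fx$nif_id, time = fixed_time("2013-01-08"))
  expect_equal(r2$outcome, "unchanged")
  expect_null(s$staged[[fx$nif_id]])
  expect_equal(s$history[[fx$nif_id]]$version, 1L)

  # vanished source -> failed run, production untouched
  unlink(fx$source)
  r3 <- run_update(s, fx$nif_id, time = fixed_time("2013-01-15"))
  expect_equal(r3$outcome, "failed")
  expect_equal(s$history[[fx$nif_id]]$version, 1L)

  hist <- run_history(s, fx$nif_id)
  expect_equal(hist$outcome, c("new_pending", "unchanged", "failed"))
})

test_that("review reports counts, samples and issues read-only", {
  s <- disco_store()
  fx <- toy_fixture()
  register_resource(s, fx$info)
  run_update(s, fx$nif_id, time = fixed_time("2013-01-01"))
  approve(s, fx$nif_id, time = fixed_time("2013-01-01"))
  writeLines(toy_csv_v2(), fx$source)
  run_update(s, fx$nif_id, time = fixed_time("2013-02-01"))

  before <- disco:::store_checksum(s)
  rv <- review(s, fx$nif_id)
  expect_identical(disco:::store_checksum(s), before)
  expect_equal(unname(rv$summary$counts), c(1L, 1L, 1L))
  expect_length(rv$summary$samples$added, 1L)

  approve(s, fx$nif_id, time = fixed_time("2013-02-01"))
  expect_error(review(s, fx$nif_id), class = "disco_not_found")

  # duplicate keys show up in the issue section
  writeLines(c(toy_csv_v2(), "5,basket cell,CA1", "5,basket cell,CA1"),
             fx$source)
  run_update(s, fx$nif_id, time = fixed_time("2013-03-01"))
  rv2 <- review(s, fx$nif_id)
  expect_equal(rv2$issue_counts$duplicate_key, 1L)
})

test_that("issues block approval unless overridden; override is logged", {
  s <- disco_store()
  fx <- toy_fixture(csv = c(toy_csv_v1(), "3,dup,row"))
  register_resource(s, fx$info)
  run_update(s, fx$nif_id, time = fixed_time("2013-01-01"))
  err <- expect_error(approve(s, fx$nif_id), class = "disco_validation")
  expect_match(conditionMessage(err), "duplicate_key")
  expect_equal(s$history[[fx$nif_id]], NULL) # nothing promoted

  approve(s, fx$nif_id, override = TRUE, time = fixed_time("2013-01-01"))
  expect_equal(s$history[[fx$nif_id]]$version, 1L)
  expect_true("override" %in% audit_trail(s)$event)
})

test_that("batch approval promotes exactly once on flush", {
  s <- disco_store()
  fx <- toy_fixture()
  register_resource(s, fx$info)
  run_update(s, fx$nif_id, time = fixed_time("2013-01-01"))
  approve(s, fx$nif_id, mode = "batch", time = fixed_time("2013-01-01"))
  expect_equal(s$staged[[fx$nif_id]]$status, "scheduled")
  expect_equal(s$history[[fx$nif_id]], NULL)

  done <- flush_batch(s, time = fixed_time("2013-01-02"))
  expect_equal(done, fx$nif_id)
  expect_equal(s$history[[fx$nif_id]]$version, 1L)
  expect_equal(flush_batch(s), character(0)) # idempotent
  expect_equal(s$history[[fx$nif_id]]$version, 1L)
})

test_that("problem versions never promote and are superseded by later runs", {
  s <- disco_store()
  fx <- toy_fixture()
  register_resource(s, fx$info)
  run_update(s, fx$nif_id, time = fixed_time("2013-01-01"))
  mark_problem(s, fx$nif_id, "header drift suspected")
  expect_equal(review(s, fx$nif_id)$note, "header drift suspected")
  expect_error(approve(s, fx$nif_id), class = "disco_not_found")
  expect_equal(flush_batch(s), character(0))
  expect_equal(s$history[[fx$nif_id]], NULL)

  # a new run supersedes the problem version (and is logged)
  r <- run_update(s, fx$nif_id, time = fixed_time("2013-01-05"))
  expect_equal(r$outcome, "new_pending")
  expect_true("superseded" %in% audit_trail(s)$event)
  expect_equal(s$staged[[fx$nif_id]]$status, "pending")
})

test_that("promotions cascade only to views that use the resource", {
  s <- disco_store()
  fx1 <- toy_fixture(nif_id = "nif-0000-0001", name = "A")
  fx2 <- toy_fixture(nif_id = "nif-0000-0002", name = "B")
  for (fx in list(fx1, fx2)) {
    register_resource(s, fx$info)
    run_update(s, fx$nif_id, time = fixed_time("2013-01-01"))
    approve(s, fx$nif_id, time = fixed_time("2013-01-01"))
  }
  mk_view <- function(name, rids) {
    define_view(s, list(
      name = name, columns = list("nm"),
      members = lapply(rids, function(r) {
        list(resource = r, map = list(nm = list(field = "neuron_name")))
      })
    ))
  }
  mk_view("only_a", "nif-0000-0001")
  mk_view("both", c("nif-0000-0001", "nif-0000-0002"))
  materialize_view(s, "only_a"); materialize_view(s, "both")
  approve_view(s, "only_a"); approve_view(s, "both")

  writeLines(toy_csv_v2(), fx2$source)
  run_update(s, fx2$nif_id, time = fixed_time("2013-02-01"))
  touched <- character()
  # capture which views cascade on approval
  approve(s, fx2$nif_id, time = fixed_time("2013-02-01"))
  vd <- views_dashboard(s)
  expect_false(vd$beta_newer[vd$view == "only_a"]) # untouched
  expect_true(vd$beta_newer[vd$view == "both"])    # rebuilt on beta only
  expect_equal(cascade_views(s, "nif-9999-00000"), character(0))
  # production channels only move via approve_view
  expect_equal(vd$production_seq[vd$view == "both"],
               s$views[["both"]]$production$seq)
  # notifications were written for curators and resource contacts
  n <- notifications(s)
  expect_setequal(unique(n$audience), c("curators", "resource_contacts"))
})

test_that("every transition lands in the append-only audit log", {
  s <- disco_store()
  fx <- toy_fixture()
  register_resource(s, fx$info)
  run_update(s, fx$nif_id, time = fixed_time("2013-01-01"))
  approve(s, fx$nif_id, time = fixed_time("2013-01-01"))
  ev <- audit_trail(s)$event
  expect_true(all(c("registered", "staged", "run_new_pending", "approved",
                    "promoted") %in% ev))
})
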