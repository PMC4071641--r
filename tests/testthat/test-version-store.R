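test_that("promotion writes reverse deltas below the threshold, snapshots above", {
  # 1 modified field over 100 rows -> 1 set_field delta, no snapshot
  s <- disco_store()
  fx <- toy_fixture(csv = c("id,neuron_name,brain_region",
                            sprintf("%d,n%d,r%d", 1:100, 1:100, 1:100)))
  register_resource(s, fx$info)
  run_update(s, fx$nif_id, time = fixed_time("2013-01-01"))
  approve(s, fx$nif_id, time = fixed_time("2013-01-01"))

  lines <- readLines(fx$source)
  lines[3] <- "2,n2,EDITED"
  writeLines(lines, fx$source)
  run_update(s, fx$nif_id, time = fixed_time("2013-02-01"))
  out <- approve(s, fx$nif_id, time = fixed_time("2013-02-01"))
  expect_false(out$snapshot)
  expect_equal(out$n_deltas, 1L)
  deltas <- s$history[[fx$nif_id]]$deltas[["1"]]
  expect_equal(deltas$op, "set_field")
  expect_equal(deltas$attribute, "brain_region")
  expect_equal(deltas$value, "r2") # the OLD value

  rep <- storage_report(s, fx$nif_id)
  expect_equal(rep$n_deltas, c(1L, 0L))
  expect_false(any(rep$snapshot))
})

test_that("the toy v1->v2 transition trips the full-copy policy (fraction 1.0)", {
  s <- disco_store()
  fx <- toy_fixture()
  register_resource(s, fx$info)
  run_update(s, fx$nif_id, time = fixed_time("2013-01-01"))
  approve(s, fx$nif_id, time = fixed_time("2013-01-01"))
  writeLines(toy_csv_v2(), fx$source)
  run_update(s, fx$nif_id, time = fixed_time("2013-02-01"))
  out <- approve(s, fx$nif_id, time = fixed_time("2013-02-01"))
  expect_true(out$snapshot) # 3 changes / 3 rows = 1.0 > 0.5
  rep <- storage_report(s, fx$nif_id)
  expect_true(rep$snapshot[rep$version == 1])

  # reconstruction of the snapshotted version is exact
  v1 <- reconstruct_version(s, fx$nif_id, 1)
  expect_identical(v1$data, toy_relation(toy_csv_v1())$data)
  # reconstructing the current version applies zero deltas
  expect_identical(reconstruct_version(s, fx$nif_id, 2)$data,
                   s$production[[fx$nif_id]]$data)
  expect_error(reconstruct_version(s, fx$nif_id, 3), class = "disco_not_found")
  expect_error(reconstruct_version(s, fx$nif_id, 0), class = "disco_not_found")
})

test_that("an empty changeset refuses to promote and promotion is atomic", {
  s <- disco_store()
  fx <- toy_fixture()
  register_resource(s, fx$info)
  run_update(s, fx$nif_id, time = fixed_time("2013-01-01"))
  approve(s, fx$nif_id, time = fixed_time("2013-01-01"))
  sc <- parse_script(fx$script)
  stage_ingest(s, fx$nif_id, sc, extract_records(sc))
  expect_error(promote(s, fx$nif_id), class = "disco_usage")
  expect_equal(s$history[[fx$nif_id]]$version, 1L) # unchanged
  s$staged[[fx$nif_id]] <- NULL

  # stale changeset: production moved after the diff was computed
  writeLines(toy_csv_v2(), fx$source)
  run_update(s, fx$nif_id, time = fixed_time("2013-02-01"))
  before <- disco:::store_checksum(s)
  s$staged[[fx$nif_id]]$production_version_seen <- 0L
  expect_error(promote(s, fx$nif_id), class = "disco_conflict")
  s$staged[[fx$nif_id]]$production_version_seen <- 1L
  expect_equal(s$history[[fx$nif_id]]$version, 1L)
})

test_that("schema deltas form a minimal forward edit script", {
  old <- toy_schema()
  new <- rbind(old, data.frame(name = "species", type = "text",
                               max_length = NA_integer_, content_kind = "value",
                               relationship = NA_character_,
                               stringsAsFactors = FALSE))
  d <- record_schema_change(old, new)
  expect_length(d, 1L)
  expect_equal(d[[1]]$op, "add_column")
  expect_equal(d[[1]]$name, "species")

  expect_length(record_schema_change(old, old), 0L)

  renamed <- old
  renamed$name[renamed$name == "brain_region"] <- "region"
  d2 <- record_schema_change(old, renamed,
                             renames = c(brain_region = "region"))
  expect_length(d2, 1L)
  expect_equal(d2[[1]]$op, "rename_column")
  # without a declared rename the same change is drop + add, never inferred
  d3 <- record_schema_change(old, renamed)
  expect_setequal(vapply(d3, `[[`, "", "op"), c("drop_column", "add_column"))

  # replaying deltas forward reproduces the new schema
  sch <- old
  for (dd in d2) sch <- disco:::apply_schema_delta(sch, dd)
  expect_equal(sch$name, renamed$name)
})

test_that("reconstruction honours the schema in force at each version", {
  s <- disco_store()
  d <- withr::local_tempdir()
  b <- generate_resource(d, seed = 5, n_records = 4)
  promote_bundle(s, b, time = fixed_time("2013-01-01"))
  st <- evolve_resource(b, list(ev_add_column("species", "text")), seed = 6)
  b <- st$bundle
  run_update(s, b$nif_id, time = fixed_time("2013-02-01"))
  approve(s, b$nif_id, time = fixed_time("2013-02-01"))

  expect_equal(schema_at(s, b$nif_id, 1)$name,
               c("id", "neuron_name", "brain_region"))
  expect_equal(schema_at(s, b$nif_id, 2)$name,
               c("id", "neuron_name", "brain_region", "species"))
  v1 <- reconstruct_version(s, b$nif_id, 1)
  expect_false("species" %in% names(v1$data)) # column added later is absent
})

test_that("delta economy: stored rows equal field-changes + deletes + adds", {
  s <- disco_store()
  d <- withr::local_tempdir()
  b <- generate_resource(d, seed = 21, n_records = 20)
  promote_bundle(s, b, time = fixed_time("2013-01-01"))
  st <- evolve_resource(b, list(ev_edit_cells(3), ev_add_rows(2),
                                ev_delete_rows(1)), seed = 22)
  b <- st$bundle
  run_update(s, b$nif_id, time = fixed_time("2013-02-01"))
  cs <- s$staged[[b$nif_id]]$changeset
  n_field_changes <- sum(vapply(cs$modified, nrow, 0L))
  out <- approve(s, b$nif_id, time = fixed_time("2013-02-01"))
  expect_false(out$snapshot)
  expect_equal(out$n_deltas,
               n_field_changes + length(cs$deleted) + length(cs$added))
  # conservation: report totals match stored delta rows
  rep <- storage_report(s, b$nif_id)
  expect_equal(sum(rep$n_deltas), out$n_deltas)
})
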