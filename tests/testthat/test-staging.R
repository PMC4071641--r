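test_that("record keys: pk tuples in keyed mode, canonical digests otherwise", {
  fx <- toy_fixture()
  keyed <- parse_script(fx$script)
  expect_equal(record_key(keyed, c(id = "2", neuron_name = "x"))$key, "2")
  expect_equal(record_key(keyed, c(id = "2"))$mode, "keyed")

  p <- tempfile(fileext = ".json")
  writeLines(toy_script_json(pk = list()), p)
  digest <- parse_script(p)
  rec <- c(id = "1", neuron_name = "granule cell", brain_region = "DG")
  k1 <- record_key(digest, rec)
  expect_equal(k1$mode, "digest")
  expect_match(k1$key, "^[0-9a-f]{64}$")
  # canonicalization: field order never matters
  expect_equal(record_key(digest, rec[c(3, 1, 2)])$key, k1$key)
  # single-character difference changes the key (direct hash comparison)
  rec2 <- rec; rec2["brain_region"] <- "DGx"
  expect_false(record_key(digest, rec2)$key == k1$key)
  # missing field and empty string hash differently
  expect_false(record_key(digest, c(id = "1", neuron_name = ""))$key ==
               record_key(digest, c(id = "1"))$key)
})

test_that("stage_ingest quarantines duplicates and records interruptions", {
  fx <- toy_fixture()
  s <- disco_store()
  register_resource(s, fx$info)
  sc <- parse_script(fx$script)
  recs <- extract_records(sc)

  staged <- stage_ingest(s, fx$nif_id, sc, recs)
  expect_equal(staged$record_count, 3L)
  expect_equal(nrow(staged$issues), 0L)
  expect_equal(staged$relation_name, "nif-0000-0001_neurons_v1_tmp")
  expect_equal(staged$version_number, 1L)

  # concurrent staged version refused
  expect_error(stage_ingest(s, fx$nif_id, sc, recs), class = "disco_conflict")
  s$staged[[fx$nif_id]] <- NULL

  # duplicate keys: first kept, later quarantined and reported
  recs4 <- rbind(recs, recs[2, ])
  staged <- stage_ingest(s, fx$nif_id, sc, recs4)
  expect_equal(staged$record_count, 3L)
  expect_equal(staged$issues$kind, "duplicate_key")
  s$staged[[fx$nif_id]] <- NULL

  # missing PK value: excluded with a data_type_error
  recs_bad <- recs; recs_bad$id[2] <- ""
  staged <- stage_ingest(s, fx$nif_id, sc, recs_bad)
  expect_equal(staged$record_count, 2L)
  expect_true("data_type_error" %in% staged$issues$kind)
  s$staged[[fx$nif_id]] <- NULL

  # simulated write interruption
  staged <- stage_ingest(s, fx$nif_id, sc, recs, interrupt_after = 1L)
  expect_equal(staged$record_count, 1L)
  expect_true("incomplete_import" %in% staged$issues$kind)
})

test_that("changeset classification matches the nested-loop oracle", {
  v1 <- toy_relation(toy_csv_v1())
  v2 <- toy_relation(toy_csv_v2())

  # identity: X vs X is all-unchanged
  cs0 <- diff_relations(v1, v1)
  expect_equal(length(cs0$added) + length(cs0$deleted) + length(cs0$modified), 0L)
  expect_equal(cs0$unchanged_count, 3L)

  cs <- diff_relations(v2, v1)
  df1 <- v1$data; df2 <- v2$data
  want <- oracle_diff(df2, df1, "id")
  expect_identical(canonical_changeset(cs), canonical_changeset(want))
  expect_equal(cs$added, "4")
  expect_equal(cs$deleted, "3")
  expect_equal(names(cs$modified), "2")
  expect_equal(cs$modified[["2"]],
               data.frame(field = "brain_region", old = "dentate gyrus",
                          new = "DG", stringsAsFactors = FALSE))
  expect_equal(cs$unchanged_count, 1L)

  # cardinality invariants
  expect_equal(nrow(v2$data),
               length(cs$added) + length(cs$modified) + cs$unchanged_count)
  expect_equal(nrow(v1$data),
               length(cs$deleted) + length(cs$modified) + cs$unchanged_count)

  # first-ever version: everything is an addition
  empty <- disco:::empty_relation(toy_schema())
  cs1 <- diff_relations(v1, empty)
  expect_equal(sort(cs1$added), sort(v1$keys))
})

test_that("digest-mode edits surface as delete+add, never as modification", {
  v1 <- toy_relation(toy_csv_v1(), pk = character(0))
  v2 <- toy_relation(toy_csv_v2(), pk = character(0))
  cs <- diff_relations(v2, v1)
  expect_length(cs$modified, 0L)
  expect_equal(length(cs$added), 2L)   # edited row 2 + new row 4
  expect_equal(length(cs$deleted), 2L) # old row 2 + deleted row 3
})

test_that("diff symmetry: swapping sides swaps added/deleted and inverts diffs", {
  set.seed(11)
  for (i in 1:10) {
    d <- withr::local_tempdir()
    b <- generate_resource(d, seed = i, n_records = 6, keyed = TRUE)
    st <- evolve_resource(b, list(ev_edit_cells(2), ev_add_rows(1),
                                  ev_delete_rows(1)), seed = i + 100)
    r1 <- disco:::canonical_relation(b$data, b$schema, b$primary_key)
    r2 <- disco:::canonical_relation(st$bundle$data, st$bundle$schema,
                                     st$bundle$primary_key)
    fwd <- diff_relations(r2, r1)
    rev <- diff_relations(r1, r2)
    expect_identical(fwd$added, rev$deleted)
    expect_identical(fwd$deleted, rev$added)
    expect_identical(names(fwd$modified), names(rev$modified))
    for (k in names(fwd$modified)) {
      f <- fwd$modified[[k]]; r <- rev$modified[[k]]
      expect_identical(f$old, r$new[match(f$field, r$field)])
      expect_identical(f$new, r$old[match(f$field, r$field)])
    }
    expect_equal(fwd$unchanged_count, rev$unchanged_count)
  }
})

test_that("summaries report exact counts with deterministic truncated samples", {
  v1 <- toy_relation(toy_csv_v1())
  v2 <- toy_relation(toy_csv_v2())
  sm <- summarize_changes(diff_relations(v2, v1))
  expect_equal(unname(sm$counts), c(1L, 1L, 1L))
  expect_match(sm$text, "1 added, 1 deleted, 1 modified")

  sm0 <- summarize_changes(diff_relations(v1, v1))
  expect_match(sm0$text, "unchanged")
  expect_equal(unname(sm0$counts), c(0L, 0L, 0L))

  # 100 additions, 5 samples, lowest keys first
  big <- data.frame(id = sprintf("%03d", 1:100), neuron_name = "n",
                    brain_region = "r", stringsAsFactors = FALSE)
  rel <- disco:::canonical_relation(big, toy_schema(), "id")
  cs <- diff_relations(rel, disco:::empty_relation(toy_schema()))
  sm100 <- summarize_changes(cs, n_samples = 5L)
  expect_equal(sm100$counts[["added"]], 100L)
  expect_equal(sm100$samples$added, sprintf("%03d", 1:5))
})
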