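# Deterministic synthetic resources.  The generator emits a complete resource
# bundle (CSV source, harvest script, information XML) and can evolve it
# through row additions/edits/deletions and column add/drop/rename, keeping a
# constructive ground-truth changeset per transition — built from the events
# themselves, never by diffing relations, so the generator and the diff
# engine cannot share a bug.  Break mode deliberately leaves the script
# stale after a structural change to reproduce the "ingestion breaks" signal.

TERM_POOL <- c(
  "cerebellum", "dentate gyrus", "CA1", "CA3", "Purkinje cell",
  "granule cell", "olfactory bulb", "mitral cell", "neocortex",
  "pyramidal neuron", "striatum", "thalamus", "substantia nigra",
  "hippocampus", "amygdala", "basket cell", "stellate cell"
)
MESSY_POOL <- c(
  "has,comma", "has \"quote\"", "  padded  ", "", "mixed, \"both\"",
  "Ünïcöde μm", "tab\tinside", "trailing space "
)

default_schema_spec <- function() {
  list(
    list(name = "id", type = "integer", content_kind = "value"),
    list(name = "neuron_name", type = "text", content_kind = "term"),
    list(name = "brain_region", type = "text", content_kind = "term")
  )
}

spec_to_schema <- function(spec) {
  do.call(rbind, lapply(spec, function(f) {
    data.frame(
      name = f$name, type = f$type %||% "text",
      max_length = if (is.null(f$max_length)) NA_integer_ else as.integer(f$max_length),
      content_kind = f$content_kind %||% "value",
      relationship = f$relationship %||% NA_character_,
      stringsAsFactors = FALSE
    )
  }))
}

gen_value <- function(type, stress = FALSE, max_length = NA_integer_) {
  if (stress && !is.na(max_length) && runif(1) < 0.25) {
    return(paste(sample(TERM_POOL, 3L), collapse = " / ")) # likely oversize
  }
  if (stress && runif(1) < 0.2) return(sample(MESSY_POOL, 1L))
  switch(type,
    integer = as.character(sample.int(99999L, 1L)),
    real = formatC(round(runif(1, 0, 1000), 3), format = "fg"),
    date = format(as.Date("2010-01-01") + sample.int(2000L, 1L), "%Y-%m-%d"),
    url = paste0("http://example.org/item/", sample.int(99999L, 1L)),
    sample(TERM_POOL, 1L)
  )
}

csv_quote <- function(x) {
  need <- grepl('[",\n\r]', x)
  x[need] <- paste0('"', gsub('"', '""', x[need]), '"')
  x
}

write_source_csv <- function(data, path) {
  lines <- c(
    paste(csv_quote(names(data)), collapse = ","),
    if (nrow(data)) {
      apply(data, 1L, function(row) paste(csv_quote(unname(row)), collapse = ","))
    }
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

write_script_json <- function(bundle) {
  fields <- lapply(seq_len(nrow(bundle$schema)), function(i) {
    f <- bundle$schema[i, ]
    out <- list(name = f$name, type = f$type, content_kind = f$content_kind)
    if (!is.na(f$max_length)) out$max_length <- f$max_length
    out
  })
  doc <- list(
    resource = bundle$nif_id,
    table = bundle$table,
    sources = list(list(
      locator = basename(bundle$source_path), format = "csv",
      record_selector = "header",
      extractors = setNames(as.list(bundle$schema$name), bundle$schema$name)
    )),
    fields = fields,
    primary_key = as.list(bundle$primary_key)
  )
  if (length(bundle$primary_key)) {
    doc$link_template <- paste0("http://example.org/", bundle$table,
                                "/{", bundle$primary_key[1], "}")
  }
  if (length(bundle$renames)) doc$renames <- as.list(bundle$renames)
  writeLines(
    jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null", pretty = TRUE),
    bundle$script_path, useBytes = TRUE
  )
  invisible(bundle$script_path)
}

write_info_xml <- function(bundle) {
  xml <- c(
    sprintf('<resource id="%s" name="%s">', bundle$nif_id, bundle$name),
    '  <contact name="Synthetic Curator" email="curator@example.org"/>',
    sprintf('  <service type="interop" script="%s"/>', basename(bundle$script_path)),
    '  <description>Synthetic evolving resource (generated fixture)</description>',
    '</resource>'
  )
  writeLines(xml, bundle$info_path, useBytes = TRUE)
  invisible(bundle$info_path)
}

#' Generate a synthetic resource bundle
#'
#' Writes a CSV source, a matching harvest script and a resource-information
#' XML file into `dir`; deterministic for a given seed.  With
#' `stress = TRUE` the value pools include CSV-hostile content (commas,
#' quotes, unicode, empty and padded strings) and, when the schema has a
#' `max_length` text field, values that overflow it.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed; the whole bundle is a pure function of it.
#' @param n_records number of data rows (>= 0).
#' @param schema_spec list of field specs (`name`, `type`, optional
#'   `max_length`, `content_kind`); default: integer `id`, two term-valued
#'   text columns.
#' @param keyed declare `id` as the primary key (`FALSE` = digest mode).
#' @param stress draw from the pathological value pools.
#' @return a bundle (list) holding paths, schema, primary key, current data
#'   and the version counter.
#' @export
generate_resource <- function(dir, seed, n_records = 10L,
                              schema_spec = default_schema_spec(),
                              keyed = TRUE, stress = FALSE) {
  if (n_records < 0L) disco_abort("validation", "n_records must be >= 0")
  schema <- spec_to_schema(schema_spec)
  if (is.null(schema) || !nrow(schema) || anyDuplicated(schema$name)) {
    disco_abort("validation", "schema spec must declare uniquely named fields")
  }
  if (keyed && !"id" %in% schema$name) {
    disco_abort("validation", "keyed bundles need an 'id' field")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nif_id <- sprintf("nif-%04d-%05d", seed %% 10000L, (seed * 7L) %% 100000L)
  bundle <- list(
    dir = dir, nif_id = nif_id,
    name = sprintf("Synthetic Resource %d", seed),
    table = "records",
    source_path = file.path(dir, "source.csv"),
    script_path = file.path(dir, "script.json"),
    info_path = file.path(dir, "info.xml"),
    schema = schema,
    primary_key = if (keyed) "id" else character(0),
    stress = stress, version = 1L, next_id = n_records + 1L,
    renames = NULL
  )
  data <- with_seed(seed, {
    rows <- lapply(seq_len(n_records), function(i) {
      vapply(seq_len(nrow(schema)), function(j) {
        if (schema$name[j] == "id") as.character(i)
        else gen_value(schema$type[j], stress, schema$max_length[j])
      }, character(1))
    })
    rows_to_frame(rows, schema$name)
  })
  bundle$data <- ensure_unique_rows(data, bundle$primary_key)$data
  write_source_csv(bundle$data, bundle$source_path)
  write_script_json(bundle)
  write_info_xml(bundle)
  bundle
}

# Digest-mode bundles must not contain duplicate records (duplicates are a
# curation problem, not a versioning fixture); nudge colliding rows apart and
# report which rows were touched so ground truth stays constructive.
ensure_unique_rows <- function(data, primary_key) {
  if (!nrow(data)) return(list(data = data, changed = integer(0)))
  keys <- relation_keys(data, primary_key)
  dup <- which(duplicated(keys))
  changed <- integer(0)
  tries <- 0L
  last_col <- names(data)[length(names(data))]
  while (length(dup) && tries < 50L) {
    for (i in dup) {
      data[[last_col]][i] <- paste0(data[[last_col]][i], " #", i, "-", tries)
    }
    changed <- union(changed, dup)
    keys <- relation_keys(data, primary_key)
    dup <- which(duplicated(keys))
    tries <- tries + 1L
  }
  list(data = data, changed = changed)
}

#' Evolution events
#'
#' Constructors for the event list consumed by [evolve_resource()].
#' @param n number of rows/cells involved.
#' @param name,old,new,type column names / declared type.
#' @name synth_events
NULL

#' @rdname synth_events
#' @export
ev_add_rows <- function(n) list(kind = "add_rows", n = as.integer(n))
#' @rdname synth_events
#' @export
ev_edit_cells <- function(n) list(kind = "edit_cells", n = as.integer(n))
#' @rdname synth_events
#' @export
ev_delete_rows <- function(n) list(kind = "delete_rows", n = as.integer(n))
#' @rdname synth_events
#' @export
ev_add_column <- function(name, type = "text") {
  list(kind = "add_column", name = name, type = type)
}
#' @rdname synth_events
#' @export
ev_drop_column <- function(name) list(kind = "drop_column", name = name)
#' @rdname synth_events
#' @export
ev_rename_column <- function(old, new) {
  list(kind = "rename_column", old = old, new = new)
}

#' Evolve a synthetic bundle one version forward
#'
#' Applies the events in order, rewrites the source file and — unless
#' `break_script = TRUE` — the harvest script, and returns the constructive
#' ground truth for the transition: the expected changeset (built from the
#' events, not by diffing) and the expected schema-delta operations.
#'
#' @param bundle a [generate_resource()] bundle.
#' @param events list of `ev_*()` events.
#' @param seed seed for the values generated by the events.
#' @param break_script keep the old script on a structural change so the next
#'   extraction fails (the "ingestion breaks" scenario).
#' @return list with `bundle` (the evolved bundle) and `truth`
#'   (`changeset`, `schema_events`, `break_script`).
#' @export
evolve_resource <- function(bundle, events, seed, break_script = FALSE) {
  events <- Filter(Negate(is.null), events)
  prev_data <- bundle$data
  prev_schema <- bundle$schema
  pk <- bundle$primary_key
  prev_rowids <- seq_len(nrow(prev_data))

  data <- prev_data
  rowids <- prev_rowids
  schema <- prev_schema
  next_rowid <- length(prev_rowids) + 1L
  edited <- integer(0)    # prev rowids with cell edits
  deleted <- integer(0)   # prev rowids removed
  added <- integer(0)     # new rowids
  schema_changed <- FALSE
  schema_events <- list()
  renames <- character()

  with_seed(seed, {
    for (ev in events) {
      if (ev$kind == "add_rows") {
        for (i in seq_len(ev$n)) {
          row <- vapply(seq_len(nrow(schema)), function(j) {
            if (schema$name[j] == "id" && length(pk)) {
              as.character(bundle$next_id + i - 1L)
            } else {
              gen_value(schema$type[j], bundle$stress, schema$max_length[j])
            }
          }, character(1))
          data[nrow(data) + 1L, ] <- row
          rowids <- c(rowids, next_rowid)
          added <- c(added, next_rowid)
          next_rowid <- next_rowid + 1L
        }
        bundle$next_id <- bundle$next_id + ev$n
      } else if (ev$kind == "edit_cells") {
        editable <- setdiff(schema$name, pk)
        if (!length(editable) || !nrow(data)) {
          disco_abort("validation", "edit_cells: no editable cells")
        }
        cells <- expand.grid(row = seq_len(nrow(data)), col = editable,
                             stringsAsFactors = FALSE)
        if (ev$n > nrow(cells)) {
          disco_abort("validation", "edit_cells: more edits than cells")
        }
        pick <- cells[sample.int(nrow(cells), ev$n), , drop = FALSE]
        for (i in seq_len(nrow(pick))) {
          r <- pick$row[i]; cn <- pick$col[i]
          old <- data[[cn]][r]
          new <- old
          guard <- 0L
          while (identical(new, old) && guard < 25L) {
            new <- gen_value(schema$type[match(cn, schema$name)], bundle$stress,
                             schema$max_length[match(cn, schema$name)])
            guard <- guard + 1L
          }
          if (identical(new, old)) new <- paste0(old, "*")
          data[[cn]][r] <- new
          if (rowids[r] <= length(prev_rowids)) edited <- union(edited, rowids[r])
        }
      } else if (ev$kind == "delete_rows") {
        if (ev$n > nrow(data)) {
          disco_abort("validation", "delete_rows: not enough rows")
        }
        drop <- sample.int(nrow(data), ev$n)
        gone <- rowids[drop]
        deleted <- union(deleted, gone[gone <= length(prev_rowids)])
        added <- setdiff(added, gone)
        data <- data[-drop, , drop = FALSE]
        rowids <- rowids[-drop]
      } else if (ev$kind == "add_column") {
        if (ev$name %in% schema$name) {
          disco_abort("validation", paste0("add_column: '", ev$name, "' exists"))
        }
        schema <- rbind(schema, data.frame(
          name = ev$name, type = ev$type, max_length = NA_integer_,
          content_kind = "value", relationship = NA_character_,
          stringsAsFactors = FALSE
        ))
        data[[ev$name]] <- vapply(seq_len(nrow(data)), function(i) {
          gen_value(ev$type, bundle$stress, NA_integer_)
        }, character(1))
        if (!nrow(data)) data[[ev$name]] <- character()
        schema_changed <- TRUE
        schema_events[[length(schema_events) + 1L]] <- list(
          op = "add_column", name = ev$name, type = ev$type
        )
      } else if (ev$kind == "drop_column") {
        if (!ev$name %in% schema$name || ev$name %in% pk) {
          disco_abort("validation", paste0("drop_column: cannot drop '", ev$name, "'"))
        }
        schema <- schema[schema$name != ev$name, , drop = FALSE]
        data[[ev$name]] <- NULL
        schema_changed <- TRUE
        schema_events[[length(schema_events) + 1L]] <- list(
          op = "drop_column", name = ev$name
        )
      } else if (ev$kind == "rename_column") {
        if (!ev$old %in% schema$name || ev$old %in% pk ||
            ev$new %in% schema$name) {
          disco_abort("validation", paste0(
            "rename_column: invalid rename ", ev$old, " -> ", ev$new
          ))
        }
        schema$name[schema$name == ev$old] <- ev$new
        names(data)[names(data) == ev$old] <- ev$new
        schema_changed <- TRUE
        schema_events[[length(schema_events) + 1L]] <- list(
          op = "rename_column", old = ev$old, new = ev$new
        )
        # collapse chains (a -> b, b -> c becomes a -> c) so the script's
        # declared renames always target declared fields
        prior <- names(renames)[renames == ev$old]
        if (length(prior)) renames[prior] <- ev$new else renames[ev$old] <- ev$new
      } else {
        disco_abort("usage", paste0("unknown event kind: ", ev$kind))
      }
    }
  })
  rownames(data) <- NULL
  dedup <- ensure_unique_rows(data, pk)
  data <- dedup$data
  for (idx in dedup$changed) {
    rid <- rowids[idx]
    if (rid <= length(prev_rowids)) edited <- union(edited, rid)
  }

  truth <- build_ground_truth(
    prev_data, prev_rowids, data, rowids, pk,
    edited, deleted, added, schema_changed
  )
  truth$schema_events <- schema_events
  truth$break_script <- break_script

  bundle$data <- data
  bundle$schema <- schema
  bundle$version <- bundle$version + 1L
  bundle$renames <- if (length(renames)) renames else NULL
  write_source_csv(data, bundle$source_path)
  if (!break_script) write_script_json(bundle)
  list(bundle = bundle, truth = truth)
}

# Constructive ground truth: only rows touched by events are examined; the
# untouched remainder is counted, never compared.
build_ground_truth <- function(prev_data, prev_rowids, new_data, new_rowids,
                               pk, edited, deleted, added, schema_changed) {
  keyed <- length(pk) > 0L
  prev_keys <- relation_keys(prev_data, pk)
  new_keys <- relation_keys(new_data, pk)
  prev_pos <- match(prev_rowids, prev_rowids) # identity; prev index by rowid
  new_pos <- match(seq_len(max(c(new_rowids, 0L))), new_rowids)

  surviving <- setdiff(prev_rowids, deleted)
  touched_prev <- if (schema_changed) surviving else intersect(edited, surviving)

  added_keys <- new_keys[new_pos[added]]
  deleted_keys <- prev_keys[deleted]
  modified <- list()

  if (keyed) {
    for (rid in touched_prev) {
      pi_ <- prev_pos[rid]
      ni <- new_pos[rid]
      old_rec <- setNames(as.character(prev_data[pi_, ]), names(prev_data))
      new_rec <- setNames(as.character(new_data[ni, ]), names(new_data))
      cols <- union(names(old_rec), names(new_rec))
      ch <- list()
      for (cn in cols) {
        o <- if (cn %in% names(old_rec)) old_rec[[cn]] else NA_character_
        nv <- if (cn %in% names(new_rec)) new_rec[[cn]] else NA_character_
        if ((is.na(o) != is.na(nv)) || (!is.na(o) && !is.na(nv) && o != nv)) {
          ch[[length(ch) + 1L]] <- data.frame(
            field = cn, old = o, new = nv, stringsAsFactors = FALSE
          )
        }
      }
      if (length(ch)) {
        modified[[prev_keys[pi_]]] <- do.call(rbind, c(ch, list(make.row.names = FALSE)))
      }
    }
  } else {
    # Whole-record identity: any touched surviving row changes key.
    for (rid in touched_prev) {
      ok <- prev_keys[prev_pos[rid]]
      nk <- new_keys[new_pos[rid]]
      if (!identical(ok, nk)) {
        deleted_keys <- c(deleted_keys, ok)
        added_keys <- c(added_keys, nk)
      }
    }
  }

  added_keys <- radix_sort(unique(added_keys))
  deleted_keys <- radix_sort(unique(deleted_keys))
  # A record that is both "added" and "deleted" (same key) is really common
  # to both versions — e.g. a digest-mode edit that lands on a deleted row's
  # old content.  Cancel the pair and count it unchanged.
  cancelled <- intersect(added_keys, deleted_keys)
  added_keys <- setdiff(added_keys, cancelled)
  deleted_keys <- setdiff(deleted_keys, cancelled)
  n_common <- length(surviving) - if (keyed) 0L else
    sum(vapply(touched_prev, function(rid) {
      !identical(prev_keys[prev_pos[rid]], new_keys[new_pos[rid]])
    }, logical(1)))
  unchanged <- n_common - length(modified) + length(cancelled)

  structure(
    list(added = added_keys, deleted = deleted_keys, modified = modified,
         unchanged_count = unchanged),
    class = "disco_changeset"
  )
}

#' Generate a multi-version synthetic history
#'
#' Chains [evolve_resource()] over randomly drawn event mixes, retaining a
#' canonical snapshot of every version plus the per-transition ground truth.
#' Deterministic for a given seed.
#'
#' @param dir bundle directory (files are rewritten in place each version).
#' @param seed integer seed.
#' @param n_versions number of versions (>= 1).
#' @param weights named sampling weights over event kinds.
#' @param n_records rows in version 1.
#' @param keyed primary-key mode (`FALSE` = digest mode).
#' @param stress pathological value pools.
#' @param on_version optional callback `function(version, bundle)` invoked
#'   after each version's files are on disk — the hook tests use to run the
#'   real ingestion pipeline over every transition.
#' @return list with `bundle` (final state), `snapshots` (list of
#'   `disco_relation`, one per version) and `truths` (one ground-truth record
#'   per transition v -> v+1).
#' @export
generate_history <- function(dir, seed, n_versions = 5L,
                             weights = c(add_rows = 3, edit_cells = 3,
                                         delete_rows = 2, add_column = 0.6,
                                         drop_column = 0.4, rename_column = 0.3),
                             n_records = 8L, keyed = TRUE, stress = FALSE,
                             on_version = NULL) {
  if (n_versions < 1L) disco_abort("validation", "n_versions must be >= 1")
  bundle <- generate_resource(dir, seed, n_records, keyed = keyed,
                              stress = stress)
  snapshots <- list(canonical_relation(bundle$data, bundle$schema,
                                       bundle$primary_key))
  if (!is.null(on_version)) on_version(1L, bundle)
  truths <- list()
  col_counter <- 0L
  for (v in seq_len(n_versions - 1L)) {
    step_seed <- (seed * 97L + v * 131L) %% .Machine$integer.max
    # Events are drawn randomly, then applied in the fixed order
    # delete < edit < structural < add, with counts clamped to what the table
    # can absorb.  That ordering guarantees every drawn event leaves a
    # visible mark (edits never land on rows added in the same transition,
    # deletions never cancel same-transition additions), so each transition
    # produces a non-empty changeset and version numbers stay dense when the
    # history is replayed through the real pipeline.
    events <- with_seed(step_seed + 1L, {
      n_events <- sample.int(3L, 1L)
      kinds <- sample(names(weights), n_events, replace = TRUE,
                      prob = weights)
      kind_order <- c("delete_rows", "edit_cells", "drop_column",
                      "rename_column", "add_column", "add_rows")
      kinds <- kinds[order(match(kinds, kind_order))]
      rows <- nrow(bundle$data)
      sim_schema <- bundle$schema$name
      evs <- list()
      for (kind in kinds) {
        droppable <- setdiff(sim_schema, c(bundle$primary_key, "id"))
        ev <- switch(kind,
          add_rows = {
            n <- sample.int(3L, 1L); rows <- rows + n
            ev_add_rows(n)
          },
          edit_cells = {
            cells <- rows * length(setdiff(sim_schema, bundle$primary_key))
            if (cells < 1L) { rows <- rows + 2L; ev_add_rows(2L) } else
              ev_edit_cells(min(sample.int(3L, 1L), cells))
          },
          delete_rows = {
            if (rows < 2L) { rows <- rows + 2L; ev_add_rows(2L) } else {
              n <- min(sample.int(2L, 1L), rows - 1L); rows <- rows - n
              ev_delete_rows(n)
            }
          },
          add_column = {
            col_counter <- col_counter + 1L
            nm <- paste0("extra_", col_counter)
            sim_schema <- c(sim_schema, nm)
            ev_add_column(nm, sample(c("text", "integer"), 1L))
          },
          drop_column = {
            if (length(droppable) < 2L) { rows <- rows + 1L; ev_add_rows(1L) } else {
              nm <- sample(droppable, 1L)
              sim_schema <- setdiff(sim_schema, nm)
              ev_drop_column(nm)
            }
          },
          rename_column = {
            if (length(droppable) < 1L) { rows <- rows + 1L; ev_add_rows(1L) } else {
              col_counter <- col_counter + 1L
              old <- sample(droppable, 1L)
              nm <- paste0("renamed_", col_counter)
              sim_schema[sim_schema == old] <- nm
              ev_rename_column(old, nm)
            }
          }
        )
        evs[[length(evs) + 1L]] <- ev
      }
      evs
    })
    step <- evolve_resource(bundle, events, seed = step_seed)
    bundle <- step$bundle
    truths[[v]] <- step$truth
    snapshots[[v + 1L]] <- canonical_relation(bundle$data, bundle$schema,
                                              bundle$primary_key)
    if (!is.null(on_version)) on_version(v + 1L, bundle)
  }
  list(bundle = bundle, snapshots = snapshots, truths = truths)
}

#' Canonical form of a changeset (for exact comparisons)
#'
#' Sorts the key vectors, orders the modified map by key and each field-change
#' table by field name, and drops row names, so two changesets describing the
#' same difference compare `identical()`.
#'
#' @param cs a `disco_changeset`.
#' @return the canonicalized changeset.
#' @export
canonical_changeset <- function(cs) {
  mod <- cs$modified[radix_sort(names(cs$modified))]
  mod <- lapply(mod, function(df) {
    df <- df[radix_order(df$field), c("field", "old", "new"), drop = FALSE]
    rownames(df) <- NULL
    df
  })
  structure(
    list(added = radix_sort(unname(cs$added)),
         deleted = radix_sort(unname(cs$deleted)),
         modified = mod,
         unchanged_count = as.integer(cs$unchanged_count)),
    class = "disco_changeset"
  )
}
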