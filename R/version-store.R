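# Concurrent-versioning back-end (EAV-style).  Production relations always
# hold the newest version; for each promotion a reverse delta set is written
# that restores the previous version (one set_field row per changed field
# holding the OLD value, one restore_record row per deleted record, one
# remove_record row per added record).  Structural changes travel the other
# way as forward schema deltas.  When more than half the production rows are
# touched, a full copy of the old version is stored instead of deltas.

FULL_COPY_THRESHOLD <- 0.5

empty_delta_frame <- function() {
  data.frame(
    entity = character(), op = character(), attribute = character(),
    value = character(), stringsAsFactors = FALSE
  )
}

build_reverse_deltas <- function(changeset, production) {
  rows <- list()
  for (key in names(changeset$modified)) {
    ch <- changeset$modified[[key]]
    rows[[length(rows) + 1L]] <- data.frame(
      entity = key, op = "set_field", attribute = ch$field, value = ch$old,
      stringsAsFactors = FALSE
    )
  }
  if (length(changeset$deleted)) {
    idx <- match(changeset$deleted, production$keys)
    payloads <- vapply(idx, function(i) {
      record_to_json(relation_record(production, i))
    }, character(1))
    rows[[length(rows) + 1L]] <- data.frame(
      entity = changeset$deleted, op = "restore_record",
      attribute = NA_character_, value = payloads, stringsAsFactors = FALSE
    )
  }
  if (length(changeset$added)) {
    rows[[length(rows) + 1L]] <- data.frame(
      entity = changeset$added, op = "remove_record",
      attribute = NA_character_, value = NA_character_, stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) return(empty_delta_frame())
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Minimal schema edit script between two versions
#'
#' Emits `rename_column` only for renames declared in the updated harvest
#' script (renames are never inferred from data), then `drop_column`,
#' `add_column` and `change_type` operations.  Applying the result to
#' `old_schema` forward reproduces `new_schema`.
#'
#' @param old_schema,new_schema schema data frames (`name`, `type`,
#'   `max_length`, `content_kind`, `relationship`).
#' @param renames named character vector `old -> new` of declared renames.
#' @return list of schema-delta records (`op` plus payload fields).
#' @export
record_schema_change <- function(old_schema, new_schema, renames = NULL) {
  deltas <- list()
  renamed_from <- character()
  renamed_to <- character()
  for (old in names(renames %||% character())) {
    new <- renames[[old]]
    if (old %in% old_schema$name && new %in% new_schema$name) {
      deltas[[length(deltas) + 1L]] <- list(op = "rename_column", old = old, new = new)
      renamed_from <- c(renamed_from, old)
      renamed_to <- c(renamed_to, new)
    }
  }
  for (dropped in setdiff(setdiff(old_schema$name, new_schema$name), renamed_from)) {
    deltas[[length(deltas) + 1L]] <- list(op = "drop_column", name = dropped)
  }
  for (added in setdiff(setdiff(new_schema$name, old_schema$name), renamed_to)) {
    i <- match(added, new_schema$name)
    deltas[[length(deltas) + 1L]] <- list(
      op = "add_column", name = added, type = new_schema$type[i],
      max_length = new_schema$max_length[i],
      content_kind = new_schema$content_kind[i]
    )
  }
  effective_old <- old_schema$name
  names(effective_old) <- old_schema$name
  if (length(renamed_from)) effective_old[renamed_from] <- renamed_to
  for (i in seq_along(effective_old)) {
    new_name <- effective_old[[i]]
    j <- match(new_name, new_schema$name)
    if (!is.na(j) && new_schema$type[j] != old_schema$type[i]) {
      deltas[[length(deltas) + 1L]] <- list(
        op = "change_type", name = new_name,
        old_type = old_schema$type[i], new_type = new_schema$type[j]
      )
    }
  }
  deltas
}

apply_schema_delta <- function(schema, d) {
  switch(d$op,
    add_column = rbind(schema, data.frame(
      name = d$name, type = d$type,
      max_length = if (is.null(d$max_length)) NA_integer_ else as.integer(d$max_length),
      content_kind = d$content_kind %||% "value",
      relationship = NA_character_, stringsAsFactors = FALSE
    )),
    drop_column = schema[schema$name != d$name, , drop = FALSE],
    rename_column = {
      schema$name[schema$name == d$old] <- d$new
      schema
    },
    change_type = {
      schema$type[schema$name == d$name] <- d$new_type
      schema
    },
    disco_abort("integrity", paste0("unknown schema delta op: ", d$op))
  )
}

#' Schema in force at a given version
#'
#' Replays forward schema deltas from version 1 up to `v`.
#'
#' @param store a [disco_store()].
#' @param resource_id resource id with version history.
#' @param v version number.
#' @return schema data frame.
#' @export
schema_at <- function(store, resource_id, v) {
  hist <- store$history[[resource_id]]
  if (is.null(hist)) disco_abort("not_found", paste0("no versions for ", resource_id))
  schema <- hist$base_schema
  for (d in hist$schema_deltas) {
    if (d$from_version < v) schema <- apply_schema_delta(schema, d)
  }
  rownames(schema) <- NULL
  schema
}

#' Promote the staged version to production
#'
#' The production relation is replaced by the staged content; reverse data
#' deltas (or, above the full-copy threshold, a snapshot of the old version)
#' and forward schema deltas are recorded; the version counter increments by
#' exactly one.  Promotion is atomic: on any error the store is unchanged.
#'
#' @param store a [disco_store()].
#' @param resource_id resource whose staged version was approved.
#' @param time promotion timestamp.
#' @return list with `version`, `snapshot` (did the full-copy policy fire),
#'   `n_deltas`, invisibly.
#' @export
promote <- function(store, resource_id, time = Sys.time()) {
  staged <- store$staged[[resource_id]]
  if (is.null(staged)) {
    disco_abort("not_found", paste0("no staged version for ", resource_id))
  }
  cs <- staged$changeset
  if (is.null(cs)) cs <- compute_changes(store, resource_id)
  if (changeset_empty(cs)) {
    disco_abort("usage", paste0(
      "staged version for ", resource_id,
      " is unchanged from production; nothing to promote"
    ))
  }
  hist <- store$history[[resource_id]]
  old_version <- if (is.null(hist)) 0L else hist$version
  if (!is.null(staged$production_version_seen) &&
      staged$production_version_seen != old_version) {
    disco_abort("conflict", paste0(
      "changeset for ", resource_id, " is stale: production moved from version ",
      staged$production_version_seen, " to ", old_version
    ))
  }
  new_version <- old_version + 1L
  production <- store$production[[resource_id]]
  script <- staged$script

  snapshot <- FALSE
  deltas <- empty_delta_frame()
  schema_deltas <- list()
  if (old_version >= 1L) {
    fraction <- changes_count(cs) / max(nrow(production$data), 1L)
    if (fraction > FULL_COPY_THRESHOLD) {
      snapshot <- TRUE
    } else {
      deltas <- build_reverse_deltas(cs, production)
    }
    renames <- script$renames
    schema_deltas <- lapply(
      record_schema_change(production$schema, staged$relation$schema, renames),
      function(d) c(list(from_version = old_version), d)
    )
  }

  if (is.null(hist)) {
    hist <- list(
      version = 0L, table_name = script$table_name,
      base_schema = staged$relation$schema,
      primary_key = script$primary_key,
      deltas = list(), schema_deltas = list(), snapshots = list(),
      promotions = list()
    )
  }
  # ---- commit point: everything below is plain assignment ----
  hist$version <- new_version
  if (old_version >= 1L) {
    if (snapshot) {
      hist$snapshots[[as.character(old_version)]] <- production
    } else {
      hist$deltas[[as.character(old_version)]] <- deltas
    }
    hist$schema_deltas <- c(hist$schema_deltas, schema_deltas)
  }
  hist$promotions[[length(hist$promotions) + 1L]] <- list(
    version = new_version, date = fmt_time(time),
    record_count = nrow(staged$relation$data),
    n_added = length(cs$added), n_deleted = length(cs$deleted),
    n_modified = length(cs$modified), snapshot = snapshot
  )
  store$history[[resource_id]] <- hist
  store$production[[resource_id]] <- staged$relation
  store$staged[[resource_id]] <- NULL
  audit_log(store, resource_id, "promoted",
            sprintf("version %d -> production (%s)", new_version,
                    if (snapshot) "snapshot of old version stored" else
                      sprintf("%d reverse delta row(s)", nrow(deltas))),
            time = time)
  invisible(list(version = new_version, snapshot = snapshot,
                 n_deltas = nrow(deltas)))
}

apply_delta_frame <- function(records, deltas, resource_id, k) {
  for (i in seq_len(nrow(deltas))) {
    op <- deltas$op[i]
    entity <- deltas$entity[i]
    if (op == "remove_record") {
      records[[entity]] <- NULL
    } else if (op == "restore_record") {
      records[[entity]] <- record_from_json(deltas$value[i])
    } else if (op == "set_field") {
      rec <- records[[entity]]
      if (is.null(rec)) {
        disco_abort("integrity", sprintf(
          "delta chain for %s version %d references unknown entity", resource_id, k
        ))
      }
      rec[[deltas$attribute[i]]] <- deltas$value[i]
      records[[entity]] <- rec
    } else {
      disco_abort("integrity", paste0("unknown delta op: ", op))
    }
  }
  records
}

#' Reconstruct a historical version
#'
#' Starts from production (or the nearest stored snapshot at or above `v`)
#' and applies reverse delta sets downward; the result is returned under the
#' schema in force at `v` and is byte-identical to the relation as it stood
#' then.
#'
#' @param store a [disco_store()].
#' @param resource_id resource id.
#' @param v target version, `1 <= v <=` current production version.
#' @return a `disco_relation`.
#' @export
reconstruct_version <- function(store, resource_id, v) {
  hist <- store$history[[resource_id]]
  if (is.null(hist)) disco_abort("not_found", paste0("no versions for ", resource_id))
  current <- hist$version
  if (!is.numeric(v) || v < 1L || v > current) {
    disco_abort("not_found", sprintf(
      "version %s of %s does not exist (current is %d)", v, resource_id, current
    ))
  }
  v <- as.integer(v)
  if (v == current) return(store$production[[resource_id]])

  snap_versions <- as.integer(names(hist$snapshots))
  candidates <- c(current, snap_versions[snap_versions >= v & snap_versions < current])
  w <- min(candidates)
  start <- if (w == current) store$production[[resource_id]] else
    hist$snapshots[[as.character(w)]]
  records <- setNames(
    lapply(seq_len(nrow(start$data)), function(i) {
      rec <- relation_record(start, i)
      rec[!is.na(rec)]
    }),
    start$keys
  )
  if (w > v) {
    for (k in seq(w - 1L, v)) {
      snap <- hist$snapshots[[as.character(k)]]
      if (!is.null(snap)) {
        records <- setNames(
          lapply(seq_len(nrow(snap$data)), function(i) {
            rec <- relation_record(snap, i)
            rec[!is.na(rec)]
          }),
          snap$keys
        )
        next
      }
      deltas <- hist$deltas[[as.character(k)]]
      if (is.null(deltas)) {
        disco_abort("integrity", sprintf(
          "missing delta set restoring version %d of %s", k, resource_id
        ))
      }
      records <- apply_delta_frame(records, deltas, resource_id, k)
    }
  }
  relation_from_records(records, schema_at(store, resource_id, v),
                        hist$primary_key)
}

#' Per-version storage accounting
#'
#' @param store a [disco_store()].
#' @param resource_id resource with at least one version.
#' @return data frame with one row per version: `version`, `n_deltas`,
#'   `snapshot`, `bytes_estimate`, `record_count`, `date`.
#' @export
storage_report <- function(store, resource_id) {
  hist <- store$history[[resource_id]]
  if (is.null(hist)) disco_abort("not_found", paste0("no versions for ", resource_id))
  versions <- seq_len(hist$version)
  rows <- lapply(versions, function(v) {
    key <- as.character(v)
    deltas <- hist$deltas[[key]]
    snap <- hist$snapshots[[key]]
    n_deltas <- if (is.null(deltas)) 0L else nrow(deltas)
    bytes <- 0L
    if (!is.null(deltas) && nrow(deltas)) {
      bytes <- bytes + sum(nchar(deltas$entity), nchar(deltas$value), na.rm = TRUE)
    }
    if (!is.null(snap)) {
      bytes <- bytes + sum(vapply(snap$data, function(col) {
        sum(nchar(col), na.rm = TRUE)
      }, numeric(1)))
    }
    promo <- hist$promotions[[v]]
    data.frame(
      version = v, n_deltas = n_deltas, snapshot = !is.null(snap),
      bytes_estimate = as.numeric(bytes),
      record_count = promo$record_count, date = promo$date,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
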