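# Staging: extracted records land in a fresh temporary relation, get identity
# (primary-key tuple or whole-record digest), are de-duplicated, and are
# diffed against the production version to produce the changeset curators see.

#' Identity key for a single record
#'
#' Keyed mode (script declares a primary key): the tuple of raw key values.
#' Digest mode: SHA-256 over the canonical serialization (`name=value` pairs
#' sorted by field name, missing fields omitted), so the key is invariant
#' under field reordering.
#'
#' @param script a parsed harvest script.
#' @param record named character vector of raw values (`NA` = missing field).
#' @return list with `key` (string, or `NA` when a key field is missing or
#'   empty) and `mode` (`"keyed"` or `"digest"`).
#' @export
record_key <- function(script, record) {
  df <- as.data.frame(as.list(record), stringsAsFactors = FALSE,
                      check.names = FALSE, optional = TRUE)
  k <- relation_keys(df, script$primary_key)
  list(
    key = k,
    mode = if (length(script$primary_key)) "keyed" else "digest"
  )
}

#' Stage extracted records into a temporary relation
#'
#' Assigns identity, quarantines records with unusable keys (missing/empty
#' primary-key values become `data_type_error` issues) and duplicate keys
#' (first occurrence kept, later ones reported as `duplicate_key`), and holds
#' everything in a temporary relation named
#' `<nif_id>_<table>_v<k>_tmp`, one version past production.
#'
#' @param store a [disco_store()].
#' @param resource_id registered resource id.
#' @param script a parsed harvest script.
#' @param records raw record data frame from [extract_records()].
#' @param issues issue data frame carried through from [coerce_records()].
#' @param interrupt_after simulate a storage failure after this many records
#'   (used by tests; default `Inf` = never).
#' @param time staging timestamp.
#' @return the staged version (invisibly); also stored as the resource's
#'   single in-flight version.
#' @export
stage_ingest <- function(store, resource_id, script, records,
                         issues = empty_issues(), interrupt_after = Inf,
                         time = Sys.time()) {
  get_resource(store, resource_id)
  inflight <- store$staged[[resource_id]]
  if (!is.null(inflight) && inflight$status %in% c("pending", "approved", "scheduled")) {
    disco_abort("conflict", paste0(
      "resource ", resource_id, " already has an in-flight staged version (",
      inflight$status, ")"
    ))
  }

  schema <- script$schema
  n <- nrow(records)
  # Align columns to the schema without sorting rows: the keep-first duplicate
  # policy depends on arrival order.
  cols <- lapply(schema$name, function(cn) {
    if (cn %in% names(records)) as.character(records[[cn]]) else rep(NA_character_, n)
  })
  data <- as.data.frame(setNames(cols, schema$name), stringsAsFactors = FALSE,
                        check.names = FALSE, optional = TRUE)
  keys <- relation_keys(data, script$primary_key)

  new_issues <- list()
  keep <- rep(TRUE, n)
  bad_key <- which(is.na(keys))
  for (r in bad_key) {
    keep[r] <- FALSE
    new_issues[[length(new_issues) + 1L]] <- new_issue(
      "data_type_error", paste0("row:", r),
      paste(script$primary_key, collapse = ","),
      "missing or empty primary-key value; record excluded from keying"
    )
  }
  seen <- !is.na(keys) & duplicated(keys, incomparables = NA)
  for (r in which(seen)) {
    keep[r] <- FALSE
    new_issues[[length(new_issues) + 1L]] <- new_issue(
      "duplicate_key", paste0("row:", r), NA_character_,
      paste0("duplicate key '", gsub(SEP_NV, "|", keys[r], fixed = TRUE),
             "'; first occurrence kept")
    )
  }

  interrupted <- is.finite(interrupt_after) && sum(keep) > interrupt_after
  if (interrupted) {
    kept_idx <- which(keep)[seq_len(interrupt_after)]
    keep <- rep(FALSE, n)
    keep[kept_idx] <- TRUE
    new_issues[[length(new_issues) + 1L]] <- new_issue(
      "incomplete_import", paste0("row:", interrupt_after + 1L), NA_character_,
      "data import failed to complete; staged version is partial"
    )
  }

  data <- data[keep, , drop = FALSE]
  keys <- keys[keep]
  ord <- radix_order(keys)
  rel <- new_relation(data[ord, , drop = FALSE], schema, keys[ord])

  prod_version <- if (is.null(store$history[[resource_id]])) 0L else
    store$history[[resource_id]]$version
  staged <- list(
    resource_id = resource_id, service = "interop",
    version_number = prod_version + 1L,
    relation_name = sprintf("%s_%s_v%d_tmp", resource_id, script$table_name,
                            prod_version + 1L),
    relation = rel,
    script = script,
    record_count = nrow(rel$data),
    created_at = fmt_time(time),
    status = "pending",
    issues = do.call(bind_issues, c(list(issues), new_issues))
  )
  store$staged[[resource_id]] <- staged
  audit_log(store, resource_id, "staged",
            sprintf("version %d staged: %d record(s), %d issue(s)",
                    staged$version_number, staged$record_count,
                    nrow(staged$issues)),
            time = time)
  invisible(staged)
}

#' Classify differences between two relations
#'
#' Records are matched by key; field comparison is exact string equality on
#' raw values, with a missing field (`NA`) distinct from the empty string.
#' Comparison runs over the union of the two relations' columns, so schema
#' drift surfaces as per-record field changes.
#'
#' @param staged,production `disco_relation` objects (production may be an
#'   empty relation for a first version).
#' @return a `disco_changeset`: list with sorted key vectors `added` and
#'   `deleted`, `modified` (named list: key -> data frame of
#'   `field`/`old`/`new`), and `unchanged_count`.
#' @export
diff_relations <- function(staged, production) {
  sk <- staged$keys
  pk <- production$keys
  added <- radix_sort(setdiff(sk, pk))
  deleted <- radix_sort(setdiff(pk, sk))
  common <- radix_sort(intersect(sk, pk))

  modified <- list()
  if (length(common)) {
    si <- match(common, sk)
    pi_ <- match(common, pk)
    cols <- union(names(staged$data), names(production$data))
    diff_by_field <- vector("list", length(cols))
    names(diff_by_field) <- cols
    for (cn in cols) {
      svals <- if (cn %in% names(staged$data)) staged$data[[cn]][si] else
        rep(NA_character_, length(common))
      pvals <- if (cn %in% names(production$data)) production$data[[cn]][pi_] else
        rep(NA_character_, length(common))
      neq <- (is.na(svals) != is.na(pvals)) |
        (!is.na(svals) & !is.na(pvals) & svals != pvals)
      diff_by_field[[cn]] <- list(neq = neq, old = pvals, new = svals)
    }
    any_diff <- Reduce(`|`, lapply(diff_by_field, `[[`, "neq"))
    for (j in which(any_diff)) {
      fields <- cols[vapply(diff_by_field, function(d) d$neq[j], logical(1))]
      modified[[common[j]]] <- data.frame(
        field = fields,
        old = vapply(fields, function(cn) diff_by_field[[cn]]$old[j], character(1)),
        new = vapply(fields, function(cn) diff_by_field[[cn]]$new[j], character(1)),
        stringsAsFactors = FALSE, row.names = NULL
      )
    }
  } else {
    any_diff <- logical(0)
  }
  unchanged <- length(common) - length(modified)
  structure(
    list(added = added, deleted = deleted,
         modified = modified[radix_sort(names(modified))],
         unchanged_count = unchanged),
    class = "disco_changeset"
  )
}

#' @export
print.disco_changeset <- function(x, ...) {
  cat(sprintf(
    "<disco_changeset> +%d / -%d / ~%d, %d unchanged\n",
    length(x$added), length(x$deleted), length(x$modified), x$unchanged_count
  ))
  invisible(x)
}

changes_count <- function(cs) {
  length(cs$added) + length(cs$deleted) + length(cs$modified)
}

changeset_empty <- function(cs) changes_count(cs) == 0L

#' Compute the changeset for a resource's in-flight staged version
#'
#' @param store a [disco_store()].
#' @param resource_id resource with a staged version.
#' @return the `disco_changeset` (also attached to the staged version).
#' @export
compute_changes <- function(store, resource_id) {
  staged <- store$staged[[resource_id]]
  if (is.null(staged)) {
    disco_abort("not_found", paste0("no staged version for ", resource_id))
  }
  prod <- store$production[[resource_id]] %||% empty_relation(staged$relation$schema)
  cs <- diff_relations(staged$relation, prod)
  staged$changeset <- cs
  staged$production_version_seen <- if (is.null(store$history[[resource_id]])) 0L else
    store$history[[resource_id]]$version
  store$staged[[resource_id]] <- staged
  cs
}

#' Curator-facing summary of a changeset
#'
#' Counts per class plus up to `n_samples` deterministic sample diffs per
#' class (lowest keys first).
#'
#' @param changeset a `disco_changeset`.
#' @param n_samples samples per class (default 5).
#' @return list with `counts`, `samples`, `unchanged`, and a one-line `text`.
#' @export
summarize_changes <- function(changeset, n_samples = 5L) {
  take <- function(keys) utils::head(keys, n_samples)
  counts <- c(
    added = length(changeset$added),
    deleted = length(changeset$deleted),
    modified = length(changeset$modified)
  )
  samples <- list(
    added = take(changeset$added),
    deleted = take(changeset$deleted),
    modified = changeset$modified[take(names(changeset$modified))]
  )
  text <- if (sum(counts) == 0L) {
    sprintf("unchanged (%d record(s))", changeset$unchanged_count)
  } else {
    sprintf("%d added, %d deleted, %d modified, %d unchanged",
            counts[["added"]], counts[["deleted"]], counts[["modified"]],
            changeset$unchanged_count)
  }
  list(counts = counts, samples = samples,
       unchanged = changeset$unchanged_count, text = text)
}
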