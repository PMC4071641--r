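# Relations: the in-store representation of one version of one resource's
# data.  All cells are raw strings exactly as extracted; NA marks a field
# absent from the record (distinct from the empty string "").  A relation is
# kept in canonical form — columns in schema order, rows sorted by key — so
# version reconstruction can be compared byte-for-byte against snapshots.

new_relation <- function(data, schema, keys) {
  stopifnot(is.data.frame(data), nrow(data) == length(keys))
  rownames(data) <- NULL
  structure(
    list(data = data, schema = schema, keys = keys),
    class = "disco_relation"
  )
}

#' @export
print.disco_relation <- function(x, ...) {
  cat(sprintf(
    "<disco_relation> %d record(s), %d column(s): %s\n",
    nrow(x$data), ncol(x$data), paste(names(x$data), collapse = ", ")
  ))
  invisible(x)
}

empty_relation <- function(schema) {
  data <- as.data.frame(
    setNames(rep(list(character()), nrow(schema)), schema$name),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  new_relation(data, schema, character())
}

# Canonical serialization of one record for digest keys: `name<US>value` for
# every non-missing field, sorted by field name, joined with <RS>.  Invariant
# under column reordering; missing fields are omitted so that a missing field
# and an empty string hash differently.
canonical_record_strings <- function(data) {
  n <- nrow(data)
  if (n == 0L) return(character())
  cols <- radix_sort(names(data))
  pieces <- lapply(cols, function(cn) {
    v <- data[[cn]]
    out <- rep(NA_character_, n)
    ok <- !is.na(v)
    out[ok] <- paste0(cn, SEP_NV, v[ok])
    out
  })
  mat <- do.call(cbind, pieces)
  apply(mat, 1L, function(row) paste(row[!is.na(row)], collapse = SEP_REC))
}

# Key vector for a relation.  Keyed mode: primary-key values joined with <US>;
# rows with a missing or empty PK component get an NA key (callers quarantine
# them).  Digest mode (empty pk): SHA-256 of the canonical serialization.
relation_keys <- function(data, primary_key) {
  if (length(primary_key) > 0L) {
    if (nrow(data) == 0L) return(character())
    vals <- data[primary_key]
    bad <- Reduce(`|`, lapply(vals, function(v) is.na(v) | v == ""))
    keys <- do.call(paste, c(vals, list(sep = SEP_NV)))
    keys[bad] <- NA_character_
    keys
  } else {
    sha256_hex(canonical_record_strings(data))
  }
}

# Build a canonical relation from extracted data: align columns to the schema
# (absent columns become all-missing), compute keys, sort rows by key.
canonical_relation <- function(data, schema, primary_key) {
  n <- nrow(data)
  cols <- lapply(schema$name, function(cn) {
    if (cn %in% names(data)) as.character(data[[cn]]) else rep(NA_character_, n)
  })
  df <- as.data.frame(
    setNames(cols, schema$name),
    stringsAsFactors = FALSE, check.names = FALSE, optional = TRUE
  )
  if (n == 0L) {
    df <- as.data.frame(
      setNames(rep(list(character()), nrow(schema)), schema$name),
      stringsAsFactors = FALSE, check.names = FALSE
    )
  }
  keys <- relation_keys(df, primary_key)
  ord <- radix_order(keys)
  new_relation(df[ord, , drop = FALSE], schema, keys[ord])
}

# record <-> named character vector helpers (NA = missing field).
relation_record <- function(rel, i) {
  setNames(as.character(rel$data[i, , drop = TRUE]), names(rel$data))
}

record_to_json <- function(rec) {
  rec <- rec[!is.na(rec)]
  rec <- rec[radix_sort(names(rec))]
  as.character(jsonlite::toJSON(as.list(rec), auto_unbox = TRUE))
}

record_from_json <- function(json) {
  lst <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  setNames(vapply(lst, as.character, character(1)), names(lst))
}

# Rebuild a canonical relation from a keyed map of records under a schema.
relation_from_records <- function(records, schema, primary_key) {
  cols <- lapply(schema$name, function(cn) {
    vapply(records, function(r) {
      if (cn %in% names(r)) r[[cn]] else NA_character_
    }, character(1), USE.NAMES = FALSE)
  })
  df <- as.data.frame(
    setNames(cols, schema$name),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  if (!length(records)) {
    df <- as.data.frame(
      setNames(rep(list(character()), nrow(schema)), schema$name),
      stringsAsFactors = FALSE, check.names = FALSE
    )
  }
  canonical_relation(df, schema, primary_key)
}
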