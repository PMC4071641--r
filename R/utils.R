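# Shared plumbing: classed conditions, deterministic RNG scoping, timestamps.

# Field separators used in canonical record serializations.  US (0x1f)
# separates a name from a value, RS (0x1e) separates fields; neither occurs in
# sane tabular payloads and both survive UTF-8 round-trips.
SEP_NV <- "\x1f"
SEP_REC <- "\x1e"

disco_abort <- function(class, msg, ..., call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("disco_", class), "disco_error", "error", "condition"),
    list(message = msg, call = call, ...)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom stats runif
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# All timestamps live in one configured zone (default UTC).
disco_time <- function(x = Sys.time()) {
  as.POSIXct(x, tz = "UTC")
}

fmt_time <- function(x) format(as.POSIXct(x, tz = "UTC"), "%Y-%m-%d %H:%M:%S", tz = "UTC")

# Deterministic, locale-independent ordering for key strings.
radix_order <- function(...) order(..., method = "radix")
radix_sort <- function(x) if (length(x)) x[order(x, method = "radix")] else x

empty_issues <- function() {
  data.frame(
    kind = character(), record = character(), field = character(),
    message = character(), stringsAsFactors = FALSE
  )
}

new_issue <- function(kind, record, field, message) {
  stopifnot(kind %in% c(
    "data_type_error", "duplicate_key", "field_overflow", "incomplete_import"
  ))
  data.frame(
    kind = kind, record = as.character(record),
    field = if (is.null(field)) NA_character_ else as.character(field),
    message = message, stringsAsFactors = FALSE
  )
}

bind_issues <- function(...) {
  parts <- Filter(function(x) !is.null(x) && nrow(x) > 0, list(...))
  if (!length(parts)) return(empty_issues())
  do.call(rbind, c(parts, list(make.row.names = FALSE)))
}
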