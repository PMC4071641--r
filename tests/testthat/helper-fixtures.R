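# Shared fixtures, built in code at test time.
#
# The "toy neuron" fixture mirrors the worked example used throughout the
# module tests: version 1 holds rows {1, 2, 3}; version 2 edits row 2's
# brain_region ("dentate gyrus" -> "DG"), deletes row 3 and adds row 4.

toy_schema <- function() {
  data.frame(
    name = c("id", "neuron_name", "brain_region"),
    type = c("integer", "text", "text"),
    max_length = NA_integer_,
    content_kind = c("value", "term", "term"),
    relationship = NA_character_,
    stringsAsFactors = FALSE
  )
}

toy_csv_v1 <- function() {
  c("id,neuron_name,brain_region",
    "1,granule cell,dentate gyrus",
    "2,pyramidal neuron,dentate gyrus",
    "3,Purkinje cell,cerebellum")
}

toy_csv_v2 <- function() {
  c("id,neuron_name,brain_region",
    "1,granule cell,dentate gyrus",
    "2,pyramidal neuron,DG",
    "4,mitral cell,olfactory bulb")
}

toy_script_json <- function(source_file = "source.csv", pk = list("id"),
                            max_length = NULL) {
  fields <- list(
    list(name = "id", type = "integer", content_kind = "value"),
    list(name = "neuron_name", type = "text", content_kind = "term"),
    list(name = "brain_region", type = "text", content_kind = "term")
  )
  if (!is.null(max_length)) fields[[2]]$max_length <- max_length
  jsonlite::toJSON(list(
    resource = "nif-0000-0001", table = "neurons",
    sources = list(list(locator = source_file, format = "csv",
                        record_selector = "header",
                        extractors = list(id = "id", neuron_name = "neuron_name",
                                          brain_region = "brain_region"))),
    fields = fields,
    primary_key = pk,
    link_template = "http://example.org/neuron/{id}"
  ), auto_unbox = TRUE, pretty = TRUE)
}

# Writes a complete toy resource into a fresh temp dir; returns paths.
toy_fixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                        csv = toy_csv_v1(), pk = list("id"),
                        nif_id = "nif-0000-0001", name = "ToyNeuronDB") {
  writeLines(csv, file.path(dir, "source.csv"))
  writeLines(toy_script_json(pk = pk), file.path(dir, "script.json"))
  writeLines(c(
    sprintf('<resource id="%s" name="%s">', nif_id, name),
    '  <contact name="Ada Curator" email="ada@example.org"/>',
    '  <service type="interop" script="script.json"/>',
    '  <description>Toy neuron database</description>',
    '</resource>'
  ), file.path(dir, "info.xml"))
  list(dir = dir, nif_id = nif_id, name = name,
       source = file.path(dir, "source.csv"),
       script = file.path(dir, "script.json"),
       info = file.path(dir, "info.xml"))
}

toy_relation <- function(csv = toy_csv_v1(), pk = "id") {
  df <- utils::read.csv(text = csv, colClasses = "character",
                        na.strings = character(0), check.names = FALSE)
  disco:::canonical_relation(df, toy_schema(), pk)
}

# Independent brute-force diff oracle: nested loops, no shared code with
# diff_relations.  Keys are recomputed naively from the primary key columns.
oracle_diff <- function(staged_df, prod_df, pk) {
  key_of <- function(df, i) paste(unlist(df[i, pk, drop = FALSE]), collapse = "\x1f")
  skeys <- vapply(seq_len(nrow(staged_df)), function(i) key_of(staged_df, i), "")
  pkeys <- vapply(seq_len(nrow(prod_df)), function(i) key_of(prod_df, i), "")
  added <- character(); deleted <- character(); modified <- list(); unchanged <- 0L
  for (i in seq_along(skeys)) {
    j <- which(pkeys == skeys[i])
    if (!length(j)) { added <- c(added, skeys[i]); next }
    cols <- union(names(staged_df), names(prod_df))
    ch <- list()
    for (cn in cols) {
      sv <- if (cn %in% names(staged_df)) staged_df[[cn]][i] else NA_character_
      pv <- if (cn %in% names(prod_df)) prod_df[[cn]][j] else NA_character_
      same <- (is.na(sv) && is.na(pv)) || (!is.na(sv) && !is.na(pv) && sv == pv)
      if (!same) ch[[length(ch) + 1L]] <- data.frame(
        field = cn, old = pv, new = sv, stringsAsFactors = FALSE)
    }
    if (length(ch)) modified[[skeys[i]]] <- do.call(rbind, c(ch, list(make.row.names = FALSE)))
    else unchanged <- unchanged + 1L
  }
  for (j in seq_along(pkeys)) {
    if (!any(skeys == pkeys[j])) deleted <- c(deleted, pkeys[j])
  }
  structure(list(added = sort(added, method = "radix"),
                 deleted = sort(deleted, method = "radix"),
                 modified = modified[sort(names(modified), method = "radix")],
                 unchanged_count = unchanged),
            class = "disco_changeset")
}

# Register, harvest and approve one version of a bundle in a fresh store.
promote_bundle <- function(store, bundle, time = as.POSIXct("2013-06-01", tz = "UTC"),
                           override = TRUE) {
  if (is.null(store$resources[[bundle$nif_id]])) {
    register_resource(store, bundle$info_path, time = time)
  }
  run_update(store, bundle$nif_id, time = time)
  approve(store, bundle$nif_id, override = override, time = time)
}

fixed_time <- function(day, hhmm = "12:00") {
  as.POSIXct(paste(day, hhmm), tz = "UTC")
}
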