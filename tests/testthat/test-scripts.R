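test_that("parse_script validates structure and cross-references", {
  fx <- toy_fixture()
  sc <- parse_script(fx$script)
  expect_s3_class(sc, "disco_script")
  expect_equal(nrow(sc$schema), 3L)
  expect_equal(sc$primary_key, "id")
  expect_equal(sc$link_template, "http://example.org/neuron/{id}")

  rewrite <- function(mutate) {
    doc <- jsonlite::fromJSON(fx$script, simplifyVector = FALSE)
    doc <- mutate(doc)
    p <- tempfile(fileext = ".json")
    writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null"), p)
    p
  }
  # PK naming an undeclared field
  p <- rewrite(function(d) { d$primary_key <- list("idd"); d })
  err <- expect_error(parse_script(p), class = "disco_validation")
  expect_match(conditionMessage(err), "idd")
  # duplicate field
  p <- rewrite(function(d) { d$fields[[4]] <- d$fields[[1]]; d })
  expect_error(parse_script(p), class = "disco_validation")
  # unknown format tag
  p <- rewrite(function(d) { d$sources[[1]]$format <- "xlsx"; d })
  expect_error(parse_script(p), class = "disco_validation")
  # link template placeholder must be declared
  p <- rewrite(function(d) { d$link_template <- "http://x/{nope}"; d })
  expect_error(parse_script(p), class = "disco_validation")
  # max_length only on text
  p <- rewrite(function(d) { d$fields[[1]]$max_length <- 5; d })
  expect_error(parse_script(p), class = "disco_validation")
})

test_that("fetch_source returns bytes unmodified with metadata", {
  fx <- toy_fixture()
  sc <- parse_script(fx$script)
  f <- fetch_source(sc$sources[[1]], sc$dir)
  expect_identical(f$content, readBin(fx$source, "raw", file.size(fx$source)))
  expect_equal(f$size, file.size(fx$source))
  f2 <- fetch_source(sc$sources[[1]], sc$dir)
  expect_equal(f2$size, f$size)

  unlink(fx$source)
  err <- expect_error(fetch_source(sc$sources[[1]], sc$dir), class = "disco_fetch")
  expect_equal(err$reason, "not_found")
  expect_match(err$locator, "source.csv")
})

test_that("extraction is deterministic and equivalent across formats", {
  fx <- toy_fixture()
  sc <- parse_script(fx$script)
  csv_recs <- extract_records(sc)
  expect_equal(nrow(csv_recs), 3L)
  expect_identical(csv_recs, extract_records(sc)) # deterministic

  base <- utils::read.csv(text = toy_csv_v1(), colClasses = "character",
                          na.strings = character(0))
  # TSV variant
  tsv_path <- file.path(fx$dir, "source.tsv")
  writeLines(c(paste(names(base), collapse = "\t"),
               apply(base, 1, paste, collapse = "\t")), tsv_path)
  # JSON variant (records nested under /data/rows)
  json_path <- file.path(fx$dir, "source.json")
  writeLines(as.character(jsonlite::toJSON(list(data = list(rows =
    lapply(seq_len(nrow(base)), function(i) as.list(base[i, ])))),
    auto_unbox = TRUE)), json_path)
  # XML variant with one attribute extractor
  xml_path <- file.path(fx$dir, "source.xml")
  writeLines(c("<table>", vapply(seq_len(nrow(base)), function(i) {
    sprintf('<row id="%s"><neuron_name>%s</neuron_name><brain_region>%s</brain_region></row>',
            base$id[i], base$neuron_name[i], base$brain_region[i])
  }, ""), "</table>"), xml_path)

  variant <- function(locator, format, selector, extractors) {
    doc <- jsonlite::fromJSON(fx$script, simplifyVector = FALSE)
    doc$sources[[1]]$locator <- locator
    doc$sources[[1]]$format <- format
    doc$sources[[1]]$record_selector <- selector
    doc$sources[[1]]$extractors <- extractors
    p <- file.path(fx$dir, paste0("script_", format, ".json"))
    writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE), p)
    extract_records(parse_script(p))
  }
  ident <- list(id = "id", neuron_name = "neuron_name", brain_region = "brain_region")
  expect_identical(variant("source.tsv", "tsv", "header", ident), csv_recs)
  expect_identical(variant("source.json", "json", "/data/rows", ident), csv_recs)
  expect_identical(
    variant("source.xml", "xml", "row",
            list(id = "@id", neuron_name = "neuron_name",
                 brain_region = "brain_region")),
    csv_recs
  )
})

test_that("a vanished column raises an extraction error naming it", {
  fx <- toy_fixture(csv = c("id,neuron_name", "1,granule cell"))
  sc <- parse_script(fx$script)
  err <- expect_error(extract_records(sc), class = "disco_extraction")
  expect_match(conditionMessage(err), "brain_region")
  expect_equal(err$selector, "brain_region")
})

test_that("csv quoting is resolved and values stay untrimmed", {
  fx <- toy_fixture(csv = c(
    "id,neuron_name,brain_region",
    '1,"has, comma","has ""quote"""',
    "2,  padded  ,cerebellum"
  ))
  recs <- extract_records(parse_script(fx$script))
  expect_equal(recs$neuron_name, c("has, comma", "  padded  "))
  expect_equal(recs$brain_region[1], 'has "quote"')
})

test_that("coercion collects issues without truncating or throwing", {
  fx <- toy_fixture(csv = c(
    "id,neuron_name,brain_region",
    "55,925,x",        # '925' lands in neuron_name; craft real case below
    "2,ok,cerebellum"
  ))
  sc <- parse_script(fx$script)
  # comma-grouped integer is a data_type_error, never silently parsed
  recs <- data.frame(id = c("55,925", "2"), neuron_name = c("a", "b"),
                     brain_region = c("x", "y"), stringsAsFactors = FALSE)
  out <- coerce_records(sc, recs)
  expect_equal(out$issues$kind, "data_type_error")
  expect_equal(out$issues$field, "id")
  expect_identical(out$records, recs) # raw values untouched

  # overflow detected, value reported but not truncated
  p <- tempfile(fileext = ".json")
  writeLines(toy_script_json(max_length = 10), p)
  sc10 <- parse_script(p)
  recs2 <- data.frame(id = "1", neuron_name = "abcdefghijkl",
                      brain_region = "x", stringsAsFactors = FALSE)
  out2 <- coerce_records(sc10, recs2)
  expect_equal(out2$issues$kind, "field_overflow")
  expect_equal(nchar(out2$records$neuron_name), 12L)
})

test_that("date dialect accepts ISO-8601 and M/D/YY with 1970 pivot", {
  doc <- jsonlite::fromJSON(toy_script_json(), simplifyVector = FALSE)
  doc$fields[[3]] <- list(name = "brain_region", type = "date",
                          content_kind = "value")
  p <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null"), p)
  sc <- parse_script(p)
  recs <- data.frame(id = c("1", "2", "3", "4"), neuron_name = "n",
                     brain_region = c("4/4/13", "2013-12-04", "12/31/69", "4/31/13"),
                     stringsAsFactors = FALSE)
  out <- coerce_records(sc, recs)
  expect_equal(out$typed$brain_region[1], "2013-04-04")
  expect_equal(out$typed$brain_region[2], "2013-12-04")
  expect_equal(out$typed$brain_region[3], "2069-12-31") # 69 -> 2069 (pivot 1970)
  expect_equal(out$issues$record, "row:4") # April 31st is not a date
})

test_that("drill-down links substitute declared placeholders", {
  fx <- toy_fixture()
  sc <- parse_script(fx$script)
  expect_equal(drilldown_link(sc, c(id = "7")), "http://example.org/neuron/7")
})
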