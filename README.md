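# disco

Scheduled harvest, versioning and curated release of federated tabular data.

## The problem

Federated biomedical warehouses — the motivating setting is a neuroscience
data federation — copy selected data elements out of dozens to hundreds of
independently run resources into one searchable store. Those resources keep
changing underneath: rows are added, edited and deleted; columns appear, get
renamed and vanish; uploads arrive dirty (type errors, duplicate keys,
oversize text, truncated downloads). `disco` is the warehouse-side engine for
that loop:

* **registry** — resources described by XML information files (id, name,
  contacts, services), imported and listed/searched/paged;
* **harvest scripts** — declarative JSON templates naming sources (CSV, TSV,
  XML, JSON), per-field extractors, declared types, the primary key, and a
  per-record drill-down link template;
* **staging + diff** — extracted records get identity (primary-key tuple, or
  a SHA-256 whole-record digest for unstructured resources) and are diffed
  against production into `added` / `deleted` / `modified` / unchanged, by
  exact raw-string comparison;
* **version store** — production always holds the current version; reverse
  data deltas (old values) and forward schema deltas make every previous
  version reconstructible byte-for-byte, with a full-copy fallback when a
  promotion touches more than half the rows
  (`(|A|+|D|+|M|)/max(|prod|,1) > 0.5`);
* **lifecycle** — new data is held *pending* until a curator approves
  (immediately or in batches), flags a problem, or the run proves the data
  unchanged; all import issues block approval unless overridden; everything
  is audit-logged;
* **views** — materialized union-concatenations over one or more resources
  with provenance columns, a beta channel rebuilt on member promotions and a
  production channel moved only by explicit approval;
* **scheduler** — weekly / bi-weekly / monthly / ad-hoc cadences with
  calendar clamping (day 31 → last day of month), an on-demand tick, and
  size/mtime change probing;
* **concept mapper** — tiered lexical matching of term-valued columns
  against a loadable vocabulary (exact > normalized > synonym > normalized
  synonym; no fuzzy matching);
* **synth** — a deterministic generator of evolving synthetic resources with
  constructive ground-truth changesets, used as the independent oracle for
  the whole pipeline.

## Worked example

```r
library(disco)

dir <- tempfile(); dir.create(dir)
writeLines(c("id,neuron_name,brain_region",
             "1,granule cell,dentate gyrus",
             "2,pyramidal neuron,dentate gyrus",
             "3,Purkinje cell,cerebellum"), file.path(dir, "source.csv"))
writeLines('{
  "resource": "nif-0000-0001", "table": "neurons",
  "sources": [{"locator": "source.csv", "format": "csv",
               "record_selector": "header",
               "extractors": {"id": "id", "neuron_name": "neuron_name",
                              "brain_region": "brain_region"}}],
  "fields": [{"name": "id", "type": "integer"},
             {"name": "neuron_name", "type": "text", "content_kind": "term"},
             {"name": "brain_region", "type": "text", "content_kind": "term"}],
  "primary_key": ["id"],
  "link_template": "http://example.org/neuron/{id}"
}', file.path(dir, "script.json"))
writeLines('<resource id="nif-0000-0001" name="ToyNeuronDB">
  <service type="interop" script="script.json"/>
</resource>', file.path(dir, "info.xml"))

s <- disco_store()
register_resource(s, file.path(dir, "info.xml"))
run_update(s, "nif-0000-0001")
approve(s, "nif-0000-0001")

# the resource evolves: row 2 edited, row 3 gone, row 4 new
writeLines(c("id,neuron_name,brain_region",
             "1,granule cell,dentate gyrus",
             "2,pyramidal neuron,DG",
             "4,mitral cell,olfactory bulb"), file.path(dir, "source.csv"))
run_update(s, "nif-0000-0001")
review(s, "nif-0000-0001")$summary$text
#> [1] "1 added, 1 deleted, 1 modified, 1 unchanged"
approve(s, "nif-0000-0001")

# 3 of 3 production rows changed -> change fraction 1.0 > 0.5: version 1 was
# kept as a full snapshot rather than deltas, and reconstructs exactly
storage_report(s, "nif-0000-0001")[, c("version", "n_deltas", "snapshot")]
#>   version n_deltas snapshot
#> 1       1        0     TRUE
#> 2       2        0    FALSE
reconstruct_version(s, "nif-0000-0001", 1)$data$brain_region
#> [1] "dentate gyrus" "dentate gyrus" "cerebellum"
```

The first `review()` line means: against production, the new upload adds one
record (id 4), deletes one (id 3), modifies one (id 2, `brain_region`
`"dentate gyrus"` → `"DG"`) and leaves one untouched.

Command-line equivalent (state persists in `--store`):

```sh
disco="Rscript $(Rscript -e 'cat(system.file("cli","disco",package="disco"))')"
$disco --store st.json register info.xml
$disco --store st.json harvest nif-0000-0001
$disco --store st.json approve nif-0000-0001
$disco --store st.json dashboard sources
$disco --store st.json reconstruct nif-0000-0001 --version 1 --out v1.csv
```

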