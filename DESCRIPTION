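Package: disco
Title: Scheduled Harvest, Versioning and Curated Release of Federated Tabular Data
Version: 0.9.0
Authors@R:
    person("DISCO", "Maintainers", email = "disco@example.org", role = c("aut", "cre"))
Description: An extensible data-aggregation engine for federated warehouses of
    tabular biomedical data. Resources are registered from XML metadata files,
    harvested on a schedule through declarative extraction scripts (CSV, TSV,
    XML and JSON sources), staged into temporary relations, diffed against the
    production version by primary key or whole-record hash, and released
    through a curated pending/approved/production lifecycle. Historical
    versions are kept as reverse data deltas and forward schema deltas in an
    entity-attribute-value store with a full-copy fallback for large changes,
    so any prior version can be reconstructed exactly. Materialized
    cross-resource views with beta and production channels, lexical concept
    mapping against a loadable vocabulary, calendar-based scheduling with
    change probing, command-line dashboards, and a deterministic generator of
    evolving synthetic resources with constructive ground-truth changesets
    complete the toolkit.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
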