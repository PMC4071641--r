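---
title: "Harvest, versioning and curated release: the disco data model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harvest, versioning and curated release: the disco data model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A federated warehouse of biomedical data — the setting this package targets
is a neuroscience data federation, but nothing is neuroscience-specific —
copies *selected* data elements out of many independently run resources into
one searchable store, while each resource keeps evolving on its own schedule.
Three things make this hard in practice:

1. **Resources change silently.** Rows are added, edited and deleted; columns
   appear, vanish and get renamed; there is no push notification. The
   warehouse must detect change itself, classify it, and keep enough history
   to reconstruct what it held at any earlier point.
2. **Upstream data is dirty.** Type errors, duplicate keys, oversized text
   and half-finished downloads are routine. A curated warehouse cannot let
   those flow straight into production.
3. **Integrated views multiply the blast radius.** A view combining several
   resources must be rebuilt when any member changes, but its deployed
   version must only move under curator control.

`disco` models the full loop: registration → scheduled harvest → staging and
diff → curated approval → reverse-delta versioning → view cascade, plus
lexical concept mapping and dashboards, all driven through R functions or the
bundled CLI.

## Record identity and the changeset

Change detection needs record identity across versions. Two modes exist, per
resource:

* **Keyed mode** — the harvest script declares a primary key; the identity is
  the tuple of raw key values. Records sharing a key across versions with
  differing fields are *modified*.
* **Digest mode** — for unstructured resources with no usable key, identity
  is a SHA-256 digest of the whole record, computed over `name⟨US⟩value`
  pairs sorted by field name and joined with `⟨RS⟩` (missing fields omitted).
  The digest is invariant under column reordering, and a missing field hashes
  differently from an empty string. In digest mode any edit changes the key,
  so a modification surfaces as one deletion plus one addition and the
  `modified` class is structurally empty.

The changeset between a staged version and production partitions records into
`added`, `deleted`, `modified` (with per-field old/new values) and an
unchanged count. Field comparison is **exact byte equality on raw strings**:
the warehouse's job is to mirror the resource faithfully, so `"1.0"` vs `"1"`
is a genuine upstream change, and comparisons are case-sensitive. Missing
(`NA`) and empty (`""`) are distinct states throughout. Comparison runs over
the union of both versions' columns, which is what lets structural change
(column added/dropped/renamed) fall out naturally as per-record field
changes.

## Reverse deltas, forward schema deltas, and the full-copy fallback

Production relations always hold the *current* version; no delta is ever
applied to serve a current-version read. At each promotion the store writes
the reverse edit script that turns the new version back into the old one:

* one `set_field` row per modified field, carrying the **old** value;
* one `restore_record` row per deleted record, carrying the full old record;
* one `remove_record` row per added record.

Schema changes travel the other way, as forward deltas (`add_column`,
`drop_column`, `rename_column`, `change_type`) replayed from version 1 to
obtain the schema in force at any version. Renames are recorded **only when
declared** in the updated harvest script — they are never inferred from data,
because a drop-plus-add and a rename are indistinguishable byte-wise and
guessing would corrupt history.

When a promotion touches more than half of production —
`(|added|+|deleted|+|modified|) / max(|production|, 1) > 0.5` — a full
snapshot of the old version is stored *instead of* deltas. The 0.5 threshold
is a design choice balancing storage against reconstruction cost: below it a
delta chain is cheaper than a copy; above it the delta set approaches the
size of the data anyway and a snapshot caps the cost of later
reconstructions. Reconstruction starts from production or the nearest
snapshot at-or-above the target version, applies delta sets downward, then
projects onto the target version's schema; the result is byte-identical to
the relation as it stood (canonical form: columns in schema order, rows
sorted by key).

Version numbers are dense integers from 1 per resource; history is strictly
linear (no branching). Promotion is atomic — all bookkeeping is computed
before any store field is assigned — and refuses stale changesets.

## The curation lifecycle

`run_update()` executes fetch → extract → coerce → stage → diff. An empty
changeset is recorded as an `unchanged` run and the temporary relation is
discarded; otherwise the staged version is held `pending` with a change
summary. The state machine is deliberately small:

* `pending → approved → production` (immediate) or
  `pending → scheduled → production` (batch, via `flush_batch()`);
* `pending → problem` with a persisted note; the staged relation is retained
  for debugging and a later run supersedes it;
* at most one version per resource is ever in flight
  (`pending`/`approved`/`scheduled`); a new run while one is in flight is
  refused rather than queued, keeping the curator's view unambiguous.

All four import-issue kinds (`data_type_error`, `duplicate_key`,
`field_overflow`, `incomplete_import`) block approval by default, with a
logged override. This is the conservative reading of a workflow in which
problems are recorded and resolved by people: nothing dirty reaches
production implicitly. Duplicate keys keep the first occurrence and
quarantine the rest — de-duplication is a curator decision, not an automatic
merge. Every transition appends to an audit log that is never rewritten.

## Views

A view is a union-concatenation of per-member projections onto a shared
column list, with constants available where a member lacks a field, and two
provenance columns (`.source`, `.key`) resolving every row to exactly one
production record. Equi-joins are deliberately excluded: the modelled
operation is copying data elements from member tables into a new table, and
row conservation (`|view| = Σ |members|`) is the invariant the tests lean on.
Views read only production member versions. Each view has a beta channel,
rebuilt automatically when a member is promoted, and a production channel
that moves only through `approve_view()`.

## Scheduling

Four frequencies: weekly (ISO day-of-week anchor), bi-weekly (every 14 days
from an anchor date — the simplest reading of "bi-weekly", not
"1st and 3rd week"), monthly (day-of-month, with days 29–31 clamped to the
month's last day), and ad hoc (manual trigger only). All timestamps live in
one configured zone, default UTC, at minute resolution. `next_run()` returns
the smallest matching instant strictly after its argument; the test suite
checks it against a brute-force minute-enumeration oracle over a three-year
window. The engine ticks on demand (`scheduler_tick()`), never as a daemon,
and runs at most one update per resource at a time. Probing
(`probe_source()`) compares source size/mtime against the last fetch and is
advisory only: it may queue an early ad-hoc run but never suppresses a
scheduled one. Failed runs simply remain due.

## Concept mapping

Term-valued columns (declared `content_kind = "term"` in the script) are
mapped against a loadable vocabulary through a strictly lexical tier ladder:
exact label > normalized label > exact synonym > normalized synonym, where
normalization lowercases, trims, collapses internal whitespace and strips
surrounding punctuation. There is no stemming and no edit-distance matching:
mapping in this setting is semi-automated, and a wrong automatic match is
worse than an unmapped term, so typos land in the curator-facing unmapped
report (most frequent first). Any tab-delimited vocabulary with `term_id`,
`label`, pipe-separated `synonyms` and `category` columns works; no specific
ontology is bundled.

## The synthetic-resource generator

`generate_resource()` / `evolve_resource()` / `generate_history()` emulate
the upstream world: CSV resources that gain, edit and lose rows and columns
over time, with value pools drawn from neuroanatomy-flavoured terms plus, in
stress mode, CSV-hostile content (embedded commas and quotes, unicode, empty
and padded strings, oversize values against `max_length` fields). Defaults —
8 rows at version 1, 1–3 events per transition weighted toward row-level
change with occasional structural change — reflect the modest per-resource
tables and frequent small updates typical of the setting; they are fixed
once here and not tuned against test outcomes.

Two properties make the generator a trustworthy oracle:

* **Constructive ground truth.** The expected changeset of each transition is
  built from the events themselves (only touched rows are ever examined),
  never by diffing relations — so the generator and the diff engine cannot
  share a bug.
* **Retained snapshots.** Every version's canonical relation is kept, giving
  the reconstruction round-trip test an independent byte-level target.

In `generate_history()` events are applied in the fixed order delete < edit <
structural < add with counts clamped to table size, so every drawn event
leaves a visible mark and version numbers stay dense when a history is
replayed through the real pipeline. Break mode deliberately leaves the
harvest script stale after a structural change, reproducing the
"ingestion breaks" failure the lifecycle must survive.

What a green test does **not** establish: the generator writes clean local
CSV files, so network behaviour (latency, timeouts, auth), non-UTF-8
encodings, JavaScript-rendered pages and multi-gigabyte tables are all out of
its world; format breadth beyond CSV/TSV/XML/JSON is untested by
construction.

## Numerical and representational choices

* Digest: SHA-256 (compiled, FIPS 180-4). Collision risk is negligible at
  warehouse scale; only determinism and collision resistance are relied on.
* Dates: ISO-8601 plus `M/D/YY` with pivot year 1970 (`"4/4/13"` →
  2013-04-04, `"12/31/69"` → 2069). Thousands separators in numerics are
  rejected, never silently parsed — locale guessing hides upstream errors.
* Ordering: all key orderings use byte-wise (radix) sort for locale
  independence; ties in listings break by resource id.
* Storage: the reference store is an in-memory environment with lossless
  JSON serialization (`store_save()`/`store_load()`), standing in for an
  embedded SQL database; no R SQLite driver is assumed. The EAV layout (one
  delta table, one schema-delta list, one snapshot map per resource) is
  engine-agnostic and all mutations funnel through package functions.
* The empty changeset refuses promotion upstream (recorded as `unchanged`)
  rather than minting identical versions.

## Known limitations

* No fuzzy record matching across versions; a changed primary key is a
  delete-plus-add by design.
* No multi-curator roles, no distribution across machines, linear history
  only.
* Remote locators are fetched naively (no retries, no conditional GET);
  probing requires a local file path to stat.
* Reconstruction cost grows with chain length between snapshots; the 0.5
  full-copy threshold bounds but does not eliminate it.
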