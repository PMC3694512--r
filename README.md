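# ehrest

RESTful versioned storage, querying and messaging for archetype-based
electronic health records — a desk-scale, dependency-light R implementation of
the service architecture used by openEHR-style record systems.

## The problem

Archetype-based EHR systems separate a small, stable *reference model* (typed
tree nodes: quantities, coded text, timestamps) from clinician-authored
*archetypes and templates* that constrain those trees into clinical documents
(compositions). Storing such records safely requires append-only version
control — every change is an atomic, audited **contribution** of immutable
**versions**, and deletion only ever adds a version marked deleted — while
retrieving them requires path addressing into document trees and a
storage-independent query language (AQL). `ehrest` implements that whole
service surface behind HTTP semantics:

* **Version store** — append-only versioned objects per record; atomic
  contribution commits; lookup by exact uid
  (`object_id::creating_system_id::version_tree_id`), by `@latest_version`,
  or by `@{timestamp}`; a write-through metadata cache (latest modification
  time + contribution id) per record.
* **AQL subset engine** — `SELECT`ed paths, `FROM EHR` with chained
  `CONTAINS` archetype predicates, `WHERE` comparisons / `MATCHES` code sets /
  `AND`/`OR`, and `$parameters`; translated through a pluggable backend
  registry (the native in-memory backend ships) into plans with a printable
  debug form. Only latest, non-deleted compositions are visible to queries.
* **Content-addressed query protocol** — queries are POSTed once, stored
  immutably under the SHA-1 of their text plus canonicalized (alphabetically
  sorted JSON) static parameters, and re-run via a 303 redirect to
  `/ehr:{ehr_id}/q/AQL/{sha}/?...`, so every run is an ordinary cacheable GET
  that lands in the access log. Underscore-prefixed POST parameters are
  dynamic and travel in the redirect URI; `debug=true` returns the plan text.
* **HTTP caching** — immutable versions get `Cache-Control: private` with a
  high max-age and no ETag; statics are `public`; mutable record views carry
  `ETag = "latest contribution id"` and `Last-Modified`, so a matching
  `If-None-Match` answers **304 without touching the store** and a stale
  `If-Match` write is refused with **412**.
* **Contribution builder** — a per-committer, per-record editing workspace
  (`/cb/{committer}/{ehr}/{build}/`, the first build per patient named
  `default`) with six document-sourcing commands, validation reports, and
  all-or-nothing commit (201 + contribution id) that destroys the build.
* **Three-level validation and skeletons** — reference-model conformance,
  archetype constraints, and narrowing template constraints from plain-JSON
  constraint documents; min/max instance-skeleton generation (midpoint values
  for range-constrained quantities without defaults).
* **Opaque bookmarks** — `/bm/{6-char id}` short links that reveal nothing of
  the target URI, resolved by 303 redirect with more/none/less change
  detection against a creation-time version snapshot and a
  resolve/warn/block policy.
* **Trigger bus** — exactly one identifier-only commit event per
  contribution, published to `/contributions/{ehr_id}` and delivered to
  wildcard-matched subscriptions (`*` one segment, `#` any tail); STOMP-style
  text frames at the wire boundary. A bundled replication subscriber turns
  the event stream into a byte-identical replica store for lagged
  population-wide (`/multi/`) reads.
* **Synthetic populations** — a deterministic generator of multi-patient
  blood-pressure histories (creations, amendments, logical deletions) plus
  the brute-force scan oracle the query engine is verified against.

## Worked example

```r
library(ehrest)
set.seed(42)
srv <- ehr_server(host = "test2.eee.mi.imt.liu.se")
ehr_id <- srv$store$create_ehr("12344321")

# commit a blood-pressure recording through the contribution builder
srv$dispatch("POST", "/cb/dr_who/12344321/new-cb-id/")
srv$dispatch("POST", "/cb/dr_who/12344321/default/new/from-form/",
             body = list(data = composition_to_xml(
               make_bp_composition(191.5, 99, "2005-08-02T04:00:00"))))
r <- srv$dispatch("POST", "/cb/dr_who/12344321/default/commit/")
cat("commit:", r$status, r$body, "\n")

# register the canonical query (systolic > 185) and follow the redirect
r <- srv$dispatch("POST", "/ehr:12344321/q/AQL/",
                  body = list(q = bp_aql(185, "single")))
cat("redirect:", r$status, r$headers[["Location"]], "\n")
res <- srv$dispatch("GET", r$headers[["Location"]],
                    headers = list(Accept = "application/json"))
print(as.data.frame(parse_resultset(res$body, "json")))
```

prints

```
commit: 201 0fe76384-d391-e288a34ec431
redirect: 303 /ehr:12344321/q/AQL/b219b0c13fef5916bcda144cc3f0468d2761403c/
  systolic diastolic                                                   .uid
1    191.5        99 b729097d-ae59-73351cb43171::test2.eee.mi.imt.liu.se::1
```

The `201` carries the new contribution's id; the `303` Location is the
stored query's permanent, content-addressed URI (its 40-hex SHA-1 names the
query text plus static parameters, so re-POSTing the identical query lands on
the same URI). The result row reports the one systolic reading above
185 mm[Hg] together with its provenance — the exact version uid the value
came from, fetchable at `/ehr:12344321/{uid}`.

## Package layout

* `R/` — reference-model core, version store, AQL engine, query registry,
  REST facade, contribution builder, validation/skeletons, bookmarks,
  trigger bus, synthetic generator.
* `inst/extdata/` — shipped blood-pressure archetype + narrowing template
  (JSON constraint documents) and the result-set XML schema.
* `vignettes/archetype-ehr-services.Rmd` — the methods vignette: data model,
  protocol semantics, design decisions and limitations.
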