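---
title: "Archetype-based EHR services over REST semantics: data model, protocols and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Archetype-based EHR services over REST semantics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehrest)
```

# The data model and its assumptions

Two-level modelling separates a small technical reference model from the
clinical content definitions layered on top of it. `ehrest` implements a
deliberately reduced reference model: a document node (`rm_node`) has an
attribute name, an optional archetype/node id, and either an ordered list of
children or exactly one typed leaf value — a quantity (magnitude + units),
coded text (code + terminology + label), plain text, or an ISO 8601
timestamp. Compositions are the roots of such trees; every node is
addressable by a path of `attribute[predicate]` segments, and predicates are
opaque tokens compared by string equality. This is a simplification of the
full openEHR reference model (no ENTRY subtypes, participations, or the rich
name/value predicate grammar); it is the smallest model on which the
versioning, querying, validation and caching semantics can be expressed and
tested end to end.

Assumptions baked into the model:

* **Document order matters** and is preserved by both serializations (the XML
  dialect and its JSON mirror round-trip losslessly, by construction and by
  property test).
* **Zoneless timestamps are UTC.** Example instants in the interface (e.g.
  `@2005-08-02T04:30:00`) carry no zone; reading them as UTC makes at-time
  lookups reproducible across machines.
* **A path with a trailing slash equals the same path without it.** The URI
  grammar prints sub-paths with trailing slashes; nothing in the semantics
  distinguishes the two, so the parser normalizes.

# Versioning semantics

All writes are **contributions**: atomic change sets of one or more versions
against one record. A creation mints a fresh object id with version tree id
`"1"`; amendments, logical deletions and attestations must name the *current
latest* version of their object as `preceding_uid` and receive the next trunk
tree id. Anything else is a stale-update conflict and the whole contribution
is rejected — the store state before a failed commit is byte-identical to the
state after, which the tests check by injecting validation failures at every
position of a multi-version commit.

The store is append-only in a strong, checkable sense: its serialized state
is a newline-delimited JSON commit log, and every mutation appends lines
without touching earlier ones, so "state before is a prefix of state after"
is asserted directly on bytes. Logical deletion appends a data-less version
marked `deleted`; earlier versions of the object remain fetchable forever.
Branch-form tree ids (`1.2.1`) parse and order correctly
(segment-by-segment), but branch creation is not implemented: this package
only ever mints trunk versions, treating branching as a capability of the
identifier scheme rather than of this store.

Two ordering decisions were genuinely open and are fixed as follows:

* **Commit sequence, not timestamp, is the authoritative order.** Timestamps
  are advisory (they drive `@{time}` lookups); paging and `@latest_version`
  follow the monotone commit counter, which is immune to clock skew and ties.
* **`all_version_ids` returns commit order**, which equals tree-id order for
  trunk-only histories.

Incomplete-lifecycle versions are returned by ordinary reads with their
lifecycle flag exposed; hiding unfinished work from clinical reads is a
policy decision left to callers, and trigger subscribers can filter on the
flag.

# The query pipeline

The AQL subset covers `SELECT` with aliased paths and `AS` labels, `FROM EHR`
with an optional `[ehr_id=$param]` predicate, a linear chain of `CONTAINS
<CLASS> alias [archetype-id]` steps, and `WHERE` with `=, !=, <, <=, >, >=`,
`MATCHES {codes}`, `AND`/`OR` and parentheses. `TOP`, `ORDER BY` and
`TIMEWINDOW` are not implemented: the subset is the minimum that expresses
the canonical clinical scenario (all blood pressures with a systolic value
above a threshold, per record or population-wide). Numeric comparisons apply
to quantity magnitudes; string comparisons are exact; `MATCHES` is code-set
membership on coded text. Comparing a numeric literal against a text value
(or vice versa) is an error rather than `FALSE` — silent type coercion in a
clinical query language hides authoring mistakes. An absent path value simply
fails the predicate and the row is dropped.

Parsing yields an AST; a registered backend translates it into a plan.
Translation is deterministic (the same AST yields a byte-identical printable
plan, which is what `debug=true` returns), and only the `"native"` in-memory
backend ships — the registry exists so translators targeting other storage
engines can be added without touching the parser. Execution sees exactly the
latest, non-deleted composition of every object; at-time querying is out of
scope. Row order is record id, then object commit order, then document order
of containment bindings.

Correctness rests on a dual route: an independent brute-force oracle
(`oracle_query()`) rescans every latest composition with the plain recursive
path resolver and a hand-built predicate, and the acceptance suite compares
engine and oracle row multisets over 100 random (query, population) pairs.

## The stored-query protocol

Queries are registered by POST, validated by the parser (a syntax error is a
400 and stores nothing), and addressed by the SHA-1 of their content. The
digest covers the UTF-8 bytes of the query text, a single `0x0A` separator,
then the canonical static-parameter text — a JSON object with keys sorted by
code point and no insignificant whitespace. The separator byte is this
package's choice: the protocol prescribes the digest ingredients but not the
byte layout, and an explicit separator prevents text/parameter boundary
collisions. The query language is *not* digested (the URI scopes the sha
under `/q/{language}/`), and dynamic (underscore-prefixed) parameters never
reach the digest because they vary per call. Registration is idempotent:
re-POSTing identical content returns the same sha and redirect URI and
leaves the registry unchanged. In single-record scope the executing context
binds the parameter `ehr_id` to the URI's record id, and additionally binds
`$current_ehr_uid` when the query declares it and nothing else bound it —
that parameter is documented as "supplied by the calling program context",
and the URI *is* the calling context here.

# HTTP caching model

Three resource classes cover every route:

| class | headers | rationale |
|---|---|---|
| immutable version | `Cache-Control: private, max-age=31536000` (configurable), no ETag | a stored version never changes; update checking is pointless; `private` keeps record content out of shared proxies so each access is logged at the origin |
| static public | `Cache-Control: public, max-age=604800` (configurable) | UI assets carry no patient data |
| mutable record view | `ETag: "<latest contribution id>"`, `Last-Modified` (seconds precision), `private` | any change to the record — including administrative access-rule objects, which are committed like everything else — moves the validator |

A GET with matching `If-None-Match` is answered 304 from the metadata cache
alone; the instrumented store read counter proves no data access happened. A
write with non-matching `If-Match` is refused with 412 before any state
change. The metadata cache is write-through on commit and refilled on demand
with exactly one store read — the same entry feeds ETags, bookmark change
detection and trigger bookkeeping, which is why it lives in the store rather
than the HTTP layer.

# Contribution builder

The builder is transient, per-committer, per-record state; the first build
for each patient is named `default` and commits destroy builds. Of the six
temp-version commands, three fetch documents over HTTP and are therefore
restricted: fetch hosts must be allow-listed (default: the deployment
itself), and the outgoing `Referer` is pinned to
`{host}/static/restricted.txt` so committer and record identifiers never
leak into a foreign access log. Template instantiation uses a neutral
`{{name}}` placeholder syntax with every POSTed variable in scope — the
mechanism is deliberately engine-agnostic and replaceable. Unbound
placeholders and unresolvable `from-ehr-path` substitution paths are errors
that name the offenders. "POST modifies contents" on a temp version is
implemented as wholesale replacement of the data field via the `data` form
variable; no patch dialect is defined, and that restriction is intentional.
Builds are reconstructed after a process restart only if the embedding
application persists them; the builder itself treats them as transient.

# Validation and skeletons

Constraint documents are a flat, file-friendly simplification of archetypes:
a root descriptor plus a list of constrained paths with occurrence bounds,
leaf kinds, magnitude ranges, unit and code-set requirements, and optional
defaults. Three levels run in order — reference-model conformance first
(structure and leaf typing), then every archetype whose id appears in the
document, then every template whose base does; findings are tagged with
their level, and when both an archetype and a template fire on the same path
both findings are reported. Narrowing is a checkable property
(`verify_narrowing()`): a template may tighten bounds, ranges and code sets
but never relax them, drop mandatory paths, or add new ones, and a
randomized test confirms the semantic consequence — template acceptance
implies archetype acceptance.

Skeleton generation populates mandatory nodes (`min` strategy) or all nodes
at their occurrence maxima (`max`; unbounded maxima are taken as one
instance, and when a replicated node has constrained descendants those are
placed in its first instance). Leaf defaults win when present; otherwise
range-constrained quantities take the **midpoint** of their range (the spec
of the generation strategy says only "valid values in the validation range";
the midpoint is deterministic and maximally far from both bounds), coded
leaves take the first allowed code, text and timestamp leaves fixed
placeholders. Every skeleton validates against its own constraint document,
asserted in tests.

The shipped fixtures — `bp_archetype.json` (permissive 0–1000 mm[Hg] ranges)
and `bp_template.json` (40–280 / 20–200 mm[Hg], diastolic mandatory) — are
synthetic stand-ins authored for this package, not published archetypes; the
composition-rooted layout (one document constraining the whole encounter
composition) is a simplification that keeps validation single-pass.

# Bookmarks

Short ids are six characters from a 62-symbol alphabet, re-drawn on collision
and on any 4+ character substring overlap with the target's identifiers, so
the link reveals nothing of record structure. Resolution is always a 303 —
the bookmark service never serves record bytes, which preserves target-side
authentication and logging. Change detection is two-stage: if the record's
ETag equals the creation-time snapshot, the answer is `none` with no target
re-resolution (cheap enough for frequent lookups); otherwise the target's
version set is recomputed and diffed. The diff operator was left open by the
protocol and is fixed here as: any target object newly deleted ⇒ `less`;
otherwise a strict superset of version uids ⇒ `more`; an identical set ⇒
`none` (the ETag moved for an unrelated object). The default policy warns on
`more` and on `less` and resolves silently only on `none` — silent
resolution after information loss is the dangerous cell of the policy
matrix; a strict policy that blocks on `less` ships for deployments that
need it. Whether `more` should ever block is left configurable.

# Triggers and replication

Each successful commit publishes exactly one message to
`/contributions/{ehr_id}` (the topic scheme is this package's choice — the
protocol fixes message semantics, not topic naming). Messages carry
identifiers only: patient, committer, contribution URI, changed resource
URIs, and the archetype/template ids that the *validators* collected during
commit — the versioning layer deliberately does not inspect clinical
content, so the validator hands the archetype list along with its report and
the commit forwards it to the bus. Wildcards are `*` (one segment) and `#`
(trailing tail only); regular-expression subscriptions are not implemented.
Subscriber failures are logged and isolated. The wire form is a STOMP-style
text frame (command line, `key:value` headers, blank line, body); list
headers are comma-joined with commas escaped, which makes the frame
round-trip exact except that a one-element list is indistinguishable from a
scalar on the wire. The bus is in-process; the text frame is the boundary at
which an external broker could be substituted.

Replication falls out of the event stream: the bundled subscriber fetches
each committed contribution from the source store (messages carry no
content) and ingests it with original identifiers preserved, so the
replica's commit log is byte-identical to the source's — asserted in tests.
Lagged replicas for population (`/multi/`) reads replay exactly the events
with commit time at or before `now − lag`.

# The synthetic population generator

The generator emulates the versioning shape of a small vital-signs cohort:
per patient, 1–5 contributions over calendar year 2005 at strictly
increasing times, each a blood-pressure composition creation, an amendment
of an existing observation (rate 0.2), or a logical deletion (rate 0.05).
Systolic pressures are Normal(130, 20) mm[Hg] clipped to [60, 260] and
diastolic Normal(80, 10) clipped to [30, 160]; clipping keeps every value
inside the shipped template ranges so generated data validate by
construction, and the default mean/spread put roughly the top half-percent
of readings above the 185 mm[Hg] query threshold — rare, as severe
hypertension should be, but reliably present in populations of a few hundred
readings. Magnitudes are rounded to one decimal so serializations are
byte-stable across platforms.

Determinism is per patient: patient *k* draws from a stream seeded by a
fixed affine hash of (population seed, *k*) kept inside the 32-bit integer
range, so growing a population extends its commit log without rewriting
earlier patients' bytes — asserted as a prefix property.

What the generator does **not** emulate: longitudinal physiology (readings
are i.i.d., not trending), demographics, multi-observation compositions,
folders, or cross-record correlation. Tests passing on these populations
therefore demonstrate protocol and engine correctness — versioning
invariants, oracle equivalence, caching soundness — not clinical realism of
the content.

# Problem sizes and numerical choices

The test and acceptance suites run at desk scale by design: oracle
equivalence uses 100 random (query, population) pairs with up to 50 patients
each; rate calibration uses 2 000 committed events; identifier uniqueness is
checked over 10 000 minted ids; bookmark opacity over 1 000 random targets.
Numeric leaf values serialize with 15 significant digits (`%.15g`), which
round-trips every value the package produces and keeps commit logs
deterministic; result-set and composition round-trips are compared with
`identical()`, not tolerances. Equal commit timestamps are legal and broken
by commit sequence. Degenerate inputs are exercised directly: empty stores
and empty result sets serialize to schema-valid documents, an empty build
refuses to commit, `n = 0` populations yield empty stores, and at-time
lookups before the first commit are not-found rather than empty.

# Known limitations

* One linear `CONTAINS` chain per query; no aggregation, ordering, or
  terminology subsumption in predicates.
* Authentication is a header-carried identity stub (`X-Committer`), logged
  verbatim; there are no access-control lists.
* No physical sharding, record merging, or cross-record transactions; the
  `/multi/` path is a single lag-configurable replica.
* The in-memory store plus replayable commit log is the only persistence
  model; there is no external database backend.
* Builder state is process-local; shared multi-device builds are out of
  scope.
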