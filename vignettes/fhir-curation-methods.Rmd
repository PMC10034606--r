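---
title: "Curating tabular health data into profile-conformant FHIR: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating tabular health data into profile-conformant FHIR: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Health data accumulates in institutional silos as CSV extracts, spreadsheets
and relational tables, each with local column names, local code lists and
local conventions for dates and missing values. Making such data shareable
and machine-actionable means two things at once: a *syntactic* lift into a
community standard — HL7 FHIR R4 resources (Patient, Encounter, Observation,
Condition, MedicationStatement) — and a *semantic* lift of coded values into
standard terminologies (HL7 administrative gender, ICD-10, LOINC, ATC).
fhircurate implements that lift as a headless, validating ETL engine, and
then closes the loop by measuring two properties of the result: whether the
analytical content survived (data utility) and how FAIR the curated
repository is (RDA FAIR Data Maturity Model levels).

## The pipeline and its contracts

The engine is profile-driven end to end. A `CapabilityStatement` tells it
which resource types and profiles the target repository supports;
snapshot-bearing `StructureDefinition`s are flattened into a constraint
model — one row per element path carrying cardinality, datatype codes,
binding strength and value set, fixed values and reference targets. Choice
elements (`Observation.value[x]`) are expanded into one constraint per
declared type. We deliberately accept only snapshots: differential merging
against base definitions is a large, error-prone machinery that none of the
supported workflows needs, and profile authoring tools emit snapshots
routinely. Slices are read under their unsliced path, first declaration
wins.

Mappings are expressed in a small, versioned JSON language of our own
design: per source table, a target resource type and profile, the business
key columns, and one element mapping per populated path. Three mapping
kinds cover observed practice: `value` (typed literal from a column),
`reference` (foreign key to another mapped table) and `fixed` (a constant,
used for profile-required elements like `Observation.status` that tabular
extracts never carry). A full FHIR Mapping Language engine would add
expressive power — functions over columns, one-row-to-many fan-out — at a
complexity cost the curation workflow does not repay; both features are
explicit non-goals.

Static checking (`check_mapping()`) runs before any row is touched and is
monotone by construction: adding a mapping can only shrink the set of
missing-required errors. A target path is *known* if it is a profile
constraint or reachable from one through a table of common complex
datatypes (Quantity, Coding, CodeableConcept, Period, Reference,
Identifier, HumanName); a bare child of the resource root is rejected. This
shallow datatype walk is a deliberate simplification — it covers every
element the shipped mappings and, in our experience, typical tabular
curation touch, without embedding the entire R4 datatype graph.

### Identity and referential integrity

Every resource id is `SHA-256("<Type>|<key1>|<key2>…")` in lowercase hex —
64 characters, exactly the FHIR id length budget. Hashing the same foreign
key under the referenced type reproduces the target's id, so referential
integrity falls out of determinism rather than bookkeeping. Type-salting
keeps a patient and their observation distinct even when a source reuses
key values across tables. Composite keys are joined with `|` before
hashing; the separator cannot occur in a single-column key's hash input
ambiguously because the type prefix is always present and keys are
trimmed, not escaped — a documented limitation for keys that themselves
contain `|`.

### Translation and validation

Coded values are translated before insertion: identity passthrough when
source and target systems coincide (ICD-10 sources into ICD-10-bound
elements need no configuration), ConceptMap lookup otherwise, with an
optional remote `$translate` hook. Translations are strictly one-to-one;
a ConceptMap offering two targets for one source code is an ambiguity
error at indexing time, because silent choice would make the pipeline
non-deterministic.

Validation is local and structural: cardinality, primitive datatype
parses, required-binding membership against locally loaded
ValueSet/CodeSystem fixtures, fixed-value equality. Binding strengths
follow FHIR semantics — only `required` bindings block persistence;
extensible/preferred/example produce warnings. A required binding whose
value set is not loaded degrades to a warning rather than failing rows on
missing infrastructure; the trade-off is documented rather than silent. A
remote `$validate` hook, when configured, is authoritative for the
persistence gate, but local validation always runs first because it gives
path-precise diagnostics.

Rows are rejected — never silently dropped — for exactly four reasons:
missing id key, unparseable value, untranslatable code, or validation
failure. A row whose every mapped cell is null produces an "empty"
resource (id only); we reject those under the validation-failed reason
because an empty resource has no analytical utility and almost always
signals a source defect.

### Sessions and metadata

A transformation session is two-phase: all rows are transformed and
validated before anything is written, so a failing store leaves no partial
session. After the data resources, exactly one Provenance (targets = every
created resource, agent = configured author, recorded = session end) and
one DocumentManifest (author, license code verbatim in the free-text
`description` field, one content reference per resource) are written. The
session id is derived from the created-id set, not the clock, so an
idempotent re-run updates (re-versions) the same metadata instead of
duplicating it. Listing every created resource directly on the Provenance
is acceptable at desk scale; at millions of resources an intermediate List
resource would be the revisit point.

The embedded store is an in-memory FHIR repository with create-or-update
keyed by id, `meta.versionId` incrementing by one per write, soft deletion
(tombstones keep ids reserved and session metadata retrievable after data
deletion — the RDA A2 behaviour), a practical search subset (`_id`, token,
date ranges with `ge`/`le` prefixes, `subject`/`encounter` references,
`_count`), and CapabilityStatement generation that round-trips through the
package's own parser. Unsupported search parameters raise an explicit
error instead of being ignored, because silently widened searches corrupt
store-side cohort counts. The engine talks to the store through the same
call surface a remote server adapter would implement.

## The synthetic corpus: what it emulates and what it does not

`generate_synth_ehr()` emulates two-institution EHR extracts: preset A is
hospital-like (Spanish-style `H`/`M` gender codes, ISO dates), preset B
registry-like (numeric sex codes, `DD/MM/YYYY` dates, different table and
column names). Both presets ship with matching mapping configurations, so
the same pipeline exercises two source dialects.

The generator *plants* cohorts with exact target counts and records them
in a ledger; every downstream count is audited against that ledger rather
than against a re-implementation of the criterion. Defaults (chosen once,
as round realistic fractions of the cohort): 200 patients, 1–3 admissions
each over a 2-year window, and planted counts of 20% (female patients with
a top-5 condition), 12.5% (COPD, codes J44/J44.0/J44.1/J44.9), 15%
(polypharmacy, ≥5 distinct medications), 7.5% (30-day readmissions, one
gap forced to exactly 30 days so the boundary is always exercised) and 10%
(males with hemoglobin 138–172 g/L; other males are kept outside
[137.5, 172.5] so rounding cannot leak into the cohort). The five "common"
condition codes are made frequency-dominant by capping every other code
below the common-code floor, which makes the top-5 set deterministic and
tie-free by construction.

Planted invalid rows go only where nothing references them: untranslatable
gender codes on childless patients, missing ids and unparseable numerics
on filler observations and on prescriptions of non-polypharmacy patients.
This keeps two properties simultaneously true under any error rate: the
rejected-row set equals the ledger exactly, and the post-session
referential-integrity scan stays clean.

What the generator does *not* emulate: clinical plausibility of value
joint distributions, free-text fields, longitudinal care patterns,
multi-table join keys beyond the patient/admission foreign keys, and
volume. Passing tests on this corpus therefore demonstrate the engine's
contracts (count conservation, validation gating, referential integrity,
translation correctness, boundary conventions) — not that real
institutional extracts will map without profile- or source-specific
configuration work.

## Utility criteria and their boundary conventions

Five privacy-concerned criteria are computed on both sides — directly on
the source tables, and via search queries against the store — and compared
as `accuracy = 100·(1 − |source − transformed| / max(source, 1))`, with
100 when both sides are zero. The criteria report cohort *counts*, never
distributions, which is what makes them privacy-acceptable. Three
conventions the criteria text leaves open are fixed and documented here:
"between 138 and 172" and "within 30 days" are inclusive; "prescriptions
included ≥5 medications" counts distinct medication codes, not
prescription rows (the natural clinical reading of polypharmacy); top-5
frequency ties break lexicographically (made unreachable in the synthetic
corpus by construction). The readmission reference point is the most
recent prior discharge of the same patient.

## FAIR assessment

The indicator catalogue is data (editable JSON): 41 indicators in RDA
identifier style, partitioned F:7, A:12, I:12, R:10 with RDA priorities.
Each indicator names a *probe* — a literal check of repository facts:
every resource resolves at its URL, ids are unique and well-formed,
Provenance and DocumentManifest exist and target resolvable data ids,
search works, codings carry system URIs, the reference scan is clean,
persisted resources re-validate, the license code comes from a controlled
list. Indicators whose satisfaction is contractual (authentication
support) are probed via declared capabilities, since enforcement belongs
to the hosting deployment, not the data. Probes that quantify over
resources fail on an empty store: an empty repository satisfies nothing.

The cross-community provenance-language indicator (RDA-R1.2-02M, the only
`useful` indicator under R) is scored `not_considered`: the repository
deliberately uses the health-care community standard (FHIR Provenance)
rather than a cross-community language, and `not_considered` is how the
maturity model records a deliberate non-goal.

Levels roll up per principle: 5 all pass; 4 all essential+important and
some but not all useful; 3 all essential+important, no useful; 2 all
essential; 1 ≥1 essential; 0 otherwise — with one guard: a principle with
no passing indicator is 0 regardless. The guard matters because the I
principle has no essential indicators in the RDA model, and without it an
empty repository would vacuously reach level 2. The rule lives in one
function (`fair_level()`) and is tested exhaustively against a brute-force
table over all pass/fail vectors of a toy catalogue.

## Numerical and degenerate-input choices

Null tokens `""`, `"NA"`, `"NULL"` (case-insensitive) normalize to null at
read time. Dates parse from ISO 8601 plus `DD/MM/YYYY` (a configurable
list); date-typed columns are promoted only when every non-null cell
parses. CSV dialect is UTF-8, comma, double-quote, header row. Database
sources are read-only, one table per mapping. Empty source tables produce
an empty report and no session metadata (a Provenance with zero targets is
meaningless). Unbounded cardinality is the `Inf` sentinel. Problem sizes
in the shipped tests — 60-patient corpora for module tests, 200 patients
for the end-to-end runs, 1,000 resources for the search-oracle property —
were chosen as the smallest sizes at which every planted cohort and
boundary case is non-trivially populated.

## Known limitations

FHIRPath invariants and extension authoring are out of scope; the datatype
walk is shallow; one source row maps to at most one resource per mapping;
very large sources are not streamed; the remote hooks ($translate,
$validate, profile fetch) are interface points, exercised in tests through
local stand-ins rather than live servers. The shipped profiles are
synthetic demonstration profiles — real implementation-guide profiles will
exercise corners (slicing, extensions, nested requireds under optional
parents) that the engine handles only in the simplified forms described
above.
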