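# fhircurate

Profile-driven curation of tabular health data into HL7 FHIR, with FAIR
maturity assessment.

Health data sits in institutional silos as CSV extracts, spreadsheets and
relational tables — local column names, local code lists, local date
dialects. **fhircurate** is a headless R engine for data stewards and
health-informatics engineers that lifts such tables into FHIR R4 resources
under the constraints of machine-readable profiles, and then *measures* the
result: did the analytical content survive (data utility), and how FAIR is
the curated repository (RDA FAIR Data Maturity Model)?

## What it does

1. **Conformance parsing** — a server `CapabilityStatement` and
   snapshot-bearing `StructureDefinition`s are flattened into a queryable
   constraint model (cardinality, datatypes, bindings, fixed values).
2. **Mapping** — a small versioned JSON language ties source columns to
   profiled element paths, with three kinds: `value`, `reference`, `fixed`.
   `check_mapping()` flags missing required elements, unknown paths and
   columns, type clashes and untranslated coded elements before any row is
   touched.
3. **Terminology translation** — ConceptMap semantics, offline-first:
   identity passthrough when source and target systems coincide, local
   ConceptMap lookup otherwise, optional remote `$translate` hook.
   Translations are strictly one-to-one.
4. **Transformation** — resource ids are deterministic:

   ```
   id = sha256("<ResourceType>|<key1>|<key2>…")   # lowercase hex, 64 chars
   ```

   Hashing a foreign-key column under the referenced type reproduces the
   target's id, so references stay intact by construction. Every resource
   is validated against its profile before persistence; invalid rows are
   rejected with a reason (missing id key, unparseable value,
   untranslatable code, validation failure), never silently dropped. Each
   session automatically writes one **Provenance** and one
   **DocumentManifest** (author + license) covering everything it created.
5. **Embedded FHIR store** — in-memory, versioned, validating on write,
   soft-deleting (metadata survives data deletion), with a practical search
   subset and CapabilityStatement generation. A remote repository can be
   swapped in behind the same call surface.
6. **Evaluation** — five privacy-concerned utility criteria computed on
   both sides (source tables vs. store queries) with per-criterion accuracy
   `100·(1 − |source − transformed|/max(source, 1))`, and a data-driven RDA
   indicator catalogue (41 indicators, F/A/I/R) probed against concrete
   repository facts and rolled up into maturity levels 0–5.
7. **Synthetic EHR generator** — seeded, two institution presets, exact
   planted cohort counts and plantable invalid rows, so the entire pipeline
   is testable with no data download.

## Worked example

```r
library(fhircurate)

# a seeded 200-patient hospital-style extract, no planted defects
synth <- generate_synth_ehr(synth_config(seed = 42, n_patients = 200))

profiles  <- load_profiles(fhircurate_extdata("profiles"))
valuesets <- load_valuesets(fhircurate_extdata("terminology"))
index     <- index_concept_maps(fhircurate_extdata("terminology"))
mapping   <- load_mapping(fhircurate_extdata("mappings", "institution-a.json"))

store  <- fhir_store(profiles, valuesets)
report <- run_session(mapping, synth$tables, profiles, index, store,
                      author = "Data Steward", license = "CC-BY-4.0")
print(report)
#> <transform_report> session 27cfd53dddca4577
#>   created: Patient=200, Encounter=258, Observation=503, Condition=274, MedicationStatement=488
#>   rejected: 0 row(s)
#>   provenance: 3452050332f025d3bbc2c84d1ea768e9ff3b21824ee00f9f92691b4face285e7
#>   manifest:   c259ceb0e0a39cccc9a0974ac6fa082d93ef28bf99ee2b28782a1a9077a23cf1
```

Every source row became exactly one resource (created + rejected equals the
table's row count, per table), and the session metadata was written once.
Now measure utility — each criterion is computed independently on the
source tables and via store queries:

```r
evaluate_utility(synth$tables, store, synth$schema)
#>     criterion_id source_value transformed_value accuracy_pct
#> 1    female_top5           40                40          100
#> 2           copd           25                25          100
#> 3  polypharmacy5           30                30          100
#> 4      readmit30           15                15          100
#> 5 hgb_male_range           20                20          100
```

All five cohorts (female patients with a top-5 condition; COPD patients,
ICD-10 J44/J44.0/J44.1/J44.9; polypharmacy ≥5 distinct medications; 30-day
readmissions; males with hemoglobin 138–172 g/L, LOINC 718-7) agree exactly
— 100% accuracy, and both columns equal the generator's planted ledger.
Finally, the FAIR maturity of the curated repository:

```r
assess_fair(store, report)
#> <fair_assessment>
#>   F: level 5  (7/7 indicators pass)
#>   A: level 5  (12/12 indicators pass)
#>   I: level 5  (12/12 indicators pass)
#>   R: level 3  (9/10 indicators pass)
#>   unmet:
#>     RDA-R1.2-02M (R, useful): not_considered
```

Findable, Accessible and Interoperable reach the maximum level 5; Reusable
reaches level 3 because the single `useful` indicator under R — provenance
in a cross-community language — is deliberately not considered: the
repository uses the health-care community standard (FHIR Provenance)
instead.

## Command line

A thin wrapper over the same functions ships with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "fhircurate", package = "fhircurate"))')
Rscript "$CLI" generate-synth --seed 42 --patients 200 --out corpus/
Rscript "$CLI" check-map  --mapping mapping.json --source corpus/ --profiles profiles/
Rscript "$CLI" transform  --mapping mapping.json --source corpus/ \
               --profiles profiles/ --terminology terminology/ --out out/
Rscript "$CLI" assess-fair  --store out/store.ndjson --profiles profiles/ \
               --terminology terminology/ --out out/
Rscript "$CLI" eval-utility --source corpus/ --store out/store.ndjson \
               --profiles profiles/ --terminology terminology/ --out out/
```

Exit codes: 0 success, 1 pipeline error or blocking mapping issues, 2 usage
error. Machine-readable outputs (transform report, store dump, FAIR and
utility reports, run manifest) land under `--out`.

## Package layout

- `R/` — conformance parsing, source readers, mapping language, terminology,
  validation, transform engine, embedded store, FAIR assessment, utility
  evaluation, synthetic generator, CLI.
- `inst/extdata/profiles/` — synthetic demonstration StructureDefinitions.
- `inst/extdata/terminology/` — ValueSet/CodeSystem/ConceptMap fixtures.
- `inst/extdata/mappings/` — mapping configurations for both institution
  presets.
- `inst/extdata/fair/rda_indicators.json` — the editable indicator
  catalogue.
- `vignettes/fhir-curation-methods.Rmd` — the methods vignette: model,
  conventions, design decisions, limitations.
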