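Package: fhircurate
Title: Profile-Driven Curation of Tabular Health Data into FHIR with FAIR
    Maturity Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless data-curation engine that transforms tabular health
    data (CSV, Excel sheets, relational tables) into HL7 FHIR R4 resources
    under the constraints of machine-readable profiles (StructureDefinition
    snapshots). Mappings between source columns and profiled element paths
    are expressed in a versioned JSON mapping language; coded values are
    translated between code systems with ConceptMap semantics; every
    generated resource is structurally validated before persistence, and
    resource identifiers are derived by deterministic hashing so that
    cross-references stay intact. Each transformation session records its
    provenance (a Provenance resource) and data-set metadata including
    author and license (a DocumentManifest resource). An embedded
    in-memory FHIR repository supports create/read/update, versioning,
    soft deletion and a practical search subset. The curated repository
    can be scored against the RDA FAIR Data Maturity Model indicator
    catalogue, yielding per-principle maturity levels 0-5, and audited
    with privacy-concerned data-utility criteria comparing source-side and
    FHIR-side cohort counts. A seeded synthetic EHR generator produces
    two-institution-style extracts with plantable cohort counts and
    plantable invalid rows for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    digest,
    stats,
    utils,
    tools
Suggests:
    readxl,
    DBI,
    RSQLite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
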