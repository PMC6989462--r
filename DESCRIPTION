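Package: cgdm
Title: Clinical Genome Data Model with Variant Normalization and Pharmacogenomic Decision Support
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a clinical genome data model (cGDM): an eight-entity,
    forty-six-attribute relational schema for clinical-grade storage of
    NGS-derived variant observations together with full procedural provenance
    (pipeline tool/step/parameter and reference data source origin, version and
    genome build). On top of the schema the package provides minimal-representation
    variant normalization (allele trimming and left alignment against a reference
    window), HGVS nomenclature parsing with completeness validation, VCF and MAF
    extract-transform-load into a file-backed embedded store, semantic variant
    queries over an alias index, a declarative clinical-decision-support rule
    engine, and the IWPC warfarin dosing algorithm (pharmacogenetic and clinical
    models) driven by CYP2C9/VKORC1 genotypes derived from stored variants.
    Synthetic fixture generators make every component testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
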