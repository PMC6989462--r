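---
title: "The cgdm data model and its computational methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cgdm data model and its computational methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgdm)
```

## Why a data model, and what it assumes

A genomic test result is not a static measurement: it is the product of a
pipeline of tools, reference databases and parameter choices, any of which
can change the reported value. `cgdm` treats that procedural dimension as
first-class data. Every stored variant observation is linked to the
pipeline stages that produced it (tool, version, step, parameters, and the
origin/version/genome build of every reference data source) and to the
test's quality metrics (base quality, average depth, percent mapped
reads). The working assumption is that a clinician or downstream CDS
system should be able to decide, from the stored record alone, whether a
result is reliable enough to act on — so the model refuses several kinds of
silent convenience: reference alleles are never invented, reference states
are never inferred without coverage evidence, incomplete variant names are
flagged rather than corrected, and degraded normalization is recorded as
such.

### The eight entities and the 46-attribute convention

The model comprises eight entities: clinical linkage identifiers,
experiment description, pipeline provenance, genomic alterations, quality
checks, clinical annotations, microsatellite instability and tumour
mutation burden. The last is included as a first-class entity because
sample-level predictive biomarkers (MSI, TMB) sit structurally parallel to
one another: both are per-test results of downstream computation that the
model stores but does not compute.

The headline attribute count (46) follows a documented convention,
because the count depends on how composites and keys are treated:

* only *domain* attributes count — surrogate primary keys, pure
  foreign-key columns and supplementary operational columns (the stage
  classifier, the denormalized `genome_build` join column on alterations,
  the `normalization_mode` flag, TMB's `panel_size` context) do not;
* composite attributes count once but expand into several columns: Gene
  (HGNC symbol, Entrez, Ensembl), the variant descriptor (HGVS g/c/p,
  dbSNP, dbVar), the external reference pair (ClinVar, COSMIC), and Tool
  (name, version).

This yields 5 + 7 + 9 + 16 + 3 + 3 + 2 + 1 = 46 across the eight entities.
`introspectSchema()` derives these numbers from the live registry (so a
registered extension entity changes them), and the embedded store's catalog
carries the same per-column attribute labels, letting
`catalogSummary()` reproduce the census from a created database rather
than from the registry.

### The embedded store

The reference deployment target for the schema is a relational server, for
which `emitDdl("ansi")` and `emitDdl("sqlite")` produce executable DDL. For
a self-contained, dependency-free workflow the package also executes its
own DDL against a file-backed tabular store (`CgdmDb`): one TSV per table
plus a catalog, with all-or-nothing loads implemented by staging on a copy
and committing only on success. This store is deliberately simple — no
indexes, no concurrent writers — and is intended for single-analyst and
testing use; its value is that the DDL-execution round trip (emit → execute
→ introspect catalog) is honest and reproducible anywhere.

## Minimal-representation normalization

Two operators make equivalent variant spellings byte-identical.

**Trimming** removes the longest shared allele *suffix* first, then the
longest shared *prefix* (advancing the position), with both alleles always
retaining at least one base. Suffix-before-prefix is the order that
preserves the VCF anchor-base convention for indels: `CG>CTG` trims to
`C>CT` (anchored insertion) rather than `G>TG`. For length-preserving
variants trimming alone produces the unique minimal form.

**Left alignment** applies to trimmed indels with reference context: while
the allele pair ends in a shared base, that base is dropped and the
preceding reference base is prepended, sliding the representation leftwards
through the repeat tract; a final prefix trim restores the minimal anchored
form. The result is the smallest position whose edit reproduces the same
sequence. The operation is idempotent, and `normalizeVariant()` composes
the two operators.

Numerical and edge-case choices:

* Coordinates are 1-based VCF-style throughout; chromosome names are
  stripped of the `chr` prefix at construction so joins use one canonical
  form.
* Multi-allelic sites are split before normalization — minimal
  representation is defined per alternative allele.
* The ambiguous base `N` participates in trimming (identity is unambiguous)
  but blocks left alignment, because a shift comparison against `N` is
  unsound; such records are stored flagged `trim_only`.
* A window that does not cover the needed left context raises an error
  naming the required span rather than returning a partially shifted
  record; a window disagreeing with the stated reference allele is a
  reference-mismatch error, and during ETL such records are rejected
  per-record into a sidecar file, never silently dropped.
* Without any reference context (MAF-only ingestion) normalization is
  trim-only and says so in the stored record. MAF `-` alleles are anchored
  with a synthetic `N` — never with sequence the input did not contain.

Two records are *equivalent* iff their normalized forms are identical on
the same genome build; records on different builds are never equivalent,
because a position is only meaningful relative to its assembly.

**Deduplication policy.** Two input records that normalize to the same
(subject, build, chromosome, position, ref, alt) collapse to one stored
alteration, with the merge count recorded in a provenance row. This is a
design decision: the purpose of normalization here is consistent
identification, and storing both spellings would reintroduce the ambiguity
the model exists to remove.

## HGVS completeness and semantic query

A protein-level variant name is only complete when it carries the
versioned accession that defines its numbering — the BRAF V600E/V599E
renumbering is the canonical cautionary tale. `validateCompleteness()`
classifies failures into three meta-categories (`origin`, `reference`,
`symbol`); a missing or out-of-domain accession version is a `reference`
failure. The historical renumbering is *not* auto-corrected: mapping V599E
to V600E would require the actual RefSeq sequences, so the package flags
and stores the expression verbatim instead. Protein changes are compared
case-sensitively after normalizing three-letter codes to one-letter.

Stored alterations are indexed under every name they carry (gene + protein
change, dbSNP ID, each full HGVS string). Fragment queries return exact
matches first; a protein-change-only fragment returns *all* candidate
genes with an ambiguity flag, ordered stably by gene symbol — among
multiple exact matches no ranking signal exists in the model, so
alphabetical gene order was chosen as the deterministic tie-break.

## The IWPC dosing function

The pharmacogenetic model is a linear predictor on the square root of the
weekly warfarin dose (mg); its covariates are age in decades, height in
cm, weight in kg, race group, enzyme-inducer and amiodarone comedication,
the CYP2C9 diplotype over the closed set {\*1/\*1 … \*3/\*3} and the
VKORC1 -1639 genotype {GG, GA, AA}. Coefficients live in a versioned
knowledge CSV (`knowledge_version: IWPC-2009`) rather than in code,
mirroring how the model treats all external knowledge as replaceable,
versioned references. The clinical (non-genetic) model ships alongside.

Dispatch is strict: when either genotype is `unknown` the pharmacogenetic
model *refuses*, and the default `"auto"` mode falls back to the clinical
model with the audit trail marked accordingly. Covariates are never
imputed; a missing covariate is an error. Every calculation returns an
audit table (term, value, coefficient, contribution) so the arithmetic is
checkable line by line.

Genotype derivation requires evidence in both directions: a variant call
for the non-reference state, and a QualityCheck row for the test before
absence of a defining variant may be read as the reference state. More
than two variant alleles at a gene is a data-inconsistency error naming
the offending records, not a silent clamp.

## The fixture generators

Every test input is generated in code. Reference windows are built from
60-bp slots, each embedding one tandem repeat tract (unit length 1–3,
tract length ≥ `repeat_context_length`, default 6 bp) at least the maximal
indel length (12 bp) from slot and window edges, so left alignment never
lacks context on fixture variants. Non-minimal spellings are produced by
*reversing* the normalization operators — padding shared bases and
right-shifting within the tract via whole-sequence comparison — so
equivalence with the minimal form holds by construction rather than by
trusting the code under test. The fixture build label is `FIXTURE1`,
making accidental joins against real assemblies impossible. PGx cohorts
assign each subject a known diplotype and VKORC1 state and emit genotypes
that realise the assignment exactly; one subject is emitted without
coverage evidence and must come back `unknown`.

Default generator conditions: 5 subjects × 10 variants, half SNV / half
indel, non-minimal fraction 0.5; the normalization property corpus uses
1,000 indel cases; the dosing grid crosses 3 ages × 2 heights × 2 weights
× 4 race groups × 2 × 2 comedication flags × 6 diplotypes × 3 VKORC1
states. These sizes were chosen so the full suite exercises every code
path and every closed-set value within a desktop-scale run.

What the generators do **not** emulate: real allele-frequency spectra,
mutation signatures, linkage between PGx loci, sequencing error, or
multi-sample genotype correlation. Passing tests therefore demonstrate
correctness of the representation, normalization and dosing machinery —
not calling accuracy on real data, which is upstream of this package's
scope.

## Known limitations

* Symbolic and structural alleles (CNV, fusions) are stored descriptively
  but not normalized; there is no right-alignment mode.
* No liftover: builds are recorded and compared, never converted.
* The embedded store is not a concurrent database; server deployments
  should execute the emitted DDL on a real RDBMS.
* The alias index covers names present in the stored record; it does not
  consult external transcript databases, so a query by a name the record
  never carried cannot match.
* MSI and TMB are stored results; computing them from reads is out of
  scope.
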