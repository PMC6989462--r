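# cgdm — a clinical genome data model with variant normalization and pharmacogenomic decision support

NGS-derived variant results rarely make it into routine clinical
decision-making in a form a clinician can trust: the same indel is spelled
differently by different callers, protein-level variant names circulate
without the versioned reference sequence their numbering depends on, and the
provenance needed to judge a result's reliability (which pipeline, which
reference build, what coverage) is usually lost between the bioinformatics
workflow and the hospital information system. `cgdm` is an R implementation
of a clinical genome data model that addresses all three failure modes at
the data layer. It is aimed at clinical bioinformaticians and medical
informaticians who need to store genomic test results next to clinical data
with enough procedural metadata to use them as evidence.

## What the package implements

**The data model.** Eight entities with 46 domain attributes:
`CLINICAL_IDENTIFIER` (minimal linkage to clinical records),
`EXPERIMENT_INFO`, `PIPELINE_PROVENANCE` (tool/step/parameter plus reference
data source origin, version and genome build for every processing stage),
`GENOMIC_ALTERATION` (one normalized variant observation with location,
genotype, descriptive and functional annotation), `QUALITY_CHECK`,
`CLINICAL_ANNOTATION` (ACMG-actionable / FDA-qualified / user-defined
biomarker classes), `MICROSATELLITE_INSTABILITY` and
`TUMOR_MUTATION_BURDEN`. The schema is held in a live registry
(`introspectSchema()`), emitted as ANSI-SQL or SQLite DDL (`emitDdl()`), and
executed against a file-backed embedded store (`initDb()`, a `CgdmDb` S4
object). Composite attributes (e.g. Gene = HGNC symbol + Entrez + Ensembl
IDs) count once and expand into several columns; surrogate and foreign keys
are excluded from the count.

**Minimal-representation normalization.** Equivalent indel spellings are
made byte-identical before storage: shared allele bases are trimmed (suffix
first, then prefix, keeping the VCF anchor base), and indels are
left-aligned against reference sequence to the smallest position `p` such
that applying the edit reproduces the same sequence — for an insertion of
unit `u` inside a tandem repeat, the leftmost anchored spelling
`(p, r, r·u)`. `normalizeVariant()` is idempotent and, without reference
context, degrades explicitly to trim-only normalization with a stored flag.

**HGVS completeness.** `parseHgvs()` / `validateCompleteness()` enforce
that a variant name pins its numbering to a versioned reference accession
(`NP_004324.2:p.V600E` is complete; `NP_004324:p.V599E` is flagged with
failure category `reference` and stored verbatim, never auto-corrected).
An alias index (`registerAliases()`, `resolveQuery()`) resolves fragmented
queries such as `"V600E"` with explicit ambiguity instead of a silent guess.

**ETL.** `loadDataset()` reads VCF (via vcfR) or MAF, splits multi-allelic
sites, maps genotypes to zygosity/phasing/missingness, normalizes and
deduplicates en route, and loads transactionally with provenance, QC and
annotation rows; rejected records go to a sidecar file with reasons.

**Decision support.** `derivePgxGenotype()` reconstructs CYP2C9 star-allele
diplotypes and the VKORC1 -1639G>A genotype from stored variants — inferring
the reference state only when coverage evidence exists — and
`iwpcWarfarinDose()` implements the IWPC warfarin algorithm: a linear
predictor on the square root of the weekly dose,

```
sqrt(dose/week) = 5.6044 − 0.2614·age(decades) + 0.0087·height(cm) + 0.0128·weight(kg)
                  − 0.8677·[VKORC1 G/A] − 1.6974·[VKORC1 A/A]
                  − 0.5211·[*1/*2] − 0.9357·[*1/*3] − 1.0616·[*2/*2]
                  − 1.9206·[*2/*3] − 2.3312·[*3/*3]
                  − 0.1092·[Asian] − 0.2760·[Black] − 0.1032·[mixed/missing]
                  + 1.1816·[enzyme inducer] − 0.5503·[amiodarone]
```

with the non-genetic clinical model as the fallback when genotype is
unknown. Coefficients ship as a versioned knowledge table
(`inst/extdata/iwpc_dosing_coefficients.csv`), and a declarative rule engine
(`cdsRule()`, `evaluateRules()`) ties alerts and dose calculations back to
the alteration IDs and knowledge references that fired.

## Worked example

```r
library(cgdm)

## two spellings of the same insertion become one record
normalizeVariant(rawVariant("chr10", 11805838, "CG", "CTG", "GRCh37"))
#> RawVariant 10:11805838 C>CT (GRCh37)

## load a small VCF (the two equivalent spellings plus one SNV)
db  <- initDb()
man <- etlManifest(vcf, "VCF", test_id = "TEST-001", genome_build = "GRCh37",
                   pipeline_provenance = list(provenanceRecord(
                     "variant_calling", tool_name = "GATK HaplotypeCaller",
                     tool_version = "4.2", origin_source = "GRCh37 reference",
                     origin_version = "hs37d5", origin_build = "GRCh37")),
                   normalization_mode = "trim_only",
                   qc = list(base_quality = 31, depth_of_coverage = 84,
                             mapping_quality = 98.6))
loadDataset(man, db)
#> LoadReport: read 3, loaded 3, rejected 0 (merged 1)
db
#> CgdmDb (in-memory)
#>   CLINICAL_IDENTIFIER                1 rows
#>   EXPERIMENT_INFO                    1 rows
#>   PIPELINE_PROVENANCE                2 rows
#>   GENOMIC_ALTERATION                 2 rows
#>   QUALITY_CHECK                      1 rows
#>   ...
```

Three VCF records collapse to two stored alterations: the two spellings of
the chr10 insertion were recognised as the same variant and merged, with the
merge recorded in a provenance row. An incomplete variant name is detected,
not guessed at:

```r
validateCompleteness(parseHgvs("NP_004324:p.V599E"))
#> $complete: FALSE   $category: "reference"
#> $message: "accession version absent; numbering reference underspecified"
```

And a warfarin dose for a 68-year-old, 170 cm, 70 kg patient of the
reference race group with CYP2C9 \*1/\*3 and VKORC1 G/A:

```r
g <- derivePgxGenotype("PATIENT1", db, loadAlleleDefinitions())  # or built by hand
iwpcWarfarinDose(dosingInput(6.8, 170, 70, "white", FALSE, FALSE, g))
#> weekly 19.35 mg, daily 2.76 mg, model pharmacogenetic
```

The audit trail lists every term's value, coefficient and contribution
(intercept 5.6044; age −1.77752; height +1.479; weight +0.896; ...), so a
pharmacist can check each step of the calculation.

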