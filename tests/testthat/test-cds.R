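# Shared fixture: one melanoma-like subject with an annotated BRAF V600E
# record plus QC and provenance, loaded through the normal ETL path.
braf_db <- function() {
  resetSchema()
  db <- initDb()
  vcf <- write_mini_vcf(tempfile(fileext = ".vcf"), c(
    "7\t140453136\t.\tA\tT\t.\tPASS\t.\tGT\t0/1",
    "12\t25398284\t.\tC\tA\t.\tPASS\t.\tGT\t0/1"))
  man <- fixture_manifest(vcf, test_id = "T-MEL", build = "GRCh37",
                          qc = list(base_quality = 30, depth_of_coverage = 120,
                                    mapping_quality = 99))
  loadDataset(man, db)
  ga <- dbTable(db, "GenomicAlteration")
  braf <- ga$alteration_id[ga$position == 140453136]
  ga$gene_symbol[ga$alteration_id == braf] <- "BRAF"
  ga$hgvs_p[ga$alteration_id == braf] <- "NP_004324.2:p.V600E"
  assign("GENOMIC_ALTERATION", ga, envir = db@tables)
  registerAliases(db, braf)
  cgdm:::.insert_rows(db, "ClinicalAnnotation", data.frame(
    alteration_id = braf, annotation_class = "fda_qualified_biomarker",
    annotation_value = "BRAF p.V600E", stringsAsFactors = FALSE))
  db
}

test_that("queries return alterations with provenance and quality attached", {
  db <- braf_db()
  hits <- queryVariants(queryFilter(gene_symbol = "BRAF"), db)
  expect_length(hits, 1L)
  h <- hits[[1]]
  expect_identical(h$alteration$position, 140453136L)
  expect_gt(nrow(h$provenance), 0L)
  expect_identical(h$quality$depth_of_coverage, 120)
  expect_false(is.na(h$alteration$genome_build))
  # provenance completeness holds for unfiltered subject queries too
  all_hits <- queryVariants(queryFilter(subject_id = "S1"), db)
  expect_true(all(vapply(all_hits, function(x) nrow(x$provenance) > 0, logical(1))))
  # stable (chromosome, position) ordering
  expect_identical(vapply(all_hits, function(x) x$alteration$chromosome,
                          character(1)), c("12", "7"))
})

test_that("quality thresholds and annotation classes filter correctly", {
  db <- braf_db()
  expect_length(queryVariants(queryFilter(gene_symbol = "BRAF",
                                          min_depth = 500), db), 0L)
  fda <- queryVariants(queryFilter(
    annotation_class = "fda_qualified_biomarker"), db)
  expect_length(fda, 1L)
  expect_identical(fda[[1]]$alteration$gene_symbol, "BRAF")
  expect_error(queryFilter(), "at least one constraint",
               class = "cgdm_usage_error")
  expect_error(queryFilter(min_depth = -1), class = "cgdm_value_error")
})

test_that("new annotations change annotation-filtered queries without touching variants", {
  db <- braf_db()
  before <- nrow(dbTable(db, "GenomicAlteration"))
  acmg <- function() queryVariants(queryFilter(annotation_class = "acmg_actionable"), db)
  expect_length(acmg(), 0L)
  ga <- dbTable(db, "GenomicAlteration")
  cgdm:::.insert_rows(db, "ClinicalAnnotation", data.frame(
    alteration_id = ga$alteration_id[ga$chromosome == "12"],
    annotation_class = "acmg_actionable", annotation_value = "reclassified",
    stringsAsFactors = FALSE))
  expect_length(acmg(), 1L)
  expect_identical(nrow(dbTable(db, "GenomicAlteration")), before)
})

test_that("PGx genotypes derive from stored variants plus coverage evidence", {
  resetSchema()
  defs <- loadAlleleDefinitions()
  cohort <- makePgxCohort(fixtureSpec(seed = 5))
  db <- initDb()
  loadPgxCohort(cohort, db)
  for (i in seq_len(nrow(cohort$expected))) {
    e <- cohort$expected[i, ]
    g <- derivePgxGenotype(e$subject, db, defs)
    expect_identical(g$cyp2c9_star, e$cyp2c9_star)
    expect_identical(g$vkorc1_1639, e$vkorc1_1639)
  }
  # direct spot checks of the mapping
  het3 <- cohort$expected$subject[cohort$expected$cyp2c9_star == "*1/*3"]
  expect_identical(derivePgxGenotype(het3, db, defs)$cyp2c9_star, "*1/*3")
  hom_aa <- cohort$expected$subject[cohort$expected$vkorc1_1639 == "AA"][1]
  expect_identical(derivePgxGenotype(hom_aa, db, defs)$vkorc1_1639, "AA")
  # no coverage evidence -> unknown, never inferred reference
  expect_identical(derivePgxGenotype("PGX99", db, defs)$cyp2c9_star, "unknown")
})

test_that("conflicting zygosity evidence is a data-inconsistency error", {
  resetSchema()
  db <- initDb()
  defs <- loadAlleleDefinitions()
  cgdm:::.insert_rows(db, "ClinicalIdentifier", data.frame(
    institution_id = "I", subject_id = "S1", test_id = "T1"))
  cgdm:::.insert_rows(db, "QualityCheck", data.frame(
    test_id = "T1", depth_of_coverage = 50, mapping_quality = 99))
  # three CYP2C9 variant alleles cannot exist in a diploid genotype
  cgdm:::.insert_rows(db, "GenomicAlteration", data.frame(
    test_id = "T1", subject_id = "S1", genome_build = "GRCh37",
    chromosome = "10", position = c(96702047L, 96741053L),
    ref_allele = c("C", "A"), alt_allele = c("T", "C"),
    zygosity = c("homozygous", "heterozygous"), stringsAsFactors = FALSE))
  expect_error(derivePgxGenotype("S1", db, defs), "alterations",
               class = "cgdm_data_inconsistency")
})

test_that("IWPC dosing matches the arithmetic oracle across the covariate grid", {
  coef <- loadDosingCoefficients()
  grid <- expand.grid(age = c(3, 6, 9), ht = c(152, 178), wt = c(55, 95),
                      race = c("white", "asian", "black", "mixed_or_missing"),
                      ind = c(FALSE, TRUE), amio = c(FALSE, TRUE),
                      cyp = c("*1/*1", "*1/*2", "*1/*3", "*2/*2", "*2/*3", "*3/*3"),
                      vk = c("GG", "GA", "AA"), stringsAsFactors = FALSE)
  idx <- seq(1L, nrow(grid), by = 7L)             # 1/7 stratified subsample
  for (i in idx) {
    g <- grid[i, ]
    res <- iwpcWarfarinDose(dosingInput(g$age, g$ht, g$wt, g$race, g$ind,
                                        g$amio, pgx_genotype(g$cyp, g$vk)),
                            coefficients = coef)
    expect_equal(res$weekly_dose_mg,
                 oracle_iwpc(g$age, g$ht, g$wt, g$race, g$ind, g$amio,
                             g$cyp, g$vk), tolerance = 1e-12)
    expect_gt(res$weekly_dose_mg, 0)
    expect_equal(res$daily_dose_mg * 7, res$weekly_dose_mg)
    expect_equal(sum(res$audit$contribution), res$sqrt_dose)
  }
})

test_that("dose decreases in VKORC1 A-allele and CYP2C9 variant-allele count", {
  coef <- loadDosingCoefficients()
  base <- function(cyp, vk)
    iwpcWarfarinDose(dosingInput(6, 170, 75, "white", FALSE, FALSE,
                                 pgx_genotype(cyp, vk)),
                     coefficients = coef)$weekly_dose_mg
  for (cyp in c("*1/*1", "*1/*3", "*3/*3")) {
    expect_gt(base(cyp, "GG"), base(cyp, "GA"))
    expect_gt(base(cyp, "GA"), base(cyp, "AA"))
  }
  for (vk in c("GG", "GA", "AA")) {
    expect_gt(base("*1/*1", vk), base("*1/*2", vk))
    expect_gt(base("*1/*2", vk), base("*2/*2", vk))
    expect_gt(base("*1/*3", vk), base("*3/*3", vk))
    expect_gt(base("*2/*2", vk), base("*2/*3", vk))
  }
  # age enters only through its own term: doubling age changes the
  # sqrt-dose by exactly the age coefficient times the difference
  d1 <- iwpcWarfarinDose(dosingInput(4, 170, 75, "white", FALSE, FALSE,
                                     pgx_genotype("*1/*1", "GG")))
  d2 <- iwpcWarfarinDose(dosingInput(8, 170, 75, "white", FALSE, FALSE,
                                     pgx_genotype("*1/*1", "GG")))
  expect_equal(d1$sqrt_dose - d2$sqrt_dose, 0.2614 * 4, tolerance = 1e-12)
})

test_that("unknown genotypes dispatch to the clinical fallback model", {
  inp <- dosingInput(6, 170, 75, "white", FALSE, FALSE,
                     pgx_genotype("unknown", "GG"))
  res <- iwpcWarfarinDose(inp)
  expect_identical(res$model, "clinical")
  expect_match(res$audit_note, "clinical algorithm")
  expect_equal(res$weekly_dose_mg,
               oracle_iwpc(6, 170, 75, "white", FALSE, FALSE, NA, NA,
                           model = "clinical"), tolerance = 1e-12)
  # explicitly requesting the genetic model refuses with guidance
  expect_error(iwpcWarfarinDose(inp, model = "pharmacogenetic"),
               "clinical .*fallback", class = "cgdm_value_error")
  # covariates may never be silently imputed
  expect_error(dosingInput(NA, 170, 75, "white", FALSE, FALSE,
                           pgx_genotype("*1/*1", "GG")),
               "imputation", class = "cgdm_value_error")
})

test_that("rules trigger deterministically with full traceability", {
  db <- braf_db()
  rules <- loadCdsRules(system.file("extdata", "example_cds_rules.yaml",
                                    package = "cgdm"))
  alert_rule <- rules[[1]]
  hits <- evaluateRules("S1", list(alert_rule), db)
  expect_length(hits, 1L)
  expect_identical(hits[[1]]$rule_id, "braf-v600e-alert")
  expect_match(hits[[1]]$knowledge_ref, "melanoma")
  ga <- dbTable(db, "GenomicAlteration")
  expect_identical(hits[[1]]$alteration_ids,
                   ga$alteration_id[ga$gene_symbol %in% "BRAF"])
  # pure function of database state: identical on re-evaluation
  expect_identical(evaluateRules("S1", list(alert_rule), db), hits)
  # a subject with no matching data triggers nothing
  expect_length(evaluateRules("NOBODY", list(alert_rule), db), 0L)
  # misconfigured dosing rules fail at validation time
  expect_error(cdsRule("bad", list(genotype = TRUE), "dose_calculation",
                       parameters = list(dosing_function = "nosuch")),
               "unregistered", class = "cgdm_config_error")
  expect_error(cdsRule("empty", list(), "alert"), class = "cgdm_config_error")
})

test_that("a dose rule reproduces the standalone dosing calculation", {
  resetSchema()
  cohort <- makePgxCohort(fixtureSpec(seed = 9))
  db <- initDb()
  loadPgxCohort(cohort, db)
  defs <- loadAlleleDefinitions()
  subj <- cohort$expected$subject[cohort$expected$cyp2c9_star == "*1/*2"]
  rule <- cdsRule("warfarin", list(genotype = TRUE), "dose_calculation",
                  knowledge_ref = "IWPC-2009",
                  parameters = list(dosing_function = "iwpc_warfarin",
                                    age_decades = 7, height_cm = 168,
                                    weight_kg = 82, race_group = "asian",
                                    enzyme_inducer = FALSE, amiodarone = TRUE))
  hits <- evaluateRules(subj, list(rule), db)
  expect_length(hits, 1L)
  standalone <- iwpcWarfarinDose(dosingInput(
    7, 168, 82, "asian", FALSE, TRUE, derivePgxGenotype(subj, db, defs)))
  expect_equal(hits[[1]]$dose$weekly_dose_mg, standalone$weekly_dose_mg)
  expect_identical(hits[[1]]$dose$model, "pharmacogenetic")
  expect_identical(hits[[1]]$genotype$cyp2c9_star, "*1/*2")
})
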