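test_that("VCF genotypes map to zygosity, phasing and missingness", {
  vcf <- write_mini_vcf(tempfile(fileext = ".vcf"), c(
    "10\t11805838\t.\tCG\tCTG\t.\tPASS\t.\tGT\t0/1",
    "7\t140453136\t.\tA\tT\t.\tPASS\t.\tGT\t1|1",
    "7\t140453200\t.\tG\tC\t.\tPASS\t.\tGT\t./.",
    "X\t5000\t.\tT\tA\t.\tPASS\t.\tGT\t1"))
  recs <- readVcfVariants(vcf)
  expect_length(recs, 4L)
  expect_identical(recs[[1]]$variant$ref_allele, "CG")
  expect_identical(recs[[1]]$zygosity, "heterozygous")
  expect_identical(recs[[1]]$phasing, "unphased")
  expect_identical(recs[[2]]$zygosity, "homozygous")
  expect_identical(recs[[2]]$phasing, "phased")
  expect_true(recs[[3]]$missing_flag)
  expect_identical(recs[[4]]$zygosity, "hemizygous")
  expect_identical(nrow(attr(recs, "rejects")), 0L)
})

test_that("multi-allelic sites split and symbolic or malformed records reject", {
  vcf <- write_mini_vcf(tempfile(fileext = ".vcf"), c(
    "1\t100\t.\tA\tT,C\t.\tPASS\t.\tGT\t1/2",
    "1\t200\t.\tG\t<DEL>\t.\tPASS\t.\tGT\t0/1",
    "1\t300\tbroken-line"))
  recs <- readVcfVariants(vcf)
  expect_length(recs, 2L)                 # one per alt of the 1/2 genotype
  alts <- vapply(recs, function(r) r$variant$alt_allele, character(1))
  expect_setequal(alts, c("T", "C"))
  expect_true(all(vapply(recs, `[[`, character(1), "zygosity") == "heterozygous"))
  rej <- attr(recs, "rejects")
  expect_identical(nrow(rej), 2L)
  expect_setequal(rej$reason, c("symbolic allele", "malformed line"))
  # a header-less file is a format error, not a per-record rejection
  noheader <- tempfile(fileext = ".vcf")
  writeLines("1\t100\t.\tA\tT\t.\tPASS\t.", noheader)
  expect_error(readVcfVariants(noheader), "header", class = "cgdm_format_error")
})

test_that("MAF rows convert to anchored VCF-style records", {
  maf <- tempfile(fileext = ".maf")
  write.table(data.frame(
    Hugo_Symbol = c("BRAF", "BRAF", "KRAS", "TP53"),
    Chromosome = c("7", "7", "12", "17"),
    Start_Position = c(140453136L, 140753336L, 25398280L, 7578400L),
    Reference_Allele = c("A", "A", "-", "CAG"),
    Tumor_Seq_Allele2 = c("T", "T", "TTT", "-"),
    Variant_Classification = c("Missense_Mutation", "Missense_Mutation",
                               "Frame_Shift_Ins", "Frame_Shift_Del"),
    NCBI_Build = c("GRCh37", "GRCh38", "GRCh37", "GRCh37"),
    Tumor_Sample_Barcode = "TCGA-01", stringsAsFactors = FALSE),
    maf, sep = "\t", row.names = FALSE, quote = FALSE)
  recs <- readMafVariants(maf)
  expect_length(recs, 4L)
  # build travels with each record
  expect_identical(recs[[1]]$variant$genome_build, "GRCh37")
  expect_identical(recs[[2]]$variant$genome_build, "GRCh38")
  expect_identical(recs[[2]]$variant$position, 140753336L)
  # insertion: "-" reference becomes an N-anchored allele pair
  expect_identical(recs[[3]]$variant$ref_allele, "N")
  expect_identical(recs[[3]]$variant$alt_allele, "NTTT")
  expect_true(recs[[3]]$anchor_synthesized)
  # deletion: anchor position one base left of the first deleted base
  expect_identical(recs[[4]]$variant$position, 7578399L)
  expect_identical(recs[[4]]$variant$ref_allele, "NCAG")
  expect_identical(recs[[4]]$variant$alt_allele, "N")
  # a header-only file yields an empty record set
  empty <- tempfile(fileext = ".maf")
  writeLines(paste(c("Hugo_Symbol", "Chromosome", "Start_Position",
                     "Reference_Allele", "Tumor_Seq_Allele2",
                     "Variant_Classification", "NCBI_Build"),
                   collapse = "\t"), empty)
  expect_length(readMafVariants(empty), 0L)
  # missing required columns are named in the error
  bad <- tempfile(fileext = ".maf")
  writeLines("Hugo_Symbol\tChromosome", bad)
  expect_error(readMafVariants(bad), "Start_Position",
               class = "cgdm_format_error")
})

test_that("loading dedupes equivalent spellings and conserves record counts", {
  resetSchema()
  db <- initDb()
  vcf <- write_mini_vcf(tempfile(fileext = ".vcf"), c(
    "10\t11805838\t.\tC\tCT\t.\tPASS\t.\tGT\t0/1",
    "10\t11805838\t.\tCG\tCTG\t.\tPASS\t.\tGT\t0/1"))
  rep <- loadDataset(fixture_manifest(vcf, build = "GRCh37"), db)
  expect_identical(rep$records_read, 2L)
  expect_identical(rep$records_loaded + rep$records_rejected, rep$records_read)
  ga <- dbTable(db, "GenomicAlteration")
  expect_identical(nrow(ga), 1L)
  expect_identical(ga$position, 11805838L)
  expect_identical(rep$merged, 1L)
  # the merge is visible in provenance
  pp <- dbTable(db, "PipelineProvenance")
  expect_true(any(pp$step == "normalization-dedup" & pp$parameters == "merged=1"))
  expect_length(referentialViolations(db), 0L)
})

test_that("a full fixture load satisfies conservation, determinism and round trip", {
  resetSchema()
  spec <- fixtureSpec(seed = 21, n_subjects = 4, n_variants_per_subject = 6,
                      fraction_nonminimal = 0.7)
  win <- makeReferenceWindow(spec)
  fa <- tempfile(fileext = ".fasta")
  fx <- makeVcf(spec, win, fasta_path = fa)
  load_once <- function() {
    db <- initDb()
    rep <- loadDataset(fixture_manifest(fx$path, mode = "full", fasta = fa), db)
    list(db = db, rep = rep)
  }
  r1 <- load_once(); r2 <- load_once()
  expect_identical(r1$rep$records_read,
                   r1$rep$records_loaded + r1$rep$records_rejected)
  expect_identical(entityCounts(r1$db), entityCounts(r2$db))       # determinism
  ga <- dbTable(r1$db, "GenomicAlteration")
  expect_identical(nrow(ga), nrow(fx$truth))                       # dedup to truth
  expect_identical(nrow(dbTable(r1$db, "ClinicalIdentifier")), spec$n_subjects)
  # export -> reload reproduces the normalized records byte-wise
  out <- tempfile(fileext = ".vcf")
  exportVcf(r1$db, out)
  db2 <- initDb()
  loadDataset(fixture_manifest(out, mode = "full", fasta = fa), db2)
  key <- function(d) sort(paste(d$subject_id, d$genome_build, d$chromosome,
                                d$position, d$ref_allele, d$alt_allele))
  expect_identical(key(dbTable(db2, "GenomicAlteration")), key(ga))
})

test_that("a failing load leaves the store untouched", {
  resetSchema()
  db <- initDb()
  vcf <- write_mini_vcf(tempfile(fileext = ".vcf"),
                        "10\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/1")
  before <- entityCounts(db)
  man <- fixture_manifest(vcf)
  # poison a post-variant step: an annotation with an illegal allele string
  man$annotations <- data.frame(chromosome = "10", position = 100,
                                ref_allele = "?", alt_allele = "T",
                                annotation_class = "fda_qualified_biomarker",
                                annotation_value = "x", stringsAsFactors = FALSE)
  expect_error(loadDataset(man, db))
  expect_identical(entityCounts(db), before)        # transaction rolled back
  expect_identical(sum(entityCounts(db)), 0L)
})

test_that("manifest-supplied QC and annotations land in their entities", {
  resetSchema()
  db <- initDb()
  vcf <- write_mini_vcf(tempfile(fileext = ".vcf"),
                        "7\t140453136\t.\tA\tT\t.\tPASS\t.\tGT\t0/1")
  man <- fixture_manifest(vcf, build = "GRCh37",
                          qc = list(base_quality = 32, depth_of_coverage = 80,
                                    mapping_quality = 98.5))
  man$annotations <- data.frame(chromosome = "7", position = 140453136,
                                ref_allele = "A", alt_allele = "T",
                                annotation_class = "fda_qualified_biomarker",
                                annotation_value = "BRAF V600E biomarker",
                                stringsAsFactors = FALSE)
  loadDataset(man, db)
  expect_identical(nrow(dbTable(db, "QualityCheck")), 1L)
  expect_identical(dbTable(db, "QualityCheck")$mapping_quality, 98.5)
  ca <- dbTable(db, "ClinicalAnnotation")
  expect_identical(nrow(ca), 1L)
  expect_identical(ca$annotation_class, "fda_qualified_biomarker")
  expect_length(referentialViolations(db), 0L)
})

test_that("MAF ingestion records trim-only normalization", {
  resetSchema()
  db <- initDb()
  spec <- fixtureSpec(seed = 31, n_variants_per_subject = 6)
  mf <- makeMaf(spec)
  man <- etlManifest(source_path = mf$path, source_format = "MAF",
                     test_id = "T-MAF", genome_build = spec$build_label,
                     pipeline_provenance = list(provenanceRecord(
                       "variant_calling", tool_name = "caller",
                       origin_build = spec$build_label)),
                     normalization_mode = "trim_only",
                     reject_path = tempfile())
  rep <- loadDataset(man, db)
  expect_identical(rep$records_rejected, 0L)
  ga <- dbTable(db, "GenomicAlteration")
  expect_identical(nrow(ga), nrow(mf$truth))
  expect_true(all(ga$normalization_mode == "trim_only"))
  got <- ga[order(ga$position), c("chromosome", "position", "ref_allele",
                                  "alt_allele")]
  want <- mf$truth[order(mf$truth$position), ]
  rownames(got) <- rownames(want) <- NULL
  expect_identical(got, want)
  # annotation columns came along
  expect_true(all(grepl("^GENE", ga$gene_symbol)))
})
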