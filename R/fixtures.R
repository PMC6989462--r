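## ---------------------------------------------------------------------------
## Synthetic fixtures
##
## Self-contained generators for reference windows with controlled tandem
## repeats, VCF/MAF files containing equivalent-but-differently-spelled
## variants, and PGx cohorts with known diplotypes. Non-minimal spellings
## are produced by reversing the normalization operators (padding shared
## bases, right-shifting within the repeat tract), so equivalence holds by
## construction. The fixture genome build is labelled "FIXTURE1" so that
## accidental joins against real builds are impossible. All generators are
## deterministic under the spec seed.
## ---------------------------------------------------------------------------

#' Specify a fixture generation run
#'
#' @param seed Integer RNG seed; identical spec + seed gives byte-identical
#'   outputs.
#' @param n_subjects,n_variants_per_subject Cohort shape.
#' @param fraction_nonminimal Proportion of variants additionally emitted in
#'   a non-minimal spelling, in `[0, 1]`.
#' @param repeat_context_length Length (bases) of each embedded tandem
#'   repeat tract.
#' @param build_label Genome-build label stamped on all fixture records.
#' @return A `FixtureSpec` list.
#' @export
fixtureSpec <- function(seed = 1L, n_subjects = 5L, n_variants_per_subject = 10L,
                        fraction_nonminimal = 0.5, repeat_context_length = 6L,
                        build_label = "FIXTURE1") {
  if (fraction_nonminimal < 0 || fraction_nonminimal > 1)
    .cgdm_error("fraction_nonminimal must lie in [0, 1]", "cgdm_value_error")
  if (n_subjects < 0 || n_variants_per_subject < 0)
    .cgdm_error("counts must be non-negative", "cgdm_value_error")
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 n_variants_per_subject = as.integer(n_variants_per_subject),
                 fraction_nonminimal = fraction_nonminimal,
                 repeat_context_length = as.integer(repeat_context_length),
                 build_label = build_label),
            class = "FixtureSpec")
}

.rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

## Slot layout: each variant lives in its own 60 bp slot so that distinct
## true variants can never normalize onto each other.
.slot_len <- 60L
.max_indel <- 12L

#' Generate a reference window with embedded tandem repeats
#'
#' The window is divided into 60 bp slots, each carrying one tandem repeat
#' tract of `repeat_context_length` bases placed at least the maximal indel
#' length away from the slot (and window) edges, so left alignment never
#' runs out of context on fixture variants.
#'
#' @param spec A [fixtureSpec()].
#' @param n_slots Number of slots (default: one per fixture variant).
#' @return A `ReferenceWindow` on chromosome `"F1"` with
#'   `attr(, "tracts")`: data.frame `slot`, `start`, `end`, `unit`
#'   (window-relative 1-based coordinates).
#' @export
makeReferenceWindow <- function(spec,
                                n_slots = spec$n_subjects * spec$n_variants_per_subject) {
  set.seed(spec$seed)
  n_slots <- max(n_slots, 1L)
  parts <- character(n_slots)
  tracts <- vector("list", n_slots)
  for (i in seq_len(n_slots)) {
    unit_len <- sample(1:3, 1L)
    unit <- .rand_seq(unit_len)
    reps <- max(2L, ceiling(spec$repeat_context_length / unit_len))
    tract <- paste(rep(unit, reps), collapse = "")
    lead <- .rand_seq(20L)
    ## avoid accidental tract extension at the seams
    while (substr(lead, 20L, 20L) == substr(tract, nchar(tract), nchar(tract)))
      lead <- .rand_seq(20L)
    tail_len <- .slot_len - 20L - nchar(tract)
    trail <- .rand_seq(tail_len)
    while (substr(trail, 1L, 1L) == substr(unit, 1L, 1L))
      trail <- .rand_seq(tail_len)
    parts[i] <- paste0(lead, tract, trail)
    tracts[[i]] <- data.frame(slot = i, start = (i - 1L) * .slot_len + 21L,
                              end = (i - 1L) * .slot_len + 20L + nchar(tract),
                              unit = unit, stringsAsFactors = FALSE)
  }
  win <- referenceWindow("F1", 1L, paste(parts, collapse = ""), spec$build_label)
  attr(win, "tracts") <- do.call(rbind, tracts)
  win
}

## rightmost equivalent spelling via whole-sequence comparison (prefix trim
## first, then suffix), used to reverse left alignment.
.rightmost_spelling <- function(v, win) {
  S <- win$sequence
  E <- applyVariant(v, win)
  sv <- utf8ToInt(S); ev <- utf8ToInt(E)
  ls <- length(sv); le <- length(ev)
  n <- min(ls, le)
  d1 <- which(sv[seq_len(n)] != ev[seq_len(n)])
  cp <- if (length(d1)) d1[1] - 1L else n
  d2 <- which(rev(sv)[seq_len(n)] != rev(ev)[seq_len(n)])
  cs <- min(if (length(d2)) d2[1] - 1L else n, n - cp)
  ref <- substr(S, cp + 1L, ls - cs)
  alt <- substr(E, cp + 1L, le - cs)
  pos <- win$start + cp
  if (!nzchar(ref) || !nzchar(alt)) {
    anchor <- substr(S, cp, cp)
    ref <- paste0(anchor, ref); alt <- paste0(anchor, alt)
    pos <- win$start + cp - 1L
  }
  rawVariant(v$chromosome, pos, ref, alt, v$genome_build)
}

.pad_spelling <- function(v, win) {
  nxt_pos <- v$position + nchar(v$ref_allele)
  if (nxt_pos <= win$end) {
    b <- .window_sub(win, nxt_pos, nxt_pos)
    rawVariant(v$chromosome, v$position, paste0(v$ref_allele, b),
               paste0(v$alt_allele, b), v$genome_build)
  } else v
}

.make_slot_variant <- function(win, tract, type = c("indel", "snv")) {
  type <- match.arg(type)
  chrom <- win$chromosome; build <- win$genome_build
  if (type == "snv") {
    pos <- tract$start - sample(5:15, 1L)
    ref <- .window_sub(win, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    return(rawVariant(chrom, pos, ref, alt, build))
  }
  unit <- tract$unit
  anchor_pos <- tract$start - 1L
  anchor <- .window_sub(win, anchor_pos, anchor_pos)
  if (runif(1) < 0.5) {        # insertion of one repeat unit at the left edge
    rawVariant(chrom, anchor_pos, anchor, paste0(anchor, unit), build)
  } else {                     # deletion of one repeat unit from the left edge
    rawVariant(chrom, anchor_pos, paste0(anchor, unit), anchor, build)
  }
}

#' Generate a corpus of indel spellings with known normal forms
#'
#' Each case holds one true indel and one spelling drawn from
#' {minimal, padded, right-shifted, padded right-shifted}. Intended for
#' property testing of the normalizer against the exhaustive
#' whole-sequence oracle.
#'
#' @param spec A [fixtureSpec()].
#' @param n Number of cases.
#' @return List with `window` and `cases`, each case a list
#'   `spelling` (`RawVariant`) and `truth` (leftmost minimal `RawVariant`).
#' @export
makeIndelCorpus <- function(spec, n = 1000L) {
  win <- makeReferenceWindow(spec, n_slots = n)
  tracts <- attr(win, "tracts")
  set.seed(spec$seed + 1L)
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    v <- .make_slot_variant(win, tracts[i, ], "indel")
    truth <- v                                   # constructed leftmost minimal
    sp <- v
    style <- sample(c("minimal", "pad", "shift", "pad_shift"), 1L)
    if (style %in% c("shift", "pad_shift")) sp <- .rightmost_spelling(sp, win)
    if (style %in% c("pad", "pad_shift")) sp <- .pad_spelling(sp, win)
    cases[[i]] <- list(spelling = sp, truth = truth, style = style)
  }
  list(window = win, cases = cases)
}

.vcf_header <- function(subjects, build) {
  c("##fileformat=VCFv4.2",
    paste0("##reference=", build),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", subjects), collapse = "\t"))
}

#' Generate a multi-sample fixture VCF with a truth manifest
#'
#' Each true variant belongs to one subject and is emitted in its minimal
#' spelling plus, with probability `fraction_nonminimal`, an equivalent
#' non-minimal spelling (padded and/or right-shifted). The truth manifest
#' records the unique normalized form of every true variant; the
#' manifest size therefore equals the expected GenomicAlteration row count
#' after a normalizing, deduplicating load.
#'
#' @param spec A [fixtureSpec()].
#' @param window Window from [makeReferenceWindow()] (generated if `NULL`).
#' @param path Output VCF path.
#' @param fasta_path Optional path to also write the window as FASTA.
#' @return List: `path`, `fasta_path`, `window`, `truth` (data.frame
#'   `subject`, `chromosome`, `position`, `ref_allele`, `alt_allele`,
#'   `genome_build`, `zygosity`), `records_emitted`.
#' @export
makeVcf <- function(spec, window = NULL, path = tempfile(fileext = ".vcf"),
                    fasta_path = NULL) {
  if (is.null(window)) window <- makeReferenceWindow(spec)
  tracts <- attr(window, "tracts")
  set.seed(spec$seed + 2L)
  subjects <- sprintf("SUBJ%02d", seq_len(spec$n_subjects))
  n_total <- spec$n_subjects * spec$n_variants_per_subject
  lines <- list(); truth <- list()
  slot <- 0L
  for (s in subjects) {
    for (j in seq_len(spec$n_variants_per_subject)) {
      slot <- slot + 1L
      type <- if (j %% 2L == 0L) "snv" else "indel"
      v <- .make_slot_variant(window, tracts[slot, ], type)
      nv <- normalizeVariant(v, window)
      zyg <- sample(c("heterozygous", "homozygous"), 1L)
      gt <- if (zyg == "heterozygous") "0/1" else "1/1"
      gts <- setNames(rep("0/0", length(subjects)), subjects)
      gts[s] <- gt
      emit <- function(var) paste(c(var$chromosome, var$position, ".",
                                    var$ref_allele, var$alt_allele, ".",
                                    "PASS", ".", "GT", gts), collapse = "\t")
      lines[[length(lines) + 1L]] <- c(pos = v$position, line = emit(v))
      if (runif(1) < spec$fraction_nonminimal) {
        alt_sp <- if (type == "indel" && runif(1) < 0.5)
          .pad_spelling(.rightmost_spelling(v, window), window)
        else .pad_spelling(v, window)
        lines[[length(lines) + 1L]] <- c(pos = alt_sp$position,
                                         line = emit(alt_sp))
      }
      truth[[length(truth) + 1L]] <- data.frame(
        subject = s, chromosome = nv$chromosome, position = nv$position,
        ref_allele = nv$ref_allele, alt_allele = nv$alt_allele,
        genome_build = nv$genome_build, zygosity = zyg,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, lapply(lines, function(x)
    data.frame(pos = as.integer(x["pos"]), line = x["line"],
               stringsAsFactors = FALSE)))
  df <- df[order(df$pos), , drop = FALSE]
  writeLines(c(.vcf_header(subjects, spec$build_label), df$line), path)
  if (!is.null(fasta_path))
    writeLines(c(paste0(">", window$chromosome), window$sequence), fasta_path)
  list(path = path, fasta_path = fasta_path, window = window,
       truth = do.call(rbind, truth), records_emitted = nrow(df))
}

#' Generate a small fixture MAF
#'
#' Emits SNV rows plus MAF-convention ("-" allele) insertion and deletion
#' rows derived from the same window, with a truth manifest of trim-only
#' normalized forms.
#'
#' @param spec A [fixtureSpec()].
#' @param window Window from [makeReferenceWindow()] (generated if `NULL`).
#' @param path Output MAF path.
#' @return List: `path`, `truth` data.frame.
#' @export
makeMaf <- function(spec, window = NULL, path = tempfile(fileext = ".maf")) {
  if (is.null(window)) window <- makeReferenceWindow(spec)
  tracts <- attr(window, "tracts")
  set.seed(spec$seed + 3L)
  n <- min(nrow(tracts), spec$n_variants_per_subject)
  rows <- list(); truth <- list()
  for (i in seq_len(n)) {
    v <- .make_slot_variant(window, tracts[i, ],
                            if (i %% 2L == 0L) "snv" else "indel")
    lr <- nchar(v$ref_allele); la <- nchar(v$alt_allele)
    if (lr == 1L && la == 1L) {
      row <- data.frame(Hugo_Symbol = sprintf("GENE%03d", i),
                        Chromosome = v$chromosome,
                        Start_Position = v$position,
                        Reference_Allele = v$ref_allele,
                        Tumor_Seq_Allele2 = v$alt_allele,
                        Variant_Classification = "Missense_Mutation",
                        NCBI_Build = spec$build_label,
                        Tumor_Sample_Barcode = "TUMOR01",
                        stringsAsFactors = FALSE)
    } else if (la > lr) {      # insertion: drop the anchor, "-" reference
      row <- data.frame(Hugo_Symbol = sprintf("GENE%03d", i),
                        Chromosome = v$chromosome,
                        Start_Position = v$position,
                        Reference_Allele = "-",
                        Tumor_Seq_Allele2 = substring(v$alt_allele, 2L),
                        Variant_Classification = "Frame_Shift_Ins",
                        NCBI_Build = spec$build_label,
                        Tumor_Sample_Barcode = "TUMOR01",
                        stringsAsFactors = FALSE)
    } else {                   # deletion: drop the anchor, "-" tumour allele
      row <- data.frame(Hugo_Symbol = sprintf("GENE%03d", i),
                        Chromosome = v$chromosome,
                        Start_Position = v$position + 1L,
                        Reference_Allele = substring(v$ref_allele, 2L),
                        Tumor_Seq_Allele2 = "-",
                        Variant_Classification = "Frame_Shift_Del",
                        NCBI_Build = spec$build_label,
                        Tumor_Sample_Barcode = "TUMOR01",
                        stringsAsFactors = FALSE)
    }
    rows[[i]] <- row
    ## expectation after MAF ingestion: indel anchors are synthesized as "N"
    truth[[i]] <- if (lr == la)
      data.frame(chromosome = v$chromosome, position = v$position,
                 ref_allele = v$ref_allele, alt_allele = v$alt_allele,
                 stringsAsFactors = FALSE)
    else
      data.frame(chromosome = v$chromosome, position = v$position,
                 ref_allele = paste0("N", substring(v$ref_allele, 2L)),
                 alt_allele = paste0("N", substring(v$alt_allele, 2L)),
                 stringsAsFactors = FALSE)
  }
  write.table(do.call(rbind, rows), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  list(path = path, truth = do.call(rbind, truth))
}

#' Generate a PGx cohort with known diplotypes
#'
#' Subjects cover every CYP2C9 diplotype in the closed set (`*1/*1` ...
#' `*3/*3`) with VKORC1 -1639 states cycled across them; emitted genotypes
#' realise the assignment exactly, so the expected table is a
#' construction-by-definition oracle for [derivePgxGenotype()]. One
#' additional subject is emitted with no coverage evidence (no QualityCheck
#' row) and expected genotype `unknown`.
#'
#' @param spec A [fixtureSpec()] (seed shuffles subject order only).
#' @param allele_definitions Table from [loadAlleleDefinitions()].
#' @param path Output VCF path.
#' @return List: `path`, `expected` (data.frame `subject`, `cyp2c9_star`,
#'   `vkorc1_1639`, `covered`), `covariates` (data.frame of dosing
#'   covariates per subject), `build`.
#' @export
makePgxCohort <- function(spec, allele_definitions = loadAlleleDefinitions(),
                          path = tempfile(fileext = ".vcf")) {
  defs <- allele_definitions
  build <- unique(defs$genome_build)[1]
  diplos <- c("*1/*1", "*1/*2", "*1/*3", "*2/*2", "*2/*3", "*3/*3")
  vk_states <- c("GG", "GA", "AA")
  set.seed(spec$seed + 4L)
  assign_df <- data.frame(subject = sprintf("PGX%02d", seq_along(diplos)),
                          cyp2c9_star = diplos,
                          vkorc1_1639 = vk_states[(seq_along(diplos) - 1L) %% 3L + 1L],
                          covered = TRUE, stringsAsFactors = FALSE)
  assign_df <- assign_df[sample(nrow(assign_df)), , drop = FALSE]
  uncovered <- data.frame(subject = "PGX99", cyp2c9_star = "unknown",
                          vkorc1_1639 = "unknown", covered = FALSE,
                          stringsAsFactors = FALSE)
  expected <- rbind(assign_df, uncovered)
  subjects <- expected$subject
  sites <- defs[order(defs$chromosome, defs$position), , drop = FALSE]
  count_for <- function(diplo, allele) {
    if (diplo == "unknown") return(0L)
    sum(strsplit(diplo, "/", fixed = TRUE)[[1]] == allele)
  }
  gt_of <- function(n) c("0/0", "0/1", "1/1")[n + 1L]
  lines <- vapply(seq_len(nrow(sites)), function(i) {
    st <- sites[i, ]
    gts <- vapply(seq_len(nrow(expected)), function(k) {
      e <- expected[k, ]
      n <- if (st$gene == "CYP2C9") count_for(e$cyp2c9_star, st$allele)
           else sum(strsplit(
             c(GG = "G/G", GA = "G/A", AA = "A/A",
               unknown = "G/G")[[e$vkorc1_1639]], "/")[[1]] == "A")
      gt_of(n)
    }, character(1))
    paste(c(st$chromosome, st$position, st$rsid, st$ref_allele, st$alt_allele,
            ".", "PASS", ".", "GT", gts), collapse = "\t")
  }, character(1))
  writeLines(c(.vcf_header(subjects, build), lines), path)
  covariates <- data.frame(
    subject = subjects,
    age_decades = sample(4:9, length(subjects), replace = TRUE),
    height_cm = round(runif(length(subjects), 150, 195)),
    weight_kg = round(runif(length(subjects), 50, 110)),
    race_group = sample(c("white", "asian", "black", "mixed_or_missing"),
                        length(subjects), replace = TRUE),
    enzyme_inducer = sample(c(TRUE, FALSE), length(subjects), replace = TRUE),
    amiodarone = sample(c(TRUE, FALSE), length(subjects), replace = TRUE),
    stringsAsFactors = FALSE)
  list(path = path, expected = expected, covariates = covariates, build = build)
}

#' Load a PGx cohort VCF subject-by-subject
#'
#' Each subject is loaded as its own test so that coverage evidence
#' (QualityCheck) can differ per subject; covered subjects get a QC row,
#' uncovered ones do not.
#'
#' @param cohort Result of [makePgxCohort()].
#' @param db A [CgdmDb].
#' @return Invisibly, the list of LoadReports.
#' @export
loadPgxCohort <- function(cohort, db) {
  reports <- lapply(seq_len(nrow(cohort$expected)), function(i) {
    e <- cohort$expected[i, ]
    man <- etlManifest(
      source_path = cohort$path, source_format = "VCF",
      test_id = paste0("T-", e$subject), genome_build = cohort$build,
      pipeline_provenance = list(provenanceRecord(
        "variant_calling", tool_name = "fixturecaller", tool_version = "1.0",
        origin_source = "fixture", origin_version = "1", origin_build = cohort$build)),
      normalization_mode = "trim_only", sample = e$subject,
      qc = if (e$covered) list(base_quality = 30, depth_of_coverage = 60,
                               mapping_quality = 99) else NULL,
      reject_path = tempfile())
    loadDataset(man, db)
  })
  invisible(reports)
}
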