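## ---------------------------------------------------------------------------
## Extract-Transform-Load: VCF and MAF into the clinical genome data model
## ---------------------------------------------------------------------------

#' Describe one pipeline-provenance stage
#'
#' @param stage One of `alignment`, `realignment_recalibration`,
#'   `variant_calling`, `sequence_annotation`, `clinical_annotation`.
#' @param tool_name,tool_version Tool identification.
#' @param step,parameters Free-text step label and key-value parameter string.
#' @param origin_source,origin_version,origin_build Reference data source
#'   name, version and genome assembly. `origin_build` is mandatory for any
#'   stage that assigns genomic coordinates.
#' @param analytics_institution,bioinformatician Actor attribution.
#' @param received_date ISO 8601 timestamp.
#' @return Named list usable in an [etlManifest()] provenance list.
#' @export
provenanceRecord <- function(stage, tool_name = NA, tool_version = NA,
                             step = NA, parameters = NA,
                             origin_source = NA, origin_version = NA,
                             origin_build = NA,
                             analytics_institution = NA,
                             bioinformatician = NA, received_date = NA) {
  coord_stages <- c("alignment", "realignment_recalibration", "variant_calling")
  if (stage %in% coord_stages && (is.na(origin_build) || !nzchar(origin_build)))
    .cgdm_error(paste0("origin_build required for coordinate-assigning stage '",
                       stage, "'"), "cgdm_value_error")
  list(stage = stage, tool_name = tool_name, tool_version = tool_version,
       step = step, parameters = parameters, origin_source = origin_source,
       origin_version = origin_version, origin_build = origin_build,
       analytics_institution = analytics_institution,
       bioinformatician = bioinformatician, received_date = received_date)
}

#' Build an ETL manifest
#'
#' The manifest carries everything a load needs beyond the variant file
#' itself: the test identity, the genome build, the pipeline provenance
#' (which must cover at least the variant-calling stage), the normalization
#' mode, and optional side inputs (reference FASTA for left alignment,
#' quality-check metrics, clinical annotations, subject mapping).
#'
#' @param source_path Path to the VCF or MAF file.
#' @param source_format `"VCF"` or `"MAF"`.
#' @param test_id Test identifier (order ID / accession number).
#' @param genome_build Assembly label; mandatory.
#' @param pipeline_provenance List of [provenanceRecord()]s.
#' @param normalization_mode `"full"` (requires `reference_fasta`) or
#'   `"trim_only"`.
#' @param institution_id,ordering_clinician,submission_date Clinical linkage.
#' @param reference_fasta Optional FASTA path for left alignment.
#' @param sample Optional VCF sample column selection.
#' @param subject_map Optional named vector mapping sample IDs to subject IDs.
#' @param qc Optional data.frame/list with `base_quality`,
#'   `depth_of_coverage`, `mapping_quality`.
#' @param annotations Optional data.frame of clinical annotations with
#'   `chromosome`, `position`, `ref_allele`, `alt_allele`,
#'   `annotation_class`, `annotation_value`.
#' @param experiment Optional named list of ExperimentInfo fields.
#' @param reject_path Sidecar path for rejected records (default:
#'   `<source>.rejects.tsv`).
#' @return An `EtlManifest` list.
#' @export
etlManifest <- function(source_path, source_format = c("VCF", "MAF"),
                        test_id, genome_build,
                        pipeline_provenance = list(),
                        normalization_mode = c("full", "trim_only"),
                        institution_id = "UNSPECIFIED",
                        ordering_clinician = NA,
                        submission_date = NA,
                        reference_fasta = NULL, sample = NULL,
                        subject_map = NULL, qc = NULL, annotations = NULL,
                        experiment = NULL, reject_path = NULL) {
  source_format <- match.arg(source_format)
  normalization_mode <- match.arg(normalization_mode)
  if (missing(genome_build) || is.na(genome_build) || !nzchar(genome_build))
    .cgdm_error("genome_build is mandatory in an ETL manifest", "cgdm_value_error")
  stages <- vapply(pipeline_provenance, `[[`, character(1), "stage")
  if (!"variant_calling" %in% stages)
    .cgdm_error("pipeline provenance must cover at least the variant_calling stage",
                "cgdm_value_error")
  if (normalization_mode == "full" && is.null(reference_fasta))
    .cgdm_error("full normalization requires a reference_fasta", "cgdm_value_error")
  structure(list(source_path = source_path, source_format = source_format,
                 test_id = test_id, genome_build = genome_build,
                 pipeline_provenance = pipeline_provenance,
                 normalization_mode = normalization_mode,
                 institution_id = institution_id,
                 ordering_clinician = ordering_clinician,
                 submission_date = submission_date,
                 reference_fasta = reference_fasta, sample = sample,
                 subject_map = subject_map, qc = qc, annotations = annotations,
                 experiment = experiment,
                 reject_path = if (is.null(reject_path))
                   paste0(source_path, ".rejects.tsv") else reject_path),
            class = "EtlManifest")
}

.parse_gt <- function(gt) {
  ## vcfR surfaces "./." (and absent) genotypes as NA
  if (is.na(gt)) return(list(alleles = ".", phased = FALSE, missing = TRUE))
  gt <- sub(":.*$", "", gt)
  phased <- grepl("|", gt, fixed = TRUE)
  alleles <- strsplit(gt, "[/|]")[[1]]
  list(alleles = alleles, phased = phased,
       missing = all(alleles == ".") || gt == ".")
}

#' Read variant records from a VCF file
#'
#' Parsing of the fixed and genotype fields goes through vcfR. Multi-allelic
#' sites are split into biallelic records (minimal representation is defined
#' per alternative allele); GT fields are mapped to zygosity and phasing;
#' structurally malformed lines and symbolic alleles are rejected per record,
#' never aborting the read.
#'
#' @param path VCF file path (plain or bgzipped).
#' @param sample Optional sample name (default: all samples).
#' @return A list of records, each with elements `variant` ([rawVariant()]
#'   fields minus build), `subject`, `zygosity`, `phasing`, `missing_flag`,
#'   `site` (id/qual/filter). Rejected records are attached as
#'   `attr(, "rejects")` (data.frame `record`, `reason`).
#' @export
readVcfVariants <- function(path, sample = NULL) {
  if (!file.exists(path)) .cgdm_error(paste0("no such file: ", path),
                                      "cgdm_format_error")
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^#CHROM\t", lines)))
    .cgdm_error("VCF header (#CHROM line) missing", "cgdm_format_error")
  body <- which(!startsWith(lines, "#"))
  rejects <- list()
  bad <- body[vapply(lines[body],
                     function(l) length(strsplit(l, "\t", fixed = TRUE)[[1]]) < 8,
                     logical(1))]
  for (b in bad)
    rejects[[length(rejects) + 1L]] <-
      data.frame(record = lines[b], reason = "malformed line",
                 stringsAsFactors = FALSE)
  keep <- setdiff(seq_along(lines), bad)
  tmp <- tempfile(fileext = ".vcf")
  writeLines(lines[keep], tmp)
  on.exit(unlink(tmp), add = TRUE)
  vcf <- vcfR::read.vcfR(tmp, verbose = FALSE)
  fx <- vcfR::getFIX(vcf)
  if (is.null(dim(fx))) fx <- t(fx)            # single-record VCF
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  has_gt <- ncol(vcf@gt) > 1L
  samples <- if (has_gt) colnames(vcf@gt)[-1L] else character(0)
  if (!is.null(sample)) {
    if (!sample %in% samples)
      .cgdm_error(paste0("sample not in VCF: ", sample), "cgdm_format_error")
    samples <- sample
  }
  records <- list()
  for (i in seq_len(nrow(fix))) {
    ref <- toupper(fix$REF[i])
    alts <- strsplit(toupper(fix$ALT[i]), ",", fixed = TRUE)[[1]]
    for (k in seq_along(alts)) {
      alt <- alts[k]
      desc <- sprintf("%s:%s %s>%s", fix$CHROM[i], fix$POS[i], ref, alt)
      if (grepl("[][<>]", alt) || alt == "*") {
        rejects[[length(rejects) + 1L]] <-
          data.frame(record = desc, reason = "symbolic allele",
                     stringsAsFactors = FALSE)
        next
      }
      if (!grepl("^[ACGTN]+$", ref) || !grepl("^[ACGTN]+$", alt)) {
        rejects[[length(rejects) + 1L]] <-
          data.frame(record = desc, reason = "non-nucleotide allele",
                     stringsAsFactors = FALSE)
        next
      }
      site <- list(id = fix$ID[i], qual = fix$QUAL[i], filter = fix$FILTER[i])
      if (!length(samples)) {
        records[[length(records) + 1L]] <- list(
          variant = list(chromosome = .norm_chrom(fix$CHROM[i]),
                         position = as.integer(fix$POS[i]),
                         ref_allele = ref, alt_allele = alt),
          subject = NA_character_, zygosity = "unknown", phasing = "unknown",
          missing_flag = FALSE, site = site)
        next
      }
      for (s in samples) {
        gt <- .parse_gt(vcf@gt[i, s])
        if (gt$missing) {
          records[[length(records) + 1L]] <- list(
            variant = list(chromosome = .norm_chrom(fix$CHROM[i]),
                           position = as.integer(fix$POS[i]),
                           ref_allele = ref, alt_allele = alt),
            subject = s, zygosity = "unknown",
            phasing = if (gt$phased) "phased" else "unknown",
            missing_flag = TRUE, site = site)
          next
        }
        n_alt <- sum(gt$alleles == as.character(k))
        if (n_alt == 0L) next
        zyg <- if (length(gt$alleles) == 1L) "hemizygous"
               else if (n_alt == length(gt$alleles)) "homozygous"
               else "heterozygous"
        records[[length(records) + 1L]] <- list(
          variant = list(chromosome = .norm_chrom(fix$CHROM[i]),
                         position = as.integer(fix$POS[i]),
                         ref_allele = ref, alt_allele = alt),
          subject = s, zygosity = zyg,
          phasing = if (gt$phased) "phased" else "unphased",
          missing_flag = FALSE, site = site)
      }
    }
  }
  attr(records, "rejects") <- if (length(rejects)) do.call(rbind, rejects) else
    data.frame(record = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  records
}

.maf_synonyms <- list(
  chromosome = c("Chromosome"),
  position = c("Start_Position", "Start_position"),
  ref_allele = c("Reference_Allele"),
  alt_allele = c("Tumor_Seq_Allele2", "Tumour_Seq_Allele2"),
  gene_symbol = c("Hugo_Symbol"),
  variant_classification = c("Variant_Classification"),
  genome_build = c("NCBI_Build", "Build")
)

#' Read variant records from a MAF file
#'
#' MAF's "-" convention for pure insertions/deletions is converted to
#' anchored VCF-style alleles. Because the MAF carries no local reference
#' sequence, the anchor base is synthesized as `"N"` (sequence is never
#' invented) and such records can only be trim-only normalized.
#'
#' @param path Tab-delimited MAF file (GDC column names accepted).
#' @return List of records with elements `variant` (including
#'   `genome_build`), `subject` (tumour sample barcode when present) and
#'   `annotation` (gene symbol, variant classification). Rejects attached as
#'   in [readVcfVariants()].
#' @export
readMafVariants <- function(path) {
  if (!file.exists(path)) .cgdm_error(paste0("no such file: ", path),
                                      "cgdm_format_error")
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                   check.names = FALSE)
  colmap <- list()
  for (want in names(.maf_synonyms)) {
    hit <- intersect(.maf_synonyms[[want]], names(df))
    if (!length(hit)) next
    colmap[[want]] <- hit[1]
  }
  missing_cols <- setdiff(names(.maf_synonyms), names(colmap))
  if (length(missing_cols))
    .cgdm_error(paste0("MAF lacks required columns: ",
                       paste(vapply(.maf_synonyms[missing_cols], `[`, character(1), 1),
                             collapse = ", ")), "cgdm_format_error")
  subj_col <- intersect(c("Tumor_Sample_Barcode", "Tumour_Sample_Barcode"),
                        names(df))
  records <- list(); rejects <- list()
  for (i in seq_len(nrow(df))) {
    ref <- toupper(df[[colmap$ref_allele]][i])
    alt <- toupper(df[[colmap$alt_allele]][i])
    pos <- as.integer(df[[colmap$position]][i])
    anchored <- FALSE
    if (ref == "-" && alt != "-") {          # insertion: start = base before
      ref <- "N"; alt <- paste0("N", alt); anchored <- TRUE
    } else if (alt == "-" && ref != "-") {   # deletion: start = first deleted base
      alt <- "N"; ref <- paste0("N", ref); pos <- pos - 1L; anchored <- TRUE
    }
    desc <- sprintf("%s:%d %s>%s", df[[colmap$chromosome]][i], pos, ref, alt)
    if (!grepl("^[ACGTN]+$", ref) || !grepl("^[ACGTN]+$", alt)) {
      rejects[[length(rejects) + 1L]] <-
        data.frame(record = desc, reason = "non-nucleotide allele",
                   stringsAsFactors = FALSE)
      next
    }
    records[[length(records) + 1L]] <- list(
      variant = list(chromosome = .norm_chrom(df[[colmap$chromosome]][i]),
                     position = pos, ref_allele = ref, alt_allele = alt,
                     genome_build = as.character(df[[colmap$genome_build]][i])),
      subject = if (length(subj_col)) df[[subj_col[1]]][i] else NA_character_,
      zygosity = "unknown", phasing = "unknown", missing_flag = FALSE,
      anchor_synthesized = anchored,
      annotation = list(gene_symbol = df[[colmap$gene_symbol]][i],
                        molecular_effect = df[[colmap$variant_classification]][i]))
  }
  attr(records, "rejects") <- if (length(rejects)) do.call(rbind, rejects) else
    data.frame(record = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  records
}

.variant_type_of <- function(ref, alt) {
  if (nchar(ref) == 1L && nchar(alt) == 1L) "SNV" else "InDel"
}

#' Load a variant file into a cGDM database
#'
#' Runs the full ETL: read, per-record normalization (left alignment when a
#' reference FASTA is supplied), validation, normalization-level
#' deduplication, clinical-identifier / experiment / provenance / QC /
#' annotation row creation, and alias indexing. The load is transactional
#' per source file: on any internal error the store is left untouched.
#' Rejected records are written to a tab-delimited sidecar, never silently
#' dropped.
#'
#' Two input spellings that normalize to the same
#' (subject, build, chromosome, position, ref, alt) collapse to one stored
#' alteration; the merge is recorded in a provenance row.
#'
#' @param manifest An [etlManifest()].
#' @param db A [CgdmDb] (mutated in place on success; re-saved when
#'   path-backed).
#' @return A `LoadReport`: `records_read`, `records_loaded`,
#'   `records_rejected`, `rejection_reasons`, `entity_rows`, `merged`.
#' @export
loadDataset <- function(manifest, db) {
  stopifnot(inherits(manifest, "EtlManifest"), is(db, "CgdmDb"))
  stage_db <- .clone_db(db)
  report <- .load_into(manifest, stage_db)      # errors propagate; db untouched
  for (nm in ls(stage_db@tables))
    assign(nm, get(nm, envir = stage_db@tables), envir = db@tables)
  if (!is.na(db@path)) saveDb(db)
  report
}

.load_into <- function(manifest, db) {
  recs <- if (manifest$source_format == "VCF")
    readVcfVariants(manifest$source_path, sample = manifest$sample)
  else readMafVariants(manifest$source_path)
  rejects <- attr(recs, "rejects")
  windows <- NULL
  if (!is.null(manifest$reference_fasta)) {
    seqs <- Biostrings::readDNAStringSet(manifest$reference_fasta)
    names(seqs) <- .norm_chrom(sub("\\s.*$", "", names(seqs)))
    windows <- lapply(seqs, function(s)
      referenceWindow("x", 1L, as.character(s), manifest$genome_build))
    for (nm in names(windows)) windows[[nm]]$chromosome <- nm
  }
  n_read <- length(recs) + nrow(rejects)
  ga_rows <- list(); merged <- 0L
  key_of <- function(subj, v) paste(subj, v$genome_build, v$chromosome,
                                    v$position, v$ref_allele, v$alt_allele,
                                    sep = "|")
  seen <- character(0)
  subjects <- character(0)
  loaded <- 0L
  for (r in recs) {
    subj <- r$subject
    if (!is.null(manifest$subject_map) && !is.na(subj) &&
        subj %in% names(manifest$subject_map))
      subj <- unname(manifest$subject_map[[subj]])
    if (is.na(subj)) subj <- paste0(manifest$test_id, "-S1")
    vb <- r$variant
    build <- if (!is.null(vb$genome_build)) vb$genome_build else manifest$genome_build
    v <- rawVariant(vb$chromosome, vb$position, vb$ref_allele, vb$alt_allele, build)
    win <- if (!is.null(windows)) windows[[v$chromosome]] else NULL
    nv <- tryCatch(
      normalizeVariant(v, if (manifest$normalization_mode == "full") win else NULL),
      cgdmError = function(e) e)
    if (inherits(nv, "error")) {
      rejects <- rbind(rejects, data.frame(
        record = sprintf("%s:%d %s>%s", v$chromosome, v$position,
                         v$ref_allele, v$alt_allele),
        reason = conditionMessage(nv), stringsAsFactors = FALSE))
      next
    }
    row <- list(test_id = manifest$test_id, subject_id = subj,
                genome_build = nv$genome_build, chromosome = nv$chromosome,
                position = nv$position, ref_allele = nv$ref_allele,
                alt_allele = nv$alt_allele, zygosity = r$zygosity,
                phasing = r$phasing, missing_flag = r$missing_flag,
                variant_type = .variant_type_of(nv$ref_allele, nv$alt_allele),
                normalization_mode = nv$normalization_mode)
    if (!is.null(r$annotation)) row <- c(row, r$annotation)
    vr <- validateRecord("GenomicAlteration", row)
    if (!vr$pass) {
      rejects <- rbind(rejects, data.frame(
        record = sprintf("%s:%d %s>%s", nv$chromosome, nv$position,
                         nv$ref_allele, nv$alt_allele),
        reason = paste(vr$violations$message, collapse = "; "),
        stringsAsFactors = FALSE))
      next
    }
    k <- key_of(subj, nv)
    loaded <- loaded + 1L
    subjects <- union(subjects, subj)
    if (k %in% seen) { merged <- merged + 1L; next }
    seen <- c(seen, k)
    ga_rows[[length(ga_rows) + 1L]] <-
      as.data.frame(row[!vapply(row, is.null, logical(1))],
                    stringsAsFactors = FALSE)
  }
  ## subjects present in the file but with only missing/absent genotypes still
  ## belong to the test; take the union with the manifest's subject universe
  if (manifest$source_format == "VCF") {
    hdr <- readLines(manifest$source_path, warn = FALSE)
    chrom_line <- grep("^#CHROM\t", hdr, value = TRUE)[1]
    cols <- strsplit(chrom_line, "\t", fixed = TRUE)[[1]]
    if (length(cols) > 9L) {
      samp <- cols[10:length(cols)]
      if (!is.null(manifest$sample)) samp <- intersect(samp, manifest$sample)
      if (!is.null(manifest$subject_map)) {
        m <- manifest$subject_map[samp]
        samp <- ifelse(is.na(m), samp, unname(m))
      }
      subjects <- union(subjects, samp)
    }
  }
  ## entity rows ------------------------------------------------------------
  ci <- do.call(rbind, lapply(sort(subjects), function(s)
    data.frame(institution_id = manifest$institution_id, subject_id = s,
               test_id = manifest$test_id,
               submission_date = manifest$submission_date,
               ordering_clinician = manifest$ordering_clinician,
               stringsAsFactors = FALSE)))
  old_ci <- dbTable(db, "ClinicalIdentifier")
  if (!is.null(ci)) {
    dup <- paste(ci$subject_id, ci$test_id) %in%
      paste(old_ci$subject_id, old_ci$test_id)
    if (any(!dup)) .insert_rows(db, "ClinicalIdentifier", ci[!dup, , drop = FALSE])
  }
  exp_row <- c(list(test_id = manifest$test_id),
               if (!is.null(manifest$experiment)) manifest$experiment)
  old_exp <- dbTable(db, "ExperimentInfo")
  if (!manifest$test_id %in% old_exp$test_id)
    .insert_rows(db, "ExperimentInfo",
                 as.data.frame(exp_row, stringsAsFactors = FALSE))
  prov <- lapply(manifest$pipeline_provenance, function(p)
    as.data.frame(c(list(test_id = manifest$test_id), p),
                  stringsAsFactors = FALSE))
  if (merged > 0L)
    prov[[length(prov) + 1L]] <- data.frame(
      test_id = manifest$test_id, stage = "variant_calling",
      tool_name = "cgdm", step = "normalization-dedup",
      parameters = paste0("merged=", merged), stringsAsFactors = FALSE)
  for (p in prov) .insert_rows(db, "PipelineProvenance", p)
  if (!is.null(manifest$qc))
    .insert_rows(db, "QualityCheck",
                 as.data.frame(c(list(test_id = manifest$test_id),
                                 as.list(manifest$qc)),
                               stringsAsFactors = FALSE))
  new_ga <- NULL
  if (length(ga_rows)) {
    ga_df <- do.call(rbind, lapply(ga_rows, function(r) {
      tmpl <- dbTable(db, "GenomicAlteration")[0, ]
      for (cl in names(r)) if (cl %in% names(tmpl)) tmpl[1, cl] <- r[[cl]]
      tmpl$test_id <- r$test_id
      tmpl
    }))
    new_ga <- .insert_rows(db, "GenomicAlteration", ga_df)
    for (aid in new_ga$alteration_id) {
      ga <- dbTable(db, "GenomicAlteration")
      row <- ga[ga$alteration_id == aid, ][1, ]
      if (length(.alias_keys_for_row(row))) registerAliases(db, aid)
    }
  }
  if (!is.null(manifest$annotations) && !is.null(new_ga)) {
    ga <- dbTable(db, "GenomicAlteration")
    an <- manifest$annotations
    for (i in seq_len(nrow(an))) {
      nv <- normalizeVariant(rawVariant(an$chromosome[i], an$position[i],
                                        an$ref_allele[i], an$alt_allele[i],
                                        manifest$genome_build))
      hit <- ga$chromosome == nv$chromosome & ga$position == nv$position &
        ga$ref_allele == nv$ref_allele & ga$alt_allele == nv$alt_allele &
        ga$test_id == manifest$test_id
      if (any(hit))
        .insert_rows(db, "ClinicalAnnotation", data.frame(
          alteration_id = ga$alteration_id[hit],
          annotation_class = an$annotation_class[i],
          annotation_value = an$annotation_value[i],
          documentation_date = if ("documentation_date" %in% names(an))
            an$documentation_date[i] else NA,
          stringsAsFactors = FALSE))
    }
  }
  if (nrow(rejects))
    write.table(rejects, manifest$reject_path, sep = "\t", row.names = FALSE,
                quote = TRUE)
  reasons <- if (nrow(rejects)) table(rejects$reason) else integer(0)
  structure(list(records_read = n_read, records_loaded = loaded,
                 records_rejected = nrow(rejects),
                 rejection_reasons = reasons,
                 entity_rows = entityCounts(db), merged = merged),
            class = "LoadReport")
}

#' @export
print.LoadReport <- function(x, ...) {
  cat(sprintf("LoadReport: read %d, loaded %d, rejected %d (merged %d)\n",
              x$records_read, x$records_loaded, x$records_rejected, x$merged))
  invisible(x)
}

#' Export stored alterations back to VCF
#'
#' One sample column per subject; genotypes reconstructed from zygosity and
#' phasing. Re-loading the export reproduces the stored normalized records
#' byte-wise on chromosome/position/ref/alt/build.
#'
#' @param db A [CgdmDb].
#' @param path Output VCF path.
#' @param test_id Optional restriction to one test.
#' @return Invisibly, the path.
#' @export
exportVcf <- function(db, path, test_id = NULL) {
  ga <- dbTable(db, "GenomicAlteration")
  if (!is.null(test_id)) ga <- ga[ga$test_id == test_id, , drop = FALSE]
  subjects <- sort(unique(ga$subject_id))
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=cgdm_export"),
           paste0("##reference=", paste(unique(ga$genome_build), collapse = ",")),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", subjects), collapse = "\t"))
  sites <- unique(ga[, c("chromosome", "position", "ref_allele", "alt_allele")])
  sites <- sites[order(sites$chromosome, sites$position,
                       sites$ref_allele, sites$alt_allele), , drop = FALSE]
  gt_of <- function(zyg, phs, miss) {
    sep <- if (identical(phs, "phased")) "|" else "/"
    if (isTRUE(miss)) return(paste0(".", sep, "."))
    switch(zyg,
           heterozygous = paste0("0", sep, "1"),
           homozygous = paste0("1", sep, "1"),
           hemizygous = "1",
           paste0(".", sep, "."))
  }
  lines <- vapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    gts <- vapply(subjects, function(sub) {
      hit <- ga$subject_id == sub & ga$chromosome == s$chromosome &
        ga$position == s$position & ga$ref_allele == s$ref_allele &
        ga$alt_allele == s$alt_allele
      if (!any(hit)) return("0/0")
      r <- ga[hit, ][1, ]
      gt_of(r$zygosity, r$phasing, r$missing_flag)
    }, character(1))
    paste(c(s$chromosome, s$position, ".", s$ref_allele, s$alt_allele,
            ".", "PASS", ".", "GT", gts), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, lines), path)
  invisible(path)
}
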