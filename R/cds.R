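## ---------------------------------------------------------------------------
## Query layer and clinical decision support
##
## Queries always return each alteration together with its pipeline
## provenance and quality-check context: a genomic result is only clinical
## evidence when its reliability can be judged. On top of the query layer sit
## a declarative rule engine and the IWPC warfarin dosing algorithm
## (pharmacogenetic model on sqrt weekly dose; clinical model as the
## non-genetic fallback), driven by CYP2C9/VKORC1 genotypes derived from
## stored, normalized variants.
## ---------------------------------------------------------------------------

#' Build a variant query filter
#'
#' At least one constraint must be set; quality thresholds are non-negative.
#'
#' @param subject_id,gene_symbol,annotation_class,genome_build,variant_type
#'   Optional equality constraints.
#' @param min_depth,min_mapping_quality Optional quality thresholds applied
#'   via the test's QualityCheck row.
#' @return A `QueryFilter` list.
#' @export
queryFilter <- function(subject_id = NULL, gene_symbol = NULL,
                        annotation_class = NULL, genome_build = NULL,
                        variant_type = NULL, min_depth = NULL,
                        min_mapping_quality = NULL) {
  flt <- list(subject_id = subject_id, gene_symbol = gene_symbol,
              annotation_class = annotation_class, genome_build = genome_build,
              variant_type = variant_type, min_depth = min_depth,
              min_mapping_quality = min_mapping_quality)
  if (all(vapply(flt, is.null, logical(1))))
    .cgdm_error("a query filter needs at least one constraint", "cgdm_usage_error")
  for (th in c("min_depth", "min_mapping_quality"))
    if (!is.null(flt[[th]]) && flt[[th]] < 0)
      .cgdm_error("quality thresholds must be non-negative", "cgdm_value_error")
  structure(flt, class = "QueryFilter")
}

#' Query stored alterations with provenance and quality context
#'
#' Every returned record carries its pipeline provenance rows and the test's
#' quality-check metrics, so the confidence level of the result can be
#' judged at the point of use. Results are stably ordered by
#' (chromosome, position).
#'
#' @param filter A [queryFilter()].
#' @param db A [CgdmDb].
#' @return List of records; each has `alteration` (one-row data.frame),
#'   `provenance` (data.frame) and `quality` (data.frame).
#' @export
queryVariants <- function(filter, db) {
  if (!inherits(filter, "QueryFilter"))
    .cgdm_error("filter must be a QueryFilter", "cgdm_usage_error")
  ga <- dbTable(db, "GenomicAlteration")
  keep <- rep(TRUE, nrow(ga))
  for (f in c("subject_id", "gene_symbol", "genome_build", "variant_type"))
    if (!is.null(filter[[f]])) keep <- keep & !is.na(ga[[f]]) & ga[[f]] %in% filter[[f]]
  if (!is.null(filter$annotation_class)) {
    ca <- dbTable(db, "ClinicalAnnotation")
    ids <- ca$alteration_id[ca$annotation_class %in% filter$annotation_class]
    keep <- keep & ga$alteration_id %in% ids
  }
  qc <- dbTable(db, "QualityCheck")
  if (!is.null(filter$min_depth) || !is.null(filter$min_mapping_quality)) {
    ok_tests <- qc$test_id
    if (!is.null(filter$min_depth))
      ok_tests <- intersect(ok_tests,
                            qc$test_id[!is.na(qc$depth_of_coverage) &
                                         qc$depth_of_coverage >= filter$min_depth])
    if (!is.null(filter$min_mapping_quality))
      ok_tests <- intersect(ok_tests,
                            qc$test_id[!is.na(qc$mapping_quality) &
                                         qc$mapping_quality >= filter$min_mapping_quality])
    keep <- keep & ga$test_id %in% ok_tests
  }
  hits <- ga[keep, , drop = FALSE]
  hits <- hits[order(hits$chromosome, hits$position, hits$ref_allele,
                     hits$alt_allele), , drop = FALSE]
  pp <- dbTable(db, "PipelineProvenance")
  lapply(seq_len(nrow(hits)), function(i) {
    r <- hits[i, , drop = FALSE]
    list(alteration = r,
         provenance = pp[pp$test_id == r$test_id, , drop = FALSE],
         quality = qc[qc$test_id == r$test_id, , drop = FALSE])
  })
}

## ---------------------------------------------------------------------------
## Pharmacogenomics
## ---------------------------------------------------------------------------

#' Load a star-allele / VKORC1 definition table
#'
#' Tab-delimited with columns `gene`, `allele` (e.g. `*2`, `*3`, `A` for the
#' VKORC1 -1639 A allele), `genome_build`, `chromosome`, `position`,
#' `ref_allele`, `alt_allele`, `rsid`. The packaged GRCh37 table covers the
#' IWPC-relevant CYP2C9 *2/*3 and VKORC1 -1639G>A (rs9923231) defining
#' variants.
#'
#' @param path Path to the table; default is the packaged knowledge table.
#' @return data.frame of defining variants.
#' @export
loadAlleleDefinitions <- function(path = system.file("extdata",
                                                     "pgx_allele_definitions.tsv",
                                                     package = "cgdm")) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("gene", "allele", "genome_build", "chromosome", "position",
            "ref_allele", "alt_allele")
  if (length(setdiff(need, names(df))))
    .cgdm_error("allele definition table lacks required columns",
                "cgdm_config_error")
  df$chromosome <- .norm_chrom(df$chromosome)
  df
}

.allele_dose <- function(zygosity) {
  switch(zygosity, homozygous = 2L, heterozygous = 1L, hemizygous = 1L, NA_integer_)
}

#' Derive CYP2C9 and VKORC1 genotypes for a subject
#'
#' Matches the subject's stored, normalized alterations against the defining
#' variants. Absence of a defining variant implies the reference state only
#' when the test carries coverage evidence (a QualityCheck row): absence of
#' evidence is never evidence of reference, so an uncovered subject is
#' `unknown`. Conflicting zygosity evidence (more than two CYP2C9 variant
#' alleles) is a data-inconsistency error naming the records.
#'
#' @param subject_id Subject identifier.
#' @param db A [CgdmDb].
#' @param allele_definitions data.frame from [loadAlleleDefinitions()].
#' @return A `PgxGenotype`: list with `cyp2c9_star` (e.g. `"*1/*3"`) and
#'   `vkorc1_1639` (`"GG"`, `"GA"`, `"AA"` or `"unknown"`).
#' @export
derivePgxGenotype <- function(subject_id, db, allele_definitions) {
  ga <- dbTable(db, "GenomicAlteration")
  qc <- dbTable(db, "QualityCheck")
  mine <- ga[ga$subject_id == subject_id, , drop = FALSE]
  covered <- any(mine$test_id %in% qc$test_id) ||
    (nrow(mine) == 0L &&
       any(dbTable(db, "ClinicalIdentifier")$subject_id == subject_id &
             dbTable(db, "ClinicalIdentifier")$test_id %in% qc$test_id))
  defs <- allele_definitions
  hits <- merge(mine, defs,
                by.x = c("genome_build", "chromosome", "position",
                         "ref_allele", "alt_allele"),
                by.y = c("genome_build", "chromosome", "position",
                         "ref_allele", "alt_allele"))
  if (!covered)
    return(structure(list(cyp2c9_star = "unknown", vkorc1_1639 = "unknown"),
                     class = "PgxGenotype"))
  ## CYP2C9
  cy <- hits[hits$gene == "CYP2C9", , drop = FALSE]
  counts <- setNames(integer(2), c("*2", "*3"))
  for (i in seq_len(nrow(cy))) {
    d <- .allele_dose(cy$zygosity[i])
    if (is.na(d))
      .cgdm_error(paste0("unresolvable zygosity for alteration ",
                         cy$alteration_id[i]), "cgdm_data_inconsistency")
    counts[cy$allele[i]] <- counts[cy$allele[i]] + d
  }
  if (sum(counts) > 2L)
    .cgdm_error(paste0("conflicting CYP2C9 zygosity evidence (alterations ",
                       paste(cy$alteration_id, collapse = ","), ")"),
                "cgdm_data_inconsistency")
  star <- c(rep("*2", counts["*2"]), rep("*3", counts["*3"]))
  star <- c(rep("*1", 2L - length(star)), star)
  cyp <- paste(star, collapse = "/")
  ## VKORC1 -1639
  vk <- hits[hits$gene == "VKORC1", , drop = FALSE]
  a_count <- 0L
  for (i in seq_len(nrow(vk))) {
    d <- .allele_dose(vk$zygosity[i])
    if (is.na(d))
      .cgdm_error(paste0("unresolvable zygosity for alteration ",
                         vk$alteration_id[i]), "cgdm_data_inconsistency")
    a_count <- a_count + d
  }
  if (a_count > 2L)
    .cgdm_error("conflicting VKORC1 zygosity evidence", "cgdm_data_inconsistency")
  vkorc <- c("GG", "GA", "AA")[a_count + 1L]
  structure(list(cyp2c9_star = cyp, vkorc1_1639 = vkorc), class = "PgxGenotype")
}

#' Assemble the covariates for a warfarin dose calculation
#'
#' All covariates must be present; the calculation refuses silent
#' imputation.
#'
#' @param age_decades Age in decades (e.g. 68 years -> 6.8 or integer 6; the
#'   published model uses decades).
#' @param height_cm,weight_kg Positive anthropometrics.
#' @param race_group One of `"white"`, `"asian"`, `"black"`,
#'   `"mixed_or_missing"`.
#' @param enzyme_inducer,amiodarone Logical comedication flags.
#' @param genotype A `PgxGenotype` from [derivePgxGenotype()] (or built by
#'   hand).
#' @return A `DosingInput` list.
#' @export
dosingInput <- function(age_decades, height_cm, weight_kg, race_group,
                        enzyme_inducer, amiodarone, genotype) {
  race_group <- match.arg(race_group,
                          c("white", "asian", "black", "mixed_or_missing"))
  vals <- list(age_decades = age_decades, height_cm = height_cm,
               weight_kg = weight_kg, enzyme_inducer = enzyme_inducer,
               amiodarone = amiodarone)
  for (nm in names(vals))
    if (is.null(vals[[nm]]) || is.na(vals[[nm]]))
      .cgdm_error(paste0("covariate '", nm, "' missing: no silent imputation"),
                  "cgdm_value_error")
  if (age_decades < 0 || height_cm <= 0 || weight_kg <= 0)
    .cgdm_error("implausible covariate value", "cgdm_value_error")
  structure(list(age_decades = age_decades, height_cm = height_cm,
                 weight_kg = weight_kg, race_group = race_group,
                 enzyme_inducer = isTRUE(enzyme_inducer),
                 amiodarone = isTRUE(amiodarone), genotype = genotype),
            class = "DosingInput")
}

#' Load the IWPC dosing coefficient knowledge table
#'
#' The coefficients of the published IWPC algorithms (pharmacogenetic and
#' clinical models on the square root of weekly dose) ship as a versioned
#' CSV knowledge table rather than being hard-coded, mirroring the model's
#' treatment of external knowledge as a replaceable, versioned reference.
#'
#' @param path CSV path; default is the packaged table.
#' @return data.frame with columns `model`, `term`, `coefficient` and an
#'   attached `knowledge_version` attribute.
#' @export
loadDosingCoefficients <- function(path = system.file("extdata",
                                                      "iwpc_dosing_coefficients.csv",
                                                      package = "cgdm")) {
  first <- readLines(path, n = 1L)
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  attr(df, "knowledge_version") <-
    sub("^#\\s*knowledge_version:\\s*", "",
        grep("knowledge_version", readLines(path, n = 5L), value = TRUE)[1])
  df
}

.iwpc_terms <- function(input, model, coef) {
  cf <- coef[coef$model == model, ]
  val <- function(term) cf$coefficient[cf$term == term]
  g <- input$genotype
  x <- c(intercept = 1,
         age_decades = input$age_decades,
         height_cm = input$height_cm,
         weight_kg = input$weight_kg,
         race_asian = as.numeric(input$race_group == "asian"),
         race_black = as.numeric(input$race_group == "black"),
         race_mixed_or_missing = as.numeric(input$race_group == "mixed_or_missing"),
         enzyme_inducer = as.numeric(input$enzyme_inducer),
         amiodarone = as.numeric(input$amiodarone))
  if (model == "pharmacogenetic") {
    x <- c(x,
           vkorc1_GA = as.numeric(g$vkorc1_1639 == "GA"),
           vkorc1_AA = as.numeric(g$vkorc1_1639 == "AA"),
           cyp2c9_12 = as.numeric(g$cyp2c9_star == "*1/*2"),
           cyp2c9_13 = as.numeric(g$cyp2c9_star == "*1/*3"),
           cyp2c9_22 = as.numeric(g$cyp2c9_star == "*2/*2"),
           cyp2c9_23 = as.numeric(g$cyp2c9_star == "*2/*3"),
           cyp2c9_33 = as.numeric(g$cyp2c9_star == "*3/*3"))
  }
  terms <- data.frame(term = names(x), value = unname(x),
                      coefficient = vapply(names(x), val, numeric(1)),
                      stringsAsFactors = FALSE)
  terms$contribution <- terms$value * terms$coefficient
  terms
}

#' Predict a warfarin maintenance dose with the IWPC algorithm
#'
#' The pharmacogenetic model is a linear predictor on the square root of the
#' weekly dose over clinical covariates plus CYP2C9 diplotype and VKORC1
#' -1639 genotype; the prediction is the squared linear predictor in
#' mg/week. When either genotype is `unknown` the calculation refuses the
#' genetic model and (in `"auto"` mode) dispatches to the clinical
#' (non-genetic) IWPC model, marking the audit trail accordingly.
#'
#' @param input A [dosingInput()].
#' @param model `"auto"` (default), `"pharmacogenetic"` or `"clinical"`.
#' @param coefficients Knowledge table from [loadDosingCoefficients()].
#' @return List: `weekly_dose_mg`, `daily_dose_mg`, `model` (model actually
#'   used), `sqrt_dose`, and `audit` (data.frame with one row per term:
#'   value, coefficient, contribution).
#' @examples
#' g <- structure(list(cyp2c9_star = "*1/*1", vkorc1_1639 = "GG"),
#'                class = "PgxGenotype")
#' iwpcWarfarinDose(dosingInput(6.8, 170, 70, "white", FALSE, FALSE, g))
#' @export
iwpcWarfarinDose <- function(input, model = c("auto", "pharmacogenetic", "clinical"),
                             coefficients = loadDosingCoefficients()) {
  stopifnot(inherits(input, "DosingInput"))
  model <- match.arg(model)
  g <- input$genotype
  unknown <- is.null(g) || identical(g$cyp2c9_star, "unknown") ||
    identical(g$vkorc1_1639, "unknown")
  used <- model
  note <- NULL
  if (model == "pharmacogenetic" && unknown)
    .cgdm_error(paste0("genotype unknown: the pharmacogenetic model is not ",
                       "applicable; use the clinical (non-genetic) fallback model"),
                "cgdm_value_error")
  if (model == "auto") {
    used <- if (unknown) "clinical" else "pharmacogenetic"
    if (unknown) note <- "clinical algorithm (genotype unknown; non-genetic fallback)"
  }
  terms <- .iwpc_terms(input, used, coefficients)
  s <- sum(terms$contribution)
  out <- list(weekly_dose_mg = s^2, daily_dose_mg = s^2 / 7,
              model = used, sqrt_dose = s, audit = terms,
              knowledge_version = attr(coefficients, "knowledge_version"))
  if (!is.null(note)) out$audit_note <- note
  out
}

## ---------------------------------------------------------------------------
## Rule engine
## ---------------------------------------------------------------------------

#' Define a clinical-decision-support rule
#'
#' @param rule_id Identifier.
#' @param trigger List with either `alias` (an alias-index pattern such as
#'   `"BRAF:V600E"`) or `genotype = TRUE` (fires for subjects with a
#'   derivable PGx genotype).
#' @param action `"alert"` or `"dose_calculation"`.
#' @param knowledge_ref Citation for the knowledge the rule encodes.
#' @param parameters Named list (alert text; dosing covariates; for
#'   `dose_calculation` the registered dosing function name, currently
#'   `"iwpc_warfarin"`).
#' @return A `CdsRule`.
#' @export
cdsRule <- function(rule_id, trigger, action = c("alert", "dose_calculation"),
                    knowledge_ref = NA_character_, parameters = list()) {
  action <- match.arg(action)
  if (is.null(trigger) || !length(trigger))
    .cgdm_error("rule trigger must be non-empty", "cgdm_config_error")
  if (action == "dose_calculation") {
    fn <- parameters$dosing_function
    if (is.null(fn) || !fn %in% c("iwpc_warfarin"))
      .cgdm_error(paste0("rule ", rule_id,
                         " names an unregistered dosing function"),
                  "cgdm_config_error")
  }
  structure(list(rule_id = rule_id, trigger = trigger, action = action,
                 knowledge_ref = knowledge_ref, parameters = parameters),
            class = "CdsRule")
}

#' Read CDS rules from a YAML file
#' @param path YAML file: a list of rule mappings with the [cdsRule()] fields.
#' @return List of `CdsRule`s (validated at load time).
#' @export
loadCdsRules <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(r)
    cdsRule(r$rule_id, r$trigger, r$action, r$knowledge_ref,
            if (is.null(r$parameters)) list() else r$parameters))
}

#' Evaluate CDS rules for one subject
#'
#' Deterministic, pure function of the database state and the rule set. Each
#' triggered action cites the alteration IDs and the rule's knowledge
#' reference, preserving traceability from recommendation back to stored
#' evidence.
#'
#' @param subject_id Subject identifier.
#' @param rules List of [cdsRule()]s.
#' @param db A [CgdmDb].
#' @param allele_definitions,coefficients Knowledge tables for
#'   dose-calculation rules.
#' @return List of triggered actions: `rule_id`, `action`, `knowledge_ref`,
#'   `alteration_ids`, and for dose rules the full dose result.
#' @export
evaluateRules <- function(subject_id, rules, db,
                          allele_definitions = loadAlleleDefinitions(),
                          coefficients = loadDosingCoefficients()) {
  ga <- dbTable(db, "GenomicAlteration")
  ai <- dbTable(db, "AliasIndex")
  mine <- ga[ga$subject_id == subject_id, , drop = FALSE]
  out <- list()
  for (rule in rules) {
    stopifnot(inherits(rule, "CdsRule"))
    if (!is.null(rule$trigger$alias)) {
      res <- resolveQuery(rule$trigger$alias, db)
      ids <- intersect(res$candidates$alteration_id, mine$alteration_id)
      if (!length(ids)) next
      hit <- list(rule_id = rule$rule_id, action = rule$action,
                  knowledge_ref = rule$knowledge_ref, alteration_ids = ids)
      if (rule$action == "alert")
        hit$alert_text <- rule$parameters$alert_text
    } else if (isTRUE(rule$trigger$genotype)) {
      if (!nrow(mine) &&
          !subject_id %in% dbTable(db, "ClinicalIdentifier")$subject_id) next
      geno <- derivePgxGenotype(subject_id, db, allele_definitions)
      defs <- allele_definitions
      def_hit <- merge(mine, defs,
                       by.x = c("genome_build", "chromosome", "position",
                                "ref_allele", "alt_allele"),
                       by.y = c("genome_build", "chromosome", "position",
                                "ref_allele", "alt_allele"))
      hit <- list(rule_id = rule$rule_id, action = rule$action,
                  knowledge_ref = rule$knowledge_ref,
                  alteration_ids = def_hit$alteration_id,
                  genotype = geno)
    } else next
    if (rule$action == "dose_calculation") {
      p <- rule$parameters
      geno <- if (!is.null(hit$genotype)) hit$genotype else
        derivePgxGenotype(subject_id, db, allele_definitions)
      inp <- dosingInput(p$age_decades, p$height_cm, p$weight_kg,
                         p$race_group, isTRUE(p$enzyme_inducer),
                         isTRUE(p$amiodarone), geno)
      hit$dose <- iwpcWarfarinDose(inp, coefficients = coefficients)
    }
    out[[length(out) + 1L]] <- hit
  }
  out
}
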