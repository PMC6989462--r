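#' @import methods
#' @importFrom utils read.delim write.table head tail modifyList
#' @importFrom stats setNames
NULL

## ---------------------------------------------------------------------------
## Entity registry
##
## The clinical genome data model is held as a registry of entity definitions.
## Each entity carries a column table; columns are classed by `role`:
##   domain        -- a clinico-genomic attribute of the model (counted)
##   surrogate     -- synthetic primary key (not counted)
##   foreign       -- pure foreign-key linkage column (not counted)
##   supplementary -- operational column (flags, denormalisations; not counted)
## Composite attributes (e.g. Gene = HGNC symbol + Entrez + Ensembl) expand to
## several columns sharing one `attribute` label; the model's attribute count
## is the number of distinct (entity, attribute) pairs with role == "domain".
## ---------------------------------------------------------------------------

.cgdm <- new.env(parent = emptyenv())

.default_vocabularies <- function() {
  list(
    sequence_type    = c("WGS", "WES", "panel", "targeted", "other"),
    stage            = c("alignment", "realignment_recalibration", "variant_calling",
                         "sequence_annotation", "clinical_annotation"),
    zygosity         = c("heterozygous", "homozygous", "hemizygous", "unknown"),
    phasing          = c("phased", "unphased", "unknown"),
    variant_type     = c("SNV", "InDel", "CNV", "translocation_fusion"),
    annotation_class = c("acmg_actionable", "fda_qualified_biomarker",
                         "user_defined_biomarker"),
    msi_status       = c("MSI-H", "MSI-L", "MSS", "unknown")
  )
}

.col <- function(column, type, role = "domain", attribute = column,
                 nullable = TRUE, enum = NA_character_, check = NA_character_) {
  data.frame(column = column, type = type, role = role, attribute = attribute,
             nullable = nullable, enum = enum, check = check,
             stringsAsFactors = FALSE)
}

.entity_definitions <- function() {
  list(
    ClinicalIdentifier = list(
      table = "CLINICAL_IDENTIFIER",
      columns = rbind(
        .col("clinical_identifier_id", "integer", "surrogate", nullable = FALSE),
        .col("institution_id", "text", nullable = FALSE),
        .col("subject_id", "text", nullable = FALSE),
        .col("test_id", "text", nullable = FALSE),
        .col("submission_date", "timestamp"),
        .col("ordering_clinician", "text")
      ),
      unique = list(c("subject_id", "test_id"))
    ),
    ExperimentInfo = list(
      table = "EXPERIMENT_INFO",
      columns = rbind(
        .col("experiment_id", "integer", "surrogate", nullable = FALSE),
        .col("test_id", "text", "foreign", nullable = FALSE),
        .col("test_description", "text"),
        .col("sequence_type", "text", enum = "sequence_type"),
        .col("platform_technology", "text"),
        .col("sequencer", "text"),
        .col("collection_date", "timestamp"),
        .col("sequencing_institution", "text"),
        .col("experimenter", "text")
      ),
      unique = list("test_id")
    ),
    PipelineProvenance = list(
      table = "PIPELINE_PROVENANCE",
      columns = rbind(
        .col("provenance_id", "integer", "surrogate", nullable = FALSE),
        .col("test_id", "text", "foreign", nullable = FALSE),
        .col("stage", "text", "supplementary", enum = "stage", nullable = FALSE),
        .col("tool_name", "text", attribute = "tool"),
        .col("tool_version", "text", attribute = "tool"),
        .col("step", "text"),
        .col("parameters", "text"),
        .col("origin_source", "text"),
        .col("origin_version", "text"),
        .col("origin_build", "text"),
        .col("analytics_institution", "text"),
        .col("bioinformatician", "text"),
        .col("received_date", "timestamp")
      ),
      unique = list()
    ),
    GenomicAlteration = list(
      table = "GENOMIC_ALTERATION",
      columns = rbind(
        .col("alteration_id", "integer", "surrogate", nullable = FALSE),
        .col("test_id", "text", "foreign", nullable = FALSE),
        .col("subject_id", "text", "foreign", nullable = FALSE),
        .col("genome_build", "text", "supplementary", nullable = FALSE),
        .col("chromosome", "text", nullable = FALSE),
        .col("position", "integer", nullable = FALSE, check = "position >= 1"),
        .col("ref_allele", "text", nullable = FALSE, check = "allele"),
        .col("alt_allele", "text", nullable = FALSE, check = "allele"),
        .col("zygosity", "text", enum = "zygosity"),
        .col("phasing", "text", enum = "phasing"),
        .col("missing_flag", "boolean"),
        .col("gene_symbol", "text", attribute = "gene"),
        .col("entrez_id", "integer", attribute = "gene"),
        .col("ensembl_id", "text", attribute = "gene"),
        .col("hgvs_g", "text", attribute = "variant_descriptor"),
        .col("hgvs_c", "text", attribute = "variant_descriptor"),
        .col("hgvs_p", "text", attribute = "variant_descriptor"),
        .col("dbsnp_id", "text", attribute = "variant_descriptor"),
        .col("dbvar_id", "text", attribute = "variant_descriptor"),
        .col("clinvar_id", "text", attribute = "external_reference"),
        .col("cosmic_id", "text", attribute = "external_reference"),
        .col("cytogenetic_location", "text"),
        .col("codon", "integer"),
        .col("exon", "integer"),
        .col("molecular_effect", "text"),
        .col("variant_type", "text", enum = "variant_type"),
        .col("functional_domain", "text"),
        .col("normalization_mode", "text", "supplementary")
      ),
      unique = list(c("subject_id", "genome_build", "chromosome", "position",
                      "ref_allele", "alt_allele"))
    ),
    QualityCheck = list(
      table = "QUALITY_CHECK",
      columns = rbind(
        .col("qc_id", "integer", "surrogate", nullable = FALSE),
        .col("test_id", "text", "foreign", nullable = FALSE),
        .col("base_quality", "numeric", check = "base_quality >= 0"),
        .col("depth_of_coverage", "numeric", check = "depth_of_coverage >= 0"),
        .col("mapping_quality", "numeric",
             check = "mapping_quality >= 0 & mapping_quality <= 100")
      ),
      unique = list()
    ),
    ClinicalAnnotation = list(
      table = "CLINICAL_ANNOTATION",
      columns = rbind(
        .col("annotation_id", "integer", "surrogate", nullable = FALSE),
        .col("alteration_id", "integer", "foreign", nullable = FALSE),
        .col("annotation_class", "text", enum = "annotation_class", nullable = FALSE),
        .col("annotation_value", "text"),
        .col("documentation_date", "timestamp")
      ),
      unique = list()
    ),
    MicrosatelliteInstability = list(
      table = "MICROSATELLITE_INSTABILITY",
      columns = rbind(
        .col("msi_id", "integer", "surrogate", nullable = FALSE),
        .col("test_id", "text", "foreign", nullable = FALSE),
        .col("msi_status", "text", enum = "msi_status", nullable = FALSE),
        .col("msi_score", "numeric", check = "msi_score >= 0 & msi_score <= 1")
      ),
      unique = list()
    ),
    TumorMutationBurden = list(
      table = "TUMOR_MUTATION_BURDEN",
      columns = rbind(
        .col("tmb_id", "integer", "surrogate", nullable = FALSE),
        .col("test_id", "text", "foreign", nullable = FALSE),
        .col("tmb_value", "numeric", nullable = FALSE, check = "tmb_value >= 0"),
        .col("panel_size", "numeric", "supplementary", check = "panel_size > 0")
      ),
      unique = list()
    )
  )
}

## Auxiliary tables live in the store but are not cGDM entities.
.auxiliary_definitions <- function() {
  list(
    AliasIndex = list(
      table = "ALIAS_INDEX",
      columns = rbind(
        .col("alias_key", "text", "supplementary", nullable = FALSE),
        .col("alias_type", "text", "supplementary", nullable = FALSE),
        .col("gene_symbol", "text", "supplementary"),
        .col("alteration_id", "integer", "foreign", nullable = FALSE)
      ),
      unique = list()
    )
  )
}

.registry_init <- function() {
  .cgdm$entities <- .entity_definitions()
  .cgdm$auxiliary <- .auxiliary_definitions()
  .cgdm$vocabularies <- .default_vocabularies()
  invisible(NULL)
}

.registry <- function() {
  if (is.null(.cgdm$entities)) .registry_init()
  .cgdm
}

#' Reset the schema registry to the packaged cGDM definition
#'
#' Drops any user-registered extension entities and restores the packaged
#' vocabularies.
#' @return Invisibly, `NULL`.
#' @export
resetSchema <- function() .registry_init()

#' List entity names of the clinical genome data model
#' @return Character vector of entity names.
#' @export
schemaEntities <- function() names(.registry()$entities)

.entity_def <- function(entity) {
  reg <- .registry()
  def <- reg$entities[[entity]]
  if (is.null(def)) def <- reg$auxiliary[[entity]]
  if (is.null(def))
    stop("unknown entity type: ", entity, call. = FALSE)
  def
}

#' Register an extension entity
#'
#' The model is deliberately scalable: new variant-information subtypes can be
#' added as first-class entities. The extension participates in introspection,
#' validation and DDL emission exactly like the packaged entities.
#'
#' @param entity Entity name (CamelCase).
#' @param table SQL table name.
#' @param columns data.frame with columns `column`, `type`, `role`,
#'   `attribute`, `nullable`, `enum`, `check` (as produced internally; see
#'   source of the packaged definitions).
#' @param unique list of character vectors naming unique column sets.
#' @return Invisibly, the updated entity count.
#' @export
registerEntity <- function(entity, table, columns, unique = list()) {
  reg <- .registry()
  if (entity %in% c(names(reg$entities), names(reg$auxiliary)))
    stop("entity already registered: ", entity, call. = FALSE)
  needed <- c("column", "type", "role", "attribute", "nullable", "enum", "check")
  missing_cols <- setdiff(needed, names(columns))
  if (length(missing_cols))
    stop("column definition lacks: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  reg$entities[[entity]] <- list(table = table, columns = columns, unique = unique)
  invisible(length(reg$entities))
}

#' Load controlled vocabularies from a YAML file
#'
#' Enumerated attributes (sequence type, zygosity, variant type, ...) are
#' closed but configurable vocabularies. A YAML mapping of vocabulary name to
#' a list of permitted values replaces or extends the packaged defaults.
#'
#' @param path Path to a YAML file.
#' @return Invisibly, the active vocabulary list.
#' @export
loadVocabularies <- function(path) {
  if (!file.exists(path)) stop("vocabulary file not found: ", path, call. = FALSE)
  vv <- yaml::read_yaml(path)
  reg <- .registry()
  reg$vocabularies <- modifyList(reg$vocabularies, lapply(vv, as.character))
  invisible(reg$vocabularies)
}

#' Introspect the clinical genome data model
#'
#' Counts are derived from the live registry (including any extension
#' entities), never from stored constants. Composite attributes count once;
#' surrogate keys, foreign keys and supplementary columns are excluded.
#'
#' @return A list with `entity_count`, `attribute_total`, and
#'   `attributes_per_entity` (named integer vector).
#' @export
introspectSchema <- function() {
  reg <- .registry()
  per <- vapply(reg$entities, function(def) {
    dom <- def$columns[def$columns$role == "domain", , drop = FALSE]
    length(unique(dom$attribute))
  }, integer(1))
  list(entity_count = length(reg$entities),
       attribute_total = as.integer(sum(per)),
       attributes_per_entity = per)
}

## ---------------------------------------------------------------------------
## DDL emission
## ---------------------------------------------------------------------------

.sql_type <- function(type, dialect) {
  if (dialect == "sqlite") {
    switch(type, text = "TEXT", integer = "INTEGER", numeric = "REAL",
           boolean = "INTEGER", timestamp = "TEXT",
           stop("unknown column type: ", type, call. = FALSE))
  } else {
    switch(type, text = "VARCHAR(255)", integer = "INTEGER", numeric = "NUMERIC",
           boolean = "BOOLEAN", timestamp = "VARCHAR(40)",
           stop("unknown column type: ", type, call. = FALSE))
  }
}

#' Emit the data definition language script for the model
#'
#' Generates `CREATE TABLE` statements for all eight entities (plus, on
#' request, auxiliary service tables such as the variant alias index). Each
#' column line carries a structured trailing comment
#' `-- attribute: <name> [<role>]` so that a catalog built by executing the
#' script retains the attribute-counting convention.
#'
#' @param dialect `"ansi"` (generic SQL) or `"sqlite"` (embedded-database
#'   dialect, also understood by [executeDdl()]).
#' @param if_not_exists logical; emit `IF NOT EXISTS` guards so the script is
#'   idempotent on re-execution. Default `FALSE` (second execution is
#'   rejected).
#' @param include_auxiliary logical; also emit auxiliary (non-entity) tables.
#' @return A single character string containing the DDL script.
#' @export
emitDdl <- function(dialect = c("ansi", "sqlite"), if_not_exists = FALSE,
                    include_auxiliary = FALSE) {
  if (!is.character(dialect) || !dialect[1] %in% c("ansi", "sqlite"))
    stop("unsupported DDL dialect: ", dialect[1], call. = FALSE)
  dialect <- dialect[1]
  reg <- .registry()
  defs <- reg$entities
  if (include_auxiliary) defs <- c(defs, reg$auxiliary)
  guard <- if (if_not_exists) "IF NOT EXISTS " else ""
  stmts <- vapply(names(defs), function(entity) {
    def <- defs[[entity]]
    cols <- def$columns
    lines <- vapply(seq_len(nrow(cols)), function(i) {
      cl <- cols[i, ]
      nn <- if (!cl$nullable) " NOT NULL" else ""
      pk <- if (cl$role == "surrogate") " PRIMARY KEY" else ""
      sprintf("  %-24s %s%s%s, -- attribute: %s [%s]",
              cl$column, .sql_type(cl$type, dialect), nn, pk,
              cl$attribute, cl$role)
    }, character(1))
    uq <- vapply(def$unique, function(u)
      sprintf("  UNIQUE (%s),", paste(u, collapse = ", ")), character(1))
    body <- c(lines, uq)
    ## drop trailing comma of the final definition line (comment-aware)
    body[length(body)] <- sub(", --", " --", body[length(body)])
    body[length(body)] <- sub(",$", "", body[length(body)])
    paste0("CREATE TABLE ", guard, def$table, " (\n",
           paste(body, collapse = "\n"), "\n);")
  }, character(1))
  paste0("-- clinical genome data model DDL (dialect: ", dialect, ")\n",
         paste(stmts, collapse = "\n\n"), "\n")
}

## Parse a DDL script produced by emitDdl into a catalog data.frame.
.parse_ddl <- function(ddl) {
  lines <- strsplit(ddl, "\n", fixed = TRUE)[[1]]
  cat_rows <- list()
  current <- NULL
  for (ln in lines) {
    m <- regmatches(ln, regexec("^CREATE TABLE (IF NOT EXISTS )?([A-Z_]+) \\($", ln))[[1]]
    if (length(m)) { current <- m[3]; next }
    if (grepl("^\\);", ln)) { current <- NULL; next }
    if (is.null(current)) next
    cm <- regmatches(ln, regexec(
      "^  ([a-z_]+)\\s+([A-Z()0-9]+)( NOT NULL)?( PRIMARY KEY)?,? -- attribute: ([a-z_]+) \\[([a-z]+)\\]", ln))[[1]]
    if (length(cm)) {
      cat_rows[[length(cat_rows) + 1L]] <- data.frame(
        table_name = current, column = cm[2], sql_type = cm[3],
        nullable = cm[4] == "", attribute = cm[6], role = cm[7],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, cat_rows)
}

#' Summarise a database catalog with the model's counting convention
#'
#' @param catalog Catalog data.frame as stored in a [CgdmDb] (columns
#'   `table_name`, `column`, `attribute`, `role`).
#' @param entity_tables optional character vector restricting the summary to
#'   entity tables (auxiliary tables are excluded by default).
#' @return list with `entity_count` and `attribute_total`.
#' @export
catalogSummary <- function(catalog, entity_tables = NULL) {
  if (is.null(entity_tables)) {
    aux <- vapply(.registry()$auxiliary, `[[`, character(1), "table")
    entity_tables <- setdiff(unique(catalog$table_name), aux)
  }
  cat_e <- catalog[catalog$table_name %in% entity_tables, , drop = FALSE]
  dom <- cat_e[cat_e$role == "domain", , drop = FALSE]
  list(entity_count = length(unique(cat_e$table_name)),
       attribute_total = length(unique(paste(dom$table_name, dom$attribute))))
}

## ---------------------------------------------------------------------------
## Record validation
## ---------------------------------------------------------------------------

.coerce_ok <- function(value, type) {
  if (is.null(value) || (length(value) == 1 && is.na(value))) return(TRUE)
  switch(type,
    text = is.character(value) || is.factor(value),
    integer = {
      suppressWarnings(iv <- as.numeric(value))
      !is.na(iv) && iv == round(iv)
    },
    numeric = { suppressWarnings(nv <- as.numeric(value)); !is.na(nv) },
    boolean = is.logical(value) || value %in% c(0, 1, "TRUE", "FALSE"),
    timestamp = {
      !is.na(suppressWarnings(as.POSIXct(as.character(value), tz = "UTC",
        tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S", "%Y-%m-%d"))))
    },
    TRUE)
}

.cross_field_rules <- list(
  GenomicAlteration = function(r) {
    out <- character(0)
    ref <- r[["ref_allele"]]; alt <- r[["alt_allele"]]
    if (!is.null(ref) && !is.null(alt) && !is.na(ref) && !is.na(alt) &&
        identical(toupper(ref), toupper(alt)))
      out <- c(out, "ref equals alt")
    out
  }
)

#' Validate one entity record against the model
#'
#' Applies the attribute contracts of the named entity: required fields,
#' type coercion, closed-vocabulary membership, range checks, allele syntax
#' and cross-field rules (e.g. the reference allele may not equal the
#' alternative allele). The input is never mutated and validation never
#' raises for a well-typed record; only an unknown entity type is an error.
#'
#' @param entity Entity type name, e.g. `"GenomicAlteration"`.
#' @param record Named list (or single-row data.frame) of field values.
#' @return A `cgdmValidation` list: `entity`, `pass` (logical), and
#'   `violations`, a data.frame with columns `field`, `rule`, `message`.
#' @examples
#' validateRecord("QualityCheck",
#'                list(test_id = "T1", mapping_quality = 101))$pass
#' @export
validateRecord <- function(entity, record) {
  def <- .entity_def(entity)           # errors on unknown entity type
  if (is.data.frame(record)) record <- as.list(record[1, , drop = FALSE])
  vocab <- .registry()$vocabularies
  viol <- list()
  add <- function(field, rule, message)
    viol[[length(viol) + 1L]] <<- data.frame(field = field, rule = rule,
                                             message = message,
                                             stringsAsFactors = FALSE)
  cols <- def$columns
  unknown <- setdiff(names(record), cols$column)
  for (f in unknown) add(f, "unknown_field", paste0("field not in ", entity))
  for (i in seq_len(nrow(cols))) {
    cl <- cols[i, ]
    if (cl$role == "surrogate") next
    v <- record[[cl$column]]
    absent <- is.null(v) || (length(v) == 1 && is.na(v))
    if (absent) {
      if (!cl$nullable && cl$role %in% c("domain", "foreign", "supplementary"))
        add(cl$column, "required", "missing value for required field")
      next
    }
    if (!.coerce_ok(v, cl$type)) {
      add(cl$column, "type", paste0("not coercible to ", cl$type))
      next
    }
    if (!is.na(cl$enum)) {
      allowed <- vocab[[cl$enum]]
      if (!is.null(allowed) && !as.character(v) %in% allowed)
        add(cl$column, "enum",
            paste0("value '", v, "' not in vocabulary '", cl$enum, "'"))
    }
    if (!is.na(cl$check)) {
      if (identical(cl$check, "allele")) {
        if (!grepl("^[ACGTN]+$", as.character(v)))
          add(cl$column, "allele_syntax",
              "allele must be uppercase [ACGTN]+ (symbolic alleles rejected)")
      } else {
        env <- list(); env[[cl$column]] <- as.numeric(v)
        ok <- isTRUE(eval(parse(text = cl$check), envir = env))
        if (!ok) add(cl$column, "range", paste0("violates ", cl$check))
      }
    }
  }
  rule_fn <- .cross_field_rules[[entity]]
  if (!is.null(rule_fn))
    for (msg in rule_fn(record)) add(NA_character_, "cross_field", msg)
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(field = character(0), rule = character(0),
               message = character(0), stringsAsFactors = FALSE)
  structure(list(entity = entity, pass = nrow(violations) == 0L,
                 violations = violations),
            class = "cgdmValidation")
}

#' @export
print.cgdmValidation <- function(x, ...) {
  cat("cGDM validation [", x$entity, "]: ",
      if (x$pass) "PASS" else "FAIL", "\n", sep = "")
  if (!x$pass) print(x$violations)
  invisible(x)
}
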