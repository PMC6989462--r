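## ---------------------------------------------------------------------------
## Embedded tabular store
##
## The store is a directory of plain TSV tables (one per entity) plus a
## catalog table built by executing the model's DDL. An in-memory store
## (path = NA) behaves identically minus persistence. The design goal is a
## dependency-free embedded database whose catalog honours the model's
## attribute-counting convention; for server deployments the same DDL is
## emitted in ANSI or SQLite dialect.
## ---------------------------------------------------------------------------

#' CgdmDb: an embedded clinical genome database
#'
#' S4 container for a cGDM database: a catalog (one row per column of every
#' created table) and an environment of entity tables. Create one with
#' [initDb()] or open an existing one with [cgdmConnect()].
#'
#' @slot path Directory backing the store, or `NA` for in-memory.
#' @slot tables Environment mapping table names to data.frames.
#' @slot catalog data.frame describing every created column
#'   (`table_name`, `column`, `sql_type`, `nullable`, `attribute`, `role`).
#' @export
setClass("CgdmDb", representation(path = "character",
                                  tables = "environment",
                                  catalog = "data.frame"))

setValidity("CgdmDb", function(object) {
  msgs <- character(0)
  for (tb in unique(object@catalog$table_name)) {
    if (!exists(tb, envir = object@tables, inherits = FALSE)) {
      msgs <- c(msgs, paste0("catalog table missing from store: ", tb))
      next
    }
    want <- object@catalog$column[object@catalog$table_name == tb]
    got <- names(get(tb, envir = object@tables))
    if (!identical(sort(want), sort(got)))
      msgs <- c(msgs, paste0("column mismatch in ", tb))
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CgdmDb", function(object) {
  cat("CgdmDb (",
      if (is.na(object@path)) "in-memory" else object@path, ")\n", sep = "")
  counts <- entityCounts(object)
  for (nm in names(counts))
    cat(sprintf("  %-34s %d rows\n", nm, counts[[nm]]))
})

.r_type_for <- function(sql_type) {
  switch(toupper(sub("\\(.*", "", sql_type)),
         TEXT = character(0), VARCHAR = character(0),
         INTEGER = integer(0), REAL = numeric(0), NUMERIC = numeric(0),
         BOOLEAN = logical(0), character(0))
}

.empty_table <- function(catalog, table_name) {
  cols <- catalog[catalog$table_name == table_name, , drop = FALSE]
  tb <- lapply(cols$sql_type, .r_type_for)
  names(tb) <- cols$column
  ## booleans round-trip as logical even in the sqlite dialect (INTEGER)
  reg <- .registry()
  for (def in c(reg$entities, reg$auxiliary)) {
    if (def$table == table_name) {
      for (i in seq_len(nrow(def$columns)))
        if (def$columns$type[i] == "boolean") tb[[def$columns$column[i]]] <- logical(0)
    }
  }
  as.data.frame(tb, stringsAsFactors = FALSE)
}

#' Execute a DDL script against an embedded store
#'
#' Parses a script produced by [emitDdl()] and creates the corresponding
#' empty tables and catalog. Re-execution on a store that already holds the
#' tables is rejected unless the script carries `IF NOT EXISTS` guards, in
#' which case it is a no-op (idempotent).
#'
#' @param ddl DDL script text (sqlite or ansi dialect from [emitDdl()]).
#' @param db optional existing [CgdmDb] to execute against.
#' @param path backing directory for a new store (`NA` = in-memory).
#' @return A [CgdmDb].
#' @export
executeDdl <- function(ddl, db = NULL, path = NA_character_) {
  catalog <- .parse_ddl(ddl)
  if (is.null(catalog) || !nrow(catalog))
    stop("DDL script contains no parseable CREATE TABLE statements", call. = FALSE)
  idempotent <- grepl("IF NOT EXISTS", ddl, fixed = TRUE)
  if (is.null(db)) {
    db <- new("CgdmDb", path = path, tables = new.env(parent = emptyenv()),
              catalog = catalog[0, , drop = FALSE])
  }
  existing <- unique(db@catalog$table_name)
  clash <- intersect(unique(catalog$table_name), existing)
  if (length(clash)) {
    if (idempotent) return(db)
    stop("tables already exist: ", paste(clash, collapse = ", "),
         " (re-run with if_not_exists for idempotent execution)", call. = FALSE)
  }
  for (tb in unique(catalog$table_name))
    assign(tb, .empty_table(catalog, tb), envir = db@tables)
  db@catalog <- rbind(db@catalog, catalog)
  validObject(db)
  db
}

#' Initialise a cGDM database
#'
#' Creates the full 8-entity schema (plus the auxiliary variant alias index)
#' by emitting and executing the embedded-dialect DDL, then persists the
#' empty store when a path is given.
#'
#' @param path Backing directory (created), or `NA` for an in-memory store.
#' @param force Overwrite a non-empty existing target.
#' @return A [CgdmDb]. The attached `summary` attribute echoes the
#'   introspected entity and attribute counts.
#' @export
initDb <- function(path = NA_character_, force = FALSE) {
  if (!is.na(path) && file.exists(file.path(path, "_catalog.tsv")) && !force)
    stop("target database already initialised: ", path,
         " (use force = TRUE)", call. = FALSE)
  db <- executeDdl(emitDdl("sqlite"), path = path)
  ## auxiliary service tables (alias index) are created alongside the entities
  full <- .parse_ddl(emitDdl("sqlite", include_auxiliary = TRUE))
  aux_tables <- setdiff(unique(full$table_name), unique(db@catalog$table_name))
  for (tb in aux_tables) {
    add <- full[full$table_name == tb, , drop = FALSE]
    assign(tb, .empty_table(add, tb), envir = db@tables)
    db@catalog <- rbind(db@catalog, add)
  }
  validObject(db)
  if (!is.na(path)) saveDb(db)
  summ <- catalogSummary(db@catalog)
  attr(db, "summary") <- summ
  db
}

#' Persist an embedded store to its backing directory
#' @param db A [CgdmDb] with a non-`NA` path.
#' @return Invisibly, the path.
#' @export
saveDb <- function(db) {
  stopifnot(is(db, "CgdmDb"))
  if (is.na(db@path)) stop("in-memory store has no backing path", call. = FALSE)
  dir.create(db@path, recursive = TRUE, showWarnings = FALSE)
  write.table(db@catalog, file.path(db@path, "_catalog.tsv"),
              sep = "\t", row.names = FALSE, quote = TRUE)
  for (tb in unique(db@catalog$table_name))
    write.table(get(tb, envir = db@tables), file.path(db@path, paste0(tb, ".tsv")),
                sep = "\t", row.names = FALSE, quote = TRUE, na = "")
  invisible(db@path)
}

#' Open an existing embedded cGDM store
#' @param path Backing directory previously written by [initDb()]/[saveDb()].
#' @return A [CgdmDb].
#' @export
cgdmConnect <- function(path) {
  cat_path <- file.path(path, "_catalog.tsv")
  if (!file.exists(cat_path))
    stop("no cGDM database at ", path, call. = FALSE)
  catalog <- read.delim(cat_path, stringsAsFactors = FALSE)
  tables <- new.env(parent = emptyenv())
  for (tb in unique(catalog$table_name)) {
    tmpl <- .empty_table(catalog, tb)
    f <- file.path(path, paste0(tb, ".tsv"))
    df <- read.delim(f, stringsAsFactors = FALSE, na.strings = "",
                     colClasses = vapply(tmpl, function(x) class(x)[1], character(1)))
    tables[[tb]] <- df[, names(tmpl), drop = FALSE]
  }
  db <- new("CgdmDb", path = path, tables = tables, catalog = catalog)
  validObject(db)
  db
}

## Deep copy for transactional staging.
.clone_db <- function(db) {
  env <- new.env(parent = emptyenv())
  for (nm in ls(db@tables)) assign(nm, get(nm, envir = db@tables), envir = env)
  new("CgdmDb", path = db@path, tables = env, catalog = db@catalog)
}

#' @rdname dbTable
#' @export
setGeneric("dbTable", function(db, entity) standardGeneric("dbTable"))

#' Read one entity table from a store
#'
#' @param db A [CgdmDb].
#' @param entity Entity name (e.g. `"GenomicAlteration"`) or raw table name.
#' @return The table as a data.frame.
#' @export
setMethod("dbTable", "CgdmDb", function(db, entity) {
  tb <- if (exists(entity, envir = db@tables, inherits = FALSE)) entity
        else .entity_def(entity)$table
  get(tb, envir = db@tables)
})

#' @rdname entityCounts
#' @export
setGeneric("entityCounts", function(db) standardGeneric("entityCounts"))

#' Per-entity row counts of a store
#' @param db A [CgdmDb].
#' @return Named integer vector over the model's entity tables.
#' @export
setMethod("entityCounts", "CgdmDb", function(db) {
  ents <- .registry()$entities
  vapply(setNames(names(ents), vapply(ents, `[[`, character(1), "table")),
         function(e) nrow(dbTable(db, e)), integer(1))
})

## Append validated rows; assigns surrogate keys. Internal.
.insert_rows <- function(db, entity, rows) {
  def <- .entity_def(entity)
  tb <- dbTable(db, entity)
  sur <- def$columns$column[def$columns$role == "surrogate"]
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  for (cl in setdiff(names(tb), names(rows))) rows[[cl]] <- NA
  rows <- rows[, names(tb), drop = FALSE]
  if (length(sur)) {
    base <- if (nrow(tb)) max(tb[[sur]], 0L, na.rm = TRUE) else 0L
    rows[[sur]] <- base + seq_len(nrow(rows))
  }
  for (cl in names(tb)) {
    target <- class(tb[[cl]])[1]
    rows[[cl]] <- switch(target,
                         integer = as.integer(rows[[cl]]),
                         numeric = as.numeric(rows[[cl]]),
                         logical = as.logical(rows[[cl]]),
                         as.character(rows[[cl]]))
  }
  assign(.entity_def(entity)$table, rbind(tb, rows), envir = db@tables)
  rows
}

#' Check referential closure of a store
#'
#' Verifies that every foreign-key reference resolves: annotations point at
#' stored alterations, per-test tables at stored test identifiers, and every
#' stored alteration's test has at least one pipeline-provenance row.
#'
#' @param db A [CgdmDb].
#' @return Character vector of violation messages (empty when closed).
#' @export
referentialViolations <- function(db) {
  msgs <- character(0)
  ci <- dbTable(db, "ClinicalIdentifier")
  ga <- dbTable(db, "GenomicAlteration")
  pp <- dbTable(db, "PipelineProvenance")
  for (e in c("ExperimentInfo", "QualityCheck", "MicrosatelliteInstability",
              "TumorMutationBurden", "PipelineProvenance", "GenomicAlteration")) {
    t <- dbTable(db, e)
    bad <- setdiff(t$test_id, ci$test_id)
    if (length(bad))
      msgs <- c(msgs, paste0(e, ": unresolved test_id ", paste(bad, collapse = ",")))
  }
  ca <- dbTable(db, "ClinicalAnnotation")
  bad <- setdiff(ca$alteration_id, ga$alteration_id)
  if (length(bad))
    msgs <- c(msgs, paste0("ClinicalAnnotation: orphan alteration_id ",
                           paste(bad, collapse = ",")))
  orphan_ga <- setdiff(ga$test_id, pp$test_id)
  if (length(orphan_ga))
    msgs <- c(msgs, paste0("GenomicAlteration without provenance for test ",
                           paste(orphan_ga, collapse = ",")))
  ai <- dbTable(db, "AliasIndex")
  bad <- setdiff(ai$alteration_id, ga$alteration_id)
  if (length(bad))
    msgs <- c(msgs, paste0("AliasIndex: orphan alteration_id ",
                           paste(bad, collapse = ",")))
  msgs
}
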