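## ---------------------------------------------------------------------------
## HGVS nomenclature: parsing, completeness validation, alias indexing
##
## A complete HGVS expression pins its numbering to a versioned reference
## accession (e.g. NP_004324.2:p.V600E). Expressions lacking the version are
## a classic source of misinterpretation (the historical V599E/V600E
## renumbering of BRAF); they are detected and flagged, never auto-corrected.
## ---------------------------------------------------------------------------

.aa3to1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
             Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
             Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
             Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V",
             Ter = "*")

.protein_change_1letter <- function(change) {
  out <- change
  for (aa in names(.aa3to1))
    out <- gsub(aa, .aa3to1[[aa]], out, fixed = TRUE)
  gsub("\\s+", "", out)
}

.acc_level_class <- function(accession) {
  if (grepl("^(NP_|AP_|XP_|ENSP)", accession)) return("p")
  if (grepl("^(NM_|NR_|XM_|ENST)", accession)) return("c")
  if (grepl("^(NC_|NG_|NT_|NW_|ENSG|LRG)", accession)) return("g")
  NA_character_
}

#' Parse an HGVS expression
#'
#' Accepts genomic (g.), coding (c.) and protein (p.) level expressions with
#' RefSeq or Ensembl accessions, with or without an accession version. The
#' original text is preserved; protein changes are additionally normalized to
#' one-letter amino-acid codes for comparison.
#'
#' @param text An HGVS string such as `"NP_004324.2:p.V600E"`.
#' @return An `HgvsExpression`: list with `accession`, `version` (integer or
#'   `NA`), `level` (`"g"`, `"c"` or `"p"`), `change` (verbatim),
#'   `change_norm` (one-letter normalized for p-level) and `text`.
#' @examples
#' parseHgvs("NP_004324.2:p.V600E")$version
#' parseHgvs("NP_004324:p.V599E")$version
#' @export
parseHgvs <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  raw <- trimws(text)
  rx <- "^([A-Za-z]{2,4}_[0-9]+|ENS[A-Z]*[0-9]+):([gcpnmr])\\.(\\S+)$"
  rx_ver <- "^([A-Za-z]{2,4}_[0-9]+|ENS[A-Z]*[0-9]+)\\.([0-9]+):([gcpnmr])\\.(\\S+)$"
  if (grepl(rx_ver, raw)) {
    m <- regmatches(raw, regexec(rx_ver, raw))[[1]]
    acc <- m[2]; ver <- as.integer(m[3]); lev <- m[4]; chg <- m[5]
  } else if (grepl(rx, raw)) {
    m <- regmatches(raw, regexec(rx, raw))[[1]]
    acc <- m[2]; ver <- NA_integer_; lev <- m[3]; chg <- m[4]
  } else {
    ## locate the failure point for the error message
    acc_m <- regexpr("^([A-Za-z]{2,4}_[0-9]+(\\.[0-9]+)?|ENS[A-Z]*[0-9]+(\\.[0-9]+)?)",
                     raw)
    at <- if (acc_m > 0) attr(acc_m, "match.length") + 1L else 1L
    .cgdm_error(sprintf("cannot parse HGVS expression '%s' (at character %d)",
                        raw, at), "cgdm_parse_error")
  }
  expected <- .acc_level_class(acc)
  if (!is.na(expected) && expected != lev)
    .cgdm_error(sprintf(
      "HGVS level '%s.' inconsistent with accession class of %s (expected '%s.')",
      lev, acc, expected), "cgdm_parse_error")
  structure(list(accession = acc, version = ver, level = lev, change = chg,
                 change_norm = if (lev == "p") .protein_change_1letter(chg) else chg,
                 text = raw),
            class = "HgvsExpression")
}

#' Format an HGVS expression back to text
#' @param expr An `HgvsExpression` from [parseHgvs()].
#' @return Character scalar; round-trips [parseHgvs()] input.
#' @export
formatHgvs <- function(expr) {
  ver <- if (!is.na(expr$version)) paste0(".", expr$version) else ""
  paste0(expr$accession, ver, ":", expr$level, ".", expr$change)
}

#' @export
print.HgvsExpression <- function(x, ...) {
  cat("HgvsExpression:", formatHgvs(x),
      if (is.na(x$version)) "[version absent]" else "", "\n")
  invisible(x)
}

#' Validate completeness of an HGVS expression
#'
#' A complete expression carries a reference accession with its version; the
#' version pins the exact sequence the numbering is defined against. Failures
#' are categorised into the information-distortion meta-categories
#' `origin`, `reference`, `symbol`: a missing or out-of-domain version is a
#' `reference` failure (the reference sequence is underspecified).
#'
#' @param expr An `HgvsExpression`.
#' @return List: `complete` (logical), `category` (`NA` when complete) and
#'   `message`.
#' @examples
#' validateCompleteness(parseHgvs("NP_004324.2:p.V600E"))$complete
#' validateCompleteness(parseHgvs("NP_004324:p.V599E"))$category
#' @export
validateCompleteness <- function(expr) {
  if (!inherits(expr, "HgvsExpression"))
    .cgdm_error("expected a parsed HgvsExpression", "cgdm_value_error")
  if (!nzchar(expr$change))
    return(list(complete = FALSE, category = "symbol",
                message = "empty change description"))
  if (is.na(expr$version))
    return(list(complete = FALSE, category = "reference",
                message = "accession version absent; numbering reference underspecified"))
  if (expr$version < 1L)
    return(list(complete = FALSE, category = "reference",
                message = "accession versions are >= 1"))
  list(complete = TRUE, category = NA_character_, message = "complete")
}

## ---------------------------------------------------------------------------
## Alias index
## ---------------------------------------------------------------------------

.alias_keys_for_row <- function(row) {
  keys <- list()
  pchg <- NA_character_
  if (!is.na(row$hgvs_p) && nzchar(row$hgvs_p)) {
    pe <- tryCatch(parseHgvs(row$hgvs_p), error = function(e) NULL)
    if (!is.null(pe)) pchg <- pe$change_norm
  }
  if (!is.na(row$gene_symbol) && !is.na(pchg))
    keys[[length(keys) + 1L]] <- c(key = paste0(row$gene_symbol, ":", pchg),
                                   type = "gene_protein")
  if (!is.na(row$dbsnp_id) && nzchar(row$dbsnp_id))
    keys[[length(keys) + 1L]] <- c(key = row$dbsnp_id, type = "dbsnp")
  for (f in c("hgvs_g", "hgvs_c", "hgvs_p"))
    if (!is.na(row[[f]]) && nzchar(row[[f]]))
      keys[[length(keys) + 1L]] <- c(key = row[[f]], type = "hgvs")
  keys
}

#' Register semantic-query aliases for a stored alteration
#'
#' Generates alias keys (gene + protein change, dbSNP id, every full HGVS
#' string present) and inserts them into the store's alias index, enabling
#' fragmented-query resolution. When no naming field is populated an empty
#' key set is returned with a coverage warning.
#'
#' @param db A [CgdmDb].
#' @param alteration_id ID of a stored GenomicAlteration row.
#' @return Character vector of alias keys (invisibly stored in the index).
#' @export
registerAliases <- function(db, alteration_id) {
  ga <- dbTable(db, "GenomicAlteration")
  row <- ga[ga$alteration_id == alteration_id, , drop = FALSE]
  if (!nrow(row))
    .cgdm_error(paste0("no stored alteration with id ", alteration_id),
                "cgdm_value_error")
  row <- row[1, ]
  keys <- .alias_keys_for_row(row)
  if (!length(keys)) {
    warning("alteration ", alteration_id,
            " has no naming fields; it is unreachable by semantic query",
            call. = FALSE)
    return(character(0))
  }
  idx <- do.call(rbind, lapply(keys, function(k)
    data.frame(alias_key = unname(k["key"]), alias_type = unname(k["type"]),
               gene_symbol = row$gene_symbol, alteration_id = row$alteration_id,
               stringsAsFactors = FALSE)))
  ai <- dbTable(db, "AliasIndex")
  new <- idx[!paste(idx$alias_key, idx$alteration_id) %in%
               paste(ai$alias_key, ai$alteration_id), , drop = FALSE]
  if (nrow(new))
    assign("ALIAS_INDEX", rbind(ai, new), envir = db@tables)
  idx$alias_key
}

#' Resolve a (possibly fragmented) variant query
#'
#' Exact alias matches are returned first. A fragment matching only the
#' protein-change component of gene+protein aliases (e.g. `"V600E"`) returns
#' every candidate gene with an ambiguity flag when more than one gene
#' matches — never a silent single guess. Candidates are stably ordered by
#' gene symbol.
#'
#' @param fragment Query text (full alias key or protein-change fragment).
#' @param db A [CgdmDb] with a populated alias index.
#' @return List with `candidates` (data.frame: `alias_key`, `gene_symbol`,
#'   `alteration_id`, `match_type`) and `ambiguous` (logical).
#' @export
resolveQuery <- function(fragment, db) {
  ai <- dbTable(db, "AliasIndex")
  fragment <- trimws(fragment)
  exact <- ai[ai$alias_key == fragment, , drop = FALSE]
  if (nrow(exact)) {
    exact$match_type <- "exact"
    exact <- exact[order(exact$gene_symbol, exact$alteration_id), , drop = FALSE]
    return(list(candidates = exact[, c("alias_key", "gene_symbol",
                                       "alteration_id", "match_type")],
                ambiguous = FALSE))
  }
  gp <- ai[ai$alias_type == "gene_protein", , drop = FALSE]
  part <- gp[sub("^[^:]*:", "", gp$alias_key) == fragment, , drop = FALSE]
  if (nrow(part)) {
    part$match_type <- "partial"
    part <- part[order(part$gene_symbol, part$alteration_id), , drop = FALSE]
    return(list(candidates = part[, c("alias_key", "gene_symbol",
                                      "alteration_id", "match_type")],
                ambiguous = length(unique(part$gene_symbol)) > 1L))
  }
  list(candidates = data.frame(alias_key = character(0),
                               gene_symbol = character(0),
                               alteration_id = integer(0),
                               match_type = character(0),
                               stringsAsFactors = FALSE),
       ambiguous = FALSE)
}
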