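## ---------------------------------------------------------------------------
## Minimal-representation variant normalization
##
## The same indel can be spelled many ways in VCF output (padded alleles,
## right-shifted positions inside repeat tracts). Normalization makes
## equivalent spellings byte-identical: shared allele bases are trimmed
## (suffix first, then prefix, always retaining the VCF anchor base), and
## indels are left-aligned against local reference sequence to the smallest
## position that produces the same edited sequence.
## ---------------------------------------------------------------------------

.norm_chrom <- function(chrom) sub("^chr", "", as.character(chrom))

.cgdm_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "cgdmError")))
}

#' Construct a raw variant record
#'
#' Coordinates are 1-based, VCF-style; the "chr" prefix is stripped at this
#' boundary so that a single canonical chromosome form is used internally.
#'
#' @param chromosome chromosome name (with or without "chr" prefix).
#' @param position 1-based position of the first reference base.
#' @param ref_allele,alt_allele uppercase nucleotide strings (`[ACGTN]+`).
#' @param genome_build reference assembly label (e.g. `"GRCh37"`).
#' @return A `RawVariant` (named list).
#' @examples
#' rawVariant("chr10", 11805838, "CG", "CTG", "GRCh37")
#' @export
rawVariant <- function(chromosome, position, ref_allele, alt_allele,
                       genome_build) {
  ref_allele <- toupper(ref_allele); alt_allele <- toupper(alt_allele)
  if (!grepl("^[ACGTN]+$", ref_allele) || !grepl("^[ACGTN]+$", alt_allele))
    .cgdm_error("alleles must be non-empty uppercase [ACGTN]+", "cgdm_value_error")
  position <- as.integer(position)
  if (is.na(position) || position < 1L)
    .cgdm_error("position must be a 1-based integer coordinate", "cgdm_value_error")
  structure(list(chromosome = .norm_chrom(chromosome), position = position,
                 ref_allele = ref_allele, alt_allele = alt_allele,
                 genome_build = as.character(genome_build)),
            class = "RawVariant")
}

#' @export
print.RawVariant <- function(x, ...) {
  cat(sprintf("RawVariant %s:%d %s>%s (%s)\n", x$chromosome, x$position,
              x$ref_allele, x$alt_allele, x$genome_build))
  invisible(x)
}

#' Construct a reference sequence window
#'
#' @param chromosome chromosome name.
#' @param start 1-based coordinate of the window's first base.
#' @param sequence uppercase nucleotide string covering the window.
#' @param genome_build assembly label.
#' @return A `ReferenceWindow` (named list with an implied `end`).
#' @export
referenceWindow <- function(chromosome, start, sequence, genome_build) {
  sequence <- toupper(sequence)
  if (!nzchar(sequence))
    .cgdm_error("window sequence must be non-empty", "cgdm_value_error")
  start <- as.integer(start)
  if (is.na(start) || start < 1L)
    .cgdm_error("window start must be >= 1", "cgdm_value_error")
  structure(list(chromosome = .norm_chrom(chromosome), start = start,
                 sequence = sequence, genome_build = as.character(genome_build),
                 end = start + nchar(sequence) - 1L),
            class = "ReferenceWindow")
}

.window_sub <- function(win, from, to) {
  if (from < win$start || to > win$end)
    .cgdm_error(sprintf(
      "reference window %s:%d-%d does not cover required span %d-%d",
      win$chromosome, win$start, win$end, from, to), "cgdm_context_error")
  substr(win$sequence, from - win$start + 1L, to - win$start + 1L)
}

.check_ref_match <- function(v, win) {
  span_end <- v$position + nchar(v$ref_allele) - 1L
  obs <- .window_sub(win, v$position, span_end)
  if (!identical(obs, v$ref_allele))
    .cgdm_error(sprintf(
      "ref allele mismatch at %s:%d: variant says '%s', window has '%s'",
      v$chromosome, v$position, v$ref_allele, obs), "cgdm_reference_mismatch")
  invisible(TRUE)
}

#' Apply a variant's edit to a reference window
#'
#' Replaces the reference allele bases at the variant position with the
#' alternative allele and returns the edited window sequence. Used to check
#' semantic preservation of normalization (two spellings are equivalent iff
#' their edited sequences are identical).
#'
#' @param v A `RawVariant` covered by the window.
#' @param win A `ReferenceWindow`.
#' @return The edited sequence (character scalar).
#' @export
applyVariant <- function(v, win) {
  .check_ref_match(v, win)
  i <- v$position - win$start + 1L
  paste0(substr(win$sequence, 1L, i - 1L), v$alt_allele,
         substr(win$sequence, i + nchar(v$ref_allele), nchar(win$sequence)))
}

#' Trim shared allele bases to the minimal spelling
#'
#' Removes the longest shared allele suffix, then the longest shared prefix
#' (advancing the position), with both alleles always retaining at least one
#' base — the VCF anchor-base convention for indels.
#'
#' @param v A `RawVariant`.
#' @return The trimmed `RawVariant`; identical edit semantics.
#' @examples
#' trimAlleles(rawVariant("10", 11805838, "CG", "CTG", "GRCh37"))
#' @export
trimAlleles <- function(v) {
  ref <- v$ref_allele; alt <- v$alt_allele; pos <- v$position
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substring(ref, 2L); alt <- substring(alt, 2L)
    pos <- pos + 1L
  }
  if (!nzchar(ref) || !nzchar(alt))
    .cgdm_error("allele emptied during trim (unreachable)", "cgdm_internal_error")
  out <- v; out$position <- pos; out$ref_allele <- ref; out$alt_allele <- alt
  out
}

#' Left-align a trimmed indel against a reference window
#'
#' Shifts an indel to the smallest position that produces an identical edited
#' sequence (the leftmost representation within a repeat tract), then
#' re-trims. Length-preserving variants (SNV/MNV) are returned unchanged, as
#' are alleles containing the ambiguous base `N` (for which shift comparison
#' is unsound; the result carries `attr(, "n_blocked") = TRUE`). The
#' operation is idempotent.
#'
#' @param v A trimmed `RawVariant`.
#' @param win A `ReferenceWindow` covering the variant and sufficient left
#'   context.
#' @return The left-aligned `RawVariant`.
#' @export
leftAlign <- function(v, win) {
  if (!identical(.norm_chrom(v$chromosome), win$chromosome))
    .cgdm_error("variant and window on different chromosomes",
                "cgdm_value_error")
  if (nchar(v$ref_allele) == nchar(v$alt_allele)) return(v)
  if (grepl("N", v$ref_allele, fixed = TRUE) ||
      grepl("N", v$alt_allele, fixed = TRUE)) {
    attr(v, "n_blocked") <- TRUE
    return(v)
  }
  .check_ref_match(v, win)
  ref <- v$ref_allele; alt <- v$alt_allele; pos <- v$position
  repeat {
    changed <- FALSE
    lr <- nchar(ref); la <- nchar(alt)
    if (lr > 0L && la > 0L &&
        substr(ref, lr, lr) == substr(alt, la, la)) {
      ref <- substr(ref, 1L, lr - 1L); alt <- substr(alt, 1L, la - 1L)
      changed <- TRUE
    }
    if (!nzchar(ref) || !nzchar(alt)) {
      if (pos - 1L < win$start)
        .cgdm_error(sprintf(
          "window %s:%d-%d lacks left context before position %d",
          win$chromosome, win$start, win$end, pos), "cgdm_context_error")
      b <- .window_sub(win, pos - 1L, pos - 1L)
      ref <- paste0(b, ref); alt <- paste0(b, alt)
      pos <- pos - 1L
      changed <- TRUE
    }
    if (!changed) break
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substring(ref, 2L); alt <- substring(alt, 2L)
    pos <- pos + 1L
  }
  out <- v; out$position <- pos; out$ref_allele <- ref; out$alt_allele <- alt
  out
}

#' Normalize a variant to its minimal representation
#'
#' Trims shared allele bases and, when a reference window is supplied,
#' left-aligns indels. Without reference context only trimming is possible
#' and the result is flagged `normalization_mode = "trim_only"` so that the
#' degraded normalization is recorded rather than silently assumed complete.
#' Idempotent: `normalizeVariant(normalizeVariant(x, w), w)` equals
#' `normalizeVariant(x, w)`.
#'
#' @param v A `RawVariant`.
#' @param win Optional `ReferenceWindow`.
#' @return The normalized `RawVariant` with a `normalization_mode` element
#'   (`"full"` or `"trim_only"`).
#' @examples
#' w <- NULL
#' a <- normalizeVariant(rawVariant("10", 11805838, "C",  "CT",  "GRCh37"))
#' b <- normalizeVariant(rawVariant("10", 11805838, "CG", "CTG", "GRCh37"))
#' identical(a, b)
#' @export
normalizeVariant <- function(v, win = NULL) {
  v$normalization_mode <- NULL
  out <- trimAlleles(v)
  mode <- "trim_only"
  if (!is.null(win) && nchar(out$ref_allele) != nchar(out$alt_allele)) {
    out <- leftAlign(out, win)
    mode <- if (isTRUE(attr(out, "n_blocked"))) "trim_only" else "full"
    attr(out, "n_blocked") <- NULL
  } else if (!is.null(win)) {
    ## length-preserving variants are position-unique; trimming completes it
    mode <- "full"
  }
  out$normalization_mode <- mode
  out
}

#' Test whether two variant spellings denote the same edit
#'
#' Two variants are equivalent iff their normalized representations are
#' identical on the same genome build. Records on different builds are never
#' equivalent (the same variant has different coordinates across builds); in
#' that case the result carries `attr(, "note") = "build mismatch"`.
#'
#' @param a,b `RawVariant`s on the same chromosome.
#' @param win Optional shared `ReferenceWindow`.
#' @return Logical scalar.
#' @examples
#' areEquivalent(rawVariant("10", 11805838, "C", "CT", "GRCh37"),
#'               rawVariant("10", 11805838, "CG", "CTG", "GRCh37"))
#' @export
areEquivalent <- function(a, b, win = NULL) {
  if (!identical(a$genome_build, b$genome_build)) {
    out <- FALSE
    attr(out, "note") <- "build mismatch"
    return(out)
  }
  na <- normalizeVariant(a, win); nb <- normalizeVariant(b, win)
  identical(na[c("chromosome", "position", "ref_allele", "alt_allele")],
            nb[c("chromosome", "position", "ref_allele", "alt_allele")])
}

#' Extract a reference window from a FASTA file
#'
#' Reads an indexed or plain FASTA via Biostrings and cuts the requested
#' span. Sequence names are matched with and without the "chr" prefix.
#'
#' @param fasta_path Path to a FASTA file.
#' @param chromosome,start,end 1-based inclusive span to extract.
#' @param genome_build Assembly label recorded on the window.
#' @return A `ReferenceWindow`.
#' @export
fastaWindow <- function(fasta_path, chromosome, start, end, genome_build) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  key <- .norm_chrom(chromosome)
  hit <- which(.norm_chrom(names(seqs)) == key)
  if (!length(hit))
    .cgdm_error(paste0("chromosome not in FASTA: ", chromosome),
                "cgdm_context_error")
  sq <- seqs[[hit[1]]]
  if (end > length(sq))
    .cgdm_error("requested span extends beyond FASTA sequence",
                "cgdm_context_error")
  referenceWindow(chromosome, start,
                  as.character(Biostrings::subseq(sq, start, end)),
                  genome_build)
}
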