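# Independent oracles, kept deliberately separate from the package's own
# algorithms: they work on whole edited sequences or by exhaustive
# enumeration, where the implementation shifts per-allele.

# Edited window sequence for a variant, computed from scratch.
oracle_apply <- function(v, win) {
  i <- v$position - win$start + 1L
  stopifnot(substr(win$sequence, i, i + nchar(v$ref_allele) - 1L) == v$ref_allele)
  paste0(substr(win$sequence, 1L, i - 1L), v$alt_allele,
         substring(win$sequence, i + nchar(v$ref_allele)))
}

# Leftmost minimal representation by whole-sequence comparison: trim the
# longest common suffix of (reference, edited) first, then the longest common
# prefix, re-anchoring when an allele empties.
oracle_minimal <- function(v, win) {
  S <- win$sequence
  E <- oracle_apply(v, win)
  sv <- utf8ToInt(S); ev <- utf8ToInt(E)
  ls <- length(sv); le <- length(ev)
  n <- min(ls, le)
  d2 <- which(rev(sv)[seq_len(n)] != rev(ev)[seq_len(n)])
  cs <- if (length(d2)) d2[1] - 1L else n
  d1 <- which(sv[seq_len(n)] != ev[seq_len(n)])
  cp <- min(if (length(d1)) d1[1] - 1L else n, n - cs)
  ref <- substr(S, cp + 1L, ls - cs)
  alt <- substr(E, cp + 1L, le - cs)
  pos <- win$start + cp
  if (!nzchar(ref) || !nzchar(alt)) {
    stopifnot(cp >= 1L)
    ref <- paste0(substr(S, cp, cp), ref)
    alt <- paste0(substr(E, cp, cp), alt)
    pos <- pos - 1L
  }
  list(chromosome = v$chromosome, position = pos, ref_allele = ref,
       alt_allele = alt)
}

# Exhaustive enumeration of minimal spellings producing the same edited
# sequence, restricted to a window around the variant (an edit cannot be
# represented further away than the shared-context run it sits in; fixture
# slots are 60 bp). Returns the representation at the smallest position.
oracle_enumerate <- function(v, win, span = 60L) {
  S <- win$sequence
  E <- oracle_apply(v, win)
  ls <- nchar(S); le <- nchar(E)
  delta <- le - ls
  # a candidate (pos, ref, alt) with alt lifted from E reproduces E exactly
  # iff the bases before it lie inside the S/E common prefix and the bases
  # after it inside the common suffix; precompute both runs once so the
  # per-candidate equality test is O(1) instead of rebuilding the sequence
  sv <- utf8ToInt(S); ev <- utf8ToInt(E)
  n <- min(ls, le)
  d1 <- which(sv[seq_len(n)] != ev[seq_len(n)])
  cp_max <- if (length(d1)) d1[1] - 1L else n
  d2 <- which(rev(sv)[seq_len(n)] != rev(ev)[seq_len(n)])
  cs_max <- if (length(d2)) d2[1] - 1L else n
  lo <- max(win$start, v$position - span)
  hi <- min(win$end, v$position + span)
  for (pos in lo:hi) {
    i <- pos - win$start + 1L
    if (i - 1L > cp_max) break           # prefix mismatch from here rightwards
    for (rl in 0:15) {
      al <- rl + delta
      # anchored minimal forms only: both alleles non-empty
      if (al < 1L || rl < 1L) next
      if (i + rl - 1L > ls || i + al - 1L > le) next
      if (ls - (i + rl) + 1L > cs_max) next   # trailing bases don't match E
      ref <- substr(S, i, i + rl - 1L)
      alt <- substr(E, i, i + al - 1L)
      # minimality: trimming the candidate must be a fixed point
      if (rl > 1L && al > 1L &&
          (substr(ref, rl, rl) == substr(alt, al, al) ||
           substr(ref, 1L, 1L) == substr(alt, 1L, 1L))) next
      # positions scan left to right: the first hit is the leftmost form
      return(list(position = pos, ref_allele = ref, alt_allele = alt))
    }
  }
  NULL
}

# Brute force over every legal order of single-base prefix/suffix removals;
# returns all reachable spellings that are semantically equal to the input
# and cannot be trimmed further.
oracle_trim_exhaustive <- function(pos, ref, alt) {
  seen <- new.env(parent = emptyenv())
  results <- list()
  recurse <- function(pos, ref, alt) {
    key <- paste(pos, ref, alt)
    if (exists(key, envir = seen)) return()
    assign(key, TRUE, envir = seen)
    moves <- 0L
    lr <- nchar(ref); la <- nchar(alt)
    if (lr > 1L && la > 1L && substr(ref, lr, lr) == substr(alt, la, la)) {
      moves <- moves + 1L
      recurse(pos, substr(ref, 1L, lr - 1L), substr(alt, 1L, la - 1L))
    }
    if (lr > 1L && la > 1L && substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
      moves <- moves + 1L
      recurse(pos + 1L, substring(ref, 2L), substring(alt, 2L))
    }
    if (moves == 0L)
      results[[length(results) + 1L]] <<- list(position = pos, ref_allele = ref,
                                               alt_allele = alt)
  }
  recurse(pos, ref, alt)
  results
}

# Spreadsheet-style IWPC arithmetic, written out as explicit formulas with
# the published coefficients; deliberately not reading the packaged table.
oracle_iwpc <- function(age, ht, wt, race, inducer, amiodarone, cyp, vk,
                        model = "pharmacogenetic") {
  s <- if (model == "pharmacogenetic") {
    5.6044 - 0.2614 * age + 0.0087 * ht + 0.0128 * wt -
      0.8677 * (vk == "GA") - 1.6974 * (vk == "AA") -
      0.5211 * (cyp == "*1/*2") - 0.9357 * (cyp == "*1/*3") -
      1.0616 * (cyp == "*2/*2") - 1.9206 * (cyp == "*2/*3") -
      2.3312 * (cyp == "*3/*3") -
      0.1092 * (race == "asian") - 0.2760 * (race == "black") -
      0.1032 * (race == "mixed_or_missing") +
      1.1816 * inducer - 0.5503 * amiodarone
  } else {
    4.0376 - 0.2546 * age + 0.0118 * ht + 0.0134 * wt -
      0.6752 * (race == "asian") + 0.4060 * (race == "black") +
      0.0443 * (race == "mixed_or_missing") +
      1.2799 * inducer - 0.5695 * amiodarone
  }
  s^2
}

pgx_genotype <- function(cyp, vk)
  structure(list(cyp2c9_star = cyp, vkorc1_1639 = vk), class = "PgxGenotype")

# Minimal VCF writer for hand-built fixtures.
write_mini_vcf <- function(path, body_lines, samples = "S1") {
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t"),
               body_lines), path)
  path
}

fixture_manifest <- function(path, test_id = "T1", build = "FIXTURE1",
                             mode = "trim_only", fasta = NULL, ...) {
  etlManifest(source_path = path, source_format = "VCF", test_id = test_id,
              genome_build = build,
              pipeline_provenance = list(provenanceRecord(
                "variant_calling", tool_name = "caller", tool_version = "1",
                origin_source = "fixture", origin_version = "1",
                origin_build = build)),
              normalization_mode = mode, reference_fasta = fasta,
              reject_path = tempfile(), ...)
}
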