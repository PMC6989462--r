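test_that("the two spellings of the same insertion normalize identically", {
  a <- normalizeVariant(rawVariant("chr10", 11805838, "C", "CT", "GRCh37"))
  b <- normalizeVariant(rawVariant("chr10", 11805838, "CG", "CTG", "GRCh37"))
  expect_identical(a, b)
  expect_identical(a$position, 11805838L)
  expect_identical(a$ref_allele, "C")
  expect_identical(a$alt_allele, "CT")
  # an already-minimal SNV is a bitwise fixed point
  snv <- rawVariant("chr7", 140453136, "A", "T", "GRCh37")
  expect_identical(trimAlleles(snv), snv)
})

test_that("trimming removes shared bases suffix-first and matches brute force", {
  v <- trimAlleles(rawVariant("chrX", 100, "ACCA", "ATCA", "B"))
  expect_identical(v$position, 101L)
  expect_identical(v$ref_allele, "C")
  expect_identical(v$alt_allele, "T")
  # brute-force oracle: every order of legal removals reaches one fully
  # trimmed spelling, and it is the one the implementation returns
  reached <- oracle_trim_exhaustive(100L, "ACCA", "ATCA")
  expect_length(reached, 1L)
  expect_identical(reached[[1]],
                   v[c("position", "ref_allele", "alt_allele")])
  # anchored indels keep one leading shared base
  v2 <- trimAlleles(rawVariant("1", 50, "CG", "CTG", "B"))
  expect_identical(v2$ref_allele, "C")
  expect_identical(v2$alt_allele, "CT")
})

test_that("left alignment shifts an insertion to the repeat tract's left edge", {
  # window 1..16: GG ATATAT CCCCCCCC; insertion of AT at the tract's right edge
  win <- referenceWindow("5", 1, "GGATATATCCCCCCCC", "B")
  v <- rawVariant("5", 8, "T", "TAT", "B")       # right-edge spelling
  la <- leftAlign(v, win)
  expect_identical(la$position, 2L)              # anchor just left of tract
  expect_identical(la$ref_allele, "G")
  expect_identical(la$alt_allele, "GAT")
  # oracle: edited sequences identical, and enumeration finds the same form
  expect_identical(oracle_apply(la, win), oracle_apply(v, win))
  expect_identical(oracle_enumerate(v, win)[c("position", "ref_allele",
                                              "alt_allele")],
                   la[c("position", "ref_allele", "alt_allele")])
  # SNVs pass through unchanged
  snv <- rawVariant("5", 10, "C", "A", "B")
  expect_identical(leftAlign(snv, win), snv)
  # a deletion in non-repetitive context does not move
  win2 <- referenceWindow("5", 1, "TTGACGTACT", "B")
  del <- rawVariant("5", 4, "ACG", "A", "B")
  expect_identical(leftAlign(del, win2)$position, 4L)
  expect_identical(oracle_enumerate(del, win2)$position, 4L)
})

test_that("left alignment reports missing context and reference mismatch", {
  win <- referenceWindow("5", 5, "ATATATC", "B")  # spans 5..11
  # insertion shifts past the window's left edge -> context error names span
  v <- rawVariant("5", 10, "T", "TAT", "B")
  err <- tryCatch(leftAlign(v, win), error = function(e) e)
  expect_s3_class(err, "cgdm_context_error")
  expect_match(conditionMessage(err), "5:5-11")
  # window disagreeing with the stated reference allele
  v2 <- rawVariant("5", 6, "GG", "G", "B")
  expect_error(leftAlign(v2, win), "mismatch",
               class = "cgdm_reference_mismatch")
})

test_that("ambiguous N alleles trim but block left alignment", {
  win <- referenceWindow("2", 1, "GGATATATCC", "B")
  v <- rawVariant("2", 2, "N", "NAT", "B")
  nv <- normalizeVariant(v, win)
  expect_identical(nv$normalization_mode, "trim_only")
  expect_identical(nv$position, 2L)                # not shifted
  # shared N bases still trim away; what remains may then fully normalize
  v2 <- normalizeVariant(rawVariant("2", 4, "TN", "TATN", "B"), win)
  expect_identical(v2$normalization_mode, "full")
  expect_false(grepl("N", v2$alt_allele))
})

test_that("normalization is idempotent and semantics-preserving on a corpus", {
  corpus <- makeIndelCorpus(fixtureSpec(seed = 11), n = 120)
  win <- corpus$window
  for (cs in corpus$cases) {
    nv <- normalizeVariant(cs$spelling, win)
    expect_identical(normalizeVariant(nv, win), nv)
    expect_identical(oracle_apply(nv, win), oracle_apply(cs$spelling, win))
    om <- oracle_minimal(cs$spelling, win)
    expect_identical(nv[c("position", "ref_allele", "alt_allele")],
                     om[c("position", "ref_allele", "alt_allele")])
  }
})

test_that("equivalence testing is an equivalence relation within one build", {
  win <- makeIndelCorpus(fixtureSpec(seed = 13), n = 30)
  cases <- win$cases; w <- win$window
  # reflexive on every spelling; symmetric and transitive via shared truth
  for (cs in cases[1:10]) {
    expect_true(areEquivalent(cs$spelling, cs$spelling, w))
    expect_true(areEquivalent(cs$spelling, cs$truth, w))
    expect_true(areEquivalent(cs$truth, cs$spelling, w))
  }
  # spellings of two different true variants are not equivalent
  expect_false(areEquivalent(cases[[1]]$spelling, cases[[2]]$spelling, w))
  # the same coordinates on different builds are never the same variant
  a <- rawVariant("7", 140453136, "A", "T", "GRCh37")
  b <- rawVariant("7", 140453136, "A", "T", "GRCh38")
  eq <- areEquivalent(a, b)
  expect_false(eq)
  expect_identical(attr(eq, "note"), "build mismatch")
})

test_that("FASTA windows feed left alignment", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">chr5 test contig", "GGATATATCCCCCCCC"), fa)
  win <- fastaWindow(fa, "5", 1, 16, "B")
  expect_identical(win$sequence, "GGATATATCCCCCCCC")
  la <- leftAlign(rawVariant("5", 8, "T", "TAT", "B"), win)
  expect_identical(la$position, 2L)
  expect_error(fastaWindow(fa, "9", 1, 10, "B"), "not in FASTA",
               class = "cgdm_context_error")
})
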