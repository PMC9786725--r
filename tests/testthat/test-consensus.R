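test_that("a stack of identical sequences is fully highly conserved", {
  rs <- RegionSet(
    Biostrings::DNAStringSet(rep("ACGTACGT", 3)),
    S4Vectors::DataFrame(orf_id = c("a", "b", "c"), kind = "tis_flank",
                         start = 1L, end = 8L, strand = "+", wraps = FALSE,
                         short = FALSE, anchor = "t"))
  st <- stackRegions(rs)
  expect_equal(dim(st), c(3L, 8L))
  cr <- consensusFromStack(st, anchor = "tis")
  expect_equal(consensusSeq(cr), "ACGTACGT")
  expect_true(all(conservedFlags(cr) == "highly_conserved"))
  expect_equal(colSums(consensusFrequencies(cr)), rep(1, 8),
               ignore_attr = TRUE)
})

test_that("mixed widths refuse to stack", {
  rs <- RegionSet(
    Biostrings::DNAStringSet(c("ACGTACGT", "ACGT")),
    S4Vectors::DataFrame(orf_id = c("ok", "bad"), kind = "tis_flank",
                         start = 1L, end = c(8L, 4L), strand = "+",
                         wraps = FALSE, short = FALSE, anchor = "t"))
  expect_error(stackRegions(rs), "bad")
})

test_that("column rules: plurality base, IUPAC ties, N coverage", {
  # 50/50 A and T ties at the plurality threshold -> W, never arbitrary
  st <- rbind(strsplit("AA", "")[[1]], strsplit("AT", "")[[1]],
              strsplit("TA", "")[[1]], strsplit("TT", "")[[1]])
  cr <- consensusFromStack(st, anchor = "tis")
  expect_equal(consensusSeq(cr), "WW")
  # octamers identical at 1-7 and covering all four bases at position 8
  # produce the partially degenerate ATTGCAAN consensus
  seqs <- c("ATTGCAAG", "ATTGCAAG", "ATTGCAAA", "ATTGCAAA",
            "ATTGCAAC", "ATTGCAAC", "ATTGCAAT", "ATTGCAAT")
  st2 <- do.call(rbind, strsplit(seqs, ""))
  cr2 <- consensusFromStack(st2, anchor = "tss")
  expect_equal(consensusSeq(cr2), "ATTGCAAN")
  expect_equal(conservedFlags(cr2)[8], "none")
  expect_true(all(conservedFlags(cr2)[1:7] == "highly_conserved"))
  # empty stacks are rejected
  expect_error(consensusFromStack(st2[1, , drop = FALSE]), "at least 2")
})

test_that("consensus is invariant to row order and cross-checks Biostrings", {
  set.seed(33)
  seqs <- vapply(1:12, function(i)
    paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE), collapse = ""),
    "")
  st <- do.call(rbind, strsplit(seqs, ""))
  c1 <- consensusFromStack(st, anchor = "tis")
  c2 <- consensusFromStack(st[sample(nrow(st)), ], anchor = "tis")
  expect_equal(consensusSeq(c1), consensusSeq(c2))
  expect_equal(consensusFrequencies(c1), consensusFrequencies(c2))
  # independent frequency oracle
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(seqs),
                                    as.prob = TRUE, baseOnly = TRUE)
  expect_equal(unname(consensusFrequencies(c1)),
               unname(cm[c("A", "C", "G", "T"), ]))
})

test_that("a planted position-frequency model is recovered at n = 50", {
  set.seed(44)
  width <- 12L
  major <- sample(c("A", "C", "G", "T"), width, replace = TRUE)
  rows <- vapply(1:50, function(i) {
    paste(vapply(seq_len(width), function(j) {
      if (runif(1) < 0.8) major[j] else sample(setdiff(c("A", "C", "G", "T"),
                                                       major[j]), 1)
    }, ""), collapse = "")
  }, "")
  st <- do.call(rbind, strsplit(rows, ""))
  cr <- consensusFromStack(st, anchor = "tss")
  # the generating plurality base wins every column outright
  expect_equal(consensusSeq(cr), paste(major, collapse = ""))
  top <- apply(consensusFrequencies(cr), 2, max)
  expect_true(all(top >= 0.5))
  expect_true(mean(top >= 0.7) > 0.8)   # most columns near the 0.8 model
})

test_that("flank position numbering skips zero", {
  g <- toyGenome()
  fl <- extractTisFlank(g, "g1", up = 3L, down = 3L)
  cr <- consensusFromStack(rbind(stackRegions(fl), stackRegions(fl)),
                           anchor = "tis", up = 3L)
  expect_equal(cr@positions, c(-3L, -2L, -1L, 1L, 2L, 3L))
})

test_that("per-class consensus and the curated class behave on synthetic data", {
  sim <- generateSynthetic(smallSpec(seed = 23L))
  g <- classifyOrfs(sim$genome)$genome
  cons <- classConsensus(g, "tss")
  expect_true(length(cons) >= 3L)
  for (cr in cons) {
    # TAAG is planted at every TSS: positions -1, +1..+3 of a 15/15 flank
    expect_equal(substr(consensusSeq(cr), 15, 18), "TAAG")
    expect_true(all(conservedFlags(cr)[15:18] == "highly_conserved"))
  }
  # curated set: Very High + High minus the two very-late genes
  ids <- curatedClass(g, exclusions = c("polh", "p10"))
  gr <- orfs(g)
  vh_high <- gr$orf_id[gr$expr_class %in% c("Very High", "High")]
  expect_equal(length(ids), length(vh_high) - 2L)
  expect_false(any(c("polh", "p10") %in% gr$name[gr$orf_id %in% ids]))
  # empty exclusions give the plain union; excluding everything errors
  expect_setequal(curatedClass(g, exclusions = character()), vh_high)
  expect_warning(curatedClass(g, exclusions = c("polh", "nosuch")), "nosuch")
  expect_error(suppressWarnings(
    curatedClass(g, exclusions = gr$orf_id[gr$orf_id %in% vh_high])))
})
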