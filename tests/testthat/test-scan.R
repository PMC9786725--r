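test_that("exact scan finds identity matches and handles short sequences", {
  hits <- fuzzyScan("ATTGCAAG", "ATTGCAAG")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$position, 1L)
  expect_equal(hits$mismatches, 0L)
  expect_equal(nrow(fuzzyScan("ATT", "ATTGCAAG")), 0L)
  # degenerate query letters allowed only at 0 mismatches
  expect_equal(fuzzyScan("AATTAAGG", "TWAG")$position, 4L)
  expect_error(fuzzyScan("AATTAAGG", "TWAG", maxMismatches = 1L), "degenerate")
  expect_error(fuzzyScan("ACGT", "ACGT", maxMismatches = 4L), "smaller")
})

test_that("the Hamming ball of an octamer at d<=2 has 277 members", {
  # closed form: 1 + 8*3 + choose(8,2)*9
  expect_equal(hammingBallSize(8, 2), 1 + 8 * 3 + choose(8, 2) * 9)
  expect_equal(hammingBallSize(8, 2), 277)
  # by explicit neighbourhood enumeration
  nb <- hammingNeighbors("ATTGCAAG", 2)
  expect_equal(length(nb), 277L)
  expect_equal(length(unique(nb)), 277L)
  # and by exhaustive distance counting over all 4^4 4-mers at k=4
  all4 <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), 4)))
  d <- vapply(all4, function(w)
    sum(strsplit(w, "")[[1]] != strsplit("ACGT", "")[[1]]), 1L)
  expect_equal(sum(d <= 2), hammingBallSize(4, 2))
})

test_that("fuzzy scan agrees with brute-force and Biostrings oracles on 10 kb", {
  g <- nullGenome(10000L, seed = 5L)
  s <- genomeSeq(g)
  for (d in 0:2) {
    mine <- fuzzyScan(s, "ATTGCAAG", d, strands = "plus")
    # independent in-suite brute force
    expect_equal(mine$position, naiveScan(s, "ATTGCAAG", d))
    # independent library oracle
    bst <- Biostrings::matchPattern("ATTGCAAG", Biostrings::DNAString(s),
                                    max.mismatch = d)
    expect_equal(mine$position, start(bst))
  }
  # minus strand equals plus-strand scan of the reverse complement query
  mm <- fuzzyScan(s, "ATTGCAAG", 2, strands = "minus")
  bst <- Biostrings::matchPattern(
    Biostrings::reverseComplement(Biostrings::DNAString("ATTGCAAG")),
    Biostrings::DNAString(s), max.mismatch = 2)
  expect_equal(mm$position, start(bst))
})

test_that("strand symmetry and tolerance monotonicity hold", {
  g <- nullGenome(5000L, seed = 6L)
  q <- "ATTAGGAA"
  both <- fuzzyScan(genomeSeq(g), q, 2, strands = "both")
  swapped <- fuzzyScan(genomeSeq(g), revCompChr(q), 2, strands = "both")
  # reverse-complementing the query swaps the per-strand counts
  expect_equal(sum(both$strand == "+"), sum(swapped$strand == "-"))
  expect_equal(sum(both$strand == "-"), sum(swapped$strand == "+"))
  expect_equal(nrow(both), nrow(swapped))
  # matches(d) is nested in matches(d+1)
  prev <- integer()
  for (d in 0:3) {
    cur <- fuzzyScan(genomeSeq(g), q, d, strands = "plus")$position
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("circular genome scans include origin-spanning windows", {
  # all-A circular genome: every rotation matches on the plus strand,
  # and every rotation of the revcomp (all T) matches on the minus strand
  g <- GenomeRecord("CIRC", strrep("A", 40), circular = TRUE)
  s <- genomeScan(g, "AAAAAAAA", 0)
  expect_equal(s@plusCount, 40L)
  expect_equal(totalMatches(genomeScan(g, "TTTTTTTT", 0)), 40L)
  expect_equal(ratePerKbp(s), 1000 * 40 / 40)
  # a window that exists only across the origin
  g2 <- GenomeRecord("CIRC2", paste0("CCGG", strrep("T", 30), "AATT"),
                     circular = TRUE)
  hits <- fuzzyScan(genomeSeq(g2), "AATTCCGG", 0, strands = "plus",
                    circular = TRUE)
  expect_equal(hits$position, 35L)
  expect_equal(nrow(fuzzyScan(genomeSeq(g2), "AATTCCGG", 0,
                              strands = "plus", circular = FALSE)), 0L)
})

test_that("per-region tables, histograms and shared octamers follow set semantics", {
  rs <- RegionSet(
    Biostrings::DNAStringSet(c(
      "CCCCATTGCAAGCCCC",            # one exact match
      "GGGGGGGGGGGGGGGG",            # none
      "ATTGCAAGAAATTGCAAG")),        # two matches of the same text
    S4Vectors::DataFrame(orf_id = c("r1", "r2", "r3"), kind = "upstream",
                         start = 1L, end = 16L, strand = "+", wraps = FALSE,
                         short = FALSE, anchor = "test"))
  prt <- perRegionMatchTable(rs, "ATTGCAAG", 0)
  expect_equal(prt$table$n_matches, c(1L, 0L, 2L))
  expect_equal(prt$histogram[["0"]], 1 / 3)
  expect_equal(prt$histogram[["1"]], 1 / 3)
  # r3's duplicate counts once: ATTGCAAG present in 2 distinct regions
  sh <- sharedOctamers(prt$matchList)
  expect_equal(sh, c(ATTGCAAG = 2L))
  # disjoint matched texts -> empty mapping
  expect_length(sharedOctamers(list(a = "AAAAAAAA", b = "CCCCCCCC")), 0L)
})

test_that("motif presence by class recovers planted proportions exactly", {
  sim <- generateSynthetic(syntheticSpec(
    classQuotas = c("Very High" = 4L, "Very Low" = 6L),
    motifProbs = data.frame(class = c("Very High", "Very Low"),
                            TATA = c(0, 1), CAGT = c(0, 0.5)),
    hrCount = 0L, seed = 31L))
  g <- classifyOrfs(sim$genome)$genome
  pres <- motifPresenceByClass(g)
  vh <- pres[pres$class == "Very High", ]
  vl <- pres[pres$class == "Very Low", ]
  expect_equal(vh$TAAG, 1.0)
  expect_equal(vh$TATA, 0.0)
  expect_equal(vl$TATA, 1.0)
  expect_equal(vl$TAAG, 1.0)
  # planted CAGT proportion matches the manifest, not the nominal rate
  man <- sim$manifest$orfs
  vl_ids <- man$orf_id[man$class == "Very Low"]
  expect_equal(vl$CAGT, mean(grepl("CAGT", man$motifs[man$orf_id %in% vl_ids])))
  # a class with zero ORFs is reported as missing
  expect_true(is.na(pres$TAAG[pres$class == "Medium"]))
})

test_that("octamer spacing follows the gap convention and tiling identity", {
  sim <- generateSynthetic(smallSpec(
    seed = 41L,
    plantedOctamers = data.frame(sequence = "ATTGCAAG", offset = 150L,
                                 n_orfs = 6L)))
  g <- sim$genome
  man <- sim$manifest
  for (id in man$octamers$orf_id) {
    rep <- octamerSpacingReport(g, id, "ATTGCAAG")
    expect_equal(nrow(rep), 1L)
    expect_false(rep$multiple)
    utr_len <- man$orfs$utr_length[man$orfs$orf_id == id]
    # octamer at window offset 150 (3' end at 157) in a 225 nt window:
    # 68 nt strictly between the octamer and the T of TAAG
    expect_equal(rep$taag_gap, 225L - 150L - 8L + 1L)
    expect_equal(rep$atg_gap - rep$taag_gap, 4L + utr_len)
    # 5'-end offset convention differs by the octamer length
    rep5 <- octamerSpacingReport(g, id, "ATTGCAAG", taagFrom = "5p")
    expect_equal(rep5$taag_gap, rep$taag_gap + 8L)
  }
  # absent octamer -> empty report with a reason
  none <- octamerSpacingReport(g, man$orfs$orf_id[!man$orfs$orf_id %in%
                                                    man$octamers$orf_id][1],
                               "ATTGCAAG")
  expect_equal(nrow(none), 0L)
  expect_match(attr(none, "reason"), "no exact match")
})

test_that("expected fuzzy hit probability matches the closed form", {
  expect_equal(expectedHitProbability("ATTGCAAG", 2), 277 / 4^8)
  # an A/T-rich background raises the hit rate of an A/T-rich octamer
  atrich <- c(A = 0.35, C = 0.15, G = 0.15, T = 0.35)
  expect_gt(expectedHitProbability("ATTGCAAG", 2, atrich), 277 / 4^8)
})
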