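test_that("5'UTR runs strictly between TAAG and ATG, both excluded", {
  g <- toyGenome()
  utr <- extract5UTR(g, "g1")
  expect_equal(as.character(regionSequences(utr))[1], "AACCA")
  expect_equal(regionInfo(utr)$start, 25L)
  expect_equal(regionInfo(utr)$end, 29L)
  # minus strand: UTR "TT" by construction
  utr2 <- extract5UTR(g, "g2")
  expect_equal(as.character(regionSequences(utr2))[1], "TT")
})

test_that("TAAG adjacent to ATG yields an empty UTR; TAAG downstream errors", {
  seq <- paste0(strrep("C", 20), "TAAG", "ATGAAATAA", strrep("C", 10))
  si <- GenomeInfoDb::Seqinfo("ADJ", nchar(seq))
  orfs <- GenomicRanges::GRanges("ADJ", IRanges::IRanges(25L, 33L),
                                 strand = "+", orf_id = "adj", name = "adj",
                                 seqinfo = si)
  g <- GenomeRecord("ADJ", seq, orfs = orfs,
                    tss = S4Vectors::DataFrame(orf_id = "adj", taag_pos = 21L,
                                               motifs = "TAAG", source = "f"))
  utr <- extract5UTR(g, "adj")
  expect_equal(nchar(as.character(regionSequences(utr))[1]), 0L)
  # a TAAG claimed downstream of the ATG is an error naming the ORF
  expect_error(extract5UTR(g, "adj", taagPos = 30L), "adj")
})

test_that("upstream windows respect width, strand and the TAAG exclusion", {
  g <- toyGenome()
  # window = 1: the single base immediately 5' of the T of TAAG
  up1 <- extractUpstream(g, "g1", window = 1L)
  expect_equal(as.character(regionSequences(up1))[1], "T")  # spacer1[20]
  up20 <- extractUpstream(g, "g1", window = 20L)
  expect_equal(as.character(regionSequences(up20))[1], "ACGTACGTACGTACGTACGT")
  # linear genome, insufficient room -> truncated and flagged short
  up30 <- extractUpstream(g, "g1", window = 30L)
  expect_true(regionInfo(up30)$short)
  expect_equal(nchar(as.character(regionSequences(up30))[1]), 20L)
})

test_that("upstream windows wrap the origin on circular genomes", {
  g <- toyGenome(circular = TRUE)
  L <- genomeLength(g)
  up30 <- extractUpstream(g, "g1", window = 30L)
  info <- regionInfo(up30)
  expect_true(info$wraps)
  expect_false(info$short)
  seq <- as.character(regionSequences(up30))[1]
  expect_equal(nchar(seq), 30L)
  # tail + head concatenation
  expect_equal(seq, paste0(substr(genomeSeq(g), L - 9L, L),
                           substr(genomeSeq(g), 1L, 20L)))
})

test_that("TIS flank numbering: A of ATG is +1, no position 0", {
  g <- toyGenome()
  fl <- extractTisFlank(g, "g1", up = 3L, down = 3L)
  expect_equal(as.character(regionSequences(fl))[1], "CCAATG")
  # minus-strand ORF: flank equals the computation on the coding block
  fl2 <- extractTisFlank(g, "g2", up = 2L, down = 4L)
  expect_equal(as.character(regionSequences(fl2))[1], "TTATGA")
  # default window is -10..+6
  fl3 <- extractTisFlank(g, "g1")
  expect_equal(nchar(as.character(regionSequences(fl3))[1]), 16L)
})

test_that("TSS flank numbering: first A of TAAG is +1, T is -1", {
  g <- toyGenome()
  fl <- extractTssFlank(g, "g1", up = 2L, down = 3L)
  # positions -2,-1,+1,+2,+3 -> one 5' base then TAAG
  expect_equal(as.character(regionSequences(fl))[1], "TTAAG")
  fl2 <- extractTssFlank(g, "g2", up = 2L, down = 3L)
  expect_equal(as.character(regionSequences(fl2))[1], "ATAAG")  # coding2[9:13]
})

test_that("named promoters extract at table coordinates, strand-resolved", {
  g <- nullGenome(119000L, seed = 3L)
  tab <- data.frame(
    name = c("polh", "p6.9", "dp10"),
    start = c(4428L, 86889L, 118635L),
    end = c(4519L, 87204L, 118808L),
    strand = c("+", "-", "+"))
  rs <- extractNamedPromoters(g, tab)
  expect_equal(nchar(as.character(regionSequences(rs))), c(92L, 316L, 174L))
  # minus-strand promoter is reverse-complemented
  expect_equal(as.character(regionSequences(rs))[2],
               as.character(Biostrings::reverseComplement(Biostrings::DNAString(
                 substr(genomeSeq(g), 86889L, 87204L)))))
  expect_error(extractNamedPromoters(g, data.frame(
    name = "x", start = 118900L, end = 120000L, strand = "+")), "range")
})

test_that("regions re-slice from their recorded interval exactly", {
  sim <- generateSynthetic(smallSpec(seed = 21L))
  g <- sim$genome
  for (kind in c("utr5", "upstream", "tss_flank", "tis_flank")) {
    rs <- suppressWarnings(extractRegionSet(g, kind))
    info <- regionInfo(rs)
    for (i in seq_len(length(rs))) {
      if (info$end[i] < info$start[i]) next   # empty UTR
      expect_equal(
        as.character(regionSequences(rs))[i],
        sliceGenome(g, info$start[i], info$end[i], info$strand[i],
                    info$wraps[i]),
        info = sprintf("%s region %d", kind, i))
    }
  }
})

test_that("upstream, TAAG, 5'UTR and ATG tile contiguously on the coding strand", {
  sim <- generateSynthetic(smallSpec(seed = 22L))
  g <- sim$genome
  man <- sim$manifest$orfs
  for (i in seq_len(5L)) {
    id <- man$orf_id[i]
    up <- as.character(regionSequences(extractUpstream(g, id, window = 50L)))[1]
    utr <- as.character(regionSequences(extract5UTR(g, id)))[1]
    strandi <- man$strand[i]
    cds_start <- if (strandi == "+") man$start[i] else man$end[i]
    atg <- if (strandi == "+") {
      substr(genomeSeq(g), cds_start, cds_start + 2L)
    } else {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(
        substr(genomeSeq(g), cds_start - 2L, cds_start))))
    }
    tiled <- paste0(up, "TAAG", utr, atg)
    # recover the same stretch directly in coding orientation
    whole <- if (strandi == "+") {
      substr(genomeSeq(g), man$taag_pos[i] - 50L, cds_start + 2L)
    } else {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(
        substr(genomeSeq(g), cds_start - 2L, man$taag_pos[i] + 50L))))
    }
    expect_equal(tiled, whole)
    expect_equal(atg, "ATG")
  }
})
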