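test_that("a minimal GenBank fixture parses with correct strands and cds_start", {
  gb <- writeToyGenBank(c(
    "LOCUS       MINI  60 bp    DNA     circular VRL",
    "ACCESSION   MINI1",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    "     CDS             10..21",
    "                     /gene=\"fwd\"",
    "                     /locus_tag=\"orfF\"",
    "     CDS             complement(10..21)",
    "                     /gene=\"rev\"",
    "                     /locus_tag=\"orfR\"",
    "ORIGIN",
    "        1 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt",
    "//"))
  g <- readGenBank(gb)
  expect_s4_class(g, "GenomeRecord")
  expect_true(isCircularGenome(g))
  expect_equal(genomeLength(g), 60L)
  expect_equal(accession(g), "MINI1")
  gr <- orfs(g)
  expect_equal(length(gr), 2L)
  expect_equal(as.character(strand(gr)), c("+", "-"))
  # plus-strand CDS 10..21 starts at 10; minus-strand complement(10..21)
  # has its ATG's A at the numerically larger end
  expect_equal(cdsStart(gr), c(10L, 21L))
  expect_equal(cdsEnd(gr), c(21L, 10L))
})

test_that("origin-spanning join is normalized; other compound locations skip with warning", {
  gb <- writeToyGenBank(c(
    "LOCUS       WRAP  60 bp    DNA     circular VRL",
    "FEATURES             Location/Qualifiers",
    "     CDS             join(55..60,1..9)",
    "                     /locus_tag=\"spanner\"",
    "     CDS             join(5..10,20..25)",
    "                     /locus_tag=\"weird\"",
    "ORIGIN",
    "        1 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt",
    "//"))
  expect_warning(g <- readGenBank(gb), "weird")
  gr <- orfs(g)
  expect_equal(gr$orf_id, "spanner")
  # unrolled past the origin: 55..(9 + 60)
  expect_equal(start(gr), 55L)
  expect_equal(end(gr), 69L)
})

test_that("a missing sequence is a fatal parse error", {
  gb <- writeToyGenBank(c(
    "LOCUS       EMPTY  0 bp    DNA     linear VRL",
    "FEATURES             Location/Qualifiers",
    "//"))
  expect_error(readGenBank(gb), "ORIGIN|sequence")
})

test_that("GenBank write/read round-trips a synthetic genome exactly", {
  sim <- generateSynthetic(smallSpec())
  path <- tempfile(fileext = ".gb")
  writeGenBank(sim$genome, path)
  g2 <- readGenBank(path)
  expect_equal(genomeSeq(g2), genomeSeq(sim$genome))
  expect_true(isCircularGenome(g2))
  gr1 <- orfs(sim$genome); gr2 <- orfs(g2)
  expect_equal(gr2$orf_id, gr1$orf_id)
  expect_equal(start(gr2), start(gr1))
  expect_equal(end(gr2), end(gr1))
  expect_equal(as.character(strand(gr2)), as.character(strand(gr1)))
  expect_equal(hrRegions(g2)$hr_id, hrRegions(sim$genome)$hr_id)
  expect_equal(start(hrRegions(g2)), start(hrRegions(sim$genome)))
})

test_that("annotation tables parse, validate and attach", {
  rp <- tempfile(); ts <- tempfile(); hr <- tempfile()
  writeLines(c("orf_id\trpkm", "vp39\t12345.6", "polh\t99000"), rp)
  expect_equal(readRpkmTable(rp)[["vp39"]], 12345.6)

  writeLines(c("orf_id\trpkm", "vp39\tnot_a_number"), rp)
  expect_error(readRpkmTable(rp), "line")

  # duplicate (orf_id, taag_pos) rows are deduplicated with a warning
  writeLines(c("orf_id\ttaag_pos\tmotifs", "g1\t21\tTAAG", "g1\t21\tTAAG",
               "g2\t73\tTAAG"), ts)
  expect_warning(tss <- readTssTable(ts), "duplicate")
  expect_equal(nrow(tss), 2L)

  # empty TSS table loads cleanly (motif-discovery mode stays possible)
  writeLines("orf_id\ttaag_pos\tmotifs\tsource", ts)
  expect_equal(nrow(readTssTable(ts)), 0L)

  writeLines(c("hr_id\tstart\tend", "hr1\t100\t500"), hr)
  expect_equal(readHrTable(hr)$end, 500L)

  # unknown ids are reported, not silently dropped; hr table wins with warning
  g <- toyGenome()
  expect_warning(attachAnnotations(g, rpkm = c(g1 = 10, ghost = 5)), "ghost")
  sim <- generateSynthetic(smallSpec())
  expect_warning(
    attachAnnotations(sim$genome, hrs = data.frame(hr_id = "hrX", start = 5L,
                                                   end = 50L)),
    "replacing")
})

test_that("regions FASTA round-trips and suffixes duplicate headers", {
  g <- toyGenome()
  r1 <- extractUpstream(g, "g1", window = 15L)
  path <- tempfile(fileext = ".fasta")
  writeRegionsFasta(r1, path)
  back <- Biostrings::readDNAStringSet(path)
  expect_equal(length(back), 1L)
  expect_equal(Biostrings::width(back), 15L)
  expect_equal(as.character(back[[1]]),
               as.character(regionSequences(r1))[1])
  # duplicated region -> suffixed header, both records written
  dup <- RegionSet(c(regionSequences(r1), regionSequences(r1)),
                   rbind(regionInfo(r1), regionInfo(r1)))
  expect_warning(writeRegionsFasta(dup, path), "duplicate")
  expect_equal(length(Biostrings::readDNAStringSet(path)), 2L)
})

test_that("minus-strand extraction is the reverse complement of the plus slice", {
  g <- toyGenome()
  up <- extractUpstream(g, "g2", window = 10L)
  info <- regionInfo(up)
  plus_slice <- substr(genomeSeq(g), info$start, info$end)
  expect_equal(as.character(regionSequences(up))[1],
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(plus_slice))))
  # and it recovers the coding-block prefix by construction
  expect_equal(as.character(regionSequences(up))[1], "GGGTTTCCCA")
})
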