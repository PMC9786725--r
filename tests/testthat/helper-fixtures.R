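# In-code fixtures shared across the suite.

# Hand-built two-ORF genome with fully known coordinates (73 nt total).
# Plus-strand ORF g1:  [1-20 spacer][TAAG 21-24][UTR AACCA 25-29][CDS 30-38]
# Minus-strand ORF g2: coding block GGGTTTCCCA + TAAG + TT + ATGAAATAA (25 nt),
# reverse-complemented on the plus strand at 39-63 (coding position j sits at
# genomic 64 - j: T of TAAG at 53, A of ATG at 47, stop at 39), then a spacer.
toyGenome <- function(circular = FALSE) {
  spacer1 <- "ACGTACGTACGTACGTACGT"            # 20 nt
  coding1 <- paste0(spacer1, "TAAG", "AACCA", "ATGCCCTAA")
  coding2 <- paste0("GGGTTTCCCA", "TAAG", "TT", "ATGAAATAA")
  part2 <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(coding2)))
  seq <- paste0(coding1, part2, "GGCCGGCCGG")
  acc <- "TOY"
  si <- GenomeInfoDb::Seqinfo(acc, nchar(seq), isCircular = circular)
  orfs <- GenomicRanges::GRanges(acc,
    IRanges::IRanges(c(30L, 39L), c(38L, 47L)), strand = c("+", "-"),
    orf_id = c("g1", "g2"), name = c("geneA", "geneB"), seqinfo = si)
  tss <- S4Vectors::DataFrame(
    orf_id = c("g1", "g2"), taag_pos = c(21L, 53L),
    motifs = c("TAAG", "TAAG"), source = "fixture")
  GenomeRecord(acc, seq, circular = circular, orfs = orfs, tss = tss)
}

# small synthetic spec used where the full 149-ORF genome would be overkill
smallSpec <- function(seed = 11L, ...) {
  syntheticSpec(
    classQuotas = c("Very High" = 3L, "High" = 3L, "Medium" = 4L,
                    "Low" = 5L, "Very Low" = 5L),
    hrCount = 2L, ...,
    seed = seed)
}

revCompChr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# naive per-position Hamming scan used as the in-suite brute-force oracle
naiveScan <- function(sequence, query, d) {
  k <- nchar(query)
  n <- nchar(sequence)
  if (n < k) return(integer())
  qs <- strsplit(query, "")[[1]]
  hits <- integer()
  for (p in seq_len(n - k + 1)) {
    w <- strsplit(substr(sequence, p, p + k - 1), "")[[1]]
    if (sum(w != qs) <= d) hits <- c(hits, p)
  }
  hits
}

# write a minimal GenBank fixture and return its path
writeToyGenBank <- function(lines, path = tempfile(fileext = ".gb")) {
  writeLines(lines, path)
  path
}
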