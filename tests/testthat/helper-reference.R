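# A genome built to the published AcMNPV p6.9/vp39 octamer geometry:
# both ORFs on the minus strand with 225 nt upstream windows carrying the
# upstream (ATTGCAAG) and downstream (ATTAGGAA) octamers at offsets chosen
# so that, under the package's documented conventions, the octamer-to-ATG
# gaps are 201/190 (upstream octamer) and 120/137 (downstream octamer) and
# the upstream octamer's 5'-end offset to the TAAG is 143/148 nt — with
# 4 extra upstream-octamer copies and 1 extra downstream-octamer copy
# planted outside the promoter windows, as in the reference genome.
referenceLikeGenome <- function(seed = 91L) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  comp <- c(0.295, 0.205, 0.205, 0.295)
  rnd <- function(n) paste(sample(bases, n, replace = TRUE, prob = comp),
                           collapse = "")
  up_oct <- "ATTGCAAG"; down_oct <- "ATTAGGAA"

  codingBlock <- function(utr_len, up_off, down_off) {
    upstream <- rnd(225)
    substr(upstream, up_off, up_off + 7L) <- up_oct
    substr(upstream, down_off, down_off + 7L) <- down_oct
    cds <- paste0("ATG", rnd(114), "TAA")
    paste0(upstream, "TAAG", rnd(utr_len), cds)
  }
  # vp39: atg_gap 201 -> utr 62 with up_off 83; down_off 164 gives 120
  # p6.9: atg_gap 190 -> utr 46 with up_off 78; down_off 131 gives 137
  blk_vp39 <- codingBlock(62L, 83L, 164L)
  blk_p69 <- codingBlock(46L, 78L, 131L)

  fillerA <- rnd(1500)
  extra <- rnd(800)
  for (p in c(50L, 200L, 420L, 640L)) substr(extra, p, p + 7L) <- up_oct
  substr(extra, 760L, 767L) <- down_oct
  fillerC <- rnd(600)

  seq <- paste0(fillerA, revCompChr(blk_vp39), extra, revCompChr(blk_p69),
                fillerC)
  L <- nchar(seq)
  b2 <- 1501L; len2 <- nchar(blk_vp39)          # vp39 plus-strand placement
  b4 <- b2 + len2 + 800L; len4 <- nchar(blk_p69)

  # genomic coordinates of the planted features (coding pos j at b+len-j)
  feat <- function(b, len, utr_len, up_off, down_off) {
    list(taag = b + len - 226L,
         cds_end_hi = b + len - (229L + utr_len + 1L),  # A of ATG
         planted = c(b + len - (up_off + 7L), b + len - (down_off + 7L)))
  }
  f2 <- feat(b2, len2, 62L, 83L, 164L)
  f4 <- feat(b4, len4, 46L, 78L, 131L)
  extra_pos <- 1500L + len2 + c(50L, 200L, 420L, 640L, 760L)

  # scrub accidental exact copies of either octamer (both strands, seam
  # included) anywhere outside the planted positions
  expected <- sort(c(f2$planted, f4$planted, extra_pos))
  findAll <- function(subject, pat) {
    m <- gregexpr(pat, subject, fixed = TRUE)[[1]]
    if (m[1] == -1L) integer() else as.integer(m)
  }
  for (iter in 1:10) {
    hits <- integer()
    for (q in c(up_oct, down_oct, revCompChr(up_oct), revCompChr(down_oct))) {
      hits <- c(hits, findAll(seq, q))
      seam <- paste0(substr(seq, L - 6L, L), substr(seq, 1L, 7L))
      hits <- c(hits, (L - 6L:0L)[findAll(seam, q)])
    }
    bad <- setdiff(unique(hits), expected)
    bad <- bad[!is.na(bad)]
    if (!length(bad)) break
    protected <- unlist(lapply(expected, function(e) e:(e + 7L)))
    for (p in bad) {
      cand <- setdiff(((p:(p + 7L) - 1L) %% L) + 1L, protected)
      if (!length(cand)) next
      j <- cand[ceiling(length(cand) / 2)]
      cur <- substr(seq, j, j)
      substr(seq, j, j) <- sample(setdiff(bases, cur), 1L)
    }
  }

  acc <- "REFLIKE"
  si <- GenomeInfoDb::Seqinfo(acc, L, isCircular = TRUE)
  orfs <- GenomicRanges::GRanges(acc,
    IRanges::IRanges(c(b2, b4), c(f2$cds_end_hi, f4$cds_end_hi)),
    strand = "-", orf_id = c("vp39", "p6.9"), name = c("vp39", "p6.9"),
    seqinfo = si)
  tss <- S4Vectors::DataFrame(
    orf_id = c("vp39", "p6.9"), taag_pos = c(f2$taag, f4$taag),
    motifs = "TAAG", source = "construction")
  GenomeRecord(acc, seq, circular = TRUE, orfs = orfs, tss = tss)
}
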