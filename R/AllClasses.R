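#' GenomeRecord: an annotated (possibly circular) viral genome
#'
#' Container for one chromosome and its promoter-relevant annotation:
#' the DNA sequence, ORF features as a [GenomicRanges::GRanges] (metadata
#' columns `orf_id`, `name`, `rpkm`, `expr_class`), homologous repeat (hr)
#' blocks as a `GRanges` (metadata column `hr_id`), and transcription start
#' site annotations as a [S4Vectors::DataFrame] with columns `orf_id`,
#' `taag_pos` (1-based genomic coordinate of the T of the TAAG motif on the
#' ORF's coding strand), `motifs` (comma-separated subset of
#' TATA/CAGT/TAAG) and `source`.
#'
#' For a minus-strand ORF the coding start `cdsStart()` is the numerically
#' larger end of the plus-strand interval (the genomic position of the A of
#' the ATG); `cdsEnd()` is the other end.
#'
#' @slot accession genome accession label.
#' @slot sequence the chromosome as a [Biostrings::DNAString].
#' @slot circular logical; circular topology (intervals may wrap the origin).
#' @slot orfs `GRanges` of CDS features.
#' @slot hrs `GRanges` of hr regions.
#' @slot tss `DataFrame` of TSS annotations.
#'
#' @aliases GenomeRecord
#' @export
setClass("GenomeRecord",
  slots = c(
    accession = "character",
    sequence  = "DNAString",
    circular  = "logical",
    orfs      = "GRanges",
    hrs       = "GRanges",
    tss       = "DataFrame"
  )
)

setValidity("GenomeRecord", function(object) {
  msg <- character()
  L <- length(object@sequence)
  if (length(object@accession) != 1L) msg <- c(msg, "accession must be length 1")
  if (length(object@circular) != 1L) msg <- c(msg, "circular must be length 1")
  if (!grepl("^[ACGTNRYSWKMBDHV]*$", as.character(object@sequence)))
    msg <- c(msg, "sequence must be uppercase IUPAC DNA")
  for (nm in c("orf_id", "name")) {
    if (!nm %in% colnames(mcols(object@orfs)))
      msg <- c(msg, sprintf("orfs must carry an '%s' metadata column", nm))
  }
  if (length(object@orfs)) {
    if (anyDuplicated(object@orfs$orf_id))
      msg <- c(msg, "ORF ids must be unique")
    # circular genomes may carry one origin-spanning feature unrolled past L
    max_end <- if (isTRUE(object@circular)) 2L * L else L
    if (any(start(object@orfs) < 1L) || any(end(object@orfs) > max_end) ||
        any(width(object@orfs) > L))
      msg <- c(msg, "ORF intervals must lie within the (possibly unrolled) genome")
    if (any(!as.character(strand(object@orfs)) %in% c("+", "-")))
      msg <- c(msg, "ORF strand must be '+' or '-'")
  }
  if (length(object@hrs)) {
    if (!"hr_id" %in% colnames(mcols(object@hrs)))
      msg <- c(msg, "hrs must carry an 'hr_id' metadata column")
    else if (anyDuplicated(object@hrs$hr_id))
      msg <- c(msg, "hr ids must be unique")
    if (any(start(object@hrs) < 1L) || any(end(object@hrs) > L))
      msg <- c(msg, "hr intervals must lie within [1, genome length]")
  }
  if (nrow(object@tss)) {
    need <- c("orf_id", "taag_pos", "motifs", "source")
    miss <- setdiff(need, colnames(object@tss))
    if (length(miss))
      msg <- c(msg, paste0("tss table missing columns: ", paste(miss, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeRecord
#'
#' @param accession accession label.
#' @param sequence DNA sequence (character or `DNAString`).
#' @param circular logical topology flag.
#' @param orfs `GRanges` with `orf_id`, `name` (and optionally `rpkm`,
#'   `expr_class`) metadata columns, or NULL.
#' @param hrs `GRanges` with an `hr_id` metadata column, or NULL.
#' @param tss `DataFrame`/data.frame of TSS annotations, or NULL.
#' @return a [GenomeRecord-class] object.
#' @export
GenomeRecord <- function(accession, sequence, circular = FALSE,
                         orfs = NULL, hrs = NULL, tss = NULL) {
  sequence <- DNAString(toupper(as.character(sequence)))
  L <- length(sequence)
  si <- Seqinfo(seqnames = accession, seqlengths = L, isCircular = circular)
  emptyGR <- function(cols) {
    gr <- GRanges(seqinfo = si)
    for (nm in names(cols)) mcols(gr)[[nm]] <- cols[[nm]]
    gr
  }
  if (is.null(orfs)) {
    orfs <- emptyGR(list(orf_id = character(), name = character(),
                         rpkm = numeric(), expr_class = character()))
  } else {
    if (!"rpkm" %in% colnames(mcols(orfs))) orfs$rpkm <- NA_real_
    if (!"expr_class" %in% colnames(mcols(orfs))) orfs$expr_class <- NA_character_
  }
  if (is.null(hrs)) hrs <- emptyGR(list(hr_id = character()))
  if (is.null(tss)) {
    tss <- DataFrame(orf_id = character(), taag_pos = integer(),
                     motifs = character(), source = character())
  } else {
    tss <- as(tss, "DataFrame")
  }
  new("GenomeRecord", accession = accession, sequence = sequence,
      circular = circular, orfs = orfs, hrs = hrs, tss = tss)
}

#' @describeIn GenomeRecord genome length in nucleotides.
#' @param x,object a `GenomeRecord`.
#' @export
genomeLength <- function(x) length(x@sequence)

#' @describeIn GenomeRecord the genome sequence as a single character string.
#' @export
genomeSeq <- function(x) as.character(x@sequence)

#' @describeIn GenomeRecord accession label.
#' @export
accession <- function(x) x@accession

#' @describeIn GenomeRecord TRUE for circular topology.
#' @export
isCircularGenome <- function(x) x@circular

#' @describeIn GenomeRecord ORF features (`GRanges`).
#' @export
orfs <- function(x) x@orfs

#' @describeIn GenomeRecord hr regions (`GRanges`).
#' @export
hrRegions <- function(x) x@hrs

#' @describeIn GenomeRecord TSS annotation table (`DataFrame`).
#' @export
tssAnnotations <- function(x) x@tss

#' Strand-aware coding start / end of ORF features
#'
#' `cdsStart()` is the genomic coordinate of the A of the ATG on the coding
#' strand (the larger end of the plus-strand interval for minus-strand
#' ORFs); `cdsEnd()` is the last base of the stop codon.
#'
#' @param gr a `GRanges` of ORF features (or a `GenomeRecord`).
#' @return integer vector of genomic coordinates.
#' @export
cdsStart <- function(gr) {
  if (is(gr, "GenomeRecord")) gr <- orfs(gr)
  ifelse(as.character(strand(gr)) == "+", start(gr), end(gr))
}

#' @rdname cdsStart
#' @export
cdsEnd <- function(gr) {
  if (is(gr, "GenomeRecord")) gr <- orfs(gr)
  ifelse(as.character(strand(gr)) == "+", end(gr), start(gr))
}

setMethod("show", "GenomeRecord", function(object) {
  cat(sprintf("GenomeRecord %s: %d nt, %s\n", object@accession,
              genomeLength(object),
              if (object@circular) "circular" else "linear"))
  cat(sprintf("  %d ORFs (%d with RPKM), %d hr regions, %d TSS annotations\n",
              length(object@orfs), sum(!is.na(object@orfs$rpkm)),
              length(object@hrs), nrow(object@tss)))
})

#' RegionSet: extracted, coding-strand-oriented subsequences
#'
#' A set of regions (5'UTRs, upstream promoter windows, TIS/TSS flanks,
#' named promoters) extracted from a genome. Sequences are always reported
#' in coding-strand orientation; `info` records, per region: `orf_id`,
#' `kind` (one of `utr5`, `upstream`, `tis_flank`, `tss_flank`,
#' `named_promoter`), the 1-based closed plus-strand genomic interval
#' (`start`, `end`, `wraps`), `strand`, `short` (TRUE when a linear genome
#' truncated the window) and `anchor` (a description of the +1 convention).
#'
#' @slot sequences a [Biostrings::DNAStringSet].
#' @slot info a [S4Vectors::DataFrame], one row per sequence.
#' @aliases RegionSet
#' @export
setClass("RegionSet",
  slots = c(sequences = "DNAStringSet", info = "DataFrame"))

setValidity("RegionSet", function(object) {
  msg <- character()
  if (length(object@sequences) != nrow(object@info))
    msg <- c(msg, "sequences and info must have matching length")
  need <- c("orf_id", "kind", "start", "end", "strand", "wraps", "short", "anchor")
  miss <- setdiff(need, colnames(object@info))
  if (length(miss))
    msg <- c(msg, paste0("info missing columns: ", paste(miss, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

RegionSet <- function(sequences, info) {
  names(sequences) <- NULL
  new("RegionSet", sequences = DNAStringSet(sequences), info = as(info, "DataFrame"))
}

#' @describeIn RegionSet the region sequences (`DNAStringSet`).
#' @param x,object a `RegionSet`.
#' @export
regionSequences <- function(x) x@sequences

#' @describeIn RegionSet the per-region metadata (`DataFrame`).
#' @export
regionInfo <- function(x) x@info

setMethod("show", "RegionSet", function(object) {
  kinds <- table(object@info$kind)
  cat(sprintf("RegionSet: %d regions (%s)\n", length(object@sequences),
              paste(sprintf("%s: %d", names(kinds), kinds), collapse = ", ")))
})

setMethod("length", "RegionSet", function(x) length(x@sequences))

setMethod("[", "RegionSet", function(x, i, j, ..., drop = TRUE) {
  RegionSet(x@sequences[i], x@info[i, , drop = FALSE])
})

#' ScanSummary: genome-wide motif scan result
#'
#' @slot query the query sequence.
#' @slot maxMismatches mismatch tolerance used.
#' @slot matches `DataFrame` of matches (`position`, `strand`, `mismatches`,
#'   `matched_text`), positions are 1-based plus-strand window starts.
#' @slot totalMatches,plusCount,minusCount match counts.
#' @slot ratePerKbp matches per 1000 nt of genome, both strands pooled.
#' @slot genomeLength length of the scanned genome.
#' @aliases ScanSummary
#' @export
setClass("ScanSummary",
  slots = c(query = "character", maxMismatches = "integer",
            matches = "DataFrame", totalMatches = "integer",
            plusCount = "integer", minusCount = "integer",
            ratePerKbp = "numeric", genomeLength = "integer"))

setValidity("ScanSummary", function(object) {
  if (object@totalMatches != object@plusCount + object@minusCount)
    return("totalMatches must equal plusCount + minusCount")
  TRUE
})

setMethod("show", "ScanSummary", function(object) {
  cat(sprintf("ScanSummary: %s (<=%d mm) on %d nt genome\n",
              object@query, object@maxMismatches, object@genomeLength))
  cat(sprintf("  %d matches (+: %d, -: %d), %.2f per kbp\n",
              object@totalMatches, object@plusCount, object@minusCount,
              object@ratePerKbp))
})

#' @describeIn ScanSummary the match table.
#' @param x,object a `ScanSummary`.
#' @export
scanMatches <- function(x) x@matches

#' @describeIn ScanSummary total match count.
#' @export
totalMatches <- function(x) x@totalMatches

#' @describeIn ScanSummary matches per kbp of genome (both strands pooled).
#' @export
ratePerKbp <- function(x) x@ratePerKbp

#' ConsensusResult: anchored per-class consensus
#'
#' Column-wise base frequencies, IUPAC consensus string and conservation
#' flags for a gap-free stack of anchor-aligned windows (see
#' [consensusFromStack()]). Positions follow the -/+ numbering of the
#' anchor (no position 0).
#'
#' @slot label class label of the stack.
#' @slot anchor `"tis"` or `"tss"`.
#' @slot positions integer position labels.
#' @slot frequencies 4 x width matrix of base fractions (rows A,C,G,T).
#' @slot consensus IUPAC consensus string.
#' @slot flags per-position conservation flags
#'   (`none`/`conserved`/`highly_conserved`).
#' @slot nSequences number of rows in the stack.
#' @aliases ConsensusResult
#' @export
setClass("ConsensusResult",
  slots = c(label = "character", anchor = "character",
            positions = "integer", frequencies = "matrix",
            consensus = "character", flags = "character",
            nSequences = "integer"))

setValidity("ConsensusResult", function(object) {
  msg <- character()
  if (nchar(object@consensus) != ncol(object@frequencies))
    msg <- c(msg, "consensus length must equal frequency matrix width")
  if (ncol(object@frequencies) &&
      any(abs(colSums(object@frequencies) - 1) > 1e-9))
    msg <- c(msg, "column frequencies must sum to 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ConsensusResult", function(object) {
  cat(sprintf("ConsensusResult [%s, anchor=%s, n=%d]\n", object@label,
              object@anchor, object@nSequences))
  cat("  ", object@consensus, "\n", sep = "")
  n_hi <- sum(object@flags == "highly_conserved")
  cat(sprintf("  %d/%d positions highly conserved\n", n_hi,
              length(object@flags)))
})

#' @describeIn ConsensusResult the IUPAC consensus string.
#' @param x,object a `ConsensusResult`.
#' @export
consensusSeq <- function(x) x@consensus

#' @describeIn ConsensusResult the per-column base-frequency matrix.
#' @export
consensusFrequencies <- function(x) x@frequencies

#' @describeIn ConsensusResult per-position conservation flags.
#' @export
conservedFlags <- function(x) x@flags
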