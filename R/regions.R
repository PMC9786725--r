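# Extraction of promoter-associated regions, coding-strand oriented.
#
# Anchor conventions (no position 0 anywhere):
#   * TIS flank:  the A of the ATG start codon is +1.
#   * TSS flank:  the first A of the TAAG motif is +1, the T of TAAG is -1.
#   * 5'UTR:      the bases strictly between the last G of TAAG and the A
#                 of ATG, both excluded (length may be 0).
#   * upstream:   the `window` bases immediately 5' of the T of TAAG,
#                 TAAG excluded.
# On circular genomes intervals may wrap the origin; on linear genomes an
# upstream window is truncated (flagged `short`), while flank windows that
# leave the sequence are an error.

# interval in plus-strand coordinates, possibly out of [1, L]; normalizes
# wrap and truncation and returns one region row + sequence
makeRegion <- function(genome, s, e, strand, kind, orf_id, anchor,
                       clip = c("error", "truncate")) {
  clip <- match.arg(clip)
  L <- genomeLength(genome)
  short <- FALSE
  if (e < s) {                                   # empty region (0-length UTR)
    s0 <- if (isCircularGenome(genome)) wrapPos(s, L) else s
    return(list(seq = "", orf_id = orf_id, kind = kind, start = s0,
                end = s0 - 1L, strand = strand, wraps = FALSE, short = FALSE,
                anchor = anchor))
  }
  if (e - s + 1L > L)
    stop(sprintf("region of ORF %s longer than the genome", orf_id))
  if (isCircularGenome(genome)) {
    s2 <- wrapPos(s, L); e2 <- wrapPos(e, L)
    wraps <- s2 > e2
  } else {
    if (s < 1L || e > L) {
      if (clip == "error")
        stop(sprintf("window of ORF %s exceeds the linear genome [%d, %d]",
                     orf_id, s, e))
      short <- TRUE
      s <- max(s, 1L); e <- min(e, L)
    }
    s2 <- s; e2 <- e; wraps <- FALSE
  }
  seq <- plusSlice(genomeSeq(genome), s2, e2, wraps)
  if (strand == "-") seq <- revComp(seq)
  list(seq = seq, orf_id = orf_id, kind = kind, start = s2, end = e2,
       strand = strand, wraps = wraps, short = short, anchor = anchor)
}

regionSetFromRows <- function(rows) {
  if (!length(rows)) {
    return(RegionSet(DNAStringSet(),
                     DataFrame(orf_id = character(), kind = character(),
                               start = integer(), end = integer(),
                               strand = character(), wraps = logical(),
                               short = logical(), anchor = character())))
  }
  info <- DataFrame(
    orf_id = vapply(rows, `[[`, "", "orf_id"),
    kind   = vapply(rows, `[[`, "", "kind"),
    start  = vapply(rows, function(r) as.integer(r$start), 1L),
    end    = vapply(rows, function(r) as.integer(r$end), 1L),
    strand = vapply(rows, `[[`, "", "strand"),
    wraps  = vapply(rows, `[[`, TRUE, "wraps"),
    short  = vapply(rows, `[[`, TRUE, "short"),
    anchor = vapply(rows, `[[`, "", "anchor"))
  RegionSet(DNAStringSet(vapply(rows, `[[`, "", "seq")), info)
}

orfById <- function(genome, orfId) {
  gr <- orfs(genome)
  i <- match(orfId, gr$orf_id)
  if (is.na(i)) stop("unknown ORF id: ", orfId)
  gr[i]
}

#' TSS annotations for an ORF, nearest the ATG first
#'
#' The 5'-of-ATG distance of a TAAG TSS is the coding-strand gap between
#' the motif and the start codon; when an ORF carries several annotated
#' TSSs the one nearest the initiation codon is used by default for
#' extraction and consensus building.
#'
#' @param genome a [GenomeRecord-class].
#' @param orfId an ORF id.
#' @return a `DataFrame` of the ORF's TSS rows sorted by distance to the
#'   ATG (nearest first); zero rows when the ORF has no annotation.
#' @export
tssForOrf <- function(genome, orfId) {
  tss <- tssAnnotations(genome)
  rows <- tss[tss$orf_id == orfId, , drop = FALSE]
  if (!nrow(rows)) return(rows)
  orf <- orfById(genome, orfId)
  a <- cdsStart(orf)
  d <- if (as.character(strand(orf)) == "+") a - rows$taag_pos
       else rows$taag_pos - a
  rows[order(d), , drop = FALSE]
}

# resolve (orfId, taagPos): explicit position, or nearest annotated TSS
resolveTss <- function(genome, orfId, taagPos) {
  if (!is.null(taagPos)) return(as.integer(taagPos))
  rows <- tssForOrf(genome, orfId)
  if (!nrow(rows)) return(NA_integer_)
  rows$taag_pos[1]
}

#' Extract the 5'UTR of an ORF
#'
#' The 5'UTR is the coding-strand sequence strictly between the last G of
#' the TAAG motif and the A of the ATG start codon, both excluded; its
#' length may be zero (TAAG immediately adjacent to ATG). A TAAG
#' positioned downstream of the ATG is an error naming the ORF.
#'
#' @param genome a [GenomeRecord-class].
#' @param orfId an ORF id.
#' @param taagPos genomic coordinate of the T of the TAAG on the coding
#'   strand; default: the ORF's annotated TSS nearest the ATG.
#' @return a [RegionSet-class] of length 1.
#' @export
extract5UTR <- function(genome, orfId, taagPos = NULL) {
  orf <- orfById(genome, orfId)
  t <- resolveTss(genome, orfId, taagPos)
  if (is.na(t)) stop("ORF ", orfId, " has no TSS annotation")
  a <- cdsStart(orf)
  st <- as.character(strand(orf))
  gap <- if (st == "+") a - t - 4L else t - a - 4L
  if (gap < 0L)
    stop("TAAG motif of ORF ", orfId, " lies downstream of its ATG")
  anchor <- "between last G of TAAG (excl) and A of ATG (excl)"
  row <- if (st == "+") {
    makeRegion(genome, t + 4L, a - 1L, "+", "utr5", orfId, anchor)
  } else {
    makeRegion(genome, a + 1L, t - 4L, "-", "utr5", orfId, anchor)
  }
  regionSetFromRows(list(row))
}

#' Extract the fixed-length upstream promoter window of a TSS
#'
#' The `window` nucleotides immediately 5' of the T of the TAAG motif on
#' the coding strand, TAAG excluded. Wraps the origin on circular
#' genomes; on a linear genome an out-of-range window is truncated and
#' flagged `short`.
#'
#' @inheritParams extract5UTR
#' @param window window width in nucleotides (default 225).
#' @return a [RegionSet-class] of length 1.
#' @export
extractUpstream <- function(genome, orfId, taagPos = NULL, window = 225L) {
  stopifnot(window >= 1L)
  orf <- orfById(genome, orfId)
  t <- resolveTss(genome, orfId, taagPos)
  if (is.na(t)) stop("ORF ", orfId, " has no TSS annotation")
  st <- as.character(strand(orf))
  anchor <- sprintf("%d nt immediately 5' of the T of TAAG", window)
  row <- if (st == "+") {
    makeRegion(genome, t - window, t - 1L, "+", "upstream", orfId, anchor,
               clip = "truncate")
  } else {
    makeRegion(genome, t + 1L, t + window, "-", "upstream", orfId, anchor,
               clip = "truncate")
  }
  regionSetFromRows(list(row))
}

#' Extract the translation-initiation-site flank of an ORF
#'
#' Positions `-up..+down` with the A of the ATG as +1 and no position 0,
#' so the window covers `up + down` nucleotides and the ATG occupies
#' positions +1..+3. Defaults `up = 10`, `down = 6`.
#'
#' @inheritParams extract5UTR
#' @param up,down nucleotides upstream / downstream of the anchor.
#' @return a [RegionSet-class] of length 1.
#' @export
extractTisFlank <- function(genome, orfId, up = 10L, down = 6L) {
  stopifnot(up >= 1L, down >= 1L)
  orf <- orfById(genome, orfId)
  a <- cdsStart(orf)
  st <- as.character(strand(orf))
  anchor <- "A of ATG = +1, no position 0"
  row <- if (st == "+") {
    makeRegion(genome, a - up, a + down - 1L, "+", "tis_flank", orfId, anchor)
  } else {
    makeRegion(genome, a - down + 1L, a + up, "-", "tis_flank", orfId, anchor)
  }
  regionSetFromRows(list(row))
}

#' Extract the transcription-start-site flank of a TSS
#'
#' Positions `-up..+down` with the first A of the TAAG motif as +1, the T
#' of TAAG as -1 and no position 0, so TAAG occupies positions
#' -1, +1, +2, +3. Defaults `up = 15`, `down = 15`.
#'
#' @inheritParams extractTisFlank
#' @param taagPos genomic coordinate of the T of the TAAG on the coding
#'   strand; default: the ORF's annotated TSS nearest the ATG.
#' @return a [RegionSet-class] of length 1.
#' @export
extractTssFlank <- function(genome, orfId, taagPos = NULL,
                            up = 15L, down = 15L) {
  stopifnot(up >= 1L, down >= 1L)
  orf <- orfById(genome, orfId)
  t <- resolveTss(genome, orfId, taagPos)
  if (is.na(t)) stop("ORF ", orfId, " has no TSS annotation")
  st <- as.character(strand(orf))
  anchor <- "first A of TAAG = +1, T of TAAG = -1, no position 0"
  row <- if (st == "+") {
    makeRegion(genome, t - up + 1L, t + down, "+", "tss_flank", orfId, anchor)
  } else {
    makeRegion(genome, t - down, t + up - 1L, "-", "tss_flank", orfId, anchor)
  }
  regionSetFromRows(list(row))
}

#' Extract a batch of regions for many ORFs
#'
#' Applies one of the single-region extractors to every requested ORF
#' (default: all ORFs with a TSS annotation for TSS-anchored kinds; all
#' ORFs for `tis_flank`). ORFs lacking a needed TSS are skipped with one
#' summary warning. Multiple TSSs per ORF follow the nearest-ATG rule.
#'
#' @param genome a [GenomeRecord-class].
#' @param kind one of `"utr5"`, `"upstream"`, `"tis_flank"`, `"tss_flank"`.
#' @param orfIds ORF ids (default all).
#' @param window upstream window width (for `kind = "upstream"`).
#' @param up,down flank widths (for the flank kinds).
#' @return a [RegionSet-class].
#' @export
extractRegionSet <- function(genome,
                             kind = c("utr5", "upstream", "tis_flank", "tss_flank"),
                             orfIds = NULL, window = 225L,
                             up = NULL, down = NULL) {
  kind <- match.arg(kind)
  if (is.null(orfIds)) orfIds <- orfs(genome)$orf_id
  needTss <- kind != "tis_flank"
  skipped <- character()
  out <- list()
  for (id in orfIds) {
    if (needTss && !nrow(tssForOrf(genome, id))) {
      skipped <- c(skipped, id)
      next
    }
    rs <- switch(kind,
      utr5      = extract5UTR(genome, id),
      upstream  = extractUpstream(genome, id, window = window),
      tis_flank = extractTisFlank(genome, id, up = up %||% 10L,
                                  down = down %||% 6L),
      tss_flank = extractTssFlank(genome, id, up = up %||% 15L,
                                  down = down %||% 15L))
    out[[length(out) + 1L]] <- rs
  }
  if (length(skipped))
    warning(length(skipped), " ORF(s) without TSS annotation skipped: ",
            paste(head(skipped, 10L), collapse = ", "),
            if (length(skipped) > 10L) ", ...")
  if (!length(out)) return(regionSetFromRows(list()))
  RegionSet(do.call(c, lapply(out, regionSequences)),
            do.call(rbind, lapply(out, regionInfo)))
}

#' Extract named promoter regions from a coordinate table
#'
#' The table gives one promoter per row (`name`, `start`, `end`,
#' `strand`), coordinates 1-based and closed on the plus strand;
#' minus-strand promoters are reverse-complemented so every sequence is
#' coding-strand oriented.
#'
#' @param genome a [GenomeRecord-class].
#' @param table a data.frame with columns `name`, `start`, `end`, `strand`.
#' @return a [RegionSet-class], lengths `end - start + 1`.
#' @export
extractNamedPromoters <- function(genome, table) {
  stopifnot(all(c("name", "start", "end", "strand") %in% names(table)))
  L <- genomeLength(genome)
  rows <- lapply(seq_len(nrow(table)), function(i) {
    s <- as.integer(table$start[i]); e <- as.integer(table$end[i])
    if (s < 1L || e > L || s > e)
      stop(sprintf("promoter %s: coordinates %d..%d out of range",
                   table$name[i], s, e))
    makeRegion(genome, s, e, as.character(table$strand[i]),
               "named_promoter", table$name[i],
               "plus-strand closed interval from coordinate table")
  })
  regionSetFromRows(rows)
}
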