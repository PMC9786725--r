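# Anchored per-class consensus sequences.
#
# Because TIS- and TSS-flank windows have a fixed width and a fixed anchor
# (+1 at the A of ATG, or at the first A of TAAG), stacking them
# positionally is an exact, gap-free multiple alignment: equal-length
# anchored windows admit no meaningful gaps, so no gapped MSA is run and
# the construction is deterministic.

#' Stack anchor-aligned regions into a position matrix
#'
#' @param regions a [RegionSet-class] of one kind (`tis_flank` or
#'   `tss_flank`) and one width; a width mismatch is an error naming the
#'   offending ORFs.
#' @return a character matrix, rows = regions (named by `orf_id`),
#'   columns = positions.
#' @export
stackRegions <- function(regions) {
  if (!length(regions)) stop("no regions to stack")
  info <- regionInfo(regions)
  if (length(unique(info$kind)) != 1L)
    stop("regions of mixed kind cannot be stacked")
  seqs <- as.character(regionSequences(regions))
  w <- nchar(seqs)
  if (length(unique(w)) != 1L)
    stop("width mismatch in stack: ",
         paste(info$orf_id[w != stats::median(w)], collapse = ", "))
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- info$orf_id
  m
}

# -up..+down labels with no position 0
flankPositions <- function(width, up) {
  p <- seq_len(width) - up
  ifelse(p <= 0L, p - 1L, p)
}

#' IUPAC consensus of a positional stack
#'
#' Per column: if the top base's fraction reaches `plurality` (default
#' 0.5) that base is emitted (ties between top bases are broken by the
#' minimal IUPAC degenerate code covering them, never arbitrarily);
#' otherwise the minimal IUPAC code covering all bases with fraction at
#' least `secondary` (default 0.25), or `N` if none qualifies. A position
#' is flagged `conserved` when the top fraction reaches
#' `conservedThreshold` (default 0.5) and `highly_conserved` at
#' `highThreshold` (default 0.8).
#'
#' @param stack a character matrix from [stackRegions()] (>= 2 rows).
#' @param label class label to record.
#' @param anchor `"tis"` or `"tss"`.
#' @param up the `up` width used for extraction (fixes the -/+ position
#'   numbering; positions run `-up..-1, +1..+down` with no 0).
#' @param plurality,secondary,conservedThreshold,highThreshold thresholds,
#'   as fractions.
#' @param degenerate emit degenerate codes below plurality? With
#'   `FALSE`, sub-plurality columns become `N`.
#' @return a [ConsensusResult-class].
#' @export
consensusFromStack <- function(stack, label = "all", anchor = c("tis", "tss"),
                               up = NULL, plurality = 0.5, secondary = 0.25,
                               conservedThreshold = 0.5, highThreshold = 0.8,
                               degenerate = TRUE) {
  anchor <- match.arg(anchor)
  if (is.null(dim(stack)) || nrow(stack) < 2L)
    stop("consensus needs a stack of at least 2 sequences")
  bases <- c("A", "C", "G", "T")
  w <- ncol(stack)
  freq <- vapply(seq_len(w), function(j) {
    tab <- table(factor(stack[, j], levels = bases))
    as.numeric(tab) / nrow(stack)
  }, numeric(4))
  rownames(freq) <- bases

  cons <- character(w)
  flags <- character(w)
  for (j in seq_len(w)) {
    f <- freq[, j]
    top <- max(f)
    top_bases <- bases[f == top]
    if (top >= plurality) {
      cons[j] <- if (length(top_bases) == 1L) top_bases else
        iupacCode(top_bases)        # tie at the top -> degenerate code
    } else if (degenerate) {
      covered <- bases[f >= secondary]
      cons[j] <- if (length(covered)) iupacCode(covered) else "N"
    } else {
      cons[j] <- "N"
    }
    flags[j] <- if (top >= highThreshold) "highly_conserved"
                else if (top >= conservedThreshold) "conserved" else "none"
  }
  positions <- if (is.null(up)) seq_len(w) else flankPositions(w, up)
  new("ConsensusResult", label = label, anchor = anchor,
      positions = as.integer(positions), frequencies = freq,
      consensus = paste(cons, collapse = ""), flags = flags,
      nSequences = nrow(stack))
}

#' Per-class anchored consensus sequences
#'
#' Extracts the TIS- or TSS-flank window of every classified ORF (one TSS
#' per ORF, nearest the ATG), stacks them per expression class and
#' computes each class's consensus. Classes with fewer than 2 usable ORFs
#' are skipped.
#'
#' @param genome a classified [GenomeRecord-class].
#' @param anchor `"tis"` or `"tss"`.
#' @param up,down flank widths (defaults: 10/6 for TIS, 15/15 for TSS).
#' @param classes class labels to include (default: all in the scheme,
#'   plus any label already present on the ORFs, e.g. "Curated").
#' @param scheme the class scheme.
#' @param ... thresholds passed to [consensusFromStack()].
#' @return a named list of [ConsensusResult-class], one per class.
#' @export
classConsensus <- function(genome, anchor = c("tis", "tss"),
                           up = NULL, down = NULL, classes = NULL,
                           scheme = defaultClassScheme(), ...) {
  anchor <- match.arg(anchor)
  if (is.null(up)) up <- if (anchor == "tis") 10L else 15L
  if (is.null(down)) down <- if (anchor == "tis") 6L else 15L
  gr <- orfs(genome)
  if (is.null(classes))
    classes <- intersect(c(scheme$label, "Curated"), unique(gr$expr_class))
  kind <- if (anchor == "tis") "tis_flank" else "tss_flank"
  out <- list()
  for (cl in classes) {
    ids <- gr$orf_id[!is.na(gr$expr_class) & gr$expr_class == cl]
    if (anchor == "tss")
      ids <- ids[vapply(ids, function(id) nrow(tssForOrf(genome, id)) > 0L, TRUE)]
    if (length(ids) < 2L) next
    regions <- suppressWarnings(
      extractRegionSet(genome, kind, orfIds = ids, up = up, down = down))
    if (length(regions) < 2L) next
    out[[cl]] <- consensusFromStack(stackRegions(regions), label = cl,
                                    anchor = anchor, up = up, ...)
  }
  out
}

#' Curated high-abundance ORF set for consensus building
#'
#' The most abundantly transcribed ORFs (Very High and High classes)
#' minus named exclusions — typically the two hyperexpressed very-late
#' genes (polh, p10), whose TSS context is atypical. The returned ids can
#' be relabelled "Curated" for a dedicated consensus track.
#'
#' @param genome a classified [GenomeRecord-class].
#' @param exclusions ORF names or ids to drop (unknown names warn).
#' @param classes class labels forming the base set.
#' @return character vector of ORF ids.
#' @export
curatedClass <- function(genome, exclusions = c("polh", "p10"),
                         classes = c("Very High", "High")) {
  gr <- orfs(genome)
  ids <- gr$orf_id[!is.na(gr$expr_class) & gr$expr_class %in% classes]
  known <- exclusions %in% gr$orf_id | exclusions %in% gr$name
  if (any(!known))
    warning("unknown exclusion name(s): ",
            paste(exclusions[!known], collapse = ", "))
  drop_ids <- gr$orf_id[gr$orf_id %in% exclusions | gr$name %in% exclusions]
  out <- setdiff(ids, drop_ids)
  if (!length(out)) stop("curated class is empty after exclusions")
  out
}
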