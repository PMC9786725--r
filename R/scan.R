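# Exact and Hamming-tolerant motif scanning.
#
# The scanner counts, at every start position, the number of substitutions
# between the query and the window (no indels). Overlapping matches are all
# counted; both-strand scans are two independent strand scans (a position
# can count twice when both strands match). On circular genomes a genome
# scan also includes windows spanning the origin.

# per-position mismatch counts of `query` along `subject`
# IUPAC letters in the query match their base set (a degenerate position
# never counts as a mismatch for a covered base)
mismatchCounts <- function(subject, query) {
  n <- nchar(subject)
  k <- nchar(query)
  if (n < k) return(integer(0))
  s <- strsplit(toupper(subject), "")[[1]]
  q <- strsplit(toupper(query), "")[[1]]
  npos <- n - k + 1L
  mm <- integer(npos)
  for (j in seq_len(k)) {
    allowed <- IUPAC_SETS[[q[j]]]
    if (is.null(allowed)) stop("invalid query letter: ", q[j])
    mm <- mm + !(s[j:(j + npos - 1L)] %in% allowed)
  }
  mm
}

validateQuery <- function(query, maxMismatches) {
  query <- toupper(query)
  if (!isIupacDNA(query)) stop("query must be IUPAC DNA: ", query)
  if (maxMismatches < 0L) stop("maxMismatches must be >= 0")
  if (maxMismatches >= nchar(query))
    stop("maxMismatches must be smaller than the query length")
  if (maxMismatches > 0L && !isConcreteDNA(query))
    stop("degenerate query letters are not allowed with maxMismatches > 0 ",
         "(mismatch counting would be ambiguous)")
  query
}

#' Scan a sequence for a motif within a Hamming-distance tolerance
#'
#' Reports every start position whose window is within `maxMismatches`
#' substitutions of the query. Overlapping matches are all counted. A
#' minus-strand search scans the reverse complement of the query along the
#' plus strand and reports plus-strand start coordinates; `matched_text`
#' is always given in the query's (coding) orientation. With
#' `circular = TRUE` windows spanning the origin are included, and start
#' positions stay in `[1, L]`.
#'
#' IUPAC degenerate letters are permitted in the query only at
#' `maxMismatches = 0`.
#'
#' @param sequence a DNA character string (or `DNAString`).
#' @param query the query motif.
#' @param maxMismatches Hamming tolerance (default 0).
#' @param strands `"plus"`, `"minus"` or `"both"`.
#' @param circular include origin-spanning windows?
#' @return a data.frame with columns `position` (1-based plus-strand start),
#'   `strand`, `mismatches`, `matched_text`; zero rows when the sequence is
#'   shorter than the query.
#' @export
fuzzyScan <- function(sequence, query, maxMismatches = 0L,
                      strands = c("plus", "minus", "both"),
                      circular = FALSE) {
  strands <- match.arg(strands)
  query <- validateQuery(query, maxMismatches)
  sequence <- toupper(as.character(sequence))
  k <- nchar(query)
  if (nchar(sequence) < k) {
    return(data.frame(position = integer(), strand = character(),
                      mismatches = integer(), matched_text = character(),
                      stringsAsFactors = FALSE))
  }
  subject <- if (circular && nchar(sequence) >= k) {
    paste0(sequence, substr(sequence, 1L, k - 1L))
  } else sequence
  npos <- if (circular) nchar(sequence) else nchar(sequence) - k + 1L

  scanOne <- function(q, strand_label) {
    mm <- mismatchCounts(subject, q)
    if (length(mm) > npos) mm <- mm[seq_len(npos)]
    hit <- which(mm <= maxMismatches)
    if (!length(hit)) {
      return(data.frame(position = integer(), strand = character(),
                        mismatches = integer(), matched_text = character(),
                        stringsAsFactors = FALSE))
    }
    txt <- substring(subject, hit, hit + k - 1L)
    if (strand_label == "-") txt <- vapply(txt, revComp, "", USE.NAMES = FALSE)
    data.frame(position = hit, strand = strand_label, mismatches = mm[hit],
               matched_text = txt, stringsAsFactors = FALSE)
  }

  out <- list()
  if (strands %in% c("plus", "both")) out$p <- scanOne(query, "+")
  if (strands %in% c("minus", "both")) out$m <- scanOne(revComp(query), "-")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$position, res$strand), , drop = FALSE]
}

#' Genome-wide motif scan with background rate
#'
#' Scans both strands of a genome (origin-spanning windows included on
#' circular genomes) and reports the totals plus the background rate in
#' matches per 1000 nt of genome, both strands pooled:
#' `rate = 1000 * total / genome length`.
#'
#' @param genome a [GenomeRecord-class].
#' @param query the query motif.
#' @param maxMismatches Hamming tolerance.
#' @param strands `"plus"`, `"minus"` or `"both"` (default both).
#' @param circular include origin-spanning windows? Defaults to the
#'   genome's topology.
#' @return a [ScanSummary-class].
#' @export
genomeScan <- function(genome, query, maxMismatches = 0L, strands = "both",
                       circular = isCircularGenome(genome)) {
  m <- fuzzyScan(genomeSeq(genome), query, maxMismatches, strands,
                 circular = circular)
  L <- genomeLength(genome)
  plus <- sum(m$strand == "+")
  minus <- sum(m$strand == "-")
  new("ScanSummary", query = toupper(query),
      maxMismatches = as.integer(maxMismatches),
      matches = as(m, "DataFrame"), totalMatches = plus + minus,
      plusCount = plus, minusCount = minus,
      ratePerKbp = 1000 * (plus + minus) / L, genomeLength = as.integer(L))
}

#' Per-region match table and match-count histogram
#'
#' Scans each extracted region (coding orientation, linear) and tabulates
#' the number of matches per region, together with the fraction of regions
#' carrying 0, 1, 2, ... matches.
#'
#' @param regions a [RegionSet-class].
#' @param query the query motif.
#' @param maxMismatches Hamming tolerance.
#' @return a list with `table` (data.frame `region`, `n_matches`),
#'   `histogram` (named fractions of regions by match count),
#'   `totalMatches`, and `matchList` (per-region matched texts, for
#'   [sharedOctamers()]).
#' @export
perRegionMatchTable <- function(regions, query, maxMismatches = 0L) {
  if (!length(regions)) {
    return(list(table = data.frame(region = character(), n_matches = integer(),
                                   stringsAsFactors = FALSE),
                histogram = numeric(), totalMatches = 0L,
                matchList = list()))
  }
  ids <- regionInfo(regions)$orf_id
  seqs <- as.character(regionSequences(regions))
  matchList <- lapply(seqs, function(s) {
    fuzzyScan(s, query, maxMismatches, strands = "plus")$matched_text
  })
  names(matchList) <- ids
  n <- vapply(matchList, length, 1L)
  hist <- table(n) / length(n)
  list(table = data.frame(region = ids, n_matches = unname(n),
                          stringsAsFactors = FALSE),
       histogram = setNames(as.numeric(hist), names(hist)),
       totalMatches = sum(n),
       matchList = matchList)
}

#' Octamer sequences shared between regions
#'
#' Counts, for every matched text, the number of distinct regions that
#' contain it (duplicate matches within one region count that region
#' once), and returns only those present in at least two regions, in
#' lexicographic order.
#'
#' @param matchList per-region matched texts, as returned by
#'   [perRegionMatchTable()] (element `matchList`).
#' @return a named integer vector: matched text -> number of regions.
#' @export
sharedOctamers <- function(matchList) {
  per_region <- lapply(matchList, unique)
  tab <- table(unlist(per_region))
  tab <- tab[tab >= 2L]
  if (!length(tab)) return(setNames(integer(), character()))
  tab <- tab[order(names(tab))]
  setNames(as.integer(tab), names(tab))
}

#' Promoter-motif presence by expression class
#'
#' For each expression class, the proportion of ORFs whose TSS annotations
#' carry each promoter motif (TATA and CAGT mark host RNA polymerase II
#' promoters; TAAG marks the viral late-gene promoter). An ORF with any
#' TSS carrying a motif counts once; the denominator is the number of
#' classified ORFs in the class. A class with zero ORFs is reported as
#' `NA`.
#'
#' @param genome a classified [GenomeRecord-class] (see [classifyOrfs()])
#'   with TSS annotations.
#' @param scheme the class scheme used.
#' @param motifs motif labels to tabulate.
#' @return a data.frame: one row per class, columns `class`, `n_orfs` and
#'   one proportion column per motif.
#' @export
motifPresenceByClass <- function(genome, scheme = defaultClassScheme(),
                                 motifs = c("TATA", "CAGT", "TAAG")) {
  gr <- orfs(genome)
  tss <- tssAnnotations(genome)
  per_orf <- lapply(setNames(gr$orf_id, gr$orf_id), function(id) {
    rows <- tss[tss$orf_id == id, , drop = FALSE]
    if (!nrow(rows)) return(character())
    unique(trimws(unlist(strsplit(rows$motifs, ","))))
  })
  out <- lapply(scheme$label, function(cl) {
    ids <- gr$orf_id[!is.na(gr$expr_class) & gr$expr_class == cl]
    row <- data.frame(class = cl, n_orfs = length(ids),
                      stringsAsFactors = FALSE)
    for (m in motifs) {
      row[[m]] <- if (!length(ids)) NA_real_ else
        mean(vapply(per_orf[ids], function(x) m %in% x, TRUE))
    }
    row
  })
  do.call(rbind, out)
}

#' Octamer spacing relative to the ATG and the TAAG TSS
#'
#' Locates exact matches of an octamer in the upstream promoter window of
#' an ORF and reports, per match, its distance to the ATG initiation
#' codon and to the TAAG TSS motif (the TSS nearest the ATG). The default
#' convention measures both distances as the count of nucleotides strictly
#' between the octamer's 3' end and the anchor base (A of ATG; T of TAAG),
#' under which `atg_gap - taag_gap = 4 + 5'UTR length` for any upstream
#' octamer. `taagFrom = "5p"` instead reports the 5'-end offset of the
#' octamer to the T of TAAG (the number of coding-strand steps from the
#' octamer's first base to the T).
#'
#' @param genome a [GenomeRecord-class].
#' @param orfId an ORF id.
#' @param query the octamer.
#' @param taagPos optional explicit TSS (T of TAAG, coding strand).
#' @param window upstream window width searched (default 225).
#' @param taagFrom `"3p"` (strict gap, default) or `"5p"` (5'-end offset).
#' @return a data.frame with one row per exact match (`orf_id`, `octamer`,
#'   `offset` within the window, `atg_gap`, `taag_gap`, `n_matches`,
#'   `multiple` flag); zero rows (with a `reason` attribute) when the
#'   octamer is absent.
#' @export
octamerSpacingReport <- function(genome, orfId, query, taagPos = NULL,
                                 window = 225L, taagFrom = c("3p", "5p")) {
  taagFrom <- match.arg(taagFrom)
  query <- validateQuery(query, 0L)
  up <- extractUpstream(genome, orfId, taagPos, window = window)
  useq <- as.character(regionSequences(up))[1]
  w <- nchar(useq)
  utr <- extract5UTR(genome, orfId, taagPos)
  utr_len <- nchar(as.character(regionSequences(utr))[1])
  hits <- fuzzyScan(useq, query, 0L, strands = "plus")
  if (!nrow(hits)) {
    out <- data.frame(orf_id = character(), octamer = character(),
                      offset = integer(), atg_gap = integer(),
                      taag_gap = integer(), n_matches = integer(),
                      multiple = logical(), stringsAsFactors = FALSE)
    attr(out, "reason") <- sprintf(
      "no exact match of %s in the %d nt upstream window of %s",
      query, w, orfId)
    return(out)
  }
  k <- nchar(query)
  o <- hits$position
  taag_gap <- switch(taagFrom,
    "3p" = w - o - k + 1L,      # strictly between octamer 3' end and the T
    "5p" = w - o + 1L)          # coding-strand offset from the 5' base to the T
  atg_gap <- (w - o - k + 1L) + 4L + utr_len
  data.frame(orf_id = orfId, octamer = query, offset = o,
             atg_gap = atg_gap, taag_gap = taag_gap,
             n_matches = nrow(hits), multiple = nrow(hits) > 1L,
             stringsAsFactors = FALSE)
}

#' Genome-wide matches outside a set of regions
#'
#' Splits a genome scan's matches into those whose plus-strand footprint
#' lies entirely inside one of the given regions and the "additional"
#' matches elsewhere in the genome.
#'
#' @param summary a [ScanSummary-class] from [genomeScan()].
#' @param regions a [RegionSet-class] (e.g. upstream promoter windows).
#' @return a list with counts `inside` and `additional`.
#' @export
additionalMatches <- function(summary, regions) {
  m <- scanMatches(summary)
  k <- nchar(summary@query)
  L <- summary@genomeLength
  info <- regionInfo(regions)
  insideAny <- function(p) {
    foot <- c(p, p + k - 1L)
    any(vapply(seq_len(nrow(info)), function(i) {
      s <- info$start[i]; e <- info$end[i]
      if (info$wraps[i]) {
        # wrapped region covers [s, L] and [1, e]
        (foot[1] >= s || foot[2] <= e)
      } else {
        foot[1] >= s && foot[2] <= e
      }
    }, TRUE))
  }
  if (!nrow(m)) return(list(inside = 0L, additional = 0L))
  ins <- vapply(m$position, insideAny, TRUE)
  list(inside = sum(ins), additional = sum(!ins))
}

#' Size of a Hamming ball over the DNA alphabet
#'
#' The number of distinct k-mers within Hamming distance `d` of a fixed
#' k-mer: `sum_{i=0..d} choose(k, i) * 3^i`. For `k = 8, d = 2` this is
#' 277, the figure behind the expected background hit rate of a 2-mismatch
#' octamer search.
#'
#' @param k word length.
#' @param d maximum Hamming distance.
#' @return an integer count.
#' @export
hammingBallSize <- function(k, d) {
  sum(vapply(0:d, function(i) choose(k, i) * 3^i, 1))
}

#' Enumerate the Hamming neighbourhood of a DNA word
#'
#' All distinct words within Hamming distance `d` of `query` (including
#' the query itself).
#'
#' @param query a concrete DNA word.
#' @param d maximum Hamming distance.
#' @return a character vector of words.
#' @export
hammingNeighbors <- function(query, d) {
  query <- validateQuery(query, 0L)
  stopifnot(isConcreteDNA(query))
  bases <- c("A", "C", "G", "T")
  words <- query
  for (step in seq_len(d)) {
    new_words <- unlist(lapply(words, function(w) {
      chars <- strsplit(w, "")[[1]]
      unlist(lapply(seq_along(chars), function(j) {
        vapply(setdiff(bases, chars[j]), function(b) {
          x <- chars; x[j] <- b; paste(x, collapse = "")
        }, "")
      }))
    }))
    words <- unique(c(words, new_words))
  }
  words
}

#' Expected per-position fuzzy hit probability under an i.i.d. background
#'
#' For an i.i.d. background with the given base composition, the
#' probability that a window matches the query within Hamming distance
#' `d`, obtained by summing the composition probability of every word in
#' the query's Hamming ball. For the uniform composition this equals
#' `hammingBallSize(k, d) / 4^k`.
#'
#' @param query a concrete DNA word.
#' @param d maximum Hamming distance.
#' @param composition named base probabilities (A, C, G, T), summing to 1.
#' @return a probability.
#' @export
expectedHitProbability <- function(query, d,
                                   composition = c(A = 0.25, C = 0.25,
                                                   G = 0.25, T = 0.25)) {
  stopifnot(abs(sum(composition) - 1) < 1e-9)
  words <- hammingNeighbors(query, d)
  sum(vapply(words, function(w) {
    prod(composition[strsplit(w, "")[[1]]])
  }, 1, USE.NAMES = FALSE))
}
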