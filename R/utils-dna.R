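# DNA / coordinate helpers shared across the package.
# Convention (used everywhere): coordinates are 1-based, fully closed
# intervals on the plus strand. On circular genomes an interval may wrap the
# origin, represented as (start, end, wraps = TRUE) with end < start; its
# sequence is the tail of the chromosome followed by its head.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# minimal degenerate code for a set of concrete bases
iupacCode <- function(bases) {
  bases <- sort(unique(toupper(bases)))
  key <- paste(bases, collapse = "")
  codes <- vapply(IUPAC_SETS, function(s) paste(sort(s), collapse = ""), "")
  hit <- names(codes)[match(key, codes)]
  if (is.na(hit)) stop("no IUPAC code for base set: ", key)
  hit
}

isConcreteDNA <- function(x) {
  grepl("^[ACGT]+$", toupper(x))
}

isIupacDNA <- function(x) {
  grepl("^[ACGTRYSWKMBDHVN]+$", toupper(x))
}

revComp <- function(x) {
  as.character(reverseComplement(DNAString(x)))
}

#' A+T content of a DNA sequence
#'
#' Fraction of bases that are A or T. The 5'UTRs of strongly expressed
#' baculovirus late genes are characteristically A/T rich, which is the
#' reason this quantity is tracked per expression class.
#'
#' @param x a single DNA string over A/C/G/T (case-insensitive).
#' @return a fraction in `[0, 1]`; `NA_real_` for an empty sequence.
#' @examples
#' atContent("ATAT")  # 1
#' atContent("ATGC")  # 0.5
#' @export
atContent <- function(x) {
  x <- toupper(as.character(x))
  stopifnot(length(x) == 1L)
  if (nchar(x) == 0L) return(NA_real_)
  if (!isConcreteDNA(x)) stop("atContent() requires a concrete A/C/G/T sequence")
  n <- nchar(x)
  at <- sum(strsplit(x, "")[[1]] %in% c("A", "T"))
  at / n
}

#' @rdname atContent
#' @export
gcContent <- function(x) {
  v <- atContent(x)
  if (is.na(v)) NA_real_ else 1 - v
}

# normalize a 1-based position onto a circular chromosome of length L
wrapPos <- function(pos, L) ((pos - 1L) %% L) + 1L

# length of a closed interval, accounting for origin wrap
intervalLength <- function(start, end, L, wraps = FALSE) {
  if (!wraps) end - start + 1L else L - start + 1L + end
}

# plus-strand subsequence of a genome string; concatenates tail+head on wrap
plusSlice <- function(seqchar, start, end, wraps = FALSE) {
  if (!wraps) {
    substr(seqchar, start, end)
  } else {
    paste0(substr(seqchar, start, nchar(seqchar)), substr(seqchar, 1L, end))
  }
}
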