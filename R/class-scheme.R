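# Transcript-abundance classing of ORFs from RPKM values.

#' The default RPKM class scheme
#'
#' Five transcript-abundance classes by steady-state RPKM, lower-inclusive
#' and upper-exclusive: Very High (RPKM >= 50,000), High (20,000-50,000),
#' Medium (10,000-20,000), Low (1,000-10,000) and Very Low (< 1,000).
#' A scheme is a data.frame with columns `label`, `lower` (inclusive) and
#' `upper` (exclusive; `Inf` for the top class); bounds must be contiguous,
#' non-overlapping and cover `[0, Inf)`.
#'
#' @return a class-scheme data.frame, ordered from highest to lowest class.
#' @export
defaultClassScheme <- function() {
  data.frame(
    label = c("Very High", "High", "Medium", "Low", "Very Low"),
    lower = c(50000, 20000, 10000, 1000, 0),
    upper = c(Inf, 50000, 20000, 10000, 1000),
    stringsAsFactors = FALSE
  )
}

validateScheme <- function(scheme) {
  stopifnot(is.data.frame(scheme),
            all(c("label", "lower", "upper") %in% names(scheme)))
  if (anyDuplicated(scheme$label)) stop("class labels must be unique")
  s <- scheme[order(scheme$lower), , drop = FALSE]
  if (s$lower[1] != 0) stop("class scheme must cover [0, Inf): lowest bound != 0")
  if (!is.infinite(s$upper[nrow(s)])) stop("top class must be unbounded above")
  if (nrow(s) > 1 && any(s$upper[-nrow(s)] != s$lower[-1]))
    stop("class bounds must be contiguous and non-overlapping")
  invisible(scheme)
}

#' Assign an RPKM value to an expression class
#'
#' Intervals are lower-inclusive and upper-exclusive, so e.g. under the
#' default scheme an RPKM of exactly 20,000 is High while 19,999.9 is
#' Medium, and 50,000 is Very High.
#'
#' @param rpkm non-negative RPKM value(s).
#' @param scheme a class scheme (see [defaultClassScheme()]).
#' @return a character vector of class labels, one per input value.
#' @examples
#' assignClass(c(50000, 0, 19999.9, 20000))
#' @export
assignClass <- function(rpkm, scheme = defaultClassScheme()) {
  validateScheme(scheme)
  if (any(is.na(rpkm))) stop("rpkm must not be NA")
  if (any(rpkm < 0)) stop("rpkm must be non-negative")
  vapply(rpkm, function(v) {
    hit <- scheme$label[v >= scheme$lower & v < scheme$upper]
    stopifnot(length(hit) == 1L)  # guaranteed by the scheme invariants
    hit
  }, character(1))
}

#' Classify every ORF of a genome and tally the classes
#'
#' Each ORF with an RPKM value receives exactly one `expr_class` label;
#' ORFs without an RPKM are left unclassified, reported with a warning and
#' listed in the result (classes are never forced onto missing data).
#'
#' @param genome a [GenomeRecord-class] whose ORFs carry `rpkm` values
#'   (see [attachAnnotations()]).
#' @param scheme a class scheme (see [defaultClassScheme()]).
#' @return a list with elements `genome` (the record with `expr_class`
#'   filled in), `tally` (named integer vector in scheme order, summing to
#'   the number of classified ORFs), `table` (per-ORF data.frame of
#'   `orf_id`, `rpkm`, `class`) and `unclassified` (ids lacking RPKM).
#' @export
classifyOrfs <- function(genome, scheme = defaultClassScheme()) {
  validateScheme(scheme)
  gr <- orfs(genome)
  if (!length(gr)) stop("genome has no ORF features")
  has <- !is.na(gr$rpkm)
  if (any(!has))
    warning("ORF(s) without RPKM excluded from classification: ",
            paste(gr$orf_id[!has], collapse = ", "))
  cls <- rep(NA_character_, length(gr))
  cls[has] <- assignClass(gr$rpkm[has], scheme)
  gr$expr_class <- cls
  genome@orfs <- gr
  tally <- setNames(integer(nrow(scheme)), scheme$label)
  tb <- table(factor(cls[has], levels = scheme$label))
  tally[names(tb)] <- as.integer(tb)
  list(
    genome = genome,
    tally = tally,
    table = data.frame(orf_id = gr$orf_id[has], rpkm = gr$rpkm[has],
                       class = cls[has], stringsAsFactors = FALSE),
    unclassified = gr$orf_id[!has]
  )
}

#' Rank of a class label within a scheme
#'
#' Rank 1 is the highest-abundance class. Used for monotonicity checks and
#' for ordering per-class outputs.
#'
#' @param label class label(s).
#' @param scheme a class scheme.
#' @return integer rank(s).
#' @export
classRank <- function(label, scheme = defaultClassScheme()) {
  ord <- scheme$label[order(-scheme$lower)]
  match(label, ord)
}
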