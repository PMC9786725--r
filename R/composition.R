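# Per-class 5'UTR length and A+T-content statistics.

#' Per-ORF 5'UTR composition table
#'
#' Extracts the 5'UTR of every classified ORF with a TSS annotation and
#' tabulates its length and A+T content. Zero-length UTRs have undefined
#' (`NA`) A+T content.
#'
#' @param genome a classified [GenomeRecord-class] (see [classifyOrfs()]).
#' @return a data.frame with columns `orf_id`, `class`, `utr_length`,
#'   `at_content`.
#' @export
utrCompositionTable <- function(genome) {
  gr <- orfs(genome)
  keep <- !is.na(gr$expr_class)
  rows <- lapply(gr$orf_id[keep], function(id) {
    if (!nrow(tssForOrf(genome, id))) return(NULL)
    utr <- as.character(regionSequences(extract5UTR(genome, id)))[1]
    data.frame(orf_id = id,
               class = gr$expr_class[gr$orf_id == id],
               utr_length = nchar(utr),
               at_content = if (nchar(utr)) atContent(utr) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(orf_id = character(), class = character(),
                      utr_length = integer(), at_content = numeric(),
                      stringsAsFactors = FALSE)
  }
  out
}

starsFor <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Pairwise between-class comparisons
#'
#' Two-sided pairwise tests of a per-ORF quantity (5'UTR length or A+T
#' content) between expression classes. The default is Welch's t-test
#' (unequal variances; the classes are small and unbalanced);
#' Mann-Whitney U is available via `method = "wilcox"`. P-values are
#' reported uncorrected by default, with Holm correction available.
#' Significance stars: `*` for p < 0.05, `**` for p < 0.01.
#'
#' @param values a named list: class label -> numeric vector. Classes with
#'   fewer than 2 finite values are excluded with a warning.
#' @param method `"welch"` or `"wilcox"`.
#' @param mode `"all_pairs"` (default) or `"vs_reference"`.
#' @param reference reference class for `mode = "vs_reference"`.
#' @param adjust `"none"` (default) or any [stats::p.adjust] method.
#' @return a data.frame with columns `class1`, `class2`, `statistic`,
#'   `p_value`, `stars`.
#' @export
compareClasses <- function(values, method = c("welch", "wilcox"),
                           mode = c("all_pairs", "vs_reference"),
                           reference = NULL, adjust = "none") {
  method <- match.arg(method)
  mode <- match.arg(mode)
  values <- lapply(values, function(v) v[is.finite(v)])
  n <- vapply(values, length, 1L)
  if (any(n < 2L)) {
    warning("class(es) with fewer than 2 values excluded: ",
            paste(names(values)[n < 2L], collapse = ", "))
    values <- values[n >= 2L]
  }
  if (length(values) < 2L) stop("need at least 2 classes with >= 2 values")
  labs <- names(values)
  pairs <- if (mode == "all_pairs") {
    utils::combn(labs, 2L, simplify = FALSE)
  } else {
    if (is.null(reference) || !reference %in% labs)
      stop("mode = 'vs_reference' needs a reference class present in values")
    lapply(setdiff(labs, reference), function(l) c(reference, l))
  }
  rows <- lapply(pairs, function(pr) {
    x <- values[[pr[1]]]; y <- values[[pr[2]]]
    res <- if (method == "welch") {
      t.test(x, y, var.equal = FALSE)
    } else {
      suppressWarnings(wilcox.test(x, y, exact = FALSE))
    }
    data.frame(class1 = pr[1], class2 = pr[2],
               statistic = unname(res$statistic), p_value = res$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_value <- stats::p.adjust(out$p_value, method = adjust)
  out$stars <- starsFor(out$p_value)
  out
}

#' Class-wise composition analysis of the 5'UTRs
#'
#' Convenience wrapper: builds the per-ORF table with
#' [utrCompositionTable()] and runs [compareClasses()] on both the UTR
#' lengths and the A+T contents.
#'
#' @inheritParams utrCompositionTable
#' @param method,mode,reference,adjust passed to [compareClasses()].
#' @return a list with `table` (per-ORF values), `length_tests` and
#'   `at_tests` (pairwise test tables).
#' @export
compositionByClass <- function(genome, method = "welch", mode = "all_pairs",
                               reference = NULL, adjust = "none") {
  tab <- utrCompositionTable(genome)
  split_by <- function(col) split(tab[[col]], tab$class)
  list(table = tab,
       length_tests = compareClasses(split_by("utr_length"), method = method,
                                     mode = mode, reference = reference,
                                     adjust = adjust),
       at_tests = compareClasses(split_by("at_content"), method = method,
                                 mode = mode, reference = reference,
                                 adjust = adjust))
}
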