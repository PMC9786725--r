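# Signed hr-to-ORF distances and the class-coloured genome map.
#
# The literal distance is pos5'(hr) - pos5'(ORF): the plus-strand
# coordinate of the hr region's 5' end minus the strand-aware coding start
# of the ORF. A positive value means the ORF's start codon lies at a
# smaller genomic coordinate than the hr (counter-clockwise of it on the
# conventional circular map). The circular variant wraps this difference
# to the minimal-magnitude signed arc.

#' Signed distance between an hr region and an ORF start codon
#'
#' @param genome a [GenomeRecord-class].
#' @param hrId an hr id.
#' @param orfId an ORF id.
#' @param circular wrap to the minimal-magnitude signed arc distance?
#'   (default FALSE: the literal subtraction).
#' @return a one-row data.frame: `orf_id`, `hr_id`, `distance`,
#'   `orientation` (`orf_before_hr` when the distance is positive,
#'   `orf_after_hr` when negative, `coincident` at 0), `class`.
#' @export
hrOrfDistance <- function(genome, hrId, orfId, circular = FALSE) {
  hr <- hrRegions(genome)
  i <- match(hrId, hr$hr_id)
  if (is.na(i)) stop("unknown hr id: ", hrId)
  orf <- orfById(genome, orfId)
  d <- signedHrDistance(start(hr)[i], cdsStart(orf), genomeLength(genome),
                        circular)
  data.frame(orf_id = orfId, hr_id = hrId, distance = d,
             orientation = if (d > 0) "orf_before_hr"
                           else if (d < 0) "orf_after_hr" else "coincident",
             class = orf$expr_class, stringsAsFactors = FALSE)
}

# d = hr5 - orf5; circular mode wraps into (-L/2, L/2]
signedHrDistance <- function(hr5, orf5, L, circular = FALSE) {
  d <- hr5 - orf5
  if (!circular) return(d)
  d <- ((d %% L) + L) %% L
  if (d > L / 2) d <- d - L
  d
}

#' All hr x ORF distances and the nearest hr per ORF
#'
#' Computes the signed distance for every (hr, ORF) pair and assigns each
#' ORF its nearest hr by absolute distance (always measured on the
#' minimal circular arc for the nearest-hr assignment, so proximity is
#' well defined on a circular chromosome); ties break toward the
#' lexicographically lower hr id.
#'
#' @param genome a [GenomeRecord-class] (ideally classified).
#' @param circular report wrapped minimal-arc distances in the pair table?
#' @return a list with `pairs` (|hr| x |ORF| rows) and `nearest` (one row
#'   per ORF: `orf_id`, `class`, `hr_id`, `distance`). With no hr regions,
#'   both are empty and a warning is raised.
#' @export
hrDistanceTable <- function(genome, circular = FALSE) {
  hr <- hrRegions(genome)
  gr <- orfs(genome)
  if (!length(hr)) {
    warning("genome has no hr regions")
    empty <- data.frame(orf_id = character(), hr_id = character(),
                        distance = integer(), orientation = character(),
                        class = character(), stringsAsFactors = FALSE)
    return(list(pairs = empty, nearest = empty))
  }
  L <- genomeLength(genome)
  orf5 <- cdsStart(gr)
  pairs <- do.call(rbind, lapply(seq_along(hr), function(i) {
    d <- vapply(orf5, function(a)
      signedHrDistance(start(hr)[i], a, L, circular), numeric(1))
    data.frame(orf_id = gr$orf_id, hr_id = hr$hr_id[i], distance = d,
               orientation = ifelse(d > 0, "orf_before_hr",
                                    ifelse(d < 0, "orf_after_hr", "coincident")),
               class = gr$expr_class, stringsAsFactors = FALSE)
  }))
  rownames(pairs) <- NULL
  hr_order <- order(hr$hr_id)
  nearest <- do.call(rbind, lapply(seq_along(gr), function(j) {
    d <- vapply(seq_along(hr), function(i)
      signedHrDistance(start(hr)[i], orf5[j], L, circular = TRUE), numeric(1))
    best <- hr_order[which.min(abs(d[hr_order]))]  # tie -> lower hr_id
    data.frame(orf_id = gr$orf_id[j], class = gr$expr_class[j],
               hr_id = hr$hr_id[best], distance = d[best],
               stringsAsFactors = FALSE)
  }))
  list(pairs = pairs, nearest = nearest)
}

#' Circular genome map coloured by expression class
#'
#' Draws a circular ideogram of the chromosome with one track per strand:
#' each ORF is an arc coloured by its expression class (unclassified ORFs
#' grey), and hr regions are marked as dark blocks on an outer track.
#' Coordinates increase clockwise from the top of the circle.
#'
#' @param genome a classified [GenomeRecord-class].
#' @param scheme the class scheme (fixes the class -> colour mapping).
#' @param main plot title.
#' @return invisibly, a list with the `arcs` data.frame (one row per ORF:
#'   start/end angle, track, colour) and the `palette` used.
#' @export
classGenomeMap <- function(genome, scheme = defaultClassScheme(),
                           main = accession(genome)) {
  gr <- orfs(genome)
  L <- genomeLength(genome)
  palette <- setNames(
    grDevices::hcl.colors(nrow(scheme), "Zissou 1"), scheme$label)
  cls <- gr$expr_class
  col <- ifelse(is.na(cls), "grey70", palette[cls])
  ang <- function(pos) pi / 2 - 2 * pi * (pos - 1) / L  # clockwise from top
  arcs <- data.frame(
    orf_id = gr$orf_id,
    a0 = ang(start(gr)), a1 = ang(end(gr)),
    track = ifelse(as.character(strand(gr)) == "+", 1.0, 0.85),
    colour = col, stringsAsFactors = FALSE)

  graphics::plot.new()
  graphics::plot.window(c(-1.35, 1.35), c(-1.35, 1.35), asp = 1)
  graphics::title(main = main)
  drawArc <- function(a0, a1, r, col, lwd) {
    tt <- seq(a0, a1, length.out = max(2L, ceiling(abs(a1 - a0) * 60)))
    graphics::lines(r * cos(tt), r * sin(tt), col = col, lwd = lwd, lend = 1)
  }
  drawArc(0, 2 * pi, 0.92, "grey85", 1)   # chromosome backbone
  for (i in seq_len(nrow(arcs)))
    drawArc(arcs$a0[i], arcs$a1[i], arcs$track[i], arcs$colour[i], lwd = 6)
  hr <- hrRegions(genome)
  for (i in seq_along(hr))
    drawArc(ang(start(hr)[i]), ang(end(hr)[i]), 1.12, "grey20", lwd = 8)
  graphics::legend("bottomright", bty = "n", cex = 0.7, lwd = 4,
                   col = c(palette, "grey70", "grey20"),
                   legend = c(names(palette), "unclassified", "hr"))
  invisible(list(arcs = arcs, palette = palette))
}
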