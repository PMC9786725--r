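# Synthetic genomes with a ground-truth manifest.
#
# The generator emulates the annotated-transcriptome setting the analysis
# expects: a circular chromosome carrying strand-alternating,
# non-overlapping ORFs, each preceded (in coding orientation) by a 225 nt
# upstream window, a TAAG late-promoter motif and a 5'UTR; hr blocks
# interspersed between genes; RPKM values drawn per class strictly inside
# the class bounds; and optional octamers planted at recorded offsets.
# Everything planted is recorded in the manifest, and accidental exact
# copies of planted octamers in the random background are scrubbed, so a
# 0-mismatch scan recovers the manifest exactly.

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

randomDNA <- function(n, composition) {
  if (n <= 0L) return("")
  paste(sample(names(composition), n, replace = TRUE, prob = composition),
        collapse = "")
}

#' Specification of a synthetic genome
#'
#' Defaults describe an AcMNPV-like study design: 149 ORFs with class
#' quotas 5/6/17/65/56 (Very High .. Very Low), 8 hr blocks of 400 nt, a
#' 59% A+T background, 225 nt upstream windows, 5'UTRs of 4-120 nt with
#' the Very High class's UTR composition shifted +0.15 in A+T, TATA/CAGT
#' motif probabilities decreasing with abundance class (zero for High and
#' Very High), and log-uniform RPKM draws inside each class's bounds.
#'
#' @param classQuotas named integer vector, class label -> ORF count.
#' @param hrCount,hrLength number and length (nt) of hr blocks.
#' @param composition background base probabilities (named, sums to 1).
#' @param upstreamWindow upstream window width (nt).
#' @param utrRange min/max 5'UTR length (nt).
#' @param atShift named per-class additive shift of UTR A+T content.
#' @param motifProbs data.frame with columns `class`, `TATA`, `CAGT`:
#'   per-class planting probabilities of the RNAP II promoter motifs.
#' @param plantedOctamers data.frame with columns `sequence`, `offset`
#'   (1-based position of the octamer's first base within the upstream
#'   window), `n_orfs` (how many ORFs receive it); or NULL.
#' @param cdsRange min/max CDS length (nt, rounded to codons).
#' @param intergenic fixed intergenic gap (nt).
#' @param genomeLength optional fixed genome length; the laid-out ORFs
#'   must fit, otherwise an error.
#' @param scheme class scheme used for the RPKM bounds.
#' @param seed RNG seed; regeneration from one seed is bit-identical.
#' @return a validated spec (list) for [generateSynthetic()].
#' @export
syntheticSpec <- function(classQuotas = c("Very High" = 5L, "High" = 6L,
                                          "Medium" = 17L, "Low" = 65L,
                                          "Very Low" = 56L),
                          hrCount = 8L, hrLength = 400L,
                          composition = c(A = 0.295, C = 0.205,
                                          G = 0.205, T = 0.295),
                          upstreamWindow = 225L,
                          utrRange = c(4L, 120L),
                          atShift = c("Very High" = 0.15),
                          motifProbs = data.frame(
                            class = c("Very High", "High", "Medium", "Low",
                                      "Very Low"),
                            TATA = c(0, 0, 0.10, 0.30, 0.55),
                            CAGT = c(0, 0, 0.10, 0.30, 0.55)),
                          plantedOctamers = NULL,
                          cdsRange = c(300L, 1500L),
                          intergenic = 60L,
                          genomeLength = NULL,
                          scheme = defaultClassScheme(),
                          seed = 1L) {
  stopifnot(abs(sum(composition) - 1) < 1e-9,
            all(names(composition) %in% c("A", "C", "G", "T")),
            all(classQuotas >= 0L), sum(classQuotas) > 0L,
            upstreamWindow >= 1L, utrRange[1] >= 0L,
            utrRange[2] >= utrRange[1])
  stopifnot(all(names(classQuotas) %in% scheme$label))
  if (!is.null(plantedOctamers)) {
    stopifnot(all(c("sequence", "offset", "n_orfs") %in% names(plantedOctamers)))
    k <- nchar(plantedOctamers$sequence)
    if (any(plantedOctamers$offset < 1L |
            plantedOctamers$offset + k - 1L > upstreamWindow))
      stop("planted octamer offsets must fit inside the upstream window")
    if (any(plantedOctamers$n_orfs > sum(classQuotas)))
      stop("planted octamer multiplicity exceeds the ORF count")
  }
  spec <- list(classQuotas = classQuotas, hrCount = hrCount,
               hrLength = hrLength, composition = composition,
               upstreamWindow = as.integer(upstreamWindow),
               utrRange = as.integer(utrRange), atShift = atShift,
               motifProbs = motifProbs, plantedOctamers = plantedOctamers,
               cdsRange = as.integer(cdsRange),
               intergenic = as.integer(intergenic),
               genomeLength = genomeLength, scheme = scheme,
               seed = as.integer(seed))
  class(spec) <- "syntheticSpec"
  spec
}

# log-uniform RPKM inside the class bounds (finite caps for the open ends)
drawRpkm <- function(class, scheme) {
  i <- match(class, scheme$label)
  lo <- max(scheme$lower[i], 10)
  hi <- if (is.infinite(scheme$upper[i])) 5e5 else scheme$upper[i]
  10^runif(1, log10(lo), log10(hi * 0.999))
}

#' Generate a synthetic annotated genome
#'
#' Lays out the genome described by a [syntheticSpec()], returning the
#' annotated [GenomeRecord-class] (RPKM, TSS and hr annotations attached)
#' together with the plain tables and a manifest recording every planted
#' item. Fully reproducible from the spec's seed.
#'
#' @param spec a [syntheticSpec()].
#' @return a list with elements `genome`, `rpkm` (named vector), `tss`
#'   (`DataFrame`), `hrs` (data.frame), `manifest` (list: `orfs`,
#'   `octamers`, `hrs`, `scrubbed`, `seed`).
#' @export
generateSynthetic <- function(spec = syntheticSpec()) {
  stopifnot(inherits(spec, "syntheticSpec"))
  withSeed(spec$seed, {
    nOrfs <- sum(spec$classQuotas)
    classes <- sample(rep(names(spec$classQuotas), spec$classQuotas))
    strands <- rep(c("+", "-"), length.out = nOrfs)

    # which ORFs receive which planted octamer
    plant_map <- list()
    if (!is.null(spec$plantedOctamers)) {
      for (i in seq_len(nrow(spec$plantedOctamers))) {
        plant_map[[i]] <- sort(sample(nOrfs, spec$plantedOctamers$n_orfs[i]))
      }
    }

    vh_names <- c("polh", "p10", "p6.9", "odv-e18", "odv-ec27")
    vh_idx <- which(classes == "Very High")
    orf_names <- sprintf("orf%03d", seq_len(nOrfs))
    orf_names[vh_idx] <- vh_names[seq_along(vh_idx)]

    hr_after <- if (spec$hrCount > 0L) {
      unique(pmin(nOrfs, round(seq_len(spec$hrCount) * nOrfs /
                               spec$hrCount)))
    } else integer()
    hr_unit <- "ATTTACAAGTACTTGTAAATGCGTTTACAA"  # AT-rich repeat unit

    chunks <- character()
    pos <- 0L
    orf_rows <- list()
    oct_rows <- list()
    hr_rows <- list()
    tss_rows <- list()
    rpkms <- numeric(nOrfs)

    addChunk <- function(s) {
      chunks[[length(chunks) + 1L]] <<- s
      pos <<- pos + nchar(s)
    }

    for (i in seq_len(nOrfs)) {
      addChunk(randomDNA(spec$intergenic + sample(0:40, 1), spec$composition))
      w <- spec$upstreamWindow
      utr_len <- sample(spec$utrRange[1]:spec$utrRange[2], 1L)
      cds_len <- 3L * sample((spec$cdsRange[1] %/% 3L):(spec$cdsRange[2] %/% 3L), 1L)

      upstream <- randomDNA(w, spec$composition)
      motifs <- "TAAG"
      mp <- spec$motifProbs[spec$motifProbs$class == classes[i], , drop = FALSE]
      motif_offsets <- list()
      if (nrow(mp) && runif(1) < mp$TATA) {
        off <- w - 27L                       # TATA box ~28 nt 5' of the TSS
        substr(upstream, off, off + 3L) <- "TATA"
        motifs <- c(motifs, "TATA"); motif_offsets$TATA <- off
      }
      if (nrow(mp) && runif(1) < mp$CAGT) {
        off <- w - 9L                        # CAGT initiator near the TSS
        substr(upstream, off, off + 3L) <- "CAGT"
        motifs <- c(motifs, "CAGT"); motif_offsets$CAGT <- off
      }
      planted_here <- list()
      if (length(plant_map)) {
        for (pi in seq_along(plant_map)) {
          if (i %in% plant_map[[pi]]) {
            oseq <- toupper(spec$plantedOctamers$sequence[pi])
            off <- spec$plantedOctamers$offset[pi]
            substr(upstream, off, off + nchar(oseq) - 1L) <- oseq
            planted_here[[length(planted_here) + 1L]] <-
              list(sequence = oseq, offset = off)
          }
        }
      }

      comp_utr <- spec$composition
      shift <- unname(spec$atShift[classes[i]])
      if (!is.na(shift) && length(shift)) {
        at0 <- comp_utr["A"] + comp_utr["T"]
        at1 <- min(0.98, at0 + shift)
        comp_utr <- c(A = at1 / 2, C = (1 - at1) / 2,
                      G = (1 - at1) / 2, T = at1 / 2)
      }
      utr <- randomDNA(utr_len, comp_utr)
      cds <- paste0("ATG", randomDNA(cds_len - 6L, spec$composition), "TAA")
      block <- paste0(upstream, "TAAG", utr, cds)
      blen <- nchar(block)
      b <- pos + 1L

      if (strands[i] == "+") {
        taag_pos <- b + w
        cds_start <- b + w + 4L + utr_len
        gstart <- cds_start; gend <- b + blen - 1L
        oct_gstart <- function(off) b + off - 1L
        addChunk(block)
      } else {
        addChunk(revComp(block))
        taag_pos <- b + blen - (w + 1L)       # coding position w+1 is the T
        cds_start <- b + blen - (w + 4L + utr_len + 1L)
        gstart <- b; gend <- cds_start
        oct_gstart <- function(off) b + blen - off - 7L
      }

      rpkms[i] <- drawRpkm(classes[i], spec$scheme)
      orf_rows[[i]] <- data.frame(
        orf_id = sprintf("orf%03d", i), name = orf_names[i],
        class = classes[i], strand = strands[i],
        start = gstart, end = gend, taag_pos = taag_pos,
        utr_length = utr_len, rpkm = rpkms[i],
        motifs = paste(motifs, collapse = ","), stringsAsFactors = FALSE)
      tss_rows[[i]] <- data.frame(
        orf_id = sprintf("orf%03d", i), taag_pos = taag_pos,
        motifs = paste(motifs, collapse = ","), source = "synthetic",
        stringsAsFactors = FALSE)
      for (pl in planted_here) {
        oct_rows[[length(oct_rows) + 1L]] <- data.frame(
          orf_id = sprintf("orf%03d", i), sequence = pl$sequence,
          offset = pl$offset, genomic_start = oct_gstart(pl$offset),
          stringsAsFactors = FALSE)
      }

      if (i %in% hr_after && length(hr_rows) < spec$hrCount) {
        addChunk(randomDNA(spec$intergenic, spec$composition))
        nrep <- ceiling(spec$hrLength / nchar(hr_unit))
        hrseq <- substr(paste(rep(hr_unit, nrep), collapse = ""), 1L,
                        spec$hrLength)
        hs <- pos + 1L
        addChunk(hrseq)
        hr_rows[[length(hr_rows) + 1L]] <- data.frame(
          hr_id = sprintf("hr%d", length(hr_rows) + 1L),
          start = hs, end = pos, stringsAsFactors = FALSE)
      }
    }
    addChunk(randomDNA(spec$intergenic, spec$composition))

    seqchar <- paste(chunks, collapse = "")
    L <- nchar(seqchar)
    if (!is.null(spec$genomeLength)) {
      if (L > spec$genomeLength)
        stop(sprintf("class quotas do not fit: layout needs %d nt, genomeLength is %d",
                     L, spec$genomeLength))
      seqchar <- paste0(seqchar,
                        randomDNA(spec$genomeLength - L, spec$composition))
      L <- spec$genomeLength
    }

    orf_df <- do.call(rbind, orf_rows)
    oct_df <- if (length(oct_rows)) do.call(rbind, oct_rows) else
      data.frame(orf_id = character(), sequence = character(),
                 offset = integer(), genomic_start = integer(),
                 stringsAsFactors = FALSE)
    hr_df <- if (length(hr_rows)) do.call(rbind, hr_rows) else
      data.frame(hr_id = character(), start = integer(), end = integer(),
                 stringsAsFactors = FALSE)

    scrub <- scrubAccidentalMatches(seqchar, spec, orf_df, oct_df)
    seqchar <- scrub$sequence

    acc <- sprintf("SYN_%06d", spec$seed)
    si <- Seqinfo(seqnames = acc, seqlengths = L, isCircular = TRUE)
    gr <- GRanges(acc, IRanges(orf_df$start, orf_df$end),
                  strand = orf_df$strand, orf_id = orf_df$orf_id,
                  name = orf_df$name, seqinfo = si)
    tss_df <- do.call(rbind, tss_rows)
    hrs_gr <- if (nrow(hr_df)) {
      GRanges(acc, IRanges(hr_df$start, hr_df$end), hr_id = hr_df$hr_id,
              seqinfo = si)
    } else NULL
    genome <- GenomeRecord(acc, seqchar, circular = TRUE, orfs = gr,
                           hrs = hrs_gr, tss = DataFrame(tss_df))
    rpkm_vec <- setNames(orf_df$rpkm, orf_df$orf_id)
    genome <- suppressWarnings(attachAnnotations(genome, rpkm = rpkm_vec))

    list(genome = genome,
         rpkm = rpkm_vec,
         tss = tssAnnotations(genome),
         hrs = hr_df,
         manifest = list(orfs = orf_df, octamers = oct_df, hrs = hr_df,
                         scrubbed = scrub$n, seed = spec$seed, spec = spec))
  })
}

# destroy accidental exact copies of planted octamers in the background so
# that 0-mismatch scans report exactly the manifest
scrubAccidentalMatches <- function(seqchar, spec, orf_df, oct_df) {
  if (!nrow(oct_df)) return(list(sequence = seqchar, n = 0L))
  protected <- integer()
  for (i in seq_len(nrow(orf_df))) {         # TAAG motifs and start codons
    t <- orf_df$taag_pos[i]
    if (orf_df$strand[i] == "+") {
      s <- orf_df$start[i]
      protected <- c(protected, t:(t + 3L), s:(s + 2L))
    } else {
      s <- orf_df$end[i]
      protected <- c(protected, (t - 3L):t, (s - 2L):s)
    }
  }
  for (i in seq_len(nrow(oct_df))) {
    k <- nchar(oct_df$sequence[i])
    protected <- c(protected,
                   oct_df$genomic_start[i]:(oct_df$genomic_start[i] + k - 1L))
  }
  protected <- unique(protected)
  L <- nchar(seqchar)
  n_fixed <- 0L
  bases <- c("A", "C", "G", "T")
  for (oseq in unique(oct_df$sequence)) {
    k <- nchar(oseq)
    legit <- oct_df$genomic_start[oct_df$sequence == oseq]
    for (iter in 1:10) {
      hits <- fuzzyScan(seqchar, oseq, 0L, strands = "both", circular = TRUE)
      bad <- hits$position[!(hits$position %in% legit)]
      if (!length(bad)) break
      for (p in bad) {
        cand <- setdiff(wrapPos(p:(p + k - 1L), L), protected)
        if (!length(cand)) next
        j <- cand[ceiling(length(cand) / 2)]
        cur <- substr(seqchar, j, j)
        substr(seqchar, j, j) <- sample(setdiff(bases, cur), 1L)
        n_fixed <- n_fixed + 1L
      }
    }
  }
  list(sequence = seqchar, n = n_fixed)
}

#' Generate a featureless i.i.d. background genome
#'
#' A circular genome of i.i.d. bases with the given composition and no
#' features; the null background for calibrating fuzzy-scan hit rates
#' against the closed-form expectation of [expectedHitProbability()].
#'
#' @param length genome length in nt (> 0).
#' @param composition named base probabilities summing to 1.
#' @param seed RNG seed.
#' @return a [GenomeRecord-class].
#' @export
nullGenome <- function(length,
                       composition = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       seed = 1L) {
  if (length <= 0L) stop("genome length must be positive")
  stopifnot(abs(sum(composition) - 1) < 1e-9)
  withSeed(seed, {
    GenomeRecord(sprintf("NULL_%06d", seed),
                 randomDNA(length, composition), circular = TRUE)
  })
}

#' Write a synthetic bundle to disk
#'
#' Writes the GenBank genome, a genome FASTA, the RPKM/TSS/hr TSV tables
#' and the JSON manifest into a directory, in the same dialects the
#' readers of this package consume.
#'
#' @param sim result of [generateSynthetic()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
writeSyntheticBundle <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    genbank = file.path(dir, "genome.gb"),
    fasta = file.path(dir, "genome.fasta"),
    rpkm = file.path(dir, "rpkm.tsv"),
    tss = file.path(dir, "tss.tsv"),
    hr = file.path(dir, "hr.tsv"),
    manifest = file.path(dir, "manifest.json"))
  writeGenBank(sim$genome, paths["genbank"])
  fa <- DNAStringSet(genomeSeq(sim$genome))
  names(fa) <- accession(sim$genome)
  writeXStringSet(fa, paths["fasta"])
  write.table(data.frame(orf_id = names(sim$rpkm), rpkm = sim$rpkm),
              paths["rpkm"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(sim$tss), paths["tss"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$hrs, paths["hr"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  man <- sim$manifest
  man$spec <- unclass(man$spec)
  man$spec$scheme <- NULL                      # data.frame round-trips poorly
  man$spec$classQuotas <- as.list(man$spec$classQuotas)
  jsonlite::write_json(man, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(paths)
}
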