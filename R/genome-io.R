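# GenBank flat-file input/output and the TSV tables the pipeline consumes.
#
# The reader covers the dialect an annotated viral genome actually uses:
# LOCUS topology, CDS features with complement() and origin-spanning join(),
# repeat_region/misc_feature hr annotations, and the ORIGIN sequence block.
# Origin-spanning CDS features on a circular genome are normalized to an
# unrolled interval [start, end + L] (GenomicRanges' convention for
# out-of-bound ranges on circular sequences).

#' Read an annotated genome from a GenBank flat file
#'
#' Builds a [GenomeRecord-class] from a GenBank record: one ORF per CDS
#' feature (strand-resolved, so `cdsStart()` is the genomic position of the
#' A of the ATG on the coding strand), hr regions recognised from
#' repeat_region/misc_feature qualifiers containing an "hr" label, and
#' topology taken from the LOCUS line (default linear).
#'
#' @param path path to a GenBank flat file containing a sequence.
#' @return a [GenomeRecord-class].
#' @details A CDS with a `join()` spanning the origin of a circular genome
#'   is normalized to a single wrapped interval; any other compound
#'   location is skipped with a warning naming the feature.
#' @export
readGenBank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^LOCUS", lines[1]))
    stop("not a GenBank flat file (no LOCUS line): ", path)
  circular <- grepl("\\bcircular\\b", lines[1], ignore.case = TRUE)
  locus_name <- strsplit(trimws(sub("^LOCUS", "", lines[1])), "\\s+")[[1]][1]

  acc <- locus_name
  vline <- grep("^VERSION", lines, value = TRUE)
  aline <- grep("^ACCESSION", lines, value = TRUE)
  if (length(vline)) {
    acc <- strsplit(trimws(sub("^VERSION", "", vline[1])), "\\s+")[[1]][1]
  } else if (length(aline)) {
    acc <- strsplit(trimws(sub("^ACCESSION", "", aline[1])), "\\s+")[[1]][1]
  }

  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) stop("GenBank record has no ORIGIN sequence block: ", path)
  endrec <- grep("^//", lines)
  endrec <- if (length(endrec)) endrec[endrec > ori[1]][1] else length(lines) + 1L
  seqlines <- lines[(ori[1] + 1L):(endrec - 1L)]
  seqchar <- toupper(gsub("[^A-Za-z]", "", paste(seqlines, collapse = "")))
  if (!nchar(seqchar)) stop("GenBank record has an empty sequence: ", path)
  L <- nchar(seqchar)

  feats <- parseGenBankFeatures(lines, ori[1])

  orf_rows <- list()
  hr_rows <- list()
  skipped <- character()
  n_cds <- 0L
  for (ft in feats) {
    if (ft$key == "CDS") {
      n_cds <- n_cds + 1L
      id <- ft$qualifiers[["locus_tag"]] %||% ft$qualifiers[["gene"]] %||%
        sprintf("CDS_%04d", n_cds)
      loc <- parseGenBankLocation(ft$location, L, circular)
      if (is.null(loc)) {
        skipped <- c(skipped, id)
        next
      }
      orf_rows[[length(orf_rows) + 1L]] <- data.frame(
        start = loc$start, end = loc$end, strand = loc$strand,
        orf_id = id,
        name = ft$qualifiers[["gene"]] %||% ft$qualifiers[["product"]] %||% id,
        stringsAsFactors = FALSE)
    } else if (ft$key %in% c("repeat_region", "misc_feature", "rpt_region")) {
      txt <- tolower(paste(unlist(ft$qualifiers), collapse = " "))
      m <- regmatches(txt, regexpr("\\bhr[0-9]+[a-z]?\\b", txt))
      if (length(m)) {
        loc <- parseGenBankLocation(ft$location, L, circular)
        if (!is.null(loc)) {
          hr_rows[[length(hr_rows) + 1L]] <- data.frame(
            start = loc$start, end = loc$end, hr_id = m[1],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(skipped)) {
    warning("skipped CDS features with unsupported compound locations: ",
            paste(skipped, collapse = ", "))
  }

  si <- Seqinfo(seqnames = acc, seqlengths = L, isCircular = circular)
  orfs <- NULL
  if (length(orf_rows)) {
    df <- do.call(rbind, orf_rows)
    df$orf_id <- make.unique(df$orf_id)
    orfs <- GRanges(acc, IRanges(df$start, df$end), strand = df$strand,
                    orf_id = df$orf_id, name = df$name, seqinfo = si)
  }
  hrs <- NULL
  if (length(hr_rows)) {
    df <- do.call(rbind, hr_rows)
    hrs <- GRanges(acc, IRanges(df$start, df$end), hr_id = df$hr_id,
                   seqinfo = si)
  }
  GenomeRecord(acc, seqchar, circular = circular, orfs = orfs, hrs = hrs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# split the FEATURES block into (key, location, qualifiers) entries
parseGenBankFeatures <- function(lines, origin_idx) {
  fstart <- grep("^FEATURES", lines)
  if (!length(fstart)) return(list())
  block <- lines[(fstart[1] + 1L):(origin_idx - 1L)]
  feats <- list()
  cur <- NULL
  qual_name <- NULL
  for (ln in block) {
    if (grepl("^ {5}\\S", ln)) {                       # new feature header
      if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
      key <- trimws(substr(ln, 6L, 20L))
      cur <- list(key = key, location = trimws(substring(ln, 21L)),
                  qualifiers = list())
      qual_name <- NULL
    } else if (!is.null(cur)) {
      body <- trimws(ln)
      if (startsWith(body, "/")) {                     # qualifier
        eq <- regexpr("=", body, fixed = TRUE)
        if (eq > 0) {
          qual_name <- substr(body, 2L, eq - 1L)
          val <- gsub("^\"|\"$", "", substring(body, eq + 1L))
        } else {
          qual_name <- substring(body, 2L)
          val <- ""
        }
        cur$qualifiers[[qual_name]] <- val
      } else if (!is.null(qual_name)) {                # qualifier continuation
        cur$qualifiers[[qual_name]] <-
          paste(cur$qualifiers[[qual_name]], gsub("\"$", "", body))
      } else {                                          # location continuation
        cur$location <- paste0(cur$location, body)
      }
    }
  }
  if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
  feats
}

# returns list(start, end, strand) with end possibly > L for an
# origin-spanning feature on a circular genome, or NULL if unsupported
parseGenBankLocation <- function(loc, L, circular) {
  loc <- gsub("\\s", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    segs <- strsplit(inner, ",", fixed = TRUE)[[1]]
    iv <- lapply(segs, parseGenBankInterval)
    if (any(vapply(iv, is.null, TRUE))) return(NULL)
    if (length(iv) == 2L && circular &&
        iv[[1]]$end == L && iv[[2]]$start == 1L) {
      # origin-spanning join: unroll past the origin
      return(list(start = iv[[1]]$start, end = iv[[2]]$end + L,
                  strand = strand))
    }
    return(NULL)
  }
  iv <- parseGenBankInterval(loc)
  if (is.null(iv)) return(NULL)
  list(start = iv$start, end = iv$end, strand = strand)
}

parseGenBankInterval <- function(x) {
  x <- gsub("[<>]", "", x)
  if (!grepl("^[0-9]+\\.\\.[0-9]+$", x)) return(NULL)
  parts <- as.integer(strsplit(x, "..", fixed = TRUE)[[1]])
  list(start = parts[1], end = parts[2])
}

#' Write a GenomeRecord as a GenBank flat file
#'
#' Emits LOCUS topology, one CDS feature per ORF (with `/gene` and
#' `/locus_tag`), one repeat_region per hr (with `/note`), and the ORIGIN
#' block. The output is readable by [readGenBank()].
#'
#' @param genome a [GenomeRecord-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenBank <- function(genome, path) {
  L <- genomeLength(genome)
  topo <- if (isCircularGenome(genome)) "circular" else "linear"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %-8s VRL",
                     accession(genome), L, topo), con)
  writeLines(sprintf("ACCESSION   %s", accession(genome)), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", L), con)
  gr <- orfs(genome)
  if (length(gr)) {
    for (i in seq_along(gr)) {
      loc <- locationString(start(gr)[i], end(gr)[i],
                            as.character(strand(gr))[i], L)
      writeLines(sprintf("     CDS             %s", loc), con)
      writeLines(sprintf("                     /gene=\"%s\"", gr$name[i]), con)
      writeLines(sprintf("                     /locus_tag=\"%s\"", gr$orf_id[i]), con)
    }
  }
  hr <- hrRegions(genome)
  if (length(hr)) {
    for (i in seq_along(hr)) {
      writeLines(sprintf("     repeat_region   %d..%d", start(hr)[i], end(hr)[i]), con)
      writeLines(sprintf("                     /note=\"%s\"", hr$hr_id[i]), con)
    }
  }
  writeLines("ORIGIN", con)
  s <- genomeSeq(genome)
  pos <- seq(1L, nchar(s), by = 60L)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59L, nchar(s)))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, tolower(paste(groups, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}

locationString <- function(s, e, strand, L) {
  core <- if (e > L) sprintf("join(%d..%d,1..%d)", s, L, e - L) else
    sprintf("%d..%d", s, e)
  if (strand == "-") sprintf("complement(%s)", core) else core
}

#' Read the RPKM / TSS / hr annotation tables
#'
#' All three tables are tab-separated with a header row and 1-based
#' coordinates. `readRpkmTable()` expects columns `orf_id` and `rpkm`;
#' `readTssTable()` expects `orf_id`, `taag_pos` and optionally `motifs`
#' (comma-separated subset of TATA/CAGT/TAAG) and `source`;
#' `readHrTable()` expects `hr_id`, `start`, `end`.
#'
#' @param path path to a TSV file.
#' @return `readRpkmTable()`: a named numeric vector of RPKM values;
#'   `readTssTable()`: a `DataFrame` of TSS annotations;
#'   `readHrTable()`: a data.frame of hr coordinates.
#' @export
readRpkmTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("orf_id", "rpkm")
  if (!all(need %in% names(df)))
    stop("RPKM table must have columns orf_id and rpkm: ", path)
  bad <- which(is.na(suppressWarnings(as.numeric(df$rpkm))))
  if (length(bad))
    stop("malformed rpkm value(s) at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path)
  setNames(as.numeric(df$rpkm), df$orf_id)
}

#' @rdname readRpkmTable
#' @export
readTssTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!nrow(df)) {
    return(DataFrame(orf_id = character(), taag_pos = integer(),
                     motifs = character(), source = character()))
  }
  need <- c("orf_id", "taag_pos")
  if (!all(need %in% names(df)))
    stop("TSS table must have columns orf_id and taag_pos: ", path)
  bad <- which(is.na(suppressWarnings(as.integer(df$taag_pos))))
  if (length(bad))
    stop("malformed taag_pos at line(s) ", paste(bad + 1L, collapse = ", "),
         " of ", path)
  if (!"motifs" %in% names(df)) df$motifs <- ""
  if (!"source" %in% names(df)) df$source <- "table"
  dup <- duplicated(df[, c("orf_id", "taag_pos")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (orf_id, taag_pos) row(s) removed")
    df <- df[!dup, , drop = FALSE]
  }
  DataFrame(orf_id = df$orf_id, taag_pos = as.integer(df$taag_pos),
            motifs = df$motifs, source = df$source)
}

#' @rdname readRpkmTable
#' @export
readHrTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("hr_id", "start", "end")
  if (!all(need %in% names(df)))
    stop("hr table must have columns hr_id, start, end: ", path)
  bad <- which(is.na(suppressWarnings(as.integer(df$start))) |
               is.na(suppressWarnings(as.integer(df$end))))
  if (length(bad))
    stop("malformed coordinates at line(s) ", paste(bad + 1L, collapse = ", "),
         " of ", path)
  data.frame(hr_id = df$hr_id, start = as.integer(df$start),
             end = as.integer(df$end), stringsAsFactors = FALSE)
}

#' Attach RPKM / TSS / hr annotations to a GenomeRecord
#'
#' Merges externally supplied tables into the record. RPKM values are
#' matched by `orf_id`; ids absent from the genome are reported with a
#' warning, never silently dropped. An hr table, when supplied, replaces
#' hr features parsed from the GenBank annotation (with a warning when
#' both exist and disagree).
#'
#' @param genome a [GenomeRecord-class].
#' @param rpkm named numeric vector (from [readRpkmTable()]), or NULL.
#' @param tss a TSS `DataFrame` (from [readTssTable()]), or NULL.
#' @param hrs an hr data.frame (from [readHrTable()]), or NULL.
#' @return the annotated `GenomeRecord`.
#' @export
attachAnnotations <- function(genome, rpkm = NULL, tss = NULL, hrs = NULL) {
  gr <- orfs(genome)
  if (!is.null(rpkm)) {
    unknown <- setdiff(names(rpkm), gr$orf_id)
    if (length(unknown))
      warning("RPKM table ids not present in genome: ",
              paste(unknown, collapse = ", "))
    gr$rpkm <- unname(rpkm[gr$orf_id])
    genome@orfs <- gr
  }
  if (!is.null(tss)) {
    unknown <- setdiff(tss$orf_id, gr$orf_id)
    if (length(unknown))
      warning("TSS table ids not present in genome: ",
              paste(unknown, collapse = ", "))
    genome@tss <- as(tss, "DataFrame")
  }
  if (!is.null(hrs)) {
    if (length(hrRegions(genome)))
      warning("hr table supplied; replacing ", length(hrRegions(genome)),
              " hr feature(s) parsed from the genome annotation")
    si <- Seqinfo(seqnames = accession(genome),
                  seqlengths = genomeLength(genome),
                  isCircular = isCircularGenome(genome))
    genome@hrs <- GRanges(accession(genome), IRanges(hrs$start, hrs$end),
                          hr_id = hrs$hr_id, seqinfo = si)
  }
  validObject(genome)
  genome
}

#' Slice a genome interval, strand- and wrap-aware
#'
#' Returns the coding-strand sequence of the 1-based closed plus-strand
#' interval `[start, end]`; when `wraps = TRUE` (circular genome, interval
#' crossing the origin) the slice concatenates the chromosome tail and
#' head. Minus-strand slices are reverse-complemented.
#'
#' @param genome a [GenomeRecord-class].
#' @param start,end 1-based closed plus-strand interval.
#' @param strand `"+"` or `"-"`.
#' @param wraps does the interval cross the origin?
#' @return a character DNA sequence.
#' @export
sliceGenome <- function(genome, start, end, strand = "+", wraps = FALSE) {
  L <- genomeLength(genome)
  if (wraps && !isCircularGenome(genome))
    stop("wrapped interval on a linear genome")
  if (start < 1L || start > L || end < 1L || end > L)
    stop(sprintf("interval [%d, %d] out of range for genome of length %d",
                 start, end, L))
  s <- plusSlice(genomeSeq(genome), start, end, wraps)
  if (strand == "-") revComp(s) else s
}

#' Write extracted regions to FASTA
#'
#' Headers encode `orf_id|kind|start-end|strand`; sequences are the
#' coding-strand-oriented region sequences. Duplicate headers are suffixed
#' (with a warning) so every record stays addressable.
#'
#' @param regions a [RegionSet-class].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
writeRegionsFasta <- function(regions, path) {
  if (!length(regions)) stop("no regions to write")
  info <- regionInfo(regions)
  headers <- sprintf("%s|%s|%d-%d|%s", info$orf_id, info$kind,
                     info$start, info$end, info$strand)
  if (anyDuplicated(headers)) {
    warning("duplicate FASTA headers suffixed: ",
            paste(unique(headers[duplicated(headers)]), collapse = ", "))
    headers <- make.unique(headers, sep = "_dup")
  }
  seqs <- regionSequences(regions)
  names(seqs) <- headers
  writeXStringSet(seqs, path)
  invisible(path)
}
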