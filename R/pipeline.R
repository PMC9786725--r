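# Full-analysis orchestration and the genome-anchored reference checks.

#' Default pipeline configuration
#'
#' All tunables of the full analysis with their shipped defaults: the
#' class scheme, the 225 nt upstream window, TIS flank -10..+6, TSS flank
#' -15..+15, the two query octamers (upstream 5'-ATTGCAAG-3', downstream
#' 5'-ATTAGGAA-3'), a Hamming tolerance of 2, Welch pairwise tests, and
#' the 0.5/0.8 conservation thresholds.
#'
#' @param ... overrides of any default.
#' @return a config list for [runPipeline()].
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    genbank = NULL, rpkm = NULL, tss = NULL, hr = NULL,
    outDir = NULL,
    scheme = defaultClassScheme(),
    upstreamWindow = 225L,
    tisFlank = c(up = 10L, down = 6L),
    tssFlank = c(up = 15L, down = 15L),
    octamers = c(upstream = "ATTGCAAG", downstream = "ATTAGGAA"),
    maxMismatches = 2L,
    testMethod = "welch",
    plurality = 0.5, secondary = 0.25,
    conservedThreshold = 0.5, highThreshold = 0.8,
    circularDistance = FALSE,
    curatedExclusions = c("polh", "p10"),
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path a YAML file whose keys are [pipelineConfig()] arguments.
#' @return a config list.
#' @export
readPipelineConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipelineConfig, vals)
}

#' Run the full promoter-landscape analysis
#'
#' Stages, in order: load and annotate the genome; classify ORFs by RPKM;
#' extract 5'UTRs, upstream windows and TIS/TSS flanks; scan the octamers
#' per region and genome-wide; per-class 5'UTR composition statistics;
#' hr-to-ORF distances; per-class consensus sequences. Partial inputs
#' degrade gracefully: without a TSS table the TSS-anchored stages are
#' skipped, without RPKM the classification-dependent stages are skipped;
#' every skip is logged. All tables are written as TSV, the summary as
#' JSON (carrying an MD5 hash of the configuration), and a run log
#' records every default in effect.
#'
#' @param config a list from [pipelineConfig()] or a path to a YAML file.
#' @param genome optionally, an already-built [GenomeRecord-class]
#'   (overrides the file inputs).
#' @return invisibly, a list with the `genome`, all stage results and the
#'   `summary` written to JSON.
#' @export
runPipeline <- function(config = pipelineConfig(), genome = NULL) {
  if (is.character(config)) config <- readPipelineConfig(config)
  outDir <- config$outDir %||% tempfile("promoter_report_")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  log <- character()
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }

  # the hash covers the analysis parameters, not the output location
  hashable <- config[setdiff(names(config), "outDir")]
  cfg_json <- jsonlite::toJSON(
    hashable[!vapply(hashable, is.null, TRUE)], auto_unbox = TRUE,
    digits = NA, dataframe = "columns", force = TRUE)
  cfg_path <- file.path(outDir, "config.json")
  writeLines(cfg_json, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  note("config hash %s", cfg_hash)
  for (key in c("upstreamWindow", "maxMismatches", "testMethod",
                "plurality", "highThreshold", "seed"))
    note("config %s = %s", key, paste(config[[key]], collapse = ","))

  # -- load ------------------------------------------------------------
  if (is.null(genome)) {
    if (is.null(config$genbank)) stop("[load] no genome supplied")
    genome <- readGenBank(config$genbank)
    rpkm <- if (!is.null(config$rpkm)) readRpkmTable(config$rpkm) else NULL
    tss <- if (!is.null(config$tss)) readTssTable(config$tss) else NULL
    hrs <- if (!is.null(config$hr)) readHrTable(config$hr) else NULL
    genome <- attachAnnotations(genome, rpkm = rpkm, tss = tss, hrs = hrs)
  }
  note("[load] %s: %d nt, %d ORFs, %d hr regions, %d TSS annotations",
       accession(genome), genomeLength(genome), length(orfs(genome)),
       length(hrRegions(genome)), nrow(tssAnnotations(genome)))
  hasRpkm <- any(!is.na(orfs(genome)$rpkm))
  hasTss <- nrow(tssAnnotations(genome)) > 0L
  results <- list(config_hash = cfg_hash)

  # -- classify --------------------------------------------------------
  if (hasRpkm) {
    cls <- suppressWarnings(classifyOrfs(genome, config$scheme))
    genome <- cls$genome
    results$classification <- cls
    write.table(cls$table, file.path(outDir, "classes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    note("[classify] tally: %s",
         paste(sprintf("%s=%d", names(cls$tally), cls$tally), collapse = " "))
  } else {
    note("[classify] skipped: no RPKM values (scan-only mode)")
  }

  # -- extract ---------------------------------------------------------
  regions <- list()
  if (hasTss) {
    for (kind in c("utr5", "upstream", "tss_flank")) {
      regions[[kind]] <- suppressWarnings(extractRegionSet(
        genome, kind, window = config$upstreamWindow,
        up = config$tssFlank[["up"]], down = config$tssFlank[["down"]]))
    }
  } else {
    note("[extract] TSS-anchored kinds skipped: no TSS annotations")
  }
  regions$tis_flank <- extractRegionSet(
    genome, "tis_flank", up = config$tisFlank[["up"]],
    down = config$tisFlank[["down"]])
  for (kind in names(regions)) {
    if (length(regions[[kind]]))
      writeRegionsFasta(regions[[kind]],
                        file.path(outDir, paste0(kind, ".fasta")))
  }
  results$regions <- regions
  note("[extract] %s", paste(sprintf("%s: %d", names(regions),
       vapply(regions, length, 1L)), collapse = ", "))

  # -- scan ------------------------------------------------------------
  scans <- list()
  for (nm in names(config$octamers)) {
    q <- config$octamers[[nm]]
    scans[[nm]] <- list(
      exact = genomeScan(genome, q, 0L),
      fuzzy = genomeScan(genome, q, config$maxMismatches))
    if (!is.null(regions$upstream) && length(regions$upstream)) {
      prt <- perRegionMatchTable(regions$upstream, q, config$maxMismatches)
      scans[[nm]]$per_region <- prt
      scans[[nm]]$shared <- sharedOctamers(prt$matchList)
      write.table(prt$table,
                  file.path(outDir, sprintf("matches_%s.tsv", nm)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    note("[scan] %s (%s): exact %d, <=%dmm %d (%.2f/kbp)", nm, q,
         totalMatches(scans[[nm]]$exact), config$maxMismatches,
         totalMatches(scans[[nm]]$fuzzy), ratePerKbp(scans[[nm]]$fuzzy))
  }
  results$scans <- scans
  if (hasRpkm && hasTss) {
    results$motif_presence <- motifPresenceByClass(genome, config$scheme)
    write.table(results$motif_presence,
                file.path(outDir, "motif_presence.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  # -- composition -----------------------------------------------------
  if (hasRpkm && hasTss) {
    comp <- tryCatch(
      compositionByClass(genome, method = config$testMethod),
      error = function(e) { note("[stats] skipped: %s", conditionMessage(e)); NULL })
    if (!is.null(comp)) {
      results$composition <- comp
      write.table(comp$table, file.path(outDir, "utr_composition.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(comp$at_tests, file.path(outDir, "at_tests.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  } else {
    note("[stats] skipped: needs both RPKM and TSS annotations")
  }

  # -- hr distances ----------------------------------------------------
  if (length(hrRegions(genome))) {
    hrd <- hrDistanceTable(genome, circular = config$circularDistance)
    results$hr_distances <- hrd
    write.table(hrd$pairs, file.path(outDir, "hr_distances.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    grDevices::png(file.path(outDir, "genome_map.png"), width = 900,
                   height = 900)
    if (hasRpkm) classGenomeMap(genome, config$scheme)
    else classGenomeMap(genome)
    grDevices::dev.off()
  } else {
    note("[hrmap] skipped: no hr regions")
  }

  # -- consensus -------------------------------------------------------
  if (hasRpkm) {
    cons <- list(tis = classConsensus(genome, "tis",
                                      plurality = config$plurality,
                                      secondary = config$secondary,
                                      conservedThreshold = config$conservedThreshold,
                                      highThreshold = config$highThreshold))
    if (hasTss) {
      cons$tss <- classConsensus(genome, "tss",
                                 plurality = config$plurality,
                                 secondary = config$secondary,
                                 conservedThreshold = config$conservedThreshold,
                                 highThreshold = config$highThreshold)
    }
    results$consensus <- cons
    cons_lines <- unlist(lapply(names(cons), function(anch)
      vapply(cons[[anch]], function(cr)
        sprintf("%s\t%s\t%s", anch, cr@label, cr@consensus), "")))
    writeLines(c("anchor\tclass\tconsensus", cons_lines),
               file.path(outDir, "consensus.tsv"))
  }

  # -- summary ---------------------------------------------------------
  summary <- list(
    schema_version = "1.0",
    config_hash = cfg_hash,
    accession = accession(genome),
    genome_length = genomeLength(genome),
    n_orfs = length(orfs(genome)),
    n_hrs = length(hrRegions(genome)),
    class_tally = if (hasRpkm) as.list(results$classification$tally),
    scan_totals = lapply(scans, function(s) list(
      exact = totalMatches(s$exact), fuzzy = totalMatches(s$fuzzy),
      rate_per_kbp = ratePerKbp(s$fuzzy))),
    consensus = if (!is.null(results$consensus))
      lapply(results$consensus, function(a)
        lapply(a, function(cr) cr@consensus)))
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(log, file.path(outDir, "run.log"))
  results$summary <- summary
  results$outDir <- outDir
  results$genome <- genome
  invisible(results)
}

#' Genome-anchored octamer checks
#'
#' Recomputes, for a supplied annotated genome and TSS table, the
#' reference quantities of the octamer analysis: exact genome-wide match
#' counts of the upstream (ATTGCAAG) and downstream (ATTAGGAA) octamers
#' and how many fall outside the named upstream promoter windows
#' ("additional" matches), the 2-mismatch genome-wide totals with their
#' per-kbp rates, and the octamer spacing distances (gap to the ATG;
#' distance to the TAAG) for the named ORFs. For the AcMNPV reference
#' genome the named ORFs are p6.9 and vp39; the helper script in
#' `inst/scripts/fetch_reference.R` documents how to obtain the accession.
#'
#' @param genome an annotated [GenomeRecord-class] with TSS annotations.
#' @param orfNames ORF names/ids whose upstream windows anchor the check.
#' @param octamers named queries (default upstream/downstream octamers).
#' @param window upstream window width.
#' @param maxMismatches fuzzy tolerance.
#' @param taagFrom spacing convention (see [octamerSpacingReport()]).
#' @return a list: per octamer, `exact_total`, `additional`,
#'   `fuzzy_total`, `fuzzy_rate_per_kbp`, `per_strand`; plus `spacings`,
#'   a data.frame of per-ORF spacing rows.
#' @export
referenceOctamerChecks <- function(genome, orfNames = c("p6.9", "vp39"),
                                   octamers = c(upstream = "ATTGCAAG",
                                                downstream = "ATTAGGAA"),
                                   window = 225L, maxMismatches = 2L,
                                   taagFrom = "3p") {
  gr <- orfs(genome)
  ids <- gr$orf_id[gr$orf_id %in% orfNames | gr$name %in% orfNames]
  if (!length(ids)) stop("none of the named ORFs found in the genome")
  upstreams <- suppressWarnings(
    extractRegionSet(genome, "upstream", orfIds = ids, window = window))
  out <- list()
  for (nm in names(octamers)) {
    q <- octamers[[nm]]
    exact <- genomeScan(genome, q, 0L)
    fuzzy <- genomeScan(genome, q, maxMismatches)
    extra <- additionalMatches(exact, upstreams)
    out[[nm]] <- list(
      exact_total = totalMatches(exact),
      inside_named_upstreams = extra$inside,
      additional = extra$additional,
      fuzzy_total = totalMatches(fuzzy),
      fuzzy_rate_per_kbp = ratePerKbp(fuzzy),
      per_strand = c(plus = fuzzy@plusCount, minus = fuzzy@minusCount))
  }
  spac <- list()
  for (id in ids) {
    for (nm in names(octamers)) {
      rep <- octamerSpacingReport(genome, id, octamers[[nm]],
                                  window = window, taagFrom = taagFrom)
      if (nrow(rep)) {
        rep$octamer_role <- nm
        spac[[length(spac) + 1L]] <- rep
      }
    }
  }
  out$spacings <- if (length(spac)) do.call(rbind, spac) else
    data.frame()
  out
}
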