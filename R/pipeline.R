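#' Pipeline configuration
#'
#' Bundles everything one end-to-end run needs: the synthetic-cohort
#' configuration (or paths to real inputs loaded via [readSVVcf()] /
#' [readSampleManifest()]), filter thresholds, unification rule, centromere
#' track and output directory. The seed is recorded in all outputs.
#'
#' @param seed Integer seed driving every stochastic stage.
#' @param sim A [simConfig()]; defaults to the standard synthetic study at
#'   this seed.
#' @param filters A filter configuration ([defaultFilterConfig()]).
#' @param unify A [unifyRule()].
#' @param centromeres `GRanges` of centromere intervals; default places a
#'   50 kb centromere mid-contig on each synthetic contig.
#' @param outdir Output directory (created if needed).
#' @param doCompare,doLd,doIrs Toggle the comparison, LD-tagging and
#'   intensity-validation stages.
#' @return A list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(seed, sim = simConfig(seed = seed),
                           filters = defaultFilterConfig(),
                           unify = unifyRule(), centromeres = NULL,
                           outdir = tempfile("svharmony_run_"),
                           doCompare = TRUE, doLd = TRUE, doIrs = TRUE) {
  if (missing(seed)) .stopf("pipelineConfig requires a seed")
  if (is.null(centromeres)) {
    mid <- vapply(sim$contigs, function(L) round(L / 2), numeric(1))
    centromeres <- GRanges(names(sim$contigs),
                           IRanges(mid - 25000, mid + 25000))
  }
  structure(list(seed = seed, sim = sim, filters = filters, unify = unify,
                 centromeres = centromeres, outdir = outdir,
                 doCompare = doCompare, doLd = doLd, doIrs = doIrs),
            class = "PipelineConfig")
}

# Stable serialisation of the config for hashing (drop environments etc.).
.configHash <- function(config) {
  clean <- rapply(unclass(config), function(v) {
    if (inherits(v, "GRanges")) {
      paste(as.character(seqnames(v)), start(v), end(v), collapse = ";")
    } else v
  }, how = "replace")
  clean$outdir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(clean, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

.writeTsv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Write a VCF without the volatile fileDate line and with the config hash.
.writeVcfStable <- function(x, path, hash) {
  writeSVVcf(x, path)
  lines <- readLines(path)
  lines <- lines[!grepl("^##fileDate=", lines)]
  ff <- grepl("^##fileformat=", lines)
  lines <- c(lines[ff], sprintf("##config_hash=%s", hash), lines[!ff])
  writeLines(lines, path)
  invisible(path)
}

#' Replace stitched constituents by their stitch breakpoints
#'
#' Builds the post-stitching call set: constituent records are marked
#' `constituent` and replaced by one breakpoint record per stitch cluster
#' spanning the first constituent's start to the last one's end. The
#' breakpoint's genotype row is taken from its highest-GSCNQUAL
#' constituent (a stand-in for re-genotyping the new interval) and each
#' stitch is validated with [validateStitch()]; clusters failing validation
#' are unstitched (constituents restored).
#'
#' @param x The [SVCallSet-class] that was stitched.
#' @param stitch Output of [stitchGenomestrip()].
#' @return List: `callset` (stitched call set), `stitches` (with final
#'   status).
#' @export
applyStitches <- function(x, stitch) {
  st <- stitch$stitches
  if (!nrow(st)) return(list(callset = x, stitches = st))
  ids <- siteId(x)
  cn <- cnMatrix(x); lq <- lqMatrix(x)
  gs <- stats::setNames(qualMetric(x, "GSCNQUAL"), ids)
  drop <- character(); recs <- list(); cnRows <- list(); gtRows <- list()
  for (k in seq_len(nrow(st))) {
    mem <- stitch$members$site_id[stitch$members$stitch_id == st$stitch_id[k]]
    mi <- match(mem, ids)
    best <- mem[order(-ifelse(is.na(gs[mem]), -Inf, gs[mem]), mem)][1]
    row <- cn[match(best, ids), ]
    lqf <- if (!is.null(lq)) mean(lq[mi, , drop = FALSE], na.rm = TRUE) else 0
    status <- validateStitch(row, cn[mi, , drop = FALSE], lqf,
                             isNew = !st$is_preexisting[k])
    st$status[k] <- status
    if (status == "stitched") {
      drop <- c(drop, mem)
      recs[[length(recs) + 1L]] <- data.frame(
        site_id = st$stitch_id[k], chrom = st$chrom[k], start = st$start[k],
        end = st$end[k], svtype = svType(x)[mi[1]],
        GSCNQUAL = max(gs[mem], na.rm = TRUE),
        cluster_id = rowData(x)$cluster_id[mi[1]] %||% NA_character_,
        stringsAsFactors = FALSE)
      cnRows[[length(cnRows) + 1L]] <- row
      gtRows[[length(gtRows) + 1L]] <- gtMatrix(x)[match(best, ids), ]
    }
  }
  keep <- x[!(ids %in% drop), ]
  if (length(recs)) {
    df <- do.call(rbind, recs)
    cnM <- do.call(rbind, cnRows); colnames(cnM) <- colnames(x)
    gtM <- do.call(rbind, gtRows); colnames(gtM) <- colnames(x)
    new <- SVCallSet(GRanges(df$chrom, IRanges(df$start, df$end)),
                     siteId = df$site_id, caller = "genomestrip",
                     svtype = df$svtype,
                     quality = df[, "GSCNQUAL", drop = FALSE],
                     gt = gtM, cn = cnM,
                     sampleInfo = as.data.frame(colData(x)))
    rowData(new)$cluster_id <- df$cluster_id
    out <- .rbindCallSets(list(keep, new))
  } else {
    out <- keep
  }
  list(callset = out, stitches = st)
}

#' Run the full harmonization pipeline
#'
#' Stage order: synthetic-cohort generation, per-caller hard filters,
#' within-caller deduplication, long-CNV cross-sample clustering, stitching
#' of fragmented read-depth CNVs, cross-caller unification, cohort QC
#' (batch and HWE flags annotate rather than remove), replication-rate
#' annotation, and the optional comparison / LD / intensity-validation
#' stages. Every output file carries the configuration hash; a rerun with
#' the same configuration is byte-identical.
#'
#' @param config A [pipelineConfig()].
#' @return Invisibly, a list with the final call set, per-stage tables and
#'   output paths.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- .configHash(config)
  log <- character()
  say <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  say("svharmony run: seed=%d config_hash=%s", config$seed, hash)

  ## simulate
  cohort <- stage("simulate", simulateCohort(config$sim))
  truth <- stage("simulate", simulateTruth(config$sim, cohort))
  views <- stage("simulate", emitCallerViews(truth, config$sim))
  say("cohort: %d samples, %d replicate pairs", nrow(cohort$samples),
      nrow(cohort$pairs))
  for (v in names(views)) say("view %s: %d records", v, nrow(views[[v]]))

  ## per-caller filters
  filt <- list()
  reports <- list()
  if (!is.null(views$speedseq)) {
    r <- stage("filter", filterSpeedseq(views$speedseq, config$filters))
    filt$speedseq <- r$callset; reports$speedseq <- r$report
  }
  if (!is.null(views$genomestrip)) {
    r <- stage("filter", filterGenomestrip(views$genomestrip, config$filters))
    filt$genomestrip <- r$callset; reports$genomestrip <- r$report
  }
  if (!is.null(views$gs_lcnv)) {
    r <- stage("filter", suppressWarnings(
      filterLcnv(views$gs_lcnv, config$filters, config$centromeres)))
    filt$gs_lcnv <- r$callset; reports$gs_lcnv <- r$report
  }
  if (!is.null(views$melt)) {
    r <- stage("filter", filterMelt(views$melt, config$filters))
    filt$melt <- r$callset; reports$melt <- r$report
  }
  if (!is.null(views$hipstr)) {
    r <- stage("filter", filterHipstr(views$hipstr, config$filters))
    filt$hipstr <- r$callset; reports$hipstr <- r$report
  }
  for (cal in intersect(c("wham", "manta"), names(views))) {
    r <- stage("filter", filterQual(views[[cal]], config$filters))
    filt[[cal]] <- r$callset; reports[[cal]] <- r$report
  }
  for (v in names(filt)) {
    say("filter %s: %d kept / %d", v, nrow(filt[[v]]), nrow(views[[v]]))
  }

  ## within-caller dedup, LCNV clustering, stitching
  ssd <- stage("dedup", dedupSpeedseq(filt$speedseq))
  say("speedseq dedup: %d clusters, %d nonredundant",
      length(unique(ssd$clusters$cluster_id)), nrow(ssd$nonredundant))
  lcnvMerged <- NULL
  if (!is.null(filt$gs_lcnv) && nrow(filt$gs_lcnv)) {
    lcnvMerged <- stage("dedup", clusterLcnv(filt$gs_lcnv))
    say("lcnv clustering: %d records -> %d sites", nrow(filt$gs_lcnv),
        nrow(lcnvMerged$callset))
  }
  stitch <- stage("stitch", stitchGenomestrip(filt$genomestrip))
  stitched <- stage("stitch", applyStitches(filt$genomestrip, stitch))
  say("stitching: %d stitch clusters (%d stitched)",
      nrow(stitch$stitches), sum(stitched$stitches$status == "stitched"))

  ## cross-caller unification
  graph <- stage("unify", buildUnifyGraph(stitched$callset,
                                          ssd$nonredundant, config$unify))
  unified <- stage("unify", assembleNonredundant(graph))
  say("unify: %d clusters; %d nonredundant CNV/SV sites",
      length(unique(graph$clusters$cluster_id)), nrow(unified$nonredundant))
  final <- unified$nonredundant

  ## cohort QC (flags annotate, never remove)
  unrelated <- cohort$samples$sample_id[!duplicated(cohort$samples$donor_id)]
  batch <- stage("qc", batchEffectTest(final, unrelated))
  final <- attr(batch, "callset")
  hwe <- stage("qc", hweTestSites(final, unrelated))
  final <- attr(hwe, "callset")
  cps <- stage("qc", callsPerSample(final))
  af <- stage("qc", afByStudy(final, unrelated))
  say("qc: %d batch-flagged, %d hwe-flagged, study NMAF r=%.3f",
      sum(batch$flagged), sum(hwe$flagged), af$r)

  ## replication-rate annotation
  rr <- stage("rr", rrTable(final, cohort$pairs))
  rowData(final)$rr <- rr$rr
  rowData(final)$n_informative <- rr$n_informative
  say("rr: mean %.3f over %d segregating sites",
      mean(rr$rr, na.rm = TRUE), sum(rr$segregating))

  ## optional comparisons
  compareRes <- ldRes <- irsRes <- NULL
  if (isTRUE(config$doCompare)) {
    ext <- truth$sites
    extGr <- GRanges(ext$chrom, IRanges(ext$start, ext$end))
    extGr$svtype <- ext$svtype
    names(extGr) <- ext$truth_id
    compareRes <- stage("compare", coDiscovery(
      final, extGr, queryNmaf = {
        afq <- afByStudy(final, unrelated)$table$nmaf
        afq
      }))
    say("compare: %d of %d final sites co-discovered with the truth set",
        length(unique(compareRes$matches$query_id)), nrow(final))
  }
  if (isTRUE(config$doLd)) {
    snp <- stage("ld", emitSnpPanel(truth, cohort, config$sim))
    eur <- cohort$samples$sample_id[cohort$samples$superpopulation == "EUR"]
    ldRes <- stage("ld", ldTagging(final, snp$gt, snp$positions,
                                   samples = eur))
    tagged <- !is.na(ldRes$max_r2) & ldRes$max_r2 > 0.8
    say("ld: %d/%d sites tagged at R2 > 0.8", sum(tagged), nrow(ldRes))
  }
  if (isTRUE(config$doIrs)) {
    probes <- stage("irs", emitProbeIntensities(truth, cohort, config$sim))
    irsRes <- stage("irs", irsTest(filt$genomestrip, probes$intensity,
                                   probes$probes, probes$covariates))
    say("irs: %d sites tested, FDR estimate %.4f", irsRes$n_tested, irsRes$fdr)
  }

  ## outputs
  paths <- list(
    final_vcf = file.path(config$outdir, "final.vcf"),
    manifest = file.path(config$outdir, "samples.tsv"),
    pairs = file.path(config$outdir, "pairs.tsv"),
    rr = file.path(config$outdir, "rr.tsv"),
    clusters = file.path(config$outdir, "clusters.tsv"),
    stitches = file.path(config$outdir, "stitches.tsv"),
    qc = file.path(config$outdir, "qc_flags.tsv"),
    calls_per_sample = file.path(config$outdir, "calls_per_sample.tsv"),
    log = file.path(config$outdir, "run.log"),
    summary = file.path(config$outdir, "run_summary.json"))
  .writeVcfStable(final, paths$final_vcf, hash)
  .writeTsv(cohort$samples, paths$manifest, hash)
  .writeTsv(cohort$pairs, paths$pairs, hash)
  .writeTsv(rr, paths$rr, hash)
  allClusters <- rbind(
    cbind(stage = "speedseq_dedup", ssd$clusters[, c("cluster_id", "site_id", "role")]),
    cbind(stage = "unify",
          graph$clusters[, c("cluster_id", "site_id")],
          role = ifelse(graph$clusters$site_id %in%
                        unified$assignments$site_id[unified$assignments$role == "primary"],
                        "primary", "secondary")))
  .writeTsv(allClusters, paths$clusters, hash)
  .writeTsv(stitched$stitches, paths$stitches, hash)
  qcTab <- data.frame(site_id = siteId(final),
                      batch_p = batch$p, batch_flag = batch$flagged,
                      hwe_p = hwe$p, hwe_flag = hwe$flagged)
  .writeTsv(qcTab, paths$qc, hash)
  .writeTsv(cps, paths$calls_per_sample, hash)
  if (!is.null(ldRes)) {
    paths$ld <- file.path(config$outdir, "ld_tagging.tsv")
    .writeTsv(ldRes, paths$ld, hash)
  }
  if (!is.null(irsRes)) {
    paths$irs <- file.path(config$outdir, "irs.tsv")
    .writeTsv(irsRes$table, paths$irs, hash)
  }
  writeLines(log, paths$log)
  summary_ <- list(seed = config$seed, config_hash = hash,
                   n_samples = nrow(cohort$samples),
                   n_pairs = nrow(cohort$pairs),
                   n_truth_sites = nrow(truth$sites),
                   n_final_sites = nrow(final),
                   mean_rr = mean(rr$rr, na.rm = TRUE),
                   n_batch_flagged = sum(batch$flagged),
                   n_hwe_flagged = sum(hwe$flagged),
                   irs_fdr = if (!is.null(irsRes)) irsRes$fdr else NULL)
  jsonlite::write_json(summary_, paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(final = final, truth = truth, cohort = cohort,
                 views = views, filtered = filt, reports = reports,
                 dedup = ssd, lcnv = lcnvMerged, stitch = stitched,
                 graph = graph, unified = unified, rr = rr, batch = batch,
                 hwe = hwe, calls_per_sample = cps, af = af,
                 compare = compareRes, ld = ldRes, irs = irsRes,
                 paths = paths, config_hash = hash, log = log))
}
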