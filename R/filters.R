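# Per-caller hard filters. Every filter returns list(callset, report):
# the report accounts for every input record exactly once, with an ordered
# character vector of failed-rule reason codes ("" when kept), and the
# callset is the surviving subset (genotype-level filters may instead mask
# cells). Filters are idempotent.

.mkReport <- function(siteIds, reasons, caller) {
  kept <- !vapply(reasons, length, integer(1))
  rep_ <- data.frame(site_id = siteIds, kept = kept,
                     reasons = vapply(reasons, paste, character(1),
                                      collapse = ";"),
                     stringsAsFactors = FALSE)
  attr(rep_, "caller") <- caller
  rep_
}

.applyReport <- function(x, report) {
  keep <- report$kept[match(siteId(x), report$site_id)]
  x[keep, ]
}

.missingRate <- function(x) {
  gt <- gtMatrix(x)
  if (is.null(gt) || ncol(x) == 0) return(rep(0, nrow(x)))
  rowMeans(is.na(gt))
}

#' SpeedSeq standard and MSQ filters
#'
#' Applies, in order: (1) deletions shorter than 418 bp must have split-read
#' support (SR > 0); (2) non-BND events must be at least 50 bp; (3) BND
#' calls need 25% of their supporting evidence (SU) from split or paired-end
#' reads; (4) inversions with QUAL > 100 need at least 10% split/paired-end
#' evidence; (5) sites with more than 10% missing genotypes are removed; and
#' (6) class-specific MSQ thresholds (strictly greater): DEL/rMEI 20, DUP
#' 100, INV 90, BND 90. All thresholds come from `config$speedseq` and are
#' overridable.
#'
#' @param x An [SVCallSet-class] of SpeedSeq records.
#' @param config A filter configuration, see [defaultFilterConfig()].
#' @return `list(callset, report)`; the report lists every record with its
#'   ordered failed-rule reason codes.
#' @export
filterSpeedseq <- function(x, config = defaultFilterConfig()) {
  if (!all(svCaller(x) == "speedseq")) .stopf("records are not speedseq calls")
  cfg <- config$speedseq
  tp <- svType(x); len <- svLen(x)
  msq <- qualMetric(x, "MSQ"); qual <- qualMetric(x, "QUAL")
  su <- qualMetric(x, "SU"); sr <- qualMetric(x, "SR"); pe <- qualMetric(x, "PE")
  supFrac <- ifelse(!is.na(su) & su > 0, (ifelse(is.na(sr), 0, sr) +
                                          ifelse(is.na(pe), 0, pe)) / su, NA)
  missRate <- .missingRate(x)
  reasons <- vector("list", nrow(x))
  add <- function(i, code) reasons[[i]] <<- c(reasons[[i]], code)
  for (i in seq_len(nrow(x))) {
    if (tp[i] == "DEL" && !is.na(len[i]) && len[i] < cfg$del_sr_len &&
        (is.na(sr[i]) || sr[i] == 0)) add(i, "del_short_no_sr")
    if (tp[i] != "BND" && !is.na(len[i]) && len[i] < cfg$min_len) add(i, "min_len")
    if (tp[i] == "BND" &&
        (is.na(supFrac[i]) || supFrac[i] < cfg$bnd_support_frac)) {
      add(i, "bnd_support")
    }
    if (tp[i] == "INV" && !is.na(qual[i]) && qual[i] > cfg$inv_qual &&
        (is.na(supFrac[i]) || supFrac[i] < cfg$inv_support_frac)) {
      add(i, "inv_support")
    }
    if (missRate[i] > cfg$max_missing) add(i, "missing_rate")
    thr <- cfg$msq[tp[i]]
    if (!is.na(thr)) {
      if (is.na(msq[i])) add(i, "no_msq")
      else if (msq[i] <= thr) add(i, paste0("msq_", tp[i]))
    }
  }
  report <- .mkReport(siteId(x), reasons, "speedseq")
  list(callset = .applyReport(x, report), report = report)
}

#' MELT hard-flag and tranche filter
#'
#' Removes records carrying any flag among the exclusion set (lc, s25, rSD,
#' hDP) and requires the ASSESS quality tranche to equal 5.
#'
#' @inheritParams filterSpeedseq
#' @export
filterMelt <- function(x, config = defaultFilterConfig()) {
  if (!all(svCaller(x) == "melt")) .stopf("records are not MELT calls")
  cfg <- config$melt
  fl <- as.list(meltFlags(x))
  assess <- qualMetric(x, "ASSESS")
  reasons <- vector("list", nrow(x))
  for (i in seq_len(nrow(x))) {
    hit <- intersect(fl[[i]], cfg$exclude_flags)
    if (length(hit)) reasons[[i]] <- c(reasons[[i]], paste0("flag_", sort(hit)))
    if (is.na(assess[i]) || assess[i] != cfg$assess) {
      reasons[[i]] <- c(reasons[[i]], "assess")
    }
  }
  report <- .mkReport(siteId(x), reasons, "melt")
  list(callset = .applyReport(x, report), report = report)
}

#' Genome STRiP CNVDiscovery site filters
#'
#' Requires a minimum GSCNQUAL per class (DEL 2, mCNV 12, DUP 14;
#' at-least comparisons), removes sites monoallelic across the cohort (all
#' non-missing copy numbers identical), and removes sites with more than 10%
#' of non-iPSC genotypes flagged low-quality (the LQ format field). iPSC
#' samples are excluded from the LQ fraction because they are genotyped
#' outside discovery.
#'
#' @inheritParams filterSpeedseq
#' @param nonIpscSamples Character vector of non-iPSC sample ids (must be
#'   non-empty).
#' @export
filterGenomestrip <- function(x, config = defaultFilterConfig(),
                              nonIpscSamples = NULL) {
  if (!all(svCaller(x) == "genomestrip")) .stopf("records are not Genome STRiP calls")
  cfg <- config$genomestrip
  if (is.null(nonIpscSamples) && "cell_type" %in% colnames(colData(x))) {
    nonIpscSamples <- colnames(x)[colData(x)$cell_type != "iPSC"]
  }
  if (!length(nonIpscSamples)) .stopf("non-iPSC sample set is empty")
  nonIpsc <- intersect(nonIpscSamples, colnames(x))
  gs <- qualMetric(x, "GSCNQUAL")
  cn <- cnMatrix(x); lq <- lqMatrix(x); tp <- svType(x)
  reasons <- vector("list", nrow(x))
  for (i in seq_len(nrow(x))) {
    thr <- cfg$gscnqual[tp[i]]
    if (!is.na(thr) && (is.na(gs[i]) || gs[i] < thr)) {
      reasons[[i]] <- c(reasons[[i]], paste0("gscnqual_", tp[i]))
    }
    if (!is.null(cn) && ncol(x) > 0) {
      v <- cn[i, ][!is.na(cn[i, ])]
      if (length(v) && length(unique(v)) == 1L) {
        reasons[[i]] <- c(reasons[[i]], "monoallelic")
      }
    }
    if (!is.null(lq) && length(nonIpsc)) {
      frac <- mean(lq[i, nonIpsc], na.rm = TRUE)
      if (!is.nan(frac) && frac > cfg$max_lq_frac) {
        reasons[[i]] <- c(reasons[[i]], "lq_fraction")
      }
    }
  }
  report <- .mkReport(siteId(x), reasons, "genomestrip")
  list(callset = .applyReport(x, report), report = report)
}

#' Long-CNV (read-depth, per-sample) filters
#'
#' Requires NBINS >= 10 and SCORE >= 1000; removes sites entirely contained
#' within a centromere interval or fully containing one; and requires the
#' carrier's absolute copy number to exceed 2.75 for duplications or fall
#' below 1.25 for deletions.
#'
#' @inheritParams filterSpeedseq
#' @param centromeres `GRanges` of centromere intervals; when NULL the
#'   centromere rule is skipped with a warning.
#' @export
filterLcnv <- function(x, config = defaultFilterConfig(), centromeres = NULL) {
  if (!all(svCaller(x) == "gs_lcnv")) .stopf("records are not long-CNV calls")
  cfg <- config$lcnv
  nb <- qualMetric(x, "NBINS"); sc <- qualMetric(x, "SCORE")
  cn <- cnMatrix(x); tp <- svType(x)
  inCentro <- containsCentro <- rep(FALSE, nrow(x))
  if (is.null(centromeres)) {
    .warnf("no centromere track supplied; centromere rule skipped")
  } else {
    gr <- rowRanges(x)
    inCentro <- IRanges::overlapsAny(gr, centromeres, type = "within")
    containsCentro <- rep(FALSE, length(gr))
    hits <- findOverlaps(centromeres, gr, type = "within")
    containsCentro[unique(S4Vectors::subjectHits(hits))] <- TRUE
  }
  reasons <- vector("list", nrow(x))
  for (i in seq_len(nrow(x))) {
    if (is.na(nb[i]) || nb[i] < cfg$min_nbins) {
      reasons[[i]] <- c(reasons[[i]], "nbins")
    }
    if (is.na(sc[i]) || sc[i] < cfg$min_score) {
      reasons[[i]] <- c(reasons[[i]], "score")
    }
    if (inCentro[i] || containsCentro[i]) {
      reasons[[i]] <- c(reasons[[i]], "centromere")
    }
    if (!is.null(cn) && ncol(x) > 0) {
      v <- cn[i, ][!is.na(cn[i, ])]
      if (length(v)) {
        ok <- if (tp[i] == "DUP") max(v) > cfg$dup_min_cn
              else if (tp[i] == "DEL") min(v) < cfg$del_max_cn
              else TRUE
        if (!ok) reasons[[i]] <- c(reasons[[i]], "carrier_cn")
      }
    }
  }
  report <- .mkReport(siteId(x), reasons, "gs_lcnv")
  list(callset = .applyReport(x, report), report = report)
}

#' HipSTR call-level and call-rate filters
#'
#' Genotype-level: cells failing any of the five per-call thresholds
#' (call quality >= 0.9, flank-indel fraction <= 0.15, stutter fraction <=
#' 0.15, allele bias >= -2, strand bias >= -2; channels in the Q,
#' FLANKINDEL, STUTTER, AB_BIAS, STRAND_BIAS assays) are converted to
#' missing rather than dropping the site. Site-level: the call rate must
#' exceed 80% within every designated sample subset.
#'
#' @inheritParams filterSpeedseq
#' @param subsets Named list of character vectors partitioning the samples
#'   (e.g. per genotyping batch); must cover every sample.
#' @return `list(callset, report)`; the callset keeps surviving sites with
#'   failing genotypes masked to NA.
#' @export
filterHipstr <- function(x, config = defaultFilterConfig(), subsets = NULL) {
  if (!all(svCaller(x) == "hipstr")) .stopf("records are not HipSTR calls")
  cfg <- config$hipstr
  if (is.null(subsets)) {
    subsets <- if ("study" %in% colnames(colData(x))) {
      split(colnames(x), colData(x)$study)
    } else list(all = colnames(x))
  }
  covered <- sort(unique(unlist(subsets)))
  if (!identical(covered, sort(colnames(x)))) {
    .stopf("subsets must cover all samples exactly")
  }
  gt <- gtMatrix(x)
  fail <- matrix(FALSE, nrow(x), ncol(x))
  chk <- function(name, op, thr) {
    m <- .assayOrNull(x, name)
    if (!is.null(m)) fail <<- fail | (!is.na(m) & op(m, thr))
  }
  chk("Q", `<`, cfg$min_call_qual)
  chk("FLANKINDEL", `>`, cfg$max_flank_indel)
  chk("STUTTER", `>`, cfg$max_stutter)
  chk("AB_BIAS", `<`, cfg$min_allele_bias)
  chk("STRAND_BIAS", `<`, cfg$min_strand_bias)
  gt[fail] <- NA_integer_
  y <- x
  SummarizedExperiment::assay(y, "gt") <- gt
  reasons <- vector("list", nrow(x))
  for (i in seq_len(nrow(x))) {
    for (nm in names(subsets)) {
      cr <- mean(!is.na(gt[i, subsets[[nm]]]))
      if (!(cr > cfg$min_call_rate)) {
        reasons[[i]] <- c(reasons[[i]], paste0("call_rate_", nm))
      }
    }
  }
  report <- .mkReport(siteId(x), reasons, "hipstr")
  list(callset = .applyReport(y, report), report = report)
}

#' QUAL filter for wham/manta call sets
#'
#' Keeps records with a QUAL score of at least `config$qual$min_qual`
#' (default 250); records lacking QUAL are removed with reason `no_qual`.
#'
#' @inheritParams filterSpeedseq
#' @export
filterQual <- function(x, config = defaultFilterConfig()) {
  cfg <- config$qual
  q <- qualMetric(x, "QUAL")
  reasons <- lapply(seq_len(nrow(x)), function(i) {
    if (is.na(q[i])) "no_qual"
    else if (q[i] < cfg$min_qual) "qual"
    else character()
  })
  report <- .mkReport(siteId(x), reasons, svCaller(x)[1] %||% "external")
  list(callset = .applyReport(x, report), report = report)
}
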