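#' Chi-squared test for allele-distribution differences between studies
#'
#' Compares per-category genotype/allele counts between two collections
#' (e.g. 0/1/2 copies of an insertion plus a missing category) with a
#' standard contingency chi-squared test without continuity correction.
#' Categories whose total count is zero carry zero expectation and are
#' dropped (pooling on sparse tables); an all-zero or single-category table
#' yields NA.
#'
#' @param countsA,countsB Integer vectors over the same categories
#'   (including a missing-genotype category when present).
#' @return `list(statistic, df, p)` (`NA`s for degenerate tables).
#' @export
#' @examples
#' batchAlleleTest(c(10, 20, 10), c(10, 20, 10))  # p = 1
batchAlleleTest <- function(countsA, countsB) {
  if (length(countsA) != length(countsB)) .stopf("category sets differ")
  tot <- countsA + countsB
  keep <- tot > 0
  a <- countsA[keep]; b <- countsB[keep]
  if (length(a) < 2L || sum(a) == 0 || sum(b) == 0) {
    return(list(statistic = NA_real_, df = NA_real_, p = NA_real_))
  }
  tab <- rbind(a, b)
  exp_ <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - exp_)^2 / exp_)
  df <- length(a) - 1
  list(statistic = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Hardy-Weinberg equilibrium chi-squared test
#'
#' Compares observed genotype counts at a biallelic site to the counts
#' expected under HWE at the estimated allele frequency
#' (`p_hat = (2 n_rr + n_ra) / 2n`), chi-squared with one degree of
#' freedom. Monomorphic sites have expectation equal to observation and
#' return statistic 0.
#'
#' @param counts Integer vector `(n_rr, n_ra, n_aa)` of hom-ref, het and
#'   hom-alt genotype counts among unrelated samples.
#' @return `list(statistic, df, p)`; all NA when `n = 0`.
#' @export
#' @examples
#' hweTest(c(25, 50, 25))  # statistic 0, p = 1
#' hweTest(c(40, 20, 40))  # statistic 36
hweTest <- function(counts) {
  stopifnot(length(counts) == 3L)
  n <- sum(counts)
  if (n == 0) return(list(statistic = NA_real_, df = 1, p = NA_real_))
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  exp_ <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  keep <- exp_ > 0
  stat <- sum((counts[keep] - exp_[keep])^2 / exp_[keep])
  list(statistic = unname(stat), df = 1,
       p = unname(stats::pchisq(stat, 1, lower.tail = FALSE)))
}

.gtCategories <- function(v, channel) {
  # category label per sample, missing as its own category
  lab <- if (channel == "cn") as.character(v) else as.character(v)
  lab[is.na(v)] <- "missing"
  lab
}

#' Site-wise batch-effect flags for a call set
#'
#' Runs [batchAlleleTest()] per site on genotype (or copy-number, for mCNV)
#' category counts — missing genotypes included as a unique category — of
#' unrelated samples from each study, and flags sites with
#' Bonferroni-corrected p below `alpha`, with m = number of sites actually
#' tested.
#'
#' @param x An [SVCallSet-class] with `study` in its colData.
#' @param unrelated Optional character vector of unrelated sample ids (one
#'   member per donor is a common choice); defaults to all samples.
#' @param alpha Family-wise error target (default 0.05).
#' @return Data frame with `site_id`, `statistic`, `p`, `flagged`; also
#'   returned via `rowData(x)$batch_flag` in the `"callset"` attribute.
#' @export
batchEffectTest <- function(x, unrelated = NULL, alpha = 0.05) {
  if (!"study" %in% colnames(colData(x))) .stopf("colData lacks 'study'")
  samp <- unrelated %||% colnames(x)
  st <- colData(x)[samp, "study"]
  if (length(unique(st)) < 2L) .stopf("a study has zero samples")
  ch <- siteChannel(x)
  gt <- gtMatrix(x); cn <- cnMatrix(x)
  res <- lapply(seq_len(nrow(x)), function(i) {
    m <- if (ch[i] == "cn") cn[i, samp] else gt[i, samp]
    lab <- .gtCategories(m, ch[i])
    cats <- sort(unique(lab))
    ta <- table(factor(lab[st == "iPSCORE"], levels = cats))
    tb <- table(factor(lab[st == "HipSci"], levels = cats))
    r <- batchAlleleTest(as.integer(ta), as.integer(tb))
    data.frame(statistic = r$statistic, p = r$p)
  })
  res <- do.call(rbind, res)
  m <- sum(!is.na(res$p))
  flagged <- !is.na(res$p) & res$p < alpha / max(m, 1L)
  out <- data.frame(site_id = siteId(x), statistic = res$statistic,
                    p = res$p, flagged = flagged, stringsAsFactors = FALSE)
  rowData(x)$batch_flag <- flagged
  attr(out, "callset") <- x
  attr(out, "m") <- m
  out
}

#' Site-wise Hardy-Weinberg flags for a call set
#'
#' Applies [hweTest()] to biallelic sites using unrelated blood/fibroblast
#' samples (iPSC clones are excluded: reprogramming-associated somatic
#' changes violate the population model), flagging sites with
#' Bonferroni-corrected p below `alpha`. mCNV and copy-number-only rows are
#' skipped (NA).
#'
#' @inheritParams batchEffectTest
#' @return Data frame with `site_id`, `statistic`, `p`, `flagged`; the
#'   call set with `rowData()$hwe_flag` is in the `"callset"` attribute.
#' @export
hweTestSites <- function(x, unrelated = NULL, alpha = 0.05) {
  samp <- unrelated %||% colnames(x)
  if ("cell_type" %in% colnames(colData(x))) {
    samp <- samp[colData(x)[samp, "cell_type"] %in% c("blood", "fibroblast")]
  }
  gt <- gtMatrix(x)
  biallelic <- siteChannel(x) == "gt"
  res <- lapply(seq_len(nrow(x)), function(i) {
    if (!biallelic[i] || is.null(gt)) {
      return(data.frame(statistic = NA_real_, p = NA_real_))
    }
    v <- gt[i, samp]
    counts <- c(sum(v == 0, na.rm = TRUE), sum(v == 1, na.rm = TRUE),
                sum(v >= 2, na.rm = TRUE))
    r <- hweTest(counts)
    data.frame(statistic = r$statistic, p = r$p)
  })
  res <- do.call(rbind, res)
  m <- sum(!is.na(res$p))
  flagged <- !is.na(res$p) & res$p < alpha / max(m, 1L)
  out <- data.frame(site_id = siteId(x), statistic = res$statistic,
                    p = res$p, flagged = flagged, stringsAsFactors = FALSE)
  rowData(x)$hwe_flag <- flagged
  attr(out, "callset") <- x
  attr(out, "m") <- m
  out
}

#' Calls-per-sample diagnostics
#'
#' Counts non-reference calls (gt > 0, or copy number different from the
#' site's modal value for mCNV rows) and missing genotypes per sample, with
#' study / cell type / superpopulation from the sample metadata for
#' group-level comparison.
#'
#' @param x An [SVCallSet-class].
#' @return Data frame with one row per sample.
#' @export
callsPerSample <- function(x) {
  ch <- siteChannel(x)
  gt <- gtMatrix(x); cn <- cnMatrix(x)
  nonref <- matrix(FALSE, nrow(x), ncol(x))
  missing_ <- matrix(FALSE, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) {
    v <- if (ch[i] == "cn") cn[i, ] else gt[i, ]
    missing_[i, ] <- is.na(v)
    nonref[i, ] <- if (ch[i] == "cn") !is.na(v) & v != .modalValue(v)
                   else !is.na(v) & v > 0
  }
  out <- data.frame(sample_id = colnames(x),
                    n_calls = colSums(nonref),
                    n_missing = colSums(missing_),
                    stringsAsFactors = FALSE)
  cd <- as.data.frame(colData(x))
  for (col in intersect(c("study", "cell_type", "superpopulation", "donor_id"),
                        colnames(cd))) {
    out[[col]] <- cd[[col]]
  }
  rownames(out) <- NULL
  out
}

#' Non-mode allele frequency
#'
#' For genotype rows, 1 minus the frequency of the modal allele (equals the
#' minor allele frequency at a biallelic site); for copy-number rows, 1
#' minus the frequency of the modal copy-number state across samples.
#'
#' @param v Numeric vector of genotypes (alt-allele counts) or copy
#'   numbers.
#' @param channel `"gt"` (allele-based) or `"cn"` (state-based).
#' @return A frequency in `[0, 1]` (NA when all values are missing).
#' @export
#' @examples
#' nmaf(c(2, 2, 2, 1, 2, 2, 2, 2, 2, 2), channel = "cn")  # 0.1
nmaf <- function(v, channel = c("gt", "cn")) {
  channel <- match.arg(channel)
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  if (channel == "gt") {
    p <- sum(v) / (2 * length(v))  # alt allele frequency
    min(p, 1 - p)
  } else {
    1 - max(table(v)) / length(v)
  }
}

#' Per-study allele-frequency summary and concordance
#'
#' Computes per-site non-mode allele frequency separately for the unrelated
#' samples of each study and their Pearson correlation over sites
#' polymorphic in either study. High correlation indicates that variant
#' calling is not study-batched.
#'
#' @inheritParams batchEffectTest
#' @return A list: `table` (site_id, nmaf overall and per study) and `r`
#'   (Pearson correlation between per-study NMAFs).
#' @export
afByStudy <- function(x, unrelated = NULL) {
  if (!"study" %in% colnames(colData(x))) .stopf("colData lacks 'study'")
  samp <- unrelated %||% colnames(x)
  st <- colData(x)[samp, "study"]
  if (length(unique(st)) < 2L) .stopf("a study has zero samples")
  ch <- siteChannel(x)
  gt <- gtMatrix(x); cn <- cnMatrix(x)
  one <- function(i, who) {
    v <- if (ch[i] == "cn") cn[i, samp[who]] else gt[i, samp[who]]
    nmaf(v, if (ch[i] == "cn") "cn" else "gt")
  }
  n <- nrow(x)
  fA <- vapply(seq_len(n), function(i) one(i, st == "iPSCORE"), numeric(1))
  fB <- vapply(seq_len(n), function(i) one(i, st == "HipSci"), numeric(1))
  fAll <- vapply(seq_len(n), function(i) one(i, rep(TRUE, length(samp))),
                 numeric(1))
  poly <- (!is.na(fA) & fA > 0) | (!is.na(fB) & fB > 0)
  r <- .safeCor(fA[poly], fB[poly])
  list(table = data.frame(site_id = siteId(x), nmaf = fAll,
                          nmaf_ipscore = fA, nmaf_hipsci = fB,
                          stringsAsFactors = FALSE),
       r = r)
}
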