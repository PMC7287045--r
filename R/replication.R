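#' Per-site replication rate from genetic replicates
#'
#' The replication rate (RR) of a site is the number of replicate pairs with
#' matching non-reference genotypes divided by the number of pairs in which
#' at least one member carries a non-reference genotype (informative pairs).
#' Pairs with a missing genotype in either member are excluded from both
#' numerator and denominator. Two concordance readings are provided:
#' \describe{
#'   \item{strict}{a pair matches only when both genotypes are identical and
#'     non-reference (the conservative reading; default)}
#'   \item{nonref_only}{a pair matches whenever both members are
#'     non-reference, regardless of the exact genotype}
#' }
#' For copy-number channels (mCNV sites) "non-reference" means a copy number
#' different from the modal copy number across samples, and strict
#' concordance means equal copy number.
#'
#' @param row Named numeric vector of per-sample genotypes (alt-allele
#'   counts) or copy numbers; names are sample ids.
#' @param pairs Replicate-pair data frame (`sample_a`, `sample_b`,
#'   `pair_type`).
#' @param mode `"strict"` or `"nonref_only"`.
#' @param channel `"gt"` (non-reference = value > 0) or `"cn"`
#'   (non-reference = value != modal value of `row`).
#' @return `list(rr, n_informative)`; `rr` is NA when no pair is
#'   informative.
#' @export
#' @examples
#' row <- c(a1 = 1, a2 = 1, b1 = 1, b2 = 0, c1 = 0, c2 = 0, d1 = 2, d2 = 2)
#' pairs <- data.frame(sample_a = c("a1", "b1", "c1", "d1"),
#'                     sample_b = c("a2", "b2", "c2", "d2"),
#'                     pair_type = "mz_twin")
#' siteRR(row, pairs)  # rr = 2/3 over 3 informative pairs
siteRR <- function(row, pairs, mode = c("strict", "nonref_only"),
                   channel = c("gt", "cn")) {
  mode <- match.arg(mode)
  channel <- match.arg(channel)
  if (!nrow(pairs)) .stopf("empty replicate pair list")
  miss <- setdiff(c(pairs$sample_a, pairs$sample_b), names(row))
  if (length(miss)) .stopf("pair member(s) absent from row: %s", miss[1])
  a <- row[pairs$sample_a]; b <- row[pairs$sample_b]
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  nonref <- if (channel == "cn") {
    md <- .modalValue(row)
    cbind(a != md, b != md)
  } else {
    cbind(a > 0, b > 0)
  }
  informative <- nonref[, 1] | nonref[, 2]
  n <- sum(informative)
  if (n == 0L) return(list(rr = NA_real_, n_informative = 0L))
  match_ <- if (mode == "strict") {
    nonref[, 1] & nonref[, 2] & a == b
  } else {
    nonref[, 1] & nonref[, 2]
  }
  list(rr = sum(match_ & informative) / n, n_informative = n)
}

#' Replication-rate table for a call set
#'
#' Applies [siteRR()] to every site of a call set, choosing the evidence
#' channel per site via [siteChannel()] (copy number for mCNV rows,
#' genotypes otherwise), vectorised over sites.
#'
#' @param x An [SVCallSet-class].
#' @param pairs Replicate-pair data frame; optionally pre-filtered to one
#'   pair type.
#' @param mode Concordance mode, see [siteRR()].
#' @return Data frame with one row per site: `site_id`, `rr`,
#'   `n_informative`, `segregating` (any informative pair).
#' @export
rrTable <- function(x, pairs, mode = c("strict", "nonref_only")) {
  mode <- match.arg(mode)
  if (!nrow(pairs)) .stopf("empty replicate pair list")
  ia <- match(pairs$sample_a, colnames(x))
  ib <- match(pairs$sample_b, colnames(x))
  if (anyNA(ia) || anyNA(ib)) .stopf("pair member absent from call set")
  ch <- siteChannel(x)
  gt <- gtMatrix(x); cn <- cnMatrix(x)
  n <- nrow(x)
  rr <- rep(NA_real_, n); ninf <- integer(n)
  for (i in seq_len(n)) {
    m <- if (ch[i] == "cn") cn[i, ] else gt[i, ]
    a <- m[ia]; b <- m[ib]
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]; b <- b[ok]
    if (ch[i] == "cn") {
      md <- .modalValue(m)
      na_ <- a != md; nb <- b != md
    } else {
      na_ <- a > 0; nb <- b > 0
    }
    inf <- na_ | nb
    ninf[i] <- sum(inf)
    if (ninf[i] > 0L) {
      mt <- if (mode == "strict") na_ & nb & a == b else na_ & nb
      rr[i] <- sum(mt) / ninf[i]
    }
  }
  data.frame(site_id = siteId(x), rr = rr, n_informative = ninf,
             segregating = ninf > 0L, stringsAsFactors = FALSE)
}

#' Mean replication rate by caller and variant class
#'
#' @param x An [SVCallSet-class].
#' @param pairs Replicate pairs; when `byPairType = TRUE` the table is also
#'   split by pair type (twin vs fibroblast-iPSC).
#' @param by rowData grouping columns (default caller and svtype).
#' @param mode Concordance mode.
#' @param byPairType Split by replicate pair type.
#' @return Data frame of group, `n_sites` (with defined RR) and `mean_rr`
#'   (NA with count 0 for empty groups).
#' @export
classRR <- function(x, pairs, by = c("caller", "svtype"),
                    mode = c("strict", "nonref_only"), byPairType = FALSE) {
  mode <- match.arg(mode)
  groupsOf <- function(p, label) {
    tab <- rrTable(x, p, mode)
    key <- do.call(paste, c(lapply(by, function(b) rowData(x)[[b]]),
                            list(sep = "\r")))
    res <- do.call(rbind, lapply(split(seq_len(nrow(tab)), key), function(ix) {
      def <- !is.na(tab$rr[ix])
      parts <- strsplit(key[ix[1]], "\r", fixed = TRUE)[[1]]
      g <- as.data.frame(as.list(parts), col.names = by)
      g$n_sites <- sum(def)
      g$mean_rr <- if (any(def)) mean(tab$rr[ix][def]) else NA_real_
      g
    }))
    if (!is.null(label)) res <- cbind(pair_type = label, res)
    rownames(res) <- NULL
    res
  }
  if (byPairType) {
    do.call(rbind, lapply(split(pairs, pairs$pair_type), function(p)
      groupsOf(p, p$pair_type[1])))
  } else {
    groupsOf(pairs, NULL)
  }
}

#' Quality-threshold sweep of replication rate
#'
#' At each threshold `t`, restricts the call set to sites whose quality
#' metric passes `t` and reports the surviving site count and their mean RR,
#' reproducing the RR-versus-sites-remaining trade-off used to pick hard
#' filter thresholds. Comparison direction follows the published reading of
#' each metric: strictly greater for MSQ ("must have MSQ > 20"), at-least
#' for GSCNQUAL and QUAL ("minimum score required" / "at least 250");
#' override with `strict`.
#'
#' @param x An [SVCallSet-class].
#' @param pairs Replicate pairs.
#' @param metric Quality key among `svQualityKeys()`.
#' @param thresholds Numeric vector of thresholds (must be non-empty).
#' @param strict Logical: use `>` instead of `>=`. Default: TRUE for MSQ.
#' @param mode Concordance mode.
#' @return Data frame with `threshold`, `n_sites` (passing, metric present),
#'   `mean_rr`, and `n_no_metric` (records lacking the metric, excluded and
#'   counted separately).
#' @export
thresholdSweep <- function(x, pairs, metric, thresholds,
                           strict = identical(metric, "MSQ"),
                           mode = c("strict", "nonref_only")) {
  mode <- match.arg(mode)
  if (!length(thresholds)) .stopf("empty threshold list")
  q <- qualMetric(x, metric)
  nNo <- sum(is.na(q))
  tab <- rrTable(x, pairs, mode)
  out <- lapply(sort(thresholds), function(t) {
    keep <- !is.na(q) & (if (strict) q > t else q >= t)
    def <- keep & !is.na(tab$rr)
    data.frame(threshold = t, n_sites = sum(keep),
               mean_rr = if (any(def)) mean(tab$rr[def]) else NA_real_,
               n_no_metric = nNo)
  })
  do.call(rbind, out)
}

#' Replication-rate impact of MELT hard-filter flag subsets
#'
#' Evaluates, for each MELT exclusion-flag subset (each of lc, s25, rSD,
#' hDP alone; all four; all four plus the ASSESS = 5 tranche requirement),
#' the number of sites surviving removal of records carrying any flag in the
#' subset and their mean RR.
#'
#' @param x An [SVCallSet-class] of MELT records.
#' @param pairs Replicate pairs.
#' @param mode Concordance mode.
#' @return Data frame with `subset`, `n_sites`, `mean_rr`.
#' @export
meltFlagSweep <- function(x, pairs, mode = c("strict", "nonref_only")) {
  mode <- match.arg(mode)
  if (!all(svCaller(x) == "melt")) .stopf("meltFlagSweep requires MELT records")
  tab <- rrTable(x, pairs, mode)
  fl <- as.list(meltFlags(x))
  subsets <- c(as.list(.meltFlagSet),
               list(.meltFlagSet), list(.meltFlagSet))
  labels <- c(.meltFlagSet, "all4", "all4+ASSESS5")
  assess <- qualMetric(x, "ASSESS")
  out <- lapply(seq_along(subsets), function(k) {
    drop <- vapply(fl, function(f) length(intersect(f, subsets[[k]])) > 0,
                   logical(1))
    keep <- !drop
    if (labels[k] == "all4+ASSESS5") keep <- keep & !is.na(assess) & assess == 5
    def <- keep & !is.na(tab$rr)
    data.frame(subset = labels[k], n_sites = sum(keep),
               mean_rr = if (any(def)) mean(tab$rr[def]) else NA_real_)
  })
  do.call(rbind, out)
}
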