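#' Co-discovery matching against an external call set
#'
#' Matches query sites to an external (target) call set under the published
#' co-discovery rules: CNV classes (DEL, DUP, mCNV) and rMEIs match on at
#' least 25% reciprocal overlap, or full containment where the smaller
#' variant spans at least 20% of the larger; inversions require 80%
#' reciprocal overlap; breakends match when breakpoints lie within 50 bp.
#' Classes must be equal, except mCNVs match duplications or deletions in
#' either direction. When the query carries redundancy clusters
#' (`clusterIds`), captured fractions treat a cluster as a single site.
#'
#' @param query,target [SVCallSet-class] objects (or `GRanges` with
#'   `svtype` metadata column).
#' @param minRO,containFrac,invRO,bndDist Rule thresholds.
#' @param queryNmaf Optional per-site non-mode allele frequencies of the
#'   query used for the captured-fraction summary.
#' @param nmafBreak Common/rare split for the captured-fraction summary
#'   (default 0.05).
#' @param clusterIds Optional per-query-site cluster ids (NA = singleton).
#' @return List: `matches` (query_id, target_id, rule), `captured`
#'   (per NMAF bin: n sites, fraction captured).
#' @export
coDiscovery <- function(query, target, minRO = 0.25, containFrac = 0.2,
                        invRO = 0.8, bndDist = 50, queryNmaf = NULL,
                        nmafBreak = 0.05, clusterIds = NULL) {
  qgr <- if (inherits(query, "SVCallSet")) rowRanges(query) else query
  tgr <- if (inherits(target, "SVCallSet")) rowRanges(target) else target
  qtp <- if (inherits(query, "SVCallSet")) svType(query) else query$svtype
  ttp <- if (inherits(target, "SVCallSet")) svType(target) else target$svtype
  qid <- if (inherits(query, "SVCallSet")) siteId(query) else
    (names(qgr) %||% as.character(seq_along(qgr)))
  tid <- if (inherits(target, "SVCallSet")) siteId(target) else
    (names(tgr) %||% as.character(seq_along(tgr)))

  ivClasses <- c("DEL", "DUP", "mCNV", "rMEI")
  rows <- list()
  # interval classes: reciprocal overlap / containment
  pr <- .overlapPairs(qgr, tgr)
  for (k in seq_len(nrow(pr))) {
    i <- pr$i[k]; j <- pr$j[k]
    a <- qtp[i]; b <- ttp[j]
    compat <- a == b | (a == "mCNV" & b %in% c("DEL", "DUP")) |
      (b == "mCNV" & a %in% c("DEL", "DUP"))
    if (!compat) next
    if (a == "INV" && b == "INV") {
      if (min(pr$frac_i[k], pr$frac_j[k]) >= invRO) {
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = qid[i], target_id = tid[j], rule = "inversion_ro",
          frac_query = pr$frac_i[k], frac_target = pr$frac_j[k])
      }
    } else if (a %in% ivClasses && b %in% ivClasses) {
      wq <- width(qgr)[i]; wt <- width(tgr)[j]
      contain <- (pr$i_in_j[k] && wq >= containFrac * wt) ||
                 (pr$j_in_i[k] && wt >= containFrac * wq)
      if (min(pr$frac_i[k], pr$frac_j[k]) >= minRO) {
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = qid[i], target_id = tid[j], rule = "reciprocal",
          frac_query = pr$frac_i[k], frac_target = pr$frac_j[k])
      } else if (contain) {
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = qid[i], target_id = tid[j], rule = "containment",
          frac_query = pr$frac_i[k], frac_target = pr$frac_j[k])
      }
    }
  }
  # breakends: distance rule
  qb <- which(qtp == "BND"); tb <- which(ttp == "BND")
  for (i in qb) {
    for (j in tb) {
      if (as.character(seqnames(qgr))[i] != as.character(seqnames(tgr))[j]) next
      d <- abs(start(qgr)[i] - start(tgr)[j])
      if (d <= bndDist) {
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = qid[i], target_id = tid[j], rule = "breakend_distance",
          frac_query = NA_real_, frac_target = NA_real_)
      }
    }
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query_id = character(), target_id = character(),
               rule = character(), frac_query = numeric(),
               frac_target = numeric())
  matches <- unique(matches)

  captured <- NULL
  if (!is.null(queryNmaf)) {
    unit <- clusterIds %||% rep(NA_character_, length(qid))
    unit <- ifelse(is.na(unit), paste0("singleton_", qid), unit)
    hit <- qid %in% matches$query_id
    df <- data.frame(unit = unit, nmaf = queryNmaf, hit = hit)
    agg <- do.call(rbind, lapply(split(df, df$unit), function(d)
      data.frame(nmaf = max(d$nmaf, na.rm = TRUE), hit = any(d$hit))))
    bin <- ifelse(agg$nmaf >= nmafBreak, "common", "rare")
    captured <- do.call(rbind, lapply(split(agg, bin), function(d)
      data.frame(bin = ifelse(d$nmaf[1] >= nmafBreak, "common", "rare"),
                 n = nrow(d), captured = mean(d$hit))))
    rownames(captured) <- NULL
  }
  list(matches = matches, captured = captured)
}

#' Co-discovery matching for insertions
#'
#' Insertion breakpoints match when they lie within 50 bp of each other and
#' the two element lengths differ by less than twofold (insertion sequence
#' is typically unavailable for direct comparison).
#'
#' @param query,target [SVCallSet-class] objects of point insertion records
#'   with `sv_len` set.
#' @param maxDist Maximum breakpoint distance in bp (default 50).
#' @param maxFold Length-ratio bound (strict <, default 2).
#' @return Data frame of matches (query_id, target_id, distance,
#'   fold_diff).
#' @export
coDiscoveryInsertions <- function(query, target, maxDist = 50, maxFold = 2) {
  qgr <- rowRanges(query); tgr <- rowRanges(target)
  ql <- svLen(query); tl <- svLen(target)
  if (any(is.na(ql) | ql <= 0) || any(is.na(tl) | tl <= 0)) {
    .stopf("insertion records must carry positive sv_len")
  }
  rows <- list()
  for (i in seq_len(nrow(query))) {
    for (j in seq_len(nrow(target))) {
      if (as.character(seqnames(qgr))[i] != as.character(seqnames(tgr))[j]) next
      d <- abs(start(qgr)[i] - start(tgr)[j])
      if (d > maxDist) next
      fold <- max(ql[i], tl[j]) / min(ql[i], tl[j])
      if (fold < maxFold) {
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = siteId(query)[i], target_id = siteId(target)[j],
          distance = d, fold_diff = fold, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(query_id = character(), target_id = character(),
               distance = numeric(), fold_diff = numeric())
}

#' Allele-frequency concordance over matched sites
#'
#' Pearson correlation between the query and target allele frequencies of
#' co-discovered pairs; NA with fewer than three pairs.
#'
#' @param matches Match table from [coDiscovery()].
#' @param queryAf,targetAf Named frequency vectors (by site id).
#' @return List: `r`, `table` (paired frequencies).
#' @export
afConcordance <- function(matches, queryAf, targetAf) {
  tab <- data.frame(query_id = matches$query_id, target_id = matches$target_id,
                    af_query = as.numeric(queryAf[matches$query_id]),
                    af_target = as.numeric(targetAf[matches$target_id]))
  tab <- unique(tab)
  ok <- stats::complete.cases(tab[, c("af_query", "af_target")])
  r <- if (sum(ok) < 3L) NA_real_ else .safeCor(tab$af_query[ok], tab$af_target[ok])
  list(r = r, table = tab)
}

#' Linkage-disequilibrium tagging of SVs by nearby SNPs
#'
#' For every SV (optionally restricted by `mask`, e.g. proximity to
#' expressed genes), computes the maximum squared Pearson correlation
#' between the SV dosage (alt-allele count; copy number for mCNV) and the
#' genotypes of all SNPs within `window` bp of the SV boundaries. Returns
#' NA for SVs with no SNP in the window or zero dosage variance.
#'
#' @param x [SVCallSet-class] of SVs/STRs.
#' @param snpGt SNP-by-sample genotype matrix (same sample universe or a
#'   shared subset).
#' @param snpPos Data frame `snp_id`, `chrom`, `pos` aligned to `snpGt`
#'   rows.
#' @param window Window in bp on each side of the SV (default 50 kb).
#' @param mask Optional logical vector or site-id vector restricting the
#'   SVs tested.
#' @param samples Optional sample subset (e.g. one superpopulation).
#' @return Data frame: `site_id`, `best_snp`, `max_r2`, `n_snps`.
#' @export
ldTagging <- function(x, snpGt, snpPos, window = 50000, mask = NULL,
                      samples = NULL) {
  ids <- siteId(x)
  test <- if (is.null(mask)) rep(TRUE, nrow(x)) else if (is.logical(mask)) mask
          else ids %in% mask
  shared <- intersect(colnames(x), colnames(snpGt))
  if (!is.null(samples)) shared <- intersect(shared, samples)
  if (length(shared) < 3L) .stopf("fewer than 3 shared samples for LD")
  ch <- siteChannel(x)
  gt <- gtMatrix(x); cn <- cnMatrix(x)
  gr <- rowRanges(x)
  snpM <- snpGt[, shared, drop = FALSE]
  out <- lapply(which(test), function(i) {
    dosage <- if (ch[i] == "cn") cn[i, shared] else gt[i, shared]
    inWin <- snpPos$chrom == as.character(seqnames(gr))[i] &
      snpPos$pos >= start(gr)[i] - window & snpPos$pos <= end(gr)[i] + window
    n <- sum(inWin)
    if (n == 0L || length(unique(dosage[!is.na(dosage)])) < 2L) {
      return(data.frame(site_id = ids[i], best_snp = NA_character_,
                        max_r2 = NA_real_, n_snps = n))
    }
    r2 <- vapply(which(inWin), function(s) {
      r <- .safeCor(dosage, snpM[s, ])
      if (is.na(r)) NA_real_ else r^2
    }, numeric(1))
    if (all(is.na(r2))) {
      return(data.frame(site_id = ids[i], best_snp = NA_character_,
                        max_r2 = NA_real_, n_snps = n))
    }
    best <- which.max(r2)
    data.frame(site_id = ids[i], best_snp = snpPos$snp_id[which(inWin)[best]],
               max_r2 = max(r2, na.rm = TRUE), n_snps = n,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Residualize each probe's intensities on covariates by least squares.
.residualizeProbes <- function(intensity, covariates) {
  mm <- stats::model.matrix(~ ., data = covariates)
  t(apply(intensity, 1, function(y) {
    ok <- !is.na(y)
    r <- y
    r[ok] <- stats::lm.fit(mm[ok, , drop = FALSE], y[ok])$residuals
    r
  }))
}

#' Intensity rank-sum (IRS) validation of CNV calls against array probes
#'
#' Tests whether called CNV genotypes agree with independent array probe
#' intensities. Probe intensities are first residualized on nuisance
#' covariates (batch, plate) by probe-wise least squares. For each site
#' overlapping at least three probes and having at least one carrier, the
#' residual intensities of each probe are ranked across samples and the
#' carrier ranks are summed over probes; the pooled rank-sum is compared to
#' its null mean and variance (sampling without replacement per probe)
#' under a normal approximation with continuity correction, one-sided in
#' the direction implied by the class (deletion carriers lower, duplication
#' carriers higher). The call-set false discovery rate is estimated as
#' `2 * P(p >= 0.5)` over tested sites.
#'
#' @param x [SVCallSet-class] of CNV sites (DEL/DUP; mCNV rows are tested
#'   on the dominant direction of their copy numbers).
#' @param intensity Probe-by-sample intensity matrix (log R ratio).
#' @param probePos Data frame `probe_id`, `chrom`, `pos` aligned to
#'   `intensity` rows.
#' @param covariates Optional data frame of per-sample nuisance covariates
#'   (rows aligned to `colnames(intensity)`).
#' @param minProbes Minimum probes per tested site (default 3).
#' @return List: `table` (site_id, n_probes, n_carriers, p, or skip
#'   reason), `fdr` (the 2 x P(p >= 0.5) estimate), `n_tested`.
#' @export
irsTest <- function(x, intensity, probePos, covariates = NULL,
                    minProbes = 3) {
  res <- if (is.null(covariates)) intensity else {
    cov <- covariates[, setdiff(colnames(covariates), "sample_id"),
                      drop = FALSE]
    .residualizeProbes(intensity, cov)
  }
  shared <- intersect(colnames(x), colnames(intensity))
  ch <- siteChannel(x)
  gt <- gtMatrix(x); cn <- cnMatrix(x)
  gr <- rowRanges(x)
  ids <- siteId(x)
  rows <- lapply(seq_len(nrow(x)), function(i) {
    skip <- function(reason) data.frame(site_id = ids[i], n_probes = NA_integer_,
                                        n_carriers = NA_integer_, p = NA_real_,
                                        skip = reason, stringsAsFactors = FALSE)
    if (!(svType(x)[i] %in% c("DEL", "DUP", "mCNV"))) return(skip("class"))
    pidx <- which(probePos$chrom == as.character(seqnames(gr))[i] &
                  probePos$pos >= start(gr)[i] & probePos$pos <= end(gr)[i])
    if (length(pidx) < minProbes) return(skip("lt3_probes"))
    dosage <- if (ch[i] == "cn") cn[i, shared] else gt[i, shared]
    if (ch[i] == "cn") {
      md <- .modalValue(dosage)
      carrier <- !is.na(dosage) & dosage != md
      # dominant direction of the non-modal copy numbers
      dirUp <- mean(dosage[carrier]) > md
    } else {
      carrier <- !is.na(dosage) & dosage > 0
      dirUp <- svType(x)[i] == "DUP"
    }
    ok <- !is.na(dosage)
    if (sum(carrier) == 0 || sum(carrier) == sum(ok)) return(skip("no_carriers"))
    T <- 0; mu <- 0; v <- 0
    for (p in pidx) {
      y <- res[p, shared][ok]
      rk <- rank(y)
      nc <- sum(carrier[ok]); nn <- sum(ok) - nc; N <- nc + nn
      T <- T + sum(rk[carrier[ok]])
      mu <- mu + nc * (N + 1) / 2
      v <- v + nc * nn * (N + 1) / 12
    }
    z <- if (dirUp) (T - mu - 0.5) / sqrt(v) else (T - mu + 0.5) / sqrt(v)
    p_ <- if (dirUp) stats::pnorm(z, lower.tail = FALSE) else stats::pnorm(z)
    data.frame(site_id = ids[i], n_probes = length(pidx),
               n_carriers = sum(carrier), p = p_, skip = NA_character_,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tested <- !is.na(tab$p)
  fdr <- if (any(tested)) 2 * mean(tab$p[tested] >= 0.5) else NA_real_
  list(table = tab, fdr = fdr, n_tested = sum(tested))
}
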