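# Independent oracles and fixture builders used across the suite.
# These deliberately re-derive results with the plainest possible code
# (explicit loops, hand-rolled union-find) so they share nothing with the
# implementation paths they check.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
})

# --- hand-rolled union-find ------------------------------------------------
ufNew <- function(n) seq_len(n)
ufFind <- function(uf, i) {
  while (uf[i] != i) i <- uf[i]
  i
}
ufUnion <- function(uf, i, j) {
  ri <- ufFind(uf, i); rj <- ufFind(uf, j)
  if (ri != rj) uf[max(ri, rj)] <- min(ri, rj)
  uf
}
ufPartition <- function(uf) {
  roots <- vapply(seq_along(uf), function(i) ufFind(uf, i), integer(1))
  match(roots, unique(roots))
}

# Compare two partitions (integer membership vectors) up to label renaming.
samePartition <- function(a, b) {
  canon <- function(m) {
    g <- unname(lapply(split(seq_along(m), m), sort))
    g[order(vapply(g, min, integer(1)))]
  }
  identical(canon(a), canon(b))
}

# Brute-force per-site replication rate by pair enumeration.
oracleSiteRR <- function(row, pairs, mode = "strict", channel = "gt") {
  md <- if (channel == "cn") {
    v <- row[!is.na(row)]
    as.numeric(names(sort(table(v), decreasing = TRUE))[1])
  } else NA
  isNonref <- function(v) if (channel == "cn") v != md else v > 0
  inf <- 0L; mat <- 0L
  for (k in seq_len(nrow(pairs))) {
    a <- row[[pairs$sample_a[k]]]; b <- row[[pairs$sample_b[k]]]
    if (is.na(a) || is.na(b)) next
    if (isNonref(a) || isNonref(b)) {
      inf <- inf + 1L
      hit <- if (mode == "strict") isNonref(a) && isNonref(b) && a == b
             else isNonref(a) && isNonref(b)
      if (hit) mat <- mat + 1L
    }
  }
  list(rr = if (inf > 0) mat / inf else NA_real_, n_informative = inf)
}

# Plain-arithmetic reciprocal overlap of two closed intervals.
oracleRO <- function(s1, e1, s2, e2) {
  ov <- max(0, min(e1, e2) - max(s1, s2) + 1)
  c(ov / (e1 - s1 + 1), ov / (e2 - s2 + 1))
}

# Brute-force exhaustive max R^2 between a dosage and all SNPs in window.
oracleMaxR2 <- function(dosage, snpGt, snpPos, chrom, s, e, window) {
  best <- NA_real_; bestId <- NA_character_
  for (k in seq_len(nrow(snpGt))) {
    if (snpPos$chrom[k] != chrom) next
    if (snpPos$pos[k] < s - window || snpPos$pos[k] > e + window) next
    ok <- !is.na(dosage) & !is.na(snpGt[k, ])
    if (sum(ok) < 2) next
    if (sd(dosage[ok]) == 0 || sd(snpGt[k, ok]) == 0) next
    r2 <- cor(dosage[ok], snpGt[k, ok])^2
    if (is.na(best) || r2 > best) { best <- r2; bestId <- snpPos$snp_id[k] }
  }
  list(max_r2 = best, best_snp = bestId)
}

# --- fixture builders ------------------------------------------------------

# Minimal SVCallSet from parallel vectors; genotype matrices optional.
makeCallSet <- function(chrom, start, end, svtype, caller = "external",
                        siteId = sprintf("s%03d", seq_along(start)),
                        svLen = NULL, quality = NULL, gt = NULL, cn = NULL,
                        ab = NULL, lq = NULL, meltFlags = NULL,
                        sampleInfo = NULL, extraAssays = list()) {
  gr <- GRanges(chrom, IRanges(start, end))
  SVCallSet(gr, siteId = siteId, caller = caller, svtype = svtype,
            svLen = svLen, quality = quality, gt = gt, cn = cn, ab = ab,
            lq = lq, meltFlags = meltFlags, sampleInfo = sampleInfo,
            extraAssays = extraAssays)
}

# A toy cohort of n twin pairs (all iPSCORE blood) + optional singles.
makePairs <- function(nPairs, nSingles = 0) {
  ids <- c(rbind(sprintf("P%02d_A", seq_len(nPairs)),
                 sprintf("P%02d_B", seq_len(nPairs))),
           if (nSingles) sprintf("S%02d", seq_len(nSingles)))
  samples <- data.frame(
    sample_id = ids,
    donor_id = c(rep(sprintf("D%02d", seq_len(nPairs)), each = 2),
                 if (nSingles) sprintf("DS%02d", seq_len(nSingles))),
    study = "iPSCORE", cell_type = "blood", superpopulation = "EUR",
    sex = "F", stringsAsFactors = FALSE)
  pairs <- data.frame(sample_a = sprintf("P%02d_A", seq_len(nPairs)),
                      sample_b = sprintf("P%02d_B", seq_len(nPairs)),
                      pair_type = rep("mz_twin", nPairs),
                      stringsAsFactors = FALSE)
  list(samples = samples, pairs = pairs)
}

# Random non-overlapping-ish interval set for clustering oracles.
randomIntervals <- function(n, chroms = c("c1", "c2"), maxPos = 100000,
                            lenRange = c(100, 5000)) {
  chrom <- sample(chroms, n, replace = TRUE)
  len <- round(runif(n, lenRange[1], lenRange[2]))
  start <- round(runif(n, 1, maxPos))
  data.frame(chrom = chrom, start = start, end = start + len - 1)
}
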