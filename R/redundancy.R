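#' Reciprocal overlap of two interval vectors
#'
#' Element-wise reciprocal overlap between parallel `GRanges` vectors:
#' `frac_a = overlap / width(a)` and `frac_b = overlap / width(b)`; both 0
#' when the intervals are disjoint or on different chromosomes.
#'
#' @param a,b Parallel `GRanges` (recycled if length 1).
#' @return A two-column matrix `frac_a`, `frac_b`.
#' @export
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 250))
#' reciprocalOverlap(a, b)  # 0.5, 0.5
reciprocalOverlap <- function(a, b) {
  if (length(a) == 1L) a <- rep(a, length(b))
  if (length(b) == 1L) b <- rep(b, length(a))
  stopifnot(length(a) == length(b))
  same <- as.character(seqnames(a)) == as.character(seqnames(b))
  ov <- pmin(end(a), end(b)) - pmax(start(a), start(b)) + 1
  ov <- ifelse(same & ov > 0, ov, 0)
  cbind(frac_a = ov / width(a), frac_b = ov / width(b))
}

# All overlapping pairs (i < j) within `gr` or across gr/gr2, with overlap
# fractions and containment flags.
.overlapPairs <- function(gr, gr2 = NULL) {
  if (is.null(gr2)) {
    h <- findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
    i <- S4Vectors::queryHits(h); j <- S4Vectors::subjectHits(h)
    ro <- reciprocalOverlap(gr[i], gr[j])
  } else {
    h <- findOverlaps(gr, gr2)
    i <- S4Vectors::queryHits(h); j <- S4Vectors::subjectHits(h)
    ro <- reciprocalOverlap(gr[i], gr2[j])
  }
  g2 <- gr2 %||% gr
  data.frame(i = i, j = j, frac_i = ro[, 1], frac_j = ro[, 2],
             i_in_j = start(gr)[i] >= start(g2)[j] & end(gr)[i] <= end(g2)[j],
             j_in_i = start(g2)[j] >= start(gr)[i] & end(g2)[j] <= end(gr)[i])
}

# Order cluster processing deterministically by (chrom, start, site_id).
.siteOrder <- function(x) {
  order(as.character(seqnames(rowRanges(x))), start(rowRanges(x)), siteId(x))
}

.pickPrimary <- function(ids, quality) {
  # max quality, ties to lexicographically smaller id
  q <- ifelse(is.na(quality), -Inf, quality)
  ids[order(-q, ids)][1]
}

#' Within-caller deduplication of SpeedSeq calls
#'
#' Graph-based redundancy collapsing: (1) sites with reciprocal overlap of
#' at least 50% are connected; (2) edges are retained only when the allele
#' balance of the two sites correlates with r > 0.25 across samples; (3) in
#' every remaining connected component the record with the highest MSQ is
#' the primary and the rest are secondary; (4) additionally, when one call
#' is fully contained within another and their allele balance correlates at
#' r >= 0.5, only the higher-MSQ call survives. Correlation undefined
#' (missing AB or zero variance) drops the edge.
#'
#' @param x An [SVCallSet-class] of filtered SpeedSeq records with an `ab`
#'   assay.
#' @param minRO Reciprocal overlap to create a candidate edge (0.5).
#' @param minAbCor Allele-balance correlation to keep an edge (0.25,
#'   strict).
#' @param containCor Allele-balance correlation for the containment rule
#'   (0.5, at-least).
#' @return List: `clusters` (cluster_id, site_id, role), `edges`,
#'   `callset` (input with cluster annotations; secondaries marked in
#'   `filterStatus`), `nonredundant` (primaries and singletons only).
#' @export
dedupSpeedseq <- function(x, minRO = 0.5, minAbCor = 0.25, containCor = 0.5) {
  ab <- abMatrix(x)
  if (is.null(ab)) .stopf("speedseq dedup requires the ab assay")
  gr <- rowRanges(x)
  pr <- .overlapPairs(gr)
  keep <- logical(nrow(pr))
  if (nrow(pr)) {
    corv <- vapply(seq_len(nrow(pr)), function(k)
      .safeCor(ab[pr$i[k], ], ab[pr$j[k], ]), numeric(1))
    roPass <- pmin(pr$frac_i, pr$frac_j) >= minRO &
      !is.na(corv) & corv > minAbCor
    containPass <- (pr$i_in_j | pr$j_in_i) & !is.na(corv) & corv >= containCor
    keep <- roPass | containPass
  }
  pr <- pr[keep, , drop = FALSE]
  ids <- siteId(x)
  memb <- .components(ids, ids[pr$i], ids[pr$j])
  msq <- stats::setNames(qualMetric(x, "MSQ"), ids)
  comps <- split(names(memb), memb)
  multi <- Filter(function(m) length(m) >= 2L, comps)
  multi <- multi[order(vapply(multi, min, character(1)))]
  clusters <- do.call(rbind, lapply(seq_along(multi), function(k) {
    members <- sort(multi[[k]])
    prim <- .pickPrimary(members, msq[members])
    data.frame(cluster_id = sprintf("ssc%04d", k), site_id = members,
               role = ifelse(members == prim, "primary", "secondary"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(clusters)) {
    clusters <- data.frame(cluster_id = character(), site_id = character(),
                           role = character())
  }
  secondary <- clusters$site_id[clusters$role == "secondary"]
  st <- filterStatus(x)
  st[ids %in% secondary] <- "secondary"
  filterStatus(x) <- st
  rowData(x)$dedup_cluster <- clusters$cluster_id[match(ids, clusters$site_id)]
  rowData(x)$primary <- !(ids %in% secondary)
  list(clusters = clusters,
       edges = data.frame(id_a = ids[pr$i], id_b = ids[pr$j],
                          frac_a = pr$frac_i, frac_b = pr$frac_j),
       callset = x,
       nonredundant = x[!(ids %in% secondary), ])
}

# Fraction of non-mode samples (union over the two rows) whose values
# differ; NA when no sample is non-mode at either site.
.nonModeDiff <- function(a, b) {
  ma <- .modalValue(a); mb <- .modalValue(b)
  u <- which((!is.na(a) & a != ma) | (!is.na(b) & b != mb))
  u <- u[!is.na(a[u]) & !is.na(b[u])]
  if (!length(u)) return(NA_real_)
  mean(a[u] != b[u])
}

#' Cross-discovery-set deduplication of Genome STRiP calls
#'
#' Collapses redundant CNVs discovered separately in two sample collections.
#' A pair is redundant when it has (1) at least 50% reciprocal overlap, (2)
#' Pearson correlation of copy numbers among non-iPSC samples > 0.95, and
#' (3) differing copy-number genotypes in fewer than 5% of the non-mode
#' (union) non-iPSC samples. Exactly coinciding pairs are resolved first
#' (higher GSCNQUAL is primary); remaining overlaps are processed greedily
#' within connected components by descending average percentage overlap,
#' higher GSCNQUAL primary, ties to the smaller site id.
#'
#' @param setA,setB [SVCallSet-class] objects from the two discovery sets
#'   (same sample universe).
#' @param nonIpsc Character vector of non-iPSC sample ids; must be
#'   non-empty.
#' @param minRO,minCnCor,maxNonModeDiff Rule thresholds.
#' @return List: `clusters` (cluster_id, site_id, set, role), `redundant`
#'   ids, `nonredundant` (combined call set without redundant records).
#' @export
dedupGenomestrip <- function(setA, setB, nonIpsc = NULL, minRO = 0.5,
                             minCnCor = 0.95, maxNonModeDiff = 0.05) {
  if (is.null(nonIpsc) && "cell_type" %in% colnames(colData(setA))) {
    nonIpsc <- colnames(setA)[colData(setA)$cell_type != "iPSC"]
  }
  if (!length(nonIpsc)) .stopf("non-iPSC sample set is empty")
  cnA <- cnMatrix(setA)[, nonIpsc, drop = FALSE]
  cnB <- cnMatrix(setB)[, nonIpsc, drop = FALSE]
  grA <- rowRanges(setA); grB <- rowRanges(setB)
  idsA <- siteId(setA); idsB <- siteId(setB)
  qA <- qualMetric(setA, "GSCNQUAL"); qB <- qualMetric(setB, "GSCNQUAL")
  pr <- .overlapPairs(grA, grB)
  if (nrow(pr)) {
    ok <- pmin(pr$frac_i, pr$frac_j) >= minRO
    pr <- pr[ok, , drop = FALSE]
    ok <- vapply(seq_len(nrow(pr)), function(k) {
      r <- .safeCor(cnA[pr$i[k], ], cnB[pr$j[k], ])
      if (is.na(r) || r <= minCnCor) return(FALSE)
      d <- .nonModeDiff(cnA[pr$i[k], ], cnB[pr$j[k], ])
      !is.na(d) && d < maxNonModeDiff
    }, logical(1))
    pr <- pr[ok, , drop = FALSE]
  }
  redundant <- character()
  rows <- list()
  cid <- 0L
  mark <- function(prim, sec, setP, setS) {
    cid <<- cid + 1L
    redundant <<- c(redundant, sec)
    rows[[length(rows) + 1L]] <<- data.frame(
      cluster_id = sprintf("gsc%04d", cid),
      site_id = c(prim, sec), set = c(setP, setS),
      role = c("primary", "redundant"), stringsAsFactors = FALSE)
  }
  exact <- nrow(pr) > 0 &
    start(grA)[pr$i] == start(grB)[pr$j] & end(grA)[pr$i] == end(grB)[pr$j]
  for (k in which(exact)) {
    a <- idsA[pr$i[k]]; b <- idsB[pr$j[k]]
    if (a %in% redundant || b %in% redundant) next
    if (.pickPrimary(c(a, b), c(qA[pr$i[k]], qB[pr$j[k]])) == a) {
      mark(a, b, "A", "B")
    } else mark(b, a, "B", "A")
  }
  rest <- pr[!exact, , drop = FALSE]
  if (nrow(rest)) {
    avg <- (rest$frac_i + rest$frac_j) / 2
    qsum <- ifelse(is.na(qA[rest$i]), 0, qA[rest$i]) +
      ifelse(is.na(qB[rest$j]), 0, qB[rest$j])
    ord <- order(-avg, -qsum, idsA[rest$i], idsB[rest$j])
    for (k in ord) {
      a <- idsA[rest$i[k]]; b <- idsB[rest$j[k]]
      if (a %in% redundant || b %in% redundant) next
      if (.pickPrimary(c(a, b), c(qA[rest$i[k]], qB[rest$j[k]])) == a) {
        mark(a, b, "A", "B")
      } else mark(b, a, "B", "A")
    }
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = character(), site_id = character(),
               set = character(), role = character())
  keepA <- setA[!(idsA %in% redundant), ]
  keepB <- setB[!(idsB %in% redundant), ]
  combined <- .rbindCallSets(list(keepA, keepB))
  list(clusters = clusters, redundant = redundant, nonredundant = combined)
}

# Row-bind call sets sharing one sample universe.
.rbindCallSets <- function(xs) {
  xs <- xs[vapply(xs, nrow, integer(1)) > 0]
  if (length(xs) == 1L) return(xs[[1]])
  common <- Reduce(union, lapply(xs, assayNames))
  samples <- colnames(xs[[1]])
  naProto <- function(nm, x) {
    proto <- if (nm == "gt") NA_integer_ else if (nm == "lq") NA else NA_real_
    matrix(proto, nrow(x), length(samples),
           dimnames = list(siteId(x), samples))
  }
  gr <- do.call(c, lapply(xs, function(x) GRanges(seqnames(rowRanges(x)),
                                                  IRanges(start(rowRanges(x)),
                                                          end(rowRanges(x))))))
  qual <- do.call(rbind, lapply(xs, function(x)
    as.data.frame(rowData(x)[, svQualityKeys(), drop = FALSE])))
  asy <- lapply(stats::setNames(common, common), function(nm)
    do.call(rbind, lapply(xs, function(x)
      if (nm %in% assayNames(x)) assay(x, nm)[, samples, drop = FALSE]
      else naProto(nm, x))))
  y <- SVCallSet(gr,
                 siteId = unlist(lapply(xs, siteId)),
                 caller = unlist(lapply(xs, svCaller)),
                 svtype = unlist(lapply(xs, svType)),
                 svLen = unlist(lapply(xs, svLen)),
                 quality = qual,
                 meltFlags = do.call(c, lapply(xs, meltFlags)),
                 gt = asy$gt, cn = asy$cn, ab = asy$ab, lq = asy$lq,
                 sampleInfo = as.data.frame(colData(xs[[1]])),
                 filterStatus = unlist(lapply(xs, filterStatus)),
                 extraAssays = asy[setdiff(names(asy), c("gt", "cn", "ab", "lq"))])
  if (all(vapply(xs, function(x) !is.null(rowData(x)$cluster_id), logical(1)))) {
    rowData(y)$cluster_id <- unlist(lapply(xs, function(x) rowData(x)$cluster_id))
  }
  y
}

#' Stitch adjacent fragmented Genome STRiP CNVs
#'
#' Read-depth callers occasionally report one CNV as several adjacent
#' fragments. Per chromosome, CNV pairs with copy-number genotype
#' correlation > 0.9 are connected; within each connected component,
#' position-sorted adjacent pairs are merged when they additionally show at
#' least 80% copy-number concordance among the union of non-mode samples
#' and lie within `maxGap` bp of each other. Each resulting group becomes a
#' stitch breakpoint spanning the first constituent's start to the last
#' constituent's end; a constituent already spanning the whole interval
#' makes the breakpoint pre-existing.
#'
#' @param x Filtered, non-redundant [SVCallSet-class] of read-depth CNVs
#'   with a `cn` assay.
#' @param maxGap Maximum gap between adjacent fragments (default 30 kb).
#' @param minCor Copy-number correlation to connect a pair (strict >, 0.9).
#' @param minConcord Concordance among union non-mode samples (at least,
#'   0.8).
#' @return List: `stitches` (stitch_id, chrom, start, end, n_constituents,
#'   is_preexisting, status), `members` (stitch_id, site_id).
#' @export
stitchGenomestrip <- function(x, maxGap = 30000, minCor = 0.9,
                              minConcord = 0.8) {
  cn <- cnMatrix(x)
  if (is.null(cn)) .stopf("stitching requires the cn assay")
  gr <- rowRanges(x)
  ids <- siteId(x)
  stitches <- list(); members <- list()
  sid <- 0L
  for (chrom in unique(as.character(seqnames(gr)))) {
    ix <- which(as.character(seqnames(gr)) == chrom)
    ix <- ix[order(start(gr)[ix], ids[ix])]
    if (length(ix) < 2L) next
    # correlation graph on this chromosome
    ef <- integer(); et <- integer()
    for (a in seq_along(ix)) {
      for (b in seq_len(a - 1L)) {
        r <- .safeCor(cn[ix[a], ], cn[ix[b], ])
        if (!is.na(r) && r > minCor) { ef <- c(ef, a); et <- c(et, b) }
      }
    }
    memb <- .components(as.character(seq_along(ix)), as.character(ef),
                        as.character(et))
    for (comp in split(seq_along(ix), memb)) {
      if (length(comp) < 2L) next
      comp <- comp[order(start(gr)[ix[comp]], ids[ix[comp]])]
      # merge adjacent pairs passing concordance and gap rules (union-find)
      grp <- seq_along(comp)
      for (k in seq_len(length(comp) - 1L)) {
        i1 <- ix[comp[k]]; i2 <- ix[comp[k + 1L]]
        gap <- max(0L, start(gr)[i2] - end(gr)[i1] - 1L)
        if (gap > maxGap) next
        conc <- 1 - .nonModeDiff(cn[i1, ], cn[i2, ])
        if (is.na(conc) || conc < minConcord) next
        grp[grp == grp[k + 1L]] <- grp[k]
      }
      for (g in unique(grp)) {
        sel <- ix[comp[grp == g]]
        if (length(sel) < 2L) next
        sid <- sid + 1L
        s0 <- min(start(gr)[sel]); e0 <- max(end(gr)[sel])
        pre <- any(start(gr)[sel] == s0 & end(gr)[sel] == e0)
        stitches[[sid]] <- data.frame(
          stitch_id = sprintf("stitch%04d", sid), chrom = chrom,
          start = s0, end = e0, n_constituents = length(sel),
          is_preexisting = pre, status = "stitched",
          stringsAsFactors = FALSE)
        members[[sid]] <- data.frame(stitch_id = sprintf("stitch%04d", sid),
                                     site_id = ids[sel],
                                     stringsAsFactors = FALSE)
      }
    }
  }
  list(stitches = if (length(stitches)) do.call(rbind, stitches) else
         data.frame(stitch_id = character(), chrom = character(),
                    start = integer(), end = integer(),
                    n_constituents = integer(), is_preexisting = logical(),
                    status = character()),
       members = if (length(members)) do.call(rbind, members) else
         data.frame(stitch_id = character(), site_id = character()))
}

#' Validate a stitch breakpoint against its constituents
#'
#' A stitch stands when the breakpoint's copy-number genotypes correlate
#' with the constituents at mean r >= 0.9, carry at most 10% low-quality
#' flags, and the breakpoint is polymorphic. Otherwise the cluster is
#' unstitched, and a newly created (not pre-existing) breakpoint is
#' additionally marked filtered.
#'
#' @param stitchRow Copy-number vector of the stitch breakpoint across
#'   samples.
#' @param constituentRows Matrix of constituent copy-number rows.
#' @param lqFraction Fraction of low-quality genotypes at the breakpoint.
#' @param isNew Whether the breakpoint was newly created by stitching.
#' @return `"stitched"`, `"unstitched"`, or `"filtered"`.
#' @export
validateStitch <- function(stitchRow, constituentRows, lqFraction = 0,
                           isNew = TRUE) {
  rs <- apply(constituentRows, 1, function(r) .safeCor(stitchRow, r))
  meanR <- mean(rs, na.rm = TRUE)
  poly <- length(unique(stitchRow[!is.na(stitchRow)])) > 1L
  ok <- !is.nan(meanR) && !is.na(meanR) && meanR >= 0.9 &&
    lqFraction <= 0.1 && poly
  if (ok) "stitched" else if (isNew) "filtered" else "unstitched"
}

#' Merge per-sample long-CNV calls across samples
#'
#' Long CNVs are called per sample; calls from different samples with at
#' least 80% reciprocal overlap are grouped into clusters and represented
#' by a single breakpoint spanning the minimum start to the maximum end.
#' Copy numbers are rounded to integers; singleton calls pass through.
#'
#' @param x [SVCallSet-class] of per-sample long-CNV records.
#' @param minRO Reciprocal overlap for clustering (at least, 0.8).
#' @return List: `callset` (merged sites), `clusters` (merged_id, site_id).
#' @export
clusterLcnv <- function(x, minRO = 0.8) {
  gr <- rowRanges(x)
  ids <- siteId(x)
  pr <- .overlapPairs(gr)
  pr <- pr[pmin(pr$frac_i, pr$frac_j) >= minRO &
           svType(x)[pr$i] == svType(x)[pr$j], , drop = FALSE]
  memb <- .components(ids, ids[pr$i], ids[pr$j])
  cn <- cnMatrix(x)
  ord <- .siteOrder(x)
  groups <- split(seq_len(nrow(x)), memb[ids])
  groups <- groups[order(vapply(groups, function(g) min(match(g, ord)), numeric(1)))]
  recs <- list(); cnRows <- list(); membership <- list()
  for (gidx in seq_along(groups)) {
    g <- groups[[gidx]]
    mid <- sprintf("lcnvm%04d", gidx)
    s0 <- min(start(gr)[g]); e0 <- max(end(gr)[g])
    row <- rep(NA_real_, ncol(x))
    if (!is.null(cn)) {
      sub <- cn[g, , drop = FALSE]
      row <- suppressWarnings(apply(sub, 2, function(v)
        if (all(is.na(v))) NA_real_ else round(mean(v, na.rm = TRUE))))
    }
    recs[[gidx]] <- data.frame(
      site_id = mid, chrom = as.character(seqnames(gr))[g[1]],
      start = s0, end = e0, svtype = svType(x)[g[1]],
      n_samples = length(g), stringsAsFactors = FALSE)
    cnRows[[gidx]] <- row
    membership[[gidx]] <- data.frame(merged_id = mid, site_id = ids[g],
                                     stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, recs)
  cnM <- do.call(rbind, cnRows)
  colnames(cnM) <- colnames(x)
  gtM <- ifelse(is.na(cnM), NA_integer_, as.integer(pmin(2, abs(cnM - 2))))
  y <- SVCallSet(GRanges(df$chrom, IRanges(df$start, df$end)),
                 siteId = df$site_id, caller = "gs_lcnv", svtype = df$svtype,
                 gt = gtM, cn = cnM,
                 sampleInfo = as.data.frame(colData(x)))
  rowData(y)$n_samples <- df$n_samples
  list(callset = y, clusters = do.call(rbind, membership))
}

#' Generic cross-caller merge by reciprocal overlap and class
#'
#' Connects pairs of records (from any callers) with matching variant
#' classes and reciprocal overlap of at least `minRO`; connected components
#' become merged sites spanning the minimum start to the maximum end, with
#' the number of supporting callers reported.
#'
#' @param xs List of [SVCallSet-class] objects (or a single one).
#' @param minRO Reciprocal overlap threshold (at least, default 0.5).
#' @param classMatch Require equal svtype on edges (default TRUE).
#' @return List: `merged` (data frame of merged sites with `n_callers`),
#'   `members` (merged_id, site_id, caller).
#' @export
mergeGeneric <- function(xs, minRO = 0.5, classMatch = TRUE) {
  if (inherits(xs, "SVCallSet")) xs <- list(xs)
  all_ <- .rbindCallSets(xs)
  gr <- rowRanges(all_)
  ids <- siteId(all_)
  pr <- .overlapPairs(gr)
  ok <- pmin(pr$frac_i, pr$frac_j) >= minRO
  if (classMatch) ok <- ok & svType(all_)[pr$i] == svType(all_)[pr$j]
  pr <- pr[ok, , drop = FALSE]
  memb <- .components(ids, ids[pr$i], ids[pr$j])
  groups <- split(seq_len(nrow(all_)), memb[ids])
  ord <- .siteOrder(all_)
  groups <- groups[order(vapply(groups, function(g) min(match(g, ord)), numeric(1)))]
  merged <- list(); members <- list()
  for (gidx in seq_along(groups)) {
    g <- groups[[gidx]]
    mid <- sprintf("mrg%05d", gidx)
    merged[[gidx]] <- data.frame(
      merged_id = mid, chrom = as.character(seqnames(gr))[g[1]],
      start = min(start(gr)[g]), end = max(end(gr)[g]),
      svtype = svType(all_)[g[1]],
      n_members = length(g),
      n_callers = length(unique(svCaller(all_)[g])),
      stringsAsFactors = FALSE)
    members[[gidx]] <- data.frame(merged_id = mid, site_id = ids[g],
                                  caller = svCaller(all_)[g],
                                  stringsAsFactors = FALSE)
  }
  list(merged = do.call(rbind, merged), members = do.call(rbind, members))
}
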