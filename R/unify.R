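#' Unification rule thresholds
#'
#' Thresholds for cross-caller unification of read-depth (Genome STRiP) and
#' split-read (SpeedSeq) call sets: pairs connect on > 50% reciprocal
#' overlap or full containment where the smaller variant spans at least 40%
#' of the larger; within overlap components, genotype-evidence squared
#' correlation must exceed 0.5 — except components pairing a SpeedSeq DUP
#' and DEL with a Genome STRiP mCNV, where any positive R-squared connects.
#'
#' @param min_ro Reciprocal overlap threshold (strict >).
#' @param containment_min_frac Minimum fraction of the larger variant's
#'   length spanned by a fully contained smaller variant; NA disables the
#'   containment shortcut (pure reciprocal-overlap rule, as in the
#'   threshold sweep).
#' @param r2_general Squared-correlation threshold (strict >).
#' @param r2_mcnv_mixed Threshold for the mCNV-mixed exemption (strict >).
#' @return A list of class `"UnifyRule"`.
#' @export
unifyRule <- function(min_ro = 0.5, containment_min_frac = 0.4,
                      r2_general = 0.5, r2_mcnv_mixed = 0) {
  vals <- c(min_ro, containment_min_frac, r2_general, r2_mcnv_mixed)
  if (any(!is.na(vals) & (vals < 0 | vals > 1))) {
    .stopf("unify thresholds must lie in [0, 1]")
  }
  structure(list(min_ro = min_ro, containment_min_frac = containment_min_frac,
                 r2_general = r2_general, r2_mcnv_mixed = r2_mcnv_mixed),
            class = "UnifyRule")
}

#' SV class compatibility for cross-caller matching
#'
#' Same classes always match; mCNVs additionally match duplications and
#' deletions (an mCNV is seen as a DUP or DEL by a biallelic caller), and
#' deletions match reference mobile element insertions (rMEIs appear as
#' deletions).
#'
#' @param a,b SV class strings (vectorised).
#' @return Logical vector.
#' @export
#' @examples
#' typeCompatible("mCNV", "DUP")  # TRUE
#' typeCompatible("INV", "DEL")   # FALSE
typeCompatible <- function(a, b) {
  same <- a == b
  mcnv <- (a == "mCNV" & b %in% c("DEL", "DUP")) |
          (b == "mCNV" & a %in% c("DEL", "DUP"))
  rmei <- (a == "DEL" & b == "rMEI") | (b == "DEL" & a == "rMEI")
  same | mcnv | rmei
}

# Squared Pearson correlation of the two records' native evidence channels
# (copy number for Genome STRiP, allele balance for SpeedSeq), over shared
# samples; NA when < 2 shared observations or zero variance.
.evidenceR2 <- function(evA, evB) {
  r <- .safeCor(evA, evB)
  if (is.na(r)) NA_real_ else r^2
}

.evidenceRow <- function(x, i) {
  if (svCaller(x)[i] %in% c("genomestrip", "gs_lcnv")) cnMatrix(x)[i, ]
  else if (!is.null(abMatrix(x))) abMatrix(x)[i, ]
  else gtMatrix(x)[i, ]
}

#' Build the cross-caller unification graph
#'
#' Stage 1 connects Genome STRiP and SpeedSeq records that are
#' type-compatible and either reciprocally overlap by more than
#' `rule$min_ro` or exhibit full containment with the smaller variant
#' spanning at least `rule$containment_min_frac` of the larger. Stage 2
#' re-tests every pair within each stage-1 connected component on
#' genotype-evidence squared correlation (copy number for the read-depth
#' caller, allele balance for the split-read caller, over shared samples):
#' edges need R-squared above `rule$r2_general`, relaxed to
#' `rule$r2_mcnv_mixed` in components containing a SpeedSeq DUP and DEL
#' together with a Genome STRiP mCNV. Stage-2 components are the final
#' clusters; refinement can only split stage-1 components.
#'
#' @param gs,ss Filtered, internally deduplicated [SVCallSet-class] objects
#'   (read-depth and split-read call sets).
#' @param rule A [unifyRule()].
#' @return List: `clusters` (cluster_id, site_id, caller, degree),
#'   `combined` call set, `edges` (stage-2 edges).
#' @export
buildUnifyGraph <- function(gs, ss, rule = unifyRule()) {
  both <- .rbindCallSets(list(gs, ss))
  ids <- siteId(both)
  gr <- rowRanges(both)
  caller <- svCaller(both)
  fromGS <- caller %in% c("genomestrip", "gs_lcnv")
  pr <- .overlapPairs(gr)
  # stage 1: cross-caller, type-compatible, RO or containment
  cross <- fromGS[pr$i] != fromGS[pr$j]
  tc <- typeCompatible(svType(both)[pr$i], svType(both)[pr$j])
  roPass <- pmin(pr$frac_i, pr$frac_j) > rule$min_ro
  wi <- width(gr)
  containPass <- if (is.na(rule$containment_min_frac)) rep(FALSE, nrow(pr)) else
    (pr$i_in_j & wi[pr$i] >= rule$containment_min_frac * wi[pr$j]) |
    (pr$j_in_i & wi[pr$j] >= rule$containment_min_frac * wi[pr$i])
  s1 <- pr[cross & tc & (roPass | containPass), , drop = FALSE]
  memb1 <- .components(ids, ids[s1$i], ids[s1$j])
  # stage 2: within each stage-1 component, evidence correlation on all pairs
  ef <- character(); et <- character(); er2 <- numeric()
  for (comp in split(seq_len(nrow(both)), memb1)) {
    if (length(comp) < 2L) next
    mixed <- any(caller[comp] == "speedseq" & svType(both)[comp] == "DUP") &&
             any(caller[comp] == "speedseq" & svType(both)[comp] == "DEL") &&
             any(fromGS[comp] & svType(both)[comp] == "mCNV")
    thr <- if (mixed) rule$r2_mcnv_mixed else rule$r2_general
    for (a in seq_along(comp)) {
      for (b in seq_len(a - 1L)) {
        i <- comp[a]; j <- comp[b]
        r2 <- .evidenceR2(.evidenceRow(both, i), .evidenceRow(both, j))
        if (!is.na(r2) && r2 > thr) {
          ef <- c(ef, ids[i]); et <- c(et, ids[j]); er2 <- c(er2, r2)
        }
      }
    }
  }
  memb2 <- .components(ids, ef, et)
  deg <- stats::setNames(integer(length(ids)), ids)
  for (k in seq_along(ef)) {
    deg[ef[k]] <- deg[ef[k]] + 1L
    deg[et[k]] <- deg[et[k]] + 1L
  }
  comps <- split(names(memb2), memb2)
  multi <- Filter(function(m) length(m) >= 2L, comps)
  multi <- multi[order(vapply(multi, min, character(1)))]
  clusters <- do.call(rbind, lapply(seq_along(multi), function(k) {
    members <- sort(multi[[k]])
    data.frame(cluster_id = sprintf("uc%04d", k), site_id = members,
               caller = caller[match(members, ids)],
               degree = unname(deg[members]), stringsAsFactors = FALSE)
  }))
  clusters <- clusters %||% data.frame(cluster_id = character(),
                                       site_id = character(),
                                       caller = character(),
                                       degree = integer())
  list(clusters = clusters, combined = both,
       edges = data.frame(id_a = ef, id_b = et, r2 = er2,
                          stringsAsFactors = FALSE))
}

#' Select the primary site of a unification cluster
#'
#' Per caller, the candidate is the member connected to the most other
#' members (highest degree), ties broken by quality score (GSCNQUAL for the
#' read-depth caller, MSQ for the split-read caller), then smaller site id.
#' The read-depth candidate is primary — its integer copy numbers and
#' higher replication make it the better representative — except when the
#' cluster pairs a Genome STRiP deletion with a SpeedSeq rMEI, in which
#' case the SpeedSeq record is primary.
#'
#' @param cluster One cluster's rows from [buildUnifyGraph()] (`site_id`,
#'   `caller`, `degree`).
#' @param quality Named numeric vector of quality scores per site id.
#' @param svtypes Named character vector of SV classes per site id.
#' @return `list(primary, secondaries)`.
#' @export
selectPrimary <- function(cluster, quality, svtypes) {
  if (!nrow(cluster)) .stopf("empty cluster")
  cand <- vapply(split(cluster, cluster$caller), function(cc) {
    q <- ifelse(is.na(quality[cc$site_id]), -Inf, quality[cc$site_id])
    cc$site_id[order(-cc$degree, -q, cc$site_id)][1]
  }, character(1))
  gsIds <- cluster$site_id[cluster$caller %in% c("genomestrip", "gs_lcnv")]
  ssIds <- cluster$site_id[cluster$caller == "speedseq"]
  rmeiException <- any(svtypes[gsIds] == "DEL") && any(svtypes[ssIds] == "rMEI")
  primary <- if (rmeiException && "speedseq" %in% names(cand)) {
    cand[["speedseq"]]
  } else if ("genomestrip" %in% names(cand)) {
    cand[["genomestrip"]]
  } else if ("gs_lcnv" %in% names(cand)) {
    cand[["gs_lcnv"]]
  } else {
    cand[[1]]
  }
  list(primary = primary,
       secondaries = setdiff(cluster$site_id, primary))
}

#' Assemble the unified non-redundant call set
#'
#' The final set consists of the primary site of every unification cluster
#' plus all records that entered no cluster; members of a cluster other
#' than the primary are marked secondary and tagged with the cluster id.
#' Re-running on its own output is the identity.
#'
#' @param graph Output of [buildUnifyGraph()].
#' @return List: `callset` (full, annotated), `nonredundant` (primaries
#'   plus singletons), `assignments` (site_id, cluster_id, role),
#'   `class_counts` (table of final classes).
#' @export
assembleNonredundant <- function(graph) {
  both <- graph$combined
  ids <- siteId(both)
  quality <- stats::setNames(
    ifelse(svCaller(both) %in% c("genomestrip", "gs_lcnv"),
           qualMetric(both, "GSCNQUAL"), qualMetric(both, "MSQ")), ids)
  svt <- stats::setNames(svType(both), ids)
  assigns <- list()
  for (cid in unique(graph$clusters$cluster_id)) {
    cl <- graph$clusters[graph$clusters$cluster_id == cid, ]
    sel <- selectPrimary(cl, quality, svt)
    assigns[[cid]] <- data.frame(
      site_id = c(sel$primary, sel$secondaries), cluster_id = cid,
      role = c("primary", rep("secondary", length(sel$secondaries))),
      stringsAsFactors = FALSE)
  }
  assignments <- if (length(assigns)) do.call(rbind, assigns) else
    data.frame(site_id = character(), cluster_id = character(),
               role = character())
  rownames(assignments) <- NULL
  secondary <- assignments$site_id[assignments$role == "secondary"]
  st <- filterStatus(both)
  st[ids %in% secondary] <- "secondary"
  filterStatus(both) <- st
  rowData(both)$unify_cluster <- assignments$cluster_id[match(ids, assignments$site_id)]
  rowData(both)$primary <- !(ids %in% secondary)
  nonred <- both[!(ids %in% secondary), ]
  list(callset = both, nonredundant = nonred, assignments = assignments,
       class_counts = table(svType(nonred)))
}

#' Sweep reciprocal-overlap and genotype-correlation thresholds
#'
#' Runs [buildUnifyGraph()] over a grid of thresholds and reports, per
#' cell, how many records enter clusters (`n_combined`) and how many final
#' sites result (`n_output` = clusters + singletons). The sweep varies the
#' pure reciprocal-overlap rule (containment shortcut disabled) so combined
#' counts are non-increasing in both thresholds and a threshold above every
#' overlap merges nothing.
#'
#' @param gs,ss Call sets as in [buildUnifyGraph()].
#' @param roGrid,r2Grid Numeric vectors of thresholds.
#' @return Data frame with `ro`, `r2`, `n_input`, `n_combined`,
#'   `n_clusters`, `n_output`.
#' @export
unifyParameterSweep <- function(gs, ss, roGrid = c(0.1, 0.5, 0.9),
                                r2Grid = c(0.1, 0.5, 0.9)) {
  nIn <- nrow(gs) + nrow(ss)
  out <- list()
  for (ro in roGrid) {
    for (r2 in r2Grid) {
      g <- buildUnifyGraph(gs, ss, unifyRule(min_ro = ro, r2_general = r2,
                                             containment_min_frac = NA))
      nComb <- length(unique(g$clusters$site_id))
      nClust <- length(unique(g$clusters$cluster_id))
      out[[length(out) + 1L]] <- data.frame(
        ro = ro, r2 = r2, n_input = nIn, n_combined = nComb,
        n_clusters = nClust, n_output = nIn - nComb + nClust)
    }
  }
  do.call(rbind, out)
}
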