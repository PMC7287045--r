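#' Simulation configuration for synthetic multi-caller cohorts
#'
#' Defines the synthetic study: a two-collection cohort (iPSCORE-like with
#' monozygotic twin pairs of blood samples; HipSci-like with fibroblast-iPSC
#' pairs), planted SV/STR loci with Hardy-Weinberg genotypes, and per-caller
#' "views" of those loci with breakpoint jitter, quality-linked genotype
#' error, CNV fragmentation, MELT hard-filter flags, array probe intensities
#' and SNPs in linkage disequilibrium with the planted variants. Defaults
#' mirror the study design the package targets: 25 twin pairs and 152
#' fibroblast-iPSC pairs on a small synthetic genome (3 contigs x 10 Mb).
#'
#' The genotype error model is a symmetric flip among genotype states with
#' probability `e(q) = error_max * plogis(-(q - error_mid) / error_scale)`
#' where `q` is the simulated site quality on a 0-100 scale, so replication
#' rate rises monotonically with quality score, and MELT-flagged sites carry
#' `flag_error_mult`-fold elevated error.
#'
#' @param seed Integer seed; mandatory. Every emission is a deterministic
#'   function of (config, seed).
#' @param n_donors Total donor genomes; donors beyond the paired ones
#'   contribute one sample each.
#' @param n_twin_pairs,n_fib_ipsc_pairs Replicate-pair counts.
#' @param sites Named integer vector of truth-site counts per SV class.
#' @param n_lcnv Number of long (>=100 kb) CNV truth sites called per sample.
#' @param af_range Population allele-frequency range for planted sites.
#' @param error_max,error_mid,error_scale Genotype error schedule (see
#'   above).
#' @param jitter Maximum breakpoint jitter in bp applied to emitted records.
#' @param frag_prob,frag_max_k,frag_max_gap Probability that a read-depth
#'   caller reports a CNV as `k` in 2..`frag_max_k` adjacent fragments with
#'   gaps up to `frag_max_gap` bp (stitching targets).
#' @param dup_prob Probability of emitting a redundant second record for a
#'   site within the split-read caller (deduplication targets).
#' @param mcnv_ss_frac Fraction of mCNV loci that the split-read caller
#'   reports as an overlapping DUP + DEL pair (unification exemption
#'   targets).
#' @param fp_per_caller Planted false-positive records per caller, emitted
#'   with low quality scores and random genotypes.
#' @param melt_flag_probs Named probabilities for the lc/s25/rSD/hDP flags.
#' @param flag_error_mult Error multiplier for flagged MELT sites.
#' @param n_hwe_violation,hwe_f Number of planted HWE-violating sites and
#'   their inbreeding coefficient (excess homozygosity).
#' @param n_batch_skew,batch_af_shift Number of planted batch-skewed sites
#'   and the allele-frequency shift applied to the second collection.
#' @param probe_spacing,probe_sigma,probe_alpha Array probe spacing (bp),
#'   intensity noise SD, and intensity change per copy relative to diploid.
#' @param n_batches,n_plates,batch_sd Array batch/plate structure and offset
#'   SD for intensity covariates.
#' @param snp_per_sv,tagged_frac,ld_eps,snp_window SNP panel: SNPs drawn per
#'   SV, fraction of SVs given a tagging SNP within `snp_window` bp whose
#'   genotype equals the SV dosage with per-sample flip probability
#'   `ld_eps`.
#' @param contigs Named vector of contig lengths.
#' @param callers Callers to emit views for.
#' @return A list with class `"SimConfig"`.
#' @export
simConfig <- function(seed,
                      n_donors = 300,
                      n_twin_pairs = 25,
                      n_fib_ipsc_pairs = 152,
                      sites = c(DEL = 120, DUP = 40, mCNV = 24, INV = 15,
                                BND = 20, rMEI = 20, ALU = 40, LINE1 = 10,
                                SVA = 5, STR = 40),
                      n_lcnv = 10,
                      af_range = c(0.05, 0.5),
                      error_max = 0.3, error_mid = 40, error_scale = 12,
                      jitter = 20,
                      frag_prob = 0.2, frag_max_k = 5, frag_max_gap = 5000,
                      dup_prob = 0.1,
                      mcnv_ss_frac = 0.25,
                      fp_per_caller = 10,
                      melt_flag_probs = c(lc = 0.15, s25 = 0.05,
                                          rSD = 0.05, hDP = 0.05),
                      flag_error_mult = 6,
                      n_hwe_violation = 0, hwe_f = 0.5,
                      n_batch_skew = 0, batch_af_shift = 0.3,
                      probe_spacing = 2000, probe_sigma = 0.15,
                      probe_alpha = 0.4,
                      n_batches = 4, n_plates = 8, batch_sd = 0.05,
                      snp_per_sv = 8, tagged_frac = 0.7, ld_eps = 0.02,
                      snp_window = 50000,
                      contigs = c(chr1 = 1e7, chr2 = 1e7, chr3 = 1e7),
                      callers = c("speedseq", "genomestrip", "gs_lcnv",
                                  "melt", "hipstr", "wham", "manta")) {
  if (missing(seed)) .stopf("simConfig requires an explicit seed")
  probs <- c(unname(melt_flag_probs), frag_prob, dup_prob, tagged_frac,
             ld_eps, mcnv_ss_frac, error_max)
  if (any(probs < 0 | probs > 1)) .stopf("probabilities must lie in [0, 1]")
  if (n_donors < n_twin_pairs + n_fib_ipsc_pairs) {
    .stopf("n_donors (%d) < donors needed for pairs (%d)",
           n_donors, n_twin_pairs + n_fib_ipsc_pairs)
  }
  if (n_donors <= 0) .stopf("cohort must contain at least one sample")
  cfg <- as.list(environment())
  class(cfg) <- "SimConfig"
  cfg
}

.errorRate <- function(cfg, q) {
  cfg$error_max * stats::plogis(-(q - cfg$error_mid) / cfg$error_scale)
}

#' Simulate the cohort: samples and replicate pairs
#'
#' Twin-pair donors contribute two blood samples to the iPSCORE-like
#' collection; fibroblast-iPSC donors contribute a fibroblast and an iPSC
#' sample to the HipSci-like collection; remaining donors contribute one
#' sample, alternating between the collections.
#'
#' @param config A [simConfig()] object.
#' @return `list(samples, pairs)` as in [readSampleManifest()].
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  .withSeed(config$seed, {
    donors <- sprintf("D%04d", seq_len(config$n_donors))
    rows <- list(); pairs <- list()
    sp <- sample(.superpops, config$n_donors, replace = TRUE,
                 prob = c(0.8, 0.05, 0.05, 0.05, 0.05))
    sex <- sample(c("M", "F"), config$n_donors, replace = TRUE)
    i <- 1L
    for (k in seq_len(config$n_twin_pairs)) {
      d <- donors[i]
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = paste0(d, c("_A", "_B")), donor_id = d, study = "iPSCORE",
        cell_type = "blood", superpopulation = sp[i], sex = sex[i])
      pairs[[length(pairs) + 1L]] <- data.frame(
        sample_a = paste0(d, "_A"), sample_b = paste0(d, "_B"),
        pair_type = "mz_twin")
      i <- i + 1L
    }
    for (k in seq_len(config$n_fib_ipsc_pairs)) {
      d <- donors[i]
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = paste0(d, c("_F", "_I")), donor_id = d, study = "HipSci",
        cell_type = c("fibroblast", "iPSC"), superpopulation = sp[i],
        sex = sex[i])
      pairs[[length(pairs) + 1L]] <- data.frame(
        sample_a = paste0(d, "_F"), sample_b = paste0(d, "_I"),
        pair_type = "fib_ipsc")
      i <- i + 1L
    }
    j <- 0L
    while (i <= config$n_donors) {
      d <- donors[i]
      st <- if (j %% 2L == 0L) "iPSCORE" else "HipSci"
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = paste0(d, "_S"), donor_id = d, study = st,
        cell_type = if (st == "iPSCORE") "blood" else "fibroblast",
        superpopulation = sp[i], sex = sex[i])
      i <- i + 1L; j <- j + 1L
    }
    samples <- do.call(rbind, rows)
    rownames(samples) <- NULL
    pairs <- if (length(pairs)) do.call(rbind, pairs) else
      data.frame(sample_a = character(), sample_b = character(),
                 pair_type = character())
    list(samples = samples, pairs = pairs)
  })
}

.classLenRange <- function(svtype) {
  switch(svtype,
         DEL = c(500, 50000), DUP = c(500, 50000), mCNV = c(2000, 50000),
         INV = c(500, 20000), BND = c(1000, 1000), rMEI = c(300, 6000),
         ALU = c(280, 320), LINE1 = c(5500, 6500), SVA = c(1300, 1700),
         STR = c(30, 200), c(500, 10000))
}

# Draw donor genotypes at one biallelic site: HWE multinomial unless an
# inbreeding coefficient f > 0 (excess homozygosity) is requested.
.drawBiallelic <- function(nDonor, p, f = 0) {
  pr <- c(`0` = (1 - p)^2 + f * p * (1 - p),
          `1` = 2 * p * (1 - p) * (1 - f),
          `2` = p^2 + f * p * (1 - p))
  sample(0:2, nDonor, replace = TRUE, prob = pr)
}

#' Simulate planted truth sites and genotypes
#'
#' Places `sites` truth loci on the synthetic contigs, draws per-donor
#' genotypes under Hardy-Weinberg (multinomial in (p^2, 2pq, q^2)), copies
#' the donor genotype to both members of each replicate pair (error is
#' injected later, at emission), and labels optional planted HWE-violating
#' and batch-skewed loci. mCNV loci segregate >= 3 copy-number alleles;
#' their truth is carried as copy number.
#'
#' @param config A [simConfig()] object.
#' @param cohort Output of [simulateCohort()].
#' @return A list of class `"SVTruth"`: `sites` (data frame with truth_id,
#'   interval, class, af, quality score, fragmentation plan, flags),
#'   `gt`/`cn` (site-by-sample matrices of true genotypes), `cohort`,
#'   `config`.
#' @export
simulateTruth <- function(config, cohort) {
  stopifnot(inherits(config, "SimConfig"))
  .withSeed(config$seed + 1L, {
    samples <- cohort$samples
    donors <- unique(samples$donor_id)
    nd <- length(donors)
    d2s <- match(samples$donor_id, donors)

    cls <- rep(names(config$sites), config$sites)
    if (config$n_lcnv > 0) {
      cls <- c(cls, rep(c("DEL", "DUP"), length.out = config$n_lcnv))
    }
    n <- length(cls)
    isLcnv <- c(rep(FALSE, sum(config$sites)), rep(TRUE, config$n_lcnv))
    chrom <- sample(names(config$contigs), n, replace = TRUE)
    len <- vapply(seq_len(n), function(i) {
      r <- if (isLcnv[i]) c(1e5, 1e6) else .classLenRange(cls[i])
      round(exp(runif(1, log(r[1]), log(r[2]))))
    }, numeric(1))
    start <- vapply(seq_len(n), function(i)
      round(runif(1, 1e4, config$contigs[[chrom[i]]] - len[i] - 1e4)),
      numeric(1))
    af <- runif(n, config$af_range[1], config$af_range[2])
    quality <- runif(n, 5, 95)

    hweIdx <- integer(); batchIdx <- integer()
    biallelic <- which(cls %in% c("DEL", "DUP") & !isLcnv)
    if (config$n_hwe_violation > 0) {
      hweIdx <- biallelic[seq_len(min(config$n_hwe_violation, length(biallelic)))]
    }
    rest <- setdiff(biallelic, hweIdx)
    if (config$n_batch_skew > 0) {
      batchIdx <- rest[seq_len(min(config$n_batch_skew, length(rest)))]
    }

    hipsciDonor <- donors %in% samples$donor_id[samples$study == "HipSci"]
    gt <- matrix(NA_integer_, n, nrow(samples),
                 dimnames = list(NULL, samples$sample_id))
    cn <- matrix(NA_real_, n, nrow(samples),
                 dimnames = list(NULL, samples$sample_id))
    for (i in seq_len(n)) {
      if (cls[i] == "mCNV") {
        # three copy-number alleles (0, 1, 2 copies per haplotype)
        aw <- c(af[i] / 2, 1 - af[i], af[i] / 2)
        a1 <- sample(0:2, nd, replace = TRUE, prob = aw)
        a2 <- sample(0:2, nd, replace = TRUE, prob = aw)
        dcn <- a1 + a2
        cn[i, ] <- dcn[d2s]
        gt[i, ] <- as.integer(cn[i, ] != .modalValue(cn[i, ]))
      } else {
        dgt <- if (i %in% hweIdx) {
          .drawBiallelic(nd, af[i], f = config$hwe_f)
        } else if (i %in% batchIdx) {
          g <- .drawBiallelic(nd, af[i])
          p2 <- min(0.95, af[i] + config$batch_af_shift)
          g[hipsciDonor] <- .drawBiallelic(sum(hipsciDonor), p2)
          g
        } else {
          .drawBiallelic(nd, af[i])
        }
        gt[i, ] <- dgt[d2s]
        if (cls[i] %in% c("DEL", "DUP")) {
          cn[i, ] <- if (cls[i] == "DEL") 2 - gt[i, ] else 2 + gt[i, ]
        }
      }
    }

    # fragmentation plan for read-depth views of long-enough CNVs
    fragK <- rep(1L, n)
    fragPlan <- vector("list", n)
    cand <- which(cls %in% c("DEL", "DUP", "mCNV") & !isLcnv & len >= 5000)
    frag <- cand[runif(length(cand)) < config$frag_prob]
    for (i in frag) {
      k <- sample(2:config$frag_max_k, 1)
      gaps <- round(runif(k - 1, 50, config$frag_max_gap))
      segLen <- (len[i] - sum(gaps)) / k
      if (segLen < 300) next
      s <- start[i] + cumsum(c(0, rep(segLen, k - 1) + gaps))
      fragK[i] <- k
      fragPlan[[i]] <- data.frame(start = round(s),
                                  end = round(s + segLen - 1))
    }

    sites <- data.frame(
      truth_id = sprintf("T%04d", seq_len(n)), chrom = chrom,
      start = start, end = start + len - 1, svtype = cls, sv_len = len,
      af = af, quality = quality, lcnv = isLcnv,
      hwe_violation = seq_len(n) %in% hweIdx,
      batch_skew = seq_len(n) %in% batchIdx, frag_k = fragK,
      stringsAsFactors = FALSE)
    rownames(gt) <- rownames(cn) <- sites$truth_id
    out <- list(sites = sites, frag_plan = fragPlan, gt = gt, cn = cn,
                cohort = cohort, config = config)
    class(out) <- "SVTruth"
    out
  })
}

# Symmetric genotype error: each cell independently replaced by one of the
# other states with probability e (vector or scalar, recycled over rows).
.flipGt <- function(m, e, states = 0:2) {
  n <- nrow(m); p <- ncol(m)
  if (!n || !p) return(m)
  eMat <- matrix(rep(e, length.out = n), n, p)
  hit <- !is.na(m) & matrix(runif(n * p), n, p) < eMat
  idx <- which(hit)
  if (length(idx)) {
    cur <- m[idx]
    m[idx] <- vapply(cur, function(g)
      sample(setdiff(states, g), 1), numeric(1))
  }
  m
}

.abFromGt <- function(gt) {
  ab <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  ab[!is.na(gt) & gt == 0] <- pmax(0, rnorm(sum(gt == 0, na.rm = TRUE), 0.02, 0.015))
  ab[!is.na(gt) & gt == 1] <- pmin(1, pmax(0, rnorm(sum(gt == 1, na.rm = TRUE), 0.5, 0.05)))
  ab[!is.na(gt) & gt >= 2] <- pmin(1, rnorm(sum(gt >= 2, na.rm = TRUE), 0.97, 0.02))
  ab
}

.jitterIv <- function(start, end, j) {
  if (j <= 0) return(cbind(start, end))
  s <- start + sample(seq(-j, j), length(start), replace = TRUE)
  e <- end + sample(seq(-j, j), length(end), replace = TRUE)
  cbind(s, pmax(e, s + 1))
}

# Build one SVCallSet from an accumulated record data frame.
.viewSet <- function(df, samples, assaysList) {
  gr <- GRanges(df$chrom, IRanges(df$start, df$end))
  qual <- df[, intersect(colnames(df), svQualityKeys()), drop = FALSE]
  mf <- if (!is.null(df$flags)) {
    CharacterList(lapply(strsplit(ifelse(is.na(df$flags), "", df$flags), ";"),
                         function(f) f[nzchar(f)]))
  } else NULL
  x <- SVCallSet(gr, siteId = df$site_id, caller = df$caller,
                 svtype = df$svtype, svLen = df$sv_len, quality = qual,
                 meltFlags = mf,
                 gt = assaysList$gt, cn = assaysList$cn, ab = assaysList$ab,
                 lq = assaysList$lq, sampleInfo = samples,
                 extraAssays = assaysList$extra %||% list())
  rowData(x)$cluster_id <- df$truth_id
  rowData(x)$is_fp <- is.na(df$truth_id)
  x
}

#' Emit per-caller views of the truth
#'
#' Produces one [SVCallSet-class] per requested caller. Each emitted record
#' carries breakpoint jitter bounded by `config$jitter`; genotype cells are
#' flipped symmetrically with the quality-linked error probability; the
#' split-read caller gets allele balance concentrated near 0/0.5/1 by
#' genotype plus occasional redundant duplicate records; the read-depth
#' caller gets integer copy numbers, sporadic LQ flags and emits planted
#' fragmented CNVs as adjacent records with identical genotype rows; the MEI
#' caller gets hard-filter flags (flagged sites carry elevated error) and an
#' ASSESS tranche; long CNVs are emitted per carrier sample with fractional
#' copy number; the STR caller carries call-level quality channels. Planted
#' false positives get low quality scores and random genotypes. Every record
#' is linked to its truth site via `rowData()$cluster_id` (NA for false
#' positives).
#'
#' @param truth Output of [simulateTruth()].
#' @param config The same [simConfig()].
#' @return Named list of [SVCallSet-class] objects.
#' @export
emitCallerViews <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "SVTruth"))
  .withSeed(config$seed + 2L, {
    st <- truth$sites
    samples <- truth$cohort$samples
    ns <- nrow(samples)
    e <- .errorRate(config, st$quality)
    out <- list()

    addFp <- function(recs, rows, caller, svtype, prefix) {
      for (k in seq_len(config$fp_per_caller)) {
        chrom <- sample(names(config$contigs), 1)
        ln <- round(runif(1, 500, 20000))
        s <- round(runif(1, 1e4, config$contigs[[chrom]] - ln))
        tp <- sample(svtype, 1)
        point <- tp %in% svPointTypes()
        q <- runif(1, 0, 15)
        recs[[length(recs) + 1L]] <- data.frame(
          site_id = sprintf("%s_fp%03d", prefix, k), caller = caller,
          svtype = tp, chrom = chrom, start = s,
          end = if (point) s else s + ln - 1,
          sv_len = ln, truth_id = NA_character_, q = q,
          stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- rbinom(ns, 2, 0.15)
      }
      list(recs = recs, rows = rows)
    }

    ## --- speedseq ------------------------------------------------------
    if ("speedseq" %in% config$callers) {
      recs <- list(); rows <- list()
      ssIdx <- which(st$svtype %in% c("DEL", "DUP", "INV", "BND", "rMEI") &
                     !st$lcnv)
      mcnvIdx <- which(st$svtype == "mCNV" & !st$lcnv)
      mcnvSS <- mcnvIdx[runif(length(mcnvIdx)) < config$mcnv_ss_frac]
      emitOne <- function(i, tp, tag) {
        point <- tp %in% svPointTypes()
        iv <- .jitterIv(st$start[i], st$end[i], config$jitter)
        g <- .flipGt(matrix(truth$gt[i, ], 1), e[i])
        recs[[length(recs) + 1L]] <<- data.frame(
          site_id = sprintf("ss_%s%s", st$truth_id[i], tag),
          caller = "speedseq", svtype = tp, chrom = st$chrom[i],
          start = iv[1], end = if (point) iv[1] else iv[2],
          sv_len = st$sv_len[i], truth_id = st$truth_id[i], q = st$quality[i],
          stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <<- g[1, ]
      }
      for (i in ssIdx) {
        emitOne(i, st$svtype[i], "")
        if (st$svtype[i] %in% c("DEL", "DUP") && runif(1) < config$dup_prob) {
          emitOne(i, st$svtype[i], "b")  # redundant duplicate
        }
      }
      for (i in mcnvSS) { emitOne(i, "DUP", "d"); emitOne(i, "DEL", "e") }
      fp <- addFp(recs, rows, "speedseq", c("DEL", "DUP", "INV", "BND"), "ss")
      recs <- fp$recs; rows <- fp$rows
      gt <- do.call(rbind, rows); colnames(gt) <- samples$sample_id
      df <- do.call(rbind, recs)
      dupDel <- df$svtype %in% c("DUP", "DEL") &
        !is.na(df$truth_id) & df$truth_id %in% st$truth_id[mcnvSS]
      if (any(dupDel)) {
        # DUP/DEL views of an mCNV: carriers are high- or low-copy samples
        for (r in which(dupDel)) {
          i <- match(df$truth_id[r], st$truth_id)
          cnr <- truth$cn[i, ]
          g <- if (df$svtype[r] == "DUP") pmin(2, pmax(0, cnr - 2))
               else pmin(2, pmax(0, 2 - cnr))
          gt[r, ] <- .flipGt(matrix(as.numeric(g), 1), e[i])[1, ]
        }
      }
      ab <- .abFromGt(gt)
      msq <- df$q
      dupB <- grepl("b$", df$site_id)
      msq[dupB] <- pmax(1, msq[dupB] - 5)
      qual <- data.frame(MSQ = msq, QUAL = df$q * 6,
                         SU = round(10 + df$q / 4))
      qual$SR <- round(qual$SU * runif(nrow(df), 0.2, 0.6))
      qual$PE <- qual$SU - qual$SR
      df <- cbind(df, qual)
      out$speedseq <- .viewSet(df, samples,
                               list(gt = gt, ab = ab))
    }

    ## --- genomestrip ---------------------------------------------------
    if ("genomestrip" %in% config$callers) {
      recs <- list(); rows <- list()
      gsIdx <- which(st$svtype %in% c("DEL", "DUP", "mCNV") & !st$lcnv)
      for (i in gsIdx) {
        cnTrue <- if (st$svtype[i] == "mCNV") truth$cn[i, ] else
          (if (st$svtype[i] == "DEL") 2 - truth$gt[i, ] else 2 + truth$gt[i, ])
        cnRow <- .flipGt(matrix(as.numeric(cnTrue), 1), e[i], states = 0:4)[1, ]
        if (st$frag_k[i] > 1L) {
          plan <- truth$frag_plan[[i]]
          for (k in seq_len(nrow(plan))) {
            iv <- .jitterIv(plan$start[k], plan$end[k], config$jitter)
            recs[[length(recs) + 1L]] <- data.frame(
              site_id = sprintf("gs_%s_f%d", st$truth_id[i], k),
              caller = "genomestrip", svtype = st$svtype[i],
              chrom = st$chrom[i], start = iv[1], end = iv[2],
              sv_len = iv[2] - iv[1] + 1, truth_id = st$truth_id[i],
              q = st$quality[i], stringsAsFactors = FALSE)
            rows[[length(rows) + 1L]] <- cnRow  # identical genotypes
          }
        } else {
          iv <- .jitterIv(st$start[i], st$end[i], config$jitter)
          recs[[length(recs) + 1L]] <- data.frame(
            site_id = sprintf("gs_%s", st$truth_id[i]),
            caller = "genomestrip", svtype = st$svtype[i],
            chrom = st$chrom[i], start = iv[1], end = iv[2],
            sv_len = iv[2] - iv[1] + 1, truth_id = st$truth_id[i],
            q = st$quality[i], stringsAsFactors = FALSE)
          rows[[length(rows) + 1L]] <- cnRow
        }
      }
      fp <- addFp(recs, rows, "genomestrip", c("DEL", "DUP"), "gs")
      recs <- fp$recs
      rows <- fp$rows
      df <- do.call(rbind, recs)
      cn <- do.call(rbind, rows); colnames(cn) <- samples$sample_id
      fpRow <- is.na(df$truth_id)
      cn[fpRow, ] <- 2 + cn[fpRow, ]  # fp rows were drawn as alt counts
      gt <- matrix(NA_integer_, nrow(df), ns,
                   dimnames = list(NULL, samples$sample_id))
      for (r in seq_len(nrow(df))) {
        md <- .modalValue(cn[r, ])
        gt[r, ] <- if (df$svtype[r] == "mCNV") as.integer(cn[r, ] != md)
                   else as.integer(pmin(2, abs(cn[r, ] - 2)))
      }
      lq <- matrix(runif(nrow(df) * ns) < 0.02, nrow(df), ns,
                   dimnames = list(NULL, samples$sample_id))
      df$GSCNQUAL <- df$q * 0.3
      out$genomestrip <- .viewSet(df, samples,
                                  list(gt = gt, cn = cn, lq = lq))
    }

    ## --- gs_lcnv (per-sample long CNV calls) --------------------------
    if ("gs_lcnv" %in% config$callers && any(st$lcnv)) {
      recs <- list(); cnRows <- list()
      for (i in which(st$lcnv)) {
        carriers <- which(truth$gt[i, ] > 0)
        for (s in carriers) {
          iv <- .jitterIv(st$start[i], st$end[i], config$jitter * 50)
          cnVal <- max(0, (if (st$svtype[i] == "DEL") 2 - truth$gt[i, s]
                           else 2 + truth$gt[i, s]) + rnorm(1, 0, 0.08))
          row <- rep(NA_real_, ns); row[s] <- cnVal
          recs[[length(recs) + 1L]] <- data.frame(
            site_id = sprintf("lcnv_%s_%s", st$truth_id[i],
                              samples$sample_id[s]),
            caller = "gs_lcnv", svtype = st$svtype[i], chrom = st$chrom[i],
            start = iv[1], end = iv[2], sv_len = iv[2] - iv[1] + 1,
            truth_id = st$truth_id[i], q = st$quality[i],
            NBINS = floor((iv[2] - iv[1] + 1) / 10000),
            SCORE = st$quality[i] * 30, stringsAsFactors = FALSE)
          cnRows[[length(cnRows) + 1L]] <- row
        }
      }
      if (length(recs)) {
        df <- do.call(rbind, recs)
        cn <- do.call(rbind, cnRows); colnames(cn) <- samples$sample_id
        gt <- ifelse(is.na(cn), NA_integer_,
                     as.integer(pmin(2, round(abs(cn - 2)))))
        out$gs_lcnv <- .viewSet(df, samples,
                                list(gt = gt, cn = cn))
      }
    }

    ## --- melt ----------------------------------------------------------
    if ("melt" %in% config$callers) {
      recs <- list(); rows <- list()
      meiIdx <- which(st$svtype %in% c("ALU", "LINE1", "SVA"))
      flags <- vapply(meiIdx, function(i) {
        f <- names(config$melt_flag_probs)[
          runif(length(config$melt_flag_probs)) < config$melt_flag_probs]
        paste(f, collapse = ";")
      }, character(1))
      for (j in seq_along(meiIdx)) {
        i <- meiIdx[j]
        ei <- min(0.5, e[i] * if (nzchar(flags[j])) config$flag_error_mult else 1)
        iv <- .jitterIv(st$start[i], st$start[i], config$jitter)
        recs[[length(recs) + 1L]] <- data.frame(
          site_id = sprintf("melt_%s", st$truth_id[i]), caller = "melt",
          svtype = st$svtype[i], chrom = st$chrom[i], start = iv[1],
          end = iv[1], sv_len = st$sv_len[i], truth_id = st$truth_id[i],
          q = st$quality[i], flags = flags[j],
          ASSESS = max(1, min(5, 1 + floor(st$quality[i] / 19))),
          stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- .flipGt(matrix(truth$gt[i, ], 1), ei)[1, ]
      }
      df <- do.call(rbind, recs)
      gt <- do.call(rbind, rows); colnames(gt) <- samples$sample_id
      out$melt <- .viewSet(df, samples,
                           list(gt = gt))
    }

    ## --- hipstr --------------------------------------------------------
    if ("hipstr" %in% config$callers) {
      strIdx <- which(st$svtype == "STR")
      if (length(strIdx)) {
        recs <- list(); rows <- list()
        for (i in strIdx) {
          recs[[length(recs) + 1L]] <- data.frame(
            site_id = sprintf("str_%s", st$truth_id[i]), caller = "hipstr",
            svtype = "STR", chrom = st$chrom[i], start = st$start[i],
            end = st$end[i], sv_len = st$sv_len[i],
            truth_id = st$truth_id[i], q = st$quality[i],
            stringsAsFactors = FALSE)
          rows[[length(rows) + 1L]] <- .flipGt(matrix(truth$gt[i, ], 1), e[i])[1, ]
        }
        df <- do.call(rbind, recs)
        gt <- do.call(rbind, rows); colnames(gt) <- samples$sample_id
        nr <- nrow(gt)
        extra <- list(
          Q = matrix(pmin(1, 1 - stats::rbeta(nr * ns, 1, 30)), nr, ns),
          FLANKINDEL = matrix(stats::rbeta(nr * ns, 1, 20), nr, ns),
          STUTTER = matrix(stats::rbeta(nr * ns, 1, 20), nr, ns),
          AB_BIAS = matrix(rnorm(nr * ns, -0.5, 0.6), nr, ns),
          STRAND_BIAS = matrix(rnorm(nr * ns, -0.5, 0.6), nr, ns))
        out$hipstr <- .viewSet(df, samples,
                               list(gt = gt, extra = extra))
      }
    }

    ## --- wham / manta --------------------------------------------------
    for (cal in intersect(c("wham", "manta"), config$callers)) {
      types <- if (cal == "wham") c("DEL", "DUP", "INV") else c("DEL", "DUP")
      idx <- which(st$svtype %in% types & !st$lcnv)
      recs <- list(); rows <- list()
      for (i in idx) {
        iv <- .jitterIv(st$start[i], st$end[i], config$jitter)
        recs[[length(recs) + 1L]] <- data.frame(
          site_id = sprintf("%s_%s", cal, st$truth_id[i]), caller = cal,
          svtype = st$svtype[i], chrom = st$chrom[i], start = iv[1],
          end = iv[2], sv_len = st$sv_len[i], truth_id = st$truth_id[i],
          q = st$quality[i], stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- .flipGt(matrix(truth$gt[i, ], 1), e[i])[1, ]
      }
      fp <- addFp(recs, rows, cal, c("DEL", "DUP"), cal)
      recs <- fp$recs; rows <- fp$rows
      df <- do.call(rbind, recs)
      df$QUAL <- df$q * 6
      gt <- do.call(rbind, rows); colnames(gt) <- samples$sample_id
      out[[cal]] <- .viewSet(df, samples,
                             list(gt = gt))
    }
    out
  })
}

#' Emit array probe intensities for planted CNVs
#'
#' Biallelic DEL/DUP truth sites wide enough for three or more probes get
#' probes every `probe_spacing` bp; probe intensity is
#' `alpha * (cn - 2) + batch + plate + N(0, sigma)` so carriers separate from
#' non-carriers up to noise and planted batch/plate offsets (recoverable by
#' least-squares residualization).
#'
#' @param truth Output of [simulateTruth()].
#' @param cohort Cohort list (defaults to `truth$cohort`).
#' @param config A [simConfig()].
#' @return List with `intensity` (probe x sample matrix), `probes` (probe_id,
#'   chrom, pos), `covariates` (sample_id, batch, plate) and the planted
#'   `offsets`.
#' @export
emitProbeIntensities <- function(truth, cohort = truth$cohort,
                                 config = truth$config) {
  .withSeed(config$seed + 3L, {
    st <- truth$sites
    samples <- cohort$samples; ns <- nrow(samples)
    idx <- which(st$svtype %in% c("DEL", "DUP") & !st$lcnv &
                 st$sv_len >= 3 * config$probe_spacing)
    probes <- do.call(rbind, lapply(idx, function(i) {
      pos <- seq(st$start[i] + 200, st$end[i] - 200, by = config$probe_spacing)
      data.frame(probe_id = sprintf("%s_p%02d", st$truth_id[i], seq_along(pos)),
                 chrom = st$chrom[i], pos = pos, truth_id = st$truth_id[i])
    }))
    batch <- sample(seq_len(config$n_batches), ns, replace = TRUE)
    plate <- sample(seq_len(config$n_plates), ns, replace = TRUE)
    bOff <- rnorm(config$n_batches, 0, config$batch_sd)
    pOff <- rnorm(config$n_plates, 0, config$batch_sd)
    intensity <- matrix(NA_real_, nrow(probes), ns,
                        dimnames = list(probes$probe_id, samples$sample_id))
    for (r in seq_len(nrow(probes))) {
      i <- match(probes$truth_id[r], st$truth_id)
      cnr <- if (st$svtype[i] == "DEL") 2 - truth$gt[i, ] else 2 + truth$gt[i, ]
      intensity[r, ] <- config$probe_alpha * (cnr - 2) + bOff[batch] +
        pOff[plate] + rnorm(ns, 0, config$probe_sigma)
    }
    list(intensity = intensity, probes = probes,
         covariates = data.frame(sample_id = samples$sample_id,
                                 batch = factor(batch), plate = factor(plate)),
         offsets = list(batch = bOff, plate = pOff))
  })
}

#' Emit a SNP panel in LD with planted SVs
#'
#' For each biallelic truth SV, draws `snp_per_sv` SNPs at positions within
#' +/- 1.2 x `snp_window` of the locus. SVs designated as tagged (probability
#' `tagged_frac`) get one SNP inside the window whose genotype equals the SV
#' dosage with per-sample flip probability `ld_eps`; all other SNPs segregate
#' independently under HWE.
#'
#' @inheritParams emitProbeIntensities
#' @return List with `gt` (SNP x sample matrix), `positions` (snp_id, chrom,
#'   pos) and `tags` (truth_id, tagged, snp_id of the planted tag or NA).
#' @export
emitSnpPanel <- function(truth, cohort = truth$cohort, config = truth$config) {
  .withSeed(config$seed + 4L, {
    st <- truth$sites
    samples <- cohort$samples; ns <- nrow(samples)
    donors <- unique(samples$donor_id); d2s <- match(samples$donor_id, donors)
    idx <- which(st$svtype %in% c("DEL", "DUP", "rMEI", "INV", "ALU",
                                  "LINE1", "SVA") & !st$lcnv)
    rows <- list(); pos <- list(); tags <- list()
    for (i in idx) {
      tagged <- runif(1) < config$tagged_frac
      w <- config$snp_window
      p <- round(runif(config$snp_per_sv, st$start[i] - 1.2 * w,
                       st$end[i] + 1.2 * w))
      ids <- sprintf("snp_%s_%02d", st$truth_id[i], seq_along(p))
      tagId <- NA_character_
      for (k in seq_along(p)) {
        if (tagged && k == 1L) {
          p[k] <- round(runif(1, max(1, st$start[i] - w * 0.9),
                              st$end[i] + w * 0.9))
          g <- truth$gt[i, ]
          flip <- runif(ns) < config$ld_eps
          g[flip] <- sample(0:2, sum(flip), replace = TRUE)
          rows[[length(rows) + 1L]] <- g
          tagId <- ids[k]
        } else {
          af <- runif(1, 0.05, 0.5)
          rows[[length(rows) + 1L]] <- .drawBiallelic(length(donors), af)[d2s]
        }
        pos[[length(pos) + 1L]] <- data.frame(snp_id = ids[k],
                                              chrom = st$chrom[i], pos = p[k])
      }
      tags[[length(tags) + 1L]] <- data.frame(truth_id = st$truth_id[i],
                                              tagged = tagged, snp_id = tagId)
    }
    gt <- do.call(rbind, rows)
    positions <- do.call(rbind, pos)
    rownames(gt) <- positions$snp_id
    colnames(gt) <- samples$sample_id
    list(gt = gt, positions = positions, tags = do.call(rbind, tags))
  })
}
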