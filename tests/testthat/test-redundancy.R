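test_that("reciprocal overlap follows plain interval arithmetic", {
  a <- GRanges("c1", IRanges(101, 200))
  expect_equal(unname(reciprocalOverlap(a, a)[1, ]), c(1, 1))
  b <- GRanges("c1", IRanges(151, 250))
  expect_equal(unname(reciprocalOverlap(a, b)[1, ]), c(0.5, 0.5))
  d <- GRanges("c1", IRanges(500, 600))
  expect_equal(unname(reciprocalOverlap(a, d)[1, ]), c(0, 0))
  other <- GRanges("c2", IRanges(101, 200))
  expect_equal(unname(reciprocalOverlap(a, other)[1, ]), c(0, 0))
  # random spot-check against the oracle
  set.seed(9)
  iv <- randomIntervals(30, chroms = "c1")
  g <- GRanges(iv$chrom, IRanges(iv$start, iv$end))
  for (k in 1:15) {
    i <- sample(30, 1); j <- sample(30, 1)
    expect_equal(unname(reciprocalOverlap(g[i], g[j])[1, ]),
                 oracleRO(iv$start[i], iv$end[i], iv$start[j], iv$end[j]))
  }
})

.abFor <- function(gtRow) ifelse(gtRow == 0, 0.02, ifelse(gtRow == 1, 0.5, 0.97))

test_that("speedseq dedup composes overlap, correlation and MSQ rules", {
  co <- makePairs(0, nSingles = 30)
  ns <- 30
  set.seed(77)
  g1 <- sample(0:2, ns, replace = TRUE, prob = c(.5, .3, .2))
  g2 <- sample(0:2, ns, replace = TRUE, prob = c(.5, .3, .2))
  ab <- rbind(.abFor(g1), .abFor(g1) + rnorm(ns, 0, 0.01),  # correlated pair
              .abFor(g2))                                    # unrelated AB
  ab <- pmin(pmax(ab, 0), 1)
  colnames(ab) <- co$samples$sample_id
  # a/b overlap RO 0.6 and share AB; c overlaps both but has unrelated AB
  x <- makeCallSet("c1", c(1000, 1400, 1200), c(2000, 2400, 2200), "DEL",
                   caller = "speedseq", siteId = c("a", "b", "c"),
                   quality = data.frame(MSQ = c(80, 60, 70)),
                   ab = ab, sampleInfo = co$samples)
  res <- dedupSpeedseq(x)
  cl <- res$clusters
  expect_equal(length(unique(cl$cluster_id)), 1L)
  expect_setequal(cl$site_id, c("a", "b"))
  expect_equal(cl$site_id[cl$role == "primary"], "a")  # highest MSQ
  expect_setequal(siteId(res$nonredundant), c("a", "c"))
})

test_that("speedseq dedup containment rule collapses nested correlated calls", {
  co <- makePairs(0, nSingles = 25)
  ns <- 25
  set.seed(78)
  g <- sample(0:2, ns, replace = TRUE, prob = c(.4, .4, .2))
  ab <- rbind(.abFor(g), .abFor(g))
  colnames(ab) <- co$samples$sample_id
  # inner spans 30% of outer: RO fails, containment + AB corr >= 0.5 applies
  x <- makeCallSet("c1", c(1000, 1200), c(11000, 4200), "DEL",
                   caller = "speedseq", siteId = c("outer", "inner"),
                   quality = data.frame(MSQ = c(50, 90)),
                   ab = ab, sampleInfo = co$samples)
  res <- dedupSpeedseq(x)
  expect_equal(siteId(res$nonredundant), "inner")  # max MSQ survives
})

test_that("genomestrip dedup applies its three criteria and exact-overlap rule", {
  nonIpsc <- sprintf("s%02d", 1:40)
  samples <- data.frame(sample_id = nonIpsc, donor_id = nonIpsc,
                        study = "iPSCORE", cell_type = "blood",
                        superpopulation = "EUR", sex = "F")
  set.seed(91)
  base <- sample(c(1, 2, 2, 2, 3), 40, replace = TRUE)
  mkSet <- function(ids, starts, ends, cnRows, quals) {
    makeCallSet("c1", starts, ends, "DEL", caller = "genomestrip",
                siteId = ids,
                quality = data.frame(GSCNQUAL = quals),
                cn = {
                  m <- do.call(rbind, cnRows); colnames(m) <- nonIpsc; m
                },
                sampleInfo = samples)
  }
  noisy <- base; noisy[1:12] <- sample(c(1, 3), 12, replace = TRUE)  # decorrelate
  setA <- mkSet(c("a1", "a2", "a3"), c(1000, 20000, 40000),
                c(2000, 21000, 41000), list(base, base, base), c(30, 30, 30))
  setB <- mkSet(c("b1", "b2", "b3"), c(1000, 20400, 40000),
                c(2000, 21400, 41000), list(base, base, noisy), c(20, 20, 50))
  res <- dedupGenomestrip(setA, setB, nonIpsc = nonIpsc)
  # a1/b1: exact coordinates, identical cn -> b1 redundant (lower GSCNQUAL)
  expect_true("b1" %in% res$redundant)
  # a2/b2: RO 0.6, cn identical -> redundant pair, higher quality primary
  expect_true("b2" %in% res$redundant)
  # a3/b3: exact interval but cn correlation broken -> both kept
  expect_false(any(c("a3", "b3") %in% res$redundant))
  expect_setequal(siteId(res$nonredundant), c("a1", "a2", "a3", "b3"))
  expect_error(dedupGenomestrip(setA, setB, nonIpsc = character()), "empty")
})

test_that("genomestrip dedup rejects high correlation with >5% non-mode differences", {
  nonIpsc <- sprintf("s%02d", 1:100)
  samples <- data.frame(sample_id = nonIpsc, donor_id = nonIpsc,
                        study = "iPSCORE", cell_type = "blood",
                        superpopulation = "EUR", sex = "F")
  cnA <- c(rep(1, 30), rep(2, 70))
  cnB <- cnA; cnB[1:3] <- 0   # 3/30 non-mode differ = 10% > 5%; corr still high
  stopifnot(cor(cnA, cnB) > 0.95)
  mk <- function(id, cn, q) makeCallSet(
    "c1", 1000, 2000, "DEL", caller = "genomestrip", siteId = id,
    quality = data.frame(GSCNQUAL = q),
    cn = matrix(cn, 1, 100, dimnames = list(NULL, nonIpsc)),
    sampleInfo = samples)
  res <- dedupGenomestrip(mk("a", cnA, 10), mk("b", cnB, 9), nonIpsc)
  expect_equal(length(res$redundant), 0L)
})

test_that("stitching merges adjacent correlated fragments and respects gaps", {
  samples <- sprintf("s%02d", 1:60)
  set.seed(13)
  cnRow <- sample(c(1, 2, 2, 3), 60, replace = TRUE)
  other <- sample(c(1, 2, 2, 3), 60, replace = TRUE)
  cn <- rbind(cnRow, cnRow, other)
  colnames(cn) <- samples
  x <- makeCallSet("c1", c(1000, 2500, 300000), c(2000, 3500, 301000), "DEL",
                   caller = "genomestrip", siteId = c("f1", "f2", "z"),
                   quality = data.frame(GSCNQUAL = c(10, 10, 10)), cn = cn)
  res <- stitchGenomestrip(x)
  expect_equal(nrow(res$stitches), 1L)
  expect_equal(res$stitches$start, 1000)
  expect_equal(res$stitches$end, 3500)
  expect_setequal(res$members$site_id, c("f1", "f2"))

  # same fragments with a 31 kb gap: correlated but never merged
  y <- makeCallSet("c1", c(1000, 34000), c(2000, 35000), "DEL",
                   caller = "genomestrip", siteId = c("g1", "g2"),
                   quality = data.frame(GSCNQUAL = c(10, 10)),
                   cn = cn[1:2, ])
  expect_equal(nrow(stitchGenomestrip(y)$stitches), 0L)

  # high correlation but < 80% non-mode concordance: not merged
  a <- c(rep(1, 20), rep(2, 40))
  b <- a; b[1:5] <- 0  # 25% of non-mode samples differ
  stopifnot(cor(a, b) > 0.9, 1 - mean(a[1:20] != b[1:20]) < 0.8)
  z <- makeCallSet("c1", c(1000, 2500), c(2000, 3500), "DEL",
                   caller = "genomestrip", siteId = c("h1", "h2"),
                   quality = data.frame(GSCNQUAL = c(10, 10)),
                   cn = {
                     m <- rbind(a, b); colnames(m) <- samples; m
                   })
  expect_equal(nrow(stitchGenomestrip(z)$stitches), 0L)
})

test_that("stitch validation unstitches weak or low-quality breakpoints", {
  set.seed(3)
  row <- sample(c(1, 2, 2, 3), 80, replace = TRUE)
  cons <- rbind(row, row)
  expect_equal(validateStitch(row, cons, lqFraction = 0, isNew = TRUE),
               "stitched")
  # decorrelated breakpoint genotypes
  noisy <- sample(row)
  stopifnot(cor(noisy, row) < 0.9)
  expect_equal(validateStitch(noisy, cons, 0, isNew = FALSE), "unstitched")
  expect_equal(validateStitch(noisy, cons, 0, isNew = TRUE), "filtered")
  # 11% low-quality genotypes
  expect_equal(validateStitch(row, cons, lqFraction = 0.11, isNew = TRUE),
               "filtered")
  # non-polymorphic breakpoint
  expect_equal(validateStitch(rep(2, 80), cons, 0, isNew = FALSE),
               "unstitched")
})

test_that("long-CNV clustering groups calls at 80% reciprocal overlap", {
  samples <- data.frame(sample_id = c("s1", "s2", "s3"),
                        donor_id = c("d1", "d2", "d3"), study = "iPSCORE",
                        cell_type = "blood", superpopulation = "EUR",
                        sex = "F")
  cn <- rbind(c(3.2, NA, NA), c(NA, 2.9, NA), c(NA, NA, 3.1))
  colnames(cn) <- samples$sample_id
  # three per-sample calls with pairwise RO ~0.9
  x <- makeCallSet("c1", c(100000, 105000, 102000),
                   c(200000, 205000, 202000), "DUP", caller = "gs_lcnv",
                   siteId = c("p1", "p2", "p3"), cn = cn,
                   sampleInfo = samples)
  res <- clusterLcnv(x)
  expect_equal(nrow(res$callset), 1L)
  expect_equal(start(rowRanges(res$callset)), 100000)
  expect_equal(end(rowRanges(res$callset)), 205000)
  expect_equal(unname(cnMatrix(res$callset)[1, ]), c(3, 3, 3))  # rounded

  # RO 0.7: separate sites
  y <- makeCallSet("c1", c(100000, 130000), c(200000, 230000), "DUP",
                   caller = "gs_lcnv", siteId = c("q1", "q2"),
                   cn = cn[1:2, ], sampleInfo = samples)
  expect_equal(nrow(clusterLcnv(y)$callset), 2L)
  # single-sample call passes through unchanged
  z <- makeCallSet("c2", 5e5, 7e5, "DEL", caller = "gs_lcnv", siteId = "solo",
                   cn = cn[1, , drop = FALSE], sampleInfo = samples)
  zz <- clusterLcnv(z)
  expect_equal(nrow(zz$callset), 1L)
  expect_equal(start(rowRanges(zz$callset)), 5e5)
})

test_that("generic merge respects class matching and connected components", {
  wham <- makeCallSet("c1", c(1000, 50000), c(2000, 51000), c("DEL", "DEL"),
                      caller = "wham", siteId = c("w1", "w2"))
  manta <- makeCallSet("c1", c(1100, 50100), c(2100, 51400),
                       c("DEL", "DUP"), caller = "manta",
                       siteId = c("m1", "m2"))
  res <- mergeGeneric(list(wham, manta), minRO = 0.5)
  m <- res$merged
  # w1+m1 merge (same class, RO 0.8); w2/m2 differ in class
  expect_equal(m$n_callers[m$n_members == 2], 2L)
  expect_equal(nrow(m), 3L)
  # transitivity: chain a-b, b-c merges all three even if a-c overlap < RO
  chain <- makeCallSet("c1", c(1000, 1500, 2000), c(2000, 2500, 3000), "DEL",
                       caller = "wham", siteId = c("a", "b", "c"))
  res2 <- mergeGeneric(chain, minRO = 0.45)
  expect_equal(nrow(res2$merged), 1L)
  expect_equal(res2$merged$start, 1000)
  expect_equal(res2$merged$end, 3000)
})

test_that("clustering equals a brute-force union-find oracle on random sets", {
  set.seed(200)
  for (rep_ in 1:20) {
    n <- sample(20:60, 1)
    iv <- randomIntervals(n, chroms = c("c1", "c2"), maxPos = 50000)
    tp <- sample(c("DEL", "DUP"), n, replace = TRUE)
    x <- makeCallSet(iv$chrom, iv$start, iv$end, tp, caller = "wham",
                     siteId = sprintf("r%03d", 1:n))
    res <- mergeGeneric(x, minRO = 0.5)
    # oracle: all-pairs rule + union-find
    uf <- ufNew(n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (iv$chrom[i] != iv$chrom[j] || tp[i] != tp[j]) next
        ro <- oracleRO(iv$start[i], iv$end[i], iv$start[j], iv$end[j])
        if (min(ro) >= 0.5) uf <- ufUnion(uf, i, j)
      }
    }
    want <- ufPartition(uf)
    got <- match(res$members$merged_id[match(sprintf("r%03d", 1:n),
                                             res$members$site_id)],
                 unique(res$members$merged_id))
    expect_true(samePartition(want, got))
  }
})

test_that("synthgen planted duplicate clusters are recovered exactly", {
  cfg <- simConfig(seed = 301, n_donors = 80, n_twin_pairs = 20,
                   n_fib_ipsc_pairs = 20, sites = c(DEL = 60, DUP = 20),
                   n_lcnv = 0, dup_prob = 0.5, fp_per_caller = 0,
                   error_max = 0, jitter = 5, frag_prob = 0,
                   callers = "speedseq")
  co <- simulateCohort(cfg)
  v <- emitCallerViews(simulateTruth(cfg, co), cfg)
  res <- dedupSpeedseq(v$speedseq)
  truthIds <- rowData(v$speedseq)$cluster_id
  planted <- table(truthIds)
  dupTruth <- names(planted)[planted > 1]
  # every planted duplicate pair lands in one cluster with a single survivor
  for (tid in dupTruth) {
    members <- siteId(v$speedseq)[truthIds == tid]
    inCl <- res$clusters[res$clusters$site_id %in% members, ]
    expect_equal(length(unique(inCl$cluster_id)), 1L)
    expect_equal(sum(inCl$role == "primary"), 1L)
  }
  # no cluster ever mixes two different truth sites
  for (cid in unique(res$clusters$cluster_id)) {
    members <- res$clusters$site_id[res$clusters$cluster_id == cid]
    expect_equal(length(unique(truthIds[match(members, siteId(v$speedseq))])),
                 1L)
  }
})
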