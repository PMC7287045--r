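test_that("co-discovery applies the published overlap, containment and class rules", {
  q <- makeCallSet(rep("c1", 4), c(1, 2000, 10000, 50000),
                   c(1000, 2999, 10999, 50999),
                   c("DEL", "INV", "DEL", "mCNV"),
                   siteId = c("qDel", "qInv", "qSmall", "qM"))
  t_ <- makeCallSet(rep("c1", 4), c(201, 2400, 9000, 50100),
                    c(1100, 3399, 14999, 51099),
                    c("DEL", "INV", "DEL", "DUP"),
                    siteId = c("tDel", "tInv", "tBig", "tDup"))
  res <- coDiscovery(q, t_)
  m <- res$matches
  # qDel/tDel: RO (0.8, 0.89) -> reciprocal match
  expect_true(any(m$query_id == "qDel" & m$target_id == "tDel"))
  # qInv/tInv: RO 0.6 < 0.8 inversion rule -> no match
  expect_false(any(m$query_id == "qInv"))
  # qSmall inside tBig spanning 1000/6000 = 17% < 20% -> no match
  expect_false(any(m$query_id == "qSmall" & m$target_id == "tBig"))
  # mCNV matches DUP
  expect_true(any(m$query_id == "qM" & m$target_id == "tDup"))
})

test_that("co-discovery boundary cases behave per the stated conventions", {
  # exactly 25% reciprocal overlap is a match (at least)
  q <- makeCallSet("c1", 1, 400, "DEL", siteId = "q")
  t_ <- makeCallSet("c1", 301, 700, "DEL", siteId = "t")
  expect_equal(nrow(coDiscovery(q, t_)$matches), 1L)
  # containment exactly 20% of the larger is a match
  q2 <- makeCallSet("c1", 101, 300, "DEL", siteId = "q2")       # len 200
  t2 <- makeCallSet("c1", 1, 1000, "DEL", siteId = "t2")        # len 1000
  m2 <- coDiscovery(q2, t2)$matches
  expect_equal(m2$rule, "containment")
  # inversions at exactly 80% reciprocal overlap match
  q3 <- makeCallSet("c1", 1, 1000, "INV", siteId = "q3")
  t3 <- makeCallSet("c1", 201, 1200, "INV", siteId = "t3")
  expect_equal(nrow(coDiscovery(q3, t3)$matches), 1L)
  # breakends at exactly 50 bp match; 51 bp do not
  q4 <- makeCallSet("c1", 1000, 1000, "BND", siteId = "q4", svLen = 1)
  t4 <- makeCallSet("c1", 1050, 1050, "BND", siteId = "t4", svLen = 1)
  expect_equal(nrow(coDiscovery(q4, t4)$matches), 1L)
  t5 <- makeCallSet("c1", 1051, 1051, "BND", siteId = "t5", svLen = 1)
  expect_equal(nrow(coDiscovery(q4, t5)$matches), 0L)
})

test_that("insertion matching uses 50 bp distance and twofold length rules", {
  q <- makeCallSet("c1", c(1000, 5000), c(1000, 5000), "ALU",
                   siteId = c("i1", "i2"), svLen = c(300, 300))
  t_ <- makeCallSet("c1", c(1030, 5051), c(1030, 5051), "ALU",
                    siteId = c("j1", "j2"), svLen = c(400, 300))
  m <- coDiscoveryInsertions(q, t_)
  expect_equal(m$query_id, "i1")          # 30 bp apart, ratio 1.33
  # i2/j2: 51 bp apart -> no match
  expect_false("i2" %in% m$query_id)
  # exactly twofold length difference is not a match (strict <)
  t2 <- makeCallSet("c1", 1010, 1010, "ALU", siteId = "k", svLen = 600)
  expect_equal(nrow(coDiscoveryInsertions(q[1, ], t2)), 0L)
  t3 <- makeCallSet("c1", 1010, 1010, "ALU", siteId = "k2", svLen = 599)
  expect_equal(nrow(coDiscoveryInsertions(q[1, ], t3)), 1L)
  bad <- makeCallSet("c1", 1, 1, "ALU", siteId = "z", svLen = 300)
  rowData(bad)$sv_len <- NA_integer_
  expect_error(coDiscoveryInsertions(bad, t2), "sv_len")
})

test_that("allele-frequency concordance needs three pairs and detects identity", {
  matches <- data.frame(query_id = c("a", "b", "c"),
                        target_id = c("x", "y", "z"))
  qa <- c(a = 0.1, b = 0.3, c = 0.45)
  ta <- c(x = 0.1, y = 0.3, z = 0.45)
  res <- afConcordance(matches, qa, ta)
  expect_equal(res$r, 1)
  expect_true(is.na(afConcordance(matches[1:2, ], qa, ta)$r))
})

test_that("LD tagging equals the exhaustive oracle and handles edge cases", {
  set.seed(404)
  co <- makePairs(0, nSingles = 60)
  ns <- 60
  gt <- matrix(sample(0:2, 5 * ns, replace = TRUE, prob = c(.5, .35, .15)),
               5, dimnames = list(NULL, co$samples$sample_id))
  x <- makeCallSet("c1", c(1e5, 2e5, 3e5, 4e5, 5e5),
                   c(1e5 + 999, 2e5 + 999, 3e5 + 999, 4e5 + 999, 5e5 + 999),
                   "DEL", caller = "speedseq",
                   siteId = sprintf("sv%d", 1:5), gt = gt,
                   sampleInfo = co$samples)
  nSnp <- 80
  snpPos <- data.frame(snp_id = sprintf("snp%03d", 1:nSnp), chrom = "c1",
                       pos = round(runif(nSnp, 1, 7e5)))
  snpGt <- matrix(sample(0:2, nSnp * ns, replace = TRUE), nSnp,
                  dimnames = list(snpPos$snp_id, co$samples$sample_id))
  # plant a perfect tag for sv1
  snpGt[1, ] <- gt[1, ]; snpPos$pos[1] <- 1e5 + 500
  res <- ldTagging(x, snpGt, snpPos)
  expect_equal(res$max_r2[res$site_id == "sv1"], 1)
  for (i in 1:5) {
    o <- oracleMaxR2(gt[i, ], snpGt, snpPos, "c1",
                     start(rowRanges(x))[i], end(rowRanges(x))[i], 50000)
    expect_equal(res$max_r2[i], o$max_r2)
    expect_equal(res$best_snp[i], o$best_snp)
  }
  # no SNP in window -> NA
  far <- makeCallSet("c2", 1e5, 1e5 + 999, "DEL", caller = "speedseq",
                     siteId = "lonely", gt = gt[1, , drop = FALSE],
                     sampleInfo = co$samples)
  resFar <- ldTagging(far, snpGt, snpPos)
  expect_true(is.na(resFar$max_r2))
  expect_equal(resFar$n_snps, 0L)
  # zero dosage variance -> NA
  mono <- makeCallSet("c1", 1e5, 1e5 + 999, "DEL", caller = "speedseq",
                      siteId = "mono",
                      gt = matrix(1L, 1, ns,
                                  dimnames = list(NULL, co$samples$sample_id)),
                      sampleInfo = co$samples)
  expect_true(is.na(ldTagging(mono, snpGt, snpPos)$max_r2))
})

test_that("IRS separates perfect signal and skips underpowered sites", {
  set.seed(505)
  ns <- 80
  samples <- data.frame(sample_id = sprintf("a%02d", 1:ns),
                        donor_id = sprintf("a%02d", 1:ns), study = "iPSCORE",
                        cell_type = "blood", superpopulation = "EUR",
                        sex = "F")
  n <- 10
  gt <- matrix(rbinom(n * ns, 2, 0.25), n,
               dimnames = list(NULL, samples$sample_id))
  starts <- seq(1e4, by = 5e4, length.out = n)
  x <- makeCallSet("c1", starts, starts + 2e4, "DEL", caller = "genomestrip",
                   siteId = sprintf("d%02d", 1:n), gt = gt,
                   sampleInfo = samples)
  probes <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(probe_id = sprintf("p%02d_%d", i, 1:4), chrom = "c1",
               pos = starts[i] + c(1000, 6000, 11000, 16000))))
  # noise-free separation: intensity = -gt per probe
  intensity <- matrix(NA_real_, nrow(probes), ns,
                      dimnames = list(probes$probe_id, samples$sample_id))
  for (r in seq_len(nrow(probes))) {
    i <- ceiling(r / 4)
    intensity[r, ] <- -gt[i, ] + rnorm(ns, 0, 1e-6)
  }
  res <- irsTest(x, intensity, probes)
  expect_true(all(res$table$p < 1e-4, na.rm = TRUE))
  expect_equal(res$fdr, 0)
  # a site with only 2 probes is skipped with a reason
  probes2 <- probes[probes$probe_id %in% c("p01_1", "p01_2"), ]
  res2 <- irsTest(x[1, ], intensity[1:2, , drop = FALSE], probes2)
  expect_equal(res2$n_tested, 0L)
  expect_equal(res2$table$skip, "lt3_probes")
  # a site with no carriers is skipped
  gt0 <- gt; gt0[1, ] <- 0L
  x0 <- makeCallSet("c1", starts, starts + 2e4, "DEL", caller = "genomestrip",
                    siteId = sprintf("d%02d", 1:n), gt = gt0,
                    sampleInfo = samples)
  res3 <- irsTest(x0[1, ], intensity, probes)
  expect_equal(res3$table$skip[1], "no_carriers")
})

test_that("IRS p-values are uniform under a permutation null", {
  set.seed(606)
  ns <- 100
  samples <- data.frame(sample_id = sprintf("b%03d", 1:ns),
                        donor_id = sprintf("b%03d", 1:ns), study = "iPSCORE",
                        cell_type = "blood", superpopulation = "EUR",
                        sex = "F")
  n <- 200
  gt <- matrix(rbinom(n * ns, 2, 0.3), n,
               dimnames = list(NULL, samples$sample_id))
  starts <- seq(1e4, by = 4e4, length.out = n)
  x <- makeCallSet("c1", starts, starts + 1.5e4, "DEL",
                   caller = "genomestrip", siteId = sprintf("n%03d", 1:n),
                   gt = gt, sampleInfo = samples)
  probes <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(probe_id = sprintf("q%03d_%d", i, 1:3), chrom = "c1",
               pos = starts[i] + c(1000, 6000, 11000))))
  # intensities independent of genotype: the permutation null
  intensity <- matrix(rnorm(nrow(probes) * ns), nrow(probes),
                      dimnames = list(probes$probe_id, samples$sample_id))
  res <- irsTest(x, intensity, probes)
  p <- res$table$p[!is.na(res$table$p)]
  expect_gt(length(p), 150)
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
  expect_gt(res$fdr, 0.7)  # null call set: FDR estimate near 1
})

test_that("probe residualization removes planted batch offsets", {
  cfg <- simConfig(seed = 97, n_donors = 60, n_twin_pairs = 10,
                   n_fib_ipsc_pairs = 10, sites = c(DEL = 12), n_lcnv = 0,
                   probe_sigma = 0.01, batch_sd = 0.5)
  co <- simulateCohort(cfg)
  tr <- simulateTruth(cfg, co)
  pr <- emitProbeIntensities(tr, co, cfg)
  raw <- pr$intensity[1, ]
  batch <- pr$covariates$batch
  # strong planted batch structure in the raw intensities
  expect_gt(summary(lm(raw ~ batch))$r.squared, 0.3)
  resid <- SVHarmony:::.residualizeProbes(pr$intensity,
                                          pr$covariates[, c("batch", "plate")])
  expect_lt(summary(lm(resid[1, ] ~ batch))$r.squared, 1e-6)
})
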