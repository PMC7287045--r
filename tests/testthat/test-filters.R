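# Each fixture plants a known number of records failing each rule; the
# reports must account for every record exactly once with stable reason
# codes, and applying a filter twice must equal applying it once.

test_that("speedseq filter applies the published rules at their boundaries", {
  co <- makePairs(2)
  ns <- nrow(co$samples)
  mkss <- function(svtype, len, msq, sr = 10, pe = 10, su = 20, qual = 50,
                   gtRow = rep(1L, ns)) {
    list(svtype = svtype, len = len, msq = msq, sr = sr, pe = pe, su = su,
         qual = qual, gt = gtRow)
  }
  rows <- list(
    a = mkss("DEL", 417, msq = 50, sr = 0),        # rule 1: short DEL, no SR
    b = mkss("DEL", 418, msq = 21, sr = 0),        # boundary: kept
    c = mkss("DUP", 40, msq = 200),                # rule 2: < 50 bp
    d = mkss("BND", 1, msq = 95, sr = 2, pe = 2, su = 20),  # rule 3: 20% < 25%
    e = mkss("INV", 5000, msq = 95, qual = 150, sr = 1, pe = 0, su = 20), # rule 4
    f = mkss("DEL", 1000, msq = 50, gtRow = c(NA, NA, rep(1L, ns - 2))), # rule 5
    g = mkss("DUP", 1000, msq = 100),              # rule 6 boundary: strict >
    h = mkss("DUP", 1000, msq = 101),              # kept
    i = mkss("INV", 5000, msq = 90, qual = 50),    # msq_INV (rule 4 skipped)
    j = mkss("rMEI", 500, msq = 20))               # msq_rMEI boundary
  n <- length(rows)
  gt <- do.call(rbind, lapply(rows, `[[`, "gt"))
  colnames(gt) <- co$samples$sample_id
  len <- vapply(rows, `[[`, numeric(1), "len")
  x <- makeCallSet("c1", seq(1, by = 50000, length.out = n),
                   seq(1, by = 50000, length.out = n) +
                     ifelse(vapply(rows, `[[`, character(1), "svtype") == "BND",
                            0, len - 1),
                   vapply(rows, `[[`, character(1), "svtype"),
                   caller = "speedseq", siteId = names(rows), svLen = len,
                   quality = data.frame(
                     MSQ = vapply(rows, `[[`, numeric(1), "msq"),
                     QUAL = vapply(rows, `[[`, numeric(1), "qual"),
                     SU = vapply(rows, `[[`, numeric(1), "su"),
                     SR = vapply(rows, `[[`, numeric(1), "sr"),
                     PE = vapply(rows, `[[`, numeric(1), "pe")),
                   gt = gt, sampleInfo = co$samples)
  res <- filterSpeedseq(x)
  rep_ <- res$report
  expect_equal(nrow(rep_), n)                      # every record accounted for
  keptIds <- rep_$site_id[rep_$kept]
  expect_setequal(keptIds, c("b", "h"))
  reason <- setNames(rep_$reasons, rep_$site_id)
  expect_match(reason[["a"]], "del_short_no_sr")
  expect_match(reason[["c"]], "min_len")
  expect_match(reason[["d"]], "bnd_support")
  expect_match(reason[["e"]], "inv_support")
  expect_match(reason[["f"]], "missing_rate")
  expect_match(reason[["g"]], "msq_DUP")
  expect_match(reason[["i"]], "msq_INV")
  expect_match(reason[["j"]], "msq_rMEI")
  # idempotence
  res2 <- filterSpeedseq(res$callset)
  expect_true(all(res2$report$kept))
  expect_identical(siteId(res2$callset), siteId(res$callset))
})

test_that("melt filter removes flagged records and non-5 tranches", {
  x <- makeCallSet("c1", c(100, 200, 300), c(100, 200, 300),
                   "ALU", caller = "melt", svLen = 300,
                   siteId = c("m1", "m2", "m3"),
                   quality = data.frame(ASSESS = c(5, 4, 5)),
                   meltFlags = IRanges::CharacterList(list(
                     "lc", character(), character())))
  res <- filterMelt(x)
  expect_setequal(res$report$site_id[res$report$kept], "m3")
  reason <- setNames(res$report$reasons, res$report$site_id)
  expect_match(reason[["m1"]], "flag_lc")
  expect_match(reason[["m2"]], "assess")
  expect_true(all(filterMelt(res$callset)$report$kept))
})

test_that("genomestrip filter enforces GSCNQUAL, polymorphism and LQ rules", {
  samples <- data.frame(
    sample_id = sprintf("s%03d", 1:100), donor_id = sprintf("d%03d", 1:100),
    study = "iPSCORE", cell_type = "blood", superpopulation = "EUR",
    sex = "F")
  ns <- 100
  cnPoly <- c(rep(2, 80), rep(1, 20))
  mk <- function(cnRow) matrix(cnRow, 1, ns)
  cn <- rbind(cnPoly, cnPoly, rep(2, ns), cnPoly, cnPoly)
  lq <- matrix(FALSE, 5, ns)
  lq[4, 1:11] <- TRUE   # 11% LQ among non-iPSC
  lq[5, 1:10] <- TRUE   # exactly 10%: kept
  gt <- matrix(rep(pmin(2, abs(2 - t(cn))), 1), nrow = 5, byrow = FALSE)
  gt <- abs(sweep(cn, 1, 2))  # not used by the rules under test
  x <- makeCallSet("c1", 1000 * (1:5), 1000 * (1:5) + 999,
                   c("DEL", "DEL", "DEL", "DEL", "DEL"),
                   caller = "genomestrip",
                   siteId = sprintf("g%d", 1:5),
                   quality = data.frame(GSCNQUAL = c(2, 1.99, 10, 10, 10)),
                   cn = cn, lq = lq, gt = gt, sampleInfo = samples)
  res <- filterGenomestrip(x, nonIpscSamples = samples$sample_id)
  reason <- setNames(res$report$reasons, res$report$site_id)
  expect_true(res$report$kept[res$report$site_id == "g1"])  # >= 2 boundary
  expect_match(reason[["g2"]], "gscnqual_DEL")
  expect_match(reason[["g3"]], "monoallelic")
  expect_match(reason[["g4"]], "lq_fraction")
  expect_true(res$report$kept[res$report$site_id == "g5"])  # 10% is not > 10%
  expect_error(filterGenomestrip(x, nonIpscSamples = character()), "empty")
})

test_that("long-CNV filter checks NBINS, SCORE, centromeres and carrier CN", {
  samples <- data.frame(sample_id = c("s1", "s2"), donor_id = c("d1", "d2"),
                        study = "iPSCORE", cell_type = "blood",
                        superpopulation = "EUR", sex = "M")
  cn <- rbind(c(3.0, NA), c(3.0, NA), c(2.8, NA), c(2.75, NA), c(1.0, NA),
              c(3.0, NA))
  x <- makeCallSet("c1", c(1e5, 2e6, 4e6, 6e6, 8e6, 4.9e6),
                   c(1e5 + 2e5, 2e6 + 2e5, 4e6 + 2e5, 6e6 + 2e5,
                     8e6 + 2e5, 5.1e6),
                   c("DUP", "DUP", "DUP", "DUP", "DEL", "DUP"),
                   caller = "gs_lcnv", siteId = sprintf("L%d", 1:6),
                   quality = data.frame(NBINS = c(9, 20, 20, 20, 20, 20),
                                        SCORE = c(2000, 999, 1500, 1500,
                                                  1500, 1500)),
                   cn = cn, sampleInfo = samples)
  centro <- GRanges("c1", IRanges(5e6 - 25000, 5e6 + 25000))
  res <- filterLcnv(x, centromeres = centro)
  reason <- setNames(res$report$reasons, res$report$site_id)
  expect_match(reason[["L1"]], "nbins")
  expect_match(reason[["L2"]], "score")
  expect_true(res$report$kept[res$report$site_id == "L3"])   # cn 2.8 > 2.75
  expect_match(reason[["L4"]], "carrier_cn")                 # 2.75 not > 2.75
  expect_true(res$report$kept[res$report$site_id == "L5"])   # DEL cn 1 < 1.25
  expect_match(reason[["L6"]], "centromere")                 # contains centromere
  expect_warning(filterLcnv(x), "centromere")
})

test_that("hipstr filter masks failing genotypes and applies call-rate rule", {
  co <- makePairs(0, nSingles = 10)
  ns <- 10
  gt <- matrix(1L, 3, ns, dimnames = list(NULL, co$samples$sample_id))
  q <- matrix(0.95, 3, ns)
  q[1, 1] <- 0.89            # one failing call at site 1
  q[2, 1:3] <- 0.5           # 3/10 failing at site 2 -> call rate 70%
  x <- makeCallSet("c1", c(100, 5000, 9000), c(160, 5060, 9060), "STR",
                   caller = "hipstr", siteId = c("h1", "h2", "h3"), gt = gt,
                   sampleInfo = co$samples,
                   extraAssays = list(Q = q))
  res <- filterHipstr(x, subsets = list(all = co$samples$sample_id))
  expect_true(is.na(gtMatrix(res$callset)[match("h1", siteId(res$callset)), 1]))
  expect_false("h2" %in% siteId(res$callset))      # 70% call rate < 80%
  expect_true(res$report$kept[res$report$site_id == "h3"])
  expect_error(filterHipstr(x, subsets = list(some = co$samples$sample_id[1:3])),
               "cover")
})

test_that("hipstr call-rate boundary is strict (80% is removed)", {
  co <- makePairs(0, nSingles = 10)
  gt <- matrix(1L, 1, 10, dimnames = list(NULL, co$samples$sample_id))
  q <- matrix(1, 1, 10); q[1, 1:2] <- 0   # 80% call rate after masking
  x <- makeCallSet("c1", 100, 160, "STR", caller = "hipstr", gt = gt,
                   sampleInfo = co$samples, extraAssays = list(Q = q))
  res <- filterHipstr(x, subsets = list(all = co$samples$sample_id))
  expect_false(any(res$report$kept))
})

test_that("wham/manta QUAL filter keeps >= 250 and flags missing QUAL", {
  x <- makeCallSet("c1", c(100, 3000, 6000), c(1099, 3999, 6999), "DEL",
                   caller = "wham", siteId = c("w1", "w2", "w3"),
                   quality = data.frame(QUAL = c(250, 249, NA)))
  res <- filterQual(x)
  expect_setequal(res$report$site_id[res$report$kept], "w1")
  reason <- setNames(res$report$reasons, res$report$site_id)
  expect_equal(reason[["w2"]], "qual")
  expect_equal(reason[["w3"]], "no_qual")
  allPass <- makeCallSet("c1", 100, 1099, "DEL", caller = "manta",
                         quality = data.frame(QUAL = 900))
  expect_true(all(filterQual(allPass)$report$kept))
})

test_that("planted per-rule counts are recovered exactly on a mixed fixture", {
  set.seed(55)
  co <- makePairs(3)
  ns <- nrow(co$samples)
  nPass <- 12; nShort <- 4; nMsq <- 5; nMissing <- 3
  n <- nPass + nShort + nMsq + nMissing
  svtype <- rep("DEL", n)
  len <- c(rep(1000, nPass), rep(45, nShort), rep(1000, nMsq + nMissing))
  msq <- c(rep(60, nPass + nShort), rep(10, nMsq), rep(60, nMissing))
  gt <- matrix(1L, n, ns, dimnames = list(NULL, co$samples$sample_id))
  gt[(nPass + nShort + nMsq + 1):n, 1] <- NA  # 1/6 missing > 10%
  x <- makeCallSet("c1", seq(1, by = 10000, length.out = n),
                   seq(1, by = 10000, length.out = n) + len - 1,
                   svtype, caller = "speedseq", svLen = len,
                   quality = data.frame(MSQ = msq, SU = 20, SR = 10, PE = 10),
                   gt = gt, sampleInfo = co$samples)
  res <- filterSpeedseq(x)
  codes <- strsplit(res$report$reasons[!res$report$kept], ";")
  tab <- table(unlist(codes))
  expect_equal(sum(res$report$kept), nPass)
  expect_equal(unname(tab[["min_len"]]), nShort)
  expect_equal(unname(tab[["msq_DEL"]]), nMsq)
  expect_equal(unname(tab[["missing_rate"]]), nMissing)
})
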