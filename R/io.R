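#' @importFrom VariantAnnotation readVcf writeVcf VCF VCFHeader header geno
#'   info ref alt fixed header<- geno<- info<-
#' @importFrom Biostrings DNAStringSet
NULL

# INFO/FORMAT dialect shared by the reader and writer. Quality metrics are
# namespaced into one per-site map (rowData columns) so filtering and merging
# code stays caller-generic.
.vcfInfoHeader <- function() {
  DataFrame(
    Number = c("1", "1", "1", "1", rep("1", length(svQualityKeys())), "1", "0"),
    Type = c("String", "Integer", "Integer", "String",
             rep("Float", length(svQualityKeys())), "String", "Flag"),
    Description = c("SV class", "End position", "SV length", "Caller of origin",
                    paste("Quality metric", svQualityKeys()),
                    "Redundancy cluster id", "Primary site of its cluster"),
    row.names = c("SVTYPE", "END", "SVLEN", "CALLER", svQualityKeys(),
                  "CLUSTER_ID", "PRIMARY"))
}

.vcfGenoHeader <- function(extra = character()) {
  nm <- c("GT", "CN", "AB", "FT", extra)
  DataFrame(
    Number = rep("1", length(nm)),
    Type = c("String", "Float", "Float", "String", rep("Float", length(extra))),
    Description = c("Genotype", "Copy number", "Allele balance",
                    "Per-genotype filter (LQ = low quality)",
                    sprintf("Call-level metric %s", extra)),
    row.names = nm)
}

.gtCodeFromString <- function(g) {
  # "0/0" -> 0, "0/1" -> 1, "1/1" -> 2, "./." -> NA; any non-reference allele
  # index counts toward the alt-allele count.
  vapply(strsplit(g, "[/|]"), function(a) {
    if (any(a == ".")) return(NA_integer_)
    sum(a != "0")
  }, integer(1))
}

.gtStringFromCode <- function(code) {
  out <- rep("./.", length(code))
  out[!is.na(code) & code == 0] <- "0/0"
  out[!is.na(code) & code == 1] <- "0/1"
  out[!is.na(code) & code >= 2] <- "1/1"
  out
}

#' Read a structural variant VCF into an SVCallSet
#'
#' Parses a VCF 4.2 call set written in one caller's dialect: SVTYPE/END/SVLEN
#' INFO keys define the site interval and class, caller quality keys (MSQ,
#' GSCNQUAL, QUAL, SU, SR, PE, ASSESS, NBINS, SCORE) are collected into the
#' per-site quality map, and GT/CN/AB/FT FORMAT fields populate the core
#' assays. For `caller = "melt"` the FILTER column is parsed into the MELT
#' hard-filter flag set (lc, s25, rSD, hDP). Breakpoint classes (BND, INS,
#' ALU, LINE1, SVA) become 1-bp point records. POS..END map to the 1-based
#' closed internal interval, so `width == SVLEN` for interval classes.
#'
#' Records with an SVTYPE outside the controlled vocabulary are dropped and
#' reported via the `"record_errors"` attribute (and a warning).
#'
#' @param path VCF file (plain text or bgzip).
#' @param caller One of `svCallers()`.
#' @return An [SVCallSet-class].
#' @export
readSVVcf <- function(path, caller = "external") {
  stopifnot(caller %in% svCallers())
  vcf <- VariantAnnotation::readVcf(path, genome = "synthetic")
  inf <- info(vcf)
  n <- nrow(vcf)
  svtype <- as.character(inf$SVTYPE)
  bad <- is.na(svtype) | !(svtype %in% svTypes())
  recErrors <- character()
  if (any(bad)) {
    recErrors <- sprintf("record %s: unknown SVTYPE '%s'",
                         rownames(vcf)[bad], svtype[bad])
    .warnf("dropped %d record(s) with unknown SVTYPE", sum(bad))
    vcf <- vcf[!bad, ]
    inf <- info(vcf)
    svtype <- as.character(inf$SVTYPE)
    n <- nrow(vcf)
  }
  pos <- start(SummarizedExperiment::rowRanges(vcf))
  endv <- if (is.null(inf$END)) rep(NA_integer_, n) else
    suppressWarnings(as.integer(inf$END))
  point <- svtype %in% svPointTypes()
  endv[point | is.na(endv)] <- pos[point | is.na(endv)]
  gr <- GRanges(as.character(seqnames(SummarizedExperiment::rowRanges(vcf))),
                IRanges(pos, pmax(pos, endv)))
  svlen <- if (is.null(inf$SVLEN)) rep(NA_integer_, n) else
    suppressWarnings(abs(as.integer(inf$SVLEN)))
  svlen[is.na(svlen) & !point] <- width(gr)[is.na(svlen) & !point]

  qual <- DataFrame(row.names = seq_len(n))
  for (k in svQualityKeys()) {
    if (k %in% colnames(inf)) {
      qual[[k]] <- suppressWarnings(as.numeric(inf[[k]]))
    }
  }
  # site QUAL column doubles as the QUAL quality key when INFO lacks it
  if (is.null(qual[["QUAL"]]) && any(!is.na(fixed(vcf)$QUAL))) {
    qual[["QUAL"]] <- as.numeric(fixed(vcf)$QUAL)
  }

  flt <- as.character(fixed(vcf)$FILTER)
  mf <- if (caller == "melt") {
    CharacterList(lapply(strsplit(flt, ";"), function(f)
      intersect(f, .meltFlagSet)))
  } else NULL

  gmats <- list()
  gn <- geno(vcf)
  if ("GT" %in% names(gn) && ncol(vcf) > 0) {
    gmats$gt <- matrix(.gtCodeFromString(as.character(gn$GT)), nrow = n,
                       dimnames = dimnames(gn$GT))
  }
  if ("CN" %in% names(gn)) gmats$cn <- matrix(as.numeric(gn$CN), nrow = n,
                                              dimnames = dimnames(gn$CN))
  if ("AB" %in% names(gn)) gmats$ab <- matrix(as.numeric(gn$AB), nrow = n,
                                              dimnames = dimnames(gn$AB))
  if ("FT" %in% names(gn)) {
    ft <- matrix(as.character(gn$FT), nrow = n, dimnames = dimnames(gn$FT))
    gmats$lq <- !is.na(ft) & ft == "LQ"
  }
  extra <- list()
  for (k in setdiff(names(gn), c("GT", "CN", "AB", "FT"))) {
    extra[[k]] <- matrix(as.numeric(gn[[k]]), nrow = n,
                         dimnames = dimnames(gn[[k]]))
  }

  cl <- if ("CALLER" %in% colnames(inf)) as.character(inf$CALLER) else caller
  cl[is.na(cl)] <- caller
  x <- SVCallSet(gr, siteId = rownames(vcf), caller = cl, svtype = svtype,
                 svLen = svlen, quality = qual, meltFlags = mf,
                 gt = gmats$gt, cn = gmats$cn, ab = gmats$ab, lq = gmats$lq,
                 extraAssays = extra)
  if ("CLUSTER_ID" %in% colnames(inf)) {
    rowData(x)$cluster_id <- as.character(inf$CLUSTER_ID)
  }
  if ("PRIMARY" %in% colnames(inf) && is.logical(inf$PRIMARY)) {
    rowData(x)$primary <- inf$PRIMARY
  }
  attr(x, "record_errors") <- recErrors
  x
}

#' Write an SVCallSet as VCF 4.2
#'
#' Inverse of [readSVVcf()]: emits SVTYPE/END/SVLEN/CALLER INFO keys, the
#' per-site quality metrics present for this call set, CLUSTER_ID/PRIMARY
#' tags when the object carries them, GT/CN/AB/FT FORMAT fields for the
#' assays present, and MELT flags in the FILTER column. Reading the file back
#' with [readSVVcf()] reproduces the object for all supported fields.
#'
#' @param x An [SVCallSet-class].
#' @param path Output path (".vcf"; VariantAnnotation appends ".bgz" when
#'   `index = TRUE` is passed through).
#' @param ... Passed to [VariantAnnotation::writeVcf()].
#' @return `path`, invisibly.
#' @export
writeSVVcf <- function(x, path, ...) {
  n <- nrow(x)
  if (n == 0L) {
    cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
    if (ncol(x)) cols <- c(cols, "FORMAT", colnames(x))
    writeLines(c("##fileformat=VCFv4.2",
                 paste(cols, collapse = "\t")), path)
    return(invisible(path))
  }
  gr <- rowRanges(x)
  rd <- rowData(x)
  posGr <- GRanges(seqnames(gr), IRanges(start(gr), start(gr)))
  names(posGr) <- rd$site_id

  inf <- DataFrame(SVTYPE = rd$svtype, END = end(gr), SVLEN = rd$sv_len,
                   CALLER = rd$caller)
  hdrInfo <- .vcfInfoHeader()
  keep <- c("SVTYPE", "END", "SVLEN", "CALLER")
  for (k in svQualityKeys()) {
    if (any(!is.na(rd[[k]]))) { inf[[k]] <- rd[[k]]; keep <- c(keep, k) }
  }
  if (!is.null(rd$cluster_id)) { inf$CLUSTER_ID <- rd$cluster_id; keep <- c(keep, "CLUSTER_ID") }
  if (!is.null(rd$primary)) { inf$PRIMARY <- rd$primary; keep <- c(keep, "PRIMARY") }

  flt <- vapply(as.list(rd$melt_flags), function(f)
    if (length(f)) paste(f, collapse = ";") else "PASS", character(1))

  gn <- list()
  extra <- setdiff(assayNames(x), c("gt", "cn", "ab", "lq"))
  if (ncol(x) > 0) {
    if (!is.null(gtMatrix(x))) {
      gn$GT <- matrix(.gtStringFromCode(gtMatrix(x)), nrow = n,
                      dimnames = dimnames(gtMatrix(x)))
    }
    if (!is.null(cnMatrix(x))) gn$CN <- cnMatrix(x)
    if (!is.null(abMatrix(x))) gn$AB <- abMatrix(x)
    if (!is.null(lqMatrix(x))) {
      lq <- lqMatrix(x)
      ft <- matrix("PASS", nrow(lq), ncol(lq), dimnames = dimnames(lq))
      ft[is.na(lq)] <- "."
      ft[!is.na(lq) & lq] <- "LQ"
      gn$FT <- ft
    }
    for (k in extra) gn[[k]] <- assay(x, k)
  }
  if (!length(gn)) {
    gn$GT <- matrix(character(0), nrow = n, ncol = 0)
  }

  hdr <- VCFHeader(samples = colnames(x))
  VariantAnnotation::info(hdr) <- hdrInfo[keep, , drop = FALSE]
  VariantAnnotation::geno(hdr) <- .vcfGenoHeader(extra)[names(gn), , drop = FALSE]
  VariantAnnotation::meta(hdr) <- IRanges::DataFrameList(
    fileformat = DataFrame(Value = "VCFv4.2", row.names = "fileformat"))

  out <- VCF(rowRanges = posGr,
             colData = DataFrame(Samples = seq_len(ncol(x)),
                                 row.names = colnames(x)),
             exptData = list(header = hdr),
             fixed = DataFrame(
               REF = DNAStringSet(rep("N", n)),
               ALT = CharacterList(as.list(paste0("<", rd$svtype, ">"))),
               QUAL = as.numeric(rd$QUAL),
               FILTER = flt),
             info = inf[, keep, drop = FALSE],
             geno = SimpleList(lapply(gn, identity)))
  VariantAnnotation::writeVcf(out, path, ...)
  invisible(path)
}

.studies <- c("iPSCORE", "HipSci")
.cellTypes <- c("blood", "fibroblast", "iPSC")
.superpops <- c("EUR", "AFR", "EAS", "SAS", "AMR")

#' Read sample metadata and replicate-pair manifest
#'
#' The manifest is a TSV with header and columns `sample_id`, `donor_id`,
#' `study` (iPSCORE/HipSci), `cell_type` (blood/fibroblast/iPSC),
#' `superpopulation` (EUR/AFR/EAS/SAS/AMR) and `sex` (M/F). Replicate pairs
#' — two samples sharing one donor genome — are either read from an explicit
#' pairs TSV (`sample_a`, `sample_b`, `pair_type` in mz_twin/fib_ipsc) or,
#' when `pairsPath` is NULL, derived from donors contributing exactly two
#' samples (two blood samples = mz_twin; fibroblast + iPSC = fib_ipsc).
#'
#' @param path Sample metadata TSV.
#' @param pairsPath Optional replicate-pair TSV.
#' @return `list(samples = data.frame, pairs = data.frame)`.
#' @export
readSampleManifest <- function(path, pairsPath = NULL) {
  s <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("sample_id", "donor_id", "study", "cell_type", "superpopulation", "sex")
  miss <- setdiff(need, colnames(s))
  if (length(miss)) .stopf("manifest lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(s$sample_id)) {
    .stopf("duplicate sample_id: %s", s$sample_id[duplicated(s$sample_id)][1])
  }
  for (col in c("study", "cell_type", "superpopulation", "sex")) {
    valid <- switch(col, study = .studies, cell_type = .cellTypes,
                    superpopulation = .superpops, sex = c("M", "F"))
    badRow <- which(!(s[[col]] %in% valid))
    if (length(badRow)) {
      .stopf("row %d: unknown %s value '%s'", badRow[1], col, s[[col]][badRow[1]])
    }
  }
  if (!is.null(pairsPath)) {
    p <- utils::read.delim(pairsPath, stringsAsFactors = FALSE)
    pairs <- validateReplicatePairs(p, s)
  } else {
    pairs <- do.call(rbind, lapply(split(s, s$donor_id), function(d) {
      if (nrow(d) != 2L) return(NULL)
      ct <- sort(d$cell_type)
      type <- if (identical(ct, c("blood", "blood"))) "mz_twin"
              else if (identical(ct, c("fibroblast", "iPSC"))) "fib_ipsc"
              else return(NULL)
      data.frame(sample_a = d$sample_id[1], sample_b = d$sample_id[2],
                 pair_type = type, stringsAsFactors = FALSE)
    }))
    pairs <- pairs %||% data.frame(sample_a = character(), sample_b = character(),
                                   pair_type = character())
    rownames(pairs) <- NULL
  }
  list(samples = s, pairs = pairs)
}

#' Validate a replicate-pair table against sample metadata
#'
#' @param pairs Data frame with `sample_a`, `sample_b`, `pair_type`.
#' @param samples Sample metadata data frame.
#' @return The validated pairs data frame.
#' @export
validateReplicatePairs <- function(pairs, samples) {
  stopifnot(all(c("sample_a", "sample_b", "pair_type") %in% colnames(pairs)))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$sample_a[i]; b <- pairs$sample_b[i]
    if (a == b) .stopf("pair row %d: sample_a equals sample_b ('%s')", i, a)
    if (!(a %in% samples$sample_id)) .stopf("pair row %d: unknown sample '%s'", i, a)
    if (!(b %in% samples$sample_id)) .stopf("pair row %d: unknown sample '%s'", i, b)
    if (!(pairs$pair_type[i] %in% c("mz_twin", "fib_ipsc"))) {
      .stopf("pair row %d: unknown pair_type '%s'", i, pairs$pair_type[i])
    }
    da <- samples$donor_id[samples$sample_id == a]
    db <- samples$donor_id[samples$sample_id == b]
    if (pairs$pair_type[i] == "fib_ipsc" && da != db) {
      .stopf("pair row %d: fib_ipsc pair spans donors '%s' and '%s'", i, da, db)
    }
  }
  pairs
}

#' Write a sample manifest TSV
#' @param samples Sample metadata data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeSampleManifest <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-caller hard-filter thresholds
#'
#' Defaults are the published per-caller, per-class thresholds: SpeedSeq MSQ
#' must exceed 20 (DEL, rMEI), 100 (DUP) and 90 (INV, BND); deletions shorter
#' than 418 bp need split-read support; non-BND events must span at least
#' 50 bp; BNDs need 25% split/paired-end support; QUAL > 100 inversions need
#' 10% split/paired-end evidence; sites with over 10% missing genotypes are
#' dropped. Genome STRiP requires a minimum GSCNQUAL of 2/12/14 for
#' DEL/mCNV/DUP, polymorphism, and at most 10% low-quality genotypes among
#' non-iPSC samples. Long-CNV calls need NBINS >= 10, SCORE >= 1000 and a
#' carrier copy number above 2.75 (DUP) or below 1.25 (DEL). MELT records
#' must carry no hard-filter flag and an ASSESS tranche of 5. HipSTR calls
#' face five per-genotype thresholds and a per-subset call rate above 80%.
#' wham/manta sites need QUAL of at least 250. Every threshold is
#' overridable.
#'
#' @return Nested list of thresholds.
#' @export
defaultFilterConfig <- function() {
  list(
    speedseq = list(
      msq = c(DEL = 20, rMEI = 20, DUP = 100, INV = 90, BND = 90),
      del_sr_len = 418, min_len = 50, bnd_support_frac = 0.25,
      inv_qual = 100, inv_support_frac = 0.10, max_missing = 0.10),
    melt = list(exclude_flags = c("lc", "s25", "rSD", "hDP"), assess = 5),
    genomestrip = list(
      gscnqual = c(DEL = 2, mCNV = 12, DUP = 14), max_lq_frac = 0.10),
    lcnv = list(min_nbins = 10, min_score = 1000,
                dup_min_cn = 2.75, del_max_cn = 1.25),
    hipstr = list(min_call_qual = 0.9, max_flank_indel = 0.15,
                  max_stutter = 0.15, min_allele_bias = -2,
                  min_strand_bias = -2, min_call_rate = 0.8),
    qual = list(min_qual = 250))
}

#' Read / write a filter configuration as JSON
#' @param path JSON file.
#' @return For `readFilterConfig`, the nested threshold list merged over the
#'   defaults (unknown keys rejected).
#' @export
readFilterConfig <- function(path) {
  usr <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- defaultFilterConfig()
  for (caller in names(usr)) {
    if (!caller %in% names(cfg)) .stopf("unknown filter section '%s'", caller)
    for (k in names(usr[[caller]])) {
      if (!k %in% names(cfg[[caller]])) {
        .stopf("unknown filter key '%s' in section '%s'", k, caller)
      }
      v <- usr[[caller]][[k]]
      if (is.numeric(cfg[[caller]][[k]]) && !all(is.finite(unlist(v)))) {
        .stopf("non-finite threshold for %s/%s", caller, k)
      }
      if (!is.null(names(cfg[[caller]][[k]])) && is.list(v)) v <- unlist(v)
      cfg[[caller]][[k]] <- v
    }
  }
  cfg
}

#' @rdname readFilterConfig
#' @param config Nested threshold list.
#' @export
writeFilterConfig <- function(config, path) {
  # named vectors become JSON objects so per-class thresholds keep names
  enc <- lapply(config, function(sec)
    lapply(sec, function(v) if (!is.null(names(v))) as.list(v) else v))
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
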