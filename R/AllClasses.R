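#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges CharacterList
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#'   pintersect
#' @importFrom SummarizedExperiment SummarizedExperiment rowRanges rowData
#'   colData assay assays assayNames rowData<- colData<-
NULL

#' Controlled vocabularies
#'
#' Caller identities and structural variant classes understood by the
#' package. `svPointTypes()` lists the classes stored as 1-bp breakpoint
#' records (insertions and breakends, matched by distance rather than span);
#' all other classes are true intervals.
#'
#' @return Character vectors of valid values.
#' @export
#' @examples
#' svCallers()
#' svTypes()
svCallers <- function() c("speedseq", "genomestrip", "gs_lcnv", "melt",
                          "hipstr", "wham", "manta", "external")

#' @rdname svCallers
#' @export
svTypes <- function() c("DEL", "DUP", "mCNV", "INV", "BND", "rMEI",
                        "ALU", "LINE1", "SVA", "INS", "STR")

#' @rdname svCallers
#' @export
svPointTypes <- function() c("BND", "INS", "ALU", "LINE1", "SVA")

#' @rdname svCallers
#' @export
svQualityKeys <- function() c("MSQ", "GSCNQUAL", "QUAL", "SU", "SR", "PE",
                              "ASSESS", "NBINS", "SCORE")

.meltFlagSet <- c("lc", "s25", "rSD", "hDP")
.filterStatuses <- c("pass", "filtered", "secondary", "constituent")

#' SVCallSet: a structural variant call set with genotypes
#'
#' The central container of the package: one caller's view of a cohort.
#' It extends \linkS4class{RangedSummarizedExperiment}; rows are called sites
#' (a `GRanges` whose metadata columns carry site id, caller, SV class,
#' length, per-caller quality metrics, MELT flags and filter status) and
#' columns are samples. Core assays are
#' \describe{
#'   \item{gt}{integer alt-allele count (0/1/2), NA = missing}
#'   \item{cn}{copy number; integer for read-depth callers, possibly
#'     fractional before rounding}
#'   \item{ab}{allele balance, fraction of non-reference reads in [0,1]}
#'   \item{lq}{logical low-quality genotype flag (the FT=LQ format field)}
#' }
#' Extra per-caller assays (e.g. HipSTR call-level quality channels) are
#' carried alongside. Quality metrics absent for a caller are NA columns.
#'
#' @export
setClass("SVCallSet", contains = "RangedSummarizedExperiment")

.validSVCallSet <- function(object) {
  msg <- character()
  rd <- rowData(object)
  need <- c("site_id", "caller", "svtype", "sv_len", "filter_status")
  miss <- setdiff(need, colnames(rd))
  if (length(miss)) {
    return(paste("missing rowData columns:", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(rd$site_id)) msg <- c(msg, "site_id values must be unique")
  if (!all(rd$caller %in% svCallers())) msg <- c(msg, "unknown caller value")
  if (!all(rd$svtype %in% svTypes())) msg <- c(msg, "unknown svtype value")
  if (!all(rd$filter_status %in% .filterStatuses)) {
    msg <- c(msg, "invalid filter_status")
  }
  if (any(!is.na(rd$sv_len) & rd$sv_len <= 0)) {
    msg <- c(msg, "sv_len must be positive")
  }
  pt <- rd$svtype %in% svPointTypes()
  if (any(width(rowRanges(object))[pt] != 1L)) {
    msg <- c(msg, "breakpoint classes (BND/INS/MEI) must be 1-bp point records")
  }
  core <- intersect(c("gt", "cn", "ab", "lq"), assayNames(object))
  if ("ab" %in% core) {
    ab <- assay(object, "ab")
    if (any(!is.na(ab) & (ab < 0 | ab > 1))) {
      msg <- c(msg, "allele balance must lie in [0, 1]")
    }
  }
  if ("cn" %in% core) {
    cn <- assay(object, "cn")
    if (any(!is.na(cn) & cn < 0)) msg <- c(msg, "copy number must be >= 0")
  }
  if (length(msg)) msg else TRUE
}
setValidity("SVCallSet", .validSVCallSet)

#' Construct an SVCallSet
#'
#' @param ranges `GRanges` of called sites, 1-based closed coordinates
#'   (`width(ranges)` equals the event length for interval classes;
#'   breakpoint classes are 1-bp records whose element length lives in
#'   `svLen`).
#' @param siteId,caller,svtype Per-site identifiers, caller of origin and SV
#'   class. `caller` may be a single value recycled to all sites.
#' @param svLen Event length in bp; defaults to `width(ranges)` for interval
#'   classes and must be supplied for breakpoint classes.
#' @param quality Data frame / DataFrame of per-site quality metrics, with
#'   columns among `svQualityKeys()`.
#' @param meltFlags `CharacterList` of MELT hard-filter flags per site
#'   (subset of lc, s25, rSD, hDP).
#' @param gt,cn,ab,lq Site-by-sample matrices (may be NULL); see class docs.
#' @param sampleInfo Data frame of sample metadata (columns `sample_id`,
#'   `donor_id`, `study`, `cell_type`, `superpopulation`, `sex`); used as
#'   `colData`.
#' @param filterStatus Per-site status, one of pass/filtered/secondary/
#'   constituent (default "pass").
#' @param extraAssays Named list of additional site-by-sample matrices.
#' @return An [SVCallSet-class] object.
#' @export
SVCallSet <- function(ranges, siteId, caller, svtype, svLen = NULL,
                      quality = NULL, meltFlags = NULL,
                      gt = NULL, cn = NULL, ab = NULL, lq = NULL,
                      sampleInfo = NULL, filterStatus = "pass",
                      extraAssays = list()) {
  n <- length(ranges)
  caller <- rep(as.character(caller), length.out = n)
  svtype <- as.character(svtype)
  if (is.null(svLen)) {
    svLen <- ifelse(svtype %in% svPointTypes(), NA_integer_, width(ranges))
  }
  rd <- DataFrame(site_id = as.character(siteId), caller = caller,
                  svtype = svtype, sv_len = as.integer(svLen),
                  filter_status = rep(filterStatus, length.out = n))
  qk <- svQualityKeys()
  qm <- matrix(NA_real_, n, length(qk), dimnames = list(NULL, qk))
  if (!is.null(quality)) {
    for (k in intersect(colnames(quality), qk)) qm[, k] <- as.numeric(quality[[k]])
  }
  rd <- cbind(rd, DataFrame(qm))
  if (is.null(meltFlags)) meltFlags <- CharacterList(rep(list(character()), n))
  rd$melt_flags <- meltFlags
  mcols(ranges) <- NULL
  names(ranges) <- rd$site_id

  asy <- list()
  nsamp <- NULL
  for (nm in c("gt", "cn", "ab", "lq")) {
    m <- switch(nm, gt = gt, cn = cn, ab = ab, lq = lq)
    if (!is.null(m)) {
      m <- as.matrix(m)
      nsamp <- nsamp %||% ncol(m)
      asy[[nm]] <- m
    }
  }
  for (nm in names(extraAssays)) asy[[nm]] <- as.matrix(extraAssays[[nm]])
  if (is.null(nsamp)) nsamp <- if (length(asy)) ncol(asy[[1]]) else 0L
  if (!length(asy)) {
    asy <- list(gt = matrix(NA_integer_, n, nsamp))
  }
  cd <- if (!is.null(sampleInfo)) {
    si <- as.data.frame(sampleInfo)
    rownames(si) <- si$sample_id
    DataFrame(si)
  } else if (!is.null(asy[[1]]) && !is.null(colnames(asy[[1]]))) {
    DataFrame(row.names = colnames(asy[[1]]))
  } else {
    DataFrame(row.names = if (nsamp) paste0("S", seq_len(nsamp)) else character())
  }
  asy <- lapply(asy, function(m) {
    dimnames(m) <- list(rd$site_id, rownames(cd))
    m
  })
  se <- SummarizedExperiment(assays = asy, rowRanges = ranges, colData = cd)
  rowData(se) <- rd
  new("SVCallSet", se)
}

setMethod("show", "SVCallSet", function(object) {
  rd <- rowData(object)
  cat("SVCallSet with", nrow(object), "sites x", ncol(object), "samples\n")
  if (nrow(object)) {
    cat("  callers:", paste(unique(rd$caller), collapse = ", "), "\n")
    tab <- table(rd$svtype)
    cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
    cat("  filter_status:", paste(sprintf("%s=%d", names(table(rd$filter_status)),
                                          table(rd$filter_status)), collapse = " "), "\n")
  }
  cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
})
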