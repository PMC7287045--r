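#' Accessors for SVCallSet
#'
#' Slot access goes through these accessors rather than direct `rowData()`
#' manipulation. Matrix accessors return NULL when the assay is absent.
#'
#' @param x An [SVCallSet-class].
#' @param metric A quality key among `svQualityKeys()`.
#' @param value Replacement value.
#' @return Per-site vectors (siteId, svCaller, svType, svLen, filterStatus,
#'   qualMetric), a `CharacterList` (meltFlags) or site-by-sample matrices.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("siteId", function(x) standardGeneric("siteId"))
#' @rdname accessors
#' @export
setMethod("siteId", "SVCallSet", function(x) rowData(x)$site_id)

#' @rdname accessors
#' @export
setGeneric("svCaller", function(x) standardGeneric("svCaller"))
#' @rdname accessors
#' @export
setMethod("svCaller", "SVCallSet", function(x) rowData(x)$caller)

#' @rdname accessors
#' @export
setGeneric("svType", function(x) standardGeneric("svType"))
#' @rdname accessors
#' @export
setMethod("svType", "SVCallSet", function(x) rowData(x)$svtype)

#' @rdname accessors
#' @export
setGeneric("svLen", function(x) standardGeneric("svLen"))
#' @rdname accessors
#' @export
setMethod("svLen", "SVCallSet", function(x) rowData(x)$sv_len)

#' @rdname accessors
#' @export
setGeneric("filterStatus", function(x) standardGeneric("filterStatus"))
#' @rdname accessors
#' @export
setMethod("filterStatus", "SVCallSet", function(x) rowData(x)$filter_status)

#' @rdname accessors
#' @export
setGeneric("filterStatus<-", function(x, value) standardGeneric("filterStatus<-"))
#' @rdname accessors
#' @export
setMethod("filterStatus<-", "SVCallSet", function(x, value) {
  stopifnot(all(value %in% .filterStatuses))
  rowData(x)$filter_status <- rep(value, length.out = nrow(x))
  x
})

#' @rdname accessors
#' @export
setGeneric("qualMetric", function(x, metric) standardGeneric("qualMetric"))
#' @rdname accessors
#' @export
setMethod("qualMetric", "SVCallSet", function(x, metric) {
  stopifnot(metric %in% svQualityKeys())
  rowData(x)[[metric]]
})

#' @rdname accessors
#' @export
setGeneric("meltFlags", function(x) standardGeneric("meltFlags"))
#' @rdname accessors
#' @export
setMethod("meltFlags", "SVCallSet", function(x) rowData(x)$melt_flags)

.assayOrNull <- function(x, name) {
  if (name %in% assayNames(x)) assay(x, name) else NULL
}

#' @rdname accessors
#' @export
gtMatrix <- function(x) .assayOrNull(x, "gt")
#' @rdname accessors
#' @export
cnMatrix <- function(x) .assayOrNull(x, "cn")
#' @rdname accessors
#' @export
abMatrix <- function(x) .assayOrNull(x, "ab")
#' @rdname accessors
#' @export
lqMatrix <- function(x) .assayOrNull(x, "lq")

#' Genotype evidence channel for a site
#'
#' Multiallelic CNVs are represented by copy number only; their gt assay is a
#' derived non-mode indicator. This helper returns the channel used for
#' replication and concordance computations: `cn` for mCNV rows (and rows
#' whose gt is entirely missing but cn present), otherwise `gt`.
#' @param x An [SVCallSet-class].
#' @return Character vector ("gt" or "cn") per site.
#' @export
siteChannel <- function(x) {
  ch <- rep("gt", nrow(x))
  cn <- cnMatrix(x); gt <- gtMatrix(x)
  if (!is.null(cn)) {
    ch[svType(x) == "mCNV"] <- "cn"
    if (!is.null(gt) && ncol(x) > 0) {
      allmiss <- rowSums(!is.na(gt)) == 0 & rowSums(!is.na(cn)) > 0
      ch[allmiss] <- "cn"
    }
  }
  ch
}
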