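#' @importFrom stats sd plogis rbeta model.matrix lm.fit
#' @importFrom utils read.delim write.table
#' @importFrom tools md5sum
#' @importFrom jsonlite read_json write_json toJSON
#' @importFrom igraph make_empty_graph add_edges components V
#' @importFrom GenomeInfoDb seqnames
NULL
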