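# Internal helpers shared across modules.

#' @importFrom stats cor pchisq pnorm rbinom rnorm runif setNames complete.cases
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pearson correlation tolerant of missing data and zero variance
#'
#' Pairwise-complete Pearson correlation; returns NA when fewer than two
#' complete observations remain or either vector is constant. Monomorphic
#' evidence carries no linking information, so callers treat NA as a failed
#' correlation threshold.
#' @noRd
.safeCor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

# Modal (most frequent) non-missing value; ties broken toward the smallest
# value so the result is independent of input order.
.modalValue <- function(v) {
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  tab <- table(v)
  as.numeric(names(tab)[which.max(tab)])
}

# Connected components of an undirected edge list over `ids`.
# Returns an integer membership vector named by id; singletons get their
# own component.
.components <- function(ids, from, to) {
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  igraph::V(g)$name <- ids
  if (length(from)) {
    g <- igraph::add_edges(g, rbind(match(from, ids), match(to, ids)))
  }
  memb <- igraph::components(g)$membership
  stats::setNames(as.integer(memb), ids)
}

# Deterministic RNG scope: runs `expr` under set.seed(seed) and restores
# the caller's RNG state afterwards.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  set.seed(seed)
  expr
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
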