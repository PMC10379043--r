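# The comparison suite of degree-based topological indices.  M1 and F are
# vertex sums (degree-sequence determined); the rest are edge sums.

#' Degree-based topological index suite
#'
#' Computes, for one molecular graph, the k-th degree-based entropy
#' together with the seven classical degree-based indices used as its
#' comparison panel:
#' \describe{
#'   \item{M1}{first Zagreb index, sum of squared degrees}
#'   \item{M2}{second Zagreb index, sum over edges of `d_u * d_v`}
#'   \item{F}{forgotten index, sum of cubed degrees}
#'   \item{ISI}{inverse sum indeg, sum over edges of `d_u d_v / (d_u + d_v)`}
#'   \item{SDD}{symmetric division degree, sum over edges of
#'     `d_u/d_v + d_v/d_u`}
#'   \item{SCI}{sum connectivity, sum over edges of `(d_u + d_v)^(-1/2)`}
#'   \item{RR}{reciprocal Randic, sum over edges of `sqrt(d_u d_v)`}
#' }
#'
#' @param x a [MolecularGraph-class].
#' @param k entropy exponent passed to [degreeEntropy()], default 2.
#' @return a named numeric vector with elements
#'   `Id_k, M1, M2, F, ISI, SDD, SCI, RR`.
#' @examples
#' indexSuite(fromEdgeList("1 2\n2 3"))
#' @rdname indexSuite
#' @export
setMethod("indexSuite", "MolecularGraph", function(x, k = 2) {
  d <- degreeVector(x)
  e <- edgeMatrix(x)
  du <- d[e[, 1L]]
  dv <- d[e[, 2L]]
  c(
    Id_k = degreeEntropy(x, k),
    M1 = sum(d^2),
    M2 = sum(du * dv),
    F = sum(d^3),
    ISI = sum(du * dv / (du + dv)),
    SDD = sum(du / dv + dv / du),
    SCI = sum(1 / sqrt(du + dv)),
    RR = sum(sqrt(du * dv))
  )
})

#' Index table for a collection of graphs
#'
#' Applies [indexSuite()] to each graph and assembles a data frame with
#' one row per graph, in input order.
#'
#' @param graphs list of [MolecularGraph-class] objects.
#' @param k entropy exponent, default 2.
#' @return data.frame with columns `name, Id_k, M1, M2, F, ISI, SDD, SCI, RR`.
#' @export
computeIndexTable <- function(graphs, k = 2) {
  stopifnot(is.list(graphs))
  if (!length(graphs)) {
    return(data.frame(name = character(0), Id_k = numeric(0),
                      M1 = numeric(0), M2 = numeric(0), F = numeric(0),
                      ISI = numeric(0), SDD = numeric(0), SCI = numeric(0),
                      RR = numeric(0)))
  }
  rows <- t(vapply(graphs, indexSuite, numeric(8), k = k))
  out <- data.frame(
    name = vapply(graphs, graphName, ""),
    rows,
    row.names = NULL, check.names = FALSE
  )
  out
}

#' Write an index table as CSV
#'
#' Floating-point columns are formatted at 6 significant digits; the file
#' has a header row and comma separators.
#'
#' @param tab data.frame as produced by [computeIndexTable()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeIndexCSV <- function(tab, path) {
  fmt <- tab
  num <- vapply(fmt, is.numeric, TRUE)
  fmt[num] <- lapply(fmt[num], function(col) signif(col, 6))
  utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
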