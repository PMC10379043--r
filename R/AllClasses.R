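#' @import methods
NULL

#' MolecularGraph: a hydrogen-suppressed molecular skeleton
#'
#' An S4 container for a simple, connected, undirected graph whose vertices
#' are heavy atoms and whose edges are bonds.  All descriptors in this
#' package are functions of vertex degrees only, so element identity, bond
#' order and geometry are deliberately not represented.
#'
#' Vertex ids are the integers `1..n`; they carry no meaning and no
#' operation in the package depends on the labelling (every descriptor is
#' an isomorphism invariant).  Edges are stored as a two-column integer
#' matrix with `u < v` in each row, rows sorted lexicographically, so two
#' objects built from the same edge set compare identical.
#'
#' @slot name character label for the compound.
#' @slot nVertices number of vertices (heavy atoms).
#' @slot edges integer matrix with two columns, one row per bond.
#'
#' @section Validity:
#' An object is valid when the graph is simple (no self-loops, no
#' duplicate edges), every endpoint lies in `1..nVertices`, and the graph
#' is connected.  Disconnected structures are rejected rather than split
#' into components.
#'
#' @seealso [molecularGraph()], [fromEdgeList()], [fromSmiles()]
#' @exportClass MolecularGraph
setClass("MolecularGraph",
  representation(
    name = "character",
    nVertices = "integer",
    edges = "matrix"
  )
)

setValidity("MolecularGraph", function(object) {
  n <- object@nVertices
  e <- object@edges
  msg <- character(0)
  if (length(object@name) != 1L) {
    msg <- c(msg, "'name' must be a single string")
  }
  if (length(n) != 1L || is.na(n) || n < 1L) {
    msg <- c(msg, "'nVertices' must be a single integer >= 1")
  }
  if (!is.integer(e) || ncol(e) != 2L) {
    msg <- c(msg, "'edges' must be a two-column integer matrix")
    return(msg)
  }
  if (nrow(e) > 0) {
    if (any(e < 1L) || any(e > n)) {
      msg <- c(msg, "edge endpoints must lie in 1..nVertices")
    }
    if (any(e[, 1L] == e[, 2L])) {
      msg <- c(msg, "self-loops are not allowed")
    }
    key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
    if (anyDuplicated(key)) {
      msg <- c(msg, "duplicate edges are not allowed")
    }
  }
  if (!length(msg) && !.isConnectedEdges(e, n)) {
    msg <- c(msg, "graph must be connected")
  }
  if (length(msg)) msg else TRUE
})

#' FitResult: one simple-OLS structure-property fit
#'
#' Holds the complete report of a simple linear regression of a property
#' on a descriptor: slope and intercept with their standard errors, the
#' coefficient of determination, the residual standard error, the
#' regression F statistic with its significance (p-value), the sample
#' size, and per-record residuals.  Coefficient uncertainties are
#' conventionally reported as plus/minus twice the standard error; the
#' `show` method and [fitReport()] print them that way.
#'
#' @slot slope,intercept least-squares coefficients.
#' @slot slopeSE,interceptSE their standard errors.
#' @slot r2 coefficient of determination in `[0, 1]`.
#' @slot se residual standard error, `sqrt(RSS / (n - 2))`.
#' @slot fstat regression F statistic with `(1, n - 2)` degrees of freedom.
#' @slot sf upper-tail p-value of `fstat` (the "significance F").
#' @slot n sample size.
#' @slot residuals observed minus fitted values.
#'
#' @seealso [fitSimpleOLS()], [fitReport()]
#' @exportClass FitResult
setClass("FitResult",
  representation(
    slope = "numeric",
    intercept = "numeric",
    slopeSE = "numeric",
    interceptSE = "numeric",
    r2 = "numeric",
    se = "numeric",
    fstat = "numeric",
    sf = "numeric",
    n = "integer",
    residuals = "numeric"
  )
)

setValidity("FitResult", function(object) {
  msg <- character(0)
  if (object@r2 < -1e-12 || object@r2 > 1 + 1e-12) {
    msg <- c(msg, "r2 must lie in [0, 1]")
  }
  if (object@sf <= 0 || object@sf > 1) {
    msg <- c(msg, "sf must lie in (0, 1]")
  }
  if (object@n != length(object@residuals)) {
    msg <- c(msg, "length(residuals) must equal n")
  }
  if (length(msg)) msg else TRUE
})
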