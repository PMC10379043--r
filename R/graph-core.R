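# Graph construction, readers and accessors.  Everything downstream of
# this file consumes MolecularGraph objects only.

# connectivity on a raw edge matrix; n = 1 with no edges counts as connected
.isConnectedEdges <- function(edges, n) {
  if (n == 1L) return(nrow(edges) == 0L)
  if (nrow(edges) < n - 1L) return(FALSE)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::vcount(g) < n) {
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  }
  igraph::is_connected(g)
}

# normalize an edge matrix: u < v within rows, rows sorted, integer storage
.normalizeEdges <- function(edges) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) > 0) {
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                   pmax(edges[, 1L], edges[, 2L]))
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  edges
}

#' Construct a MolecularGraph from an edge matrix
#'
#' @param edges two-column matrix (or data.frame) of vertex-id pairs, one
#'   bond per row.  Vertex ids must be the integers `1..n`.
#' @param name compound label.
#' @param nVertices number of vertices; defaults to the largest id seen in
#'   `edges`.  Only a single-vertex graph may have zero edges.
#' @return a validated [MolecularGraph-class] object.
#' @examples
#' molecularGraph(rbind(c(1, 2), c(2, 3)), "propane")
#' @export
molecularGraph <- function(edges, name = "", nVertices = NULL) {
  edges <- .normalizeEdges(as.matrix(edges))
  if (is.null(nVertices)) {
    nVertices <- if (nrow(edges)) max(edges) else 1L
  }
  methods::new("MolecularGraph", name = as.character(name),
               nVertices = as.integer(nVertices), edges = edges)
}

#' Read a molecular graph from an edge-list text block
#'
#' Parses whitespace-separated vertex-id pairs, one edge per line.  The
#' vertex set is the union of endpoints, relabelled to `1..n` preserving
#' numeric order.  Each violation of the graph contract raises a distinct
#' error: parse failure, self-loop, duplicate edge, or disconnectedness.
#'
#' @param block character scalar (possibly multi-line) or character vector
#'   of lines.
#' @param name compound label.
#' @return a [MolecularGraph-class].
#' @examples
#' fromEdgeList("1 2\n2 3", "propane")
#' @export
fromEdgeList <- function(block, name = "") {
  lines <- unlist(strsplit(block, "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    stop("edge-list parse failure: no edges in block", call. = FALSE)
  }
  toks <- strsplit(lines, "[[:space:]]+")
  bad <- which(vapply(toks, length, 0L) != 2L)
  if (length(bad)) {
    stop(sprintf("edge-list parse failure at line %d: expected 'u v', got '%s'",
                 bad[1L], lines[bad[1L]]), call. = FALSE)
  }
  uv <- suppressWarnings(matrix(as.integer(unlist(toks)),
                                ncol = 2L, byrow = TRUE))
  if (anyNA(uv)) {
    stop("edge-list parse failure: non-integer vertex id", call. = FALSE)
  }
  if (any(uv[, 1L] == uv[, 2L])) {
    stop("self-loop in edge list", call. = FALSE)
  }
  ids <- sort(unique(as.vector(uv)))
  uv[] <- match(uv, ids)
  key <- paste(pmin(uv[, 1L], uv[, 2L]), pmax(uv[, 1L], uv[, 2L]))
  if (anyDuplicated(key)) {
    stop("duplicate edge in edge list", call. = FALSE)
  }
  n <- length(ids)
  if (!.isConnectedEdges(uv, n)) {
    stop("disconnected graph in edge list", call. = FALSE)
  }
  molecularGraph(uv, name = name, nVertices = n)
}

#' Read a molecular graph from a SMILES string
#'
#' Parses a SMILES string (via \pkg{ChemmineR}/\pkg{ChemmineOB}) and keeps
#' only the heavy-atom connectivity: hydrogens stay implicit, element
#' identity, charges and bond orders are discarded, and aromatic bonds
#' become ordinary edges.  All descriptors in this package depend only on
#' the skeleton, so nothing else is needed.  Dot-separated (disconnected)
#' SMILES are rejected.
#'
#' @param smiles a single SMILES string.
#' @param name compound label; defaults to the SMILES itself.
#' @return a [MolecularGraph-class].
#' @examples
#' \donttest{
#' fromSmiles("CCCCCCCC", "n-octane")
#' }
#' @export
fromSmiles <- function(smiles, name = smiles) {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("fromSmiles() requires the ChemmineR and ChemmineOB packages",
         call. = FALSE)
  }
  stopifnot(is.character(smiles), length(smiles) == 1L)
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) {
      stop(sprintf("invalid SMILES '%s'", smiles), call. = FALSE)
    })
  con <- ChemmineR::conMA(sdf[[1]])
  n <- nrow(con)
  if (is.null(n) || n < 1L) {
    stop(sprintf("invalid SMILES '%s'", smiles), call. = FALSE)
  }
  adj <- con > 0
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- cbind(idx[, 1L], idx[, 2L])
  if (!.isConnectedEdges(.normalizeEdges(edges), n)) {
    stop(sprintf("disconnected SMILES '%s' rejected", smiles), call. = FALSE)
  }
  molecularGraph(edges, name = name, nVertices = n)
}

#' Read a file of SMILES records
#'
#' One record per line, `SMILES<TAB>name`; the name is optional.  Blank
#' lines and lines starting with `#` are skipped.  A malformed SMILES
#' raises an error naming the offending line.
#'
#' @param path file path.
#' @return a named list of [MolecularGraph-class] objects, in input order.
#' @export
readSmilesFile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  out <- vector("list", length(keep))
  nms <- character(length(keep))
  for (i in seq_along(keep)) {
    ln <- keep[i]
    parts <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    smi <- trimws(parts[1L])
    nm <- if (length(parts) > 1L && nzchar(trimws(parts[2L]))) {
      trimws(parts[2L])
    } else smi
    out[[i]] <- tryCatch(fromSmiles(smi, nm), error = function(e) {
      stop(sprintf("line %d of '%s': %s", ln, path, conditionMessage(e)),
           call. = FALSE)
    })
    nms[i] <- nm
  }
  names(out) <- nms
  out
}

#' Read a file of edge-list blocks
#'
#' Blocks are separated by header lines of the form `# <name>`; each block
#' holds one edge per line as `u v`.
#'
#' @param path file path.
#' @return a named list of [MolecularGraph-class] objects, in file order.
#' @export
readEdgeListFile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- which(startsWith(trimws(lines), "#"))
  if (!length(hdr)) {
    stop(sprintf("'%s': no '# <name>' block headers found", path),
         call. = FALSE)
  }
  ends <- c(hdr[-1L] - 1L, length(lines))
  out <- vector("list", length(hdr))
  nms <- character(length(hdr))
  for (i in seq_along(hdr)) {
    nms[i] <- trimws(sub("^\\s*#\\s*", "", lines[hdr[i]]))
    body <- lines[seq(hdr[i] + 1L, ends[i])]
    out[[i]] <- fromEdgeList(paste(body, collapse = "\n"), name = nms[i])
  }
  names(out) <- nms
  out
}

#' Accessors for MolecularGraph
#'
#' `graphName`, `numVertices`, `numEdges` and `edgeMatrix` return the
#' corresponding slots; `degreeVector` returns the integer vector of
#' vertex degrees (indexed by vertex id), which satisfies the handshake
#' identity `sum(degrees) == 2 * numEdges(x)`.
#'
#' @param x a [MolecularGraph-class].
#' @return see individual descriptions.
#' @name MolecularGraph-accessors
#' @aliases graphName numVertices numEdges edgeMatrix degreeVector
#' @examples
#' degreeVector(fromEdgeList("1 2\n2 3"))  # 1 2 1
NULL

#' @rdname MolecularGraph-accessors
#' @export
setMethod("graphName", "MolecularGraph", function(x) x@name)

#' @rdname MolecularGraph-accessors
#' @export
setMethod("numVertices", "MolecularGraph", function(x) x@nVertices)

#' @rdname MolecularGraph-accessors
#' @export
setMethod("numEdges", "MolecularGraph", function(x) nrow(x@edges))

#' @rdname MolecularGraph-accessors
#' @export
setMethod("edgeMatrix", "MolecularGraph", function(x) x@edges)

#' @rdname MolecularGraph-accessors
#' @export
setMethod("degreeVector", "MolecularGraph", function(x) {
  tabulate(x@edges, nbins = x@nVertices)
})

#' Convert a MolecularGraph to an igraph object
#'
#' @param x a [MolecularGraph-class].
#' @return an undirected \pkg{igraph} graph with `numVertices(x)` vertices.
#' @rdname asIgraph
#' @export
setMethod("asIgraph", "MolecularGraph", function(x) {
  g <- igraph::make_empty_graph(n = x@nVertices, directed = FALSE)
  if (nrow(x@edges)) {
    g <- igraph::add_edges(g, t(x@edges))
  }
  g
})

setMethod("show", "MolecularGraph", function(object) {
  d <- degreeVector(object)
  tab <- table(d)
  cat(sprintf("MolecularGraph '%s': %d vertices, %d edges\n",
              object@name, object@nVertices, nrow(object@edges)))
  cat("  degree multiset:",
      paste(sprintf("%s^%d", names(tab), as.integer(tab)), collapse = " "),
      "\n")
  invisible(object)
})
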