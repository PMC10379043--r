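# Test helpers: graph builders and independent oracles.  The oracles here
# deliberately avoid the package's own code paths: Pruefer decoding is
# reimplemented, and isomorphism/canonicalization goes through igraph.

pathGraph <- function(n, name = sprintf("path%d", n)) {
  fromEdgeList(paste(seq_len(n - 1), seq_len(n - 1) + 1, collapse = "\n"),
               name)
}

cycleGraph <- function(n, name = sprintf("cycle%d", n)) {
  molecularGraph(cbind(seq_len(n), c(seq_len(n - 1) + 1L, 1L)), name)
}

# apply a vertex permutation to a graph (perm[i] = new label of vertex i)
relabelGraph <- function(g, perm) {
  e <- edgeMatrix(g)
  molecularGraph(cbind(perm[e[, 1]], perm[e[, 2]]),
                 name = graphName(g), nVertices = numVertices(g))
}

# independent Pruefer decoder (oracle; package has its own)
oraclePruferDecode <- function(pr, n) {
  deg <- tabulate(pr, nbins = n) + 1L
  edges <- matrix(0L, n - 1L, 2L)
  for (i in seq_along(pr)) {
    leaf <- which.max(deg == 1L)
    edges[i, ] <- c(leaf, pr[i])
    deg[leaf] <- 0L
    deg[pr[i]] <- deg[pr[i]] - 1L
  }
  edges[n - 1L, ] <- which(deg == 1L)
  edges
}

# canonical string via igraph's BLISS canonical labeling (oracle for
# isomorphism-class identity, independent of the package's AHU code)
oracleCanonStr <- function(edges) {
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  p <- igraph::canonical_permutation(g)$labeling
  e2 <- cbind(p[edges[, 1]], p[edges[, 2]])
  e2 <- cbind(pmin(e2[, 1], e2[, 2]), pmax(e2[, 1], e2[, 2]))
  paste(e2[order(e2[, 1], e2[, 2]), ], collapse = ",")
}

# brute-force count of unlabeled trees on n vertices with max degree <= cap:
# enumerate every Pruefer sequence, decode, dedup by igraph canonical form
oracleTreeClassCount <- function(n, cap = Inf) {
  if (n <= 2) return(1L)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  seen <- new.env(hash = TRUE, parent = emptyenv())
  cnt <- 0L
  for (i in seq_len(nrow(seqs))) {
    pr <- seqs[i, ]
    if (max(tabulate(pr, nbins = n)) + 1L > cap) next
    cs <- oracleCanonStr(oraclePruferDecode(pr, n))
    if (is.null(seen[[cs]])) {
      assign(cs, TRUE, envir = seen)
      cnt <- cnt + 1L
    }
  }
  cnt
}

graphsIsomorphic <- function(g1, g2) {
  igraph::isomorphic(asIgraph(g1), asIgraph(g2))
}
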