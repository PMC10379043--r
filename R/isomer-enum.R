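# Exact enumeration of alkane constitutional isomers: unlabeled trees on n
# vertices with bounded maximum degree (cap 4 for carbon skeletons).
# Identification of isomorphism classes uses a centroid-rooted AHU
# canonical code; enumeration grows trees by leaf augmentation with
# deduplication on that code, which is exact because deleting a leaf from a
# degree-capped tree leaves a degree-capped tree.

# adjacency list from an edge matrix
.adjList <- function(edges, n) {
  adj <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    u <- edges[i, 1L]; v <- edges[i, 2L]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  adj
}

# centroid vertex/vertices of a tree given as adjacency list
.treeCentroids <- function(adj, n) {
  if (n == 1L) return(1L)
  parent <- integer(n); ord <- integer(n); visited <- logical(n)
  ord[1L] <- 1L; visited[1L] <- TRUE; cnt <- 1L; head <- 1L
  while (head <= cnt) {
    v <- ord[head]; head <- head + 1L
    for (w in adj[[v]]) if (!visited[w]) {
      visited[w] <- TRUE; cnt <- cnt + 1L; ord[cnt] <- w; parent[w] <- v
    }
  }
  sz <- rep(1L, n)
  for (i in n:2) {
    v <- ord[i]
    sz[parent[v]] <- sz[parent[v]] + sz[v]
  }
  cents <- integer(0)
  for (v in seq_len(n)) {
    mx <- n - sz[v]
    for (w in adj[[v]]) if (parent[w] == v) mx <- max(mx, sz[w])
    if (mx <= n %/% 2L) cents <- c(cents, v)
  }
  cents
}

# AHU canonical string of the tree rooted at r
.ahuRooted <- function(adj, r) {
  rec <- function(v, p) {
    ch <- adj[[v]]
    ch <- ch[ch != p]
    if (!length(ch)) return("()")
    paste0("(", paste(sort(vapply(ch, rec, "", p = v)), collapse = ""), ")")
  }
  rec(r, 0L)
}

.canonicalCodeEdges <- function(edges, n) {
  adj <- .adjList(edges, n)
  min(vapply(.treeCentroids(adj, n), function(r) .ahuRooted(adj, r), ""))
}

#' Canonical code of an unlabeled tree
#'
#' Produces a centroid-rooted AHU (parenthesis-string) canonical form: two
#' trees receive the same code exactly when they are isomorphic, and the
#' code decodes back to a representative via [decodeCanonicalCode()].  A
#' tree has one or two centroids; with two, the lexicographically smaller
#' of the two rooted codes is taken, which is label-independent because
#' isomorphisms map centroids to centroids.
#'
#' @param x a [MolecularGraph-class] that is a tree
#'   (`numEdges(x) == numVertices(x) - 1`).
#' @return a single string.
#' @examples
#' canonicalCode(fromEdgeList("1 2\n1 3\n1 4"))  # 4-star
#' @rdname canonicalCode
#' @export
setMethod("canonicalCode", "MolecularGraph", function(x) {
  n <- numVertices(x)
  if (numEdges(x) != n - 1L) {
    stop("canonicalCode is defined for trees only", call. = FALSE)
  }
  .canonicalCodeEdges(edgeMatrix(x), n)
})

#' Decode a canonical tree code
#'
#' Inverse of [canonicalCode()] up to isomorphism: parses the parenthesis
#' string back into a tree whose canonical code equals the input.
#'
#' @param code string produced by [canonicalCode()].
#' @param name label for the resulting graph; defaults to the code.
#' @return a [MolecularGraph-class].
#' @export
decodeCanonicalCode <- function(code, name = code) {
  chars <- strsplit(code, "", fixed = TRUE)[[1]]
  if (!length(chars) || chars[1L] != "(" ||
      sum(chars == "(") != sum(chars == ")")) {
    stop("malformed canonical code", call. = FALSE)
  }
  n <- 0L
  edges <- matrix(integer(0), 0L, 2L)
  stack <- integer(0)
  for (ch in chars) {
    if (ch == "(") {
      n <- n + 1L
      if (length(stack)) {
        edges <- rbind(edges, c(stack[length(stack)], n))
      }
      stack <- c(stack, n)
    } else if (ch == ")") {
      if (!length(stack)) stop("malformed canonical code", call. = FALSE)
      stack <- stack[-length(stack)]
    } else {
      stop("malformed canonical code", call. = FALSE)
    }
  }
  if (length(stack)) stop("malformed canonical code", call. = FALSE)
  molecularGraph(edges, name = name, nVertices = n)
}

#' Enumerate alkane constitutional isomers
#'
#' Generates exactly one representative per isomorphism class of unlabeled
#' trees on `n` vertices with maximum degree at most `maxDegree` — for
#' `maxDegree = 4` these are the carbon skeletons of the alkane
#' constitutional isomers C\eqn{n}H\eqn{2n+2}.  Enumeration proceeds by
#' attaching a leaf to every degree-admissible vertex of every tree one
#' size down and deduplicating on [canonicalCode()]; the output is sorted
#' lexicographically by code, so the order is reproducible bit for bit.
#'
#' @param n number of vertices (carbon atoms), `1 <= n <= 20`.
#' @param maxDegree degree cap, default 4.  Use `Inf` (or `n`) for
#'   unrestricted unlabeled trees.
#' @return a named list of [MolecularGraph-class] objects; names are
#'   `C<n>_<index>`.  The canonical codes are attached as
#'   `attr(, "codes")`.
#' @examples
#' length(enumerateAlkanes(8))  # 18 octane isomers
#' @export
enumerateAlkanes <- function(n, maxDegree = 4) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n > 20 || n != round(n)) {
    stop("n must be an integer in 1..20", call. = FALSE)
  }
  n <- as.integer(n)
  level <- list(matrix(integer(0), 0L, 2L))
  if (n > 1L) {
    for (m in 2:n) {
      seen <- new.env(hash = TRUE, parent = emptyenv())
      nxt <- list()
      for (edges in level) {
        deg <- tabulate(edges, nbins = m - 1L)
        for (v in seq_len(m - 1L)) {
          if (deg[v] >= maxDegree) next
          e2 <- rbind(edges, c(v, m))
          cd <- .canonicalCodeEdges(e2, m)
          if (is.null(seen[[cd]])) {
            assign(cd, TRUE, envir = seen)
            nxt[[length(nxt) + 1L]] <- e2
          }
        }
      }
      level <- nxt
    }
  }
  codes <- vapply(level, .canonicalCodeEdges, "", n = n)
  ord <- order(codes)
  level <- level[ord]
  codes <- codes[ord]
  out <- lapply(seq_along(level), function(i) {
    molecularGraph(level[[i]], name = sprintf("C%d_%02d", n, i),
                   nVertices = n)
  })
  names(out) <- vapply(out, graphName, "")
  attr(out, "codes") <- codes
  out
}
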