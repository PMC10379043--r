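# Degree-based graph entropies.  The core quantity is the Shannon entropy
# of the distribution obtained by normalizing a positive vertex functional;
# the k-th degree-based entropy takes the functional phi(v) = d(v)^k, whose
# normalizer at k = 2 is the first Zagreb index.

#' Shannon entropy of a probability vector
#'
#' Computes `-sum(w * log(w))` in natural log units (nats).  The weights
#' must be strictly positive and sum to one; the maximum value `log(n)` is
#' attained exactly at the uniform distribution.
#'
#' @param w numeric vector of probabilities.
#' @param tol tolerance on `sum(w) - 1`.
#' @return entropy in nats, a value in `[0, log(length(w))]`.
#' @examples
#' shannonEntropy(rep(1 / 6, 6))  # log(6)
#' @export
shannonEntropy <- function(w, tol = 1e-8) {
  if (!is.numeric(w) || !length(w)) {
    stop("weights must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(w <= 0)) {
    stop("all weights must be strictly positive", call. = FALSE)
  }
  if (abs(sum(w) - 1) > tol) {
    stop("weights must sum to 1", call. = FALSE)
  }
  -sum(w * log(w))
}

#' Entropy of a graph under a positive vertex functional
#'
#' Normalizes a positive functional phi over the vertices into a
#' probability distribution `alpha_i = phi(v_i) / sum_j phi(v_j)` and
#' returns its Shannon entropy.  With `phi` constant this is `log(n)`;
#' with `phi(v) = d(v)^k` it equals [degreeEntropy()].
#'
#' @param x a [MolecularGraph-class].
#' @param phi either a numeric vector of positive values, one per vertex,
#'   or a function applied to the degree vector of `x` that returns one
#'   positive value per vertex.
#' @return entropy in nats, in `[0, log(numVertices(x))]`.
#' @examples
#' p3 <- fromEdgeList("1 2\n2 3")
#' functionalEntropy(p3, function(d) d)    # degree functional
#' functionalEntropy(p3, c(1, 1, 1))       # log(3)
#' @rdname functionalEntropy
#' @export
setMethod("functionalEntropy", "MolecularGraph", function(x, phi) {
  vals <- if (is.function(phi)) phi(degreeVector(x)) else phi
  if (!is.numeric(vals) || length(vals) != numVertices(x)) {
    stop("phi must yield one numeric value per vertex", call. = FALSE)
  }
  if (any(vals <= 0)) {
    stop("phi must be strictly positive on every vertex", call. = FALSE)
  }
  shannonEntropy(vals / sum(vals))
})

#' k-th degree-based graph entropy
#'
#' The Shannon entropy of the distribution obtained by normalizing the
#' k-th powers of the vertex degrees,
#' \deqn{I_{d,k}(G) = -\sum_i \frac{d_i^k}{\sum_j d_j^k}
#'       \ln \frac{d_i^k}{\sum_j d_j^k},}
#' in nats.  `k = 2` gives the second-degree-based entropy, whose
#' normalizer is the first Zagreb index; it is the descriptor this package
#' exists for.  Any finite `k` (negative and fractional included) is
#' admissible because every vertex of a connected graph on two or more
#' vertices has degree at least one.  The value lies in `[0, log(n)]`,
#' with `log(n)` exactly when the graph is regular or `k = 0`.
#'
#' @param x a [MolecularGraph-class] with at least 2 vertices.
#' @param k real exponent, default 2.
#' @return entropy in nats.
#' @examples
#' octane <- fromEdgeList(paste(1:7, 2:8, collapse = "\n"), "n-octane")
#' round(degreeEntropy(octane, k = 2), 4)  # 1.9784
#' @rdname degreeEntropy
#' @export
setMethod("degreeEntropy", "MolecularGraph", function(x, k = 2) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k)) {
    stop("k must be a single finite number", call. = FALSE)
  }
  d <- degreeVector(x)
  if (numVertices(x) < 2L || any(d < 1L)) {
    stop("degree entropy needs a connected graph on >= 2 vertices",
         call. = FALSE)
  }
  w <- d^k
  shannonEntropy(w / sum(w))
})
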