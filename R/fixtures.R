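# Bundled benchmark datasets and synthetic-data generators.
#
# The three fixtures transcribe published measurement tables for octane
# isomers (entropy S, enthalpy of vaporization HVAP, standard enthalpy of
# vaporization DHVAP, acentric factor AF), benzenoid hydrocarbons (boiling
# point BP, pi-electron energy Epi) and sixteen drug-related compounds
# (BP, molar refraction MR), each together with the tabulated
# second-degree-based entropy Id2.  Structures (edge lists) ship for all
# 18 octanes and for the three benzenoids identifiable from their data
# (naphthalene, phenanthrene, anthracene), so Id2 can be recomputed from
# scratch for those records; the remaining benzenoids and the drug
# compounds carry tabulated Id2 values only.
#
# Note on the benzenoid table: the source table's header order is
# inconsistent with the magnitudes of its columns; recomputing Id2 for the
# three identifiable structures proves the first numeric column is Id2,
# the second BP (degrees C) and the third Epi (units of beta).  The fixture
# stores the corrected roles.

.fixtureFile <- function(file) {
  path <- system.file("extdata", file, package = "degent", mustWork = TRUE)
  sums <- system.file("extdata", "MD5SUMS", package = "degent")
  if (nzchar(sums)) {
    want <- utils::read.table(sums, col.names = c("md5", "file"),
                              stringsAsFactors = FALSE)
    w <- want$md5[want$file == file]
    if (length(w) == 1L && !identical(unname(tools::md5sum(path)), w)) {
      warning(sprintf("checksum mismatch for fixture '%s'", file),
              call. = FALSE)
    }
  }
  path
}

#' Load a bundled benchmark dataset
#'
#' @param which one of `"octane"` (18 octane isomers with S, HVAP, DHVAP,
#'   AF and Id2), `"bhc"` (21 benzenoid hydrocarbons with Id2, BP, Epi) or
#'   `"drug"` (16 drug-related compounds with BP, MR, Id2).
#' @return a data.frame, one record per compound.  Where structures are
#'   bundled (all octanes; benzenoids 1-3) they are attached as a named
#'   list of [MolecularGraph-class] objects in `attr(, "structures")`.
#' @examples
#' oct <- loadFixture("octane")
#' head(oct)
#' @export
loadFixture <- function(which = c("octane", "bhc", "drug")) {
  which <- match.arg(which)
  ds <- utils::read.csv(.fixtureFile(paste0(which, "_properties.csv")),
                        check.names = FALSE)
  if (which %in% c("octane", "bhc")) {
    structures <- readEdgeListFile(
      .fixtureFile(paste0(which, "_structures.edges")))
    attr(ds, "structures") <- structures
  }
  ds
}

#' Structures attached to a fixture
#'
#' @param ds data.frame returned by [loadFixture()].
#' @return the named list of [MolecularGraph-class] objects bundled with
#'   the dataset, or `NULL` for fixtures shipped without structures.
#' @export
fixtureStructures <- function(ds) {
  attr(ds, "structures")
}

#' Generate a synthetic descriptor-property dataset
#'
#' Draws descriptor values uniformly on the range spanned by the octane
#' second-degree entropies and adds property values from a known linear
#' model with Gaussian noise: `y = slope * x + intercept + N(0, noiseSd^2)`.
#' Defaults mirror the octane acentric-factor study conditions (n = 18,
#' slope 0.2, intercept 0.003) with `noiseSd` set so the population R^2 is
#' about 0.93.  Used for regression parameter-recovery testing.
#'
#' @param n number of records, at least 3.
#' @param slope,intercept true model coefficients.
#' @param noiseSd Gaussian noise standard deviation, `>= 0`.
#' @param seed integer seed; output is a deterministic function of it.
#' @param xRange range the descriptor is drawn from.
#' @return data.frame with columns `name, x, y`.
#' @export
generateSyntheticRegression <- function(n = 18, slope = 0.2,
                                        intercept = 0.003,
                                        noiseSd = 0.0108, seed,
                                        xRange = c(1.30, 1.98)) {
  if (!is.numeric(n) || n < 3) {
    stop("n must be at least 3", call. = FALSE)
  }
  if (noiseSd < 0) {
    stop("noiseSd must be non-negative", call. = FALSE)
  }
  n <- as.integer(n)
  .withSeed(seed, {
    x <- stats::runif(n, xRange[1L], xRange[2L])
    y <- slope * x + intercept + stats::rnorm(n, 0, noiseSd)
    data.frame(name = sprintf("synth%02d", seq_len(n)), x = x, y = y)
  })
}

# decode a Pruefer sequence over 1..n into the edge matrix of the labeled
# tree it encodes (O(n^2), plenty for molecular sizes)
.pruferToEdges <- function(seq, n) {
  if (n == 2L) return(matrix(c(1L, 2L), 1L, 2L))
  deg <- rep(1L, n)
  for (s in seq) deg[s] <- deg[s] + 1L
  edges <- matrix(0L, n - 1L, 2L)
  for (i in seq_along(seq)) {
    s <- seq[i]
    leaf <- which.max(deg == 1L)  # smallest remaining leaf
    edges[i, ] <- c(leaf, s)
    deg[leaf] <- 0L
    deg[s] <- deg[s] - 1L
  }
  edges[n - 1L, ] <- which(deg == 1L)
  edges
}

#' Generate a random degree-capped tree
#'
#' Draws uniform random labeled trees via random Pruefer sequences and
#' rejects until the degree cap is met, so every isomorphism class with
#' maximum degree `<= maxDegree` has positive probability (weighted by its
#' number of labelings).  Deterministic per seed.
#'
#' @param n number of vertices, `>= 2`.
#' @param maxDegree degree cap, default 4.
#' @param seed integer seed.
#' @return a [MolecularGraph-class] tree.
#' @export
generateRandomTree <- function(n, maxDegree = 4, seed) {
  if (!is.numeric(n) || n < 2) {
    stop("n must be at least 2", call. = FALSE)
  }
  n <- as.integer(n)
  if (n > 2L && maxDegree < 2) {
    stop("no tree on >= 3 vertices has maximum degree 1", call. = FALSE)
  }
  if (n == 2L) {
    return(molecularGraph(matrix(c(1L, 2L), 1L, 2L),
                          name = sprintf("randtree_n2_s%d", seed),
                          nVertices = 2L))
  }
  edges <- .withSeed(seed, {
    repeat {
      pr <- sample.int(n, n - 2L, replace = TRUE)
      deg <- tabulate(pr, nbins = n) + 1L
      if (max(deg) <= maxDegree) break
    }
    .pruferToEdges(pr, n)
  })
  molecularGraph(edges, name = sprintf("randtree_n%d_s%d", n, seed),
                 nVertices = n)
}
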