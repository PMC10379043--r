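test_that("shannonEntropy matches closed-form values and rejects bad weights", {
  expect_equal(shannonEntropy(rep(1 / 6, 6)), log(6))
  expect_equal(shannonEntropy(1), 0)
  # -0.75 log 0.75 - 3 * (1/12) log(1/12), evaluated by hand
  expect_equal(round(shannonEntropy(c(0.75, rep(1 / 12, 3))), 5), 0.83699)
  expect_error(shannonEntropy(c(0.5, 0, 0.5)), "positive")
  expect_error(shannonEntropy(c(0.5, 0.4)), "sum to 1")
})

test_that("functionalEntropy normalizes the functional and hits known values", {
  p3 <- pathGraph(3)
  expect_equal(functionalEntropy(p3, function(d) rep(1, length(d))), log(3))
  # phi = degree on the path of 3: alpha = (1/4, 1/2, 1/4) -> 1.5 log 2
  expect_equal(functionalEntropy(p3, function(d) d), 1.5 * log(2))
  expect_equal(functionalEntropy(p3, c(1, 2, 1)), 1.5 * log(2))
  expect_error(functionalEntropy(p3, c(1, -1, 1)), "positive")
  expect_error(functionalEntropy(p3, c(1, 1)), "per vertex")
})

test_that("degreeEntropy reproduces tabulated second-degree entropies", {
  expect_equal(round(degreeEntropy(pathGraph(8), k = 2), 4), 1.9784)
  tmb <- fromEdgeList("1 2\n2 3\n3 4\n2 5\n2 6\n3 7\n3 8")
  expect_equal(round(degreeEntropy(tmb, k = 2), 4), 1.3028)
  nap <- fixtureStructures(loadFixture("bhc"))[["BHC1"]]
  expect_equal(round(degreeEntropy(nap, k = 2), 4), 2.2338)
})

test_that("degree entropy is log(n) exactly for regular graphs and k = 0", {
  for (k in c(-2, -1, 0.5, 1, 2, 3)) {
    expect_equal(degreeEntropy(cycleGraph(7), k = k), log(7))
    expect_equal(degreeEntropy(pathGraph(2), k = k), log(2))
  }
  for (s in 1:10) {
    g <- generateRandomTree(5 + s, seed = s)
    expect_equal(degreeEntropy(g, k = 0), log(numVertices(g)))
  }
})

test_that("degreeEntropy satisfies the algebraic identity and Shannon form", {
  set.seed(42)
  for (rep in 1:50) {
    g <- generateRandomTree(sample(4:20, 1), seed = rep)
    k <- stats::runif(1, -3, 3)
    d <- degreeVector(g)
    w <- d^k
    identityVal <- log(sum(w)) - sum(w * log(w)) / sum(w)
    expect_equal(degreeEntropy(g, k), identityVal, tolerance = 1e-10)
    expect_equal(degreeEntropy(g, k), functionalEntropy(g, function(d) d^k),
                 tolerance = 1e-12)
  }
})

test_that("degree entropy stays within [0, log n] on random trees", {
  for (s in 1:200) {
    g <- generateRandomTree(2 + (s %% 18), seed = s)
    for (k in c(-2, 0.5, 1, 2, 3)) {
      h <- degreeEntropy(g, k)
      expect_gte(h, 0)
      expect_lte(h, log(numVertices(g)) + 1e-12)
    }
  }
})

test_that("indexSuite matches hand-evaluated values on small graphs", {
  s <- indexSuite(pathGraph(3))
  expect_equal(unname(s["M1"]), 6)
  expect_equal(unname(s["M2"]), 4)
  expect_equal(unname(s["F"]), 10)
  expect_equal(unname(s["ISI"]), 4 / 3)
  expect_equal(unname(s["SDD"]), 5)
  expect_equal(unname(s["SCI"]), 2 / sqrt(3))
  expect_equal(unname(s["RR"]), 2 * sqrt(2))
  expect_equal(unname(s["Id_k"]), degreeEntropy(pathGraph(3)))

  expect_equal(unname(indexSuite(pathGraph(8))["M1"]), 26)

  # r-regular graph with m edges: M2 = m r^2, SDD = 2m
  cyc <- cycleGraph(9)
  s <- indexSuite(cyc)
  expect_equal(unname(s["M2"]), 9 * 4)
  expect_equal(unname(s["SDD"]), 18)
})

test_that("all indices are isomorphism invariant under random relabelings", {
  set.seed(7)
  for (rep in 1:30) {
    g <- generateRandomTree(sample(4:15, 1), seed = 100 + rep)
    perm <- sample(numVertices(g))
    g2 <- relabelGraph(g, perm)
    expect_equal(indexSuite(g2, k = 2), indexSuite(g, k = 2))
    expect_equal(indexSuite(g2, k = -1.5), indexSuite(g, k = -1.5))
  }
  # also on a cyclic graph
  nap <- fixtureStructures(loadFixture("bhc"))[["BHC1"]]
  perm <- sample(10)
  expect_equal(indexSuite(relabelGraph(nap, perm)), indexSuite(nap))
})

test_that("Id2, M1 and F are determined by the degree multiset", {
  oct <- loadFixture("octane")
  s <- fixtureStructures(oct)
  # the four monomethyl/ethyl heptane-class octanes share {1^3, 2^4, 3}
  cls <- c("C8:02", "C8:03", "C8:04", "C8:05")
  vals <- vapply(s[cls], degreeEntropy, 0, k = 2)
  expect_equal(max(vals) - min(vals), 0)
  m1 <- vapply(s[cls], function(g) unname(indexSuite(g)["M1"]), 0)
  expect_equal(max(m1) - min(m1), 0)
})

test_that("computeIndexTable and writeIndexCSV produce the CSV contract", {
  gs <- list(pathGraph(3, "p3"), cycleGraph(4, "c4"))
  tab <- computeIndexTable(gs)
  expect_identical(names(tab),
                   c("name", "Id_k", "M1", "M2", "F", "ISI", "SDD", "SCI", "RR"))
  expect_identical(tab$name, c("p3", "c4"))
  csv <- tempfile(fileext = ".csv")
  writeIndexCSV(tab, csv)
  back <- read.csv(csv, check.names = FALSE)
  expect_equal(back$M1, tab$M1)
  expect_equal(back$SCI, signif(tab$SCI, 6))
})
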