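test_that("manhattanDistance and defaultGrid follow their definitions", {
  expect_equal(manhattanDistance(c(0, 0), c(0, 0)), 0L)
  expect_equal(manhattanDistance(c(0, 0), c(2, 3)), 5L)
  expect_equal(manhattanDistance(c(1, 4), c(3, 1)), 5L)
  expect_equal(defaultGrid(pathGraph(6)), 3L)
  expect_equal(defaultGrid(pathGraph(4)), 2L)
  expect_equal(defaultGrid(1), 1L)
  expect_equal(defaultGrid(pathGraph(6), slack = TRUE), 4L)
})

test_that("the brute-force oracle finds known optima", {
  e1 <- embedBruteforce(pathGraph(2), side = 2)
  expect_equal(objectiveValue(e1), 1)
  expect_true(isProvenOptimal(e1))

  edgeless <- buildPathwayGraph("e", lapply(1:3, function(k)
    reaction(paste0("R", k), substrates = paste0("S", k))))
  expect_equal(objectiveValue(embedBruteforce(edgeless)), 0)

  expect_equal(objectiveValue(embedBruteforce(cycleGraph(4), side = 2)), 4)
  expect_error(embedBruteforce(pathGraph(9)), "refuses")
})

test_that("exact solver matches the oracle on a random small-graph suite", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    g <- graphFromAdjacency(randomConnectedAdjacency(n, sample(0:2, 1)))
    side <- defaultGrid(g)
    opt <- objectiveValue(embedBruteforce(g, side))
    for (cuts in list(character(),
                      c("star", "clique", "odd_cycle",
                        "bounded_degree_tree"))) {
      for (sym in c(TRUE, FALSE)) {
        e <- embedExact(g, side, cuts = cuts, symmetryBreaking = sym)
        expect_equal(objectiveValue(e), opt)
        expect_equal(totalEdgeLength(g, e), opt)
        expect_true(isProvenOptimal(e))
        expect_equal(optimalityGap(e), 1)
      }
    }
  }
})

test_that("heuristic is seeded, monotone in effort, and near-optimal", {
  g <- pathGraph(4)
  # iterations = 0 returns the seeded initial placement, reproducibly
  h0a <- embedHeuristic(g, side = 2, seed = 5, iterations = 0)
  h0b <- embedHeuristic(g, side = 2, seed = 5, iterations = 0)
  expect_identical(placement(h0a), placement(h0b))
  expect_equal(objectiveValue(h0a), totalEdgeLength(g, h0a))

  # enough iterations recover the oracle optimum on most small graphs
  set.seed(33)
  hits <- 0L
  for (rep in 1:50) {
    n <- sample(3:6, 1)
    gg <- graphFromAdjacency(randomConnectedAdjacency(n, sample(0:2, 1)))
    opt <- objectiveValue(embedBruteforce(gg))
    h <- embedHeuristic(gg, seed = rep, iterations = 10000)
    expect_gte(objectiveValue(h), opt)  # incumbent never beats the optimum
    if (objectiveValue(h) == opt) hits <- hits + 1L
  }
  expect_gte(hits / 50, 0.95)
})

test_that("motif lower bounds come from exhaustive lattice optimization", {
  expect_equal(motifLowerBound("star", 1), 1L)
  expect_equal(motifLowerBound("star", 4), 4L)
  expect_equal(motifLowerBound("star", 5), 6L)  # only 4 unit neighbors
  expect_equal(motifLowerBound("odd_cycle", 3), 4L)
  expect_equal(motifLowerBound("odd_cycle", 5), 6L)
  expect_equal(motifLowerBound("clique", 4), 8L)
  expect_equal(motifLowerBound("bounded_degree_tree", 7), 6L)
  expect_error(motifLowerBound("odd_cycle", 7), "C3 and C5")
  expect_error(motifLowerBound("wheel", 4))
  # bounds are true lower bounds: check against oracle optima
  expect_equal(objectiveValue(embedBruteforce(starGraph(4), side = 3)), 4)
  expect_equal(objectiveValue(embedBruteforce(cycleGraph(5), side = 3)), 6)
})

test_that("totalEdgeLength evaluates placements and validates inputs", {
  g <- cycleGraph(3)
  pl <- rbind(R1 = c(0L, 0L), R2 = c(0L, 1L), R3 = c(1L, 0L))
  colnames(pl) <- c("i", "j")
  e <- new("GridEmbedding", pathwayId = "cycle", side = 2L, placement = pl,
           objective = 4, provenOptimal = TRUE, gap = 1, method = "manual")
  expect_equal(totalEdgeLength(g, e), 4L)
  # any embedding of E edges has length >= |E|
  set.seed(9)
  for (rep in 1:10) {
    gg <- graphFromAdjacency(randomConnectedAdjacency(5, 2))
    h <- embedHeuristic(gg, seed = rep, iterations = 0)
    expect_gte(totalEdgeLength(gg, h), nEdges(gg))
  }
  g4 <- pathGraph(4)
  expect_error(totalEdgeLength(g4, e), "does not place")
})

test_that("infeasible grids are rejected and gap/optimality are coherent", {
  expect_error(embedExact(pathGraph(5), side = 2), "infeasible")
  expect_error(embedHeuristic(pathGraph(5), side = 2), "infeasible")
  set.seed(77)
  for (rep in 1:10) {
    gg <- graphFromAdjacency(randomConnectedAdjacency(5, 1))
    h <- embedHeuristic(gg, seed = rep, iterations = 2000)
    expect_true(optimalityGap(h) > 0 && optimalityGap(h) <= 1)
    if (isProvenOptimal(h)) expect_equal(optimalityGap(h), 1)
  }
})

test_that("embedPathway dispatches by size and keeps determinism", {
  small <- embedPathway(pathGraph(4))
  expect_equal(small@method, "exact")
  big <- embedPathway(pathGraph(12), iterations = 3000)
  expect_equal(big@method, "heuristic")
  big2 <- embedPathway(pathGraph(12), iterations = 3000)
  expect_identical(placement(big), placement(big2))
})
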