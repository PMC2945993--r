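test_that("generated pathways are connected, sized and seeded", {
  d <- simulationDesign(n_pathways = 4, reactions_per_pathway = 6,
                        extra_edges = 2, seed = 5)
  pws <- generatePathways(d)
  expect_length(pws, 4L)
  for (g in pws) {
    expect_equal(nReactions(g), 6L)
    expect_gte(nEdges(g), 5L)
    ig <- igraph::graph_from_adjacency_matrix(adjacency(g),
                                              mode = "undirected")
    expect_true(igraph::is_connected(ig))
  }
  # determinism
  pws2 <- generatePathways(d)
  expect_identical(lapply(pws, adjacency), lapply(pws2, adjacency))
  # zero extra edges give exactly a spanning tree
  dTree <- simulationDesign(extra_edges = 0, seed = 5)
  expect_true(all(vapply(generatePathways(dTree), nEdges,
                         integer(1)) == 5L))
})

test_that("expression generation is reproducible and honors the design", {
  d <- simulationDesign(pattern = "switch", effect_size = 2, seed = 9)
  pws <- generatePathways(d)
  s1 <- generateExpression(d, pws)
  s2 <- generateExpression(d, pws)
  expect_identical(s1$expr, s2$expr)
  expect_identical(s1$truth, s2$truth)
  # truth consistency: planted reactions belong to planted pathways
  expect_true(all(s1$truth$pathway %in%
                    paste0("pw", d$planted_pathways)))
  expect_setequal(s1$truth$direction, c("up", "down"))
  # switch plants one adjacent reaction pair
  g1 <- pws[[1L]]
  iu <- match(s1$truth$reaction[s1$truth$direction == "up"],
              reactionIds(g1))
  idn <- match(s1$truth$reaction[s1$truth$direction == "down"],
               reactionIds(g1))
  expect_equal(adjacency(g1)[iu, idn], 1L)
  # labels encode the intended split
  expect_equal(sum(s1$labels == "favorable"), d$n_favorable)
  expect_equal(sum(s1$labels == "unfavorable"), d$n_unfavorable)
})

test_that("zero effect size reduces every pattern to the null", {
  pws <- generatePathways(simulationDesign(seed = 13))
  null <- generateExpression(simulationDesign(pattern = "null", seed = 13),
                             pws)
  zero <- generateExpression(simulationDesign(pattern = "switch",
                                              effect_size = 0, seed = 13),
                             pws)
  expect_identical(null$expr, zero$expr)
  expect_equal(nrow(zero$truth), 0L)
  # null group means differ only by sampling noise
  diff <- rowMeans(null$expr[, null$labels == "unfavorable"]) -
    rowMeans(null$expr[, null$labels == "favorable"])
  expect_lt(max(abs(diff)), 6 * sqrt(1 / 30 + 1 / 30))
})

test_that("per-feature type-I error is calibrated under the null", {
  ps <- c()
  for (r in 1:8) {
    d <- simulationDesign(pattern = "null", seed = 700 + r)
    pws <- generatePathways(d)
    sim <- generateExpression(d, pws)
    labels <- sim$labels
    iu <- which(labels == "unfavorable")
    iff <- which(labels == "favorable")
    for (g in pws) {
      rd <- mapExpressionToReactions(sim$expr, g)
      ft <- nontrivialFeatures(featureTable(embedPathway(g), rd$values))
      ps <- c(ps, GridWave:::rowWilcoxon(
        featureValues(ft)[, c(iu, iff), drop = FALSE], seq_along(iu)))
    }
  }
  expect_gte(length(ps), 2000L)
  rate <- mean(ps <= 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("switch patterns are detectable per reaction at delta = 2 sd", {
  hits <- 0L
  nseed <- 25L
  for (r in seq_len(nseed)) {
    d <- simulationDesign(pattern = "switch", effect_size = 2,
                          seed = 900 + r)
    pws <- generatePathways(d)
    sim <- generateExpression(d, pws)
    g <- pws[[1L]]
    rd <- mapExpressionToReactions(sim$expr, g)
    cls <- perReactionRegulation(rd$values, sim$labels, rd$measured)
    upOk <- all(cls[sim$truth$reaction[sim$truth$direction == "up"]] ==
                  "up")
    dnOk <- all(cls[sim$truth$reaction[sim$truth$direction == "down"]] ==
                  "down")
    if (upOk && dnOk) hits <- hits + 1L
  }
  expect_gt(hits / nseed, 0.8)
})

test_that("detection rate is monotone in the planted effect size", {
  rate <- function(delta) {
    top <- 0L
    for (r in 1:20) {
      d <- simulationDesign(pattern = "switch", effect_size = delta,
                            seed = 3000 + r)
      pws <- generatePathways(d)
      sim <- generateExpression(d, pws)
      sc <- GridWave:::gridwaveScores(pws, sim$expr, sim$labels)
      if (names(which.min(sc)) == "pw1") top <- top + 1L
    }
    top / 20
  }
  rates <- vapply(c(0.25, 1, 2.5), rate, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3L], rates[1L])
})

test_that("the sensitivity benchmark emits a coherent ROC table", {
  d <- simulationDesign(pattern = "switch", effect_size = 1, seed = 2)
  b <- benchmarkSensitivity(d, methods = c("gridwave", "fisher"),
                            n_replicates = 5, seed = 11,
                            thresholds = c(0.001, 0.05, 1))
  expect_setequal(unique(b$roc$method), c("gridwave", "fisher"))
  expect_equal(nrow(b$roc), 2L * 3L)
  expect_true(all(b$roc$sensitivity >= 0 & b$roc$sensitivity <= 1))
  expect_true(all(b$roc$specificity >= 0 & b$roc$specificity <= 1))
  # sensitivity is monotone in the threshold within a method
  for (m in c("gridwave", "fisher")) {
    sub <- b$roc[b$roc$method == m, ]
    expect_true(all(diff(sub$sensitivity[order(sub$threshold)]) >= 0))
  }
  # AUC agrees with an independent ROC implementation
  sc <- b$scores[b$scores$method == "gridwave", ]
  ref <- as.numeric(pROC::auc(pROC::roc(sc$planted, sc$p,
                                        levels = c(FALSE, TRUE),
                                        direction = ">", quiet = TRUE)))
  expect_equal(unname(b$auc[["gridwave"]]), ref, tolerance = 1e-10)
  # determinism
  b2 <- benchmarkSensitivity(d, methods = c("gridwave", "fisher"),
                             n_replicates = 5, seed = 11,
                             thresholds = c(0.001, 0.05, 1))
  expect_identical(b$roc, b2$roc)
  expect_identical(b$auc, b2$auc)
})
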