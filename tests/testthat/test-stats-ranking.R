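test_that("wilcoxonRankSum matches exact enumeration and handles ties", {
  expect_equal(wilcoxonRankSum(1:3, 4:6), 0.1)
  expect_equal(wilcoxonRankSum(c(1, 2), c(1, 2)), 1)
  expect_error(wilcoxonRankSum(numeric(), 1:3), "non-empty")
  # rank invariance under strictly monotone transforms
  set.seed(8)
  a <- rnorm(6); b <- rnorm(7)
  p0 <- wilcoxonRankSum(a, b)
  expect_equal(wilcoxonRankSum(exp(a), exp(b)), p0)
  expect_equal(wilcoxonRankSum(a^3 + 2 * a, b^3 + 2 * b), p0)
  # exact mode with ties falls back to the approximation
  expect_equal(wilcoxonRankSum(c(1, 1, 2), c(2, 3, 4), mode = "exact"),
               wilcoxonRankSum(c(1, 1, 2), c(2, 3, 4),
                               mode = "normal_approx"))
})

test_that("vectorized rank-sum equals wilcox.test row by row", {
  set.seed(12)
  x <- matrix(c(sample(1:6, 120, TRUE), rnorm(120)), nrow = 12,
              byrow = TRUE)
  p <- GridWave:::rowWilcoxon(x, 1:8)
  ref <- apply(x, 1L, function(r) suppressWarnings(
    wilcox.test(r[1:8], r[9:20], exact = FALSE, correct = FALSE)$p.value))
  expect_equal(p, ref, tolerance = 1e-12)
})

test_that("bonferroni multiplies, caps and validates", {
  expect_equal(bonferroni(0.004, 10), 0.04)
  expect_equal(bonferroni(0.2, 10), 1)
  expect_equal(bonferroni(c(0.3, 0.01), 2), c(0.6, 0.02))
  expect_equal(bonferroni(0.7, 1), 0.7)
  expect_error(bonferroni(1.2, 2), "\\[0, 1\\]")
  expect_error(bonferroni(c(0.1, 0.2), 1), "family size")
})

test_that("per-reaction regulation classifies direction at alpha", {
  set.seed(21)
  labels <- rep(c("favorable", "unfavorable"), each = 10)
  base <- matrix(rnorm(30 * 20, sd = 0.5), 30, 20)
  up <- c(rep(0, 10), rep(2, 10))     # unfavorable >= favorable + 2
  m <- rbind(base[1, ] * 0 + up, base)
  rownames(m) <- paste0("R", seq_len(nrow(m)))
  cls <- perReactionRegulation(m, labels)
  expect_equal(as.character(cls[["R1"]]), "up")
  # identical distributions stay unchanged almost always; flip for 'down'
  down <- m
  down["R1", ] <- -up
  expect_equal(as.character(perReactionRegulation(down, labels)[["R1"]]),
               "down")
  # unmeasured reactions are unchanged no matter the values
  measured <- stats::setNames(rep(TRUE, nrow(m)), rownames(m))
  measured[["R1"]] <- FALSE
  expect_equal(as.character(
    perReactionRegulation(m, labels, measured)[["R1"]]), "unchanged")
  expect_error(perReactionRegulation(m, rep("favorable", 20)), "non-empty")
})

test_that("pathway ranking applies both significance conditions", {
  # a large planted block makes the pathway significant; a 2-reaction
  # switch has too few regulated reactions despite a tiny p-value
  dBlock <- simulationDesign(pattern = "block_up", block_size = 5,
                             effect_size = 3, seed = 60)
  pws <- generatePathways(dBlock)
  sim <- generateExpression(dBlock, pws)
  emb <- runEmbedding(pws)
  rr <- runRanking(emb, sim$expr, sim$clinical)
  res <- rr$results
  expect_equal(res$pathway[1L], "pw1")
  expect_true(res$significant[1L])
  expect_gte(res$n_diff_regulated[1L], 4L)
  expect_true(all(diff(res$p_raw) >= 0))                  # sorted
  expect_true(all(res$p_adjusted >= res$p_raw))
  expect_true(all(res$n_up + res$n_down == res$n_diff_regulated))
  expect_true(all(res$n_diff_regulated <= res$n_reactions))

  dSwitch <- simulationDesign(pattern = "switch", effect_size = 3,
                              seed = 61)
  pws2 <- generatePathways(dSwitch)
  sim2 <- generateExpression(dSwitch, pws2)
  rr2 <- runRanking(runEmbedding(pws2), sim2$expr, sim2$clinical)
  res2 <- rr2$results
  expect_equal(res2$pathway[1L], "pw1")
  expect_lt(res2$p_adjusted[1L], 0.05)
  expect_false(res2$significant[1L])   # only 2 regulated reactions
  # the full ranked list is returned even with an empty significant set
  expect_equal(nrow(res2), length(pws2))
})

test_that("feature p-values are invariant to positive rescaling", {
  set.seed(31)
  v <- matrix(rnorm(200), 10, 20)
  p1 <- GridWave:::rowWilcoxon(v, 1:9)
  p2 <- GridWave:::rowWilcoxon(v * 137.5, 1:9)
  expect_identical(p1, p2)
})

test_that("fisherEnrichment reproduces hypergeometric enumeration", {
  universe <- paste0("g", 1:10)
  pw <- paste0("g", 1:5)
  de <- paste0("g", 1:5)
  expect_equal(fisherEnrichment(de, pw, universe), 2 / 252,
               tolerance = 1e-12)
  # independent margins give p = 1
  expect_equal(fisherEnrichment(paste0("g", c(1, 6)), pw, universe), 1)
  # depletion is detected by the same two-sided enumeration
  deRev <- paste0("g", 6:10)
  expect_equal(fisherEnrichment(deRev, pw, universe), 2 / 252,
               tolerance = 1e-12)
  expect_error(fisherEnrichment(de, pw, character()), "empty")
})

test_that("rank-enrichment baseline is calibrated at the extremes", {
  set.seed(41)
  labels <- rep(c("favorable", "unfavorable"), each = 15)
  expr <- matrix(rnorm(50 * 30), 50, 30,
                 dimnames = list(paste0("g", 1:50), paste0("s", 1:30)))
  inset <- paste0("g", 1:8)
  expr[inset, labels == "unfavorable"] <-
    expr[inset, labels == "unfavorable"] + 1.5
  res <- rankEnrichmentBaseline(expr, labels, inset,
                                n_permutations = 199, seed = 3)
  expect_lte(res$p, 1 / 200 + 1e-12)
  expect_gt(res$es, 0)
  # deterministic for a fixed seed
  res2 <- rankEnrichmentBaseline(expr, labels, inset,
                                 n_permutations = 199, seed = 3)
  expect_identical(res, res2)
  # reversing the ranking flips the score sign
  labFlip <- ifelse(labels == "favorable", "unfavorable", "favorable")
  resFlip <- rankEnrichmentBaseline(expr, labFlip, inset,
                                    n_permutations = 199, seed = 3)
  expect_equal(resFlip$es, -res$es, tolerance = 1e-12)
})
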