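test_that("zero padding extends to even dimensions, bottom/right", {
  m3 <- padMatrix(matrix(1, 3, 3))
  expect_equal(dim(m3), c(4L, 4L))
  expect_true(all(m3[4L, ] == 0) && all(m3[, 4L] == 0))
  m4 <- matrix(rnorm(16), 4, 4)
  expect_identical(padMatrix(m4), m4)
  m1 <- padMatrix(matrix(7, 1, 1))
  expect_equal(m1, matrix(c(7, 0, 0, 0), 2, 2))
})

test_that("haarBlock computes the four combined values and inverts exactly", {
  expect_equal(haarBlock(matrix(1, 2, 2)), c(1, 0, 0, 0))
  expect_equal(haarBlock(matrix(0, 2, 2)), c(0, 0, 0, 0))
  # block (4, 2; 0, 2)
  blk <- matrix(c(4, 0, 2, 2), 2, 2)
  expect_equal(haarBlock(blk), c(2, 2, 0, 4))
  expect_equal(reconstructBlock(c(2, 2, 0, 4)), blk)
  expect_equal(reconstructBlock(c(1, 0, 0, 0)), matrix(1, 2, 2))
  set.seed(1)
  for (rep in 1:200) {
    b <- matrix(rnorm(4), 2, 2)
    expect_equal(reconstructBlock(haarBlock(b)), b, tolerance = 1e-12)
  }
})

test_that("cascade of an even constant image gives grand mean, zero details", {
  m <- matrix(3.5, 4, 4)
  ft <- waveletCascade(m, offsetsMode = "single")
  d <- featureDescriptors(ft)
  v <- featureValues(ft)[, 1L]
  top <- which(d$level == max(d$level) & d$coeff_type == 1L)
  expect_equal(v[top], 3.5)
  expect_true(all(abs(v[d$coeff_type != 1L]) < 1e-12))
})

test_that("top-level smoothing coefficient conserves the image sum", {
  set.seed(2)
  for (s in c(2, 3, 4, 5, 6)) {
    m <- matrix(rnorm(s * s), s, s)
    ft <- waveletCascade(m, offsetsMode = "single")
    d <- featureDescriptors(ft)
    L <- max(d$level) + 1L
    top <- which(d$level == L - 1L & d$coeff_type == 1L)
    expect_equal(unname(featureValues(ft)[top, 1L]) * 4^L, sum(m),
                 tolerance = 1e-10)
  }
})

test_that("the full cascade is linear", {
  set.seed(3)
  for (rep in 1:10) {
    s <- sample(2:6, 1)
    x <- matrix(rnorm(s * s), s, s)
    y <- matrix(rnorm(s * s), s, s)
    a <- rnorm(1); b <- rnorm(1)
    vx <- featureValues(waveletCascade(x))[, 1L]
    vy <- featureValues(waveletCascade(y))[, 1L]
    vxy <- featureValues(waveletCascade(a * x + b * y))[, 1L]
    expect_equal(vxy, a * vx + b * vy, tolerance = 1e-10)
  }
})

test_that("feature counts match explicit block enumeration", {
  # independent enumeration of blocks per level for an s x s image
  countFeatures <- function(nr, nc) {
    total <- 0L
    repeat {
      if (nr %% 2L) nr <- nr + 1L
      if (nc %% 2L) nc <- nc + 1L
      nbr <- nr %/% 2L; nbc <- nc %/% 2L
      total <- total + 4L * nbr * nbc
      nr <- nbr; nc <- nbc
      if (nbr == 1L && nbc == 1L) break
    }
    total
  }
  for (s in 2:7) {
    m <- matrix(rnorm(s * s), s, s)
    single <- waveletCascade(m, offsetsMode = "single")
    expect_equal(nrow(featureValues(single)), countFeatures(s, s))
    all4 <- waveletCascade(m, offsetsMode = "all4")
    expect_equal(nrow(featureValues(all4)),
                 countFeatures(s, s) + countFeatures(s + 1L, s) +
                   countFeatures(s, s + 1L) + countFeatures(s + 1L, s + 1L))
  }
  # a 2x2 image yields exactly 4 features at level 0 of the aligned tiling
  d2 <- featureDescriptors(waveletCascade(matrix(rnorm(4), 2, 2),
                                          offsetsMode = "single"))
  expect_equal(sum(d2$level == 0L), 4L)
})

test_that("the multi-sample operator equals per-sample cascades", {
  set.seed(5)
  g <- graphFromAdjacency(randomConnectedAdjacency(6, 2))
  e <- embedExact(g)
  vals <- matrix(rnorm(6 * 4), 6, 4,
                 dimnames = list(reactionIds(g), paste0("s", 1:4)))
  ft <- featureTable(e, vals)
  for (k in 1:4) {
    img <- paintReactionImage(e, vals[, k], paste0("s", k))
    expect_equal(featureValues(waveletCascade(img))[, 1L],
                 featureValues(ft)[, k], tolerance = 1e-12)
  }
  expect_equal(colnames(featureValues(ft)), paste0("s", 1:4))
})

test_that("feature support reflects the occupied footprint", {
  g <- pathGraph(2, "p2")
  e <- embedExact(g, side = 2)
  vals <- matrix(rnorm(4), 2, 2, dimnames = list(reactionIds(g),
                                                 c("s1", "s2")))
  ft <- featureTable(e, vals)
  d <- featureDescriptors(ft)
  # aligned level-0 tiling of the 2x2 grid holds both reactions in 1 block
  aligned0 <- d$off_y == 0L & d$off_x == 0L & d$level == 0L
  expect_true(all(d$support_size[aligned0] == 2L))
  expect_setequal(featureSupport(ft)[[which(aligned0)[1L]]], c("R1", "R2"))
})

test_that("non-trivial filtering drops empty-support and constant features", {
  g <- pathGraph(2, "p2")
  e <- embedExact(g, side = 2)
  vals <- matrix(c(1, 0, 2, 0), 2, 2,
                 dimnames = list(reactionIds(g), c("s1", "s2")))
  ft <- featureTable(e, vals, offsetsMode = "all4")
  nt <- nontrivialFeatures(ft)
  d <- featureDescriptors(nt)
  expect_true(all(d$support_size >= 1L))
  rng <- apply(featureValues(nt), 1L, function(x) max(x) - min(x))
  expect_true(all(rng > 0))
  expect_lt(nrow(featureValues(nt)), nrow(featureValues(ft)))
  # R2 is constant across samples but R1 varies: features over R1 survive
  expect_true(any(vapply(featureSupport(nt), function(s) "R1" %in% s,
                         logical(1))))
})

test_that("feature tables over the same samples can be combined", {
  g1 <- pathGraph(3, "a"); g2 <- pathGraph(4, "b")
  e1 <- embedExact(g1); e2 <- embedExact(g2)
  v1 <- matrix(rnorm(6), 3, 2, dimnames = list(reactionIds(g1),
                                               c("s1", "s2")))
  v2 <- matrix(rnorm(8), 4, 2, dimnames = list(reactionIds(g2),
                                               c("s1", "s2")))
  ft <- bindFeatureTables(list(featureTable(e1, v1), featureTable(e2, v2)))
  expect_setequal(unique(featureDescriptors(ft)$pathway), c("a", "b"))
  v3 <- v2; colnames(v3) <- c("s2", "s1")
  expect_error(bindFeatureTables(list(featureTable(e1, v1),
                                      featureTable(e2, v3))),
               "same samples")
})
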