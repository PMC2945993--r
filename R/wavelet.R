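#' Pad a matrix to even dimensions with zeros
#'
#' Rows/columns of zeros are appended at the bottom/right until both
#' dimensions are even, so the matrix tiles into disjoint 2x2 blocks. The
#' same rule is applied again at every cascade level that produces an odd
#' dimension.
#'
#' @param m numeric matrix.
#' @return zero-padded matrix with even dimensions.
#' @examples
#' dim(padMatrix(matrix(1, 3, 3)))  # 4 4
#' @export
padMatrix <- function(m) {
  stopifnot(is.matrix(m))
  if (nrow(m) %% 2L == 1L) m <- rbind(m, 0)
  if (ncol(m) %% 2L == 1L) m <- cbind(m, 0)
  m
}

padSupport <- function(sup) {
  # same shape logic as padMatrix for the list-matrix of support sets
  if (nrow(sup) %% 2L == 1L) {
    sup <- rbind(sup, rep(list(character()), ncol(sup)))
  }
  if (ncol(sup) %% 2L == 1L) {
    sup <- cbind(sup, rep(list(character()), nrow(sup)))
  }
  sup
}

#' Haar coefficients of one 2x2 block
#'
#' For a block (a, b; c, d) with upper-row mean m_u = (a + b)/2, lower-row
#' mean m_l = (c + d)/2, upper difference d_u = a - b and lower difference
#' d_l = c - d, the four combined values are the mean of means
#' f1 = (m_u + m_l)/2, the difference of means f2 = m_u - m_l, the mean of
#' differences f3 = (d_u + d_l)/2 and the difference of differences
#' f4 = d_u - d_l. Means average without orthonormal rescaling and
#' differences are plain; downstream rank tests are invariant to any fixed
#' positive scaling.
#'
#' @param block 2x2 numeric matrix, or the 4 values a, b, c, d.
#' @return numeric vector (f1, f2, f3, f4).
#' @examples
#' haarBlock(matrix(c(4, 0, 2, 2), 2, 2))  # 2 2 0 4
#' @export
haarBlock <- function(block) {
  v <- as.numeric(block)
  stopifnot(length(v) == 4L)
  if (is.matrix(block)) {
    a <- block[1L, 1L]; b <- block[1L, 2L]
    c_ <- block[2L, 1L]; d <- block[2L, 2L]
  } else {
    a <- v[1L]; b <- v[2L]; c_ <- v[3L]; d <- v[4L]
  }
  mu <- (a + b) / 2; ml <- (c_ + d) / 2
  du <- a - b; dl <- c_ - d
  c((mu + ml) / 2, mu - ml, (du + dl) / 2, du - dl)
}

#' Invert [haarBlock()]
#'
#' @param f numeric vector (f1, f2, f3, f4).
#' @return 2x2 numeric matrix (a, b; c, d) with
#'   `haarBlock(reconstructBlock(f)) == f`.
#' @export
reconstructBlock <- function(f) {
  stopifnot(length(f) == 4L)
  mu <- f[1L] + f[2L] / 2; ml <- f[1L] - f[2L] / 2
  du <- f[3L] + f[4L] / 2; dl <- f[3L] - f[4L] / 2
  matrix(c(mu + du / 2, ml + dl / 2, mu - du / 2, ml - dl / 2), 2L, 2L)
}

# One full cascade over a single matrix. `support` is a list-matrix of the
# same shape carrying the reaction ids sitting on each cell. Returns the
# descriptor rows (without pathway/offset columns), the feature values in
# descriptor order, and the support sets.
cascadeCore <- function(m, support) {
  level <- 0L
  lev <- brow <- bcol <- ctype <- integer()
  vals <- numeric()
  sup_out <- list()
  repeat {
    m <- padMatrix(m)
    support <- padSupport(support)
    nbr <- nrow(m) %/% 2L
    nbc <- ncol(m) %/% 2L
    # block corners (a, b; c, d) for the whole level at once
    io <- 2L * seq_len(nbr) - 1L
    jo <- 2L * seq_len(nbc) - 1L
    a <- m[io, jo, drop = FALSE]
    b <- m[io, jo + 1L, drop = FALSE]
    cc <- m[io + 1L, jo, drop = FALSE]
    d <- m[io + 1L, jo + 1L, drop = FALSE]
    mu <- (a + b) / 2; ml <- (cc + d) / 2
    du <- a - b; dl <- cc - d
    f1 <- (mu + ml) / 2
    fs <- rbind(as.numeric(f1), as.numeric(mu - ml),
                as.numeric((du + dl) / 2), as.numeric(du - dl))
    nb <- nbr * nbc
    s1 <- matrix(list(character()), nbr, nbc)
    blocksup <- vector("list", nb)
    k <- 0L
    for (bc in seq_len(nbc)) {
      for (br in seq_len(nbr)) {
        k <- k + 1L
        i <- io[br]; j <- jo[bc]
        bs <- unlist(support[c(i, i + 1L), c(j, j + 1L)], use.names = FALSE)
        bs <- if (length(bs)) sort(unique(bs)) else character()
        s1[[br, bc]] <- bs
        blocksup[[k]] <- bs
      }
    }
    lev <- c(lev, rep(level, 4L * nb))
    brow <- c(brow, rep(rep(seq_len(nbr) - 1L, times = nbc), each = 4L))
    bcol <- c(bcol, rep(rep(seq_len(nbc) - 1L, each = nbr), each = 4L))
    ctype <- c(ctype, rep(1:4, nb))
    vals <- c(vals, as.numeric(fs))
    sup_out <- c(sup_out, rep(blocksup, each = 4L))
    level <- level + 1L
    m <- f1
    support <- s1
    if (nbr == 1L && nbc == 1L) break
  }
  list(descriptors = data.frame(level = lev, block_row = brow,
                                block_col = bcol, coeff_type = ctype),
       values = vals, support = sup_out)
}

# shift a matrix by prepending dy zero rows / dx zero columns
shiftMatrix <- function(m, dy, dx) {
  if (dy > 0L) m <- rbind(matrix(0, dy, ncol(m)), m)
  if (dx > 0L) m <- cbind(matrix(0, nrow(m), dx), m)
  m
}

shiftSupport <- function(sup, dy, dx) {
  if (dy > 0L) sup <- rbind(matrix(list(character()), dy, ncol(sup)), sup)
  if (dx > 0L) sup <- cbind(matrix(list(character()), nrow(sup), dx), sup)
  sup
}

cellSupport <- function(embedding) {
  s <- embedding@side
  sup <- matrix(list(character()), s, s)
  pl <- placement(embedding)
  for (r in rownames(pl))
    sup[[pl[r, 1L] + 1L, pl[r, 2L] + 1L]] <- r
  sup
}

theOffsets <- function(offsetsMode)
  switch(offsetsMode,
         single = list(c(0L, 0L)),
         all4 = list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L)))

#' Wavelet cascade of one reaction image
#'
#' Tiles the (zero-padded) image into disjoint 2x2 blocks, computes the four
#' Haar coefficients per block, then recurses on the matrix of mean-of-means
#' coefficients (padding again wherever a dimension turns odd) until a
#' single block remains. With `offsetsMode = "all4"` the cascade is repeated
#' for the four shift origins (0,0), (0,1), (1,0), (1,1), the shifted image
#' padded with zeros, covering all four possible 2x2 arrangements.
#'
#' @param image a [ReactionImage-class] (or plain matrix; support then
#'   empty).
#' @param offsetsMode `"all4"` (default) or `"single"`.
#' @return a [FeatureTable-class] with one sample column.
#' @export
waveletCascade <- function(image, offsetsMode = c("all4", "single")) {
  offsetsMode <- match.arg(offsetsMode)
  if (is(image, "ReactionImage")) {
    m <- image@values
    sup <- matrix(list(character()), nrow(m), ncol(m))
    occ <- image@occupied
    idx <- which(occ, arr.ind = TRUE)
    for (k in seq_len(nrow(idx)))
      sup[[idx[k, 1L], idx[k, 2L]]] <- paste0("cell_", idx[k, 1L], "_",
                                              idx[k, 2L])
    pid <- image@pathwayId
    sid <- image@sampleId
  } else {
    m <- image
    sup <- matrix(list(character()), nrow(m), ncol(m))
    pid <- "pathway"
    sid <- "sample"
  }
  desc <- list(); vals <- numeric(); supl <- list()
  for (off in theOffsets(offsetsMode)) {
    cc <- cascadeCore(shiftMatrix(m, off[1L], off[2L]),
                      shiftSupport(sup, off[1L], off[2L]))
    d <- cc$descriptors
    d$off_y <- off[1L]
    d$off_x <- off[2L]
    desc[[length(desc) + 1L]] <- d
    vals <- c(vals, cc$values)
    supl <- c(supl, cc$support)
  }
  d <- do.call(rbind, desc)
  d$pathway <- pid
  d$support_size <- lengths(supl)
  d <- d[, c("pathway", "level", "block_row", "block_col", "off_y", "off_x",
             "coeff_type", "support_size")]
  rownames(d) <- NULL
  new("FeatureTable", descriptors = d,
      values = matrix(vals, ncol = 1L, dimnames = list(NULL, sid)),
      support = supl)
}

#' Wavelet feature table for all samples of a pathway
#'
#' Because every step of the cascade is linear in the image and the image is
#' linear in the reaction values, the whole feature map is a fixed linear
#' operator of the embedding: it is assembled once from cascades of the
#' reaction indicator images and applied to the reactions x samples matrix
#' by a single multiplication.
#'
#' @param embedding a [GridEmbedding-class].
#' @param reactionValues reactions x samples numeric matrix (rownames =
#'   reaction ids placed by the embedding).
#' @param offsetsMode `"all4"` (default) or `"single"`.
#' @return a [FeatureTable-class] with one column per sample.
#' @export
featureTable <- function(embedding, reactionValues,
                         offsetsMode = c("all4", "single")) {
  offsetsMode <- match.arg(offsetsMode)
  stopifnot(is.matrix(reactionValues))
  pl <- placement(embedding)
  ids <- rownames(pl)
  if (!setequal(rownames(reactionValues), ids))
    stop("reactionValues rows must match the embedded reactions")
  reactionValues <- reactionValues[ids, , drop = FALSE]
  s <- embedding@side
  sup <- cellSupport(embedding)
  desc <- list(); supl <- list(); ops <- list()
  for (off in theOffsets(offsetsMode)) {
    # structure + support from one cascade of the occupancy pattern
    base <- matrix(0, s, s)
    cc0 <- cascadeCore(shiftMatrix(base, off[1L], off[2L]),
                       shiftSupport(sup, off[1L], off[2L]))
    d <- cc0$descriptors
    d$off_y <- off[1L]
    d$off_x <- off[2L]
    desc[[length(desc) + 1L]] <- d
    supl <- c(supl, cc0$support)
    # operator columns from indicator images, one per reaction
    L <- matrix(0, length(cc0$values), length(ids))
    empty_sup <- matrix(list(character()), s, s)
    for (k in seq_along(ids)) {
      e <- matrix(0, s, s)
      e[pl[ids[k], 1L] + 1L, pl[ids[k], 2L] + 1L] <- 1
      L[, k] <- cascadeCore(shiftMatrix(e, off[1L], off[2L]),
                            shiftSupport(empty_sup, off[1L],
                                         off[2L]))$values
    }
    ops[[length(ops) + 1L]] <- L
  }
  d <- do.call(rbind, desc)
  d$pathway <- embedding@pathwayId
  d$support_size <- lengths(supl)
  d <- d[, c("pathway", "level", "block_row", "block_col", "off_y", "off_x",
             "coeff_type", "support_size")]
  rownames(d) <- NULL
  vals <- do.call(rbind, ops) %*% reactionValues
  colnames(vals) <- colnames(reactionValues)
  new("FeatureTable", descriptors = d, values = vals, support = supl)
}

#' Keep non-trivial features
#'
#' A feature is non-trivial when its spatial support contains at least one
#' reaction-occupied cell (a structural property of the embedding) and its
#' value vector is not constant across samples (zero-variance features are
#' untestable by a rank test).
#'
#' @param table a [FeatureTable-class].
#' @return the filtered [FeatureTable-class].
#' @export
nontrivialFeatures <- function(table) {
  stopifnot(is(table, "FeatureTable"))
  v <- table@values
  varying <- apply(v, 1L, function(x) max(x) - min(x)) > 0
  keep <- table@descriptors$support_size >= 1L & varying
  new("FeatureTable", descriptors = table@descriptors[keep, , drop = FALSE],
      values = v[keep, , drop = FALSE], support = table@support[keep])
}

#' Combine per-pathway feature tables
#'
#' @param tables list of [FeatureTable-class] objects over identical samples.
#' @return one [FeatureTable-class].
#' @export
bindFeatureTables <- function(tables) {
  stopifnot(length(tables) >= 1L)
  cols <- lapply(tables, function(t) colnames(t@values))
  if (!all(vapply(cols, identical, logical(1), cols[[1L]])))
    stop("feature tables must share the same samples in the same order")
  desc <- do.call(rbind, lapply(tables, featureDescriptors))
  rownames(desc) <- NULL
  new("FeatureTable", descriptors = desc,
      values = do.call(rbind, lapply(tables, featureValues)),
      support = do.call(c, lapply(tables, featureSupport)))
}
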