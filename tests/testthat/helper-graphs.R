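# shared fixtures built in code

# all connected graphs on n labelled nodes, reduced to one representative
# per isomorphism class (canonical form via igraph/BLISS)
enumerateConnectedGraphs <- function(n) {
  pairs <- t(combn(n, 2L))
  m <- nrow(pairs)
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (mask in 0:(2^m - 1)) {
    M <- matrix(0L, n, n)
    bits <- bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0
    if (!any(bits) && n > 1) next
    for (e in which(bits)) {
      M[pairs[e, 1L], pairs[e, 2L]] <- 1L
      M[pairs[e, 2L], pairs[e, 1L]] <- 1L
    }
    g <- igraph::graph_from_adjacency_matrix(M, mode = "undirected")
    if (!igraph::is_connected(g)) next
    cp <- igraph::canonical_permutation(g)$labeling
    gc <- igraph::permute(g, cp)
    key <- paste(as.integer(igraph::as_adjacency_matrix(gc,
                                                        sparse = FALSE)),
                 collapse = "")
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    out[[length(out) + 1L]] <- M
  }
  out
}

# random connected adjacency matrix: random recursive tree + extra edges
randomConnectedAdjacency <- function(n, extra = 1L) {
  M <- matrix(0L, n, n)
  if (n > 1L)
    for (b in 2:n) {
      a <- if (b == 2L) 1L else sample.int(b - 1L, 1L)
      M[a, b] <- M[b, a] <- 1L
    }
  free <- which(upper.tri(M) & M == 0L)
  if (extra > 0L && length(free) > 0L) {
    M[free[sample.int(length(free), min(extra, length(free)))]] <- 1L
    M <- pmax(M, t(M))
  }
  M
}

# independent exact two-sided Wilcoxon oracle: full enumeration of all
# C(n, na) rank assignments of the pooled (tie-free) values
enumWilcoxonP <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  n <- length(pooled)
  na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- combn(n, na)
  u_all <- apply(combos, 2L, function(idx)
    sum(rank(pooled)[idx]) - na * (na + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}
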