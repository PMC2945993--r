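#' Manhattan distance between two grid points
#'
#' The lattice metric |i1 - i2| + |j1 - j2| used throughout the embedding.
#'
#' @param u,v integer vectors of length 2 (row, column).
#' @return non-negative integer.
#' @examples
#' manhattanDistance(c(0, 0), c(2, 3))  # 5
#' @export
manhattanDistance <- function(u, v) {
  stopifnot(length(u) == 2L, length(v) == 2L)
  as.integer(abs(u[1L] - v[1L]) + abs(u[2L] - v[2L]))
}

#' Smallest square grid holding a graph
#'
#' Side length ceiling(sqrt(|V|)), the grid of the smallest possible size,
#' optionally with one row/column of slack.
#'
#' @param graph a [PathwayGraph-class] (or an integer node count).
#' @param slack logical; add 1 to the side length.
#' @return integer side length s with s^2 >= |V|.
#' @export
defaultGrid <- function(graph, slack = FALSE) {
  n <- if (is(graph, "PathwayGraph")) nReactions(graph) else as.integer(graph)
  stopifnot(n >= 1L)
  as.integer(ceiling(sqrt(n))) + as.integer(isTRUE(slack))
}

newEmbedding <- function(graph, side, assignment, objective, proven, gap,
                         method) {
  ids <- reactionIds(graph)
  pl <- cbind(i = assignment %/% side, j = assignment %% side)
  rownames(pl) <- ids
  new("GridEmbedding", pathwayId = pathwayId(graph),
      side = as.integer(side), placement = pl,
      objective = as.numeric(objective),
      provenOptimal = proven, gap = gap, method = method)
}

#' Exhaustive embedding oracle
#'
#' Enumerates every injective placement of the nodes on the grid and returns
#' a global optimum. Intended as a test oracle for small graphs; refuses
#' graphs above `cap` nodes.
#'
#' @param graph a [PathwayGraph-class].
#' @param side grid side length (default [defaultGrid()]).
#' @param cap maximum number of nodes accepted (default 7).
#' @return a [GridEmbedding-class] with `provenOptimal = TRUE`.
#' @export
embedBruteforce <- function(graph, side = defaultGrid(graph), cap = 7L) {
  n <- nReactions(graph)
  if (n > cap)
    stop("embedBruteforce refuses graphs with more than ", cap, " nodes")
  if (side * side < n) stop("grid side ", side, " cannot hold ", n, " nodes")
  res <- cpp_embed_bruteforce(adjacency(graph), as.integer(side))
  newEmbedding(graph, side, res$assignment, res$objective, TRUE, 1,
               "bruteforce")
}

#' Exact lattice embedding by branch and bound
#'
#' Solves the placement integer program: minimize the total Manhattan length
#' of network edges over injective assignments of nodes to grid cells
#' (binary placement variables with each node placed exactly once and each
#' cell used at most once; distance variables are needed only for adjacent
#' pairs since non-edges contribute nothing to the objective). The authored
#' solver is an exact branch and bound: `cuts` selects motif families
#' (stars, cliques, odd cycles, bounded-degree trees) whose precomputed
#' lattice lower bounds `lb(G')` are combined over an edge-disjoint motif
#' cover into a valid root lower bound used for optimality proofs and the
#' reported gap; `symmetryBreaking` restricts the first placed node to a
#' fundamental domain of the grid's rotation/reflection symmetries. Neither
#' device changes the optimal objective. On hitting `timeLimit` the best
#' incumbent is returned with `provenOptimal = FALSE` and the achieved gap.
#'
#' @param graph a [PathwayGraph-class].
#' @param side grid side length (default [defaultGrid()]).
#' @param cuts character vector among `"star"`, `"clique"`, `"odd_cycle"`,
#'   `"bounded_degree_tree"`; empty disables motif bounds (an edge-count
#'   bound is always available).
#' @param symmetryBreaking logical.
#' @param timeLimit seconds per pathway (default 300).
#' @return a [GridEmbedding-class].
#' @examples
#' g <- pathGraph(4)
#' objectiveValue(embedExact(g, side = 2))  # 3
#' @export
embedExact <- function(graph, side = defaultGrid(graph),
                       cuts = c("star", "clique", "odd_cycle",
                                "bounded_degree_tree"),
                       symmetryBreaking = TRUE, timeLimit = 300) {
  n <- nReactions(graph)
  if (side * side < n)
    stop("infeasible grid: side ", side, " cannot hold ", n, " nodes")
  lb <- graphLowerBound(graph, cuts)
  if (nEdges(graph) == 0L) {
    # nothing to optimize; any placement (first cells) is optimal
    return(newEmbedding(graph, side, seq_len(n) - 1L, 0, TRUE, 1, "exact"))
  }
  res <- cpp_embed_exact(adjacency(graph), as.integer(side),
                         isTRUE(symmetryBreaking), as.numeric(timeLimit),
                         as.integer(lb))
  proven <- isTRUE(res$proven_optimal)
  gap <- if (proven) 1 else min(1, lb / res$objective)
  newEmbedding(graph, side, res$assignment, res$objective, proven, gap,
               "exact")
}

#' Randomized local-search embedding
#'
#' Simulated annealing over pairwise swap/relocate moves, deterministic for
#' a given seed. With `iterations = 0` the seeded random initial placement is
#' returned unchanged. The gap is computed from the best known combinatorial
#' lower bound (edge count strengthened by motif bounds).
#'
#' @param graph a [PathwayGraph-class].
#' @param side grid side length.
#' @param seed integer seed for the solver's private RNG.
#' @param iterations number of proposed moves (default 10000).
#' @param t0 initial temperature in objective units.
#' @return a [GridEmbedding-class] with `provenOptimal = FALSE` (unless the
#'   incumbent meets the lower bound).
#' @export
embedHeuristic <- function(graph, side = defaultGrid(graph), seed = 1L,
                           iterations = 10000L, t0 = 2) {
  n <- nReactions(graph)
  if (side * side < n)
    stop("infeasible grid: side ", side, " cannot hold ", n, " nodes")
  res <- cpp_embed_anneal(adjacency(graph), as.integer(side),
                          as.integer(seed), as.integer(iterations),
                          as.numeric(t0))
  lb <- graphLowerBound(graph, c("star", "clique", "odd_cycle",
                                 "bounded_degree_tree"))
  proven <- nEdges(graph) == 0L || res$objective <= lb
  gap <- if (res$objective == 0) 1 else min(1, lb / res$objective)
  newEmbedding(graph, side, res$assignment, res$objective, proven,
               if (proven) 1 else gap, "heuristic")
}

#' Total Manhattan edge length of an embedding
#'
#' @param graph a [PathwayGraph-class].
#' @param embedding a [GridEmbedding-class] placing all of the graph's nodes.
#' @return integer sum of Manhattan distances over adjacent pairs.
#' @export
totalEdgeLength <- function(graph, embedding) {
  ids <- reactionIds(graph)
  pl <- placement(embedding)
  if (!all(ids %in% rownames(pl)))
    stop("embedding does not place all reactions: ",
         paste(setdiff(ids, rownames(pl)), collapse = ", "))
  pl <- pl[ids, , drop = FALSE]
  assignment <- as.integer(pl[, 1L] * embedding@side + pl[, 2L])
  as.integer(cpp_total_edge_length(adjacency(graph), assignment,
                                   embedding@side))
}

#' Embed a pathway with the appropriate solver
#'
#' Dispatcher used by the pipeline: exact branch and bound up to `exactMax`
#' nodes, simulated annealing beyond (or on request).
#'
#' @param graph a [PathwayGraph-class].
#' @param method `"auto"`, `"exact"`, `"heuristic"` or `"bruteforce"`.
#' @param slack passed to [defaultGrid()].
#' @param exactMax node-count limit for the exact solver under `"auto"`.
#' @param seed,iterations heuristic parameters.
#' @param timeLimit exact-solver time limit in seconds.
#' @return a [GridEmbedding-class].
#' @export
embedPathway <- function(graph, method = c("auto", "exact", "heuristic",
                                           "bruteforce"),
                         slack = FALSE, exactMax = 9L, seed = 1L,
                         iterations = 20000L, timeLimit = 300) {
  method <- match.arg(method)
  side <- defaultGrid(graph, slack)
  if (method == "auto")
    method <- if (nReactions(graph) <= exactMax) "exact" else "heuristic"
  switch(method,
         exact = embedExact(graph, side, timeLimit = timeLimit),
         heuristic = embedHeuristic(graph, side, seed = seed,
                                    iterations = iterations),
         bruteforce = embedBruteforce(graph, side))
}

# ---- motif lower bounds ----------------------------------------------------

.motif_cache <- new.env(parent = emptyenv())

motifAdjacency <- function(motif_kind, k) {
  switch(motif_kind,
         star = {
           stopifnot(k >= 1L)
           n <- k + 1L
           M <- matrix(0L, n, n)
           M[1L, 2L:n] <- M[2L:n, 1L] <- 1L
           M
         },
         clique = {
           stopifnot(k >= 2L, k <= 10L)
           M <- matrix(1L, k, k); diag(M) <- 0L
           M
         },
         odd_cycle = {
           if (!(k %in% c(3L, 5L)))
             stop("supported odd cycles are C3 and C5")
           M <- matrix(0L, k, k)
           for (a in seq_len(k)) {
             b <- a %% k + 1L
             M[a, b] <- M[b, a] <- 1L
           }
           M
         },
         stop("unsupported motif kind: ", motif_kind))
}

#' Lattice lower bound for a subgraph motif
#'
#' Least total Manhattan edge length any embedding of the motif can achieve
#' on an (unbounded) square lattice. These right-hand sides depend only on
#' the motif, not on the host graph, so each is computed once by exhaustive
#' lattice optimization of the motif and cached for the session. For
#' `bounded_degree_tree` (any tree with maximum vertex degree <= 4) the
#' bound is k - 1: every edge has length at least 1 and paths attain it.
#'
#' @param motif_kind `"star"` (k = number of leaves), `"clique"` (k nodes,
#'   k <= 10), `"odd_cycle"` (k in 3, 5) or `"bounded_degree_tree"` (k
#'   nodes).
#' @param k motif size parameter.
#' @return integer lower bound lb(G').
#' @examples
#' motifLowerBound("star", 4)      # 4
#' motifLowerBound("odd_cycle", 3) # 4
#' @export
motifLowerBound <- function(motif_kind, k) {
  motif_kind <- match.arg(motif_kind,
                          c("star", "clique", "odd_cycle",
                            "bounded_degree_tree"))
  k <- as.integer(k)
  if (motif_kind == "bounded_degree_tree") {
    stopifnot(k >= 1L)
    return(k - 1L)  # each edge >= 1; attained by a lattice path
  }
  key <- paste(motif_kind, k, sep = ":")
  if (!is.null(.motif_cache[[key]])) return(.motif_cache[[key]])
  M <- motifAdjacency(motif_kind, k)
  n <- nrow(M)
  # a side of ceil(sqrt(n)) + 2 leaves room around the compact optimum, so
  # the finite-grid optimum equals the unbounded-lattice optimum
  side <- as.integer(ceiling(sqrt(n))) + 2L
  res <- cpp_embed_exact(M, side, TRUE, 600, sum(M) %/% 2L)
  if (!isTRUE(res$proven_optimal))
    stop("motif optimization did not complete for ", key)
  lb <- as.integer(res$objective)
  .motif_cache[[key]] <- lb
  lb
}

# Detect an edge-disjoint collection of motifs and combine their lattice
# bounds with 1 per uncovered edge into a valid global lower bound on the
# total edge length of any embedding of `graph`.
graphLowerBound <- function(graph, cuts = character()) {
  M <- adjacency(graph)
  n <- nrow(M)
  nE <- sum(M) %/% 2L
  if (nE == 0L) return(0L)
  covered <- matrix(FALSE, n, n)
  bound <- 0L
  g <- igraph::graph_from_adjacency_matrix(M, mode = "undirected")
  if ("clique" %in% cuts && n >= 3L) {
    cl <- igraph::max_cliques(g, min = 3L, max = 10L)
    cl <- cl[order(-lengths(cl))]
    for (nodes in cl) {
      nodes <- as.integer(nodes)
      pairs <- t(combn(nodes, 2L))
      if (any(covered[pairs])) next
      covered[pairs] <- TRUE
      covered[pairs[, c(2L, 1L)]] <- TRUE
      bound <- bound + motifLowerBound(if (length(nodes) == 3L) "odd_cycle"
                                       else "clique", length(nodes))
    }
  }
  if ("odd_cycle" %in% cuts && n >= 5L) {
    # 5-cycles edge-disjoint from what is covered so far
    ring <- igraph::subgraph_isomorphisms(igraph::make_ring(5L), g,
                                          induced = FALSE)
    for (mp in ring) {
      nodes <- as.integer(mp)
      e <- cbind(nodes, nodes[c(2:5, 1)])
      if (any(covered[e])) next
      covered[e] <- TRUE
      covered[e[, c(2L, 1L)]] <- TRUE
      bound <- bound + motifLowerBound("odd_cycle", 5L)
    }
  }
  if ("star" %in% cuts) {
    deg <- rowSums(M)
    for (v in order(-deg)) {
      if (deg[v] < 5L) break  # stars with <= 4 leaves add nothing over edges
      leaves <- which(M[v, ] == 1L & !covered[v, ])
      if (length(leaves) < 5L) next
      covered[v, leaves] <- covered[leaves, v] <- TRUE
      bound <- bound + motifLowerBound("star", length(leaves))
    }
  }
  # remaining edges contribute at least 1 each (the bounded-degree-tree /
  # single-edge bound)
  uncovered <- sum(M == 1L & !covered) %/% 2L
  max(bound + uncovered, nE)
}
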