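# run expr with a local, restorable RNG state seeded from `seed`
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  expr
}

deriveSeed <- function(seed, k)
  as.integer((as.numeric(seed) * 1009 + as.numeric(k)) %% 2147483629)

#' Toy graphs on synthetic reactions
#'
#' Convenience constructors for small named graphs, and a generic builder
#' realizing an arbitrary symmetric adjacency matrix with synthetic
#' metabolites (one metabolite per edge, produced by one endpoint and
#' consumed by the other) so the neighbor rule reproduces exactly the
#' requested adjacency.
#'
#' @param M symmetric 0/1 adjacency matrix with zero diagonal.
#' @param pathway_id identifier for the constructed pathway.
#' @param genes_per_reaction genes annotated per reaction (default 1).
#' @return a [PathwayGraph-class].
#' @examples
#' nEdges(pathGraph(4))  # 3
#' @export
graphFromAdjacency <- function(M, pathway_id = "toy",
                               genes_per_reaction = 1L) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M), all(M %in% c(0, 1)),
            all(M == t(M)), all(diag(M) == 0))
  n <- nrow(M)
  ids <- if (!is.null(rownames(M))) rownames(M) else paste0("R", seq_len(n))
  subs <- rep(list(character()), n)
  prods <- rep(list(character()), n)
  eidx <- 0L
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (b > a && M[a, b] == 1) {
        eidx <- eidx + 1L
        met <- paste0("M", eidx)
        prods[[a]] <- c(prods[[a]], met)
        subs[[b]] <- c(subs[[b]], met)
      }
    }
  }
  rs <- lapply(seq_len(n), function(k) {
    reaction(ids[k],
             gene_ids = paste0("g_", pathway_id, "_", ids[k], "_",
                               seq_len(genes_per_reaction)),
             substrates = c(subs[[k]], paste0("S_", ids[k])),
             products = prods[[k]])
  })
  buildPathwayGraph(pathway_id, rs)
}

#' @rdname graphFromAdjacency
#' @param n number of nodes.
#' @export
pathGraph <- function(n, pathway_id = "path") {
  M <- matrix(0L, n, n)
  for (a in seq_len(n - 1L)) M[a, a + 1L] <- M[a + 1L, a] <- 1L
  graphFromAdjacency(M, pathway_id)
}

#' @rdname graphFromAdjacency
#' @param k number of leaves of the star K1,k.
#' @export
starGraph <- function(k, pathway_id = "star") {
  M <- matrix(0L, k + 1L, k + 1L)
  M[1L, -1L] <- M[-1L, 1L] <- 1L
  graphFromAdjacency(M, pathway_id)
}

#' @rdname graphFromAdjacency
#' @export
cycleGraph <- function(n, pathway_id = "cycle") {
  M <- matrix(0L, n, n)
  for (a in seq_len(n)) {
    b <- a %% n + 1L
    M[a, b] <- M[b, a] <- 1L
  }
  graphFromAdjacency(M, pathway_id)
}

#' Simulation design for synthetic two-group pathway data
#'
#' Describes the generated study: how many pathways and reactions, how many
#' genes per reaction, group sizes, the Normal noise level of the log-ratio
#' expression, the planted regulation pattern and its effect size in
#' log-ratio units, which pathways carry it, and the seed everything flows
#' from. Defaults emulate a modest two-group microarray study: 5 pathways of
#' 6 connected reactions, 2 genes per reaction, 30 samples per prognosis
#' group, unit-SD log-ratio noise.
#'
#' @param n_pathways,reactions_per_pathway,genes_per_reaction counts >= 1.
#' @param n_favorable,n_unfavorable samples per group.
#' @param noise_sd Normal SD of gene log-ratios (> 0).
#' @param pattern `"null"`, `"block_up"`, `"block_down"` or `"switch"`.
#' @param effect_size mean shift delta in log-ratio units added to
#'   unfavorable samples on the planted reactions' genes.
#' @param planted_pathways indices of pathways carrying the pattern
#'   (ignored for `"null"`).
#' @param block_size reactions per planted block (block patterns; the
#'   switch pattern always uses one adjacent reaction pair).
#' @param extra_edges edges added per pathway beyond its spanning tree.
#' @param seed integer seed; identical designs give byte-identical data.
#' @return validated list of class `"SimulationDesign"`.
#' @export
simulationDesign <- function(n_pathways = 5L, reactions_per_pathway = 6L,
                             genes_per_reaction = 2L, n_favorable = 30L,
                             n_unfavorable = 30L, noise_sd = 1,
                             pattern = c("null", "block_up", "block_down",
                                         "switch"),
                             effect_size = 2, planted_pathways = 1L,
                             block_size = 3L, extra_edges = 2L, seed = 1L) {
  pattern <- match.arg(pattern)
  stopifnot(n_pathways >= 1L, reactions_per_pathway >= 1L,
            genes_per_reaction >= 1L, n_favorable >= 1L,
            n_unfavorable >= 1L, noise_sd > 0, effect_size >= 0,
            block_size >= 1L, extra_edges >= 0L)
  if (pattern != "null")
    stopifnot(all(planted_pathways >= 1L),
              all(planted_pathways <= n_pathways))
  structure(list(n_pathways = as.integer(n_pathways),
                 reactions_per_pathway = as.integer(reactions_per_pathway),
                 genes_per_reaction = as.integer(genes_per_reaction),
                 n_favorable = as.integer(n_favorable),
                 n_unfavorable = as.integer(n_unfavorable),
                 noise_sd = noise_sd, pattern = pattern,
                 effect_size = effect_size,
                 planted_pathways = if (pattern == "null") integer()
                                    else as.integer(planted_pathways),
                 block_size = as.integer(block_size),
                 extra_edges = as.integer(extra_edges),
                 seed = as.integer(seed)),
            class = "SimulationDesign")
}

#' @export
print.SimulationDesign <- function(x, ...) {
  cat("SimulationDesign:", x$n_pathways, "pathways x",
      x$reactions_per_pathway, "reactions x", x$genes_per_reaction,
      "genes;", x$n_favorable, "favorable vs", x$n_unfavorable,
      "unfavorable; noise_sd =", x$noise_sd, "\n  pattern =", x$pattern,
      "(delta =", x$effect_size, ") planted:",
      if (length(x$planted_pathways))
        paste(x$planted_pathways, collapse = ",") else "none",
      "; seed =", x$seed, "\n")
  invisible(x)
}

#' Generate connected random reaction networks
#'
#' Each pathway is a random recursive spanning tree on
#' `reactions_per_pathway` nodes plus `extra_edges` uniformly chosen extra
#' edges; metabolites are synthesized to realize exactly those adjacencies
#' and every reaction gets its own genes. Deterministic for a given design.
#'
#' @param design a [simulationDesign()].
#' @return list of [PathwayGraph-class] objects.
#' @export
generatePathways <- function(design) {
  stopifnot(inherits(design, "SimulationDesign"))
  withSeed(deriveSeed(design$seed, 1L), {
    lapply(seq_len(design$n_pathways), function(p) {
      n <- design$reactions_per_pathway
      M <- matrix(0L, n, n)
      if (n > 1L)
        for (b in 2L:n) {
          a <- if (b == 2L) 1L else sample.int(b - 1L, 1L)
          M[a, b] <- M[b, a] <- 1L
        }
      free <- which(upper.tri(M) & M == 0L)
      if (design$extra_edges > 0L && length(free) > 0L) {
        add <- free[sample.int(length(free),
                               min(design$extra_edges, length(free)))]
        M[add] <- 1L
        M <- pmax(M, t(M))
      }
      graphFromAdjacency(M, paste0("pw", p),
                         genes_per_reaction = design$genes_per_reaction)
    })
  })
}

plantReactions <- function(design, graph) {
  # connected reaction subset carrying the planted pattern
  n <- nReactions(graph)
  M <- adjacency(graph)
  if (design$pattern == "switch") {
    ut <- which(upper.tri(M) & M == 1L, arr.ind = FALSE)
    e <- if (length(ut) == 1L) ut else sample(ut, 1L)
    b <- (e - 1L) %/% n + 1L
    a <- e - (b - 1L) * n
    list(up = a, down = b)
  } else {
    size <- min(design$block_size, n)
    start <- sample.int(n, 1L)
    sel <- start
    while (length(sel) < size) {
      nb <- setdiff(which(rowSums(M[, sel, drop = FALSE]) > 0L), sel)
      if (length(nb) == 0L) break
      sel <- c(sel, nb[sample.int(length(nb), 1L)])
    }
    if (design$pattern == "block_up") list(up = sel, down = integer())
    else list(up = integer(), down = sel)
  }
}

#' Generate two-group expression with planted regulation
#'
#' Gene log-ratios are Normal(0, noise_sd^2). In planted pathways,
#' unfavorable samples get +delta on the genes of a connected reaction
#' block (`block_up`), -delta (`block_down`), or +delta and -delta on the
#' two reactions of a randomly chosen network edge (`switch`, the
#' contrasting-neighbor pattern). The clinical table encodes the intended
#' labels (favorable: t = 6 years, no metastasis; unfavorable: t = 2 years
#' with metastasis).
#'
#' @param design a [simulationDesign()].
#' @param pathways result of [generatePathways()] for the same design.
#' @return list with `expr` (genes x samples matrix), `clinical`
#'   (data.frame `sample_id`, `time_recurrence_years`, `metastasis`),
#'   `labels` (factor from [labelSamples()]) and `truth` (data.frame of
#'   planted pathway/reaction/direction).
#' @export
generateExpression <- function(design, pathways) {
  stopifnot(inherits(design, "SimulationDesign"))
  withSeed(deriveSeed(design$seed, 2L), {
    genes <- unlist(lapply(pathways, pathwayGenes))
    stopifnot(!anyDuplicated(genes))
    ns <- design$n_favorable + design$n_unfavorable
    samples <- sprintf("S%03d", seq_len(ns))
    expr <- matrix(rnorm(length(genes) * ns, 0, design$noise_sd),
                   length(genes), ns, dimnames = list(genes, samples))
    unfav <- seq.int(design$n_favorable + 1L, ns)
    truth <- data.frame(pathway = character(), reaction = character(),
                        direction = character(), stringsAsFactors = FALSE)
    if (design$pattern != "null" && design$effect_size > 0) {
      for (p in design$planted_pathways) {
        g <- pathways[[p]]
        sel <- plantReactions(design, g)
        ids <- reactionIds(g)
        for (dir in c("up", "down")) {
          for (k in sel[[dir]]) {
            gg <- g@reactions[[k]]$gene_ids
            shift <- if (dir == "up") design$effect_size else
              -design$effect_size
            expr[gg, unfav] <- expr[gg, unfav] + shift
            truth <- rbind(truth,
                           data.frame(pathway = pathwayId(g),
                                      reaction = ids[k], direction = dir,
                                      stringsAsFactors = FALSE))
          }
        }
      }
    }
    clinical <- data.frame(
      sample_id = samples,
      time_recurrence_years = c(rep(6, design$n_favorable),
                                rep(2, design$n_unfavorable)),
      metastasis = c(rep(0L, design$n_favorable),
                     rep(1L, design$n_unfavorable)))
    list(expr = expr, clinical = clinical, labels = labelSamples(clinical),
         truth = truth)
  })
}

aucFromScores <- function(p_planted, p_null) {
  # probability that a planted pathway gets the smaller p-value
  if (length(p_planted) == 0L || length(p_null) == 0L) return(NA_real_)
  r <- rank(c(p_planted, p_null))
  u <- sum(r[seq_along(p_planted)]) -
    length(p_planted) * (length(p_planted) + 1) / 2
  1 - u / (length(p_planted) * length(p_null))
}

#' Sensitivity benchmark against enrichment baselines
#'
#' Runs replicated simulations of a planted design, scores every pathway
#' with each method (the wavelet pipeline's best raw feature p-value,
#' Fisher's exact enrichment over per-gene Wilcoxon DE calls at 0.05, and
#' optionally the permutation rank-enrichment baseline) and reports
#' sensitivity/specificity across a significance-threshold sweep plus a
#' threshold-free ROC AUC per method.
#'
#' @param design a [simulationDesign()] with a planted pattern.
#' @param methods subset of `"gridwave"`, `"fisher"`, `"rank_enrichment"`.
#' @param n_replicates number of simulated datasets (>= 2; the sweep is
#'   pooled over replicates).
#' @param seed integer master seed for the replicate series.
#' @param thresholds significance thresholds for the sweep.
#' @param offsetsMode passed to [featureTable()].
#' @return list with `roc` (data.frame method/threshold/sensitivity/
#'   specificity), `auc` (named numeric) and `scores` (per replicate,
#'   pathway and method).
#' @export
benchmarkSensitivity <- function(design,
                                 methods = c("gridwave", "fisher"),
                                 n_replicates = 50L, seed = 1L,
                                 thresholds = 10^seq(-8, 0, length.out = 33),
                                 offsetsMode = "all4") {
  methods <- match.arg(methods, c("gridwave", "fisher", "rank_enrichment"),
                       several.ok = TRUE)
  stopifnot(n_replicates >= 2L, length(design$planted_pathways) >= 1L)
  rows <- list()
  for (r in seq_len(n_replicates)) {
    d <- design
    d$seed <- deriveSeed(seed, r)
    pws <- generatePathways(d)
    sim <- generateExpression(d, pws)
    planted <- paste0("pw", d$planted_pathways)
    labels <- sim$labels
    idx_u <- which(labels == "unfavorable")
    idx_f <- which(labels == "favorable")
    if ("gridwave" %in% methods) {
      res <- gridwaveScores(pws, sim$expr, labels, offsetsMode = offsetsMode)
      rows[[length(rows) + 1L]] <-
        data.frame(replicate = r, method = "gridwave",
                   pathway = names(res), p = unname(res),
                   planted = names(res) %in% planted)
    }
    if ("fisher" %in% methods || "rank_enrichment" %in% methods) {
      sub <- sim$expr[, c(idx_u, idx_f), drop = FALSE]
      gene_p <- rowWilcoxon(sub, seq_along(idx_u))
      de <- rownames(sim$expr)[gene_p <= 0.05]
      universe <- rownames(sim$expr)
      for (g in pws) {
        pid <- pathwayId(g)
        if ("fisher" %in% methods)
          rows[[length(rows) + 1L]] <-
            data.frame(replicate = r, method = "fisher", pathway = pid,
                       p = fisherEnrichment(de, pathwayGenes(g), universe),
                       planted = pid %in% planted)
        if ("rank_enrichment" %in% methods)
          rows[[length(rows) + 1L]] <-
            data.frame(replicate = r, method = "rank_enrichment",
                       pathway = pid,
                       p = rankEnrichmentBaseline(
                         sim$expr, labels, pathwayGenes(g),
                         n_permutations = 200L,
                         seed = deriveSeed(seed, 100000L + r))$p,
                       planted = pid %in% planted)
      }
    }
  }
  scores <- do.call(rbind, rows)
  roc <- do.call(rbind, lapply(unique(scores$method), function(m) {
    sc <- scores[scores$method == m, ]
    do.call(rbind, lapply(thresholds, function(thr) data.frame(
      method = m, threshold = thr,
      sensitivity = mean(sc$p[sc$planted] <= thr),
      specificity = mean(sc$p[!sc$planted] > thr))))
  }))
  auc <- vapply(unique(scores$method), function(m) {
    sc <- scores[scores$method == m, ]
    aucFromScores(sc$p[sc$planted], sc$p[!sc$planted])
  }, numeric(1))
  list(roc = roc, auc = auc, scores = scores)
}

# best raw feature p-value per pathway from the full wavelet pipeline
gridwaveScores <- function(pathways, expr, labels, offsetsMode = "all4",
                           aggregation = "mean") {
  labels <- as.character(labels)
  idx_u <- which(labels == "unfavorable")
  idx_f <- which(labels == "favorable")
  out <- c()
  for (g in pathways) {
    g <- mergeDuplicateReactions(g)
    if (nEdges(g) == 0L) next
    rd <- mapExpressionToReactions(expr, g, aggregation)
    if (is.null(rd)) next
    emb <- embedPathway(g)
    ft <- nontrivialFeatures(featureTable(emb, rd$values, offsetsMode))
    if (nrow(featureValues(ft)) == 0L) next
    p <- rowWilcoxon(featureValues(ft)[, c(idx_u, idx_f), drop = FALSE],
                     seq_along(idx_u))
    out[pathwayId(g)] <- min(p)
  }
  out
}
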