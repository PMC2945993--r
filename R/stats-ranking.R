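#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact distribution when the pooled size is at most 20 and there are no
#' ties; otherwise the normal approximation with mid-ranks and tie-corrected
#' variance (no continuity correction). `mode = "exact"` falls back to the
#' approximation in the presence of ties.
#'
#' @param group_a,group_b non-empty numeric vectors.
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`.
#' @return two-sided p-value.
#' @examples
#' wilcoxonRankSum(1:3, 4:6)  # 0.1
#' @export
wilcoxonRankSum <- function(group_a, group_b,
                            mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("both groups must be non-empty")
  ties <- anyDuplicated(c(group_a, group_b)) > 0L
  n <- length(group_a) + length(group_b)
  exact <- switch(mode,
                  auto = n <= 20L && !ties,
                  exact = !ties,
                  normal_approx = FALSE)
  suppressWarnings(
    wilcox.test(group_a, group_b, exact = exact, correct = FALSE)$p.value)
}

# Vectorized tie-corrected normal-approximation rank-sum test over the rows
# of a matrix; agrees with wilcox.test(exact = FALSE, correct = FALSE).
rowWilcoxon <- function(values, idx_a) {
  stopifnot(is.matrix(values))
  n <- ncol(values)
  na <- length(idx_a)
  nb <- n - na
  stopifnot(na >= 1L, nb >= 1L)
  p <- numeric(nrow(values))
  for (k in seq_len(nrow(values))) {
    x <- values[k, ]
    r <- rank(x)
    W <- sum(r[idx_a]) - na * (na + 1) / 2  # Mann-Whitney U
    rl <- rle(sort(x))$lengths
    tie <- sum(rl^3 - rl)
    sigma2 <- na * nb / 12 * ((n + 1) - tie / (n * (n - 1)))
    if (sigma2 <= 0) {
      p[k] <- 1
    } else {
      z <- (W - na * nb / 2) / sqrt(sigma2)
      p[k] <- min(1, 2 * pnorm(-abs(z)))
    }
  }
  p
}

#' Bonferroni adjustment
#'
#' @param p_values p-values in `[0, 1]`.
#' @param m family size; at least `length(p_values)`.
#' @return `pmin(1, p_values * m)`.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  if (m < length(p_values))
    stop("family size m must be at least the number of p-values")
  pmin(1, p_values * m)
}

#' Classify per-reaction regulation
#'
#' Each measured reaction is tested favorable vs unfavorable with a
#' two-sided Wilcoxon rank-sum test at the (uncorrected) level `alpha`;
#' significant reactions are `up` or `down` in the unfavorable group by the
#' sign of the median difference (unfavorable minus favorable). Unmeasured
#' reactions are always `unchanged`.
#'
#' @param reactionMatrix reactions x samples matrix.
#' @param labels factor/character of `favorable`/`unfavorable` per column.
#' @param measured logical per reaction (default all TRUE).
#' @param alpha significance level (default 0.05).
#' @return factor per reaction with levels `up`, `down`, `unchanged`.
#' @export
perReactionRegulation <- function(reactionMatrix, labels, measured = NULL,
                                  alpha = 0.05) {
  stopifnot(is.matrix(reactionMatrix))
  labels <- as.character(labels)
  idx_f <- which(labels == "favorable")
  idx_u <- which(labels == "unfavorable")
  if (length(idx_f) == 0L || length(idx_u) == 0L)
    stop("both prognosis groups must be non-empty")
  if (is.null(measured)) measured <- rep(TRUE, nrow(reactionMatrix))
  sub <- reactionMatrix[, c(idx_u, idx_f), drop = FALSE]
  p <- rowWilcoxon(sub, seq_along(idx_u))
  md <- apply(reactionMatrix[, idx_u, drop = FALSE], 1L, median) -
    apply(reactionMatrix[, idx_f, drop = FALSE], 1L, median)
  cls <- rep("unchanged", nrow(reactionMatrix))
  sig <- measured & p <= alpha & md != 0
  cls[sig & md > 0] <- "up"
  cls[sig & md < 0] <- "down"
  factor(stats::setNames(cls, rownames(reactionMatrix)),
         levels = c("up", "down", "unchanged"))
}

#' Rank pathways by their best discriminating feature
#'
#' For each pathway the smallest raw Wilcoxon p-value over its non-trivial
#' wavelet features is selected and Bonferroni-adjusted over the declared
#' family (by default all non-trivial features of the whole run; optionally
#' per pathway). A pathway is significant when its adjusted best-feature
#' p-value is at most `alpha` and it has more than `minReactions`
#' significantly differentially regulated reactions (strictly more;
#' duplicate-gene-set reactions were merged upstream so each counts once).
#'
#' @param featureTables named list (by pathway) of non-trivial
#'   [FeatureTable-class] objects over the same samples.
#' @param reactionData named list (by pathway) of
#'   [mapExpressionToReactions()] results.
#' @param labels factor of `favorable`/`unfavorable` per sample column.
#' @param alpha significance level (default 0.05).
#' @param minReactions strict threshold for differentially regulated
#'   reactions (default 3, i.e. at least 4 required).
#' @param familyScope `"global"` or `"per_pathway"` Bonferroni family.
#' @return data.frame, one row per pathway sorted by ascending best-feature
#'   p-value, with columns `rank`, `pathway`, `n_diff_regulated`,
#'   `n_reactions`, `n_down`, `n_up`, `p_raw`, `p_adjusted`, `significant`
#'   and the best feature's descriptor columns.
#' @export
rankPathways <- function(featureTables, reactionData, labels, alpha = 0.05,
                         minReactions = 3L,
                         familyScope = c("global", "per_pathway")) {
  familyScope <- match.arg(familyScope)
  stopifnot(length(featureTables) >= 1L,
            identical(names(featureTables), names(reactionData)))
  labels <- as.character(labels)
  idx_u <- which(labels == "unfavorable")
  idx_f <- which(labels == "favorable")
  if (length(idx_u) < 2L || length(idx_f) < 2L)
    stop("need at least 2 samples per prognosis group")
  m_global <- sum(vapply(featureTables,
                         function(ft) nrow(featureValues(ft)), integer(1)))
  rows <- list()
  for (pw in names(featureTables)) {
    ft <- featureTables[[pw]]
    nfeat <- nrow(featureValues(ft))
    if (nfeat == 0L) next
    sub <- featureValues(ft)[, c(idx_u, idx_f), drop = FALSE]
    p <- rowWilcoxon(sub, seq_along(idx_u))
    best <- which.min(p)
    m <- if (familyScope == "global") m_global else nfeat
    rd <- reactionData[[pw]]
    cls <- perReactionRegulation(rd$values, labels, rd$measured, alpha)
    n_up <- sum(cls == "up")
    n_down <- sum(cls == "down")
    bestd <- featureDescriptors(ft)[best, , drop = FALSE]
    rows[[pw]] <- data.frame(
      pathway = pw,
      n_diff_regulated = n_up + n_down,
      n_reactions = nrow(rd$values),
      n_down = n_down, n_up = n_up,
      p_raw = p[best],
      p_adjusted = bonferroni(p[best], m),
      best_level = bestd$level, best_block_row = bestd$block_row,
      best_block_col = bestd$block_col, best_off_y = bestd$off_y,
      best_off_x = bestd$off_x, best_coeff_type = bestd$coeff_type,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$p_raw), , drop = FALSE]
  out$significant <- out$p_adjusted <= alpha &
    out$n_diff_regulated > minReactions
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Fisher's exact pathway enrichment
#'
#' Two-sided Fisher's exact test on the 2x2 table crossing pathway
#' membership with differential expression. The DE set is defined upstream,
#' conventionally by per-gene Wilcoxon tests at p <= 0.05.
#'
#' @param de_genes character set of differentially expressed genes (subset
#'   of `universe`).
#' @param pathway_genes character set of the pathway's genes (subset of
#'   `universe`).
#' @param universe character set of all measured genes; non-empty.
#' @return two-sided p-value.
#' @export
fisherEnrichment <- function(de_genes, pathway_genes, universe) {
  if (length(universe) == 0L) stop("empty gene universe")
  de_genes <- intersect(de_genes, universe)
  pathway_genes <- intersect(pathway_genes, universe)
  a <- length(intersect(de_genes, pathway_genes))
  b <- length(setdiff(pathway_genes, de_genes))
  c_ <- length(setdiff(de_genes, pathway_genes))
  d <- length(universe) - a - b - c_
  fisher.test(matrix(c(a, b, c_, d), 2L, 2L))$p.value
}

#' Permutation-based rank-enrichment baseline
#'
#' A simplified weighted running-sum enrichment score over genes ranked by
#' the difference of group means, with a sample-label permutation null and
#' a two-sided p-value. Deterministic for a given seed.
#'
#' @param expr genes x samples matrix with rownames.
#' @param labels factor of `favorable`/`unfavorable` per column.
#' @param pathway_genes character vector of the gene set.
#' @param n_permutations at least 100 (default 1000).
#' @param seed integer seed.
#' @param weight exponent on the ranking statistic (default 1).
#' @return list with `es` (observed enrichment score) and `p` (two-sided
#'   permutation p-value).
#' @export
rankEnrichmentBaseline <- function(expr, labels, pathway_genes,
                                   n_permutations = 1000L, seed = 1L,
                                   weight = 1) {
  stopifnot(n_permutations >= 100L)
  labels <- as.character(labels)
  idx_u <- which(labels == "unfavorable")
  idx_f <- which(labels == "favorable")
  in_set <- rownames(expr) %in% pathway_genes
  if (!any(in_set)) stop("no pathway gene measured")
  score <- function(iu, if_) {
    stat <- rowMeans(expr[, iu, drop = FALSE]) -
      rowMeans(expr[, if_, drop = FALSE])
    ord <- order(stat, decreasing = TRUE)
    s <- abs(stat[ord])^weight
    hit <- in_set[ord]
    p_hit <- cumsum(ifelse(hit, s, 0)) / sum(s[hit])
    p_miss <- cumsum(!hit) / sum(!hit)
    dev <- p_hit - p_miss
    dev[which.max(abs(dev))]
  }
  es <- score(idx_u, idx_f)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  n <- length(c(idx_u, idx_f))
  pool <- c(idx_u, idx_f)
  null_es <- vapply(seq_len(n_permutations), function(b) {
    perm <- sample(pool)
    score(perm[seq_along(idx_u)], perm[-seq_along(idx_u)])
  }, numeric(1))
  list(es = es,
       p = (1 + sum(abs(null_es) >= abs(es))) / (n_permutations + 1))
}
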