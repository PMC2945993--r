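#' Run configuration
#'
#' Collects the tunable thresholds of the pipeline: significance level,
#' strict minimum of differentially regulated reactions, grid slack, solver
#' choice and time limit, tiling offsets, gene-to-reaction aggregation,
#' Bonferroni family scope and the master seed. All values are recorded in
#' output provenance headers.
#'
#' @param alpha significance level in (0, 1).
#' @param minReactions strict lower bound on differentially regulated
#'   reactions for significance (default 3, i.e. more than 3 required).
#' @param gridSlack add one row/column of grid slack.
#' @param solver `"auto"`, `"exact"` or `"heuristic"`.
#' @param timeLimit exact-solver seconds per pathway.
#' @param offsetsMode `"all4"` or `"single"`.
#' @param aggregation `"mean"`, `"median"` or `"max"`.
#' @param familyScope `"global"` or `"per_pathway"`.
#' @param seed master seed; all randomness flows from it.
#' @return named list of class `"RunConfig"`.
#' @export
runConfig <- function(alpha = 0.05, minReactions = 3L, gridSlack = FALSE,
                      solver = c("auto", "exact", "heuristic"),
                      timeLimit = 300, offsetsMode = c("all4", "single"),
                      aggregation = c("mean", "median", "max"),
                      familyScope = c("global", "per_pathway"), seed = 1L) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(alpha = alpha, minReactions = as.integer(minReactions),
                 gridSlack = isTRUE(gridSlack),
                 solver = match.arg(solver), timeLimit = timeLimit,
                 offsetsMode = match.arg(offsetsMode),
                 aggregation = match.arg(aggregation),
                 familyScope = match.arg(familyScope),
                 seed = as.integer(seed)),
            class = "RunConfig")
}

#' Embed every retained pathway of a pathway file
#'
#' Reads the pathway TSV, merges duplicate-gene-set reactions, discards
#' pathways without any connected reaction, embeds the rest and (optionally)
#' serializes the embeddings to JSON. Objective and gap are reported per
#' pathway via message().
#'
#' @param pathways path to a pathway TSV or a list of
#'   [PathwayGraph-class] objects.
#' @param config a [runConfig()].
#' @param outFile optional JSON output path.
#' @param verbose log per-pathway progress.
#' @return named list with `graphs` (merged, filtered) and `embeddings`.
#' @export
runEmbedding <- function(pathways, config = runConfig(), outFile = NULL,
                         verbose = FALSE) {
  if (is.character(pathways)) pathways <- readPathwayTsv(pathways)
  if (length(pathways) == 0L) {
    warning("no pathways in input")
    if (!is.null(outFile)) writeEmbeddingJson(list(), outFile)
    return(list(graphs = list(), embeddings = list()))
  }
  graphs <- filterPathways(lapply(pathways, mergeDuplicateReactions))
  embeddings <- list()
  for (g in graphs) {
    method <- if (config$solver == "auto") "auto" else config$solver
    e <- embedPathway(g, method = method, slack = config$gridSlack,
                      seed = config$seed, timeLimit = config$timeLimit)
    if (verbose)
      message("embedded ", pathwayId(g), ": objective ", objectiveValue(e),
              ", gap ", signif(optimalityGap(e), 4))
    embeddings[[pathwayId(g)]] <- e
  }
  names(graphs) <- vapply(graphs, pathwayId, character(1))
  if (!is.null(outFile)) writeEmbeddingJson(embeddings, outFile)
  list(graphs = graphs, embeddings = embeddings)
}

#' Rank pathways from expression and clinical data
#'
#' The full analysis: label samples by prognosis, aggregate genes to
#' reactions, paint each sample onto the embedded grids, compute the Haar
#' feature cascade, test every non-trivial feature favorable vs unfavorable
#' and rank pathways by their best feature (Bonferroni-corrected), with
#' per-reaction regulation counts.
#'
#' @param embedded result of [runEmbedding()] (list with `graphs` and
#'   `embeddings`).
#' @param expr genes x samples matrix or expression TSV path.
#' @param clinical clinical data.frame or TSV path.
#' @param config a [runConfig()].
#' @param resultsFile,featuresFile optional output TSV paths.
#' @return list with `results` (ranked data.frame), `features` (combined
#'   non-trivial [FeatureTable-class]), `labels` and `familySize`.
#' @export
runRanking <- function(embedded, expr, clinical, config = runConfig(),
                       resultsFile = NULL, featuresFile = NULL) {
  if (is.character(expr)) expr <- readExpressionTsv(expr)
  if (is.character(clinical)) clinical <- readClinicalTsv(clinical)
  labels <- labelSamples(clinical)
  keep <- names(labels)[labels != "discarded"]
  keep <- intersect(colnames(expr), keep)
  if (sum(labels[keep] == "favorable") < 2L ||
      sum(labels[keep] == "unfavorable") < 2L)
    stop("need at least 2 samples in each prognosis group")
  expr <- expr[, keep, drop = FALSE]
  labels <- labels[keep]
  fts <- list()
  rds <- list()
  for (pw in names(embedded$graphs)) {
    g <- embedded$graphs[[pw]]
    rd <- mapExpressionToReactions(expr, g, config$aggregation)
    if (is.null(rd)) next
    ft <- nontrivialFeatures(
      featureTable(embedded$embeddings[[pw]], rd$values,
                   config$offsetsMode))
    fts[[pw]] <- ft
    rds[[pw]] <- rd
  }
  if (length(fts) == 0L) stop("no pathway with measured genes")
  results <- rankPathways(fts, rds, labels, alpha = config$alpha,
                          minReactions = config$minReactions,
                          familyScope = config$familyScope)
  m <- sum(vapply(fts, function(ft) nrow(featureValues(ft)), integer(1)))
  if (!is.null(resultsFile))
    writeResultsTsv(results, resultsFile,
                    config = c(config, familySize = m))
  allft <- bindFeatureTables(fts)
  if (!is.null(featuresFile)) writeFeatureTsv(allft, featuresFile)
  list(results = results, features = allft, labels = labels,
       familySize = m)
}

#' Write a simulated dataset to the pipeline's TSV dialects
#'
#' @param design a [simulationDesign()].
#' @param dir output directory (created if needed).
#' @return invisible list of the file paths plus the truth record.
#' @export
runSimulate <- function(design, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pws <- generatePathways(design)
  sim <- generateExpression(design, pws)
  paths <- list(pathways = file.path(dir, "pathways.tsv"),
                expression = file.path(dir, "expression.tsv"),
                clinical = file.path(dir, "clinical.tsv"))
  writePathwayTsv(pws, paths$pathways)
  writeExpressionTsv(sim$expr, paths$expression)
  writeClinicalTsv(sim$clinical, paths$clinical)
  invisible(c(paths, list(truth = sim$truth)))
}

#' Run the sensitivity benchmark and write its ROC table
#'
#' @param design a [simulationDesign()] with a planted pattern.
#' @param methods,n_replicates,seed passed to [benchmarkSensitivity()].
#' @param outFile optional TSV path for the ROC table.
#' @return the [benchmarkSensitivity()] result.
#' @export
runBenchmark <- function(design, methods = c("gridwave", "fisher"),
                         n_replicates = 50L, seed = 1L, outFile = NULL) {
  bench <- benchmarkSensitivity(design, methods = methods,
                                n_replicates = n_replicates, seed = seed)
  if (!is.null(outFile))
    write.table(bench$roc, outFile, sep = "\t", quote = FALSE,
                row.names = FALSE)
  bench
}
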