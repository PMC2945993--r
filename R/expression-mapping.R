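#' Label samples by prognosis
#'
#' Samples with time to recurrence above 5 years are `favorable`; samples
#' with time to recurrence below 3 years and an event of metastasis are
#' `unfavorable`; everything else (including the exact boundaries t = 3 and
#' t = 5, recurrence below 3 years without metastasis, and rows with missing
#' fields) is `discarded`.
#'
#' @param clinical data.frame with columns `sample_id`,
#'   `time_recurrence_years` (non-negative) and `metastasis` (0/1 or
#'   logical).
#' @return factor with levels `favorable`, `unfavorable`, `discarded`, named
#'   by sample id; the three classes partition the input rows.
#' @examples
#' labelSamples(data.frame(sample_id = c("a", "b", "c"),
#'                         time_recurrence_years = c(6.2, 2.0, 4.0),
#'                         metastasis = c(0, 1, 1)))
#' @export
labelSamples <- function(clinical) {
  need <- c("sample_id", "time_recurrence_years", "metastasis")
  if (!all(need %in% colnames(clinical)))
    stop("clinical table must have columns: ", paste(need, collapse = ", "))
  t <- as.numeric(clinical$time_recurrence_years)
  met <- as.logical(clinical$metastasis)
  bad <- is.na(t) | is.na(met)
  if (any(bad))
    warning(sum(bad), " sample(s) with missing clinical fields discarded")
  lab <- rep("discarded", nrow(clinical))
  lab[!bad & t > 5] <- "favorable"
  lab[!bad & t < 3 & met] <- "unfavorable"
  factor(stats::setNames(lab, as.character(clinical$sample_id)),
         levels = c("favorable", "unfavorable", "discarded"))
}

#' Aggregate gene expression to reactions
#'
#' Each reaction's value in a sample is the aggregate (mean by default) of
#' its annotated genes' values. Reactions with no measured gene are given
#' the neutral value 0 on the log-ratio scale and flagged unmeasured; the
#' flag, not the value, decides feature triviality downstream.
#'
#' @param expr numeric matrix, genes x samples, rownames = gene ids.
#' @param graph a [PathwayGraph-class].
#' @param aggregation `"mean"`, `"median"` or `"max"`.
#' @return list with `values` (reactions x samples matrix, rownames =
#'   reaction ids) and `measured` (named logical vector); `NULL` with a
#'   warning when no gene of the pathway is measured.
#' @export
mapExpressionToReactions <- function(expr, graph,
                                     aggregation = c("mean", "median",
                                                     "max")) {
  aggregation <- match.arg(aggregation)
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  if (anyDuplicated(rownames(expr))) stop("duplicate gene ids in expression")
  if (anyDuplicated(colnames(expr))) stop("duplicate sample ids in expression")
  agg <- switch(aggregation, mean = colMeans,
                median = function(m) apply(m, 2L, median),
                max = function(m) apply(m, 2L, max))
  ids <- reactionIds(graph)
  out <- matrix(0, length(ids), ncol(expr),
                dimnames = list(ids, colnames(expr)))
  measured <- stats::setNames(logical(length(ids)), ids)
  for (k in seq_along(ids)) {
    genes <- intersect(graph@reactions[[k]]$gene_ids, rownames(expr))
    if (length(genes) == 0L) next
    vals <- expr[genes, , drop = FALSE]
    vals <- vals[rowSums(is.na(vals)) == 0L, , drop = FALSE]
    if (nrow(vals) == 0L) next
    out[k, ] <- agg(vals)
    measured[k] <- TRUE
  }
  if (!any(measured)) {
    warning("pathway '", pathwayId(graph),
            "' has no measured gene; skipped")
    return(NULL)
  }
  list(values = out, measured = measured)
}

#' Paint one sample's reaction values onto the embedded grid
#'
#' Builds the side x side image whose cell (i, j) carries the value of the
#' reaction placed there and 0 elsewhere; the occupied mask marks
#' reaction-bearing cells (measured or not).
#'
#' @param embedding a [GridEmbedding-class].
#' @param values named numeric vector of reaction values for one sample;
#'   names must match the embedding's placed reactions exactly.
#' @param sampleId sample identifier carried on the image.
#' @return a [ReactionImage-class].
#' @export
paintReactionImage <- function(embedding, values, sampleId = "sample") {
  pl <- placement(embedding)
  if (is.null(names(values)) || !setequal(names(values), rownames(pl)) ||
      length(values) != nrow(pl))
    stop("values must be named by exactly the placed reactions")
  s <- embedding@side
  img <- matrix(0, s, s)
  occ <- matrix(FALSE, s, s)
  for (r in rownames(pl)) {
    i <- pl[r, 1L] + 1L
    j <- pl[r, 2L] + 1L
    img[i, j] <- values[[r]]
    occ[i, j] <- TRUE
  }
  new("ReactionImage", pathwayId = embedding@pathwayId,
      sampleId = as.character(sampleId), values = img, occupied = occ)
}
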