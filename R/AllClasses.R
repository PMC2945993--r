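#' Reaction record
#'
#' A reaction is described by its identifier, the genes encoding its
#' enzyme(s), EC numbers, and the metabolites it consumes (substrates) and
#' produces (products). Reactions are plain lists validated by this
#' constructor; they live inside a [PathwayGraph-class].
#'
#' @param reaction_id character scalar, unique within a pathway.
#' @param gene_ids character vector of gene identifiers (may be empty).
#' @param ec_numbers character vector of EC numbers (may be empty).
#' @param substrates,products character vectors of metabolite identifiers;
#'   their union must be non-empty.
#' @return a named list of class `"Reaction"`.
#' @examples
#' reaction("R1", gene_ids = "g1", substrates = "M0", products = "M1")
#' @export
reaction <- function(reaction_id, gene_ids = character(),
                     ec_numbers = character(), substrates = character(),
                     products = character()) {
  stopifnot(is.character(reaction_id), length(reaction_id) == 1L,
            nzchar(reaction_id))
  if (length(substrates) == 0L && length(products) == 0L)
    stop("reaction '", reaction_id,
         "' has neither substrates nor products")
  structure(list(reaction_id = reaction_id,
                 gene_ids = sort(unique(as.character(gene_ids))),
                 ec_numbers = sort(unique(as.character(ec_numbers))),
                 substrates = sort(unique(as.character(substrates))),
                 products = sort(unique(as.character(products)))),
            class = "Reaction")
}

#' PathwayGraph: a reaction-neighborhood graph
#'
#' Reactions are nodes; two reactions are adjacent when a metabolite is the
#' product of one and the substrate of the other. The symmetric, zero-diagonal
#' adjacency matrix is indexed by reaction identifiers.
#'
#' @slot pathwayId single pathway identifier.
#' @slot reactions list of [reaction()] records, in node order.
#' @slot adjacency symmetric 0/1 integer matrix with zero diagonal, dimnames
#'   equal to the reaction identifiers.
#' @slot mergeMap named list recording, after
#'   [mergeDuplicateReactions()], which original reactions each node stands
#'   for (empty before merging).
#' @exportClass PathwayGraph
setClass("PathwayGraph",
         representation(pathwayId = "character", reactions = "list",
                        adjacency = "matrix", mergeMap = "list"))

setValidity("PathwayGraph", function(object) {
  ids <- vapply(object@reactions, `[[`, character(1), "reaction_id")
  M <- object@adjacency
  msg <- character()
  if (length(object@pathwayId) != 1L) msg <- c(msg, "pathwayId must be scalar")
  if (anyDuplicated(ids)) msg <- c(msg, "duplicate reaction ids")
  if (nrow(M) != length(ids) || ncol(M) != length(ids))
    msg <- c(msg, "adjacency dimensions do not match reactions")
  else {
    if (!identical(rownames(M), ids) || !identical(colnames(M), ids))
      msg <- c(msg, "adjacency dimnames must equal reaction ids")
    if (!isTRUE(all(M %in% c(0L, 1L)))) msg <- c(msg, "adjacency must be 0/1")
    if (!isTRUE(all(M == t(M)))) msg <- c(msg, "adjacency must be symmetric")
    if (length(ids) && any(diag(M) != 0L))
      msg <- c(msg, "adjacency diagonal must be zero")
  }
  if (length(msg)) msg else TRUE
})

#' GridEmbedding: placement of reactions on a square lattice
#'
#' @slot pathwayId pathway identifier.
#' @slot side grid side length s; cells are (i, j) with 0 <= i, j < s.
#' @slot placement integer matrix (nodes x 2, columns `i`, `j`, rownames =
#'   reaction ids) with 0-based row/column coordinates; injective.
#' @slot objective total Manhattan length over adjacent reaction pairs.
#' @slot provenOptimal TRUE when the solver proved global optimality.
#' @slot gap ratio lower bound / objective in (0, 1]; 1 when proven optimal.
#' @slot method solver used: "exact", "bruteforce" or "heuristic".
#' @exportClass GridEmbedding
setClass("GridEmbedding",
         representation(pathwayId = "character", side = "integer",
                        placement = "matrix", objective = "numeric",
                        provenOptimal = "logical", gap = "numeric",
                        method = "character"))

setValidity("GridEmbedding", function(object) {
  p <- object@placement
  s <- object@side
  msg <- character()
  if (ncol(p) != 2L) msg <- c(msg, "placement must have two columns")
  if (is.null(rownames(p))) msg <- c(msg, "placement must have rownames")
  if (any(p < 0L) || any(p >= s)) msg <- c(msg, "coordinates outside grid")
  if (anyDuplicated(p[, 1L] * s + p[, 2L]))
    msg <- c(msg, "placement must be injective")
  if (!(object@gap > 0 && object@gap <= 1 + 1e-9))
    msg <- c(msg, "gap must lie in (0, 1]")
  if (object@provenOptimal && abs(object@gap - 1) > 1e-9)
    msg <- c(msg, "gap must be 1 when proven optimal")
  if (length(msg)) msg else TRUE
})

#' ReactionImage: one sample's expression painted onto the grid
#'
#' @slot pathwayId pathway identifier.
#' @slot sampleId sample identifier.
#' @slot values side x side numeric matrix; cells without a reaction are 0.
#' @slot occupied logical matrix marking reaction-bearing cells.
#' @exportClass ReactionImage
setClass("ReactionImage",
         representation(pathwayId = "character", sampleId = "character",
                        values = "matrix", occupied = "matrix"))

setValidity("ReactionImage", function(object) {
  if (!identical(dim(object@values), dim(object@occupied)))
    return("values and occupied must have identical dimensions")
  if (any(object@values[!object@occupied] != 0))
    return("cells outside the occupied mask must be exactly 0")
  TRUE
})

#' FeatureTable: wavelet features across samples
#'
#' One row per feature. A feature is identified by pathway, cascade level,
#' 2x2 block position at that level, tiling offset and coefficient type
#' (1 = mean of means, 2 = difference of row means, 3 = mean of row
#' differences, 4 = difference of row differences).
#'
#' @slot descriptors data.frame with columns `pathway`, `level`, `block_row`,
#'   `block_col`, `off_y`, `off_x`, `coeff_type`, `support_size`.
#' @slot values features x samples numeric matrix.
#' @slot support list (one element per feature) of the reaction ids inside
#'   the feature's spatial footprint.
#' @exportClass FeatureTable
setClass("FeatureTable",
         representation(descriptors = "data.frame", values = "matrix",
                        support = "list"))

setValidity("FeatureTable", function(object) {
  msg <- character()
  need <- c("pathway", "level", "block_row", "block_col", "off_y", "off_x",
            "coeff_type", "support_size")
  if (!all(need %in% colnames(object@descriptors)))
    msg <- c(msg, "descriptors missing required columns")
  if (nrow(object@descriptors) != nrow(object@values))
    msg <- c(msg, "one descriptor row per feature row required")
  if (length(object@support) != nrow(object@values))
    msg <- c(msg, "one support set per feature required")
  if (nrow(object@descriptors) &&
      !all(object@descriptors$coeff_type %in% 1:4))
    msg <- c(msg, "coeff_type must be in 1..4")
  if (length(msg)) msg else TRUE
})

# ---- generics --------------------------------------------------------------

#' @rdname PathwayGraph-class
#' @param object,x a `PathwayGraph`
#' @export
setGeneric("pathwayId", function(object) standardGeneric("pathwayId"))
#' @rdname PathwayGraph-class
#' @export
setGeneric("reactions", function(object) standardGeneric("reactions"))
#' @rdname PathwayGraph-class
#' @export
setGeneric("reactionIds", function(object) standardGeneric("reactionIds"))
#' @rdname PathwayGraph-class
#' @export
setGeneric("adjacency", function(object) standardGeneric("adjacency"))
#' @rdname PathwayGraph-class
#' @export
setGeneric("nReactions", function(object) standardGeneric("nReactions"))
#' @rdname PathwayGraph-class
#' @export
setGeneric("nEdges", function(object) standardGeneric("nEdges"))
#' @rdname GridEmbedding-class
#' @param object a `GridEmbedding`
#' @export
setGeneric("placement", function(object) standardGeneric("placement"))
#' @rdname GridEmbedding-class
#' @export
setGeneric("objectiveValue", function(object) standardGeneric("objectiveValue"))
#' @rdname GridEmbedding-class
#' @export
setGeneric("isProvenOptimal",
           function(object) standardGeneric("isProvenOptimal"))
#' @rdname GridEmbedding-class
#' @export
setGeneric("optimalityGap", function(object) standardGeneric("optimalityGap"))
#' @rdname FeatureTable-class
#' @param object a `FeatureTable`
#' @export
setGeneric("featureDescriptors",
           function(object) standardGeneric("featureDescriptors"))
#' @rdname FeatureTable-class
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))
#' @rdname FeatureTable-class
#' @export
setGeneric("featureSupport",
           function(object) standardGeneric("featureSupport"))

# ---- accessors -------------------------------------------------------------

#' @rdname PathwayGraph-class
setMethod("pathwayId", "PathwayGraph", function(object) object@pathwayId)
#' @rdname GridEmbedding-class
setMethod("pathwayId", "GridEmbedding", function(object) object@pathwayId)
#' @rdname PathwayGraph-class
setMethod("reactions", "PathwayGraph", function(object) object@reactions)
#' @rdname PathwayGraph-class
setMethod("reactionIds", "PathwayGraph", function(object)
  vapply(object@reactions, `[[`, character(1), "reaction_id"))
#' @rdname PathwayGraph-class
setMethod("adjacency", "PathwayGraph", function(object) object@adjacency)
#' @rdname PathwayGraph-class
setMethod("nReactions", "PathwayGraph",
          function(object) length(object@reactions))
#' @rdname PathwayGraph-class
setMethod("nEdges", "PathwayGraph",
          function(object) sum(object@adjacency) %/% 2L)
#' @rdname GridEmbedding-class
setMethod("placement", "GridEmbedding", function(object) object@placement)
#' @rdname GridEmbedding-class
setMethod("objectiveValue", "GridEmbedding",
          function(object) object@objective)
#' @rdname GridEmbedding-class
setMethod("isProvenOptimal", "GridEmbedding",
          function(object) object@provenOptimal)
#' @rdname GridEmbedding-class
setMethod("optimalityGap", "GridEmbedding", function(object) object@gap)
#' @rdname FeatureTable-class
setMethod("featureDescriptors", "FeatureTable",
          function(object) object@descriptors)
#' @rdname FeatureTable-class
setMethod("featureValues", "FeatureTable", function(object) object@values)
#' @rdname FeatureTable-class
setMethod("featureSupport", "FeatureTable", function(object) object@support)

# ---- show ------------------------------------------------------------------

setMethod("show", "PathwayGraph", function(object) {
  cat("PathwayGraph '", object@pathwayId, "': ", nReactions(object),
      " reactions, ", nEdges(object), " edges",
      if (length(object@mergeMap)) " (duplicate gene sets merged)" else "",
      "\n", sep = "")
})

setMethod("show", "GridEmbedding", function(object) {
  cat("GridEmbedding '", object@pathwayId, "': ", nrow(object@placement),
      " reactions on a ", object@side, "x", object@side,
      " grid\n  objective = ", object@objective,
      ", gap = ", signif(object@gap, 4),
      if (object@provenOptimal) " (proven optimal)" else "",
      "  [", object@method, "]\n", sep = "")
})

setMethod("show", "ReactionImage", function(object) {
  cat("ReactionImage '", object@pathwayId, "' / sample '", object@sampleId,
      "': ", nrow(object@values), "x", ncol(object@values), " grid, ",
      sum(object@occupied), " occupied cells\n", sep = "")
})

setMethod("show", "FeatureTable", function(object) {
  cat("FeatureTable: ", nrow(object@values), " features x ",
      ncol(object@values), " samples (",
      length(unique(object@descriptors$pathway)), " pathway(s))\n", sep = "")
})
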