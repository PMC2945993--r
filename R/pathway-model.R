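#' Build a reaction-neighborhood graph
#'
#' Two reactions are neighbors when some metabolite is the product of one and
#' the substrate of the other. With `treatReversible = TRUE` (the default)
#' the rule is applied in both directions, so the edge exists whenever either
#' reaction produces a metabolite the other consumes; with `FALSE` only the
#' listed substrate/product orientation in input node order is used before
#' symmetrizing. Metabolites in `excludeMetabolites` (e.g. currency compounds
#' such as H2O or ATP) are ignored when computing neighborhoods; the list is
#' empty by default.
#'
#' @param pathway_id pathway identifier.
#' @param reactions list of [reaction()] records with unique ids.
#' @param treatReversible logical; apply the neighbor rule in both directions.
#' @param excludeMetabolites character vector of metabolite ids to ignore.
#' @return a [PathwayGraph-class].
#' @examples
#' r1 <- reaction("R1", substrates = "M0", products = "M1")
#' r2 <- reaction("R2", substrates = "M1", products = "M2")
#' g <- buildPathwayGraph("toy", list(r1, r2))
#' adjacency(g)
#' @export
buildPathwayGraph <- function(pathway_id, reactions,
                              treatReversible = TRUE,
                              excludeMetabolites = character()) {
  stopifnot(is.list(reactions), length(reactions) >= 1L)
  ids <- vapply(reactions, `[[`, character(1), "reaction_id")
  if (anyDuplicated(ids))
    stop("duplicate reaction_id in pathway '", pathway_id, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  n <- length(reactions)
  M <- matrix(0L, n, n, dimnames = list(ids, ids))
  subs <- lapply(reactions, function(r) setdiff(r$substrates,
                                                excludeMetabolites))
  prods <- lapply(reactions, function(r) setdiff(r$products,
                                                 excludeMetabolites))
  if (n > 1L) {
    for (a in seq_len(n - 1L)) {
      for (b in (a + 1L):n) {
        hit <- length(intersect(prods[[a]], subs[[b]])) > 0L
        if (treatReversible)
          hit <- hit || length(intersect(prods[[b]], subs[[a]])) > 0L
        if (hit) M[a, b] <- M[b, a] <- 1L
      }
    }
  }
  new("PathwayGraph", pathwayId = as.character(pathway_id),
      reactions = reactions, adjacency = M, mergeMap = list())
}

#' Merge reactions carried by identical gene sets
#'
#' Reactions annotated with exactly the same non-empty set of genes are
#' counted as one reaction: they collapse to a single node whose edges are
#' the union of the members' edges (self-loops dropped). Reactions with empty
#' gene sets are never merged. The merge map (merged node id -> original
#' member ids) is retained on the returned graph for reporting.
#'
#' @param graph a [PathwayGraph-class] with gene annotations.
#' @return a [PathwayGraph-class]; idempotent.
#' @export
mergeDuplicateReactions <- function(graph) {
  stopifnot(is(graph, "PathwayGraph"))
  rs <- graph@reactions
  keys <- vapply(rs, function(r)
    if (length(r$gene_ids)) paste(r$gene_ids, collapse = "\r") else
      paste0("\x01", r$reaction_id), character(1))
  groups <- split(seq_along(rs), keys)
  if (all(lengths(groups) == 1L)) return(graph)
  reps <- sort(vapply(groups, `[`, integer(1), 1L))  # keep input order
  ids <- vapply(rs, `[[`, character(1), "reaction_id")
  M <- graph@adjacency
  newM <- matrix(0L, length(reps), length(reps),
                 dimnames = list(ids[reps], ids[reps]))
  mergeMap <- list()
  member_of <- integer(length(rs))
  for (g in groups) member_of[g] <- min(g)
  repIndex <- match(reps, reps)  # identity; map original rep -> position
  posOf <- match(member_of, reps)
  for (a in seq_along(rs)) {
    for (b in seq_along(rs)) {
      if (M[a, b] == 1L) {
        pa <- posOf[a]; pb <- posOf[b]
        if (pa != pb) newM[pa, pb] <- newM[pb, pa] <- 1L
      }
    }
  }
  newReactions <- vector("list", length(reps))
  for (k in seq_along(reps)) {
    members <- which(posOf == k)
    r0 <- rs[[reps[k]]]
    newReactions[[k]] <- structure(list(
      reaction_id = r0$reaction_id,
      gene_ids = sort(unique(unlist(lapply(rs[members], `[[`, "gene_ids")))),
      ec_numbers = sort(unique(unlist(lapply(rs[members], `[[`,
                                             "ec_numbers")))),
      substrates = sort(unique(unlist(lapply(rs[members], `[[`,
                                             "substrates")))),
      products = sort(unique(unlist(lapply(rs[members], `[[`, "products"))))),
      class = "Reaction")
    if (length(members) > 1L)
      mergeMap[[r0$reaction_id]] <- ids[members]
  }
  new("PathwayGraph", pathwayId = graph@pathwayId, reactions = newReactions,
      adjacency = newM, mergeMap = mergeMap)
}

#' Discard pathways without any connected reaction
#'
#' Pathways whose graph has no edge carry no neighborhood information and are
#' removed; input order of the retained pathways is preserved.
#'
#' @param pathways list of [PathwayGraph-class] objects.
#' @return the filtered list.
#' @export
filterPathways <- function(pathways) {
  stopifnot(is.list(pathways))
  pathways[vapply(pathways, function(g) nEdges(g) > 0L, logical(1))]
}

# all gene ids annotated on a pathway
pathwayGenes <- function(graph)
  sort(unique(unlist(lapply(graph@reactions, `[[`, "gene_ids"))))
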