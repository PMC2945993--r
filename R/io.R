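#' Read pathway definitions from the link-table TSV dialect
#'
#' One row per reaction-metabolite link with header columns `pathway_id`,
#' `reaction_id`, `role` (`substrate` or `product`), `metabolite_id`,
#' `gene_ids` (`;`-separated, may be empty) and `ec_numbers`
#' (`;`-separated, may be empty). Returns one [PathwayGraph-class] per
#' pathway, in file order; no filtering is applied.
#'
#' @param file path to a UTF-8 TSV file with a header row.
#' @param treatReversible,excludeMetabolites passed to
#'   [buildPathwayGraph()].
#' @return named list of [PathwayGraph-class] objects.
#' @export
readPathwayTsv <- function(file, treatReversible = TRUE,
                           excludeMetabolites = character()) {
  df <- read.delim(file, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("pathway_id", "reaction_id", "role", "metabolite_id",
            "gene_ids", "ec_numbers")
  if (!all(need %in% colnames(df)))
    stop("pathway TSV must have columns: ", paste(need, collapse = ", "))
  bad <- which(!df$role %in% c("substrate", "product"))
  if (length(bad))
    stop("invalid role at line ", bad[1L] + 1L, " of ", file,
         " (expected 'substrate' or 'product')")
  splitIds <- function(x) {
    x <- as.character(x)
    if (is.na(x) || !nzchar(x)) character() else strsplit(x, ";",
                                                          fixed = TRUE)[[1L]]
  }
  out <- list()
  for (pw in unique(df$pathway_id)) {
    sub <- df[df$pathway_id == pw, , drop = FALSE]
    rs <- lapply(unique(sub$reaction_id), function(rid) {
      rsub <- sub[sub$reaction_id == rid, , drop = FALSE]
      reaction(rid,
               gene_ids = unique(unlist(lapply(rsub$gene_ids, splitIds))),
               ec_numbers = unique(unlist(lapply(rsub$ec_numbers,
                                                 splitIds))),
               substrates = unique(rsub$metabolite_id[rsub$role ==
                                                        "substrate"]),
               products = unique(rsub$metabolite_id[rsub$role ==
                                                      "product"]))
    })
    out[[pw]] <- buildPathwayGraph(pw, rs, treatReversible,
                                   excludeMetabolites)
  }
  out
}

#' Write pathways to the link-table TSV dialect
#'
#' @param pathways list of [PathwayGraph-class] objects.
#' @param file output path.
#' @export
writePathwayTsv <- function(pathways, file) {
  rows <- list()
  for (g in pathways) {
    for (r in reactions(g)) {
      genes <- paste(r$gene_ids, collapse = ";")
      ecs <- paste(r$ec_numbers, collapse = ";")
      for (m in r$substrates)
        rows[[length(rows) + 1L]] <-
          data.frame(pathway_id = pathwayId(g), reaction_id = r$reaction_id,
                     role = "substrate", metabolite_id = m,
                     gene_ids = genes, ec_numbers = ecs)
      for (m in r$products)
        rows[[length(rows) + 1L]] <-
          data.frame(pathway_id = pathwayId(g), reaction_id = r$reaction_id,
                     role = "product", metabolite_id = m,
                     gene_ids = genes, ec_numbers = ecs)
    }
  }
  write.table(do.call(rbind, rows), file, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(file)
}

#' Read a pathway from a KGML (KEGG XML) file
#'
#' Maps `<reaction>` elements with their `<substrate>`/`<product>` children
#' to [reaction()] records; gene identifiers come from `<entry type="gene">`
#' elements linked through their `reaction` attribute.
#'
#' @param file path to a KGML file.
#' @param treatReversible,excludeMetabolites passed to
#'   [buildPathwayGraph()].
#' @return a [PathwayGraph-class].
#' @export
readKgml <- function(file, treatReversible = TRUE,
                     excludeMetabolites = character()) {
  doc <- xml2::read_xml(file)
  pw <- xml2::xml_attr(doc, "name")
  if (is.na(pw)) pw <- basename(file)
  entries <- xml2::xml_find_all(doc, ".//entry[@type='gene']")
  gene_of <- list()
  for (e in entries) {
    rn <- xml2::xml_attr(e, "reaction")
    if (is.na(rn)) next
    genes <- strsplit(xml2::xml_attr(e, "name"), " +")[[1L]]
    for (r in strsplit(rn, " +")[[1L]])
      gene_of[[r]] <- union(gene_of[[r]], genes)
  }
  rx <- xml2::xml_find_all(doc, ".//reaction")
  rs <- lapply(rx, function(x) {
    rid <- xml2::xml_attr(x, "name")
    reaction(rid,
             gene_ids = if (is.null(gene_of[[rid]])) character()
                        else gene_of[[rid]],
             substrates = xml2::xml_attr(
               xml2::xml_find_all(x, "./substrate"), "name"),
             products = xml2::xml_attr(
               xml2::xml_find_all(x, "./product"), "name"))
  })
  buildPathwayGraph(pw, rs, treatReversible, excludeMetabolites)
}

#' Read an expression matrix TSV
#'
#' First column = gene id, remaining columns = samples, header row
#' required; missing values may be empty or `NA`.
#'
#' @param file path.
#' @return numeric matrix genes x samples.
#' @export
readExpressionTsv <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes)) stop("duplicate gene ids in ", file)
  m <- as.matrix(df[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- genes
  m
}

#' @rdname readExpressionTsv
#' @param expr genes x samples matrix.
#' @export
writeExpressionTsv <- function(expr, file) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read/write the clinical table TSV
#'
#' Columns `sample_id`, `time_recurrence_years`, `metastasis` (0/1).
#'
#' @param file path.
#' @return data.frame.
#' @export
readClinicalTsv <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("sample_id", "time_recurrence_years", "metastasis")
  if (!all(need %in% colnames(df)))
    stop("clinical TSV must have columns: ", paste(need, collapse = ", "))
  df
}

#' @rdname readClinicalTsv
#' @param clinical data.frame.
#' @export
writeClinicalTsv <- function(clinical, file) {
  write.table(clinical, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Serialize embeddings to JSON
#'
#' One record per pathway: pathway_id, side_length, placements (reaction_id
#' with 0-based row `i` and column `j`), objective, proven_optimal, gap.
#'
#' @param embeddings list of [GridEmbedding-class] objects.
#' @param file output path.
#' @export
writeEmbeddingJson <- function(embeddings, file) {
  recs <- lapply(embeddings, function(e) {
    pl <- placement(e)
    list(pathway_id = pathwayId(e), side_length = e@side,
         placements = data.frame(reaction_id = rownames(pl),
                                 i = unname(pl[, 1L]), j = unname(pl[, 2L])),
         objective = objectiveValue(e), proven_optimal = isProvenOptimal(e),
         gap = optimalityGap(e), method = e@method)
  })
  jsonlite::write_json(recs, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' @rdname writeEmbeddingJson
#' @return `readEmbeddingJson`: named list of [GridEmbedding-class].
#' @export
readEmbeddingJson <- function(file) {
  recs <- jsonlite::read_json(file, simplifyVector = FALSE)
  out <- list()
  for (rec in recs) {
    pl <- do.call(rbind, lapply(rec$placements, function(p)
      c(i = as.integer(p$i), j = as.integer(p$j))))
    rownames(pl) <- vapply(rec$placements, function(p)
      as.character(p$reaction_id), character(1))
    out[[rec$pathway_id]] <-
      new("GridEmbedding", pathwayId = as.character(rec$pathway_id),
          side = as.integer(rec$side_length), placement = pl,
          objective = as.numeric(rec$objective),
          provenOptimal = as.logical(rec$proven_optimal),
          gap = as.numeric(rec$gap),
          method = as.character(rec$method))
  }
  out
}

# provenance comment header written on result files
provenanceHeader <- function(config, extra = character()) {
  c("# GridWave results",
    paste0("# generated: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("# ", names(config), " = ",
           vapply(config, function(v) paste(v, collapse = ","),
                  character(1))),
    extra)
}

#' Write the ranked pathway results TSV
#'
#' Mirrors the ranked-table shape (`rank`, `pathway`, `n_diff_regulated`,
#' `n_reactions`, `n_down`, `n_up`, raw and adjusted p-values) with a
#' provenance comment header recording the configuration and family size.
#'
#' @param results data.frame from [rankPathways()].
#' @param file output path.
#' @param config named list recorded in the header.
#' @export
writeResultsTsv <- function(results, file, config = list()) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(provenanceHeader(config), con)
  cols <- c("rank", "pathway", "n_diff_regulated", "n_reactions", "n_down",
            "n_up", "p_raw", "p_adjusted", "significant")
  write.table(results[, cols], con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' @rdname writeResultsTsv
#' @export
readResultsTsv <- function(file) {
  read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write a feature table TSV
#'
#' Descriptor columns followed by one column per sample.
#'
#' @param table a [FeatureTable-class].
#' @param file output path.
#' @export
writeFeatureTsv <- function(table, file) {
  df <- cbind(featureDescriptors(table),
              as.data.frame(featureValues(table)))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
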