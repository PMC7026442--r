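#' Shared dysregulated genes between two sets
#'
#' The number of dysregulated genes two disorders have in common,
#' `n_ij = N(G_i intersect G_j)`, together with the intersection itself.
#'
#' @param set_i,set_j Character vectors of gene symbols.
#' @return List with `count` and `genes` (sorted).
#' @export
shared_genes <- function(set_i, set_j) {
  g <- sort(intersect(norm_symbols(set_i), norm_symbols(set_j)))
  list(count = length(g), genes = g)
}

#' Jaccard edge-prediction score between two gene sets
#'
#' Intersection over union, `E(i,j) = N(G_i intersect G_j) / N(G_i union
#' G_j)`, the edge score placed on disease-disease associations.
#'
#' @inheritParams shared_genes
#' @return Numeric scalar in `[0, 1]`.
#' @export
jaccard_score <- function(set_i, set_j) {
  a <- unique(norm_symbols(set_i)); b <- unique(norm_symbols(set_j))
  u <- length(union(a, b))
  if (u == 0L) stop("Jaccard score undefined: both sets empty", call. = FALSE)
  length(intersect(a, b)) / u
}

#' Build a direction-stratified exposure-centred diseasome network
#'
#' Bipartite gene-disease graph for one direction of dysregulation. Gene
#' nodes are exactly the genes the exposure shares with at least one
#' disease; each retained gene is linked to the exposure and to every
#' disease whose significant set contains it. Disease-disease association
#' records carry the shared count `n_ij` and Jaccard score `E(i,j)` for all
#' exposure-disease pairs and for every disease-disease pair sharing at
#' least one gene.
#'
#' @param exposure A `disease_gene_set` for the exposure signature.
#' @param diseases List of `disease_gene_set`s.
#' @param direction `"up"` or `"down"`.
#' @return A `diseasome_network`: fields `direction`, `exposure_id`,
#'   `disease_ids`, `genes`, `gene_edges` (data frame `disease`, `gene`),
#'   `associations` (data frame `i`, `j`, `n_shared`, `jaccard`), and
#'   `sets` (the significant sets used).
#' @export
build_diseasome <- function(exposure, diseases, direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(inherits(exposure, "disease_gene_set"))
  ids <- vapply(diseases, function(d) d$disease_id, character(1))
  if (anyDuplicated(c(exposure$disease_id, ids))) {
    stop("duplicate disease ids", call. = FALSE)
  }
  sets <- c(stats::setNames(list(exposure[[direction]]), exposure$disease_id),
            stats::setNames(lapply(diseases, `[[`, direction), ids))

  expo_set <- sets[[1L]]
  genes <- sort(unique(unlist(lapply(ids, function(i)
    intersect(expo_set, sets[[i]])), use.names = FALSE)))

  gene_edges <- do.call(rbind, c(list(
    data.frame(disease = character(), gene = character(),
               stringsAsFactors = FALSE)),
    lapply(names(sets), function(d) {
      g <- sort(intersect(genes, sets[[d]]))
      if (length(g) == 0L) return(NULL)
      data.frame(disease = d, gene = g, stringsAsFactors = FALSE)
    })))

  all_ids <- names(sets)
  pairs <- utils::combn(all_ids, 2L)
  assoc <- do.call(rbind, c(list(
    data.frame(i = character(), j = character(), n_shared = integer(),
               jaccard = numeric(), stringsAsFactors = FALSE)),
    lapply(seq_len(ncol(pairs)), function(k) {
      i <- pairs[1L, k]; j <- pairs[2L, k]
      sg <- shared_genes(sets[[i]], sets[[j]])
      is_expo <- i == exposure$disease_id || j == exposure$disease_id
      if (!is_expo && sg$count < 1L) return(NULL)
      jac <- if (length(sets[[i]]) + length(sets[[j]]) == 0L) NA_real_ else
        jaccard_score(sets[[i]], sets[[j]])
      data.frame(i = i, j = j, n_shared = sg$count, jaccard = jac,
                 stringsAsFactors = FALSE)
    })))

  structure(
    list(direction = direction, exposure_id = exposure$disease_id,
         disease_ids = ids, genes = genes, gene_edges = gene_edges,
         associations = assoc, sets = sets),
    class = "diseasome_network")
}

#' @export
print.diseasome_network <- function(x, ...) {
  cat(sprintf("diseasome_network (%s): exposure '%s', %d diseases, %d gene nodes, %d bipartite edges\n",
              x$direction, x$exposure_id, length(x$disease_ids),
              length(x$genes), nrow(x$gene_edges)))
  invisible(x)
}

#' Genes connected to at least k nodes of the diseasome
#'
#' Bipartite degree filter: returns the genes linked to `k` or more
#' disease/exposure nodes, i.e. dysregulated in the exposure plus at least
#' `k - 1` diseases.
#'
#' @param network A `diseasome_network`.
#' @param k Minimum degree (>= 2).
#' @return Sorted character vector of gene symbols.
#' @export
multi_disease_genes <- function(network, k) {
  stopifnot(inherits(network, "diseasome_network"))
  k <- assert_count(k, "k")
  if (k < 2L) stop("`k` must be >= 2", call. = FALSE)
  deg <- table(network$gene_edges$gene)
  sort(names(deg)[deg >= k])
}

#' Export a diseasome network
#'
#' Writers for Cytoscape-compatible formats. Nodes are ordered
#' lexicographically (diseases, then genes) so output is bit-stable.
#' `"graphml"` goes through igraph and carries node attributes `type`
#' (disease/gene) and `direction`, plus `n_shared`/`jaccard` on association
#' edges; `"sif"` writes one line per edge with relations `links`
#' (disease-gene) and `assoc` (disease-disease); `"tsv"` writes the edge
#' list with columns `source`, `target`, `type`, `n_shared`, `jaccard`.
#'
#' @param network A `diseasome_network`.
#' @param path Output file.
#' @param format `"graphml"`, `"sif"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("graphml", "sif", "tsv")) {
  stopifnot(inherits(network, "diseasome_network"))
  if (!format[1L] %in% c("graphml", "sif", "tsv")) {
    stop(sprintf("unknown format '%s'", format[1L]), call. = FALSE)
  }
  format <- match.arg(format)
  dn <- sort(c(network$exposure_id, network$disease_ids))
  ge <- network$gene_edges[order(network$gene_edges$disease,
                                 network$gene_edges$gene), , drop = FALSE]
  as_ <- network$associations
  if (nrow(as_) > 0L) as_ <- as_[order(as_$i, as_$j), , drop = FALSE]

  edges <- rbind(
    if (nrow(ge) > 0L)
      data.frame(source = ge$disease, target = ge$gene, type = "links",
                 n_shared = NA_integer_, jaccard = NA_real_,
                 stringsAsFactors = FALSE),
    if (nrow(as_) > 0L)
      data.frame(source = as_$i, target = as_$j, type = "assoc",
                 n_shared = as_$n_shared, jaccard = as_$jaccard,
                 stringsAsFactors = FALSE),
    data.frame(source = character(), target = character(), type = character(),
               n_shared = integer(), jaccard = numeric(),
               stringsAsFactors = FALSE))

  if (format == "tsv") {
    write_tsv_det(edges, path)
  } else if (format == "sif") {
    lines <- sprintf("%s\t%s\t%s", edges$source, edges$type, edges$target)
    writeLines(lines, path)
  } else {
    nodes <- data.frame(
      name = c(dn, network$genes),
      type = rep(c("disease", "gene"), c(length(dn), length(network$genes))),
      direction = network$direction, stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
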