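#' Build a bipartite miRNA-target regulatory network
#'
#' Expands differentially expressed miRNAs by interaction databases and
#' keeps the edges whose target gene is itself differentially expressed.
#' One edge is created per supporting database (parallel edges), nodes are
#' restricted to edge endpoints, and the log2 fold changes are stored as
#' node attributes. miRNA identifiers are matched to the databases through
#' the human-namespace mapping; gene symbols are matched
#' case-insensitively.
#'
#' @param de_mirnas,de_genes named numeric vectors: names are feature
#'   identifiers, values the log2 fold changes.
#' @param interactions list of interaction data.frames (columns `mirna_id`,
#'   `gene_id`, `db_name`).
#' @param id_map optional override table for [map_mirna_ids()].
#' @param contrast optional contrast label stored on the graph.
#' @return an `igraph` object with vertex attributes `kind` ("miRNA" or
#'   "gene") and `log2fc`, and edge attribute `db`.
#' @export
build_network <- function(de_mirnas, de_genes, interactions, id_map = NULL,
                          contrast = NULL) {
  stopifnot(!is.null(names(de_mirnas)), !is.null(names(de_genes)))
  if (is.data.frame(interactions)) interactions <- list(interactions)
  mapped <- map_mirna_ids(names(de_mirnas), override = id_map)
  if (anyNA(mapped)) {
    dropped <- names(de_mirnas)[is.na(mapped)]
    if (length(setdiff(dropped, dropped[is_provisional_mirna(dropped)])))
      warning("unmappable miRNA identifiers: ", paste(dropped, collapse = ", "))
  }
  lut_mi <- setNames(names(de_mirnas), tolower(mapped))
  lut_g <- setNames(names(de_genes), tolower(names(de_genes)))

  edges <- do.call(rbind, lapply(interactions, function(tab) {
    if (nrow(tab) == 0) return(NULL)
    mi <- lut_mi[tolower(tab$mirna_id)]
    g <- lut_g[tolower(tab$gene_id)]
    keep <- !is.na(mi) & !is.na(g)
    if (!any(keep)) return(NULL)
    data.frame(mirna_id = unname(mi[keep]), gene_id = unname(g[keep]),
               db = tab$db_name[keep], stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(mirna_id = character(0), gene_id = character(0),
                        db = character(0), stringsAsFactors = FALSE)
  edges <- unique(edges)
  edges <- edges[order(edges$mirna_id, edges$gene_id, edges$db), , drop = FALSE]

  v_mi <- sort(unique(edges$mirna_id))
  v_g <- sort(unique(edges$gene_id))
  vertices <- data.frame(
    name = c(v_mi, v_g),
    kind = rep(c("miRNA", "gene"), c(length(v_mi), length(v_g))),
    log2fc = c(unname(de_mirnas[v_mi]), unname(de_genes[v_g])),
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges[, c("mirna_id", "gene_id", "db")], directed = FALSE,
    vertices = vertices)
  if (!is.null(contrast)) g <- igraph::set_graph_attr(g, "contrast", paste(contrast, collapse = ":"))
  assert_bipartite(g)
  g
}

# internal: every edge must join a miRNA to a gene
assert_bipartite <- function(g) {
  if (igraph::ecount(g) == 0) return(invisible(g))
  ends <- igraph::ends(g, igraph::E(g))
  kind <- setNames(igraph::V(g)$kind, igraph::V(g)$name)
  if (!all(kind[ends[, 1]] != kind[ends[, 2]]))
    stop("network is not bipartite")
  invisible(g)
}

#' Node degrees and distinct-neighbor counts
#'
#' Degree counts every incident edge including parallel per-database
#' edges; the neighbor count is the number of distinct partners.
#'
#' @param network a [build_network()] graph.
#' @return data.frame with columns `node`, `kind`, `degree`,
#'   `n_neighbors`, sorted by degree descending then node name.
#' @export
node_degrees <- function(network) {
  v <- igraph::V(network)
  deg <- igraph::degree(network)
  nb <- vapply(seq_along(v), function(i)
    length(unique(igraph::neighbors(network, i))), integer(1))
  out <- data.frame(node = v$name, kind = v$kind, degree = unname(deg),
                    n_neighbors = nb, stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genes regulated by multiple miRNAs
#'
#' Gene nodes with at least `k` distinct miRNA neighbors, sorted by
#' neighbor count (descending) then identifier.
#'
#' @param network a [build_network()] graph.
#' @param k minimum number of distinct regulating miRNAs (default 2).
#' @return character vector of gene identifiers.
#' @export
multi_regulated_genes <- function(network, k = 2) {
  stopifnot(k >= 2)
  d <- node_degrees(network)
  d <- d[d$kind == "gene" & d$n_neighbors >= k, , drop = FALSE]
  d <- d[order(-d$n_neighbors, d$node), , drop = FALSE]
  d$node
}

#' Export a regulatory network to GraphML
#'
#' Writes the graph with its `kind`, `log2fc` and `db` attributes; the file
#' re-imports to an equal node/edge multiset via [import_graphml()].
#'
#' @param network a [build_network()] graph.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(network, path) {
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}

#' Import a GraphML regulatory network
#'
#' @param path a file written by [export_graphml()].
#' @return an `igraph` object.
#' @export
import_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if (!is.null(igraph::vertex_attr(g, "id")))
    g <- igraph::delete_vertex_attr(g, "id")
  g
}

#' Export a network in SIF format
#'
#' One line per edge: `mirna<TAB>db<TAB>gene`.
#'
#' @param network a [build_network()] graph.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
export_sif <- function(network, path) {
  if (igraph::ecount(network) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  ends <- igraph::ends(network, igraph::E(network))
  kind <- setNames(igraph::V(network)$kind, igraph::V(network)$name)
  mi <- ifelse(kind[ends[, 1]] == "miRNA", ends[, 1], ends[, 2])
  g <- ifelse(kind[ends[, 1]] == "miRNA", ends[, 2], ends[, 1])
  writeLines(paste(mi, igraph::E(network)$db, g, sep = "\t"), path)
  invisible(path)
}
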