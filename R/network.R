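#' Build a signed interaction network from significant edges
#'
#' Nodes are the taxa incident to at least one significant residual
#' correlation (taxa modeled but never flagged are not part of the network);
#' self-edges are rejected and duplicate pairs are deduplicated with a
#' warning. Organism-group and trophic labels are attached as vertex
#' attributes; the posterior median correlation becomes the edge weight.
#'
#' @param edges data.frame from [significant_edges()] (columns `taxon_a`,
#'   `taxon_b`, `median`, `sign`, optionally `lower`/`upper`).
#' @param annotations a [community_table()] or data.frame with columns
#'   `taxon_id`, `group`, `trophic`; `NULL` labels everything "unknown".
#' @return an undirected `igraph` graph with vertex attributes `group`,
#'   `trophic` and edge attributes `weight`, `sign`, `lower`, `upper`.
#' @export
build_network <- function(edges, annotations = NULL) {
  if (nrow(edges) == 0) {
    return(igraph::make_empty_graph(n = 0, directed = FALSE))
  }
  if (any(edges$taxon_a == edges$taxon_b)) stop("self-edges are not allowed")
  key <- apply(cbind(pmin(edges$taxon_a, edges$taxon_b),
                     pmax(edges$taxon_a, edges$taxon_b)), 1, paste, collapse = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate taxon pairs in edge list; deduplicated")
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  taxa <- sort(unique(c(edges$taxon_a, edges$taxon_b)))
  group <- trophic <- stats::setNames(rep("unknown", length(taxa)), taxa)
  if (!is.null(annotations)) {
    if (inherits(annotations, "community_table")) {
      ann <- data.frame(taxon_id = colnames(annotations$counts),
                        group = unname(annotations$group),
                        trophic = unname(annotations$trophic))
    } else ann <- annotations
    unknown <- setdiff(taxa, ann$taxon_id)
    if (length(unknown)) {
      stop("edges reference taxa absent from annotations: ",
           paste(unknown, collapse = ", "))
    }
    idx <- match(taxa, ann$taxon_id)
    group[] <- ann$group[idx]
    trophic[] <- ann$trophic[idx]
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$taxon_a, to = edges$taxon_b,
               weight = edges$median,
               lower = edges$lower %||% rep(NA_real_, nrow(edges)),
               upper = edges$upper %||% rep(NA_real_, nrow(edges)),
               sign = edges$sign),
    directed = FALSE,
    vertices = data.frame(name = taxa, group = unname(group),
                          trophic = unname(trophic)))
  g
}

#' Linkage density: edges per node
#'
#' The network complexity metric: number of edges divided by number of
#' nodes (average connections per taxon); 0 for an empty network. Accepts
#' either a network or a list/named vector giving `nodes` and `edges`
#' counts directly (as printed in a summary table).
#'
#' @param net an `igraph` network, or `list(nodes = , edges = )`.
#' @return linkage density (real).
#' @export
linkage_density <- function(net) {
  if (igraph::is_igraph(net)) {
    nodes <- igraph::vcount(net)
    edges <- igraph::ecount(net)
  } else {
    nodes <- net[["nodes"]]
    edges <- net[["edges"]]
  }
  if (nodes == 0) return(0)
  edges / nodes
}

#' Network summary statistics
#'
#' Node and edge counts, linkage density, percent positive edges, node
#' counts per organism group, and the number of photosynthetic microbes
#' (photosynthetic nodes that are not plants).
#'
#' @param net an `igraph` network from [build_network()].
#' @return named list of statistics.
#' @export
network_stats <- function(net) {
  nodes <- igraph::vcount(net)
  edges <- igraph::ecount(net)
  group <- if (nodes) igraph::vertex_attr(net, "group") else character(0)
  trophic <- if (nodes) igraph::vertex_attr(net, "trophic") else character(0)
  sign <- if (edges) igraph::edge_attr(net, "sign") else character(0)
  per_group <- vapply(GROUP_LEVELS, function(g) sum(group == g), integer(1))
  per_group[["unknown"]] <- sum(group == "unknown")
  list(nodes = nodes,
       edges = edges,
       linkage_density = linkage_density(net),
       pct_positive = if (edges) 100 * sum(sign == "positive") / edges else NA_real_,
       n_bacteria = per_group[["bacteria"]],
       n_fungi = per_group[["fungi"]],
       n_small_eukaryotes = per_group[["small_eukaryote"]],
       n_microfauna = per_group[["microfauna"]],
       n_plants = per_group[["plant"]],
       n_unknown_group = per_group[["unknown"]],
       n_photosynthetic_microbes = sum(trophic == "photosynthetic" &
                                         group != "plant"))
}

match_selector <- function(group, trophic, selector) {
  ok <- rep(TRUE, length(group))
  if (!is.null(selector$group)) ok <- ok & group %in% selector$group
  if (!is.null(selector$trophic)) ok <- ok & trophic %in% selector$trophic
  ok
}

#' Count edges between two classes of taxa
#'
#' Counts edges with one endpoint matching `selector_a` and the other
#' matching `selector_b`, where a selector is a list with optional `group`
#' and `trophic` entries (NULL = any). The count is symmetric in the two
#' selectors. Example: heterotrophic bacteria vs photosynthetic microbes.
#'
#' @param net an `igraph` network from [build_network()].
#' @param selector_a,selector_b lists such as
#'   `list(group = "bacteria", trophic = "heterotrophic")`.
#' @return integer edge count.
#' @export
cross_group_edge_count <- function(net, selector_a, selector_b) {
  if (igraph::ecount(net) == 0) return(0L)
  group <- igraph::vertex_attr(net, "group")
  trophic <- igraph::vertex_attr(net, "trophic")
  a_ok <- match_selector(group, trophic, selector_a)
  b_ok <- match_selector(group, trophic, selector_b)
  ends <- igraph::ends(net, igraph::E(net), names = FALSE)
  sum((a_ok[ends[, 1]] & b_ok[ends[, 2]]) |
        (a_ok[ends[, 2]] & b_ok[ends[, 1]]))
}

#' Rank network taxa by degree
#'
#' Taxa sorted by number of connections, descending; ties broken by taxon
#' id. Highly connected taxa are candidate network "hubs".
#'
#' @param net an `igraph` network.
#' @return data.frame with columns `taxon_id`, `degree`, in rank order.
#' @export
degree_ranking <- function(net) {
  if (igraph::vcount(net) == 0) {
    return(data.frame(taxon_id = character(0), degree = integer(0)))
  }
  deg <- igraph::degree(net)
  ord <- order(-deg, names(deg))
  data.frame(taxon_id = names(deg)[ord], degree = unname(deg[ord]),
             row.names = NULL)
}
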