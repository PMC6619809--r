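#' Path-overlap similarity of a node to a query gene set
#'
#' Measures how strongly a node co-occurs with a query gene set within the
#' paths of a consensus subnetwork: the Jaccard overlap between P_c(n), the
#' consensus paths containing node n, and the union over query genes q of
#' P_c(q). When both sets are empty the similarity is 0 by convention (such
#' a node is unrelated to the concept).
#'
#' @param n A node id.
#' @param query A set of query gene ids.
#' @param consensus_paths A `subnetip_paths` (e.g. the `$paths` of a
#'   [consensus_subnetwork()] result).
#' @return A number in \[0, 1\].
#' @export
path_similarity <- function(n, query, consensus_paths) {
  stopifnot(inherits(consensus_paths, "subnetip_paths"))
  pn <- consensus_paths$node_index[[norm_id(n)]] %||% integer(0)
  pq <- sort(unique(unlist(
    lapply(norm_id(query), function(q) consensus_paths$node_index[[q]])
  ))) %||% integer(0)
  denom <- length(union(pn, pq))
  if (denom == 0) {
    return(0)
  }
  length(intersect(pn, pq)) / denom
}

#' Generate a concept view of a consensus subnetwork
#'
#' Ranks every consensus node outside the query set (and outside the
#' designated targets) by [path_similarity()] to the query, takes the top `k`
#' as predicted additions to the concept, and extracts the view: all
#' consensus paths that consist exclusively of query nodes, predicted
#' additions and targets. Ties at rank `k` break by similarity, then by
#' path support `|P_c(n)|`, then by node id.
#'
#' @param consensus_paths A `subnetip_paths` or `subnetip_consensus`.
#' @param query Query gene ids defining the concept; genes absent from the
#'   consensus are ignored with a warning.
#' @param k Number of predicted additions (>= 0); default 10.
#' @param targets The task's designated target node ids (e.g. viral
#'   components), admitted in view paths without being query members or
#'   additions.
#' @return A `subnetip_view`: `$query_genes`, `$predicted_additions`
#'   (tibble `id`, `similarity`, `support`), `$ranking` (all candidates),
#'   `$paths` (the view `subnetip_paths`), `$nodes`, `$edges`.
#' @export
generate_view <- function(consensus_paths, query, k = 10, targets = character(0)) {
  if (inherits(consensus_paths, "subnetip_consensus")) {
    consensus_paths <- consensus_paths$paths
  }
  stopifnot(inherits(consensus_paths, "subnetip_paths"))
  if (k < 0) abort("k must be >= 0")
  if (nrow(consensus_paths$paths) == 0) abort("consensus contains no paths")
  query <- norm_id(query)
  targets <- norm_id(targets)
  in_consensus <- names(consensus_paths$node_index)
  missing_q <- setdiff(query, in_consensus)
  if (length(missing_q) > 0) {
    warn(sprintf("%d query gene(s) not in the consensus; ignored", length(missing_q)))
  }
  query_in <- intersect(query, in_consensus)

  candidates <- setdiff(in_consensus, c(query, targets))
  ranking <- tibble(
    id = candidates,
    similarity = map_dbl(candidates, path_similarity,
      query = query_in, consensus_paths = consensus_paths
    ),
    support = map_int(candidates, ~ length(consensus_paths$node_index[[.x]]))
  )
  ranking <- arrange(
    ranking,
    dplyr::desc(.data$similarity), dplyr::desc(.data$support), .data$id
  )
  additions <- utils::head(ranking, k)

  allowed <- c(query_in, additions$id, targets)
  pt <- consensus_paths$paths
  keep_path <- map_lgl(pt$nodes, ~ all(.x %in% allowed))
  view_paths <- index_paths(path_list(consensus_paths)[which(keep_path)])
  structure(
    list(
      query_genes = query_in,
      predicted_additions = additions,
      ranking = ranking,
      targets = targets,
      paths = view_paths,
      nodes = sort(unique(unlist(view_paths$paths$nodes))),
      edges = instance_edges(view_paths)
    ),
    class = "subnetip_view"
  )
}

#' @export
print.subnetip_view <- function(x, ...) {
  cat(sprintf(
    "<subnetip_view> %d query genes, %d predicted additions; %d paths over %d nodes / %d edges\n",
    length(x$query_genes), nrow(x$predicted_additions),
    nrow(x$paths$paths), length(x$nodes), nrow(x$edges)
  ))
  invisible(x)
}

#' @export
tidy.subnetip_view <- function(x, ...) x$ranking

#' Export a view to GraphML
#'
#' Nodes carry a `category` attribute (`query-anchor`, `predicted-addition`
#' or `target`) mirroring the usual rendering legend.
#'
#' @param view A `subnetip_view`.
#' @param path Destination `.graphml` file.
#' @return Invisibly, the igraph object written.
#' @export
write_view_graphml <- function(view, path) {
  stopifnot(inherits(view, "subnetip_view"))
  cat_of <- function(id) {
    if (id %in% view$query_genes) {
      "query-anchor"
    } else if (id %in% view$predicted_additions$id) {
      "predicted-addition"
    } else {
      "target"
    }
  }
  verts <- data.frame(
    name = view$nodes, category = vapply(view$nodes, cat_of, character(1)),
    stringsAsFactors = FALSE
  )
  ed <- data.frame(
    from = view$edges$a, to = view$edges$b,
    class = view$edges$class, directed = view$edges$directed,
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(ed, directed = TRUE, vertices = verts)
  igraph::write_graph(g, path, format = "graphml")
  invisible(g)
}
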