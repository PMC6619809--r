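#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr filter mutate select arrange distinct group_by ungroup
#'   summarise left_join anti_join bind_rows n row_number if_else pull rename
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_chr map_int map_dbl map_lgl map2 pmap imap keep
NULL

NODE_KINDS <- c("gene", "complex", "reaction", "small_molecule", "viral_component")
NODE_ROLES <- c("hit", "interface", "de_target", "source")
EDGE_CLASSES <- c(
  "ppi", "kinase_substrate", "ptm", "protein_dna",
  "complex_membership", "reaction_io", "literature_regulatory"
)
# interaction classes whose semantics fix an orientation
ALWAYS_DIRECTED <- c(
  "complex_membership", "reaction_io", "protein_dna", "literature_regulatory"
)

norm_id <- function(x) toupper(trimws(as.character(x)))

#' Construct a typed, partially-directed background network
#'
#' The background network is the universe of candidate molecular entities and
#' interactions from which a subnetwork is inferred. Nodes are typed (gene,
#' protein complex, reaction, small molecule, viral component) and may carry
#' experimental roles: `hit` (screen-identified source gene), `interface`
#' (host gene product that physically contacts a target component),
#' `de_target` (differentially expressed target gene) and `source` (designated
#' regulatory source). Edges are typed interactions; protein-DNA, complex
#' membership, reaction input/output and literature-derived regulatory edges
#' are inherently directed, protein-protein interactions may be undirected.
#'
#' Identifiers are upper-cased and trimmed. Self-loops are dropped with a
#' warning. Undirected edges are stored once with endpoints in lexicographic
#' order; duplicates are removed per (pair, class) for undirected edges and
#' per (from, to, class) for directed ones.
#'
#' @param nodes A data frame with columns `id`, `kind`, optional `roles`
#'   (semicolon-separated subset of `hit`, `interface`, `de_target`,
#'   `source`, or logical columns of those names) and optional `score`
#'   (nonnegative).
#' @param edges A data frame with columns `source`, `target`, `directed`
#'   (logical) and `class`.
#' @return An object of class `subnetip_network`: a list with tibbles
#'   `$nodes` (id, kind, hit, interface, de_target, source, score) and
#'   `$edges` (from, to, directed, class), plus a `$roles` index holding the
#'   role sets (hits, interfaces, unconfirmed, complexes, reactions, sources,
#'   de_targets).
#' @examples
#' nodes <- tibble::tibble(
#'   id = c("a", "b", "v"),
#'   kind = c("gene", "gene", "viral_component"),
#'   roles = c("hit", "interface", "")
#' )
#' edges <- tibble::tibble(
#'   source = "a", target = "b", directed = FALSE, class = "ppi"
#' )
#' net <- background_network(nodes, edges)
#' net$roles$hits
#' @export
background_network <- function(nodes, edges) {
  nodes <- as_tibble(nodes)
  edges <- as_tibble(edges)

  if (!all(c("id", "kind") %in% names(nodes))) {
    abort("node table needs columns `id` and `kind`")
  }
  nodes$id <- norm_id(nodes$id)
  nodes$kind <- as.character(nodes$kind)
  bad_kind <- which(!nodes$kind %in% NODE_KINDS)
  if (length(bad_kind) > 0) {
    abort(sprintf(
      "unknown node kind '%s' in node table row %d (id %s)",
      nodes$kind[bad_kind[1]], bad_kind[1], nodes$id[bad_kind[1]]
    ))
  }
  if (anyDuplicated(nodes$id)) {
    dup <- nodes$id[duplicated(nodes$id)][1]
    abort(sprintf("duplicate node id '%s' in node table", dup))
  }

  # roles: accept a semicolon/comma separated `roles` column or logical columns
  role_flags <- matrix(FALSE, nrow(nodes), length(NODE_ROLES),
    dimnames = list(NULL, NODE_ROLES)
  )
  if ("roles" %in% names(nodes)) {
    rl <- as.character(nodes$roles)
    rl[is.na(rl)] <- ""
    toks <- strsplit(rl, "[;,]")
    for (i in seq_along(toks)) {
      tk <- trimws(tolower(toks[[i]]))
      tk <- tk[nzchar(tk)]
      bad <- setdiff(tk, NODE_ROLES)
      if (length(bad) > 0) {
        abort(sprintf("unknown role '%s' in node table row %d", bad[1], i))
      }
      role_flags[i, tk] <- TRUE
    }
  }
  for (r in NODE_ROLES) {
    if (r %in% names(nodes)) role_flags[, r] <- isTRUE_vec(nodes[[r]])
  }
  score <- if ("score" %in% names(nodes)) as.numeric(nodes$score) else rep(0, nrow(nodes))
  score[is.na(score)] <- 0
  if (any(score < 0)) abort("node scores must be nonnegative")

  nodes <- tibble(
    id = nodes$id, kind = nodes$kind,
    hit = role_flags[, "hit"], interface = role_flags[, "interface"],
    de_target = role_flags[, "de_target"], source = role_flags[, "source"],
    score = score
  )
  if (any(nodes$hit & nodes$kind == "viral_component")) {
    abort("a viral_component node cannot carry the hit role")
  }

  if (!all(c("source", "target", "directed", "class") %in% names(edges))) {
    abort("edge table needs columns `source`, `target`, `directed`, `class`")
  }
  edges <- tibble(
    from = norm_id(edges$source), to = norm_id(edges$target),
    directed = as.logical(edges$directed), class = as.character(edges$class)
  )
  bad_cl <- which(!edges$class %in% EDGE_CLASSES)
  if (length(bad_cl) > 0) {
    abort(sprintf(
      "unknown interaction class '%s' in edge table row %d",
      edges$class[bad_cl[1]], bad_cl[1]
    ))
  }
  loops <- edges$from == edges$to
  if (any(loops)) {
    warn(sprintf("dropping %d self-loop edge(s)", sum(loops)))
    edges <- edges[!loops, ]
  }
  fix_dir <- edges$class %in% ALWAYS_DIRECTED & !edges$directed
  if (any(fix_dir)) {
    warn(sprintf(
      "%d edge(s) of an inherently directed class marked undirected; treating as directed",
      sum(fix_dir)
    ))
    edges$directed[fix_dir] <- TRUE
  }
  unknown <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(unknown) > 0) {
    abort(sprintf("edge references unknown node '%s'", unknown[1]))
  }

  # canonical storage order for undirected edges, then dedup
  swap <- !edges$directed & edges$from > edges$to
  tmp <- edges$from[swap]
  edges$from[swap] <- edges$to[swap]
  edges$to[swap] <- tmp
  edges <- distinct(edges, .data$from, .data$to, .data$directed, .data$class)
  edges <- arrange(edges, .data$from, .data$to, .data$class, .data$directed)

  net <- structure(
    list(nodes = arrange(nodes, .data$id), edges = edges, roles = NULL),
    class = "subnetip_network"
  )
  derive_roles(net)
}

isTRUE_vec <- function(x) {
  if (is.logical(x)) {
    x & !is.na(x)
  } else {
    tolower(as.character(x)) %in% c("true", "1", "yes")
  }
}

#' Recompute the role index of a background network
#'
#' The unconfirmed set is derived, not declared: it contains every gene-kind
#' node that carries neither the hit nor the interface role. A gene may be
#' both hit and interface (screens and interaction databases overlap); such a
#' gene belongs to both sets and never to the unconfirmed set.
#'
#' @param net A `subnetip_network`.
#' @return The network with its `$roles` index rebuilt.
#' @export
derive_roles <- function(net) {
  stopifnot(inherits(net, "subnetip_network"))
  nd <- net$nodes
  genes <- nd$id[nd$kind == "gene"]
  net$roles <- list(
    hits = nd$id[nd$hit],
    interfaces = nd$id[nd$interface],
    unconfirmed = nd$id[nd$kind == "gene" & !nd$hit & !nd$interface],
    complexes = nd$id[nd$kind == "complex"],
    reactions = nd$id[nd$kind == "reaction"],
    sources = nd$id[nd$source],
    de_targets = nd$id[nd$de_target],
    genes = genes
  )
  net
}

roles_string <- function(nodes) {
  apply(
    cbind(
      ifelse(nodes$hit, "hit", NA), ifelse(nodes$interface, "interface", NA),
      ifelse(nodes$de_target, "de_target", NA), ifelse(nodes$source, "source", NA)
    ), 1,
    function(r) paste(stats::na.omit(r), collapse = ";")
  )
}

#' Read a background network from node and edge TSV tables
#'
#' The edge table is tab-separated with header
#' `source  target  directed  class`; the node table with header
#' `id  kind  roles  score` (`roles` semicolon-separated, possibly empty).
#'
#' @param edge_table_path,node_table_path Paths to the two TSV files.
#' @return A validated `subnetip_network`. Node and edge counts are reported
#'   with a message.
#' @export
load_network <- function(edge_table_path, node_table_path) {
  if (!file.exists(edge_table_path)) abort(paste("no such file:", edge_table_path))
  if (!file.exists(node_table_path)) abort(paste("no such file:", node_table_path))
  edges <- readr::read_tsv(edge_table_path,
    col_types = readr::cols(
      source = readr::col_character(), target = readr::col_character(),
      directed = readr::col_logical(), class = readr::col_character()
    )
  )
  nodes <- readr::read_tsv(node_table_path,
    col_types = readr::cols(
      id = readr::col_character(), kind = readr::col_character(),
      roles = readr::col_character(), score = readr::col_double()
    )
  )
  net <- background_network(nodes, edges)
  inform(sprintf(
    "loaded network: %d nodes, %d edges (%d hits, %d interfaces, %d unconfirmed)",
    nrow(net$nodes), nrow(net$edges),
    length(net$roles$hits), length(net$roles$interfaces), length(net$roles$unconfirmed)
  ))
  net
}

#' Write a background network to node and edge TSV tables
#'
#' Inverse of [load_network()]: the written files reload to a network equal to
#' the input, and repeated writes of the same network are byte-identical.
#'
#' @param net A `subnetip_network`.
#' @param edge_table_path,node_table_path Destination paths.
#' @return Invisibly, `net`.
#' @export
write_network <- function(net, edge_table_path, node_table_path) {
  stopifnot(inherits(net, "subnetip_network"))
  ed <- net$edges
  readr::write_tsv(
    tibble(
      source = ed$from, target = ed$to,
      directed = ed$directed, class = ed$class
    ),
    edge_table_path
  )
  nd <- net$nodes
  readr::write_tsv(
    tibble(id = nd$id, kind = nd$kind, roles = roles_string(nd), score = nd$score),
    node_table_path
  )
  invisible(net)
}

#' Export a background network to GraphML
#'
#' Nodes carry `kind` and `roles` attributes and edges carry `class` and
#' `directed` attributes, for viewing in Cytoscape or similar tools. The graph
#' is exported as directed, with undirected interactions flagged by the
#' `directed` edge attribute.
#'
#' @param net A `subnetip_network`.
#' @param path Destination `.graphml` file.
#' @return Invisibly, the igraph object written.
#' @export
write_network_graphml <- function(net, path) {
  g <- network_igraph(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(g)
}

network_igraph <- function(net) {
  nd <- net$nodes
  verts <- data.frame(
    name = nd$id, kind = nd$kind, roles = roles_string(nd),
    score = nd$score, stringsAsFactors = FALSE
  )
  ed <- data.frame(
    from = net$edges$from, to = net$edges$to,
    class = net$edges$class, directed = net$edges$directed,
    stringsAsFactors = FALSE
  )
  igraph::graph_from_data_frame(ed, directed = TRUE, vertices = verts)
}

#' @export
print.subnetip_network <- function(x, ...) {
  cat(sprintf(
    "<subnetip_network> %d nodes, %d edges\n", nrow(x$nodes), nrow(x$edges)
  ))
  cat(sprintf(
    "  roles: %d hits, %d interfaces, %d unconfirmed, %d complexes, %d reactions, %d DE targets\n",
    length(x$roles$hits), length(x$roles$interfaces), length(x$roles$unconfirmed),
    length(x$roles$complexes), length(x$roles$reactions), length(x$roles$de_targets)
  ))
  invisible(x)
}

#' Tidy a background network into a tibble
#'
#' @param x A `subnetip_network`.
#' @param what Either `"nodes"` (default) or `"edges"`.
#' @param ... Unused.
#' @return The requested tibble.
#' @export
tidy.subnetip_network <- function(x, what = c("nodes", "edges"), ...) {
  what <- match.arg(what)
  x[[what]]
}

#' @export
glance.subnetip_network <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
    n_hits = length(x$roles$hits), n_interfaces = length(x$roles$interfaces),
    n_unconfirmed = length(x$roles$unconfirmed),
    n_complexes = length(x$roles$complexes), n_reactions = length(x$roles$reactions),
    n_de_targets = length(x$roles$de_targets)
  )
}

network_equal <- function(a, b) {
  isTRUE(all.equal(as.data.frame(a$nodes), as.data.frame(b$nodes))) &&
    isTRUE(all.equal(as.data.frame(a$edges), as.data.frame(b$edges)))
}

#' Set or add node roles in a background network
#'
#' Convenience for assigning experiment roles (hits, interfaces, DE targets,
#' regulatory source) after loading a bare network.
#'
#' @param net A `subnetip_network`.
#' @param role One of `"hit"`, `"interface"`, `"de_target"`, `"source"`.
#' @param ids Node ids to receive the role (case-insensitive).
#' @param value Logical, `TRUE` to grant or `FALSE` to revoke.
#' @return The modified network with a rebuilt role index.
#' @export
set_role <- function(net, role, ids, value = TRUE) {
  stopifnot(inherits(net, "subnetip_network"))
  role <- match.arg(role, NODE_ROLES)
  ids <- norm_id(ids)
  missing_ids <- setdiff(ids, net$nodes$id)
  if (length(missing_ids) > 0) {
    abort(sprintf("unknown node id '%s' in set_role()", missing_ids[1]))
  }
  net$nodes[[role]][net$nodes$id %in% ids] <- value
  if (role == "hit" && any(net$nodes$hit & net$nodes$kind == "viral_component")) {
    abort("a viral_component node cannot carry the hit role")
  }
  derive_roles(net)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
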