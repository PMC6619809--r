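# Canonical identity of a network edge. Undirected edges are keyed on the
# sorted endpoint pair so both traversal orientations hit the same key.
edge_key <- function(from, to, directed, class) {
  n <- max(length(from), length(to), length(directed), length(class))
  from <- rep_len(from, n)
  to <- rep_len(to, n)
  directed <- rep_len(directed, n)
  a <- ifelse(directed, from, pmin(from, to))
  b <- ifelse(directed, to, pmax(from, to))
  paste(a, b, ifelse(directed, ">", "-"), rep_len(class, n), sep = "|")
}

# adjacency list: for every node, the edges traversable out of it
build_adjacency <- function(net) {
  ed <- net$edges
  fwd <- tibble(
    at = ed$from, nxt = ed$to, class = ed$class, directed = ed$directed,
    key = edge_key(ed$from, ed$to, ed$directed, ed$class)
  )
  und <- ed[!ed$directed, ]
  bwd <- tibble(
    at = und$to, nxt = und$from, class = und$class, directed = und$directed,
    key = edge_key(und$from, und$to, und$directed, und$class)
  )
  adj <- bind_rows(fwd, bwd)
  adj <- arrange(adj, .data$at, .data$nxt, .data$class)
  split(adj[c("nxt", "class", "key")], adj$at)
}

#' Enumerate simple source-to-target paths up to a depth bound
#'
#' Performs a depth-first traversal from each source, finding every simple
#' path (no repeated node) of at most `max_edges` interactions that ends at a
#' target. Directed edges are traversed only in their stored orientation;
#' undirected edges may be traversed either way, and a given path fixes one
#' orientation per edge. A path ends at the first target it touches:
#' intermediate occurrences of target nodes are disallowed unless
#' `allow_through_targets = TRUE`. Nodes that are both source and target are
#' used as enumeration sources, and zero-edge paths are never emitted.
#'
#' When `terminal_class` is given (e.g. `"protein_dna"` for a regulatory
#' task, where each path must end in a direct protein-DNA or
#' literature-derived regulatory interaction), only paths whose final edge
#' belongs to one of those classes are kept; this equals post-hoc filtering
#' of the unconstrained enumeration.
#'
#' @param net A `subnetip_network`.
#' @param sources,targets Nonempty sets of node ids present in the network.
#' @param max_edges Maximum number of interactions per path (>= 1); with
#'   `max_edges = 3` every path has at most four nodes.
#' @param terminal_class Optional character vector of interaction classes the
#'   final edge must belong to.
#' @param allow_through_targets If `TRUE`, paths may continue through a target
#'   node and end at a later one.
#' @return A `subnetip_paths` object: `$paths` is a tibble with one row per
#'   path (`path_id`, `source`, `terminal`, `n_edges`, `chain`, list-columns
#'   `nodes`, `edges`), and `$node_index` / `$edge_index` map node ids and
#'   edge keys to the integer ids of the paths containing them.
#' @export
enumerate_paths <- function(net, sources, targets, max_edges = 3,
                            terminal_class = NULL,
                            allow_through_targets = FALSE) {
  stopifnot(inherits(net, "subnetip_network"))
  if (length(sources) == 0 || length(targets) == 0) {
    abort("sources and targets must be nonempty")
  }
  if (!is.numeric(max_edges) || max_edges < 1) abort("max_edges must be >= 1")
  sources <- norm_id(sources)
  targets <- norm_id(targets)
  unknown <- setdiff(c(sources, targets), net$nodes$id)
  if (length(unknown) > 0) abort(sprintf("unknown node id '%s'", unknown[1]))
  if (!is.null(terminal_class)) {
    bad <- setdiff(terminal_class, EDGE_CLASSES)
    if (length(bad) > 0) abort(sprintf("unknown interaction class '%s'", bad[1]))
  }

  adj <- build_adjacency(net)
  is_target <- structure(rep(TRUE, length(targets)), names = targets)
  out_nodes <- list()
  out_steps <- list()
  k <- 0L

  # iterative DFS per source; stack entries carry the node chain and the
  # oriented steps (from, to, class, key) taken so far
  for (s in sort(sources)) {
    stack <- list(list(chain = s, steps = NULL))
    while (length(stack) > 0) {
      fr <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      cur <- fr$chain[length(fr$chain)]
      depth <- length(fr$chain) - 1L
      at_target <- !is.na(is_target[cur]) && depth >= 1L
      if (at_target) {
        last_cl <- fr$steps$class[nrow(fr$steps)]
        if (is.null(terminal_class) || last_cl %in% terminal_class) {
          k <- k + 1L
          out_nodes[[k]] <- fr$chain
          out_steps[[k]] <- fr$steps
        }
        if (!allow_through_targets) next
      }
      if (depth >= max_edges) next
      nb <- adj[[cur]]
      if (is.null(nb)) next
      ok <- !(nb$nxt %in% fr$chain)
      if (!any(ok)) next
      nb <- nb[ok, ]
      # push in reverse so lexicographically first neighbor is explored first
      for (i in rev(seq_len(nrow(nb)))) {
        step <- tibble(
          from = cur, to = nb$nxt[i], class = nb$class[i], key = nb$key[i]
        )
        stack[[length(stack) + 1L]] <- list(
          chain = c(fr$chain, nb$nxt[i]),
          steps = bind_rows(fr$steps, step)
        )
      }
    }
  }
  index_paths(lapply(seq_len(k), function(i) {
    list(nodes = out_nodes[[i]], edges = out_steps[[i]])
  }))
}

#' Build a path set with node and edge indices
#'
#' Takes a list of paths (each a list with `nodes`, an ordered id vector, and
#' `edges`, a tibble of oriented steps with columns `from`, `to`, `class` and
#' optionally `key`) and constructs the indexed path set used by the integer
#' programs: P(n), the paths containing node n, and P(e), the paths containing
#' edge e. Paths are sorted canonically (by node chain, then edge classes) and
#' assigned integer ids; exact duplicates collapse.
#'
#' @param paths A list of paths, or the `$paths` tibble of an existing path
#'   set.
#' @return A `subnetip_paths` object.
#' @export
index_paths <- function(paths) {
  if (inherits(paths, "subnetip_paths")) paths <- path_list(paths)
  if (is.data.frame(paths)) paths <- df_to_path_list(paths)
  n <- length(paths)
  if (n == 0) {
    return(structure(
      list(
        paths = tibble(
          path_id = integer(), source = character(), terminal = character(),
          n_edges = integer(), chain = character(),
          nodes = list(), edges = list()
        ),
        node_index = list(), edge_index = list()
      ),
      class = "subnetip_paths"
    ))
  }
  rows <- map(paths, function(p) {
    ed <- as_tibble(p$edges)
    if (!"key" %in% names(ed)) {
      # orientation is per-path; recover the canonical key from the step,
      # treating any class outside the always-directed set as undirected
      # unless a `directed` column says otherwise
      dir <- if ("directed" %in% names(ed)) ed$directed else ed$class %in% ALWAYS_DIRECTED
      ed$key <- edge_key(ed$from, ed$to, dir, ed$class)
    }
    nodes <- as.character(p$nodes)
    if (anyDuplicated(nodes)) abort("path repeats a node; paths must be simple")
    if (length(nodes) != nrow(ed) + 1L) abort("path has inconsistent node/edge counts")
    tibble(
      source = nodes[1], terminal = nodes[length(nodes)],
      n_edges = nrow(ed),
      chain = paste(nodes, collapse = "|"),
      class_chain = paste(ed$class, collapse = "|"),
      nodes = list(nodes), edges = list(ed[c("from", "to", "class", "key")])
    )
  })
  pt <- bind_rows(rows)
  pt <- arrange(pt, .data$chain, .data$class_chain)
  pt <- pt[!duplicated(paste(pt$chain, pt$class_chain, sep = "#")), ]
  pt$path_id <- seq_len(nrow(pt))
  pt <- pt[c("path_id", "source", "terminal", "n_edges", "chain", "nodes", "edges")]

  node_index <- list()
  edge_index <- list()
  for (i in seq_len(nrow(pt))) {
    for (nd in pt$nodes[[i]]) node_index[[nd]] <- c(node_index[[nd]], i)
    for (ky in pt$edges[[i]]$key) edge_index[[ky]] <- c(edge_index[[ky]], i)
  }
  structure(
    list(paths = pt, node_index = node_index, edge_index = edge_index),
    class = "subnetip_paths"
  )
}

path_list <- function(ps) {
  map(seq_len(nrow(ps$paths)), function(i) {
    list(nodes = ps$paths$nodes[[i]], edges = ps$paths$edges[[i]])
  })
}

df_to_path_list <- function(df) {
  map(seq_len(nrow(df)), function(i) list(nodes = df$nodes[[i]], edges = df$edges[[i]]))
}

#' @export
print.subnetip_paths <- function(x, ...) {
  cat(sprintf(
    "<subnetip_paths> %d paths over %d nodes and %d edges\n",
    nrow(x$paths), length(x$node_index), length(x$edge_index)
  ))
  invisible(x)
}

#' @export
tidy.subnetip_paths <- function(x, ...) {
  select(x$paths, "path_id", "source", "terminal", "n_edges", "chain")
}

#' Write a path set to a TSV table
#'
#' One row per path: pipe-delimited node chain, edge classes and oriented
#' steps, readable back with [read_paths()].
#'
#' @param ps A `subnetip_paths` object.
#' @param path Destination file.
#' @return Invisibly, `ps`.
#' @export
write_paths <- function(ps, path) {
  stopifnot(inherits(ps, "subnetip_paths"))
  pt <- ps$paths
  readr::write_tsv(
    tibble(
      path_id = pt$path_id, chain = pt$chain,
      classes = map_chr(pt$edges, ~ paste(.x$class, collapse = "|")),
      keys = map_chr(pt$edges, ~ paste(.x$key, collapse = ";"))
    ),
    path
  )
  invisible(ps)
}

#' Read a path set written by [write_paths()]
#' @param path Source file.
#' @return A `subnetip_paths` object.
#' @export
read_paths <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  paths <- map(seq_len(nrow(df)), function(i) {
    nodes <- strsplit(df$chain[i], "|", fixed = TRUE)[[1]]
    classes <- strsplit(df$classes[i], "|", fixed = TRUE)[[1]]
    keys <- strsplit(df$keys[i], ";", fixed = TRUE)[[1]]
    list(nodes = nodes, edges = tibble(
      from = nodes[-length(nodes)], to = nodes[-1], class = classes, key = keys
    ))
  })
  index_paths(paths)
}
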