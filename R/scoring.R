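#' Diffusion-kernel relevance scores from a seed gene set
#'
#' Scores every node by its proximity and connectivity to a set of seed nodes
#' (typically the screen hits): each seed carries unit weight that is
#' partially diffused to its neighbors through the network. The kernel is
#' `K = expm(-bandwidth * L)` with `L` the symmetric normalized Laplacian of
#' the undirected skeleton of the network (all edges undirected, unit weight,
#' parallel interactions collapsed), and the score of node `n` is
#' `sum over seeds h of K[n, h]`. Connected components diffuse independently;
#' an isolated seed contributes only to itself.
#'
#' The kernel is evaluated exactly by eigendecomposition of `L`, so the cost
#' is cubic in the number of nodes; this is intended for the desk-scale
#' networks this package targets, not genome-scale graphs.
#'
#' @param net A `subnetip_network`.
#' @param seeds Nonempty set of seed node ids.
#' @param bandwidth Positive diffusion bandwidth; as it approaches 0 the
#'   kernel approaches the identity and all diffusion vanishes.
#' @return A tibble `(id, score)` over all network nodes, scores nonnegative.
#' @export
diffusion_scores <- function(net, seeds, bandwidth = 0.5) {
  stopifnot(inherits(net, "subnetip_network"))
  if (length(seeds) == 0) abort("seeds must be nonempty")
  if (!is.numeric(bandwidth) || bandwidth <= 0) abort("bandwidth must be > 0")
  seeds <- norm_id(seeds)
  ids <- net$nodes$id
  unknown <- setdiff(seeds, ids)
  if (length(unknown) > 0) abort(sprintf("unknown seed id '%s'", unknown[1]))

  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  ed <- distinct(tibble(
    a = pmin(net$edges$from, net$edges$to),
    b = pmax(net$edges$from, net$edges$to)
  ))
  A[cbind(ed$a, ed$b)] <- 1
  A[cbind(ed$b, ed$a)] <- 1
  deg <- rowSums(A)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  L <- -A * tcrossprod(dinv)
  diag(L) <- ifelse(deg > 0, 1, 0)

  eg <- eigen(L, symmetric = TRUE)
  K <- eg$vectors %*% (exp(-bandwidth * eg$values) * t(eg$vectors))
  dimnames(K) <- list(ids, ids)
  sc <- rowSums(K[, seeds, drop = FALSE])
  sc <- pmax(sc, 0) # clip eigendecomposition noise below zero
  tibble(id = ids, score = as.numeric(sc))
}

#' Expression weights and expression filter from counts-per-million
#'
#' Converts normalized counts-per-million (CPM) values into node selection
#' weights for the regulatory integer program. Genes below `min_cpm` are
#' marked ineligible — they are considered not expressed in the assayed cells
#' and are excluded from path enumeration and subnetwork candidacy. Eligible
#' genes receive the damped weight `log2(CPM + 1)`, so a handful of very
#' highly expressed genes cannot dominate the score objective.
#'
#' @param cpm_table A data frame with columns `gene` and `cpm` (nonnegative).
#' @param min_cpm Nonnegative expression threshold; default 1 CPM.
#' @return A tibble `(gene, cpm, eligible, weight)`; `weight` is `NA` for
#'   ineligible genes.
#' @export
expression_weights <- function(cpm_table, min_cpm = 1) {
  tb <- as_tibble(cpm_table)
  if (!all(c("gene", "cpm") %in% names(tb))) {
    abort("cpm_table needs columns `gene` and `cpm`")
  }
  if (any(is.na(tb$cpm)) || any(tb$cpm < 0)) abort("CPM values must be nonnegative")
  if (min_cpm < 0) abort("min_cpm must be nonnegative")
  mutate(
    tibble(gene = norm_id(tb$gene), cpm = as.numeric(tb$cpm)),
    eligible = .data$cpm >= min_cpm,
    weight = if_else(.data$eligible, log2(.data$cpm + 1), NA_real_)
  )
}

#' Remove unexpressed genes from a background network
#'
#' Drops gene-kind nodes marked ineligible by [expression_weights()], along
#' with their edges, so unexpressed genes cannot appear in enumerated paths.
#' Designated source and DE-target nodes are retained regardless (the task
#' defines them), as are non-gene nodes.
#'
#' @param net A `subnetip_network`.
#' @param weights Output of [expression_weights()].
#' @return The filtered network.
#' @export
filter_expressed <- function(net, weights) {
  stopifnot(inherits(net, "subnetip_network"))
  drop <- weights$gene[!weights$eligible]
  nd <- net$nodes
  drop <- intersect(drop, nd$id[nd$kind == "gene" & !nd$source & !nd$de_target])
  if (length(drop) == 0) {
    return(net)
  }
  nodes <- filter(nd, !.data$id %in% drop)
  edges <- filter(net$edges, !.data$from %in% drop & !.data$to %in% drop)
  net$nodes <- nodes
  net$edges <- edges
  derive_roles(net)
}

# normalize a score table/vector to a named numeric lookup
as_score_map <- function(scores) {
  if (is.numeric(scores) && !is.null(names(scores))) {
    return(scores)
  }
  tb <- as_tibble(scores)
  id_col <- intersect(c("id", "gene", "node"), names(tb))[1]
  val_col <- intersect(c("score", "weight"), names(tb))[1]
  if (is.na(id_col) || is.na(val_col)) {
    abort("scores must be a named numeric vector or a table with id/gene and score/weight columns")
  }
  v <- tb[[val_col]]
  v[is.na(v)] <- 0
  structure(as.numeric(v), names = norm_id(tb[[id_col]]))
}
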