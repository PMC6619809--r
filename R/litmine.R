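#' Build a literature corpus abstraction
#'
#' The corpus is an offline abstraction of a literature search service: for
#' each gene, the set of abstract ids mentioning it, and for each query, the
#' set of abstract ids matching it. No text is stored or mined; the
#' memberships are precomputed inputs.
#'
#' @param gene_abstracts A data frame `(gene, abstract_id)`, one row per
#'   mention, or a named list of abstract-id vectors.
#' @param query_abstracts A data frame `(query, abstract_id)` or a named list
#'   of abstract-id vectors.
#' @return A `subnetip_corpus` with `$gene_abstracts` and `$query_abstracts`
#'   as named lists of unique abstract-id character vectors.
#' @export
corpus <- function(gene_abstracts, query_abstracts) {
  to_sets <- function(x, key, norm = identity) {
    if (is.data.frame(x)) {
      x <- as_tibble(x)
      if (!all(c(key, "abstract_id") %in% names(x))) {
        abort(sprintf("table needs columns `%s` and `abstract_id`", key))
      }
      sets <- split(as.character(x$abstract_id), norm(x[[key]]))
    } else {
      sets <- x
      names(sets) <- norm(names(sets))
    }
    lapply(sets, function(s) sort(unique(as.character(s))))
  }
  structure(
    list(
      gene_abstracts = to_sets(gene_abstracts, "gene", norm_id),
      query_abstracts = to_sets(query_abstracts, "query")
    ),
    class = "subnetip_corpus"
  )
}

#' Read a corpus from gene-abstract and query-abstract TSV tables
#'
#' @param gene_abstract_path TSV with header `gene  abstract_id`.
#' @param query_abstract_path TSV with header `query  abstract_id`.
#' @return A `subnetip_corpus`.
#' @export
read_corpus <- function(gene_abstract_path, query_abstract_path) {
  ga <- readr::read_tsv(gene_abstract_path,
    col_types = readr::cols(.default = readr::col_character())
  )
  qa <- readr::read_tsv(query_abstract_path,
    col_types = readr::cols(.default = readr::col_character())
  )
  corpus(ga, qa)
}

#' @export
print.subnetip_corpus <- function(x, ...) {
  cat(sprintf(
    "<subnetip_corpus> %d genes, %d queries, %d distinct abstracts\n",
    length(x$gene_abstracts), length(x$query_abstracts),
    length(unique(c(unlist(x$gene_abstracts), unlist(x$query_abstracts))))
  ))
  invisible(x)
}

#' Rank genes against a literature query
#'
#' For each gene g with abstract set A_g, and a query q with abstract set
#' A_q, the query-matching support is the intersection A_g^q. The ranking
#' criterion is the F1 (harmonic mean) of an adjusted precision
#' `|A_g^q| / (|A_g| + pseudocount)` — the pseudocount biases the measure
#' toward genes with more total literature evidence — and the recall
#' `|A_g^q| / |A_q|`, the fraction of query-matching abstracts that mention
#' the gene. F1 is 0 exactly when the support is 0.
#'
#' @param corp A `subnetip_corpus`.
#' @param query A query id present in the corpus.
#' @param pseudocount Nonnegative integer added to `|A_g|` in the precision
#'   denominator; default 10.
#' @return A `subnetip_ranking` tibble `(gene, support, precision, recall,
#'   f1)` sorted by f1 descending, ties broken by support then gene id.
#' @export
rank_genes <- function(corp, query, pseudocount = 10) {
  stopifnot(inherits(corp, "subnetip_corpus"))
  if (pseudocount < 0) abort("pseudocount must be nonnegative")
  Aq <- corp$query_abstracts[[query]]
  if (is.null(Aq)) abort(sprintf("query '%s' not in corpus", query))
  if (length(Aq) == 0) abort("query matches no abstracts; recall undefined")

  rows <- imap(corp$gene_abstracts, function(Ag, g) {
    support <- length(intersect(Ag, Aq))
    precision <- support / (length(Ag) + pseudocount)
    recall <- support / length(Aq)
    f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
    tibble(gene = g, support = support, precision = precision, recall = recall, f1 = f1)
  })
  out <- bind_rows(rows)
  out <- arrange(out, dplyr::desc(.data$f1), dplyr::desc(.data$support), .data$gene)
  structure(out, class = c("subnetip_ranking", class(out)), query = query)
}

#' Promote literature-supported genes to source roles
#'
#' Genes whose query-matching abstract support reaches `min_support`
#' (default: mentioned in two or more query-matching abstracts), that exist
#' in the network as gene-kind nodes and are not already hits or interfaces,
#' gain the hit (source) role. Ranked genes absent from the network are
#' skipped with a warning. The operation is idempotent.
#'
#' @param net A `subnetip_network`.
#' @param ranking A `subnetip_ranking` from [rank_genes()].
#' @param min_support Minimum query-matching abstract count; default 2.
#' @param top_k Optional cap: use only the `top_k` highest-ranked qualifying
#'   genes.
#' @param role Role granted to qualifying genes, `"hit"` (default) or
#'   `"source"`.
#' @return The augmented network; the number of promoted genes is reported
#'   with a message.
#' @export
augment_sources <- function(net, ranking, min_support = 2, top_k = NULL,
                            role = c("hit", "source")) {
  stopifnot(inherits(net, "subnetip_network"))
  role <- match.arg(role)
  if (min_support < 1) abort("min_support must be a positive integer")
  cand <- filter(as_tibble(ranking), .data$support >= min_support)
  absent <- setdiff(cand$gene, net$nodes$id)
  if (length(absent) > 0) {
    warn(sprintf("%d supported gene(s) absent from the network; skipped", length(absent)))
  }
  nd <- net$nodes
  eligible <- nd$id[nd$kind == "gene" & !nd$hit & !nd$interface]
  add <- cand$gene[cand$gene %in% eligible]
  if (!is.null(top_k)) add <- utils::head(add, top_k)
  if (length(add) > 0) net <- set_role(net, role, add, TRUE)
  inform(sprintf("augment_sources: promoted %d gene(s) to role '%s'", length(add), role))
  net
}

#' Import literature-derived regulatory interactions as network edges
#'
#' Adds directed `literature_regulatory` edges (regulator -> target) from a
#' text-mining export. When `required_downstream` is given, only rows whose
#' target belongs to it are imported (the use case: interactions with one of
#' the task's DE genes as the downstream target). Pairs already covered by a
#' directed protein-DNA edge are not duplicated, so the imported interactions
#' complement, and are treated the same as, the protein-DNA interactions.
#'
#' @param net A `subnetip_network`.
#' @param edge_table A data frame with columns `regulator` and `target`
#'   (optionally `provenance`), or a path to such a TSV.
#' @param required_downstream Optional gene set the target must belong to.
#' @param create_nodes If `TRUE`, endpoints absent from the network are
#'   created as gene-kind nodes; otherwise such rows are skipped with a
#'   warning.
#' @return The augmented network.
#' @export
import_literature_edges <- function(net, edge_table, required_downstream = NULL,
                                    create_nodes = FALSE) {
  stopifnot(inherits(net, "subnetip_network"))
  tb <- if (is.character(edge_table) && length(edge_table) == 1) {
    readr::read_tsv(edge_table, col_types = readr::cols(.default = readr::col_character()))
  } else {
    as_tibble(edge_table)
  }
  if (!all(c("regulator", "target") %in% names(tb))) {
    abort("edge table needs columns `regulator` and `target`")
  }
  bad <- which(is.na(tb$regulator) | is.na(tb$target) |
    !nzchar(trimws(tb$regulator)) | !nzchar(trimws(tb$target)))
  if (length(bad) > 0) abort(sprintf("malformed literature edge in row %d", bad[1]))
  tb <- tibble(regulator = norm_id(tb$regulator), target = norm_id(tb$target))
  if (!is.null(required_downstream)) {
    tb <- filter(tb, .data$target %in% norm_id(required_downstream))
  }
  tb <- distinct(tb)
  tb <- filter(tb, .data$regulator != .data$target)
  if (nrow(tb) == 0) {
    return(net)
  }

  missing_nodes <- setdiff(c(tb$regulator, tb$target), net$nodes$id)
  if (length(missing_nodes) > 0) {
    if (create_nodes) {
      net$nodes <- bind_rows(net$nodes, tibble(
        id = missing_nodes, kind = "gene", hit = FALSE, interface = FALSE,
        de_target = FALSE, source = FALSE, score = 0
      ))
    } else {
      warn(sprintf(
        "%d edge(s) reference nodes absent from the network; skipped", sum(
          tb$regulator %in% missing_nodes | tb$target %in% missing_nodes
        )
      ))
      tb <- filter(tb, !.data$regulator %in% missing_nodes & !.data$target %in% missing_nodes)
    }
  }

  pd <- filter(net$edges, .data$class == "protein_dna" & .data$directed)
  dup_pd <- paste(tb$regulator, tb$target) %in% paste(pd$from, pd$to)
  tb <- tb[!dup_pd, ]

  new_edges <- tibble(
    from = tb$regulator, to = tb$target, directed = TRUE,
    class = "literature_regulatory"
  )
  net$edges <- distinct(bind_rows(net$edges, new_edges))
  net$edges <- arrange(net$edges, .data$from, .data$to, .data$class, .data$directed)
  net$nodes <- arrange(net$nodes, .data$id)
  derive_roles(net)
}
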