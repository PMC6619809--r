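# evaluate code under a temporary RNG seed, restoring global RNG state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Hold aside a fraction of role-confirmed genes
#'
#' Draws a uniform random subset of the confirmed genes (by default the hits
#' and interfaces) and strips those roles from them, so they are treated as
#' unconfirmed during inference. This is the subsampling step of the
#' ensemble protocol: the held-aside genes stay in the background network,
#' only the knowledge of their role is hidden.
#'
#' @param net A `subnetip_network`.
#' @param hold_fraction Fraction of confirmed genes to hold aside, in (0, 1);
#'   default 0.25. The held count is `round(hold_fraction * n)` clamped to
#'   `[1, n - 1]`.
#' @param seed Integer seed; identical seeds give identical draws.
#' @param roles Which roles define the confirmed pool (default hit and
#'   interface; use `"de_target"` for the regulatory task).
#' @return A list with `$network` (roles stripped, index rebuilt) and
#'   `$held` (the held-aside gene ids).
#' @export
subsample_roles <- function(net, hold_fraction = 0.25, seed = 1,
                            roles = c("hit", "interface")) {
  stopifnot(inherits(net, "subnetip_network"))
  if (!is.numeric(hold_fraction) || hold_fraction <= 0 || hold_fraction >= 1) {
    abort("hold_fraction must be in (0, 1)")
  }
  roles <- match.arg(roles, NODE_ROLES, several.ok = TRUE)
  pool <- sort(unique(unlist(lapply(roles, function(r) net$nodes$id[net$nodes[[r]]]))))
  if (length(pool) < 2) abort("need at least 2 role-confirmed genes to subsample")
  n_hold <- min(max(1L, as.integer(round(hold_fraction * length(pool)))), length(pool) - 1L)
  held <- with_local_seed(seed, sort(sample(pool, n_hold)))
  mod <- net
  for (r in roles) mod$nodes[[r]][mod$nodes$id %in% held] <- FALSE
  list(network = derive_roles(mod), held = held)
}

run_one <- function(net, formulation, params, scores_fixed) {
  max_edges <- params$max_edges %||% 3
  if (formulation == "hostvirus") {
    sources <- net$roles$hits
    targets <- net$roles$interfaces
    if (length(sources) == 0 || length(targets) == 0) abort("no hits or no interfaces left")
    ps <- enumerate_paths(net, sources, targets,
      max_edges = max_edges,
      allow_through_targets = isTRUE(params$allow_through_targets)
    )
    if (nrow(ps$paths) == 0) abort("no candidate paths")
    scores <- scores_fixed %||%
      diffusion_scores(net, seeds = sources, bandwidth = params$bandwidth %||% 0.5)
    inst <- build_hostvirus_ip(net, ps, scores,
      delta = params$delta, epsilon = params$epsilon %||% 0.1,
      beta_override = params$beta_override
    )
  } else {
    terminal <- params$terminal_class %||% c("protein_dna", "literature_regulatory")
    src <- net$roles$sources
    targets <- net$roles$de_targets
    if (length(targets) == 0) abort("no DE targets left")
    ps <- enumerate_paths(net, src, targets,
      max_edges = max_edges, terminal_class = terminal,
      allow_through_targets = isTRUE(params$allow_through_targets)
    )
    if (nrow(ps$paths) == 0) abort("no candidate paths")
    weights <- scores_fixed %||% params$weights
    if (is.null(weights)) abort("regulatory runs need expression weights (params$weights)")
    inst <- build_regulatory_ip(net, ps, weights)
  }
  sol <- solve_lexicographic(inst,
    tolerance = params$tolerance %||% 1e-6,
    node_limit = params$node_limit %||% 5e5
  )
  list(ps = ps, inst = inst, sol = sol)
}

#' Run a subsample ensemble of subnetwork inferences
#'
#' Repeats `n_runs` times: hold aside a fraction of the role-confirmed genes
#' ([subsample_roles()]), re-enumerate candidate paths on the subsampled
#' network, build the chosen integer program, and solve it. Inclusion
#' frequencies are computed over the successful runs; per-gene hold-aside
#' confidences record how often a gene was recovered in the runs where its
#' role was hidden. Infeasible or failed runs are excluded from the
#' denominators and logged.
#'
#' @param net A `subnetip_network` with roles set.
#' @param ps Optional master `subnetip_paths` on the full network (used for
#'   the consensus path restriction); enumerated if `NULL`.
#' @param scores Optional fixed score map used for every run (a tibble or
#'   named vector). When `NULL`, host-virus runs recompute diffusion scores
#'   from each run's visible hits, and regulatory runs use `params$weights`.
#' @param params A list of inference parameters: `delta`, `epsilon`,
#'   `beta_override`, `tolerance`, `max_edges`, `terminal_class`,
#'   `bandwidth`, `weights`, `allow_through_targets`, `node_limit`.
#' @param n_runs Number of subsample cycles (default 100).
#' @param base_seed Integer; run `r` uses seed `base_seed + r`.
#' @param formulation `"hostvirus"` or `"regulatory"`.
#' @param hold_fraction Passed to [subsample_roles()]; default 0.25.
#' @return A `subnetip_ensemble`: `$runs` (per-run held set, status, relevant
#'   nodes/edges), `$node_frequency` and `$edge_frequency` tibbles,
#'   `$holdout_confidence` tibble (`gene`, `n_held`, `confidence`),
#'   `$master_paths`, `$n_success`, and the resolved parameters.
#' @export
run_ensemble <- function(net, ps = NULL, scores = NULL, params = list(),
                         n_runs = 100, base_seed = 1,
                         formulation = c("hostvirus", "regulatory"),
                         hold_fraction = 0.25) {
  stopifnot(inherits(net, "subnetip_network"))
  formulation <- match.arg(formulation)
  if (n_runs < 1) abort("n_runs must be >= 1")
  roles <- if (formulation == "hostvirus") c("hit", "interface") else "de_target"
  scores_fixed <- if (!is.null(scores)) as_score_map(scores)

  if (is.null(ps)) {
    ps <- if (formulation == "hostvirus") {
      enumerate_paths(net, net$roles$hits, net$roles$interfaces,
        max_edges = params$max_edges %||% 3,
        allow_through_targets = isTRUE(params$allow_through_targets)
      )
    } else {
      enumerate_paths(net, net$roles$sources, net$roles$de_targets,
        max_edges = params$max_edges %||% 3,
        terminal_class = params$terminal_class %||% c("protein_dna", "literature_regulatory"),
        allow_through_targets = isTRUE(params$allow_through_targets)
      )
    }
  }

  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    seed_r <- base_seed + r
    sub <- subsample_roles(net, hold_fraction, seed = seed_r, roles = roles)
    res <- tryCatch(
      {
        out <- run_one(sub$network, formulation, params, scores_fixed)
        if (out$sol$status != "optimal") abort("infeasible")
        a <- out$sol$assignment
        v <- out$sol$vars
        list(
          held = sub$held, seed = seed_r, status = "optimal",
          rel_nodes = v$ref[v$family == "y" & a[v$name] == 1L],
          rel_edges = v$ref[v$family == "x" & a[v$name] == 1L],
          objective_values = out$sol$objective_values
        )
      },
      error = function(e) {
        inform(sprintf("ensemble run %d (seed %d) failed: %s", r, seed_r, conditionMessage(e)))
        list(held = sub$held, seed = seed_r, status = "failed")
      }
    )
    runs[[r]] <- res
  }

  ok <- keep(runs, ~ .x$status == "optimal")
  if (length(ok) == 0) abort("all ensemble runs failed or were infeasible")

  all_ids <- net$nodes$id
  node_count <- structure(rep(0L, length(all_ids)), names = all_ids)
  edge_count <- list()
  for (rn in ok) {
    node_count[rn$rel_nodes] <- node_count[rn$rel_nodes] + 1L
    for (e in rn$rel_edges) edge_count[[e]] <- (edge_count[[e]] %||% 0L) + 1L
  }
  node_frequency <- tibble(id = all_ids, frequency = as.numeric(node_count) / length(ok))
  edge_frequency <- tibble(
    key = names(edge_count),
    frequency = map_dbl(edge_count, ~ .x / length(ok))
  )

  held_tally <- list()
  for (rn in ok) {
    for (g in rn$held) {
      ht <- held_tally[[g]] %||% c(0L, 0L)
      held_tally[[g]] <- ht + c(1L, as.integer(g %in% rn$rel_nodes))
    }
  }
  holdout_confidence <- tibble(
    gene = names(held_tally),
    n_held = map_int(held_tally, 1),
    confidence = map_dbl(held_tally, ~ .x[2] / .x[1])
  )
  holdout_confidence <- arrange(holdout_confidence, .data$gene)

  structure(
    list(
      runs = runs, node_frequency = node_frequency, edge_frequency = edge_frequency,
      holdout_confidence = holdout_confidence, master_paths = ps,
      n_success = length(ok),
      params = c(params, list(
        formulation = formulation, n_runs = n_runs,
        base_seed = base_seed, hold_fraction = hold_fraction
      ))
    ),
    class = "subnetip_ensemble"
  )
}

#' @export
print.subnetip_ensemble <- function(x, ...) {
  cat(sprintf(
    "<subnetip_ensemble> %s: %d/%d runs optimal; %d genes held aside at least once\n",
    x$params$formulation, x$n_success, x$params$n_runs, nrow(x$holdout_confidence)
  ))
  invisible(x)
}

#' @export
tidy.subnetip_ensemble <- function(x, ...) x$node_frequency

#' @export
glance.subnetip_ensemble <- function(x, ...) {
  tibble(
    formulation = x$params$formulation, n_runs = x$params$n_runs,
    n_success = x$n_success,
    n_ever_included = sum(x$node_frequency$frequency > 0),
    n_held_genes = nrow(x$holdout_confidence)
  )
}

#' Consensus subnetwork from an ensemble
#'
#' Keeps the nodes and edges whose ensemble inclusion frequency reaches
#' `freq_threshold`, and restricts the master path set to paths all of whose
#' nodes and edges survive.
#'
#' @param er A `subnetip_ensemble`.
#' @param freq_threshold Inclusion-frequency threshold in (0, 1]; default 0.5.
#' @return A `subnetip_consensus` list: `$nodes` (ids), `$edges` (keys),
#'   `$paths` (a `subnetip_paths`), `$threshold`.
#' @export
consensus_subnetwork <- function(er, freq_threshold = 0.5) {
  stopifnot(inherits(er, "subnetip_ensemble"))
  if (freq_threshold <= 0 || freq_threshold > 1) abort("freq_threshold must be in (0, 1]")
  nodes <- er$node_frequency$id[er$node_frequency$frequency >= freq_threshold]
  edges <- er$edge_frequency$key[er$edge_frequency$frequency >= freq_threshold]
  pt <- er$master_paths$paths
  keep_path <- map_lgl(seq_len(nrow(pt)), function(i) {
    all(pt$nodes[[i]] %in% nodes) && all(pt$edges[[i]]$key %in% edges)
  })
  structure(
    list(
      nodes = nodes, edges = edges,
      paths = index_paths(path_list(er$master_paths)[which(keep_path)]),
      threshold = freq_threshold
    ),
    class = "subnetip_consensus"
  )
}

#' @export
print.subnetip_consensus <- function(x, ...) {
  cat(sprintf(
    "<subnetip_consensus> threshold %.2f: %d nodes, %d edges, %d paths\n",
    x$threshold, length(x$nodes), length(x$edges), nrow(x$paths$paths)
  ))
  invisible(x)
}

#' Hold-aside precision-recall curve
#'
#' Scores the positive genes by their hold-aside confidence (how often they
#' were recovered when their role was hidden) and the negative genes by their
#' overall inclusion frequency, then sweeps a threshold over every distinct
#' confidence value. At threshold `t` a gene is predicted relevant if its
#' score is `>= t`; recall is the fraction of positives predicted relevant
#' and precision the fraction of predicted-relevant genes that are positives.
#' Positives never held aside carry no confidence and are excluded with a
#' warning.
#'
#' @param er A `subnetip_ensemble`.
#' @param positives Gene ids known to be relevant (e.g. all hits and
#'   interfaces).
#' @param negatives Gene ids presumed irrelevant (e.g. all unconfirmed
#'   background genes); must be disjoint from `positives`.
#' @return A `subnetip_pr` tibble `(threshold, precision, recall)` ordered by
#'   decreasing threshold, with attributes `prevalence`, `n_positives`,
#'   `n_negatives`.
#' @export
pr_curve <- function(er, positives, negatives) {
  stopifnot(inherits(er, "subnetip_ensemble"))
  positives <- norm_id(positives)
  negatives <- norm_id(negatives)
  if (length(positives) == 0 || length(negatives) == 0) {
    abort("positives and negatives must be nonempty")
  }
  if (length(intersect(positives, negatives)) > 0) {
    abort("positives and negatives must be disjoint")
  }
  hc <- structure(er$holdout_confidence$confidence, names = er$holdout_confidence$gene)
  no_conf <- setdiff(positives, names(hc))
  if (length(no_conf) > 0) {
    warn(sprintf("%d positive gene(s) never held aside; excluded from the curve", length(no_conf)))
    positives <- setdiff(positives, no_conf)
  }
  if (length(positives) == 0) abort("no positive gene carries a hold-aside confidence")
  nf <- structure(er$node_frequency$frequency, names = er$node_frequency$id)
  neg_scores <- ifelse(is.na(nf[negatives]), 0, nf[negatives])

  score <- c(structure(hc[positives], names = positives),
    structure(neg_scores, names = negatives)
  )
  is_pos <- c(rep(TRUE, length(positives)), rep(FALSE, length(negatives)))
  thresholds <- sort(unique(as.numeric(score)), decreasing = TRUE)
  rows <- map(thresholds, function(t) {
    pred <- score >= t - 1e-12
    tp <- sum(pred & is_pos)
    tibble(
      threshold = t,
      precision = tp / sum(pred),
      recall = tp / length(positives)
    )
  })
  out <- bind_rows(rows)
  prevalence <- length(positives) / (length(positives) + length(negatives))
  structure(out,
    class = c("subnetip_pr", class(out)),
    prevalence = prevalence,
    n_positives = length(positives), n_negatives = length(negatives)
  )
}

#' Area under a precision-recall curve
#'
#' Step-wise average precision: sums precision at each achieved recall level
#' weighted by the recall increment.
#'
#' @param pr A `subnetip_pr` curve.
#' @return A single number in \[0, 1\].
#' @export
pr_auc <- function(pr) {
  stopifnot(inherits(pr, "subnetip_pr"))
  pr <- pr[order(pr$recall), ]
  dr <- diff(c(0, pr$recall))
  sum(dr * pr$precision)
}

#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_point geom_hline
#'   geom_col labs theme_minimal
#' @export
autoplot.subnetip_pr <- function(object, ...) {
  ggplot(object, aes(x = .data$recall, y = .data$precision)) +
    geom_step(direction = "vh", color = "#2166ac") +
    geom_point(size = 0.8, color = "#2166ac") +
    geom_hline(
      yintercept = attr(object, "prevalence"),
      linetype = "dashed", color = "#66bd63"
    ) +
    labs(
      x = "Recall", y = "Precision",
      title = "Hold-aside precision-recall",
      subtitle = sprintf(
        "prevalence %.3f (%d positives, %d negatives)",
        attr(object, "prevalence"),
        attr(object, "n_positives"), attr(object, "n_negatives")
      )
    ) +
    theme_minimal()
}

#' @export
autoplot.subnetip_ensemble <- function(object, ...) {
  df <- filter(object$node_frequency, .data$frequency > 0)
  ggplot(df, aes(x = stats::reorder(.data$id, -.data$frequency), y = .data$frequency)) +
    geom_col(fill = "#2166ac") +
    labs(
      x = NULL, y = "Inclusion frequency",
      title = sprintf(
        "Ensemble inclusion frequencies (%d/%d runs optimal)",
        object$n_success, object$params$n_runs
      )
    ) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, size = 6))
}
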