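# A linear 0-1 program over path (sigma), edge (x) and node (y) indicator
# variables, with an ordered list of objectives solved sequentially.
new_ip_instance <- function(vars, objectives, constraints, params) {
  structure(
    list(vars = vars, objectives = objectives, constraints = constraints, params = params),
    class = "subnetip_ip"
  )
}

#' @export
print.subnetip_ip <- function(x, ...) {
  cat(sprintf(
    "<subnetip_ip> %s: %d variables (%d paths, %d edges, %d nodes), %d objectives, %d constraints\n",
    x$params$formulation, nrow(x$vars),
    sum(x$vars$family == "sigma"), sum(x$vars$family == "x"), sum(x$vars$family == "y"),
    length(x$objectives), length(x$constraints)
  ))
  invisible(x)
}

# instance edge catalogue: one row per distinct edge key used by any path
instance_edges <- function(ps) {
  ed <- bind_rows(ps$paths$edges)
  if (nrow(ed) == 0) {
    return(tibble(
      key = character(), a = character(), b = character(),
      directed = logical(), class = character()
    ))
  }
  parts <- strsplit(unique(ed$key), "|", fixed = TRUE)
  tibble(
    key = unique(ed$key),
    a = map_chr(parts, 1), b = map_chr(parts, 2),
    directed = map_chr(parts, 3) == ">",
    class = map_chr(parts, 4)
  )
}

lin <- function(names, coefs = rep(1, length(names))) {
  v <- as.numeric(unname(coefs))
  names(v) <- as.character(names)
  v
}

# paste0() maps zero-length inputs to "", which is never a variable name
vn <- function(prefix, ids) {
  if (length(ids) == 0) character(0) else paste0(prefix, ids)
}

constraint <- function(name, coef, sense, rhs) {
  list(name = name, coef = coef, sense = sense, rhs = rhs)
}

# shared structural constraints: edges relevant iff on a selected path, nodes
# relevant iff touching a relevant edge
linkage_constraints <- function(ps, iedges) {
  cons <- list()
  pt <- ps$paths
  for (ky in iedges$key) {
    pids <- ps$edge_index[[ky]]
    cons[[length(cons) + 1]] <- constraint(
      paste0("edge_support[", ky, "]"),
      lin(c(paste0("x_", ky), vn("sigma_", pids)), c(1, rep(-1, length(pids)))),
      "<=", 0
    )
  }
  for (i in seq_len(nrow(pt))) {
    for (ky in pt$edges[[i]]$key) {
      cons[[length(cons) + 1]] <- constraint(
        paste0("path_edge[", pt$path_id[i], ",", ky, "]"),
        lin(c(paste0("sigma_", pt$path_id[i]), paste0("x_", ky)), c(1, -1)),
        "<=", 0
      )
    }
  }
  node_edges <- split(
    rep(iedges$key, 2),
    c(iedges$a, iedges$b)
  )
  for (nd in names(node_edges)) {
    keys <- unique(node_edges[[nd]])
    cons[[length(cons) + 1]] <- constraint(
      paste0("node_support[", nd, "]"),
      lin(c(paste0("y_", nd), vn("x_", keys)), c(1, rep(-1, length(keys)))),
      "<=", 0
    )
    for (ky in keys) {
      cons[[length(cons) + 1]] <- constraint(
        paste0("edge_node[", ky, ",", nd, "]"),
        lin(c(paste0("x_", ky), paste0("y_", nd)), c(1, -1)),
        "<=", 0
      )
    }
  }
  cons
}

ip_vars <- function(ps, iedges) {
  path_nodes <- sort(unique(unlist(ps$paths$nodes)))
  bind_rows(
    tibble(
      name = vn("sigma_", ps$paths$path_id), family = "sigma",
      ref = as.character(ps$paths$path_id)
    ),
    tibble(name = vn("x_", iedges$key), family = "x", ref = iedges$key),
    tibble(name = paste0("y_", path_nodes), family = "y", ref = path_nodes)
  )
}

#' Build the host-virus subnetwork integer program
#'
#' Constructs the path-selection program for the screen-to-interface task.
#' Binary variables mark paths (`sigma_p`), edges (`x_e`) and nodes (`y_n`)
#' as relevant. Two objectives are optimized in sequence: first maximize the
#' summed relevance score of included unconfirmed genes, then maximize the
#' number of included paths. Constraints: at most `delta` unconfirmed genes
#' may be included; an edge is relevant iff it lies on a relevant path and a
#' node iff it touches a relevant edge; at least a fraction `1 - epsilon` of
#' all hits, and of all interfaces, must be relevant; a complex may be
#' relevant only if at least a fraction `beta` of its protein subunits is
#' relevant (and its membership edges require the complex relevant); a
#' reaction may be relevant only if all its substrates and products are.
#'
#' The default complex-majority threshold is
#' `beta = 2 * (|N_H union N_I| + delta) / 20000`, clamped to `(0, 1]`, and
#' can be overridden.
#'
#' @param net A `subnetip_network` whose role index supplies hits,
#'   interfaces, unconfirmed genes, complexes and reactions.
#' @param ps A `subnetip_paths` set enumerated from the hits to the
#'   interface targets.
#' @param scores Relevance scores covering the unconfirmed genes: a tibble
#'   `(id, score)` (e.g. from [diffusion_scores()]) or a named numeric
#'   vector.
#' @param delta Nonnegative integer budget on included unconfirmed genes.
#'   Default `ceiling(0.1 * |N_H union N_I|)`.
#' @param epsilon Allowed miss fraction for hit and interface coverage, in
#'   `[0, 1)`. Default 0.1.
#' @param beta_override Optional complex-majority threshold in `(0, 1]`.
#' @return A `subnetip_ip` instance with ordered objectives.
#' @export
build_hostvirus_ip <- function(net, ps, scores, delta = NULL, epsilon = 0.1,
                               beta_override = NULL) {
  stopifnot(inherits(net, "subnetip_network"), inherits(ps, "subnetip_paths"))
  confirmed <- union(net$roles$hits, net$roles$interfaces)
  if (is.null(delta)) delta <- ceiling(0.1 * length(confirmed))
  if (delta < 0 || delta != round(delta)) abort("delta must be a nonnegative integer")
  if (epsilon < 0 || epsilon >= 1) abort("epsilon must be in [0, 1)")
  sc <- as_score_map(scores)

  iedges <- instance_edges(ps)
  unknown <- setdiff(unique(unlist(ps$paths$nodes)), net$nodes$id)
  if (length(unknown) > 0) abort(sprintf("path references node '%s' absent from network", unknown[1]))
  vars <- ip_vars(ps, iedges)
  path_nodes <- vars$ref[vars$family == "y"]

  uncf <- intersect(net$roles$unconfirmed, path_nodes)
  missing_sc <- setdiff(uncf, names(sc))
  if (length(missing_sc) > 0) {
    abort(sprintf("no score for unconfirmed gene '%s'", missing_sc[1]))
  }

  objectives <- list(
    list(
      name = "unconfirmed_score", sense = "max",
      coef = lin(vn("y_", uncf), sc[uncf])
    ),
    list(
      name = "n_paths", sense = "max",
      coef = lin(vn("sigma_", ps$paths$path_id))
    )
  )

  cons <- list()
  if (length(uncf) > 0) {
    cons[[length(cons) + 1]] <- constraint(
      "unconfirmed_budget", lin(vn("y_", uncf)), "<=", delta
    )
  }
  cons <- c(cons, linkage_constraints(ps, iedges))

  hits_in <- intersect(net$roles$hits, path_nodes)
  cons[[length(cons) + 1]] <- constraint(
    "hit_coverage", lin(vn("y_", hits_in)),
    ">=", (1 - epsilon) * length(net$roles$hits)
  )
  ifc_in <- intersect(net$roles$interfaces, path_nodes)
  cons[[length(cons) + 1]] <- constraint(
    "interface_coverage", lin(vn("y_", ifc_in)),
    ">=", (1 - epsilon) * length(net$roles$interfaces)
  )

  beta <- beta_override %||% (2 * (length(confirmed) + delta) / 20000)
  beta <- min(max(beta, 1e-6), 1)

  memb <- filter(net$edges, .data$class == "complex_membership")
  for (cx in intersect(net$roles$complexes, path_nodes)) {
    members <- memb$from[memb$to == cx]
    nmem <- length(members)
    if (nmem > 0) {
      mem_in <- intersect(members, path_nodes)
      cons[[length(cons) + 1]] <- constraint(
        paste0("complex_majority[", cx, "]"),
        lin(c(vn("y_", mem_in), paste0("y_", cx)), c(rep(1, length(mem_in)), -nmem)),
        ">=", (beta - 1) * nmem
      )
    }
    mkeys <- iedges$key[iedges$class == "complex_membership" & iedges$b == cx]
    for (ky in mkeys) {
      cons[[length(cons) + 1]] <- constraint(
        paste0("membership_edge[", ky, "]"),
        lin(c(paste0("x_", ky), paste0("y_", cx)), c(1, -1)),
        "<=", 0
      )
    }
  }

  rio <- filter(net$edges, .data$class == "reaction_io")
  for (r in intersect(net$roles$reactions, path_nodes)) {
    partners <- union(rio$from[rio$to == r], rio$to[rio$from == r])
    for (n in partners) {
      coef <- if (n %in% path_nodes) {
        lin(c(paste0("y_", r), paste0("y_", n)), c(1, -1))
      } else {
        lin(paste0("y_", r), 1) # partner can never be relevant
      }
      cons[[length(cons) + 1]] <- constraint(
        paste0("reaction_io[", r, ",", n, "]"), coef, "<=", 0
      )
    }
  }

  new_ip_instance(
    vars, objectives, cons,
    list(
      formulation = "hostvirus", delta = delta, epsilon = epsilon, beta = beta,
      n_hits = length(net$roles$hits), n_interfaces = length(net$roles$interfaces)
    )
  )
}

#' Build the regulatory subnetwork integer program
#'
#' Constructs the path-selection program connecting a single regulatory
#' source (a transcription factor) to its differentially expressed (DE)
#' target genes. Four objectives are optimized in sequence: (1) maximize the
#' number of DE genes reached, (2) minimize the number of intermediate
#' (non-source, non-target) nodes, (3) maximize the summed expression weight
#' of included intermediates, (4) maximize the number of included edges.
#' Constraints: a DE gene counts as reached only if at least one selected
#' path contains it and at least one relevant directed edge enters it; the
#' usual path/edge/node linkage; and intermediates may have no relevant
#' incoming directed edge, so regulation flows only into the targets.
#'
#' @param net A `subnetip_network` with exactly one `source`-role node and
#'   `de_target` roles set.
#' @param ps A `subnetip_paths` set enumerated from the source to the DE
#'   targets, terminally constrained to direct regulatory interaction
#'   classes (`protein_dna`, `literature_regulatory`).
#' @param weights Expression weights covering intermediate genes: output of
#'   [expression_weights()] or a named numeric vector.
#' @return A `subnetip_ip` instance with four ordered objectives.
#' @export
build_regulatory_ip <- function(net, ps, weights) {
  stopifnot(inherits(net, "subnetip_network"), inherits(ps, "subnetip_paths"))
  src <- net$roles$sources
  if (length(src) != 1) abort("the regulatory task requires exactly one source node")
  targets <- net$roles$de_targets
  wt <- as_score_map(weights)

  iedges <- instance_edges(ps)
  vars <- ip_vars(ps, iedges)
  path_nodes <- vars$ref[vars$family == "y"]
  tgt_in <- intersect(targets, path_nodes)
  interm <- setdiff(path_nodes, c(src, targets))
  missing_wt <- setdiff(interm, names(wt))
  if (length(missing_wt) > 0) {
    abort(sprintf("no expression weight for intermediate '%s'", missing_wt[1]))
  }

  objectives <- list(
    list(name = "de_reached", sense = "max", coef = lin(vn("y_", tgt_in))),
    list(name = "n_intermediates", sense = "min", coef = lin(vn("y_", interm))),
    list(
      name = "intermediate_weight", sense = "max",
      coef = lin(vn("y_", interm), wt[interm])
    ),
    list(name = "n_edges", sense = "max", coef = lin(vn("x_", iedges$key)))
  )

  cons <- list()
  for (tg in tgt_in) {
    pids <- ps$node_index[[tg]]
    cons[[length(cons) + 1]] <- constraint(
      paste0("target_support[", tg, "]"),
      lin(c(paste0("y_", tg), vn("sigma_", pids)), c(1, rep(-1, length(pids)))),
      "<=", 0
    )
  }
  cons <- c(cons, linkage_constraints(ps, iedges))

  for (tg in tgt_in) {
    inkeys <- iedges$key[iedges$directed & iedges$b == tg]
    cons[[length(cons) + 1]] <- constraint(
      paste0("target_directed_entry[", tg, "]"),
      lin(c(paste0("y_", tg), vn("x_", inkeys)), c(1, rep(-1, length(inkeys)))),
      "<=", 0
    )
  }
  for (n in interm) {
    inkeys <- iedges$key[iedges$directed & iedges$b == n]
    if (length(inkeys) > 0) {
      cons[[length(cons) + 1]] <- constraint(
        paste0("intermediate_no_entry[", n, "]"),
        lin(vn("x_", inkeys)), "==", 0
      )
    }
  }

  new_ip_instance(
    vars, objectives, cons,
    list(formulation = "regulatory", source = src, n_targets = length(targets))
  )
}

#' Export an IP instance in LP file format
#'
#' Writes the first objective and all constraints of the instance in the
#' conventional LP text format, for solver-independent inspection. Later
#' objectives are included as comments.
#'
#' @param inst A `subnetip_ip`.
#' @param path Destination `.lp` file.
#' @return Invisibly, `path`.
#' @export
write_lp <- function(inst, path) {
  stopifnot(inherits(inst, "subnetip_ip"))
  term_str <- function(coef) {
    paste(sprintf("%+g %s", unname(coef), names(coef)), collapse = " ")
  }
  con <- file(path, "w")
  on.exit(close(con))
  o1 <- inst$objectives[[1]]
  writeLines(c(
    sprintf("\\ subnetip %s instance", inst$params$formulation),
    if (o1$sense == "max") "Maximize" else "Minimize",
    sprintf(" obj_%s: %s", o1$name, term_str(o1$coef))
  ), con)
  for (ob in inst$objectives[-1]) {
    writeLines(sprintf("\\ later objective (%s): %s %s", ob$sense, ob$name, term_str(ob$coef)), con)
  }
  writeLines("Subject To", con)
  for (cn in inst$constraints) {
    sense <- switch(cn$sense, "<=" = "<=", ">=" = ">=", "==" = "=")
    writeLines(
      sprintf(" %s: %s %s %g", gsub("[^A-Za-z0-9_]", "_", cn$name), term_str(cn$coef), sense, cn$rhs),
      con
    )
  }
  writeLines(c("Binary", paste(" ", paste(inst$vars$name, collapse = " ")), "End"), con)
  invisible(path)
}
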