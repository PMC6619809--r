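# Independent oracles used across the suite. These deliberately avoid the
# package's own search/solve machinery: paths are found by exhaustive
# node-sequence scanning, IPs by enumerating every subset of path variables,
# constraints by direct matrix arithmetic.

# --- brute-force path enumeration ------------------------------------------

# all traversable parallel edges from a to b, as canonical keys + classes
oracle_edge_options <- function(net, a, b) {
  ed <- net$edges
  sel <- (ed$from == a & ed$to == b) | (!ed$directed & ed$from == b & ed$to == a)
  ed <- ed[sel, ]
  if (nrow(ed) == 0) {
    return(NULL)
  }
  data.frame(
    class = ed$class,
    key = subnetip:::edge_key(ed$from, ed$to, ed$directed, ed$class),
    stringsAsFactors = FALSE
  )
}

# returns a character set of path signatures "chain##key1,key2,..."
oracle_paths <- function(net, sources, targets, max_edges,
                         terminal_class = NULL, allow_through = FALSE) {
  sources <- toupper(sources)
  targets <- toupper(targets)
  ids <- net$nodes$id
  chains <- list()
  grow <- function(chain) {
    cur <- chain[length(chain)]
    if (length(chain) >= 2 && cur %in% targets) {
      chains[[length(chains) + 1]] <<- chain
      if (!allow_through) {
        return(invisible(NULL))
      }
    }
    if (length(chain) - 1 >= max_edges) {
      return(invisible(NULL))
    }
    for (nb in setdiff(ids, chain)) {
      if (!is.null(oracle_edge_options(net, cur, nb))) grow(c(chain, nb))
    }
    invisible(NULL)
  }
  for (s in sources) grow(s)

  sigs <- character(0)
  for (chain in chains) {
    steps <- lapply(seq_len(length(chain) - 1), function(j) {
      oracle_edge_options(net, chain[j], chain[j + 1])
    })
    combos <- expand.grid(lapply(steps, function(s) seq_len(nrow(s))))
    for (r in seq_len(nrow(combos))) {
      keys <- vapply(seq_along(steps), function(j) steps[[j]]$key[combos[r, j]], "")
      classes <- vapply(seq_along(steps), function(j) steps[[j]]$class[combos[r, j]], "")
      if (anyDuplicated(keys) > 0) next # a path uses each network edge once
      if (!is.null(terminal_class) && !classes[length(classes)] %in% terminal_class) next
      sigs <- c(sigs, paste0(paste(chain, collapse = "|"), "##", paste(keys, collapse = ",")))
    }
  }
  sort(unique(sigs))
}

path_signatures <- function(ps) {
  sort(vapply(seq_len(nrow(ps$paths)), function(i) {
    paste0(ps$paths$chain[i], "##", paste(ps$paths$edges[[i]]$key, collapse = ","))
  }, ""))
}

# --- exhaustive IP oracle ---------------------------------------------------

# the x/y completion induced by a path subset: an edge is relevant iff on a
# selected path, a node iff it is an endpoint of a relevant edge
oracle_completions <- function(inst, ps) {
  vars <- inst$vars
  pids <- ps$paths$path_id
  P <- length(pids)
  stopifnot(P <= 16)
  xkeys <- vars$ref[vars$family == "x"]
  ynodes <- vars$ref[vars$family == "y"]

  S <- t(as.matrix(expand.grid(rep(list(0:1), P)))) # P x 2^P
  P2E <- matrix(0, length(xkeys), P, dimnames = list(xkeys, NULL))
  for (i in seq_len(P)) P2E[ps$paths$edges[[i]]$key, i] <- 1
  X <- (P2E %*% S > 0) * 1

  parts <- strsplit(xkeys, "|", fixed = TRUE)
  N2E <- matrix(0, length(ynodes), length(xkeys), dimnames = list(ynodes, xkeys))
  for (j in seq_along(parts)) {
    N2E[parts[[j]][1], j] <- 1
    N2E[parts[[j]][2], j] <- 1
  }
  Y <- (N2E %*% X > 0) * 1

  V <- matrix(0, nrow(vars), ncol(S), dimnames = list(vars$name, NULL))
  V[paste0("sigma_", pids), ] <- S
  if (length(xkeys) > 0) V[paste0("x_", xkeys), ] <- X
  if (length(ynodes) > 0) V[paste0("y_", ynodes), ] <- Y
  V
}

oracle_feasible <- function(inst, V) {
  ok <- rep(TRUE, ncol(V))
  for (cn in inst$constraints) {
    act <- as.numeric(matrix(cn$coef, nrow = 1) %*% V[names(cn$coef), , drop = FALSE])
    ok <- ok & switch(cn$sense,
      "<=" = act <= cn$rhs + 1e-7,
      ">=" = act >= cn$rhs - 1e-7,
      "==" = abs(act - cn$rhs) <= 1e-7
    )
  }
  ok
}

# lexicographically optimal objective vector over all path subsets, or NULL
# when no subset is feasible
oracle_lex <- function(inst, ps) {
  V <- oracle_completions(inst, ps)
  keep <- oracle_feasible(inst, V)
  if (!any(keep)) {
    return(NULL)
  }
  vec <- numeric(0)
  for (ob in inst$objectives) {
    vals <- as.numeric(matrix(ob$coef, nrow = 1) %*% V[names(ob$coef), , drop = FALSE])
    s <- if (ob$sense == "min") -1 else 1
    best <- max(s * vals[keep])
    keep <- keep & (s * vals >= best - 1e-9)
    vec <- c(vec, s * best)
  }
  list(objective = vec, n_feasible = sum(oracle_feasible(inst, V)))
}

# independent constraint evaluation for corruption tests
oracle_violations <- function(inst, assign) {
  n_bad <- 0L
  for (cn in inst$constraints) {
    act <- sum(cn$coef * assign[names(cn$coef)])
    bad <- switch(cn$sense,
      "<=" = act > cn$rhs + 1e-6,
      ">=" = act < cn$rhs - 1e-6,
      "==" = abs(act - cn$rhs) > 1e-6
    )
    if (bad) n_bad <- n_bad + 1L
  }
  n_bad
}

# --- random instance generators --------------------------------------------

tiny_net <- function(nodes, edges) {
  suppressMessages(suppressWarnings(background_network(nodes, edges)))
}

# random partially-directed gene network with hit/interface roles
random_hostvirus_case <- function(seed, n_genes = 8, p_edge = 0.3) {
  subnetip:::with_local_seed(seed, {
    ids <- sprintf("N%02d", seq_len(n_genes))
    roles <- rep("", n_genes)
    hitn <- sample(n_genes, 2)
    ifcn <- sample(setdiff(seq_len(n_genes), hitn), 2)
    roles[hitn] <- "hit"
    roles[ifcn] <- "interface"
    nodes <- tibble::tibble(id = ids, kind = "gene", roles = roles)
    pairs <- t(utils::combn(ids, 2))
    pick <- stats::runif(nrow(pairs)) < p_edge
    if (!any(pick)) pick[sample(nrow(pairs), 2)] <- TRUE
    dird <- stats::runif(sum(pick)) < 0.3
    edges <- tibble::tibble(
      source = pairs[pick, 1], target = pairs[pick, 2],
      directed = dird,
      class = ifelse(dird, "kinase_substrate", "ppi")
    )
    net <- tiny_net(nodes, edges)
    scores <- tibble::tibble(
      id = net$nodes$id, score = round(stats::runif(nrow(net$nodes)), 3)
    )
    list(
      net = net, scores = scores,
      delta = sample(0:3, 1), epsilon = sample(c(0, 0.2, 0.5), 1)
    )
  })
}

# random single-source regulatory network with protein_dna terminal edges
random_regulatory_case <- function(seed, n_tfs = 3, n_targets = 3, n_extra = 2) {
  subnetip:::with_local_seed(seed, {
    src <- "SRC"
    tfs <- sprintf("TF%d", seq_len(n_tfs))
    tgts <- sprintf("DE%d", seq_len(n_targets))
    extras <- sprintf("XX%d", seq_len(n_extra))
    nodes <- tibble::tibble(
      id = c(src, tfs, tgts, extras), kind = "gene",
      roles = c("source", rep("", n_tfs), rep("de_target", n_targets), rep("", n_extra))
    )
    edges <- list()
    for (tf in tfs) {
      if (stats::runif(1) < 0.8) {
        edges[[length(edges) + 1]] <- tibble::tibble(
          source = src, target = tf, directed = FALSE, class = "ppi"
        )
      }
    }
    for (tg in tgts) {
      reg <- sample(c(src, tfs), 1)
      edges[[length(edges) + 1]] <- tibble::tibble(
        source = reg, target = tg, directed = TRUE, class = "protein_dna"
      )
    }
    others <- c(tfs, extras)
    pairs <- t(utils::combn(others, 2))
    pick <- stats::runif(nrow(pairs)) < 0.3
    for (j in which(pick)) {
      dir_pd <- stats::runif(1) < 0.3
      edges[[length(edges) + 1]] <- tibble::tibble(
        source = pairs[j, 1], target = pairs[j, 2],
        directed = dir_pd, class = ifelse(dir_pd, "protein_dna", "ppi")
      )
    }
    net <- tiny_net(nodes, dplyr::bind_rows(edges))
    weights <- tibble::tibble(
      gene = net$nodes$id, weight = round(stats::runif(nrow(net$nodes), 0, 5), 2)
    )
    list(net = net, weights = weights)
  })
}

# build + enumerate + instance; NULL when the case has no or too many paths
make_hostvirus_instance <- function(seed, max_paths = 8) {
  cs <- random_hostvirus_case(seed)
  ps <- enumerate_paths(cs$net, cs$net$roles$hits, cs$net$roles$interfaces, max_edges = 3)
  if (nrow(ps$paths) == 0 || nrow(ps$paths) > max_paths) {
    return(NULL)
  }
  inst <- build_hostvirus_ip(cs$net, ps, cs$scores, delta = cs$delta, epsilon = cs$epsilon)
  list(net = cs$net, ps = ps, inst = inst)
}

make_regulatory_instance <- function(seed, max_paths = 8) {
  cs <- random_regulatory_case(seed)
  ps <- tryCatch(
    enumerate_paths(cs$net, cs$net$roles$sources, cs$net$roles$de_targets,
      max_edges = 3, terminal_class = c("protein_dna", "literature_regulatory")
    ),
    error = function(e) NULL
  )
  if (is.null(ps) || nrow(ps$paths) == 0 || nrow(ps$paths) > max_paths) {
    return(NULL)
  }
  inst <- build_regulatory_ip(cs$net, ps, cs$weights)
  list(net = cs$net, ps = ps, inst = inst)
}
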