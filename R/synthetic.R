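#' Specification for a planted synthetic background network
#'
#' Collects the generator parameters for [make_network()]: a gene universe
#' with designated hits and interfaces, planted hit-to-interface paths routed
#' through designated unconfirmed genes, random decoy interactions, and
#' optional complex/reaction gadgets. The defaults describe a desk-scale
#' benchmark with the qualitative shape of a genome-wide screen analysis:
#' hits and interfaces are minorities of the gene universe, every hit has a
#' genuine route to an interface, and decoy density is low enough that the
#' planted subnetwork is the parsimonious explanation.
#'
#' @param n_genes Gene universe size (default 40).
#' @param n_complexes,n_reactions Number of complex and reaction nodes wired
#'   into planted paths when `planted_path_length >= 3` (defaults 2, 2).
#' @param n_hits,n_interfaces Screen hits and interface genes (defaults 6, 5).
#' @param n_planted_unconfirmed Unconfirmed genes routed through by planted
#'   paths (default 6).
#' @param planted_path_length Interactions per planted path (default 2).
#' @param decoy_edge_probability Probability of a decoy interaction per
#'   unordered gene pair (default 0.02).
#' @param directed_fraction Fraction of decoy interactions that are directed
#'   kinase-substrate edges (default 0.25).
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return A `subnetip_synth_spec` list.
#' @export
synthetic_spec <- function(n_genes = 40, n_complexes = 2, n_reactions = 2,
                           n_hits = 6, n_interfaces = 5,
                           n_planted_unconfirmed = 6, planted_path_length = 2,
                           decoy_edge_probability = 0.02,
                           directed_fraction = 0.25, seed = 1) {
  spec <- list(
    n_genes = n_genes, n_complexes = n_complexes, n_reactions = n_reactions,
    n_hits = n_hits, n_interfaces = n_interfaces,
    n_planted_unconfirmed = n_planted_unconfirmed,
    planted_path_length = planted_path_length,
    decoy_edge_probability = decoy_edge_probability,
    directed_fraction = directed_fraction, seed = seed
  )
  if (n_hits + n_interfaces + n_planted_unconfirmed > n_genes) {
    abort("role counts exceed n_genes")
  }
  if (planted_path_length < 1) abort("planted_path_length must be >= 1")
  if (planted_path_length > 1 && n_planted_unconfirmed < 1) {
    abort("paths longer than one interaction need planted unconfirmed genes")
  }
  if (decoy_edge_probability < 0 || decoy_edge_probability > 1) {
    abort("decoy_edge_probability must be in [0, 1]")
  }
  if (directed_fraction < 0 || directed_fraction > 1) {
    abort("directed_fraction must be in [0, 1]")
  }
  structure(spec, class = "subnetip_synth_spec")
}

#' Generate a background network with planted relevant paths
#'
#' Builds a synthetic benchmark: every hit receives at least one planted
#' simple path of exactly `planted_path_length` interactions to an
#' interface, routed through the designated planted unconfirmed genes (used
#' round-robin, so each is on at least one planted path). Each hit also gets
#' a direct interface contact and a bridge interaction to the next hit, and
#' the interfaces form a ring: this redundancy mirrors the multiplicity of
#' routes in real interactomes and keeps role-confirmed genes recoverable as
#' intermediates when their role is held aside. The planted truth is defined
#' as every path enumerable on the decoy-free network. Decoy protein
#' interactions are overlaid at `decoy_edge_probability` per gene pair; any
#' decoy that would complete a non-planted hit-to-interface path within the
#' planted depth is removed post-generation (unless `allow_shortcuts`), so
#' the planted truth stays the unique parsimonious explanation. When
#' `planted_path_length >= 3` and complexes/reactions are requested, some
#' planted paths are routed hit -> complex -> reaction -> interface to
#' exercise the complex-majority and reaction constraints. A single viral
#' component node is attached to every interface.
#'
#' @param spec A `subnetip_synth_spec`.
#' @param allow_shortcuts If `TRUE`, decoy edges may create additional
#'   hit-to-interface paths within the planted depth.
#' @return A list with `$network` (a `subnetip_network`) and `$truth`
#'   (planted `$nodes`, `$edge_keys`, and `$paths` as a `subnetip_paths`).
#' @export
make_network <- function(spec, allow_shortcuts = FALSE) {
  stopifnot(inherits(spec, "subnetip_synth_spec"))
  with_local_seed(spec$seed, {
    genes <- sprintf("G%03d", seq_len(spec$n_genes))
    pool <- sample(genes)
    hits <- sort(pool[seq_len(spec$n_hits)])
    interfaces <- sort(pool[spec$n_hits + seq_len(spec$n_interfaces)])
    planted_u <- sort(pool[spec$n_hits + spec$n_interfaces +
      seq_len(spec$n_planted_unconfirmed)])
    cxs <- if (spec$n_complexes > 0) sprintf("CPX%02d", seq_len(spec$n_complexes)) else character(0)
    rxs <- if (spec$n_reactions > 0) sprintf("RXN%02d", seq_len(spec$n_reactions)) else character(0)

    L <- spec$planted_path_length
    n_gadget <- if (L >= 3) min(spec$n_complexes, spec$n_reactions, length(hits)) else 0
    planted_edges <- list()
    planted_paths <- list()
    u_cursor <- 0L
    next_u <- function() {
      u_cursor <<- u_cursor + 1L
      planted_u[(u_cursor - 1L) %% length(planted_u) + 1L]
    }
    add_edge <- function(from, to, directed, class) {
      planted_edges[[length(planted_edges) + 1L]] <<-
        tibble(source = from, target = to, directed = directed, class = class)
    }

    nH <- length(hits)
    nI <- length(interfaces)
    for (i in seq_along(hits)) {
      h <- hits[i]
      tgtA <- interfaces[(i - 1L) %% nI + 1L]
      if (i <= n_gadget) {
        cx <- cxs[i]
        rx <- rxs[i]
        add_edge(h, cx, TRUE, "complex_membership")
        # a second planted subunit keeps the complex-majority row non-trivial
        add_edge(next_u(), cx, TRUE, "complex_membership")
        add_edge(cx, rx, TRUE, "reaction_io")
        add_edge(rx, tgtA, TRUE, "reaction_io")
      } else {
        mids <- if (L > 1) vapply(seq_len(L - 1), function(j) next_u(), character(1)) else character(0)
        while (anyDuplicated(c(h, mids, tgtA)) > 0) {
          mids <- vapply(seq_len(L - 1), function(j) next_u(), character(1))
        }
        chain <- c(h, mids, tgtA)
        for (j in seq_len(length(chain) - 1L)) {
          add_edge(chain[j], chain[j + 1L], FALSE, "ppi")
        }
      }
      # direct interface contact and a bridge to the next hit: redundancy
      # mirrors real interactomes, and keeps hits recoverable when held
      # aside (a path from another hit can then run through them)
      tgtB <- interfaces[i %% nI + 1L]
      add_edge(h, tgtB, FALSE, "ppi")
      if (nH > 1 && hits[i %% nH + 1L] != h) add_edge(h, hits[i %% nH + 1L], FALSE, "ppi")
    }
    # interface ring: a held-aside interface stays reachable as an
    # intermediate between a hit and a neighboring interface
    if (nI > 1) {
      for (j in seq_len(if (nI > 2) nI else 1L)) {
        add_edge(interfaces[j], interfaces[j %% nI + 1L], FALSE, "ppi")
      }
    }

    # unwired complexes/reactions hang off planted genes without joining paths
    if (length(cxs) > n_gadget) {
      for (cx in cxs[(n_gadget + 1):length(cxs)]) {
        mem <- sample(planted_u, min(2, length(planted_u)))
        for (m in mem) add_edge(m, cx, TRUE, "complex_membership")
      }
    }
    if (length(rxs) > n_gadget) {
      for (rx in rxs[(n_gadget + 1):length(rxs)]) {
        io <- sample(planted_u, min(2, length(planted_u)))
        add_edge(io[1], rx, TRUE, "reaction_io")
        add_edge(rx, io[length(io)], TRUE, "reaction_io")
      }
    }

    viral <- "HIVP1"
    for (ifc in interfaces) add_edge(ifc, viral, FALSE, "ppi")

    edges <- distinct(bind_rows(planted_edges))

    nodes <- bind_rows(
      tibble(
        id = genes, kind = "gene",
        roles = dplyr::case_when(
          genes %in% hits & genes %in% interfaces ~ "hit;interface",
          genes %in% hits ~ "hit",
          genes %in% interfaces ~ "interface",
          TRUE ~ ""
        )
      ),
      tibble(id = cxs, kind = "complex", roles = ""),
      tibble(id = rxs, kind = "reaction", roles = ""),
      tibble(id = viral, kind = "viral_component", roles = "")
    )
    no_decoys <- tibble(
      source = character(0), target = character(0),
      directed = logical(0), class = character(0)
    )
    build <- function(decoy_tb) {
      background_network(nodes, bind_rows(edges, decoy_tb))
    }

    # the planted truth is everything enumerable on the decoy-free network
    net0 <- build(no_decoys)
    truth_ps <- enumerate_paths(net0, hits, interfaces, max_edges = L)
    planted_chains <- truth_ps$paths$chain
    planted_keys <- sort(unique(unlist(map(truth_ps$paths$edges, "key"))))

    # decoy overlay on gene pairs
    pairs <- utils::combn(genes, 2)
    existing <- paste(pmin(edges$source, edges$target), pmax(edges$source, edges$target))
    cand <- which(!paste(pairs[1, ], pairs[2, ]) %in% existing)
    draw <- cand[stats::runif(length(cand)) < spec$decoy_edge_probability]
    if (length(draw) > 0) {
      dird <- stats::runif(length(draw)) < spec$directed_fraction
      flip <- stats::runif(length(draw)) < 0.5
      a <- ifelse(flip, pairs[2, draw], pairs[1, draw])
      b <- ifelse(flip, pairs[1, draw], pairs[2, draw])
      decoys <- tibble(
        source = a, target = b, directed = dird,
        class = if_else(dird, "kinase_substrate", "ppi")
      )
    } else {
      decoys <- no_decoys
    }
    net <- build(decoys)

    if (!allow_shortcuts && nrow(decoys) > 0) {
      # drop decoys that complete non-planted hit->interface paths within depth
      repeat {
        ps <- enumerate_paths(net, hits, interfaces, max_edges = L)
        extra <- ps$paths[!ps$paths$chain %in% planted_chains, ]
        if (nrow(extra) == 0) break
        offending <- unique(unlist(map(extra$edges, "key"))) |>
          setdiff(planted_keys)
        decoy_keys <- edge_key(
          pmin(decoys$source, decoys$target), pmax(decoys$source, decoys$target),
          decoys$directed, decoys$class
        )
        # directed decoys are keyed on their stored orientation
        decoy_keys[decoys$directed] <- edge_key(
          decoys$source[decoys$directed], decoys$target[decoys$directed],
          TRUE, decoys$class[decoys$directed]
        )
        drop <- decoy_keys %in% offending
        if (!any(drop)) break
        decoys <- decoys[!drop, ]
        net <- build(decoys)
      }
    }

    list(
      network = net,
      truth = list(
        nodes = sort(unique(unlist(truth_ps$paths$nodes))),
        edge_keys = planted_keys,
        paths = truth_ps,
        hits = hits, interfaces = interfaces, planted_unconfirmed = planted_u
      )
    )
  })
}

#' Generate a synthetic regulatory-task background network
#'
#' Builds a benchmark for the single-source regulatory formulation: a source
#' transcription factor, a layer of intermediate regulators reached by
#' undirected protein interactions, directed protein-DNA edges from
#' regulators (and sometimes the source itself) into differentially
#' expressed target genes, plus random decoy interactions.
#'
#' @param n_targets Number of DE target genes (default 6).
#' @param n_tfs Number of intermediate transcription factors (default 3).
#' @param n_decoy_genes Extra genes carrying only decoy interactions
#'   (default 6).
#' @param p_direct Probability a target is regulated directly by the source
#'   (default 0.3); otherwise it is reached through a TF.
#' @param decoy_edge_probability Decoy interaction probability per gene pair
#'   (default 0.05).
#' @param seed Integer seed.
#' @return A list with `$network` (source role on `SRC`, `de_target` roles
#'   set) and `$truth` (the wiring used).
#' @export
make_regulatory_network <- function(n_targets = 6, n_tfs = 3, n_decoy_genes = 6,
                                    p_direct = 0.3, decoy_edge_probability = 0.05,
                                    seed = 1) {
  with_local_seed(seed, {
    src <- "SRC"
    tfs <- sprintf("TF%02d", seq_len(n_tfs))
    tgts <- sprintf("DE%02d", seq_len(n_targets))
    extras <- if (n_decoy_genes > 0) sprintf("X%02d", seq_len(n_decoy_genes)) else character(0)

    edges <- list()
    add <- function(from, to, directed, class) {
      edges[[length(edges) + 1L]] <<-
        tibble(source = from, target = to, directed = directed, class = class)
    }
    for (tf in tfs) add(src, tf, FALSE, "ppi")
    wiring <- list()
    for (tg in tgts) {
      if (stats::runif(1) < p_direct) {
        add(src, tg, TRUE, "protein_dna")
        wiring[[tg]] <- src
      } else {
        tf <- sample(tfs, 1)
        add(tf, tg, TRUE, "protein_dna")
        wiring[[tg]] <- tf
      }
    }
    all_g <- c(tfs, extras)
    if (length(all_g) >= 2) {
      pairs <- utils::combn(all_g, 2)
      pick <- stats::runif(ncol(pairs)) < decoy_edge_probability
      for (j in which(pick)) add(pairs[1, j], pairs[2, j], FALSE, "ppi")
    }

    nodes <- tibble(
      id = c(src, tfs, tgts, extras), kind = "gene",
      roles = c("source", rep("", n_tfs), rep("de_target", n_targets), rep("", length(extras)))
    )
    list(
      network = background_network(nodes, bind_rows(edges)),
      truth = list(source = src, tfs = tfs, targets = tgts, wiring = wiring)
    )
  })
}

#' Generate a synthetic literature corpus
#'
#' Emulates a query-associated literature: abstracts match the query at a
#' base rate, every gene mentions abstracts at a base rate, and the enriched
#' genes co-occur with query-matching abstracts at `enrichment` times the
#' base mention rate.
#'
#' @param genes Gene universe.
#' @param enriched Subset of `genes` genuinely associated with the query.
#' @param n_abstracts Corpus size (default 500).
#' @param enrichment Fold increase of the mention rate of enriched genes in
#'   query-matching abstracts (> 1; default 8).
#' @param seed Integer seed.
#' @param base_rate Per-abstract mention probability for any gene
#'   (default 0.02).
#' @param query_rate Fraction of abstracts matching the query (default 0.3).
#' @param query_id Query identifier (default `"QUERY"`).
#' @return A `subnetip_corpus` with one query.
#' @export
make_corpus <- function(genes, enriched, n_abstracts = 500, enrichment = 8,
                        seed = 1, base_rate = 0.02, query_rate = 0.3,
                        query_id = "QUERY") {
  genes <- norm_id(genes)
  enriched <- norm_id(enriched)
  if (!all(enriched %in% genes)) abort("enriched genes must be a subset of genes")
  if (enrichment <= 1) abort("enrichment must exceed 1")
  with_local_seed(seed, {
    abstracts <- sprintf("A%05d", seq_len(n_abstracts))
    is_q <- stats::runif(n_abstracts) < query_rate
    mention <- function(g) {
      p <- rep(base_rate, n_abstracts)
      if (g %in% enriched) p[is_q] <- pmin(1, base_rate * enrichment)
      abstracts[stats::runif(n_abstracts) < p]
    }
    ga <- lapply(stats::setNames(genes, genes), mention)
    qa <- stats::setNames(list(abstracts[is_q]), query_id)
    corpus(ga, qa)
  })
}

#' Generate a synthetic expression (CPM) table
#'
#' Expressed genes draw log-normal counts-per-million; the remainder are 0.
#'
#' @param genes Gene universe.
#' @param expressed_fraction Fraction of genes expressed, in \[0, 1\]
#'   (default 0.8).
#' @param seed Integer seed.
#' @param meanlog,sdlog Log-normal parameters of expressed CPM values
#'   (defaults 4, 1.5).
#' @return A tibble `(gene, cpm)`.
#' @export
make_expression <- function(genes, expressed_fraction = 0.8, seed = 1,
                            meanlog = 4, sdlog = 1.5) {
  if (expressed_fraction < 0 || expressed_fraction > 1) {
    abort("expressed_fraction must be in [0, 1]")
  }
  genes <- norm_id(genes)
  with_local_seed(seed, {
    on <- stats::runif(length(genes)) < expressed_fraction
    tibble(
      gene = genes,
      cpm = if_else(on, stats::rlnorm(length(genes), meanlog, sdlog), 0)
    )
  })
}
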