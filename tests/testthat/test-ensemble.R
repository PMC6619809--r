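syn_fix <- function(seed = 7) make_network(synthetic_spec(seed = seed))

ens_params <- function(spec = synthetic_spec()) {
  # budget sized to the planted unconfirmed genes plus the hold-aside pool
  n_conf <- spec$n_hits + spec$n_interfaces
  list(
    max_edges = spec$planted_path_length, epsilon = 0.1,
    delta = spec$n_planted_unconfirmed + round(0.25 * n_conf)
  )
}

test_that("subsampling strips roles reproducibly without touching the input", {
  syn <- syn_fix()
  net <- syn$network
  n_conf <- length(union(net$roles$hits, net$roles$interfaces))
  s1 <- subsample_roles(net, 0.25, seed = 5)
  s2 <- subsample_roles(net, 0.25, seed = 5)
  s3 <- subsample_roles(net, 0.25, seed = 6)
  expect_identical(s1$held, s2$held)
  expect_false(identical(s1$held, s3$held))
  expect_equal(length(s1$held), round(0.25 * n_conf))
  # held genes became unconfirmed; original network unmodified
  expect_true(all(s1$held %in% s1$network$roles$unconfirmed))
  expect_true(all(s1$held %in% union(net$roles$hits, net$roles$interfaces)))
  expect_error(subsample_roles(net, 0), "hold_fraction")
  expect_error(subsample_roles(net, 1), "hold_fraction")
})

test_that("a quarter of eight confirmed genes means exactly two held aside", {
  nodes <- tibble::tibble(
    id = sprintf("g%d", 1:10), kind = "gene",
    roles = c(rep("hit", 4), rep("interface", 4), "", "")
  )
  net <- background_network(nodes, tibble::tibble(
    source = "g1", target = "g2", directed = FALSE, class = "ppi"
  ))
  s <- subsample_roles(net, 0.25, seed = 1)
  expect_length(s$held, 2)
})

test_that("hold frequencies match the uniform rate across seeds", {
  syn <- syn_fix()
  net <- syn$network
  pool <- union(net$roles$hits, net$roles$interfaces)
  n_iter <- 400
  counts <- structure(rep(0, length(pool)), names = pool)
  for (s in seq_len(n_iter)) {
    held <- subsample_roles(net, 0.25, seed = s)$held
    counts[held] <- counts[held] + 1
  }
  # 3 of 11 held per draw: per-gene rate 3/11, binomial 99.9% bounds
  p <- round(0.25 * length(pool)) / length(pool)
  bound <- 3.3 * sqrt(p * (1 - p) / n_iter)
  expect_true(all(abs(counts / n_iter - p) < bound))
})

test_that("a single-run ensemble has 0/1 frequencies and is reproducible", {
  syn <- syn_fix()
  er1 <- suppressMessages(run_ensemble(syn$network,
    params = ens_params(), n_runs = 1,
    base_seed = 2, formulation = "hostvirus"
  ))
  expect_true(all(er1$node_frequency$frequency %in% c(0, 1)))
  er2 <- suppressMessages(run_ensemble(syn$network,
    params = ens_params(), n_runs = 1,
    base_seed = 2, formulation = "hostvirus"
  ))
  expect_identical(er1$node_frequency, er2$node_frequency)
  expect_identical(er1$holdout_confidence, er2$holdout_confidence)
})

test_that("ensemble recovers planted genes more often than decoys", {
  syn <- syn_fix(11)
  er <- suppressMessages(run_ensemble(syn$network,
    params = ens_params(), n_runs = 8,
    base_seed = 4, formulation = "hostvirus"
  ))
  expect_gte(er$n_success, 6)
  nf <- structure(er$node_frequency$frequency, names = er$node_frequency$id)
  planted <- syn$truth$planted_unconfirmed
  decoys <- setdiff(syn$network$roles$unconfirmed, syn$truth$nodes)
  expect_gt(mean(nf[planted]), mean(nf[decoys]))
})

test_that("consensus keeps high-frequency elements and surviving paths", {
  syn <- syn_fix(11)
  er <- suppressMessages(run_ensemble(syn$network,
    params = ens_params(), n_runs = 6,
    base_seed = 9, formulation = "hostvirus"
  ))
  cons <- consensus_subnetwork(er, 0.5)
  nf <- structure(er$node_frequency$frequency, names = er$node_frequency$id)
  expect_true(all(nf[cons$nodes] >= 0.5))
  for (i in seq_len(nrow(cons$paths$paths))) {
    expect_true(all(cons$paths$paths$nodes[[i]] %in% cons$nodes))
    expect_true(all(cons$paths$paths$edges[[i]]$key %in% cons$edges))
  }
  # a threshold above the maximum frequency empties the consensus
  empty <- consensus_subnetwork(er, 1)
  if (max(er$node_frequency$frequency) < 1) expect_length(empty$nodes, 0)
  expect_error(consensus_subnetwork(er, 0), "freq_threshold")
})

test_that("consensus of a hand-built 4-run ensemble equals the hand intersection", {
  key_ab <- subnetip:::edge_key("A", "B", FALSE, "ppi")
  key_bc <- subnetip:::edge_key("B", "C", FALSE, "ppi")
  mk_path <- list(nodes = c("A", "B", "C"), edges = tibble::tibble(
    from = c("A", "B"), to = c("B", "C"), class = "ppi", key = c(key_ab, key_bc)
  ))
  er <- structure(list(
    node_frequency = tibble::tibble(
      id = c("A", "B", "C", "D"), frequency = c(1, 0.75, 0.75, 0.25)
    ),
    edge_frequency = tibble::tibble(
      key = c(key_ab, key_bc), frequency = c(0.75, 0.75)
    ),
    master_paths = index_paths(list(mk_path))
  ), class = "subnetip_ensemble")
  cons <- consensus_subnetwork(er, 0.75)
  expect_setequal(cons$nodes, c("A", "B", "C"))
  expect_setequal(cons$edges, c(key_ab, key_bc))
  expect_equal(nrow(cons$paths$paths), 1)
  # D misses the 0.75 cut
  expect_false("D" %in% cons$nodes)
})

test_that("pr_curve matches a direct sort-and-count sweep on random confidences", {
  set.seed(123)
  for (rep in 1:5) {
    pos <- sprintf("P%02d", 1:12)
    neg <- sprintf("N%02d", 1:18)
    conf <- round(runif(12), 2)
    freq <- round(runif(18), 2)
    er <- structure(list(
      holdout_confidence = tibble::tibble(gene = pos, n_held = 3, confidence = conf),
      node_frequency = tibble::tibble(id = neg, frequency = freq)
    ), class = "subnetip_ensemble")
    pr <- pr_curve(er, pos, neg)
    # independent sweep
    score <- c(conf, freq)
    lab <- c(rep(TRUE, 12), rep(FALSE, 18))
    for (i in seq_len(nrow(pr))) {
      t <- pr$threshold[i]
      pred <- score >= t - 1e-12
      expect_equal(pr$precision[i], sum(pred & lab) / sum(pred))
      expect_equal(pr$recall[i], sum(pred & lab) / 12)
    }
    # recall nonincreasing in threshold; curve ends at full recall
    expect_true(all(diff(pr$recall) >= 0)) # rows ordered by decreasing threshold
    expect_equal(pr$recall[nrow(pr)], 1)
    expect_equal(attr(pr, "prevalence"), 12 / 30)
  }
})

test_that("perfect separation gives precision 1 at recall 1", {
  er <- structure(list(
    holdout_confidence = tibble::tibble(gene = c("P1", "P2"), n_held = 2, confidence = 1),
    node_frequency = tibble::tibble(id = c("N1", "N2"), frequency = 0)
  ), class = "subnetip_ensemble")
  pr <- pr_curve(er, c("P1", "P2"), c("N1", "N2"))
  expect_equal(pr$precision[1], 1)
  expect_equal(pr$recall[1], 1)
  # all-equal confidences collapse to a single point at prevalence
  er2 <- structure(list(
    holdout_confidence = tibble::tibble(gene = c("P1", "P2"), n_held = 2, confidence = 0.5),
    node_frequency = tibble::tibble(id = c("N1", "N2"), frequency = 0.5)
  ), class = "subnetip_ensemble")
  pr2 <- pr_curve(er2, c("P1", "P2"), c("N1", "N2"))
  expect_equal(nrow(pr2), 1)
  expect_equal(pr2$precision, 0.5)
  expect_error(pr_curve(er2, character(0), "N1"), "nonempty")
  expect_error(pr_curve(er2, c("P1"), c("P1")), "disjoint")
})

test_that("precision at the lowest threshold converges to prevalence", {
  syn <- syn_fix(13)
  er <- suppressMessages(run_ensemble(syn$network,
    params = ens_params(), n_runs = 6,
    base_seed = 21, formulation = "hostvirus"
  ))
  pr <- suppressWarnings(pr_curve(er,
    positives = union(syn$truth$hits, syn$truth$interfaces),
    negatives = syn$network$roles$unconfirmed
  ))
  # the final sweep point predicts everyone positive
  expect_equal(pr$precision[nrow(pr)], attr(pr, "prevalence"), tolerance = 1e-9)
})

test_that("regulatory ensembles subsample DE targets and stay structurally valid", {
  reg <- make_regulatory_network(n_targets = 8, n_tfs = 4, seed = 3)
  wt <- tibble::tibble(gene = reg$network$nodes$id, weight = 1)
  er <- suppressMessages(run_ensemble(reg$network,
    params = list(max_edges = 3, weights = wt),
    n_runs = 5, base_seed = 17, formulation = "regulatory"
  ))
  expect_gte(er$n_success, 4)
  held <- unique(unlist(lapply(er$runs, `[[`, "held")))
  expect_true(all(held %in% reg$truth$targets))
})

test_that("ensemble plots build", {
  syn <- syn_fix(11)
  er <- suppressMessages(run_ensemble(syn$network,
    params = ens_params(), n_runs = 2,
    base_seed = 4, formulation = "hostvirus"
  ))
  pr <- suppressWarnings(pr_curve(er,
    positives = union(syn$truth$hits, syn$truth$interfaces),
    negatives = syn$network$roles$unconfirmed
  ))
  expect_s3_class(ggplot2::autoplot(pr), "ggplot")
  expect_s3_class(ggplot2::autoplot(er), "ggplot")
})
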