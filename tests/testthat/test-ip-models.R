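# one hit, one interface, one 2-edge path through an unconfirmed gene
single_path_fixture <- function() {
  nodes <- tibble::tibble(
    id = c("h", "u", "i"), kind = "gene", roles = c("hit", "", "interface")
  )
  edges <- tibble::tibble(
    source = c("h", "u"), target = c("u", "i"), directed = FALSE, class = "ppi"
  )
  net <- background_network(nodes, edges)
  ps <- enumerate_paths(net, "h", "i", max_edges = 3)
  scores <- tibble::tibble(id = c("H", "U", "I"), score = c(0.5, 0.9, 0.2))
  list(net = net, ps = ps, scores = scores)
}

test_that("the single-path host-virus instance has the expected shape and optimum", {
  fx <- single_path_fixture()
  inst <- build_hostvirus_ip(fx$net, fx$ps, fx$scores, delta = 1, epsilon = 0)
  expect_equal(sum(inst$vars$family == "sigma"), 1)
  expect_equal(sum(inst$vars$family == "x"), 2)
  expect_equal(sum(inst$vars$family == "y"), 3)
  sol <- solve_lexicographic(inst)
  expect_equal(sol$status, "optimal")
  expect_true(all(sol$assignment == 1))
  expect_equal(unname(sol$objective_values), c(0.9, 1))
  expect_equal(nrow(check_solution(inst, sol)), 0)
})

test_that("a zero unconfirmed budget makes hit coverage infeasible", {
  fx <- single_path_fixture()
  inst <- build_hostvirus_ip(fx$net, fx$ps, fx$scores, delta = 0, epsilon = 0)
  sol <- solve_lexicographic(inst)
  expect_equal(sol$status, "infeasible")
  # and the oracle agrees that no path subset is feasible
  expect_null(oracle_lex(inst, fx$ps))
})

test_that("parameter validation errors early", {
  fx <- single_path_fixture()
  expect_error(build_hostvirus_ip(fx$net, fx$ps, fx$scores, delta = -1), "delta")
  expect_error(build_hostvirus_ip(fx$net, fx$ps, fx$scores, delta = 1, epsilon = 1), "epsilon")
  expect_error(
    build_hostvirus_ip(fx$net, fx$ps, tibble::tibble(id = "h", score = 1), delta = 1),
    "score"
  )
})

test_that("the all-zero assignment is reported as violating hit coverage", {
  fx <- single_path_fixture()
  inst <- build_hostvirus_ip(fx$net, fx$ps, fx$scores, delta = 1, epsilon = 0)
  zero <- structure(rep(0L, nrow(inst$vars)), names = inst$vars$name)
  rep_ <- check_solution(inst, zero)
  expect_true("hit_coverage" %in% rep_$constraint)
  expect_error(check_solution(inst, zero[-1]), "missing variable")
})

test_that("host-virus lexicographic optima equal the exhaustive subset oracle", {
  n_done <- 0
  seed <- 0
  while (n_done < 40 && seed < 400) {
    seed <- seed + 1
    fx <- make_hostvirus_instance(seed)
    if (is.null(fx)) next
    n_done <- n_done + 1
    want <- oracle_lex(fx$inst, fx$ps)
    sol <- solve_lexicographic(fx$inst)
    if (is.null(want)) {
      expect_equal(sol$status, "infeasible")
    } else {
      expect_equal(sol$status, "optimal")
      expect_equal(unname(sol$objective_values), want$objective, tolerance = 1e-6)
      expect_equal(nrow(check_solution(fx$inst, sol)), 0)
    }
  }
  expect_gte(n_done, 40)
})

test_that("regulatory lexicographic optima equal the exhaustive subset oracle", {
  n_done <- 0
  seed <- 1000
  while (n_done < 40 && seed < 1400) {
    seed <- seed + 1
    fx <- make_regulatory_instance(seed)
    if (is.null(fx)) next
    n_done <- n_done + 1
    want <- oracle_lex(fx$inst, fx$ps)
    sol <- solve_lexicographic(fx$inst)
    expect_equal(sol$status, "optimal") # selecting no paths is always feasible
    expect_equal(unname(sol$objective_values), want$objective, tolerance = 1e-6)
    expect_equal(nrow(check_solution(fx$inst, sol)), 0)
  }
  expect_gte(n_done, 40)
})

test_that("direct regulation of one DE gene yields objectives (1, 0, 0, 1)", {
  nodes <- tibble::tibble(
    id = c("src", "de"), kind = "gene", roles = c("source", "de_target")
  )
  edges <- tibble::tibble(
    source = "src", target = "de", directed = TRUE, class = "protein_dna"
  )
  net <- background_network(nodes, edges)
  ps <- enumerate_paths(net, "src", "de", max_edges = 3, terminal_class = "protein_dna")
  inst <- build_regulatory_ip(net, ps, tibble::tibble(gene = c("SRC", "DE"), weight = c(1, 1)))
  sol <- solve_lexicographic(inst)
  expect_equal(unname(sol$objective_values), c(1, 0, 0, 1))
})

test_that("a DE gene whose only route enters an intermediate by a directed edge is unreachable", {
  # src -(protein_dna)-> tf -(protein_dna)-> de : the path exists, but
  # selecting it would give intermediate tf an incoming directed edge
  nodes <- tibble::tibble(
    id = c("src", "tf", "de"), kind = "gene", roles = c("source", "", "de_target")
  )
  edges <- tibble::tibble(
    source = c("src", "tf"), target = c("tf", "de"),
    directed = TRUE, class = "protein_dna"
  )
  net <- background_network(nodes, edges)
  ps <- enumerate_paths(net, "src", "de", max_edges = 3, terminal_class = "protein_dna")
  expect_equal(nrow(ps$paths), 1)
  inst <- build_regulatory_ip(net, ps, tibble::tibble(gene = "TF", weight = 2))
  sol <- solve_lexicographic(inst)
  expect_equal(unname(sol$objective_values)[1], 0)
  # the oracle agrees the empty selection is the lexicographic optimum
  expect_equal(oracle_lex(inst, ps)$objective, c(0, 0, 0, 0))
})

test_that("the regulatory task rejects multiple sources", {
  nodes <- tibble::tibble(
    id = c("s1", "s2", "de"), kind = "gene", roles = c("source", "source", "de_target")
  )
  edges <- tibble::tibble(
    source = "s1", target = "de", directed = TRUE, class = "protein_dna"
  )
  net <- background_network(nodes, edges)
  ps <- enumerate_paths(net, "s1", "de", max_edges = 2)
  expect_error(build_regulatory_ip(net, ps, tibble::tibble(gene = "S1", weight = 1)), "source")
})

test_that("later stages break ties among earlier optima", {
  # two disjoint 2-edge paths with equal unconfirmed score; delta admits only
  # one unconfirmed gene, so stage 1 ties; a third parallel path shares u1,
  # so stage 2 prefers the u1 side (2 paths > 1)
  nodes <- tibble::tibble(
    id = c("h", "u1", "u2", "i"), kind = "gene",
    roles = c("hit", "", "", "interface")
  )
  edges <- tibble::tibble(
    source = c("h", "u1", "h", "u2", "h"),
    target = c("u1", "i", "u2", "i", "u1"),
    directed = FALSE,
    class = c("ppi", "ppi", "ppi", "ppi", "ptm")
  )
  net <- background_network(nodes, edges)
  ps <- enumerate_paths(net, "h", "i", max_edges = 2)
  scores <- tibble::tibble(id = net$nodes$id, score = c(0, 0.5, 0.5, 0))
  inst <- build_hostvirus_ip(net, ps, scores, delta = 1, epsilon = 0)
  sol <- solve_lexicographic(inst)
  expect_equal(unname(sol$objective_values), c(0.5, 2))
  expect_equal(unname(sol$assignment["y_U1"]), 1L)
  expect_equal(unname(sol$assignment["y_U2"]), 0L)
  expect_equal(oracle_lex(inst, ps)$objective, c(0.5, 2))
})

test_that("increasing delta never decreases the stage-1 optimum", {
  for (seed in c(3, 8, 15)) {
    fx <- NULL
    s <- seed
    while (is.null(fx)) {
      fx <- make_hostvirus_instance(s)
      s <- s + 100
    }
    prev <- -Inf
    for (delta in 0:4) {
      inst <- build_hostvirus_ip(
        fx$net, fx$ps,
        tibble::tibble(id = fx$net$nodes$id, score = seq_len(nrow(fx$net$nodes)) / 10),
        delta = delta, epsilon = 0.5
      )
      sol <- solve_lexicographic(inst)
      if (sol$status == "optimal") {
        expect_gte(sol$objective_values[1], prev - 1e-9)
        prev <- sol$objective_values[1]
      }
    }
  }
})

test_that("check_solution flags corrupted assignments exactly as direct evaluation", {
  set.seed(99)
  n_corruptions <- 0
  for (seed in c(2, 7, 12, 31)) {
    fx <- NULL
    s <- seed
    while (is.null(fx)) {
      fx <- make_hostvirus_instance(s)
      s <- s + 50
    }
    sol <- solve_lexicographic(fx$inst)
    if (sol$status != "optimal") next
    for (k in 1:10) {
      bad <- sol$assignment
      flip <- sample(length(bad), sample(1:3, 1))
      bad[flip] <- 1L - bad[flip]
      rep_ <- check_solution(fx$inst, bad)
      expect_equal(nrow(rep_) > 0, oracle_violations(fx$inst, bad) > 0)
      n_corruptions <- n_corruptions + 1
    }
  }
  expect_gte(n_corruptions, 20)
})

test_that("extract_subnetwork returns exactly the value-1 families with closure", {
  fx <- single_path_fixture()
  inst <- build_hostvirus_ip(fx$net, fx$ps, fx$scores, delta = 1, epsilon = 0)
  sol <- solve_lexicographic(inst)
  sub <- extract_subnetwork(fx$net, fx$ps, sol)
  expect_setequal(sub$nodes$id, c("H", "U", "I"))
  expect_equal(nrow(sub$edges), 2)
  expect_equal(nrow(sub$paths$paths), 1)
  # every relevant edge lies on a relevant path; every node touches an edge
  path_keys <- unique(unlist(lapply(sub$paths$paths$edges, function(e) e$key)))
  expect_true(all(sub$edges$key %in% path_keys))
  expect_true(all(sub$nodes$id %in% c(sub$edges$a, sub$edges$b)))
})

test_that("complex and reaction gadget constraints are honored end to end", {
  syn <- make_network(synthetic_spec(
    planted_path_length = 3, n_complexes = 2, n_reactions = 2,
    decoy_edge_probability = 0, seed = 13
  ))
  net <- syn$network
  ps <- enumerate_paths(net, net$roles$hits, net$roles$interfaces, max_edges = 3)
  sc <- diffusion_scores(net, net$roles$hits)
  inst <- build_hostvirus_ip(net, ps, sc, delta = 12, epsilon = 0.2)
  expect_true(any(grepl("complex_majority", vapply(inst$constraints, `[[`, "", "name"))))
  expect_true(any(grepl("reaction_io", vapply(inst$constraints, `[[`, "", "name"))))
  sol <- solve_lexicographic(inst)
  expect_equal(sol$status, "optimal")
  expect_equal(nrow(check_solution(inst, sol)), 0)
  # budget invariant: relevant unconfirmed genes within delta
  uncf <- intersect(net$roles$unconfirmed, inst$vars$ref[inst$vars$family == "y"])
  expect_lte(sum(sol$assignment[paste0("y_", uncf)]), 12)
})

test_that("LP export writes a parseable file mentioning every variable family", {
  fx <- single_path_fixture()
  inst <- build_hostvirus_ip(fx$net, fx$ps, fx$scores, delta = 1, epsilon = 0)
  f <- withr::local_tempfile(fileext = ".lp")
  write_lp(inst, f)
  txt <- readLines(f)
  expect_true(any(grepl("^Maximize", txt)))
  expect_true(any(grepl("Binary", txt)))
  expect_true(any(grepl("sigma_1", txt)))
})

test_that("solution tidiers expose assignments and objective values", {
  fx <- single_path_fixture()
  inst <- build_hostvirus_ip(fx$net, fx$ps, fx$scores, delta = 1, epsilon = 0)
  sol <- solve_lexicographic(inst)
  td <- tidy(sol)
  expect_setequal(td$family, c("sigma", "x", "y"))
  expect_true(all(td$value %in% 0:1))
  gl <- glance(sol)
  expect_equal(gl$status, "optimal")
  expect_equal(gl$n_paths, 1)
})
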