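test_that("reaction-graph arcs follow producer/consumer with filters", {
  r1 <- reaction("R1", "a", "b")
  r2 <- reaction("R2", "b", "c")
  g <- build_reaction_graph(mk_net("O", list(r1, r2)))
  expect_identical(g$arcs$from, "R1")
  expect_identical(g$arcs$to, "R2")
  expect_identical(g$arcs$witness, "b")
  # currency compound witnesses no arc
  r3 <- reaction("R3", "x", "WATER")
  r4 <- reaction("R4", "WATER", "y")
  g2 <- build_reaction_graph(mk_net("O", list(r3, r4)))
  expect_equal(nrow(g2$arcs), 0L)
  # cofactor pair co-transformed in one reaction is suppressed there
  kin <- reaction("KIN", c("glc", "ATP"), c("g6p", "ADP"))
  use <- reaction("USE", "ADP", "amp")
  g3 <- build_reaction_graph(mk_net("O", list(kin, use)))
  expect_equal(nrow(g3$arcs), 0L)
  # but a reaction producing ADP without the pair still connects
  mk <- reaction("MK", "amp2", "ADP")
  g4 <- build_reaction_graph(mk_net("O", list(mk, use)))
  expect_equal(nrow(g4$arcs), 1L)
  # reversible reactions contribute both orientations: the reverse of
  # R5 produces a, which R6 consumes
  r5 <- reaction("R5", "a", "b", reversible = TRUE)
  r6 <- reaction("R6", "a", "m")
  g5 <- build_reaction_graph(mk_net("O", list(r5, r6)))
  expect_true(any(g5$arcs$from == "R5" & g5$arcs$to == "R6"))
  g5s <- build_reaction_graph(mk_net("O", list(r5, r6)),
                              strict_direction = TRUE)
  expect_false(any(g5s$arcs$from == "R5" & g5s$arcs$to == "R6"))
  # empty network gives an empty graph
  expect_equal(nrow(build_reaction_graph(
    metabolic_network(mk_org("E"), list()))$arcs), 0L)
})

test_that("random graphs match the brute-force arc oracle", {
  set.seed(31)
  for (i in 1:8) {
    net <- random_rxn_network(50)
    for (strict in c(FALSE, TRUE)) {
      g <- build_reaction_graph(net, strict_direction = strict)
      expect_identical(
        arcs_to_strings(g$arcs),
        oracle_arcs(net, default_currency(), default_cofactor_pairs(),
                    strict))
    }
  }
})

test_that("arcs are deterministic and currency filtering only removes arcs", {
  set.seed(77)
  net <- random_rxn_network(40)
  g1 <- build_reaction_graph(net)
  # input order invariance
  net2 <- metabolic_network(net$org, rev(unname(net$reactions)))
  g2 <- build_reaction_graph(net2)
  expect_identical(arcs_to_strings(g1$arcs), arcs_to_strings(g2$arcs))
  # enlarging the currency list is monotone in arc removal
  extra_cur <- c(default_currency(), "c01", "c02", "c03")
  g3 <- build_reaction_graph(net, currency = extra_cur)
  a1 <- paste(g1$arcs$from, g1$arcs$to)
  a3 <- paste(g3$arcs$from, g3$arcs$to)
  expect_true(all(a3 %in% a1))
})

test_that("union graph merges nodes, arcs and witnesses", {
  set.seed(13)
  nets <- lapply(1:4, function(i)
    random_rxn_network(20, org = sprintf("O%d", i)))
  graphs <- lapply(nets, build_reaction_graph)
  u <- union_graph(graphs)
  # idempotence
  expect_identical(arcs_to_strings(union_graph(list(u, u))$arcs),
                   arcs_to_strings(u$arcs))
  # arc present iff present in >= 1 input, witnesses merged
  all_pairs <- unique(unlist(lapply(graphs, function(g)
    paste(g$arcs$from, g$arcs$to, sep = "|"))))
  expect_setequal(paste(u$arcs$from, u$arcs$to, sep = "|"), all_pairs)
  for (k in sample(nrow(u$arcs), 10)) {
    wit <- sort(unique(unlist(lapply(graphs, function(g) {
      hit <- g$arcs$from == u$arcs$from[k] & g$arcs$to == u$arcs$to[k]
      unlist(strsplit(g$arcs$witness[hit], ";"))
    }))))
    expect_identical(u$arcs$witness[k], paste(wit, collapse = ";"))
  }
  # disjoint graphs: component counts add
  gA <- build_reaction_graph(mk_net("A", list(
    reaction("R1", "a", "b"), reaction("R2", "b", "c"))))
  gB <- build_reaction_graph(mk_net("B", list(
    reaction("R3", "x", "y"), reaction("R4", "y", "z"))))
  uAB <- union_graph(list(gA, gB))
  comps <- induced_components(uAB, uAB$nodes)
  expect_length(comps$components, 2L)
})

test_that("induced components match a breadth-first-search oracle", {
  # path A -> B -> C induced on {A, C}: two isolated nodes, no arcs
  g <- build_reaction_graph(mk_net("O", list(
    reaction("A", "m1", "m2"), reaction("B", "m2", "m3"),
    reaction("C", "m3", "m4"))))
  ind <- induced_components(g, c("A", "C"))
  expect_length(ind$components, 0L)
  expect_setequal(ind$isolated, c("A", "C"))
  expect_equal(ind$n_arcs, 0L)
  full <- induced_components(g, c("A", "B", "C"))
  expect_length(full$components, 1L)
  expect_setequal(full$components[[1]], c("A", "B", "C"))
  expect_error(induced_components(g, "NOPE"), "absent")
  set.seed(19)
  for (i in 1:6) {
    net <- random_rxn_network(40)
    gr <- build_reaction_graph(net)
    subset <- sample(gr$nodes, 25)
    ind <- induced_components(gr, subset)
    arcs <- gr$arcs[gr$arcs$from %in% subset & gr$arcs$to %in% subset, ]
    comps <- oracle_components(subset, arcs)
    expect_setequal(
      vapply(ind$components, paste, character(1), collapse = ","),
      vapply(Filter(function(x) length(x) >= 2, comps), paste,
             character(1), collapse = ","))
    expect_setequal(ind$isolated,
                    c(character(), unlist(Filter(function(x)
                      length(x) == 1, comps))))
    expect_equal(ind$n_arcs, nrow(arcs))
  }
})

test_that("connected EC occurrences match trivial cases", {
  r1 <- reaction("R1", "a", "b", ec_numbers = "1.1.1.1")
  r2 <- reaction("R2", "b", "c", ec_numbers = "2.2.2.2")
  net <- mk_net("O", list(r1, r2))
  g <- build_reaction_graph(net)
  em <- reaction_ec_map(net)
  occ <- connected_ec_occurrences(g, c("1.1.1", "2.2.2"), em, "count")
  expect_equal(occ$n_occurrences, 1L)
  expect_setequal(occ$occurrences[[1]], c("R1", "R2"))
  # no path: zero occurrences
  r3 <- reaction("R3", "x", "y", ec_numbers = "2.2.2.2")
  net2 <- mk_net("O", list(r1, r3))
  occ2 <- connected_ec_occurrences(build_reaction_graph(net2),
                                   c("1.1.1", "2.2.2"),
                                   reaction_ec_map(net2), "count")
  expect_equal(occ2$n_occurrences, 0L)
  expect_false(occ2$exists)
  # class with no candidate: absent, not an error
  occ3 <- connected_ec_occurrences(g, c("1.1.1", "9.9.9"), em, "exists")
  expect_identical(occ3$status, "absent")
  # a reaction may fill only one class per occurrence
  rx <- reaction("RX", "a", "b", ec_numbers = c("1.1.1.1", "2.2.2.2"))
  netx <- mk_net("O", list(rx))
  occ4 <- connected_ec_occurrences(build_reaction_graph(netx),
                                   c("1.1.1", "2.2.2"),
                                   reaction_ec_map(netx), "count")
  expect_equal(occ4$n_occurrences, 0L)
})

test_that("occurrence counts match exhaustive enumeration on random graphs", {
  set.seed(23)
  classes <- c("1.1.1", "2.7.1", "4.2.1", "6.3.2")
  for (i in 1:5) {
    net <- random_rxn_network(40)
    # overwrite EC annotations: up to 6 candidates per class
    ids <- names(net$reactions)
    ec_map <- stats::setNames(
      replicate(length(ids), character(), simplify = FALSE), ids)
    for (cl in classes) {
      cand <- sample(ids, sample(1:6, 1))
      for (cd in cand)
        ec_map[[cd]] <- unique(c(ec_map[[cd]], cl))
    }
    g <- build_reaction_graph(net)
    occ <- connected_ec_occurrences(g, classes, ec_map, "count")
    candidates <- lapply(classes, function(cl)
      ids[vapply(ec_map, function(v) cl %in% v, logical(1))])
    expect_equal(occ$n_occurrences,
                 oracle_occurrences(g$nodes, g$arcs, candidates))
    # exists mode agrees with the count
    occ_e <- connected_ec_occurrences(g, classes, ec_map, "exists")
    expect_identical(occ_e$exists, occ$n_occurrences > 0L)
  }
})

test_that("union graph never has fewer occurrences than any single organism", {
  set.seed(57)
  classes <- c("1.1.1", "2.7.1")
  nets <- lapply(1:3, function(i)
    random_rxn_network(25, org = sprintf("O%d", i)))
  # shared annotation map across organisms
  all_ids <- unique(unlist(lapply(nets, function(n) names(n$reactions))))
  ec_map <- stats::setNames(
    replicate(length(all_ids), character(), simplify = FALSE), all_ids)
  for (cl in classes)
    for (cd in sample(all_ids, 5))
      ec_map[[cd]] <- unique(c(ec_map[[cd]], cl))
  graphs <- lapply(nets, build_reaction_graph)
  u <- union_graph(graphs)
  n_union <- connected_ec_occurrences(u, classes, ec_map,
                                      "count")$n_occurrences
  for (g in graphs) {
    n_org <- connected_ec_occurrences(g, classes, ec_map,
                                      "count")$n_occurrences
    if (!is.na(n_org)) expect_gte(n_union, n_org)
  }
})

test_that("tuple cap returns an explicit status", {
  r1 <- reaction("R1", "a", "b", ec_numbers = "1.1.1.1")
  r2 <- reaction("R2", "b", "c", ec_numbers = "2.2.2.2")
  net <- mk_net("O", list(r1, r2))
  occ <- connected_ec_occurrences(build_reaction_graph(net),
                                  c("1.1.1", "2.2.2"),
                                  reaction_ec_map(net), "count", cap = 0)
  expect_identical(occ$status, "cap_exceeded")
  expect_true(is.na(occ$n_occurrences))
})
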