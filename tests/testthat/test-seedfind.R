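test_that("compound graph arcs link substrates to products", {
  r <- reaction("R", c("a", "b"), "c")
  g <- build_compound_graph(mk_net("O", list(r)))
  expect_setequal(paste(g$arcs$from, g$arcs$to),
                  c("a c", "b c"))
  # reversible reactions contribute both directions
  rv <- reaction("R2", "a", "b", reversible = TRUE)
  g2 <- build_compound_graph(mk_net("O", list(rv)))
  expect_setequal(paste(g2$arcs$from, g2$arcs$to), c("a b", "b a"))
  # currency and dNDP nodes are deleted
  rc <- reaction("R3", c("a", "WATER"), c("dADP", "b"))
  g3 <- build_compound_graph(mk_net("O", list(rc)))
  expect_false(any(c("WATER", "dADP") %in% g3$nodes))
  expect_setequal(paste(g3$arcs$from, g3$arcs$to), "a b")
})

test_that("compound graph arcs match a brute-force loop", {
  set.seed(61)
  for (i in 1:5) {
    net <- random_rxn_network(30)
    g <- build_compound_graph(net)
    drop <- union(default_currency(), default_excluded_dndps())
    expected <- character()
    for (r in net$reactions) {
      subs <- setdiff(r$substrates, drop)
      prods <- setdiff(r$products, drop)
      for (pp in default_cofactor_pairs())
        if ((pp[1] %in% r$substrates && pp[2] %in% r$products) ||
            (pp[2] %in% r$substrates && pp[1] %in% r$products)) {
          subs <- setdiff(subs, pp); prods <- setdiff(prods, pp)
        }
      for (s in subs) for (pr in prods) {
        if (s != pr) expected <- c(expected, paste(s, pr))
        if (r$reversible && s != pr) expected <- c(expected, paste(pr, s))
      }
    }
    expect_setequal(paste(g$arcs$from, g$arcs$to), unique(expected))
  }
})

test_that("seed detection handles chains, cycles and isolated nodes", {
  chain <- structure(list(
    nodes = c("a", "b", "c"),
    arcs = data.frame(from = c("a", "b"), to = c("b", "c"),
                      stringsAsFactors = FALSE),
    provenance = "T"), class = "sc_cpd_graph")
  s <- find_seeds(chain)
  expect_identical(s$seeds, "a")
  expect_equal(unname(s$confidence["a"]), 1)
  # cycle a <-> b feeding c: source component {a, b}, confidence 1/2
  cyc <- structure(list(
    nodes = c("a", "b", "c"),
    arcs = data.frame(from = c("a", "b", "b"), to = c("b", "a", "c"),
                      stringsAsFactors = FALSE),
    provenance = "T"), class = "sc_cpd_graph")
  s2 <- find_seeds(cyc)
  expect_setequal(s2$seeds, c("a", "b"))
  expect_equal(unname(s2$confidence), c(0.5, 0.5))
  expect_length(s2$source_components, 1L)
  # isolated node is its own source component
  iso <- structure(list(
    nodes = c("a", "b", "z"),
    arcs = data.frame(from = "a", to = "b", stringsAsFactors = FALSE),
    provenance = "T"), class = "sc_cpd_graph")
  expect_setequal(find_seeds(iso)$seeds, c("a", "z"))
})

test_that("seeds equal the transitive-closure definition on random graphs", {
  set.seed(83)
  for (i in 1:8) {
    g <- random_cpd_graph(sample(20:60, 1), arc_prob = 0.03)
    rep <- find_seeds(g)
    expect_identical(rep$seeds, oracle_seeds(g$nodes, g$arcs))
    # every compound is reachable from the union of seed components
    reach <- oracle_reachable_from(g$nodes, g$arcs, rep$seeds)
    expect_setequal(reach, g$nodes)
    # seeds are the union of the source components
    expect_setequal(unlist(rep$source_components), rep$seeds)
  }
})

test_that("seeds are invariant to arc duplication and reaction order", {
  set.seed(5)
  net <- random_rxn_network(25)
  g1 <- build_compound_graph(net)
  net2 <- metabolic_network(net$org, rev(unname(net$reactions)))
  g2 <- build_compound_graph(net2)
  expect_identical(find_seeds(g1)$seeds, find_seeds(g2)$seeds)
  g_dup <- g1
  g_dup$arcs <- rbind(g_dup$arcs, g_dup$arcs[1:5, ])
  expect_identical(find_seeds(g_dup)$seeds, find_seeds(g1)$seeds)
})

test_that("distance-one extension adds only cross-witnessed adjacent compounds", {
  # O1: glc -> g6p -> pyr  (seed glc)
  # O2: g6p -> pyr         (seed g6p; glc adjacent? no - not in O2)
  r1 <- reaction("HK", "glc", "g6p"); r2 <- reaction("GLY", "g6p", "pyr")
  o1 <- mk_net("O1", list(r1, r2))
  o2 <- mk_net("O2", list(r2))
  p <- panel(list(o1, o2))
  graphs <- lapply(p$networks, build_compound_graph)
  reports <- lapply(graphs, find_seeds)
  expect_identical(reports$O1$seeds, "glc")
  expect_identical(reports$O2$seeds, "g6p")
  ext <- distance_one_extension(reports, graphs)
  # O1: g6p is adjacent to seed glc and is a seed of O2 -> extended
  expect_identical(ext$O1$extended, "g6p")
  expect_identical(ext$O1$extended_witness$g6p, "O2")
  # O2: glc is not a node of O2, nothing to add
  expect_length(ext$O2$extended, 0L)
  # extended seeds stay disjoint from base seeds
  expect_length(intersect(ext$O1$extended, ext$O1$seeds), 0L)
  # directed mode: g6p is a successor (not predecessor) of glc -> dropped
  ext_in <- distance_one_extension(reports, graphs, mode = "in")
  expect_length(ext_in$O1$extended, 0L)
})

test_that("extension is a no-op without cross-organism seed overlap", {
  r1 <- reaction("RA", "a1", "a2")
  r2 <- reaction("RB", "b1", "b2")
  p <- panel(list(mk_net("O1", list(r1)), mk_net("O2", list(r2))))
  graphs <- lapply(p$networks, build_compound_graph)
  reports <- lapply(graphs, find_seeds)
  ext <- distance_one_extension(reports, graphs)
  expect_length(ext$O1$extended, 0L)
  expect_length(ext$O2$extended, 0L)
  expect_warning(distance_one_extension(reports[1], graphs[1]),
                 "at least two")
})

test_that("extended intersections are never smaller than base (random panels)", {
  set.seed(97)
  for (i in 1:3) {
    nets <- lapply(1:5, function(j)
      random_rxn_network(20, org = sprintf("O%d", j)))
    p <- panel(nets)
    graphs <- lapply(p$networks, build_compound_graph)
    reports <- lapply(graphs, find_seeds)
    ext <- distance_one_extension(reports, graphs)
    base <- compare_inputs(reports, p)
    extended <- compare_inputs(ext, p, use_extended = TRUE)
    expect_true(all(extended$intersection >= base$intersection))
    expect_true(all(extended$union >= base$union))
  }
})

test_that("group input comparison matches naive folds", {
  sets <- list(O1 = c("a", "b", "c"), O2 = c("b", "c", "d"),
               O3 = c("x"))
  reports <- lapply(names(sets), function(o)
    structure(list(org = o, seeds = sets[[o]],
                   source_components = list(sets[[o]]),
                   confidence = NULL, nodes = sets[[o]]),
              class = "sc_seed_report"))
  names(reports) <- names(sets)
  r <- reaction("R", "s", "p")
  p <- panel(list(mk_net("O1", list(r), group = "EXTRA"),
                  mk_net("O2", list(r), group = "EXTRA"),
                  mk_net("O3", list(r), group = "INTRA")))
  tab <- compare_inputs(reports, p)
  ex <- tab[tab$group == "EXTRA", ]
  expect_equal(ex$intersection, 2)  # {b, c}
  expect_equal(ex$union, 4)
  expect_equal(ex$mean, 3)
  all_row <- tab[tab$group == "ALL", ]
  expect_equal(all_row$intersection, 0)
  expect_equal(all_row$union, 5)
})
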