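# Small hand-built fixtures used across test files.

mk_org <- function(id, group = "EXTRA", sub = NA_character_,
                   n_genes = 100L, n_met = 25L)
  organism_meta(id, group, subcategory = sub, tax_class = "Testia",
                n_genes = n_genes, n_metabolic_genes = n_met)

mk_net <- function(id, reactions, group = "EXTRA", ...)
  metabolic_network(mk_org(id, group, ...), reactions)

# two-organism toy panel: shared R1, private R2/R3
toy_panel <- function() {
  r1 <- reaction("R1", "a", "b", ec_numbers = "1.1.1.1",
                 processes = "biosynthesis")
  r2 <- reaction("R2", "b", "c", ec_numbers = "2.5.1.3",
                 processes = "degradation")
  r3 <- reaction("R3", c("c", "d"), "e", ec_numbers = "2.5.1.9",
                 processes = "biosynthesis")
  panel(list(mk_net("ORG1", list(r1, r2)),
             mk_net("ORG2", list(r1, r3), group = "INTRA", sub = "MIV")))
}

# random panel of bare element sets wrapped as trivial reactions, for
# set-algebra oracle tests (compound structure irrelevant)
random_set_panel <- function(n_orgs, universe_size, mean_size,
                             groups = c("INTRA", "CA", "EXTRA", "FL")) {
  universe <- sprintf("RX%04d", seq_len(universe_size))
  ecs <- paste0(sample(1:6, universe_size, TRUE), ".",
                sample(1:9, universe_size, TRUE), ".",
                sample(1:9, universe_size, TRUE), ".",
                sample(1:40, universe_size, TRUE))
  nets <- lapply(seq_len(n_orgs), function(i) {
    k <- max(1L, min(universe_size,
                     stats::rpois(1, mean_size)))
    idx <- sample.int(universe_size, k)
    rxns <- lapply(idx, function(j)
      reaction(universe[j], sprintf("S%d", j), sprintf("P%d", j),
               ec_numbers = ecs[j]))
    mk_net(sprintf("ORG%02d", i), rxns,
           group = sample(groups, 1))
  })
  panel(nets)
}

# random reaction network with currency salting, for graph oracles
random_rxn_network <- function(n_rxn, n_cpd = 30, org = "ORG1",
                               rev_frac = 0.3, currency_frac = 0.3) {
  cpds <- sprintf("c%02d", seq_len(n_cpd))
  cur <- default_currency()
  rxns <- lapply(seq_len(n_rxn), function(i) {
    subs <- sample(cpds, sample(1:3, 1))
    prods <- sample(setdiff(cpds, subs), sample(1:3, 1))
    if (stats::runif(1) < currency_frac) subs <- c(subs, sample(cur, 1))
    if (stats::runif(1) < currency_frac) prods <- c(prods, sample(cur, 1))
    if (stats::runif(1) < 0.15) { # occasional cofactor pair usage
      subs <- c(subs, "ADP"); prods <- c(prods, "ATP")
    }
    reaction(sprintf("R%03d", i), subs, prods,
             reversible = stats::runif(1) < rev_frac)
  })
  mk_net(org, rxns)
}

# random directed compound graph wrapped as sc_cpd_graph
random_cpd_graph <- function(n_nodes, arc_prob, org = "G") {
  nodes <- sprintf("m%03d", seq_len(n_nodes))
  pairs <- expand.grid(from = nodes, to = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- stats::runif(nrow(pairs)) < arc_prob
  arcs <- pairs[keep, , drop = FALSE]
  rownames(arcs) <- NULL
  structure(list(nodes = nodes, arcs = arcs, provenance = org),
            class = "sc_cpd_graph")
}
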