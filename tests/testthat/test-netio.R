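test_that("EC truncation keeps three specific fields and is idempotent", {
  expect_identical(truncate_ec("2.5.1.3"), "2.5.1")
  expect_identical(truncate_ec("4.2.1"), "4.2.1")
  expect_identical(truncate_ec(truncate_ec("1.2.3.4")), "1.2.3")
  expect_true(is.na(truncate_ec("2.5.-.-")))
  expect_true(is.na(truncate_ec("2.5")))
  expect_error(truncate_ec("not-an-ec"), "malformed")
  expect_error(truncate_ec("1.2.3.4.5"), "malformed")
  # length-monotone: output never has more fields than input
  for (ec in c("1.1", "1.1.1", "1.1.1.1", "3.4.-.-")) {
    out <- truncate_ec(ec)
    if (!is.na(out))
      expect_lte(length(strsplit(out, ".", fixed = TRUE)[[1]]),
                 length(strsplit(ec, ".", fixed = TRUE)[[1]]))
  }
})

test_that("network compound sets are derived from reactions", {
  p <- toy_panel()
  for (net in p$networks) {
    brute <- sort(unique(unlist(lapply(net$reactions, function(r)
      c(r$substrates, r$products)))))
    expect_identical(net$compounds, brute)
  }
  expect_identical(p$networks$ORG1$compounds, c("a", "b", "c"))
})

test_that("constructor invariants are enforced", {
  expect_error(reaction("R", character(), "b"), "non-empty")
  expect_error(reaction("R", "a", "b", ec_numbers = "abc"), "malformed")
  expect_error(reaction("R", "a", "b", processes = "catabolism"),
               "unknown process")
  expect_error(organism_meta("X", "INTRA", n_genes = 10,
                             n_metabolic_genes = 20), "n_metabolic_genes")
  expect_error(organism_meta("X", "EXTRA", subcategory = "MIV"),
               "inconsistent")
  r <- reaction("R", "a", "b")
  expect_error(metabolic_network(mk_org("O"), list(r, r)), "duplicate")
  n <- mk_net("SAME", list(r))
  expect_error(panel(list(n, n)), "duplicate org_id")
  # catalytic self-loops allowed but flagged
  expect_true(reaction("R", c("a", "x"), c("a", "y"))$self_loop)
})

test_that("small-molecule filter removes macromolecule reactions and their compounds", {
  r_small <- reaction("R1", "a", "b")
  r_macro <- reaction("R2", "protein1", "protein2", small_molecule = FALSE)
  p <- panel(list(mk_net("O1", list(r_small, r_macro)),
                  mk_net("O2", list(r_small))))
  pf <- apply_small_molecule_filter(p)
  expect_identical(names(pf$networks$O1$reactions), "R1")
  expect_identical(pf$networks$O1$compounds, c("a", "b"))
  expect_identical(unname(pf$removed_reactions), c(1L, 0L))
  # all-small networks are unchanged
  expect_identical(pf$networks$O2$reactions, p$networks$O2$reactions)
  # a network emptied by the filter warns but is kept
  p2 <- panel(list(mk_net("O1", list(r_macro)), mk_net("O2", list(r_small))))
  expect_warning(pf2 <- apply_small_molecule_filter(p2), "no reactions")
  expect_length(pf2$networks$O1$reactions, 0L)
})

test_that("validate_panel reports without mutating", {
  p <- toy_panel()
  rep0 <- validate_panel(p)
  expect_true(all(rep0$level != "error"))
  bad <- reaction("RB", "a", "b", ec_numbers = "7.1.1.1")
  p2 <- panel(list(mk_net("O1", list(bad)), mk_net("O2", list(bad))))
  rep2 <- validate_panel(p2)
  expect_true(any(grepl("outside 1..6", rep2$message, fixed = TRUE)))
  # unused filter compounds get an informational note
  expect_true(any(rep2$level == "note" &
                  grepl("filter compound", rep2$message)))
})

test_that("TSV and JSON round-trips are field-identical", {
  p <- suppressWarnings(generate_panel(panel_spec(
    groups = list(list(code = "EXTRA", n = 3L, rxn_range = c(20L, 30L))),
    shared_core_size = 5L, variable_pool_size = 40L,
    presence_prob = 0.4, rng_seed = 11L)))
  for (fmt in c("tsv", "json")) {
    path <- if (fmt == "tsv") withr::local_tempdir()
            else withr::local_tempfile(fileext = ".json")
    write_panel(p, path, fmt)
    p2 <- load_panel(path, fmt)
    expect_identical(org_ids(p2), org_ids(p))
    for (id in org_ids(p)) {
      n1 <- p$networks[[id]]; n2 <- p2$networks[[id]]
      expect_identical(sort(names(n2$reactions)), sort(names(n1$reactions)))
      for (rid in names(n1$reactions)) {
        r1 <- n1$reactions[[rid]]; r2 <- n2$reactions[[rid]]
        for (f in c("substrates", "products", "ec_numbers", "pathways",
                    "processes"))
          expect_setequal(r2[[f]], r1[[f]])
        expect_identical(r2$reversible, r1$reversible)
        expect_identical(r2$small_molecule, r1$small_molecule)
      }
      expect_identical(n2$org[c("group", "n_genes", "n_metabolic_genes")],
                       n1$org[c("group", "n_genes", "n_metabolic_genes")])
    }
    expect_setequal(p2$currency, p$currency)
    expect_identical(p2$excluded_dndps, p$excluded_dndps)
  }
})

test_that("SBML round-trip preserves reversibility, EC and participants", {
  r1 <- reaction("PEP-RXN", c("PEP", "ADP"), c("PYRUVATE", "ATP"),
                 reversible = FALSE, ec_numbers = "2.7.1.40",
                 processes = "degradation")
  r2 <- reaction("ENO-RXN", "2-PG", c("PEP", "WATER"), reversible = TRUE,
                 ec_numbers = c("4.2.1.11", "4.2.1"))
  p <- panel(list(mk_net("ORGA", list(r1, r2))))
  dir <- withr::local_tempdir()
  write_panel(p, dir, "sbml")
  p2 <- load_panel(dir, "sbml")
  q1 <- p2$networks$ORGA$reactions[["PEP-RXN"]]
  q2 <- p2$networks$ORGA$reactions[["ENO-RXN"]]
  expect_false(q1$reversible)
  expect_true(q2$reversible)
  expect_setequal(q1$substrates, c("PEP", "ADP"))
  expect_setequal(q1$products, c("PYRUVATE", "ATP"))
  expect_setequal(q2$ec_numbers, c("4.2.1.11", "4.2.1"))
  expect_setequal(q1$ec_numbers, "2.7.1.40")
})

test_that("loading rejects inconsistent inputs with named errors", {
  p <- toy_panel()
  dir <- withr::local_tempdir()
  write_panel(p, dir, "tsv")
  # dangling compound reference names the reaction
  rdf <- utils::read.delim(file.path(dir, "reactions.tsv"),
                           colClasses = "character")
  rdf$substrates[1] <- "GHOST-CPD"
  utils::write.table(rdf, file.path(dir, "reactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(load_panel(dir, "tsv"), "GHOST-CPD")
  # duplicate reaction id within one organism
  dir2 <- withr::local_tempdir()
  write_panel(p, dir2, "tsv")
  rdf2 <- utils::read.delim(file.path(dir2, "reactions.tsv"),
                            colClasses = "character")
  rdf2 <- rbind(rdf2, rdf2[1, ])
  utils::write.table(rdf2, file.path(dir2, "reactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(load_panel(dir2, "tsv"), "duplicate reaction id")
  # missing organism metadata names the organism
  dir3 <- withr::local_tempdir()
  write_panel(p, dir3, "tsv")
  odf <- utils::read.delim(file.path(dir3, "organisms.tsv"),
                           colClasses = "character")
  utils::write.table(odf[odf$org_id != "ORG2", ],
                     file.path(dir3, "organisms.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(load_panel(dir3, "tsv"), "ORG2")
  # same label with different compound lists across organisms
  dir4 <- withr::local_tempdir()
  write_panel(p, dir4, "tsv")
  rdf4 <- utils::read.delim(file.path(dir4, "reactions.tsv"),
                            colClasses = "character")
  i <- which(rdf4$reaction_id == "R1" & rdf4$org_id == "ORG2")
  rdf4$products[i] <- "c"
  utils::write.table(rdf4, file.path(dir4, "reactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(load_panel(dir4, "tsv"), "different compound lists")
})
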