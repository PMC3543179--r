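#' Load a panel from disk
#'
#' Reads the TSV, JSON or SBML interchange dialect. The TSV dialect is a
#' directory of `organisms.tsv`, `reactions.tsv`, `compounds.tsv` and an
#' optional `filters.json`; the JSON dialect is a single document
#' mirroring the domain types; the SBML dialect is a directory of one
#' `<org_id>.sbml` model per organism plus `organisms.tsv` and optional
#' `filters.json` (SBML carries no lifestyle metadata).
#'
#' @param path Directory (tsv, sbml) or file (json).
#' @param format One of `"tsv"`, `"json"`, `"sbml"`.
#' @return A validated [panel()]. Missing organism metadata, a dangling
#'   compound reference, a duplicate reaction id within one organism, or
#'   the same reaction label carrying different compound lists in two
#'   organisms are hard errors (label identity is the comparison key).
#' @export
load_panel <- function(path, format = c("tsv", "json", "sbml")) {
  format <- match.arg(format)
  switch(format,
         tsv = load_panel_tsv(path),
         json = load_panel_json(path),
         sbml = load_panel_sbml(path))
}

#' Write a panel to disk
#'
#' Inverse of [load_panel()]: round-tripping a panel through export and
#' import is field-identical for the TSV and JSON dialects.
#'
#' @param panel An `sc_panel`.
#' @param path Target directory (tsv, sbml) or file (json).
#' @param format One of `"tsv"`, `"json"`, `"sbml"`.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, format = c("tsv", "json", "sbml")) {
  stopifnot(inherits(panel, "sc_panel"))
  format <- match.arg(format)
  switch(format,
         tsv = write_panel_tsv(panel, path),
         json = write_panel_json(panel, path),
         sbml = write_panel_sbml(panel, path))
  invisible(path)
}

# ---- shared helpers ---------------------------------------------------

SC_SEP <- ";"

split_field <- function(x) {
  if (is.na(x) || !nzchar(x)) character() else strsplit(x, SC_SEP, fixed = TRUE)[[1]]
}

join_field <- function(x) paste(x, collapse = SC_SEP)

read_tsv_file <- function(file) {
  utils::read.delim(file, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, colClasses = "character",
                    quote = "", fileEncoding = "UTF-8")
}

organisms_from_df <- function(df) {
  need <- c("org_id", "group", "subcategory", "tax_class", "n_genes",
            "n_metabolic_genes")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("organisms table missing column(s): ", paste(miss, collapse = ", "))
  orgs <- lapply(seq_len(nrow(df)), function(i)
    organism_meta(df$org_id[i], df$group[i],
                  subcategory = df$subcategory[i],
                  tax_class = df$tax_class[i],
                  n_genes = as.integer(df$n_genes[i]),
                  n_metabolic_genes = as.integer(df$n_metabolic_genes[i])))
  names(orgs) <- df$org_id
  orgs
}

reaction_from_row <- function(row) {
  reaction(id = row$reaction_id,
           substrates = split_field(row$substrates),
           products = split_field(row$products),
           reversible = row$reversible %in% c("1", "true", "TRUE"),
           ec_numbers = split_field(row$ec_numbers),
           pathways = split_field(row$pathways),
           processes = split_field(row$processes),
           small_molecule = row$small_molecule %in% c("1", "true", "TRUE"))
}

check_compound_refs <- function(reactions, known, org) {
  for (r in reactions) {
    dangling <- setdiff(c(r$substrates, r$products), known)
    if (length(dangling))
      stop("organism '", org, "', reaction '", r$id,
           "': dangling compound reference(s): ",
           paste(dangling, collapse = ", "))
  }
}

# Label identity is the cross-organism comparison key: one label must mean
# one transformation everywhere in the panel.
check_label_consistency <- function(networks) {
  seen <- new.env(parent = emptyenv())
  for (net in networks) {
    for (r in net$reactions) {
      key <- paste(join_field(sort(r$substrates)),
                   join_field(sort(r$products)), sep = "=>")
      prev <- get0(r$id, envir = seen)
      if (is.null(prev)) {
        assign(r$id, key, envir = seen)
      } else if (!identical(prev, key)) {
        stop("reaction label '", r$id,
             "' carries different compound lists in different organisms")
      }
    }
  }
}

filters_from_list <- function(fl) {
  list(cofactor_pairs = if (is.null(fl$cofactor_pairs))
         default_cofactor_pairs()
       else lapply(fl$cofactor_pairs, as.character),
       currency = if (is.null(fl$currency)) default_currency()
                  else as.character(fl$currency),
       excluded_dndps = if (is.null(fl$excluded_dndps))
         default_excluded_dndps()
       else as.character(fl$excluded_dndps))
}

assemble_panel <- function(orgs, reactions_by_org, known_compounds,
                           filters, rng_seed = NULL) {
  nets <- lapply(names(reactions_by_org), function(id) {
    if (is.null(orgs[[id]]))
      stop("missing organism metadata for network '", id, "'")
    rx <- reactions_by_org[[id]]
    if (!is.null(known_compounds))
      check_compound_refs(rx, known_compounds, id)
    metabolic_network(orgs[[id]], rx)
  })
  check_label_consistency(nets)
  panel(nets, cofactor_pairs = filters$cofactor_pairs,
        currency = filters$currency,
        excluded_dndps = filters$excluded_dndps,
        rng_seed = rng_seed)
}

# ---- TSV dialect ------------------------------------------------------

load_panel_tsv <- function(path) {
  stopifnot(dir.exists(path))
  odf <- read_tsv_file(file.path(path, "organisms.tsv"))
  rdf <- read_tsv_file(file.path(path, "reactions.tsv"))
  cdf <- read_tsv_file(file.path(path, "compounds.tsv"))
  if (anyDuplicated(cdf$compound_id))
    stop("duplicate compound id(s) in compounds.tsv: ",
         paste(unique(cdf$compound_id[duplicated(cdf$compound_id)]),
               collapse = ", "))
  orgs <- organisms_from_df(odf)
  reactions_by_org <- lapply(split(rdf, rdf$org_id), function(sub) {
    if (anyDuplicated(sub$reaction_id))
      stop("organism '", sub$org_id[1],
           "': duplicate reaction id(s): ",
           paste(unique(sub$reaction_id[duplicated(sub$reaction_id)]),
                 collapse = ", "))
    lapply(seq_len(nrow(sub)), function(i) reaction_from_row(sub[i, ]))
  })
  fpath <- file.path(path, "filters.json")
  filters <- filters_from_list(
    if (file.exists(fpath)) jsonlite::read_json(fpath, simplifyVector = FALSE)
    else list())
  assemble_panel(orgs, reactions_by_org, cdf$compound_id, filters)
}

write_panel_tsv <- function(panel, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  orgs <- lapply(panel$networks, `[[`, "org")
  odf <- data.frame(
    org_id = vapply(orgs, `[[`, character(1), "org_id"),
    group = vapply(orgs, `[[`, character(1), "group"),
    subcategory = vapply(orgs, function(o)
      if (is.na(o$subcategory)) "" else o$subcategory, character(1)),
    tax_class = vapply(orgs, function(o)
      if (is.na(o$tax_class)) "" else o$tax_class, character(1)),
    n_genes = vapply(orgs, `[[`, integer(1), "n_genes"),
    n_metabolic_genes = vapply(orgs, `[[`, integer(1), "n_metabolic_genes"),
    stringsAsFactors = FALSE)
  rows <- list()
  for (id in names(panel$networks)) {
    for (r in panel$networks[[id]]$reactions) {
      rows[[length(rows) + 1L]] <- data.frame(
        org_id = id, reaction_id = r$id,
        reversible = as.integer(r$reversible),
        ec_numbers = join_field(r$ec_numbers),
        substrates = join_field(r$substrates),
        products = join_field(r$products),
        pathways = join_field(r$pathways),
        processes = join_field(r$processes),
        small_molecule = as.integer(r$small_molecule),
        stringsAsFactors = FALSE)
    }
  }
  rdf <- do.call(rbind, rows)
  cpds <- sort(unique(c(unlist(lapply(panel$networks, `[[`, "compounds")),
                        panel$currency, unlist(panel$cofactor_pairs),
                        panel$excluded_dndps)))
  cdf <- data.frame(compound_id = cpds, name = cpds,
                    stringsAsFactors = FALSE)
  wr <- function(df, file)
    utils::write.table(df, file.path(path, file), sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  wr(odf, "organisms.tsv"); wr(rdf, "reactions.tsv"); wr(cdf, "compounds.tsv")
  jsonlite::write_json(
    list(cofactor_pairs = panel$cofactor_pairs, currency = panel$currency,
         excluded_dndps = panel$excluded_dndps),
    file.path(path, "filters.json"), auto_unbox = FALSE, pretty = TRUE)
  path
}

# ---- JSON dialect -----------------------------------------------------

load_panel_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  orgs <- list()
  reactions_by_org <- list()
  for (nw in doc$networks) {
    om <- nw$organism
    if (is.null(om) || is.null(om$org_id))
      stop("missing organism metadata for a network in '", path, "'")
    id <- om$org_id
    orgs[[id]] <- organism_meta(
      id, om$group,
      subcategory = if (is.null(om$subcategory)) NA_character_ else om$subcategory,
      tax_class = if (is.null(om$tax_class)) NA_character_ else om$tax_class,
      n_genes = as.integer(om$n_genes),
      n_metabolic_genes = as.integer(om$n_metabolic_genes))
    rx <- lapply(nw$reactions, function(r)
      reaction(r$id, as.character(r$substrates), as.character(r$products),
               reversible = isTRUE(r$reversible),
               ec_numbers = as.character(r$ec_numbers %||% character()),
               pathways = as.character(r$pathways %||% character()),
               processes = as.character(r$processes %||% character()),
               small_molecule = isTRUE(r$small_molecule)))
    ids <- vapply(rx, `[[`, character(1), "id")
    if (anyDuplicated(ids))
      stop("organism '", id, "': duplicate reaction id(s): ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    reactions_by_org[[id]] <- rx
  }
  filters <- filters_from_list(doc$filters %||% list())
  assemble_panel(orgs, reactions_by_org, NULL, filters,
                 rng_seed = doc$rng_seed)
}

write_panel_json <- function(panel, path) {
  doc <- list(
    networks = lapply(unname(panel$networks), function(net) list(
      organism = net$org[c("org_id", "group", "subcategory", "tax_class",
                           "n_genes", "n_metabolic_genes")],
      reactions = lapply(unname(net$reactions), function(r)
        r[c("id", "substrates", "products", "reversible", "ec_numbers",
            "pathways", "processes", "small_molecule")]))),
    filters = list(cofactor_pairs = panel$cofactor_pairs,
                   currency = panel$currency,
                   excluded_dndps = panel$excluded_dndps),
    rng_seed = panel$rng_seed)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- SBML dialect -----------------------------------------------------
# Minimal SBML level 3 version 1 subset: species, reactions with
# reactant/product species references, the reversible flag, and EC
# annotations stored as <notes> body lines "EC: a.b.c.d". Covers this
# package's own fields, not general SBML.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"

load_panel_sbml <- function(path) {
  stopifnot(dir.exists(path))
  odf <- read_tsv_file(file.path(path, "organisms.tsv"))
  orgs <- organisms_from_df(odf)
  files <- list.files(path, pattern = "\\.sbml$", full.names = TRUE)
  if (!length(files)) stop("no .sbml files found in '", path, "'")
  reactions_by_org <- list()
  for (f in files) {
    id <- sub("\\.sbml$", "", basename(f))
    reactions_by_org[[id]] <- read_sbml_reactions(f)
  }
  fpath <- file.path(path, "filters.json")
  filters <- filters_from_list(
    if (file.exists(fpath)) jsonlite::read_json(fpath, simplifyVector = FALSE)
    else list())
  assemble_panel(orgs, reactions_by_org, NULL, filters)
}

read_sbml_reactions <- function(file) {
  doc <- xml2::read_xml(file)
  ns <- c(s = SBML_NS)
  # original labels live in `name`; SIds are sanitised versions of them
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  sp_name <- stats::setNames(xml2::xml_attr(sp, "name"),
                             xml2::xml_attr(sp, "id"))
  rx_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  lapply(rx_nodes, function(node) {
    grab <- function(which) {
      refs <- xml2::xml_find_all(
        node, paste0("./s:", which, "/s:speciesReference"), ns)
      unname(sp_name[xml2::xml_attr(refs, "species")])
    }
    notes <- xml2::xml_text(xml2::xml_find_all(
      node, "./s:notes//*[local-name()='p']", ns))
    ec <- sub("^EC: *", "", grep("^EC: ", notes, value = TRUE))
    proc <- sub("^PROCESS: *", "", grep("^PROCESS: ", notes, value = TRUE))
    pw <- sub("^PATHWAY: *", "", grep("^PATHWAY: ", notes, value = TRUE))
    sm <- !any(notes == "MACROMOLECULE")
    reaction(xml2::xml_attr(node, "name"),
             substrates = grab("listOfReactants"),
             products = grab("listOfProducts"),
             reversible = identical(xml2::xml_attr(node, "reversible"), "true"),
             ec_numbers = ec, pathways = pw, processes = proc,
             small_molecule = sm)
  })
}

write_panel_sbml <- function(panel, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (id in names(panel$networks))
    write_sbml_model(panel$networks[[id]], file.path(path, paste0(id, ".sbml")))
  orgs <- lapply(panel$networks, `[[`, "org")
  odf <- data.frame(
    org_id = vapply(orgs, `[[`, character(1), "org_id"),
    group = vapply(orgs, `[[`, character(1), "group"),
    subcategory = vapply(orgs, function(o)
      if (is.na(o$subcategory)) "" else o$subcategory, character(1)),
    tax_class = vapply(orgs, function(o)
      if (is.na(o$tax_class)) "" else o$tax_class, character(1)),
    n_genes = vapply(orgs, `[[`, integer(1), "n_genes"),
    n_metabolic_genes = vapply(orgs, `[[`, integer(1), "n_metabolic_genes"),
    stringsAsFactors = FALSE)
  utils::write.table(odf, file.path(path, "organisms.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(cofactor_pairs = panel$cofactor_pairs, currency = panel$currency,
         excluded_dndps = panel$excluded_dndps),
    file.path(path, "filters.json"), auto_unbox = FALSE, pretty = TRUE)
  path
}

write_sbml_model <- function(network, file) {
  doc <- xml2::xml_new_root("sbml", xmlns = SBML_NS, level = "3",
                            version = "1")
  model <- xml2::xml_add_child(doc, "model",
                               id = xml_safe_id(network$org$org_id))
  los <- xml2::xml_add_child(model, "listOfSpecies")
  for (cpd in network$compounds)
    xml2::xml_add_child(los, "species", id = xml_safe_id(cpd), name = cpd,
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  cpd_map <- stats::setNames(vapply(network$compounds, xml_safe_id,
                                    character(1)), network$compounds)
  lor <- xml2::xml_add_child(model, "listOfReactions")
  for (r in network$reactions) {
    rn <- xml2::xml_add_child(
      lor, "reaction", id = xml_safe_id(r$id), name = r$id,
      reversible = if (r$reversible) "true" else "false", fast = "false")
    notes <- xml2::xml_add_child(rn, "notes")
    body <- xml2::xml_add_child(notes, "body",
                                xmlns = "http://www.w3.org/1999/xhtml")
    for (ec in r$ec_numbers)
      xml2::xml_add_child(body, "p", paste0("EC: ", ec))
    for (p in r$processes)
      xml2::xml_add_child(body, "p", paste0("PROCESS: ", p))
    for (p in r$pathways)
      xml2::xml_add_child(body, "p", paste0("PATHWAY: ", p))
    if (!r$small_molecule)
      xml2::xml_add_child(body, "p", "MACROMOLECULE")
    lre <- xml2::xml_add_child(rn, "listOfReactants")
    for (s in r$substrates)
      xml2::xml_add_child(lre, "speciesReference", species = cpd_map[[s]],
                          stoichiometry = "1", constant = "true")
    lpr <- xml2::xml_add_child(rn, "listOfProducts")
    for (p in r$products)
      xml2::xml_add_child(lpr, "speciesReference", species = cpd_map[[p]],
                          stoichiometry = "1", constant = "true")
  }
  xml2::write_xml(doc, file)
  file
}

# SBML SIds allow [A-Za-z0-9_] and must not start with a digit.
xml_safe_id <- function(x) {
  x <- gsub("[^A-Za-z0-9_]", "_", x)
  if (grepl("^[0-9]", x)) x <- paste0("x", x)
  x
}
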