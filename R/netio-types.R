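#' Construct a metabolic reaction
#'
#' A reaction is an identified biochemical transformation compared across
#' organisms by its label (BioCyc-style id string), not by stoichiometry.
#'
#' @param id Stable label string, e.g. `"PEPDEPHOS-RXN"`.
#' @param substrates Character vector of compound ids (at least one).
#' @param products Character vector of compound ids (at least one).
#' @param reversible Logical; reversible reactions contribute both
#'   orientations in graph construction.
#' @param ec_numbers Character vector of EC strings, full (`"a.b.c.d"`) or
#'   partial (`"a.b.c"`); may be empty.
#' @param pathways Character vector of pathway labels.
#' @param processes Character vector, subset of
#'   `c("biosynthesis", "degradation", "other")`.
#' @param small_molecule Logical; reactions involving macromolecules carry
#'   `FALSE` and are removed by [apply_small_molecule_filter()].
#' @return An object of class `sc_reaction`.
#' @export
reaction <- function(id, substrates, products, reversible = FALSE,
                     ec_numbers = character(), pathways = character(),
                     processes = character(), small_molecule = TRUE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  substrates <- unique(as.character(substrates))
  products <- unique(as.character(products))
  if (length(substrates) < 1L || length(products) < 1L)
    stop("reaction '", id, "': substrates and products must each be non-empty")
  ec_numbers <- unique(as.character(ec_numbers))
  for (ec in ec_numbers) assert_ec_syntax(ec, context = id)
  processes <- unique(as.character(processes))
  bad <- setdiff(processes, c("biosynthesis", "degradation", "other"))
  if (length(bad))
    stop("reaction '", id, "': unknown process label(s): ",
         paste(bad, collapse = ", "))
  structure(
    list(id = id, substrates = substrates, products = products,
         reversible = isTRUE(reversible), ec_numbers = ec_numbers,
         pathways = unique(as.character(pathways)), processes = processes,
         small_molecule = isTRUE(small_molecule),
         self_loop = length(intersect(substrates, products)) > 0L),
    class = "sc_reaction")
}

#' Construct organism metadata
#'
#' @param org_id Short organism code (HAMAP-style, e.g. `"MYCGE"`).
#' @param group Lifestyle group, one of `"INTRA"` (obligate intracellular),
#'   `"CA"` (cell-associated), `"EXTRA"` (extracellular), `"FL"` (free-living).
#' @param subcategory Optional code combining association type (M/C/P) and
#'   transmission (V/H), e.g. `"MIV"`; `NA` when not assigned.
#' @param tax_class Taxonomic class string.
#' @param n_genes Total gene count (non-negative).
#' @param n_metabolic_genes Metabolic gene count, at most `n_genes`.
#' @return An object of class `sc_organism`.
#' @export
organism_meta <- function(org_id, group, subcategory = NA_character_,
                          tax_class = NA_character_, n_genes = 0L,
                          n_metabolic_genes = 0L) {
  stopifnot(is.character(org_id), length(org_id) == 1L, nzchar(org_id))
  group <- match.arg(group, c("INTRA", "CA", "EXTRA", "FL"))
  n_genes <- as.integer(n_genes)
  n_metabolic_genes <- as.integer(n_metabolic_genes)
  if (is.na(n_genes) || n_genes < 0L)
    stop("organism '", org_id, "': n_genes must be a non-negative integer")
  if (is.na(n_metabolic_genes) || n_metabolic_genes < 0L ||
      n_metabolic_genes > n_genes)
    stop("organism '", org_id,
         "': n_metabolic_genes must lie in [0, n_genes]")
  if (!is.na(subcategory) && nzchar(subcategory)) {
    # association letter must agree with the lifestyle group (MIV is INTRA)
    assoc <- substr(subcategory, 2L, 2L)
    ok <- switch(group, INTRA = assoc == "I", CA = assoc %in% c("C", "A"),
                 EXTRA = assoc == "E", FL = TRUE)
    if (!isTRUE(ok))
      stop("organism '", org_id, "': subcategory '", subcategory,
           "' inconsistent with group '", group, "'")
  } else {
    subcategory <- NA_character_
  }
  structure(
    list(org_id = org_id, group = group, subcategory = subcategory,
         tax_class = tax_class, n_genes = n_genes,
         n_metabolic_genes = n_metabolic_genes),
    class = "sc_organism")
}

#' Construct one organism's metabolic network
#'
#' The compound set is always derived from the retained reactions: a
#' metabolite not appearing as substrate or product of any reaction is not
#' part of the network.
#'
#' @param org An [organism_meta()] object.
#' @param reactions List of [reaction()] objects with unique ids.
#' @return An object of class `sc_network` with derived `compounds`.
#' @export
metabolic_network <- function(org, reactions) {
  stopifnot(inherits(org, "sc_organism"))
  if (length(reactions)) {
    stopifnot(all(vapply(reactions, inherits, logical(1), "sc_reaction")))
    ids <- vapply(reactions, `[[`, character(1), "id")
    if (anyDuplicated(ids))
      stop("organism '", org$org_id, "': duplicate reaction id(s): ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    names(reactions) <- ids
  } else {
    reactions <- structure(list(), names = character())
  }
  structure(
    list(org = org, reactions = reactions,
         compounds = derive_compounds(reactions)),
    class = "sc_network")
}

derive_compounds <- function(reactions) {
  if (!length(reactions)) return(character())
  sort(unique(unlist(lapply(reactions, function(r)
    c(r$substrates, r$products)), use.names = FALSE)))
}

#' Default currency-compound and cofactor-pair filters
#'
#' Currency compounds (water, proton, CO2, phosphate, diphosphate, NH3,
#' H2O2, O2) are ubiquitous metabolites excluded from graph construction
#' because they spuriously connect unrelated reactions. The cofactor-pair
#' list covers the ADP/ATP and NAD+/NADH co-transformations; both lists are
#' plain data and can be extended by the caller.
#'
#' @return `default_currency()`: character vector of compound ids.
#' @export
default_currency <- function() {
  c("WATER", "PROTON", "CARBON-DIOXIDE", "Pi", "PPI", "AMMONIA",
    "HYDROGEN-PEROXIDE", "OXYGEN-MOLECULE")
}

#' @rdname default_currency
#' @return `default_cofactor_pairs()`: list of unordered id pairs.
#' @export
default_cofactor_pairs <- function() {
  list(c("ADP", "ATP"), c("NAD", "NADH"))
}

#' @rdname default_currency
#' @return `default_excluded_dndps()`: the dNDP compounds excluded from
#'   compound graphs because they are produced only by macromolecule
#'   reactions (dADP, dCDP, dUDP, dGDP).
#' @export
default_excluded_dndps <- function() {
  c("dADP", "dCDP", "dUDP", "dGDP")
}

#' Assemble a panel of metabolic networks
#'
#' The panel is the unit of every comparative analysis: a set of organisms'
#' networks plus the filter configuration shared by all graph analyses.
#'
#' @param networks List of [metabolic_network()] objects (at least two for
#'   comparative operations; one is allowed for construction).
#' @param cofactor_pairs List of unordered compound-id pairs suppressed as
#'   arc witnesses when co-transformed within one reaction.
#' @param currency Character vector of currency compound ids.
#' @param excluded_dndps Compound ids removed before seed detection.
#' @param rng_seed Optional integer recorded for provenance.
#' @return An object of class `sc_panel`; networks named by `org_id`.
#' @export
panel <- function(networks, cofactor_pairs = default_cofactor_pairs(),
                  currency = default_currency(),
                  excluded_dndps = default_excluded_dndps(),
                  rng_seed = NULL) {
  stopifnot(length(networks) >= 1L,
            all(vapply(networks, inherits, logical(1), "sc_network")))
  ids <- vapply(networks, function(n) n$org$org_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate org_id(s) in panel: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(networks) <- ids
  stopifnot(all(vapply(cofactor_pairs, length, integer(1)) == 2L))
  structure(
    list(networks = networks,
         cofactor_pairs = lapply(cofactor_pairs, as.character),
         currency = as.character(currency),
         excluded_dndps = as.character(excluded_dndps),
         rng_seed = rng_seed,
         removed_reactions = NULL),
    class = "sc_panel")
}

#' @export
print.sc_panel <- function(x, ...) {
  ng <- table(vapply(x$networks, function(n) n$org$group, character(1)))
  cat("<sc_panel> ", length(x$networks), " organisms (",
      paste(names(ng), unname(ng), sep = ":", collapse = ", "), ")\n",
      sep = "")
  nr <- vapply(x$networks, function(n) length(n$reactions), integer(1))
  cat("  reactions per organism: ", min(nr), "-", max(nr),
      "; currency filter: ", length(x$currency), " compounds; ",
      length(x$cofactor_pairs), " cofactor pairs\n", sep = "")
  invisible(x)
}

#' @export
print.sc_network <- function(x, ...) {
  cat("<sc_network> ", x$org$org_id, " (", x$org$group, "): ",
      length(x$reactions), " reactions, ", length(x$compounds),
      " compounds\n", sep = "")
  invisible(x)
}

#' Organism ids of a panel
#' @param panel An `sc_panel`.
#' @return Character vector of organism ids.
#' @export
org_ids <- function(panel) {
  stopifnot(inherits(panel, "sc_panel"))
  names(panel$networks)
}

#' Extract an organism's comparison element set
#'
#' The three element universes the comparative analyses operate on:
#' reaction labels, derived compound labels, or the level-3 truncation
#' image of all EC annotations (a reaction with several EC numbers
#' contributes every truncation; unannotated reactions contribute nothing).
#'
#' @param network An `sc_network`.
#' @param element_kind One of `"reaction"`, `"compound"`, `"partial_ec"`.
#' @return Character vector (a set).
#' @export
element_set <- function(network,
                        element_kind = c("reaction", "compound", "partial_ec")) {
  element_kind <- match.arg(element_kind)
  switch(element_kind,
    reaction = names(network$reactions),
    compound = network$compounds,
    partial_ec = {
      ecs <- unlist(lapply(network$reactions, `[[`, "ec_numbers"),
                    use.names = FALSE)
      if (!length(ecs)) return(character())
      tr <- vapply(unique(ecs), truncate_ec, character(1))
      sort(unique(tr[!is.na(tr)]))
    })
}

assert_ec_syntax <- function(ec, context = NULL) {
  if (!grepl("^[0-9]+(\\.([0-9]+|-)){1,3}$", ec))
    stop("malformed EC string '", ec, "'",
         if (!is.null(context)) paste0(" (reaction '", context, "')"))
  invisible(TRUE)
}

#' Truncate an EC number to level 3
#'
#' Level-3 ("partial") EC classes, e.g. `2.5.1` from `2.5.1.3`, denote a
#' biochemical capability broader than a single reaction; they are the
#' comparison unit that absorbs non-orthologous gene displacement and
#' alternative pathway branches.
#'
#' @param ec EC string with 2-4 dot-separated fields; trailing fields may
#'   be `"-"` placeholders.
#' @return The first three fields joined by dots, or `NA_character_` when
#'   fewer than three specific fields are present (e.g. `"2.5.-.-"`).
#'   Idempotent on level-3 input.
#' @examples
#' truncate_ec("2.5.1.3")  # "2.5.1"
#' truncate_ec("4.2.1")    # "4.2.1"
#' truncate_ec("2.5.-.-")  # NA
#' @export
truncate_ec <- function(ec) {
  assert_ec_syntax(ec)
  fields <- strsplit(ec, ".", fixed = TRUE)[[1]]
  if (length(fields) < 3L || any(fields[1:3] == "-"))
    return(NA_character_)
  paste(fields[1:3], collapse = ".")
}

#' Remove macromolecule reactions from a panel
#'
#' All comparative analyses are restricted to the small-molecule
#' metabolism: reactions flagged `small_molecule = FALSE` are dropped from
#' every network and the derived compound sets recomputed, so compounds
#' appearing only in macromolecule reactions disappear. Per-organism
#' removal counts are recorded in the returned panel's
#' `removed_reactions`.
#'
#' @param panel An `sc_panel`.
#' @return The filtered `sc_panel`. A network left with zero reactions
#'   triggers a warning but is retained (size-0 networks are legal).
#' @export
apply_small_molecule_filter <- function(panel) {
  stopifnot(inherits(panel, "sc_panel"))
  removed <- integer(length(panel$networks))
  names(removed) <- names(panel$networks)
  for (id in names(panel$networks)) {
    net <- panel$networks[[id]]
    keep <- vapply(net$reactions, `[[`, logical(1), "small_molecule")
    removed[[id]] <- sum(!keep)
    if (any(!keep)) {
      net$reactions <- net$reactions[keep]
      net$compounds <- derive_compounds(net$reactions)
      panel$networks[[id]] <- net
    }
    if (!length(net$reactions))
      warning("organism '", id,
              "' has no reactions after the small-molecule filter",
              call. = FALSE)
  }
  panel$removed_reactions <- removed
  panel
}

#' Validate a panel
#'
#' Report-only check: EC syntax and class range, duplicate compound usage,
#' empty networks, and filter-list ids that no reaction uses. Never
#' mutates and never throws.
#'
#' @param panel An `sc_panel`.
#' @return Data frame with columns `level` (`"error"`, `"warning"`,
#'   `"note"`), `org_id` and `message`; zero rows for a clean panel.
#' @export
validate_panel <- function(panel) {
  stopifnot(inherits(panel, "sc_panel"))
  rows <- list()
  add <- function(level, org, msg)
    rows[[length(rows) + 1L]] <<- data.frame(
      level = level, org_id = org, message = msg,
      stringsAsFactors = FALSE)
  all_cpds <- character()
  for (id in names(panel$networks)) {
    net <- panel$networks[[id]]
    if (!length(net$reactions))
      add("warning", id, "network has zero reactions")
    for (r in net$reactions) {
      for (ec in r$ec_numbers) {
        cls <- suppressWarnings(as.integer(strsplit(ec, ".", fixed = TRUE)[[1]][1]))
        if (is.na(cls) || cls < 1L || cls > 6L)
          add("warning", id, paste0("reaction '", r$id, "': EC class '",
                                    ec, "' outside 1..6"))
      }
      if (r$self_loop)
        add("note", id, paste0("reaction '", r$id,
                               "' is a catalytic self-loop"))
    }
    all_cpds <- union(all_cpds, net$compounds)
  }
  filt <- unique(c(panel$currency, unlist(panel$cofactor_pairs),
                   panel$excluded_dndps))
  unused <- setdiff(filt, all_cpds)
  for (u in unused)
    add("note", NA_character_,
        paste0("filter compound '", u, "' not used by any reaction"))
  if (!length(rows))
    return(data.frame(level = character(), org_id = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
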