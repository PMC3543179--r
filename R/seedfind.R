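#' Build the directed compound graph of one organism
#'
#' Nodes are metabolites (after removing currency compounds and the
#' excluded dNDPs, which are products of macromolecule reactions and
#' would otherwise show up as spurious inputs); each retained reaction
#' contributes an arc from every substrate to every product, and
#' reversible reactions contribute both directions. Cofactor-pair
#' members co-transformed within a reaction are dropped from that
#' reaction, mirroring reaction-graph filtering.
#'
#' @param network An `sc_network`, filtered to small molecules.
#' @param currency Currency compound ids.
#' @param cofactor_pairs List of unordered id pairs.
#' @param excluded_dndps Compound ids excluded by node deletion before
#'   any component computation.
#' @return An object of class `sc_cpd_graph`: list with `nodes`, `arcs`
#'   (data frame `from`, `to`), `provenance`.
#' @export
build_compound_graph <- function(network, currency = default_currency(),
                                 cofactor_pairs = default_cofactor_pairs(),
                                 excluded_dndps = default_excluded_dndps()) {
  stopifnot(inherits(network, "sc_network"))
  drop <- union(currency, excluded_dndps)
  nodes <- setdiff(network$compounds, drop)
  from <- character(); to <- character()
  for (r in network$reactions) {
    subs <- setdiff(r$substrates, drop)
    prods <- setdiff(r$products, drop)
    for (pair in cofactor_pairs) {
      a <- pair[1]; b <- pair[2]
      if ((a %in% r$substrates && b %in% r$products) ||
          (b %in% r$substrates && a %in% r$products)) {
        subs <- setdiff(subs, pair)
        prods <- setdiff(prods, pair)
      }
    }
    if (length(subs) && length(prods)) {
      grid <- expand.grid(s = subs, p = prods, stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
      from <- c(from, grid$s); to <- c(to, grid$p)
    }
    if (r$reversible) {
      grid <- expand.grid(s = prods, p = subs, stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
      from <- c(from, grid$s); to <- c(to, grid$p)
    }
  }
  arcs <- unique(data.frame(from = from, to = to,
                            stringsAsFactors = FALSE))
  arcs <- arcs[arcs$from != arcs$to, , drop = FALSE]
  arcs <- arcs[order(arcs$from, arcs$to), , drop = FALSE]
  rownames(arcs) <- NULL
  structure(list(nodes = nodes, arcs = arcs,
                 provenance = network$org$org_id),
            class = "sc_cpd_graph")
}

#' @export
print.sc_cpd_graph <- function(x, ...) {
  cat("<sc_cpd_graph> [", x$provenance, "] ", length(x$nodes),
      " compounds, ", nrow(x$arcs), " arcs\n", sep = "")
  invisible(x)
}

#' Detect seed (potential input) metabolites
#'
#' Seed-set detection on the directed compound graph: compute strongly
#' connected components, condense the graph, and take the source
#' components (those with no incoming arc from outside). Every member
#' of a source component is a potential environmental input with
#' confidence `1 / |component|` — topologically, at least one member
#' must be acquired from outside, but the graph cannot say which.
#'
#' @param graph An `sc_cpd_graph`.
#' @return An object of class `sc_seed_report`: list with `org`,
#'   `seeds` (character vector, the union of source components),
#'   `source_components` (list of character vectors), `confidence`
#'   (named numeric over seeds), `nodes`.
#' @export
find_seeds <- function(graph) {
  stopifnot(inherits(graph, "sc_cpd_graph"))
  if (!length(graph$nodes))
    return(structure(list(org = graph$provenance, seeds = character(),
                          source_components = list(),
                          confidence = numeric(), nodes = character()),
                     class = "sc_seed_report"))
  g <- igraph::graph_from_data_frame(
    graph$arcs, directed = TRUE,
    vertices = data.frame(name = graph$nodes))
  scc <- igraph::components(g, mode = "strong")
  memb <- scc$membership
  # a component is a source iff no arc enters it from another component
  has_incoming <- rep(FALSE, scc$no)
  if (nrow(graph$arcs)) {
    cf <- memb[graph$arcs$from]
    ct <- memb[graph$arcs$to]
    cross <- cf != ct
    has_incoming[unique(ct[cross])] <- TRUE
  }
  groups <- split(names(memb), memb)
  src <- groups[!has_incoming]
  src <- lapply(unname(src), sort)
  src <- src[order(vapply(src, `[[`, character(1), 1L))]
  seeds <- sort(unlist(src, use.names = FALSE))
  conf <- unlist(lapply(src, function(comp)
    stats::setNames(rep(1 / length(comp), length(comp)), comp)))
  structure(list(org = graph$provenance, seeds = seeds,
                 source_components = src, confidence = conf[seeds],
                 nodes = graph$nodes),
            class = "sc_seed_report")
}

#' @export
print.sc_seed_report <- function(x, ...) {
  cat("<sc_seed_report> [", x$org, "] ", length(x$seeds), " seeds in ",
      length(x$source_components), " source components\n", sep = "")
  invisible(x)
}

#' Seed reports for every organism of a panel
#'
#' @param panel An `sc_panel`.
#' @return Named list of `sc_seed_report` objects.
#' @export
panel_seed_reports <- function(panel) {
  stopifnot(inherits(panel, "sc_panel"))
  lapply(panel$networks, function(net)
    find_seeds(build_compound_graph(net, panel$currency,
                                    panel$cofactor_pairs,
                                    panel$excluded_dndps)))
}

#' Distance-one seed extension across a panel
#'
#' Copes with inputs missed by network reconstruction: a compound is
#' added to an organism's extended inputs when it lies within one arc of
#' one of that organism's base seeds (undirected adjacency by default,
#' incoming-arc-only with `mode = "in"`) and is itself a base seed of at
#' least one other organism in the panel. Witnessing organisms are
#' recorded; extended seeds are disjoint from base seeds.
#'
#' @param reports Named list of `sc_seed_report` objects (all organisms).
#' @param graphs Named list of the matching `sc_cpd_graph` objects.
#' @param mode `"all"` (undirected adjacency) or `"in"` (directed
#'   predecessors of a seed only).
#' @return The reports, each gaining `extended` (character vector) and
#'   `extended_witness` (named list: compound -> witnessing org ids).
#'   A single-organism panel returns unchanged with a warning.
#' @export
distance_one_extension <- function(reports, graphs,
                                   mode = c("all", "in")) {
  mode <- match.arg(mode)
  stopifnot(identical(names(reports), names(graphs)))
  if (length(reports) < 2L) {
    warning("distance-one extension needs at least two organisms",
            call. = FALSE)
    return(lapply(reports, function(r) {
      r$extended <- character(); r$extended_witness <- list(); r
    }))
  }
  seed_owner <- list()
  for (org in names(reports))
    for (s in reports[[org]]$seeds)
      seed_owner[[s]] <- c(seed_owner[[s]], org)
  for (org in names(reports)) {
    rep_o <- reports[[org]]
    arcs <- graphs[[org]]$arcs
    near <- character()
    if (length(rep_o$seeds) && nrow(arcs)) {
      adj_out <- arcs$to[arcs$from %in% rep_o$seeds]
      adj_in <- arcs$from[arcs$to %in% rep_o$seeds]
      near <- unique(if (mode == "all") c(adj_out, adj_in) else adj_in)
    }
    near <- setdiff(near, rep_o$seeds)
    ext <- character(); wit <- list()
    for (c_id in near) {
      owners <- setdiff(seed_owner[[c_id]], org)
      if (length(owners)) {
        ext <- c(ext, c_id)
        wit[[c_id]] <- owners
      }
    }
    rep_o$extended <- sort(ext)
    rep_o$extended_witness <- wit
    reports[[org]] <- rep_o
  }
  reports
}

#' Group-level comparison of potential input sets
#'
#' Intersection, union and mean sizes of per-organism input sets
#' (base seeds, optionally including the distance-one extension) per
#' lifestyle group and over the whole panel.
#'
#' @param reports Named list of `sc_seed_report` objects.
#' @param panel The `sc_panel` the reports came from (for group labels).
#' @param use_extended Logical; include extended seeds when present.
#' @return Data frame with one row per group plus an `"ALL"` row:
#'   `group`, `n_orgs`, `intersection`, `union`, `mean`.
#' @export
compare_inputs <- function(reports, panel, use_extended = FALSE) {
  stopifnot(inherits(panel, "sc_panel"))
  input_sets <- lapply(reports, function(r) {
    s <- r$seeds
    if (use_extended && !is.null(r$extended)) s <- union(s, r$extended)
    s
  })
  groups <- vapply(panel$networks[names(reports)],
                   function(n) n$org$group, character(1))
  scopes <- c(split(names(reports), groups), list(ALL = names(reports)))
  do.call(rbind, lapply(names(scopes), function(g) {
    sets <- input_sets[scopes[[g]]]
    data.frame(group = g, n_orgs = length(sets),
               intersection = length(Reduce(intersect, sets)),
               union = length(Reduce(union, sets)),
               mean = mean(vapply(sets, length, integer(1))),
               stringsAsFactors = FALSE)
  }))
}
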