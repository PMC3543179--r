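#' Build the reaction graph of one organism
#'
#' Nodes are reactions; a directed arc links a producer of a compound to
#' a consumer of that compound. Currency compounds never witness an arc.
#' Cofactor-pair members are treated like currency within any reaction
#' that co-transforms the pair (one member consumed, the other produced),
#' so e.g. the ADP consumed and ATP produced by a kinase do not connect
#' it to unrelated ATP users. Reversible reactions contribute both
#' orientations unless `strict_direction` is set. Self-arcs are never
#' generated.
#'
#' @param network An `sc_network`, already filtered to small molecules.
#' @param currency Character vector of currency compound ids.
#' @param cofactor_pairs List of unordered id pairs.
#' @param strict_direction Logical; when `TRUE` a reversible reaction is
#'   used only in its written direction.
#' @return An object of class `sc_rxn_graph`: list with `nodes`
#'   (character), `arcs` (data frame `from`, `to`, `witness` with
#'   `;`-joined compound ids) and `provenance` (the organism id).
#' @export
build_reaction_graph <- function(network, currency = default_currency(),
                                 cofactor_pairs = default_cofactor_pairs(),
                                 strict_direction = FALSE) {
  stopifnot(inherits(network, "sc_network"))
  nodes <- names(network$reactions)
  role <- reaction_roles(network$reactions, currency, cofactor_pairs,
                         strict_direction)
  arcs <- arcs_from_roles(role$out, role$from)
  structure(list(nodes = nodes, arcs = arcs,
                 provenance = network$org$org_id),
            class = "sc_rxn_graph")
}

# Effective producer ("out") and consumer ("from") witness sets per
# reaction after currency and per-reaction cofactor-pair suppression.
reaction_roles <- function(reactions, currency, cofactor_pairs,
                           strict_direction) {
  out <- list(); from <- list()
  for (r in reactions) {
    subs <- setdiff(r$substrates, currency)
    prods <- setdiff(r$products, currency)
    for (pair in cofactor_pairs) {
      a <- pair[1]; b <- pair[2]
      if ((a %in% r$substrates && b %in% r$products) ||
          (b %in% r$substrates && a %in% r$products)) {
        subs <- setdiff(subs, pair)
        prods <- setdiff(prods, pair)
      }
    }
    if (r$reversible && !strict_direction) {
      both <- union(subs, prods)
      out[[r$id]] <- both
      from[[r$id]] <- both
    } else {
      out[[r$id]] <- prods
      from[[r$id]] <- subs
    }
  }
  list(out = out, from = from)
}

arcs_from_roles <- function(out, from) {
  # index compounds -> producing / consuming reactions
  producers <- invert_membership(out)
  consumers <- invert_membership(from)
  acc <- new.env(parent = emptyenv())
  for (cpd in names(producers)) {
    cons <- consumers[[cpd]]
    if (is.null(cons)) next
    for (p in producers[[cpd]]) {
      for (q in cons) {
        if (p == q) next
        key <- paste0(p, "\r", q)
        assign(key, c(get0(key, envir = acc), cpd), envir = acc)
      }
    }
  }
  keys <- ls(acc)
  if (!length(keys))
    return(data.frame(from = character(), to = character(),
                      witness = character(), stringsAsFactors = FALSE))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  df <- data.frame(
    from = vapply(parts, `[[`, character(1), 1L),
    to = vapply(parts, `[[`, character(1), 2L),
    witness = vapply(keys, function(k)
      paste(sort(unique(get(k, envir = acc))), collapse = ";"),
      character(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  df[order(df$from, df$to), , drop = FALSE]
}

invert_membership <- function(sets) {
  if (!length(sets)) return(list())
  pairs <- data.frame(
    id = rep(names(sets), lengths(sets)),
    cpd = unlist(sets, use.names = FALSE),
    stringsAsFactors = FALSE)
  split(pairs$id, pairs$cpd)
}

#' @export
print.sc_rxn_graph <- function(x, ...) {
  cat("<sc_rxn_graph> [", x$provenance, "] ", length(x$nodes),
      " reactions, ", nrow(x$arcs), " arcs\n", sep = "")
  invisible(x)
}

#' Union of reaction graphs
#'
#' Node set is the union of node sets; an arc is present when present in
#' at least one input graph, with witness compounds merged. Used to
#' analyse connectivity of core reactions over a whole panel.
#'
#' @param graphs List of `sc_rxn_graph` objects (at least one).
#' @return An `sc_rxn_graph` with provenance `"union"`.
#' @export
union_graph <- function(graphs) {
  stopifnot(length(graphs) >= 1L,
            all(vapply(graphs, inherits, logical(1), "sc_rxn_graph")))
  nodes <- sort(unique(unlist(lapply(graphs, `[[`, "nodes"))))
  arcs <- do.call(rbind, lapply(graphs, `[[`, "arcs"))
  if (nrow(arcs)) {
    key <- paste(arcs$from, arcs$to, sep = "\r")
    merged <- lapply(split(arcs$witness, key), function(w)
      paste(sort(unique(unlist(strsplit(w, ";", fixed = TRUE)))),
            collapse = ";"))
    parts <- strsplit(names(merged), "\r", fixed = TRUE)
    arcs <- data.frame(
      from = vapply(parts, `[[`, character(1), 1L),
      to = vapply(parts, `[[`, character(1), 2L),
      witness = unlist(merged, use.names = FALSE),
      stringsAsFactors = FALSE)
    arcs <- arcs[order(arcs$from, arcs$to), , drop = FALSE]
  }
  structure(list(nodes = nodes, arcs = arcs, provenance = "union"),
            class = "sc_rxn_graph")
}

#' Panel-wide union reaction graph
#'
#' Convenience wrapper building each organism's reaction graph with the
#' panel's filters and taking their union.
#'
#' @param panel An `sc_panel`.
#' @param strict_direction Passed to [build_reaction_graph()].
#' @return An `sc_rxn_graph`.
#' @export
panel_union_graph <- function(panel, strict_direction = FALSE) {
  union_graph(lapply(panel$networks, build_reaction_graph,
                     currency = panel$currency,
                     cofactor_pairs = panel$cofactor_pairs,
                     strict_direction = strict_direction))
}

#' Induced subgraph and its connected components
#'
#' Restricts a reaction graph to a node subset (typically a core reaction
#' set) and reports the weakly connected components of size >= 2, the
#' isolated nodes, and the arc count — the "k components apart from m
#' isolated reactions" statistic.
#'
#' @param graph An `sc_rxn_graph`.
#' @param node_subset Character vector, subset of `graph$nodes`.
#' @return List with `components` (list of character vectors, size >= 2,
#'   largest first), `isolated` (character), `n_arcs`, and `arcs` (the
#'   induced arc data frame).
#' @export
induced_components <- function(graph, node_subset) {
  stopifnot(inherits(graph, "sc_rxn_graph"))
  node_subset <- unique(node_subset)
  missing <- setdiff(node_subset, graph$nodes)
  if (length(missing))
    stop("node(s) absent from graph: ", paste(missing, collapse = ", "))
  arcs <- graph$arcs[graph$arcs$from %in% node_subset &
                     graph$arcs$to %in% node_subset, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    arcs[, c("from", "to")], directed = TRUE,
    vertices = data.frame(name = node_subset))
  comp <- igraph::components(g, mode = "weak")
  groups <- split(names(comp$membership), comp$membership)
  sizes <- lengths(groups)
  components <- unname(lapply(groups[sizes >= 2L], sort))
  components <- components[order(-lengths(components))]
  list(components = components,
       isolated = sort(as.character(unlist(groups[sizes == 1L],
                                           use.names = FALSE))),
       n_arcs = nrow(arcs), arcs = arcs)
}

#' Level-3 EC class map of reactions
#'
#' @param x An `sc_panel` or `sc_network`.
#' @return Named list: reaction id -> character vector of level-3 EC
#'   classes (empty for unannotated reactions).
#' @export
reaction_ec_map <- function(x) {
  nets <- if (inherits(x, "sc_panel")) x$networks else list(x)
  map <- list()
  for (net in nets)
    for (r in net$reactions)
      if (is.null(map[[r$id]])) {
        tr <- if (length(r$ec_numbers))
          vapply(r$ec_numbers, truncate_ec, character(1)) else character()
        map[[r$id]] <- sort(unique(tr[!is.na(tr)]))
      }
  map
}

#' Search for connected one-reaction-per-EC-class occurrences
#'
#' Looks for reaction sets containing exactly one representative of each
#' given level-3 EC class whose induced undirected subgraph is connected
#' — the question of whether a shared set of enzymatic capabilities
#' corresponds to a connected portion of the metabolic network.
#' Occurrences are node sets: the same set reachable through different
#' class assignments counts once, and each reaction fills exactly one
#' class within an occurrence.
#'
#' @param graph An `sc_rxn_graph`.
#' @param ec_classes Character vector of distinct level-3 EC classes.
#' @param ec_map Named list from [reaction_ec_map()]; defaults to classes
#'   carried by the graph when built from a network are not stored, so
#'   this argument is required.
#' @param mode `"exists"` (short-circuit) or `"count"` (enumerate).
#' @param cap Maximum number of candidate tuples enumerated in `count`
#'   mode before the search stops with status `"cap_exceeded"`.
#' @return An object of class `sc_occurrences`: list with `status`
#'   (`"ok"`, `"absent"` — some class has no candidate — or
#'   `"cap_exceeded"`), `exists`, `n_occurrences` (`NA` in exists mode),
#'   `occurrences` (list of sorted reaction-id sets in count mode) and
#'   `candidates` (per-class candidate reactions).
#' @export
connected_ec_occurrences <- function(graph, ec_classes, ec_map,
                                     mode = c("exists", "count"),
                                     cap = 1e6) {
  stopifnot(inherits(graph, "sc_rxn_graph"))
  mode <- match.arg(mode)
  ec_classes <- unique(ec_classes)
  candidates <- lapply(ec_classes, function(cl)
    intersect(graph$nodes,
              names(ec_map)[vapply(ec_map, function(v) cl %in% v,
                                   logical(1))]))
  names(candidates) <- ec_classes
  empty <- lengths(candidates) == 0L
  if (any(empty))
    return(structure(list(status = "absent", exists = FALSE,
                          n_occurrences = 0L, occurrences = list(),
                          candidates = candidates),
                     class = "sc_occurrences"))
  n_tuples <- prod(lengths(candidates))
  if (n_tuples > cap)
    return(structure(list(status = "cap_exceeded", exists = NA,
                          n_occurrences = NA_integer_, occurrences = list(),
                          candidates = candidates),
                     class = "sc_occurrences"))
  adj <- undirected_adjacency(graph, unique(unlist(candidates)))
  found <- new.env(parent = emptyenv())
  exists_flag <- FALSE
  grid <- expand_tuples(candidates)
  for (i in seq_len(nrow(grid))) {
    tuple <- as.character(grid[i, ])
    if (anyDuplicated(tuple)) next   # one reaction fills one class only
    key <- paste(sort(tuple), collapse = "\r")
    if (!is.null(get0(key, envir = found))) next
    if (is_connected_set(tuple, adj)) {
      assign(key, TRUE, envir = found)
      exists_flag <- TRUE
      if (mode == "exists") break
    } else {
      assign(key, FALSE, envir = found)
    }
  }
  occ <- Filter(isTRUE, as.list(found))
  structure(
    list(status = "ok", exists = exists_flag,
         n_occurrences = if (mode == "count") length(occ) else NA_integer_,
         occurrences = if (mode == "count")
           lapply(names(occ), function(k) strsplit(k, "\r", fixed = TRUE)[[1]])
         else list(),
         candidates = candidates),
    class = "sc_occurrences")
}

expand_tuples <- function(candidates) {
  grid <- do.call(expand.grid,
                  c(candidates, list(stringsAsFactors = FALSE,
                                     KEEP.OUT.ATTRS = FALSE)))
  grid
}

undirected_adjacency <- function(graph, nodes) {
  arcs <- graph$arcs[graph$arcs$from %in% nodes &
                     graph$arcs$to %in% nodes, , drop = FALSE]
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(arcs))) {
    a <- arcs$from[i]; b <- arcs$to[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, unique)
}

is_connected_set <- function(nodes, adj) {
  if (length(nodes) <= 1L) return(TRUE)
  seen <- nodes[1]
  frontier <- nodes[1]
  while (length(frontier)) {
    nxt <- setdiff(intersect(unlist(adj[frontier], use.names = FALSE),
                             nodes), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == length(nodes)
}

#' Per-organism tally of a connected EC occurrence
#'
#' Evaluates [connected_ec_occurrences()] in `exists` mode on every
#' organism's own reaction graph, reproducing the "pattern found in k of
#' n organisms" statistic.
#'
#' @param panel An `sc_panel`.
#' @param ec_classes Character vector of level-3 EC classes.
#' @param strict_direction Passed to [build_reaction_graph()].
#' @return Named logical vector over organisms.
#' @export
occurrence_per_organism <- function(panel, ec_classes,
                                    strict_direction = FALSE) {
  ec_map <- reaction_ec_map(panel)
  vapply(panel$networks, function(net) {
    g <- build_reaction_graph(net, panel$currency, panel$cofactor_pairs,
                              strict_direction)
    isTRUE(connected_ec_occurrences(g, ec_classes, ec_map,
                                    mode = "exists")$exists)
  }, logical(1))
}
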