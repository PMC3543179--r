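# Independent brute-force oracles. These re-derive expected results by
# the most literal method available (nested loops, full enumeration,
# transitive closure) and never call the code paths they check.

oracle_core_pan <- function(sets) {
  core <- sets[[1]]
  for (s in sets[-1]) core <- core[core %in% s]
  pan <- character()
  for (s in sets) pan <- unique(c(pan, s))
  list(core = sort(unique(core)), pan = sort(pan),
       variable = sort(pan[!pan %in% core]))
}

# arc oracle: literal double loop over reaction pairs and compounds,
# applying currency and per-reaction cofactor-pair suppression
oracle_arcs <- function(network, currency, cofactor_pairs,
                        strict_direction = FALSE) {
  eff <- lapply(network$reactions, function(r) {
    subs <- setdiff(r$substrates, currency)
    prods <- setdiff(r$products, currency)
    for (pp in cofactor_pairs) {
      if ((pp[1] %in% r$substrates && pp[2] %in% r$products) ||
          (pp[2] %in% r$substrates && pp[1] %in% r$products)) {
        subs <- setdiff(subs, pp); prods <- setdiff(prods, pp)
      }
    }
    if (r$reversible && !strict_direction)
      list(out = union(subs, prods), inn = union(subs, prods))
    else list(out = prods, inn = subs)
  })
  res <- character()
  ids <- names(network$reactions)
  for (a in ids) for (b in ids) {
    if (a == b) next
    w <- intersect(eff[[a]]$out, eff[[b]]$inn)
    if (length(w))
      res <- c(res, paste(a, b, paste(sort(w), collapse = ";"),
                          sep = "|"))
  }
  sort(res)
}

arcs_to_strings <- function(arcs)
  sort(paste(arcs$from, arcs$to, arcs$witness, sep = "|"))

# undirected connected components by literal breadth-first search
oracle_components <- function(nodes, arcs) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(arcs))) {
    adj[[arcs$from[i]]] <- c(adj[[arcs$from[i]]], arcs$to[i])
    adj[[arcs$to[i]]] <- c(adj[[arcs$to[i]]], arcs$from[i])
  }
  unvisited <- nodes
  comps <- list()
  while (length(unvisited)) {
    queue <- unvisited[1]
    comp <- character()
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      queue <- c(queue, setdiff(unlist(adj[v]), comp))
    }
    comps[[length(comps) + 1L]] <- sort(comp)
    unvisited <- setdiff(unvisited, comp)
  }
  comps
}

# connected EC-occurrence count by exhaustive Cartesian enumeration
oracle_occurrences <- function(nodes, arcs, candidates) {
  grid <- do.call(expand.grid, c(candidates,
                                 list(stringsAsFactors = FALSE)))
  seen <- character()
  count <- 0L
  for (i in seq_len(nrow(grid))) {
    tuple <- unique(as.character(grid[i, ]))
    if (length(tuple) != length(candidates)) next
    key <- paste(sort(tuple), collapse = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    sub_arcs <- arcs[arcs$from %in% tuple & arcs$to %in% tuple, ,
                     drop = FALSE]
    comps <- oracle_components(tuple, sub_arcs)
    if (length(comps) == 1L) count <- count + 1L
  }
  count
}

# seed sets from the definition: a node is a seed iff nothing outside
# its mutual-reachability class reaches it (via full transitive closure)
oracle_seeds <- function(nodes, arcs) {
  n <- length(nodes)
  reach <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  diag(reach) <- TRUE
  for (i in seq_len(nrow(arcs)))
    reach[arcs$from[i], arcs$to[i]] <- TRUE
  repeat { # Warshall closure
    nxt <- reach | (reach %*% reach > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  seeds <- character()
  for (v in nodes) {
    incoming <- nodes[reach[, v] & !reach[v, ]]
    if (!length(incoming)) seeds <- c(seeds, v)
  }
  sort(seeds)
}

oracle_reachable_from <- function(nodes, arcs, sources) {
  n <- length(nodes)
  reach <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  diag(reach) <- TRUE
  for (i in seq_len(nrow(arcs)))
    reach[arcs$from[i], arcs$to[i]] <- TRUE
  repeat {
    nxt <- reach | (reach %*% reach > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  if (!length(sources)) return(character())
  nodes[colSums(reach[sources, , drop = FALSE]) > 0]
}

# Fisher exact two-sided p by hypergeometric point-mass enumeration
oracle_fisher2x2 <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x)
    stats::dhyper(x, m, n, k), numeric(1))
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# two-sided Wilcoxon rank-sum p by full permutation enumeration
oracle_wilcoxon_perm <- function(x, y) {
  vals <- c(x, y)
  n <- length(vals); nx <- length(x)
  ranks <- rank(vals)
  obs <- sum(ranks[seq_len(nx)])
  combs <- utils::combn(n, nx)
  stat <- apply(combs, 2, function(idx) sum(ranks[idx]))
  mu <- nx * (n + 1) / 2
  mean(abs(stat - mu) >= abs(obs - mu) - 1e-9)
}

# per-depth mean intersection size by enumerating all k! removal orders
oracle_order_scan <- function(sets, ranked, keep_always) {
  k <- length(ranked)
  perms <- all_perms(ranked)
  base <- Reduce(intersect, sets[keep_always])
  means <- numeric(k + 1L)
  for (d in 0:k) {
    vals <- vapply(perms, function(ord) {
      retained <- setdiff(ranked, ord[seq_len(d)])
      cur <- base
      for (id in retained) cur <- intersect(cur, sets[[id]])
      length(cur)
    }, numeric(1))
    means[d + 1L] <- mean(vals)
  }
  means
}

all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in all_perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

# exhaustive expectation of loss-simulation statistics on a tiny
# fixture: enumerate source choices x retained reaction subsets
oracle_loss_expectation <- function(src_rxn_ec, target_sizes) {
  src_names <- names(src_rxn_ec)
  per_target_outcomes <- lapply(target_sizes, function(ts) {
    outs <- list()
    for (s in src_names) {
      rx <- src_rxn_ec[[s]]
      if (length(rx) < ts) next
      subs <- utils::combn(length(rx), ts, simplify = FALSE)
      for (ss in subs)
        outs[[length(outs) + 1L]] <- list(
          ec = unique(unlist(rx[ss], use.names = FALSE)),
          w = 1 / (length(src_names) * length(subs)))
    }
    # aggregate outcomes by identical EC set to shrink the product space
    keys <- vapply(outs, function(o) paste(sort(o$ec), collapse = "|"),
                   character(1))
    agg <- lapply(split(seq_along(outs), keys), function(idx)
      list(ec = outs[[idx[1]]]$ec,
           w = sum(vapply(outs[idx], `[[`, numeric(1), "w"))))
    unname(agg)
  })
  # full joint distribution over independent products of per-target
  # outcomes: one row per combination with its probability
  grids <- as.matrix(expand.grid(lapply(per_target_outcomes, seq_along)))
  n_comb <- nrow(grids)
  v_mean <- v_union <- v_inter <- v_w <- numeric(n_comb)
  for (i in seq_len(n_comb)) {
    sel <- lapply(seq_along(target_sizes), function(t)
      per_target_outcomes[[t]][[grids[i, t]]])
    ecs <- lapply(sel, `[[`, "ec")
    v_mean[i] <- mean(lengths(ecs))
    v_union[i] <- length(Reduce(union, ecs))
    v_inter[i] <- length(Reduce(intersect, ecs))
    v_w[i] <- prod(vapply(sel, `[[`, numeric(1), "w"))
  }
  data.frame(mean = v_mean, union = v_union, intersection = v_inter,
             w = v_w)
}

oracle_loss_expectation_stats <- function(dist) {
  c(mean = sum(dist$mean * dist$w),
    union = sum(dist$union * dist$w),
    intersection = sum(dist$intersection * dist$w))
}
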