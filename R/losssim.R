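#' Configure a differential random-loss simulation
#'
#' Emulates genome reduction: each target organism (e.g. a mutualistic
#' intracellular symbiont) is matched to a randomly drawn source
#' organism (e.g. an extracellular relative) whose reactions are removed
#' uniformly at random until a stopping rule tied to the target's size
#' is reached.
#'
#' @param target_orgs,source_orgs Disjoint non-empty character vectors
#'   of organism ids.
#' @param mode `"reaction_loss"` (stop at the target's reaction count)
#'   or `"capability_loss"` (stop when the level-3 EC set has shrunk to
#'   the target's partial-EC count).
#' @param reps Number of replicates (default 1000).
#' @param replace Logical; draw sources with replacement across targets
#'   (default) or as a matching without replacement.
#' @param rng_seed Integer seed.
#' @return An object of class `sc_loss_config`.
#' @export
loss_sim_config <- function(target_orgs, source_orgs,
                            mode = c("reaction_loss", "capability_loss"),
                            reps = 1000L, replace = TRUE, rng_seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(target_orgs) >= 1L, length(source_orgs) >= 1L)
  if (length(intersect(target_orgs, source_orgs)))
    stop("target and source groups must be disjoint")
  if (!replace && length(source_orgs) < length(target_orgs))
    stop("without replacement, need at least as many sources as targets")
  structure(list(target_orgs = target_orgs, source_orgs = source_orgs,
                 mode = mode, reps = as.integer(reps),
                 replace = isTRUE(replace),
                 rng_seed = as.integer(rng_seed)),
            class = "sc_loss_config")
}

#' Run the differential random-loss simulation
#'
#' Per replicate: every target is matched to a drawn source; reactions
#' are removed from the source one at a time, uniformly at random
#' without replacement, until the stopping rule is met; the surviving
#' reactions are mapped to their level-3 EC classes; and the mean, union
#' and intersection sizes of the simulated group's partial-EC sets are
#' recorded. Observed statistics of the real target group are computed
#' alongside, with Monte-Carlo p-values from [monte_carlo_p()].
#'
#' In `capability_loss` mode every simulated organism's partial-EC set
#' size equals its target size exactly (the stopping rule acts on the EC
#' set), so the per-replicate mean has zero spread when targets are
#' fixed. A source that cannot reach a target's size is redrawn, logged,
#' and a hard error is raised after `max_redraws` consecutive failures.
#'
#' @param panel An `sc_panel`.
#' @param config An `sc_loss_config`.
#' @param max_redraws Redraw budget per matching (default 100).
#' @param alternatives Named list with tail directions for `mean`,
#'   `union`, `intersection` (defaults: less, less, two_sided — the
#'   direction in which reduced genomes are expected to deviate).
#' @return An object of class `sc_loss_result`: list with `observed`
#'   (named vector), `simulated` (reps x 3 matrix), `sim_sizes`
#'   (reps x targets matrix of per-organism simulated set sizes),
#'   `target_sizes`, `p_values`, `sim_means`, `sim_sds`, `n_redraws`,
#'   `config`.
#' @export
simulate_loss <- function(panel, config, max_redraws = 100L,
                          alternatives = list(mean = "less",
                                              union = "less",
                                              intersection = "two_sided")) {
  stopifnot(inherits(panel, "sc_panel"), inherits(config, "sc_loss_config"))
  ids <- org_ids(panel)
  missing <- setdiff(c(config$target_orgs, config$source_orgs), ids)
  if (length(missing))
    stop("organism(s) not in panel: ", paste(missing, collapse = ", "))
  mode <- config$mode
  tgt_nets <- panel$networks[config$target_orgs]
  src_nets <- panel$networks[config$source_orgs]
  size_of <- function(net)
    if (mode == "reaction_loss") length(net$reactions)
    else length(element_set(net, "partial_ec"))
  target_sizes <- vapply(tgt_nets, size_of, integer(1))
  src_rxn_ec <- lapply(src_nets, function(net)
    lapply(net$reactions, function(r) {
      if (!length(r$ec_numbers)) return(character())
      tr <- vapply(r$ec_numbers, truncate_ec, character(1))
      unique(tr[!is.na(tr)])
    }))
  observed <- group_ec_stats(lapply(tgt_nets, element_set, "partial_ec"))
  set.seed(config$rng_seed)
  sim <- matrix(NA_real_, nrow = config$reps, ncol = 3,
                dimnames = list(NULL, c("mean", "union", "intersection")))
  sim_sizes <- matrix(NA_integer_, nrow = config$reps,
                      ncol = length(target_sizes),
                      dimnames = list(NULL, names(target_sizes)))
  n_redraws <- 0L
  n_t <- length(target_sizes)
  for (rep_i in seq_len(config$reps)) {
    sim_sets <- vector("list", n_t)
    if (config$replace) {
      for (t in seq_len(n_t)) {
        tries <- 0L
        repeat {
          src <- config$source_orgs[sample.int(length(config$source_orgs), 1L)]
          res <- lose_reactions(src_rxn_ec[[src]], target_sizes[[t]], mode)
          if (!is.null(res)) break
          tries <- tries + 1L
          n_redraws <- n_redraws + 1L
          if (tries > max_redraws)
            stop("target size ", target_sizes[[t]],
                 " unattainable from the source pool after ", max_redraws,
                 " redraws")
        }
        sim_sets[[t]] <- res
      }
    } else {
      # one matching per replicate; redraw the whole matching on failure
      tries <- 0L
      repeat {
        matching <- config$source_orgs[
          sample.int(length(config$source_orgs), n_t)]
        res_all <- lapply(seq_len(n_t), function(t)
          lose_reactions(src_rxn_ec[[matching[t]]], target_sizes[[t]], mode))
        if (!any(vapply(res_all, is.null, logical(1)))) {
          sim_sets <- res_all
          break
        }
        tries <- tries + 1L
        n_redraws <- n_redraws + 1L
        if (tries > max_redraws)
          stop("no attainable source matching after ", max_redraws,
               " redraws")
      }
    }
    sim[rep_i, ] <- group_ec_stats(sim_sets)
    sim_sizes[rep_i, ] <- lengths(sim_sets)
  }
  p_values <- c(
    mean = monte_carlo_p(sim[, "mean"], observed[["mean"]],
                         alternatives$mean),
    union = monte_carlo_p(sim[, "union"], observed[["union"]],
                          alternatives$union),
    intersection = monte_carlo_p(sim[, "intersection"],
                                 observed[["intersection"]],
                                 alternatives$intersection))
  structure(
    list(observed = observed, simulated = sim, sim_sizes = sim_sizes,
         target_sizes = target_sizes, p_values = p_values,
         sim_means = colMeans(sim), sim_sds = apply(sim, 2, stats::sd),
         n_redraws = n_redraws, config = config),
    class = "sc_loss_result")
}

# Remove reactions one at a time until the stopping rule; returns the
# surviving partial-EC set, or NULL when the target is unattainable.
lose_reactions <- function(rxn_ec, target_size, mode) {
  n <- length(rxn_ec)
  if (mode == "reaction_loss") {
    if (n < target_size) return(NULL)
    keep <- sample.int(n, target_size)
    ecs <- unique(unlist(rxn_ec[keep], use.names = FALSE))
    return(if (is.null(ecs)) character() else ecs)
  }
  # capability_loss: remove until the EC set size reaches the target,
  # tracking per-class reaction counts incrementally; a removal that
  # would overshoot the target is undone and the sweep continues
  vocab <- unique(unlist(rxn_ec, use.names = FALSE))
  if (length(vocab) < target_size) return(NULL)
  idx <- lapply(rxn_ec, function(cl) match(cl, vocab))
  counts <- tabulate(unlist(idx, use.names = FALSE), length(vocab))
  ec_size <- sum(counts > 0L)
  keep <- rep(TRUE, n)
  for (i in sample.int(n, n)) {
    if (ec_size == target_size) break
    ci <- idx[[i]]
    counts[ci] <- counts[ci] - 1L
    lost <- sum(counts[ci] == 0L)
    if (ec_size - lost < target_size) {
      counts[ci] <- counts[ci] + 1L  # overshoot: put the reaction back
    } else {
      keep[i] <- FALSE
      ec_size <- ec_size - lost
    }
  }
  if (ec_size != target_size) return(NULL)
  ecs <- unique(unlist(rxn_ec[keep], use.names = FALSE))
  if (is.null(ecs)) character() else ecs
}

group_ec_stats <- function(sets) {
  c(mean = mean(vapply(sets, length, integer(1))),
    union = length(Reduce(union, sets)),
    intersection = length(Reduce(intersect, sets)))
}

#' Monte-Carlo p-value
#'
#' Randomisation-test p-value with the +1 correction:
#' `p = (#{simulated at least as extreme as observed} + 1) / (reps + 1)`.
#' The two-sided value doubles the smaller tail and is capped at 1.
#'
#' @param simulated Numeric vector of simulated statistics (non-empty).
#' @param observed Observed statistic.
#' @param alternative `"less"`, `"greater"` or `"two_sided"`.
#' @return p-value in (0, 1].
#' @export
monte_carlo_p <- function(simulated, observed,
                          alternative = c("less", "greater", "two_sided")) {
  alternative <- match.arg(alternative)
  if (!length(simulated)) stop("empty simulation list")
  n <- length(simulated)
  p_less <- (sum(simulated <= observed) + 1) / (n + 1)
  p_greater <- (sum(simulated >= observed) + 1) / (n + 1)
  switch(alternative,
         less = p_less,
         greater = p_greater,
         two_sided = min(1, 2 * min(p_less, p_greater)))
}

#' @export
print.sc_loss_result <- function(x, ...) {
  cat("<sc_loss_result> mode=", x$config$mode, ", reps=",
      x$config$reps, "\n", sep = "")
  tab <- rbind(observed = x$observed, sim_mean = x$sim_means,
               sim_sd = x$sim_sds, p = x$p_values)
  print(round(tab, 3))
  invisible(x)
}
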