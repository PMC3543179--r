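#' Level-3 EC class catalogue
#'
#' Thirty realistic level-3 EC prefixes spanning all six enzyme classes
#' (oxidoreductases through ligases), used as the default catalogue from
#' which the generator assigns annotations.
#'
#' @return Character vector of 30 level-3 EC classes.
#' @export
ec_class_catalogue <- function() {
  c("1.1.1", "1.2.1", "1.5.1",
    "2.1.1", "2.1.2", "2.2.1", "2.3.1", "2.4.1", "2.5.1", "2.6.1",
    "2.7.1", "2.7.2", "2.7.4", "2.7.6", "2.7.7", "2.7.8",
    "3.1.3", "3.5.1", "3.5.4", "3.6.1",
    "4.1.1", "4.1.2", "4.2.1",
    "5.1.1", "5.1.3", "5.3.1", "5.4.2", "5.4.99",
    "6.3.2", "6.3.4")
}

#' Specify a synthetic panel
#'
#' Describes the statistical structure of a generated panel: a shared
#' core of reactions present in every organism, group-specific cores, a
#' long tail of variable reactions (independent Bernoulli presence with
#' probability `presence_prob`, or a per-organism richness gradient
#' filling up to a target size drawn from each group's
#' reactions-per-organism range), shared capability classes (each
#' organism receives its own private reaction annotated with the class,
#' so level-3 capabilities are shared even when reactions are not), and
#' annotation/reversibility/currency rates.
#'
#' @param groups List of `list(code, n, rxn_range)` entries; `rxn_range`
#'   (length-2 integer) is used by the gradient mode. A group may also
#'   carry `presence_prob` (flat Bernoulli presence for that group) or
#'   `freq_shape` (explicit Beta shape parameters for its frequency
#'   spectrum), overriding the derived spectrum.
#' @param shared_core_size Reactions present in every organism.
#' @param group_core_sizes Named integer vector (by group code).
#' @param variable_pool_size Size of the variable reaction pool.
#' @param presence_prob Bernoulli presence probability for variable
#'   reactions, or `NULL` for the richness-gradient mode.
#' @param shared_capability_classes Level-3 EC classes planted as
#'   organism-private reaction variants in every organism.
#' @param ec_annotation_rate Probability a catalogue reaction carries an
#'   EC annotation.
#' @param reversible_fraction Probability a reaction is reversible.
#' @param currency_usage Probability a reaction additionally consumes
#'   and produces currency compounds.
#' @param process_probs Probabilities for the biosynthesis, degradation
#'   and other process labels (summing to 1).
#' @param n_compounds Size of the non-currency compound universe;
#'   default scales with the catalogue size.
#' @param macro_range Integer range of per-organism macromolecule
#'   reactions (flagged `small_molecule = FALSE`).
#' @param rng_seed Integer seed; the same spec and seed always generate
#'   the identical panel.
#' @return An object of class `sc_panel_spec`.
#' @export
panel_spec <- function(groups,
                       shared_core_size = 0L,
                       group_core_sizes = integer(),
                       variable_pool_size = 0L,
                       presence_prob = NULL,
                       shared_capability_classes = character(),
                       ec_annotation_rate = 0.85,
                       reversible_fraction = 0.3,
                       currency_usage = 0.5,
                       process_probs = c(biosynthesis = 0.55,
                                         degradation = 0.25, other = 0.20),
                       n_compounds = NULL,
                       macro_range = c(0L, 0L),
                       rng_seed = 1L) {
  stopifnot(is.list(groups), length(groups) >= 1L)
  codes <- vapply(groups, `[[`, character(1), "code")
  if (anyDuplicated(codes)) stop("duplicate group codes in spec")
  for (g in groups) {
    if (!g$code %in% c("INTRA", "CA", "EXTRA", "FL"))
      stop("unknown group code '", g$code, "'")
    if (g$n < 1L) stop("group '", g$code, "' must have >= 1 organism")
  }
  shared_core_size <- as.integer(shared_core_size)
  variable_pool_size <- as.integer(variable_pool_size)
  if (shared_core_size < 0L || variable_pool_size < 0L)
    stop("sizes must be non-negative")
  gcs <- stats::setNames(integer(length(codes)), codes)
  gcs[names(group_core_sizes)] <- as.integer(group_core_sizes)
  if (any(gcs < 0L)) stop("group core sizes must be non-negative")
  if (is.null(presence_prob)) {
    for (g in groups) {
      lo <- g$rxn_range[1]
      floor_n <- shared_core_size + gcs[[g$code]]
      if (lo < floor_n)
        stop("group '", g$code, "': reactions-per-organism lower bound (",
             lo, ") below shared core + group core (", floor_n, ")")
    }
  } else if (presence_prob < 0 || presence_prob > 1) {
    stop("presence_prob must lie in [0, 1]")
  }
  if (abs(sum(process_probs) - 1) > 1e-8)
    stop("process_probs must sum to 1")
  structure(
    list(groups = groups, shared_core_size = shared_core_size,
         group_core_sizes = gcs,
         variable_pool_size = variable_pool_size,
         presence_prob = presence_prob,
         shared_capability_classes = as.character(shared_capability_classes),
         ec_annotation_rate = ec_annotation_rate,
         reversible_fraction = reversible_fraction,
         currency_usage = currency_usage,
         process_probs = process_probs,
         n_compounds = n_compounds,
         macro_range = as.integer(macro_range),
         rng_seed = as.integer(rng_seed)),
    class = "sc_panel_spec")
}

#' Study-shaped default panel spec
#'
#' The default conditions the package's end-to-end analyses run under:
#' three lifestyle groups with a genome-size gradient (tiny obligate
#' intracellular networks, large cell-associated and extracellular
#' ones), no reaction shared by all organisms, group cores planted for
#' CA and EXTRA only, four capability classes shared by every organism
#' through organism-private reaction variants, and a long variable tail.
#'
#' @param rng_seed Integer seed.
#' @return An `sc_panel_spec`.
#' @export
default_study_spec <- function(rng_seed = 1L) {
  panel_spec(
    groups = list(
      list(code = "INTRA", n = 20L, rxn_range = c(40L, 110L),
           presence_prob = 0.1),
      list(code = "CA", n = 12L, rxn_range = c(250L, 450L)),
      list(code = "EXTRA", n = 14L, rxn_range = c(350L, 600L))),
    shared_core_size = 0L,
    group_core_sizes = c(INTRA = 0L, CA = 40L, EXTRA = 60L),
    variable_pool_size = 800L,
    presence_prob = NULL,
    shared_capability_classes = c("2.3.1", "2.5.1", "3.5.1", "4.2.1"),
    ec_annotation_rate = 0.85,
    reversible_fraction = 0.3,
    currency_usage = 0.5,
    macro_range = c(0L, 5L),
    rng_seed = rng_seed)
}

#' Generate a synthetic panel
#'
#' Deterministic given the spec's seed: a global stream builds the
#' reaction catalogue and organism sub-streams (derived from the seed
#' and the organism id) draw per-organism content, so a panel is stable
#' under reordering of organisms.
#'
#' @param spec An `sc_panel_spec`.
#' @return An [panel()] carrying the spec's seed.
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "sc_panel_spec"))
  set.seed(spec$rng_seed)
  catalogue_size <- spec$shared_core_size + sum(spec$group_core_sizes) +
    spec$variable_pool_size
  n_cpd <- spec$n_compounds %||% max(50L, ceiling(0.8 * max(catalogue_size, 60L)))
  cpds <- sprintf("CPD-%05d", seq_len(n_cpd))
  currency <- default_currency()

  draw_reaction_body <- function(id, small_molecule = TRUE) {
    subs <- sample(cpds, sample.int(3L, 1L))
    prods <- sample(setdiff(cpds, subs), sample.int(3L, 1L))
    if (stats::runif(1) < spec$currency_usage) {
      subs <- c(subs, sample(currency, 1L))
      prods <- c(prods, sample(currency, 1L))
    }
    ec <- character()
    if (stats::runif(1) < spec$ec_annotation_rate) {
      n_ec <- if (stats::runif(1) < 0.1) 2L else 1L
      cls <- sample(ec_class_catalogue(), n_ec)
      ec <- paste0(cls, ".", sample.int(30L, n_ec, replace = TRUE))
    }
    procs <- sample(names(spec$process_probs), 1L,
                    prob = spec$process_probs)
    if (stats::runif(1) < 0.05)
      procs <- unique(c(procs, sample(names(spec$process_probs), 1L)))
    reaction(id, subs, prods,
             reversible = stats::runif(1) < spec$reversible_fraction,
             ec_numbers = ec, processes = procs,
             small_molecule = small_molecule)
  }

  shared_core <- lapply(seq_len(spec$shared_core_size), function(i)
    draw_reaction_body(sprintf("CORE-RXN-%04d", i)))
  group_cores <- lapply(names(spec$group_core_sizes), function(code)
    lapply(seq_len(spec$group_core_sizes[[code]]), function(i)
      draw_reaction_body(sprintf("G%s-RXN-%04d", code, i))))
  names(group_cores) <- names(spec$group_core_sizes)
  var_pool <- lapply(seq_len(spec$variable_pool_size), function(i)
    draw_reaction_body(sprintf("VAR-RXN-%04d", i)))
  # gradient mode: per-group frequency spectrum over the variable pool.
  # Frequencies are Beta-distributed with a fixed shape a and a group
  # shape b chosen so the mean variable count matches the group's target
  # range; small-genome groups get b >> a (almost everything rare),
  # large-genome groups get b < 1 (heavy mass of near-universal
  # reactions), which is what makes their shared-reaction decay slow.
  var_freq <- NULL
  if (is.null(spec$presence_prob) && spec$variable_pool_size) {
    var_freq <- list()
    for (g in spec$groups) {
      if (!is.null(g$presence_prob)) {
        var_freq[[g$code]] <- rep(g$presence_prob, spec$variable_pool_size)
        next
      }
      if (!is.null(g$freq_shape)) {
        a <- g$freq_shape[1]; b <- g$freq_shape[2]
      } else {
        fixed_n <- spec$shared_core_size + spec$group_core_sizes[[g$code]] +
          length(spec$shared_capability_classes)
        m <- max(0.005, min(0.95, (mean(g$rxn_range) - fixed_n) /
                                    spec$variable_pool_size))
        a <- 0.4
        b <- a * (1 - m) / m
      }
      var_freq[[g$code]] <- stats::rbeta(spec$variable_pool_size, a, b)
    }
  }

  # capability families: one body per class, shared compounds, but each
  # organism later gets a private variant (own id and level-4 digit)
  cap_bodies <- lapply(spec$shared_capability_classes, function(cl) {
    subs <- sample(cpds, 2L)
    prods <- sample(setdiff(cpds, subs), 2L)
    list(class = cl, subs = subs, prods = prods)
  })

  nets <- list()
  org_counter <- 0L
  for (g in spec$groups) {
    for (i in seq_len(g$n)) {
      org_counter <- org_counter + 1L
      org_id <- sprintf("%s%02d", substr(g$code, 1L, 3L), i)
      set.seed(derive_seed(spec$rng_seed, org_id))
      rxns <- c(shared_core, group_cores[[g$code]])
      if (spec$variable_pool_size > 0L) {
        if (!is.null(spec$presence_prob)) {
          present <- stats::runif(spec$variable_pool_size) < spec$presence_prob
          rxns <- c(rxns, var_pool[present])
        } else {
          present <- stats::runif(spec$variable_pool_size) <
            var_freq[[g$code]]
          rxns <- c(rxns, var_pool[present])
        }
      }
      for (cb in cap_bodies) {
        vid <- sprintf("CAP-%s-%s", gsub(".", "_", cb$class, fixed = TRUE),
                       org_id)
        rxns <- c(rxns, list(reaction(
          vid, cb$subs, cb$prods,
          reversible = stats::runif(1) < spec$reversible_fraction,
          ec_numbers = paste0(cb$class, ".", org_counter),
          processes = "biosynthesis")))
      }
      n_macro <- if (spec$macro_range[2] > 0L)
        runif_int(spec$macro_range[1], spec$macro_range[2]) else 0L
      if (n_macro > 0L)
        rxns <- c(rxns, lapply(seq_len(n_macro), function(j)
          draw_reaction_body(sprintf("MACRO-RXN-%s-%02d", org_id, j),
                             small_molecule = FALSE)))
      n_rxn <- length(rxns)
      n_genes <- round(n_rxn / stats::runif(1, 0.15, 0.45))
      meta <- organism_meta(
        org_id, g$code,
        subcategory = if (g$code == "INTRA") "MIV" else NA_character_,
        tax_class = "Gammaproteobacteria",
        n_genes = n_genes,
        n_metabolic_genes = min(n_rxn, n_genes))
      nets[[org_id]] <- metabolic_network(meta, rxns)
    }
  }
  panel(nets, rng_seed = spec$rng_seed)
}

# uniform integer in [lo, hi]; sample(lo:hi, 1) misbehaves when lo == hi
runif_int <- function(lo, hi) {
  as.integer(lo + floor(stats::runif(1) * (hi - lo + 1L)))
}

derive_seed <- function(seed, org_id) {
  h <- sum(utf8ToInt(org_id) * seq_along(utf8ToInt(org_id)) * 131)
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587)
}

#' Generate a decay curve from a known model
#'
#' Evaluates the exponential or logistic decay model on an x grid and
#' adds i.i.d. normal noise; used for fit-recovery checks.
#'
#' @param model `"exponential"` or `"logistic"`.
#' @param params Named list or vector with `alpha`, `r`, `N`.
#' @param x Integer vector of subset sizes.
#' @param noise_sd Non-negative residual standard deviation.
#' @param rng_seed Integer seed.
#' @return An `sc_decay_data`-compatible list with `x`, `y_bar` and the
#'   generating parameters under `truth`.
#' @export
generate_decay_curve <- function(model = c("exponential", "logistic"),
                                 params, x, noise_sd = 0, rng_seed = 1L) {
  model <- match.arg(model)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  p <- as.list(params)
  stopifnot(all(c("alpha", "r", "N") %in% names(p)))
  fn <- if (model == "exponential") decay_exponential else decay_logistic
  y <- fn(x, N = p$N, r = p$r, alpha = p$alpha)
  if (noise_sd > 0) {
    set.seed(rng_seed)
    y <- y + stats::rnorm(length(x), 0, noise_sd)
  }
  structure(list(group = "synthetic", element_kind = "reaction",
                 x = as.numeric(x), reps = 1L, y_reps = as.list(y),
                 y_bar = y, y_sd = rep(noise_sd, length(x)),
                 truth = p, model = model, rng_seed = rng_seed),
            class = "sc_decay_data")
}
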