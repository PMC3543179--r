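#' Build a pipeline run configuration
#'
#' @param input Either an `sc_panel`, an `sc_panel_spec` (generated at
#'   run time), or a list `list(path = , format = )` for [load_panel()].
#' @param stages Stages to execute, in dependency order; default all.
#' @param params Named list of per-stage parameter blocks. Recognised
#'   blocks: `decay` (`element_kind`, `reps`, `exclude`, `x_values`),
#'   `losssim` (`target_group`, `source_group`, `mode`, `reps`),
#'   `robustness` (`element_kind`, `k`), `graph` (`ec_classes`).
#' @param out_dir Optional output directory; when given, stage outputs
#'   and the manifest are written there as JSON/TSV.
#' @param rng_seed Integer seed propagated to every stochastic stage.
#' @return An object of class `sc_run_config`.
#' @export
run_config <- function(input,
                       stages = c("filter", "coresets", "graph",
                                  "robustness", "decay", "losssim",
                                  "seeds", "report"),
                       params = list(), out_dir = NULL, rng_seed = 1L) {
  known <- c("filter", "coresets", "graph", "robustness", "decay",
             "losssim", "seeds", "report")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(input = input, stages = known[known %in% stages],
                 params = params, out_dir = out_dir,
                 rng_seed = as.integer(rng_seed)),
            class = "sc_run_config")
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in dependency order (load, filter,
#' core/pan sets, union-graph connectivity, robustness scan, decay
#' simulation and fits, loss simulation, seed detection, report tables).
#' A stage failure marks that stage failed in the manifest and skips
#' its dependents; reruns with the same config and seed reproduce all
#' stochastic outputs exactly.
#'
#' @param config An `sc_run_config`.
#' @return List with `manifest` (per-stage status, seed, timing) and
#'   `results` (named list of stage outputs, including the loaded
#'   `panel`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "sc_run_config"))
  manifest <- list(rng_seed = config$rng_seed,
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stages = list())
  results <- list()
  note <- function(stage, status, detail = NULL)
    manifest$stages[[stage]] <<- list(status = status, detail = detail)

  panel_obj <- tryCatch({
    inp <- config$input
    if (inherits(inp, "sc_panel")) inp
    else if (inherits(inp, "sc_panel_spec")) generate_panel(inp)
    else if (is.list(inp) && !is.null(inp$path))
      load_panel(inp$path, inp$format %||% "tsv")
    else stop("config input must be a panel, a panel spec, or a path")
  }, error = function(e) {
    note("load", "failed", conditionMessage(e))
    NULL
  })
  if (is.null(panel_obj)) {
    manifest$ok <- FALSE
    return(list(manifest = manifest, results = results))
  }
  note("load", "ok", paste0(length(panel_obj$networks), " organisms"))
  manifest$input_digest <- cheap_digest(lapply(panel_obj$networks,
                                               element_set, "reaction"))

  run_stage <- function(stage, fn) {
    if (!stage %in% config$stages) return(invisible(NULL))
    out <- tryCatch(fn(), error = function(e) {
      note(stage, "failed", conditionMessage(e))
      NULL
    })
    if (!is.null(out)) {
      results[[stage]] <<- out
      note(stage, "ok")
    }
    invisible(NULL)
  }

  run_stage("filter", function() {
    panel_obj <<- suppressWarnings(apply_small_molecule_filter(panel_obj))
    list(removed = panel_obj$removed_reactions)
  })
  results$panel <- panel_obj
  pp <- config$params

  run_stage("coresets", function() {
    kinds <- c("reaction", "compound", "partial_ec")
    reports <- lapply(kinds, function(k) core_pan_variable(panel_obj, k))
    names(reports) <- kinds
    groups <- unique(vapply(panel_obj$networks,
                            function(n) n$org$group, character(1)))
    summaries <- list()
    for (k in kinds)
      for (g in groups)
        if (length(group_members(panel_obj, g)) >= 2L)
          summaries[[paste(k, g, sep = ".")]] <-
            group_summary(panel_obj, k, g)
    list(reports = reports, group_summaries = summaries)
  })

  run_stage("graph", function() {
    ug <- panel_union_graph(panel_obj)
    core_rxns <- if (!is.null(results$coresets))
      results$coresets$reports$reaction$core else character()
    ind <- if (length(core_rxns) >= 1L)
      induced_components(ug, core_rxns) else NULL
    ecp <- pp$graph$ec_classes %||%
      head(core_pan_variable(panel_obj, "partial_ec")$core, 4L)
    occ <- if (length(ecp) >= 2L)
      connected_ec_occurrences(ug, ecp, reaction_ec_map(panel_obj),
                               mode = "count", cap = 2e5)
    else NULL
    per_org <- if (length(ecp) >= 2L)
      occurrence_per_organism(panel_obj, ecp) else NULL
    list(union_graph = ug, induced = ind, ec_classes = ecp,
         occurrences = occ, per_organism = per_org)
  })

  run_stage("robustness", function() {
    k <- pp$robustness$k %||% 6L
    kind <- pp$robustness$element_kind %||% "partial_ec"
    removal_scan(panel_obj, kind, min(k, length(panel_obj$networks) - 1L))
  })

  run_stage("decay", function() {
    kind <- pp$decay$element_kind %||% "reaction"
    reps <- pp$decay$reps %||% 1000L
    groups <- unique(vapply(panel_obj$networks,
                            function(n) n$org$group, character(1)))
    out <- list()
    for (g in groups) {
      n_g <- length(setdiff(group_members(panel_obj, g),
                            pp$decay$exclude %||% character()))
      if (n_g < 4L) next
      dat <- simulate_decay(panel_obj, g, kind, reps = reps,
                            exclude = pp$decay$exclude %||% character(),
                            rng_seed = config$rng_seed)
      fits <- list(exponential = fit_decay(dat, "exponential"),
                   logistic = fit_decay(dat, "logistic"))
      out[[g]] <- list(data = dat, fits = fits,
                       alpha_tests = lapply(fits, asymptote_zero_test))
    }
    out
  })

  run_stage("losssim", function() {
    tg <- pp$losssim$target_group %||% "INTRA"
    sg <- pp$losssim$source_group %||% "EXTRA"
    cfg <- loss_sim_config(group_members(panel_obj, tg),
                           group_members(panel_obj, sg),
                           mode = pp$losssim$mode %||% "capability_loss",
                           reps = pp$losssim$reps %||% 1000L,
                           rng_seed = config$rng_seed)
    simulate_loss(panel_obj, cfg)
  })

  run_stage("seeds", function() {
    graphs <- lapply(panel_obj$networks, function(net)
      build_compound_graph(net, panel_obj$currency,
                           panel_obj$cofactor_pairs,
                           panel_obj$excluded_dndps))
    reports <- lapply(graphs, find_seeds)
    ext <- distance_one_extension(reports, graphs)
    list(reports = ext,
         base_summary = compare_inputs(reports, panel_obj),
         extended_summary = compare_inputs(ext, panel_obj,
                                           use_extended = TRUE))
  })

  run_stage("report", function() render_tables(results))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
    if (!is.null(results$report))
      for (nm in names(results$report))
        utils::write.table(results$report[[nm]],
                           file.path(config$out_dir, paste0(nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest$ok <- !any(vapply(manifest$stages, function(s)
    identical(s$status, "failed"), logical(1)))
  list(manifest = manifest, results = results)
}

# order-insensitive content digest without external dependencies
cheap_digest <- function(x) {
  s <- paste(utils::capture.output(utils::str(x, vec.len = 1e6,
                                              list.len = 1e6)),
             collapse = "\n")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

#' Render report tables
#'
#' Shapes stage outputs into presentation tables: per-group set-size
#' ratios with percentage rounding (rounding happens only here), decay
#' fit parameters formatted as `estimate±SE`, and loss-simulation
#' summaries.
#'
#' @param results The `results` list of [run_pipeline()] (any subset of
#'   stages may be present; absent stages yield omitted tables).
#' @return Named list of data frames.
#' @export
render_tables <- function(results) {
  out <- list()
  if (!is.null(results$coresets)) {
    gs <- results$coresets$group_summaries
    if (length(gs))
      out$group_ratios <- do.call(rbind, lapply(names(gs), function(nm) {
        s <- gs[[nm]]
        data.frame(element_kind = s$element_kind, group = s$group,
                   n_orgs = s$n_orgs,
                   mean = round(s$mean_size, 1),
                   union = s$union_size,
                   intersection = s$intersection_size,
                   mean_over_union = paste0(
                     round(100 * s$mean_over_union), "%"),
                   intersection_over_mean = paste0(
                     round(100 * s$intersection_over_mean), "%"),
                   stringsAsFactors = FALSE)
      }))
    out$core_sizes <- do.call(rbind, lapply(
      names(results$coresets$reports), function(k) {
        r <- results$coresets$reports[[k]]
        data.frame(element_kind = k, core = length(r$core),
                   pan = length(r$pan), variable = length(r$variable),
                   stringsAsFactors = FALSE)
      }))
  }
  if (!is.null(results$decay) && length(results$decay)) {
    out$decay_fits <- do.call(rbind, lapply(names(results$decay),
                                            function(g) {
      fits <- results$decay[[g]]$fits
      do.call(rbind, lapply(names(fits), function(m) {
        f <- fits[[m]]
        data.frame(group = g, model = m,
                   alpha = format_pm(f$estimates[["alpha"]],
                                     f$se[["alpha"]]),
                   r = format_pm(f$estimates[["r"]], f$se[["r"]]),
                   N = format_pm(f$estimates[["N"]], f$se[["N"]]),
                   rss = round(f$rss, 2),
                   stringsAsFactors = FALSE)
      }))
    }))
  }
  if (!is.null(results$losssim)) {
    ls <- results$losssim
    out$loss_sim <- data.frame(
      statistic = names(ls$observed),
      observed = unname(ls$observed),
      simulated = vapply(names(ls$observed), function(s)
        format_pm(ls$sim_means[[s]], ls$sim_sds[[s]], digits = 1),
        character(1)),
      p_value = unname(round(ls$p_values, 4)),
      stringsAsFactors = FALSE)
  }
  if (!is.null(results$seeds))
    out$seed_summary <- results$seeds$extended_summary
  out
}

format_pm <- function(est, se, digits = 2) {
  if (is.na(est)) return("NA")
  if (is.na(se)) return(sprintf(paste0("%.", digits, "f"), est))
  sprintf(paste0("%.", digits, "f±%.", digits, "f"), est, se)
}
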