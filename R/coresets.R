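#' Core, pan and variable sets across a panel
#'
#' The core metabolism of a set of organisms is the intersection of their
#' element sets (reactions, compounds, or level-3 partial EC classes),
#' the pan-metabolism is the union, and the variable metabolism is the
#' difference (elements missing from at least one organism).
#'
#' @param panel An `sc_panel`.
#' @param element_kind `"reaction"`, `"compound"` or `"partial_ec"`.
#' @param org_subset Optional character vector of organism ids (default:
#'   all). Must be non-empty and contained in the panel.
#' @return An object of class `sc_core_report`: list with `element_kind`,
#'   `scope` (the organism ids), `core`, `pan`, `variable` (character
#'   sets) and `per_org_sizes` (named integer vector).
#' @export
core_pan_variable <- function(panel,
                              element_kind = c("reaction", "compound",
                                               "partial_ec"),
                              org_subset = NULL) {
  stopifnot(inherits(panel, "sc_panel"))
  element_kind <- match.arg(element_kind)
  ids <- org_ids(panel)
  if (is.null(org_subset)) org_subset <- ids
  if (!length(org_subset)) stop("org_subset must contain at least one organism")
  unknown <- setdiff(org_subset, ids)
  if (length(unknown))
    stop("organism(s) not in panel: ", paste(unknown, collapse = ", "))
  sets <- lapply(panel$networks[org_subset], element_set, element_kind)
  core <- Reduce(intersect, sets)
  pan <- Reduce(union, sets)
  structure(
    list(element_kind = element_kind, scope = org_subset,
         core = sort(core), pan = sort(pan),
         variable = sort(setdiff(pan, core)),
         per_org_sizes = vapply(sets, length, integer(1))),
    class = "sc_core_report")
}

#' @export
print.sc_core_report <- function(x, ...) {
  cat("<sc_core_report> ", x$element_kind, " sets over ",
      length(x$scope), " organisms\n", sep = "")
  cat("  core ", length(x$core), " | pan ", length(x$pan),
      " | variable ", length(x$variable), "\n", sep = "")
  invisible(x)
}

#' Lifestyle-group size summary
#'
#' Mean per-organism set size, union and intersection sizes, and the two
#' diversity ratios mean/union (how much of the group's universe an
#' average organism covers) and intersection/mean (how much of an average
#' organism is shared by all). Ratios are kept at full precision;
#' rounding happens only in [render_tables()].
#'
#' @param panel An `sc_panel`.
#' @param element_kind `"reaction"`, `"compound"` or `"partial_ec"`.
#' @param group Lifestyle code present in the panel with >= 2 members.
#' @return An object of class `sc_group_summary`.
#' @export
group_summary <- function(panel,
                          element_kind = c("reaction", "compound",
                                           "partial_ec"),
                          group) {
  stopifnot(inherits(panel, "sc_panel"))
  element_kind <- match.arg(element_kind)
  members <- group_members(panel, group)
  if (length(members) < 2L)
    stop("group '", group, "' has fewer than 2 members")
  rep <- core_pan_variable(panel, element_kind, members)
  mean_size <- mean(rep$per_org_sizes)
  structure(
    list(group = group, element_kind = element_kind,
         n_orgs = length(members),
         mean_size = mean_size,
         union_size = length(rep$pan),
         intersection_size = length(rep$core),
         mean_over_union = mean_size / length(rep$pan),
         intersection_over_mean = length(rep$core) / mean_size),
    class = "sc_group_summary")
}

group_members <- function(panel, group) {
  if (!group %in% c("INTRA", "CA", "EXTRA", "FL"))
    stop("unknown lifestyle group code '", group, "'")
  ids <- org_ids(panel)
  ids[vapply(panel$networks, function(n) n$org$group, character(1)) == group]
}

#' Biosynthesis/degradation composition of a reaction scope
#'
#' Counts the reactions of a core/variable/pan scope by process label.
#' Multi-label reactions are counted in each class (so biosynthesis and
#' degradation proportions may sum to more than 100%) and separately in
#' `n_both`.
#'
#' @param panel An `sc_panel`.
#' @param report An `sc_core_report` with `element_kind = "reaction"`.
#' @param scope `"core"`, `"variable"` or `"pan"`.
#' @return An object of class `sc_process_composition` with counts
#'   `n_total`, `n_biosynthesis`, `n_degradation`, `n_both`, `n_other`.
#' @export
process_composition <- function(panel, report,
                                scope = c("core", "variable", "pan")) {
  stopifnot(inherits(panel, "sc_panel"), inherits(report, "sc_core_report"))
  if (report$element_kind != "reaction")
    stop("process composition is defined over reaction reports")
  scope <- match.arg(scope)
  rxn_ids <- report[[scope]]
  procs <- reaction_process_table(panel)[rxn_ids]
  n_b <- sum(vapply(procs, function(p) "biosynthesis" %in% p, logical(1)))
  n_d <- sum(vapply(procs, function(p) "degradation" %in% p, logical(1)))
  n_both <- sum(vapply(procs, function(p)
    all(c("biosynthesis", "degradation") %in% p), logical(1)))
  n_other <- sum(vapply(procs, function(p)
    !any(c("biosynthesis", "degradation") %in% p), logical(1)))
  structure(
    list(scope = scope, n_total = length(rxn_ids),
         n_biosynthesis = n_b, n_degradation = n_d,
         n_both = n_both, n_other = n_other),
    class = "sc_process_composition")
}

reaction_process_table <- function(panel) {
  tab <- list()
  for (net in panel$networks)
    for (r in net$reactions)
      if (is.null(tab[[r$id]])) tab[[r$id]] <- r$processes
  tab
}

#' Compare process proportions between two compositions
#'
#' Fisher exact test on the 2x2 table of (in-class, not-in-class) counts
#' for a chosen process class; used to ask e.g. whether a variable
#' metabolism is enriched in biosynthetic reactions relative to another
#' group's.
#'
#' @param comp_a,comp_b `sc_process_composition` objects.
#' @param process `"biosynthesis"` or `"degradation"`.
#' @param alternative Passed to [stats::fisher.test()]; default
#'   two-sided, with one-sided options for directional enrichment.
#' @return The `htest` result of the Fisher exact test.
#' @export
compare_process_proportions <- function(comp_a, comp_b,
                                        process = c("biosynthesis",
                                                    "degradation"),
                                        alternative = c("two.sided",
                                                        "less", "greater")) {
  process <- match.arg(process)
  alternative <- match.arg(alternative)
  field <- paste0("n_", process)
  tab <- matrix(c(comp_a[[field]], comp_a$n_total - comp_a[[field]],
                  comp_b[[field]], comp_b$n_total - comp_b[[field]]),
                nrow = 2, byrow = TRUE)
  stats::fisher.test(tab, alternative = alternative)
}

#' Metabolic-gene ratios with rank tests
#'
#' Ratio of metabolic genes to total genes per organism, summarised by
#' lifestyle group or subcategory, with Wilcoxon rank-sum (two groups)
#' and Kruskal-Wallis (k groups) wrappers.
#'
#' @param panel An `sc_panel`.
#' @param grouping `"group"` or `"subcategory"`; subcategory `NA` values
#'   are pooled under `"other"`.
#' @return List with `ratios` (data frame org_id/grouping/ratio),
#'   `summary` (per-group mean and sd) and `tests` (Kruskal-Wallis over
#'   all groups; pairwise Wilcoxon when exactly two groups). Organisms
#'   with zero genes are excluded with a warning.
#' @export
metabolic_gene_ratios <- function(panel, grouping = c("group", "subcategory")) {
  stopifnot(inherits(panel, "sc_panel"))
  grouping <- match.arg(grouping)
  orgs <- lapply(panel$networks, `[[`, "org")
  n_genes <- vapply(orgs, `[[`, integer(1), "n_genes")
  zero <- n_genes == 0L
  if (any(zero)) {
    warning("excluding organism(s) with zero genes: ",
            paste(names(orgs)[zero], collapse = ", "), call. = FALSE)
    orgs <- orgs[!zero]
  }
  df <- data.frame(
    org_id = vapply(orgs, `[[`, character(1), "org_id"),
    grp = vapply(orgs, function(o) {
      g <- o[[grouping]]
      if (is.na(g)) "other" else g
    }, character(1)),
    ratio = vapply(orgs, function(o)
      o$n_metabolic_genes / o$n_genes, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  agg <- do.call(rbind, lapply(split(df$ratio, df$grp), function(v)
    data.frame(mean = mean(v), sd = stats::sd(v), n = length(v))))
  agg$grp <- rownames(agg)
  tests <- list()
  if (length(unique(df$grp)) >= 2L) {
    tests$kruskal <- stats::kruskal.test(ratio ~ factor(grp), data = df)
    if (length(unique(df$grp)) == 2L) {
      sp <- split(df$ratio, df$grp)
      tests$wilcoxon <- wilcox_exact_fallback(sp[[1]], sp[[2]])
    }
  }
  list(ratios = df, summary = agg, tests = tests)
}

#' Two-group Wilcoxon rank-sum on a named split
#'
#' Thin wrapper used by reporting code: compares the metabolic-gene
#' ratios of one group against all remaining organisms (e.g. MIV versus
#' the rest).
#'
#' @param panel An `sc_panel`.
#' @param subcategory Subcategory code defining the focal group.
#' @return `htest` result.
#' @export
focal_subcategory_test <- function(panel, subcategory) {
  orgs <- lapply(panel$networks, `[[`, "org")
  keep <- vapply(orgs, function(o) o$n_genes > 0L, logical(1))
  orgs <- orgs[keep]
  ratio <- vapply(orgs, function(o) o$n_metabolic_genes / o$n_genes,
                  numeric(1))
  focal <- vapply(orgs, function(o)
    identical(o$subcategory, subcategory), logical(1))
  if (!any(focal) || all(focal))
    stop("subcategory '", subcategory, "' does not split the panel")
  wilcox_exact_fallback(ratio[focal], ratio[!focal])
}

# exact distribution for small untied samples, normal approximation
# (with continuity correction) when ties make the exact p undefined;
# fully tied data carry no evidence at all
wilcox_exact_fallback <- function(x, y) {
  if (length(unique(c(x, y))) == 1L) {
    res <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    res$p.value <- 1
    return(res)
  }
  has_ties <- anyDuplicated(c(x, y)) > 0L
  stats::wilcox.test(x, y, exact = !has_ties, correct = TRUE)
}
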