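#' Simulate the decay of shared elements under random subsampling
#'
#' For each subset size x (2 <= x <= n-1 within the chosen lifestyle
#' group), draws `reps` uniform random x-subsets of organisms (without
#' replacement within a draw, independently across replicates) and
#' computes the exact intersection of their element sets. The mean curve
#' over replicates is the input to [fit_decay()].
#'
#' @param panel An `sc_panel`.
#' @param group Lifestyle code; `NULL` uses the whole panel.
#' @param element_kind `"reaction"`, `"compound"` or `"partial_ec"`.
#' @param reps Replicates per subset size (default 1000).
#' @param exclude Organism ids removed before sampling (e.g. dropping
#'   outlier species with extremely reduced genomes from a group).
#' @param x_values Optional integer vector of subset sizes; default
#'   `2:(n-1)`.
#' @param rng_seed Integer seed; the simulation is reproducible given
#'   the seed.
#' @return An object of class `sc_decay_data`: list with `group`, `x`,
#'   `reps`, `y_reps` (list, per x, of replicate intersection sizes),
#'   `y_bar`, `y_sd`, `orgs`, `rng_seed`.
#' @export
simulate_decay <- function(panel, group = NULL,
                           element_kind = c("reaction", "compound",
                                            "partial_ec"),
                           reps = 1000L, exclude = character(),
                           x_values = NULL, rng_seed = 1L) {
  stopifnot(inherits(panel, "sc_panel"))
  element_kind <- match.arg(element_kind)
  orgs <- if (is.null(group)) org_ids(panel) else group_members(panel, group)
  orgs <- setdiff(orgs, exclude)
  n <- length(orgs)
  if (n < 3L) stop("need at least 3 organisms after exclusion, got ", n)
  if (is.null(x_values)) x_values <- 2:(n - 1L)
  x_values <- sort(unique(as.integer(x_values)))
  if (!length(x_values) || any(x_values < 2L | x_values > n - 1L))
    stop("subset sizes must lie in [2, ", n - 1L, "]")
  sets <- lapply(panel$networks[orgs], element_set, element_kind)
  # membership matrix: intersection size of a drawn subset is the number
  # of elements present in all x drawn organisms
  universe <- unique(unlist(sets, use.names = FALSE))
  memb <- vapply(sets, function(s) universe %in% s,
                 logical(length(universe)))
  if (is.null(dim(memb))) memb <- matrix(memb, nrow = length(universe))
  storage.mode(memb) <- "integer"
  set.seed(rng_seed)
  y_reps <- lapply(x_values, function(x) {
    vapply(seq_len(reps), function(i) {
      drawn <- sample.int(n, x, replace = FALSE)
      sum(rowSums(memb[, drawn, drop = FALSE]) == x)
    }, integer(1))
  })
  structure(
    list(group = if (is.null(group)) "ALL" else group,
         element_kind = element_kind, x = x_values, reps = reps,
         y_reps = y_reps,
         y_bar = vapply(y_reps, mean, numeric(1)),
         y_sd = vapply(y_reps, stats::sd, numeric(1)),
         orgs = orgs, rng_seed = rng_seed),
    class = "sc_decay_data")
}

#' Decay model curves
#'
#' The exponential model is `y = N * exp(-r * x) + alpha`; the logistic
#' model is `y = N * alpha / ((alpha - N) * exp(-r * x) + N)`. Both
#' satisfy `y(0) = N` up to the exponential's offset (`N + alpha`) and
#' tend to the asymptote `alpha` as `x` grows; `r > 0` is the decay
#' rate. An asymptote of zero means the shared set is expected to vanish
#' as organisms are added.
#'
#' @param x Numeric vector of subset sizes.
#' @param N,r,alpha Model parameters.
#' @return Numeric vector of model values.
#' @export
decay_exponential <- function(x, N, r, alpha) N * exp(-r * x) + alpha

#' @rdname decay_exponential
#' @export
decay_logistic <- function(x, N, r, alpha)
  N * alpha / ((alpha - N) * exp(-r * x) + N)

#' Fit a decay model to a mean intersection curve
#'
#' Nonlinear least squares on the per-x mean curve (not the replicate
#' cloud), with bounds `alpha >= 0`, `r` in (1e-6, 10), `N > 0`.
#' Starting values come from a log-linear pre-fit of `y_bar - alpha0`
#' with `alpha0 = min(y_bar)`; on failure up to 20 seeded random
#' restarts perturb the start. Non-convergence returns the best iterate
#' with `converged = FALSE` rather than an error; flat data yield
#' status `"unidentifiable_r"`.
#'
#' @param data An `sc_decay_data`, or any list with numeric `x` and
#'   `y_bar` (and optionally `y_reps` for the weighted option).
#' @param model `"exponential"` or `"logistic"`.
#' @param weighted Logical; when `TRUE`, weight each x by the inverse
#'   replicate variance (off by default).
#' @return An object of class `sc_model_fit`: list with `model`,
#'   `estimates` (named vector alpha, r, N), `se`, `residual_sd`,
#'   `rss`, `aicc`, `converged`, `n_iter`, `status`, `boundary` (named
#'   logical), and the fitted `nls` object under `$fit` when available.
#' @export
fit_decay <- function(data, model = c("exponential", "logistic"),
                      weighted = FALSE) {
  model <- match.arg(model)
  x <- as.numeric(data$x)
  y <- as.numeric(data$y_bar)
  stopifnot(length(x) == length(y), all(is.finite(y)))
  if (length(unique(x)) < 4L)
    stop("need at least 4 distinct subset sizes to fit 3 parameters")
  if (stats::sd(y) < sqrt(.Machine$double.eps) * max(1, mean(y)))
    return(empty_fit(model, status = "unidentifiable_r", y = y))
  w <- if (weighted && !is.null(data$y_reps)) {
    v <- vapply(data$y_reps, stats::var, numeric(1))
    1 / pmax(v, 1e-8)
  } else rep(1, length(x))
  start <- decay_start_values(x, y)
  lower <- c(alpha = 0, r = 1e-6, N = 1e-8)
  upper <- c(alpha = Inf, r = 10, N = Inf)
  fml <- switch(model,
    exponential = y ~ N * exp(-r * x) + alpha,
    logistic = y ~ N * alpha / ((alpha - N) * exp(-r * x) + N))
  df <- data.frame(x = x, y = y)
  attempt <- function(st) {
    st <- pmin(pmax(st, lower + 1e-8), c(alpha = max(y), r = 10 - 1e-6,
                                         N = 10 * max(y)))
    # logistic is singular at alpha = 0; nudge off the boundary
    if (model == "logistic") st["alpha"] <- max(st["alpha"], 1e-3)
    tryCatch(
      minpack.lm::nlsLM(fml, data = df, start = as.list(st),
                        lower = lower, upper = upper, weights = w,
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
  }
  # multi-start: the pre-fit start plus deterministic variants guard
  # against the logistic's degenerate local minima; keep the lowest RSS
  starts <- list(
    start,
    c(alpha = max(min(y), 1e-2), r = start[["r"]], N = max(y)),
    c(alpha = max(min(y), 1e-2), r = 0.05, N = 2 * max(y)),
    c(alpha = 0.5 * min(y) + 1e-3, r = 0.5, N = max(y)),
    c(alpha = mean(y), r = 0.1, N = max(y)))
  fits <- Filter(Negate(is.null), lapply(starts, attempt))
  n_restart <- 0L
  if (!length(fits)) {
    if (!is.null(data$rng_seed)) set.seed(data$rng_seed + 7L)
    while (n_restart < 20L && !length(fits)) {
      n_restart <- n_restart + 1L
      jitter <- stats::runif(3, 0.3, 3)
      fits <- Filter(Negate(is.null), list(attempt(start * jitter)))
    }
  }
  fit <- if (length(fits))
    fits[[which.min(vapply(fits, function(f)
      sum(stats::resid(f)^2), numeric(1)))]]
  else NULL
  if (is.null(fit))
    return(empty_fit(model, status = "no_convergence", y = y))
  est <- stats::coef(fit)[c("alpha", "r", "N")]
  se <- tryCatch(summary(fit)$coefficients[c("alpha", "r", "N"),
                                           "Std. Error"],
                 error = function(e)
                   stats::setNames(rep(NA_real_, 3),
                                   c("alpha", "r", "N")))
  res <- stats::resid(fit)
  rss <- sum(res^2)
  k <- 4  # 3 parameters + sigma
  nobs <- length(y)
  aic <- nobs * log(rss / nobs) + 2 * k
  aicc <- if (nobs - k - 1 > 0) aic + 2 * k * (k + 1) / (nobs - k - 1)
          else NA_real_
  boundary <- c(alpha = est[["alpha"]] <= lower[["alpha"]] + 1e-7,
                r = est[["r"]] >= upper[["r"]] - 1e-7 ||
                    est[["r"]] <= lower[["r"]] + 1e-7,
                N = FALSE)
  structure(
    list(model = model, estimates = est, se = se,
         residual_sd = sqrt(rss / max(1, nobs - 3)),
         rss = rss, aicc = aicc,
         converged = isTRUE(fit$convInfo$isConv %||% TRUE),
         n_iter = fit$convInfo$finIter %||% NA_integer_,
         n_restarts = n_restart, status = "ok", boundary = boundary,
         fit = fit),
    class = "sc_model_fit")
}

decay_start_values <- function(x, y) {
  alpha0 <- max(min(y) * 0.9, 0)
  pos <- y - alpha0 > 0
  if (sum(pos) >= 2) {
    lf <- stats::lm(log(y[pos] - alpha0) ~ x[pos])
    r0 <- max(1e-4, -stats::coef(lf)[[2]])
    N0 <- max(exp(stats::coef(lf)[[1]]), max(y) - alpha0)
  } else {
    r0 <- 0.1
    N0 <- max(y)
  }
  c(alpha = alpha0, r = min(r0, 9), N = N0)
}

empty_fit <- function(model, status, y) {
  structure(
    list(model = model,
         estimates = c(alpha = mean(y), r = NA_real_, N = NA_real_),
         se = c(alpha = NA_real_, r = NA_real_, N = NA_real_),
         residual_sd = stats::sd(y), rss = NA_real_, aicc = NA_real_,
         converged = FALSE, n_iter = 0L, n_restarts = 0L,
         status = status, boundary = c(alpha = FALSE, r = FALSE, N = FALSE),
         fit = NULL),
    class = "sc_model_fit")
}

#' @export
print.sc_model_fit <- function(x, ...) {
  cat("<sc_model_fit> ", x$model, " (", x$status, ")\n", sep = "")
  est <- x$estimates; se <- x$se
  for (p in names(est))
    cat(sprintf("  %-5s %10.4f +/- %s\n", p, est[[p]],
                if (is.na(se[[p]])) "NA" else sprintf("%.4f", se[[p]])))
  invisible(x)
}

#' Wald test of a zero asymptote
#'
#' Tests whether the fitted asymptote differs from zero: statistic
#' `alpha_hat / SE(alpha_hat)` against a standard normal reference,
#' one-sided (alpha > 0). A significant result means the shared set is
#' not expected to vanish as organisms are added. The result is flagged
#' unreliable when the estimate sits on the alpha >= 0 boundary.
#'
#' @param fit An `sc_model_fit`, or a list with `estimates["alpha"]` and
#'   `se["alpha"]`.
#' @param level Significance level for the `significant` flag.
#' @return List with `statistic`, `p_value` (one-sided), `significant`,
#'   `status` (`"ok"`, `"boundary"`, `"untestable"`).
#' @export
asymptote_zero_test <- function(fit, level = 0.05) {
  a <- fit$estimates[["alpha"]]
  se <- fit$se[["alpha"]]
  if (is.na(se) || !is.finite(se) || se <= 0)
    return(list(statistic = NA_real_, p_value = NA_real_,
                significant = NA, status = "untestable"))
  z <- a / se
  p <- stats::pnorm(z, lower.tail = FALSE)
  status <- if (isTRUE(fit$boundary[["alpha"]])) "boundary" else "ok"
  list(statistic = z, p_value = p, significant = p < level,
       status = status)
}

#' Compare decay models on one data set
#'
#' Fits both the exponential and the logistic model and reports residual
#' sums of squares and small-sample AIC side by side; no automatic
#' selection is made.
#'
#' @param data An `sc_decay_data`.
#' @return Data frame with one row per model.
#' @export
compare_decay_models <- function(data) {
  fits <- list(exponential = fit_decay(data, "exponential"),
               logistic = fit_decay(data, "logistic"))
  do.call(rbind, lapply(names(fits), function(m) {
    f <- fits[[m]]
    data.frame(model = m, rss = f$rss, aicc = f$aicc,
               alpha = f$estimates[["alpha"]],
               r = f$estimates[["r"]], N = f$estimates[["N"]],
               converged = f$converged, stringsAsFactors = FALSE)
  }))
}
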