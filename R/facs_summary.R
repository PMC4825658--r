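# Summaries of per-cell fluorescence samples: median fold changes
# between strains/conditions and detection of bimodal subpopulations by
# two-component normal mixture fits on the log10 axis.

#' Median fold change between two fluorescence samples
#'
#' Flow-cytometry distributions are heavy-tailed, so location comparison
#' uses medians on the log axis: `10^(median(sample) - median(reference))`.
#'
#' @param sample,reference Numeric vectors of per-cell log10 fluorescence.
#' @return Linear-scale fold change (> 0).
#' @export
median_fold_change <- function(sample, reference) {
  if (!length(sample) || !length(reference)) stop("empty fluorescence sample")
  stopifnot(all(is.finite(sample)), all(is.finite(reference)))
  10^(stats::median(sample) - stats::median(reference))
}

# One EM run from a given initialization; returns NULL on degeneracy.
#' @noRd
em_normal2 <- function(x, w, m1, m2, s1, s2, tol = 1e-8, max_iter = 500L,
                       sd_floor = NULL) {
  n <- length(x)
  sd_floor <- sd_floor %||% max(stats::sd(x) * 1e-3, 1e-6)
  ll_old <- -Inf
  trace_ok <- TRUE
  for (it in seq_len(max_iter)) {
    d1 <- (1 - w) * stats::dnorm(x, m1, s1)
    d2 <- w * stats::dnorm(x, m2, s2)
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    if (ll < ll_old - 1e-6) trace_ok <- FALSE  # EM must not decrease
    r <- d2 / tot
    w <- mean(r)
    if (w < 1e-10 || w > 1 - 1e-10) {
      return(NULL)
    }
    m1 <- sum((1 - r) * x) / sum(1 - r)
    m2 <- sum(r * x) / sum(r)
    s1 <- max(sqrt(sum((1 - r) * (x - m1)^2) / sum(1 - r)), sd_floor)
    s2 <- max(sqrt(sum(r * (x - m2)^2) / sum(r)), sd_floor)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  list(w = w, m1 = m1, m2 = m2, s1 = s1, s2 = s2, loglik = ll,
       iterations = it, monotone = trace_ok)
}

#' Fit a 1- or 2-component normal mixture on the log10 axis
#'
#' For k = 2, expectation-maximization with a quantile-split
#' initialization (below/above the sample median) plus random restarts
#' under fixed derived seeds; the best log-likelihood wins and components
#' are reported in increasing location order. Component scales are
#' floored at 1e-3 sample SDs to keep the likelihood bounded. The
#' model-selection score is the BIC difference (1-component minus
#' 2-component; positive favours two components).
#'
#' @param x Per-cell log10 fluorescence values.
#' @param k 1 or 2 components.
#' @param seed RNG seed for the random restarts.
#' @param n_restarts Random restarts beyond the quantile split (default 4).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per start.
#' @return List of class `mixture_fit`: `k`, `weights`, `locations`,
#'   `scales`, `loglik`, `bic`, `score` (BIC_1 - BIC_2; only for k = 2),
#'   `converged`.
#' @export
fit_mixture <- function(x, k = 2L, seed = 1L, n_restarts = 4L, tol = 1e-8,
                        max_iter = 500L) {
  stopifnot(k %in% c(1L, 2L), all(is.finite(x)))
  n <- length(x)
  if (n < 1L) stop("empty sample")
  m <- mean(x); s <- stats::sd(x)
  if (!is.finite(s) || s == 0) s <- 1e-6
  ll1 <- sum(stats::dnorm(x, m, max(s * sqrt((n - 1) / n), 1e-9), log = TRUE))
  bic1 <- -2 * ll1 + 2 * log(n)
  if (k == 1L) {
    return(structure(list(k = 1L, weights = 1, locations = m, scales = s,
                          loglik = ll1, bic = bic1, score = NA_real_,
                          converged = TRUE),
                     class = "mixture_fit"))
  }
  if (n < 50L) stop("k = 2 mixture fit requires n >= 50 cells")
  med <- stats::median(x)
  lo <- x[x <= med]; hi <- x[x > med]
  if (!length(hi)) hi <- max(x)
  inits <- list(list(w = 0.5, m1 = mean(lo), m2 = mean(hi),
                     s1 = max(stats::sd(x) / 2, 1e-6),
                     s2 = max(stats::sd(x) / 2, 1e-6)))
  if (!is.null(seed)) set.seed(as.integer(seed))
  for (i in seq_len(n_restarts)) {
    cm <- sort(sample(x, 2L))
    inits[[length(inits) + 1L]] <-
      list(w = stats::runif(1, 0.2, 0.8), m1 = cm[1], m2 = cm[2],
           s1 = max(s / 2, 1e-6), s2 = max(s / 2, 1e-6))
  }
  best <- NULL
  for (init in inits) {
    fit <- em_normal2(x, init$w, init$m1, init$m2, init$s1, init$s2,
                      tol = tol, max_iter = max_iter)
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    # all starts collapsed: report the 1-component solution as a
    # degenerate 2-component fit with a vanishing minor weight
    return(structure(list(k = 2L, weights = c(1, 0), locations = c(m, m),
                          scales = c(s, s), loglik = ll1, bic = bic1,
                          score = 0, converged = FALSE),
                     class = "mixture_fit"))
  }
  if (!best$monotone) {
    stop("EM log-likelihood decreased; fit diagnostics: loglik = ",
         best$loglik, ", iterations = ", best$iterations)
  }
  ord <- order(c(best$m1, best$m2))
  weights <- c(1 - best$w, best$w)[ord]
  locations <- c(best$m1, best$m2)[ord]
  scales <- c(best$s1, best$s2)[ord]
  bic2 <- -2 * best$loglik + 5 * log(n)
  structure(list(k = 2L, weights = weights, locations = locations,
                 scales = scales, loglik = best$loglik, bic = bic2,
                 score = bic1 - bic2,
                 converged = best$iterations < max_iter),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("mixture_fit k =", x$k, "\n  weights:  ",
      paste(signif(x$weights, 3), collapse = ", "), "\n  locations:",
      paste(signif(x$locations, 4), collapse = ", "), "\n  scales:   ",
      paste(signif(x$scales, 3), collapse = ", "), "\n")
  if (x$k == 2L) cat("  score (BIC1 - BIC2):", signif(x$score, 4), "\n")
  invisible(x)
}

#' Detect a bimodal subpopulation
#'
#' A sample is called bimodal iff the 2-component mixture wins model
#' selection (BIC difference above `score_min`), the minor component
#' carries at least `min_weight` of the population, and the component
#' locations are separated by at least `min_separation` log10 units.
#'
#' @param x Per-cell log10 fluorescence values (n >= 50).
#' @param score_min Minimum BIC improvement of the 2-component model
#'   (default 10, "very strong" evidence on the usual BIC scale).
#' @param min_weight Minimum minor-component weight (default 0.05).
#' @param min_separation Minimum location separation in log10 units
#'   (default 0.3, i.e. a two-fold fluorescence difference).
#' @param seed RNG seed for the mixture restarts.
#' @return List: `bimodal` (logical), `fit` (the 2-component
#'   [fit_mixture()] result).
#' @export
detect_bimodality <- function(x, score_min = 10, min_weight = 0.05,
                              min_separation = 0.3, seed = 1L) {
  fit <- fit_mixture(x, k = 2L, seed = seed)
  bimodal <- isTRUE(fit$score > score_min) &&
    min(fit$weights) >= min_weight &&
    abs(diff(fit$locations)) >= min_separation
  list(bimodal = bimodal, fit = fit)
}
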