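#' Upper tail of the discrete power law
#'
#' Survival function \eqn{P(X \ge x) = \zeta(\alpha, x) / \zeta(\alpha, x_{min})}
#' for a discrete power-law variable supported on the integers
#' \eqn{x \ge x_{min}}.
#'
#' @param x integer quantile(s), each >= \code{xmin}. Vectorized.
#' @param alpha power-law exponent, > 1.
#' @param xmin lower support boundary, integer >= 1.
#' @return numeric vector of tail probabilities in (0, 1].
#' @examples
#' powerlaw_tail(1, 2, 1)   # 1
#' powerlaw_tail(2, 2, 1)   # 1 - 6/pi^2
#' @export
powerlaw_tail <- function(x, alpha, xmin = 1L) {
  if (alpha <= 1) stop("powerlaw_tail: 'alpha' must be > 1 (tail diverges)")
  if (xmin < 1) stop("powerlaw_tail: 'xmin' must be >= 1")
  if (any(x < xmin)) stop("powerlaw_tail: 'x' must be >= xmin")
  hurwitz_zeta(alpha, x) / hurwitz_zeta(alpha, xmin)
}

# Profile log-likelihood of the tail sample at exponent alpha:
#   l(alpha) = -n log zeta(alpha, xmin) - alpha * sum(log x_i)
powerlaw_loglik <- function(alpha, xmin, n_tail, sum_log_x) {
  -n_tail * log(hurwitz_zeta(alpha, xmin)) - alpha * sum_log_x
}

#' Maximum-likelihood exponent for a discrete power law at fixed xmin
#'
#' Maximizes \eqn{\ell(\alpha) = -n \log \zeta(\alpha, x_{min}) -
#' \alpha \sum \log x_i} over the tail counts (those >= \code{xmin}) by
#' deterministic bounded golden-section search on
#' \eqn{\alpha \in (1 + 10^{-6}, 20]}.
#'
#' @param counts integer vector of clone abundances.
#' @param xmin lower estimation boundary; only counts >= xmin enter the fit.
#' @param min_tail minimum number of tail counts required.
#' @return list with \code{alpha} and \code{log_lik}.
#' @export
fit_alpha_mle <- function(counts, xmin, min_tail = 10L) {
  tail_x <- counts[counts >= xmin]
  n_tail <- length(tail_x)
  if (n_tail < min_tail)
    stop("fit_alpha_mle: fewer than ", min_tail, " counts >= xmin = ", xmin)
  if (all(tail_x == xmin))
    stop("fit_alpha_mle: all tail counts equal xmin; likelihood unbounded")
  sum_log_x <- sum(log(tail_x))
  opt <- stats::optimize(powerlaw_loglik, interval = c(1 + 1e-6, 20),
                         maximum = TRUE, tol = 1e-8,
                         xmin = xmin, n_tail = n_tail, sum_log_x = sum_log_x)
  list(alpha = opt$maximum, log_lik = opt$objective)
}

# KS distance between the empirical CDF of the tail counts and the fitted
# discrete power-law CDF, evaluated at the observed unique tail values.
powerlaw_ks <- function(tail_x, alpha, xmin) {
  u <- sort(unique(tail_x))
  emp <- cumsum(tabulate(factor(tail_x, levels = u))) / length(tail_x)
  fit <- 1 - powerlaw_tail(u + 1L, alpha, xmin)
  max(abs(emp - fit))
}

#' Fit a discrete power law to clone abundances
#'
#' Fits \eqn{P(X = x) = x^{-\alpha} / \zeta(\alpha, x_{min})} to a vector of
#' clone read counts by maximum likelihood. When \code{xmin} is \code{NULL}
#' (the default) the lower estimation boundary is selected by scanning every
#' candidate \eqn{x_{min}} among the unique observed counts that leaves at
#' least \code{min_tail} counts in the tail, fitting \eqn{\alpha} at each,
#' and keeping the candidate minimizing the Kolmogorov--Smirnov distance
#' between the empirical and fitted tail CDFs; ties go to the smallest
#' candidate. Counts below the selected boundary are excluded from the fit
#' and are never eligible to be outliers.
#'
#' @param counts positive integer vector of clone abundances (one per clone).
#' @param xmin optional fixed lower boundary; if supplied no selection scan
#'   is run.
#' @param min_tail minimum tail size for a candidate boundary (default 10).
#' @return an object of class \code{"powerlaw_fit"}: a list with elements
#'   \code{alpha}, \code{xmin}, \code{n_tail}, \code{ks_stat},
#'   \code{log_lik}, \code{n} (total counts supplied), and \code{scan}
#'   (the candidate table when selection was run).
#' @examples
#' set.seed(1)
#' x <- rpowerlaw(500, alpha = 2.5)
#' fit <- fit_powerlaw(x)
#' fit
#' coef(fit)
#' @seealso [clone_evalue()], [call_disease_clones()], [rpowerlaw()]
#' @export
fit_powerlaw <- function(counts, xmin = NULL, min_tail = 10L) {
  if (length(counts) == 0L || any(counts < 1) || any(counts != floor(counts)))
    stop("fit_powerlaw: 'counts' must be positive integers")
  counts <- as.numeric(counts)
  if (!is.null(xmin)) {
    mle <- fit_alpha_mle(counts, xmin, min_tail)
    tail_x <- counts[counts >= xmin]
    fit <- list(alpha = mle$alpha, xmin = as.integer(xmin),
                n_tail = length(tail_x),
                ks_stat = powerlaw_ks(tail_x, mle$alpha, xmin),
                log_lik = mle$log_lik, n = length(counts), scan = NULL)
    class(fit) <- "powerlaw_fit"
    return(fit)
  }
  cand <- sort(unique(counts))
  cand <- cand[vapply(cand, function(v) sum(counts >= v), 0) >= min_tail]
  # a candidate whose tail is all ties has an unbounded likelihood: skip it
  cand <- cand[vapply(cand, function(v) any(counts > v), FALSE)]
  if (length(cand) == 0L)
    stop("fit_powerlaw: no candidate xmin leaves a non-degenerate tail of >= ",
         min_tail, " counts")
  scan <- do.call(rbind, lapply(cand, function(v) {
    mle <- fit_alpha_mle(counts, v, min_tail)
    tail_x <- counts[counts >= v]
    data.frame(xmin = v, alpha = mle$alpha, n_tail = length(tail_x),
               ks_stat = powerlaw_ks(tail_x, mle$alpha, v),
               log_lik = mle$log_lik)
  }))
  best <- which.min(scan$ks_stat)  # which.min takes the first = smallest xmin
  fit <- list(alpha = scan$alpha[best], xmin = as.integer(scan$xmin[best]),
              n_tail = scan$n_tail[best], ks_stat = scan$ks_stat[best],
              log_lik = scan$log_lik[best], n = length(counts), scan = scan)
  class(fit) <- "powerlaw_fit"
  fit
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat("Discrete power-law fit\n")
  cat(sprintf("  alpha    %.4f\n", x$alpha))
  cat(sprintf("  xmin     %d  (tail: %d of %d clones)\n",
              x$xmin, x$n_tail, x$n))
  cat(sprintf("  KS stat  %.4f\n", x$ks_stat))
  cat(sprintf("  logLik   %.2f\n", x$log_lik))
  invisible(x)
}

#' @export
coef.powerlaw_fit <- function(object, ...) {
  c(alpha = object$alpha, xmin = object$xmin)
}

#' @export
logLik.powerlaw_fit <- function(object, ...) {
  structure(object$log_lik, df = 1L, nobs = object$n_tail, class = "logLik")
}

#' Tail probabilities or e-values from a fitted power law
#'
#' @param object a \code{"powerlaw_fit"}.
#' @param newdata integer counts (>= the fitted xmin).
#' @param type \code{"tail"} for \eqn{P(X \ge x)}, \code{"evalue"} for
#'   \eqn{n_{tail} \cdot P(X \ge x)}.
#' @param ... unused.
#' @export
predict.powerlaw_fit <- function(object, newdata,
                                 type = c("tail", "evalue"), ...) {
  type <- match.arg(type)
  p <- powerlaw_tail(newdata, object$alpha, object$xmin)
  if (type == "evalue") object$n_tail * p else p
}

#' @export
simulate.powerlaw_fit <- function(object, nsim = 1, seed = NULL, ...) {
  rpowerlaw(nsim, object$alpha, object$xmin, seed = seed)
}

#' Rank-abundance plot of counts against a fitted power law
#'
#' Log-log plot of the empirical tail \eqn{P(X \ge x)} of the supplied
#' counts with the fitted tail overlaid; the vertical line marks the fitted
#' lower boundary.
#'
#' @param x a \code{"powerlaw_fit"}.
#' @param counts the count vector that was fitted.
#' @param ... passed to \code{plot}.
#' @export
plot.powerlaw_fit <- function(x, counts, ...) {
  u <- sort(unique(counts))
  emp <- vapply(u, function(v) mean(counts >= v), 0)
  graphics::plot(u, emp, log = "xy", xlab = "read count",
                 ylab = "P(X >= x)", pch = 16, cex = 0.6, ...)
  xs <- u[u >= x$xmin]
  scale <- x$n_tail / length(counts)
  graphics::lines(xs, scale * powerlaw_tail(xs, x$alpha, x$xmin), col = 2)
  graphics::abline(v = x$xmin, lty = 3)
  invisible(x)
}

#' Expected number of clones at or above a count under the fitted null
#'
#' The e-value of an abundance \eqn{x} is the number of clones in the fitted
#' range multiplied by the null tail probability:
#' \eqn{e(x) = n_{tail} \cdot P(X \ge x)}. Small e-values mark abundances
#' too extreme for the power-law background.
#'
#' @param count integer count(s), each >= \code{fit$xmin}.
#' @param fit a \code{"powerlaw_fit"}.
#' @return nonnegative numeric vector.
#' @examples
#' set.seed(1)
#' fit <- fit_powerlaw(rpowerlaw(500, 2.5))
#' clone_evalue(max(rpowerlaw(500, 2.5)), fit)
#' @export
clone_evalue <- function(count, fit) {
  stopifnot(inherits(fit, "powerlaw_fit"))
  if (any(count < fit$xmin))
    stop("clone_evalue: count below the fitted xmin has no e-value")
  fit$n_tail * powerlaw_tail(count, fit$alpha, fit$xmin)
}
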