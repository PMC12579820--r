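# Reference values for the Hurwitz zeta computed independently with
# scipy.special.zeta (mpmath-backed), frozen here.
scipy_zeta <- data.frame(
  s = c(2, 2.5, 2.5, 1.5, 3.7, 1.01, 20, 2),
  a = c(1, 1, 5, 3, 12, 1, 2, 100),
  z = c(1.6449340668482266, 1.3414872572509176, 0.06931053204432189,
        1.2588219580922144, 0.0005051158675789875, 100.5779433384968,
        9.53962033872796e-07, 0.010050166663333573))

test_that("Hurwitz zeta matches an independent reference to near machine precision", {
  for (i in seq_len(nrow(scipy_zeta)))
    expect_equal(hurwitz_zeta(scipy_zeta$s[i], scipy_zeta$a[i]),
                 scipy_zeta$z[i], tolerance = 1e-13)
  expect_equal(hurwitz_zeta(2, 1), pi^2 / 6, tolerance = 1e-14)
  expect_error(hurwitz_zeta(1, 1), "> 1")
  expect_error(hurwitz_zeta(2, -1), "positive")
})

test_that("discrete power-law tail has closed-form values and unit normalization", {
  expect_equal(powerlaw_tail(1, 2, 1), 1.0)
  expect_equal(powerlaw_tail(2, 2, 1), 1 - 6 / pi^2, tolerance = 1e-9)
  expect_equal(powerlaw_tail(5, 2.5, 5), 1.0)
  # pmf sums to 1: telescoping check over a truncated support
  for (alpha in c(1.5, 2.5, 4)) {
    x <- 1:2000
    pmf <- x^(-alpha) / hurwitz_zeta(alpha, 1)
    expect_equal(sum(pmf) + powerlaw_tail(2001, alpha, 1), 1,
                 tolerance = 1e-9)
  }
  # strictly decreasing in x
  tail_vals <- powerlaw_tail(1:50, 2.5, 1)
  expect_true(all(diff(tail_vals) < 0))
  expect_error(powerlaw_tail(2, 1, 1), "alpha")
  expect_error(powerlaw_tail(1, 2, 3), "xmin")
})

test_that("alpha MLE matches an exhaustive grid-search oracle", {
  grid_alpha <- function(counts, xmin) {
    tail_x <- counts[counts >= xmin]
    alphas <- seq(1.01, 20, by = 1e-4)
    ll <- vapply(alphas, function(a)
      -length(tail_x) * log(hurwitz_zeta(a, xmin)) - a * sum(log(tail_x)),
      numeric(1))
    alphas[which.max(ll)]
  }
  counts <- c(1, 1, 1, 1, 2, 2, 3, 5, 1, 2)
  fit <- fit_alpha_mle(counts, xmin = 1, min_tail = 5)
  expect_equal(fit$alpha, grid_alpha(counts, 1), tolerance = 1e-3)
  set.seed(101)
  counts2 <- rpowerlaw(300, 2.2)
  fit2 <- fit_alpha_mle(counts2, xmin = 1)
  expect_equal(fit2$alpha, grid_alpha(counts2, 1), tolerance = 1e-3)
  expect_error(fit_alpha_mle(rep(3, 20), xmin = 3), "unbounded")
  expect_error(fit_alpha_mle(c(1, 2, 3), xmin = 1, min_tail = 10), "fewer")
})

test_that("xmin selection equals an exhaustive scan over valid candidates", {
  set.seed(7)
  counts <- c(rpowerlaw(180, 2.3, xmin = 2), sample(1:3, 20, replace = TRUE))
  fit <- fit_powerlaw(counts, min_tail = 10)
  # independent scan: every unique count with a big-enough non-tied tail
  cand <- sort(unique(counts))
  cand <- cand[vapply(cand, function(v)
    sum(counts >= v) >= 10 && any(counts > v), FALSE)]
  scan <- t(vapply(cand, function(v) {
    a <- fit_alpha_mle(counts, v)$alpha
    tail_x <- counts[counts >= v]
    u <- sort(unique(tail_x))
    emp <- vapply(u, function(q) mean(tail_x <= q), 0)
    ks <- max(abs(emp - (1 - powerlaw_tail(u + 1, a, v))))
    c(xmin = v, alpha = a, ks = ks)
  }, c(0, 0, 0)))
  best <- which.min(scan[, "ks"])
  expect_identical(fit$xmin, as.integer(scan[best, "xmin"]))
  expect_equal(fit$alpha, unname(scan[best, "alpha"]), tolerance = 1e-6)
  expect_equal(fit$ks_stat, unname(scan[best, "ks"]), tolerance = 1e-9)
})

test_that("fit recovers the generating exponent as n grows", {
  err <- vapply(c(1e3, 1e4, 5e4), function(n) {
    x <- rpowerlaw(n, 2.5, seed = 20260100 + n)
    abs(fit_powerlaw(x, xmin = 1)$alpha - 2.5)
  }, numeric(1))
  expect_lt(err[3], 0.05)       # +-0.05 at n = 50,000
  expect_lt(err[3], err[1])     # error shrinks with n
})

test_that("selected xmin stays near 1 on pure power-law data", {
  sel <- vapply(1:100, function(s)
    fit_powerlaw(rpowerlaw(5000, 2.5, seed = 300 + s))$xmin, integer(1))
  expect_gte(mean(sel <= 3), 0.95)
})

test_that("e-values follow the tail formula and decrease with count", {
  fit <- structure(list(alpha = 2, xmin = 1L, n_tail = 1000L,
                        ks_stat = 0, log_lik = 0, n = 1000L, scan = NULL),
                   class = "powerlaw_fit")
  expect_equal(clone_evalue(1, fit), 1000)  # tail = 1 at xmin
  expect_equal(clone_evalue(2, fit), 1000 * (1 - 6 / pi^2),
               tolerance = 1e-9)
  ev <- clone_evalue(1:100, fit)
  expect_true(all(diff(ev) < 0))
  expect_error(clone_evalue(0, fit), "below")
})

test_that("fit object supports the standard model-object verbs", {
  set.seed(5)
  x <- rpowerlaw(400, 2.5)
  fit <- fit_powerlaw(x)
  expect_named(coef(fit), c("alpha", "xmin"))
  expect_s3_class(logLik(fit), "logLik")
  expect_equal(predict(fit, fit$xmin, type = "tail"), 1)
  expect_equal(predict(fit, fit$xmin, type = "evalue"), fit$n_tail)
  sim <- simulate(fit, nsim = 50, seed = 9)
  expect_length(sim, 50)
  expect_true(all(sim >= fit$xmin))
  expect_output(print(fit), "alpha")
})
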