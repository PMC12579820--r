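# Brute-force Pearson chi-square from first principles.
chisq_brute <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(chi2 = chi2, p = pchisq(chi2, df, lower.tail = FALSE))
}

test_that("contingency builder tallies pairs in declared order and tracks drops", {
  a <- c("UDC", "IDC", "IDC")
  b <- c("<10", ">=10", ">=10")
  tab <- build_contingency(a, b, levels_a = c("UDC", "IDC", "CDC"),
                           levels_b = c("<10", ">=10"))
  expect_equal(as.vector(tab), c(1, 0, 0, 0, 2, 0))
  expect_equal(dimnames(tab), list(c("UDC", "IDC", "CDC"), c("<10", ">=10")))
  expect_equal(attr(tab, "n_dropped"), 0L)
  tab2 <- build_contingency(c("UDC", NA, "IDC", "CDC"),
                            c("<10", "<10", NA, ">=10"))
  expect_equal(attr(tab2, "n_dropped"), 2L)
  expect_equal(sum(tab2), 2)
  expect_error(build_contingency(c(NA, "x"), c("y", NA)), "no complete pairs")
})

test_that("Pearson chi-square agrees with the first-principles formula", {
  set.seed(23)
  for (i in 1:25) {
    tab <- matrix(rpois(6, 20) + 1, nrow = 3)
    res <- chi_square_independence(tab)
    ref <- chisq_brute(tab)
    expect_equal(res$chi2, ref$chi2, tolerance = 1e-10)
    expect_equal(res$p_value, ref$p, tolerance = 1e-10)
    expect_equal(res$df, 2L)
  }
  # perfectly proportional table: no association
  res0 <- chi_square_independence(matrix(c(10, 10, 10, 10), 2))
  expect_equal(res0$chi2, 0)
  expect_equal(res0$p_value, 1)
  expect_error(chi_square_independence(matrix(c(1, 2, 0, 0), 2)),
               "zero margin")
})

test_that("published clonotype association p-values are reproduced from their tables", {
  # rows UDC / IDC / CDC, columns = covariate levels
  age <- matrix(c(5, 10, 46, 25, 36, 14), nrow = 3, byrow = TRUE)
  mrd <- matrix(c(6, 8, 28, 42, 18, 31), nrow = 3, byrow = TRUE)
  sex <- matrix(c(6, 9, 36, 35, 30, 20), nrow = 3, byrow = TRUE)
  wbc <- matrix(c(9, 6, 46, 25, 29, 21), nrow = 3, byrow = TRUE)
  expect_equal(round(chi_square_independence(age)$p_value, 2), 0.02)
  expect_equal(round(chi_square_independence(mrd)$p_value, 2), 0.89)
  expect_equal(round(chi_square_independence(sex)$p_value, 2), 0.34)
  expect_equal(round(chi_square_independence(wbc)$p_value, 2), 0.74)
})

test_that("Mann-Whitney p matches exact enumeration on small samples", {
  # independent oracle: enumerate all assignments of ranks to group a
  mw_exact <- function(a, b) {
    pooled <- c(a, b)
    n_a <- length(a)
    u_obs <- sum(rank(pooled)[seq_len(n_a)]) - n_a * (n_a + 1) / 2
    combos <- combn(length(pooled), n_a)
    u_all <- apply(combos, 2, function(idx)
      sum(rank(pooled)[idx]) - n_a * (n_a + 1) / 2)
    mean(abs(u_all - n_a * length(b) / 2) >= abs(u_obs - n_a * length(b) / 2))
  }
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6)),
               mw_exact(c(1, 2, 3), c(4, 5, 6)))
  set.seed(61)
  for (i in 1:10) {
    a <- sample(seq(0.1, 100, by = 0.1), 4)
    b <- sample(setdiff(seq(0.1, 100, by = 0.1), a), 5)
    expect_equal(mann_whitney_u(a, b), mw_exact(a, b))
  }
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(mann_whitney_u(c(1, 5, 9), c(2, 4, 8)),
               mann_whitney_u(c(2, 4, 8), c(1, 5, 9)))
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("Kruskal-Wallis handles ties, symmetry and the two-group asymptotic case", {
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3))), 1.0)
  set.seed(62)
  g <- list(rnorm(30), rnorm(30, 0.5), rnorm(30, 1))
  expect_equal(kruskal_wallis(g), kruskal_wallis(rev(g)))
  # two groups at large n: agrees with the Mann-Whitney normal approximation
  a <- rnorm(200, 0, 1); b <- rnorm(200, 0.2, 1)
  expect_equal(kruskal_wallis(list(a, b)), mann_whitney_u(a, b),
               tolerance = 0.01)
  expect_error(kruskal_wallis(list(1:3)), ">= 2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "empty")
})

test_that("cohort association runs one chi-square per covariate with pairwise deletion", {
  set.seed(63)
  n <- 120
  clono <- data.frame(
    patient_id = sprintf("P%03d", 1:n),
    label = sample(c("UDC", "IDC", "CDC"), n, TRUE, c(0.2, 0.4, 0.4)))
  meta <- data.frame(
    patient_id = sprintf("P%03d", 1:n),
    age_group = sample(c("<10", ">=10"), n, TRUE),
    mrd_status = replace(sample(c("Pos", "Neg"), n, TRUE),
                         sample(n, 3), NA))
  res <- cohort_association(clono, meta)
  expect_equal(res$covariate, c("age_group", "mrd_status"))
  expect_equal(res$n_used[2], n - 3)
  expect_equal(res$n_dropped[2], 3L)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  tabs <- attr(res, "tables")
  expect_equal(chi_square_independence(tabs$age_group)$p_value,
               res$p_value[1])
})
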