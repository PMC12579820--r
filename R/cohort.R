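#' Cross-tabulate two categorical vectors
#'
#' Builds the contingency table of two paired categorical variables (e.g.
#' clonotype against an age group). Pairs with a missing value in either
#' variable are dropped and counted; rows and columns follow the declared
#' category orders.
#'
#' @param labels_a,labels_b equal-length vectors (e.g. per-patient
#'   clonotype and covariate).
#' @param levels_a,levels_b category orders (default: sorted unique
#'   observed values).
#' @return integer matrix with a \code{"n_dropped"} attribute.
#' @export
build_contingency <- function(labels_a, labels_b,
                              levels_a = NULL, levels_b = NULL) {
  if (length(labels_a) != length(labels_b))
    stop("build_contingency: inputs must have equal length")
  keep <- !is.na(labels_a) & !is.na(labels_b)
  if (!any(keep))
    stop("build_contingency: no complete pairs after dropping missing values")
  if (is.null(levels_a)) levels_a <- sort(unique(labels_a[keep]))
  if (is.null(levels_b)) levels_b <- sort(unique(labels_b[keep]))
  tab <- table(factor(labels_a[keep], levels = levels_a),
               factor(labels_b[keep], levels = levels_b))
  m <- matrix(as.integer(tab), nrow = length(levels_a),
              dimnames = list(levels_a, levels_b))
  attr(m, "n_dropped") <- sum(!keep)
  m
}

#' Pearson chi-square test of independence
#'
#' Classic Pearson statistic \eqn{\chi^2 = \sum (O - E)^2 / E} with
#' expected counts from the margins and the upper chi-square tail at
#' \eqn{df = (r-1)(c-1)}. No continuity correction is applied (the
#' clonotype tables are 3 x 2, where the Yates correction does not apply).
#'
#' @param table r x c matrix of nonnegative integer counts, r, c >= 2, all
#'   row and column sums positive.
#' @return object of class \code{"contingency_result"}: list with
#'   \code{table}, \code{chi2}, \code{df}, \code{p_value}, \code{expected},
#'   \code{n_dropped}.
#' @examples
#' age <- matrix(c(5, 10, 46, 25, 36, 14), nrow = 3, byrow = TRUE,
#'               dimnames = list(c("UDC", "IDC", "CDC"), c("<10", ">=10")))
#' chi_square_independence(age)
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L)
    stop("chi_square_independence: need at least a 2 x 2 table")
  if (any(table < 0)) stop("chi_square_independence: negative cell count")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("chi_square_independence: zero margin; drop the empty category")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  res <- list(table = table, chi2 = unname(ct$statistic),
              df = unname(ct$parameter), p_value = ct$p.value,
              expected = ct$expected,
              n_dropped = attr(table, "n_dropped"))
  class(res) <- "contingency_result"
  res
}

#' @export
print.contingency_result <- function(x, ...) {
  print(x$table)
  cat(sprintf("chi-square = %.4f, df = %d, p = %.4g\n",
              x$chi2, x$df, x$p_value))
  if (!is.null(x$n_dropped) && x$n_dropped > 0)
    cat(sprintf("(%d pairs with missing values dropped)\n", x$n_dropped))
  invisible(x)
}

#' Two-sided Mann-Whitney U test
#'
#' Rank test for a location difference between two groups. The exact null
#' distribution is enumerated for small samples (\eqn{n_a + n_b \le 12})
#' without ties; otherwise the normal approximation with tie correction is
#' used.
#'
#' @param a,b numeric vectors, both non-empty.
#' @return two-sided p-value.
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L)
    stop("mann_whitney_u: both groups must be non-empty")
  has_ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- (length(a) + length(b) <= 12L) && !has_ties
  stats::wilcox.test(a, b, alternative = "two.sided", exact = use_exact,
                     correct = FALSE)$p.value
}

#' Kruskal-Wallis rank test across groups
#'
#' H statistic with tie correction, referred to the chi-square distribution
#' with k - 1 degrees of freedom.
#'
#' @param groups list of two or more non-empty numeric vectors.
#' @return p-value.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("kruskal_wallis: need a list of >= 2 groups")
  if (any(lengths(groups) == 0L))
    stop("kruskal_wallis: empty group")
  stats::kruskal.test(groups)$p.value
}

#' Clonotype-by-covariate association table
#'
#' For each covariate column, cross-tabulates clonotype labels against the
#' covariate (missing values dropped pairwise) and runs the Pearson
#' chi-square test — the cohort-level association analysis between
#' clonotypes and patient characteristics.
#'
#' @param clonotypes data frame with \code{patient_id} and \code{label}
#'   (one row per patient; e.g. stacked [classify_clonotype()] rows plus a
#'   patient id).
#' @param metadata data frame from [read_metadata()].
#' @param covariates covariate column names (default: all metadata columns
#'   except identifiers).
#' @return data frame with one row per covariate: \code{covariate},
#'   \code{chi2}, \code{df}, \code{p_value}, \code{n_used},
#'   \code{n_dropped}; the tables themselves are in the \code{"tables"}
#'   attribute.
#' @export
cohort_association <- function(clonotypes, metadata, covariates = NULL) {
  stopifnot(all(c("patient_id", "label") %in% names(clonotypes)),
            "patient_id" %in% names(metadata))
  if (is.null(covariates))
    covariates <- setdiff(names(metadata), c("patient_id", "sample_id",
                                             "timepoint"))
  m <- match(clonotypes$patient_id, metadata$patient_id)
  rows <- lapply(covariates, function(cov) {
    # an untestable covariate (e.g. a single observed level) yields NA,
    # never an aborted cohort run
    out <- tryCatch({
      tab <- build_contingency(clonotypes$label, metadata[[cov]][m],
                               levels_a = intersect(c("UDC", "IDC", "CDC"),
                                                    unique(clonotypes$label)))
      ct <- chi_square_independence(tab)
      list(row = data.frame(covariate = cov, chi2 = ct$chi2, df = ct$df,
                            p_value = ct$p_value, n_used = sum(tab),
                            n_dropped = attr(tab, "n_dropped"),
                            stringsAsFactors = FALSE),
           table = tab)
    }, error = function(e)
      list(row = data.frame(covariate = cov, chi2 = NA_real_,
                            df = NA_integer_, p_value = NA_real_,
                            n_used = NA_integer_, n_dropped = NA_integer_,
                            stringsAsFactors = FALSE),
           table = NULL))
    out
  })
  out <- do.call(rbind, lapply(rows, `[[`, "row"))
  attr(out, "tables") <- stats::setNames(lapply(rows, `[[`, "table"),
                                         covariates)
  out
}
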