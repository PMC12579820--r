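#' Shannon entropy of clone abundances
#'
#' \eqn{H = -\sum_i p_i \log_b p_i} over clone frequencies
#' \eqn{p_i = x_i / \sum x}. Measures repertoire diversity: 0 for a
#' monoclonal sample, \eqn{\log_b n} for a perfectly even one.
#'
#' @param counts nonnegative abundance vector with at least one positive
#'   entry; zeros are dropped (they carry no mass).
#' @param base logarithm base (default 2, i.e. bits).
#' @return nonnegative scalar.
#' @examples
#' shannon_entropy(c(5, 5, 5, 5))  # 2 bits
#' shannon_entropy(c(2, 1, 1))     # 1.5 bits
#' @export
shannon_entropy <- function(counts, base = 2) {
  if (length(counts) == 0L || any(counts < 0) || sum(counts) <= 0)
    stop("shannon_entropy: need a nonnegative vector with positive sum")
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = base))
}

#' Align two repertoires on clone identity
#'
#' Clones are matched across samples by the identity rule used throughout:
#' two clones are the same rearrangement when their DJ junction sequences
#' match within the same junction class. COMPLETE and ONGOING clones share
#' class \code{VDJ} (an ongoing clone is a set of complete rearrangements
#' on one DJ stem); INCOMPLETE clones form class \code{DJ}. Within one
#' repertoire, clones mapping to the same key have their counts summed.
#'
#' @param rep1,rep2 repertoires (conventionally diagnosis and relapse).
#' @return data frame over the union of identity keys with columns
#'   \code{key}, \code{class}, \code{dj_junction}, \code{x} (counts in
#'   \code{rep1}) and \code{y} (counts in \code{rep2}); zero where a key is
#'   absent from a sample.
#' @export
align_by_identity <- function(rep1, rep2) {
  validate_repertoire(rep1)
  validate_repertoire(rep2)
  key_of <- function(cl) {
    class <- ifelse(cl$rearrangement_type == "INCOMPLETE", "DJ", "VDJ")
    paste(class, cl$dj_junction, sep = ":")
  }
  k1 <- key_of(rep1$clones); k2 <- key_of(rep2$clones)
  x1 <- tapply(rep1$clones$read_count, k1, sum)
  x2 <- tapply(rep2$clones$read_count, k2, sum)
  keys <- sort(union(names(x1), names(x2)))
  data.frame(key = keys,
             class = sub(":.*$", "", keys),
             dj_junction = sub("^[^:]*:", "", keys),
             x = ifelse(keys %in% names(x1), x1[keys], 0),
             y = ifelse(keys %in% names(x2), x2[keys], 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Morisita-Horn similarity between two abundance vectors
#'
#' \deqn{MH = \frac{2 \sum_i x_i y_i}{(d_x + d_y) X Y}, \quad
#'   d_x = \sum x_i^2 / X^2, \; d_y = \sum y_i^2 / Y^2}
#' with \eqn{X = \sum x}, \eqn{Y = \sum y}. An abundance-weighted overlap in
#' [0, 1]: 1 for identical relative compositions, 0 for disjoint supports.
#' Vectors must be aligned index-by-index (see [align_by_identity()]).
#'
#' @param x,y nonnegative abundance vectors of equal length, each with a
#'   positive sum. \code{x} may also be the data frame returned by
#'   [align_by_identity()], in which case \code{y} is taken from it.
#' @return similarity in [0, 1].
#' @examples
#' morisita_horn(c(2, 1, 0), c(0, 1, 2))  # 0.2
#' @export
morisita_horn <- function(x, y = NULL) {
  if (is.data.frame(x)) { y <- x$y; x <- x$x }
  if (length(x) != length(y))
    stop("morisita_horn: 'x' and 'y' must have equal length")
  if (any(x < 0) || any(y < 0))
    stop("morisita_horn: abundances must be nonnegative")
  X <- sum(x); Y <- sum(y)
  if (X <= 0 || Y <= 0)
    stop("morisita_horn: each vector needs a positive sum")
  d_x <- sum(x^2) / X^2
  d_y <- sum(y^2) / Y^2
  2 * sum(x * y) / ((d_x + d_y) * X * Y)
}
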