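#' Group complete clones by their DJ junction
#'
#' Exact string grouping of COMPLETE clones on \code{dj_junction}.
#' INCOMPLETE (and any other) clones are excluded. Groups are ordered by
#' descending size, then junction lexicographically.
#'
#' @param rep an \code{"igh_repertoire"}.
#' @return list of groups, each a list with \code{dj_junction},
#'   \code{rows} (row indices into \code{rep$clones}) and \code{k} (size).
#' @export
index_by_dj <- function(rep) {
  validate_repertoire(rep)
  idx <- which(rep$clones$rearrangement_type == "COMPLETE")
  if (length(idx) == 0L) return(list())
  by_junction <- split(idx, rep$clones$dj_junction[idx])
  ord <- order(-lengths(by_junction), names(by_junction), method = "radix")
  lapply(names(by_junction)[ord], function(j) {
    list(dj_junction = j, rows = by_junction[[j]],
         k = length(by_junction[[j]]))
  })
}

#' Poisson tail probability for a shared-junction group
#'
#' Under the null that complete clones land on junctions independently and
#' uniformly, the number of clones sharing one junction is approximately
#' Poisson with rate \code{lam}; the test statistic for a group of size
#' \code{k} is the upper tail \eqn{P(X \ge k)}.
#'
#' @param k observed group size, integer >= 0.
#' @param lam Poisson rate (expected clones per junction), > 0.
#' @return probability in [0, 1].
#' @examples
#' poisson_group_pvalue(6, 1.25)   # 0.0018...
#' @export
poisson_group_pvalue <- function(k, lam) {
  if (any(k < 0)) stop("poisson_group_pvalue: 'k' must be >= 0")
  if (!is.finite(lam) || lam <= 0)
    stop("poisson_group_pvalue: 'lam' must be finite and positive")
  stats::ppois(k - 1, lam, lower.tail = FALSE)
}

#' Merge complete clones sharing a DJ junction into ongoing clones
#'
#' Several distinct V segments rearranged onto the same DJ stem appear in a
#' clone table as multiple COMPLETE clones with an identical DJ junction.
#' For each such group of size \eqn{k \ge 2} this tests whether the sharing
#' is explicable by chance under a Poisson null with rate
#' \eqn{\lambda = C / D}, where \eqn{C} is the number of COMPLETE clones in
#' the sample and \eqn{D} the number of distinct junctions among them. When
#' \eqn{P(X \ge k) <} \code{p_threshold} the group is collapsed into one
#' ONGOING clone: its read count is the sum over members, its
#' \code{member_v_calls} the sorted distinct member V calls, and its
#' \code{clone_id} that of the most abundant member. Groups that fail the
#' test are left as separate COMPLETE clones; total reads are conserved.
#'
#' @param rep an \code{"igh_repertoire"} with no ONGOING clones (merging is
#'   one-shot; re-merging a merged repertoire is a state error).
#' @param p_threshold Poisson p-value threshold (default 0.01).
#' @return a new \code{"igh_repertoire"}.
#' @export
merge_ongoing <- function(rep, p_threshold = 0.01) {
  validate_repertoire(rep)
  if (any(rep$clones$rearrangement_type == "ONGOING"))
    stop("merge_ongoing: input already contains ONGOING clones")
  complete <- rep$clones$rearrangement_type == "COMPLETE"
  n_complete <- sum(complete)
  groups <- index_by_dj(rep)
  if (n_complete == 0L || length(groups) == 0L) return(rep)
  lam <- n_complete / length(groups)
  drop_rows <- integer(0)
  merged <- list()
  for (g in groups) {
    if (g$k < 2L) break  # groups are sorted by descending size
    if (poisson_group_pvalue(g$k, lam) >= p_threshold) next
    members <- rep$clones[g$rows, ]
    # an ongoing rearrangement needs several V segments on one DJ stem
    if (length(unique(members$v_call)) < 2L) next
    lead <- order(-members$read_count, members$clone_id)[1L]
    merged[[length(merged) + 1L]] <- data.frame(
      clone_id = members$clone_id[lead],
      v_call = NA_character_,
      d_call = members$d_call[lead],
      j_call = members$j_call[lead],
      dj_junction = g$dj_junction,
      read_count = sum(members$read_count),
      rearrangement_type = "ONGOING",
      member_v_calls = paste(sort(unique(members$v_call)), collapse = ","),
      stringsAsFactors = FALSE)
    drop_rows <- c(drop_rows, g$rows)
  }
  if (length(drop_rows) == 0L) return(rep)
  clones <- rbind(rep$clones[-drop_rows, ], do.call(rbind, merged))
  igh_repertoire(clones, sample_id = rep$sample_id,
                 patient_id = rep$patient_id, timepoint = rep$timepoint)
}
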