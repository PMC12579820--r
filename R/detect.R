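#' Call disease clones as power-law outliers
#'
#' Fits the per-sample discrete power-law background to all clone
#' abundances (complete, ongoing and incomplete pooled) with
#' [fit_powerlaw()], then scores every clone in the fitted range by its
#' e-value \eqn{e = n_{tail} \cdot P(X \ge x)} — the expected number of
#' clones at least that abundant under the null. A clone is a DISEASE clone
#' when \eqn{e <} \code{e_threshold}; otherwise MINOR. Clones below the
#' fitted lower boundary are outside the modelled range and get status
#' BELOW_RANGE with an undefined e-value; they can never be DISEASE.
#'
#' When the background cannot be fit (too few clones, or a degenerate tail
#' of identical counts) the sample is reported unfit: no calls are made and
#' downstream classification treats it as having no detectable disease
#' clone.
#'
#' @param rep an \code{"igh_repertoire"}, typically after
#'   [merge_ongoing()].
#' @param e_threshold e-value threshold for a DISEASE call (default 0.01).
#' @param min_tail minimum tail size for the power-law fit (default 10).
#' @return an object of class \code{"disease_calls"}: a list with
#'   \code{sample_id}, \code{fit} (a \code{"powerlaw_fit"} or \code{NULL}),
#'   \code{unfit} (logical), \code{fit_error} (message when unfit) and
#'   \code{calls} — a data frame with one row per clone (zero rows when
#'   unfit): \code{clone_id}, \code{read_count}, \code{rearrangement_type},
#'   \code{e_value} (\code{NA} below range) and \code{status}.
#' @examples
#' rep <- generate_repertoire(sim_config(n_clones = 300, seed = 7,
#'   disease_spec = list(list(type = "COMPLETE", target_e = 1e-6))))$repertoire
#' calls <- call_disease_clones(rep)
#' calls
#' @export
call_disease_clones <- function(rep, e_threshold = 0.01, min_tail = 10L) {
  validate_repertoire(rep)
  if (e_threshold <= 0 || e_threshold >= 1)
    stop("call_disease_clones: 'e_threshold' must be in (0, 1)")
  empty <- data.frame(clone_id = character(), read_count = integer(),
                      rearrangement_type = character(), e_value = numeric(),
                      status = character(), stringsAsFactors = FALSE)
  fit <- tryCatch(fit_powerlaw(rep$clones$read_count, min_tail = min_tail),
                  error = function(e) e)
  if (inherits(fit, "error")) {
    res <- list(sample_id = rep$sample_id, fit = NULL, unfit = TRUE,
                fit_error = conditionMessage(fit), calls = empty)
    class(res) <- "disease_calls"
    return(res)
  }
  cl <- rep$clones
  in_range <- cl$read_count >= fit$xmin
  e_value <- rep.int(NA_real_, nrow(cl))
  e_value[in_range] <- clone_evalue(cl$read_count[in_range], fit)
  status <- ifelse(!in_range, "BELOW_RANGE",
                   ifelse(e_value < e_threshold, "DISEASE", "MINOR"))
  res <- list(sample_id = rep$sample_id, fit = fit, unfit = FALSE,
              fit_error = NA_character_,
              calls = data.frame(clone_id = cl$clone_id,
                                 read_count = cl$read_count,
                                 rearrangement_type = cl$rearrangement_type,
                                 e_value = e_value, status = status,
                                 stringsAsFactors = FALSE))
  class(res) <- "disease_calls"
  res
}

#' @export
print.disease_calls <- function(x, ...) {
  cat(sprintf("Disease-clone calls for sample '%s'\n", x$sample_id))
  if (x$unfit) {
    cat("  background fit failed:", x$fit_error, "\n")
    return(invisible(x))
  }
  cat(sprintf("  background: alpha = %.3f, xmin = %d, n_tail = %d\n",
              x$fit$alpha, x$fit$xmin, x$fit$n_tail))
  n_dis <- sum(x$calls$status == "DISEASE")
  cat(sprintf("  %d of %d clones called DISEASE\n", n_dis, nrow(x$calls)))
  if (n_dis > 0) {
    d <- x$calls[x$calls$status == "DISEASE", ]
    d <- d[order(d$e_value), ]
    print(d, row.names = FALSE)
  }
  invisible(x)
}

#' Classify a sample into the UDC / IDC / CDC clonotype
#'
#' Patient-level clonotype from the sample's disease-clone calls:
#' \describe{
#'   \item{UDC}{undetectable disease clone — no DISEASE call (including
#'     samples where the background fit failed, flagged \code{unfit}).}
#'   \item{IDC}{incomplete disease clone — at least one DISEASE call on an
#'     INCOMPLETE rearrangement; the presence of an incomplete disease
#'     clone dominates any complete ones.}
#'   \item{CDC}{complete disease clone — one or more DISEASE calls, all on
#'     COMPLETE or ONGOING rearrangements.}
#' }
#' The three rules are mutually exclusive and exhaustive.
#'
#' @param calls a \code{"disease_calls"} object.
#' @param rep the repertoire the calls were made on (consistency-checked).
#' @return one-row data frame: \code{sample_id}, \code{label},
#'   \code{n_disease}, \code{n_complete}, \code{n_ongoing},
#'   \code{n_incomplete} (DISEASE calls by rearrangement type) and
#'   \code{unfit}.
#' @export
classify_clonotype <- function(calls, rep = NULL) {
  stopifnot(inherits(calls, "disease_calls"))
  if (!is.null(rep)) {
    validate_repertoire(rep)
    unknown <- setdiff(calls$calls$clone_id, rep$clones$clone_id)
    if (length(unknown))
      stop("classify_clonotype: call references unknown clone_id '",
           unknown[1L], "'")
  }
  disease <- calls$calls[calls$calls$status == "DISEASE", ]
  by_type <- table(factor(disease$rearrangement_type,
                          levels = c("COMPLETE", "ONGOING", "INCOMPLETE")))
  n_disease <- nrow(disease)
  label <- if (n_disease == 0L) "UDC"
           else if (by_type[["INCOMPLETE"]] >= 1L) "IDC"
           else "CDC"
  data.frame(sample_id = calls$sample_id, label = label,
             n_disease = n_disease,
             n_complete = as.integer(by_type[["COMPLETE"]]),
             n_ongoing = as.integer(by_type[["ONGOING"]]),
             n_incomplete = as.integer(by_type[["INCOMPLETE"]]),
             unfit = calls$unfit, stringsAsFactors = FALSE)
}
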