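#' Classify a diagnosis-to-relapse clone trajectory
#'
#' Per-clone evolution pattern from the pair of statuses at the two
#' timepoints (each one of \code{DISEASE}, \code{MINOR},
#' \code{BELOW_RANGE}, \code{ABSENT}):
#' \describe{
#'   \item{A}{a disease clone at diagnosis that persisted as a disease
#'     clone at relapse.}
#'   \item{B}{a disease clone at diagnosis that shrank to a minor clone or
#'     became undetectable at relapse.}
#'   \item{C}{a minor or undetectable clone at diagnosis that expanded or
#'     newly emerged as a disease clone at relapse.}
#'   \item{NONE}{neither endpoint is a disease clone.}
#' }
#' MINOR, BELOW_RANGE and ABSENT all count as "minor or undetectable"; the
#' finer status is kept in the trajectory table for audit. The function is
#' total over all 16 status pairs, and swapping the timepoints maps B to C
#' and back while fixing A and NONE.
#'
#' @param diag_status,rel_status status strings. Vectorized.
#' @return character vector over \{"A", "B", "C", "NONE"\}.
#' @export
evolution_pattern <- function(diag_status, rel_status) {
  ok <- c("DISEASE", "MINOR", "BELOW_RANGE", "ABSENT")
  if (!all(diag_status %in% ok) || !all(rel_status %in% ok))
    stop("evolution_pattern: unknown status")
  ifelse(diag_status == "DISEASE" & rel_status == "DISEASE", "A",
    ifelse(diag_status == "DISEASE", "B",
      ifelse(rel_status == "DISEASE", "C", "NONE")))
}

#' Build clone trajectories between diagnosis and relapse
#'
#' Matches clones across the two timepoints by identity key (DJ junction
#' within junction class, [align_by_identity()]) and emits one trajectory
#' per key that is a DISEASE clone at either timepoint. A key absent from a
#' sample has status ABSENT there; otherwise the status comes from that
#' sample's disease-clone calls (when several clones share one key, the
#' most significant status — DISEASE over MINOR over BELOW_RANGE — is
#' used).
#'
#' @param diag_rep,diag_calls diagnosis repertoire and its
#'   \code{"disease_calls"}.
#' @param rel_rep,rel_calls relapse repertoire and its calls.
#' @return data frame: \code{key}, \code{class}, \code{dj_junction},
#'   \code{diag_count}, \code{rel_count}, \code{diag_status},
#'   \code{rel_status}, \code{pattern}.
#' @export
build_trajectories <- function(diag_rep, diag_calls, rel_rep, rel_calls) {
  stopifnot(inherits(diag_calls, "disease_calls"),
            inherits(rel_calls, "disease_calls"))
  if (diag_rep$patient_id != rel_rep$patient_id)
    stop("build_trajectories: samples belong to different patients ('",
         diag_rep$patient_id, "' vs '", rel_rep$patient_id, "')")
  aligned <- align_by_identity(diag_rep, rel_rep)
  key_status <- function(rep, calls) {
    if (calls$unfit || nrow(calls$calls) == 0L)
      return(stats::setNames(rep.int("MINOR", 0), character()))
    class <- ifelse(rep$clones$rearrangement_type == "INCOMPLETE",
                    "DJ", "VDJ")
    key <- paste(class, rep$clones$dj_junction, sep = ":")
    status <- calls$calls$status[match(rep$clones$clone_id,
                                       calls$calls$clone_id)]
    rank <- c(DISEASE = 1, MINOR = 2, BELOW_RANGE = 3)
    best <- tapply(rank[status], key, min)
    stats::setNames(names(rank)[best], names(best))
  }
  s1 <- key_status(diag_rep, diag_calls)
  s2 <- key_status(rel_rep, rel_calls)
  diag_status <- ifelse(aligned$x == 0, "ABSENT",
                        unname(s1[aligned$key]))
  rel_status <- ifelse(aligned$y == 0, "ABSENT",
                       unname(s2[aligned$key]))
  # a present key with no call means the sample was unfit: nothing detected
  diag_status[is.na(diag_status)] <- "MINOR"
  rel_status[is.na(rel_status)] <- "MINOR"
  keep <- diag_status == "DISEASE" | rel_status == "DISEASE"
  out <- data.frame(key = aligned$key[keep], class = aligned$class[keep],
                    dj_junction = aligned$dj_junction[keep],
                    diag_count = aligned$x[keep], rel_count = aligned$y[keep],
                    diag_status = diag_status[keep],
                    rel_status = rel_status[keep],
                    stringsAsFactors = FALSE)
  out$pattern <- evolution_pattern(out$diag_status, out$rel_status)
  rownames(out) <- NULL
  out
}

#' Summarize one patient's diagnosis-to-relapse comparison
#'
#' Runs the full matched comparison for one patient: clone trajectories
#' with A/B/C patterns, the Morisita-Horn overlap of the two repertoires
#' (over all clones), the clonotype at each timepoint, and two summary
#' flags — \code{clonality_changed}, true when any pattern B or C clone is
#' present (the clonal composition of the disease shifted), and
#' \code{clonotype_changed}, true when the UDC/IDC/CDC label differs
#' between timepoints.
#'
#' @param diag_rep,rel_rep diagnosis and relapse repertoires (same
#'   patient), already merged.
#' @param e_threshold,min_tail passed to [call_disease_clones()].
#' @return an object of class \code{"patient_comparison"}: a list with
#'   \code{patient_id}, \code{morisita_horn}, \code{trajectories},
#'   \code{patterns_present}, \code{clonotype_diag}, \code{clonotype_rel},
#'   \code{clonotype_changed}, \code{clonality_changed}, and the two
#'   \code{"disease_calls"} objects.
#' @export
summarize_patient <- function(diag_rep, rel_rep, e_threshold = 0.01,
                              min_tail = 10L) {
  if (diag_rep$patient_id != rel_rep$patient_id)
    stop("summarize_patient: samples belong to different patients")
  diag_calls <- call_disease_clones(diag_rep, e_threshold, min_tail)
  rel_calls <- call_disease_clones(rel_rep, e_threshold, min_tail)
  traj <- build_trajectories(diag_rep, diag_calls, rel_rep, rel_calls)
  patterns <- sort(unique(traj$pattern[traj$pattern != "NONE"]))
  res <- list(
    patient_id = diag_rep$patient_id,
    morisita_horn = morisita_horn(align_by_identity(diag_rep, rel_rep)),
    trajectories = traj,
    patterns_present = patterns,
    clonotype_diag = classify_clonotype(diag_calls, diag_rep)$label,
    clonotype_rel = classify_clonotype(rel_calls, rel_rep)$label,
    diag_calls = diag_calls, rel_calls = rel_calls)
  res$clonotype_changed <- res$clonotype_diag != res$clonotype_rel
  res$clonality_changed <- any(c("B", "C") %in% patterns)
  class(res) <- "patient_comparison"
  res
}

#' @export
print.patient_comparison <- function(x, ...) {
  cat(sprintf("Patient '%s': diagnosis vs relapse\n", x$patient_id))
  cat(sprintf("  Morisita-Horn overlap  %.3f\n", x$morisita_horn))
  cat(sprintf("  clonotype  %s -> %s%s\n", x$clonotype_diag, x$clonotype_rel,
              if (x$clonotype_changed) "  (changed)" else ""))
  cat(sprintf("  %d disease-clone trajectories; patterns: %s\n",
              nrow(x$trajectories),
              if (length(x$patterns_present))
                paste(x$patterns_present, collapse = ", ") else "none"))
  cat(sprintf("  clonality changed: %s\n",
              if (x$clonality_changed) "yes (pattern B/C present)" else "no"))
  invisible(x)
}
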