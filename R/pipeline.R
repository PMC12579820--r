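#' Run the full IGH clonality analysis
#'
#' End-to-end orchestration over a set of samples: merge ongoing
#' rearrangements, fit the power-law background and call disease clones,
#' classify clonotypes, compute Shannon entropy; then, where both
#' timepoints of a patient are present, the diagnosis/relapse comparison
#' (Morisita-Horn overlap, A/B/C patterns, clonotype shift); and, when
#' metadata are supplied, the clonotype-by-covariate association tests.
#' A failure in one sample (e.g. an unfittable background) marks that
#' sample unfit and never aborts the cohort run.
#'
#' All stages are deterministic functions of the inputs and parameters;
#' re-running reproduces identical outputs.
#'
#' @param samples named list of \code{"igh_repertoire"} objects, or a
#'   character vector of clone-table paths read with [read_clone_table()].
#' @param metadata optional data frame from [read_metadata()].
#' @param format clone-table dialect when \code{samples} are paths.
#' @param p_threshold Poisson threshold for [merge_ongoing()].
#' @param e_threshold e-value threshold for [call_disease_clones()].
#' @param min_tail minimum power-law tail size.
#' @param entropy_base logarithm base for [shannon_entropy()].
#' @param output_dir optional directory; when given, per-sample and
#'   per-patient tables are written as TSV and the run manifest as JSON.
#' @return list of class \code{"ighclonal_run"}: \code{samples} (per-sample
#'   data frame: sample_id, patient_id, timepoint, clone and read counts,
#'   fit parameters, entropy, clonotype label, unfit flag), \code{calls}
#'   (named list of \code{"disease_calls"}), \code{comparisons} (named list
#'   of \code{"patient_comparison"}), \code{comparison_table},
#'   \code{cohort_tests} (from [cohort_association()], or \code{NULL}),
#'   and \code{manifest} (parameters and per-sample fit status).
#' @export
run_pipeline <- function(samples, metadata = NULL, format = "simple",
                         p_threshold = 0.01, e_threshold = 0.01,
                         min_tail = 10L, entropy_base = 2,
                         output_dir = NULL) {
  if (is.character(samples))
    samples <- stats::setNames(
      lapply(samples, read_clone_table, format = format),
      sub("\\.[^.]*$", "", basename(samples)))
  if (length(samples) == 0L)
    stop("run_pipeline: no input samples")
  if (is.null(names(samples)) || any(names(samples) == ""))
    names(samples) <- vapply(samples, `[[`, "", "sample_id")

  calls <- list()
  rows <- list()
  merged <- list()
  for (nm in names(samples)) {
    rep <- samples[[nm]]
    rep <- tryCatch(merge_ongoing(rep, p_threshold), error = function(e) rep)
    merged[[nm]] <- rep
    cl <- call_disease_clones(rep, e_threshold, min_tail)
    calls[[nm]] <- cl
    ct <- classify_clonotype(cl, rep)
    rows[[nm]] <- data.frame(
      sample_id = rep$sample_id, patient_id = rep$patient_id,
      timepoint = rep$timepoint, n_clones = nrow(rep$clones),
      total_reads = rep$total_reads,
      alpha = if (cl$unfit) NA_real_ else cl$fit$alpha,
      xmin = if (cl$unfit) NA_integer_ else cl$fit$xmin,
      n_tail = if (cl$unfit) NA_integer_ else cl$fit$n_tail,
      entropy = shannon_entropy(rep$clones$read_count, base = entropy_base),
      label = ct$label, n_disease = ct$n_disease, unfit = ct$unfit,
      stringsAsFactors = FALSE)
  }
  sample_table <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  # pair diagnosis/relapse samples of the same patient
  comparisons <- list()
  for (pid in unique(sample_table$patient_id)) {
    idx <- which(sample_table$patient_id == pid)
    tps <- sample_table$timepoint[idx]
    if (!all(c("DIAGNOSIS", "RELAPSE") %in% tps)) next
    d_nm <- names(samples)[idx[match("DIAGNOSIS", tps)]]
    r_nm <- names(samples)[idx[match("RELAPSE", tps)]]
    comparisons[[pid]] <- summarize_patient(merged[[d_nm]], merged[[r_nm]],
                                            e_threshold, min_tail)
  }
  comparison_table <- if (length(comparisons))
    do.call(rbind, lapply(comparisons, function(pc) data.frame(
      patient_id = pc$patient_id, morisita_horn = pc$morisita_horn,
      patterns = paste(pc$patterns_present, collapse = ""),
      clonotype_diag = pc$clonotype_diag, clonotype_rel = pc$clonotype_rel,
      clonotype_changed = pc$clonotype_changed,
      clonality_changed = pc$clonality_changed,
      stringsAsFactors = FALSE)))
  else NULL

  cohort_tests <- NULL
  if (!is.null(metadata)) {
    diag_rows <- sample_table[sample_table$timepoint == "DIAGNOSIS", ]
    cohort_tests <- cohort_association(
      data.frame(patient_id = diag_rows$patient_id, label = diag_rows$label,
                 stringsAsFactors = FALSE),
      metadata)
  }

  manifest <- list(
    parameters = list(p_threshold = p_threshold, e_threshold = e_threshold,
                      min_tail = min_tail, entropy_base = entropy_base),
    n_samples = length(samples),
    fit_status = stats::setNames(
      ifelse(sample_table$unfit, "unfit", "ok"), sample_table$sample_id))

  res <- list(samples = sample_table, calls = calls,
              comparisons = comparisons,
              comparison_table = comparison_table,
              cohort_tests = cohort_tests, manifest = manifest)
  class(res) <- "ighclonal_run"

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(sample_table, file.path(output_dir, "samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    all_calls <- do.call(rbind, lapply(names(calls), function(nm) {
      df <- calls[[nm]]$calls
      if (nrow(df)) cbind(sample_id = nm, df) else NULL
    }))
    if (!is.null(all_calls))
      utils::write.table(all_calls, file.path(output_dir, "calls.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(comparison_table))
      utils::write.table(comparison_table,
                         file.path(output_dir, "comparisons.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(cohort_tests))
      utils::write.table(cohort_tests, file.path(output_dir, "cohort.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  res
}

#' @export
print.ighclonal_run <- function(x, ...) {
  cat(sprintf("IGH clonality run: %d samples\n", nrow(x$samples)))
  print(table(clonotype = x$samples$label))
  if (any(x$samples$unfit))
    cat(sprintf("%d sample(s) unfit for the power-law background\n",
                sum(x$samples$unfit)))
  if (!is.null(x$comparison_table))
    cat(sprintf("%d diagnosis/relapse pairs compared\n",
                nrow(x$comparison_table)))
  if (!is.null(x$cohort_tests)) {
    cat("clonotype-covariate association:\n")
    print(x$cohort_tests, row.names = FALSE)
  }
  invisible(x)
}
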