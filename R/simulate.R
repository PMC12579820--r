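# Small built-in IGH gene-call vocabularies for simulated clone tables.
.ighv_genes <- c("IGHV1-2", "IGHV1-18", "IGHV1-69", "IGHV2-5", "IGHV3-7",
                 "IGHV3-11", "IGHV3-21", "IGHV3-23", "IGHV3-30", "IGHV3-48",
                 "IGHV4-34", "IGHV4-39", "IGHV4-59", "IGHV5-51", "IGHV6-1")
.ighd_genes <- c("IGHD1-26", "IGHD2-2", "IGHD3-10", "IGHD3-22", "IGHD4-17",
                 "IGHD6-19")
.ighj_genes <- c("IGHJ1", "IGHJ2", "IGHJ3", "IGHJ4", "IGHJ5", "IGHJ6")

rand_junctions <- function(n, min_len = 12L, max_len = 60L) {
  len <- sample(min_len:max_len, n, replace = TRUE)
  vapply(len, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    character(1L))
}

#' Draw from the discrete power law
#'
#' i.i.d. samples from \eqn{P(X = x) = x^{-\alpha} / \zeta(\alpha, x_{min})}
#' on the integers \eqn{x \ge x_{min}}, by inversion: a cumulative table of
#' the CDF is grown by doubling until it covers the drawn quantiles, and
#' the few draws beyond the table (deep tail) are inverted individually by
#' doubling plus binary search on the Hurwitz-zeta tail. Fully determined
#' by the seed.
#'
#' @param n number of draws.
#' @param alpha exponent > 1.
#' @param xmin integer lower support bound >= 1.
#' @param seed optional integer seed; when \code{NULL} the current RNG
#'   stream is used.
#' @return integer vector of length \code{n}, all >= \code{xmin}.
#' @examples
#' rpowerlaw(5, 2.5, seed = 1)
#' @export
rpowerlaw <- function(n, alpha, xmin = 1L, seed = NULL) {
  if (alpha <= 1) stop("rpowerlaw: 'alpha' must be > 1")
  if (n < 1) stop("rpowerlaw: 'n' must be >= 1")
  if (xmin < 1 || xmin != floor(xmin)) stop("rpowerlaw: bad 'xmin'")
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(n)
  H <- hurwitz_zeta(alpha, xmin)
  # CDF table F(x) for x = xmin .. xmin + m - 1, grown until it covers u
  m <- 2048L
  repeat {
    grid <- xmin:(xmin + m - 1L)
    cdf <- cumsum(grid^(-alpha)) / H
    if (cdf[m] >= max(u) || m >= 2^20) break
    m <- m * 4L
  }
  idx <- findInterval(u, cdf, left.open = TRUE) + 1L
  x <- grid[pmin(idx, m)]
  beyond <- which(idx > m)
  for (i in beyond)   # deep-tail draws: exact inversion on the zeta tail
    x[i] <- qpowerlaw_tail(1 - u[i], alpha, xmin, H)
  as.integer(x)
}

# Smallest integer x >= xmin with P(X >= x + 1) <= v, i.e. F(x) >= 1 - v.
qpowerlaw_tail <- function(v, alpha, xmin, H = hurwitz_zeta(alpha, xmin)) {
  lo <- xmin
  hi <- max(2L * xmin, 2L)
  while (hurwitz_zeta(alpha, hi + 1) / H > v) {
    lo <- hi
    hi <- hi * 2L
  }
  while (hi > lo) {
    mid <- lo + (hi - lo) %/% 2L
    if (hurwitz_zeta(alpha, mid + 1) / H <= v) hi <- mid else lo <- mid + 1L
  }
  hi
}

# Smallest count whose e-value under the (alpha, xmin, n_tail) null is <= e;
# the e-value uses the inclusive tail P(X >= x), hence the + 1 relative to
# the quantile function (which conditions on P(X >= x + 1)).
count_for_evalue <- function(e, alpha, xmin, n_tail) {
  v <- e / n_tail
  if (v >= 1) return(as.integer(xmin))
  qpowerlaw_tail(v, alpha, xmin) + 1L
}

#' Configuration for a simulated repertoire
#'
#' Bundles the generator parameters with their study-scale defaults: 264
#' background clones (the cohort's median repertoire size), exponent 2.5,
#' support from 1, 14.5% incomplete DJ rearrangements, and 3% of complete
#' clones reusing an existing junction (which exercises the
#' ongoing-rearrangement merger).
#'
#' @param n_clones number of background clones.
#' @param alpha background power-law exponent (> 1).
#' @param xmin background lower support bound.
#' @param disease_spec list of disease-clone specs, each a list with
#'   \code{type} (\code{"COMPLETE"}, \code{"INCOMPLETE"} or
#'   \code{"ONGOING"}) and either \code{target_e} (the clone is placed at
#'   the smallest count whose true e-value is below it) or
#'   \code{target_count}.
#' @param frac_incomplete fraction of background clones typed INCOMPLETE.
#' @param dj_shared_rate fraction of complete background clones that reuse
#'   an earlier complete clone's DJ junction.
#' @param e_threshold detection threshold the truth is defined against; a
#'   \code{target_e} at or above it is unreachable and rejected.
#' @param seed integer seed.
#' @return list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_clones = 264L, alpha = 2.5, xmin = 1L,
                       disease_spec = list(), frac_incomplete = 0.145,
                       dj_shared_rate = 0.03, e_threshold = 0.01,
                       seed = 1L) {
  if (n_clones < 1) stop("sim_config: 'n_clones' must be >= 1")
  if (alpha <= 1) stop("sim_config: 'alpha' must be > 1")
  if (frac_incomplete < 0 || frac_incomplete > 1)
    stop("sim_config: 'frac_incomplete' must be in [0, 1]")
  if (dj_shared_rate < 0 || dj_shared_rate > 1)
    stop("sim_config: 'dj_shared_rate' must be in [0, 1]")
  for (d in disease_spec) {
    if (!d$type %in% c("COMPLETE", "INCOMPLETE", "ONGOING"))
      stop("sim_config: unknown disease clone type '", d$type, "'")
    if (is.null(d$target_e) && is.null(d$target_count))
      stop("sim_config: disease spec needs target_e or target_count")
    if (!is.null(d$target_e) && d$target_e >= e_threshold)
      stop("sim_config: target_e ", d$target_e, " is not below the ",
           "e-threshold ", e_threshold, "; the truth would be unreachable")
  }
  structure(list(n_clones = as.integer(n_clones), alpha = alpha,
                 xmin = as.integer(xmin), disease_spec = disease_spec,
                 frac_incomplete = frac_incomplete,
                 dj_shared_rate = dj_shared_rate,
                 e_threshold = e_threshold, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate one synthetic repertoire with ground truth
#'
#' Background clone abundances are drawn from the configured discrete
#' power law; junctions are random distinct A/C/G/T strings of length
#' 12-60 except that a \code{dj_shared_rate} fraction of complete clones
#' reuse an existing complete junction (so the Poisson merger has material
#' to work on); V/D/J calls are drawn from built-in gene lists. Disease
#' clones are appended with counts chosen by inverting the e-value formula
#' against the background's \emph{true} parameters (alpha, xmin, and the
#' background tail size), so the recorded truth never depends on the
#' detector under test.
#'
#' @param config a [sim_config()].
#' @param sample_id,patient_id,timepoint repertoire metadata.
#' @return list with \code{repertoire} (an \code{"igh_repertoire"}) and
#'   \code{truth} — a list with \code{clones} (data frame: clone_id,
#'   is_disease, rearrangement_type) and \code{clonotype} (the truth
#'   UDC/IDC/CDC label).
#' @export
generate_repertoire <- function(config, sample_id = "sim",
                                patient_id = sample_id,
                                timepoint = "DIAGNOSIS") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_clones
  counts <- rpowerlaw(n, config$alpha, config$xmin)
  type <- ifelse(stats::runif(n) < config$frac_incomplete,
                 "INCOMPLETE", "COMPLETE")
  junction <- rand_junctions(n)
  while (anyDuplicated(junction))
    junction[duplicated(junction)] <-
      rand_junctions(sum(duplicated(junction)))
  v_call <- ifelse(type == "COMPLETE",
                   sample(.ighv_genes, n, replace = TRUE), NA)
  d_call <- sample(.ighd_genes, n, replace = TRUE)
  j_call <- sample(.ighj_genes, n, replace = TRUE)
  # junction reuse among complete clones: an ongoing rearrangement is one
  # DJ stem carrying several V segments, so reused junctions concentrate
  # on a few stems rather than spreading over many pairs
  complete_idx <- which(type == "COMPLETE")
  n_share <- round(config$dj_shared_rate * length(complete_idx))
  if (n_share > 0 && length(complete_idx) > n_share + 1L) {
    n_stem <- max(1L, ceiling(n_share / 5L))
    stems <- sample(complete_idx, n_stem)
    recv <- sample(setdiff(complete_idx, stems), n_share)
    donor <- stems[1L + (seq_len(n_share) - 1L) %% n_stem]
    junction[recv] <- junction[donor]
    for (i in seq_len(n_share))  # a different V on the shared DJ stem
      v_call[recv[i]] <- sample(setdiff(.ighv_genes, v_call[donor[i]]), 1L)
  }
  clones <- data.frame(
    clone_id = sprintf("%s_bg%04d", sample_id, seq_len(n)),
    v_call = v_call, d_call = d_call, j_call = j_call,
    dj_junction = junction, read_count = counts,
    rearrangement_type = type, member_v_calls = "",
    stringsAsFactors = FALSE)
  is_disease <- rep.int(FALSE, n)

  n_tail_bg <- sum(counts >= config$xmin)  # background tail truth
  ds <- config$disease_spec
  for (i in seq_along(ds)) {
    d <- ds[[i]]
    cnt <- if (!is.null(d$target_e))
      count_for_evalue(d$target_e, config$alpha, config$xmin, n_tail_bg)
    else d$target_count
    ongoing <- d$type == "ONGOING"
    members <- if (ongoing)
      paste(sort(sample(.ighv_genes, 3L)), collapse = ",") else ""
    clones <- rbind(clones, data.frame(
      clone_id = sprintf("%s_dis%02d", sample_id, i),
      v_call = if (d$type == "COMPLETE") sample(.ighv_genes, 1L)
               else NA_character_,
      d_call = sample(.ighd_genes, 1L), j_call = sample(.ighj_genes, 1L),
      dj_junction = rand_junctions(1L), read_count = cnt,
      rearrangement_type = d$type, member_v_calls = members,
      stringsAsFactors = FALSE))
    is_disease <- c(is_disease, TRUE)
  }
  rep <- igh_repertoire(clones, sample_id = sample_id,
                        patient_id = patient_id, timepoint = timepoint)
  types <- vapply(ds, `[[`, "", "type")
  clonotype <- if (length(ds) == 0L) "UDC"
               else if (any(types == "INCOMPLETE")) "IDC" else "CDC"
  list(repertoire = rep,
       truth = list(clones = data.frame(clone_id = clones$clone_id,
                                        is_disease = is_disease,
                                        rearrangement_type =
                                          clones$rearrangement_type,
                                        stringsAsFactors = FALSE),
                    clonotype = clonotype))
}

#' Generate a paired diagnosis/relapse sample with planned evolution
#'
#' Generates two repertoires for one patient and plants clones realizing
#' the requested evolution patterns: an \code{"A"} clone is disease-sized
#' at both timepoints, a \code{"B"} clone is disease-sized at diagnosis and
#' minor (or, when \code{overlap} is 0, absent) at relapse, a \code{"C"}
#' clone the mirror image. A fraction \code{overlap} of the background
#' clones of the smaller sample shares its identity keys (junction and
#' class) across timepoints.
#'
#' @param config_diag,config_rel [sim_config()]s for the two backgrounds;
#'   their \code{disease_spec}s are extended by the plan.
#' @param pattern_plan character vector over \{"A", "B", "C"\}.
#' @param overlap fraction in [0, 1] of background clones shared between
#'   timepoints. A plan containing \code{"A"} requires \code{overlap > 0}
#'   (a persisting clone is by definition shared).
#' @param seed integer seed for the pairing (sub-seeds for the two samples
#'   are derived from it).
#' @param patient_id patient identifier.
#' @return list with \code{diagnosis}, \code{relapse} (repertoires) and
#'   \code{truth} (patterns per planted clone, clonotype truth per
#'   timepoint).
#' @export
generate_paired <- function(config_diag = sim_config(),
                            config_rel = sim_config(),
                            pattern_plan = character(), overlap = 0.5,
                            seed = 1L, patient_id = "patient1") {
  if (overlap < 0 || overlap > 1)
    stop("generate_paired: 'overlap' must be in [0, 1]")
  if (overlap == 0 && "A" %in% pattern_plan)
    stop("generate_paired: pattern A needs a shared clone but overlap is 0")
  target_e <- 1e-6
  add_spec <- function(spec, patterns) {
    c(spec, lapply(patterns, function(p)
      list(type = "COMPLETE", target_e = target_e)))
  }
  diag_pat <- pattern_plan[pattern_plan %in% c("A", "B")]
  rel_pat <- pattern_plan[pattern_plan %in% c("A", "C")]
  config_diag$disease_spec <- add_spec(config_diag$disease_spec, diag_pat)
  config_rel$disease_spec <- add_spec(config_rel$disease_spec, rel_pat)
  config_diag$seed <- (seed * 2L) %% .Machine$integer.max
  config_rel$seed <- (seed * 2L + 1L) %% .Machine$integer.max
  g_d <- generate_repertoire(config_diag, sample_id = paste0(patient_id, "_dx"),
                             patient_id = patient_id, timepoint = "DIAGNOSIS")
  g_r <- generate_repertoire(config_rel, sample_id = paste0(patient_id, "_rl"),
                             patient_id = patient_id, timepoint = "RELAPSE")
  cl_d <- g_d$repertoire$clones
  cl_r <- g_r$repertoire$clones
  set.seed((seed * 2L + 2L) %% .Machine$integer.max)

  # share background identities across timepoints, matched by type
  n_planned_d <- length(diag_pat)
  n_planned_r <- length(rel_pat)
  bg_d <- which(!g_d$truth$clones$is_disease)
  bg_r <- which(!g_r$truth$clones$is_disease)
  for (ty in c("COMPLETE", "INCOMPLETE")) {
    src <- bg_d[cl_d$rearrangement_type[bg_d] == ty]
    dst <- bg_r[cl_r$rearrangement_type[bg_r] == ty]
    n_sh <- round(overlap * min(length(src), length(dst)))
    if (n_sh < 1) next
    src <- sample(src, n_sh)
    dst <- sample(dst, n_sh)
    cl_r$dj_junction[dst] <- cl_d$dj_junction[src]
    cl_r$v_call[dst] <- cl_d$v_call[src]
    cl_r$d_call[dst] <- cl_d$d_call[src]
    cl_r$j_call[dst] <- cl_d$j_call[src]
  }

  # realize the plan: planted disease rows sit at the end, in plan order
  dis_d <- which(g_d$truth$clones$is_disease)
  dis_r <- which(g_r$truth$clones$is_disease)
  plant_d <- utils::tail(dis_d, n_planned_d)  # rows for diag_pat, in order
  plant_r <- utils::tail(dis_r, n_planned_r)
  truth_rows <- list()
  i_d <- 1L; i_r <- 1L
  minor_count <- function() min(rpowerlaw(1L, config_rel$alpha, 1L), 5L)
  for (p in pattern_plan) {
    if (p == "A") {
      row_d <- plant_d[i_d]; row_r <- plant_r[i_r]
      cl_r$dj_junction[row_r] <- cl_d$dj_junction[row_d]
      cl_r$v_call[row_r] <- cl_d$v_call[row_d]
      i_d <- i_d + 1L; i_r <- i_r + 1L
      key_j <- cl_d$dj_junction[row_d]
    } else if (p == "B") {
      row_d <- plant_d[i_d]; i_d <- i_d + 1L
      key_j <- cl_d$dj_junction[row_d]
      if (overlap > 0) {  # present but minor at relapse
        cl_r <- rbind(cl_r, data.frame(
          clone_id = sprintf("%s_rl_min%02d", patient_id, length(truth_rows)),
          v_call = cl_d$v_call[row_d], d_call = cl_d$d_call[row_d],
          j_call = cl_d$j_call[row_d], dj_junction = key_j,
          read_count = minor_count(), rearrangement_type = "COMPLETE",
          member_v_calls = "", stringsAsFactors = FALSE))
      }
    } else if (p == "C") {
      row_r <- plant_r[i_r]; i_r <- i_r + 1L
      key_j <- cl_r$dj_junction[row_r]
      if (overlap > 0) {  # present but minor at diagnosis
        cl_d <- rbind(cl_d, data.frame(
          clone_id = sprintf("%s_dx_min%02d", patient_id, length(truth_rows)),
          v_call = cl_r$v_call[row_r], d_call = cl_r$d_call[row_r],
          j_call = cl_r$j_call[row_r], dj_junction = key_j,
          read_count = minor_count(), rearrangement_type = "COMPLETE",
          member_v_calls = "", stringsAsFactors = FALSE))
      }
    } else stop("generate_paired: unknown pattern '", p, "'")
    truth_rows[[length(truth_rows) + 1L]] <-
      data.frame(pattern = p, dj_junction = key_j, class = "VDJ",
                 stringsAsFactors = FALSE)
  }
  diag <- igh_repertoire(cl_d, sample_id = g_d$repertoire$sample_id,
                         patient_id = patient_id, timepoint = "DIAGNOSIS")
  rel <- igh_repertoire(cl_r, sample_id = g_r$repertoire$sample_id,
                        patient_id = patient_id, timepoint = "RELAPSE")
  list(diagnosis = diag, relapse = rel,
       truth = list(patterns = if (length(truth_rows))
                      do.call(rbind, truth_rows)
                    else data.frame(pattern = character(),
                                    dj_junction = character(),
                                    class = character()),
                    clonotype_diag = g_d$truth$clonotype,
                    clonotype_rel = g_r$truth$clonotype))
}

#' Generate a synthetic cohort with known clonotype truth
#'
#' Draws per-patient truth clonotypes from \code{clonotype_mix} and
#' categorical covariates from the chosen model: under
#' \code{"independent"} every covariate is drawn independently of the
#' clonotype (so association tests have a true null); under
#' \code{"age_assoc"} the age group depends on the clonotype (UDC patients
#' skew older), giving the age test a true signal. Marginal covariate
#' frequencies follow the source cohort. When \code{repertoires = TRUE} a
#' clone table is generated per patient whose disease-clone composition
#' realizes the truth label (UDC: none; IDC: one incomplete and one
#' complete disease clone; CDC: one complete).
#'
#' @param n_patients cohort size.
#' @param clonotype_mix named probabilities for UDC/IDC/CDC, summing to 1.
#' @param covariate_model \code{"independent"} or \code{"age_assoc"}.
#' @param seed integer seed.
#' @param repertoires generate clone tables (slow for large cohorts) or
#'   labels and covariates only.
#' @param config base [sim_config()] for the per-patient backgrounds.
#' @return list with \code{metadata} (data frame: patient_id, covariates),
#'   \code{truth} (data frame: patient_id, clonotype), and
#'   \code{repertoires} (named list or \code{NULL}).
#' @export
generate_cohort <- function(n_patients,
                            clonotype_mix = c(UDC = 0.110, IDC = 0.515,
                                              CDC = 0.375),
                            covariate_model = c("independent", "age_assoc"),
                            seed = 1L, repertoires = TRUE,
                            config = sim_config()) {
  covariate_model <- match.arg(covariate_model)
  if (abs(sum(clonotype_mix) - 1) > 1e-8 || any(clonotype_mix < 0))
    stop("generate_cohort: 'clonotype_mix' must be nonnegative and sum to 1")
  if (!all(names(clonotype_mix) %in% c("UDC", "IDC", "CDC")))
    stop("generate_cohort: 'clonotype_mix' names must be UDC/IDC/CDC")
  set.seed(seed)
  ids <- sprintf("P%04d", seq_len(n_patients))
  label <- sample(names(clonotype_mix), n_patients, replace = TRUE,
                  prob = clonotype_mix)
  p_old <- switch(covariate_model,
                  independent = rep.int(0.36, n_patients),
                  age_assoc = c(UDC = 0.67, IDC = 0.35, CDC = 0.28)[label])
  metadata <- data.frame(
    patient_id = ids,
    age_group = ifelse(stats::runif(n_patients) < p_old, ">=10", "<10"),
    sex = ifelse(stats::runif(n_patients) < 0.53, "Male", "Female"),
    wbc_group = ifelse(stats::runif(n_patients) < 0.62, "<50k", ">=50k"),
    mrd_status = ifelse(stats::runif(n_patients) < 0.39,
                        "Positive", "Negative"),
    stringsAsFactors = FALSE)
  spec_for <- function(lab) switch(lab,
    UDC = list(),
    IDC = list(list(type = "INCOMPLETE", target_e = 1e-6),
               list(type = "COMPLETE", target_e = 1e-6)),
    CDC = list(list(type = "COMPLETE", target_e = 1e-6)))
  reps <- NULL
  if (repertoires) {
    sub_seed <- sample.int(.Machine$integer.max - 1L, n_patients)
    reps <- lapply(seq_len(n_patients), function(i) {
      cfg <- config
      cfg$disease_spec <- c(cfg$disease_spec, spec_for(label[i]))
      cfg$seed <- sub_seed[i]
      generate_repertoire(cfg, sample_id = ids[i])$repertoire
    })
    names(reps) <- ids
  }
  list(metadata = metadata,
       truth = data.frame(patient_id = ids, clonotype = label,
                          stringsAsFactors = FALSE),
       repertoires = reps)
}
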