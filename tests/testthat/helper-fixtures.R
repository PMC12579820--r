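# Distinct base-4 tags, so generated junctions never collide.
int_to_acgt <- function(i, len = 6L) {
  vapply(i, function(k)
    paste(c("A", "C", "G", "T")[1 + (k %/% 4^(0:(len - 1))) %% 4],
          collapse = ""), character(1L))
}

# Build a small repertoire from parallel vectors; defaults give valid
# COMPLETE clones with distinct junctions.
make_rep <- function(counts,
                     type = rep("COMPLETE", length(counts)),
                     junction = NULL,
                     v_call = NULL,
                     sample_id = "s1", patient_id = sample_id,
                     timepoint = "DIAGNOSIS") {
  n <- length(counts)
  if (is.null(junction))
    junction <- if (n == 0L) character(0)
                else paste0("TGTGCGAGA", int_to_acgt(seq_len(n)))
  if (is.null(v_call))
    v_call <- ifelse(type == "COMPLETE", paste0("IGHV1-", seq_len(n)), NA)
  members <- ifelse(type == "ONGOING", "IGHV1-2,IGHV3-23", "")
  igh_repertoire(
    data.frame(clone_id = sprintf("c%03d", seq_len(n)),
               v_call = as.character(v_call),
               d_call = rep("IGHD1-26", n), j_call = rep("IGHJ4", n),
               dj_junction = junction, read_count = counts,
               rearrangement_type = type, member_v_calls = members,
               stringsAsFactors = FALSE),
    sample_id = sample_id, patient_id = patient_id, timepoint = timepoint)
}

# Repertoire with given junctions (character vector, may repeat to form
# shared-junction groups), all COMPLETE, distinct V calls.
make_rep_junctions <- function(junctions, counts = rep(1L, length(junctions)),
                               ...) {
  make_rep(counts, junction = junctions,
           v_call = paste0("IGHV3-", seq_along(junctions)), ...)
}

# Minimal disease_calls object for classifier tests: statuses assigned to
# clones of the given rearrangement types.
make_calls <- function(types, statuses, sample_id = "s1") {
  stopifnot(length(types) == length(statuses))
  structure(
    list(sample_id = sample_id, fit = NULL, unfit = FALSE,
         fit_error = NA_character_,
         calls = data.frame(clone_id = sprintf("c%03d", seq_along(types)),
                            read_count = seq_along(types) + 10L,
                            rearrangement_type = types,
                            e_value = ifelse(statuses == "DISEASE", 1e-6, 1),
                            status = statuses, stringsAsFactors = FALSE)),
    class = "disease_calls")
}
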