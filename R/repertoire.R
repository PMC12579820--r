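#' Construct an IGH repertoire
#'
#' A repertoire holds all IGH clones observed in one sample at one
#' timepoint. Clones are rows of a data frame with columns \code{clone_id},
#' \code{v_call}, \code{d_call}, \code{j_call}, \code{dj_junction},
#' \code{read_count}, \code{rearrangement_type} (one of \code{COMPLETE},
#' \code{INCOMPLETE}, \code{ONGOING}) and \code{member_v_calls} (comma-joined
#' V calls of the merged members; non-empty iff ONGOING). Absent gene calls
#' are \code{NA}. Junction sequences are case-folded to uppercase so that
#' identity matching is case-insensitive.
#'
#' Rearrangement types reflect the VDJ recombination stage: a COMPLETE clone
#' carries a full VDJ junction; an INCOMPLETE clone is a DJ join without a V
#' segment (an earlier developmental step); an ONGOING clone represents
#' several V segments rearranged onto one shared DJ stem and only arises by
#' merging (see [merge_ongoing()]).
#'
#' @param clones data frame of clones (missing optional columns are filled).
#' @param sample_id sample identifier.
#' @param patient_id patient identifier (defaults to \code{sample_id}).
#' @param timepoint \code{"DIAGNOSIS"} or \code{"RELAPSE"}.
#' @return an object of class \code{"igh_repertoire"}.
#' @export
igh_repertoire <- function(clones, sample_id, patient_id = sample_id,
                           timepoint = c("DIAGNOSIS", "RELAPSE")) {
  timepoint <- match.arg(timepoint)
  clones <- as.data.frame(clones, stringsAsFactors = FALSE)
  for (col in c("v_call", "d_call", "j_call"))
    if (is.null(clones[[col]])) clones[[col]] <- NA_character_
  if (is.null(clones$member_v_calls)) clones$member_v_calls <- ""
  clones$member_v_calls[is.na(clones$member_v_calls)] <- ""
  if (is.null(clones$rearrangement_type))
    clones$rearrangement_type <-
      ifelse(is.na(clones$v_call) | clones$v_call == "",
             "INCOMPLETE", "COMPLETE")
  clones$v_call[!is.na(clones$v_call) & clones$v_call == ""] <- NA
  clones$d_call[!is.na(clones$d_call) & clones$d_call == ""] <- NA
  clones$dj_junction <- toupper(clones$dj_junction)
  clones <- clones[, c("clone_id", "v_call", "d_call", "j_call",
                       "dj_junction", "read_count", "rearrangement_type",
                       "member_v_calls")]
  rownames(clones) <- NULL
  rep <- structure(
    list(sample_id = as.character(sample_id),
         patient_id = as.character(patient_id),
         timepoint = timepoint, clones = clones,
         total_reads = sum(clones$read_count)),
    class = "igh_repertoire")
  validate_repertoire(rep)
  rep
}

#' Validate an IGH repertoire
#'
#' Checks the structural invariants: unique clone ids, integer read counts
#' >= 1, non-empty uppercase junctions over the A/C/G/T/N alphabet, absent V
#' call iff INCOMPLETE, and at least two member V calls iff ONGOING.
#'
#' @param rep an \code{"igh_repertoire"}.
#' @return \code{rep}, invisibly; errors describe the first violated rule.
#' @export
validate_repertoire <- function(rep) {
  stopifnot(inherits(rep, "igh_repertoire"))
  cl <- rep$clones
  if (anyDuplicated(cl$clone_id))
    stop("repertoire '", rep$sample_id, "': duplicate clone_id '",
         cl$clone_id[duplicated(cl$clone_id)][1L], "'")
  bad <- which(!is.finite(cl$read_count) | cl$read_count < 1 |
                 cl$read_count != floor(cl$read_count))
  if (length(bad))
    stop("repertoire '", rep$sample_id, "': read_count must be an integer ",
         ">= 1 (row ", bad[1L], ")")
  bad <- which(is.na(cl$dj_junction) | cl$dj_junction == "" |
                 grepl("[^ACGTN]", cl$dj_junction))
  if (length(bad))
    stop("repertoire '", rep$sample_id, "': dj_junction must be a non-empty ",
         "A/C/G/T/N string (row ", bad[1L], ")")
  if (!all(cl$rearrangement_type %in% c("COMPLETE", "INCOMPLETE", "ONGOING")))
    stop("repertoire '", rep$sample_id, "': unknown rearrangement_type")
  bad <- which(cl$rearrangement_type == "INCOMPLETE" & !is.na(cl$v_call))
  if (length(bad))
    stop("repertoire '", rep$sample_id, "': INCOMPLETE clone with a V call ",
         "(row ", bad[1L], ")")
  n_members <- ifelse(rep$clones$member_v_calls == "", 0L,
                      lengths(strsplit(cl$member_v_calls, ",", fixed = TRUE)))
  bad <- which((cl$rearrangement_type == "ONGOING") != (n_members >= 2L))
  if (length(bad))
    stop("repertoire '", rep$sample_id, "': member_v_calls must list >= 2 ",
         "V calls iff ONGOING (row ", bad[1L], ")")
  if (!isTRUE(all.equal(rep$total_reads, sum(cl$read_count))))
    stop("repertoire '", rep$sample_id, "': total_reads does not match the ",
         "sum of read counts")
  invisible(rep)
}

#' @export
print.igh_repertoire <- function(x, ...) {
  tab <- table(factor(x$clones$rearrangement_type,
                      levels = c("COMPLETE", "ONGOING", "INCOMPLETE")))
  cat(sprintf("IGH repertoire '%s' (patient %s, %s)\n",
              x$sample_id, x$patient_id, tolower(x$timepoint)))
  cat(sprintf("  %d clones (%d complete, %d ongoing, %d incomplete), %d reads\n",
              nrow(x$clones), tab[["COMPLETE"]], tab[["ONGOING"]],
              tab[["INCOMPLETE"]], x$total_reads))
  invisible(x)
}

.simple_cols <- c("clone_id", "v_call", "d_call", "j_call", "dj_junction",
                  "read_count", "rearrangement_type", "member_v_calls")

#' Read a clone table
#'
#' Reads one sample's IGH clone table from a tab-separated file in either
#' the AIRR Rearrangement dialect or the package's simple internal dialect.
#'
#' The AIRR dialect requires columns \code{sequence_id} (or
#' \code{clone_id}), \code{v_call}, \code{d_call}, \code{j_call},
#' \code{dj_junction} and \code{duplicate_count} (falling back to
#' \code{consensus_count}); AIRR has no dedicated DJ-junction field, so the
#' custom \code{dj_junction} column is required — the DJ junction is the
#' clone-identity key of the whole analysis. Rows without a V call are typed
#' INCOMPLETE; a comma-separated V call denotes a merged ONGOING clone (as
#' written by [write_clone_table()]); all other rows are COMPLETE.
#'
#' The simple dialect requires all of: \code{clone_id}, \code{v_call},
#' \code{d_call}, \code{j_call}, \code{dj_junction}, \code{read_count},
#' \code{rearrangement_type}, \code{member_v_calls}.
#'
#' @param path file path.
#' @param format \code{"simple"} or \code{"airr"}.
#' @param sample_id,patient_id,timepoint repertoire metadata (default:
#'   file name without extension, at diagnosis).
#' @return a validated \code{"igh_repertoire"}.
#' @export
read_clone_table <- function(path, format = c("simple", "airr"),
                             sample_id = sub("\\.[^.]*$", "", basename(path)),
                             patient_id = sample_id,
                             timepoint = "DIAGNOSIS") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_clone_table: no such file: ", path)
  tab <- utils::read.delim(path, colClasses = "character",
                           na.strings = character(), check.names = FALSE)
  required <- if (format == "simple") .simple_cols
              else c("v_call", "d_call", "j_call", "dj_junction")
  missing_cols <- setdiff(required, names(tab))
  if (format == "airr" && !any(c("sequence_id", "clone_id") %in% names(tab)))
    missing_cols <- c("sequence_id", missing_cols)
  if (format == "airr" &&
      !any(c("duplicate_count", "consensus_count") %in% names(tab)))
    missing_cols <- c(missing_cols, "duplicate_count")
  if (length(missing_cols))
    stop("read_clone_table: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (format == "airr") {
    id_col <- if ("clone_id" %in% names(tab)) "clone_id" else "sequence_id"
    cnt_col <- if ("duplicate_count" %in% names(tab)) "duplicate_count"
               else "consensus_count"
    ongoing <- grepl(",", tab$v_call, fixed = TRUE)
    clones <- data.frame(
      clone_id = tab[[id_col]],
      v_call = ifelse(ongoing, NA, tab$v_call),
      d_call = tab$d_call, j_call = tab$j_call,
      dj_junction = tab$dj_junction,
      read_count = tab[[cnt_col]],
      rearrangement_type = ifelse(ongoing, "ONGOING",
                                  ifelse(tab$v_call == "", "INCOMPLETE",
                                         "COMPLETE")),
      member_v_calls = ifelse(ongoing, tab$v_call, ""),
      stringsAsFactors = FALSE)
  } else {
    clones <- tab[, .simple_cols]
  }
  counts <- suppressWarnings(as.numeric(clones$read_count))
  bad <- which(is.na(counts) | counts < 1 | counts != floor(counts))
  if (length(bad))
    stop("read_clone_table: read_count must be an integer >= 1 (row ",
         bad[1L], ")")
  clones$read_count <- as.integer(counts)
  igh_repertoire(clones, sample_id = sample_id, patient_id = patient_id,
                 timepoint = timepoint)
}

#' Write a clone table
#'
#' Serializes a repertoire to TSV in either dialect with a fixed column
#' order; output is re-readable by [read_clone_table()]. In the AIRR
#' dialect an ONGOING clone's member V calls are comma-joined into the
#' \code{v_call} field.
#'
#' @param rep a validated \code{"igh_repertoire"}.
#' @param path output file path.
#' @param format \code{"simple"} or \code{"airr"}.
#' @export
write_clone_table <- function(rep, path, format = c("simple", "airr")) {
  format <- match.arg(format)
  validate_repertoire(rep)
  cl <- rep$clones
  if (format == "simple") {
    out <- cl[, .simple_cols]
    out$v_call[is.na(out$v_call)] <- ""
    out$d_call[is.na(out$d_call)] <- ""
  } else {
    ongoing <- cl$rearrangement_type == "ONGOING"
    out <- data.frame(
      sequence_id = cl$clone_id,
      v_call = ifelse(ongoing, cl$member_v_calls,
                      ifelse(is.na(cl$v_call), "", cl$v_call)),
      d_call = ifelse(is.na(cl$d_call), "", cl$d_call),
      j_call = cl$j_call,
      dj_junction = cl$dj_junction,
      duplicate_count = cl$read_count,
      stringsAsFactors = FALSE)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rep)
}

#' Read patient metadata
#'
#' Reads a tab-separated table of per-patient categorical covariates
#' (\code{age_group}, \code{sex}, \code{wbc_group}, \code{mrd_status},
#' \code{subtype}, ...). Blank cells are kept as missing values, never
#' imputed; association tests drop them pairwise.
#'
#' @param path TSV path; a \code{patient_id} column is required.
#' @return data frame, one row per patient.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("read_metadata: no such file: ", path)
  tab <- utils::read.delim(path, colClasses = "character",
                           na.strings = c("", "NA"), check.names = FALSE)
  if (!"patient_id" %in% names(tab))
    stop("read_metadata: missing required column: patient_id")
  if (anyDuplicated(tab$patient_id))
    stop("read_metadata: duplicate patient_id '",
         tab$patient_id[duplicated(tab$patient_id)][1L], "'")
  tab
}
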