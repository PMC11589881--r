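#' Read a protein FASTA into a tibble of records
#'
#' Reads standard FASTA via Biostrings and applies the preprocessing used
#' throughout the pipeline: selenocysteine (`U`) is substituted by cysteine
#' (`C`) with the substitution count reported per record, and records whose
#' length falls outside `[min_len, max_len]` are flagged (`length_ok`);
#' filtering itself happens downstream in [filter_proteome()].
#'
#' @param path Path to a FASTA file.
#' @param min_len,max_len Length bounds used to flag records (defaults 18
#'   and 10000 residues).
#' @return A tibble with columns `id`, `sequence`, `length`,
#'   `n_u_substituted`, `length_ok`.
#' @export
read_fasta <- function(path, min_len = 18L, max_len = 10000L) {
  if (!file.exists(path)) stop_input("FASTA file not found: %s", path)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop_input("cannot read FASTA '%s': %s",
                                                 path, conditionMessage(e)))
  if (length(set) == 0L) stop_input("empty FASTA file: %s", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop_input("duplicate FASTA id(s): %s",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- unname(as.character(set))
  n_u <- stringr::str_count(seqs, "U")
  if (sum(n_u) > 0) {
    inform(sprintf("read_fasta: substituted %d selenocysteine (U) residue(s) by C in %d record(s)",
                   sum(n_u), sum(n_u > 0)))
    seqs <- gsub("U", "C", seqs, fixed = TRUE)
  }
  tibble(id = ids, sequence = seqs,
         length = nchar(seqs), n_u_substituted = n_u,
         length_ok = nchar(seqs) >= min_len & nchar(seqs) <= max_len)
}

#' Read predictor TM-segment tables
#'
#' Reads the TSV dialect for CCTOP/TMAlphaFold-style segment lists: one row
#' per TM segment with columns `id`, `source`, `n_term_side`, `start`,
#' `end`, and optionally `tests_passed` (TMAlphaFold structure-test count,
#' repeated on each row of a protein). Rows are grouped by (`id`, `source`)
#' into one [predictor_output()] each.
#'
#' @param path Path to the TSV.
#' @return A list of `predictor_output` objects.
#' @export
read_segment_table <- function(path) {
  if (!file.exists(path)) stop_input("segment table not found: %s", path)
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("id", "source", "n_term_side", "start", "end")
  if (!all(need %in% names(tab))) {
    stop_input("segment table '%s' must have columns %s", path,
               paste(need, collapse = ", "))
  }
  if (!"tests_passed" %in% names(tab)) tab$tests_passed <- NA_integer_
  bad <- which(!tab$n_term_side %in% c("in", "out") |
                 is.na(tab$start) | is.na(tab$end) |
                 tab$start > tab$end | tab$start < 1)
  if (length(bad) > 0) {
    stop_input("malformed segment table row(s) at line(s) %s of %s",
               paste(bad + 1L, collapse = ", "), path) # +1 for the header
  }
  tab |>
    group_by(.data$id, .data$source) |>
    dplyr::group_map(function(rows, key) {
      if (dplyr::n_distinct(rows$n_term_side) > 1) {
        stop_input("conflicting n_term_side for id '%s' source '%s'",
                   key$id, key$source)
      }
      topo <- tryCatch(
        topology(rows[, c("start", "end")], rows$n_term_side[1]),
        error = function(e) stop_input("id '%s' source '%s': %s", key$id,
                                       key$source, conditionMessage(e)))
      predictor_output(id = key$id, source = key$source, topology = topo,
                       tests_passed = rows$tests_passed[1])
    })
}

#' Read a one-ID-per-line exclusion list
#'
#' Used for organelle (mitochondrial/peroxisomal) protein exclusion.
#' Blank lines and `#` comments are ignored.
#'
#' @param path Path to the list file, or `NULL` for an empty list.
#' @return Character vector of IDs.
#' @export
read_exclusion_list <- function(path) {
  if (is.null(path)) return(character())
  if (!file.exists(path)) stop_input("exclusion list not found: %s", path)
  x <- readLines(path, warn = FALSE)
  x <- trimws(sub("#.*$", "", x))
  unique(x[nzchar(x)])
}

#' Write a cohort table deterministically
#'
#' Writes a tibble of C-tail profiles as TSV, ordered by `id`, so that
#' re-runs on identical input are byte-identical.
#'
#' @param profiles A tibble with an `id` column (e.g. from
#'   [profile_cohort()]).
#' @param path Output path.
#' @return The input, invisibly.
#' @export
write_cohort_table <- function(profiles, path) {
  out <- arrange(profiles, .data$id)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(out)
}
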