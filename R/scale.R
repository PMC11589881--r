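#' The biological hydrophobicity scale
#'
#' Loads a hydrophobicity scale: per-residue apparent free energies of
#' membrane insertion (\eqn{\Delta G^{app}}, kcal/mol) for a residue placed in
#' the middle of the membrane, plus an optional positional profile used when
#' scoring candidate transmembrane (TM) helix windows. Negative values favour
#' insertion; summed over a loop or tail the mid-membrane values measure
#' hydrophilicity (positive = hydrophilic).
#'
#' The packaged default transcribes the published biological hydrophobicity
#' scale derived from translocon-mediated insertion experiments. The file is
#' a TSV with mandatory header and columns `residue` (one letter), `dg_mid`
#' (kcal/mol) and optionally `pos_sigma`, the width of a Gaussian positional
#' profile on the scaled membrane-normal coordinate (see
#' [segment_dg()]).
#'
#' @param path Path to a scale TSV. Default: the packaged scale.
#' @return An object of class `dg_scale`: a list with `per_residue_mid`
#'   (named numeric, 20 standard amino acids), `pos_sigma` (named numeric or
#'   `NULL`) and `source_tag`.
#' @examples
#' sc <- load_dg_scale()
#' sc$per_residue_mid["L"] # favourable (negative)
#' sc$per_residue_mid["N"] # hydrophilic (positive)
#' @export
load_dg_scale <- function(path = system.file("extdata",
                                             "biological_hydrophobicity_scale.tsv",
                                             package = "ctails")) {
  if (!file.exists(path)) stop_input("scale file not found: %s", path)
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("residue", "dg_mid") %in% names(tab))) {
    stop_input("scale file must have columns 'residue' and 'dg_mid': %s", path)
  }
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!setequal(tab$residue, aa20) || anyDuplicated(tab$residue)) {
    stop_input("scale file must cover exactly the 20 standard amino acids")
  }
  mid <- setNames(tab$dg_mid, tab$residue)[aa20]
  if (any(!is.finite(mid))) stop_input("non-finite dg_mid in scale file")
  sig <- NULL
  if ("pos_sigma" %in% names(tab)) {
    sig <- setNames(tab$pos_sigma, tab$residue)[aa20]
  }
  structure(
    list(per_residue_mid = mid, pos_sigma = sig,
         source_tag = basename(path)),
    class = "dg_scale"
  )
}

# Package-default scale, loaded once per session.
the <- new.env(parent = emptyenv())

default_scale <- function() {
  if (is.null(the$scale)) the$scale <- load_dg_scale()
  the$scale
}

check_residues <- function(seq, what = "sequence") {
  letters <- strsplit(seq, "")[[1]]
  bad <- setdiff(unique(letters), names(default_scale()$per_residue_mid))
  if (length(bad) > 0) {
    hint <- if ("U" %in% bad) {
      " ('U' must be substituted by 'C' upstream, see read_fasta())"
    } else {
      ""
    }
    stop_input("non-standard amino acid letter(s) %s in %s%s",
               paste0("'", bad, "'", collapse = ", "), what, hint)
  }
  letters
}

#' Mid-membrane insertion free energy of one residue
#'
#' @param aa One-letter code of a standard amino acid.
#' @param scale A `dg_scale` (default: packaged scale).
#' @return \eqn{\Delta G^{app}} contribution (kcal/mol) at the membrane
#'   centre.
#' @examples
#' residue_dg("L") < residue_dg("N") # leucine favours insertion
#' @export
residue_dg <- function(aa, scale = default_scale()) {
  stopifnot(is.character(aa), length(aa) == 1L, nchar(aa) == 1L)
  check_residues(aa, "residue lookup")
  unname(scale$per_residue_mid[aa])
}

#' Summed hydrophilicity of a loop or tail
#'
#' Sums the mid-membrane \eqn{\Delta G^{app}} values over all residues of a
#' loop or tail sequence. Positive totals mark hydrophilic segments that
#' resist translocation across the membrane. The sum is additive over
#' concatenation and 0 for the empty string.
#'
#' @param seq Amino-acid string (standard letters only; selenocysteine must
#'   already be substituted by cysteine).
#' @inheritParams residue_dg
#' @return Summed \eqn{\Delta G^{app}} in kcal/mol.
#' @examples
#' tail_hydrophilicity("GSGS") < tail_hydrophilicity("NNNN")
#' @export
tail_hydrophilicity <- function(seq, scale = default_scale()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) return(0)
  letters <- check_residues(seq)
  sum(scale$per_residue_mid[letters])
}

# Positional weights for a window of length len: a Gaussian profile on the
# scaled membrane-normal coordinate z in [-1, 1] with per-residue width
# sigma, peaking (weight 1) at the window centre.
positional_weights <- function(letters, scale) {
  len <- length(letters)
  if (len == 1L) return(1)
  z <- (seq_len(len) - (len + 1) / 2) / ((len - 1) / 2)
  sig <- scale$pos_sigma[letters]
  exp(-z^2 / (2 * sig^2))
}

#' Score a candidate transmembrane helix window
#'
#' Computes the apparent insertion free energy of the window
#' `seq[start .. start+length-1]`. With the positional model enabled
#' (the default when the scale ships positional widths) each residue's
#' mid-membrane value is attenuated by a Gaussian profile across the window,
#' so that polar residues near the membrane interfaces cost less than at the
#' centre. Without a positional model the score degrades to the plain sum of
#' mid-membrane values over the window.
#'
#' @param seq Amino-acid string.
#' @param start 1-based start of the window.
#' @param length Window length in residues; must lie within `helix_lengths`.
#' @param positional Use the positional profile if available? Default `TRUE`.
#' @param helix_lengths Allowed helix window lengths (default 19:23).
#' @inheritParams residue_dg
#' @return A one-row tibble (`start`, `end`, `dg_app`).
#' @export
segment_dg <- function(seq, start, length, scale = default_scale(),
                       positional = TRUE, helix_lengths = 19:23) {
  stopifnot(is.numeric(start), is.numeric(length))
  if (!length %in% helix_lengths) {
    stop_config("window length %d outside the allowed helix lengths [%s]",
                length, paste(range(helix_lengths), collapse = "-"))
  }
  end <- start + length - 1L
  if (start < 1L || end > nchar(seq)) {
    stop_input("window [%d, %d] out of bounds for a %d-residue sequence",
               start, end, nchar(seq))
  }
  letters <- check_residues(substr(seq, start, end))
  vals <- scale$per_residue_mid[letters]
  w <- if (positional && !is.null(scale$pos_sigma)) {
    positional_weights(letters, scale)
  } else {
    rep(1, length(letters))
  }
  tibble(start = as.integer(start), end = as.integer(end),
         dg_app = sum(vals * w))
}

#' Minimal \eqn{\Delta G^{app}} near an annotated TM centre
#'
#' Scans all candidate helix windows (every allowed length) whose centre lies
#' within `slack` residues of the annotated TM centre, and returns the window
#' with the minimal apparent insertion free energy. This re-centres fuzzy
#' predictor annotations onto the locally most hydrophobic stretch before a
#' per-TM \eqn{\Delta G^{app}} is assigned.
#'
#' The window centre is defined as `floor((start + end) / 2)`, matching the
#' TM segment convention. Candidates truncated by the sequence ends are
#' skipped; if no window of any allowed length fits, the largest window that
#' does fit (centred as close as possible) is scored and flagged
#' (`truncated = TRUE`).
#'
#' @param seq Amino-acid string.
#' @param tm_center 1-based residue index of the annotated TM centre.
#' @param slack Scan half-width in residues (default 5; the customary
#'   alternative is 6).
#' @inheritParams segment_dg
#' @return A one-row tibble (`start`, `end`, `dg_app`, `truncated`).
#' @export
min_dg_near_center <- function(seq, tm_center, slack = 5,
                               scale = default_scale(), positional = TRUE,
                               helix_lengths = 19:23) {
  stopifnot(slack >= 0)
  n <- nchar(seq)
  if (tm_center < 1L || tm_center > n) {
    stop_input("tm_center %d out of bounds for a %d-residue sequence",
               tm_center, n)
  }
  best <- NULL
  for (len in helix_lengths) {
    for (ctr in (tm_center - slack):(tm_center + slack)) {
      start <- ctr - (len - 1L) %/% 2L
      end <- start + len - 1L
      if (start < 1L || end > n) next
      sc <- segment_dg(seq, start, len, scale = scale,
                       positional = positional,
                       helix_lengths = helix_lengths)
      if (is.null(best) || sc$dg_app < best$dg_app) best <- sc
    }
  }
  if (!is.null(best)) {
    return(mutate(best, truncated = FALSE))
  }
  # No full-length window fits: score the largest window that does, pinned
  # to the sequence bounds, and flag it.
  len <- min(n, min(helix_lengths) - 1L)
  len <- max(len, 1L)
  start <- max(1L, min(tm_center - (len - 1L) %/% 2L, n - len + 1L))
  letters <- check_residues(substr(seq, start, start + len - 1L))
  vals <- scale$per_residue_mid[letters]
  w <- if (positional && !is.null(scale$pos_sigma)) {
    positional_weights(letters, scale)
  } else {
    rep(1, length(letters))
  }
  tibble(start = as.integer(start), end = as.integer(start + len - 1L),
         dg_app = sum(vals * w), truncated = TRUE)
}
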