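AA3_TO_1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
              Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
              Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
              Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")

#' Parse protein-level nonstop HGVS notation
#'
#' Parses strings of the form `"p.Ter156Leu"` (or with a transcript prefix,
#' e.g. `"NM_001694.4(ATP6V0C):p.Ter156Leu"`): the stop codon at protein
#' position N is replaced by an amino acid, so the wild-type protein has
#' N - 1 encoded residues and translation continues past position N.
#'
#' @param hgvs_p Protein-level HGVS string containing `p.Ter{N}{Aaa}`.
#' @return A list: `ter_codon` (N), `wt_protein_len` (N - 1),
#'   `replacement_aa` (one-letter).
#' @examples
#' parse_hgvs_p("p.Ter156Leu")$wt_protein_len # 155
#' @export
parse_hgvs_p <- function(hgvs_p) {
  m <- stringr::str_match(hgvs_p, "p\\.(?:Ter|\\*)(\\d+)([A-Z][a-z]{2})")
  if (is.na(m[1, 1])) {
    stop_input("cannot parse protein-level nonstop variant from '%s' (expected p.Ter{N}{Aaa})",
               hgvs_p)
  }
  aa3 <- m[1, 3]
  if (!aa3 %in% names(AA3_TO_1)) {
    stop_input("unknown amino acid code '%s' in '%s'", aa3, hgvs_p)
  }
  n <- as.integer(m[1, 2])
  list(ter_codon = n, wt_protein_len = n - 1L,
       replacement_aa = unname(AA3_TO_1[aa3]))
}

#' Parse coding-level substitution HGVS notation
#'
#' Parses `"c.{pos}{ref}>{alt}"` substitutions (optionally with a transcript
#' prefix such as `"NM_001694.4(ATP6V0C):c.467A>T"`).
#'
#' @param hgvs_c Coding-level HGVS substitution string.
#' @return A list: `pos` (1-based CDS position), `ref`, `alt` (single
#'   bases).
#' @export
parse_hgvs_c <- function(hgvs_c) {
  m <- stringr::str_match(hgvs_c, "c\\.(\\d+)([ACGT])>([ACGT])")
  if (is.na(m[1, 1])) {
    stop_input("cannot parse coding substitution from '%s' (expected c.{pos}{ref}>{alt})",
               hgvs_c)
  }
  list(pos = as.integer(m[1, 2]), ref = m[1, 3], alt = m[1, 4])
}

translate_codons <- function(dna) {
  n_codon <- nchar(dna) %/% 3L
  if (n_codon == 0L) return(character())
  codons <- substring(dna, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
  unname(Biostrings::GENETIC_CODE[codons])
}

#' Apply a stop-loss (nonstop) variant to a coding sequence
#'
#' Applies a coding substitution that abolishes the stop codon and
#' translates onward, in frame, until the next stop codon in the provided
#' sequence (which must include the 3' UTR). The wild-type protein prefix is
#' unchanged; the returned extension starts with the residue now encoded at
#' the former stop codon.
#'
#' @param cds_seq Nucleotide string: the full CDS including its stop codon,
#'   followed by (enough of) the 3' UTR.
#' @param hgvs_c Coding substitution (see [parse_hgvs_c()]) hitting the stop
#'   codon.
#' @param wt_protein_len Encoded length of the wild-type protein (residues,
#'   excluding the stop). The stop codon therefore occupies CDS positions
#'   `3 * wt_protein_len + 1 .. + 3`.
#' @return A list: `wt_protein`, `extension_seq`, `mutant_protein`
#'   (`wt_protein` + `extension_seq`), `new_stop_codon_index` (codon number
#'   of the next in-frame stop).
#' @examples
#' apply_nonstop("ATGAAATAATTTTGA", "c.7T>C", wt_protein_len = 2)$extension_seq
#' # "QF": TAA -> CAA (Q), then TTT (F), then TGA stops
#' @export
apply_nonstop <- function(cds_seq, hgvs_c, wt_protein_len) {
  cds_seq <- toupper(cds_seq)
  if (grepl("[^ACGT]", cds_seq)) {
    stop_input("cds_seq must contain only A/C/G/T")
  }
  v <- parse_hgvs_c(hgvs_c)
  stop_start <- 3L * wt_protein_len + 1L
  if (nchar(cds_seq) < stop_start + 2L) {
    stop_input("cds_seq too short for a protein of %d residues plus stop codon",
               wt_protein_len)
  }
  if (v$pos < stop_start || v$pos > stop_start + 2L) {
    stop_input("not a nonstop variant: position %d does not hit the stop codon (positions %d-%d)",
               v$pos, stop_start, stop_start + 2L)
  }
  if (substr(cds_seq, v$pos, v$pos) != v$ref) {
    stop_input("reference base mismatch at position %d: variant says '%s', sequence has '%s'",
               v$pos, v$ref, substr(cds_seq, v$pos, v$pos))
  }
  stop_codon <- substr(cds_seq, stop_start, stop_start + 2L)
  if (!Biostrings::GENETIC_CODE[stop_codon] == "*") {
    stop_input("codon at the stated stop position is '%s', not a stop codon",
               stop_codon)
  }
  mutated <- cds_seq
  substr(mutated, v$pos, v$pos) <- v$alt
  new_codon <- substr(mutated, stop_start, stop_start + 2L)
  if (Biostrings::GENETIC_CODE[new_codon] == "*") {
    stop_input("not a nonstop variant: mutated codon '%s' still encodes stop",
               new_codon)
  }
  wt_protein <- paste(
    translate_codons(substr(cds_seq, 1L, stop_start - 1L)), collapse = "")
  downstream <- translate_codons(substr(mutated, stop_start, nchar(mutated)))
  stop_at <- which(downstream == "*")[1]
  if (is.na(stop_at)) {
    stop_input("no terminating codon: no in-frame stop downstream of the variant in the provided sequence")
  }
  extension <- paste(downstream[seq_len(stop_at - 1L)], collapse = "")
  list(wt_protein = wt_protein, extension_seq = extension,
       mutant_protein = paste0(wt_protein, extension),
       new_stop_codon_index = wt_protein_len + stop_at)
}

#' Classify the effect of a C-tail extension
#'
#' Re-classifies a protein's C-terminus after a nonstop extension: the new
#' tail is the wild-type tail plus the extension; the insertion route is
#' re-assigned by the 45-residue rule; and, for `C_ext` proteins only, a
#' misinsertion flag is raised when the extended tail still requires
#' posttranslational insertion but its summed hydrophilicity exceeds the
#' insertase capacity threshold (\eqn{\Delta G^{app} \approx} 5-6 kcal/mol;
#' default flag threshold 5.5, with the outcome at both band edges
#' reported).
#'
#' @param wt_profile One-row tibble from [tail_profile()] for the wild-type
#'   protein.
#' @param extension_seq Amino-acid string appended to the C-tail.
#' @param params A [route_params()].
#' @param misinsertion_threshold Hydrophilicity threshold (kcal/mol) above
#'   which a posttranslational `C_ext` tail is predicted to misinsert
#'   (default 5.5).
#' @param threshold_band Lower/upper bound of the reported threshold band
#'   (default `c(5, 6)`).
#' @param scale A `dg_scale`.
#' @return A one-row tibble: `id`, `orientation`, `extension_seq`,
#'   `wt_tail_len`, `new_tail_len`, `wt_tail_dg`, `new_tail_dg`,
#'   `route_after`, `misinsertion_flag` (`NA` for `C_cyt`),
#'   `misinsertion_at_lower`, `misinsertion_at_upper`, `threshold_used`.
#' @export
classify_effect <- function(wt_profile, extension_seq,
                            params = route_params(),
                            misinsertion_threshold = 5.5,
                            threshold_band = c(5, 6),
                            scale = default_scale()) {
  ext_dg <- tail_hydrophilicity(extension_seq, scale)
  new_len <- wt_profile$tail_len + nchar(extension_seq)
  new_dg <- wt_profile$tail_dg + ext_dg
  route_after <- if (new_len < params$cotranslational_min_tail)
    "posttranslational" else "cotranslational_capable"
  is_cext <- wt_profile$orientation == "C_ext"
  flag_at <- function(thr) {
    if (!is_cext) NA else route_after == "posttranslational" && new_dg > thr
  }
  tibble(
    id = wt_profile$id,
    orientation = wt_profile$orientation,
    extension_seq = extension_seq,
    wt_tail_len = wt_profile$tail_len,
    new_tail_len = new_len,
    wt_tail_dg = wt_profile$tail_dg,
    new_tail_dg = new_dg,
    route_after = route_after,
    misinsertion_flag = flag_at(misinsertion_threshold),
    misinsertion_at_lower = flag_at(min(threshold_band)),
    misinsertion_at_upper = flag_at(max(threshold_band)),
    threshold_used = misinsertion_threshold
  )
}
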