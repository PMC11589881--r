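#' Insertion-route parameters
#'
#' @param cotranslational_min_tail Minimal C-tail length (residues) allowing
#'   cotranslational insertion of the last TM; tails strictly shorter require
#'   posttranslational insertion (default 45 — the length of nascent chain
#'   spanning the ribosome exit tunnel).
#' @param min_tms Minimal TM count for a protein to be retained as
#'   multispanning/translocon-inserted (default 3).
#' @param min_len,max_len Protein length bounds in residues (defaults 18 and
#'   10000).
#' @return A list of class `route_params`.
#' @export
route_params <- function(cotranslational_min_tail = 45L, min_tms = 3L,
                         min_len = 18L, max_len = 10000L) {
  vals <- c(cotranslational_min_tail, min_tms, min_len, max_len)
  if (any(vals <= 0)) stop_config("all route parameters must be positive")
  if (min_len > max_len) stop_config("min_len must be <= max_len")
  structure(list(cotranslational_min_tail = as.integer(cotranslational_min_tail),
                 min_tms = as.integer(min_tms),
                 min_len = as.integer(min_len),
                 max_len = as.integer(max_len)),
            class = "route_params")
}

#' Filter a proteome down to the analysis cohort
#'
#' Applies the cohort filters in order: protein length (retain
#' `[min_len, max_len]`), TM count (retain `>= min_tms` TMs in the
#' consensus), and organelle exclusion (drop IDs on the user-supplied
#' mitochondrial/peroxisomal list). Per-filter removal counts are recorded
#' in application order.
#'
#' @param records Tibble of protein records (from [read_fasta()] or
#'   [make_proteome()]): needs `id`, `sequence`, `length`.
#' @param consensus Tibble from [consensus_table()] (needs `id`, `n_tm`),
#'   covering every record that survives the length filter.
#' @param params A [route_params()].
#' @param exclusion_list Character vector of IDs to drop (organellar
#'   proteins), e.g. from [read_exclusion_list()].
#' @return A list with `cohort` (retained records joined with their
#'   consensus columns) and `counts` (named vector: removed per filter, in
#'   order `length`, `tm`, `organelle`).
#' @export
filter_proteome <- function(records, consensus, params = route_params(),
                            exclusion_list = character()) {
  records <- as_tibble(records)
  n0 <- nrow(records)
  keep <- records |>
    filter(.data$length >= params$min_len, .data$length <= params$max_len)
  n_len <- n0 - nrow(keep)
  missing <- setdiff(keep$id, consensus$id)
  if (length(missing) > 0) {
    stop_input("no consensus topology for id(s): %s",
               paste(head(missing, 5), collapse = ", "))
  }
  keep <- left_join(keep, consensus, by = "id")
  n1 <- nrow(keep)
  keep <- filter(keep, .data$n_tm >= params$min_tms)
  n_tm_removed <- n1 - nrow(keep)
  n2 <- nrow(keep)
  keep <- filter(keep, !.data$id %in% exclusion_list)
  n_org <- n2 - nrow(keep)
  counts <- c(length = n_len, tm = n_tm_removed, organelle = n_org)
  inform(sprintf(
    "filter_proteome: removed %d by length, %d by TM count, %d organellar; %d retained",
    counts[["length"]], counts[["tm"]], counts[["organelle"]], nrow(keep)))
  list(cohort = keep, counts = counts)
}

#' C-terminal tail profile of one protein
#'
#' Characterises the C-terminus of a protein given its consensus topology:
#' the tail is every residue after the last TM's end coordinate; its
#' orientation follows from the side of the C-terminus (`in` = `C_cyt`,
#' cytosolic; `out` = `C_ext`, extracytosolic); the insertion route is
#' assigned by the 45-residue rule (tails strictly shorter than
#' `cotranslational_min_tail` must insert posttranslationally). The tail,
#' the penultimate loop (the loop preceding the last TM) and the N-tail are
#' scored by summed mid-membrane \eqn{\Delta G^{app}}
#' ([tail_hydrophilicity()]).
#'
#' @param record One protein: a one-row tibble/list with `id`, `sequence`
#'   and optionally `signal_peptide_end`.
#' @param consensus A `consensus_topology` (from [merge_topologies()]) or a
#'   bare [topology()]; must have at least one TM.
#' @param params A [route_params()].
#' @param scale A `dg_scale`.
#' @return A one-row tibble: `id`, `n_tm`, `orientation` (`C_cyt`/`C_ext`),
#'   `tail_seq`, `tail_len`, `tail_dg`, `route` (`posttranslational` /
#'   `cotranslational_capable`), `penultimate_loop_dg`, `n_tail_dg`,
#'   `quality`.
#' @export
tail_profile <- function(record, consensus, params = route_params(),
                         scale = default_scale()) {
  topo <- if (inherits(consensus, "consensus_topology")) consensus$topology
          else consensus
  quality <- if (inherits(consensus, "consensus_topology")) consensus$quality
             else NA_character_
  if (!inherits(topo, "topology") || n_tm(topo) == 0) {
    stop_input("tail_profile needs a topology with at least one TM (id '%s')",
               record$id)
  }
  sp <- if ("signal_peptide_end" %in% names(record)) {
    record$signal_peptide_end
  } else {
    NA_integer_
  }
  if (length(sp) == 0) sp <- NA_integer_
  loops <- loops_of(topo, record$sequence, signal_peptide_end = sp)
  ctail <- loops[loops$terminal == "c_tail", ]
  ntail <- loops[loops$terminal == "n_tail", ]
  internal <- loops[loops$terminal == "internal", ]
  penult <- if (nrow(internal) > 0) tail(internal, 1) else NULL
  orientation <- if (c_term_side(topo) == "in") "C_cyt" else "C_ext"
  tail_len <- nchar(ctail$sequence)
  tibble(
    id = record$id,
    n_tm = n_tm(topo),
    orientation = orientation,
    tail_seq = ctail$sequence,
    tail_len = tail_len,
    tail_dg = tail_hydrophilicity(ctail$sequence, scale),
    route = if (tail_len < params$cotranslational_min_tail)
      "posttranslational" else "cotranslational_capable",
    penultimate_loop_dg = if (is.null(penult)) NA_real_
      else tail_hydrophilicity(penult$sequence, scale),
    n_tail_dg = tail_hydrophilicity(ntail$sequence, scale),
    quality = quality
  )
}

#' Profile every protein of a cohort
#'
#' Maps [tail_profile()] over a filtered cohort (output of
#' [filter_proteome()], or any tibble with `id`, `sequence` and a
#' `consensus` list-column), returning one row per protein ordered by `id`.
#'
#' @param cohort Cohort tibble with `id`, `sequence`, `consensus`
#'   (list-column) and optionally `signal_peptide_end`.
#' @inheritParams tail_profile
#' @return A tibble of tail profiles (see [tail_profile()]).
#' @export
profile_cohort <- function(cohort, params = route_params(),
                           scale = default_scale()) {
  purrr::map(seq_len(nrow(cohort)), function(i) {
    tail_profile(cohort[i, ], cohort$consensus[[i]], params = params,
                 scale = scale)
  }) |>
    bind_rows() |>
    arrange(.data$id) |>
    (\(x) structure(x, class = c("ctail_profiles", class(x))))()
}
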