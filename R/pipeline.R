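write_effective_config <- function(out_dir, subcommand, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- c(list(subcommand = subcommand), config)
  jsonlite::write_json(cfg, file.path(out_dir, paste0(subcommand, "_config.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(cfg)
}

#' Pipeline driver: consensus topologies
#'
#' Reads predictor segment tables, merges them per protein into consensus
#' topologies and writes `consensus.tsv` (summary columns) and
#' `consensus.json` (full segments) plus the effective configuration to
#' `out_dir`. Counts per quality label are reported.
#'
#' @param segment_table Path to the predictor segment TSV (see
#'   [read_segment_table()]).
#' @param out_dir Output directory (created if needed).
#' @param params A [consensus_params()].
#' @return The consensus tibble, invisibly.
#' @export
run_consensus <- function(segment_table, out_dir,
                          params = consensus_params()) {
  outputs <- read_segment_table(segment_table)
  cons <- consensus_table(outputs, params)
  tab <- select(cons, -"consensus")
  readr::write_tsv(tab, file.path(out_dir_create(out_dir), "consensus.tsv"),
                   progress = FALSE)
  full <- purrr::map(cons$consensus, function(cc) {
    list(quality = cc$quality, provenance = cc$provenance,
         agreement = as.list(cc$agreement),
         n_term_side = cc$topology$n_term_side,
         segments = cc$topology$segments)
  })
  names(full) <- cons$id
  jsonlite::write_json(full, file.path(out_dir, "consensus.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_effective_config(out_dir, "consensus", unclass(params))
  inform(sprintf("run_consensus: %d proteins (%s)", nrow(cons),
                 paste(sprintf("%s: %d", names(table(cons$quality)),
                               table(cons$quality)), collapse = ", ")))
  invisible(cons)
}

out_dir_create <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out_dir
}

#' Pipeline driver: cohort classification and group comparison
#'
#' Reads a proteome FASTA and a predictor segment table, builds consensus
#' topologies, filters the cohort (length, TM count, organelle exclusion),
#' profiles every C-terminus and writes `cohort.tsv`; when both orientation
#' groups are populated among posttranslational proteins, also writes
#' `comparisons.tsv` with Mann-Whitney comparisons of tail hydrophilicity
#' and length.
#'
#' @param fasta Path to the proteome FASTA.
#' @param segment_table Path to the predictor segment TSV.
#' @param out_dir Output directory.
#' @param exclusions Optional path to a one-ID-per-line exclusion list.
#' @param consensus_parameters A [consensus_params()].
#' @param route_parameters A [route_params()].
#' @return A list with `profiles`, `counts` and `comparisons` (tibble or
#'   `NULL`), invisibly.
#' @export
run_classify <- function(fasta, segment_table, out_dir, exclusions = NULL,
                         consensus_parameters = consensus_params(),
                         route_parameters = route_params()) {
  records <- read_fasta(fasta, min_len = route_parameters$min_len,
                        max_len = route_parameters$max_len)
  cons <- consensus_table(read_segment_table(segment_table),
                          consensus_parameters)
  excl <- read_exclusion_list(exclusions)
  filt <- filter_proteome(records, cons, route_parameters, excl)
  profiles <- profile_cohort(filt$cohort, route_parameters)
  write_cohort_table(profiles, file.path(out_dir_create(out_dir), "cohort.tsv"))
  comparisons <- NULL
  post <- filter(profiles, .data$route == "posttranslational")
  if (all(c("C_cyt", "C_ext") %in% post$orientation)) {
    comparisons <- bind_rows(
      tidy(compare_by_orientation(profiles, "tail_dg")),
      tidy(compare_by_orientation(profiles, "tail_len")))
    comparisons <- mutate(comparisons,
                          metric = c("tail_dg", "tail_len"), .before = 1)
    readr::write_tsv(comparisons, file.path(out_dir, "comparisons.tsv"),
                     progress = FALSE)
  } else {
    inform("run_classify: an orientation group is empty among posttranslational proteins; skipping comparisons")
  }
  write_effective_config(out_dir, "classify",
                         c(unclass(consensus_parameters),
                           unclass(route_parameters),
                           list(exclusions = exclusions %||% "")))
  invisible(list(profiles = profiles, counts = filt$counts,
                 comparisons = comparisons))
}

#' Pipeline driver: nonstop variant effects
#'
#' Applies stop-loss variants to their coding sequences, rebuilds the
#' C-tails against a cohort table of wild-type tail profiles, and writes
#' `variant_effects.tsv`. Variants that fail (not hitting the stop codon,
#' reference mismatch, missing cohort entry) become error rows rather than
#' aborting the run.
#'
#' @param cds_fasta Path to a FASTA of coding sequences (DNA; id =
#'   transcript/protein id, must include stop codon and 3' UTR).
#' @param variants Path to a TSV with columns `id`, `hgvs_c` and/or
#'   `hgvs_p` (when only `hgvs_p` plus an `extension_seq` column are given,
#'   the CDS is not needed).
#' @param cohort Path to a cohort TSV (from [run_classify()] /
#'   [write_cohort_table()]).
#' @param out_dir Output directory.
#' @param route_parameters A [route_params()].
#' @param misinsertion_threshold Threshold passed to [classify_effect()].
#' @return The variant-effect tibble (with an `error` column), invisibly.
#' @export
run_nonstop <- function(cds_fasta = NULL, variants, cohort, out_dir,
                        route_parameters = route_params(),
                        misinsertion_threshold = 5.5) {
  var_tab <- readr::read_tsv(variants, show_col_types = FALSE, progress = FALSE)
  if (!"id" %in% names(var_tab)) stop_input("variants TSV needs an 'id' column")
  prof <- readr::read_tsv(cohort, show_col_types = FALSE, progress = FALSE)
  cds <- NULL
  if (!is.null(cds_fasta)) {
    set <- Biostrings::readDNAStringSet(cds_fasta)
    cds <- setNames(as.character(set), sub("\\s.*$", "", names(set)))
  }
  rows <- purrr::map(seq_len(nrow(var_tab)), function(i) {
    v <- var_tab[i, ]
    res <- tryCatch({
      wt <- prof[prof$id == v$id, ]
      if (nrow(wt) != 1) stop_input("id '%s' not found in the cohort table", v$id)
      has <- function(col) col %in% names(v) && !is.na(v[[col]])
      ext <- if (has("extension_seq")) {
        v$extension_seq
      } else {
        if (is.null(cds) || !v$id %in% names(cds)) {
          stop_input("no CDS available for id '%s'", v$id)
        }
        wt_len <- if (has("hgvs_p")) {
          parse_hgvs_p(v$hgvs_p)$wt_protein_len
        } else if (has("wt_protein_len")) {
          v$wt_protein_len
        } else {
          stop_input("variant for id '%s' needs hgvs_p or a wt_protein_len column to locate the stop codon",
                     v$id)
        }
        apply_nonstop(cds[[v$id]], v$hgvs_c, wt_len)$extension_seq
      }
      eff <- classify_effect(wt, ext, params = route_parameters,
                             misinsertion_threshold = misinsertion_threshold)
      mutate(eff, error = NA_character_)
    }, ctails_input_error = function(e) {
      tibble(id = v$id, error = conditionMessage(e))
    })
    res
  })
  out <- bind_rows(rows)
  readr::write_tsv(out, file.path(out_dir_create(out_dir), "variant_effects.tsv"),
                   progress = FALSE)
  write_effective_config(out_dir, "nonstop",
                         c(unclass(route_parameters),
                           list(misinsertion_threshold = misinsertion_threshold)))
  invisible(out)
}

#' Pipeline driver: insertion quantification
#'
#' Computes %insertion per gel from a band table and aggregates replicates
#' per sample (mean, SEM); writes `insertion.tsv` (per gel) and
#' `insertion_summary.tsv` (per sample). The band table either carries lane
#' PEGylation percentages directly (`peg_untreated`, `peg_nem`, `peg_ams`)
#' or raw band intensities in long form (`sample_id`, `replicate`,
#' `treatment` in mock/NEM/AMS, `band_peg`, `band_unshifted`), optionally
#' corrected by a dilution-series calibration.
#'
#' @param bands Path to the band TSV.
#' @param out_dir Output directory.
#' @param calibration Optional path to a calibration TSV
#'   (`dilution_factor`, `band_intensity`).
#' @return A list with `per_gel` and `summary` tibbles, invisibly.
#' @export
run_insertion <- function(bands, out_dir, calibration = NULL) {
  tab <- readr::read_tsv(bands, show_col_types = FALSE, progress = FALSE)
  cal <- if (!is.null(calibration)) {
    calibrate_densitometry(readr::read_tsv(calibration, show_col_types = FALSE,
                                           progress = FALSE))
  }
  if (all(c("peg_untreated", "peg_nem", "peg_ams") %in% names(tab))) {
    wide <- tab
  } else {
    need <- c("sample_id", "replicate", "treatment", "band_peg", "band_unshifted")
    if (!all(need %in% names(tab))) {
      stop_input("band table must have either peg_* columns or columns %s",
                 paste(need, collapse = ", "))
    }
    treatment_key <- c(mock = "peg_untreated", NEM = "peg_nem", AMS = "peg_ams")
    if (!all(tab$treatment %in% names(treatment_key))) {
      stop_input("treatment must be one of mock, NEM, AMS")
    }
    wide <- tab |>
      mutate(peg = percent_pegylation(.data$band_peg, .data$band_unshifted, cal),
             lane = treatment_key[.data$treatment]) |>
      select("sample_id", "replicate", "lane", "peg") |>
      tidyr::pivot_wider(names_from = "lane", values_from = "peg")
  }
  per_gel <- percent_insertion(wide)
  summary <- per_gel |>
    group_by(.data$sample_id) |>
    dplyr::group_modify(~ aggregate_insertion(.x)) |>
    ungroup()
  readr::write_tsv(per_gel, file.path(out_dir_create(out_dir), "insertion.tsv"),
                   progress = FALSE)
  readr::write_tsv(summary, file.path(out_dir, "insertion_summary.tsv"),
                   progress = FALSE)
  write_effective_config(out_dir, "insertion",
                         list(calibration = calibration %||% ""))
  invisible(list(per_gel = per_gel, summary = summary))
}

#' Pipeline driver: synthetic fixture bundle
#'
#' Generates a synthetic proteome with ground truth and writes the same
#' dialects the readers consume: `proteome.fasta`, `segments.tsv` (three
#' identical or perturbed predictor outputs per protein), `truth.tsv`
#' (ground-truth labels) and the effective simulation spec.
#'
#' @param out_dir Output directory.
#' @param sim_spec A [proteome_sim_spec()].
#' @param perturbation A [perturb_spec()] applied to the predictor outputs.
#' @return A list with `proteome` and `segments` tibbles, invisibly.
#' @export
run_simulate <- function(out_dir, sim_spec = proteome_sim_spec(),
                         perturbation = perturb_spec()) {
  prot <- make_proteome(sim_spec)
  out_dir_create(out_dir)
  writeLines(paste0(">", prot$id, "\n", prot$sequence),
             file.path(out_dir, "proteome.fasta"))
  withr::local_seed(perturbation$seed)
  seg_rows <- purrr::map(seq_len(nrow(prot)), function(i) {
    outs <- make_predictor_outputs(prot$id[i], prot$topology[[i]],
                                   prot$length[i], perturbation, seed = NULL)
    purrr::map(outs, function(po) {
      if (is.null(po$topology)) return(NULL)
      mutate(po$topology$segments,
             id = po$id, source = po$source,
             n_term_side = po$topology$n_term_side,
             tests_passed = po$tests_passed)
    }) |> bind_rows()
  }) |> bind_rows()
  seg_rows <- select(seg_rows, "id", "source", "n_term_side", "start", "end",
                     "tests_passed")
  readr::write_tsv(seg_rows, file.path(out_dir, "segments.tsv"),
                   progress = FALSE)
  truth <- select(prot, "id", "true_orientation", "true_route",
                  "true_tail_len", "true_tail_dg", "n_tm")
  readr::write_tsv(truth, file.path(out_dir, "truth.tsv"), progress = FALSE)
  write_effective_config(out_dir, "simulate",
                         c(unclass(sim_spec)[setdiff(names(unclass(sim_spec)),
                                                     c("tail_len", "tail_dg"))],
                           list(perturbation = unclass(perturbation))))
  invisible(list(proteome = prot, segments = seg_rows))
}
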