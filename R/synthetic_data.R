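#' Specification for a synthetic proteome
#'
#' Describes a cohort of synthetic multispanning membrane proteins with
#' known ground truth. Defaults emulate the structure of a
#' posttranslational-insertion cohort: half the proteins carry an
#' extracytosolic C-terminus (`C_ext`), whose C-tails are short (negative
#' binomial, mean 8 residues) and only mildly hydrophilic (target summed
#' \eqn{\Delta G^{app}} of mean 3, SD 1.5 kcal/mol — below the ~5-6
#' insertase capacity band), while `C_cyt` tails are longer (mean 25) and
#' markedly hydrophilic (mean 15, SD 5 kcal/mol).
#'
#' @param n_proteins Number of proteins.
#' @param tm_count_range Integer range of TM counts (default 3:10).
#' @param frac_c_ext Probability that a protein is `C_ext` (default 0.5).
#' @param tail_len Per-orientation tail-length distributions: a list with
#'   elements `C_cyt` and `C_ext`, each `list(family, ...)` where family is
#'   `"nbinom"` (`mu`, `size`) or `"uniform"` (`min`, `max`).
#' @param tail_dg Per-orientation targets for the summed tail
#'   \eqn{\Delta G^{app}}: list with `C_cyt` and `C_ext`, each
#'   `list(mean, sd)` in kcal/mol.
#' @param loop_len_range Integer range of internal loop lengths (default
#'   5:30).
#' @param tm_len TM helix length in residues (default 21).
#' @param dg_tolerance Acceptable deviation of an achieved tail
#'   \eqn{\Delta G^{app}} from its drawn target (default 0.5 kcal/mol).
#' @param seed Integer seed fixing all downstream randomness.
#' @return A list of class `proteome_sim_spec`.
#' @export
proteome_sim_spec <- function(n_proteins = 100,
                              tm_count_range = 3:10,
                              frac_c_ext = 0.5,
                              tail_len = list(
                                C_cyt = list(family = "nbinom", mu = 25, size = 3),
                                C_ext = list(family = "nbinom", mu = 8, size = 3)),
                              tail_dg = list(
                                C_cyt = list(mean = 15, sd = 5),
                                C_ext = list(mean = 3, sd = 1.5)),
                              loop_len_range = 5:30,
                              tm_len = 21L,
                              dg_tolerance = 0.5,
                              seed = 1L) {
  if (frac_c_ext < 0 || frac_c_ext > 1) stop_config("frac_c_ext must be in [0, 1]")
  if (length(tm_count_range) == 0 || length(loop_len_range) == 0) {
    stop_config("ranges must be non-empty")
  }
  structure(list(n_proteins = n_proteins, tm_count_range = tm_count_range,
                 frac_c_ext = frac_c_ext, tail_len = tail_len,
                 tail_dg = tail_dg, loop_len_range = loop_len_range,
                 tm_len = as.integer(tm_len), dg_tolerance = dg_tolerance,
                 seed = as.integer(seed)),
            class = "proteome_sim_spec")
}

HYDROPHOBIC_AA <- c("L", "I", "F", "V", "A", "M")

sample_tail_len <- function(d) {
  switch(d$family,
         nbinom = stats::rnbinom(1, mu = d$mu, size = d$size),
         uniform = sample(d$min:d$max, 1),
         stop_config("unknown tail length family '%s'", d$family))
}

# Build a random sequence of given length whose summed mid-membrane dG is
# within tol of target, by greedy single-residue swaps against the scale.
compose_tail <- function(len, target, tol, scale) {
  aa <- names(scale$per_residue_mid)
  vals <- scale$per_residue_mid
  if (len == 0L) {
    return(if (abs(target) <= tol) "" else NULL)
  }
  lo <- len * min(vals)
  hi <- len * max(vals)
  if (target < lo - tol || target > hi + tol) return(NULL)
  letters <- sample(aa, len, replace = TRUE)
  total <- sum(vals[letters])
  for (iter in seq_len(20L * len)) {
    if (abs(total - target) <= tol) break
    i <- sample.int(len, 1)
    # replacement bringing the sum closest to the target
    cand <- total - vals[letters[i]] + vals
    best <- aa[which.min(abs(cand - target))]
    total <- total - vals[letters[i]] + vals[best]
    letters[i] <- best
  }
  if (abs(total - target) > tol) return(NULL)
  paste(letters, collapse = "")
}

#' Generate a synthetic proteome with ground truth
#'
#' Builds `n_proteins` synthetic multispanning proteins. Each protein gets
#' an orientation (`C_cyt`/`C_ext`) drawn with probability `frac_c_ext`, a
#' TM count, alternating-side topology consistent with the orientation
#' (the N-terminal side is back-computed by parity), hydrophobic TM
#' segments, random internal loops, and a C-tail whose length is drawn from
#' the orientation's distribution and whose summed \eqn{\Delta G^{app}} is
#' steered to a drawn target by greedy composition search (achieved value
#' within `dg_tolerance`; unreachable targets are resampled with a logged
#' count). Ground-truth labels ride along.
#'
#' @param spec A [proteome_sim_spec()].
#' @param scale A `dg_scale`.
#' @return A tibble with one row per protein: `id`, `sequence`, `length`,
#'   `topology` (list-column of [topology()]), plus ground truth columns
#'   `true_orientation`, `true_route`, `true_tail_len`, `true_tail_dg`
#'   (achieved), `tail_dg_target` (drawn), `n_tm`, `n_resampled`.
#' @export
make_proteome <- function(spec = proteome_sim_spec(),
                          scale = default_scale()) {
  withr::local_seed(spec$seed)
  rows <- purrr::map(seq_len(spec$n_proteins), function(k) {
    orientation <- if (stats::runif(1) < spec$frac_c_ext) "C_ext" else "C_cyt"
    n_tm <- sample(spec$tm_count_range, 1)
    c_side <- if (orientation == "C_ext") "out" else "in"
    n_side <- flip_side(c_side, n_tm)
    # draw tail length and a reachable dG target
    dist <- spec$tail_len[[orientation]]
    tg <- spec$tail_dg[[orientation]]
    n_resampled <- 0L
    tail_seq <- NULL
    repeat {
      tail_len <- sample_tail_len(dist)
      target <- stats::rnorm(1, tg$mean, tg$sd)
      tail_seq <- compose_tail(tail_len, target, spec$dg_tolerance, scale)
      if (!is.null(tail_seq)) break
      n_resampled <- n_resampled + 1L
      if (n_resampled > 100L) {
        stop_input("cannot reach tail dG target after 100 resamples; check tail_len/tail_dg settings")
      }
    }
    n_tail <- paste(sample(names(scale$per_residue_mid),
                           sample(spec$loop_len_range, 1), replace = TRUE),
                    collapse = "")
    pieces <- n_tail
    starts <- integer(n_tm)
    ends <- integer(n_tm)
    pos <- nchar(n_tail)
    for (t in seq_len(n_tm)) {
      tm <- paste(sample(HYDROPHOBIC_AA, spec$tm_len, replace = TRUE),
                  collapse = "")
      starts[t] <- pos + 1L
      ends[t] <- pos + spec$tm_len
      pieces <- c(pieces, tm)
      pos <- pos + spec$tm_len
      if (t < n_tm) {
        loop <- paste(sample(names(scale$per_residue_mid),
                             sample(spec$loop_len_range, 1), replace = TRUE),
                      collapse = "")
        pieces <- c(pieces, loop)
        pos <- pos + nchar(loop)
      }
    }
    pieces <- c(pieces, tail_seq)
    seqc <- paste(pieces, collapse = "")
    topo <- topology(tibble(start = starts, end = ends), n_side)
    tibble(id = sprintf("synp%04d", k), sequence = seqc,
           length = nchar(seqc), topology = list(topo),
           true_orientation = orientation,
           true_route = if (tail_len < 45) "posttranslational"
                        else "cotranslational_capable",
           true_tail_len = as.integer(tail_len),
           true_tail_dg = tail_hydrophilicity(tail_seq, scale),
           tail_dg_target = target,
           n_tm = n_tm, n_resampled = n_resampled)
  })
  bind_rows(rows)
}

#' Specification of predictor-output perturbations
#'
#' @param center_jitter_sd SD (residues) of the Gaussian jitter applied to
#'   each TM segment's position, per predictor (default 0).
#' @param p_drop_tm,p_add_tm Probability of dropping/adding one TM per
#'   predictor (defaults 0).
#' @param p_missing Probability a predictor returns nothing (default 0).
#' @param seed Integer seed.
#' @return A list of class `perturb_spec`.
#' @export
perturb_spec <- function(center_jitter_sd = 0, p_drop_tm = 0, p_add_tm = 0,
                         p_missing = 0, seed = 1L) {
  probs <- c(p_drop_tm, p_add_tm, p_missing)
  if (any(probs < 0 | probs > 1)) stop_config("probabilities must be in [0, 1]")
  if (center_jitter_sd < 0) stop_config("center_jitter_sd must be >= 0")
  structure(list(center_jitter_sd = center_jitter_sd, p_drop_tm = p_drop_tm,
                 p_add_tm = p_add_tm, p_missing = p_missing,
                 seed = as.integer(seed)),
            class = "perturb_spec")
}

perturb_topology <- function(truth, spec, protein_len) {
  segs <- truth$segments
  fired <- character()
  if (spec$p_drop_tm > 0 && nrow(segs) > 1 &&
      stats::runif(1) < spec$p_drop_tm) {
    segs <- segs[-sample.int(nrow(segs), 1), ]
    fired <- c(fired, "drop_tm")
  }
  if (spec$p_add_tm > 0 && stats::runif(1) < spec$p_add_tm) {
    # insert a 15-residue segment into the widest gap if it fits
    gaps_start <- c(1L, segs$end + 2L)
    gaps_end <- c(segs$start - 2L, protein_len)
    widths <- gaps_end - gaps_start + 1L
    g <- which.max(widths)
    if (widths[g] >= 17L) {
      s <- gaps_start[g] + 1L
      segs <- arrange(bind_rows(segs, tibble(start = s, end = s + 14L,
                                             center = (2L * s + 14L) %/% 2L)),
                      .data$start)
      fired <- c(fired, "add_tm")
    }
  }
  if (spec$center_jitter_sd > 0 && nrow(segs) > 0) {
    delta <- round(stats::rnorm(nrow(segs), 0, spec$center_jitter_sd))
    cand <- mutate(segs, start = .data$start + delta, end = .data$end + delta)
    ok <- all(cand$start >= 1) && all(cand$end <= protein_len) &&
      (nrow(cand) < 2 || all(cand$start[-1] > cand$end[-nrow(cand)] + 1L))
    if (ok && any(delta != 0)) {
      segs <- cand
      fired <- c(fired, "jitter")
    }
  }
  list(topology = topology(segs[, c("start", "end")], truth$n_term_side),
       fired = fired)
}

#' Generate perturbed predictor outputs from a true topology
#'
#' Emulates discordant predictors: for each of the three sources
#' independently, the true topology is either dropped (`p_missing`) or
#' copied and perturbed (centre jitter, TM drop/add). With all perturbation
#' probabilities zero the three outputs are identical to the truth and the
#' consensus is labelled `high`.
#'
#' @param id Protein id.
#' @param truth The true [topology()].
#' @param protein_len Protein length (bounds the jitter).
#' @param spec A [perturb_spec()]. The spec's seed is applied by the caller
#'   or via `seed`.
#' @param seed Optional seed overriding `spec$seed`; `NULL` leaves the RNG
#'   state alone (for use inside a seeded loop).
#' @return A list of three [predictor_output()]s (sources `cctop`,
#'   `tmalphafold`, `polyphobius`; missing ones have `NULL` topology) with
#'   attribute `"perturbations"` naming what fired per source.
#' @export
make_predictor_outputs <- function(id, truth, protein_len,
                                   spec = perturb_spec(), seed = spec$seed) {
  if (!is.null(seed)) withr::local_seed(seed)
  fired <- list()
  outs <- purrr::map(c("cctop", "tmalphafold", "polyphobius"), function(src) {
    if (spec$p_missing > 0 && stats::runif(1) < spec$p_missing) {
      fired[[src]] <<- "missing"
      return(predictor_output(id, src, topology = NULL,
                              tests_passed = if (src == "tmalphafold") 10L
                                             else NA_integer_))
    }
    pert <- perturb_topology(truth, spec, protein_len)
    fired[[src]] <<- pert$fired
    predictor_output(id, src, topology = pert$topology,
                     tests_passed = if (src == "tmalphafold") 10L
                                    else NA_integer_)
  })
  attr(outs, "perturbations") <- fired
  outs
}

CODONS_BY_AA <- split(names(Biostrings::GENETIC_CODE),
                      unname(Biostrings::GENETIC_CODE))

hamming1 <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]) == 1L
}

#' Generate a CDS and a nonstop variant reproducing a given extension
#'
#' Reverse-translates a protein (uniform codon choice), appends a stop
#' codon, codons for an extension peptide, a second stop and a random 3'
#' tail — then emits the single-base coding variant that converts the first
#' stop codon into a codon for the extension's first residue. Round trip:
#' [apply_nonstop()] on the output reproduces `extension_peptide` exactly.
#'
#' Only extensions whose first residue is one point mutation away from a
#' stop codon are constructible (as for natural single-nucleotide nonstop
#' variants): K, Q, E, S, L, Y, W, R, G or C.
#'
#' @param protein_seq Wild-type protein sequence (amino acids).
#' @param extension_peptide Extension translated after the lost stop
#'   (non-empty).
#' @param utr3_len Length of the random 3' tail after the new stop codon
#'   (default 30 nt).
#' @param seed Integer seed.
#' @return A list: `cds_seq`, `hgvs_c`, `hgvs_p`, `wt_protein_len`.
#' @export
make_cds <- function(protein_seq, extension_peptide, utr3_len = 30L,
                     seed = 1L) {
  withr::local_seed(seed)
  if (nchar(extension_peptide) == 0) stop_input("extension_peptide must be non-empty")
  check_residues(protein_seq, "protein_seq")
  check_residues(extension_peptide, "extension_peptide")
  first <- substr(extension_peptide, 1, 1)
  stops <- CODONS_BY_AA[["*"]]
  pairs <- expand.grid(stop = stops, new = CODONS_BY_AA[[first]],
                       stringsAsFactors = FALSE)
  pairs <- pairs[mapply(hamming1, pairs$stop, pairs$new), , drop = FALSE]
  if (nrow(pairs) == 0) {
    stop_input("no stop codon is one substitution away from a codon for '%s'; a single-base nonstop variant cannot produce this extension",
               first)
  }
  pick <- pairs[sample.int(nrow(pairs), 1), ]
  rev_tr <- function(aas) {
    paste(vapply(strsplit(aas, "")[[1]],
                 function(a) sample(CODONS_BY_AA[[a]], 1), character(1)),
          collapse = "")
  }
  wt_len <- nchar(protein_seq)
  cds <- paste0(
    rev_tr(protein_seq),
    pick$stop,
    if (nchar(extension_peptide) > 1)
      rev_tr(substr(extension_peptide, 2, nchar(extension_peptide))) else "",
    sample(stops, 1),
    paste(sample(c("A", "C", "G", "T"), utr3_len, replace = TRUE),
          collapse = ""))
  diff_pos <- which(strsplit(pick$stop, "")[[1]] != strsplit(pick$new, "")[[1]])
  pos <- 3L * wt_len + diff_pos
  list(cds_seq = cds,
       hgvs_c = sprintf("c.%d%s>%s", pos,
                        substr(pick$stop, diff_pos, diff_pos),
                        substr(pick$new, diff_pos, diff_pos)),
       hgvs_p = sprintf("p.Ter%d%s", wt_len + 1L,
                        names(AA3_TO_1)[AA3_TO_1 == first]),
       wt_protein_len = wt_len)
}

#' Generate synthetic gel quantifications with known true insertion
#'
#' Inverts the %insertion statistic: lane PEGylation values are constructed
#' so that the noiseless statistic equals `true_insertion` exactly
#' (`peg_untreated` = 90, `peg_nem` = 10 by default), then multiplicative
#' lognormal noise with coefficient of variation `noise_cv` is applied to
#' each band independently (mean-corrected so each lane's expectation is its
#' noiseless value). Values are clipped to the physical ranges the
#' statistic's preconditions require.
#'
#' @param true_insertion True percent insertion in \[0, 100\].
#' @param noise_cv Coefficient of variation of the per-band noise
#'   (default 0).
#' @param n_replicates Number of replicate gels (default 3).
#' @param peg_untreated,peg_nem Noiseless anchor lanes (defaults 90 and 10).
#' @param seed Integer seed.
#' @return A tibble of [percent_insertion()] input rows (`sample_id`,
#'   `replicate`, `peg_untreated`, `peg_nem`, `peg_ams`) with attribute
#'   `"true_insertion"`.
#' @export
make_gels <- function(true_insertion, noise_cv = 0, n_replicates = 3L,
                      peg_untreated = 90, peg_nem = 10, seed = 1L) {
  withr::local_seed(seed)
  if (true_insertion < 0 || true_insertion > 100) {
    stop_input("true_insertion must be in [0, 100]")
  }
  peg_ams <- peg_untreated *
    (1 - true_insertion / 100 * (1 - peg_nem / peg_untreated))
  noisy <- function(x) {
    if (noise_cv == 0) return(rep(x, n_replicates))
    sdlog <- sqrt(log(1 + noise_cv^2))
    x * stats::rlnorm(n_replicates, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  u <- pmin(100, noisy(peg_untreated))
  nem <- noisy(peg_nem)
  ams <- pmin(100, noisy(peg_ams))
  nem <- pmin(nem, u * 0.999) # preserve the NEM < untreated precondition
  tibble(sample_id = "sim", replicate = seq_len(n_replicates),
         peg_untreated = u, peg_nem = nem, peg_ams = ams) |>
    structure(true_insertion = true_insertion)
}
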