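# Shared fixture builders (all fixtures are generated in code).

# Quick topology: TM segments given as start positions, fixed length.
topo_at <- function(starts, len = 19L, n_term_side = "in") {
  topology(data.frame(start = starts, end = starts + len - 1L), n_term_side)
}

# Wrap a bare topology as the consensus object tail_profile() accepts.
as_consensus <- function(topo, quality = "high", provenance = "cctop") {
  structure(list(topology = topo, quality = quality, provenance = provenance,
                 agreement = character()),
            class = "consensus_topology")
}

# A consensus list-column for a make_proteome() tibble (perfect topologies).
with_perfect_consensus <- function(proteome) {
  proteome$consensus <- lapply(proteome$topology, as_consensus)
  proteome
}

# Write a FASTA of named sequences to a temp file.
write_temp_fasta <- function(seqs, ext = ".fasta") {
  path <- tempfile(fileext = ext)
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}

# Random protein sequence over the 20 standard letters.
random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# Independent brute-force minimum over all (center, length) helix windows
# whose center is within slack of tm_center -- oracle for min_dg_near_center.
brute_min_dg <- function(seq, tm_center, slack, helix_lengths = 19:23,
                         positional = TRUE) {
  best <- NULL
  for (len in helix_lengths) {
    for (ctr in (tm_center - slack):(tm_center + slack)) {
      start <- ctr - (len - 1L) %/% 2L
      end <- start + len - 1L
      if (start < 1L || end > nchar(seq)) next
      sc <- segment_dg(seq, start, len, positional = positional,
                       helix_lengths = helix_lengths)
      if (is.null(best) || sc$dg_app < best$dg_app) best <- sc
    }
  }
  best
}

# Exhaustive two-sided Mann-Whitney p by enumerating all assignments of the
# pooled ranks to group a (no ties assumed) -- oracle for the exact method.
enumerate_mw_p <- function(x, y) {
  n_a <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  combos <- utils::combn(length(pooled), n_a)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n_a * (n_a + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(1, p)
}
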