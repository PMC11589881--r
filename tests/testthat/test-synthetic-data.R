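test_that("generators are deterministic functions of spec and seed", {
  s <- proteome_sim_spec(n_proteins = 15, seed = 9)
  p1 <- suppressMessages(make_proteome(s))
  p2 <- suppressMessages(make_proteome(s))
  expect_identical(p1$sequence, p2$sequence)
  expect_identical(p1$true_tail_dg, p2$true_tail_dg)
  p3 <- suppressMessages(make_proteome(proteome_sim_spec(n_proteins = 15, seed = 10)))
  expect_false(identical(p1$sequence, p3$sequence))

  c1 <- make_cds("MKTWHF", "QSW", seed = 4)
  c2 <- make_cds("MKTWHF", "QSW", seed = 4)
  expect_identical(c1, c2)

  g1 <- make_gels(60, noise_cv = 0.1, n_replicates = 5, seed = 2)
  g2 <- make_gels(60, noise_cv = 0.1, n_replicates = 5, seed = 2)
  expect_identical(g1$peg_ams, g2$peg_ams)
})

test_that("achieved tail hydrophilicity hits the drawn target within tolerance", {
  spec <- proteome_sim_spec(n_proteins = 60, seed = 17)
  prot <- suppressMessages(make_proteome(spec))
  expect_true(all(abs(prot$true_tail_dg - prot$tail_dg_target) <=
                    spec$dg_tolerance))
  # orientations appear in roughly the requested mix
  expect_gt(sum(prot$true_orientation == "C_ext"), 10)
  expect_gt(sum(prot$true_orientation == "C_cyt"), 10)
  # a frac_c_ext = 1 cohort with short tails is all (C_ext, posttranslational)
  all_ext <- suppressMessages(make_proteome(proteome_sim_spec(
    n_proteins = 10, frac_c_ext = 1,
    tail_len = list(C_cyt = list(family = "uniform", min = 1, max = 10),
                    C_ext = list(family = "uniform", min = 1, max = 10)),
    seed = 2)))
  prof <- profile_cohort(with_perfect_consensus(all_ext))
  expect_true(all(prof$orientation == "C_ext"))
  expect_true(all(prof$route == "posttranslational"))
})

test_that("unperturbed predictor outputs reproduce the truth and merge as high quality", {
  prot <- suppressMessages(make_proteome(proteome_sim_spec(n_proteins = 5, seed = 3)))
  for (i in 1:5) {
    outs <- make_predictor_outputs(prot$id[i], prot$topology[[i]],
                                   prot$length[i], perturb_spec(seed = i))
    cons <- merge_topologies(outs[[1]], outs[[2]], outs[[3]])
    expect_equal(cons$quality, "high")
    expect_identical(cons$topology$segments, prot$topology[[i]]$segments)
  }
})

test_that("forced perturbations exercise the intended consensus branches", {
  prot <- suppressMessages(make_proteome(proteome_sim_spec(n_proteins = 1, seed = 6)))
  topo <- prot$topology[[1]]
  # dropping a TM from one source breaks three-way agreement
  set.seed(1)
  drop_one <- ctails:::perturb_topology(topo, perturb_spec(p_drop_tm = 1),
                                        prot$length[1])
  expect_equal(n_tm(drop_one$topology), n_tm(topo) - 1L)
  expect_true("drop_tm" %in% drop_one$fired)
  cons <- merge_topologies(predictor_output("p", "cctop", topo),
                           predictor_output("p", "tmalphafold", topo, 10L),
                           predictor_output("p", "polyphobius", drop_one$topology))
  expect_equal(cons$provenance, "cctop")
  expect_false("tmalphafold~polyphobius" %in% cons$agreement)
  # a missing source is a NULL topology, not a crash
  outs <- make_predictor_outputs(prot$id[1], topo, prot$length[1],
                                 perturb_spec(p_missing = 1, seed = 5))
  expect_true(all(vapply(outs, function(o) is.null(o$topology), logical(1))))
})

test_that("center jitter bounded by 3 residues keeps all pairs in agreement at window 14", {
  prot <- suppressMessages(make_proteome(proteome_sim_spec(n_proteins = 8, seed = 14)))
  for (i in seq_len(nrow(prot))) {
    outs <- make_predictor_outputs(prot$id[i], prot$topology[[i]],
                                   prot$length[i],
                                   perturb_spec(center_jitter_sd = 1, seed = i))
    topos <- purrr::compact(purrr::map(outs, "topology"))
    deltas <- purrr::map_dbl(topos, function(t) {
      if (n_tm(t) != n_tm(prot$topology[[i]])) return(Inf)
      max(abs(t$segments$center - prot$topology[[i]]$segments$center))
    })
    # sd-1 jitter essentially never exceeds |3|; all pairs must still agree
    if (all(deltas <= 3)) {
      for (a in seq_along(topos)) for (b in seq_along(topos)) {
        expect_true(topologies_agree(topos[[a]], topos[[b]]))
      }
    }
  }
})

test_that("generated coding variants are internally consistent", {
  mc <- make_cds("MAGW", "KNN", seed = 11)
  v <- parse_hgvs_c(mc$hgvs_c)
  expect_equal(substr(mc$cds_seq, v$pos, v$pos), v$ref)
  r <- apply_nonstop(mc$cds_seq, mc$hgvs_c, mc$wt_protein_len)
  expect_equal(r$extension_seq, "KNN")
  expect_equal(r$wt_protein, "MAGW")
  # an extension starting with a residue unreachable by one substitution
  expect_error(make_cds("MAGW", "PLL", seed = 1), "single-base nonstop")
})

test_that("gel noise model preserves lane expectations and preconditions", {
  g <- make_gels(50, noise_cv = 0.2, n_replicates = 200, seed = 31)
  expect_true(all(g$peg_nem < g$peg_untreated))
  expect_true(all(g$peg_untreated <= 100))
  expect_equal(mean(g$peg_untreated), 90, tolerance = 0.05)
  res <- percent_insertion(g)
  expect_true(all(res$percent_insertion >= 0 & res$percent_insertion <= 100))
})
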