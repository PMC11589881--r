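test_that("per-residue topology strings parse to segments and orientation", {
  po <- read_topology_string("p1", "iiiMMMMMMMMMMMMMMMMMMMooo")
  expect_equal(po$topology$segments$start, 4L)
  expect_equal(po$topology$segments$end, 22L)
  expect_equal(po$topology$n_term_side, "in")
  expect_equal(c_term_side(po$topology), "out")

  po2 <- read_topology_string("p2", "ooMMMMMMMMMMMMMMMMMMMiiMMMMMMMMMMMMMMMMMMMoo")
  expect_equal(n_tm(po2$topology), 2L)
  expect_equal(po2$topology$n_term_side, "out")
  expect_equal(c_term_side(po2$topology), "out")

  sp <- read_topology_string("p3", paste0("SSSS", "iii", strrep("M", 19), "oo"))
  expect_equal(sp$signal_peptide_end, 4L)
  expect_equal(sp$topology$n_term_side, "in")

  expect_error(read_topology_string("bad", "iiMxMM"), "'x'")
  expect_error(read_topology_string("bad", strrep("M", 20)), "orientation undefined")
})

test_that("topology round-trips through its string form", {
  set.seed(11)
  for (k in 1:20) {
    n_seg <- sample(1:4, 1)
    starts <- cumsum(sample(20:30, n_seg, replace = TRUE))
    topo <- topo_at(starts, n_term_side = sample(c("in", "out"), 1))
    len <- max(topo$segments$end) + sample(0:25, 1)
    s <- topology_string(topo, len)
    back <- read_topology_string("x", s)$topology
    expect_equal(back$segments, topo$segments)
    expect_equal(back$n_term_side, topo$n_term_side)
  }
})

test_that("loops tile the sequence exactly with alternating sides", {
  set.seed(23)
  for (k in 1:15) {
    n_seg <- sample(1:5, 1)
    starts <- cumsum(sample(21:30, n_seg, replace = TRUE))
    topo <- topo_at(starts, n_term_side = sample(c("in", "out"), 1))
    seqlen <- max(topo$segments$end) + sample(0:30, 1)
    seqc <- random_protein(seqlen)
    loops <- loops_of(topo, seqc)
    # tiling: loop + TM residues reconstruct the full sequence
    pieces <- dplyr::bind_rows(
      loops[, c("start", "end")],
      topo$segments[, c("start", "end")]) |>
      dplyr::filter(start <= end) |>
      dplyr::arrange(start)
    expect_equal(pieces$start[1], 1L)
    expect_equal(pieces$end[nrow(pieces)], seqlen)
    expect_true(all(pieces$start[-1] == pieces$end[-nrow(pieces)] + 1L))
    # side alternation across consecutive loops
    expect_true(all(loops$side[-1] != loops$side[-nrow(loops)]))
    # C-tail side: n_term_side flipped once per TM
    ctail <- loops[loops$terminal == "c_tail", ]
    expected_side <- if (n_seg %% 2 == 0) topo$n_term_side else
      setdiff(c("in", "out"), topo$n_term_side)
    expect_equal(ctail$side, expected_side)
  }
})

test_that("C-tail side parity matches TM-count arithmetic", {
  t1 <- topo_at(10, n_term_side = "in")
  expect_equal(loops_of(t1, random_protein(40))$side[2], "out")
  t6 <- topo_at(cumsum(rep(25, 6)), n_term_side = "in")
  loops6 <- loops_of(t6, random_protein(200))
  expect_equal(loops6$side[loops6$terminal == "c_tail"], "in")
  t9 <- topo_at(cumsum(rep(25, 9)), n_term_side = "in")
  loops9 <- loops_of(t9, random_protein(280))
  expect_equal(loops9$side[loops9$terminal == "c_tail"], "out")
})

test_that("signal-peptide residues are excluded from the N-tail sequence", {
  topo <- topo_at(20, n_term_side = "in")
  seqc <- random_protein(60)
  loops <- loops_of(topo, seqc, signal_peptide_end = 5L)
  ntail <- loops[loops$terminal == "n_tail", ]
  expect_equal(ntail$start, 6L)
  expect_equal(ntail$sequence, substr(seqc, 6, 19))
})

test_that("FASTA reading substitutes selenocysteine and flags lengths", {
  path <- write_temp_fasta(c(p1 = "MKTWHF", p2 = paste0("MKU", strrep("A", 20)),
                             tiny = "MKTWH"))
  expect_message(recs <- read_fasta(path), "selenocysteine")
  expect_equal(nrow(recs), 3L)
  expect_equal(recs$length[recs$id == "p1"], 6L)
  expect_equal(substr(recs$sequence[recs$id == "p2"], 3, 3), "C")
  expect_equal(recs$n_u_substituted[recs$id == "p2"], 1L)
  expect_false(recs$length_ok[recs$id == "tiny"]) # < 18 residues
  expect_false(recs$length_ok[recs$id == "p1"])

  dup <- write_temp_fasta(c(a = "MKTW", a = "MKTF"))
  expect_error(read_fasta(dup), "duplicate")
})

test_that("segment tables group rows into predictor outputs and reject overlap", {
  tab <- tibble::tibble(
    id = c("p1", "p1", "p1"),
    source = c("cctop", "cctop", "tmalphafold"),
    n_term_side = "in",
    start = c(10L, 40L, 11L),
    end = c(30L, 60L, 31L),
    tests_passed = c(NA, NA, 4L))
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(tab, path)
  outs <- read_segment_table(path)
  expect_length(outs, 2L)
  srcs <- vapply(outs, function(o) o$source, character(1))
  cct <- outs[[which(srcs == "cctop")]]
  expect_equal(n_tm(cct$topology), 2L)
  tmaf <- outs[[which(srcs == "tmalphafold")]]
  expect_equal(tmaf$tests_passed, 4L) # retained; consensus filters it later

  bad <- tab
  bad$start[2] <- 25L # overlaps the first segment
  readr::write_tsv(bad, path)
  expect_error(read_segment_table(path), "non-overlapping")

  mal <- tab
  mal$n_term_side[3] <- "inside"
  readr::write_tsv(mal, path)
  expect_error(read_segment_table(mal_path <- path), "line")
})
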