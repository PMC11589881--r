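# Single-TM topology whose center is at `center`.
topo_center <- function(center, n_term_side = "in") {
  topo_at(center - 9L, len = 19L, n_term_side = n_term_side)
}

po_of <- function(topo, source, tests_passed = NA_integer_) {
  predictor_output("p", source, topology = topo, tests_passed = tests_passed)
}

test_that("agreement requires equal TM counts and centers within half the window", {
  p <- consensus_params(center_window = 14)
  a <- topo_center(30)
  expect_true(topologies_agree(a, a, p))
  expect_true(topologies_agree(a, topo_center(37), p))  # |d| = 7
  expect_false(topologies_agree(a, topo_center(38), p)) # |d| = 8 breaks it
  two <- topo_at(c(20, 60))
  expect_false(topologies_agree(a, two, p)) # 1 vs 2 TMs
  six <- topo_at(cumsum(rep(25, 6)))
  seven <- topo_at(cumsum(rep(25, 7)))
  expect_false(topologies_agree(six, seven, p))
})

test_that("three agreeing predictors give a high-quality CCTOP-coordinate consensus", {
  t <- topo_center(30)
  cons <- merge_topologies(po_of(t, "cctop"), po_of(t, "tmalphafold", 10L),
                           po_of(t, "polyphobius"))
  expect_equal(cons$quality, "high")
  expect_equal(cons$provenance, "cctop")
  expect_setequal(cons$agreement,
                  c("cctop~tmalphafold", "tmalphafold~polyphobius",
                    "cctop~polyphobius"))
})

test_that("missing data falls back to PolyPhobius with low quality", {
  t <- topo_center(30)
  cons <- merge_topologies(polyphobius = po_of(t, "polyphobius"))
  expect_equal(cons$provenance, "polyphobius")
  expect_equal(cons$quality, "low")
  expect_error(merge_topologies(), "no topology")
})

test_that("a sub-threshold TMAlphaFold structure-test count discards that source", {
  t <- topo_center(30)
  cons <- merge_topologies(po_of(t, "cctop"), po_of(t, "tmalphafold", 4L),
                           po_of(topo_center(60), "polyphobius"))
  # tmaf discarded; cctop and poly disagree -> fallback to polyphobius
  expect_equal(cons$provenance, "polyphobius")
  expect_equal(cons$quality, "low")
  expect_length(cons$agreement, 0L)
})

test_that("merging matches a rule-table oracle over all presence and agreement patterns", {
  params <- consensus_params()
  centers <- c(20L, 27L, 34L, 60L) # pairwise gaps 7 (agree) or >= 14 (disagree)
  rank_q <- c(low = 1, medium = 2, high = 3)
  oracle <- function(cc, tm, pp, agree) {
    if (!is.null(cc) && !is.null(tm) && !is.null(pp) &&
        agree("c", "t") && agree("t", "p") && agree("c", "p")) {
      return(c("cctop", "high"))
    }
    if (!is.null(cc) && !is.null(tm) && agree("c", "t")) return(c("cctop", params$two_way_quality))
    if (!is.null(tm) && !is.null(pp) && agree("t", "p")) return(c("tmalphafold", params$two_way_quality))
    if (!is.null(pp)) return(c("polyphobius", "low"))
    if (!is.null(cc)) return(c("cctop", "low"))
    c("tmalphafold", "low")
  }
  n_cases <- 0L
  for (present in 1:7) { # bitmask: 1 = cctop, 2 = tmaf, 4 = poly
    has <- c(c = bitwAnd(present, 1) > 0, t = bitwAnd(present, 2) > 0,
             p = bitwAnd(present, 4) > 0)
    grid <- expand.grid(c = if (has["c"]) centers else NA,
                        t = if (has["t"]) centers else NA,
                        p = if (has["p"]) centers else NA)
    for (g in seq_len(nrow(grid))) {
      ctrs <- grid[g, ]
      mk <- function(k, src, tp = NA_integer_) {
        if (is.na(ctrs[[k]])) NULL else po_of(topo_center(ctrs[[k]]), src, tp)
      }
      cc <- mk("c", "cctop")
      tm <- mk("t", "tmalphafold", 10L)
      pp <- mk("p", "polyphobius")
      agree <- function(a, b) abs(ctrs[[a]] - ctrs[[b]]) <= 7
      expected <- oracle(cc, tm, pp, agree)
      got <- merge_topologies(cc, tm, pp, params)
      expect_equal(got$provenance, expected[1])
      expect_equal(got$quality, expected[2])
      # output topology is one of the inputs verbatim
      expect_true(any(vapply(list(cc, tm, pp), function(po) {
        !is.null(po) && identical(po$topology$segments, got$topology$segments)
      }, logical(1))))
      # quality monotonicity: removing any one source never raises quality
      for (drop in c("c", "t", "p")) {
        rest <- list(c = cc, t = tm, p = pp)
        rest[[drop]] <- NULL
        if (sum(!vapply(rest[c("c", "t", "p")], is.null, logical(1)),
                na.rm = TRUE) == 0) next
        if (is.null(rest$c) && is.null(rest$t) && is.null(rest$p)) next
        reduced <- merge_topologies(rest$c, rest$t, rest$p, params)
        expect_lte(rank_q[reduced$quality], rank_q[got$quality])
      }
      n_cases <- n_cases + 1L
    }
  }
  expect_gte(n_cases, 64L)
})

test_that("consensus_table summarises per protein and rejects unknown sources", {
  t <- topo_center(30)
  outs <- list(po_of(t, "cctop"), po_of(t, "tmalphafold", 10L),
               po_of(t, "polyphobius"),
               predictor_output("q", "polyphobius", topo_center(40, "out")))
  tab <- consensus_table(outs)
  expect_equal(tab$id, c("p", "q"))
  expect_equal(tab$quality, c("high", "low"))
  expect_equal(tab$c_term_side, c("out", "in"))
  expect_error(consensus_table(list(po_of(t, "phobius"))), "unknown predictor")
})
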