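#' Consensus parameters
#'
#' @param center_window Width (residues) of the window within which paired
#'   TM centres must fall for two predictions to agree; agreement requires
#'   `|delta center| <= center_window / 2` (default 14, i.e. centres within
#'   7 residues).
#' @param tmaf_min_tests Minimal TMAlphaFold structure-test count; predictions
#'   below it are discarded before merging (default 5).
#' @param two_way_quality Quality label assigned when exactly two predictors
#'   agree: `"low"` (default) or `"medium"`.
#' @return A list of class `consensus_params`.
#' @export
consensus_params <- function(center_window = 14, tmaf_min_tests = 5,
                             two_way_quality = c("low", "medium")) {
  two_way_quality <- match.arg(two_way_quality)
  if (center_window < 0) stop_config("center_window must be >= 0")
  if (tmaf_min_tests < 0) stop_config("tmaf_min_tests must be >= 0")
  structure(list(center_window = center_window,
                 tmaf_min_tests = tmaf_min_tests,
                 two_way_quality = two_way_quality),
            class = "consensus_params")
}

#' Do two topology predictions agree?
#'
#' Two predictions agree when they have the same number of TMs and, pairing
#' the TMs in order from the N-terminus, every pair of segment centres lies
#' within `center_window / 2` residues of each other.
#'
#' @param a,b [topology()] objects.
#' @param params A [consensus_params()].
#' @return `TRUE` or `FALSE`.
#' @export
topologies_agree <- function(a, b, params = consensus_params()) {
  if (n_tm(a) != n_tm(b)) return(FALSE)
  all(abs(a$segments$center - b$segments$center) <= params$center_window / 2)
}

#' Merge predictor outputs into a consensus topology
#'
#' Merges up to three per-protein predictions (CCTOP, TMAlphaFold,
#' PolyPhobius) into one topology with a quality label:
#'
#' 1. all three present and pairwise agreeing: coordinates from CCTOP,
#'    quality `"high"`;
#' 2. else CCTOP and TMAlphaFold agree: coordinates from CCTOP;
#' 3. else TMAlphaFold and PolyPhobius agree: coordinates from TMAlphaFold;
#' 4. else (no agreement, or data missing): PolyPhobius preferred over
#'    CCTOP over TMAlphaFold, quality `"low"`.
#'
#' Two-way agreements (cases 2-3) are labelled per
#' `params$two_way_quality`. TMAlphaFold predictions failing the
#' structure-test filter (`tests_passed < tmaf_min_tests`) are discarded up
#' front. The output topology is always one of the inputs verbatim; no
#' coordinate averaging.
#'
#' @param cctop,tmaf,polyphobius [predictor_output()] objects or `NULL`
#'   (missing data). A `predictor_output` with a `NULL` topology also counts
#'   as missing.
#' @param params A [consensus_params()].
#' @return A list of class `consensus_topology` with `topology`, `quality`
#'   (`"high"`/`"medium"`/`"low"`), `provenance` (source supplying the
#'   coordinates) and `agreement` (character vector of agreeing pairs such
#'   as `"cctop~tmalphafold"`).
#' @export
merge_topologies <- function(cctop = NULL, tmaf = NULL, polyphobius = NULL,
                             params = consensus_params()) {
  topo_of <- function(po) if (is.null(po)) NULL else po$topology
  tc <- topo_of(cctop)
  tt <- topo_of(tmaf)
  tp <- topo_of(polyphobius)
  if (!is.null(tt) && !is.null(tmaf$tests_passed) &&
      !is.na(tmaf$tests_passed) &&
      tmaf$tests_passed < params$tmaf_min_tests) {
    tt <- NULL
  }
  if (is.null(tc) && is.null(tt) && is.null(tp)) {
    stop_input("no topology prediction available from any source")
  }
  agree <- function(a, b) !is.null(a) && !is.null(b) &&
    topologies_agree(a, b, params)
  pairs <- character()
  if (agree(tc, tt)) pairs <- c(pairs, "cctop~tmalphafold")
  if (agree(tt, tp)) pairs <- c(pairs, "tmalphafold~polyphobius")
  if (agree(tc, tp)) pairs <- c(pairs, "cctop~polyphobius")

  if (!is.null(tc) && !is.null(tt) && !is.null(tp) && length(pairs) == 3L) {
    out <- list(topology = tc, quality = "high", provenance = "cctop")
  } else if (agree(tc, tt)) {
    out <- list(topology = tc, quality = params$two_way_quality,
                provenance = "cctop")
  } else if (agree(tt, tp)) {
    out <- list(topology = tt, quality = params$two_way_quality,
                provenance = "tmalphafold")
  } else if (!is.null(tp)) {
    out <- list(topology = tp, quality = "low", provenance = "polyphobius")
  } else if (!is.null(tc)) {
    out <- list(topology = tc, quality = "low", provenance = "cctop")
  } else {
    out <- list(topology = tt, quality = "low", provenance = "tmalphafold")
  }
  out$agreement <- pairs
  class(out) <- "consensus_topology"
  out
}

#' @export
print.consensus_topology <- function(x, ...) {
  cat(sprintf("<consensus_topology> quality '%s', coordinates from '%s'%s\n",
              x$quality, x$provenance,
              if (length(x$agreement)) paste0(" (", paste(x$agreement, collapse = ", "), ")")
              else ""))
  print(x$topology)
  invisible(x)
}

#' Build a consensus table for many proteins
#'
#' Applies [merge_topologies()] per protein to a list of
#' [predictor_output()]s (e.g. from [read_segment_table()]) and returns a
#' summary tibble; the full consensus objects ride along in a list-column.
#'
#' @param outputs A list of `predictor_output` objects (several sources per
#'   id).
#' @param params A [consensus_params()].
#' @return A tibble with one row per id: `id`, `n_tm`, `n_term_side`,
#'   `c_term_side`, `quality`, `provenance`, `consensus` (list-column of
#'   `consensus_topology`).
#' @export
consensus_table <- function(outputs, params = consensus_params()) {
  ids <- vapply(outputs, function(po) po$id, character(1))
  srcs <- vapply(outputs, function(po) po$source, character(1))
  unknown <- setdiff(unique(srcs), c("cctop", "tmalphafold", "polyphobius"))
  if (length(unknown) > 0) {
    stop_input("unknown predictor source(s): %s",
               paste(unknown, collapse = ", "))
  }
  purrr::map(unique(ids), function(i) {
    mine <- outputs[ids == i]
    by_src <- function(s) {
      hit <- mine[srcs[ids == i] == s]
      if (length(hit) > 1) stop_input("duplicate source '%s' for id '%s'", s, i)
      if (length(hit) == 1) hit[[1]] else NULL
    }
    cons <- merge_topologies(cctop = by_src("cctop"),
                             tmaf = by_src("tmalphafold"),
                             polyphobius = by_src("polyphobius"),
                             params = params)
    tibble(id = i, n_tm = n_tm(cons$topology),
           n_term_side = cons$topology$n_term_side,
           c_term_side = c_term_side(cons$topology),
           quality = cons$quality, provenance = cons$provenance,
           consensus = list(cons))
  }) |>
    bind_rows() |>
    arrange(.data$id)
}
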