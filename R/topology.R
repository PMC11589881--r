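#' Membrane topology objects
#'
#' A `topology` holds the ordered transmembrane (TM) segments of one protein
#' and the membrane side of its N-terminus. Segment coordinates are 1-based
#' inclusive (UniProt feature convention). Loop sides alternate
#' deterministically from `n_term_side` across each TM, so the side of the
#' C-terminus is implied by the segment count.
#'
#' @param segments A data frame with integer columns `start` and `end`
#'   (1-based inclusive); a `center` column is derived as
#'   `floor((start + end) / 2)`.
#' @param n_term_side `"in"` (cytosolic) or `"out"` (extracytosolic).
#' @return An object of class `topology`: list with `segments` (tibble
#'   `start`, `end`, `center`) and `n_term_side`.
#' @examples
#' topo <- topology(data.frame(start = 10, end = 29), "in")
#' c_term_side(topo) # one TM flips the side: "out"
#' @export
topology <- function(segments, n_term_side = c("in", "out")) {
  n_term_side <- match.arg(n_term_side)
  seg <- as_tibble(segments)
  stopifnot(all(c("start", "end") %in% names(seg)))
  seg <- seg |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end)) |>
    arrange(.data$start) |>
    mutate(center = (.data$start + .data$end) %/% 2L) |>
    select("start", "end", "center")
  if (nrow(seg) > 0) {
    if (any(seg$start > seg$end) || any(seg$start < 1L)) {
      stop_input("invalid TM segment coordinates (need 1 <= start <= end)")
    }
    if (nrow(seg) > 1 && any(seg$start[-1] <= seg$end[-nrow(seg)] + 1L)) {
      stop_input(
        "TM segments must be non-overlapping and separated by >= 1 loop residue")
    }
  }
  structure(list(segments = seg, n_term_side = n_term_side),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("<topology> %d TM(s), N-terminus '%s', C-terminus '%s'\n",
              n_tm(x), x$n_term_side, c_term_side(x)))
  print(x$segments)
  invisible(x)
}

#' @rdname topology
#' @param x A `topology`.
#' @export
n_tm <- function(x) nrow(x$segments)

flip_side <- function(side, times = 1L) {
  if (times %% 2L == 0L) side else setdiff(c("in", "out"), side)
}

#' @rdname topology
#' @export
c_term_side <- function(x) flip_side(x$n_term_side, n_tm(x))

#' Parse a per-residue topology string
#'
#' Parses the TOPCONS-style per-residue dialect: `i` (inside/cytosolic),
#' `o` (outside/extracytosolic), `M` (membrane) and a leading run of `S`
#' (signal peptide). Maximal runs of `M` become TM segments; the N-terminal
#' side is the first `i`/`o` character (for strings starting with `M`, the
#' side is back-propagated from the first loop character; an all-`M` string
#' is an error because the orientation is undefined).
#'
#' @param id Protein identifier (carried through).
#' @param topo_string Topology string, same length as the protein sequence.
#' @param source Predictor name tag (`"cctop"`, `"tmalphafold"`,
#'   `"polyphobius"` or any label).
#' @param tests_passed Optional integer quality metadata (TMAlphaFold-style
#'   count of structure-validation tests passed, 0-10).
#' @return A `predictor_output`: list with `id`, `source`, `topology` (a
#'   [topology()] or `NULL`), `tests_passed` and `signal_peptide_end`
#'   (`NA` if none).
#' @examples
#' po <- read_topology_string("p1", "iiiMMMMMMMMMMMMMMMMMMMooo")
#' po$topology$segments
#' @export
read_topology_string <- function(id, topo_string, source = "unknown",
                                 tests_passed = NA_integer_) {
  chars <- strsplit(topo_string, "")[[1]]
  bad <- setdiff(unique(chars), c("i", "o", "M", "S"))
  if (length(bad) > 0) {
    stop_input("invalid topology string character(s) %s for id '%s'",
               paste0("'", bad, "'", collapse = ", "), id)
  }
  sp_end <- NA_integer_
  if (chars[1] == "S") {
    run <- rle(chars)
    sp_end <- run$lengths[1]
    if ("S" %in% chars[-seq_len(sp_end)]) {
      stop_input("'S' (signal peptide) only allowed as a leading run (id '%s')",
                 id)
    }
  }
  body <- chars
  body_offset <- 0L
  if (!is.na(sp_end)) {
    body <- chars[-seq_len(sp_end)]
    body_offset <- sp_end
  }
  if (length(body) == 0L) stop_input("empty topology after signal peptide (id '%s')", id)
  runs <- rle(body)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  is_m <- runs$values == "M"
  seg <- tibble(start = starts[is_m] + body_offset,
                end = ends[is_m] + body_offset)
  first_loop <- which(!is_m)[1]
  if (is.na(first_loop)) {
    stop_input("topology string for id '%s' has no 'i'/'o' residue; orientation undefined",
               id)
  }
  # N-terminal side: first loop character, flipped back across any TMs that
  # precede it.
  n_side <- flip_side(runs$values[first_loop], sum(is_m[seq_len(first_loop - 1L)]))
  predictor_output(id = id, source = source,
                   topology = topology(seg, n_side),
                   tests_passed = tests_passed,
                   signal_peptide_end = sp_end)
}

#' @rdname read_topology_string
#' @param topology A [topology()] or `NULL` (missing prediction).
#' @param signal_peptide_end 1-based index of the last signal-peptide
#'   residue, or `NA`.
#' @export
predictor_output <- function(id, source, topology = NULL,
                             tests_passed = NA_integer_,
                             signal_peptide_end = NA_integer_) {
  structure(list(id = id, source = source, topology = topology,
                 tests_passed = as.integer(tests_passed),
                 signal_peptide_end = as.integer(signal_peptide_end)),
            class = "predictor_output")
}

#' Serialise a topology back to a per-residue string
#'
#' Inverse of [read_topology_string()] for strings without a signal-peptide
#' run; round-trips exactly.
#'
#' @param topo A [topology()].
#' @param length Protein length in residues.
#' @return A string over `i`/`o`/`M`.
#' @export
topology_string <- function(topo, length) {
  if (n_tm(topo) > 0 && max(topo$segments$end) > length) {
    stop_input("topology exceeds the given protein length")
  }
  out <- character(length)
  side <- topo$n_term_side
  pos <- 1L
  segs <- topo$segments
  for (k in seq_len(nrow(segs))) {
    if (segs$start[k] > pos) {
      out[pos:(segs$start[k] - 1L)] <- ifelse(side == "in", "i", "o")
    }
    out[segs$start[k]:segs$end[k]] <- "M"
    side <- flip_side(side)
    pos <- segs$end[k] + 1L
  }
  if (pos <= length) out[pos:length] <- ifelse(side == "in", "i", "o")
  paste(out, collapse = "")
}

#' Loops and tails implied by a topology
#'
#' Tiles every non-TM residue of a protein into loops, including the
#' N-terminal tail and the C-terminal tail as terminal "loops". Sides
#' alternate from the N-terminal side across each TM. Residues inside an
#' annotated signal peptide are excluded from the N-tail sequence (indices
#' are preserved: the N-tail simply starts after the signal peptide).
#'
#' @param topo A [topology()].
#' @param sequence The protein's amino-acid string.
#' @param signal_peptide_end 1-based index of the last signal-peptide
#'   residue, or `NA` for none.
#' @return A tibble with one row per loop: `loop` (index from the
#'   N-terminus; the N-tail is loop 0), `side`, `start`, `end`, `sequence`,
#'   `terminal` (`"n_tail"`, `"internal"` or `"c_tail"`). Terminal tails of
#'   zero length are kept as empty rows (`start > end`, `sequence == ""`).
#' @export
loops_of <- function(topo, sequence, signal_peptide_end = NA_integer_) {
  len <- nchar(sequence)
  segs <- topo$segments
  if (n_tm(topo) > 0 && max(segs$end) > len) {
    stop_input("topology exceeds sequence length")
  }
  n_start <- if (is.na(signal_peptide_end)) 1L else signal_peptide_end + 1L
  bounds_start <- c(n_start, segs$end + 1L)
  bounds_end <- c(segs$start - 1L, len)
  side <- topo$n_term_side
  rows <- vector("list", length(bounds_start))
  for (k in seq_along(bounds_start)) {
    s <- bounds_start[k]
    e <- bounds_end[k]
    rows[[k]] <- tibble(
      loop = k - 1L,
      side = side,
      start = as.integer(s),
      end = as.integer(e),
      sequence = if (s <= e) substr(sequence, s, e) else "",
      terminal = if (k == 1L) "n_tail"
                 else if (k == length(bounds_start)) "c_tail"
                 else "internal"
    )
    side <- flip_side(side)
  }
  out <- bind_rows(rows)
  if (nrow(out) == 1L) out$terminal <- "n_tail" # no TM: all one tail
  out
}
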