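#' Percent insertion from cysteine-accessibility PEGylation
#'
#' Computes the percent of membrane insertion from the PEGylation levels of
#' three treatments of a single-cysteine reporter: untreated (maximal
#' PEGylation), NEM-treated (membrane-permeable maleimide: maximal possible
#' blocking, controlling for inaccessible cysteines) and AMS-treated
#' (membrane-impermeable maleimide: blocking by periplasmic/extracytosolic
#' exposure only). The statistic is
#' \deqn{\%insertion = 100 \cdot \frac{1 - \%PEG_{AMS}/\%PEG_{untreated}}
#'                               {1 - \%PEG_{NEM}/\%PEG_{untreated}}}
#' The raw value is retained; the reported value is clamped to \[0, 100\]
#' with a flag when clamping occurred (noise can push the ratio slightly
#' outside the physical range).
#'
#' @param gels A data frame with columns `peg_untreated`, `peg_nem`,
#'   `peg_ams` (percent PEGylation, each in \[0, 100\]) and optionally
#'   `sample_id` and `replicate`; one row per gel.
#' @return The input tibble with added columns `percent_insertion_raw`,
#'   `percent_insertion` (clamped) and `clamped`.
#' @examples
#' percent_insertion(data.frame(peg_untreated = 90, peg_nem = 10,
#'                              peg_ams = 30))$percent_insertion # 75
#' @export
percent_insertion <- function(gels) {
  gels <- as_tibble(gels)
  need <- c("peg_untreated", "peg_nem", "peg_ams")
  if (!all(need %in% names(gels))) {
    stop_input("gels must have columns %s", paste(need, collapse = ", "))
  }
  vals <- unlist(gels[need])
  if (any(is.na(vals)) || any(vals < 0) || any(vals > 100)) {
    stop_input("PEGylation percentages must lie in [0, 100]")
  }
  if (any(gels$peg_untreated == 0)) {
    stop_input("peg_untreated must be > 0 (maximal PEGylation reference)")
  }
  if (any(gels$peg_nem >= gels$peg_untreated)) {
    stop_input("degenerate denominator: peg_nem must be < peg_untreated (NEM must block some PEGylation)")
  }
  raw <- 100 * (1 - gels$peg_ams / gels$peg_untreated) /
    (1 - gels$peg_nem / gels$peg_untreated)
  gels |>
    mutate(percent_insertion_raw = raw,
           percent_insertion = pmin(100, pmax(0, raw)),
           clamped = raw < 0 | raw > 100)
}

#' Calibrate densitometry with a dilution series
#'
#' Fits a calibration line, through the origin, of band intensity against
#' relative sample amount from a geometric (e.g. twofold) dilution series.
#' The fit provides a corrector mapping measured intensities onto the
#' calibrated linear range; a saturation warning is raised when the
#' brightest point falls off the line (its absolute residual exceeding twice
#' the root-mean-square of the others'), the signature of a saturated band.
#'
#' @param dilution_series A data frame with columns `dilution_factor`
#'   (1, 2, 4, ... relative to the undiluted sample) and `band_intensity`
#'   (positive); at least 3 points.
#' @return An object of class `densitometry_calibration`: list with
#'   `slope` (intensity per unit relative amount), `r_squared`,
#'   `saturation_warning`, `data`, and `correct`, a function mapping an
#'   intensity to a calibrated relative amount.
#' @export
calibrate_densitometry <- function(dilution_series) {
  ds <- as_tibble(dilution_series)
  if (!all(c("dilution_factor", "band_intensity") %in% names(ds))) {
    stop_input("dilution series needs columns dilution_factor, band_intensity")
  }
  if (nrow(ds) < 3) stop_input("calibration needs at least 3 dilution points")
  if (any(ds$band_intensity <= 0) || any(ds$dilution_factor <= 0)) {
    stop_input("dilution factors and band intensities must be positive")
  }
  ratios <- sort(ds$dilution_factor)
  ratios <- ratios[-1] / ratios[-length(ratios)]
  if (max(ratios) - min(ratios) > 1e-6 * max(ratios)) {
    stop_input("dilution factors must form a geometric series")
  }
  ds <- mutate(ds, amount = 1 / .data$dilution_factor)
  fit <- lm(band_intensity ~ 0 + amount, data = ds)
  pred <- unname(fitted(fit))
  res <- ds$band_intensity - pred
  ss_tot <- sum((ds$band_intensity - mean(ds$band_intensity))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(res^2) / ss_tot
  # Saturation check against a leave-top-out fit: a capped top band pulls a
  # through-origin fit toward itself, so its own residual must be judged
  # against the line defined by the unsaturated dilutions.
  top <- which.max(ds$amount)
  slope_sub <- sum(ds$amount[-top] * ds$band_intensity[-top]) /
    sum(ds$amount[-top]^2)
  res_sub <- ds$band_intensity[-top] - slope_sub * ds$amount[-top]
  res_top <- ds$band_intensity[top] - slope_sub * ds$amount[top]
  rms_rest <- sqrt(mean(res_sub^2))
  tol <- max(2 * rms_rest, 1e-6 * abs(slope_sub * ds$amount[top]))
  saturated <- abs(res_top) > tol
  if (saturated) {
    warn("calibrate_densitometry: top dilution point deviates from linearity; band may be saturated")
  }
  slope <- unname(coef(fit)[1])
  structure(
    list(slope = slope, r_squared = r2, saturation_warning = saturated,
         data = ds, correct = function(intensity) intensity / slope),
    class = "densitometry_calibration"
  )
}

#' @export
print.densitometry_calibration <- function(x, ...) {
  cat(sprintf("<densitometry_calibration> slope %.4g, R^2 %.4f%s\n",
              x$slope, x$r_squared,
              if (x$saturation_warning) " [saturation warning]" else ""))
  invisible(x)
}

#' @rdname calibrate_densitometry
#' @param x A `densitometry_calibration`.
#' @param ... Unused.
#' @export
glance.densitometry_calibration <- function(x, ...) {
  tibble(slope = x$slope, r.squared = x$r_squared,
         saturation_warning = x$saturation_warning,
         n = nrow(x$data))
}

#' @rdname calibrate_densitometry
#' @export
tidy.densitometry_calibration <- function(x, ...) {
  tibble(term = "amount", estimate = x$slope)
}

#' Percent PEGylation from band intensities
#'
#' Converts a pair of band intensities (PEG-shifted and unshifted species)
#' into percent PEGylation, optionally passing both through a densitometry
#' calibration first.
#'
#' @param band_peg,band_unshifted Non-negative intensities.
#' @param calibration Optional `densitometry_calibration`.
#' @return Percent PEGylation in \[0, 100\].
#' @export
percent_pegylation <- function(band_peg, band_unshifted, calibration = NULL) {
  if (any(band_peg < 0) || any(band_unshifted < 0)) {
    stop_input("band intensities must be non-negative")
  }
  if (!is.null(calibration)) {
    band_peg <- calibration$correct(band_peg)
    band_unshifted <- calibration$correct(band_unshifted)
  }
  tot <- band_peg + band_unshifted
  if (any(tot == 0)) stop_input("both bands are zero; percent PEGylation undefined")
  100 * band_peg / tot
}

#' Aggregate replicate insertion measurements
#'
#' @param results A data frame with a `percent_insertion` column (e.g. from
#'   [percent_insertion()]) or a numeric vector; at least one replicate
#'   (fewer than 3 raises a warning, matching the at-least-three-replicates
#'   reporting convention).
#' @return A one-row tibble: `mean_insertion`, `sem`, `n_replicates`.
#' @examples
#' aggregate_insertion(c(70, 80, 90)) # mean 80, SEM 10/sqrt(3)
#' @export
aggregate_insertion <- function(results) {
  vals <- if (is.data.frame(results)) results$percent_insertion else results
  if (is.null(vals) || length(vals) == 0) {
    stop_input("no replicates to aggregate")
  }
  n <- length(vals)
  if (n < 3) {
    warn(sprintf("aggregate_insertion: only %d replicate(s); means are conventionally reported over >= 3", n))
  }
  tibble(mean_insertion = mean(vals),
         sem = if (n > 1) sd(vals) / sqrt(n) else NA_real_,
         n_replicates = n)
}
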