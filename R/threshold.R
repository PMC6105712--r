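#' Parameters of the adaptive cutoff rule
#'
#' The significance cutoff is read off the ordered fold-magnitude curve:
#' magnitudes are sorted ascending, averaged in bins of \code{bin_size}
#' genes, and the per-boundary slopes of the binned curve are scanned for a
#' departure from the linear regime formed by the lowest bins.
#'
#' A boundary departs when BOTH hold: its slope exceeds
#' \code{slope_multiplier} times the baseline slope (median slope over the
#' lowest \code{baseline_fraction} of boundaries, floored at \code{epsilon}
#' so a perfectly flat null still yields a finite criterion), and the mean of
#' the bin above it exceeds the linear extrapolation of the baseline region
#' by a factor \code{1 + departure_ratio}. The second condition is what makes
#' the rule ignore the smooth convexity of a pure noise tail: a Gaussian
#' null's quantile curve steepens gradually and crosses any slope multiple
#' well inside the null bulk, but stays close to the extrapolated line;
#' planted effects leave the line.
#'
#' @param baseline_fraction Fraction of the lowest boundaries defining the
#'   null slope (default 0.5).
#' @param slope_multiplier Departure factor k on the baseline slope
#'   (default 2).
#' @param departure_ratio Relative excess over the extrapolated linear trend
#'   required at the departing bin (default 0.5).
#' @param margin Additive safety margin on the harmonized global cutoff
#'   (default 0.05 fold).
#' @param grid Rounding grid for the global cutoff; rounding is always up
#'   (default 0.05).
#' @param epsilon Slope floor guarding an all-zero baseline (default 1e-6
#'   magnitude per gene).
#' @return A \code{kdtc_cutoff_rule}.
#' @export
cutoff_rule <- function(baseline_fraction = 0.5, slope_multiplier = 2,
                        departure_ratio = 0.5, margin = 0.05, grid = 0.05,
                        epsilon = 1e-6) {
  if (baseline_fraction <= 0 || baseline_fraction >= 1) {
    kdtc_stop("kdtc_bad_rule", "baseline_fraction must lie in (0, 1)")
  }
  if (slope_multiplier <= 1) kdtc_stop("kdtc_bad_rule", "slope_multiplier must exceed 1")
  if (departure_ratio < 0) kdtc_stop("kdtc_bad_rule", "departure_ratio must be >= 0")
  if (margin < 0) kdtc_stop("kdtc_bad_rule", "margin must be >= 0")
  if (grid <= 0) kdtc_stop("kdtc_bad_rule", "grid must be > 0")
  structure(list(baseline_fraction = baseline_fraction,
                 slope_multiplier = slope_multiplier,
                 departure_ratio = departure_ratio,
                 margin = margin, grid = grid, epsilon = epsilon),
            class = "kdtc_cutoff_rule")
}

#' Bin an ordered fold-magnitude curve
#'
#' Sorts the symmetric fold magnitudes of one contrast ascending (stably;
#' ties broken by gene identifier when given), averages them every
#' \code{bin_size} genes and computes the slope at every bin boundary. A
#' final partial bin is merged into the last full bin so the extreme genes,
#' which carry the signal, are never dropped.
#'
#' @param magnitudes Vector of symmetric fold magnitudes (all \code{>= 1}).
#' @param bin_size Genes per bin (default 100).
#' @param gene_ids Optional identifiers used as a stable tie-break.
#' @param contrast Optional label carried through to reports.
#' @return A \code{kdtc_scan}: ordered magnitudes, bin assignment, bin means,
#'   boundary slopes (\code{(mean[i+1]-mean[i])/bin_size}) and the flanking
#'   gene values at every boundary.
#' @export
scan_contrast <- function(magnitudes, bin_size = 100, gene_ids = NULL,
                          contrast = NA_character_) {
  if (!is.numeric(magnitudes) || any(!is.finite(magnitudes)) || any(magnitudes < 1)) {
    kdtc_stop("kdtc_bad_magnitudes", "magnitudes must be finite and >= 1")
  }
  n <- length(magnitudes)
  if (n < 2L * bin_size) {
    kdtc_stop("kdtc_too_few_genes", "need at least 2*bin_size = ",
              2L * bin_size, " values, got ", n)
  }
  if (is.null(gene_ids)) gene_ids <- sprintf("g%09d", seq_len(n))
  ord <- order(magnitudes, gene_ids, method = "radix")
  m <- magnitudes[ord]
  n_bins <- n %/% bin_size
  bin <- pmin(ceiling(seq_len(n) / bin_size), n_bins)
  counts <- tabulate(bin, n_bins)
  ends <- cumsum(counts)
  starts <- ends - counts + 1L
  bin_means <- diff(c(0, cumsum(m)[ends])) / counts
  # gene-rank center of each bin, for the linear extrapolation
  centers <- (starts + ends) / 2
  slopes <- diff(bin_means) / bin_size
  structure(list(contrast = contrast,
                 ordered_m = m,
                 ordered_ids = gene_ids[ord],
                 bin_size = bin_size,
                 bin = bin,
                 bin_counts = counts,
                 bin_means = bin_means,
                 bin_centers = centers,
                 bin_slopes = slopes,
                 boundary_lo = m[ends[-n_bins]],
                 boundary_hi = m[starts[-1L]]),
            class = "kdtc_scan")
}

#' Locate the departure from linearity in one scan
#'
#' Applies the rule documented in \code{\link{cutoff_rule}}. The departure
#' magnitude is the midpoint of the two gene values flanking the first
#' departing boundary; an absent return (NA) signals that no boundary
#' qualifies (no signal above the linear regime).
#'
#' @param scan A \code{kdtc_scan}.
#' @param rule A \code{kdtc_cutoff_rule}.
#' @return The input scan augmented with \code{baseline_slope},
#'   \code{predicted} (extrapolated bin means), \code{flagged} (per-boundary
#'   logical) and \code{departure_magnitude} (NA if absent).
#' @export
select_cutoff <- function(scan, rule = cutoff_rule()) {
  stopifnot(inherits(scan, "kdtc_scan"))
  s <- scan$bin_slopes
  nb <- max(1L, floor(rule$baseline_fraction * length(s)))
  baseline <- stats::median(s[seq_len(nb)])
  # robust linear extrapolation of the baseline region: slope = baseline,
  # intercept = median residual of the baseline bins
  base_bins <- seq_len(nb + 1L)
  intercept <- stats::median(scan$bin_means[base_bins] -
                               baseline * scan$bin_centers[base_bins])
  predicted <- intercept + baseline * scan$bin_centers
  slope_ok <- s > rule$slope_multiplier * max(baseline, rule$epsilon)
  level_ok <- scan$bin_means[-1L] > (1 + rule$departure_ratio) * predicted[-1L]
  flagged <- slope_ok & level_ok
  hit <- which(flagged)
  scan$baseline_slope <- baseline
  scan$predicted <- predicted
  scan$flagged <- flagged
  scan$departure_magnitude <- if (length(hit)) {
    i <- hit[1L]
    (scan$boundary_lo[i] + scan$boundary_hi[i]) / 2
  } else NA_real_
  scan
}

#' Scan every contrast of a fold-change table
#'
#' @param fc A \code{kdtc_fc}.
#' @param rule A \code{kdtc_cutoff_rule}.
#' @param bin_size Genes per bin (default 100).
#' @return Named list of evaluated scans (one per contrast column of
#'   \code{fc}).
#' @export
scan_fold_changes <- function(fc, rule = cutoff_rule(), bin_size = 100) {
  mags <- fc_magnitude(fc)
  scans <- lapply(colnames(mags), function(key) {
    select_cutoff(scan_contrast(mags[, key], bin_size = bin_size,
                                gene_ids = rownames(mags), contrast = key),
                  rule)
  })
  names(scans) <- colnames(mags)
  scans
}

#' Harmonize per-contrast departures into one global cutoff
#'
#' The study applies a single significance threshold to every dataset: the
#' largest per-contrast departure plus a safety margin, rounded UP to the
#' rounding grid (never below the largest observed departure), mirroring the
#' published reading of departures between 1.5 and 1.75 harmonized to 1.8.
#'
#' @param departures Numeric vector of per-contrast departure magnitudes
#'   (NAs, i.e. absent departures, are dropped).
#' @param rule A \code{kdtc_cutoff_rule} supplying \code{margin} and
#'   \code{grid}.
#' @return The global cutoff (linear fold magnitude).
#' @export
harmonize_global_cutoff <- function(departures, rule = cutoff_rule()) {
  departures <- departures[!is.na(departures)]
  if (!length(departures)) {
    kdtc_stop("kdtc_no_departure",
              "no contrast produced a departure; use a fixed cutoff instead")
  }
  g <- max(departures) + rule$margin
  # round up to the grid; 1e-9 guards floating-point representations of
  # values already on the grid (e.g. 1.80/0.05)
  round(ceiling(g / rule$grid - 1e-9) * rule$grid, 10)
}

#' Tabulate scans for export
#' @param scans List of evaluated scans from \code{\link{scan_fold_changes}}.
#' @return Data frame: contrast, bin, n_genes, mean magnitude, boundary
#'   slope, predicted linear mean, flagged.
#' @export
scans_to_table <- function(scans) {
  do.call(rbind, lapply(scans, function(sc) {
    nb <- length(sc$bin_means)
    data.frame(contrast = sc$contrast,
               bin = seq_len(nb),
               n_genes = sc$bin_counts,
               bin_mean = sc$bin_means,
               slope = c(NA_real_, sc$bin_slopes),
               predicted = if (is.null(sc$predicted)) NA_real_ else sc$predicted,
               flagged = c(NA, if (is.null(sc$flagged)) rep(NA, nb - 1L) else sc$flagged),
               stringsAsFactors = FALSE)
  }))
}
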