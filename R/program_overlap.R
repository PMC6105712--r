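#' Define the differentiation program from control cells
#'
#' Genes activated or repressed during normal differentiation: within the
#' reference condition, each later time point is contrasted against the
#' first one, and the same inclusive fold-magnitude cutoff as the knockdown
#' analysis is applied.
#'
#' @param values Expression matrix (log2).
#' @param sheet Sample sheet.
#' @param cutoff Fold-magnitude cutoff.
#' @param reference Condition defining the program (default \code{"siCTR"},
#'   the baseline shared by the knockdown contrasts; \code{"NT"} is a valid
#'   alternative).
#' @return A \code{kdtc_program}: per time point \code{> T0}, character
#'   vectors \code{activated} and \code{repressed}, plus the underlying
#'   genes-x-timepoints log2fc matrix.
#' @export
define_program <- function(values, sheet, cutoff, reference = "siCTR") {
  if (cutoff <= 1) kdtc_stop("kdtc_bad_cutoff", "cutoff must be > 1")
  tps <- attr(sheet, "timepoints")
  t0 <- tps[1L]
  ref <- sheet$condition == reference
  t0_ids <- sheet$sample_id[ref & sheet$timepoint == t0]
  if (!length(t0_ids)) {
    kdtc_stop("kdtc_missing_t0", "no '", reference, "' samples at ", t0)
  }
  base <- rowMeans(values[, t0_ids, drop = FALSE])
  later <- intersect(tps[-1L], unique(sheet$timepoint[ref]))
  lcut <- log2(cutoff)
  l2 <- sapply(later, function(tp) {
    ids <- sheet$sample_id[ref & sheet$timepoint == tp]
    rowMeans(values[, ids, drop = FALSE]) - base
  })
  l2 <- matrix(l2, nrow = nrow(values), dimnames = list(rownames(values), later))
  sets <- lapply(later, function(tp) {
    list(activated = rownames(l2)[l2[, tp] >= lcut],
         repressed = rownames(l2)[l2[, tp] <= -lcut])
  })
  names(sets) <- later
  structure(list(sets = sets, log2fc = l2, reference = reference,
                 cutoff = cutoff, t0 = t0),
            class = "kdtc_program")
}

#' Knockdown disruption of the differentiation program
#'
#' For each later time point and program direction, the fraction of program
#' genes that carry a knockdown call (up or down, versus control at the same
#' time point) — i.e. genes whose differentiation-driven expression is not
#' properly established under the knockdown.
#'
#' @param program A \code{kdtc_program}.
#' @param status A \code{kdtc_status} holding the knockdown condition.
#' @param factor_condition Condition to assess (e.g. \code{"siCBP"}).
#' @param excluded Transfection-artifact genes, removed from program sets.
#' @return Data frame rows: analysis ("disruption"), factor, timepoint,
#'   direction ("activated"/"repressed"), numerator, denominator, fraction
#'   (NA when the program set is empty).
#' @export
program_disruption <- function(program, status, factor_condition,
                               excluded = character(0L)) {
  kd_sets <- timepoint_sets(status, factor_condition, excluded)
  rows <- list()
  for (tp in names(program$sets)) {
    affected <- union(kd_sets[[tp]]$up, kd_sets[[tp]]$down)
    for (dirn in c("activated", "repressed")) {
      prog <- setdiff(program$sets[[tp]][[dirn]], excluded)
      den <- length(prog)
      num <- length(intersect(prog, affected))
      rows[[length(rows) + 1L]] <- data.frame(
        analysis = "disruption", factor = factor_condition, timepoint = tp,
        direction = dirn, numerator = num, denominator = den,
        fraction = if (den > 0L) num / den else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Single- versus double-knockdown recapitulation and redundancy
#'
#' Per time point and direction: the fraction of each single knockdown's
#' deregulated genes also deregulated (same direction) in the double
#' knockdown (recapitulation), and the fraction of double-knockdown genes
#' affected in neither single knockdown (redundancy share, the
#' double-only signature).
#'
#' @param status A \code{kdtc_status} holding all three knockdown
#'   conditions.
#' @param cbp,p300,double Condition labels.
#' @param excluded Transfection-artifact genes.
#' @return Data frame rows keyed by (analysis, factor, timepoint,
#'   direction, numerator, denominator, fraction); analyses are
#'   "recapitulation" (factor = single knockdown) and "redundancy"
#'   (factor = double).
#' @export
recapitulation <- function(status, cbp = "siCBP", p300 = "siP300",
                           double = "siCBP_P300", excluded = character(0L)) {
  s_cbp <- timepoint_sets(status, cbp, excluded)
  s_p300 <- timepoint_sets(status, p300, excluded)
  s_dbl <- timepoint_sets(status, double, excluded)
  rows <- list()
  add <- function(analysis, fac, tp, dirn, num, den) {
    rows[[length(rows) + 1L]] <<- data.frame(
      analysis = analysis, factor = fac, timepoint = tp, direction = dirn,
      numerator = num, denominator = den,
      fraction = if (den > 0L) num / den else NA_real_,
      stringsAsFactors = FALSE)
  }
  for (tp in names(s_dbl)) {
    for (dirn in c("up", "down")) {
      D <- s_dbl[[tp]][[dirn]]
      for (fac in c(cbp, p300)) {
        S <- (if (fac == cbp) s_cbp else s_p300)[[tp]][[dirn]]
        add("recapitulation", fac, tp, dirn, length(intersect(S, D)), length(S))
      }
      singles <- union(s_cbp[[tp]][[dirn]], s_p300[[tp]][[dirn]])
      add("redundancy", double, tp, dirn, length(setdiff(D, singles)), length(D))
    }
  }
  do.call(rbind, rows)
}
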