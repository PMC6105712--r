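#' Symmetric fold magnitude
#'
#' Folds a linear expression ratio so that 1 means no change regardless of
#' direction: \code{max(r, 1/r)}.
#'
#' @param r Positive linear ratio(s).
#' @return Magnitudes \code{>= 1}.
#' @export
symmetric_fold <- function(r) {
  if (!is.numeric(r) || any(!is.finite(r)) || any(r <= 0)) {
    kdtc_stop("kdtc_bad_ratio", "linear ratios must be finite and > 0")
  }
  pmax(r, 1 / r)
}

#' Per-time-point fold changes against a reference condition
#'
#' For every requested condition and every time point where it has samples,
#' computes \code{log2fc(g) = mean log2 intensity in the condition - mean
#' log2 intensity in the reference} at that time point. Replicates are
#' averaged in log2 space (geometric mean on the linear scale); with the
#' study's single-array design this is a no-op.
#'
#' @param values Expression matrix (log2), genes x samples.
#' @param sheet Sample sheet (\code{\link{sample_sheet}}).
#' @param reference Reference condition, default \code{"siCTR"}. The same
#'   code path serves the transfection-artifact contrast (condition
#'   \code{"NT"} against \code{"siCTR"}).
#' @param conditions Conditions to contrast; default: every condition in the
#'   sheet except the reference.
#' @return A \code{kdtc_fc} object: list with \code{log2fc} (genes x
#'   contrasts matrix, columns named \code{condition@timepoint}),
#'   \code{contrasts} (data frame), \code{timepoints}, \code{reference}.
#' @export
compute_fold_changes <- function(values, sheet, reference = "siCTR",
                                 conditions = NULL) {
  validate_design(values, sheet, reference = reference)
  tps <- attr(sheet, "timepoints")
  if (is.null(conditions)) {
    conditions <- setdiff(unique(sheet$condition), reference)
    conditions <- conditions[order(match(conditions, attr(sheet, "conditions")))]
  }
  absent <- setdiff(conditions, unique(sheet$condition))
  if (length(absent)) {
    kdtc_stop("kdtc_empty_contrast", "condition(s) with zero samples: ",
              paste(absent, collapse = ", "))
  }
  ref_means <- list()
  for (tp in tps) {
    ids <- sheet$sample_id[sheet$condition == reference & sheet$timepoint == tp]
    if (length(ids)) {
      ref_means[[tp]] <- rowMeans(values[, ids, drop = FALSE])
    }
  }
  cols <- list()
  meta <- list()
  for (cond in conditions) {
    cond_tps <- intersect(tps, unique(sheet$timepoint[sheet$condition == cond]))
    for (tp in cond_tps) {
      if (is.null(ref_means[[tp]])) {
        kdtc_stop("kdtc_missing_reference", "no '", reference,
                  "' samples at timepoint ", tp)
      }
      ids <- sheet$sample_id[sheet$condition == cond & sheet$timepoint == tp]
      key <- paste0(cond, "@", tp)
      cols[[key]] <- rowMeans(values[, ids, drop = FALSE]) - ref_means[[tp]]
      meta[[key]] <- data.frame(condition = cond, timepoint = tp,
                                stringsAsFactors = FALSE)
    }
  }
  if (!length(cols)) {
    kdtc_stop("kdtc_empty_contrast", "no contrasts could be formed")
  }
  log2fc <- do.call(cbind, cols)
  rownames(log2fc) <- rownames(values)
  structure(list(log2fc = log2fc,
                 contrasts = do.call(rbind, meta),
                 timepoints = tps,
                 reference = reference),
            class = "kdtc_fc")
}

#' Symmetric fold magnitudes of a fold-change table
#' @param fc A \code{kdtc_fc}.
#' @return Matrix of magnitudes \code{2^|log2fc|}, same shape as
#'   \code{fc$log2fc}.
#' @export
fc_magnitude <- function(fc) {
  2 ^ abs(fc$log2fc)
}

# genes x timepoints log2fc submatrix for one condition
fc_condition_matrix <- function(fc, condition) {
  sel <- fc$contrasts$condition == condition
  if (!any(sel)) {
    kdtc_stop("kdtc_empty_contrast", "no contrasts for condition ", condition)
  }
  m <- fc$log2fc[, sel, drop = FALSE]
  colnames(m) <- fc$contrasts$timepoint[sel]
  m[, order(match(colnames(m), fc$timepoints)), drop = FALSE]
}

#' Long-form export of a fold-change table
#' @param fc A \code{kdtc_fc}.
#' @return Data frame: gene, condition, timepoint, log2fc, linear_fold,
#'   magnitude; genes sorted lexicographically, contrasts in design order.
#' @export
fc_to_table <- function(fc) {
  n <- nrow(fc$log2fc)
  k <- ncol(fc$log2fc)
  df <- data.frame(
    gene_id = rep(rownames(fc$log2fc), k),
    condition = rep(fc$contrasts$condition, each = n),
    timepoint = rep(fc$contrasts$timepoint, each = n),
    log2fc = as.vector(fc$log2fc),
    stringsAsFactors = FALSE)
  df$linear_fold <- 2 ^ df$log2fc
  df$magnitude <- symmetric_fold(df$linear_fold)
  df[order(match(df$gene_id, sort_c(unique(df$gene_id))),
           match(df$condition, unique(fc$contrasts$condition)),
           match(df$timepoint, fc$timepoints)), ]
}

#' Write a fold-change table as TSV
#' @param fc A \code{kdtc_fc}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fold_changes <- function(fc, path) {
  write_tsv(fc_to_table(fc), path)
}
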