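#' Flag affected genes per contrast
#'
#' A gene is called at a contrast when its symmetric fold magnitude reaches
#' the cutoff (inclusive comparison, so the fixed published threshold
#' reproduces list membership deterministically); direction comes from the
#' sign of the log2 fold change.
#'
#' @param fc A \code{kdtc_fc}.
#' @param cutoff Linear fold-magnitude cutoff (\code{> 1}), e.g. 1.8.
#' @return A \code{kdtc_status}: per condition, genes x timepoints matrices
#'   \code{direction} ("up"/"down"/"none") and \code{log2fc}.
#' @export
flag_affected <- function(fc, cutoff) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 1) {
    kdtc_stop("kdtc_bad_cutoff", "cutoff must be a single value > 1")
  }
  lcut <- log2(cutoff)
  conds <- unique(fc$contrasts$condition)
  per_cond <- lapply(conds, function(cond) {
    l2 <- fc_condition_matrix(fc, cond)
    dir <- matrix("none", nrow(l2), ncol(l2), dimnames = dimnames(l2))
    dir[l2 >= lcut] <- "up"
    dir[l2 <= -lcut] <- "down"
    list(direction = dir, log2fc = l2)
  })
  names(per_cond) <- conds
  structure(list(conditions = per_cond,
                 gene_ids = rownames(fc$log2fc),
                 timepoints = fc$timepoints,
                 cutoff = cutoff),
            class = "kdtc_status")
}

#' Transfection-artifact gene set
#'
#' Genes whose expression differs between non-transfected cells and the
#' control siRNA at any shared time point respond to the transfection
#' itself, not the knockdown, and are removed from the whole analysis.
#'
#' @param fc_nt A \code{kdtc_fc} of the NT-vs-siCTR contrast
#'   (\code{compute_fold_changes(values, sheet, conditions = "NT")}), or NULL
#'   when the design has no NT arrays (the filter is then skipped with a
#'   warning).
#' @param cutoff Fold-magnitude cutoff; the same global cutoff as the main
#'   analysis.
#' @return Character vector of excluded gene identifiers (possibly empty).
#' @export
exclude_transfection_artifacts <- function(fc_nt, cutoff) {
  if (is.null(fc_nt)) {
    kdtc_warn("kdtc_no_nt", "no NT samples: transfection-artifact filter skipped")
    return(character(0L))
  }
  if (cutoff <= 1) kdtc_stop("kdtc_bad_cutoff", "cutoff must be > 1")
  hit <- fc_magnitude(fc_nt) >= cutoff
  rownames(fc_nt$log2fc)[rowSums(hit) > 0L]
}

# aggregate one factor over timepoints: affected at >=1 timepoint, direction
# at the timepoint of maximal |log2fc| (first such timepoint on ties), plus a
# mixed flag when both up and down calls occur across timepoints
aggregate_factor <- function(cond_status) {
  dir <- cond_status$direction
  l2 <- cond_status$log2fc
  affected <- rowSums(dir != "none") > 0L
  has_up <- rowSums(dir == "up") > 0L
  has_down <- rowSums(dir == "down") > 0L
  peak <- max.col(abs(l2), ties.method = "first")
  peak_sign <- sign(l2[cbind(seq_len(nrow(l2)), peak)])
  agg <- ifelse(!affected, "none", ifelse(peak_sign >= 0, "up", "down"))
  list(affected = affected, direction = agg, mixed = has_up & has_down)
}

#' Classify genes by factor specificity
#'
#' Aggregates per-time-point calls over the time course (a factor affects a
#' gene if it is called at \code{>= 1} time point; aggregated direction is
#' the sign at the time point of maximal |log2FC|) and assigns each
#' non-excluded gene one category: \code{CBP_specific_up/down},
#' \code{P300_specific_up/down}, \code{common_up/down} (both factors, same
#' aggregated direction), \code{opposite} (both, opposite directions) or
#' \code{unaffected}. Factors with both up and down calls across time points
#' are flagged \code{*_mixed} but still categorized by their aggregated
#' direction.
#'
#' @param status A \code{kdtc_status} from \code{\link{flag_affected}}
#'   containing both single-knockdown conditions.
#' @param excluded Character vector of transfection-artifact genes; they get
#'   category \code{"excluded"} and join no other set.
#' @param cbp,p300 Condition labels of the two single knockdowns.
#' @return A \code{kdtc_classification}: data frame (gene_id, category,
#'   cbp_direction, p300_direction, cbp_mixed, p300_mixed) with the status
#'   object, cutoff and factor labels in attributes.
#' @export
classify_specificity <- function(status, excluded = character(0L),
                                 cbp = "siCBP", p300 = "siP300") {
  for (cond in c(cbp, p300)) {
    if (!cond %in% names(status$conditions)) {
      kdtc_stop("kdtc_universe_mismatch", "status lacks condition ", cond)
    }
  }
  genes <- status$gene_ids
  a_cbp <- aggregate_factor(status$conditions[[cbp]])
  a_p300 <- aggregate_factor(status$conditions[[p300]])
  category <- rep("unaffected", length(genes))
  both <- a_cbp$affected & a_p300$affected
  same <- a_cbp$direction == a_p300$direction
  category[both & same] <- paste0("common_", a_cbp$direction[both & same])
  category[both & !same] <- "opposite"
  only_cbp <- a_cbp$affected & !a_p300$affected
  category[only_cbp] <- paste0("CBP_specific_", a_cbp$direction[only_cbp])
  only_p300 <- a_p300$affected & !a_cbp$affected
  category[only_p300] <- paste0("P300_specific_", a_p300$direction[only_p300])
  category[genes %in% excluded] <- "excluded"
  out <- data.frame(gene_id = genes,
                    category = category,
                    cbp_direction = a_cbp$direction,
                    p300_direction = a_p300$direction,
                    cbp_mixed = a_cbp$mixed,
                    p300_mixed = a_p300$mixed,
                    stringsAsFactors = FALSE)
  attr(out, "status") <- status
  attr(out, "excluded") <- intersect(genes, excluded)
  attr(out, "cutoff") <- status$cutoff
  attr(out, "factors") <- c(cbp = cbp, p300 = p300)
  class(out) <- c("kdtc_classification", "data.frame")
  out
}

#' Add double-knockdown categories
#'
#' Genes deregulated only when both factors are knocked down together are
#' candidates for redundant CBP/P300 regulation: affected in the double
#' knockdown at \code{>= 1} time point but in neither single-knockdown
#' affected set. They move from \code{unaffected} to
#' \code{double_only_up/down} (aggregated double-knockdown direction).
#'
#' @param classification A \code{kdtc_classification}.
#' @param double Condition label of the double knockdown.
#' @return The classification with columns \code{double_direction},
#'   \code{double_mixed} added and \code{double_only_*} categories assigned.
#' @export
classify_double <- function(classification, double = "siCBP_P300") {
  status <- attr(classification, "status")
  if (!double %in% names(status$conditions)) {
    kdtc_stop("kdtc_universe_mismatch", "status lacks condition ", double)
  }
  a_dbl <- aggregate_factor(status$conditions[[double]])
  sel <- classification$category == "unaffected" & a_dbl$affected
  classification$category[sel] <- paste0("double_only_", a_dbl$direction[sel])
  classification$double_direction <- a_dbl$direction
  classification$double_mixed <- a_dbl$mixed
  attr(classification, "double") <- double
  classification
}

#' Category counts and percentages
#'
#' Aggregated counts of the four single-knockdown categories with
#' percentages of the single-knockdown union (specific + common + opposite),
#' reported at full precision and rounded to the nearest integer, plus a
#' per-time-point count table built from per-time-point calls.
#'
#' @param x A \code{kdtc_classification}, or a named numeric vector of
#'   aggregated category counts (names \code{P300_specific},
#'   \code{CBP_specific}, \code{common}, \code{opposite}) for a desk check
#'   against published figures.
#' @param ... Unused.
#' @return A \code{kdtc_category_summary}: list with \code{counts},
#'   \code{union}, \code{percent}, \code{percent_rounded},
#'   \code{directional_counts} and (classification input only)
#'   \code{per_timepoint}.
#' @export
summarize_categories <- function(x, ...) UseMethod("summarize_categories")

#' @export
summarize_categories.numeric <- function(x, ...) {
  need <- c("P300_specific", "CBP_specific", "common", "opposite")
  if (!all(need %in% names(x))) {
    kdtc_stop("kdtc_bad_counts", "counts need names: ", paste(need, collapse = ", "))
  }
  counts <- x[need]
  union_n <- sum(counts)
  pct <- if (union_n > 0) 100 * counts / union_n else rep(NA_real_, length(counts))
  structure(list(counts = counts,
                 union = union_n,
                 percent = pct,
                 percent_rounded = round(pct)),
            class = "kdtc_category_summary")
}

#' @export
summarize_categories.kdtc_classification <- function(x, ...) {
  cat_of <- x$category
  directional <- table(factor(cat_of, levels = c(
    "P300_specific_up", "P300_specific_down", "CBP_specific_up",
    "CBP_specific_down", "common_up", "common_down", "opposite",
    "double_only_up", "double_only_down", "excluded", "unaffected")))
  counts <- c(
    P300_specific = sum(directional[c("P300_specific_up", "P300_specific_down")]),
    CBP_specific = sum(directional[c("CBP_specific_up", "CBP_specific_down")]),
    common = sum(directional[c("common_up", "common_down")]),
    opposite = unname(directional["opposite"]))
  out <- summarize_categories(counts)
  out$directional_counts <- directional
  out$per_timepoint <- per_timepoint_counts(x)
  out
}

# per-timepoint counts from per-timepoint calls (not aggregated direction),
# mirroring a per-time-point breakdown of the category structure
per_timepoint_counts <- function(classification) {
  status <- attr(classification, "status")
  factors <- attr(classification, "factors")
  excluded <- attr(classification, "excluded")
  keep <- !(status$gene_ids %in% excluded)
  d_cbp <- status$conditions[[factors["cbp"]]]$direction[keep, , drop = FALSE]
  d_p300 <- status$conditions[[factors["p300"]]]$direction[keep, , drop = FALSE]
  do.call(rbind, lapply(colnames(d_cbp), function(tp) {
    cb <- d_cbp[, tp]
    p3 <- d_p300[, tp]
    data.frame(timepoint = tp,
               CBP_only_up = sum(cb == "up" & p3 == "none"),
               CBP_only_down = sum(cb == "down" & p3 == "none"),
               P300_only_up = sum(p3 == "up" & cb == "none"),
               P300_only_down = sum(p3 == "down" & cb == "none"),
               common_up = sum(cb == "up" & p3 == "up"),
               common_down = sum(cb == "down" & p3 == "down"),
               opposite = sum(cb != "none" & p3 != "none" & cb != p3),
               stringsAsFactors = FALSE)
  }))
}

# per-timepoint, per-direction gene sets for one condition (minus exclusions)
timepoint_sets <- function(status, condition, excluded = character(0L)) {
  dir <- status$conditions[[condition]]$direction
  keep <- !(rownames(dir) %in% excluded)
  dir <- dir[keep, , drop = FALSE]
  sets <- lapply(colnames(dir), function(tp) {
    list(up = rownames(dir)[dir[, tp] == "up"],
         down = rownames(dir)[dir[, tp] == "down"])
  })
  names(sets) <- colnames(dir)
  sets
}
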