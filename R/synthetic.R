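#' Configuration of the synthetic knockdown time course
#'
#' Describes a simulated array experiment with the study's design: five
#' conditions (NT, siCTR, siCBP, siP300, siCBP_P300) by four time points,
#' one array per design cell by default, ~20,000 genes, and planted gene
#' classes whose default sizes mirror the published aggregated category
#' counts (1,617 P300-specific, 1,048 CBP-specific, 623 common, 76 opposite,
#' split roughly evenly between directions) plus redundant
#' (double-knockdown-only), transfection-artifact and
#' differentiation-program genes.
#'
#' @param n_genes Number of genes (default 20000).
#' @param class_sizes Named integer vector of planted class sizes; names:
#'   p300_specific_down/up, cbp_specific_down/up, common_down/up, opposite,
#'   redundant_double_only, transfection_artifact, diff_activated,
#'   diff_repressed. Remaining genes are null.
#' @param effect_log2 Planted knockdown effect |log2FC| (default
#'   \code{log2(2.5)}, comfortably above the 1.8 working cutoff).
#' @param trend_log2 Differentiation-trend amplitude in log2 units (default
#'   \code{log2(2.5)}).
#' @param noise_sd Array noise SD in log2 units (default 0.2, a typical
#'   residual SD for RMA-summarized expression arrays).
#' @param baseline_mean,baseline_sd Per-gene baseline log2 intensity
#'   distribution (default Normal(8, 2), the bulk of RMA intensities).
#' @param replicates Arrays per design cell (default 1, as deposited).
#' @param timepoints Ordered time points (default transfection clock).
#' @param effect_timepoints Time points carrying planted knockdown effects
#'   and the differentiation trend (default T48 onward: knockdown and
#'   differentiation both need time to act).
#' @param program_disrupted_fraction Fraction of differentiation-program
#'   genes additionally blunted by every knockdown (opposite-sign effect in
#'   both singles and the double; default 0).
#' @param compensatory_log2 Optional small opposite-sign effect on the
#'   sibling co-activator's own transcript (two marker genes CBP/P300 are
#'   appended when > 0; default 0, off).
#' @param seed Default seed used by \code{\link{generate_dataset}}.
#' @return A \code{kdtc_syn_config}.
#' @export
synthetic_config <- function(n_genes = 20000,
                             class_sizes = c(p300_specific_down = 809,
                                             p300_specific_up = 808,
                                             cbp_specific_down = 524,
                                             cbp_specific_up = 524,
                                             common_down = 312,
                                             common_up = 311,
                                             opposite = 76,
                                             redundant_double_only = 300,
                                             transfection_artifact = 100,
                                             diff_activated = 500,
                                             diff_repressed = 500),
                             effect_log2 = log2(2.5),
                             trend_log2 = log2(2.5),
                             noise_sd = 0.2,
                             baseline_mean = 8, baseline_sd = 2,
                             replicates = 1,
                             timepoints = default_timepoints(),
                             effect_timepoints = setdiff(default_timepoints(),
                                                         default_timepoints()[1L]),
                             program_disrupted_fraction = 0,
                             compensatory_log2 = 0,
                             seed = NULL) {
  known <- c("p300_specific_down", "p300_specific_up", "cbp_specific_down",
             "cbp_specific_up", "common_down", "common_up", "opposite",
             "redundant_double_only", "transfection_artifact",
             "diff_activated", "diff_repressed")
  sizes <- stats::setNames(rep(0L, length(known)), known)
  bad <- setdiff(names(class_sizes), known)
  if (length(bad)) kdtc_stop("kdtc_bad_config", "unknown class(es): ", paste(bad, collapse = ", "))
  sizes[names(class_sizes)] <- as.integer(class_sizes)
  if (any(sizes < 0L)) kdtc_stop("kdtc_bad_config", "class sizes must be >= 0")
  if (sum(sizes) > n_genes) kdtc_stop("kdtc_bad_config", "class sizes exceed n_genes")
  if (effect_log2 <= 0) kdtc_stop("kdtc_bad_config", "effect_log2 must be > 0")
  if (noise_sd < 0) kdtc_stop("kdtc_bad_config", "noise_sd must be >= 0")
  if (replicates < 1L) kdtc_stop("kdtc_bad_config", "replicates must be >= 1")
  if (!all(effect_timepoints %in% timepoints[-1L])) {
    kdtc_stop("kdtc_bad_config", "effect_timepoints must be later timepoints")
  }
  if (program_disrupted_fraction < 0 || program_disrupted_fraction > 1) {
    kdtc_stop("kdtc_bad_config", "program_disrupted_fraction must lie in [0, 1]")
  }
  structure(list(n_genes = n_genes, class_sizes = sizes,
                 effect_log2 = effect_log2, trend_log2 = trend_log2,
                 noise_sd = noise_sd, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, replicates = as.integer(replicates),
                 timepoints = timepoints, effect_timepoints = effect_timepoints,
                 program_disrupted_fraction = program_disrupted_fraction,
                 compensatory_log2 = compensatory_log2, seed = seed),
            class = "kdtc_syn_config")
}

#' Generate a synthetic expression matrix with planted truth
#'
#' Per-sample log2 intensity = per-gene baseline + planted condition effect
#' + differentiation trend + Normal(0, noise_sd). Effects are additive in
#' log2 space (multiplicative on the linear scale), matching the fold-change
#' machinery:
#' \itemize{
#'   \item factor-specific classes shift their factor's samples and the
#'     double knockdown by \code{±effect_log2} at the effect time points;
#'   \item common classes shift both singles and the double;
#'   \item opposite genes shift the two singles with opposite signs (half
#'     CBP-up/P300-down, half reversed; the double is untouched);
#'   \item redundant genes shift only the double knockdown (half down,
#'     half up);
#'   \item transfection-artifact genes shift every transfected condition
#'     (siCTR and the three knockdowns) relative to NT at all time points,
#'     so the NT-vs-siCTR contrast flags them while knockdown-vs-siCTR and
#'     within-siCTR program contrasts stay clean;
#'   \item differentiation classes trend over time identically in every
#'     condition; a configurable fraction of them is additionally blunted
#'     by all knockdowns (planted program disruption).
#' }
#'
#' @param config A \code{kdtc_syn_config}.
#' @param seed Seed for reproducibility (defaults to \code{config$seed});
#'   the same seed yields a bit-identical matrix, sheet and truth.
#' @return List with \code{values} (matrix), \code{sheet}
#'   (\code{kdtc_sheet}), \code{truth} (data frame: gene_id, class,
#'   direction, expected_category, program_activated, program_repressed,
#'   disrupted) and \code{config}.
#' @export
generate_dataset <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "kdtc_syn_config"))
  if (!is.null(seed)) set.seed(seed)
  sizes <- config$class_sizes
  extra <- if (config$compensatory_log2 > 0) 2L else 0L
  n <- config$n_genes + extra
  width <- max(5L, nchar(as.character(n)))
  ids <- sprintf("G%0*d", width, seq_len(config$n_genes))
  cls <- rep(c(names(sizes), "null"),
             c(sizes, config$n_genes - sum(sizes)))
  if (extra) {
    ids <- c(ids, "CBP", "P300")
    cls <- c(cls, "factor_transcript_cbp", "factor_transcript_p300")
  }

  conds <- kd_conditions()
  tps <- config$timepoints
  reps <- config$replicates
  grid <- expand.grid(replicate = seq_len(reps), timepoint = tps,
                      condition = conds, stringsAsFactors = FALSE)
  sheet_df <- data.frame(
    sample_id = sprintf("%s_%s_r%d", grid$condition, grid$timepoint, grid$replicate),
    condition = grid$condition, timepoint = grid$timepoint,
    stringsAsFactors = FALSE)
  sheet <- sample_sheet(sheet_df, timepoints = tps)
  m <- nrow(sheet)

  effect_cols <- function(condset) {
    which(sheet$condition %in% condset & sheet$timepoint %in% config$effect_timepoints)
  }
  rows_of <- function(classes) which(cls %in% classes)
  half <- function(rows) {
    k <- length(rows) %/% 2L
    list(first = rows[seq_len(k)], rest = rows[setdiff(seq_along(rows), seq_len(k))])
  }

  E <- matrix(0, n, m)
  d <- config$effect_log2
  add <- function(rows, condset, sign) {
    if (length(rows)) E[rows, effect_cols(condset)] <<- E[rows, effect_cols(condset)] + sign * d
  }
  add(rows_of("cbp_specific_down"), c("siCBP", "siCBP_P300"), -1)
  add(rows_of("cbp_specific_up"), c("siCBP", "siCBP_P300"), +1)
  add(rows_of("p300_specific_down"), c("siP300", "siCBP_P300"), -1)
  add(rows_of("p300_specific_up"), c("siP300", "siCBP_P300"), +1)
  add(rows_of("common_down"), c("siCBP", "siP300", "siCBP_P300"), -1)
  add(rows_of("common_up"), c("siCBP", "siP300", "siCBP_P300"), +1)
  opp <- half(rows_of("opposite"))
  add(opp$first, "siCBP", +1); add(opp$first, "siP300", -1)
  add(opp$rest, "siCBP", -1); add(opp$rest, "siP300", +1)
  red <- half(rows_of("redundant_double_only"))
  add(red$first, "siCBP_P300", -1)
  add(red$rest, "siCBP_P300", +1)
  # the transfection insult is present from T0 in every transfected
  # condition, so it never mimics a differentiation trend within siCTR and
  # never contaminates knockdown-vs-siCTR contrasts
  transfected <- setdiff(conds, "NT")
  art <- rows_of("transfection_artifact")
  if (length(art)) {
    all_tp_cols <- which(sheet$condition %in% transfected)
    E[art, all_tp_cols] <- E[art, all_tp_cols] + d
  }

  a <- config$trend_log2
  act <- rows_of("diff_activated")
  repd <- rows_of("diff_repressed")
  if (length(act)) E[act, effect_cols(conds)] <- E[act, effect_cols(conds)] + a
  if (length(repd)) E[repd, effect_cols(conds)] <- E[repd, effect_cols(conds)] - a

  disrupted <- logical(n)
  if (config$program_disrupted_fraction > 0) {
    kd <- c("siCBP", "siP300", "siCBP_P300")
    d_act <- act[seq_len(floor(config$program_disrupted_fraction * length(act)))]
    d_rep <- repd[seq_len(floor(config$program_disrupted_fraction * length(repd)))]
    add(d_act, kd, -1)   # knockdown blunts the activation
    add(d_rep, kd, +1)   # knockdown blunts the repression
    disrupted[c(d_act, d_rep)] <- TRUE
  }
  if (extra) {
    i_cbp <- which(cls == "factor_transcript_cbp")
    i_p300 <- which(cls == "factor_transcript_p300")
    add(i_cbp, c("siCBP", "siCBP_P300"), -1)
    add(i_p300, c("siP300", "siCBP_P300"), -1)
    comp <- config$compensatory_log2
    E[i_cbp, effect_cols("siP300")] <- E[i_cbp, effect_cols("siP300")] + comp
    E[i_p300, effect_cols("siCBP")] <- E[i_p300, effect_cols("siCBP")] + comp
  }

  baseline <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
  values <- baseline + E
  if (config$noise_sd > 0) {
    values <- values + matrix(stats::rnorm(n * m, 0, config$noise_sd), n, m)
  }
  dimnames(values) <- list(ids, sheet$sample_id)

  truth <- data.frame(gene_id = ids, class = cls,
                      direction = planted_direction(cls, opp, red, seq_len(n)),
                      expected_category = expected_category(cls, opp, red, disrupted, seq_len(n)),
                      program_activated = cls == "diff_activated",
                      program_repressed = cls == "diff_repressed",
                      disrupted = disrupted,
                      stringsAsFactors = FALSE)
  list(values = values, sheet = sheet, truth = truth, config = config)
}

planted_direction <- function(cls, opp, red, idx) {
  dirn <- rep(NA_character_, length(cls))
  dirn[grepl("_down$", cls)] <- "down"
  dirn[grepl("_up$", cls)] <- "up"
  dirn[idx %in% opp$first] <- "cbp_up_p300_down"
  dirn[idx %in% opp$rest] <- "cbp_down_p300_up"
  dirn[idx %in% red$first] <- "down"
  dirn[idx %in% red$rest] <- "up"
  dirn[cls == "diff_activated"] <- "up"
  dirn[cls == "diff_repressed"] <- "down"
  dirn[cls == "transfection_artifact"] <- "up"
  dirn
}

# the category the pipeline should assign to each planted class (noiseless
# forcing; disrupted program genes are knocked down/up by both factors and
# therefore land in the common categories)
expected_category <- function(cls, opp, red, disrupted, idx) {
  out <- rep("unaffected", length(cls))
  out[cls == "p300_specific_down"] <- "P300_specific_down"
  out[cls == "p300_specific_up"] <- "P300_specific_up"
  out[cls == "cbp_specific_down"] <- "CBP_specific_down"
  out[cls == "cbp_specific_up"] <- "CBP_specific_up"
  out[cls == "common_down"] <- "common_down"
  out[cls == "common_up"] <- "common_up"
  out[cls == "opposite"] <- "opposite"
  out[idx %in% red$first] <- "double_only_down"
  out[idx %in% red$rest] <- "double_only_up"
  out[cls == "transfection_artifact"] <- "excluded"
  out[cls == "diff_activated" & disrupted] <- "common_down"
  out[cls == "diff_repressed" & disrupted] <- "common_up"
  out[cls == "factor_transcript_cbp"] <- "CBP_specific_down"
  out[cls == "factor_transcript_p300"] <- "P300_specific_down"
  out
}

#' Score pipeline classification against planted truth
#'
#' @param truth Truth data frame from \code{\link{generate_dataset}}.
#' @param classification A \code{kdtc_classification} on the same universe.
#' @return List: overall \code{accuracy}, \code{confusion} (truth x
#'   predicted table) and per-class \code{precision}/\code{recall} data
#'   frame.
#' @export
score_recovery <- function(truth, classification) {
  if (!setequal(truth$gene_id, classification$gene_id)) {
    kdtc_stop("kdtc_universe_mismatch", "truth and classification gene sets differ")
  }
  pred <- classification$category[match(truth$gene_id, classification$gene_id)]
  expected <- truth$expected_category
  levels_all <- sort(unique(c(pred, expected)))
  confusion <- table(truth = factor(expected, levels_all),
                     predicted = factor(pred, levels_all))
  per_class <- do.call(rbind, lapply(levels_all, function(cl) {
    tp <- sum(pred == cl & expected == cl)
    data.frame(class = cl,
               n_truth = sum(expected == cl),
               n_predicted = sum(pred == cl),
               precision = if (sum(pred == cl)) tp / sum(pred == cl) else NA_real_,
               recall = if (sum(expected == cl)) tp / sum(expected == cl) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(accuracy = mean(pred == expected),
       confusion = confusion,
       per_class = per_class)
}
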