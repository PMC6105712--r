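# Shared fixtures: tiny deterministic designs built in code.

# full 5-condition x 4-timepoint sheet, one array per cell
full_sheet <- function(conditions = kd_conditions(),
                       timepoints = default_timepoints()) {
  grid <- expand.grid(timepoint = timepoints, condition = conditions,
                      stringsAsFactors = FALSE)
  sample_sheet(data.frame(
    sample_id = paste(grid$condition, grid$timepoint, "r1", sep = "_"),
    condition = grid$condition, timepoint = grid$timepoint,
    stringsAsFactors = FALSE), timepoints = timepoints)
}

# constant matrix over a sheet, with per-(condition,timepoint) overrides:
# overrides is a list of lists(gene, condition, timepoint, value)
design_matrix <- function(sheet, genes = c("GA", "GB", "GC"), base = 8,
                          overrides = list()) {
  m <- matrix(base, nrow = length(genes), ncol = nrow(sheet),
              dimnames = list(genes, sheet$sample_id))
  for (ov in overrides) {
    cols <- sheet$sample_id[sheet$condition == ov$condition &
                              sheet$timepoint == ov$timepoint]
    m[ov$gene, cols] <- ov$value
  }
  m
}

# small noisy synthetic config used across test files
small_config <- function(noise_sd = 0.2, ...) {
  synthetic_config(
    n_genes = 2000,
    class_sizes = c(p300_specific_down = 81, p300_specific_up = 81,
                    cbp_specific_down = 52, cbp_specific_up = 52,
                    common_down = 31, common_up = 31, opposite = 8,
                    redundant_double_only = 30, transfection_artifact = 10,
                    diff_activated = 50, diff_repressed = 50),
    noise_sd = noise_sd, ...)
}

# run the classification stages on a generated dataset at a fixed cutoff
classify_dataset <- function(sim, cutoff = 1.8) {
  fc <- compute_fold_changes(sim$values, sim$sheet,
                             conditions = c("siCBP", "siP300", "siCBP_P300"))
  fc_nt <- compute_fold_changes(sim$values, sim$sheet, conditions = "NT")
  excluded <- exclude_transfection_artifacts(fc_nt, cutoff)
  status <- flag_affected(fc, cutoff)
  classify_double(classify_specificity(status, excluded = excluded))
}
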