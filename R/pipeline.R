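#' Assemble and validate a pipeline configuration
#'
#' A single flat configuration drives the whole run. The adaptive scan and a
#' fixed cutoff are mutually exclusive unless \code{allow_override = TRUE}
#' (in which case the fixed value wins and the scan is still exported for
#' audit).
#'
#' @param matrix_path,sheet_path Input files (ignored when \code{simulate}
#'   is a \code{kdtc_syn_config}).
#' @param simulate Optional \code{kdtc_syn_config}; when supplied the run
#'   starts from generated data instead of files.
#' @param out_dir Output directory.
#' @param enhancer_path Optional enhancer-associated gene list (plain or
#'   GMT; format by extension).
#' @param edge_path Optional interaction edge list (TSV or SIF) for hub
#'   ranking.
#' @param input_scale "log2" (default) or "linear".
#' @param fixed_cutoff Optional fixed fold-magnitude cutoff (e.g. the
#'   published 1.8) bypassing the scan.
#' @param scan Logical: run the adaptive threshold scan (default TRUE when
#'   no fixed cutoff is given).
#' @param allow_override Permit both \code{fixed_cutoff} and \code{scan}.
#' @param rule A \code{kdtc_cutoff_rule}.
#' @param bin_size Genes per scan bin.
#' @param reference Reference condition for knockdown contrasts and the
#'   differentiation program.
#' @param cluster_distance,cluster_linkage Clustering options for heatmap
#'   ordering.
#' @param seed Seed applied at the start of the run.
#' @return A validated \code{kdtc_pipeline_config}.
#' @export
pipeline_config <- function(matrix_path = NULL, sheet_path = NULL,
                            simulate = NULL, out_dir = "kdtc_out",
                            enhancer_path = NULL, edge_path = NULL,
                            input_scale = "log2",
                            fixed_cutoff = NULL, scan = is.null(fixed_cutoff),
                            allow_override = FALSE,
                            rule = cutoff_rule(), bin_size = 100,
                            reference = "siCTR",
                            cluster_distance = "euclidean",
                            cluster_linkage = "average",
                            seed = NULL) {
  if (!is.null(fixed_cutoff) && scan && !allow_override) {
    kdtc_stop("kdtc_bad_config",
              "fixed_cutoff and scan are mutually exclusive unless allow_override = TRUE")
  }
  if (is.null(simulate)) {
    for (p in c(matrix_path, sheet_path)) {
      if (is.null(p) || !file.exists(p)) {
        kdtc_stop("kdtc_missing_file", "input file missing: ", p %||% "(unset)")
      }
    }
  }
  for (p in c(enhancer_path, edge_path)) {
    if (!is.null(p) && !file.exists(p)) {
      kdtc_stop("kdtc_missing_file", "input file missing: ", p)
    }
  }
  structure(list(matrix_path = matrix_path, sheet_path = sheet_path,
                 simulate = simulate, out_dir = out_dir,
                 enhancer_path = enhancer_path, edge_path = edge_path,
                 input_scale = input_scale, fixed_cutoff = fixed_cutoff,
                 scan = scan, allow_override = allow_override, rule = rule,
                 bin_size = bin_size, reference = reference,
                 cluster_distance = cluster_distance,
                 cluster_linkage = cluster_linkage, seed = seed),
            class = "kdtc_pipeline_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' Flat JSON keys map onto \code{\link{pipeline_config}} arguments; keys
#' \code{rule} and \code{simulate} may be nested objects holding
#' \code{\link{cutoff_rule}} / \code{\link{synthetic_config}} arguments.
#'
#' @param path Path to the JSON config.
#' @return A \code{kdtc_pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) kdtc_stop("kdtc_missing_file", "config not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$rule)) raw$rule <- do.call(cutoff_rule, as.list(raw$rule))
  if (!is.null(raw$simulate)) {
    sim <- as.list(raw$simulate)
    if (!is.null(sim$class_sizes)) sim$class_sizes <- unlist(sim$class_sizes)
    raw$simulate <- do.call(synthetic_config, sim)
  }
  do.call(pipeline_config, raw)
}

#' Run the whole analysis pipeline
#'
#' Orchestrates: (optional) simulation, fold changes, threshold selection
#' (scan or fixed), transfection-artifact exclusion, specificity and
#' double-knockdown classification, category summaries, differentiation
#' program and its disruption, recapitulation/redundancy, (optional)
#' direct-target fractions and hub ranking, heatmap-ordered matrices, and a
#' JSON manifest with parameters and MD5 hashes of every output. Identical
#' config + inputs + seed yield identical manifest hashes.
#'
#' @param config A \code{kdtc_pipeline_config}.
#' @return The manifest (list), invisibly; written to
#'   \code{out_dir/manifest.json}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "kdtc_pipeline_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  log_stage <- function(...) message("[kdtc] ", ...)

  if (!is.null(config$simulate)) {
    log_stage("simulate")
    sim <- generate_dataset(config$simulate, seed = config$simulate$seed %||% config$seed)
    values <- sim$values
    sheet <- sim$sheet
    write_expression_matrix(values, file.path(out, "matrix.tsv"))
    write_sample_sheet(sheet, file.path(out, "sample_sheet.tsv"))
    write_tsv(sim$truth[order_c(sim$truth$gene_id), ], file.path(out, "truth.tsv"))
  } else {
    values <- read_expression_matrix(config$matrix_path,
                                     input_scale = config$input_scale)
    sheet <- read_sample_sheet(config$sheet_path)
  }
  validate_design(values, sheet, reference = config$reference)

  log_stage("fold_change")
  kd_conds <- intersect(c("siCBP", "siP300", "siCBP_P300"), unique(sheet$condition))
  fc <- compute_fold_changes(values, sheet, reference = config$reference,
                             conditions = kd_conds)
  write_fold_changes(fc, file.path(out, "fold_changes.tsv"))
  fc_nt <- if ("NT" %in% sheet$condition) {
    compute_fold_changes(values, sheet, reference = config$reference,
                         conditions = "NT")
  } else NULL

  log_stage("threshold")
  scans <- NULL
  if (config$scan) {
    scans <- scan_fold_changes(fc, rule = config$rule, bin_size = config$bin_size)
    write_tsv(scans_to_table(scans), file.path(out, "threshold_scans.tsv"))
  }
  cutoff <- if (!is.null(config$fixed_cutoff)) {
    config$fixed_cutoff
  } else {
    harmonize_global_cutoff(vapply(scans, `[[`, numeric(1L), "departure_magnitude"),
                            config$rule)
  }
  log_stage("cutoff = ", format(cutoff))

  log_stage("classify")
  excluded <- exclude_transfection_artifacts(fc_nt, cutoff)
  status <- flag_affected(fc, cutoff)
  cl <- classify_specificity(status, excluded = excluded)
  if ("siCBP_P300" %in% kd_conds) cl <- classify_double(cl)
  write_tsv(as.data.frame(cl)[order_c(cl$gene_id), ],
            file.path(out, "classification.tsv"))
  write_gene_sets(cl, out)
  summ <- summarize_categories(cl)
  write_tsv(data.frame(category = names(summ$counts),
                       count = as.integer(summ$counts),
                       percent = summ$percent,
                       percent_rounded = summ$percent_rounded,
                       stringsAsFactors = FALSE),
            file.path(out, "category_summary.tsv"))
  write_tsv(summ$per_timepoint, file.path(out, "per_timepoint_counts.tsv"))

  log_stage("overlap")
  program <- define_program(values, sheet, cutoff, reference = config$reference)
  overlap <- rbind(
    program_disruption(program, status, "siCBP", excluded),
    program_disruption(program, status, "siP300", excluded),
    if ("siCBP_P300" %in% kd_conds) program_disruption(program, status, "siCBP_P300", excluded),
    if ("siCBP_P300" %in% kd_conds) recapitulation(status, excluded = excluded))
  write_tsv(overlap, file.path(out, "overlap_report.tsv"))

  if (!is.null(config$enhancer_path)) {
    log_stage("direct_targets")
    fmt <- if (grepl("\\.gmt$", config$enhancer_path, ignore.case = TRUE)) "gmt" else "plain"
    enh <- normalize_symbols(read_gene_list(config$enhancer_path, format = fmt))
    reports <- lapply(c(cbp = "siCBP", p300 = "siP300"), function(cond) {
      agg <- aggregate_factor(status$conditions[[cond]])
      down <- status$gene_ids[agg$affected & agg$direction == "down"]
      direct_fraction(setdiff(down, excluded), enh, factor = cond)
    })
    write_tsv(direct_to_table(reports), file.path(out, "direct_targets.tsv"))
  }

  log_stage("cluster")
  for (categ in setdiff(sort(unique(cl$category)), c("unaffected", "excluded"))) {
    genes <- cl$gene_id[cl$category == categ]
    if (length(genes) < 2L) next
    ordd <- cluster_order(fc$log2fc[genes, , drop = FALSE],
                          distance = config$cluster_distance,
                          linkage = config$cluster_linkage)
    write_clustered_matrix(ordd, file.path(out, paste0("heatmap_", categ, ".tsv")))
  }

  if (!is.null(config$edge_path)) {
    log_stage("hubs")
    write_tsv(rank_hubs(read_edge_list(config$edge_path)),
              file.path(out, "hubs.tsv"))
  }

  log_stage("manifest")
  files <- sort(setdiff(list.files(out), "manifest.json"))
  manifest <- list(
    package = "kdtc",
    version = as.character(utils::packageVersion("kdtc")),
    parameters = list(cutoff = cutoff,
                      fixed_cutoff = config$fixed_cutoff,
                      scan = config$scan,
                      bin_size = config$bin_size,
                      rule = unclass(config$rule),
                      reference = config$reference,
                      seed = config$seed),
    n_genes = nrow(values),
    n_samples = ncol(values),
    n_excluded = length(excluded),
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out, files))), files)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
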