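#' Read a genes-by-samples expression matrix
#'
#' Reads a delimited text file whose first column holds gene identifiers and
#' whose header row holds sample identifiers. Values are normalized array
#' intensities; RMA output is log2 scale, which is the default expectation.
#' Linear-scale input is log2-transformed on load.
#'
#' @param path Path to the matrix file.
#' @param delimiter Field delimiter (default tab).
#' @param input_scale Either "log2" (default, values used as-is) or "linear"
#'   (strictly positive values, log2-transformed on load).
#' @return Numeric matrix with gene row names and sample column names.
#' @export
read_expression_matrix <- function(path, delimiter = "\t",
                                   input_scale = c("log2", "linear")) {
  input_scale <- match.arg(input_scale)
  if (!file.exists(path)) {
    kdtc_stop("kdtc_missing_file", "expression matrix file not found: ", path)
  }
  raw <- utils::read.delim(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2L) {
    kdtc_stop("kdtc_malformed_matrix", "matrix needs a gene id column and >=1 sample column")
  }
  gene_ids <- trimws(raw[[1L]])
  body <- raw[, -1L, drop = FALSE]
  suppressWarnings(values <- vapply(body, as.numeric, numeric(nrow(body))))
  if (nrow(raw) == 1L) values <- matrix(values, nrow = 1L, dimnames = list(NULL, colnames(body)))
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    kdtc_stop("kdtc_non_numeric", "non-numeric value at gene '", gene_ids[bad[1L]],
              "', sample '", colnames(values)[bad[2L]], "'")
  }
  rownames(values) <- gene_ids
  if (input_scale == "linear") {
    if (any(values <= 0)) {
      kdtc_stop("kdtc_non_positive", "linear-scale input must be strictly positive")
    }
    values <- log2(values)
  }
  validate_expression_matrix(values)
  values
}

#' Validate an expression matrix
#'
#' Checks the container invariants: finite numeric values, unique non-empty
#' gene identifiers, unique sample identifiers.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @return The matrix, invisibly.
#' @export
validate_expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    kdtc_stop("kdtc_malformed_matrix", "expression matrix must be a numeric matrix")
  }
  gene_ids <- rownames(values)
  if (is.null(gene_ids) || any(!nzchar(gene_ids))) {
    kdtc_stop("kdtc_malformed_matrix", "gene identifiers missing or empty")
  }
  if (anyDuplicated(gene_ids)) {
    kdtc_stop("kdtc_duplicate_id", "duplicate gene identifier(s): ",
              paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  sample_ids <- colnames(values)
  if (is.null(sample_ids) || anyDuplicated(sample_ids)) {
    kdtc_stop("kdtc_duplicate_id", "sample identifiers missing or duplicated")
  }
  if (!all(is.finite(values))) {
    kdtc_stop("kdtc_non_finite", "expression matrix contains non-finite values")
  }
  invisible(values)
}

#' Write an expression matrix as TSV
#'
#' Rows are sorted lexicographically by gene identifier (C locale) so output
#' is byte-stable across runs and platforms.
#'
#' @param values Numeric matrix with gene row names and sample column names.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_expression_matrix <- function(values, path) {
  validate_expression_matrix(values)
  ord <- order_c(rownames(values))
  df <- data.frame(gene_id = rownames(values)[ord],
                   values[ord, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a sample sheet
#'
#' The sheet maps each array to its condition and time point. Columns
#' \code{sample_id}, \code{condition} and \code{timepoint} are required;
#' labels are validated against the configured vocabularies.
#'
#' @param path Path to a TSV sample sheet.
#' @param conditions Allowed condition labels (default \code{kd_conditions()}).
#' @param timepoints Ordered time-point labels (default
#'   \code{default_timepoints()}).
#' @return A data frame of class \code{kdtc_sheet} with the time-point order
#'   stored in \code{attr(, "timepoints")}.
#' @export
read_sample_sheet <- function(path, conditions = kd_conditions(),
                              timepoints = default_timepoints()) {
  if (!file.exists(path)) {
    kdtc_stop("kdtc_missing_file", "sample sheet file not found: ", path)
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  sample_sheet(df, conditions = conditions, timepoints = timepoints)
}

#' Construct/validate a sample sheet
#'
#' @param df Data frame with columns sample_id, condition, timepoint.
#' @inheritParams read_sample_sheet
#' @return Validated data frame of class \code{kdtc_sheet}.
#' @export
sample_sheet <- function(df, conditions = kd_conditions(),
                         timepoints = default_timepoints()) {
  need <- c("sample_id", "condition", "timepoint")
  missing_cols <- setdiff(need, colnames(df))
  if (length(missing_cols)) {
    kdtc_stop("kdtc_malformed_sheet", "sample sheet lacks column(s): ",
              paste(missing_cols, collapse = ", "))
  }
  df <- df[, need]
  df[] <- lapply(df, function(x) trimws(as.character(x)))
  if (anyDuplicated(df$sample_id)) {
    kdtc_stop("kdtc_duplicate_id", "duplicate sample_id in sheet")
  }
  bad_cond <- setdiff(unique(df$condition), conditions)
  if (length(bad_cond)) {
    kdtc_stop("kdtc_unknown_condition", "unknown condition label(s): ",
              paste(bad_cond, collapse = ", "))
  }
  bad_tp <- setdiff(unique(df$timepoint), timepoints)
  if (length(bad_tp)) {
    kdtc_stop("kdtc_unknown_timepoint", "timepoint(s) not in configured order: ",
              paste(bad_tp, collapse = ", "))
  }
  attr(df, "timepoints") <- timepoints
  attr(df, "conditions") <- conditions
  class(df) <- c("kdtc_sheet", "data.frame")
  df
}

#' Write a sample sheet as TSV
#' @param sheet A \code{kdtc_sheet}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  write_tsv(as.data.frame(sheet)[order_c(sheet$sample_id), ], path)
}

#' Check that a matrix and sample sheet form a usable design
#'
#' Every sheet sample must be a matrix column, and the reference condition
#' must be present at every time point the sheet uses (knockdown contrasts
#' are per time point against that reference).
#'
#' @param values Expression matrix.
#' @param sheet Sample sheet.
#' @param reference Reference condition (default \code{"siCTR"}).
#' @return \code{TRUE}, invisibly; otherwise a classed error.
#' @export
validate_design <- function(values, sheet, reference = "siCTR") {
  validate_expression_matrix(values)
  absent <- setdiff(sheet$sample_id, colnames(values))
  if (length(absent)) {
    kdtc_stop("kdtc_design_error", "sheet sample(s) absent from matrix: ",
              paste(absent, collapse = ", "))
  }
  tps <- intersect(attr(sheet, "timepoints"), unique(sheet$timepoint))
  ref_tps <- unique(sheet$timepoint[sheet$condition == reference])
  missing_ref <- setdiff(tps, ref_tps)
  if (length(missing_ref)) {
    kdtc_stop("kdtc_design_error", "reference condition '", reference,
              "' missing at timepoint(s): ", paste(missing_ref, collapse = ", "))
  }
  invisible(TRUE)
}

#' Read a gene list (plain text or GMT)
#'
#' Plain format is one symbol per line; GMT is the standard tab-separated
#' record (set name, description, then members). Symbols are whitespace
#' stripped and de-duplicated; case folding is left to
#' \code{\link{normalize_symbols}} so the raw list stays auditable.
#'
#' @param path Path to the list file.
#' @param format "plain" or "gmt".
#' @param name For GMT input with several records, the record to extract
#'   (default: the sole record; ambiguous files are an error).
#' @return A list of class \code{kdtc_gene_list} with fields \code{name}
#'   and \code{genes}.
#' @export
read_gene_list <- function(path, format = c("plain", "gmt"), name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    kdtc_stop("kdtc_missing_file", "gene list file not found: ", path)
  }
  if (format == "plain") {
    lines <- trimws(readLines(path, warn = FALSE))
    genes <- lines[nzchar(lines)]
    return(gene_list(sub("\\.[^.]*$", "", basename(path)), genes))
  }
  sets <- read_gmt(path)
  if (is.null(name)) {
    if (length(sets) != 1L) {
      kdtc_stop("kdtc_malformed_gmt", "GMT holds ", length(sets),
                " records; pass `name` to pick one")
    }
    return(sets[[1L]])
  }
  if (!name %in% names(sets)) {
    kdtc_stop("kdtc_malformed_gmt", "no GMT record named '", name, "'")
  }
  sets[[name]]
}

#' Read every record of a GMT file
#' @param path Path to a GMT file.
#' @return Named list of \code{kdtc_gene_list} objects.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    kdtc_stop("kdtc_missing_file", "GMT file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) kdtc_stop("kdtc_empty_list", "GMT file is empty: ", path)
  sets <- lapply(lines, function(ln) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      kdtc_stop("kdtc_malformed_gmt", "malformed GMT record (", length(fields),
                " field(s)): ", substr(ln, 1L, 60L))
    }
    gene_list(fields[1L], fields[-(1:2)])
  })
  names(sets) <- vapply(sets, `[[`, character(1L), "name")
  sets
}

#' Construct a named gene list
#' @param name Set name.
#' @param genes Character vector of symbols; whitespace stripped, empties
#'   dropped, duplicates collapsed (first occurrence kept).
#' @return A \code{kdtc_gene_list}.
#' @export
gene_list <- function(name, genes) {
  genes <- trimws(as.character(genes))
  genes <- unique(genes[nzchar(genes)])
  if (!length(genes)) {
    kdtc_stop("kdtc_empty_list", "gene list '", name, "' is empty after stripping")
  }
  structure(list(name = as.character(name), genes = genes),
            class = "kdtc_gene_list")
}

#' Write classification gene sets as GMT plus a long-form table
#'
#' One GMT record per non-empty category (members sorted lexicographically),
#' plus \code{gene_sets.tsv} in long form: gene, category, condition,
#' timepoint, log2 fold change. Empty categories are omitted from the GMT
#' (and reported via a message).
#'
#' @param classification A \code{kdtc_classification}.
#' @param dir Output directory (created if needed).
#' @return Character vector of the two file paths, invisibly.
#' @export
write_gene_sets <- function(classification, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gmt_path <- file.path(dir, "gene_sets.gmt")
  tsv_path <- file.path(dir, "gene_sets.tsv")
  cats <- split(classification$gene_id, classification$category)
  cats <- cats[order_c(names(cats))]
  keep <- lengths(cats) > 0L
  if (any(!keep)) {
    message("omitting empty categor(ies): ", paste(names(cats)[!keep], collapse = ", "))
  }
  cats <- cats[keep]
  lines <- vapply(names(cats), function(nm) {
    paste(c(nm, "kdtc category", sort_c(cats[[nm]])), collapse = "\t")
  }, character(1L))
  writeLines(lines, gmt_path, useBytes = TRUE)

  status <- attr(classification, "status")
  long <- do.call(rbind, lapply(names(status$conditions), function(cond) {
    fc <- status$conditions[[cond]]$log2fc
    data.frame(gene_id = rep(rownames(fc), ncol(fc)),
               condition = cond,
               timepoint = rep(colnames(fc), each = nrow(fc)),
               log2fc = as.vector(fc),
               stringsAsFactors = FALSE)
  }))
  long$category <- classification$category[match(long$gene_id, classification$gene_id)]
  long <- long[order_c(long$gene_id), c("gene_id", "category", "condition", "timepoint", "log2fc")]
  tp_order <- match(long$timepoint, status$timepoints)
  cond_order <- match(long$condition, names(status$conditions))
  long <- long[order(match(long$gene_id, sort_c(unique(long$gene_id))), cond_order, tp_order), ]
  write_tsv(long, tsv_path)
  invisible(c(gmt_path, tsv_path))
}

# -- shared writer helpers ----------------------------------------------------

# lexicographic (C locale) ordering, platform-stable
order_c <- function(x) order(x, method = "radix")
sort_c <- function(x) x[order_c(x)]

write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n",
                     fileEncoding = "UTF-8")
  invisible(path)
}
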