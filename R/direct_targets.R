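#' Normalize gene symbols for cross-species set matching
#'
#' The enhancer-associated reference list comes from mouse cells, so symbols
#' are matched by uppercase identity (the usual mouse-to-human convention);
#' an optional alias table (named character vector, \code{from = to}) is
#' applied before case folding. Imperfect orthology is a declared limitation
#' of symbol matching; the alias table is the escape hatch.
#'
#' @param genes A \code{kdtc_gene_list} or character vector.
#' @param alias Optional named character vector mapping input symbols to
#'   replacements (applied case-sensitively before folding).
#' @return Same type as the input, with symbols trimmed, aliased,
#'   upper-cased and de-duplicated. Idempotent.
#' @export
normalize_symbols <- function(genes, alias = NULL) {
  is_list <- inherits(genes, "kdtc_gene_list")
  syms <- if (is_list) genes$genes else as.character(genes)
  syms <- trimws(syms)
  syms <- syms[nzchar(syms)]
  if (!is.null(alias)) {
    hit <- syms %in% names(alias)
    syms[hit] <- alias[syms[hit]]
  }
  syms <- unique(toupper(syms))
  if (!length(syms)) {
    kdtc_stop("kdtc_empty_list", "gene set empty after normalization")
  }
  if (is_list) gene_list(genes$name, syms) else syms
}

#' Fraction of downregulated genes with enhancer support
#'
#' Intersects a knockdown-downregulated gene set with an external
#' enhancer-associated gene list; the overlap fraction estimates the share
#' of likely direct targets of the knocked-down co-activator.
#'
#' @param down_genes Character vector (or \code{kdtc_gene_list}) of
#'   downregulated genes.
#' @param enhancer_genes \code{kdtc_gene_list} or character vector of
#'   enhancer-associated genes.
#' @param alias Optional alias table passed to
#'   \code{\link{normalize_symbols}}.
#' @param factor Label carried into the report.
#' @return A \code{kdtc_direct_report}: list with \code{factor},
#'   \code{n_down}, \code{n_match}, \code{fraction} (NA when the
#'   downregulated set is empty) and the sorted \code{matches}.
#' @export
direct_fraction <- function(down_genes, enhancer_genes, alias = NULL,
                            factor = NA_character_) {
  down <- if (inherits(down_genes, "kdtc_gene_list")) down_genes$genes else as.character(down_genes)
  down <- unique(toupper(trimws(down[nzchar(trimws(down))])))
  enh <- if (length(if (inherits(enhancer_genes, "kdtc_gene_list")) enhancer_genes$genes else enhancer_genes)) {
    normalize_symbols(enhancer_genes, alias = alias)
  } else enhancer_genes
  enh <- if (inherits(enh, "kdtc_gene_list")) enh$genes else as.character(enh)
  matches <- sort_c(intersect(down, enh))
  structure(list(factor = factor,
                 n_down = length(down),
                 n_match = length(matches),
                 fraction = if (length(down)) length(matches) / length(down) else NA_real_,
                 matches = matches),
            class = "kdtc_direct_report")
}

#' Tabulate direct-target reports
#' @param reports List of \code{kdtc_direct_report} objects.
#' @return Data frame: factor, n_down, n_match, fraction, percent.
#' @export
direct_to_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    data.frame(factor = r$factor, n_down = r$n_down, n_match = r$n_match,
               fraction = r$fraction, percent = 100 * r$fraction,
               stringsAsFactors = FALSE)
  }))
}
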