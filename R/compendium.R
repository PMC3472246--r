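#' Expression compendium container
#'
#' A `glucose_compendium` bundles the per-mutant average expression profiles
#' of a deletion-strain collection: a mutants x genes matrix of log2
#' fold-changes versus the average wildtype, the matching matrix of p-values,
#' the mutant -> deleted-gene map, and (optionally) replicate-level wildtype
#' profiles grown alongside the mutants.
#'
#' @param logfc Numeric matrix, mutants in rows, genes in columns, log2
#'   ratios versus the average wildtype.
#' @param pvalue Numeric matrix with the same dimnames as `logfc`; values in
#'   (0, 1].
#' @param deleted_genes Named list mapping each mutant id to a character
#'   vector of deleted gene ids (length 1 for singles, 2 for double mutants).
#' @param wt_profiles Optional numeric matrix of wildtype replicate profiles
#'   (replicates x genes, log2 ratios), genes matching `logfc` columns.
#'
#' @return An object of class `glucose_compendium`.
#' @export
new_compendium <- function(logfc, pvalue, deleted_genes, wt_profiles = NULL) {
  stopifnot(is.matrix(logfc), is.matrix(pvalue))
  if (is.null(rownames(logfc)) || is.null(colnames(logfc))) {
    stop("logfc must carry mutant rownames and gene colnames", call. = FALSE)
  }
  if (!identical(dim(logfc), dim(pvalue)) ||
      !identical(dimnames(logfc), dimnames(pvalue))) {
    stop("logfc and pvalue must share shape and dimnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(logfc)) || anyDuplicated(colnames(logfc))) {
    stop("duplicate mutant or gene ids", call. = FALSE)
  }
  if (any(!is.finite(pvalue)) || any(pvalue <= 0) || any(pvalue > 1)) {
    stop("pvalue entries must lie in (0, 1]", call. = FALSE)
  }
  if (!is.list(deleted_genes) || is.null(names(deleted_genes))) {
    stop("deleted_genes must be a named list (mutant -> gene ids)", call. = FALSE)
  }
  missing_mut <- setdiff(rownames(logfc), names(deleted_genes))
  if (length(missing_mut) > 0) {
    stop("no deleted-gene entry for mutant(s): ",
         paste(missing_mut, collapse = ", "), call. = FALSE)
  }
  unmeasured <- setdiff(unlist(deleted_genes[rownames(logfc)]), colnames(logfc))
  if (!is.null(wt_profiles)) {
    stopifnot(is.matrix(wt_profiles))
    if (!identical(colnames(wt_profiles), colnames(logfc))) {
      stop("wt_profiles genes must match logfc genes", call. = FALSE)
    }
  }
  structure(
    list(
      logfc = logfc,
      pvalue = pvalue,
      deleted_genes = deleted_genes[rownames(logfc)],
      wt_profiles = wt_profiles,
      unmeasured_deletions = unmeasured
    ),
    class = "glucose_compendium"
  )
}

#' @export
print.glucose_compendium <- function(x, ...) {
  cat("<glucose_compendium>\n")
  cat("  mutants: ", nrow(x$logfc), "\n", sep = "")
  cat("  genes:   ", ncol(x$logfc), "\n", sep = "")
  n_double <- sum(lengths(x$deleted_genes) > 1)
  if (n_double > 0) cat("  double mutants: ", n_double, "\n", sep = "")
  if (!is.null(x$wt_profiles)) {
    cat("  WT replicate profiles: ", nrow(x$wt_profiles), "\n", sep = "")
  }
  if (length(x$unmeasured_deletions) > 0) {
    cat("  unmeasured deleted genes: ",
        paste(x$unmeasured_deletions, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.glucose_compendium <- function(x) dim(x$logfc)

mutant_ids <- function(compendium) rownames(compendium$logfc)
gene_ids <- function(compendium) colnames(compendium$logfc)

#' Tidy an expression compendium into long format
#'
#' @param x A `glucose_compendium`.
#' @param ... Unused.
#' @return A tibble with columns `mutant`, `gene`, `logfc`, `pvalue`.
#' @export
tidy.glucose_compendium <- function(x, ...) {
  tibble::tibble(
    mutant = rep(rownames(x$logfc), times = ncol(x$logfc)),
    gene = rep(colnames(x$logfc), each = nrow(x$logfc)),
    logfc = as.vector(x$logfc),
    pvalue = as.vector(x$pvalue)
  )
}

#' Read an expression compendium from TSV matrices
#'
#' Matrices are stored one per file as UTF-8 tab-separated text with a header
#' row of mutant ids and gene ids in the first column (named `gene`); `NA`
#' marks missing values. The deleted-gene map is a two-column TSV
#' (`mutant`, `gene`; one row per deleted gene).
#'
#' @param logfc_path Path to the log2 fold-change matrix.
#' @param pvalue_path Path to the p-value matrix.
#' @param deleted_map_path Path to the two-column deleted-gene map.
#' @param wt_path Optional path to a wildtype replicate-profile matrix
#'   (replicate ids in the header-less first column).
#' @param exclude_genes Optional character vector (or path to a one-column
#'   file) of gene ids to drop before analysis, e.g. transposable elements
#'   and mitochondrial genes.
#' @return A `glucose_compendium`.
#' @export
read_compendium <- function(logfc_path, pvalue_path, deleted_map_path,
                            wt_path = NULL, exclude_genes = NULL) {
  logfc <- read_matrix_tsv(logfc_path, what = "logfc")
  pvalue <- read_matrix_tsv(pvalue_path, what = "pvalue")
  if (!setequal(rownames(logfc), rownames(pvalue)) ||
      !setequal(colnames(logfc), colnames(pvalue))) {
    stop("logfc and pvalue files disagree on mutant/gene labels", call. = FALSE)
  }
  # label-driven alignment: permuted row/column order is fine
  pvalue <- pvalue[rownames(logfc), colnames(logfc), drop = FALSE]
  dmap <- readr::read_tsv(deleted_map_path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  if (!all(c("mutant", "gene") %in% names(dmap))) {
    stop("deleted-gene map needs columns 'mutant' and 'gene'", call. = FALSE)
  }
  deleted <- split(dmap$gene, dmap$mutant)
  wt <- NULL
  if (!is.null(wt_path)) {
    wt <- read_matrix_tsv(wt_path, what = "wt")
    wt <- wt[, colnames(logfc), drop = FALSE]
  }
  if (!is.null(exclude_genes)) {
    if (length(exclude_genes) == 1 && file.exists(exclude_genes)) {
      exclude_genes <- readr::read_lines(exclude_genes, progress = FALSE)
    }
    keep <- setdiff(colnames(logfc), exclude_genes)
    logfc <- logfc[, keep, drop = FALSE]
    pvalue <- pvalue[, keep, drop = FALSE]
    if (!is.null(wt)) wt <- wt[, keep, drop = FALSE]
  }
  new_compendium(logfc, pvalue, deleted, wt)
}

#' Write an expression compendium to TSV matrices
#'
#' @param compendium A `glucose_compendium`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named character vector of the files written.
#' @export
write_compendium <- function(compendium, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    logfc = file.path(dir, "logfc.tsv"),
    pvalue = file.path(dir, "pvalue.tsv"),
    deleted = file.path(dir, "deleted_genes.tsv")
  )
  write_matrix_tsv(compendium$logfc, paths[["logfc"]])
  write_matrix_tsv(compendium$pvalue, paths[["pvalue"]])
  dmap <- tibble::tibble(
    mutant = rep(names(compendium$deleted_genes),
                 lengths(compendium$deleted_genes)),
    gene = unlist(compendium$deleted_genes, use.names = FALSE)
  )
  readr::write_tsv(dmap, paths[["deleted"]], progress = FALSE)
  if (!is.null(compendium$wt_profiles)) {
    paths <- c(paths, wt = file.path(dir, "wt_profiles.tsv"))
    write_matrix_tsv(compendium$wt_profiles, paths[["wt"]])
  }
  invisible(paths)
}

read_matrix_tsv <- function(path, what = "matrix") {
  df <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  if (names(df)[1] != "gene") {
    stop(what, " file must have 'gene' as its first column: ", path,
         call. = FALSE)
  }
  bad <- names(df)[-1][!vapply(df[-1], is.numeric, logical(1))]
  if (length(bad) > 0) {
    stop(what, " file has non-numeric column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$gene)) {
    stop(what, " file has duplicate gene id(s): ",
         paste(unique(df$gene[duplicated(df$gene)]), collapse = ", "),
         call. = FALSE)
  }
  m <- t(as.matrix(df[-1]))  # stored genes x mutants; used mutants x genes
  colnames(m) <- df$gene
  m
}

write_matrix_tsv <- function(m, path) {
  df <- tibble::as_tibble(t(m), rownames = "gene")
  readr::write_tsv(df, path, progress = FALSE)
}
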