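#' Epistasis analysis of a double-mutant expression profile
#'
#' Compares a double mutant with its two single-mutant parents over the
#' genes differentially expressed in any of the three profiles (the deleted
#' genes themselves are excluded). The parent whose profile the double
#' resembles most — higher cosine similarity, by at least `margin_min`, and
#' positively — is called dominant, placing its gene downstream of the
#' other parent's. Residual genes are DE in the double with the
#' non-dominant parent's direction while the dominant parent does not show
#' them (or shows the opposite), capturing compact programs that escape the
#' epistasis.
#'
#' @param compendium A `glucose_compendium` containing all three profiles.
#' @param double_id Double-mutant id.
#' @param parent_a,parent_b Single-mutant parent ids.
#' @param margin_min Minimum similarity difference to declare dominance
#'   (default 0.1).
#' @param p_threshold,fc_threshold DE thresholds defining the gene universe
#'   (defaults 0.01 and 1.7).
#' @param gene_universe `"de_any"` restricts the comparison to genes DE in
#'   any of the three profiles; `"all"` uses every measured gene.
#' @return An object of class `epistasis_verdict`: ids, per-parent
#'   similarity, `dominant` (parent id or `"inconclusive"`), `margin`,
#'   `residual_genes`, and the gene universe used.
#' @export
assess_epistasis <- function(compendium, double_id, parent_a, parent_b,
                             margin_min = 0.1, p_threshold = 0.01,
                             fc_threshold = 1.7,
                             gene_universe = c("de_any", "all")) {
  gene_universe <- match.arg(gene_universe)
  ids <- c(double_id, parent_a, parent_b)
  missing <- setdiff(ids, mutant_ids(compendium))
  if (length(missing) > 0) {
    stop("profile(s) missing from compendium: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  deleted <- unique(unlist(compendium$deleted_genes[ids]))
  calls <- compendium$pvalue[ids, , drop = FALSE] < p_threshold &
    abs(compendium$logfc[ids, , drop = FALSE]) > log2(fc_threshold)
  if (gene_universe == "de_any") {
    genes <- colnames(calls)[colSums(calls) > 0]
  } else {
    genes <- colnames(compendium$logfc)
  }
  genes <- setdiff(genes, deleted)

  verdict <- function(dominant, margin, sims) {
    structure(
      list(double_id = double_id, parent_ids = c(parent_a, parent_b),
           similarity_to_parent = sims, dominant = dominant,
           margin = margin, residual_genes = character(),
           gene_universe = gene_universe, n_genes = length(genes),
           margin_min = margin_min),
      class = "epistasis_verdict"
    )
  }
  if (length(genes) == 0) {
    return(verdict("inconclusive", NA_real_,
                   setNames(c(NA_real_, NA_real_), c(parent_a, parent_b))))
  }

  prof <- function(m) compendium$logfc[m, genes]
  sims <- setNames(
    c(cosine_similarity(prof(double_id), prof(parent_a)),
      cosine_similarity(prof(double_id), prof(parent_b))),
    c(parent_a, parent_b)
  )
  margin <- abs(sims[[1]] - sims[[2]])
  winner <- names(sims)[which.max(sims)]
  dominant <- if (margin >= margin_min && sims[[winner]] > 0) winner else
    "inconclusive"

  out <- verdict(dominant, margin, sims)
  if (dominant != "inconclusive") {
    loser <- setdiff(c(parent_a, parent_b), dominant)
    de_double <- calls[double_id, genes]
    lfc_d <- compendium$logfc[double_id, genes]
    lfc_dom <- compendium$logfc[dominant, genes]
    lfc_los <- compendium$logfc[loser, genes]
    de_dom <- calls[dominant, genes]
    de_los <- calls[loser, genes]
    residual <- de_double & de_los & sign(lfc_d) == sign(lfc_los) &
      (!de_dom | sign(lfc_dom) != sign(lfc_d))
    out$residual_genes <- genes[residual]
  }
  out
}

#' @export
print.epistasis_verdict <- function(x, ...) {
  cat("<epistasis_verdict> ", x$double_id, "\n", sep = "")
  for (p in x$parent_ids) {
    cat("  similarity to ", p, ": ",
        round(x$similarity_to_parent[[p]], 3), "\n", sep = "")
  }
  cat("  dominant: ", x$dominant, " (margin ", round(x$margin, 3), ")\n",
      sep = "")
  cat("  residual genes: ", length(x$residual_genes), "\n", sep = "")
  invisible(x)
}

#' @rdname assess_epistasis
#' @param x An `epistasis_verdict`.
#' @param ... Unused.
#' @return `tidy()`: a one-row tibble of the verdict (residual genes as a
#'   list-column).
#' @export
tidy.epistasis_verdict <- function(x, ...) {
  tibble::tibble(
    double_id = x$double_id,
    parent_a = x$parent_ids[1], parent_b = x$parent_ids[2],
    similarity_a = unname(x$similarity_to_parent[1]),
    similarity_b = unname(x$similarity_to_parent[2]),
    dominant = x$dominant, margin = x$margin,
    n_residual = length(x$residual_genes),
    residual_genes = list(x$residual_genes)
  )
}

#' Functional enrichment of epistasis residual genes
#'
#' Delegates to [enrich()] on the verdict's residual gene set.
#'
#' @param verdict An [assess_epistasis()] result.
#' @param annotations Annotation tibble (see [enrich()]).
#' @param background_genes Background gene universe.
#' @param ... Passed to [enrich()].
#' @return An enrichment tibble; empty when there are no residual genes.
#' @export
residual_enrichment <- function(verdict, annotations,
                                background_genes = NULL, ...) {
  if (length(verdict$residual_genes) == 0) {
    return(empty_enrichment_table())
  }
  enrich(verdict$residual_genes, annotations,
         background_genes = background_genes, ...)
}
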