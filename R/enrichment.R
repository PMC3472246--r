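#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(M, K, n)`: drawing `n` genes without
#' replacement from a background of `M` of which `K` belong to the term.
#'
#' @param k Observed overlap.
#' @param K Term size within the background.
#' @param n Query size.
#' @param M Background size.
#' @return Probability in (0, 1].
#' @export
hypergeom_upper_tail <- function(k, K, n, M) {
  if (any(k < 0 | K < 0 | n < 0 | M < 0) || any(K > M) || any(n > M) ||
      any(k > pmin(K, n))) {
    stop("inconsistent hypergeometric counts", call. = FALSE)
  }
  phyper(k - 1, K, M - K, n, lower.tail = FALSE)
}

empty_enrichment_table <- function() {
  tibble::tibble(term = character(), term_name = character(),
                 K = integer(), n = integer(), k = integer(), M = integer(),
                 p_raw = numeric(), p_bonferroni = numeric())
}

#' Hypergeometric over-representation test with Bonferroni correction
#'
#' Tests each annotation term for over-representation in the query set
#' against a background population (the study used the 6,359 GO-annotated
#' yeast genes) and Bonferroni-corrects over the number of terms tested.
#'
#' @param query_genes Character vector of query gene ids; genes outside the
#'   background are dropped with a warning.
#' @param annotations Tibble/data frame with columns `gene`, `term` and
#'   optionally `term_name` (see [read_annotations()] / [read_gaf()]).
#' @param background_genes Background gene universe; defaults to all
#'   annotated genes.
#' @param background_size Optional fixed background count `M` overriding
#'   `length(background_genes)` (e.g. the study's 6,359).
#' @param min_term_size Drop terms with fewer background genes than this
#'   (default 1, i.e. no minimum).
#' @return A tibble with one row per term tested: `term`, `term_name`, `K`,
#'   `n`, `k`, `M`, `p_raw`, `p_bonferroni`, sorted by `p_raw` (ties by
#'   term id).
#' @export
enrich <- function(query_genes, annotations, background_genes = NULL,
                   background_size = NULL, min_term_size = 1) {
  if (length(query_genes) == 0 || nrow(annotations) == 0) {
    return(empty_enrichment_table())
  }
  if (is.null(background_genes)) {
    background_genes <- unique(annotations$gene)
  }
  query_genes <- unique(query_genes)
  outside <- setdiff(query_genes, background_genes)
  if (length(outside) > 0) {
    warning(length(outside), " query gene(s) outside the background dropped",
            call. = FALSE)
    query_genes <- setdiff(query_genes, outside)
  }
  if (length(query_genes) == 0) return(empty_enrichment_table())

  ann <- annotations[annotations$gene %in% background_genes, , drop = FALSE]
  ann <- dplyr::distinct(tibble::as_tibble(ann[, intersect(
    c("gene", "term", "term_name"), names(ann))]))
  if (nrow(ann) == 0) return(empty_enrichment_table())

  M <- background_size %||% length(unique(background_genes))
  n <- length(query_genes)
  by_term <- dplyr::summarise(
    dplyr::group_by(ann, .data$term),
    term_name = if ("term_name" %in% names(ann))
      dplyr::first(.data$term_name) else NA_character_,
    K = dplyr::n_distinct(.data$gene),
    k = sum(unique(.data$gene) %in% query_genes),
    .groups = "drop"
  )
  by_term <- dplyr::filter(by_term, .data$K >= min_term_size)
  if (nrow(by_term) == 0) return(empty_enrichment_table())
  out <- dplyr::mutate(
    by_term,
    n = n, M = M,
    p_raw = hypergeom_upper_tail(.data$k, .data$K, n, M),
    p_bonferroni = pmin(1, .data$p_raw * dplyr::n())
  )
  out <- out[, c("term", "term_name", "K", "n", "k", "M", "p_raw",
                 "p_bonferroni")]
  dplyr::arrange(out, .data$p_raw, .data$term)
}

#' Read a two-column gene/term annotation TSV
#'
#' Expected columns: `gene`, `term`, optional `term_name`.
#'
#' @param path Path to the TSV file.
#' @return A tibble usable by [enrich()].
#' @export
read_annotations <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (!all(c("gene", "term") %in% names(df))) {
    stop("annotation file needs columns 'gene' and 'term'", call. = FALSE)
  }
  df
}

#' Read GO annotations from a GAF 2.x file
#'
#' Extracts gene symbol (column 3), GO id (column 5) and aspect
#' (column 9); comment lines starting with `!` are skipped. No
#' ontology-graph propagation is performed — annotations are used flat, as
#' obtained.
#'
#' @param path Path to the GAF file (uncompressed).
#' @param aspect Optional aspect filter, e.g. `"P"` for biological process.
#' @return A tibble with columns `gene`, `term`, `aspect`.
#' @export
read_gaf <- function(path, aspect = NULL) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 9
  if (any(short)) {
    stop("malformed GAF record(s) with fewer than 9 columns", call. = FALSE)
  }
  out <- tibble::tibble(
    gene = vapply(fields, `[`, "", 3),
    term = vapply(fields, `[`, "", 5),
    aspect = vapply(fields, `[`, "", 9)
  )
  if (!is.null(aspect)) out <- out[out$aspect %in% aspect, ]
  dplyr::distinct(out)
}
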