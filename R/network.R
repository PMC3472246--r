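#' Cosine similarity between two expression profiles
#'
#' `dot(a, b) / (|a| |b|)` over the retained genes; the centered variant is
#' the ordinary Pearson-style correlation.
#'
#' @param a,b Numeric vectors (named by gene when `exclude_genes` is used).
#' @param exclude_genes Genes dropped from both vectors before the
#'   computation (typically the deleted genes of both mutants, whose
#'   planted values would otherwise dominate).
#' @param center Center both vectors first (Pearson-style).
#' @return Similarity in \[-1, 1\].
#' @export
cosine_similarity <- function(a, b, exclude_genes = NULL, center = FALSE) {
  if (length(a) != length(b)) stop("profiles differ in length", call. = FALSE)
  if (!is.null(exclude_genes) && length(exclude_genes) > 0) {
    if (is.null(names(a)) || is.null(names(b))) {
      stop("gene exclusion needs named profiles", call. = FALSE)
    }
    keep <- !names(a) %in% exclude_genes
    a <- a[keep]; b <- b[keep]
  }
  if (center) {
    a <- a - mean(a); b <- b - mean(b)
  }
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop("similarity undefined for a zero-norm profile", call. = FALSE)
  }
  sum(a * b) / (na * nb)
}

#' Pairwise profile-similarity matrix
#'
#' @param compendium A `glucose_compendium`.
#' @param mutants Mutants to include (default all).
#' @param method `"cosine"` or centered `"pearson"`.
#' @param exclude_deleted Drop, per pair, the deleted genes of both mutants
#'   before computing the similarity (default TRUE).
#' @return Symmetric mutants x mutants matrix with unit diagonal.
#' @export
profile_similarity_matrix <- function(compendium,
                                      mutants = mutant_ids(compendium),
                                      method = c("cosine", "pearson"),
                                      exclude_deleted = TRUE) {
  method <- match.arg(method)
  x <- compendium$logfc[mutants, , drop = FALSE]
  n <- length(mutants)
  sim <- diag(1, n)
  dimnames(sim) <- list(mutants, mutants)
  if (!exclude_deleted) {
    y <- if (method == "pearson") x - rowMeans(x) else x
    nrm <- sqrt(rowSums(y^2))
    if (any(nrm == 0)) stop("zero-norm profile", call. = FALSE)
    sim <- tcrossprod(y / nrm)
    diag(sim) <- 1
    dimnames(sim) <- list(mutants, mutants)
    return(sim)
  }
  del <- compendium$deleted_genes
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- cosine_similarity(
        x[i, ], x[j, ],
        exclude_genes = c(del[[mutants[i]]], del[[mutants[j]]]),
        center = method == "pearson"
      )
      sim[i, j] <- s; sim[j, i] <- s
    }
  }
  sim
}

#' Deletion effect of one mutant on another's transcript
#'
#' The change of transcription of `y`'s deleted gene upon the deletion of
#' `x`: the fold-change is reported when it is significant (`p <
#' p_threshold`) and its linear magnitude exceeds `fc_threshold`; otherwise
#' the effect is 0. The fold-change floor is applied to the magnitude, so
#' the effect keeps its sign.
#'
#' @param compendium A `glucose_compendium`.
#' @param x Mutant whose deletion is the putative cause.
#' @param y Mutant whose deleted gene is the read-out transcript.
#' @param p_threshold,fc_threshold Significance cutoffs (defaults 0.01 and
#'   1.5).
#' @return Signed log2 effect, 0 when not significant, or `NA` when `y`'s
#'   gene is not measured.
#' @export
deletion_effect <- function(compendium, x, y, p_threshold = 0.01,
                            fc_threshold = 1.5) {
  gene <- compendium$deleted_genes[[y]]
  if (length(gene) != 1) {
    stop("deletion_effect requires a single-deletion target mutant",
         call. = FALSE)
  }
  if (!gene %in% colnames(compendium$logfc)) {
    message("deleted gene ", gene, " of ", y, " is unmeasured; pair (",
            x, ", ", y, ") skipped")
    return(NA_real_)
  }
  lfc <- compendium$logfc[x, gene]
  p <- compendium$pvalue[x, gene]
  if (p < p_threshold && abs(lfc) > log2(fc_threshold)) lfc else 0
}

#' Permutation-calibrated correlation significance thresholds
#'
#' Shuffles the gene order within every profile independently, computes all
#' pairwise similarities, repeats `n_permutations` times, pools the
#' background, and returns its lower and upper quantiles. On the study's
#' data the corresponding 0.001/0.999 thresholds were 0 and 0.18; here they
#' are always recomputed from the data at hand.
#'
#' @param compendium A `glucose_compendium`.
#' @param mutants Profiles entering the calibration (default all).
#' @param n_permutations Permutation rounds (default 1,000).
#' @param quantiles Lower and upper background quantiles (default
#'   `c(0.001, 0.999)`).
#' @param method Similarity measure, as in [profile_similarity_matrix()].
#' @param seed Integer seed.
#' @param keep_background Keep the pooled background sample on the result.
#' @return An object of class `randomization_thresholds`: `lower`, `upper`,
#'   `n_permutations`, `quantiles`, `method`, `seed`, and (optionally)
#'   `background`.
#' @export
calibrate_thresholds <- function(compendium,
                                 mutants = mutant_ids(compendium),
                                 n_permutations = 1000,
                                 quantiles = c(0.001, 0.999),
                                 method = c("cosine", "pearson"),
                                 seed = 1L, keep_background = TRUE) {
  method <- match.arg(method)
  if (length(mutants) < 2) stop("need >= 2 profiles", call. = FALSE)
  x <- compendium$logfc[mutants, , drop = FALSE]
  n <- nrow(x); g <- ncol(x)
  upper_tri <- upper.tri(matrix(0, n, n))
  background <- with_seed(seed, {
    out <- vector("list", n_permutations)
    for (r in seq_len(n_permutations)) {
      shuf <- x
      for (i in seq_len(n)) shuf[i, ] <- shuf[i, sample.int(g)]
      if (method == "pearson") shuf <- shuf - rowMeans(shuf)
      nrm <- sqrt(rowSums(shuf^2))
      sim <- tcrossprod(shuf / nrm)
      out[[r]] <- sim[upper_tri]
    }
    unlist(out, use.names = FALSE)
  })
  qs <- unname(quantile(background, quantiles))
  structure(
    list(lower = qs[1], upper = qs[2], n_permutations = n_permutations,
         quantiles = quantiles, method = method, seed = seed,
         background = if (keep_background) background else NULL),
    class = "randomization_thresholds"
  )
}

#' @export
print.randomization_thresholds <- function(x, ...) {
  cat("<randomization_thresholds> lower = ", signif(x$lower, 4),
      ", upper = ", signif(x$upper, 4), " (", x$n_permutations,
      " permutations, ", x$method, ")\n", sep = "")
  invisible(x)
}

#' Manually specified correlation thresholds
#'
#' @param lower,upper Significance bounds (e.g. the study's 0 and 0.18).
#' @return A `randomization_thresholds` object without a background sample.
#' @export
fixed_thresholds <- function(lower, upper) {
  stopifnot(lower <= upper)
  structure(
    list(lower = lower, upper = upper, n_permutations = 0L,
         quantiles = NULL, method = "fixed", seed = NULL, background = NULL),
    class = "randomization_thresholds"
  )
}

#' Apply significance thresholds to a raw correlation
#'
#' Returns the correlation when it falls outside the insignificance band
#' (`c < lower` or `c > upper`), else 0.
#'
#' @param c_raw Raw similarity value(s); vectorized.
#' @param thresholds A `randomization_thresholds` object.
#' @return Thresholded value(s).
#' @export
threshold_correlation <- function(c_raw, thresholds) {
  ifelse(c_raw < thresholds$lower | c_raw > thresholds$upper, c_raw, 0)
}

#' Type the relationship between two pathway members
#'
#' Given the deletion effect `d` of `x` on `y`'s transcript and the
#' significant profile correlation `c` between the two deletion profiles,
#' the ordered pair falls in one of four classes:
#' `L1` (`d < 0`, `c > 0`) and `L2` (`d > 0`, `c < 0`) are sequential
#' relationships (consistent with `y` acting downstream of `x`);
#' `F1` (`d > 0`, `c > 0`) and `F2` (`d < 0`, `c < 0`) are non-sequential
#' (feedback-like). When either quantity is 0 there is no edge.
#'
#' @param d Thresholded deletion effect ([deletion_effect()]).
#' @param c Thresholded correlation ([threshold_correlation()]).
#' @return `"L1"`, `"L2"`, `"F1"`, `"F2"`, or `NA_character_` for no edge.
#' @export
classify_edge <- function(d, c) {
  if (is.na(d) || is.na(c) || d == 0 || c == 0) return(NA_character_)
  if (d < 0 && c > 0) "L1"
  else if (d > 0 && c < 0) "L2"
  else if (d > 0 && c > 0) "F1"
  else "F2"
}

#' Reconstruct the hierarchical transcription network
#'
#' Evaluates every ordered pair of responsive mutants: the deletion effect
#' `d` ([deletion_effect()]), the thresholded profile correlation `c`
#' ([threshold_correlation()] over [profile_similarity_matrix()]), and the
#' edge type ([classify_edge()]). Pairs with `d = 0` or `c = 0` contribute
#' no edge. An edge `x -> y` means `x`'s deletion changes `y`'s transcript.
#'
#' @param compendium A `glucose_compendium`.
#' @param responsive_mutants Vertices of the network.
#' @param thresholds A `randomization_thresholds` object (calibrate with
#'   [calibrate_thresholds()] or supply [fixed_thresholds()]).
#' @param p_threshold,fc_threshold Deletion-effect cutoffs (defaults 0.01,
#'   1.5).
#' @param method Similarity measure for `c`.
#' @param exclude_deleted Exclude each pair's deleted genes from the
#'   correlation (default TRUE).
#' @return An object of class `hierarchy_network`: `edges` tibble
#'   (`x`, `y`, `type`, `d`, `c`, `category`), `vertices` tibble with
#'   per-category in/out degrees, and `params`.
#' @export
build_network <- function(compendium, responsive_mutants, thresholds,
                          p_threshold = 0.01, fc_threshold = 1.5,
                          method = c("cosine", "pearson"),
                          exclude_deleted = TRUE) {
  method <- match.arg(method)
  v <- responsive_mutants
  sim <- profile_similarity_matrix(compendium, v, method = method,
                                   exclude_deleted = exclude_deleted)
  rows <- list()
  for (x in v) {
    for (y in setdiff(v, x)) {
      d <- deletion_effect(compendium, x, y, p_threshold, fc_threshold)
      if (is.na(d) || d == 0) next
      c_val <- threshold_correlation(sim[x, y], thresholds)
      type <- classify_edge(d, c_val)
      if (is.na(type)) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        x = x, y = y, type = type, d = d, c = c_val,
        category = if (type %in% c("L1", "L2")) "sequential" else "non_sequential"
      )
    }
  }
  edges <- if (length(rows) > 0) dplyr::bind_rows(rows) else {
    tibble::tibble(x = character(), y = character(), type = character(),
                   d = numeric(), c = numeric(), category = character())
  }
  count_deg <- function(ids, cat) {
    e <- edges[edges$category == cat, ]
    list(inn = as.vector(table(factor(e$y, levels = v))),
         out = as.vector(table(factor(e$x, levels = v))))
  }
  seq_deg <- count_deg(v, "sequential")
  ns_deg <- count_deg(v, "non_sequential")
  vertices <- tibble::tibble(
    mutant = v,
    in_sequential = seq_deg$inn, out_sequential = seq_deg$out,
    in_nonsequential = ns_deg$inn, out_nonsequential = ns_deg$out
  )
  structure(
    list(edges = edges, vertices = vertices,
         params = list(p_threshold = p_threshold,
                       fc_threshold = fc_threshold, method = method,
                       exclude_deleted = exclude_deleted,
                       thresholds = thresholds)),
    class = "hierarchy_network"
  )
}

#' @export
print.hierarchy_network <- function(x, ...) {
  cat("<hierarchy_network> ", nrow(x$vertices), " vertices, ",
      nrow(x$edges), " edges\n", sep = "")
  if (nrow(x$edges) > 0) print(table(x$edges$type))
  invisible(x)
}

#' @rdname build_network
#' @param x A `hierarchy_network`.
#' @param ... Unused.
#' @return `tidy()`: the edge tibble; `glance()`: a one-row summary of
#'   vertex/edge counts by type.
#' @export
tidy.hierarchy_network <- function(x, ...) x$edges

#' @rdname build_network
#' @export
glance.hierarchy_network <- function(x, ...) {
  tibble::tibble(
    n_vertices = nrow(x$vertices),
    n_edges = nrow(x$edges),
    n_L1 = sum(x$edges$type == "L1"), n_L2 = sum(x$edges$type == "L2"),
    n_F1 = sum(x$edges$type == "F1"), n_F2 = sum(x$edges$type == "F2"),
    lower = x$params$thresholds$lower, upper = x$params$thresholds$upper
  )
}

#' Rank vertices from most to least transcriptionally downstream
#'
#' Orders vertices by incoming minus outgoing sequential (L1/L2) edges,
#' descending, so components that many deletions act upon — like the
#' storage-carbohydrate genes — come first. Ties break lexicographically.
#'
#' @param network A `hierarchy_network`.
#' @return Tibble (`mutant`, `in_sequential`, `out_sequential`, `score`,
#'   `rank`), most downstream first.
#' @export
downstream_ranking <- function(network) {
  v <- network$vertices
  out <- tibble::tibble(
    mutant = v$mutant,
    in_sequential = v$in_sequential,
    out_sequential = v$out_sequential,
    score = v$in_sequential - v$out_sequential
  )
  out <- out[order(-out$score, out$mutant), ]
  out$rank <- seq_len(nrow(out))
  out
}

#' Export a network as an edge-list TSV (and optionally DOT)
#'
#' @param network A `hierarchy_network`.
#' @param path Output TSV path.
#' @param dot_path Optional Graphviz DOT output path.
#' @return Invisibly, `path`.
#' @export
write_network <- function(network, path, dot_path = NULL) {
  readr::write_tsv(network$edges, path, progress = FALSE)
  if (!is.null(dot_path)) {
    lines <- c("digraph hierarchy {",
               sprintf("  \"%s\" -> \"%s\" [label=\"%s\"];",
                       network$edges$x, network$edges$y, network$edges$type),
               "}")
    writeLines(lines, dot_path)
  }
  invisible(path)
}
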