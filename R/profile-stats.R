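#' Summarize replicate profiles against a wildtype reference pool
#'
#' Collapses replicate-level log2 ratios to one average profile per mutant
#' and attaches a per-gene p-value from a variance-moderated two-sided
#' t-test of the mutant mean against the wildtype pool: the per-gene pool
#' variance is shrunk toward the median pool variance
#' (`shrink * s2_g + (1 - shrink) * median(s2)`), and the statistic
#' `t = (mean_mutant - mean_pool) / sqrt(s2_tilde * (1/n_rep + 1/n_pool))`
#' is referred to a t distribution with `n_pool - 1` degrees of freedom.
#' Moderation borrows strength across genes in the spirit of
#' empirical-Bayes variance shrinkage, matching the reference-pool design.
#'
#' @param replicate_matrix Replicates x genes matrix of log2 ratios.
#' @param wt_pool_matrix Wildtype pool profiles x genes matrix (>= 2 rows).
#' @param mutant_map Character vector, one mutant id per replicate row.
#' @param deleted_genes Named list mapping mutant ids to deleted gene ids.
#' @param wt_profiles Optional parallel wildtype replicate matrix stored on
#'   the result for threshold calibration.
#' @param shrink Weight in \[0, 1\] on the per-gene pool variance.
#' @return A [new_compendium()] object.
#' @export
summarize_replicates <- function(replicate_matrix, wt_pool_matrix,
                                 mutant_map, deleted_genes,
                                 wt_profiles = NULL, shrink = 0.5) {
  stopifnot(is.matrix(replicate_matrix), is.matrix(wt_pool_matrix),
            length(mutant_map) == nrow(replicate_matrix))
  if (nrow(wt_pool_matrix) < 2) {
    stop("wildtype pool needs at least 2 profiles", call. = FALSE)
  }
  if (!identical(colnames(replicate_matrix), colnames(wt_pool_matrix))) {
    stop("replicate and pool gene columns must match", call. = FALSE)
  }
  n_rep <- table(mutant_map)
  if (any(n_rep < 2)) {
    stop("every mutant needs at least 2 replicates", call. = FALSE)
  }

  sums <- rowsum(replicate_matrix, group = mutant_map, reorder = FALSE)
  n_m <- as.vector(table(factor(mutant_map, levels = rownames(sums))))
  means <- sums / n_m
  n_pool <- nrow(wt_pool_matrix)
  wt_mean <- colMeans(wt_pool_matrix)
  logfc <- sweep(means, 2, wt_mean)

  # per-gene pool variance, shrunk toward the median across genes
  s2 <- colMeans(wt_pool_matrix^2) - wt_mean^2
  s2 <- s2 * n_pool / (n_pool - 1)
  s2 <- pmax(s2, 0)
  s2_med <- median(s2)
  s2_tilde <- shrink * s2 + (1 - shrink) * s2_med
  if (any(s2_tilde == 0)) {
    floor_val <- if (any(s2_tilde > 0)) min(s2_tilde[s2_tilde > 0]) else 1e-12
    warning("zero wildtype variance for ", sum(s2_tilde == 0),
            " gene(s); variance floored", call. = FALSE)
    s2_tilde[s2_tilde == 0] <- floor_val
  }

  se <- sqrt(outer(1 / n_m + 1 / n_pool, s2_tilde))
  tstat <- logfc / se
  pvalue <- 2 * pt(abs(tstat), df = n_pool - 1, lower.tail = FALSE)
  pvalue <- pmax(pvalue, .Machine$double.xmin)
  dimnames(pvalue) <- dimnames(logfc)

  new_compendium(logfc, pvalue, deleted_genes, wt_profiles)
}

#' Call differential expression with joint p-value and fold-change cutoffs
#'
#' A gene is called in a mutant when `pvalue < p_threshold` and the linear
#' fold-change magnitude exceeds `fc_threshold`, i.e.
#' `|logfc| > log2(fc_threshold)`. Up- and downregulation are treated
#' symmetrically.
#'
#' @param compendium A `glucose_compendium`.
#' @param p_threshold P-value cutoff (default 0.01).
#' @param fc_threshold Linear fold-change cutoff (default 1.7).
#' @return An object of class `de_calls`: logical mutants x genes `calls`
#'   matrix, per-mutant `de_counts`, and the thresholds used.
#' @export
call_de <- function(compendium, p_threshold = 0.01, fc_threshold = 1.7) {
  stopifnot(p_threshold > 0, fc_threshold >= 1)
  calls <- compendium$pvalue < p_threshold &
    abs(compendium$logfc) > log2(fc_threshold)
  structure(
    list(
      calls = calls,
      de_counts = setNames(as.integer(rowSums(calls)), rownames(calls)),
      p_threshold = p_threshold,
      fc_threshold = fc_threshold
    ),
    class = "de_calls"
  )
}

#' @export
print.de_calls <- function(x, ...) {
  cat("<de_calls> p < ", x$p_threshold, ", FC > ", x$fc_threshold, "\n",
      sep = "")
  cat("  mutants: ", nrow(x$calls), "; DE counts ",
      min(x$de_counts), "-", max(x$de_counts), "\n", sep = "")
  invisible(x)
}

#' @rdname call_de
#' @param x A `de_calls` object.
#' @param ... Unused.
#' @return `tidy()`: a tibble with one row per mutant (`mutant`,
#'   `de_count`).
#' @export
tidy.de_calls <- function(x, ...) {
  tibble::tibble(mutant = rownames(x$calls), de_count = unname(x$de_counts))
}

#' Per-profile differential-expression counts for wildtype replicates
#'
#' Applies the same moderated test and thresholds used for mutants to each
#' single wildtype profile grown in parallel, yielding the counts that
#' calibrate the WT-likeness threshold.
#'
#' @param wt_profiles Wildtype profiles x genes matrix of log2 ratios.
#' @param wt_pool_matrix Reference pool matrix.
#' @param p_threshold,fc_threshold DE thresholds, as in [call_de()].
#' @param shrink Variance-shrinkage weight, as in [summarize_replicates()].
#' @return Integer vector of per-profile DE counts.
#' @export
wt_de_counts <- function(wt_profiles, wt_pool_matrix, p_threshold = 0.01,
                         fc_threshold = 1.7, shrink = 0.5) {
  stopifnot(identical(colnames(wt_profiles), colnames(wt_pool_matrix)))
  ids <- rownames(wt_profiles) %||% sprintf("wt%03d", seq_len(nrow(wt_profiles)))
  n_pool <- nrow(wt_pool_matrix)
  wt_mean <- colMeans(wt_pool_matrix)
  s2 <- pmax(colMeans(wt_pool_matrix^2) - wt_mean^2, 0) * n_pool / (n_pool - 1)
  s2_tilde <- shrink * s2 + (1 - shrink) * median(s2)
  logfc <- sweep(wt_profiles, 2, wt_mean)
  se <- sqrt(s2_tilde * (1 + 1 / n_pool))
  pvalue <- 2 * pt(abs(sweep(logfc, 2, se, "/")), df = n_pool - 1,
                   lower.tail = FALSE)
  calls <- pvalue < p_threshold & abs(logfc) > log2(fc_threshold)
  setNames(rowSums(calls), ids)
}

#' Calibrate the WT-likeness threshold from parallel wildtype counts
#'
#' Returns the smallest DE count no wildtype profile reaches:
#' `max(wt_call_counts) + 1`. With the study's thresholds no parallel
#' wildtype showed twelve or more changing genes, making 12 the calibrated
#' responsiveness cutoff.
#'
#' @param wt_call_counts Non-empty integer vector of per-wildtype DE counts.
#' @return Integer threshold.
#' @export
calibrate_wt_threshold <- function(wt_call_counts) {
  if (length(wt_call_counts) == 0) {
    stop("need at least one wildtype call count", call. = FALSE)
  }
  as.integer(max(wt_call_counts) + 1L)
}

#' Classify mutants as wildtype-like or transcriptionally responsive
#'
#' A mutant is responsive when its DE count reaches the calibrated
#' WT-likeness threshold (`de_count >= wt_count_threshold`).
#'
#' @param decalls A [call_de()] result.
#' @param wt_count_threshold Minimum DE count for responsiveness
#'   (default 12).
#' @return A tibble with columns `mutant`, `de_count`, `status`
#'   (`"like_wt"` or `"responsive"`).
#' @export
classify_wt_like <- function(decalls, wt_count_threshold = 12) {
  tibble::tibble(
    mutant = rownames(decalls$calls),
    de_count = unname(decalls$de_counts),
    status = unname(ifelse(decalls$de_counts >= wt_count_threshold,
                           "responsive", "like_wt"))
  )
}
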