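#' Partition responsive mutants into the two opposing glucose groups
#'
#' Performs agglomerative hierarchical clustering of the responsive mutants'
#' fold-change profiles, restricted to genes differentially expressed in at
#' least one responsive mutant, and cuts the tree into two clusters. The
#' distance is `1 - cosine similarity` by default (a centered, Pearson-style
#' variant is available); the linkage is configurable and averages by
#' default. One cluster mimics the wildtype response to high glucose and the
#' other the response to low glucose.
#'
#' Orientation: when `reference_up` is given, the cluster with the higher
#' mean fold-change over that gene set is labelled `low_glucose` (the set is
#' read as "up in the low-glucose state"). Without a reference the labelling
#' is arbitrary but stable: the cluster containing the first responsive
#' mutant in input order becomes `low_glucose`.
#'
#' @param compendium A `glucose_compendium`.
#' @param responsive_mutants Character vector of responsive mutant ids
#'   (>= 2).
#' @param decalls Optional [call_de()] result used to mask genes; computed
#'   with default thresholds when missing.
#' @param reference_up Optional gene set expected up in the low-glucose
#'   group, used to orient the labels.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @param method Similarity: `"cosine"` or centered `"pearson"`.
#' @return A tibble of class `group_assignment` with columns `mutant`,
#'   `group` (`high_glucose`/`low_glucose`/`like_wt`); attribute `source`
#'   is `"clustering"`.
#' @export
cluster_two_groups <- function(compendium, responsive_mutants,
                               decalls = NULL, reference_up = NULL,
                               linkage = "average",
                               method = c("cosine", "pearson")) {
  method <- match.arg(method)
  if (length(responsive_mutants) < 2) {
    stop("need at least 2 responsive mutants to cluster", call. = FALSE)
  }
  if (is.null(decalls)) decalls <- call_de(compendium)
  mask <- colSums(decalls$calls[responsive_mutants, , drop = FALSE]) > 0
  genes <- colnames(compendium$logfc)[mask]
  if (length(genes) < 2) {
    stop("fewer than 2 genes are DE in any responsive mutant", call. = FALSE)
  }
  x <- compendium$logfc[responsive_mutants, genes, drop = FALSE]
  if (method == "pearson") x <- x - rowMeans(x)
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm == 0)) stop("zero-norm profile; cannot cluster", call. = FALSE)
  sim <- tcrossprod(x / nrm)
  d <- as.dist(1 - sim)
  cl <- cutree(hclust(d, method = linkage), k = 2)

  if (!is.null(reference_up)) {
    ref <- intersect(reference_up, colnames(compendium$logfc))
    if (length(ref) == 0) stop("reference_up genes not found", call. = FALSE)
    mean_ref <- tapply(
      rowMeans(compendium$logfc[responsive_mutants, ref, drop = FALSE]),
      cl, mean
    )
    low_cluster <- as.integer(names(which.max(mean_ref)))
  } else {
    low_cluster <- cl[[1]]
  }
  labels <- ifelse(cl == low_cluster, "low_glucose", "high_glucose")

  all_mut <- mutant_ids(compendium)
  out <- tibble::tibble(
    mutant = all_mut,
    group = ifelse(all_mut %in% responsive_mutants,
                   labels[match(all_mut, responsive_mutants)], "like_wt")
  )
  attr(out, "source") <- "clustering"
  class(out) <- c("group_assignment", class(out))
  out
}

#' Mutants eligible for signature construction
#'
#' The signature procedure uses only responsive mutants with at least
#' `min_de_transcripts` significantly changing transcripts (30 in the
#' study, leaving 32 of the 45 responsive mutants).
#'
#' @param decalls A [call_de()] result.
#' @param groups A group assignment tibble (`mutant`, `group`).
#' @param min_de_transcripts Minimum DE count (default 30).
#' @return Tibble with columns `mutant`, `group`, `de_count`.
#' @export
eligible_mutants <- function(decalls, groups, min_de_transcripts = 30) {
  counts <- tidy.de_calls(decalls)
  out <- dplyr::inner_join(counts, groups, by = "mutant")
  dplyr::filter(out, .data$group %in% c("high_glucose", "low_glucose"),
                .data$de_count >= min_de_transcripts)[
    , c("mutant", "group", "de_count")]
}

#' Stratified train/test split of eligible mutants
#'
#' Splits mutants into a training set of `floor(train_fraction * n)` and a
#' test set of the rest, stratifying by group so both glucose groups are
#' represented on each side (per-group training counts follow largest
#' remainders).
#'
#' @param mutants Tibble with columns `mutant`, `group` (or a character
#'   vector, treated as one group).
#' @param train_fraction Fraction assigned to training (default 2/3).
#' @param seed Integer seed; the same seed reproduces the split.
#' @return List with tibbles `train` and `test`.
#' @export
split_train_test <- function(mutants, train_fraction = 2 / 3, seed = 1L) {
  if (is.character(mutants)) {
    mutants <- tibble::tibble(mutant = mutants, group = "all")
  }
  n <- nrow(mutants)
  if (n < 3) stop("need at least 3 mutants to split", call. = FALSE)
  n_train <- floor(train_fraction * n)

  grp <- split(seq_len(n), mutants$group)
  quota <- vapply(grp, function(idx) floor(train_fraction * length(idx)),
                  numeric(1))
  rem <- vapply(grp, function(idx) train_fraction * length(idx), numeric(1)) -
    quota
  short <- n_train - sum(quota)
  if (short > 0) {
    order_rem <- order(-rem, names(grp))
    bump <- order_rem[seq_len(short)]
    quota[bump] <- quota[bump] + 1
  }
  train_idx <- with_seed(seed, {
    sort(unlist(lapply(names(grp), function(g) {
      idx <- grp[[g]]
      if (quota[[g]] >= length(idx)) idx else sample(idx, quota[[g]])
    }), use.names = FALSE))
  })
  list(train = mutants[train_idx, ], test = mutants[-train_idx, ])
}

#' Minimum correctly classified mutants to reach an accuracy threshold
#'
#' With a 21-mutant training set and a 0.90 threshold this is 19.
#'
#' @param n_train Training-set size.
#' @param accuracy_threshold Required LOOCV accuracy.
#' @return Integer count.
#' @export
min_correct_for_threshold <- function(n_train, accuracy_threshold = 0.9) {
  as.integer(ceiling(accuracy_threshold * n_train - 1e-9))
}
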