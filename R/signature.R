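#' KNN signature-selection configuration
#'
#' @param K Neighbour count for the KNN classifier (odd; default 3).
#' @param accuracy_threshold Minimum LOOCV accuracy for a gene to be
#'   selected in a repeat (default 0.90).
#' @param min_de_transcripts Eligibility cutoff passed to
#'   [eligible_mutants()] (default 30).
#' @param train_fraction Training fraction per repeat (default 2/3).
#' @param n_repeats Number of resampling repeats (default 200).
#' @param seed Integer seed driving the split sequence.
#' @return A list of class `knn_config`.
#' @export
knn_config <- function(K = 3, accuracy_threshold = 0.9,
                       min_de_transcripts = 30, train_fraction = 2 / 3,
                       n_repeats = 200, seed = 1L) {
  if (K %% 2 != 1) stop("K must be odd", call. = FALSE)
  if (accuracy_threshold <= 0 || accuracy_threshold > 1) {
    stop("accuracy_threshold must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(K = as.integer(K), accuracy_threshold = accuracy_threshold,
         min_de_transcripts = as.integer(min_de_transcripts),
         train_fraction = train_fraction, n_repeats = as.integer(n_repeats),
         seed = as.integer(seed)),
    class = "knn_config"
  )
}

#' Leave-one-out KNN accuracy of a single gene
#'
#' Each training mutant is classified from its K nearest other training
#' mutants by absolute fold-change difference on this one gene (majority
#' vote; distance ties keep the earlier mutant in input order), and the
#' fraction classified correctly is returned.
#'
#' @param values Numeric vector of the gene's fold-changes, one per
#'   training mutant.
#' @param labels Group labels (two levels), same length.
#' @param K Neighbour count (odd).
#' @return Accuracy in \[0, 1\].
#' @export
gene_loocv_accuracy <- function(values, labels, K = 3) {
  stopifnot(length(values) == length(labels), K < length(values),
            K %% 2 == 1)
  codes <- as.integer(factor(labels)) - 1L
  if (max(codes) > 1) stop("more than two group labels", call. = FALSE)
  loocv_knn_accuracy(matrix(values, ncol = 1), codes, as.integer(K))[1]
}

knn_predict <- function(train_x, train_labels, test_x, K) {
  # multivariate KNN: Euclidean distance over the selected genes jointly
  apply(test_x, 1, function(v) {
    d <- sqrt(colSums((t(train_x) - v)^2))
    nn <- order(d)[seq_len(K)]
    votes <- table(train_labels[nn])
    names(votes)[which.max(votes)]
  })
}

#' Build the glucose gene signature by resampled KNN/LOOCV selection
#'
#' Repeats `n_repeats` times: split the eligible mutants into training and
#' test sets ([split_train_test()]), select every gene whose single-gene
#' LOOCV-KNN accuracy on the training set reaches the threshold
#' ([gene_loocv_accuracy()]), record the selected set and its size, and
#' classify the test mutants with a joint KNN over the selected genes
#' (Euclidean distance) to estimate predictive power. Genes are then ranked
#' by selection frequency and the top `N` kept, where `N` is the rounded
#' mean selected-set size over all repeats. Frequency ties at rank `N` are
#' broken by higher mean LOOCV accuracy, then by gene id. Each kept gene is
#' directed by the sign of its mean fold-change among low-glucose eligible
#' mutants (`up_in_low` / `down_in_low`).
#'
#' @param compendium A `glucose_compendium`.
#' @param eligible Tibble from [eligible_mutants()] (`mutant`, `group`),
#'   with both groups represented.
#' @param config A [knn_config()].
#' @return An object of class `glucose_signature` with elements `genes`
#'   (per-gene tibble: `gene`, `frequency`, `mean_accuracy`, `selected`,
#'   `direction`, `rank`), `repeats` (per-repeat tibble: `repeat_id`,
#'   `set_size`, `test_accuracy`), `N`, and `config`.
#' @export
build_signature <- function(compendium, eligible, config = knn_config()) {
  if (nrow(eligible) == 0) stop("no eligible mutants", call. = FALSE)
  groups <- unique(eligible$group)
  if (length(groups) != 2) {
    stop("both glucose groups must be represented", call. = FALSE)
  }
  x <- compendium$logfc[eligible$mutant, , drop = FALSE]
  genes <- colnames(x)
  n_genes <- length(genes)

  freq <- integer(n_genes)
  acc_sum <- numeric(n_genes)
  set_sizes <- integer(config$n_repeats)
  test_acc <- rep(NA_real_, config$n_repeats)

  split_seeds <- with_seed(config$seed, {
    sample.int(.Machine$integer.max, config$n_repeats)
  })
  for (r in seq_len(config$n_repeats)) {
    sp <- split_train_test(eligible, config$train_fraction, split_seeds[r])
    train <- sp$train; test <- sp$test
    if (min(table(train$group)) < config$K + 1) {
      warning("repeat ", r, ": a group has fewer than K+1 training members; ",
              "LOOCV is degenerate", call. = FALSE)
    }
    codes <- as.integer(factor(train$group, levels = groups)) - 1L
    acc <- loocv_knn_accuracy(x[train$mutant, , drop = FALSE], codes,
                              config$K)
    sel <- acc >= config$accuracy_threshold - 1e-9
    freq <- freq + sel
    acc_sum <- acc_sum + acc
    set_sizes[r] <- sum(sel)
    if (any(sel) && nrow(test) > 0) {
      pred <- knn_predict(x[train$mutant, sel, drop = FALSE], train$group,
                          x[test$mutant, sel, drop = FALSE], config$K)
      test_acc[r] <- mean(pred == test$group)
    }
  }

  n_top <- as.integer(round(mean(set_sizes)))
  mean_acc <- acc_sum / config$n_repeats
  ord <- order(-freq, -mean_acc, genes)
  rank <- integer(n_genes); rank[ord] <- seq_len(n_genes)
  selected <- rank <= n_top

  low_mut <- eligible$mutant[eligible$group == "low_glucose"]
  mean_low <- colMeans(compendium$logfc[low_mut, , drop = FALSE])
  direction <- ifelse(mean_low > 0, "up_in_low", "down_in_low")

  per_gene <- tibble::tibble(
    gene = genes, frequency = as.integer(freq), mean_accuracy = mean_acc,
    rank = rank, selected = selected,
    direction = ifelse(selected, direction, NA_character_)
  )
  per_gene <- dplyr::arrange(per_gene, .data$rank)

  structure(
    list(
      genes = per_gene,
      repeats = tibble::tibble(repeat_id = seq_len(config$n_repeats),
                               set_size = set_sizes,
                               test_accuracy = test_acc),
      N = n_top,
      config = config
    ),
    class = "glucose_signature"
  )
}

#' @export
print.glucose_signature <- function(x, ...) {
  cat("<glucose_signature> N = ", x$N, " genes over ",
      x$config$n_repeats, " repeats\n", sep = "")
  cat("  mean test accuracy: ",
      round(mean(x$repeats$test_accuracy, na.rm = TRUE), 3), "\n", sep = "")
  invisible(x)
}

#' Selected signature genes
#'
#' @param signature A `glucose_signature`.
#' @param direction Optionally restrict to one half of the signature.
#' @return Character vector of gene ids, in rank order.
#' @export
signature_genes <- function(signature,
                            direction = c("both", "up_in_low",
                                          "down_in_low")) {
  direction <- match.arg(direction)
  g <- dplyr::filter(signature$genes, .data$selected)
  if (direction != "both") {
    g <- dplyr::filter(g, .data$direction == !!direction)
  }
  g$gene
}

#' @rdname build_signature
#' @param x A `glucose_signature`.
#' @param ... Unused.
#' @return `tidy()`: the per-gene tibble; `glance()`: a one-row summary
#'   (`n_signature`, `n_repeats`, `mean_set_size`, `mean_test_accuracy`).
#' @export
tidy.glucose_signature <- function(x, ...) x$genes

#' @rdname build_signature
#' @export
glance.glucose_signature <- function(x, ...) {
  tibble::tibble(
    n_signature = x$N,
    n_repeats = x$config$n_repeats,
    mean_set_size = mean(x$repeats$set_size),
    mean_test_accuracy = mean(x$repeats$test_accuracy, na.rm = TRUE)
  )
}

#' Summarize a time-course against a signature
#'
#' Averages the fold-change trajectories of the signature's up-in-low set,
#' down-in-low set, and all remaining genes.
#'
#' @param timecourse Long tibble with columns `time`, `gene`, `logfc`
#'   (e.g. from [simulate_timecourse()]).
#' @param signature A `glucose_signature`, or a list with elements
#'   `up_in_low` and `down_in_low` (character gene sets).
#' @return A tibble of class `timecourse_summary`: `time`, `set`
#'   (`up_in_low`/`down_in_low`/`other`), `mean_logfc`, `sd_logfc`,
#'   `n_genes`.
#' @export
timecourse_summary <- function(timecourse, signature) {
  if (inherits(signature, "glucose_signature")) {
    up <- signature_genes(signature, "up_in_low")
    down <- signature_genes(signature, "down_in_low")
  } else {
    up <- signature$up_in_low; down <- signature$down_in_low
  }
  if (length(up) + length(down) == 0) {
    stop("empty signature", call. = FALSE)
  }
  sets <- dplyr::case_when(
    timecourse$gene %in% up ~ "up_in_low",
    timecourse$gene %in% down ~ "down_in_low",
    TRUE ~ "other"
  )
  out <- dplyr::summarise(
    dplyr::group_by(dplyr::mutate(timecourse, set = sets),
                    .data$time, .data$set),
    mean_logfc = mean(.data$logfc),
    sd_logfc = stats::sd(.data$logfc),
    n_genes = dplyr::n_distinct(.data$gene),
    .groups = "drop"
  )
  if (!"other" %in% out$set) {
    attr(out, "no_other_genes") <- TRUE
    message("signature covers all genes; 'other' trajectory is empty")
  }
  class(out) <- c("timecourse_summary", class(out))
  out
}
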