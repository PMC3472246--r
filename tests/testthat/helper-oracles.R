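# Independent reference implementations used as oracles. These deliberately
# avoid the package's code paths: plain loops, explicit formulas.

# Single-gene leave-one-out KNN accuracy, written directly from the rule:
# K nearest other mutants by |difference|, ties keep earlier input order,
# majority vote.
r_loocv_accuracy <- function(values, labels, K = 3) {
  n <- length(values)
  correct <- 0
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    d <- abs(values[others] - values[i])
    nn <- others[order(d, others)][seq_len(K)]
    tab <- table(labels[nn])
    vote <- names(tab)[which.max(tab)]
    if (vote == labels[i]) correct <- correct + 1
  }
  correct / n
}

# Upper-tail hypergeometric probability by explicit combinatorial sum.
hyper_tail_enum <- function(k, K, n, M) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(M - K, n - js)) / choose(M, n)
}

# Upper-tail hypergeometric probability by enumerating every draw of size n
# (tiny cases only).
hyper_tail_combn <- function(k, K, n, M) {
  draws <- utils::combn(M, n)
  mean(colSums(draws <= K) >= k)
}

# Brute-force network reference: every ordered pair scored directly from the
# deletion-effect and thresholded-correlation definitions, with its own
# cosine computation.
brute_network <- function(compendium, mutants, thresholds,
                          p_threshold = 0.01, fc_threshold = 1.5,
                          center = FALSE) {
  edges <- list()
  for (x in mutants) {
    for (y in mutants) {
      if (x == y) next
      gene_y <- compendium$deleted_genes[[y]]
      lfc <- compendium$logfc[x, gene_y]
      p <- compendium$pvalue[x, gene_y]
      d <- if (p < p_threshold && abs(lfc) > log2(fc_threshold)) lfc else 0
      if (d == 0) next
      drop <- c(compendium$deleted_genes[[x]], gene_y)
      keep <- setdiff(colnames(compendium$logfc), drop)
      a <- compendium$logfc[x, keep]
      b <- compendium$logfc[y, keep]
      if (center) {
        a <- a - mean(a)
        b <- b - mean(b)
      }
      cc <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
      cc <- if (cc < thresholds$lower || cc > thresholds$upper) cc else 0
      if (cc == 0) next
      type <- if (d < 0 && cc > 0) "L1" else if (d > 0 && cc < 0) "L2" else
        if (d > 0 && cc > 0) "F1" else "F2"
      edges[[length(edges) + 1]] <- data.frame(x = x, y = y, type = type,
                                               d = d, c = cc)
    }
  }
  if (length(edges) == 0) {
    return(data.frame(x = character(), y = character(), type = character(),
                      d = numeric(), c = numeric()))
  }
  do.call(rbind, edges)
}

# Random compendium (noise only) for oracle-equivalence trials: mutant i's
# deleted gene is gene i.
random_compendium <- function(n_mutants, n_genes) {
  mutants <- sprintf("rm%02d", seq_len(n_mutants))
  genes <- sprintf("rg%02d", seq_len(n_genes))
  logfc <- matrix(rnorm(n_mutants * n_genes, 0, 1.2), n_mutants, n_genes,
                  dimnames = list(mutants, genes))
  pvalue <- matrix(runif(n_mutants * n_genes, 1e-4, 1), n_mutants, n_genes,
                   dimnames = list(mutants, genes))
  new_compendium(logfc, pvalue,
                 stats::setNames(as.list(genes[seq_len(n_mutants)]), mutants))
}

# Hand-built compendium from explicit logfc/pvalue entries.
manual_compendium <- function(logfc, pvalue, deleted = NULL) {
  if (is.null(deleted)) {
    deleted <- stats::setNames(as.list(colnames(logfc)[seq_len(nrow(logfc))]),
                               rownames(logfc))
  }
  new_compendium(logfc, pvalue, deleted)
}

# Small fast generator config for unit tests.
test_sim_config <- function(...) {
  args <- list(...)
  defaults <- list(n_genes = 1200, n_mutants = 20, signature_size = 200,
                   n_wt_pool = 60, n_wt_parallel = 12, seed = 42)
  do.call(sim_config, utils::modifyList(defaults, args))
}

truth_labels <- function(truth) {
  stats::setNames(truth$labels$group, truth$labels$mutant)
}

# Fresh temporary directory per call.
withr_like_tempdir <- function() {
  d <- tempfile("gluconet-test-")
  dir.create(d)
  d
}
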