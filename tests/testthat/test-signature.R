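test_that("a perfectly separating gene scores LOOCV accuracy 1", {
  values <- c(rep(1, 11), rep(-1, 10))
  labels <- rep(c("low_glucose", "high_glucose"), c(11, 10))
  expect_identical(gene_loocv_accuracy(values, labels, K = 3), 1)
})

test_that("an uninformative constant gene matches the hand-coded LOOCV oracle", {
  values <- rep(0.3, 21)
  labels <- rep(c("low_glucose", "high_glucose"), c(12, 9))
  got <- gene_loocv_accuracy(values, labels, K = 3)
  expect_identical(got, r_loocv_accuracy(values, labels, K = 3))
  # all distances tie, so the first K mutants in input order vote everywhere
  expect_identical(got, mean(labels == "low_glucose"))
})

test_that("the C++ LOOCV kernel agrees with the R oracle on random genes", {
  set.seed(6)
  for (trial in 1:25) {
    n <- sample(8:21, 1)
    values <- round(rnorm(n), 2)  # rounding forces occasional distance ties
    labels <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c("a", "b")
    expect_equal(gene_loocv_accuracy(values, labels, K = 3),
                 r_loocv_accuracy(values, labels, K = 3))
  }
})

test_that("LOOCV accuracy is invariant to mutant reordering", {
  set.seed(7)
  values <- rnorm(15)
  labels <- sample(c("a", "b"), 15, replace = TRUE)
  perm <- sample(15)
  expect_equal(gene_loocv_accuracy(values, labels, 3),
               gene_loocv_accuracy(values[perm], labels[perm], 3))
})

eligible_from_sim <- function(sim, min_de = 30) {
  de <- call_de(sim$compendium)
  lab <- truth_labels(sim$truth)
  groups <- tibble::tibble(mutant = names(lab), group = unname(lab))
  eligible_mutants(de, groups, min_de)
}

test_that("signature construction recovers the planted signature", {
  cfg <- test_sim_config(n_mutants = 30, frac_wt_like = 0.2, seed = 21)
  sim <- simulate_compendium(cfg)
  el <- eligible_from_sim(sim)
  sg <- build_signature(sim$compendium, el,
                        knn_config(n_repeats = 50, seed = 3))
  planted <- c(sim$truth$signature_up, sim$truth$signature_down)
  expect_gte(mean(planted %in% signature_genes(sg)), 0.9)
  expect_gte(mean(sg$repeats$test_accuracy, na.rm = TRUE), 0.9)
  # planted direction: up_in_low genes are recovered as up_in_low
  sel <- tidy(sg)
  up_sel <- sel$gene[sel$selected & !is.na(sel$direction) &
                       sel$direction == "up_in_low"]
  expect_gte(mean(intersect(planted, signature_genes(sg)) %in%
                    c(up_sel, signature_genes(sg, "down_in_low"))), 0.99)
  expect_true(all(sim$truth$signature_up[sim$truth$signature_up %in%
                                           signature_genes(sg)] %in% up_sel))
  # glance reports the cut
  expect_identical(glance(sg)$n_signature, sg$N)
})

test_that("one repeat makes N that repeat's set size", {
  cfg <- test_sim_config(seed = 22, frac_wt_like = 0.2)
  sim <- simulate_compendium(cfg)
  el <- eligible_from_sim(sim)
  sg <- suppressWarnings(
    build_signature(sim$compendium, el, knn_config(n_repeats = 1, seed = 5)))
  expect_identical(sg$N, as.integer(sg$repeats$set_size[1]))
  expect_identical(sum(sg$genes$selected), sg$N)
})

test_that("selected genes are the top-N by frequency under the documented tie-break", {
  cfg <- test_sim_config(seed = 23, frac_wt_like = 0.2)
  sim <- simulate_compendium(cfg)
  el <- eligible_from_sim(sim)
  sg <- suppressWarnings(
    build_signature(sim$compendium, el, knn_config(n_repeats = 10, seed = 6)))
  tab <- sg$genes
  ord <- order(-tab$frequency, -tab$mean_accuracy, tab$gene)
  expect_identical(tab$gene[ord][seq_len(sg$N)],
                   tab$gene[tab$selected][order(tab$rank[tab$selected])])
  # determinism given the seed sequence
  sg2 <- suppressWarnings(
    build_signature(sim$compendium, el, knn_config(n_repeats = 10, seed = 6)))
  expect_identical(tidy(sg), tidy(sg2))
})

test_that("shuffled group labels collapse the signature to chance", {
  cfg <- test_sim_config(n_mutants = 30, frac_wt_like = 0.2, seed = 24)
  sim <- simulate_compendium(cfg)
  el <- eligible_from_sim(sim)
  sg_true <- build_signature(sim$compendium, el,
                             knn_config(n_repeats = 30, seed = 7))
  el_null <- el
  set.seed(8)
  el_null$group <- sample(el_null$group)
  sg_null <- suppressWarnings(
    build_signature(sim$compendium, el_null, knn_config(n_repeats = 30, seed = 7)))
  acc <- mean(sg_null$repeats$test_accuracy, na.rm = TRUE)
  expect_gte(acc, 0.4)
  expect_lte(acc, 0.6)
  expect_lte(sg_null$N, 0.05 * sg_true$N)
})

test_that("time-course summaries average the right gene sets", {
  tc <- tibble::tibble(
    time = rep(c(0, 10), each = 4),
    gene = rep(c("g1", "g2", "g3", "g4"), 2),
    logfc = c(0, 0, 0, 0, 1, 1, -1, 0.5)
  )
  sig <- list(up_in_low = c("g1", "g2"), down_in_low = "g3")
  ts <- timecourse_summary(tc, sig)
  t10 <- ts[ts$time == 10, ]
  expect_equal(t10$mean_logfc[t10$set == "up_in_low"], 1)
  expect_equal(t10$mean_logfc[t10$set == "down_in_low"], -1)
  expect_equal(t10$mean_logfc[t10$set == "other"], 0.5)
  # constant profiles stay flat at zero
  flat <- timecourse_summary(
    tibble::tibble(time = rep(c(0, 5), 2), gene = rep(c("g1", "g3"), each = 2),
                   logfc = 0),
    sig
  )
  expect_true(all(flat$mean_logfc == 0))
  # signature covering every gene leaves no 'other' trajectory
  expect_message(
    full <- timecourse_summary(tc, list(up_in_low = c("g1", "g2"),
                                        down_in_low = c("g3", "g4"))),
    "other"
  )
  expect_false("other" %in% full$set)
  expect_error(timecourse_summary(tc, list(up_in_low = character(),
                                           down_in_low = character())),
               "empty")
})
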