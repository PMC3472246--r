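test_that("zero-noise limit reproduces the planted response exactly", {
  cfg <- test_sim_config(noise_sd = 1e-6, culture_sd = 1e-9,
                         frac_wt_like = 0, frac_low_glucose = 1,
                         scale_range = c(1, 1), n_mutants = 3,
                         n_genes = 400, signature_size = 60)
  sim <- simulate_compendium(cfg)
  m <- sim$truth$labels$mutant[sim$truth$labels$group == "low_glucose"][1]
  up <- sim$compendium$logfc[m, sim$truth$signature_up]
  expect_equal(unname(up), rep(cfg$response_magnitude, length(up)),
               tolerance = 1e-4)
  down <- sim$compendium$logfc[m, sim$truth$signature_down]
  expect_equal(unname(down), rep(-cfg$response_magnitude, length(down)),
               tolerance = 1e-4)
})

test_that("identical config and seed give bit-identical output", {
  cfg <- test_sim_config(n_genes = 300, n_mutants = 8, signature_size = 50)
  a <- simulate_compendium(cfg)
  b <- simulate_compendium(cfg)
  expect_identical(a$compendium$logfc, b$compendium$logfc)
  expect_identical(a$compendium$pvalue, b$compendium$pvalue)
  expect_identical(a$truth$labels, b$truth$labels)
})

test_that("opposite groups anti-correlate and same groups agree", {
  cfg <- test_sim_config(noise_sd = 0.15, frac_wt_like = 0.2)
  sim <- simulate_compendium(cfg)
  lab <- truth_labels(sim$truth)
  low <- names(lab)[lab == "low_glucose"]
  high <- names(lab)[lab == "high_glucose"]
  sim_mat <- profile_similarity_matrix(sim$compendium, c(low, high))
  cross <- sim_mat[low, high]
  within_low <- sim_mat[low, low][upper.tri(diag(length(low)))]
  expect_lt(mean(cross), 0)
  expect_gt(mean(within_low), 0.9)
})

test_that("each mutant's own transcript is called strongly down", {
  cfg <- test_sim_config()
  sim <- simulate_compendium(cfg)
  own <- vapply(mutant_ids <- rownames(sim$compendium$logfc), function(m) {
    sim$compendium$logfc[m, sim$compendium$deleted_genes[[m]]]
  }, numeric(1))
  expect_true(all(own < -log2(1.7)))
  expect_true(all(own < -3))
})

test_that("planted edges force consistent group labels and reject like_wt endpoints", {
  cfg <- test_sim_config(
    n_mutants = 6, n_genes = 300, signature_size = 40,
    planted_edges = list(c("m001", "m002", "L1"), c("m003", "m004", "L2"))
  )
  sim <- simulate_compendium(cfg)
  lab <- truth_labels(sim$truth)
  expect_identical(unname(lab["m001"]), unname(lab["m002"]))  # L1: same group
  expect_false(lab["m003"] == lab["m004"])                    # L2: opposite
  expect_error(
    simulate_compendium(test_sim_config(
      n_mutants = 6, n_genes = 300, signature_size = 40,
      planted_edges = list(c("m001", "m002", "L1")),
      group_labels = c(m001 = "like_wt")
    )),
    "like_wt"
  )
  expect_error(
    simulate_compendium(test_sim_config(
      n_mutants = 6, n_genes = 300, signature_size = 40,
      planted_edges = list(c("m001", "m002", "L1")),
      group_labels = c(m001 = "low_glucose", m002 = "high_glucose")
    )),
    "contradictory"
  )
})

test_that("double mutant reproduces the dominant parent in the noise-free limit", {
  cfg <- test_sim_config(noise_sd = 1e-6, culture_sd = 1e-9, frac_wt_like = 0,
                         n_mutants = 6, n_genes = 500, signature_size = 80)
  sim <- simulate_compendium(cfg)
  lab <- truth_labels(sim$truth)
  pa <- names(lab)[lab == "low_glucose"][1]
  pb <- names(lab)[lab == "high_glucose"][1]
  dm <- simulate_double_mutant(sim$compendium, sim$truth, pa, pb,
                               dominant = pa, seed = 11)
  did <- dm$double_truth$double_id
  del <- unlist(dm$compendium$deleted_genes[c(pa, pb)])
  keep <- setdiff(colnames(sim$compendium$logfc), del)
  expect_equal(dm$compendium$logfc[did, keep],
               sim$truth$true_means[pa, keep], tolerance = 1e-4)
})

test_that("double mutant is closer to its dominant parent and keeps residual directions", {
  cfg <- test_sim_config(frac_wt_like = 0, side_effect_rate = 0.02)
  sim <- simulate_compendium(cfg)
  lab <- truth_labels(sim$truth)
  pa <- names(lab)[lab == "low_glucose"][1]
  pb <- names(lab)[lab == "high_glucose"][1]
  dm <- simulate_double_mutant(sim$compendium, sim$truth, pa, pb,
                               dominant = pa, n_residual = 30, seed = 12)
  did <- dm$double_truth$double_id
  res <- dm$double_truth$residual_genes[[1]]
  expect_length(res, 30)
  del <- unlist(dm$compendium$deleted_genes[c(pa, pb, did)])
  keep <- setdiff(colnames(sim$compendium$logfc), del)
  sim_a <- cosine_similarity(dm$compendium$logfc[did, keep],
                             dm$compendium$logfc[pa, keep])
  sim_b <- cosine_similarity(dm$compendium$logfc[did, keep],
                             dm$compendium$logfc[pb, keep])
  expect_gt(sim_a, sim_b)
  # residual genes retain the non-dominant parent's direction
  expect_true(all(sign(dm$compendium$logfc[did, res]) ==
                    sign(sim$truth$true_means[pb, res])))
  expect_error(
    simulate_double_mutant(sim$compendium, sim$truth, "nope", pb),
    "unknown parent"
  )
})

test_that("time-course has the printed sampling grid and saturating kinetics", {
  cfg <- test_sim_config(n_genes = 400, n_mutants = 5, signature_size = 60)
  sim <- simulate_compendium(cfg)
  tc <- simulate_timecourse(cfg, sim$truth)
  expect_identical(sort(unique(tc$time)),
                   c(0, 3, 7.5, 15, 30, 60, 110, 150, 300))
  expect_identical(nrow(tc), 9L * cfg$n_genes)

  quiet <- simulate_timecourse(cfg, sim$truth, noise_sd = 1e-9)
  rising <- sim$truth$signature_down  # glucose-induced half
  traj <- tapply(quiet$logfc[quiet$gene %in% rising],
                 quiet$time[quiet$gene %in% rising], mean)
  expect_equal(unname(traj[["0"]]), 0, tolerance = 1e-6)
  expect_true(all(diff(traj[order(as.numeric(names(traj)))]) > 0))
  expect_equal(unname(traj[["300"]]),
               cfg$response_magnitude * (1 - exp(-300 / cfg$timecourse_tau)),
               tolerance = 1e-6)
  expect_error(simulate_timecourse(cfg, sim$truth, timepoints = numeric()),
               "non-empty")
})
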