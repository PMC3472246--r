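test_that("cosine similarity matches hand computations", {
  a <- c(1, 2, 0)
  expect_equal(cosine_similarity(a, a), 1)
  expect_equal(cosine_similarity(a, -a), -1)
  b <- c(2, 1, 0)
  expect_equal(cosine_similarity(a, b), 0.8)
  # independent dot-product oracle
  expect_equal(cosine_similarity(a, b),
               sum(a * b) / sqrt(sum(a^2) * sum(b^2)))
  expect_error(cosine_similarity(a, c(0, 0, 0)), "zero-norm")
  named_a <- setNames(c(1, 2, 10), c("g1", "g2", "bad"))
  named_b <- setNames(c(2, 1, -10), c("g1", "g2", "bad"))
  expect_equal(cosine_similarity(named_a, named_b, exclude_genes = "bad"),
               0.8)
})

test_that("deletion effect applies the p < 0.01 and FC > 1.5 gates", {
  lfc <- matrix(c(0, -1.0, log2(1.4), log2(3)), 1, 4,
                dimnames = list("x", paste0("g", 1:4)))
  lfc <- rbind(x = lfc[1, ], y1 = 0, y2 = 0, y3 = 0)
  p <- matrix(c(1, 0.005, 0.005, 0.05), 4, 4, byrow = TRUE,
              dimnames = dimnames(lfc))
  p[] <- rep(c(1, 0.005, 0.005, 0.05), each = 4)
  comp <- manual_compendium(lfc, p,
                            deleted = list(x = "g1", y1 = "g2", y2 = "g3",
                                           y3 = "g4"))
  expect_equal(deletion_effect(comp, "x", "y1"), -1.0)  # ratio 2, p 0.005
  expect_equal(deletion_effect(comp, "x", "y2"), 0)     # ratio 1.4 < 1.5
  expect_equal(deletion_effect(comp, "x", "y3"), 0)     # p 0.05 > 0.01
})

test_that("correlation thresholding keeps only values outside the dead zone", {
  th <- fixed_thresholds(0, 0.18)
  expect_equal(threshold_correlation(0.10, th), 0)
  expect_equal(threshold_correlation(-0.05, th), -0.05)
  expect_equal(threshold_correlation(0.25, th), 0.25)
  expect_equal(threshold_correlation(c(0.10, -0.05, 0.25), th),
               c(0, -0.05, 0.25))
})

test_that("edge typing partitions the (d, c) quadrants exhaustively", {
  expect_identical(classify_edge(-1.2, 0.5), "L1")
  expect_identical(classify_edge(0.9, -0.3), "L2")
  expect_identical(classify_edge(0.9, 0.3), "F1")
  expect_identical(classify_edge(-1.2, -0.3), "F2")
  expect_identical(classify_edge(0, 0.9), NA_character_)
  expect_identical(classify_edge(1.2, 0), NA_character_)
  for (d in c(-1.2, 0, 0.9)) {
    for (c_val in c(-0.3, 0, 0.5)) {
      type <- classify_edge(d, c_val)
      if (d == 0 || c_val == 0) {
        expect_identical(type, NA_character_)
      } else {
        expect_true(type %in% c("L1", "L2", "F1", "F2"))
        expect_identical(type,
                         c("L1", "L2", "F1", "F2")[
                           match(paste(d < 0, c_val > 0),
                                 c("TRUE TRUE", "FALSE FALSE",
                                   "FALSE TRUE", "TRUE FALSE"))])
      }
    }
  }
})

test_that("permutation calibration is deterministic, symmetric, and covers the range", {
  set.seed(9)
  comp <- random_compendium(10, 200)
  th1 <- calibrate_thresholds(comp, n_permutations = 1000, seed = 3)
  th2 <- calibrate_thresholds(comp, n_permutations = 1000, seed = 3)
  expect_identical(th1$lower, th2$lower)
  expect_identical(th1$upper, th2$upper)
  # i.i.d. noise gives a symmetric background
  expect_lt(abs(th1$lower + th1$upper), 0.05)
  # quantiles (0, 1) return the background range
  th_range <- calibrate_thresholds(comp, n_permutations = 20,
                                   quantiles = c(0, 1), seed = 4)
  expect_identical(c(th_range$lower, th_range$upper),
                   unname(range(th_range$background)))
  # stability across seeds
  th3 <- calibrate_thresholds(comp, n_permutations = 1000, seed = 99)
  expect_lt(abs(th1$lower - th3$lower), 0.02)
  expect_lt(abs(th1$upper - th3$upper), 0.02)
})

test_that("build_network matches the brute-force reference on random compendia", {
  set.seed(10)
  for (trial in 1:60) {
    comp <- random_compendium(6, 20)
    th <- fixed_thresholds(runif(1, -0.3, 0), runif(1, 0, 0.3))
    nw <- build_network(comp, rownames(comp$logfc), th)
    ref <- brute_network(comp, rownames(comp$logfc), th)
    got <- tidy(nw)
    expect_identical(nrow(got), nrow(ref))
    if (nrow(ref) > 0) {
      key <- function(df) paste(df$x, df$y, df$type)
      expect_setequal(key(got), key(ref))
      ord_g <- order(got$x, got$y)
      ord_r <- order(ref$x, ref$y)
      expect_equal(got$d[ord_g], ref$d[ord_r])
      expect_equal(got$c[ord_g], ref$c[ord_r])
    }
  }
})

test_that("orthogonal profiles give an empty network", {
  genes <- paste0("g", 1:8)
  lfc <- diag(4) * 3
  lfc <- cbind(lfc, lfc * 0)
  dimnames(lfc) <- list(paste0("m", 1:4), genes)
  p <- matrix(1e-4, 4, 8, dimnames = dimnames(lfc))
  comp <- manual_compendium(lfc, p,
                            deleted = setNames(as.list(genes[5:8]),
                                               rownames(lfc)))
  nw <- build_network(comp, rownames(lfc), fixed_thresholds(-0.1, 0.1))
  expect_identical(nrow(tidy(nw)), 0L)
})

test_that("raising the fold-change floor never adds edges", {
  set.seed(11)
  for (trial in 1:10) {
    comp <- random_compendium(6, 25)
    th <- fixed_thresholds(-0.2, 0.2)
    loose <- tidy(build_network(comp, rownames(comp$logfc), th,
                                fc_threshold = 1.2))
    strict <- tidy(build_network(comp, rownames(comp$logfc), th,
                                 fc_threshold = 1.8))
    expect_true(all(paste(strict$x, strict$y) %in%
                      paste(loose$x, loose$y)))
  }
})

test_that("downstream ranking orders a sequential chain tail-first", {
  genes <- paste0("g", 1:9)
  mutants <- c("x", "y", "z")
  lfc <- matrix(0, 3, 9, dimnames = list(mutants, genes))
  p <- matrix(1, 3, 9, dimnames = dimnames(lfc))
  # x -> y -> z, both L1: deletion knocks the downstream transcript down
  base <- c(1, 1, 1, -1, 0, 0, 0, 0, 0)
  for (m in mutants) lfc[m, 5:9] <- base[1:5]
  lfc["x", "g2"] <- -2; p["x", "g2"] <- 1e-4
  lfc["y", "g3"] <- -2; p["y", "g3"] <- 1e-4
  comp <- manual_compendium(lfc, p,
                            deleted = list(x = "g1", y = "g2", z = "g3"))
  nw <- build_network(comp, mutants, fixed_thresholds(-0.05, 0.05))
  expect_setequal(paste(tidy(nw)$x, tidy(nw)$y), c("x y", "y z"))
  expect_true(all(tidy(nw)$type == "L1"))
  rk <- downstream_ranking(nw)
  expect_identical(rk$mutant[1], "z")
  expect_identical(rk$mutant[nrow(rk)], "x")

  empty <- build_network(comp, mutants, fixed_thresholds(-2, 2))
  expect_identical(downstream_ranking(empty)$mutant, sort(mutants))
})

test_that("edge and vertex accessors agree", {
  set.seed(12)
  comp <- random_compendium(6, 20)
  nw <- build_network(comp, rownames(comp$logfc), fixed_thresholds(-0.2, 0.2))
  g <- glance(nw)
  expect_identical(g$n_edges, nrow(tidy(nw)))
  expect_identical(g$n_L1 + g$n_L2,
                   sum(nw$vertices$in_sequential))
  expect_identical(sum(nw$vertices$in_sequential),
                   sum(nw$vertices$out_sequential))
})
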