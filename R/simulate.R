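#' Configuration for the synthetic compendium generator
#'
#' Defaults emulate the design of the yeast glucose-pathway deletion screen
#' this package targets: 91 single-deletion mutants profiled on ~6,200 genes,
#' four replicates from two independently inoculated cultures each, 56
#' wildtype cultures grown in parallel, a 200-culture wildtype reference
#' pool, a shared two-direction transcriptional response (the glucose
#' signature) that about half of the responsive mutants show in one direction
#' and half in the other, and sparse mutant-specific side responses.
#'
#' @param n_genes Number of measured genes.
#' @param n_mutants Number of deletion mutants. Each mutant `i` deletes gene
#'   `i` of the gene panel, so deleted genes are ordinary measured genes.
#' @param n_replicates_per_mutant Replicate profiles per mutant, split evenly
#'   over `n_cultures` independently inoculated cultures.
#' @param n_cultures Cultures per mutant (replicates share a culture-level
#'   random effect).
#' @param n_wt_parallel Wildtype profiles grown alongside the mutants (one
#'   profile per culture).
#' @param n_wt_pool Size of the wildtype reference pool the statistics are
#'   computed against.
#' @param signature_size Number of genes in the planted glucose signature,
#'   split evenly into an up-in-low-glucose and a down-in-low-glucose half.
#' @param frac_low_glucose Fraction of responsive mutants assigned to the
#'   low-glucose-mimicking group.
#' @param frac_wt_like Fraction of mutants whose deletion has no
#'   transcriptional consequence (profiles are noise plus the deleted
#'   transcript itself).
#' @param response_magnitude Log2 magnitude of the shared response on
#'   signature genes for a mutant of scale 1.
#' @param scale_range Per-mutant response scale is drawn uniformly from this
#'   range, so mutants differ in direction and magnitude only.
#' @param side_effect_rate Fraction of background genes given a
#'   mutant-specific response in each responsive mutant.
#' @param side_effect_magnitude Log2 magnitude of mutant-specific responses.
#' @param noise_sd Replicate-level Gaussian noise sd (log2 units).
#' @param culture_sd Culture-level random-effect sd (log2 units).
#' @param deletion_logfc Log2 value planted for a mutant's own deleted
#'   transcript(s); strongly negative so it always calls as downregulated.
#' @param edge_effect Log2 magnitude of the transcriptional effect planted
#'   for a regulatory edge (the regulator's deletion changes the target
#'   transcript by this much).
#' @param planted_edges List of `c(x, y, type)` character triples planting a
#'   typed regulatory relationship between mutants `x` and `y`
#'   (`type` one of `"L1"`, `"L2"`, `"F1"`, `"F2"`).
#' @param group_labels Optional named character vector forcing group labels
#'   (`"high_glucose"`, `"low_glucose"`, `"like_wt"`) for some or all
#'   mutants; planted-edge endpoints labelled `like_wt` are rejected.
#' @param timepoints Sampling times (minutes) of the glucose-addition
#'   time-course.
#' @param timecourse_tau Time constant (minutes) of the saturating
#'   time-course trajectories.
#' @param seed Integer seed; identical config and seed give bit-identical
#'   output.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 6200,
                       n_mutants = 91,
                       n_replicates_per_mutant = 4,
                       n_cultures = 2,
                       n_wt_parallel = 56,
                       n_wt_pool = 200,
                       signature_size = 878,
                       frac_low_glucose = 0.5,
                       frac_wt_like = 0.5,
                       response_magnitude = 1.5,
                       scale_range = c(0.6, 1.4),
                       side_effect_rate = 0.005,
                       side_effect_magnitude = 2,
                       noise_sd = 0.3,
                       culture_sd = 0.1,
                       deletion_logfc = -6,
                       edge_effect = 2.5,
                       planted_edges = list(),
                       group_labels = NULL,
                       timepoints = c(0, 3, 7.5, 15, 30, 60, 110, 150, 300),
                       timecourse_tau = 30,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_mutants = as.integer(n_mutants),
    n_replicates_per_mutant = as.integer(n_replicates_per_mutant),
    n_cultures = as.integer(n_cultures),
    n_wt_parallel = as.integer(n_wt_parallel),
    n_wt_pool = as.integer(n_wt_pool),
    signature_size = as.integer(signature_size),
    frac_low_glucose = frac_low_glucose, frac_wt_like = frac_wt_like,
    response_magnitude = response_magnitude, scale_range = scale_range,
    side_effect_rate = side_effect_rate,
    side_effect_magnitude = side_effect_magnitude,
    noise_sd = noise_sd, culture_sd = culture_sd,
    deletion_logfc = deletion_logfc, edge_effect = edge_effect,
    planted_edges = lapply(planted_edges,
                           function(e) as.character(unlist(e))),
    group_labels = group_labels,
    timepoints = timepoints, timecourse_tau = timecourse_tau,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_genes, cfg$n_mutants, cfg$n_replicates_per_mutant,
              cfg$n_cultures, cfg$n_wt_parallel, cfg$n_wt_pool,
              cfg$signature_size)
  if (any(counts < 1)) stop("all counts must be >= 1", call. = FALSE)
  if (cfg$signature_size > cfg$n_genes - cfg$n_mutants) {
    stop("signature_size must leave room beside the deleted genes",
         call. = FALSE)
  }
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (cfg$frac_low_glucose < 0 || cfg$frac_low_glucose > 1 ||
      cfg$frac_wt_like < 0 || cfg$frac_wt_like > 1) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_replicates_per_mutant %% cfg$n_cultures != 0) {
    stop("replicates must divide evenly over cultures", call. = FALSE)
  }
  for (e in cfg$planted_edges) {
    if (length(e) != 3 || !e[3] %in% c("L1", "L2", "F1", "F2")) {
      stop("planted edges must be c(x, y, type) with type L1/L2/F1/F2",
           call. = FALSE)
    }
  }
  invisible(cfg)
}

sim_ids <- function(cfg) {
  list(
    genes = sprintf("g%05d", seq_len(cfg$n_genes)),
    mutants = sprintf("m%03d", seq_len(cfg$n_mutants))
  )
}

# Edge types constrain the relative response direction of their endpoints:
# sequential-logic types pair a negative (L1) or positive (L2) deletion
# effect with like or opposite group membership; F1/F2 flip the sign the
# sequential reading would predict.
edge_sign_rules <- function(type) {
  switch(type,
    L1 = list(d_sign = -1, same_group = TRUE),
    L2 = list(d_sign = +1, same_group = FALSE),
    F1 = list(d_sign = +1, same_group = TRUE),
    F2 = list(d_sign = -1, same_group = FALSE)
  )
}

assign_group_labels <- function(cfg, mutants) {
  labels <- setNames(rep(NA_character_, length(mutants)), mutants)
  if (!is.null(cfg$group_labels)) {
    forced <- cfg$group_labels
    bad <- setdiff(names(forced), mutants)
    if (length(bad) > 0) stop("unknown mutant in group_labels: ",
                              paste(bad, collapse = ", "), call. = FALSE)
    labels[names(forced)] <- unname(forced)
  }
  edge_mutants <- unique(unlist(lapply(cfg$planted_edges, function(e) e[1:2])))
  if (any(labels[edge_mutants] %in% "like_wt")) {
    stop("planted edge endpoint labelled like_wt: ",
         paste(edge_mutants[labels[edge_mutants] %in% "like_wt"],
               collapse = ", "), call. = FALSE)
  }
  flip <- c(high_glucose = "low_glucose", low_glucose = "high_glucose")
  # propagate same/opposite-group constraints along planted edges
  for (e in cfg$planted_edges) {
    x <- e[1]; y <- e[2]
    rule <- edge_sign_rules(e[3])
    if (is.na(labels[y]) && is.na(labels[x])) {
      labels[y] <- if (runif(1) < cfg$frac_low_glucose) "low_glucose" else "high_glucose"
    }
    if (is.na(labels[y])) {
      labels[y] <- if (rule$same_group) labels[x] else flip[[labels[x]]]
    }
    expected_x <- if (rule$same_group) labels[y] else flip[[labels[y]]]
    if (is.na(labels[x])) {
      labels[x] <- expected_x
    } else if (labels[x] != expected_x) {
      stop("planted edges imply contradictory group labels for mutant ", x,
           call. = FALSE)
    }
  }
  free <- names(labels)[is.na(labels)]
  n_wt_target <- round(cfg$frac_wt_like * length(mutants))
  n_wt_have <- sum(labels %in% "like_wt", na.rm = TRUE)
  n_wt_new <- max(0, min(length(free), n_wt_target - n_wt_have))
  wt_pick <- if (n_wt_new > 0) sample(free, n_wt_new) else character()
  labels[wt_pick] <- "like_wt"
  free <- setdiff(free, wt_pick)
  labels[free] <- ifelse(runif(length(free)) < cfg$frac_low_glucose,
                         "low_glucose", "high_glucose")
  labels
}

#' Simulate a deletion-mutant expression compendium with planted truth
#'
#' Generates replicate-level profiles under the configured noise model,
#' summarizes them against a simulated wildtype reference pool (via
#' [summarize_replicates()]), and returns the compendium together with the
#' planted ground truth: group labels, per-mutant response scales, the
#' signature gene sets, and any planted regulatory edges.
#'
#' Responsive mutants carry the shared two-direction response
#' `s_m * response_magnitude` on the signature genes (positive on the
#' up-in-low half and negative on the down-in-low half for low-glucose
#' mutants; mirrored for high-glucose mutants, so the two groups are
#' anti-correlated), sparse mutant-specific side responses, and a strongly
#' negative value on their own deleted transcript. A planted edge `(x, y,
#' type)` additionally sets the transcript of `y`'s deleted gene in mutant
#' `x` per the edge type's sign rule. Wildtype profiles are pure noise.
#'
#' @param config A [sim_config()].
#' @return A list with elements `compendium` (a [new_compendium()] object)
#'   and `truth` (class `synthetic_truth`: `labels` tibble, `signature_up`,
#'   `signature_down`, `planted_edges` tibble, plus generator state used by
#'   [simulate_double_mutant()]).
#' @export
simulate_compendium <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, simulate_compendium_impl(config))
}

simulate_compendium_impl <- function(cfg) {
  ids <- sim_ids(cfg)
  genes <- ids$genes; mutants <- ids$mutants
  deleted <- setNames(as.list(genes[seq_along(mutants)]), mutants)

  labels <- assign_group_labels(cfg, mutants)
  responsive <- names(labels)[labels != "like_wt"]
  scale <- setNames(rep(0, length(mutants)), mutants)
  scale[responsive] <- runif(length(responsive), cfg$scale_range[1],
                             cfg$scale_range[2]) *
    ifelse(labels[responsive] == "low_glucose", 1, -1)

  # signature genes are drawn outside the deleted-gene block so deletion
  # effects on other mutants' genes occur only where edges are planted
  pool_genes <- genes[(cfg$n_mutants + 1):cfg$n_genes]
  sig <- sample(pool_genes, cfg$signature_size)
  n_up <- ceiling(cfg$signature_size / 2)
  signature_up <- sort(sig[seq_len(n_up)])
  signature_down <- sort(sig[-seq_len(n_up)])
  sigma <- setNames(rep(0, cfg$n_genes), genes)
  sigma[signature_up] <- cfg$response_magnitude
  sigma[signature_down] <- -cfg$response_magnitude

  true_means <- matrix(0, length(mutants), cfg$n_genes,
                       dimnames = list(mutants, genes))
  for (m in responsive) true_means[m, ] <- scale[m] * sigma

  background <- setdiff(pool_genes, sig)
  n_side <- round(cfg$side_effect_rate * cfg$n_genes)
  side_effects <- list()
  for (m in responsive) {
    if (n_side > 0) {
      sg <- sample(background, n_side)
      true_means[m, sg] <- sample(c(-1, 1), n_side, replace = TRUE) *
        cfg$side_effect_magnitude
      side_effects[[m]] <- sg
    }
  }

  edges <- cfg$planted_edges
  edge_tbl <- tibble::tibble(
    x = vapply(edges, `[`, "", 1), y = vapply(edges, `[`, "", 2),
    type = vapply(edges, `[`, "", 3)
  )
  edge_tbl$category <- ifelse(edge_tbl$type %in% c("L1", "L2"),
                              "sequential", "non_sequential")
  for (e in edges) {
    rule <- edge_sign_rules(e[3])
    true_means[e[1], deleted[[e[2]]]] <- rule$d_sign * cfg$edge_effect
  }
  for (m in mutants) true_means[m, deleted[[m]]] <- cfg$deletion_logfc

  n_rep <- cfg$n_replicates_per_mutant
  rep_per_culture <- n_rep / cfg$n_cultures
  replicates <- matrix(0, length(mutants) * n_rep, cfg$n_genes,
                       dimnames = list(NULL, genes))
  rep_mutant <- rep(mutants, each = n_rep)
  row <- 1L
  for (m in mutants) {
    for (cu in seq_len(cfg$n_cultures)) {
      culture_eff <- rnorm(cfg$n_genes, 0, cfg$culture_sd)
      for (r in seq_len(rep_per_culture)) {
        replicates[row, ] <- true_means[m, ] + culture_eff +
          rnorm(cfg$n_genes, 0, cfg$noise_sd)
        row <- row + 1L
      }
    }
  }
  rownames(replicates) <- paste0(rep_mutant, "_r", rep(seq_len(n_rep),
                                                       length(mutants)))

  wt_noise <- function(n) {
    m <- matrix(rnorm(n * cfg$n_genes, 0,
                      sqrt(cfg$culture_sd^2 + cfg$noise_sd^2)),
                n, cfg$n_genes, dimnames = list(NULL, genes))
    m
  }
  wt_pool <- wt_noise(cfg$n_wt_pool)
  rownames(wt_pool) <- sprintf("wtpool%03d", seq_len(cfg$n_wt_pool))
  wt_parallel <- wt_noise(cfg$n_wt_parallel)
  rownames(wt_parallel) <- sprintf("wt%03d", seq_len(cfg$n_wt_parallel))

  compendium <- summarize_replicates(replicates, wt_pool,
                                     mutant_map = rep_mutant,
                                     deleted_genes = deleted,
                                     wt_profiles = wt_parallel)

  truth <- structure(
    list(
      labels = tibble::tibble(mutant = mutants,
                              group = unname(labels[mutants]),
                              scale = unname(scale[mutants])),
      signature_up = signature_up,
      signature_down = signature_down,
      planted_edges = edge_tbl,
      side_effects = side_effects,
      true_means = true_means,
      wt_pool = wt_pool,
      config = cfg
    ),
    class = "synthetic_truth"
  )
  list(compendium = compendium, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth>\n")
  print(table(x$labels$group))
  cat("  signature: ", length(x$signature_up), " up + ",
      length(x$signature_down), " down genes\n", sep = "")
  cat("  planted edges: ", nrow(x$planted_edges), "\n", sep = "")
  invisible(x)
}

#' Simulate a double-deletion mutant profile
#'
#' The double mutant's true profile is a dominance-weighted blend of its two
#' parents' true profiles (`dominance = 1` reproduces the dominant parent
#' exactly on all non-deleted genes), optionally overridden on a residual
#' gene set that retains the non-dominant parent's values — emulating a
#' compact transcriptional program that escapes the epistasis. Both deleted
#' transcripts are set strongly negative. Replicates are drawn under the
#' generator's noise model and summarized against the stored wildtype pool.
#'
#' @param compendium Compendium the parents live in.
#' @param truth Matching `synthetic_truth` from [simulate_compendium()].
#' @param parent_a,parent_b Parent mutant ids.
#' @param dominant Which parent's program dominates (one of the two ids).
#' @param n_residual Number of residual genes inherited from the
#'   non-dominant parent (sampled from its side-effect/signature genes), or
#'   a character vector of explicit gene ids.
#' @param dominance Blend weight in (0.5, 1] given to the dominant parent.
#' @param double_id Id for the new profile row.
#' @param seed Seed for the replicate noise.
#' @return A list with `compendium` (input plus one row) and `double_truth`
#'   (tibble: ids, dominant, residual gene list-column).
#' @export
simulate_double_mutant <- function(compendium, truth, parent_a, parent_b,
                                   dominant = parent_a, n_residual = 0,
                                   dominance = 1,
                                   double_id = paste0(parent_a, "x", parent_b),
                                   seed = truth$config$seed + 1L) {
  mut <- mutant_ids(compendium)
  for (p in c(parent_a, parent_b)) {
    if (!p %in% mut) stop("unknown parent mutant: ", p, call. = FALSE)
  }
  stopifnot(dominant %in% c(parent_a, parent_b))
  other <- setdiff(c(parent_a, parent_b), dominant)
  cfg <- truth$config
  genes <- colnames(truth$true_means)

  mean_double <- dominance * truth$true_means[dominant, ] +
    (1 - dominance) * truth$true_means[other, ]
  if (is.character(n_residual)) {
    residual <- n_residual
  } else if (n_residual > 0) {
    cand <- truth$side_effects[[other]] %||% character()
    if (length(cand) < n_residual) {
      sig <- c(truth$signature_up, truth$signature_down)
      cand <- union(cand, sig)
    }
    residual <- sort(sample(cand, n_residual))
  } else {
    residual <- character()
  }
  mean_double[residual] <- truth$true_means[other, residual]
  del <- unique(c(unlist(compendium$deleted_genes[[parent_a]]),
                  unlist(compendium$deleted_genes[[parent_b]])))
  mean_double[del] <- cfg$deletion_logfc

  reps <- with_seed(seed, {
    n_rep <- cfg$n_replicates_per_mutant
    out <- matrix(0, n_rep, length(genes), dimnames = list(NULL, genes))
    i <- 1L
    for (cu in seq_len(cfg$n_cultures)) {
      culture_eff <- rnorm(length(genes), 0, cfg$culture_sd)
      for (r in seq_len(n_rep / cfg$n_cultures)) {
        out[i, ] <- mean_double + culture_eff + rnorm(length(genes), 0,
                                                      cfg$noise_sd)
        i <- i + 1L
      }
    }
    out
  })
  summ <- summarize_replicates(reps, truth$wt_pool,
                               mutant_map = rep(double_id, nrow(reps)),
                               deleted_genes = setNames(list(del), double_id))
  new_logfc <- rbind(compendium$logfc, summ$logfc)
  new_pvalue <- rbind(compendium$pvalue, summ$pvalue)
  deleted <- c(compendium$deleted_genes, setNames(list(del), double_id))
  out <- new_compendium(new_logfc, new_pvalue, deleted,
                        compendium$wt_profiles)
  list(
    compendium = out,
    double_truth = tibble::tibble(
      double_id = double_id, parent_a = parent_a, parent_b = parent_b,
      dominant = dominant, dominance = dominance,
      residual_genes = list(residual)
    )
  )
}

#' Simulate a glucose-addition time-course
#'
#' Models the wildtype transcriptional response after transferring
#' glucose-starved cells into glucose-rich medium: the signature half that
#' mimics high glucose (down in the low-glucose group by default) rises
#' along a saturating-exponential trajectory to `response_magnitude`, the
#' other half falls symmetrically, and background genes fluctuate around 0.
#'
#' @param config A [sim_config()]; `timepoints` and `timecourse_tau` set the
#'   sampling grid and kinetics.
#' @param truth `synthetic_truth` carrying the signature gene sets.
#' @param timepoints Sampling times in minutes (non-negative).
#' @param rising Which signature half rises upon glucose addition.
#' @param noise_sd Measurement noise sd; defaults to the config value.
#' @return A tibble with columns `time`, `gene`, `logfc`.
#' @export
simulate_timecourse <- function(config, truth,
                                timepoints = config$timepoints,
                                rising = c("down_in_low", "up_in_low"),
                                noise_sd = config$noise_sd) {
  rising <- match.arg(rising)
  if (length(timepoints) == 0 || any(timepoints < 0)) {
    stop("timepoints must be non-empty and non-negative", call. = FALSE)
  }
  genes <- colnames(truth$true_means)
  up_set <- if (rising == "down_in_low") truth$signature_down else truth$signature_up
  down_set <- setdiff(c(truth$signature_up, truth$signature_down), up_set)
  asym <- setNames(rep(0, length(genes)), genes)
  asym[up_set] <- config$response_magnitude
  asym[down_set] <- -config$response_magnitude
  with_seed(config$seed + 2L, {
    sat <- 1 - exp(-timepoints / config$timecourse_tau)
    profiles <- outer(sat, asym) +
      matrix(rnorm(length(timepoints) * length(genes), 0, noise_sd),
             length(timepoints), length(genes))
    tibble::tibble(
      time = rep(timepoints, times = length(genes)),
      gene = rep(genes, each = length(timepoints)),
      logfc = as.vector(profiles)
    )
  })
}
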