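#' Write a signature as a ranked TSV and a GMT gene-set file
#'
#' @param signature A `glucose_signature`.
#' @param path Output TSV path (columns `gene`, `direction`, rank order).
#' @param gmt_path Optional GMT path holding two sets, `up_in_low` and
#'   `down_in_low`.
#' @return Invisibly, `path`.
#' @export
write_signature <- function(signature, path, gmt_path = NULL) {
  sel <- dplyr::filter(signature$genes, .data$selected)
  readr::write_tsv(sel[, c("gene", "direction")], path, progress = FALSE)
  if (!is.null(gmt_path)) {
    up <- signature_genes(signature, "up_in_low")
    down <- signature_genes(signature, "down_in_low")
    lines <- c(
      paste(c("up_in_low", "glucose signature, up in low-glucose group", up),
            collapse = "\t"),
      paste(c("down_in_low", "glucose signature, down in low-glucose group",
              down), collapse = "\t")
    )
    writeLines(lines, gmt_path)
  }
  invisible(path)
}

#' Read a pipeline configuration
#'
#' A single YAML file mirrors the generator, DE, signature and network
#' parameter sets; unknown keys are rejected so typos fail loudly.
#'
#' @param path Path to a YAML config file.
#' @return A named list of configuration values.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("simulate", "de", "grouping", "signature", "network",
             "epistasis", "timecourse", "enrichment", "seed", "out_dir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg
}

#' Run the full compendium analysis pipeline
#'
#' Executes: simulate (optional) -> DE calling -> WT-likeness
#' classification -> two-group clustering -> signature construction ->
#' threshold calibration -> network reconstruction -> downstream ranking,
#' with optional epistasis, enrichment and time-course stages. Each stage's
#' parameters, seeds and outputs are recorded in a JSON run manifest so a
#' run can be reproduced byte-identically.
#'
#' @param config Named list (see [read_pipeline_config()]) or path to a
#'   YAML file. `config$simulate` holds [sim_config()] arguments; when
#'   absent, `compendium` must be supplied.
#' @param compendium Optional pre-built `glucose_compendium` (skips the
#'   simulate stage).
#' @param out_dir Output directory; overrides `config$out_dir`. When NULL,
#'   nothing is written.
#' @param seed Master seed; overrides `config$seed`.
#' @return A list with the stage results (`compendium`, `truth`, `decalls`,
#'   `wt_status`, `groups`, `eligible`, `signature`, `thresholds`,
#'   `network`, `ranking`, optional `timecourse`, plus `manifest`).
#' @export
run_pipeline <- function(config = list(), compendium = NULL, out_dir = NULL,
                         seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  seed <- seed %||% config$seed %||% 1L
  out_dir <- out_dir %||% config$out_dir
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("gluconet")),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, config = config, stages = list()
  )
  note <- function(name, params) {
    manifest$stages[[name]] <<- params
  }

  truth <- NULL
  if (is.null(compendium)) {
    sim_args <- config$simulate %||% list()
    sim_args$seed <- sim_args$seed %||% seed
    scfg <- stage("simulate", do.call(sim_config, sim_args))
    sim <- stage("simulate", simulate_compendium(scfg))
    compendium <- sim$compendium
    truth <- sim$truth
    note("simulate", scfg[setdiff(names(scfg), "planted_edges")])
  }

  de_cfg <- config$de %||% list()
  p_de <- de_cfg$p_threshold %||% 0.01
  fc_de <- de_cfg$fc_threshold %||% 1.7
  decalls <- stage("de_call", call_de(compendium, p_de, fc_de))

  wt_threshold <- de_cfg$wt_count_threshold
  if (is.null(wt_threshold)) {
    if (!is.null(compendium$wt_profiles) && !is.null(truth)) {
      counts <- stage("wt_threshold",
                      wt_de_counts(compendium$wt_profiles, truth$wt_pool,
                                   p_de, fc_de))
      wt_threshold <- calibrate_wt_threshold(counts)
    } else {
      wt_threshold <- 12
    }
  }
  wt_status <- stage("classify_wt", classify_wt_like(decalls, wt_threshold))
  responsive <- wt_status$mutant[wt_status$status == "responsive"]
  note("de_call", list(p_threshold = p_de, fc_threshold = fc_de,
                       wt_count_threshold = wt_threshold,
                       n_responsive = length(responsive)))

  g_cfg <- config$grouping %||% list()
  groups <- stage("grouping", cluster_two_groups(
    compendium, responsive, decalls = decalls,
    reference_up = g_cfg$reference_up,
    linkage = g_cfg$linkage %||% "average"
  ))

  s_cfg <- config$signature %||% list()
  s_cfg$seed <- s_cfg$seed %||% (seed + 1L)
  kcfg <- stage("signature", do.call(knn_config, s_cfg))
  eligible <- stage("signature",
                    eligible_mutants(decalls, groups,
                                     kcfg$min_de_transcripts))
  signature <- stage("signature",
                     build_signature(compendium, eligible, kcfg))
  note("signature", c(unclass(kcfg), list(n_eligible = nrow(eligible),
                                          N = signature$N)))

  n_cfg <- config$network %||% list()
  if (!is.null(n_cfg$lower) && !is.null(n_cfg$upper)) {
    thresholds <- fixed_thresholds(n_cfg$lower, n_cfg$upper)
  } else {
    thresholds <- stage("calibrate_thresholds", calibrate_thresholds(
      compendium, responsive,
      n_permutations = n_cfg$n_permutations %||% 1000,
      seed = n_cfg$seed %||% (seed + 2L),
      keep_background = FALSE
    ))
  }
  network <- stage("network", build_network(
    compendium, responsive, thresholds,
    p_threshold = n_cfg$p_threshold %||% 0.01,
    fc_threshold = n_cfg$fc_threshold %||% 1.5,
    method = n_cfg$method %||% "cosine"
  ))
  ranking <- stage("network", downstream_ranking(network))
  note("network", list(lower = thresholds$lower, upper = thresholds$upper,
                       n_permutations = thresholds$n_permutations,
                       seed = thresholds$seed,
                       n_edges = nrow(network$edges)))

  timecourse <- NULL
  tc_cfg <- config$timecourse %||% list()
  if (isTRUE(tc_cfg$run) && !is.null(truth)) {
    tc <- stage("timecourse", simulate_timecourse(truth$config, truth))
    timecourse <- stage("timecourse", timecourse_summary(
      tc, list(up_in_low = truth$signature_up,
               down_in_low = truth$signature_down)))
  }

  results <- list(compendium = compendium, truth = truth, decalls = decalls,
                  wt_status = wt_status, groups = groups,
                  eligible = eligible, signature = signature,
                  thresholds = thresholds, network = network,
                  ranking = ranking, timecourse = timecourse)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- write_compendium(compendium, out_dir)
    readr::write_tsv(wt_status, file.path(out_dir, "wt_status.tsv"),
                     progress = FALSE)
    readr::write_tsv(tibble::as_tibble(groups),
                     file.path(out_dir, "groups.tsv"), progress = FALSE)
    write_signature(signature, file.path(out_dir, "signature.tsv"),
                    gmt_path = file.path(out_dir, "signature.gmt"))
    write_network(network, file.path(out_dir, "network_edges.tsv"))
    readr::write_tsv(ranking, file.path(out_dir, "downstream_ranking.tsv"),
                     progress = FALSE)
    if (!is.null(truth)) {
      readr::write_tsv(truth$labels, file.path(out_dir, "truth_labels.tsv"),
                       progress = FALSE)
      readr::write_tsv(truth$planted_edges,
                       file.path(out_dir, "truth_edges.tsv"),
                       progress = FALSE)
    }
    files <- list.files(out_dir, full.names = TRUE, pattern = "\\.tsv$")
    manifest$outputs <- as.list(tools::md5sum(files))
    manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  }
  results$manifest <- manifest
  results
}
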