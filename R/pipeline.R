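#' Default pipeline configuration
#'
#' Returns the full stage-parameter tree with defaults; user configs
#' (R lists or YAML files) override leaves and may not introduce unknown
#' keys.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    simulate = list(
      n_genes = 2000L, n_cell_types = 8L, markers_per_type = 25L,
      hi_mean = 500, lo_mean = 5, fold_separation = 8,
      concentration = 5, noise_sigma = 0.15,
      n_samples_a = 150L, n_samples_b = 150L,
      overlap_fraction = 0.85, saturation_cap = 16000,
      perturbed_type = "type_8", concentration_multiplier = 10,
      n_cases = 30L, n_controls = 30L
    ),
    ingest = list(expression_threshold = 1),
    network = list(r_threshold_a = 0.70, r_threshold_b = 0.70,
                   log_transform = TRUE),
    cluster = list(inflation = 2.2, expansion = 2L, prune_threshold = 1e-5,
                   max_iterations = 100L, convergence_tol = 1e-6),
    derive = list(min_size = 5L, min_jaccard = 0.1, max_fdr = 0.01),
    score = list(pseudocount = 1),
    test = list(n_rotations = 999L, fdr_max = 0.01, concordance_min = 0.80)
  )
}

# Merge user config into defaults, rejecting unknown keys at every level.
merge_config <- function(user, defaults = default_config(), path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "), call. = FALSE)
  }
  for (key in names(user)) {
    defaults[[key]] <- if (is.list(defaults[[key]])) {
      merge_config(user[[key]], defaults[[key]], paste0(path, key, "."))
    } else {
      user[[key]]
    }
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Merges the user configuration over [default_config()] (rejecting unknown
#' keys) and checks stage parameters before anything runs (e.g. a
#' non-positive inflation is rejected here, not mid-pipeline).
#'
#' @param config nested list or path to a YAML file.
#' @return the merged, validated configuration.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(config)
  do.call(mcl_params, cfg$cluster)                 # errors on bad values
  rotation_config(cfg$test$n_rotations)
  stopifnot(cfg$network$r_threshold_a > 0, cfg$network$r_threshold_a <= 1,
            cfg$network$r_threshold_b > 0, cfg$network$r_threshold_b <= 1,
            cfg$simulate$overlap_fraction > 0, cfg$simulate$overlap_fraction <= 1)
  cfg
}

stage_state_path <- function(out_dir, stage) {
  file.path(out_dir, sprintf(".state_%s.rds", stage))
}

# Should this stage be skipped? Same params as last run and all recorded
# outputs still present with matching content hashes.
stage_is_current <- function(manifest, stage, params, out_dir) {
  rec <- manifest$stages[[stage]]
  if (is.null(rec)) return(FALSE)
  # compare in serialized form: the recorded params have been through a JSON
  # round-trip, which drops integer/double distinctions
  canon <- function(p) jsonlite::toJSON(p, auto_unbox = TRUE, digits = NA)
  if (!identical(canon(rec$params), canon(params))) return(FALSE)
  files <- c(unlist(rec$outputs_md5), use.names = TRUE)
  paths <- file.path(out_dir, names(files))
  if (!all(file.exists(paths))) return(FALSE)
  if (!file.exists(stage_state_path(out_dir, stage))) return(FALSE)
  all(unname(tools::md5sum(paths)) == unname(files))
}

record_stage <- function(manifest, stage, params, out_dir, files, skipped) {
  md5 <- tools::md5sum(file.path(out_dir, files))
  manifest$stages[[stage]] <- list(
    params = params,
    outputs_md5 = as.list(stats::setNames(unname(md5), files)),
    skipped = skipped
  )
  manifest
}

#' Run the full signature-derivation pipeline on a synthetic study
#'
#' Executes the stage sequence simulate -> ingest -> network -> cluster ->
#' derive -> score -> test from one configuration, writing every stage's
#' outputs plus a JSON run manifest (effective parameters, per-stage seeds,
#' output content hashes) to `out_dir`. A rerun with unchanged parameters
#' skips stages whose recorded outputs are intact (content-hash check). One
#' global seed deterministically derives a seed per stage, so stages are
#' reproducible independently.
#'
#' @param config nested list or YAML path; see [default_config()].
#' @param out_dir output directory.
#' @param seed optional override of `config$seed`.
#' @return invisibly, a list with the manifest and the key in-memory
#'   results (`catalog`, `lfc`, `tests`, `truth`).
#' @export
run_pipeline <- function(config = list(), out_dir, seed = NULL) {
  cfg <- validate_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  } else {
    list(stages = list())
  }
  manifest$package <- as.character(utils::packageVersion("sigweave"))
  manifest$seed <- cfg$seed
  if (is.null(manifest$stages)) manifest$stages <- list()

  run_stage <- function(stage, params, files, compute) {
    params <- c(params, list(stage_seed = derive_seed(cfg$seed, stage)))
    if (stage_is_current(manifest, stage, params, out_dir)) {
      message(sprintf("[%s] up to date, skipping", stage))
      manifest$stages[[stage]]$skipped <<- TRUE
      return(readRDS(stage_state_path(out_dir, stage)))
    }
    message(sprintf("[%s] running", stage))
    state <- tryCatch(
      compute(params$stage_seed),
      error = function(e) {
        stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
             call. = FALSE)
      }
    )
    saveRDS(state, stage_state_path(out_dir, stage))
    manifest <<- record_stage(manifest, stage, params, out_dir, files, FALSE)
    state
  }

  ## -- simulate ------------------------------------------------------------
  sp <- cfg$simulate
  sim_files <- c("platform_a_matrix.tsv", "platform_b_matrix.tsv",
                 "case_matrix.tsv", "control_matrix.tsv",
                 "true_markers.gmt", "proportions_a.tsv")
  sim <- run_stage("simulate", sp, sim_files, function(stage_seed) {
    profiles <- generate_profiles(
      sp$n_genes, sp$n_cell_types, sp$markers_per_type,
      hi_mean = sp$hi_mean, lo_mean = sp$lo_mean,
      fold_separation = sp$fold_separation, seed = derive_seed(stage_seed, "profiles")
    )
    conc <- stats::setNames(rep(sp$concentration, sp$n_cell_types),
                            profiles$cell_types)
    design_a <- mixture_design(sp$n_samples_a, conc,
                               noise_sigma = sp$noise_sigma,
                               platform = "seq-like",
                               seed = derive_seed(stage_seed, "cohort_a"))
    n_b <- round(sp$overlap_fraction * sp$n_genes)
    universe_b <- sort(withr::with_seed(
      derive_seed(stage_seed, "universe_b"),
      sample(profiles$genes, n_b)
    ))
    design_b <- mixture_design(sp$n_samples_b, conc,
                               noise_sigma = sp$noise_sigma,
                               platform = "array-like",
                               saturation_cap = sp$saturation_cap,
                               gene_universe = universe_b,
                               seed = derive_seed(stage_seed, "cohort_b"))
    cohort_a <- generate_cohort(profiles, design_a)
    cohort_b <- generate_cohort(profiles, design_b)
    pair <- generate_condition_pair(
      profiles, design_a, sp$perturbed_type, sp$concentration_multiplier,
      sp$n_cases, sp$n_controls, seed = derive_seed(stage_seed, "pair")
    )
    write_matrix(cohort_a$matrix, file.path(out_dir, "platform_a_matrix.tsv"))
    write_matrix(cohort_b$matrix, file.path(out_dir, "platform_b_matrix.tsv"))
    write_matrix(pair$cases, file.path(out_dir, "case_matrix.tsv"))
    write_matrix(pair$controls, file.path(out_dir, "control_matrix.tsv"))
    write_gmt(profiles$marker_map, file.path(out_dir, "true_markers.gmt"))
    pr <- data.frame(sample_id = rownames(cohort_a$truth$proportions),
                     cohort_a$truth$proportions, check.names = FALSE)
    utils::write.table(pr, file.path(out_dir, "proportions_a.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(profiles = profiles, cohort_a = cohort_a, cohort_b = cohort_b,
         pair = pair)
  })

  ## -- ingest --------------------------------------------------------------
  ing_files <- c("filtered_a_matrix.tsv", "filtered_b_matrix.tsv")
  ing <- run_stage("ingest", cfg$ingest, ing_files, function(stage_seed) {
    fa <- filter_expressed(sim$cohort_a$matrix, cfg$ingest$expression_threshold)
    fb <- filter_expressed(sim$cohort_b$matrix, cfg$ingest$expression_threshold)
    both <- intersect_genes(fa, fb)
    write_matrix(both$a, file.path(out_dir, "filtered_a_matrix.tsv"))
    write_matrix(both$b, file.path(out_dir, "filtered_b_matrix.tsv"))
    both
  })

  ## -- network -------------------------------------------------------------
  net_files <- c("edges_a.tsv", "edges_b.tsv")
  net <- run_stage("network", cfg$network, net_files, function(stage_seed) {
    ga <- correlation_graph(ing$a, cfg$network$r_threshold_a,
                            log_transform = cfg$network$log_transform)
    gb <- correlation_graph(ing$b, cfg$network$r_threshold_b,
                            log_transform = cfg$network$log_transform)
    write_graph_file(ga, file.path(out_dir, "edges_a.tsv"))
    write_graph_file(gb, file.path(out_dir, "edges_b.tsv"))
    list(a = ga, b = gb)
  })

  ## -- cluster -------------------------------------------------------------
  clu_files <- c("clusters_a.tsv", "clusters_b.tsv")
  clu <- run_stage("cluster", cfg$cluster, clu_files, function(stage_seed) {
    params <- do.call(mcl_params, cfg$cluster)
    ca <- mcl_cluster(net$a, params)
    cb <- mcl_cluster(net$b, params)
    write_clusters(ca, file.path(out_dir, "clusters_a.tsv"))
    write_clusters(cb, file.path(out_dir, "clusters_b.tsv"))
    list(a = ca, b = cb)
  })

  ## -- derive --------------------------------------------------------------
  der_files <- c("catalog.gmt", "overlap_table.tsv")
  catalog <- run_stage("derive", cfg$derive, der_files, function(stage_seed) {
    universe <- em_genes(ing$a)
    matches <- match_clusters(clu$a, clu$b, universe,
                              min_size = cfg$derive$min_size,
                              min_jaccard = cfg$derive$min_jaccard,
                              max_fdr = cfg$derive$max_fdr)
    cat <- derive_catalog(matches, clu$a, clu$b)
    write_catalog(cat, file.path(out_dir, "catalog.gmt"))
    ot <- overlap_table(cat)
    utils::write.table(ot$rows, file.path(out_dir, "overlap_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cat
  })

  ## -- score ---------------------------------------------------------------
  case_ids <- em_samples(sim$pair$cases)
  ctrl_ids <- em_samples(sim$pair$controls)
  combined <- expression_matrix(
    cbind(sim$pair$cases$values, sim$pair$controls$values),
    platform = sim$pair$cases$platform, scale = "linear"
  )
  sco_files <- c("scores.tsv", "lfc.tsv")
  lfc <- run_stage("score", cfg$score, sco_files, function(stage_seed) {
    scores <- signature_scores(combined, catalog,
                               pseudocount = cfg$score$pseudocount)
    lfc <- lfc_table(scores, list(
      condition_vs_control = list(test = case_ids, control = ctrl_ids)
    ))
    utils::write.table(
      data.frame(signature = rownames(scores), unclass(scores),
                 check.names = FALSE),
      file.path(out_dir, "scores.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE
    )
    utils::write.table(
      data.frame(signature = rownames(lfc), unclass(lfc), check.names = FALSE),
      file.path(out_dir, "lfc.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE
    )
    lfc
  })

  ## -- test ----------------------------------------------------------------
  tst_files <- "set_tests.tsv"
  tests <- run_stage("test", cfg$test, tst_files, function(stage_seed) {
    res <- set_test_all(
      combined, catalog, case_ids, ctrl_ids,
      cfg = rotation_config(cfg$test$n_rotations, seed = stage_seed),
      comparison = "condition_vs_control",
      pseudocount = cfg$score$pseudocount,
      fdr_max = cfg$test$fdr_max, concordance_min = cfg$test$concordance_min
    )
    utils::write.table(res, file.path(out_dir, "set_tests.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    res
  })

  manifest$config <- cfg
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(list(manifest = manifest, catalog = catalog, lfc = lfc,
                 tests = tests, truth = sim$cohort_a$truth,
                 pair_truth = sim$pair$truth))
}
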