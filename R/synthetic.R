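#' Synthetic cell-type expression profiles
#'
#' Builds a set of cell-type base-expression profiles with designated,
#' disjoint marker genes per type. A marker is expressed at `hi_mean` in its
#' own type and `lo_mean` in every other type, so its bulk abundance tracks
#' its cell type's mixing proportion — the premise that makes same-type
#' markers co-expressed across bulk mixtures. Non-marker ("housekeeping")
#' genes get one shared mean per gene (log-uniform between `lo_mean` and
#' `hi_mean`) with a small fixed per-type multiplicative jitter
#' (`exp(N(0, 0.05))`), so they correlate strongly with nothing.
#'
#' @param n_genes total number of genes.
#' @param n_cell_types number of cell types.
#' @param markers_per_type markers designated per type;
#'   `markers_per_type * n_cell_types` must not exceed `n_genes`.
#' @param hi_mean marker mean in its own type (linear scale).
#' @param lo_mean marker mean in every other type.
#' @param fold_separation required minimum ratio `hi_mean / lo_mean`
#'   (equality accepted).
#' @param cell_type_names optional labels (default `type_1`, ...).
#' @param seed integer seed; identical seeds give identical profile sets.
#' @return An object of class `CellTypeProfileSet`: list with `cell_types`,
#'   `genes`, `base_expression` (cell types x genes matrix), `marker_map`
#'   (named list: type -> marker gene IDs).
#' @export
generate_profiles <- function(n_genes, n_cell_types, markers_per_type,
                              hi_mean = 500, lo_mean = 5, fold_separation = 8,
                              cell_type_names = NULL, seed = 1) {
  if (markers_per_type * n_cell_types > n_genes) {
    stop("infeasible marker budget: markers_per_type * n_cell_types > n_genes",
         call. = FALSE)
  }
  if (hi_mean < fold_separation * lo_mean) {
    stop("hi_mean must be >= fold_separation * lo_mean", call. = FALSE)
  }
  if (is.null(cell_type_names)) {
    cell_type_names <- sprintf("type_%d", seq_len(n_cell_types))
  }
  stopifnot(length(cell_type_names) == n_cell_types)
  genes <- sprintf("gene_%05d", seq_len(n_genes))
  n_markers <- markers_per_type * n_cell_types
  marker_map <- split(
    genes[seq_len(n_markers)],
    rep(cell_type_names, each = markers_per_type)
  )[cell_type_names]
  hk <- genes[setdiff(seq_len(n_genes), seq_len(n_markers))]

  base <- matrix(lo_mean, nrow = n_cell_types, ncol = n_genes,
                 dimnames = list(cell_type_names, genes))
  for (ct in cell_type_names) base[ct, marker_map[[ct]]] <- hi_mean
  if (length(hk)) {
    withr::with_seed(seed, {
      hk_mean <- exp(stats::runif(length(hk), log(lo_mean), log(hi_mean)))
      jitter <- matrix(exp(stats::rnorm(n_cell_types * length(hk), 0, 0.05)),
                       nrow = n_cell_types)
      base[, hk] <- sweep(jitter, 2, hk_mean, `*`)
    })
  }
  structure(
    list(cell_types = cell_type_names, genes = genes,
         base_expression = base, marker_map = marker_map),
    class = "CellTypeProfileSet"
  )
}

#' Mixture design for one synthetic cohort
#'
#' Describes how bulk samples are composed: per-sample cell-type proportions
#' are drawn from a Dirichlet law (a concentration of exactly 0 means the
#' type is absent), each (gene, sample) value gets multiplicative log-normal
#' noise `exp(N(0, noise_sigma))`, and array-like platforms clip the signal
#' at `saturation_cap` (emulating probe saturation of high intensities).
#'
#' @param n_samples number of samples.
#' @param proportion_concentration named nonnegative Dirichlet concentrations,
#'   one per cell type; at least one must be positive.
#' @param noise_sigma SD of the log-normal noise on the natural-log scale.
#' @param platform `"seq-like"` or `"array-like"`.
#' @param saturation_cap positive ceiling, used only for `"array-like"`.
#' @param gene_universe genes observed on this platform (`NULL` = all).
#' @param seed integer seed.
#' @return An object of class `MixtureDesign`.
#' @export
mixture_design <- function(n_samples, proportion_concentration,
                           noise_sigma = 0.15,
                           platform = c("seq-like", "array-like"),
                           saturation_cap = 16000, gene_universe = NULL,
                           seed = 1) {
  platform <- match.arg(platform)
  if (is.null(names(proportion_concentration))) {
    stop("proportion_concentration must be named by cell type", call. = FALSE)
  }
  if (any(proportion_concentration < 0) || all(proportion_concentration == 0)) {
    stop("concentrations must be nonnegative with at least one positive",
         call. = FALSE)
  }
  if (platform == "array-like" && (!is.numeric(saturation_cap) || saturation_cap <= 0)) {
    stop("saturation_cap must be > 0 for array-like platforms", call. = FALSE)
  }
  structure(
    list(n_samples = as.integer(n_samples),
         proportion_concentration = proportion_concentration,
         noise_sigma = noise_sigma, platform = platform,
         saturation_cap = saturation_cap, gene_universe = gene_universe,
         seed = seed),
    class = "MixtureDesign"
  )
}

# Dirichlet draws; zero concentrations yield exactly-zero proportions.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(0, nrow = n, ncol = k)
  pos <- which(alpha > 0)
  g[, pos] <- matrix(stats::rgamma(n * length(pos), shape = rep(alpha[pos], each = n)),
                     nrow = n)
  g / rowSums(g)
}

#' Generate one synthetic bulk cohort
#'
#' Each sample's linear expression is the convex combination of the cell-type
#' profiles under its drawn proportions, times per-(gene, sample) log-normal
#' noise; array-like platforms then clip at the saturation cap; the matrix is
#' restricted to the design's gene universe.
#'
#' @param profiles a [generate_profiles()] result.
#' @param design a [mixture_design()]; its concentrations must be named by
#'   `profiles$cell_types` and its gene universe contained in
#'   `profiles$genes`.
#' @return list with `matrix` (an [expression_matrix()]) and `truth` (class
#'   `GroundTruth`: `marker_map`, `proportions` samples x cell types,
#'   `perturbed_types`).
#' @export
generate_cohort <- function(profiles, design) {
  stopifnot(inherits(profiles, "CellTypeProfileSet"),
            inherits(design, "MixtureDesign"))
  alpha <- design$proportion_concentration
  if (!setequal(names(alpha), profiles$cell_types)) {
    stop("concentration names must match profile cell types", call. = FALSE)
  }
  alpha <- alpha[profiles$cell_types]
  universe <- design$gene_universe %||% profiles$genes
  if (length(universe) == 0L) stop("empty gene_universe", call. = FALSE)
  if (!all(universe %in% profiles$genes)) {
    stop("gene_universe must be a subset of profile genes", call. = FALSE)
  }
  withr::with_seed(design$seed, {
    p <- rdirichlet(design$n_samples, alpha)
    signal <- profiles$base_expression  # cell types x genes
    x <- t(p %*% signal)                # genes x samples
    if (design$noise_sigma > 0) {
      x <- x * exp(matrix(stats::rnorm(length(x), 0, design$noise_sigma),
                          nrow = nrow(x)))
    }
  })
  if (design$platform == "array-like") {
    x <- pmin(x, design$saturation_cap)
  }
  dimnames(x) <- list(profiles$genes,
                      sprintf("%s_s%03d", design$platform, seq_len(design$n_samples)))
  dimnames(p) <- list(colnames(x), profiles$cell_types)
  stopifnot(max(abs(rowSums(p) - 1)) < 1e-9)
  x <- x[universe, , drop = FALSE]
  list(
    matrix = expression_matrix(x, platform = design$platform, scale = "linear"),
    truth = structure(
      list(marker_map = profiles$marker_map, proportions = p,
           perturbed_types = character()),
      class = "GroundTruth"
    )
  )
}

#' Generate a case/control cohort pair with one inflated cell type
#'
#' Controls follow `design`; cases are drawn with the perturbed type's
#' Dirichlet concentration multiplied by `concentration_multiplier`, which
#' raises its expected proportion and dilutes every other type — the bulk
#' "influx" phenomenon in which resident-cell signatures appear
#' down-regulated simply because another population expands.
#'
#' @param profiles a [generate_profiles()] result.
#' @param design a [mixture_design()]; `n_samples` is ignored in favour of
#'   `n_cases` / `n_controls`.
#' @param perturbed_type cell-type label to inflate.
#' @param concentration_multiplier positive factor on that type's
#'   concentration.
#' @param n_cases,n_controls cohort sizes.
#' @param seed integer seed.
#' @return list with `cases`, `controls` (each an [expression_matrix()]) and
#'   `truth` (proportions of both cohorts stacked; `perturbed_types` set).
#' @export
generate_condition_pair <- function(profiles, design, perturbed_type,
                                    concentration_multiplier, n_cases,
                                    n_controls, seed = 1) {
  if (!perturbed_type %in% profiles$cell_types) {
    stop("unknown cell type label: ", perturbed_type, call. = FALSE)
  }
  if (concentration_multiplier <= 0) {
    stop("concentration_multiplier must be > 0", call. = FALSE)
  }
  ctrl_design <- design
  ctrl_design$n_samples <- as.integer(n_controls)
  ctrl_design$seed <- derive_seed(seed, "controls")
  case_design <- ctrl_design
  case_design$n_samples <- as.integer(n_cases)
  case_design$seed <- derive_seed(seed, "cases")
  case_design$proportion_concentration[perturbed_type] <-
    case_design$proportion_concentration[perturbed_type] * concentration_multiplier

  ctrl <- generate_cohort(profiles, ctrl_design)
  cases <- generate_cohort(profiles, case_design)
  rename <- function(em, prefix) {
    colnames(em$values) <- paste0(prefix, "_", colnames(em$values))
    em
  }
  cm <- rename(cases$matrix, "case")
  km <- rename(ctrl$matrix, "ctrl")
  prop <- rbind(cases$truth$proportions, ctrl$truth$proportions)
  rownames(prop) <- c(colnames(cm$values), colnames(km$values))
  list(
    cases = cm, controls = km,
    truth = structure(
      list(marker_map = profiles$marker_map, proportions = prop,
           perturbed_types = perturbed_type),
      class = "GroundTruth"
    )
  )
}

#' Write a synthetic cohort to disk
#'
#' Matrix as TSV (genes as rows), marker ground truth as GMT, proportions as
#' TSV.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    matrix = file.path(dir, paste0(prefix, "_matrix.tsv")),
    markers = file.path(dir, paste0(prefix, "_markers.gmt")),
    proportions = file.path(dir, paste0(prefix, "_proportions.tsv"))
  )
  write_matrix(cohort$matrix, paths[["matrix"]])
  write_gmt(cohort$truth$marker_map, paths[["markers"]])
  pr <- data.frame(sample_id = rownames(cohort$truth$proportions),
                   cohort$truth$proportions, check.names = FALSE)
  utils::write.table(pr, paths[["proportions"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
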