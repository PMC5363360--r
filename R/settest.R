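#' Rotation-test configuration
#'
#' @param n_rotations number of random rotations (>= 99); rotations are
#'   drawn in antithetic +/- pairs, so odd values are rounded up to the next
#'   even number. The default 9999 (i.e. 10000) puts the p-value floor at
#'   1e-4, well under the 0.01 FDR threshold used by the significance rule.
#' @param seed integer seed for the rotations.
#' @param variance_shrinkage `"pooled"` shrinks each gene's residual
#'   variance toward the mean residual variance across all genes of the
#'   matrix with prior weight `prior_df` (a moderated-t-style stabilizer at
#'   small n); `"none"` uses the ordinary pooled two-sample variance.
#' @param prior_df prior weight of the shrinkage target, in residual-df
#'   units.
#' @return an object of class `RotationConfig`.
#' @export
rotation_config <- function(n_rotations = 9999L, seed = 1L,
                            variance_shrinkage = c("pooled", "none"),
                            prior_df = 4) {
  variance_shrinkage <- match.arg(variance_shrinkage)
  if (n_rotations < 99) stop("n_rotations must be >= 99", call. = FALSE)
  structure(
    list(n_rotations = as.integer(n_rotations), seed = as.integer(seed),
         variance_shrinkage = variance_shrinkage, prior_df = prior_df),
    class = "RotationConfig"
  )
}

# Two-group design pieces shared by per_gene_stats and rotation_test.
# Samples are put in canonical (sorted-ID) order and the orthonormal basis of
# the effect + residual space is built from a label-free indicator (the group
# containing the first canonical sample), so that exchanging the test and
# control labels leaves the basis — and hence the rotation null — numerically
# identical and only flips the sign of the effect coordinate. This makes the
# exchange symmetry p_up <-> p_down exact, not just distributional.
two_group_design <- function(control_ids, test_ids) {
  ids <- sort(c(control_ids, test_ids))
  n <- length(ids)
  g0 <- as.numeric(ids %in% (if (ids[1L] %in% test_ids) test_ids else control_ids))
  Q <- qr.Q(qr(cbind(rep(1, n), g0)), complete = TRUE)
  B <- Q[, -1L, drop = FALSE]          # n x (n - 1): effect + residual space
  if (sum(B[, 1L] * g0) < 0) B[, 1L] <- -B[, 1L]
  list(ids = ids, n = n, d = n - 2L, B = B,
       sign_test = if (ids[1L] %in% test_ids) 1 else -1)
}

shrink_s2 <- function(s2, cfg, d, s2_bar) {
  if (cfg$variance_shrinkage == "none") return(s2)
  (cfg$prior_df * s2_bar + d * s2) / (cfg$prior_df + d)
}

#' Per-gene two-group statistics
#'
#' For every gene: log2 fold change (test mean minus control mean) and a
#' pooled-variance t statistic; under `variance_shrinkage = "pooled"` the
#' per-gene variance is shrunk toward the across-gene mean variance with the
#' configured prior weight (with `"none"` the statistic is exactly the
#' classical pooled two-sample t).
#'
#' @param m an [expression_matrix()]; linear input is log2(x + pseudocount)
#'   transformed.
#' @param test_samples,control_samples disjoint sample groups, each of size
#'   >= 2 (the within-group variance is undefined otherwise).
#' @param cfg a [rotation_config()].
#' @param pseudocount for the log2 transform of linear input.
#' @return data.frame with columns `gene`, `lfc`, `t`, `s2` (residual
#'   variance before shrinkage), plus attribute `s2_bar`.
#' @export
per_gene_stats <- function(m, test_samples, control_samples,
                           cfg = rotation_config(), pseudocount = 1) {
  if (length(test_samples) < 2 || length(control_samples) < 2) {
    stop("each group needs >= 2 samples", call. = FALSE)
  }
  if (length(intersect(test_samples, control_samples))) {
    stop("groups must be disjoint", call. = FALSE)
  }
  lx <- em_log2_values(m, pseudocount)
  dsg <- two_group_design(control_samples, test_samples)
  Y <- t(lx[, dsg$ids, drop = FALSE])                 # n x G, canonical order
  e <- dsg$sign_test * drop(crossprod(dsg$B[, 1L], Y))  # effect coordinates
  total <- colSums(sweep(Y, 2L, colMeans(Y))^2)       # SS after intercept
  rss <- pmax(total - e^2, 0)
  s2 <- rss / dsg$d
  s2_bar <- mean(s2)
  t_stat <- e / sqrt(pmax(shrink_s2(s2, cfg, dsg$d, s2_bar), .Machine$double.eps))
  lfc <- colMeans(Y[dsg$ids %in% test_samples, , drop = FALSE]) -
    colMeans(Y[dsg$ids %in% control_samples, , drop = FALSE])
  out <- data.frame(gene = colnames(Y), lfc = lfc, t = t_stat, s2 = s2,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "s2_bar") <- s2_bar
  out
}

#' Rotation gene-set test for one signature
#'
#' Self-contained test of coordinated differential expression: the set
#' statistic is the unweighted mean of the per-gene moderated t statistics
#' over the set, and its null distribution is generated by random rotations.
#' Each rotation draws a random unit direction in the (effect + residual)
#' space of the two-group design — dimension n - 1 — projects every set
#' gene's data onto it to obtain a rotated effect coordinate, recomputes the
#' residual variance from what remains, and recomputes the set statistic.
#' `p_up = (1 + #{null >= observed}) / (n_rotations + 1)` (so p-values are
#' never exactly 0), `p_down` symmetrically, and
#' `p_two_sided = min(1, 2 min(p_up, p_down))`. Direction concordance is the
#' fraction of set genes whose observed log fold change carries the majority
#' sign (exact zeros count in neither direction; an exact half-half tie
#' reports direction `"up"` with concordance 0.5).
#'
#' @inheritParams per_gene_stats
#' @param gene_set character vector; at least 2 of its genes must be present
#'   in `m`.
#' @param label optional signature/comparison label stored on the result.
#' @return An object of class `SetTestResult`: list with `signature`,
#'   `n_genes`, `set_stat`, `p_up`, `p_down`, `p_two_sided`, `fdr` (NA until
#'   adjusted across a family), `frac_concordant`, `direction`,
#'   `significant` (NA until called), `mean_lfc`.
#' @export
rotation_test <- function(m, test_samples, control_samples, gene_set,
                          cfg = rotation_config(), pseudocount = 1,
                          label = NA_character_) {
  n <- length(test_samples) + length(control_samples)
  if (n <= 2) stop("degenerate residual space: need n_test + n_control > 2",
                   call. = FALSE)
  stats_all <- per_gene_stats(m, test_samples, control_samples, cfg,
                              pseudocount)
  set <- intersect(gene_set, stats_all$gene)
  if (length(set) < 2) {
    stop("need >= 2 set genes present in the matrix", call. = FALSE)
  }
  s2_bar <- attr(stats_all, "s2_bar")
  rows <- match(set, stats_all$gene)
  obs_stat <- mean(stats_all$t[rows])

  # coordinates of the set genes in effect + residual space (canonical basis)
  lx <- em_log2_values(m, pseudocount)
  dsg <- two_group_design(control_samples, test_samples)
  Y <- t(lx[set, dsg$ids, drop = FALSE])       # n x S
  Z <- crossprod(dsg$B, Y)                     # (n - 1) x S
  total <- colSums(Z^2)
  d <- dsg$d

  # rotations come in antithetic +/- pairs, making the null set exactly
  # symmetric under negation (and the exchange symmetry p_up <-> p_down
  # exact); odd rotation counts are rounded up to the next even number
  n_rot <- 2L * ((cfg$n_rotations + 1L) %/% 2L)
  m_pairs <- n_rot %/% 2L
  null_stats <- numeric(n_rot)
  withr::with_seed(cfg$seed, {
    done <- 0L
    while (done < m_pairs) {
      b <- min(2000L, m_pairs - done)
      R <- matrix(stats::rnorm(b * (n - 1L)), nrow = b)
      R <- R / sqrt(rowSums(R^2))
      E <- R %*% Z                                        # b x S
      rss <- pmax(sweep(-E^2, 2L, total, `+`), 0)
      s2r <- shrink_s2(rss / d, cfg, d, s2_bar)
      stat_plus <- rowMeans(E / sqrt(pmax(s2r, .Machine$double.eps)))
      null_stats[2L * done + seq_len(2L * b)] <- c(stat_plus, -stat_plus)
      done <- done + b
    }
  })
  p_up <- (1 + sum(null_stats >= obs_stat)) / (n_rot + 1)
  p_down <- (1 + sum(null_stats <= obs_stat)) / (n_rot + 1)

  sgn <- sign(stats_all$lfc[rows])
  n_up <- sum(sgn > 0)
  n_down <- sum(sgn < 0)
  structure(
    list(
      signature = label, n_genes = length(set), set_stat = obs_stat,
      p_up = p_up, p_down = p_down,
      p_two_sided = min(1, 2 * min(p_up, p_down)), fdr = NA_real_,
      frac_concordant = max(n_up, n_down) / length(set),
      direction = if (n_up >= n_down) "up" else "down",
      significant = NA, mean_lfc = mean(stats_all$lfc[rows])
    ),
    class = "SetTestResult"
  )
}

#' @export
print.SetTestResult <- function(x, ...) {
  cat(sprintf(
    "SetTestResult%s: %d genes, p_two_sided=%.3g, %s, concordance=%.2f\n",
    if (is.na(x$signature)) "" else paste0(" [", x$signature, "]"),
    x$n_genes, x$p_two_sided, x$direction, x$frac_concordant
  ))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment (via [stats::p.adjust()]) with input
#' validation: p-values must lie in (0, 1].
#'
#' @param p_values numeric vector in (0, 1].
#' @return adjusted values in input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values <= 0) || any(p_values > 1) || anyNA(p_values)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Two-part significance rule
#'
#' A signature is called significantly altered in a comparison when its FDR
#' is at most `fdr_max` AND at least `concordance_min` of its genes changed
#' in the same direction — both bounds inclusive. The concordance condition
#' deliberately withholds significance from sets whose mean shifts on the
#' strength of a minority of genes.
#'
#' @param fdr adjusted p-value(s), or a `SetTestResult` with `fdr` filled.
#' @param frac_concordant direction-concordance fraction(s); ignored when
#'   `fdr` is a `SetTestResult`.
#' @param fdr_max,concordance_min inclusive thresholds (defaults 0.01 and
#'   0.80).
#' @return logical vector.
#' @export
significance_call <- function(fdr, frac_concordant = NULL, fdr_max = 0.01,
                              concordance_min = 0.80) {
  if (inherits(fdr, "SetTestResult")) {
    if (is.na(fdr$fdr)) stop("fdr not populated on SetTestResult", call. = FALSE)
    frac_concordant <- fdr$frac_concordant
    fdr <- fdr$fdr
  }
  fdr <= fdr_max & frac_concordant >= concordance_min
}

#' Test every signature of a catalog in one comparison
#'
#' Runs [rotation_test()] per signature (each with a seed derived from the
#' configuration seed and the signature name), adjusts the two-sided
#' p-values by BH across the signature family within this comparison, and
#' applies the two-part significance rule.
#'
#' @inheritParams rotation_test
#' @param signatures a `SignatureCatalog` or named list of gene sets; sets
#'   with fewer than 2 genes present are skipped with a message.
#' @param comparison label recorded on every row.
#' @param fdr_max,concordance_min thresholds for [significance_call()].
#' @return data.frame with one row per tested signature: `comparison`,
#'   `signature`, `n_genes`, `mean_lfc`, `p_up`, `p_down`, `p_two_sided`,
#'   `fdr`, `frac_concordant`, `direction`, `significant`.
#' @export
set_test_all <- function(m, signatures, test_samples, control_samples,
                         cfg = rotation_config(), comparison = "comparison",
                         pseudocount = 1, fdr_max = 0.01,
                         concordance_min = 0.80) {
  sets <- if (inherits(signatures, "SignatureCatalog")) {
    catalog_sets(signatures)
  } else {
    signatures
  }
  usable <- vapply(sets, function(s) {
    sum(s %in% em_genes(m)) >= 2
  }, logical(1))
  if (any(!usable)) {
    message("set_test_all: skipping ", sum(!usable),
            " signature(s) with < 2 genes present")
  }
  sets <- sets[usable]
  rows <- lapply(names(sets), function(nm) {
    cfg_i <- cfg
    cfg_i$seed <- derive_seed(cfg$seed, nm)
    r <- rotation_test(m, test_samples, control_samples, sets[[nm]],
                       cfg = cfg_i, pseudocount = pseudocount, label = nm)
    data.frame(comparison = comparison, signature = nm, n_genes = r$n_genes,
               mean_lfc = r$mean_lfc, p_up = r$p_up, p_down = r$p_down,
               p_two_sided = r$p_two_sided, frac_concordant = r$frac_concordant,
               direction = r$direction, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p_two_sided)
  out$significant <- significance_call(out$fdr, out$frac_concordant,
                                       fdr_max, concordance_min)
  out[, c("comparison", "signature", "n_genes", "mean_lfc", "p_up", "p_down",
          "p_two_sided", "fdr", "frac_concordant", "direction", "significant")]
}
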