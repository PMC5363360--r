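#' All-pairs gene-gene Pearson correlations (condensed storage)
#'
#' Computes one Pearson r per unordered gene pair, stored as the condensed
#' upper triangle keyed by sorted gene order, so memory stays at
#' `n(n-1)/2` doubles; the crossproduct is evaluated in row blocks so peak
#' memory is bounded for large gene sets. Linear-scale input is log2(x + 1)
#' transformed by default (expression correlation is conventionally assessed
#' on the log scale). Constant-valued genes, whose correlation is undefined,
#' are excluded with a message and recorded on the result.
#'
#' @param m an [expression_matrix()] with at least 3 samples.
#' @param log_transform apply log2(x + 1) when `m$scale == "linear"`.
#' @param block_size rows per block of the chunked crossproduct.
#' @return An object of class `condensed_cor`: list with `r` (numeric vector,
#'   length `choose(n, 2)`, pair (i, j) of the sorted `gene_ids` at condensed
#'   index), `gene_ids` (sorted), `n_samples`, `excluded_constant`.
#' @export
pairwise_pearson <- function(m, log_transform = TRUE, block_size = 1024L) {
  x <- if (log_transform && m$scale == "linear") log2(m$values + 1) else m$values
  if (ncol(x) < 3L) stop("need at least 3 samples for gene correlations", call. = FALSE)
  x <- x[order(rownames(x)), , drop = FALSE]
  ctr <- x - rowMeans(x)
  ss <- rowSums(ctr^2)
  constant <- ss == 0
  excluded <- rownames(x)[constant]
  if (length(excluded)) {
    message(sprintf("pairwise_pearson: excluding %d constant gene(s)",
                    length(excluded)))
  }
  z <- ctr[!constant, , drop = FALSE] / sqrt(ss[!constant])
  n <- nrow(z)
  if (n < 2L) stop("fewer than 2 non-constant genes", call. = FALSE)
  r <- numeric(n * (n - 1) / 2)
  starts <- seq(1L, n, by = block_size)
  for (bi in starts) {
    i_idx <- bi:min(bi + block_size - 1L, n)
    block <- z[i_idx, , drop = FALSE] %*% t(z[min(i_idx):n, , drop = FALSE])
    for (k in seq_along(i_idx)) {
      i <- i_idx[k]
      if (i < n) {
        r[pair_index(i, (i + 1L):n, n)] <- block[k, (i - min(i_idx) + 2L):ncol(block)]
      }
    }
  }
  r <- pmin(1, pmax(-1, r))
  # correlations within 1e-12 of +/-1 are numerically indistinguishable from
  # exact collinearity; snap them so inclusive thresholds at 1 behave
  r[r >= 1 - 1e-12] <- 1
  r[r <= -1 + 1e-12] <- -1
  structure(
    list(r = r, gene_ids = rownames(z), n_samples = ncol(x),
         excluded_constant = excluded),
    class = "condensed_cor"
  )
}

#' @export
print.condensed_cor <- function(x, ...) {
  cat(sprintf("condensed_cor: %d genes, %d pairs (%d samples)\n",
              length(x$gene_ids), length(x$r), x$n_samples))
  invisible(x)
}

#' Threshold correlations into a co-expression graph
#'
#' Keeps exactly the pairs with `r >= r_threshold` (inclusive, matching the
#' usual "r >= t" network notation); genes left without any retained edge are
#' dropped from the node set.
#'
#' @param correlations a [pairwise_pearson()] result.
#' @param r_threshold Pearson cutoff in (0, 1].
#' @return An object of class `CorrelationGraph`: list with `edges`
#'   (data.frame `gene_a`, `gene_b`, `r`; `gene_a < gene_b`), `nodes`,
#'   `threshold`.
#' @export
build_graph <- function(correlations, r_threshold) {
  stopifnot(inherits(correlations, "condensed_cor"))
  if (r_threshold <= 0 || r_threshold > 1) {
    stop("r_threshold must be in (0, 1]", call. = FALSE)
  }
  ids <- correlations$gene_ids
  n <- length(ids)
  keep <- which(correlations$r >= r_threshold)
  # invert condensed index -> (i, j)
  if (length(keep)) {
    k <- keep - 1
    i <- floor((2 * n - 1 - sqrt((2 * n - 1)^2 - 8 * k)) / 2) + 1
    base <- (i - 1) * n - i * (i - 1) / 2
    j <- keep - base + i
    edges <- data.frame(gene_a = ids[i], gene_b = ids[j],
                        r = correlations$r[keep], stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        r = numeric(), stringsAsFactors = FALSE)
  }
  structure(
    list(edges = edges, nodes = sort(unique(c(edges$gene_a, edges$gene_b))),
         threshold = r_threshold),
    class = "CorrelationGraph"
  )
}

#' @export
print.CorrelationGraph <- function(x, ...) {
  cat(sprintf("CorrelationGraph: %d nodes, %d edges (r >= %g)\n",
              length(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Construct a correlation graph directly from an expression matrix
#'
#' Convenience composition of [pairwise_pearson()] and [build_graph()].
#'
#' @inheritParams pairwise_pearson
#' @inheritParams build_graph
#' @return a `CorrelationGraph`.
#' @export
correlation_graph <- function(m, r_threshold, log_transform = TRUE) {
  build_graph(pairwise_pearson(m, log_transform = log_transform), r_threshold)
}

#' Null edge report constructor
#'
#' Bookkeeping for the permutation null: exact pair count
#' `choose(n_genes, 2)` and edge frequencies `edges / n_pairs`.
#'
#' @param n_genes number of genes correlated.
#' @param observed_edges edges at the threshold in the observed data.
#' @param null_edges edges at the threshold after per-gene permutation.
#' @param r_threshold the Pearson cutoff used.
#' @param seed permutation seed (NA when constructed from counts).
#' @return An object of class `NullEdgeReport`.
#' @export
null_edge_report <- function(n_genes, observed_edges, null_edges,
                             r_threshold = NA_real_, seed = NA_integer_) {
  n_pairs <- as.numeric(n_genes) * (as.numeric(n_genes) - 1) / 2
  structure(
    list(n_genes = as.numeric(n_genes), n_pairs = n_pairs,
         observed_edges = as.numeric(observed_edges),
         null_edges = as.numeric(null_edges),
         observed_frequency = observed_edges / n_pairs,
         null_frequency = null_edges / n_pairs,
         r_threshold = r_threshold, seed = seed),
    class = "NullEdgeReport"
  )
}

#' @export
print.NullEdgeReport <- function(x, ...) {
  cat(sprintf(
    paste0("NullEdgeReport: %s genes, %s pairs\n",
           "  observed edges %s (frequency %.2g)\n",
           "  null edges     %s (frequency %.2g)\n"),
    format(x$n_genes, big.mark = ","), format(x$n_pairs, big.mark = ","),
    format(x$observed_edges, big.mark = ","), x$observed_frequency,
    format(x$null_edges, big.mark = ","), x$null_frequency
  ))
  invisible(x)
}

#' Per-gene permutation null for the edge threshold
#'
#' Randomizes each gene's values across samples independently (one
#' replicate), recomputes all pairwise correlations, and compares the number
#' of pairs reaching the threshold with the observed count — quantifying how
#' improbable the retained co-expression edges are under independence.
#' Callers wanting a distribution loop with distinct seeds.
#'
#' @inheritParams pairwise_pearson
#' @param r_threshold Pearson cutoff.
#' @param seed permutation seed.
#' @return a [null_edge_report()].
#' @export
permutation_null <- function(m, r_threshold, seed = 1, log_transform = TRUE) {
  obs <- pairwise_pearson(m, log_transform = log_transform)
  observed_edges <- sum(obs$r >= r_threshold)
  perm <- m
  withr::with_seed(seed, {
    perm$values <- t(apply(m$values, 1L, sample))
  })
  colnames(perm$values) <- colnames(m$values)
  nul <- pairwise_pearson(perm, log_transform = log_transform)
  if (length(nul$gene_ids) != length(obs$gene_ids)) {
    # permutation cannot change constancy, but guard the count basis anyway
    warning("gene counts differ between observed and permuted data")
  }
  null_edge_report(length(obs$gene_ids), observed_edges,
                   sum(nul$r >= r_threshold), r_threshold = r_threshold,
                   seed = seed)
}

#' Sample-sample correlation QC
#'
#' All pairwise sample correlations plus the maximum threshold that still
#' retains every sample: the largest t such that each sample keeps at least
#' one partner with r >= t, i.e. the minimum over samples of that sample's
#' best off-diagonal correlation.
#'
#' @inheritParams pairwise_pearson
#' @return list with `correlations` (data.frame `sample_a`, `sample_b`, `r`)
#'   and `threshold`.
#' @export
sample_qc_threshold <- function(m, log_transform = TRUE) {
  if (ncol(m$values) < 2L) stop("need at least 2 samples", call. = FALSE)
  x <- if (log_transform && m$scale == "linear") log2(m$values + 1) else m$values
  cc <- stats::cor(x)
  diag(cc) <- NA_real_
  best <- apply(cc, 1L, max, na.rm = TRUE)
  idx <- which(upper.tri(cc), arr.ind = TRUE)
  list(
    correlations = data.frame(
      sample_a = colnames(cc)[idx[, 1L]],
      sample_b = colnames(cc)[idx[, 2L]],
      r = cc[idx], stringsAsFactors = FALSE
    ),
    threshold = min(best)
  )
}

#' Export a correlation graph
#'
#' Weighted edge list TSV (`gene_a`, `gene_b`, `r`) or GraphML via igraph.
#'
#' @param g a `CorrelationGraph`.
#' @param path output path.
#' @param format `"tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_graph_file <- function(g, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(g$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    igraph::write_graph(as_igraph(g), path, format = "graphml")
  }
  invisible(path)
}

#' Convert a CorrelationGraph to an igraph object
#' @param g a `CorrelationGraph`.
#' @return an undirected weighted [igraph::graph] object.
#' @export
as_igraph <- function(g) {
  igraph::graph_from_data_frame(
    stats::setNames(g$edges, c("from", "to", "weight")),
    directed = FALSE, vertices = g$nodes
  )
}
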