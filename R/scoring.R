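#' Per-sample signature scores
#'
#' The score of a signature in a sample is the mean log2 expression of its
#' genes in that sample (linear input is log2(x + pseudocount) transformed
#' first; log2 input is used as-is). Signature genes absent from the matrix
#' are dropped and the per-signature coverage fraction is recorded; a
#' signature with no genes present is omitted with a warning.
#'
#' @param m an [expression_matrix()].
#' @param signatures a `SignatureCatalog` or a named list of gene sets.
#' @param pseudocount added before log2 for linear input (default 1, the
#'   RPKM convention).
#' @return a signatures x samples numeric matrix of class `ScoreMatrix`,
#'   with a `"coverage"` attribute (fraction of each signature's genes
#'   present).
#' @export
signature_scores <- function(m, signatures, pseudocount = 1) {
  sets <- if (inherits(signatures, "SignatureCatalog")) {
    catalog_sets(signatures)
  } else {
    signatures
  }
  if (is.null(names(sets))) stop("signatures must be named", call. = FALSE)
  lx <- em_log2_values(m, pseudocount)
  present <- lapply(sets, intersect, y = rownames(lx))
  coverage <- lengths(present) / pmax(lengths(sets), 1L)
  empty <- lengths(present) == 0L
  if (any(empty)) {
    warning("omitting signature(s) with no genes present: ",
            paste(names(sets)[empty], collapse = ", "))
    present <- present[!empty]
    coverage <- coverage[!empty]
  }
  scores <- t(vapply(present, function(g) {
    colMeans(lx[g, , drop = FALSE])
  }, numeric(ncol(lx))))
  colnames(scores) <- colnames(lx)
  structure(scores, class = c("ScoreMatrix", "matrix"), coverage = coverage)
}

#' Signature log fold change between two sample groups
#'
#' Per signature: mean score over the test samples minus mean score over the
#' control samples. Positive values indicate overrepresentation of the
#' signature in the test group.
#'
#' @param scores a [signature_scores()] matrix.
#' @param test_samples,control_samples disjoint, non-empty sample ID vectors.
#' @return named numeric vector (one value per signature).
#' @export
signature_lfc <- function(scores, test_samples, control_samples) {
  if (!length(test_samples) || !length(control_samples)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (length(intersect(test_samples, control_samples))) {
    stop("groups must be disjoint", call. = FALSE)
  }
  unknown <- setdiff(c(test_samples, control_samples), colnames(scores))
  if (length(unknown)) {
    stop("unknown sample ID(s): ", paste(utils::head(unknown, 5), collapse = ", "),
         call. = FALSE)
  }
  rowMeans(scores[, test_samples, drop = FALSE]) -
    rowMeans(scores[, control_samples, drop = FALSE])
}

#' Signature x comparison log-fold-change table
#'
#' @param scores a [signature_scores()] matrix.
#' @param comparisons named list of `list(test = <ids>, control = <ids>)`.
#' @return signatures x comparisons numeric matrix (an `LfcTable`).
#' @export
lfc_table <- function(scores, comparisons) {
  stopifnot(length(comparisons) > 0, !is.null(names(comparisons)))
  out <- vapply(comparisons, function(cmp) {
    signature_lfc(scores, cmp$test, cmp$control)
  }, numeric(nrow(scores)))
  out <- matrix(out, nrow = nrow(scores),
                dimnames = list(rownames(scores), names(comparisons)))
  structure(out, class = c("LfcTable", "matrix"))
}

#' Cluster conditions on their signature fold-change profiles
#'
#' Agglomerative clustering of the comparison (condition) columns over the
#' retained signature rows, after dropping signatures whose expression is
#' driven by sample properties unrelated to condition (supplied via
#' `exclude`). Leaf order is the deterministic `hclust` order for the given
#' input; the dendrogram is also serialized as Newick text.
#'
#' @param lfc an [lfc_table()] matrix.
#' @param exclude signature names to drop before clustering.
#' @param linkage agglomeration method (default `"average"`).
#' @param metric distance metric (default `"euclidean"`).
#' @return list with `matrix` (rows = signatures, columns reordered to leaf
#'   order), `order` (condition names in leaf order), `dendrogram_newick`,
#'   `hclust`.
#' @export
condition_heatmap <- function(lfc, exclude = character(),
                              linkage = "average", metric = "euclidean") {
  keep <- setdiff(rownames(lfc), exclude)
  mat <- lfc[keep, , drop = FALSE]
  if (ncol(mat) < 2L) stop("need >= 2 conditions after exclusion", call. = FALSE)
  h <- stats::hclust(stats::dist(t(mat), method = metric), method = linkage)
  phy <- ape::as.phylo(h)
  list(
    matrix = mat[, h$order, drop = FALSE],
    order = colnames(mat)[h$order],
    dendrogram_newick = ape::write.tree(phy),
    hclust = h
  )
}
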