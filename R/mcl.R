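#' Markov clustering parameters
#'
#' @param inflation element-wise exponent (> 1) applied after expansion;
#'   controls cluster granularity (higher = more, smaller clusters).
#'   Default 2.2, the setting used throughout the signature-derivation
#'   pipeline.
#' @param expansion matrix power (integer >= 2) simulating random-walk flow.
#' @param prune_threshold entries below this are zeroed each iteration to
#'   keep the flow matrix sparse; in [0, 1e-3].
#' @param max_iterations iteration cap.
#' @param convergence_tol stop when the largest element change falls below
#'   this.
#' @return an object of class `MclParams`.
#' @export
mcl_params <- function(inflation = 2.2, expansion = 2L,
                       prune_threshold = 1e-5, max_iterations = 100L,
                       convergence_tol = 1e-6) {
  if (!is.numeric(inflation) || inflation <= 1) {
    stop("inflation must be > 1", call. = FALSE)
  }
  if (expansion < 2) stop("expansion must be >= 2", call. = FALSE)
  if (prune_threshold < 0 || prune_threshold > 1e-3) {
    stop("prune_threshold must be in [0, 1e-3]", call. = FALSE)
  }
  structure(
    list(inflation = inflation, expansion = as.integer(expansion),
         prune_threshold = prune_threshold,
         max_iterations = as.integer(max_iterations),
         convergence_tol = convergence_tol),
    class = "MclParams"
  )
}

# Column-normalize a sparse matrix to column-stochastic form.
col_normalize <- function(M) {
  cs <- Matrix::colSums(M)
  cs[cs == 0] <- 1
  M %*% Matrix::Diagonal(x = 1 / cs)
}

#' Markov clustering of a weighted correlation graph
#'
#' The canonical MCL iteration on the weighted adjacency matrix with
#' self-loops (loop weight = the node's maximum incident edge weight):
#' column-normalize to a stochastic flow matrix, then repeat expansion
#' (matrix power), inflation (element-wise power followed by column
#' re-normalization), and pruning of entries below `prune_threshold`, until
#' the largest element change drops below `convergence_tol` or the iteration
#' cap is hit (the latter sets a `converged = FALSE` flag with a warning).
#'
#' Clusters are read off the limit matrix: attractor nodes (positive
#' diagonal mass) are grouped into attractor systems (connected via nonzero
#' limit flow among attractors); every other node joins the attractor
#' receiving its maximal limit flow, ties going to the lexicographically
#' smallest attractor gene ID; nodes with no remaining flow become
#' singletons. Clusters are ordered by decreasing size, ties by their
#' lexicographically smallest member.
#'
#' @param g a `CorrelationGraph` (see [build_graph()]); edge weights are the
#'   Pearson r values, not binarized.
#' @param params an [mcl_params()].
#' @return An object of class `ClusterSet`: list with `clusters` (list of
#'   sorted character vectors), `sizes`, `converged`, `iterations`.
#' @export
mcl_cluster <- function(g, params = mcl_params()) {
  stopifnot(inherits(g, "CorrelationGraph"), inherits(params, "MclParams"))
  nodes <- sort(g$nodes)
  n <- length(nodes)
  if (n == 0L) stop("empty graph", call. = FALSE)
  ia <- match(g$edges$gene_a, nodes)
  ib <- match(g$edges$gene_b, nodes)
  M <- Matrix::sparseMatrix(
    i = c(ia, ib), j = c(ib, ia), x = c(g$edges$r, g$edges$r),
    dims = c(n, n)
  )
  # self-loops: maximum incident edge weight (1 for isolated nodes)
  loop <- rep(1, n)
  if (nrow(g$edges)) {
    mx <- tapply(c(g$edges$r, g$edges$r), c(ia, ib), max)
    loop[as.integer(names(mx))] <- mx
  }
  Matrix::diag(M) <- loop
  M <- col_normalize(M)

  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(params$max_iterations)) {
    prev <- M
    Mexp <- M
    for (e in seq_len(params$expansion - 1L)) Mexp <- Mexp %*% M
    M <- Mexp
    M@x <- M@x^params$inflation
    M <- col_normalize(M)
    if (params$prune_threshold > 0) {
      # never empty a column: keep each column's maximum even if tiny
      cmax <- sapply(seq_len(n), function(j) {
        p <- (M@p[j] + 1L):M@p[j + 1L]
        if (M@p[j + 1L] > M@p[j]) max(M@x[p]) else 0
      })
      keep_floor <- pmin(params$prune_threshold, cmax)
      col_of <- rep(seq_len(n), diff(M@p))
      M@x[M@x < keep_floor[col_of]] <- 0
      M <- Matrix::drop0(M)
      M <- col_normalize(M)
    }
    delta <- max(abs(M - prev))
    if (delta < params$convergence_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("MCL did not converge within max_iterations; returning current clustering")
  }

  clusters <- mcl_interpret(M, nodes)
  ord <- order(-lengths(clusters),
               vapply(clusters, function(cl) cl[1L], ""))
  clusters <- clusters[ord]
  structure(
    list(clusters = clusters, sizes = lengths(clusters),
         converged = converged, iterations = iter),
    class = "ClusterSet"
  )
}

# Read the cluster partition off a (near-)limit flow matrix.
mcl_interpret <- function(M, nodes) {
  n <- length(nodes)
  d <- Matrix::diag(M)
  attractors <- which(d > 0)
  if (!length(attractors)) attractors <- seq_len(n)  # degenerate guard
  # attractor systems: components of the attractor-attractor flow support
  sub <- M[attractors, attractors, drop = FALSE]
  adj <- (sub != 0) | Matrix::t(sub != 0)
  comp <- components_binary(adj)
  system_of <- integer(n)
  system_of[attractors] <- comp
  # assign non-attractor nodes by maximal incoming limit flow
  others <- setdiff(seq_len(n), attractors)
  if (length(others)) {
    flow <- M[attractors, others, drop = FALSE]
    for (k in seq_along(others)) {
      f <- flow[, k]
      if (all(f == 0)) next  # fully pruned: singleton below
      best <- which(f == max(f))
      # tie-break: lexicographically smallest attractor gene ID
      j <- best[order(nodes[attractors[best]])][1L]
      system_of[others[k]] <- comp[j]
    }
  }
  out <- lapply(
    split(nodes[system_of > 0], system_of[system_of > 0]),
    sort
  )
  unassigned <- nodes[system_of == 0]
  c(unname(out), as.list(unassigned))
}

# Connected components of a symmetric sparse logical adjacency (BFS).
components_binary <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[, v] | adj[v, ])
      nb <- nb[comp[nb] == 0L]
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Construct a ClusterSet from a list of gene sets
#'
#' For feeding clusterings from external tools (or constructed fixtures)
#' into the matching and catalog machinery. Clusters are validated for
#' disjointness and put into canonical order: decreasing size, ties by
#' lexicographically smallest member.
#'
#' @param clusters list of character vectors (disjoint gene sets).
#' @return an object of class `ClusterSet`.
#' @export
cluster_set <- function(clusters) {
  stopifnot(is.list(clusters), all(lengths(clusters) > 0))
  members <- unlist(clusters, use.names = FALSE)
  if (anyDuplicated(members)) stop("clusters must be disjoint", call. = FALSE)
  clusters <- lapply(clusters, sort)
  ord <- order(-lengths(clusters), vapply(clusters, `[`, "", 1L))
  structure(
    list(clusters = unname(clusters[ord]), sizes = lengths(clusters[ord]),
         converged = TRUE, iterations = 0L),
    class = "ClusterSet"
  )
}

#' @export
print.ClusterSet <- function(x, ...) {
  cat(sprintf("ClusterSet: %d clusters (largest %d, >=10 genes: %d)%s\n",
              length(x$clusters), if (length(x$sizes)) max(x$sizes) else 0L,
              sum(x$sizes >= 10),
              if (isFALSE(x$converged)) " [not converged]" else ""))
  invisible(x)
}

#' Summary table of clusters at a minimum size
#'
#' @param cs a `ClusterSet`.
#' @param min_size smallest cluster size to report (>= 1).
#' @return data.frame with `cluster_id` (1-based rank by decreasing size),
#'   `size`, `members` (comma-joined gene IDs), preserving id order.
#' @export
cluster_table <- function(cs, min_size = 1L) {
  stopifnot(inherits(cs, "ClusterSet"), min_size >= 1)
  keep <- which(cs$sizes >= min_size)
  data.frame(
    cluster_id = keep,
    size = cs$sizes[keep],
    members = vapply(cs$clusters[keep], paste, "", collapse = ","),
    stringsAsFactors = FALSE
  )
}

#' Write a ClusterSet as TSV or GMT
#'
#' @param cs a `ClusterSet`.
#' @param path output path.
#' @param format `"tsv"` (`cluster_id`, `gene` rows) or `"gmt"` (one set per
#'   cluster, named `cluster_<id>`).
#' @return `path`, invisibly.
#' @export
write_clusters <- function(cs, path, format = c("tsv", "gmt")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(
      cluster_id = rep(seq_along(cs$clusters), cs$sizes),
      gene = unlist(cs$clusters, use.names = FALSE)
    )
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    sets <- stats::setNames(cs$clusters,
                            sprintf("cluster_%d", seq_along(cs$clusters)))
    write_gmt(sets, path)
  }
  invisible(path)
}
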