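# Shared fixtures and independent reference implementations used as oracles.
# Everything here is deliberately written in plain dense base R, separate
# from the package's code paths.

make_em <- function(values, platform = "unspecified", scale = "linear",
                    genes = NULL, samples = NULL) {
  if (!is.null(genes)) rownames(values) <- genes
  if (!is.null(samples)) colnames(values) <- samples
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  }
  expression_matrix(values, platform = platform, scale = scale)
}

rand_em <- function(n_genes, n_samples, seed = 1, scale = "linear") {
  withr::with_seed(seed, {
    v <- matrix(exp(rnorm(n_genes * n_samples, 3, 1)), nrow = n_genes)
  })
  make_em(v, scale = scale)
}

# Textbook two-pass Pearson correlation of two vectors.
ref_pearson_pair <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Full correlation list of a genes x samples matrix, as a data.frame over
# sorted gene order — brute force, one pair at a time.
ref_pearson_all <- function(v) {
  v <- v[order(rownames(v)), , drop = FALSE]
  ids <- rownames(v)
  n <- nrow(v)
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      rows[[length(rows) + 1]] <- data.frame(
        gene_a = ids[i], gene_b = ids[j],
        r = ref_pearson_pair(v[i, ], v[j, ]), stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

# Reference Markov clustering: dense base-R execution of the iteration
# (self-loops = max incident weight; column-normalize; expand by matrix
# power; inflate element-wise and renormalize; prune below threshold keeping
# each column's maximum; stop on max element change < tol), then read off
# attractor systems and memberships.
ref_mcl <- function(nodes, edges, inflation = 2.2, expansion = 2,
                    prune = 1e-5, tol = 1e-6, maxit = 100) {
  nodes <- sort(nodes)
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(edges))) {
    A[edges$gene_a[k], edges$gene_b[k]] <- edges$r[k]
    A[edges$gene_b[k], edges$gene_a[k]] <- edges$r[k]
  }
  for (v in seq_len(n)) {
    inc <- A[v, -v]
    A[v, v] <- if (any(inc > 0)) max(inc) else 1
  }
  normalize <- function(M) {
    cs <- colSums(M)
    cs[cs == 0] <- 1
    sweep(M, 2, cs, "/")
  }
  M <- normalize(A)
  for (it in seq_len(maxit)) {
    prev <- M
    E <- diag(n)
    for (e in seq_len(expansion)) E <- E %*% M
    M <- normalize(E^inflation)
    for (j in seq_len(n)) {
      cm <- max(M[, j])
      M[M[, j] < min(prune, cm), j] <- 0
    }
    M <- normalize(M)
    if (max(abs(M - prev)) < tol) break
  }
  attractors <- which(diag(M) > 0)
  # attractor systems: transitive closure of mutual support
  sys <- seq_along(attractors)
  repeat {
    changed <- FALSE
    for (a in seq_along(attractors)) {
      for (b in seq_along(attractors)) {
        if (sys[a] != sys[b] &&
            (M[attractors[a], attractors[b]] > 0 ||
             M[attractors[b], attractors[a]] > 0)) {
          sys[sys == max(sys[a], sys[b])] <- min(sys[a], sys[b])
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  member <- rep(NA_integer_, n)
  member[attractors] <- sys
  for (v in setdiff(seq_len(n), attractors)) {
    f <- M[attractors, v]
    if (all(f == 0)) next
    best <- which(f == max(f))
    best <- best[order(nodes[attractors[best]])][1]
    member[v] <- sys[best]
  }
  clusters <- lapply(split(nodes[!is.na(member)], member[!is.na(member)]), sort)
  clusters <- c(unname(clusters), as.list(nodes[is.na(member)]))
  clusters[order(-lengths(clusters), vapply(clusters, `[`, "", 1))]
}

# Order-insensitive comparison of two partitions (lists of gene vectors).
same_partition <- function(a, b) {
  norm <- function(p) {
    p <- lapply(p, sort)
    p[order(vapply(p, `[`, "", 1))]
  }
  identical(norm(a), norm(b))
}

# Build a CorrelationGraph by hand (for MCL fixtures).
toy_graph <- function(edges, nodes = NULL, threshold = 0.1) {
  structure(
    list(edges = edges,
         nodes = sort(unique(c(nodes, edges$gene_a, edges$gene_b))),
         threshold = threshold),
    class = "CorrelationGraph"
  )
}

toy_clusterset <- function(clusters) {
  clusters <- lapply(clusters, sort)
  ord <- order(-lengths(clusters), vapply(clusters, `[`, "", 1))
  structure(list(clusters = clusters[ord], sizes = lengths(clusters[ord]),
                 converged = TRUE, iterations = 0L),
            class = "ClusterSet")
}

# A pair of platform cohorts with known marker ground truth.
two_platform_study <- function(n_genes = 400, n_types = 4, markers = 10,
                               n_samples = 100, noise = 0.15,
                               overlap = 0.85, seed = 1,
                               concentration = 5) {
  profiles <- generate_profiles(n_genes, n_types, markers, seed = seed)
  conc <- stats::setNames(rep(concentration, n_types), profiles$cell_types)
  da <- mixture_design(n_samples, conc, noise_sigma = noise,
                       platform = "seq-like", seed = seed + 1)
  universe_b <- sort(withr::with_seed(
    seed + 2, sample(profiles$genes, round(overlap * n_genes))
  ))
  db <- mixture_design(n_samples, conc, noise_sigma = noise,
                       platform = "array-like", gene_universe = universe_b,
                       seed = seed + 3)
  list(profiles = profiles,
       a = generate_cohort(profiles, da),
       b = generate_cohort(profiles, db))
}
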