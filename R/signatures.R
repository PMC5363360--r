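#' Match clusters across two datasets by overlap
#'
#' Automates the cross-dataset annotation-matching step: every pair of
#' sufficiently large clusters is scored by the hypergeometric tail
#' probability of its gene overlap within the shared universe, p-values are
#' BH-adjusted across all tested pairs, and a pair is retained when it is
#' best-reciprocal (each cluster's smallest-p partner is the other), its FDR
#' is at most `max_fdr`, and its Jaccard index is at least `min_jaccard`.
#'
#' @param cs_a,cs_b `ClusterSet`s from the two datasets.
#' @param universe character vector: the common gene universe; clusters are
#'   restricted to it before testing.
#' @param min_size smallest cluster (after restriction) considered (>= 2).
#' @param min_jaccard minimum Jaccard index of a retained pair.
#' @param max_fdr maximum BH FDR of a retained pair.
#' @return data.frame with one row per retained pair: `cluster_a`,
#'   `cluster_b` (1-based ids), `n_a`, `n_b`, `n_common`, `jaccard`,
#'   `p_value`, `fdr`, ordered by decreasing `n_common`.
#' @export
match_clusters <- function(cs_a, cs_b, universe, min_size = 5L,
                           min_jaccard = 0.1, max_fdr = 0.01) {
  if (!length(universe)) stop("empty universe", call. = FALSE)
  if (min_size < 2) stop("min_size must be >= 2", call. = FALSE)
  restrict <- function(cs) lapply(cs$clusters, intersect, y = universe)
  A <- restrict(cs_a)
  B <- restrict(cs_b)
  ia <- which(lengths(A) >= min_size)
  ib <- which(lengths(B) >= min_size)
  if (!length(ia) || !length(ib)) {
    return(data.frame(cluster_a = integer(), cluster_b = integer(),
                      n_a = integer(), n_b = integer(), n_common = integer(),
                      jaccard = numeric(), p_value = numeric(),
                      fdr = numeric()))
  }
  N <- length(universe)
  grid <- expand.grid(a = ia, b = ib)
  k <- mapply(function(a, b) length(intersect(A[[a]], B[[b]])),
              grid$a, grid$b)
  na <- lengths(A)[grid$a]
  nb <- lengths(B)[grid$b]
  p <- stats::phyper(k - 1, nb, N - nb, na, lower.tail = FALSE)
  res <- data.frame(
    cluster_a = grid$a, cluster_b = grid$b, n_a = na, n_b = nb,
    n_common = k, jaccard = k / (na + nb - k), p_value = p,
    fdr = stats::p.adjust(p, method = "BH")
  )
  # best-reciprocal by smallest p (ties: larger overlap, then smaller ids)
  pick_best <- function(df) df[order(df$p_value, -df$n_common,
                                     df$cluster_a, df$cluster_b), ][1L, ]
  best_a <- do.call(rbind, lapply(split(res, res$cluster_a), pick_best))
  best_b <- do.call(rbind, lapply(split(res, res$cluster_b), pick_best))
  key <- paste(res$cluster_a, res$cluster_b)
  reciprocal <- key %in% paste(best_a$cluster_a, best_a$cluster_b) &
    key %in% paste(best_b$cluster_a, best_b$cluster_b)
  out <- res[reciprocal & res$fdr <= max_fdr & res$jaccard >= min_jaccard, ]
  out <- out[order(-out$n_common, out$cluster_a), ]
  rownames(out) <- NULL
  out
}

#' Construct/validate a signature catalog
#'
#' A catalog holds the cross-dataset signatures (intersection gene sets) with
#' their dataset-specific remainders, plus signatures observed in only one
#' dataset and retained unilaterally.
#'
#' @param signatures named list: signature -> shared gene set.
#' @param a_specific,b_specific named lists parallel to `signatures`: genes
#'   present only in the dataset-A (resp. B) source cluster.
#' @param dataset_specific named list of unilateral signatures.
#' @param dataset_of named character vector: which dataset each unilateral
#'   signature came from.
#' @param provenance optional data.frame of source cluster ids.
#' @return an object of class `SignatureCatalog`.
#' @export
signature_catalog <- function(signatures, a_specific = NULL, b_specific = NULL,
                              dataset_specific = list(),
                              dataset_of = character(), provenance = NULL) {
  nm <- names(signatures)
  if (is.null(nm) || anyDuplicated(c(nm, names(dataset_specific)))) {
    stop("signature names must be unique", call. = FALSE)
  }
  if (is.null(a_specific)) a_specific <- stats::setNames(rep(list(character()), length(nm)), nm)
  if (is.null(b_specific)) b_specific <- stats::setNames(rep(list(character()), length(nm)), nm)
  for (s in nm) {
    if (length(intersect(signatures[[s]], a_specific[[s]])) ||
        length(intersect(signatures[[s]], b_specific[[s]]))) {
      stop("shared and dataset-specific gene sets must be disjoint for ", s,
           call. = FALSE)
    }
  }
  structure(
    list(signatures = signatures, a_specific = a_specific[nm],
         b_specific = b_specific[nm], dataset_specific = dataset_specific,
         dataset_of = dataset_of, provenance = provenance),
    class = "SignatureCatalog"
  )
}

#' @export
print.SignatureCatalog <- function(x, ...) {
  cat(sprintf("SignatureCatalog: %d shared + %d dataset-specific signatures\n",
              length(x$signatures), length(x$dataset_specific)))
  invisible(x)
}

#' All gene sets of a catalog (shared + dataset-specific)
#' @param cat a `SignatureCatalog`.
#' @return named list of character vectors.
#' @export
catalog_sets <- function(cat) {
  c(cat$signatures, cat$dataset_specific)
}

#' Derive a signature catalog from matched cluster pairs
#'
#' Each matched pair contributes one signature: the intersection of the two
#' source clusters (the conservative cross-platform marker set), with the
#' set differences kept as dataset-specific remainders. Clusters named in
#' `keep_dataset_specific` are retained verbatim as unilateral signatures;
#' naming a matched cluster there is an error (its provenance would be
#' ambiguous).
#'
#' @param matches a [match_clusters()] result.
#' @param cs_a,cs_b the `ClusterSet`s that were matched.
#' @param keep_dataset_specific list of `list(dataset = "A"|"B",
#'   cluster = <id>, name = <optional label>)`.
#' @param names optional character vector naming the matched signatures (in
#'   `matches` row order); default `sig_001`, ... by decreasing overlap.
#' @return a [signature_catalog()].
#' @export
derive_catalog <- function(matches, cs_a, cs_b,
                           keep_dataset_specific = list(), names = NULL) {
  if (is.null(names)) {
    names <- sprintf("sig_%03d", seq_len(nrow(matches)))
  }
  stopifnot(length(names) == nrow(matches))
  sigs <- a_spec <- b_spec <- stats::setNames(
    vector("list", nrow(matches)), names
  )
  for (i in seq_len(nrow(matches))) {
    ca <- cs_a$clusters[[matches$cluster_a[i]]]
    cb <- cs_b$clusters[[matches$cluster_b[i]]]
    sigs[[i]] <- sort(intersect(ca, cb))
    a_spec[[i]] <- sort(setdiff(ca, cb))
    b_spec[[i]] <- sort(setdiff(cb, ca))
  }
  ds <- list()
  ds_of <- character()
  for (spec in keep_dataset_specific) {
    dataset <- match.arg(toupper(spec$dataset), c("A", "B"))
    id <- spec$cluster
    matched_ids <- if (dataset == "A") matches$cluster_a else matches$cluster_b
    if (id %in% matched_ids) {
      stop(sprintf("cluster %d in dataset %s is matched; cannot also keep it as dataset-specific",
                   id, dataset), call. = FALSE)
    }
    cs <- if (dataset == "A") cs_a else cs_b
    nm <- spec$name %||% sprintf("%s_cluster_%d", tolower(dataset), id)
    ds[[nm]] <- sort(cs$clusters[[id]])
    ds_of[nm] <- dataset
  }
  prov <- data.frame(
    name = names,
    cluster_a = matches$cluster_a, cluster_b = matches$cluster_b,
    n_a_specific = lengths(a_spec), n_b_specific = lengths(b_spec),
    n_common = lengths(sigs), stringsAsFactors = FALSE
  )
  signature_catalog(sigs, a_spec, b_spec, dataset_specific = ds,
                    dataset_of = ds_of, provenance = prov)
}

#' Per-signature cross-dataset overlap table
#'
#' For every shared signature: the dataset-specific counts, the common
#' count, and the common percentages relative to each source cluster,
#' rounded half away from zero to integers. The summary reports mean and
#' sample SD of each percentage column over the shared signatures, computed
#' both on the rounded integers (primary, matching how such tables are
#' printed) and on the unrounded ratios; dataset-specific signatures are
#' excluded from the summary.
#'
#' @param cat a `SignatureCatalog`.
#' @return list with `rows` (data.frame: `signature`, `n_a_specific`,
#'   `n_b_specific`, `n_common`, `pct_common_vs_a`, `pct_common_vs_b`,
#'   `shared`) and `summary` (means/SDs of both percentage columns).
#' @export
overlap_table <- function(cat) {
  stopifnot(inherits(cat, "SignatureCatalog"))
  if (!length(cat$signatures) && !length(cat$dataset_specific)) {
    stop("empty catalog", call. = FALSE)
  }
  nm <- names(cat$signatures)
  na <- lengths(cat$a_specific[nm])
  nb <- lengths(cat$b_specific[nm])
  nc <- lengths(cat$signatures)
  pa <- round_half_up(100 * nc / (nc + na))
  pb <- round_half_up(100 * nc / (nc + nb))
  rows <- data.frame(
    signature = nm, n_a_specific = unname(na), n_b_specific = unname(nb),
    n_common = unname(nc), pct_common_vs_a = unname(pa),
    pct_common_vs_b = unname(pb), shared = TRUE, stringsAsFactors = FALSE
  )
  if (length(cat$dataset_specific)) {
    dn <- names(cat$dataset_specific)
    from_a <- cat$dataset_of[dn] == "A"
    rows <- rbind(rows, data.frame(
      signature = dn,
      n_a_specific = ifelse(from_a, lengths(cat$dataset_specific), 0L),
      n_b_specific = ifelse(from_a, 0L, lengths(cat$dataset_specific)),
      n_common = lengths(cat$dataset_specific),
      pct_common_vs_a = NA_real_, pct_common_vs_b = NA_real_,
      shared = FALSE, stringsAsFactors = FALSE
    ))
  }
  rownames(rows) <- NULL
  summary <- list(
    mean_pct_vs_a = mean(pa), sd_pct_vs_a = stats::sd(pa),
    mean_pct_vs_b = mean(pb), sd_pct_vs_b = stats::sd(pb),
    mean_pct_vs_a_unrounded = mean(100 * nc / (nc + na)),
    mean_pct_vs_b_unrounded = mean(100 * nc / (nc + nb)),
    n_shared = length(nm)
  )
  list(rows = rows, summary = summary)
}

#' Split a signature into co-expression subgroups
#'
#' Rebuilds the co-expression network restricted to one signature's genes
#' (over a chosen sample subset), clusters it with MCL, and takes the two
#' largest clusters as candidate subgroups. The subgroup with the larger
#' mean per-gene log2 fold change in the designated comparison is labelled
#' `up`, the other `down`; the per-sample ratio is the mean log2 expression
#' over the up set minus that over the down set. When fewer than two
#' clusters of size >= 2 emerge, a no-split result is returned rather than
#' fabricating subgroups.
#'
#' @param sig character vector of signature genes (all present in `m`).
#' @param m an [expression_matrix()].
#' @param sample_subset samples over which the sub-network is built
#'   (`NULL` = all).
#' @param r_threshold Pearson cutoff for the sub-network (default: the
#'   platform derivation threshold in use by the caller).
#' @param params an [mcl_params()].
#' @param test_samples,control_samples disjoint sample groups defining the
#'   fold-change direction.
#' @param pseudocount for log2 transform of linear input.
#' @return An object of class `SubgroupSplit`: list with `parent`, `split`
#'   (logical), `up_set`, `down_set`, `ratio` (named per-sample values over
#'   `sample_subset`), `n_clusters`.
#' @export
split_signature <- function(sig, m, sample_subset = NULL, r_threshold,
                            params = mcl_params(), test_samples,
                            control_samples, pseudocount = 1) {
  stopifnot(all(sig %in% em_genes(m)))
  if (length(intersect(test_samples, control_samples))) {
    stop("comparison groups must be disjoint", call. = FALSE)
  }
  sub <- em_subset(m, genes = sig, samples = sample_subset)
  g <- correlation_graph(sub, r_threshold)
  no_split <- structure(
    list(parent = "signature", split = FALSE, up_set = character(),
         down_set = character(), ratio = numeric(), n_clusters = 0L),
    class = "SubgroupSplit"
  )
  if (!length(g$nodes)) return(no_split)
  cs <- mcl_cluster(g, params)
  big <- which(cs$sizes >= 2)
  no_split$n_clusters <- length(big)
  if (length(big) < 2L) return(no_split)
  g1 <- cs$clusters[[big[1L]]]
  g2 <- cs$clusters[[big[2L]]]
  lx <- em_log2_values(m, pseudocount)
  lfc <- function(genes) {
    mean(rowMeans(lx[genes, test_samples, drop = FALSE]) -
           rowMeans(lx[genes, control_samples, drop = FALSE]))
  }
  if (lfc(g1) >= lfc(g2)) {
    up <- g1; down <- g2
  } else {
    up <- g2; down <- g1
  }
  lsub <- em_log2_values(sub, pseudocount)
  ratio <- colMeans(lsub[up, , drop = FALSE]) - colMeans(lsub[down, , drop = FALSE])
  structure(
    list(parent = "signature", split = TRUE, up_set = up, down_set = down,
         ratio = ratio, n_clusters = length(big)),
    class = "SubgroupSplit"
  )
}

#' Write a signature catalog as GMT
#'
#' Shared signatures first (description records the per-dataset specific
#' counts), then dataset-specific signatures (description records the source
#' dataset).
#'
#' @param cat a `SignatureCatalog`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(cat, path) {
  sets <- catalog_sets(cat)
  desc <- c(
    sprintf("shared|a_specific=%d|b_specific=%d",
            lengths(cat$a_specific), lengths(cat$b_specific)),
    sprintf("dataset_specific|%s", cat$dataset_of[names(cat$dataset_specific)])
  )
  write_gmt(sets, path, descriptions = desc)
}
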