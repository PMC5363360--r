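#' Collapse microarray probes to gene symbols
#'
#' Two collapse policies, matching the two stages where probe-level data meet
#' symbol-level analysis: `max_mad` keeps, per symbol, the single probe with
#' the largest median absolute deviation across samples (the most variable,
#' hence most informative, probe; MAD with unit constant); `geometric_mean`
#' replaces a symbol's probes by their per-sample geometric mean. Probes
#' absent from the map are dropped with a message.
#'
#' @param m an [expression_matrix()] whose rows are probe IDs.
#' @param map a [probe_map()] (named character vector probe -> symbol).
#' @param method `"max_mad"` or `"geometric_mean"`.
#' @param pseudo_floor under `geometric_mean`, linear values below this floor
#'   are raised to it before logging so zeros never produce `-Inf`.
#' @return an [expression_matrix()] with one row per symbol. MAD ties are
#'   broken by the lexicographically smallest probe ID.
#' @export
collapse_probes <- function(m, map, method = c("max_mad", "geometric_mean"),
                            pseudo_floor = 1e-6) {
  method <- match.arg(method)
  probes <- em_genes(m)
  mapped <- probes[probes %in% names(map)]
  n_drop <- length(probes) - length(mapped)
  if (n_drop > 0) {
    message(sprintf("collapse_probes: dropping %d unmapped probe(s)", n_drop))
  }
  if (!length(mapped)) stop("no probes left after mapping", call. = FALSE)
  if (method == "geometric_mean" && m$scale != "linear") {
    stop("geometric_mean collapse requires linear-scale input", call. = FALSE)
  }
  v <- m$values[mapped, , drop = FALSE]
  sym <- unname(map[mapped])
  groups <- split(mapped, sym)

  rows <- lapply(groups, function(pr) {
    if (length(pr) == 1L) return(v[pr, ])
    sub <- v[pr, , drop = FALSE]
    if (method == "max_mad") {
      mads <- apply(sub, 1L, stats::mad, constant = 1)
      best <- pr[order(-mads, pr)][1L]
      v[best, ]
    } else {
      exp(colMeans(log(pmax(sub, pseudo_floor))))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(groups)
  expression_matrix(out, platform = m$platform, scale = m$scale)
}

#' Keep genes expressed above a threshold in at least one sample
#'
#' The expressed-gene filter for linear-scale data: a gene is retained iff
#' its value is strictly greater than `threshold` in one or more samples
#' (e.g. > 1 RPKM in at least one sample).
#'
#' @param m an [expression_matrix()] with `scale = "linear"`.
#' @param threshold strict lower bound.
#' @return the filtered [expression_matrix()] (possibly with zero genes).
#' @export
filter_expressed <- function(m, threshold = 1) {
  if (m$scale != "linear") stop("filter_expressed expects linear scale", call. = FALSE)
  keep <- apply(m$values, 1L, function(x) any(x > threshold))
  out <- m
  out$values <- m$values[keep, , drop = FALSE]
  out
}

#' Restrict two matrices to their common genes
#'
#' Both outputs carry exactly the sorted intersection of the two gene sets,
#' in the same order — the cross-platform common-symbol filtering step.
#'
#' @param a,b [expression_matrix()] objects collapsed to gene symbols.
#' @return list with elements `a` and `b`.
#' @export
intersect_genes <- function(a, b) {
  common <- sort(intersect(em_genes(a), em_genes(b)))
  if (!length(common)) stop("empty gene intersection", call. = FALSE)
  list(a = em_subset(a, genes = common), b = em_subset(b, genes = common))
}
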