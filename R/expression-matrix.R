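#' Expression matrix container
#'
#' The universal currency of the pipeline: a genes x samples numeric matrix
#' tagged with its platform of origin and measurement scale. Values are
#' linear-scale abundances (RPKM-like or array-intensity-like) unless
#' `scale = "log2"`.
#'
#' @param values numeric matrix with unique, non-empty rownames (gene IDs) and
#'   colnames (sample IDs); no missing values; nonnegative when
#'   `scale = "linear"`.
#' @param platform free-text platform tag (e.g. `"seq-like"`, `"array-like"`).
#' @param scale `"linear"` or `"log2"`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `platform`, `scale`.
#' @export
expression_matrix <- function(values, platform = "unspecified",
                              scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || anyNA(gid) || any(gid == "")) {
    stop("gene IDs (rownames) must be present and non-empty", call. = FALSE)
  }
  if (is.null(sid) || anyNA(sid) || any(sid == "")) {
    stop("sample IDs (colnames) must be present and non-empty", call. = FALSE)
  }
  if (anyDuplicated(gid)) stop("duplicate gene IDs", call. = FALSE)
  if (anyDuplicated(sid)) stop("duplicate sample IDs", call. = FALSE)
  if (anyNA(values)) stop("missing values are not allowed", call. = FALSE)
  if (scale == "linear" && any(values < 0)) {
    stop("linear-scale values must be nonnegative", call. = FALSE)
  }
  structure(
    list(values = values, platform = platform, scale = scale),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf(
    "ExpressionMatrix: %d genes x %d samples [platform=%s, scale=%s]\n",
    nrow(x$values), ncol(x$values), x$platform, x$scale
  ))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Gene and sample identifiers of an ExpressionMatrix
#' @param m an [expression_matrix()].
#' @return character vector of IDs.
#' @export
em_genes <- function(m) rownames(m$values)

#' @rdname em_genes
#' @export
em_samples <- function(m) colnames(m$values)

#' Subset an ExpressionMatrix by genes and/or samples
#'
#' @param m an [expression_matrix()].
#' @param genes,samples character vectors of IDs to retain (order preserved);
#'   `NULL` keeps all.
#' @return an [expression_matrix()].
#' @export
em_subset <- function(m, genes = NULL, samples = NULL) {
  v <- m$values
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(v))
    if (length(missing)) {
      stop("unknown gene IDs: ", paste(utils::head(missing, 5), collapse = ", "),
           call. = FALSE)
    }
    v <- v[genes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(v))
    if (length(missing)) {
      stop("unknown sample IDs: ", paste(utils::head(missing, 5), collapse = ", "),
           call. = FALSE)
    }
    v <- v[, samples, drop = FALSE]
  }
  expression_matrix(v, platform = m$platform, scale = m$scale)
}

# Values on log2 scale, applying log2(x + pseudocount) to linear input.
em_log2_values <- function(m, pseudocount = 1) {
  if (m$scale == "log2") m$values else log2(m$values + pseudocount)
}

#' Read an expression matrix from TSV or GCT
#'
#' TSV layout: header row of sample IDs, first column gene IDs, tab-separated
#' numeric body. GCT dialect: `#1.2` version line, a `n_genes<TAB>n_samples`
#' line, then a table with `NAME` and `DESCRIPTION` columns followed by one
#' column per sample.
#'
#' @param path file path.
#' @param format `"tsv"` or `"gct"`.
#' @param platform,scale passed to [expression_matrix()].
#' @return an [expression_matrix()].
#' @export
read_matrix <- function(path, format = c("tsv", "gct"),
                        platform = "unspecified", scale = "linear") {
  format <- match.arg(format)
  if (format == "gct") {
    header <- readLines(path, n = 2L)
    if (length(header) < 2L || !startsWith(header[1L], "#1.2")) {
      stop("not a GCT #1.2 file: ", path, call. = FALSE)
    }
    dims <- suppressWarnings(as.integer(strsplit(header[2L], "\t")[[1L]]))
    tab <- utils::read.delim(path, skip = 2L, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 3L) stop("GCT table needs NAME, DESCRIPTION and samples",
                             call. = FALSE)
    if (anyDuplicated(names(tab)[-(1:2)])) {
      stop("duplicate sample IDs in ", path, call. = FALSE)
    }
    body <- tab[, -(1:2), drop = FALSE]
    if (nrow(tab) != dims[1L] || ncol(body) != dims[2L]) {
      stop(sprintf(
        "GCT declared dims %d x %d but table is %d x %d",
        dims[1L], dims[2L], nrow(tab), ncol(body)
      ), call. = FALSE)
    }
    ids <- as.character(tab[[1L]])
  } else {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    # check before subsetting: `[.data.frame` silently uniquifies names
    if (anyDuplicated(names(tab)[-1L])) {
      stop("duplicate sample IDs in ", path, call. = FALSE)
    }
    ids <- as.character(tab[[1L]])
    body <- tab[, -1L, drop = FALSE]
  }
  for (j in seq_len(ncol(body))) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad)) {
        stop(sprintf(
          "non-numeric value '%s' at row %d (gene %s), column %d (sample %s)",
          col[bad[1L]], bad[1L], ids[bad[1L]], j, colnames(body)[j]
        ), call. = FALSE)
      }
      body[[j]] <- num
    }
  }
  v <- as.matrix(body)
  rownames(v) <- ids
  expression_matrix(v, platform = platform, scale = scale)
}

#' Write an expression matrix as TSV or GCT
#'
#' @param m an [expression_matrix()].
#' @param path output path.
#' @param format `"tsv"` or `"gct"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  v <- m$values
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(v), v, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(v), ncol(v), sep = "\t")), con)
    df <- data.frame(NAME = rownames(v), DESCRIPTION = rownames(v), v,
                     check.names = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a probe-to-gene-symbol map
#'
#' Two-column TSV (`probe_id`, `gene_symbol`); every probe maps to exactly one
#' non-empty symbol.
#'
#' @param path file path.
#' @return named character vector: `map[probe_id] == gene_symbol`.
#' @export
read_probe_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  probe_map(stats::setNames(as.character(tab[[2L]]), as.character(tab[[1L]])))
}

#' Construct/validate a probe map
#' @param map named character vector, names = probe IDs, values = symbols.
#' @return the validated map.
#' @export
probe_map <- function(map) {
  if (is.null(names(map)) || anyDuplicated(names(map))) {
    stop("every probe must map to exactly one symbol", call. = FALSE)
  }
  if (anyNA(map) || any(map == "")) stop("symbols must be non-empty", call. = FALSE)
  map
}

#' Read / write GMT gene-set files
#'
#' One set per line: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path file path.
#' @return `read_gmt`: a named list of character vectors, with a
#'   `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, "", 1L)
  attr(sets, "descriptions") <- stats::setNames(
    vapply(parts, `[[`, "", 2L), names(sets)
  )
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector parallel to `sets`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read sample metadata (group labels)
#'
#' Two-column TSV (`sample_id`, `group`).
#'
#' @param path file path.
#' @return data.frame with columns `sample_id`, `group`.
#' @export
read_sample_groups <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(tab)[1:2] <- c("sample_id", "group")
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample IDs", call. = FALSE)
  tab
}
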