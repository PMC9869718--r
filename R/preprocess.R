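#' Per-gene variance and median-abundance statistics
#'
#' Computes, on the raw (not yet z-scored) matrix, each gene's variance and
#' median abundance across conditions plus their percentile ranks over the
#' dataset's gene universe. Percentile rank of a gene is
#' `100 * (number of genes with strictly smaller value) / (n - 1)`, with
#' midpoint averaging for ties, so ranks span exactly \[0, 100\]. These
#' statistics drive both the pre-clustering filter and the dynamic
#' first-level filters; ranks are global (computed once on the loaded data)
#' and are not re-ranked after filtering.
#'
#' Variance is the population variance (divisor n), matching the population
#' standard deviation used by [zscore].
#'
#' @param matrix an [abundance_matrix] with `state = "raw"`.
#' @return data.frame of class `gene_stats` with columns `gene`, `variance`,
#'   `median_abundance`, `variance_pct`, `median_abundance_pct`.
#' @export
compute_gene_stats <- function(matrix) {
  stopifnot(inherits(matrix, "abundance_matrix"))
  if (matrix$state != "raw")
    stop("gene stats must be computed on raw values")
  n <- length(matrix$genes)
  if (n < 2L) stop("percentile ranks undefined for fewer than 2 genes")
  v <- matrix$values
  mu <- rowMeans(v)
  variance <- rowMeans((v - mu)^2)
  med <- apply(v, 1L, stats::median)
  out <- data.frame(gene = matrix$genes,
                    variance = variance,
                    median_abundance = med,
                    variance_pct = percentile_rank(variance),
                    median_abundance_pct = percentile_rank(med),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("gene_stats", "data.frame")
  out
}

#' Percentile ranks on \[0, 100\] with midpoint tie handling
#'
#' @param x numeric vector, length >= 2.
#' @return numeric vector of ranks in \[0, 100\].
#' @export
percentile_rank <- function(x) {
  n <- length(x)
  if (n < 2L) stop("percentile rank undefined for length < 2")
  100 * (rank(x, ties.method = "average") - 1) / (n - 1)
}

#' Specify a percentile-range filter
#'
#' @param metric `"variance"` or `"median_abundance"`.
#' @param lo,hi percentile bounds in \[0, 100\], `lo <= hi`; a gene is
#'   retained iff its metric's percentile rank lies in `[lo, hi]`.
#' @param scope `"both_datasets"` (gene must satisfy the range in both
#'   matrices of a pair) or `"single_dataset"`.
#' @return list of class `filter_spec`.
#' @export
filter_spec <- function(metric = c("variance", "median_abundance"),
                        lo = 0, hi = 100,
                        scope = c("both_datasets", "single_dataset")) {
  metric <- match.arg(metric)
  scope <- match.arg(scope)
  stopifnot(is.numeric(lo), is.numeric(hi), length(lo) == 1L, length(hi) == 1L)
  if (lo > hi) stop("lo > hi in filter_spec")
  if (lo < 0 || hi > 100) stop("percentile bounds must lie in [0, 100]")
  structure(list(metric = metric, lo = lo, hi = hi, scope = scope),
            class = "filter_spec")
}

stats_in_range <- function(stats, spec) {
  pct <- switch(spec$metric,
                variance = stats$variance_pct,
                median_abundance = stats$median_abundance_pct)
  stats$gene[pct >= spec$lo & pct <= spec$hi]
}

#' Filter genes by percentile range of a per-gene statistic
#'
#' @param matrices a single [abundance_matrix] or a list of two (required for
#'   `scope = "both_datasets"`).
#' @param spec a [filter_spec].
#' @param stats optional precomputed [compute_gene_stats] output (one per
#'   matrix, in the same order); computed on demand otherwise.
#' @return character vector of retained gene IDs. For `both_datasets` scope
#'   only genes present in both matrices and inside the range in both are
#'   retained.
#' @export
filter_by_percentile <- function(matrices, spec, stats = NULL) {
  stopifnot(inherits(spec, "filter_spec"))
  if (inherits(matrices, "abundance_matrix")) matrices <- list(matrices)
  if (is.null(stats)) stats <- lapply(matrices, compute_gene_stats)
  if (inherits(stats, "gene_stats")) stats <- list(stats)
  survivors <- lapply(stats, stats_in_range, spec = spec)
  if (spec$scope == "both_datasets") {
    if (length(survivors) != 2L)
      stop("both_datasets scope requires two matrices")
    intersect(survivors[[1L]], survivors[[2L]])
  } else {
    if (length(survivors) == 1L) survivors[[1L]]
    else unique(unlist(survivors))
  }
}

#' Per-gene z-score normalization
#'
#' Transforms each gene's profile to `(x - mean) / sd` across that gene's
#' conditions, using the population standard deviation (divisor n). This
#' removes per-gene location and scale so that clustering compares profile
#' shapes across datasets with different dynamic ranges. Genes with zero
#' standard deviation map to the all-zero profile and are listed in
#' `attr(result, "flagged")`; they are retained (the variance filter is the
#' user-facing mechanism for removing flat genes).
#'
#' @param matrix an [abundance_matrix] with `state = "raw"`.
#' @return An [abundance_matrix] with `state = "zscored"`.
#' @export
zscore <- function(matrix) {
  stopifnot(inherits(matrix, "abundance_matrix"))
  if (matrix$state != "raw") stop("matrix already z-scored")
  v <- matrix$values
  mu <- rowMeans(v)
  sdev <- sqrt(rowMeans((v - mu)^2))
  flat <- sdev == 0
  z <- (v - mu) / ifelse(flat, 1, sdev)
  z[flat, ] <- 0
  out <- abundance_matrix(z, matrix$dataset_id, state = "zscored")
  attr(out, "flagged") <- matrix$genes[flat]
  out
}

#' Restrict an abundance matrix to a gene subset
#'
#' @param matrix an [abundance_matrix].
#' @param genes character vector of gene IDs to keep (order of the original
#'   matrix is preserved).
#' @return An [abundance_matrix] over the intersection.
#' @export
subset_genes <- function(matrix, genes) {
  stopifnot(inherits(matrix, "abundance_matrix"))
  keep <- matrix$genes[matrix$genes %in% genes]
  abundance_matrix(matrix$values[keep, , drop = FALSE], matrix$dataset_id,
                   state = matrix$state)
}
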