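#' Construct an abundance matrix
#'
#' The core data container: one quantitative omics dataset with genes in rows
#' and ordered conditions in columns. Values are assumed pre-normalized
#' (e.g. FPKM, log2-LFQ); the `state` flag records whether per-gene z-score
#' normalization has been applied.
#'
#' @param values numeric matrix, genes x conditions, with rownames = gene IDs
#'   and colnames = condition names.
#' @param dataset_id short label for the dataset.
#' @param state `"raw"` or `"zscored"`.
#' @return An object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(values, dataset_id, state = "raw") {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have gene rownames and condition colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (ncol(values) < 2L)
    stop("fewer than 2 conditions")
  if (anyNA(values))
    stop("abundance_matrix must not contain missing values")
  state <- match.arg(state, c("raw", "zscored"))
  structure(
    list(dataset_id = as.character(dataset_id),
         conditions = colnames(values),
         genes = rownames(values),
         values = values,
         state = state),
    class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix '%s': %d genes x %d conditions (%s)\n",
              x$dataset_id, length(x$genes), length(x$conditions), x$state))
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

detect_delimiter <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) return("\t")
  if (grepl("\t", first)) "\t" else ","
}

#' Read an abundance matrix from delimited text
#'
#' First row = header with condition names, first column = gene IDs,
#' remaining cells numeric. Genes with any missing or non-numeric cell are
#' dropped and listed in the load report (`attr(x, "load_report")`), since
#' downstream clustering requires complete profiles.
#'
#' @param path path to a delimited text file.
#' @param dataset_id label for the dataset; defaults to the file name.
#' @param delimiter field delimiter; `NULL` auto-detects (tab, then comma).
#' @param uppercase_ids if `TRUE`, gene IDs are uppercased on load (gene-ID
#'   matching across datasets is otherwise exact and case-sensitive).
#' @return An [abundance_matrix] with `state = "raw"`; attribute
#'   `load_report` is a list with `n_input`, `n_dropped`, `dropped` IDs.
#' @export
read_abundance <- function(path, dataset_id = basename(path), delimiter = NULL,
                           uppercase_ids = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delimiter)) delimiter <- detect_delimiter(path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  if (nrow(df) == 0L) stop("empty file: ", path)
  if (ncol(df) < 3L) stop("fewer than 2 conditions in ", path)
  ids <- trimws(df[[1L]])
  if (uppercase_ids) ids <- toupper(ids)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L)
    stop("duplicate gene IDs: ", paste(dup, collapse = ", "))
  num <- vapply(df[-1L], function(col) suppressWarnings(as.numeric(col)),
                numeric(nrow(df)))
  if (nrow(df) == 1L) num <- matrix(num, nrow = 1L)
  colnames(num) <- colnames(df)[-1L]
  rownames(num) <- ids
  complete <- stats::complete.cases(num)
  dropped <- ids[!complete]
  mat <- abundance_matrix(num[complete, , drop = FALSE], dataset_id)
  attr(mat, "load_report") <- list(n_input = nrow(df),
                                   n_dropped = length(dropped),
                                   dropped = dropped)
  mat
}

#' Write an abundance matrix as delimited text
#'
#' Inverse of [read_abundance]: header row of condition names, first column
#' gene IDs. Numeric values are written at full precision (17 significant
#' digits) so a load/export round trip is exact.
#'
#' @param matrix an [abundance_matrix].
#' @param path output path.
#' @param delimiter field delimiter (default tab).
#' @export
write_abundance <- function(matrix, path, delimiter = "\t") {
  stopifnot(inherits(matrix, "abundance_matrix"))
  df <- data.frame(gene = matrix$genes,
                   format(matrix$values, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene", matrix$conditions)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene-ID query list
#'
#' Plain text, one ID per line; blank lines ignored, surrounding whitespace
#' trimmed, duplicates removed, case preserved.
#'
#' @param path path to the text file.
#' @return character vector of unique gene IDs.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ids <- trimws(readLines(path, warn = FALSE))
  unique(ids[nzchar(ids)])
}

#' Read a custom pre-clustered trend comparison
#'
#' Long-format delimited file with columns `gene`, `dataset`, `condition`,
#' `value`, `cluster`, carrying both the abundance profiles and the trend
#' labels of an externally produced pairwise clustering. Only intersecting
#' genes are describable this way, so every gene must appear in exactly two
#' datasets with identical condition sets. Arbitrary cluster labels are
#' accepted and mapped to the canonical `0..k-1` label space.
#'
#' @param path path to the file.
#' @param delimiter field delimiter; `NULL` auto-detects.
#' @return A list of class `custom_clustering` with elements `genes`,
#'   `datasets`, `conditions`, `labels` (gene x dataset matrix of integer
#'   labels), `profiles` (named list of gene x condition matrices, one per
#'   dataset) and `label_map` (original label -> canonical integer).
#' @export
read_custom_clustering <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delimiter)) delimiter <- detect_delimiter(path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene", "dataset", "condition", "value", "cluster")
  if (!all(need %in% colnames(df)))
    stop("custom clustering file must have columns: ",
         paste(need, collapse = ", "))
  datasets <- unique(df$dataset)
  if (length(datasets) != 2L)
    stop("custom clustering file must describe exactly 2 datasets, found ",
         length(datasets))
  conds <- lapply(datasets, function(d) unique(df$condition[df$dataset == d]))
  if (!identical(conds[[1L]], conds[[2L]]))
    stop("inconsistent condition sets between datasets")
  conditions <- conds[[1L]]
  genes <- sort(unique(df$gene))
  per_gene_ds <- table(unique(df[c("gene", "dataset")])$gene)
  solo <- names(per_gene_ds)[per_gene_ds != 2L]
  if (length(solo) > 0L)
    stop("genes present in only one dataset: ", paste(solo, collapse = ", "))
  # canonical labels: sorted unique original labels -> 0..k-1
  orig <- sort(unique(as.character(df$cluster)))
  label_map <- stats::setNames(seq_along(orig) - 1L, orig)
  labels <- matrix(NA_integer_, length(genes), 2L,
                   dimnames = list(genes, datasets))
  profiles <- lapply(datasets, function(d) {
    sub <- df[df$dataset == d, ]
    m <- matrix(NA_real_, length(genes), length(conditions),
                dimnames = list(genes, conditions))
    m[cbind(match(sub$gene, genes), match(sub$condition, conditions))] <-
      sub$value
    if (anyNA(m)) stop("missing profile values in dataset ", d)
    m
  })
  names(profiles) <- datasets
  lab_rows <- unique(df[c("gene", "dataset", "cluster")])
  labels[cbind(match(lab_rows$gene, genes),
               match(lab_rows$dataset, datasets))] <-
    label_map[as.character(lab_rows$cluster)]
  structure(list(genes = genes, datasets = datasets, conditions = conditions,
                 labels = labels, profiles = profiles, label_map = label_map),
            class = "custom_clustering")
}

#' Read a gene -> GO-term annotation
#'
#' Two supported formats: GMT (tab-separated: term ID, description, member
#' genes...) and two-column (gene TAB term). Term categories (molecular
#' function / biological process / cellular component) can be encoded in the
#' GMT description field as `category|name`; otherwise all terms fall into a
#' single default category. Terms with zero members are dropped with a
#' warning.
#'
#' @param path path to the annotation file.
#' @param format `"gmt"` or `"two_column"`.
#' @param default_category category assigned when none is encoded.
#' @return data.frame of class `annotation` with columns `term_id`,
#'   `term_name`, `category` and list-column `genes`.
#' @export
read_annotation <- function(path, format = c("gmt", "two_column"),
                            default_category = "biological process") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  categories <- c("molecular function", "biological process",
                  "cellular component")
  if (format == "gmt") {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 2L)
    if (length(bad) > 0L)
      stop("malformed GMT line ", bad[1L], ": expected >= 2 tab-separated fields")
    term_id <- vapply(parts, `[[`, "", 1L)
    desc <- vapply(parts, `[[`, "", 2L)
    genes <- lapply(parts, function(p) unique(trimws(p[-(1:2)])))
    genes <- lapply(genes, function(g) g[nzchar(g)])
    cat_name <- ifelse(grepl("|", desc, fixed = TRUE),
                       sub("\\|.*$", "", desc), default_category)
    term_name <- ifelse(grepl("|", desc, fixed = TRUE),
                        sub("^[^|]*\\|", "", desc), desc)
    cat_name[!cat_name %in% categories] <- default_category
    ann <- data.frame(term_id = term_id, term_name = term_name,
                      category = cat_name, stringsAsFactors = FALSE)
    ann$genes <- genes
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 2L)
    if (length(bad) > 0L)
      stop("malformed two-column line ", bad[1L],
           ": expected 'gene<TAB>term'")
    gene <- trimws(vapply(parts, `[[`, "", 1L))
    term <- trimws(vapply(parts, `[[`, "", 2L))
    terms <- sort(unique(term))
    ann <- data.frame(term_id = terms, term_name = terms,
                      category = default_category, stringsAsFactors = FALSE)
    ann$genes <- lapply(terms, function(t) unique(gene[term == t]))
  }
  empty <- lengths(ann$genes) == 0L
  if (any(empty)) {
    warning(sum(empty), " term(s) with no members dropped")
    ann <- ann[!empty, , drop = FALSE]
  }
  rownames(ann) <- NULL
  class(ann) <- c("annotation", "data.frame")
  ann
}

#' Export a result table as CSV
#'
#' Writes any of the package's tabular results (gene/trend assignments,
#' Sankey link table, selection tables, enrichment tables, overview counts)
#' as an RFC-4180-style CSV with a header row. Numeric columns keep full
#' precision so written tables round-trip through [utils::read.csv].
#'
#' @param result a data.frame (or object coercible to one via
#'   [as.data.frame]).
#' @param path output path.
#' @export
export_csv <- function(result, path) {
  df <- as.data.frame(result, stringsAsFactors = FALSE)
  # collapse list-columns (gene sets) into ';'-separated strings
  for (col in names(df))
    if (is.list(df[[col]]))
      df[[col]] <- vapply(df[[col]], paste, "", collapse = ";")
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write to ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE,
                          justify = "none"),
                   con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Export a Sankey model or comparison result as JSON
#'
#' Sankey models are written with the schema
#' `nodes [{dataset, trend, size, genes[]}]`,
#' `links [{trend_a, trend_b, size, genes[]}]`,
#' `summary {concordant, discordant, pct_concordant, pct_discordant}`.
#'
#' @param x a `sankey_model` or `comparison_result`.
#' @param path output path.
#' @export
export_json <- function(x, path) {
  if (inherits(x, "sankey_model")) {
    out <- list(
      nodes = lapply(seq_len(nrow(x$nodes)), function(i)
        list(dataset = x$nodes$dataset[i], trend = x$nodes$trend[i],
             size = x$nodes$size[i], genes = sort(x$nodes$genes[[i]]))),
      links = lapply(seq_len(nrow(x$links)), function(i)
        list(trend_a = x$links$trend_a[i], trend_b = x$links$trend_b[i],
             size = x$links$size[i], genes = sort(x$links$genes[[i]]))),
      summary = x$summary)
  } else if (inherits(x, "comparison_result")) {
    out <- list(
      dataset_a = x$dataset_a, dataset_b = x$dataset_b, k = x$k,
      intersecting = x$intersecting,
      only_a = x$only_a, only_b = x$only_b,
      centroids = x$centroids)
  } else stop("unsupported object for JSON export: ", class(x)[1L])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}
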