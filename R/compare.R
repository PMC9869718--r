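#' Classify intersecting genes as concordant or discordant
#'
#' From the joint trend assignment each intersecting gene carries two labels
#' in one shared label space — one per dataset. A gene is concordant iff its
#' two labels are equal (same trend in both datasets), discordant otherwise.
#'
#' @param pair a [cluster_pair] result, or the three assignments given
#'   separately via `joint`, `non_a`, `non_b`.
#' @param stats_a,stats_b optional [compute_gene_stats] tables (raw-value
#'   statistics) attached for dynamic filtering downstream.
#' @return list of class `comparison_result` with `intersecting` (data.frame
#'   `gene`, `label_a`, `label_b`, `concordant`), `only_a` / `only_b`
#'   (data.frames `gene`, `label`), `k`, dataset ids, `centroids`, and the
#'   attached stats.
#' @export
build_comparison <- function(pair, stats_a = NULL, stats_b = NULL) {
  stopifnot(inherits(pair, "pair_clustering"))
  joint <- pair$joint
  lab <- joint$labels
  a_id <- pair$dataset_a
  b_id <- pair$dataset_b
  la <- lab[lab$dataset == a_id, c("gene", "label")]
  lb <- lab[lab$dataset == b_id, c("gene", "label")]
  if (!setequal(la$gene, lb$gene))
    stop("corrupt assignment: gene labeled in only one dataset: ",
         paste(utils::head(c(setdiff(la$gene, lb$gene),
                             setdiff(lb$gene, la$gene)), 5L), collapse = ", "))
  genes <- sort(la$gene)
  inter <- data.frame(gene = genes,
                      label_a = la$label[match(genes, la$gene)],
                      label_b = lb$label[match(genes, lb$gene)],
                      stringsAsFactors = FALSE)
  inter$concordant <- inter$label_a == inter$label_b
  side <- function(asg) {
    df <- asg$labels[, c("gene", "label")]
    df[order(df$gene), , drop = FALSE]
  }
  structure(list(intersecting = inter,
                 only_a = side(pair$non_a), only_b = side(pair$non_b),
                 k = pair$k, dataset_a = a_id, dataset_b = b_id,
                 centroids = pair$joint$centroids,
                 stats_a = stats_a, stats_b = stats_b),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  n <- nrow(x$intersecting)
  nc <- sum(x$intersecting$concordant)
  cat(sprintf(
    "comparison_result %s vs %s (k=%d): %d intersecting (%.1f%% concordant), %d only-%s, %d only-%s\n",
    x$dataset_a, x$dataset_b, x$k, n, 100 * nc / n,
    nrow(x$only_a), x$dataset_a, nrow(x$only_b), x$dataset_b))
  invisible(x)
}

sankey_summary <- function(links) {
  diag_links <- links$trend_a == links$trend_b
  concordant <- sum(links$size[diag_links])
  total <- sum(links$size)
  list(concordant = concordant,
       discordant = total - concordant,
       pct_concordant = if (total > 0) 100 * concordant / total else NA_real_,
       pct_discordant = if (total > 0) 100 * (total - concordant) / total
                        else NA_real_)
}

#' Build the Sankey trend-intersection model
#'
#' Nodes are the (dataset, trend) gene sets; links are the gene sets at each
#' observed (trend_a, trend_b) intersection. With `k` trends per dataset at
#' most `k^2` links exist. Node and link sizes obey the conservation laws:
#' every node's size equals the sum of its incident link sizes, and link
#' sizes sum to the number of intersecting genes.
#'
#' @param result a [build_comparison] result.
#' @return list of class `sankey_model` with `nodes` (data.frame `dataset`,
#'   `trend`, `size`, list-column `genes`), `links` (data.frame `trend_a`,
#'   `trend_b`, `size`, list-column `genes`), `summary` (concordant /
#'   discordant counts and percentages), `k`, dataset ids.
#' @export
build_sankey <- function(result) {
  stopifnot(inherits(result, "comparison_result"))
  inter <- result$intersecting
  if (nrow(inter) == 0L) stop("no intersecting genes")
  node_rows <- list()
  for (ds in c("a", "b")) {
    labcol <- paste0("label_", ds)
    id <- if (ds == "a") result$dataset_a else result$dataset_b
    for (t in sort(unique(inter[[labcol]]))) {
      members <- inter$gene[inter[[labcol]] == t]
      node_rows[[length(node_rows) + 1L]] <-
        list(dataset = id, trend = t, size = length(members), genes = members)
    }
  }
  nodes <- data.frame(
    dataset = vapply(node_rows, `[[`, "", "dataset"),
    trend = vapply(node_rows, `[[`, 0L, "trend"),
    size = vapply(node_rows, `[[`, 0L, "size"),
    stringsAsFactors = FALSE)
  nodes$genes <- lapply(node_rows, `[[`, "genes")
  combos <- unique(inter[, c("label_a", "label_b")])
  combos <- combos[order(combos$label_a, combos$label_b), , drop = FALSE]
  link_genes <- lapply(seq_len(nrow(combos)), function(i)
    inter$gene[inter$label_a == combos$label_a[i] &
               inter$label_b == combos$label_b[i]])
  links <- data.frame(trend_a = combos$label_a, trend_b = combos$label_b,
                      size = lengths(link_genes), stringsAsFactors = FALSE)
  links$genes <- link_genes
  rownames(links) <- NULL
  structure(list(nodes = nodes, links = links,
                 summary = sankey_summary(links),
                 k = result$k,
                 dataset_a = result$dataset_a, dataset_b = result$dataset_b),
            class = "sankey_model")
}

#' @export
print.sankey_model <- function(x, ...) {
  cat(sprintf(
    "sankey_model %s vs %s: %d nodes, %d links, %d genes (%.1f%% concordant)\n",
    x$dataset_a, x$dataset_b, nrow(x$nodes), nrow(x$links),
    x$summary$concordant + x$summary$discordant, x$summary$pct_concordant))
  invisible(x)
}

#' Overview counts across dataset pairs
#'
#' One row per pairwise comparison with the counts shown in the overview
#' stacked bars: concordant and discordant intersecting genes plus the
#' non-intersecting genes of either side.
#'
#' @param results list of [build_comparison] results (one per pair).
#' @param partitions list of [partition_genes] results, aligned with
#'   `results`; if omitted, non-intersecting counts are taken from the
#'   comparison results' `only_a` / `only_b` label tables.
#' @return data.frame with columns `dataset_a`, `dataset_b`,
#'   `n_intersecting_concordant`, `n_intersecting_discordant`, `n_only_a`,
#'   `n_only_b`.
#' @export
overview <- function(results, partitions = NULL) {
  if (inherits(results, "comparison_result")) results <- list(results)
  stopifnot(length(results) >= 1L)
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    n_only_a <- if (!is.null(partitions)) length(partitions[[i]]$only_a)
                else nrow(r$only_a)
    n_only_b <- if (!is.null(partitions)) length(partitions[[i]]$only_b)
                else nrow(r$only_b)
    data.frame(dataset_a = r$dataset_a, dataset_b = r$dataset_b,
               n_intersecting_concordant = sum(r$intersecting$concordant),
               n_intersecting_discordant = sum(!r$intersecting$concordant),
               n_only_a = n_only_a, n_only_b = n_only_b,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("overview_counts", "data.frame")
  out
}

#' Apply dynamic filters to a Sankey model
#'
#' First-level exploration filters: percentile-range filters on the raw-value
#' gene statistics (variance or median abundance, single- or both-dataset
#' scope) remove genes from node and link member sets, and `min_link_size`
#' removes small intersections. Trend labels are NOT recomputed — filtering
#' subsets the existing clustering so trend identities stay stable during
#' exploration. Percentile ranks are the global ranks computed on the loaded
#' data. The summary is recomputed over the surviving genes.
#'
#' @param model a [build_sankey] model.
#' @param result the [build_comparison] result the model was built from
#'   (carries the `stats_a` / `stats_b` tables; required when `specs` is
#'   non-empty).
#' @param specs list of [filter_spec] objects (possibly empty).
#' @param min_link_size links smaller than this are dropped (default 0).
#' @return A filtered `sankey_model`; member sets are always subsets of the
#'   input model's.
#' @export
apply_filters <- function(model, result = NULL, specs = list(),
                          min_link_size = 0L) {
  stopifnot(inherits(model, "sankey_model"))
  if (min_link_size < 0) stop("min_link_size must be >= 0")
  if (inherits(specs, "filter_spec")) specs <- list(specs)
  keep <- unique(unlist(model$links$genes))
  for (spec in specs) {
    if (is.null(result) || is.null(result$stats_a) || is.null(result$stats_b))
      stop("gene stats required for percentile filters; pass a ",
           "comparison_result built with stats_a/stats_b")
    surv_a <- stats_in_range(result$stats_a, spec)
    surv_b <- stats_in_range(result$stats_b, spec)
    surv <- if (spec$scope == "both_datasets") intersect(surv_a, surv_b)
            else union(surv_a, surv_b)
    keep <- intersect(keep, surv)
  }
  links <- model$links
  links$genes <- lapply(links$genes, function(g) g[g %in% keep])
  links$size <- lengths(links$genes)
  links <- links[links$size >= min_link_size & links$size > 0L, ,
                 drop = FALSE]
  rownames(links) <- NULL
  nodes <- model$nodes
  nodes$genes <- lapply(nodes$genes, function(g)
    g[g %in% unlist(links$genes)])
  nodes$size <- lengths(nodes$genes)
  nodes <- nodes[nodes$size > 0L, , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, links = links,
                 summary = sankey_summary(links),
                 k = model$k, dataset_a = model$dataset_a,
                 dataset_b = model$dataset_b),
            class = "sankey_model")
}

#' Locate query genes on the Sankey model
#'
#' Resolves each queried gene ID to the (trend_a, trend_b) link it sits on,
#' or `"absent"` if it is not among the model's intersecting genes. Used to
#' draw highlighted genes in black in the trend views.
#'
#' @param model a `sankey_model`.
#' @param query character vector of gene IDs.
#' @return data.frame with columns `gene`, `trend_a`, `trend_b`, `status`
#'   (`"found"` or `"absent"`; absent rows have `NA` trends).
#' @export
highlight <- function(model, query) {
  stopifnot(inherits(model, "sankey_model"))
  query <- unique(query)
  rows <- lapply(query, function(g) {
    hit <- which(vapply(model$links$genes, function(set) g %in% set, TRUE))
    if (length(hit) == 0L)
      data.frame(gene = g, trend_a = NA_integer_, trend_b = NA_integer_,
                 status = "absent", stringsAsFactors = FALSE)
    else
      data.frame(gene = g, trend_a = model$links$trend_a[hit[1L]],
                 trend_b = model$links$trend_b[hit[1L]],
                 status = "found", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

parse_pick <- function(pick) {
  # "link:ta-tb" or "node:dataset:trend"
  if (grepl("^link:", pick)) {
    tt <- strsplit(sub("^link:", "", pick), "-", fixed = TRUE)[[1L]]
    if (length(tt) != 2L) stop("malformed link pick: ", pick)
    list(type = "link", trend_a = as.integer(tt[1L]),
         trend_b = as.integer(tt[2L]))
  } else if (grepl("^node:", pick)) {
    tt <- strsplit(sub("^node:", "", pick), ":", fixed = TRUE)[[1L]]
    if (length(tt) != 2L) stop("malformed node pick: ", pick)
    list(type = "node", dataset = tt[1L], trend = as.integer(tt[2L]))
  } else stop("unknown pick (use 'link:ta-tb' or 'node:dataset:trend'): ",
              pick)
}

#' Extract a gene selection from Sankey nodes or links
#'
#' Picks are strings of the form `"link:<trend_a>-<trend_b>"` or
#' `"node:<dataset>:<trend>"`. The selection is the deduplicated union of the
#' picked member sets; per-pick counts and the percentage of all intersecting
#' genes are reported. The selection feeds second-level analysis (profile
#' plots and GO enrichment).
#'
#' @param model a `sankey_model`.
#' @param picks character vector of pick identifiers.
#' @return list of class `selection` with `genes` (sorted character vector)
#'   and `picks` (data.frame `pick`, `n_genes`, `pct_of_intersecting`).
#' @export
select_genes <- function(model, picks) {
  stopifnot(inherits(model, "sankey_model"), length(picks) >= 1L)
  total <- sum(model$links$size)
  sets <- lapply(picks, function(p) {
    q <- parse_pick(p)
    if (q$type == "link") {
      i <- which(model$links$trend_a == q$trend_a &
                 model$links$trend_b == q$trend_b)
      if (length(i) == 0L) stop("unknown link: ", p)
      model$links$genes[[i]]
    } else {
      i <- which(model$nodes$dataset == q$dataset &
                 model$nodes$trend == q$trend)
      if (length(i) == 0L) stop("unknown node: ", p)
      model$nodes$genes[[i]]
    }
  })
  picks_df <- data.frame(pick = picks, n_genes = lengths(sets),
                         pct_of_intersecting = 100 * lengths(sets) / total,
                         stringsAsFactors = FALSE)
  structure(list(genes = sort(unique(unlist(sets))), picks = picks_df),
            class = "selection")
}
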