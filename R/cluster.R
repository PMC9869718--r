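#' Partition two datasets' genes into intersecting and non-intersecting sets
#'
#' A pairwise trend comparison analyzes genes found in both datasets
#' (intersecting) jointly, and genes found in only one dataset separately per
#' dataset. Both matrices must share identical condition names in identical
#' order, because condition order is the x-axis of every trend.
#'
#' @param a,b [abundance_matrix] objects.
#' @return list of class `gene_partition` with character vectors
#'   `intersecting`, `only_a`, `only_b` and labels `dataset_a`, `dataset_b`.
#' @export
partition_genes <- function(a, b) {
  stopifnot(inherits(a, "abundance_matrix"), inherits(b, "abundance_matrix"))
  if (!identical(a$conditions, b$conditions)) {
    diff <- union(setdiff(a$conditions, b$conditions),
                  setdiff(b$conditions, a$conditions))
    extra <- if (length(diff)) paste(diff, collapse = ", ") else
      "same names, different order"
    stop("condition mismatch between datasets: ", extra)
  }
  structure(list(intersecting = sort(intersect(a$genes, b$genes)),
                 only_a = sort(setdiff(a$genes, b$genes)),
                 only_b = sort(setdiff(b$genes, a$genes)),
                 dataset_a = a$dataset_id, dataset_b = b$dataset_id),
            class = "gene_partition")
}

#' Stack intersecting genes' z-scored profiles for early integration
#'
#' Builds the combined matrix that early integration clusters: one row per
#' (gene, dataset) over the shared conditions, i.e. `2 * |intersecting|`
#' rows. Row order is deterministic (genes sorted, dataset A before B within
#' each gene).
#'
#' @param a,b z-scored [abundance_matrix] objects.
#' @param partition a [partition_genes] result.
#' @return list of class `stacked_profiles` with `profiles` (numeric matrix)
#'   and `keys` (data.frame with columns `gene`, `dataset`).
#' @export
stack_intersecting <- function(a, b, partition) {
  stopifnot(inherits(partition, "gene_partition"))
  if (a$state != "zscored" || b$state != "zscored")
    stop("stack_intersecting requires z-scored matrices")
  genes <- partition$intersecting
  if (length(genes) == 0L)
    stop("nothing to compare: no intersecting genes")
  keys <- data.frame(gene = rep(genes, each = 2L),
                     dataset = rep(c(a$dataset_id, b$dataset_id),
                                   length(genes)),
                     stringsAsFactors = FALSE)
  profiles <- matrix(NA_real_, nrow(keys), length(a$conditions),
                     dimnames = list(NULL, a$conditions))
  idx_a <- keys$dataset == a$dataset_id
  profiles[idx_a, ] <- a$values[keys$gene[idx_a], , drop = FALSE]
  profiles[!idx_a, ] <- b$values[keys$gene[!idx_a], , drop = FALSE]
  structure(list(profiles = profiles, keys = keys),
            class = "stacked_profiles")
}

# squared Euclidean distances from each row of x to each row of centers
sq_dist <- function(x, centers) {
  xc <- rowSums(x^2)
  cc <- rowSums(centers^2)
  outer(xc, cc, "+") - 2 * x %*% t(centers)
}

kmeans_pp_seed <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- sq_dist(x, x[centers[1L], , drop = FALSE])[, 1L]
  for (i in seq_len(k - 1L) + 1L) {
    d2 <- pmax(d2, 0)
    if (sum(d2) <= 0) {
      # all remaining points coincide with a chosen center: uniform fallback
      pool <- setdiff(seq_len(n), centers[seq_len(i - 1L)])
      centers[i] <- pool[sample.int(length(pool), 1L)]
    } else {
      centers[i] <- sample.int(n, 1L, prob = d2)
    }
    d2 <- pmin(d2, sq_dist(x, x[centers[i], , drop = FALSE])[, 1L])
  }
  x[centers, , drop = FALSE]
}

lloyd <- function(x, centers, max_iter, tol) {
  k <- nrow(centers)
  for (iter in seq_len(max_iter)) {
    d <- sq_dist(x, centers)
    assign <- max.col(-d, ties.method = "first")
    new_centers <- centers
    for (j in seq_len(k)) {
      members <- assign == j
      if (!any(members)) {
        # empty-cluster repair: reseed with the point farthest from its
        # current centroid
        far <- which.max(d[cbind(seq_len(nrow(x)), assign)])
        new_centers[j, ] <- x[far, ]
        assign[far] <- j
      } else {
        new_centers[j, ] <- colMeans(x[members, , drop = FALSE])
      }
    }
    shift <- max(sqrt(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (shift < tol) break
  }
  d <- sq_dist(x, centers)
  assign <- max.col(-d, ties.method = "first")
  inertia <- sum(pmax(d[cbind(seq_len(nrow(x)), assign)], 0))
  list(assign = assign, centers = centers, inertia = inertia)
}

#' k-means++ clustering of profile rows into trends
#'
#' Lloyd's algorithm with k-means++ seeding on squared Euclidean distance,
#' `n_init` restarts keeping the lowest-inertia solution, and empty-cluster
#' repair by reseeding at the farthest point. After fitting, labels are
#' canonicalized by sorting centroids by descending value at the first
#' condition (ties broken by the following conditions), so a fixed seed gives
#' bit-identical, reproducibly ordered labels.
#'
#' @param rows a [stack_intersecting] result, or a plain numeric matrix with
#'   one profile per row.
#' @param k number of trends, between 2 and 10 (and at most the number of
#'   rows).
#' @param seed integer seed; drives seeding of all restarts.
#' @param n_init number of k-means++ restarts (default 10).
#' @param max_iter Lloyd iteration cap (default 300).
#' @param tol convergence threshold on the maximum centroid shift
#'   (default 1e-6).
#' @return list of class `trend_assignment` with `k`, `labels` (data.frame
#'   `gene`, `dataset`, `label` with labels in `0..k-1`), `centroids`
#'   (k x conditions matrix, row `i` = centroid of label `i-1`) and
#'   `inertia`.
#' @export
kmeans_pp <- function(rows, k, seed = 0L, n_init = 10L, max_iter = 300L,
                      tol = 1e-6) {
  if (inherits(rows, "stacked_profiles")) {
    x <- rows$profiles
    keys <- rows$keys
  } else {
    x <- as.matrix(rows)
    keys <- data.frame(gene = if (is.null(rownames(x)))
      as.character(seq_len(nrow(x))) else rownames(x),
      dataset = NA_character_, stringsAsFactors = FALSE)
  }
  k <- as.integer(k)
  if (k < 2L || k > 10L) stop("k must lie in [2, 10]")
  if (k > nrow(x)) stop("k exceeds the number of rows")
  best <- NULL
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  for (run in seq_len(n_init)) {
    fit <- lloyd(x, kmeans_pp_seed(x, k), max_iter, tol)
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  # canonical order: descending centroid values, first condition dominant
  ord <- do.call(order, c(as.data.frame(-best$centers), list()))
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  labels <- relabel[best$assign] - 1L
  structure(list(k = k,
                 labels = cbind(keys, data.frame(label = labels)),
                 centroids = best$centers[ord, , drop = FALSE],
                 inertia = best$inertia),
            class = "trend_assignment")
}

empty_assignment <- function(k, conditions) {
  structure(list(k = k,
                 labels = data.frame(gene = character(0),
                                     dataset = character(0),
                                     label = integer(0),
                                     stringsAsFactors = FALSE),
                 centroids = matrix(numeric(0), 0L, length(conditions),
                                    dimnames = list(NULL, conditions)),
                 inertia = 0),
            class = "trend_assignment")
}

#' Cluster a dataset pair: joint early integration plus per-dataset runs
#'
#' Z-scores both matrices (if raw), partitions genes, clusters the stacked
#' intersecting profiles jointly (one shared label space, so equal labels in
#' both datasets mean the gene follows the same trend — the basis of
#' concordance), and clusters each non-intersecting set separately whenever
#' it has at least `k` members. All three runs derive their seeds
#' deterministically from `seed` (joint: `seed`; only-A: `seed + 1`;
#' only-B: `seed + 2`), so a single integer reproduces the whole session.
#'
#' @param a,b [abundance_matrix] objects (raw or z-scored).
#' @param k number of trends (2-10).
#' @param seed integer seed.
#' @param n_init restarts per run.
#' @return list of class `pair_clustering` with `joint`, `non_a`, `non_b`
#'   ([kmeans_pp]-style assignments), the `partition`, dataset ids, `k`, and
#'   the z-scored matrices `za`, `zb`.
#' @export
cluster_pair <- function(a, b, k, seed = 0L, n_init = 10L) {
  za <- if (a$state == "raw") zscore(a) else a
  zb <- if (b$state == "raw") zscore(b) else b
  part <- partition_genes(za, zb)
  stacked <- stack_intersecting(za, zb, part)
  joint <- kmeans_pp(stacked, k, seed = seed, n_init = n_init)
  seed <- as.integer(seed)
  cluster_side <- function(m, genes, side_seed) {
    if (length(genes) < k) return(empty_assignment(k, m$conditions))
    sub <- m$values[genes, , drop = FALSE]
    fit <- kmeans_pp(sub, k, seed = side_seed, n_init = n_init)
    fit$labels$dataset <- m$dataset_id
    fit
  }
  structure(list(joint = joint,
                 non_a = cluster_side(za, part$only_a, seed + 1L),
                 non_b = cluster_side(zb, part$only_b, seed + 2L),
                 partition = part,
                 dataset_a = za$dataset_id, dataset_b = zb$dataset_id,
                 k = as.integer(k), za = za, zb = zb),
            class = "pair_clustering")
}

#' Build a pair clustering from a user-supplied custom clustering
#'
#' Wraps an externally produced trend comparison (see
#' [read_custom_clustering]) into the same structure [cluster_pair] emits,
#' so downstream comparison, Sankey and enrichment steps behave identically.
#' Centroids are recomputed as per-label means of the z-scored profiles.
#'
#' @param cc a `custom_clustering`.
#' @return A `pair_clustering` (with empty non-intersecting assignments,
#'   since custom files describe intersecting genes only).
#' @export
pair_from_custom <- function(cc) {
  stopifnot(inherits(cc, "custom_clustering"))
  ds <- cc$datasets
  mats <- lapply(ds, function(d)
    zscore(abundance_matrix(cc$profiles[[d]], d)))
  names(mats) <- ds
  part <- partition_genes(mats[[1L]], mats[[2L]])
  k <- max(2L, length(unique(as.vector(cc$labels))))
  genes <- sort(cc$genes)
  labels <- data.frame(
    gene = rep(genes, each = 2L),
    dataset = rep(ds, length(genes)),
    stringsAsFactors = FALSE)
  labels$label <- cc$labels[cbind(labels$gene, labels$dataset)]
  conds <- cc$conditions
  centroids <- matrix(0, k, length(conds), dimnames = list(NULL, conds))
  for (lab in seq_len(k) - 1L) {
    rows <- labels[labels$label == lab, ]
    if (nrow(rows) == 0L) next
    prof <- t(vapply(seq_len(nrow(rows)), function(i)
      mats[[rows$dataset[i]]]$values[rows$gene[i], ], numeric(length(conds))))
    centroids[lab + 1L, ] <- colMeans(prof)
  }
  joint <- structure(list(k = k, labels = labels, centroids = centroids,
                          inertia = NA_real_), class = "trend_assignment")
  structure(list(joint = joint,
                 non_a = empty_assignment(k, conds),
                 non_b = empty_assignment(k, conds),
                 partition = part,
                 dataset_a = ds[1L], dataset_b = ds[2L],
                 k = k, za = mats[[1L]], zb = mats[[2L]]),
            class = "pair_clustering")
}
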