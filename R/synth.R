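#' Default planted trend shapes
#'
#' Piecewise-linear prototypes over the condition axis, in z-score-like
#' units: increasing, decreasing, single-peak, single-dip, then (for more
#' than four trends) peaks and dips shifted along the axis. Shapes are the
#' qualitative trend types a trend-comparison run should recover.
#'
#' @param n_trends number of shapes (2-10).
#' @param n_conditions number of conditions (>= 2).
#' @return numeric matrix, `n_trends` x `n_conditions`.
#' @export
default_shapes <- function(n_trends, n_conditions) {
  stopifnot(n_trends >= 2L, n_trends <= 10L, n_conditions >= 2L)
  t <- seq(0, 1, length.out = n_conditions)
  tri <- function(center, sign = 1) sign * (1 - 2 * abs(t - center)) * 1.5
  protos <- list(
    2 * t - 1,                                   # increasing
    1 - 2 * t,                                   # decreasing
    tri(0.5),                                    # peak mid
    tri(0.5, -1),                                # dip mid
    tri(0.25), tri(0.75),                        # shifted peaks
    tri(0.25, -1), tri(0.75, -1),                # shifted dips
    rep(c(1, -1), length.out = n_conditions) * 1.2,  # zig-zag
    abs(2 * t - 1) * 2 - 1)                      # V shape
  do.call(rbind, protos[seq_len(n_trends)])
}

#' Specify a synthetic paired dataset with planted trend structure
#'
#' Describes the generative world: `n_trends` planted shapes; a count of
#' genes per (trend_a, trend_b) combination (scalar = every cell equally
#' populated; matrix = explicit per-cell counts, so the planted concordant
#' fraction is the diagonal mass over the total); i.i.d. Gaussian noise in
#' shape space; fractions of genes appearing in only one dataset; and affine
#' transforms mapping shape space to raw abundance units per dataset (which
#' per-gene z-scoring approximately inverts). Shapes must be separable:
#' minimum pairwise Euclidean distance greater than `4 * noise_sd`.
#'
#' @param n_trends number of planted trends (2-10).
#' @param n_conditions number of conditions (default 6).
#' @param shapes optional `n_trends` x `n_conditions` shape matrix; defaults
#'   to [default_shapes].
#' @param genes_per_cell scalar count, or an `n_trends` x `n_trends` count
#'   matrix (rows = trend in A, cols = trend in B).
#' @param noise_sd Gaussian noise sd in shape units (default 0.2).
#' @param frac_only_a,frac_only_b fractions (of the intersecting count) of
#'   extra genes present in only one dataset (default 0.1 each).
#' @param scale_a,scale_b length-2 numeric `c(mult, add)` affine transforms
#'   to raw units; defaults emulate FPKM-like (A) and log2-LFQ-like (B)
#'   scales.
#' @param seed integer seed.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_trends = 4L, n_conditions = 6L, shapes = NULL,
                           genes_per_cell = 20L, noise_sd = 0.2,
                           frac_only_a = 0.1, frac_only_b = 0.1,
                           scale_a = c(100, 500), scale_b = c(2, 20),
                           seed = 1L) {
  n_trends <- as.integer(n_trends)
  if (is.null(shapes)) shapes <- default_shapes(n_trends, n_conditions)
  stopifnot(nrow(shapes) == n_trends, ncol(shapes) == n_conditions)
  if (is.matrix(genes_per_cell)) {
    stopifnot(nrow(genes_per_cell) == n_trends,
              ncol(genes_per_cell) == n_trends)
    cells <- genes_per_cell
  } else {
    stopifnot(genes_per_cell >= 1L)
    cells <- matrix(as.integer(genes_per_cell), n_trends, n_trends)
  }
  if (sum(cells) < 1L) stop("no populated cells")
  dmin <- min(stats::dist(shapes))
  if (dmin <= 4 * noise_sd)
    stop(sprintf("inseparable shapes: min pairwise distance %.3f <= 4 * noise_sd = %.3f",
                 dmin, 4 * noise_sd))
  structure(list(n_trends = n_trends, n_conditions = as.integer(n_conditions),
                 shapes = shapes, cells = cells, noise_sd = noise_sd,
                 frac_only_a = frac_only_a, frac_only_b = frac_only_b,
                 scale_a = scale_a, scale_b = scale_b,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Per-cell counts realizing a target concordant fraction
#'
#' Distributes `n_total` genes over the `n_trends^2` (trend_a, trend_b)
#' cells so that the diagonal (concordant) cells hold `concordant_frac` of
#' the mass, spread evenly, and the off-diagonal cells share the rest evenly
#' (remainders go to the first cells in row-major order).
#'
#' @param n_trends number of trends.
#' @param n_total total intersecting gene count.
#' @param concordant_frac target fraction in \[0, 1\].
#' @return integer `n_trends` x `n_trends` matrix summing to `n_total`.
#' @export
cells_for_fraction <- function(n_trends, n_total, concordant_frac) {
  stopifnot(concordant_frac >= 0, concordant_frac <= 1)
  n_diag <- round(n_total * concordant_frac)
  n_off <- n_total - n_diag
  cells <- matrix(0L, n_trends, n_trends)
  spread <- function(total, idx) {
    base <- total %/% length(idx)
    extra <- total %% length(idx)
    counts <- rep(base, length(idx))
    if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
    counts
  }
  diag_idx <- cbind(seq_len(n_trends), seq_len(n_trends))
  cells[diag_idx] <- spread(n_diag, seq_len(n_trends))
  off <- which(row(cells) != col(cells), arr.ind = TRUE)
  off <- off[order(off[, 1L], off[, 2L]), , drop = FALSE]
  cells[off] <- spread(n_off, seq_len(nrow(off)))
  cells
}

#' Generate a synthetic dataset pair with planted trends
#'
#' For each populated (trend_a, trend_b) cell, genes receive profile
#' `scale_a[1] * (shape_a + noise) + scale_a[2]` in dataset A and
#' `scale_b[1] * (shape_b + noise') + scale_b[2]` in dataset B, with
#' independent Gaussian noise per dataset. Additional non-intersecting genes
#' (a fraction of the intersecting count per side) receive a uniformly drawn
#' trend in their single dataset. Output is deterministic in the spec's
#' seed.
#'
#' @param spec a [synthetic_spec].
#' @return list of class `synthetic_pair` with raw [abundance_matrix]
#'   objects `a` and `b` and `truth`, a data.frame with columns `gene`,
#'   `trend_a`, `trend_b` (NA where absent), `intersecting`, `concordant`;
#'   attribute `concordant_frac` gives the planted diagonal mass fraction.
#' @export
generate_pair <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)
  k <- spec$n_trends
  nc <- spec$n_conditions
  conds <- sprintf("cond%02d", seq_len(nc))
  cells <- spec$cells
  n_inter <- sum(cells)
  ta <- integer(0); tb <- integer(0)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ta <- c(ta, rep(i - 1L, cells[i, j]))
    tb <- c(tb, rep(j - 1L, cells[i, j]))
  }
  gene_ids <- sprintf("gene%05d", seq_len(n_inter))
  noise <- function(n) matrix(stats::rnorm(n * nc, sd = spec$noise_sd), n, nc)
  raw <- function(trends, scale, n) {
    profs <- spec$shapes[trends + 1L, , drop = FALSE] + noise(n)
    scale[1L] * profs + scale[2L]
  }
  va <- raw(ta, spec$scale_a, n_inter)
  vb <- raw(tb, spec$scale_b, n_inter)
  rownames(va) <- rownames(vb) <- gene_ids
  colnames(va) <- colnames(vb) <- conds
  n_oa <- round(spec$frac_only_a * n_inter)
  n_ob <- round(spec$frac_only_b * n_inter)
  truth <- data.frame(gene = gene_ids, trend_a = ta, trend_b = tb,
                      intersecting = TRUE, stringsAsFactors = FALSE)
  if (n_oa > 0L) {
    t_oa <- sample.int(k, n_oa, replace = TRUE) - 1L
    ids <- sprintf("onlyA%05d", seq_len(n_oa))
    m <- raw(t_oa, spec$scale_a, n_oa)
    rownames(m) <- ids; colnames(m) <- conds
    va <- rbind(va, m)
    truth <- rbind(truth, data.frame(gene = ids, trend_a = t_oa,
                                     trend_b = NA_integer_,
                                     intersecting = FALSE))
  }
  if (n_ob > 0L) {
    t_ob <- sample.int(k, n_ob, replace = TRUE) - 1L
    ids <- sprintf("onlyB%05d", seq_len(n_ob))
    m <- raw(t_ob, spec$scale_b, n_ob)
    rownames(m) <- ids; colnames(m) <- conds
    vb <- rbind(vb, m)
    truth <- rbind(truth, data.frame(gene = ids, trend_a = NA_integer_,
                                     trend_b = t_ob, intersecting = FALSE))
  }
  truth$concordant <- truth$intersecting & truth$trend_a == truth$trend_b
  out <- structure(list(a = abundance_matrix(va, "A"),
                        b = abundance_matrix(vb, "B"),
                        truth = truth),
                   class = "synthetic_pair")
  attr(out, "concordant_frac") <- sum(diag(cells)) / n_inter
  out
}

#' Generate a synthetic GO annotation with one planted enriched term
#'
#' `n_terms - 1` background terms whose members are drawn uniformly from all
#' genes with probability `base_prob`; one planted term whose membership
#' probability is `fold` times higher for genes in the `enriched_cell`
#' (trend_a, trend_b) combination. Categories cycle through the three main
#' GO categories. Used to test enrichment end-to-end.
#'
#' @param truth the `truth` data.frame of a [generate_pair] result.
#' @param n_terms total number of terms (>= 2).
#' @param enriched_cell integer length-2 vector `c(trend_a, trend_b)`; must
#'   be populated in `truth`.
#' @param fold membership-probability fold change inside the cell (> 1).
#' @param base_prob baseline membership probability (default 0.1).
#' @param seed integer seed.
#' @return An `annotation` table; the planted term has
#'   `term_id == "GO:PLANTED"`.
#' @export
generate_annotation <- function(truth, n_terms = 20L,
                                enriched_cell = c(0L, 0L), fold = 5,
                                base_prob = 0.1, seed = 1L) {
  if (fold <= 1) stop("fold must be > 1")
  genes <- truth$gene[truth$intersecting]
  in_cell <- truth$intersecting &
    truth$trend_a == enriched_cell[1L] & truth$trend_b == enriched_cell[2L]
  if (!any(in_cell, na.rm = TRUE)) stop("enriched cell not populated in truth")
  cell_genes <- truth$gene[which(in_cell)]
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  categories <- c("molecular function", "biological process",
                  "cellular component")
  draw_uniform <- function() genes[stats::runif(length(genes)) < base_prob]
  term_sets <- lapply(seq_len(n_terms - 1L), function(i) draw_uniform())
  p <- ifelse(genes %in% cell_genes, pmin(1, fold * base_prob), base_prob)
  term_sets[[n_terms]] <- genes[stats::runif(length(genes)) < p]
  ids <- c(sprintf("GO:%07d", seq_len(n_terms - 1L)), "GO:PLANTED")
  ann <- data.frame(term_id = ids, term_name = ids,
                    category = rep_len(categories, n_terms),
                    stringsAsFactors = FALSE)
  ann$genes <- term_sets
  keep <- lengths(ann$genes) > 0L
  ann <- ann[keep, , drop = FALSE]
  rownames(ann) <- NULL
  class(ann) <- c("annotation", "data.frame")
  ann
}
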