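#' Two-sided Fisher's exact test p-value for a 2x2 table
#'
#' Computed by hypergeometric enumeration: with margins fixed, the
#' probability of each achievable table is `dhyper`, and the two-sided
#' p-value is the sum of probabilities of all tables no more probable than
#' the observed one (the standard "small p method", as used by
#' [stats::fisher.test] at odds ratio 1).
#'
#' @param a,b,c,d cell counts: `a` = selected & in term, `b` = selected &
#'   not in term, `c` = not selected & in term, `d` = neither.
#' @return p-value in \[0, 1\].
#' @export
fisher_p <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- a + c          # white balls: genes in term
  n_ <- b + d         # black balls: genes not in term
  k <- a + b          # draws: selection size
  support <- max(0L, k - n_):min(k, m)
  probs <- stats::dhyper(support, m, n_, k)
  p_obs <- stats::dhyper(a, m, n_, k)
  # relative tolerance guards against ties lost to floating point
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg FDR (step-up)
#'
#' `q_(i) = min_{j >= i} ( m * p_(j) / j )`, reported in the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of FDR values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  ord <- order(p)
  q_sorted <- rev(cummin(rev(m * p[ord] / seq_len(m))))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

#' GO-term enrichment of a gene selection
#'
#' For every annotated term a 2x2 contingency table (selected / not-selected
#' x in-term / not-in-term) over the background universe is tested with a
#' two-sided Fisher's exact test. Direction is `over` when the observed
#' in-term count exceeds its expectation
#' (`n_selected * n_background_in_term / n_background`), `under` otherwise.
#' Benjamini-Hochberg FDR is applied within each GO category separately by
#' default (set `per_category = FALSE` for a single global correction);
#' terms with FDR below `alpha` are flagged significant.
#'
#' The background is either the whole annotation universe (union of all term
#' member sets) or an explicit gene vector, e.g. the intersecting genes of
#' the current first-level analysis. Selection genes absent from the
#' background are dropped with a warning.
#'
#' @param selection character vector of selected gene IDs (or a
#'   [select_genes] result).
#' @param annotation an [read_annotation] table.
#' @param background `"whole_annotation"` or a character vector of gene IDs.
#' @param alpha significance threshold on the FDR (default 0.05).
#' @param per_category apply BH within each GO category separately
#'   (default `TRUE`).
#' @return data.frame of class `enrichment_table` with columns `term_id`,
#'   `term_name`, `category`, `n_selected_in_term`, `n_selected`,
#'   `n_background_in_term`, `n_background`, `expected`, `direction`,
#'   `p_value`, `fdr`, `significant`, sorted by `fdr` then `p_value`.
#' @export
enrich <- function(selection, annotation, background = "whole_annotation",
                   alpha = 0.05, per_category = TRUE) {
  if (inherits(selection, "selection")) selection <- selection$genes
  selection <- unique(selection)
  stopifnot(inherits(annotation, "annotation"), nrow(annotation) > 0L)
  if (identical(background, "whole_annotation"))
    background <- unique(unlist(annotation$genes))
  background <- unique(background)
  outside <- setdiff(selection, background)
  if (length(outside) > 0L) {
    warning(length(outside), " selected gene(s) absent from background dropped")
    selection <- setdiff(selection, outside)
  }
  if (length(selection) == 0L)
    stop("empty selection after background intersection")
  if (length(background) < length(selection))
    stop("background smaller than selection")
  n_sel <- length(selection)
  n_bg <- length(background)
  rows <- lapply(seq_len(nrow(annotation)), function(i) {
    members <- intersect(annotation$genes[[i]], background)
    a <- length(intersect(selection, members))
    b <- n_sel - a
    cc <- length(members) - a
    d <- n_bg - a - b - cc
    expected <- n_sel * length(members) / n_bg
    data.frame(term_id = annotation$term_id[i],
               term_name = annotation$term_name[i],
               category = annotation$category[i],
               n_selected_in_term = a, n_selected = n_sel,
               n_background_in_term = length(members), n_background = n_bg,
               expected = expected,
               direction = if (a > expected) "over" else "under",
               p_value = fisher_p(a, b, cc, d),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[tab$n_background_in_term > 0L, , drop = FALSE]
  tab$fdr <- NA_real_
  if (per_category) {
    for (cat in unique(tab$category)) {
      idx <- tab$category == cat
      tab$fdr[idx] <- bh_fdr(tab$p_value[idx])
    }
  } else {
    tab$fdr <- bh_fdr(tab$p_value)
  }
  tab$significant <- tab$fdr < alpha
  tab <- tab[order(tab$fdr, tab$p_value, tab$term_id), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("enrichment_table", "data.frame")
  tab
}
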