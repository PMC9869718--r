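test_that("fisher_p matches stats::fisher.test on random small tables", {
  set.seed(101)
  for (i in 1:100) {
    tab <- matrix(sample.int(50, 4, replace = TRUE) - 1L, 2)
    if (sum(tab) == 0) tab[1, 1] <- 1L
    p_ref <- stats::fisher.test(tab)$p.value
    p_own <- fisher_p(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    expect_equal(p_own, p_ref, tolerance = 1e-10)
  }
  # the spec's worked table
  expect_equal(fisher_p(8, 2, 10, 80),
               stats::fisher.test(matrix(c(8, 2, 10, 80), 2, byrow = TRUE))$p.value,
               tolerance = 1e-10)
})

test_that("bh_fdr implements the step-up formula", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(102)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
    expect_equal(bh_fdr(p), stats::p.adjust(p, "BH"), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  # monotone non-decreasing when ordered by p
  p <- runif(30)
  expect_true(all(diff(bh_fdr(p)[order(p)]) >= -1e-12))
})

make_annotation <- function(terms) {
  ann <- data.frame(term_id = names(terms), term_name = names(terms),
                    category = "biological process",
                    stringsAsFactors = FALSE)
  ann$genes <- unname(terms)
  class(ann) <- c("annotation", "data.frame")
  ann
}

test_that("enrich builds correct contingency tables and directions", {
  universe <- paste0("g", 1:100)
  ann <- make_annotation(list(
    T1 = universe[1:18],     # enriched in selection below
    T2 = universe[51:90],    # depleted in selection below
    T3 = universe))          # everything
  sel <- universe[1:20]
  et <- enrich(sel, ann, background = universe)
  r1 <- et[et$term_id == "T1", ]
  expect_equal(r1$n_selected_in_term, 18L)
  expect_equal(r1$expected, 20 * 18 / 100)
  expect_equal(r1$direction, "over")
  expect_equal(r1$p_value, fisher_p(18, 2, 0, 80), tolerance = 1e-12)
  r2 <- et[et$term_id == "T2", ]
  expect_equal(r2$n_selected_in_term, 0L)
  expect_equal(r2$direction, "under")  # observed 0, expected > 0
  # selection = background -> observed = expected, p = 1
  et2 <- enrich(universe, ann, background = universe)
  expect_true(all(et2$p_value == 1))
  expect_true(all(et2$n_selected_in_term == et2$n_background_in_term))
})

test_that("enrich validates selection/background relations", {
  universe <- paste0("g", 1:20)
  ann <- make_annotation(list(T1 = universe[1:10]))
  expect_warning(et <- enrich(c("g1", "zzz"), ann, background = universe),
                 "absent from background")
  expect_equal(et$n_selected, 1L)
  expect_error(suppressWarnings(enrich("zzz", ann, background = universe)),
               "empty selection")
})

test_that("per-category BH is applied separately and globally on request", {
  universe <- paste0("g", 1:60)
  ann <- make_annotation(list(A1 = universe[1:12], A2 = universe[13:24],
                              B1 = universe[1:12], B2 = universe[25:36]))
  ann$category <- c("molecular function", "molecular function",
                    "biological process", "biological process")
  sel <- universe[1:12]
  et <- enrich(sel, ann, background = universe)
  for (cat in unique(et$category)) {
    idx <- et$category == cat
    expect_equal(et$fdr[idx], bh_oracle(et$p_value[idx]), tolerance = 1e-12)
  }
  etg <- enrich(sel, ann, background = universe, per_category = FALSE)
  expect_equal(etg$fdr, bh_oracle(etg$p_value), tolerance = 1e-12)
})

test_that("a 5-fold planted term attains the smallest FDR in its category", {
  pair <- generate_pair(synthetic_spec(n_trends = 3, genes_per_cell = 30,
                                       seed = 60))
  ann <- generate_annotation(pair$truth, n_terms = 15,
                             enriched_cell = c(1L, 2L), fold = 5, seed = 61)
  cell_genes <- pair$truth$gene[pair$truth$intersecting &
                                pair$truth$trend_a == 1L &
                                pair$truth$trend_b == 2L]
  et <- suppressWarnings(enrich(cell_genes, ann))
  planted <- et[et$term_id == "GO:PLANTED", ]
  in_cat <- et[et$category == planted$category, ]
  expect_equal(min(in_cat$fdr), planted$fdr)
  expect_equal(planted$direction, "over")
})

test_that("null annotation keeps the type-I error near its nominal level", {
  # 200 uniform selections over a fixed annotation with no planted signal
  set.seed(103)
  universe <- paste0("g", 1:150)
  terms <- lapply(1:10, function(i) sample(universe, 30))
  names(terms) <- paste0("T", 1:10)
  ann <- make_annotation(terms)
  hits <- 0L; total <- 0L
  for (i in 1:200) {
    sel <- sample(universe, 25)
    et <- enrich(sel, ann, background = universe)
    hits <- hits + sum(et$p_value < 0.05)
    total <- total + nrow(et)
  }
  # Fisher is conservative for discrete tables: rate must not exceed ~0.05
  # by more than binomial noise, and must not collapse to zero
  expect_lt(hits / total, 0.05 + 3 * sqrt(0.05 * 0.95 / total))
  expect_gt(hits / total, 0)
})
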