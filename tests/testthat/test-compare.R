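sim_session <- function(n_trends = 3, genes_per_cell = 6, seed = 20,
                        k = n_trends, ...) {
  pair <- generate_pair(synthetic_spec(n_trends = n_trends,
                                       genes_per_cell = genes_per_cell,
                                       seed = seed, ...))
  sess <- cmd_compare(session_config(list(A = pair$a, B = pair$b), k = k,
                                     seed = seed + 1), write = FALSE)
  list(pair = pair, sess = sess, p = sess$pairs[[1]])
}

test_that("build_comparison classifies concordance by label equality", {
  s <- sim_session()
  inter <- s$p$result$intersecting
  expect_identical(inter$concordant, inter$label_a == inter$label_b)
  expect_equal(nrow(inter), length(s$p$partition$intersecting))
  expect_false(anyDuplicated(inter$gene) > 0)
  # summary percentage is a direct count
  expect_equal(100 * mean(inter$concordant),
               s$p$sankey$summary$pct_concordant)
})

test_that("build_sankey obeys the conservation laws", {
  s <- sim_session(n_trends = 4, genes_per_cell = 5, seed = 3)
  model <- s$p$sankey
  inter <- s$p$result$intersecting
  expect_equal(sum(model$links$size), nrow(inter))
  expect_lte(nrow(model$links), model$k^2)
  # node size = sum of incident link sizes
  for (i in seq_len(nrow(model$nodes))) {
    nd <- model$nodes[i, ]
    col <- if (nd$dataset == model$dataset_a) "trend_a" else "trend_b"
    expect_equal(nd$size, sum(model$links$size[model$links[[col]] == nd$trend]))
  }
  # diagonal identity
  diag_sum <- sum(model$links$size[model$links$trend_a == model$links$trend_b])
  expect_equal(diag_sum, model$summary$concordant)
  expect_equal(model$summary$concordant + model$summary$discordant,
               nrow(inter))
})

test_that("all-concordant data yields exactly k diagonal links", {
  cells <- diag(10L, 3)  # diagonal-only: planted concordance = 1
  s <- sim_session(n_trends = 3, genes_per_cell = cells, seed = 12,
                   frac_only_a = 0, frac_only_b = 0)
  model <- s$p$sankey
  expect_equal(nrow(model$links), 3L)
  expect_true(all(model$links$trend_a == model$links$trend_b))
  expect_equal(model$summary$pct_concordant, 100)
})

test_that("overview counts pairs and a dataset against itself is 100% concordant", {
  # 4 datasets, all pairs -> 6 rows
  pair1 <- generate_pair(synthetic_spec(n_trends = 2, genes_per_cell = 6,
                                        seed = 1))
  pair2 <- generate_pair(synthetic_spec(n_trends = 2, genes_per_cell = 6,
                                        seed = 2))
  ds <- list(A = pair1$a, B = pair1$b, C = pair2$a, D = pair2$b)
  ds <- lapply(names(ds), function(n) {
    m <- ds[[n]]; m$dataset_id <- n; m })
  names(ds) <- c("A", "B", "C", "D")
  sess <- cmd_compare(session_config(ds, k = 2, seed = 5), write = FALSE)
  expect_equal(nrow(sess$overview), 6L)
  expect_true(all(sess$overview$n_intersecting_concordant +
                  sess$overview$n_intersecting_discordant > 0))

  # identical datasets: joint clustering of duplicated rows -> equal labels
  m <- pair1$a
  m2 <- m; m2$dataset_id <- "A2"
  sess2 <- cmd_compare(session_config(list(A = m, A2 = m2), k = 2, seed = 3),
                       write = FALSE)
  ov <- sess2$overview
  expect_equal(ov$n_intersecting_discordant, 0L)
  expect_equal(ov$n_only_a + ov$n_only_b, 0L)
})

test_that("apply_filters is contractive, respects identity and min_link_size", {
  s <- sim_session(n_trends = 3, genes_per_cell = 8, seed = 30)
  model <- s$p$sankey
  # identity
  same <- apply_filters(model, s$p$result, list(), 0L)
  expect_equal(same$links$size, model$links$size)
  expect_equal(same$summary, model$summary)
  # boundary: threshold above the largest link kills all links
  none <- apply_filters(model, s$p$result, list(),
                        max(model$links$size) + 1L)
  expect_equal(nrow(none$links), 0L)
  # percentile filter agrees with the set-algebra oracle
  spec <- filter_spec("variance", 80, 100, "both_datasets")
  filt <- apply_filters(model, s$p$result, list(spec), 0L)
  surv <- intersect(
    s$p$result$stats_a$gene[s$p$result$stats_a$variance_pct >= 80],
    s$p$result$stats_b$gene[s$p$result$stats_b$variance_pct >= 80])
  expect_setequal(unlist(filt$links$genes),
                  intersect(unlist(model$links$genes), surv))
  # contractive on every member set
  for (i in seq_len(nrow(filt$links))) {
    orig <- model$links$genes[[which(
      model$links$trend_a == filt$links$trend_a[i] &
      model$links$trend_b == filt$links$trend_b[i])]]
    expect_true(all(filt$links$genes[[i]] %in% orig))
  }
  expect_error(apply_filters(model, s$p$result, list(), -1L), ">= 0")
})

test_that("highlight inverts the link membership map", {
  s <- sim_session(n_trends = 3, genes_per_cell = 5, seed = 40)
  model <- s$p$sankey
  all_genes <- unlist(model$links$genes)
  hl <- highlight(model, all_genes)
  expect_true(all(hl$status == "found"))
  # reconstruct each link's member set from the highlight table
  for (i in seq_len(nrow(model$links))) {
    got <- hl$gene[hl$trend_a == model$links$trend_a[i] &
                   hl$trend_b == model$links$trend_b[i]]
    expect_setequal(got, model$links$genes[[i]])
  }
  absent <- highlight(model, "no_such_gene")
  expect_equal(absent$status, "absent")
  expect_true(is.na(absent$trend_a))
})

test_that("select_genes honors picks, percentages and the partition property", {
  s <- sim_session(n_trends = 3, genes_per_cell = 5, seed = 50)
  model <- s$p$sankey
  link1 <- model$links[1, ]
  pick <- sprintf("link:%d-%d", link1$trend_a, link1$trend_b)
  sel <- select_genes(model, pick)
  expect_setequal(sel$genes, link1$genes[[1]])
  expect_equal(sel$picks$pct_of_intersecting,
               100 * link1$size / sum(model$links$size))
  # node pick = union of its incident links' members
  nd <- model$nodes[1, ]
  seln <- select_genes(model, sprintf("node:%s:%d", nd$dataset, nd$trend))
  col <- if (nd$dataset == model$dataset_a) "trend_a" else "trend_b"
  expect_setequal(seln$genes,
                  unlist(model$links$genes[model$links[[col]] == nd$trend]))
  # two nodes of the same dataset are disjoint (trends partition a dataset)
  nda <- model$nodes[model$nodes$dataset == model$dataset_a, ]
  sel2 <- select_genes(model, sprintf("node:%s:%d", nda$dataset[1:2],
                                      nda$trend[1:2]))
  expect_equal(length(sel2$genes), sum(nda$size[1:2]))
  expect_error(select_genes(model, "link:7-7"), "unknown link")
  expect_error(select_genes(model, "garbage"), "unknown pick")
})
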