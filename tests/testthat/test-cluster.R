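test_that("partition_genes is exact set algebra and validates conditions", {
  a <- make_matrix(rnorm(6), c("a", "b", "c"), c("c1", "c2"), id = "A")
  b <- make_matrix(rnorm(6), c("b", "c", "d"), c("c1", "c2"), id = "B")
  p <- partition_genes(a, b)
  expect_equal(p$intersecting, c("b", "c"))
  expect_equal(p$only_a, "a")
  expect_equal(p$only_b, "d")
  # identical gene sets
  p2 <- partition_genes(a, make_matrix(rnorm(6), c("a", "b", "c"),
                                       c("c1", "c2"), id = "B"))
  expect_length(p2$only_a, 0L)
  expect_length(p2$only_b, 0L)
  # condition mismatch names the offender
  bad <- make_matrix(rnorm(6), c("a", "b", "c"), c("c1", "cX"), id = "B")
  expect_error(partition_genes(a, bad), "cX")
})

test_that("stack_intersecting produces a deterministic 2n x c table of z-rows", {
  set.seed(1)
  a <- zscore(make_matrix(rnorm(12), c("g1", "g2", "g3"),
                          paste0("c", 1:4), id = "A"))
  b <- zscore(make_matrix(rnorm(12), c("g2", "g3", "g4"),
                          paste0("c", 1:4), id = "B"))
  part <- partition_genes(a, b)
  st <- stack_intersecting(a, b, part)
  expect_equal(dim(st$profiles), c(4L, 4L))
  i <- which(st$keys$gene == "g2" & st$keys$dataset == "A")
  expect_equal(st$profiles[i, ], a$values["g2", ])
  st2 <- stack_intersecting(a, b, part)
  expect_identical(st, st2)
  # disjoint gene sets -> nothing to compare
  c_ <- zscore(make_matrix(rnorm(8), c("x1", "x2"), paste0("c", 1:4),
                           id = "C"))
  expect_error(stack_intersecting(a, c_, partition_genes(a, c_)),
               "nothing to compare")
})

test_that("kmeans_pp recovers well-separated planted shapes exactly", {
  set.seed(2)
  shapes <- rbind(c(2, 2, -2, -2), c(-2, -2, 2, 2))
  planted <- rep(1:2, each = 30)
  x <- shapes[planted, ] + matrix(rnorm(60 * 4, sd = 0.15), 60, 4)
  rownames(x) <- paste0("r", 1:60)
  fit <- kmeans_pp(x, k = 2, seed = 9)
  expect_equal(adjusted_rand_index(fit$labels$label, planted), 1)
  # same seed twice -> identical labels (determinism contract)
  fit2 <- kmeans_pp(x, k = 2, seed = 9)
  expect_identical(fit$labels, fit2$labels)
  expect_identical(fit$centroids, fit2$centroids)
})

test_that("kmeans_pp validates k and handles k = n rows", {
  x <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("r", 1:4), NULL))
  expect_error(kmeans_pp(x, k = 1), "\\[2, 10\\]")
  expect_error(kmeans_pp(x, k = 11), "\\[2, 10\\]")
  expect_error(kmeans_pp(x, k = 5), "exceeds")
  fit <- kmeans_pp(x, k = 4, seed = 1)
  expect_equal(fit$inertia, 0, tolerance = 1e-12)
  expect_equal(sort(unique(fit$labels$label)), 0:3)
})

test_that("labels are canonically ordered by descending first-condition centroid", {
  set.seed(3)
  shapes <- rbind(c(3, 0), c(0, 3), c(-3, 0))
  x <- shapes[rep(1:3, each = 20), ] + matrix(rnorm(120, sd = .1), 60, 2)
  rownames(x) <- paste0("r", 1:60)
  for (s in c(1, 2, 42)) {
    fit <- kmeans_pp(x, k = 3, seed = s)
    expect_true(all(diff(fit$centroids[, 1]) < 0))
  }
})

test_that("cluster_pair gives each intersecting gene two labels in a shared space", {
  pair <- generate_pair(synthetic_spec(n_trends = 3, genes_per_cell = 8,
                                       frac_only_a = 0.2, frac_only_b = 0,
                                       seed = 4))
  pc <- cluster_pair(pair$a, pair$b, k = 3, seed = 5)
  lab <- pc$joint$labels
  counts <- table(lab$gene)
  expect_true(all(counts == 2L))  # conservation: 2 labeled rows per gene
  expect_setequal(names(counts), pc$partition$intersecting)
  # non-intersecting side B was empty, side A clustered separately
  expect_equal(nrow(pc$non_b$labels), 0L)
  expect_equal(sort(unique(pc$non_a$labels$dataset)), "A")
  expect_equal(nrow(pc$non_a$labels), length(pc$partition$only_a))
})

test_that("joint centroids match planted shapes within noise", {
  spec <- synthetic_spec(n_trends = 4, genes_per_cell = 20, noise_sd = 0.2,
                         frac_only_a = 0, frac_only_b = 0, seed = 6)
  pair <- generate_pair(spec)
  pc <- cluster_pair(pair$a, pair$b, k = 4, seed = 7)
  # per-gene z-scoring maps shape s to (s - mean(s)) / sd, with the divisor
  # inflated by the noise variance; each planted shape, so normalized, must
  # sit within half a noise sd of a distinct recovered centroid
  best <- integer(4)
  for (i in seq_len(4)) {
    sh <- spec$shapes[i, ]
    exp_z <- (sh - mean(sh)) /
      sqrt(mean((sh - mean(sh))^2) + spec$noise_sd^2)
    devs <- apply(pc$joint$centroids, 1,
                  function(cen) max(abs(cen - exp_z)))
    expect_lt(min(devs), 0.5 * spec$noise_sd)
    best[i] <- which.min(devs)
  }
  expect_setequal(best, 1:4)  # shape-to-centroid matching is a bijection
})

test_that("kept solution has the lowest inertia across restarts", {
  set.seed(10)
  x <- matrix(rnorm(200), 50, 4, dimnames = list(paste0("r", 1:50), NULL))
  # the first restart of an n_init = 10 run replays the n_init = 1 run with
  # the same seed, so the kept solution can never be worse than it
  for (s in c(3, 8)) {
    fit10 <- kmeans_pp(x, k = 4, seed = s, n_init = 10)
    fit1 <- kmeans_pp(x, k = 4, seed = s, n_init = 1)
    expect_lte(fit10$inertia, fit1$inertia + 1e-8)
  }
})
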