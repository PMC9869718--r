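# Small in-code fixtures shared across test files.

make_matrix <- function(values, genes, conditions, id = "X",
                        state = "raw") {
  m <- matrix(values, nrow = length(genes), byrow = TRUE,
              dimnames = list(genes, conditions))
  abundance_matrix(m, id, state = state)
}

# 3 genes x 2 conditions TSV on disk; returns the path
write_tiny_tsv <- function(dir = tempdir(), body = NULL) {
  path <- tempfile("abund", tmpdir = dir, fileext = ".tsv")
  if (is.null(body))
    body <- c("gene\tc1\tc2", "g1\t1\t2", "g2\t3\t4", "g3\t5\t6")
  writeLines(body, path)
  path
}

# map each planted trend to the recovered label by majority vote, per dataset
planted_to_recovered <- function(truth, intersecting, side = c("a", "b")) {
  side <- match.arg(side)
  merged <- merge(truth[truth$intersecting, ], intersecting, by = "gene")
  planted <- merged[[paste0("trend_", side)]]
  recovered <- merged[[paste0("label_", side)]]
  vapply(sort(unique(planted)), function(t) {
    tab <- table(recovered[planted == t])
    as.integer(names(tab)[which.max(tab)])
  }, integer(1))
}

# independent BH step-up oracle: direct translation of the formula
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q[ord[i]] <- min(1, min(m * p[ord][js] / js))
  }
  q
}
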