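test_that("two-sided Fisher p matches the enumeration oracle on examples", {
  # [[3,1],[1,3]]: k=3 of K=4 foreground in a category covering n=4 of N=8
  expect_equal(fisher_two_tailed(3, 4, 4, 8), 34 / 70, tolerance = 1e-10)
  expect_equal(fisher_two_tailed(3, 4, 4, 8), fisher_oracle(3, 4, 4, 8),
               tolerance = 1e-10)
  # transposing the 2x2 table leaves p unchanged (k,K <-> k,n)
  expect_equal(fisher_two_tailed(2, 5, 7, 20), fisher_two_tailed(2, 7, 5, 20))
  # degenerate margins
  expect_equal(fisher_two_tailed(4, 4, 4, 4), 1)
  expect_equal(fisher_two_tailed(0, 5, 0, 10), 1)
  expect_error(fisher_two_tailed(5, 4, 4, 8), "margin")
  expect_error(fisher_two_tailed(2, 4, 10, 8), "margin")
  expect_error(fisher_two_tailed(-1, 4, 4, 8), "non-negative")
})

test_that("Fisher p equals the oracle on random valid tables", {
  set.seed(24)
  for (i in 1:200) {
    N <- sample(2:60, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    supp <- max(0, K + n - N):min(K, n)
    k <- supp[sample.int(length(supp), 1)]
    expect_equal(fisher_two_tailed(k, K, n, N), fisher_oracle(k, K, n, N),
                 tolerance = 1e-10)
  }
})

test_that("enrichment of foreground == background is always p = 1", {
  ann <- annotation_table(data.frame(
    accession = c("P1", "P2", "P3", "P4"), term_type = "KEGG",
    term = c("ko1", "ko1", "ko2", "ko2")))
  bg <- paste0("P", 1:4)
  r <- enrich(bg, bg, ann, "KEGG")
  expect_true(all(r$p_value == 1))
  expect_true(all(r$fold_enrichment == 1))
})

test_that("enrich validates inputs and omits foreground-absent categories", {
  ann <- annotation_table(data.frame(accession = c("P1", "P2"),
                                     term_type = "BP", term = c("b1", "b2")))
  expect_error(enrich(c("P1", "P9"), c("P1", "P2"), ann, "BP"), "subset")
  r <- enrich("P1", c("P1", "P2"), ann, "BP")
  expect_equal(r$term, "b1")  # b2 has no foreground member
})

test_that("a planted category rises to the top of the ranking", {
  set.seed(25)
  bg <- paste0("P", 1:200)
  fg <- paste0("P", 1:20)
  rows <- list(data.frame(accession = fg[1:10], term_type = "BP", term = "planted"))
  for (j in 1:10)
    rows[[j + 1]] <- data.frame(accession = sample(bg, 12), term_type = "BP",
                                term = paste0("noise", j))
  ann <- annotation_table(do.call(rbind, rows))
  r <- enrich(fg, bg, ann, "BP")
  expect_equal(r$term[1], "planted")
  expect_lt(r$p_value[1], 0.05)
  expect_true(r$significant[1])
  expect_gt(r$fold_enrichment[1], 1)
})

test_that("fold enrichment follows (k/K)/(n/N)", {
  ann <- annotation_table(data.frame(accession = c("P1", "P2", "P3"),
                                     term_type = "DOMAIN", term = "d1"))
  r <- enrich(c("P1", "P2"), paste0("P", 1:10), ann, "DOMAIN")
  expect_equal(r$fold_enrichment, (2 / 2) / (3 / 10))
})

test_that("heatmap keeps significant categories and clusters deterministically", {
  rows <- data.frame(
    term = rep(c("a", "b", "c", "d"), each = 2),
    cell = rep(c("x", "y"), 4),
    p_value = c(0.001, 0.002, 0.001, 0.002, 0.5, 0.6, 0.01, 0.9),
    k = c(5, 5, 5, 5, 4, 4, 1, 1),
    significant = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
  hm <- cluster_heatmap(rows)
  # c never significant, d has k < 2: both excluded
  expect_equal(rownames(hm$matrix), c("a", "b"))
  # identical rows sit at distance zero and adjacent leaves
  expect_equal(unname(hm$matrix["a", ]), unname(hm$matrix["b", ]))
  expect_equal(sort(hm$row_order[1:2]), 1:2)
  # permuting the input row order changes nothing
  hm2 <- cluster_heatmap(rows[sample(nrow(rows)), ])
  expect_identical(hm2$matrix, hm$matrix)
  expect_identical(hm2$row_order, hm$row_order)
})

test_that("all-p-one input yields an all-zero matrix without dendrogram issues", {
  rows <- data.frame(term = c("a", "b"), cell = c("x", "x"),
                     p_value = c(1, 1), k = c(3, 3), significant = c(TRUE, TRUE))
  hm <- cluster_heatmap(rows)
  expect_true(all(hm$matrix == 0))
  expect_null(hm$col_hclust)  # single cell: no column dendrogram
})

test_that("p-values are floored before -log10", {
  rows <- data.frame(term = c("a", "b"), cell = "x",
                     p_value = c(1e-300, 0.001), k = 3, significant = TRUE)
  hm <- cluster_heatmap(rows)
  expect_equal(unname(hm$matrix["a", "x"]), 15)
})

test_that("localization summary counts compartments with unknown fallback", {
  ann <- annotation_table(data.frame(
    accession = paste0("P", 1:4), term_type = "LOCATION",
    term = c("nucleus", "nucleus", "nucleus", "cytoplasm")))
  s <- localization_summary(paste0("P", 1:4), ann)
  expect_equal(s$percent[s$compartment == "nucleus"], 75)
  expect_equal(s$percent[s$compartment == "cytoplasm"], 25)
  expect_equal(sum(s$percent), 100, tolerance = 1e-9)
  s2 <- localization_summary(c("P1", "P9"), ann)
  expect_equal(s2$count[s2$compartment == "unknown"], 1L)
  expect_error(localization_summary(character(0), ann), "empty")
})

test_that("localization percentages sum to 100 on random label assignments", {
  set.seed(26)
  for (i in 1:20) {
    accs <- paste0("P", 1:30)
    ann <- annotation_table(data.frame(
      accession = accs, term_type = "LOCATION",
      term = sample(c("nucleus", "cytoplasm", "membrane"), 30, replace = TRUE)))
    s <- localization_summary(sample(accs, sample(1:30, 1)), ann)
    expect_equal(sum(s$percent), 100, tolerance = 1e-9)
  }
})
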