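test_that("already-balanced ratios are left unchanged by normalization", {
  design <- two_condition_design(3L)
  pep <- peptides_with_ratios(c(1, 1, 1), design)
  npx <- normalize_by_median_ratio(pep, design)
  cmp <- npx$comparisons[["B/A"]]
  expect_equal(unname(cmp$avg_ratio), c(1, 1, 1))
  expect_equal(unname(cmp$normalizer$per_replicate), rep(1, 3), tolerance = 1e-12)
  expect_equal(cmp$normalizer$grand, 1, tolerance = 1e-12)
})

test_that("ratios {0.5, 2, 8} normalize to {0.25, 1, 4} (median 2)", {
  design <- two_condition_design(3L)
  pep <- peptides_with_ratios(c(0.5, 2, 8), design)
  npx <- normalize_by_median_ratio(pep, design)
  expect_equal(unname(npx$comparisons[["B/A"]]$avg_ratio), c(0.25, 1, 4),
               tolerance = 1e-12)
})

test_that("normalized ratios are invariant to scaling any single channel", {
  set.seed(41)
  fx <- random_peptide_fixture(n = 30L)
  npx1 <- normalize_by_median_ratio(fx$peptides, fx$design)
  for (k in c(10, 0.01)) {
    pep2 <- fx$peptides
    pep2$ch2 <- pep2$ch2 * k     # one numerator-side channel
    pep2$ch5 <- pep2$ch5 / k     # and one denominator-side channel
    npx2 <- normalize_by_median_ratio(pep2, fx$design)
    expect_equal(npx2$comparisons[["B/A"]]$rep_ratios,
                 npx1$comparisons[["B/A"]]$rep_ratios, tolerance = 1e-12)
  }
})

test_that("shared peptides are carried through but excluded from the median", {
  design <- two_condition_design(3L)
  # three unique peptides at ratio 2 fix the normalizer; an extreme shared
  # peptide must not move it
  pep <- peptides_with_ratios(c(2, 2, 2, 1000), design,
                              unique_flags = c(TRUE, TRUE, TRUE, FALSE))
  npx <- normalize_by_median_ratio(pep, design)
  avg <- npx$comparisons[["B/A"]]$avg_ratio
  expect_equal(unname(avg[1:3]), c(1, 1, 1), tolerance = 1e-12)
  expect_equal(unname(avg[4]), 500, tolerance = 1e-9)  # normalized, not dropped
})

test_that("normalization errors when a comparison has no complete unique peptide", {
  design <- two_condition_design(3L)
  pep <- peptides_with_ratios(c(2, 3), design, unique_flags = c(FALSE, FALSE))
  expect_error(normalize_by_median_ratio(pep, design), "no unique peptide")
  pep2 <- peptides_with_ratios(c(2, 3), design)
  pep2$ch4[] <- NA  # every unique peptide now lacks replicate 1 of B
  expect_error(normalize_by_median_ratio(pep2, design), "B/A")
})

test_that("protein roll-up takes the median of unique-peptide ratios", {
  design <- two_condition_design(3L)
  # single peptide: protein ratio is that peptide's ratio (identity after norm)
  pep <- peptides_with_ratios(c(5), design)
  pq <- rollup_protein(normalize_by_median_ratio(pep, design))
  expect_equal(pq$table[["ratio_B/A"]], 1, tolerance = 1e-12)

  # {1, 2, 4, 100}: even-sized set, median = mean of middles = 3 after
  # removing the grand normalization
  pep <- peptides_with_ratios(c(1, 2, 4, 100), design)
  pep$accessions <- rep("P1", 4)
  npx <- normalize_by_median_ratio(pep, design)
  g <- unname(npx$comparisons[["B/A"]]$normalizer$grand *
                npx$comparisons[["B/A"]]$normalizer$per_replicate[1])
  pq <- rollup_protein(npx)
  expect_equal(pq$table[["ratio_B/A"]] * g, 3, tolerance = 1e-9)
})

test_that("duplicating the peptide set leaves protein ratios unchanged", {
  set.seed(99)
  fx <- random_peptide_fixture(n = 24L)
  pq1 <- rollup_protein(normalize_by_median_ratio(fx$peptides, fx$design))
  dup <- rbind(fx$peptides, transform(fx$peptides,
                                      peptide_seq = paste0(peptide_seq, "K")))
  pq2 <- rollup_protein(normalize_by_median_ratio(dup, fx$design))
  expect_equal(pq2$table[["ratio_B/A"]], pq1$table[["ratio_B/A"]],
               tolerance = 1e-12)
})

test_that("roll-up equals a naive sort-based median oracle", {
  set.seed(7)
  for (i in 1:25) {
    fx <- random_peptide_fixture(n = sample(8:40, 1), n_proteins = sample(2:6, 1))
    npx <- normalize_by_median_ratio(fx$peptides, fx$design)
    pq <- rollup_protein(npx)
    cmp <- npx$comparisons[["B/A"]]
    uniq <- fx$peptides$is_unique & cmp$n_reps >= 2L
    for (p in pq$table$accession) {
      rows <- which(uniq & fx$peptides$accessions == p)
      expected <- sort_median(cmp$avg_ratio[rows])
      expect_equal(pq$table[["ratio_B/A"]][pq$table$accession == p], expected,
                   tolerance = 1e-12)
    }
  }
})

test_that("proteins without unique peptides are omitted with a message", {
  design <- two_condition_design(3L)
  pep <- peptides_with_ratios(c(1, 2, 3), design,
                              unique_flags = c(TRUE, TRUE, FALSE))
  npx <- normalize_by_median_ratio(pep, design)
  expect_message(pq <- rollup_protein(npx), "omitted")
  expect_false("PX" %in% pq$table$accession)
})

test_that("site correction divides raw by protein ratio, exactly", {
  expect_equal(correct_site_ratio(3, 1.5), 2)
  expect_equal(correct_site_ratio(2.4, 2.4), 1)
  expect_true(is.na(correct_site_ratio(3, NA)))
  expect_true(is.na(correct_site_ratio(3, 0)))
  x <- correct_site_ratio(c(1, 2, 3), c(2, NA, 0))
  expect_equal(x, c(0.5, NA, NA))
})

test_that("quantify_sites reports exact corrected = raw / protein identity", {
  set.seed(5)
  sim <- simulate_experiment(simulation_config(seed = 5, n_proteins = 50,
                                               n_glycoproteins = 20,
                                               n_categories = 5))
  npx <- normalize_by_median_ratio(sim$peptides, sim$design)
  pq <- rollup_protein(npx)
  sq <- suppressMessages(quantify_sites(sim$sites, npx, pq))
  tab <- sq$table
  pidx <- match(tab$accession, pq$table$accession)
  for (lab in sim$design$comparisons$label) {
    raw <- tab[[paste0("raw_", lab)]]
    corr <- tab[[paste0("ratio_", lab)]]
    prot <- pq$table[[paste0("ratio_", lab)]][pidx]
    ok <- !is.na(corr)
    expect_identical(corr[ok], (raw / prot)[ok])
    expect_true(all(is.na(corr[is.na(raw) | is.na(prot)])))
  }
})

test_that("sites of unquantified parents are flagged, not passed through raw", {
  set.seed(6)
  sim <- simulate_experiment(simulation_config(seed = 6, n_proteins = 40,
                                               n_glycoproteins = 10,
                                               n_categories = 5))
  npx <- normalize_by_median_ratio(sim$peptides, sim$design)
  pq <- rollup_protein(npx)
  orphan <- sim$sites[1, ]
  orphan$accession <- "CT9999"
  sq <- suppressMessages(quantify_sites(rbind(orphan, sim$sites), npx, pq))
  expect_false(sq$table$parent_quantified[1])
  expect_true(all(is.na(unlist(
    sq$table[1, grep("^(ratio|p)_", names(sq$table))]))))
})

test_that("planted occupancy change is recovered after protein correction", {
  # site with 2x occupancy change on a protein with 4x abundance change:
  # the corrected ratio should recover ~2, the raw ratio ~8
  cfg <- simulation_config(seed = 42, n_proteins = 200, n_glycoproteins = 0,
                           frac_up = 0, frac_down = 0, noise_sd = 0.1,
                           dropout_rate = 0, n_categories = 0)
  sim <- simulate_experiment(cfg)
  target <- "CT0001"
  sim$peptides[sim$peptides$accessions == target,
               sim$design$channels[sim$design$conditions != "T30"]] <-
    sim$peptides[sim$peptides$accessions == target,
                 sim$design$channels[sim$design$conditions != "T30"]] * 4
  site <- data.frame(accession = target, position = 30L)
  for (ch in sim$design$channels) {
    fac <- if (sim$design$conditions[match(ch, sim$design$channels)] == "T30") 1 else 8
    site[[ch]] <- 5e4 * fac * 2^rnorm(1, 0, 0.1)
  }
  npx <- normalize_by_median_ratio(sim$peptides, sim$design)
  pq <- rollup_protein(npx)
  sq <- quantify_sites(site, npx, pq)
  expect_equal(sq$table[["raw_T50/T30"]], 8, tolerance = 0.35)
  expect_equal(sq$table[["ratio_T50/T30"]], 2, tolerance = 0.35)
})

test_that("protein ratios recover planted truth on synthetic data", {
  cfg <- simulation_config(seed = 13, n_proteins = 500, n_glycoproteins = 50,
                           n_categories = 10)
  sim <- simulate_experiment(cfg)
  pq <- rollup_protein(normalize_by_median_ratio(sim$peptides, sim$design))
  truth <- sim$truth$proteins
  lab <- "T50/T30"
  t <- truth[truth$comparison == lab, ]
  est <- pq$table[[paste0("ratio_", lab)]][match(t$accession, pq$table$accession)]
  ok <- !is.na(est)
  rel_err <- abs(est[ok] / t$true_ratio[ok] - 1)
  expect_lt(median(rel_err), 0.10)
  reg <- ok & t$true_log2fc != 0
  expect_gt(cor(est[reg], t$true_ratio[reg], method = "spearman"), 0.95)
})
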