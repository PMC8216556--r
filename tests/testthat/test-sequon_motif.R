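test_that("sequon finder matches the worked cases", {
  expect_equal(find_sequons("NVTQNPSLNGS")$position, c(1L, 9L))  # N5 has X = Pro
  expect_equal(find_sequons("NNTS")$position, c(1L, 2L))          # overlap allowed
  expect_equal(nrow(find_sequons("NPT")), 0L)                     # X = Pro excluded
  expect_equal(nrow(find_sequons("NV")), 0L)                      # too short
  expect_equal(find_sequons("NVTQNPSLNGS")$triplet, c("NVT", "NGS"))
})

test_that("sequon finder agrees with a brute-force triplet-scan oracle", {
  set.seed(14)
  for (i in 1:500) {
    s <- random_aa_sequence(sample(3:80, 1))
    expect_identical(find_sequons(s)$position, as.integer(sequon_oracle(s)))
  }
})

test_that("sequon_table collects sequons across a proteome", {
  tab <- sequon_table(c(P1 = "NVTQNPSLNGS", P2 = "AAA", P3 = "NNTS"))
  expect_equal(tab$accession, c("P1", "P1", "P3", "P3"))
  expect_equal(tab$position, c(1L, 9L, 1L, 2L))
})

test_that("flanking windows are padded at termini and centered on N", {
  s <- "NVTAAAAAAAAAAAAAAAA"
  w <- extract_window(s, 1L)
  expect_equal(nchar(w), 21L)
  expect_equal(substr(w, 1, 10), strrep("_", 10))
  expect_equal(substr(w, 11, 11), "N")
  long <- paste0(strrep("G", 10), "NAS", strrep("G", 10))
  expect_false(grepl("_", extract_window(long, 11L), fixed = TRUE))
  expect_error(extract_window(s, 2L), "not an asparagine")
  expect_error(extract_window(s, 99L), "outside")
})

test_that("window center is always N over random sequons", {
  set.seed(15)
  for (i in 1:200) {
    s <- random_aa_sequence(sample(25:120, 1))
    hits <- find_sequons(s)$position
    for (p in hits) {
      w <- extract_window(s, p)
      expect_equal(substr(w, 11, 11), "N")
      expect_equal(nchar(w), 21L)
    }
  }
})

test_that("occupancy matrix computes per-position frequencies", {
  w1 <- paste0(strrep("A", 10), "N", strrep("A", 10))
  m <- occupancy_matrix(w1)
  expect_equal(unname(m["-3", "A"]), 1)
  expect_equal(unname(m["0", "N"]), 1)
  expect_equal(unname(m["5", "G"]), 0)

  w2 <- paste0(strrep("A", 10), "NA", "S", strrep("A", 8))
  w3 <- paste0(strrep("A", 10), "NA", "T", strrep("A", 8))
  m2 <- occupancy_matrix(c(w2, w3))
  expect_equal(unname(m2["2", "S"]), 0.5)
  expect_equal(unname(m2["2", "T"]), 0.5)
})

test_that("pad characters are excluded from position denominators", {
  w <- c(paste0(strrep("_", 10), "N", strrep("A", 10)),
         paste0(strrep("G", 10), "N", strrep("A", 10)))
  m <- occupancy_matrix(w)
  # position -1: one pad, one G -> G has frequency 1 among real residues
  expect_equal(unname(m["-1", "G"]), 1)
  expect_equal(sum(m["-1", ]), 1)
})

test_that("+2 threonine frequency equals the N-X-T share of sequons", {
  set.seed(16)
  prote <- setNames(vapply(rep(120L, 40L), random_aa_sequence, ""),
                    paste0("P", 1:40))
  tab <- sequon_table(prote)
  skip_if(nrow(tab) < 5)
  wins <- vapply(seq_len(nrow(tab)), function(i)
    extract_window(prote[[tab$accession[i]]], tab$position[i]), "")
  m <- occupancy_matrix(wins)
  expect_equal(unname(m["2", "T"]),
               mean(substr(tab$triplet, 3, 3) == "T"), tolerance = 1e-12)
  # column sums: every fully-covered position sums to 1
  expect_equal(unname(rowSums(m)[as.character(-2:2)]), rep(1, 5),
               tolerance = 1e-9)
})

test_that("occupancy matrix rejects bad input", {
  expect_error(occupancy_matrix(character(0)), "no windows")
  expect_error(occupancy_matrix("AANAA"), NA)   # odd short window is fine
  expect_error(occupancy_matrix(c("AANAA", "AAANAAA")), "same length")
  expect_error(occupancy_matrix("AAAAA"), "center")
})

test_that("site-count distribution bins glycoproteins by site number", {
  d <- site_count_distribution(c("P1", "P2", "P3", "P4", "P4"))
  expect_equal(d$fraction[d$bin == "1"], 0.75)
  expect_equal(d$fraction[d$bin == "2"], 0.25)
  expect_equal(sum(d$fraction), 1)

  d2 <- site_count_distribution(rep(c("A", "B"), times = c(1, 1)))
  expect_equal(d2$fraction[d2$bin == "1"], 1)

  d3 <- site_count_distribution(rep("A", 9))
  expect_equal(d3$fraction[d3$bin == "5+"], 1)
})

test_that("random site assignments match a tally oracle and sum to 1", {
  set.seed(17)
  accs <- sample(paste0("P", 1:200), 500, replace = TRUE)
  d <- site_count_distribution(accs)
  expect_equal(sum(d$fraction), 1, tolerance = 1e-12)
  tally <- table(table(accs))
  ones <- if ("1" %in% names(tally)) as.integer(tally[["1"]]) else 0L
  expect_equal(d$n_proteins[d$bin == "1"], ones)
  expect_equal(sum(d$n_proteins), length(unique(accs)))
})

test_that("non-sequon sites are flagged non-canonical, not dropped", {
  prote <- c(P1 = paste0(strrep("A", 12), "NVT", strrep("A", 12)),
             P2 = paste0(strrep("A", 12), "NPT", strrep("A", 12)))
  sites <- data.frame(accession = c("P1", "P2"), position = c(13L, 13L))
  expect_message(cls <- classify_sites(sites, prote), "non-canonical")
  expect_equal(cls$is_sequon, c(TRUE, FALSE))
  wins <- suppressMessages(site_windows(sites, prote))
  expect_equal(length(wins), 1L)  # canonical only by default
  wins_all <- suppressMessages(site_windows(sites, prote, canonical_only = FALSE))
  expect_equal(length(wins_all), 2L)
})
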