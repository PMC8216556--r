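# Fixture builders shared across the suite. Everything is generated in code;
# no binary or on-disk fixtures.

# two-condition design, A vs B, nrep replicates each
two_condition_design <- function(nrep = 3L) {
  experiment_design(channels = paste0("ch", seq_len(2L * nrep)),
                    conditions = rep(c("A", "B"), each = nrep),
                    replicates = rep(seq_len(nrep), 2L),
                    comparisons = list(c("B", "A")))
}

# peptide table in which peptide i has the exact ratio ratios[i] (B over A)
# in every replicate; base intensities differ per peptide
peptides_with_ratios <- function(ratios, design, unique_flags = NULL) {
  nrep <- length(design$channels) / 2L
  base <- 1000 * seq_along(ratios)
  accs <- paste0("P", seq_along(ratios))
  if (!is.null(unique_flags)) accs[!unique_flags] <- paste0(accs[!unique_flags], ";PX")
  df <- data.frame(peptide_seq = strrep(LETTERS[(seq_along(ratios) %% 20) + 1L], 8L),
                   accessions = accs,
                   is_unique = if (is.null(unique_flags)) rep(TRUE, length(ratios)) else unique_flags,
                   stringsAsFactors = FALSE)
  for (ch in design$channels) {
    cond <- design$conditions[match(ch, design$channels)]
    df[[ch]] <- if (cond == "A") base else base * ratios
  }
  df
}

# random peptide fixture: n peptides over a two-condition design, log-normal
# intensities with per-channel biases; a subset non-unique
random_peptide_fixture <- function(n = 20L, nrep = 3L, n_proteins = 5L,
                                   shared_frac = 0.2) {
  design <- two_condition_design(nrep)
  nchan <- length(design$channels)
  prot <- sample(n_proteins, n, replace = TRUE)
  accs <- paste0("P", prot)
  shared <- runif(n) < shared_frac
  accs[shared] <- paste0(accs[shared], ";P", ((prot[shared]) %% n_proteins) + 1L)
  df <- data.frame(peptide_seq = vapply(seq_len(n), function(i)
    paste(sample(c("A", "G", "L", "S", "V"), 10L, replace = TRUE), collapse = ""), ""),
    accessions = accs, is_unique = !shared, stringsAsFactors = FALSE)
  bias <- exp(rnorm(nchan, 0, 0.3))
  base <- rlnorm(n, log(1e5), 1)
  for (j in seq_len(nchan))
    df[[design$channels[j]]] <- base * bias[j] * rlnorm(n, 0, 0.4)
  list(peptides = df, design = design)
}

# independent sort-based median (oracle for roll-up)
sort_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n == 0L) return(NA_real_)
  if (n %% 2L == 1L) x[(n + 1L) / 2L] else (x[n / 2L] + x[n / 2L + 1L]) / 2
}

# overlap-aware sequon oracle: brute-force triplet scan for N[^P][ST]
sequon_oracle <- function(seq) {
  n <- nchar(seq)
  if (n < 3L) return(integer(0))
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  which(vapply(seq_len(n - 2L), function(i)
    chars[i] == "N" && chars[i + 1L] != "P" && chars[i + 2L] %in% c("S", "T"),
    TRUE))
}

# exhaustive hypergeometric enumeration oracle for the two-sided Fisher test:
# sum of P(X = x) over all x in the support with P(x) <= P(observed) (relative
# slack as in standard implementations)
fisher_oracle <- function(k, K, n, N, rel_tol = 1e-7) {
  support <- max(0L, K + n - N):min(K, n)
  probs <- stats::dhyper(support, m = n, n = N - n, k = K)
  sum(probs[probs <= probs[match(k, support)] * (1 + rel_tol)])
}

random_aa_sequence <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), len, replace = TRUE),
        collapse = "")
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
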