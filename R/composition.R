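# Amino-acid composition of protein sets. Percentages are computed per protein
# first and then averaged without weighting, so long proteins do not dominate;
# the dispersion reported is the standard error of that mean over proteins.

#' Amino-acid composition profile of a protein set
#'
#' Per protein, the percent of each of the 20 standard residues is computed
#' over the residues of that protein (non-standard letters B, Z, X, U and stop
#' characters are excluded from both numerator and denominator); the profile
#' mean is the unweighted mean of those per-protein percentages and the
#' dispersion is their standard error of the mean (SEM).
#'
#' @param sequences Character vector of amino-acid sequences (names, if
#'   present, are kept as protein identifiers).
#' @return Object of class `aa_profile`: list with `table` (data frame
#'   `residue`, `mean_percent`, `sem`, summing to 100), `per_protein`
#'   (proteins x 20 percent matrix) and `n_proteins`.
#' @examples
#' aa_composition(c("AA", "GG"))$table  # A 50, G 50: per-protein averaging
#' @export
aa_composition <- function(sequences) {
  sequences <- as.character(sequences)
  if (!length(sequences)) stop("empty protein set")
  per <- t(vapply(sequences, function(s) {
    res <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
    res <- res[res %in% AA20]
    if (!length(res)) stop("sequence with no standard residues")
    counts <- table(factor(res, levels = AA20))
    100 * as.numeric(counts) / length(res)
  }, numeric(length(AA20))))
  colnames(per) <- AA20
  rownames(per) <- if (!is.null(names(sequences))) names(sequences) else NULL
  n <- nrow(per)
  means <- colMeans(per)
  sems <- if (n > 1L) apply(per, 2L, stats::sd) / sqrt(n) else rep(NA_real_, length(AA20))
  structure(list(table = data.frame(residue = AA20, mean_percent = means,
                                    sem = sems, row.names = NULL,
                                    stringsAsFactors = FALSE),
                 per_protein = per, n_proteins = n),
            class = "aa_profile")
}

#' @export
print.aa_profile <- function(x, ...) {
  cat("amino-acid composition over", x$n_proteins, "proteins\n")
  print(x$table, digits = 4)
  invisible(x)
}

#' Compare the amino-acid composition of two protein sets
#'
#' Per residue: difference of profile means (set A minus set B) and a
#' two-tailed two-sample Student t-test over the per-protein percentages.
#' Swapping the arguments negates every difference and leaves p-values
#' unchanged.
#'
#' @param profile_a,profile_b [aa_composition()] profiles (each over >= 2
#'   proteins for the t-test).
#' @return Data frame `residue`, `mean_a`, `mean_b`, `difference`, `p_value`.
#' @export
compare_composition <- function(profile_a, profile_b) {
  stopifnot(inherits(profile_a, "aa_profile"), inherits(profile_b, "aa_profile"))
  p <- vapply(AA20, function(r)
    as.numeric(student_t_two_tailed(profile_a$per_protein[, r],
                                    profile_b$per_protein[, r])), 0)
  data.frame(residue = AA20,
             mean_a = profile_a$table$mean_percent,
             mean_b = profile_b$table$mean_percent,
             difference = profile_a$table$mean_percent - profile_b$table$mean_percent,
             p_value = unname(p),
             row.names = NULL, stringsAsFactors = FALSE)
}
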