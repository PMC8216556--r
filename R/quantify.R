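# Reporter-ion quantification.
#
# The quantitation model follows standard isobaric-label practice:
#  * per comparison, replicate i's ratio of a peptide is the intensity of the
#    numerator-condition replicate-i channel over the denominator-condition
#    replicate-i channel (replicate pairing keeps 3 values for the t-test);
#  * ratios are normalized by the median ratio of all the unique peptides:
#    first per replicate pair, then by the grand median of the replicate-
#    averaged ratios, so that after normalization the median replicate-averaged
#    ratio over unique peptides is exactly 1;
#  * protein ratios are the median of their unique peptides' normalized
#    ratios; shared peptides are carried through but never enter a median;
#  * glycosite ratios are divided by the parent protein's ratio so that the
#    corrected ratio reflects occupancy change, not expression change.
# All ratio math is done in log2 internally and reported on the linear scale.

col_medians <- function(m) apply(m, 2L, stats::median, na.rm = TRUE)

#' Normalize peptide reporter ratios by the median ratio of unique peptides
#'
#' For every comparison of the design, replicate-paired intensity ratios are
#' formed (numerator replicate-i channel over denominator replicate-i channel;
#' a replicate ratio exists only when both intensities are present and
#' positive) and normalized in two stages, both using *unique* peptides only:
#' each replicate-pair column is divided by its median over unique peptides,
#' then all ratios are divided by the grand median of the replicate-averaged
#' (geometric-mean, i.e. log2-scale average) ratio over unique peptides with a
#' complete set of replicate ratios. After
#' normalization the median replicate-averaged ratio of those unique peptides
#' is exactly 1, and multiplying all intensities of any single channel by a
#' constant leaves every normalized ratio unchanged.
#'
#' Shared (multi-accession) peptides are carried through with normalized ratios
#' but are excluded from all medians.
#'
#' @param peptides Peptide data frame as returned by [read_peptide_table()].
#' @param design An [experiment_design()].
#' @return Object of class `npx` holding the peptide table, the design,
#'   per-comparison normalized replicate-ratio matrices with their normalizers,
#'   and a per-channel normalized log2 abundance matrix used by the t-tests.
#' @export
normalize_by_median_ratio <- function(peptides, design) {
  stopifnot(inherits(design, "experiment_design"))
  chans <- design$channels
  missing_ch <- setdiff(chans, names(peptides))
  if (length(missing_ch))
    stop("peptide table lacks channel column(s): ", paste(missing_ch, collapse = ", "))
  M <- as.matrix(peptides[chans])
  storage.mode(M) <- "double"
  logM <- suppressWarnings(log2(M))
  logM[!is.finite(logM)] <- NA_real_   # zeros and missing both unusable in ratios
  uniq <- peptides$is_unique
  if (!any(uniq)) stop("no unique peptides: nothing to normalize on")

  # within-peptide scaling (removes peptide-specific ionization efficiency),
  # then per-channel median normalization over unique peptides -> z
  u_log <- logM - rowMeans(logM, na.rm = TRUE)
  f_log <- apply(u_log[uniq, , drop = FALSE], 2L, stats::median, na.rm = TRUE)
  z_log <- sweep(u_log, 2L, f_log, "-")

  comparisons <- list()
  for (i in seq_len(nrow(design$comparisons))) {
    lab <- design$comparisons$label[i]
    pairs <- comparison_pairs(design, design$comparisons$numerator[i],
                              design$comparisons$denominator[i])
    Rlog <- logM[, pairs[, "num"], drop = FALSE] - logM[, pairs[, "den"], drop = FALSE]
    colnames(Rlog) <- paste0("rep", pairs[, "replicate"])
    complete <- uniq & rowSums(is.na(Rlog)) == 0L
    if (!any(complete))
      stop("no unique peptide with complete intensities for comparison ", lab)
    m_log <- apply(Rlog[uniq, , drop = FALSE], 2L, stats::median, na.rm = TRUE)
    Rlog1 <- sweep(Rlog, 2L, m_log, "-")
    ratios1 <- 2^Rlog1
    # replicate averaging on the log2 scale (geometric mean), reported linear
    avg1 <- 2^rowMeans(Rlog1, na.rm = TRUE)
    n_reps <- rowSums(!is.na(ratios1))
    avg1[n_reps == 0L] <- NA_real_
    g <- stats::median(avg1[complete])
    comparisons[[lab]] <- list(
      label = lab, pairs = pairs,
      rep_ratios = ratios1 / g,
      avg_ratio = avg1 / g,
      n_reps = n_reps,
      complete_unique = complete,
      normalizer = list(per_replicate = 2^m_log, grand = g))
  }
  structure(list(peptides = peptides, design = design, z_log = z_log,
                 channel_norm_log = f_log, comparisons = comparisons),
            class = "npx")
}

#' @export
print.npx <- function(x, ...) {
  cat("normalized peptide matrix:", nrow(x$peptides), "peptides (",
      sum(x$peptides$is_unique), "unique ),",
      length(x$comparisons), "comparisons\n")
  invisible(x)
}

#' Roll peptide ratios up to protein ratios
#'
#' Per protein and comparison, the reported ratio is the median (even-sized
#' sets: mean of the two middle values) of the replicate-averaged normalized
#' ratios of the protein's unique peptides; a peptide contributes only when it
#' has at least `min_reps` replicate ratios. Proteins with no unique peptide
#' are omitted (their count is reported with `message()`). The per-comparison
#' p-value is a pooled two-sample Student t-test on log2 normalized per-channel
#' protein abundances, numerator-condition channels versus
#' denominator-condition channels, where a protein's abundance in a channel is
#' the median over its unique peptides of the normalized relative reporter
#' value (see [normalize_by_median_ratio()]); `NA` when fewer than two finite
#' values remain in either group.
#'
#' @param npx A normalized peptide matrix from [normalize_by_median_ratio()].
#' @param min_reps Minimum replicate ratios for a peptide to contribute to a
#'   comparison (default 2, so the t-test always has >= 2 paired ratios).
#' @return Object of class `protein_quant`: list with `table` (data frame:
#'   `accession`, `n_unique_peptides`, then `ratio_<label>` / `p_<label>` per
#'   comparison), `replicate_ratios` (per comparison, proteins x replicates),
#'   `abundance_log` (proteins x channels log2 abundances) and the design.
#' @export
rollup_protein <- function(npx, min_reps = 2L) {
  stopifnot(inherits(npx, "npx"))
  pep <- npx$peptides
  uniq_idx <- which(pep$is_unique)
  if (!length(uniq_idx)) stop("no unique peptides: no protein can be quantified")
  n_shared_only <- length(setdiff(
    unlist(strsplit(pep$accessions[!pep$is_unique], ";", fixed = TRUE)),
    pep$accessions[uniq_idx]))
  if (n_shared_only > 0L)
    message("rollup_protein: ", n_shared_only,
            " protein(s) with shared peptides only were omitted")
  acc_of <- pep$accessions[uniq_idx]
  proteins <- sort(unique(acc_of))
  rows_of <- split(uniq_idx, acc_of)[proteins]

  tab <- data.frame(accession = proteins,
                    n_unique_peptides = lengths(rows_of),
                    stringsAsFactors = FALSE, row.names = NULL)

  # protein log2 abundance per channel: median over unique peptides of z
  abundance_log <- do.call(rbind, lapply(rows_of, function(r)
    col_medians(npx$z_log[r, , drop = FALSE])))
  rownames(abundance_log) <- proteins
  colnames(abundance_log) <- npx$design$channels

  replicate_ratios <- list()
  for (cmp in npx$comparisons) {
    lab <- cmp$label
    eligible <- cmp$n_reps >= min_reps
    ratio <- rep(NA_real_, length(proteins))
    pval <- rep(NA_real_, length(proteins))
    repmat <- matrix(NA_real_, length(proteins), ncol(cmp$rep_ratios),
                     dimnames = list(proteins, colnames(cmp$rep_ratios)))
    num_ch <- cmp$pairs[, "num"]
    den_ch <- cmp$pairs[, "den"]
    for (k in seq_along(proteins)) {
      r <- rows_of[[k]]
      r_ok <- r[eligible[r]]
      if (length(r_ok)) {
        ratio[k] <- stats::median(cmp$avg_ratio[r_ok])
        repmat[k, ] <- col_medians(cmp$rep_ratios[r_ok, , drop = FALSE])
        a <- col_medians(npx$z_log[r_ok, num_ch, drop = FALSE])
        b <- col_medians(npx$z_log[r_ok, den_ch, drop = FALSE])
        a <- a[is.finite(a)]; b <- b[is.finite(b)]
        if (length(a) >= 2L && length(b) >= 2L)
          pval[k] <- student_t_two_tailed(a, b)
      }
    }
    tab[[paste0("ratio_", lab)]] <- ratio
    tab[[paste0("p_", lab)]] <- pval
    replicate_ratios[[lab]] <- repmat
  }
  structure(list(table = tab, replicate_ratios = replicate_ratios,
                 abundance_log = abundance_log, design = npx$design),
            class = "protein_quant")
}

#' @export
print.protein_quant <- function(x, ...) {
  cat("protein quantification:", nrow(x$table), "proteins,",
      length(x$replicate_ratios), "comparisons\n")
  invisible(x)
}

#' Divide a glycosite ratio by its parent protein ratio
#'
#' Removes the contribution of protein-level expression change so that the
#' corrected ratio reflects change in glycosylation-site occupancy. A missing,
#' zero or non-positive protein ratio yields `NA` (flagged absent), never a
#' silent pass-through of the raw ratio.
#'
#' @param raw_ratio Numeric vector of site ratios.
#' @param protein_ratio Numeric vector (recycled) of parent protein ratios.
#' @return `raw_ratio / protein_ratio`, `NA` where the parent is unquantified.
#' @examples
#' correct_site_ratio(3, 1.5)  # 2
#' @export
correct_site_ratio <- function(raw_ratio, protein_ratio) {
  out <- raw_ratio / protein_ratio
  out[is.na(protein_ratio) | protein_ratio <= 0] <- NA_real_
  out
}

#' Quantify N-glycosites with protein-level correction
#'
#' Raw site ratios are replicate-paired reporter ratios normalized with the
#' unique-peptide normalizers of `npx` (sites share the proteome's channels, so
#' the same per-sample bias applies). The reported `raw_<label>` is the mean of
#' the normalized replicate ratios (>= `min_reps` required); the reported
#' `ratio_<label>` is the protein-corrected ratio, i.e. exactly
#' `raw / protein ratio` ([correct_site_ratio()]). For testing, correction is
#' applied per replicate *before* the test: the p-value is a pooled two-sample
#' t-test on log2 site channel values divided by the parent protein's channel
#' abundances, numerator versus denominator channels. Sites whose parent
#' protein is unquantified get `NA` corrected ratios and p-values and are
#' flagged `parent_quantified = FALSE`.
#'
#' @param sites Glycosite data frame from [read_glycosite_table()].
#' @param npx Normalized peptide matrix ([normalize_by_median_ratio()]).
#' @param protein_quant Protein quantification ([rollup_protein()]).
#' @param min_reps Minimum replicate ratios per comparison (default 2).
#' @return Object of class `site_quant`: list with `table` (data frame:
#'   `accession`, `position`, `parent_quantified`, per comparison
#'   `raw_<label>`, `ratio_<label>` (corrected) and `p_<label>`) plus
#'   per-comparison corrected replicate-ratio matrices.
#' @export
quantify_sites <- function(sites, npx, protein_quant, min_reps = 2L) {
  stopifnot(inherits(npx, "npx"), inherits(protein_quant, "protein_quant"))
  chans <- npx$design$channels
  S <- as.matrix(sites[chans])
  storage.mode(S) <- "double"
  logS <- suppressWarnings(log2(S))
  logS[!is.finite(logS)] <- NA_real_
  pidx <- match(sites$accession, protein_quant$table$accession)
  tab <- data.frame(accession = sites$accession, position = sites$position,
                    parent_quantified = !is.na(pidx), stringsAsFactors = FALSE)
  # site channel values on the same normalized log2 scale as protein abundances
  zS <- sweep(logS, 2L, npx$channel_norm_log, "-")

  corrected_reps <- list()
  for (cmp in npx$comparisons) {
    lab <- cmp$label
    m_log <- log2(cmp$normalizer$per_replicate)
    g_log <- log2(cmp$normalizer$grand)
    Rlog <- logS[, cmp$pairs[, "num"], drop = FALSE] -
      logS[, cmp$pairs[, "den"], drop = FALSE]
    Rlog <- sweep(Rlog, 2L, m_log, "-") - g_log
    raw_reps <- 2^Rlog
    n_reps <- rowSums(!is.na(raw_reps))
    raw <- 2^rowMeans(Rlog, na.rm = TRUE)   # geometric replicate mean
    raw[n_reps < min_reps] <- NA_real_

    prot_ratio <- protein_quant$table[[paste0("ratio_", lab)]][pidx]
    prot_reps <- protein_quant$replicate_ratios[[lab]][pidx, , drop = FALSE]
    corrected <- correct_site_ratio(raw, prot_ratio)
    corr_reps <- raw_reps / prot_reps

    A <- protein_quant$abundance_log[pidx, , drop = FALSE]
    pval <- rep(NA_real_, nrow(tab))
    num_ch <- cmp$pairs[, "num"]; den_ch <- cmp$pairs[, "den"]
    for (s in seq_len(nrow(tab))) {
      if (is.na(pidx[s])) next
      a <- zS[s, num_ch] - A[s, num_ch]
      b <- zS[s, den_ch] - A[s, den_ch]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      if (length(a) >= 2L && length(b) >= 2L)
        pval[s] <- student_t_two_tailed(a, b)
    }
    tab[[paste0("raw_", lab)]] <- raw
    tab[[paste0("ratio_", lab)]] <- corrected
    tab[[paste0("p_", lab)]] <- pval
    corrected_reps[[lab]] <- corr_reps
  }
  n_orphan <- sum(is.na(pidx))
  if (n_orphan > 0L)
    message("quantify_sites: ", n_orphan,
            " site(s) have an unquantified parent protein; corrected ratios flagged absent")
  structure(list(table = tab, corrected_replicate_ratios = corrected_reps,
                 design = npx$design), class = "site_quant")
}

#' @export
print.site_quant <- function(x, ...) {
  cat("glycosite quantification:", nrow(x$table), "sites (",
      sum(x$table$parent_quantified), "with quantified parent )\n")
  invisible(x)
}

#' @rdname write_peptide_table
#' @param x A `protein_quant` or `site_quant` object.
#' @export
write_quant_table <- function(x, path) {
  utils::write.table(x$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
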