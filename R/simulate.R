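# Seeded synthetic TMT experiment generator with ground truth.
#
# The generator emulates the study design the package targets: three culture
# temperatures (T30/T50/T55) in triplicate on nine channels of a TMT-10plex,
# log-normal reporter intensities with per-channel loading biases, planted
# protein fold changes, unique and shared peptides, glycosites embedded in
# valid N-X-S/T sequons with occupancy changes independent of protein
# abundance, and annotation categories with planted enrichment.

#' Configuration of a synthetic TMT glycoproteomics experiment
#'
#' Defaults reproduce the emulated study conditions: 3 conditions x 3
#' replicates, 1000 proteins with 1-10 unique peptides, 10% up- and 10%
#' down-regulated proteins per temperature contrast with effect magnitudes
#' drawn from a log-normal with median `effect_size_log2` (2-fold) and
#' `effect_size_sdlog` spread, multiplicative log-normal intensity noise of
#' sd 0.25 (log2), 150 glycoproteins whose site counts follow the
#' 59/22/10/5/4% one-to-many distribution, threonine at the sequon +2
#' position with probability 0.72, and 3 planted enriched BP categories.
#'
#' @param seed Integer seed; one seed governs all randomness.
#' @param n_proteins Number of proteins.
#' @param peptides_per_protein Integer range `c(min, max)` of unique peptides.
#' @param frac_shared_peptides Fraction of peptides additionally assigned to a
#'   second protein (non-unique).
#' @param conditions Condition labels; the first is the baseline.
#' @param n_replicates Replicates per condition.
#' @param frac_up,frac_down Per non-baseline condition, probability that a
#'   protein is up-/down-regulated relative to baseline.
#' @param effect_size_log2 Median |log2 fold change| of regulated proteins.
#' @param effect_size_sdlog sdlog of the log-normal effect-magnitude
#'   distribution (0 gives a fixed effect size).
#' @param noise_sd Log2 sd of multiplicative intensity noise.
#' @param channel_bias_sd Log2 sd of fixed per-channel loading biases.
#' @param dropout_rate Uniform probability that a measured intensity is
#'   missing.
#' @param n_glycoproteins Number of proteins carrying glycosites.
#' @param sites_per_glycoprotein Named probability vector over site counts
#'   1..6.
#' @param frac_site_regulated Per non-baseline condition, probability that a
#'   site's occupancy changes independently of its protein.
#' @param prob_thr_plus2 Probability that a planted sequon is N-X-T rather
#'   than N-X-S.
#' @param n_categories Biological-process categories to simulate.
#' @param n_planted_categories Number of categories enriched in proteins
#'   upregulated in the first comparison.
#' @param seq_length Protein length range.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_proteins = 1000L,
                              peptides_per_protein = c(1L, 10L),
                              frac_shared_peptides = 0.1,
                              conditions = c("T30", "T50", "T55"),
                              n_replicates = 3L,
                              frac_up = 0.1,
                              frac_down = 0.1,
                              effect_size_log2 = 1,
                              effect_size_sdlog = 0.5,
                              noise_sd = 0.25,
                              channel_bias_sd = 0.1,
                              dropout_rate = 0.01,
                              n_glycoproteins = 150L,
                              sites_per_glycoprotein = c(`1` = 0.59, `2` = 0.22, `3` = 0.10,
                                                         `4` = 0.05, `5` = 0.03, `6` = 0.01),
                              frac_site_regulated = 0.2,
                              prob_thr_plus2 = 0.72,
                              n_categories = 40L,
                              n_planted_categories = 3L,
                              seq_length = c(200L, 800L)) {
  cfg <- list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
              peptides_per_protein = as.integer(peptides_per_protein),
              frac_shared_peptides = frac_shared_peptides,
              conditions = conditions, n_replicates = as.integer(n_replicates),
              frac_up = frac_up, frac_down = frac_down,
              effect_size_log2 = effect_size_log2,
              effect_size_sdlog = effect_size_sdlog,
              noise_sd = noise_sd, channel_bias_sd = channel_bias_sd,
              dropout_rate = dropout_rate,
              n_glycoproteins = as.integer(n_glycoproteins),
              sites_per_glycoprotein = sites_per_glycoprotein,
              frac_site_regulated = frac_site_regulated,
              prob_thr_plus2 = prob_thr_plus2,
              n_categories = as.integer(n_categories),
              n_planted_categories = as.integer(n_planted_categories),
              seq_length = as.integer(seq_length))
  fr <- c(cfg$frac_shared_peptides, cfg$frac_up, cfg$frac_down,
          cfg$dropout_rate, cfg$frac_site_regulated, cfg$prob_thr_plus2)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$frac_up + cfg$frac_down > 1) stop("frac_up + frac_down must be <= 1")
  if (cfg$n_glycoproteins > cfg$n_proteins)
    stop("more glycoproteins than proteins is infeasible")
  if (abs(sum(cfg$sites_per_glycoprotein) - 1) > 1e-6)
    stop("sites_per_glycoprotein must sum to 1")
  if (length(cfg$conditions) < 2L) stop("need at least two conditions")
  if (cfg$noise_sd < 0 || cfg$channel_bias_sd < 0) stop("sd parameters must be >= 0")
  if (cfg$peptides_per_protein[1L] < 1L) stop("need at least one peptide per protein")
  if (cfg$seq_length[1L] < 45L) stop("proteins must be at least 45 residues")
  structure(cfg, class = "simulation_config")
}

# draw one random effect magnitude (log2 scale)
draw_effect <- function(n, cfg) {
  if (cfg$effect_size_sdlog == 0) rep(cfg$effect_size_log2, n)
  else stats::rlnorm(n, meanlog = log(cfg$effect_size_log2), sdlog = cfg$effect_size_sdlog)
}

random_peptide <- function(n, len_range = c(8L, 20L)) {
  lens <- sample(seq(len_range[1L], len_range[2L]), n, replace = TRUE)
  vapply(lens, function(l) paste(sample(AA20, l, replace = TRUE), collapse = ""), "")
}

#' Generate a synthetic TMT glycoproteomics experiment
#'
#' Builds, from one seed, a full set of pipeline inputs plus their ground
#' truth: a peptide reporter-intensity table, a glycosite intensity table, a
#' proteome FASTA in which every planted glycosite sits on a valid N-X-S/T
#' sequon, an annotation table (GO namespaces, KEGG, domains and one
#' subcellular location per protein, with planted enriched categories), and
#' truth tables carrying each protein's and site's noiseless fold change and
#' the differential call those fold changes imply at the 1.5-fold threshold.
#' Intensities follow `base x condition effect x channel bias x log-normal
#' noise`; with `noise_sd = 0` and no planted effects every true ratio is
#' exactly 1. The same configuration always yields identical output.
#'
#' @param config A [simulation_config()].
#' @return Object of class `glyco_sim`: list with `peptides`, `sites`,
#'   `proteome`, `annotations`, `truth` (list `proteins`, `sites`,
#'   `categories`), `design`, `config`.
#' @export
simulate_experiment <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  set.seed(cfg$seed)
  conds <- cfg$conditions
  nrep <- cfg$n_replicates
  nchan <- length(conds) * nrep
  channels <- if (identical(conds, c("T30", "T50", "T55")) && nrep == 3L)
    c("126", "127N", "127C", "128N", "128C", "129N", "129C", "130N", "130C")
  else paste0(rep(conds, each = nrep), "_", rep(seq_len(nrep), length(conds)))
  design <- experiment_design(channels, rep(conds, each = nrep),
                              rep(seq_len(nrep), length(conds)))
  accs <- sprintf("CT%04d", seq_len(cfg$n_proteins))

  # planted condition effects (log2, baseline condition = 0)
  e <- matrix(0, cfg$n_proteins, length(conds), dimnames = list(accs, conds))
  for (cond in conds[-1L]) {
    status <- sample(c("up", "down", "null"), cfg$n_proteins, replace = TRUE,
                     prob = c(cfg$frac_up, cfg$frac_down,
                              1 - cfg$frac_up - cfg$frac_down))
    mag <- draw_effect(cfg$n_proteins, cfg)
    e[, cond] <- ifelse(status == "up", mag, ifelse(status == "down", -mag, 0))
  }

  # sequences; proteins upregulated in the first contrast are enriched in the
  # acidic residues Glu/Asp (the compositional signature probed downstream)
  lens <- sample(seq(cfg$seq_length[1L], cfg$seq_length[2L]), cfg$n_proteins,
                 replace = TRUE)
  up_first <- e[, conds[2L]] > 0
  base_w <- stats::setNames(rep(1, 20), AA20)
  acid_w <- base_w
  acid_w[c("E", "D")] <- 1.8
  proteome <- vapply(seq_len(cfg$n_proteins), function(i) {
    w <- if (up_first[i]) acid_w else base_w
    paste(sample(AA20, lens[i], replace = TRUE, prob = w), collapse = "")
  }, "")
  names(proteome) <- accs

  # glycosites: plant valid sequons, threonine at +2 with prob_thr_plus2
  glyco_accs <- sort(sample(accs, cfg$n_glycoproteins))
  n_sites <- sample(as.integer(names(cfg$sites_per_glycoprotein)),
                    cfg$n_glycoproteins, replace = TRUE,
                    prob = cfg$sites_per_glycoprotein)
  site_rows <- list()
  for (gi in seq_along(glyco_accs)) {
    acc <- glyco_accs[gi]
    L <- nchar(proteome[[acc]])
    cand <- seq(15L, L - 15L)
    pos <- integer(0)
    for (k in seq_len(n_sites[gi])) {
      ok <- cand[vapply(cand, function(p) all(abs(p - pos) >= 4L), TRUE)]
      if (!length(ok)) break
      pos <- c(pos, if (length(ok) == 1L) ok else sample(ok, 1L))
    }
    pos <- sort(pos)
    s <- strsplit(proteome[[acc]], "", fixed = TRUE)[[1L]]
    for (p in pos) {
      s[p] <- "N"
      s[p + 1L] <- sample(setdiff(AA20, "P"), 1L)
      s[p + 2L] <- if (stats::runif(1) < cfg$prob_thr_plus2) "T" else "S"
    }
    proteome[[acc]] <- paste(s, collapse = "")
    site_rows[[gi]] <- data.frame(accession = acc, position = pos,
                                  stringsAsFactors = FALSE)
  }
  site_df <- if (length(site_rows)) do.call(rbind, site_rows) else
    data.frame(accession = character(0), position = integer(0),
               stringsAsFactors = FALSE)

  # occupancy effects, independent of protein abundance
  occ <- matrix(0, nrow(site_df), length(conds),
                dimnames = list(NULL, conds))
  for (cond in conds[-1L]) {
    if (!nrow(site_df)) break
    reg <- stats::runif(nrow(site_df)) < cfg$frac_site_regulated
    mag <- draw_effect(nrow(site_df), cfg) * sample(c(1, -1), nrow(site_df), replace = TRUE)
    occ[, cond] <- ifelse(reg, mag, 0)
  }

  bias <- 2^stats::rnorm(nchan, 0, cfg$channel_bias_sd)
  cond_of_chan <- rep(conds, each = nrep)

  intensity_block <- function(mu_base, e_log2) {
    # mu_base: length-n base abundances; e_log2: n x conditions planted log2
    n <- length(mu_base)
    mu <- mu_base * 2^e_log2[, cond_of_chan, drop = FALSE]
    noise <- matrix(2^stats::rnorm(n * nchan, 0, cfg$noise_sd), n, nchan)
    I <- sweep(mu * noise, 2L, bias, "*")
    if (cfg$dropout_rate > 0)
      I[matrix(stats::runif(n * nchan) < cfg$dropout_rate, n, nchan)] <- NA_real_
    colnames(I) <- channels
    I
  }

  # peptides
  n_pep <- sample(seq(cfg$peptides_per_protein[1L], cfg$peptides_per_protein[2L]),
                  cfg$n_proteins, replace = TRUE)
  pep_parent <- rep(seq_len(cfg$n_proteins), n_pep)
  n_peptides <- length(pep_parent)
  pep_seq <- random_peptide(n_peptides)
  while (anyDuplicated(pep_seq)) {
    dup <- duplicated(pep_seq)
    pep_seq[dup] <- random_peptide(sum(dup))
  }
  second <- rep(NA_integer_, n_peptides)
  shared <- stats::runif(n_peptides) < cfg$frac_shared_peptides
  if (cfg$n_proteins > 1L)
    second[shared] <- vapply(pep_parent[shared], function(p)
      sample(setdiff(seq_len(cfg$n_proteins), p), 1L), 1L)
  base_abund <- stats::rlnorm(cfg$n_proteins, meanlog = log(2^20), sdlog = 1)
  pep_factor <- stats::rlnorm(n_peptides, meanlog = 0, sdlog = 0.5)
  mu1 <- base_abund[pep_parent] * pep_factor
  eff <- e[pep_parent, , drop = FALSE]
  I <- intensity_block(mu1, eff)
  # shared peptides also receive signal from their second protein
  if (any(!is.na(second))) {
    sh <- which(!is.na(second))
    mu2 <- base_abund[second[sh]] * pep_factor[sh]
    add <- mu2 * 2^e[second[sh], cond_of_chan, drop = FALSE]
    add <- sweep(add * matrix(2^stats::rnorm(length(sh) * nchan, 0, cfg$noise_sd),
                              length(sh), nchan), 2L, bias, "*")
    I[sh, ] <- I[sh, , drop = FALSE] + add
  }
  peptides <- data.frame(
    peptide_seq = pep_seq,
    accessions = ifelse(is.na(second), accs[pep_parent],
                        paste(accs[pep_parent], accs[second], sep = ";")),
    is_unique = is.na(second), stringsAsFactors = FALSE)
  peptides <- cbind(peptides, as.data.frame(I))
  rownames(peptides) <- NULL

  # site intensities: parent protein effect plus independent occupancy effect
  site_parent <- match(site_df$accession, accs)
  site_base <- stats::rlnorm(nrow(site_df), meanlog = log(2^18), sdlog = 1)
  site_eff <- e[site_parent, , drop = FALSE] + occ
  sites <- cbind(site_df, as.data.frame(intensity_block(site_base, site_eff)))
  rownames(sites) <- NULL

  # annotations
  compartments <- c(nucleus = 0.28, mitochondria = 0.22, cytoplasm = 0.20,
                    extracellular = 0.12, plasma_membrane = 0.08,
                    endoplasmic_reticulum = 0.05, golgi = 0.03, vacuole = 0.02)
  glyco_comp <- c(extracellular = 0.45, plasma_membrane = 0.18, nucleus = 0.11,
                  mitochondria = 0.10, cytoplasm = 0.10,
                  endoplasmic_reticulum = 0.06)
  loc <- character(cfg$n_proteins)
  is_glyco <- accs %in% glyco_accs
  loc[!is_glyco] <- sample(names(compartments), sum(!is_glyco), replace = TRUE,
                           prob = compartments)
  loc[is_glyco] <- sample(names(glyco_comp), sum(is_glyco), replace = TRUE,
                          prob = glyco_comp)
  term_rows <- list(data.frame(accession = accs, term_type = "LOCATION",
                               term = loc, stringsAsFactors = FALSE))
  planted <- character(0)
  if (cfg$n_categories > 0L) {
    cat_ids <- sprintf("BP:%04d", seq_len(cfg$n_categories))
    planted <- cat_ids[seq_len(min(cfg$n_planted_categories, cfg$n_categories))]
    for (ci in seq_along(cat_ids)) {
      if (cat_ids[ci] %in% planted) {
        pmem <- ifelse(up_first, 0.4, 0.02)
      } else {
        pmem <- rep(stats::runif(1, 0.02, 0.08), cfg$n_proteins)
      }
      mem <- accs[stats::runif(cfg$n_proteins) < pmem]
      if (length(mem))
        term_rows[[length(term_rows) + 1L]] <-
          data.frame(accession = mem, term_type = "BP", term = cat_ids[ci],
                     stringsAsFactors = FALSE)
    }
    for (blk in list(c("MF", 20L), c("CC", 15L), c("KEGG", 15L), c("DOMAIN", 20L))) {
      ns <- blk[1L]; ncat <- as.integer(blk[2L])
      for (ci in seq_len(ncat)) {
        mem <- accs[stats::runif(cfg$n_proteins) < stats::runif(1, 0.02, 0.08)]
        if (length(mem))
          term_rows[[length(term_rows) + 1L]] <-
            data.frame(accession = mem, term_type = ns,
                       term = sprintf("%s:%04d", ns, ci), stringsAsFactors = FALSE)
      }
    }
  }
  annotations <- annotation_table(do.call(rbind, term_rows))

  # ground truth: noiseless fold changes and the calls they imply at 1.5x
  truth_call <- function(ratio, fc = 1.5)
    ifelse(ratio > fc, "up", ifelse(ratio < 1 / fc, "down", "unchanged"))
  cmp <- design$comparisons
  truth_proteins <- do.call(rbind, lapply(seq_len(nrow(cmp)), function(i) {
    fc <- e[, cmp$numerator[i]] - e[, cmp$denominator[i]]
    data.frame(accession = accs, comparison = cmp$label[i],
               true_log2fc = fc, true_ratio = 2^fc,
               true_call = truth_call(2^fc), stringsAsFactors = FALSE)
  }))
  truth_sites <- if (nrow(site_df) == 0L)
    data.frame(accession = character(0), position = integer(0),
               comparison = character(0), true_log2fc = numeric(0),
               true_ratio = numeric(0), true_call = character(0),
               stringsAsFactors = FALSE)
  else do.call(rbind, lapply(seq_len(nrow(cmp)), function(i) {
    fc <- occ[, cmp$numerator[i]] - occ[, cmp$denominator[i]]
    data.frame(accession = site_df$accession, position = site_df$position,
               comparison = cmp$label[i],
               true_log2fc = fc, true_ratio = 2^fc,
               true_call = truth_call(2^fc), stringsAsFactors = FALSE)
  }))
  truth_categories <- data.frame(
    term = sprintf("BP:%04d", seq_len(cfg$n_categories)),
    planted = sprintf("BP:%04d", seq_len(cfg$n_categories)) %in% planted,
    stringsAsFactors = FALSE)

  structure(list(peptides = peptides, sites = sites, proteome = proteome,
                 annotations = annotations,
                 truth = list(proteins = truth_proteins, sites = truth_sites,
                              categories = truth_categories),
                 design = design, config = cfg),
            class = "glyco_sim")
}

#' @export
print.glyco_sim <- function(x, ...) {
  cat("synthetic TMT experiment: seed", x$config$seed, "-",
      nrow(x$peptides), "peptides /", x$config$n_proteins, "proteins,",
      nrow(x$sites), "glycosites on", x$config$n_glycoproteins, "glycoproteins\n")
  invisible(x)
}

#' Write a synthetic experiment to disk
#'
#' Writes the exact input formats the readers consume (`peptides.tsv`,
#' `glycosites.tsv`, `proteome.fasta`, `annotations.tsv`, `design.tsv`) plus
#' the truth tables. Identical simulations produce byte-identical files.
#'
#' @param sim A [simulate_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "glyco_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(peptides = file.path(dir, "peptides.tsv"),
             sites = file.path(dir, "glycosites.tsv"),
             proteome = file.path(dir, "proteome.fasta"),
             annotations = file.path(dir, "annotations.tsv"),
             design = file.path(dir, "design.tsv"),
             truth_proteins = file.path(dir, "truth_proteins.tsv"),
             truth_sites = file.path(dir, "truth_sites.tsv"),
             truth_categories = file.path(dir, "truth_categories.tsv"))
  write_peptide_table(sim$peptides, paths["peptides"])
  write_glycosite_table(sim$sites, paths["sites"])
  write_fasta(sim$proteome, paths["proteome"])
  write_annotation_table(sim$annotations, paths["annotations"])
  write_design(sim$design, paths["design"])
  for (nm in c("proteins", "sites", "categories"))
    utils::write.table(sim$truth[[nm]], paths[paste0("truth_", nm)],
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(paths)
}

#' Confusion summary of differential calls against ground truth
#'
#' Per comparison and direction (`up`, `down`): true/false positives and
#' negatives of the calls with respect to the planted truth, with sensitivity
#' `TP / (TP + FN)` and false discovery rate `FP / (TP + FP)`. `untestable`
#' calls count as negative (the pipeline did not call them). Every call must
#' have a matching truth row.
#'
#' @param calls Data frame from [call_differential()] (protein- or
#'   site-level).
#' @param truth Truth table (`truth$proteins` or `truth$sites` of a
#'   [simulate_experiment()] result) with `accession`, optional `position`,
#'   `comparison`, `true_call`.
#' @return Data frame `comparison`, `direction`, `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `fdr`.
#' @export
truth_report <- function(calls, truth) {
  by_site <- "position" %in% names(calls) && "position" %in% names(truth)
  key <- function(d) if (by_site) paste(d$accession, d$position, d$comparison)
  else paste(d$accession, d$comparison)
  idx <- match(key(calls), key(truth))
  if (anyNA(idx))
    stop("identifier mismatch: ", sum(is.na(idx)),
         " call(s) have no matching truth row")
  tc <- truth$true_call[idx]
  out <- list()
  for (lab in unique(calls$comparison)) {
    in_cmp <- calls$comparison == lab
    for (dir in c("up", "down")) {
      called <- in_cmp & calls$call == dir
      istrue <- in_cmp & tc == dir
      tp <- sum(called & istrue); fp <- sum(called & !istrue)
      fn <- sum(!called & istrue); tn <- sum(in_cmp) - tp - fp - fn
      out[[length(out) + 1L]] <- data.frame(
        comparison = lab, direction = dir, tp = tp, fp = fp, tn = tn, fn = fn,
        sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
        fdr = if (tp + fp > 0) fp / (tp + fp) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
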