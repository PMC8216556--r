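# Differential calling: fold change > 1.5 plus two-tailed Student t (p < 0.05),
# and three-way Venn partitioning of the resulting accession sets.

#' Two-tailed equal-variance Student t-test
#'
#' Pooled-variance two-sample t-test as applied to log2 normalized replicate
#' values. Degenerate inputs follow fixed conventions: if both groups are
#' constant, p = 1 when their values are equal and p = 0 when they differ
#' (the result then carries attribute `degenerate = TRUE`).
#'
#' @param group_a,group_b Numeric vectors with at least two finite values each.
#' @return Two-sided p-value in \[0, 1\].
#' @examples
#' student_t_two_tailed(c(1, 2, 3), c(1, 2, 3))  # 1
#' @export
student_t_two_tailed <- function(group_a, group_b) {
  a <- group_a[is.finite(group_a)]
  b <- group_b[is.finite(group_b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 finite values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    p <- if (isTRUE(all.equal(mean(a), mean(b))) || mean(a) == mean(b)) 1 else 0
    return(structure(p, degenerate = TRUE))
  }
  stats::t.test(a, b, var.equal = TRUE)$p.value
}

#' Call differential proteins or glycosites
#'
#' Applies the joint threshold rule per comparison: `up` when
#' ratio > `fold_change` and p < `alpha`; `down` when ratio < 1/`fold_change`
#' and p < `alpha`; otherwise `unchanged`; `untestable` when the ratio or
#' p-value is absent (fewer than two replicate ratios, or unquantified parent
#' protein for sites). For site-level input the protein-corrected ratio is
#' used. Optionally Benjamini-Hochberg adjusts p-values within each comparison
#' before thresholding (off by default: the criterion is raw p < alpha).
#'
#' @param x A `protein_quant` or `site_quant` object, or a data frame with
#'   `accession` (optionally `position`) and `ratio_<label>` / `p_<label>`
#'   column pairs.
#' @param fold_change Fold-change threshold (> 1), default 1.5.
#' @param alpha Significance level in (0, 1), default 0.05.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data frame in long format: `accession`, (`position`,) `comparison`,
#'   `ratio`, `p_value`, `call` with call in
#'   `{"up", "down", "unchanged", "untestable"}`.
#' @export
call_differential <- function(x, fold_change = 1.5, alpha = 0.05,
                              adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!(is.numeric(fold_change) && fold_change > 1))
    stop("'fold_change' must be > 1")
  if (!(is.numeric(alpha) && alpha > 0 && alpha < 1))
    stop("'alpha' must be in (0, 1)")
  tab <- if (inherits(x, "protein_quant") || inherits(x, "site_quant")) x$table else x
  ratio_cols <- grep("^ratio_", names(tab), value = TRUE)
  if (!length(ratio_cols)) stop("no 'ratio_<comparison>' columns found")
  labels <- sub("^ratio_", "", ratio_cols)
  has_pos <- "position" %in% names(tab)
  out <- do.call(rbind, lapply(labels, function(lab) {
    ratio <- tab[[paste0("ratio_", lab)]]
    p <- tab[[paste0("p_", lab)]]
    if (is.null(p)) stop("missing column p_", lab)
    if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
    call <- rep("unchanged", nrow(tab))
    call[ratio > fold_change & p < alpha] <- "up"
    call[ratio < 1 / fold_change & p < alpha] <- "down"
    call[is.na(ratio) | is.na(p)] <- "untestable"
    d <- data.frame(accession = tab$accession, stringsAsFactors = FALSE)
    if (has_pos) d$position <- tab$position
    d$comparison <- lab
    d$ratio <- ratio
    d$p_value <- p
    d$call <- call
    d
  }))
  rownames(out) <- NULL
  out
}

#' Extract up/down accession sets from differential calls
#'
#' @param calls Data frame from [call_differential()].
#' @return Nested list: `sets[[comparison]][[direction]]` -> character vector
#'   of accessions (unique; for site-level calls a protein appears once however
#'   many of its sites move).
#' @export
differential_sets <- function(calls) {
  out <- list()
  for (lab in unique(calls$comparison)) {
    sub <- calls[calls$comparison == lab, ]
    out[[lab]] <- list(up = sort(unique(sub$accession[sub$call == "up"])),
                       down = sort(unique(sub$accession[sub$call == "down"])))
  }
  out
}

#' Three-set Venn partition
#'
#' Partitions the union of three accession sets into the 7 disjoint Venn
#' cells; the triple intersection is labelled `"common"`.
#'
#' @param set_a,set_b,set_c Character vectors (duplicates ignored).
#' @param names Labels of the three sets, default `c("A", "B", "C")`.
#' @return Data frame with `cell`, `count`, `members` (semicolon-joined,
#'   sorted). Cells are disjoint and their counts sum to the union size.
#' @examples
#' venn_partition(c("p1", "p2"), c("p2", "p3"), "p2")
#' @export
venn_partition <- function(set_a, set_b, set_c, names = c("A", "B", "C")) {
  stopifnot(length(names) == 3L)
  a <- unique(as.character(set_a)); b <- unique(as.character(set_b))
  c_ <- unique(as.character(set_c))
  all_ids <- sort(unique(c(a, b, c_)))
  ina <- all_ids %in% a; inb <- all_ids %in% b; inc <- all_ids %in% c_
  cells <- list(
    ina & !inb & !inc, !ina & inb & !inc, !ina & !inb & inc,
    ina & inb & !inc, ina & !inb & inc, !ina & inb & inc,
    ina & inb & inc)
  labels <- c(names[1L], names[2L], names[3L],
              paste(names[1L], names[2L], sep = "&"),
              paste(names[1L], names[3L], sep = "&"),
              paste(names[2L], names[3L], sep = "&"),
              "common")
  data.frame(cell = labels,
             count = vapply(cells, sum, 0L),
             members = vapply(cells, function(m) paste(all_ids[m], collapse = ";"), ""),
             stringsAsFactors = FALSE)
}
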