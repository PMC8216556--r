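# Functional enrichment: two-tailed Fisher's exact test of category membership
# in a differential set against the quantified background, enrichment-heatmap
# clustering, and subcellular-localization summaries.

#' Two-tailed Fisher's exact test on enrichment counts
#'
#' The 2x2 table is (foreground in / not in category) versus (background-only
#' in / not in category); the two-sided p-value is the minimum-likelihood
#' definition: the sum of the probabilities of all tables with the same
#' margins whose point probability does not exceed the observed one
#' (as implemented by [stats::fisher.test()]).
#'
#' @param k Foreground proteins in the category.
#' @param K Foreground size.
#' @param n Background proteins in the category (foreground included).
#' @param N Background size.
#' @return Two-sided p-value.
#' @examples
#' fisher_two_tailed(3, 4, 4, 8)  # the 2x2 table [[3,1],[1,3]]
#' @export
fisher_two_tailed <- function(k, K, n, N) {
  vals <- c(k = k, K = K, n = n, N = N)
  if (any(vals < 0) || any(vals != round(vals)))
    stop("counts must be non-negative integers")
  tab <- matrix(c(k, K - k, n - k, N - K - (n - k)), nrow = 2L)
  if (any(tab < 0))
    stop("margin violation: need k <= K <= N, k <= n <= N and n - k <= N - K")
  stats::fisher.test(tab)$p.value
}

#' Category enrichment of a protein set
#'
#' One row per annotation category (of the requested namespace) with at least
#' one foreground member, tested with [fisher_two_tailed()] against the
#' background (by default all quantified proteins, which avoids detection
#' bias; pass the whole proteome explicitly to switch). Fold enrichment is
#' `(k/K) / (n/N)`.
#'
#' @param foreground Character vector of accessions (must be a subset of
#'   `background`).
#' @param background Character vector of accessions.
#' @param annotations An [annotation_table()].
#' @param namespace One of `"BP"`, `"MF"`, `"CC"`, `"KEGG"`, `"DOMAIN"`.
#' @param alpha Significance level for the `significant` flag (default 0.05,
#'   raw p-values).
#' @return Data frame sorted by p-value: `term`, `term_type`, `k`, `K`, `n`,
#'   `N`, `fold_enrichment`, `p_value`, `significant`.
#' @export
enrich <- function(foreground, background, annotations, namespace,
                   alpha = 0.05) {
  stopifnot(inherits(annotations, "annotation_table"))
  namespace <- match.arg(namespace, c("BP", "MF", "CC", "KEGG", "DOMAIN"))
  foreground <- unique(as.character(foreground))
  background <- unique(as.character(background))
  extra <- setdiff(foreground, background)
  if (length(extra))
    stop("foreground is not a subset of the background (e.g. ", extra[1L], ")")
  t <- annotations$terms
  t <- t[t$term_type == namespace & t$accession %in% background, , drop = FALSE]
  t <- unique(t)
  K <- length(foreground)
  N <- length(background)
  cats <- sort(unique(t$term[t$accession %in% foreground]))
  rows <- lapply(cats, function(cat) {
    members <- t$accession[t$term == cat]
    k <- sum(foreground %in% members)
    n <- length(members)
    data.frame(term = cat, term_type = namespace, k = k, K = K, n = n, N = N,
               fold_enrichment = (k / K) / (n / N),
               p_value = fisher_two_tailed(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(term = character(0), term_type = character(0), k = integer(0),
               K = integer(0), n = integer(0), N = integer(0),
               fold_enrichment = numeric(0), p_value = numeric(0),
               stringsAsFactors = FALSE)
  out$significant <- out$p_value < alpha
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster an enrichment heatmap
#'
#' Builds the matrix of `-log10(p)` (p floored at `p_floor`) with one row per
#' category and one column per cell (typically comparison x direction), keeps
#' only categories significant in at least one cell and supported by at least
#' `min_k` foreground proteins somewhere, and clusters rows and columns by
#' hierarchical clustering (Euclidean distance, average linkage). Input order
#' does not affect the result: rows and columns are sorted by identifier
#' before clustering, which also makes leaf order deterministic under ties.
#'
#' @param rows Data frame with columns `term`, `cell`, `p_value`, `k`,
#'   `significant` (e.g. stacked [enrich()] results with a `cell` label added).
#' @param p_floor Smallest p used in `-log10` (default 1e-15).
#' @param min_k Minimum foreground count somewhere for a category (default 2;
#'   single-protein categories produce unstable rows).
#' @return List of class `enrichment_heatmap`: `matrix` (-log10 p),
#'   `row_order`, `col_order`, and `row_hclust` / `col_hclust`
#'   ([stats::hclust] objects, `NULL` when fewer than two rows/columns).
#' @export
cluster_heatmap <- function(rows, p_floor = 1e-15, min_k = 2L) {
  require_columns(rows, c("term", "cell", "p_value", "k", "significant"),
                  "enrichment heatmap input")
  keep_terms <- sort(unique(rows$term[ave(rows$significant, rows$term, FUN = any) > 0]))
  kmax <- tapply(rows$k, rows$term, max)
  keep_terms <- keep_terms[kmax[keep_terms] >= min_k]
  rows <- rows[rows$term %in% keep_terms, , drop = FALSE]
  terms <- sort(unique(rows$term))
  cells <- sort(unique(rows$cell))
  mat <- matrix(0, length(terms), length(cells), dimnames = list(terms, cells))
  score <- -log10(pmax(rows$p_value, p_floor))
  mat[cbind(match(rows$term, terms), match(rows$cell, cells))] <- score
  row_hclust <- if (nrow(mat) >= 2L) stats::hclust(stats::dist(mat), method = "average") else NULL
  col_hclust <- if (ncol(mat) >= 2L) stats::hclust(stats::dist(t(mat)), method = "average") else NULL
  structure(list(matrix = mat,
                 row_order = if (is.null(row_hclust)) seq_len(nrow(mat)) else row_hclust$order,
                 col_order = if (is.null(col_hclust)) seq_len(ncol(mat)) else col_hclust$order,
                 row_hclust = row_hclust, col_hclust = col_hclust),
            class = "enrichment_heatmap")
}

#' @export
print.enrichment_heatmap <- function(x, ...) {
  cat("enrichment heatmap:", nrow(x$matrix), "categories x", ncol(x$matrix), "cells\n")
  invisible(x)
}

#' Subcellular-localization summary of a protein set
#'
#' Counts and percentages per primary compartment label (as predicted
#' upstream, e.g. by Wolfpsort, and consumed through the annotation table);
#' proteins without a label are binned as `"unknown"`.
#'
#' @param accessions Character vector of proteins (non-empty).
#' @param annotations An [annotation_table()] carrying `LOCATION` rows.
#' @return Data frame `compartment`, `count`, `percent` (summing to 100),
#'   sorted by decreasing count.
#' @export
localization_summary <- function(accessions, annotations) {
  accessions <- unique(as.character(accessions))
  if (!length(accessions)) stop("empty protein set")
  labs <- annotations$locations[accessions]
  labs[is.na(labs)] <- "unknown"
  tab <- sort(table(labs), decreasing = TRUE)
  data.frame(compartment = names(tab),
             count = as.integer(tab),
             percent = 100 * as.numeric(tab) / length(accessions),
             stringsAsFactors = FALSE)
}
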