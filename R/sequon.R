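# N-glycosylation sequon analysis: the consensus is Asn-X-Ser/Thr with X any
# residue except proline. Overlapping sequons are all reported, since each
# asparagine is independently glycosylatable.

#' Find N-X-S/T sequons in a protein sequence
#'
#' Returns every (possibly overlapping) 1-based position `i` with
#' `seq[i] == "N"`, `seq[i+1] != "P"` and `seq[i+2]` in `{S, T}`.
#'
#' @param sequence Uppercase amino-acid string.
#' @return Data frame with `position` (1-based Asn index) and `triplet`.
#' @examples
#' find_sequons("NVTQNPSLNGS")$position  # 1 and 9; the Asn at 5 has X = Pro
#' @export
find_sequons <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  hits <- gregexpr("N(?=[^P][ST])", sequence, perl = TRUE)[[1L]]
  if (hits[1L] == -1L)
    return(data.frame(position = integer(0), triplet = character(0),
                      stringsAsFactors = FALSE))
  pos <- as.integer(hits)
  data.frame(position = pos,
             triplet = substring(sequence, pos, pos + 2L),
             stringsAsFactors = FALSE)
}

#' Sequons of a whole proteome
#'
#' @param proteome Named character vector (accession -> sequence).
#' @return Data frame `accession`, `position`, `triplet`.
#' @export
sequon_table <- function(proteome) {
  res <- lapply(names(proteome), function(acc) {
    s <- find_sequons(proteome[[acc]])
    if (nrow(s)) cbind(accession = acc, s, stringsAsFactors = FALSE) else NULL
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(accession = character(0), position = integer(0),
                      triplet = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Extract the 21-mer flanking window around a glycosite
#'
#' Ten residues upstream and downstream of the modified asparagine; positions
#' beyond the protein termini are padded with `"_"` so the window is always 21
#' characters with the site at the center.
#'
#' @param sequence Protein sequence.
#' @param position 1-based index of the glycosylated Asn (must be `"N"`).
#' @param flank Flank length (default 10).
#' @return Character string of length `2 * flank + 1`.
#' @export
extract_window <- function(sequence, position, flank = 10L) {
  stopifnot(length(sequence) == 1L, length(position) == 1L)
  n <- nchar(sequence)
  if (position < 1L || position > n)
    stop("position ", position, " outside sequence of length ", n)
  if (substring(sequence, position, position) != "N")
    stop("residue at position ", position, " is not an asparagine")
  lo <- position - flank
  hi <- position + flank
  core <- substring(sequence, max(1L, lo), min(n, hi))
  paste0(strrep("_", max(0L, 1L - lo)), core, strrep("_", max(0L, hi - n)))
}

#' Classify observed glycosites against the sequon consensus
#'
#' Adds `is_sequon` to a site table: `TRUE` when the position falls on an Asn
#' that heads an N-X-S/T sequon of its protein. Sites on non-sequon positions
#' (e.g. chemical deamidation artifacts) are flagged non-canonical and counted
#' in a `message()`; they are reported, never silently dropped, but excluded
#' from motif matrices by default.
#'
#' @param sites Data frame with `accession` and `position`.
#' @param proteome Named character vector of protein sequences.
#' @return `sites` with an `is_sequon` logical column.
#' @export
classify_sites <- function(sites, proteome) {
  seqs <- proteome[sites$accession]
  trip <- substring(seqs, sites$position, sites$position + 2L)
  ok <- !is.na(trip) & grepl("^N[^P][ST]$", trip)
  sites$is_sequon <- ok
  n_bad <- sum(!ok)
  if (n_bad > 0L)
    message("classify_sites: ", n_bad,
            " non-canonical site(s) (not on an N-X-S/T sequon) flagged")
  sites
}

#' Flanking windows of observed glycosites
#'
#' @inheritParams classify_sites
#' @param canonical_only Keep only sites on a valid sequon (default `TRUE`).
#' @param flank Flank length (default 10).
#' @return Character vector of 21-mer windows.
#' @export
site_windows <- function(sites, proteome, canonical_only = TRUE, flank = 10L) {
  sites <- classify_sites(sites, proteome)
  if (canonical_only) sites <- sites[sites$is_sequon, , drop = FALSE]
  vapply(seq_len(nrow(sites)), function(i)
    extract_window(proteome[[sites$accession[i]]], sites$position[i], flank),
    "")
}

#' Position-specific residue occupancy matrix
#'
#' Frequency of each of the 20 residues at each of the 21 positions (-10 .. +10
#' around the glycosylated Asn) over a set of flanking windows. Terminal pad
#' characters (`"_"`) are excluded from the denominator of their position, so
#' every position with at least one real residue sums to exactly 1.
#'
#' @param windows Character vector of equal-length windows
#'   (see [site_windows()]); the center character must be `"N"`.
#' @return Numeric matrix, rows = positions (named `"-10"` .. `"10"`),
#'   columns = the 20 amino acids.
#' @export
occupancy_matrix <- function(windows) {
  if (length(windows) == 0L) stop("no windows: cannot build an occupancy matrix")
  w <- nchar(windows[1L])
  if (any(nchar(windows) != w)) stop("windows must all have the same length")
  if (w %% 2L == 0L) stop("window length must be odd")
  flank <- (w - 1L) %/% 2L
  center <- substring(windows, flank + 1L, flank + 1L)
  if (any(center != "N")) stop("window center must be the glycosylated asparagine (N)")
  chars <- matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(windows), byrow = TRUE)
  mat <- matrix(0, nrow = w, ncol = length(AA20),
                dimnames = list(as.character(seq_len(w) - flank - 1L), AA20))
  for (p in seq_len(w)) {
    col <- chars[, p]
    col <- col[col != "_"]
    if (!length(col)) next
    counts <- table(factor(col, levels = AA20))
    mat[p, ] <- as.numeric(counts) / length(col)
  }
  mat
}

#' Glycosylation-site count distribution over glycoproteins
#'
#' Fraction of glycoproteins carrying 1, 2, 3, 4 or >= 5 sites.
#'
#' @param site_accessions Character vector with one entry per observed site
#'   (the accession of its protein), or a data frame with an `accession`
#'   column.
#' @return Data frame `bin` (`"1"`, `"2"`, `"3"`, `"4"`, `"5+"`),
#'   `n_proteins`, `fraction`; fractions sum to 1.
#' @export
site_count_distribution <- function(site_accessions) {
  if (is.data.frame(site_accessions)) site_accessions <- site_accessions$accession
  if (!length(site_accessions)) stop("no sites: cannot compute a distribution")
  counts <- table(site_accessions)
  binned <- ifelse(counts >= 5L, "5+", as.character(counts))
  tab <- table(factor(binned, levels = c("1", "2", "3", "4", "5+")))
  data.frame(bin = names(tab),
             n_proteins = as.integer(tab),
             fraction = as.numeric(tab) / length(counts),
             stringsAsFactors = FALSE)
}
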