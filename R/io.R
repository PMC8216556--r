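# Tabular and sequence I/O.
#
# All tables are strict TSV: tab separator, '.' decimal point, UTF-8, header
# row. Missing reporter intensities may be encoded as "", "NA" or "NaN" and are
# kept distinct from measured zeros (zeros enter no ratio, but they are data).
# Readers reject rows rather than silently dropping them: every rejected row is
# reported with its row number and a reason, and the rejections are attached to
# the result as attribute "rejected".

MISSING_TOKENS <- c("", "NA", "NaN", "na", "nan")
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

read_tsv_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0L && ncol(df) <= 1L) stop("empty or headerless table: ", path)
  df
}

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "))
}

# parse one character intensity column; returns list(value = numeric, bad = logical)
parse_intensity <- function(x) {
  x <- trimws(x)
  val <- rep(NA_real_, length(x))
  is_missing <- x %in% MISSING_TOKENS | is.na(x)
  num <- suppressWarnings(as.numeric(x[!is_missing]))
  val[!is_missing] <- num
  bad <- rep(FALSE, length(x))
  bad[!is_missing] <- is.na(num) | num < 0
  val[bad] <- NA_real_
  list(value = val, bad = bad)
}

finish_rejections <- function(df, bad_rows, reasons, what) {
  rejected <- data.frame(row = which(bad_rows), reason = reasons[bad_rows],
                         stringsAsFactors = FALSE)
  if (nrow(rejected)) {
    for (i in seq_len(nrow(rejected)))
      message(what, ": rejected row ", rejected$row[i], " (", rejected$reason[i], ")")
    df <- df[!bad_rows, , drop = FALSE]
    rownames(df) <- NULL
  }
  attr(df, "rejected") <- rejected
  df
}

#' Read a peptide quantification table
#'
#' Expects a TSV with columns `peptide_seq`, `accessions` (semicolon-delimited
#' protein accessions) and one reporter-intensity column per channel of the
#' design. A peptide is *unique* iff it maps to exactly one accession; the
#' derived logical column `is_unique` is added. Intensities `""`, `"NA"` and
#' `"NaN"` become missing values (`NA`), which are distinct from measured
#' zeros. Rows with an unparsable or negative intensity, an empty sequence, a
#' sequence outside the 20-letter alphabet or no accession are rejected with
#' their row number (reported via `message()` and kept in the `"rejected"`
#' attribute).
#'
#' @param path Path to the TSV file.
#' @param design An [experiment_design()]; every design channel must have a
#'   column.
#' @return A data frame with `peptide_seq`, `accessions`, `is_unique` and one
#'   numeric column per channel.
#' @export
read_peptide_table <- function(path, design) {
  df <- read_tsv_raw(path)
  require_columns(df, c("peptide_seq", "accessions", design$channels), "peptide table")
  n <- nrow(df)
  if (n == 0L) stop("peptide table has no data rows: ", path)
  bad <- rep(FALSE, n)
  reason <- rep("", n)
  flag <- function(cond, msg) {
    newly <- cond & !bad
    reason[newly] <<- msg
    bad[newly] <<- TRUE
  }
  seqs <- toupper(trimws(df$peptide_seq))
  flag(!nzchar(seqs), "empty peptide sequence")
  flag(grepl(sprintf("[^%s]", paste(AA20, collapse = "")), seqs),
       "non-standard residue in peptide sequence")
  accs <- vapply(strsplit(df$accessions, ";", fixed = TRUE),
                 function(a) paste(trimws(a[nzchar(trimws(a))]), collapse = ";"), "")
  flag(!nzchar(accs), "no protein accession")
  out <- data.frame(peptide_seq = seqs, accessions = accs,
                    is_unique = !grepl(";", accs, fixed = TRUE),
                    stringsAsFactors = FALSE)
  for (ch in design$channels) {
    p <- parse_intensity(df[[ch]])
    flag(p$bad, sprintf("unparsable or negative intensity in channel %s", ch))
    out[[ch]] <- p$value
  }
  finish_rejections(out, bad, reason, "peptide table")
}

#' Write a peptide quantification table
#'
#' Inverse of [read_peptide_table()]; missing intensities are written as `NA`
#' so that write-then-read is the identity.
#'
#' @param peptides Data frame as returned by [read_peptide_table()].
#' @param path Output path.
#' @export
write_peptide_table <- function(peptides, path) {
  out <- peptides
  out$is_unique <- NULL
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read an N-glycosite quantification table
#'
#' TSV with columns `accession`, `position` (1-based index of the glycosylated
#' asparagine) and one reporter-intensity column per design channel; an
#' optional `localization_prob` column in \[0, 1\] is carried through. If a
#' proteome is supplied, rows whose position does not fall on an `N` of the
#' named protein are rejected (reported, never silently dropped).
#'
#' @inheritParams read_peptide_table
#' @param proteome Optional named character vector of protein sequences used to
#'   validate that each site sits on an asparagine.
#' @return Data frame with `accession`, `position`, per-channel intensities and
#'   (if present) `localization_prob`.
#' @export
read_glycosite_table <- function(path, design, proteome = NULL) {
  df <- read_tsv_raw(path)
  require_columns(df, c("accession", "position", design$channels), "glycosite table")
  n <- nrow(df)
  if (n == 0L) stop("glycosite table has no data rows: ", path)
  bad <- rep(FALSE, n)
  reason <- rep("", n)
  flag <- function(cond, msg) {
    newly <- cond & !bad
    reason[newly] <<- msg
    bad[newly] <<- TRUE
  }
  pos <- suppressWarnings(as.numeric(df$position))
  flag(is.na(pos) | pos < 1 | pos != round(pos), "position is not a positive integer")
  acc <- trimws(df$accession)
  flag(!nzchar(acc), "missing accession")
  out <- data.frame(accession = acc, position = as.integer(round(pos)),
                    stringsAsFactors = FALSE)
  for (ch in design$channels) {
    p <- parse_intensity(df[[ch]])
    flag(p$bad, sprintf("unparsable or negative intensity in channel %s", ch))
    out[[ch]] <- p$value
  }
  if ("localization_prob" %in% names(df)) {
    lp <- suppressWarnings(as.numeric(df$localization_prob))
    flag(!is.na(lp) & (lp < 0 | lp > 1), "localization_prob outside [0, 1]")
    out$localization_prob <- lp
  }
  if (!is.null(proteome)) {
    res <- substring(proteome[out$accession], out$position, out$position)
    flag(is.na(res) | res != "N",
         "site position is not an asparagine of the named protein")
  }
  finish_rejections(out, bad, reason, "glycosite table")
}

#' @rdname write_peptide_table
#' @param sites Data frame as returned by [read_glycosite_table()].
#' @export
write_glycosite_table <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a proteome FASTA
#'
#' The accession of each record is the first whitespace-delimited token of its
#' header; UniProt-style `sp|ACC|NAME` / `tr|ACC|NAME` wrappers are reduced to
#' the bare accession. Sequences are uppercased and trailing/internal `*` stop
#' characters are stripped. Characters outside the 20-letter amino-acid
#' alphabet, or duplicated accessions, are errors.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector: accession -> amino-acid sequence.
#' @export
read_fasta <- function(path) {
  # readAAStringSet silently drops codes it cannot parse (with a warning);
  # escalate so malformed residues are a format error, never a silent fix
  aa <- withCallingHandlers(
    Biostrings::readAAStringSet(path),
    warning = function(w)
      stop("non-amino-acid characters in FASTA ", path, ": ",
           conditionMessage(w), call. = FALSE))
  accs <- vapply(strsplit(names(aa), "[ \t]"), `[[`, "", 1L)
  uni <- grepl("^(sp|tr)\\|", accs)
  accs[uni] <- vapply(strsplit(accs[uni], "|", fixed = TRUE), `[[`, "", 2L)
  if (anyDuplicated(accs))
    stop("duplicated accession(s) in FASTA: ",
         paste(unique(accs[duplicated(accs)]), collapse = ", "))
  seqs <- toupper(as.character(aa))
  seqs <- gsub("*", "", seqs, fixed = TRUE)
  bad <- grepl(sprintf("[^%s]", paste(AA20, collapse = "")), seqs)
  if (any(bad))
    stop("non-amino-acid characters in sequence(s): ",
         paste(accs[bad], collapse = ", "))
  names(seqs) <- accs
  seqs
}

#' Write a proteome FASTA
#'
#' @param proteome Named character vector (accession -> sequence).
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(proteome, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(proteome)) {
    writeLines(paste0(">", names(proteome)[i]), con)
    s <- proteome[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

ANNOTATION_TYPES <- c("BP", "MF", "CC", "KEGG", "DOMAIN", "LOCATION")

#' Build an annotation table
#'
#' One term per row: `accession`, `term_type` (one of `BP`, `MF`, `CC` for GO
#' namespaces, `KEGG`, `DOMAIN`, or `LOCATION` for the single primary
#' subcellular compartment), `term`. An accession may carry at most one
#' `LOCATION` row.
#'
#' @param terms Data frame with columns `accession`, `term_type`, `term`.
#' @return Object of class `annotation_table`.
#' @export
annotation_table <- function(terms) {
  require_columns(terms, c("accession", "term_type", "term"), "annotation table")
  terms <- data.frame(accession = as.character(terms$accession),
                      term_type = as.character(terms$term_type),
                      term = as.character(terms$term), stringsAsFactors = FALSE)
  unknown <- setdiff(unique(terms$term_type), ANNOTATION_TYPES)
  if (length(unknown))
    stop("unknown term type(s): ", paste(unknown, collapse = ", "),
         " (allowed: ", paste(ANNOTATION_TYPES, collapse = ", "), ")")
  loc <- terms[terms$term_type == "LOCATION", ]
  if (anyDuplicated(loc$accession))
    stop("more than one LOCATION for accession(s): ",
         paste(unique(loc$accession[duplicated(loc$accession)]), collapse = ", "))
  locations <- stats::setNames(loc$term, loc$accession)
  structure(list(terms = terms[terms$term_type != "LOCATION", ],
                 locations = locations),
            class = "annotation_table")
}

#' @rdname annotation_table
#' @param path Path of a TSV with the three columns above.
#' @export
read_annotation_table <- function(path) {
  df <- read_tsv_raw(path)
  annotation_table(df)
}

#' @rdname annotation_table
#' @param annotations An `annotation_table`.
#' @export
write_annotation_table <- function(annotations, path) {
  loc <- data.frame(accession = names(annotations$locations),
                    term_type = rep("LOCATION", length(annotations$locations)),
                    term = unname(annotations$locations), stringsAsFactors = FALSE)
  utils::write.table(rbind(annotations$terms, loc), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Look up annotation terms for one accession
#'
#' @param annotations An [annotation_table()].
#' @param accession Protein accession.
#' @param type Term type (`"BP"`, `"MF"`, `"CC"`, `"KEGG"`, `"DOMAIN"`).
#' @return Character vector of terms (empty if the accession is unannotated).
#' @export
annot_terms <- function(annotations, accession, type) {
  stopifnot(inherits(annotations, "annotation_table"))
  t <- annotations$terms
  t$term[t$accession == accession & t$term_type == type]
}

#' @rdname annot_terms
#' @return `annot_location` returns the primary compartment label or
#'   `NA_character_`.
#' @export
annot_location <- function(annotations, accession) {
  stopifnot(inherits(annotations, "annotation_table"))
  loc <- annotations$locations[accession]
  unname(ifelse(is.na(loc), NA_character_, loc))
}

#' @export
print.annotation_table <- function(x, ...) {
  cat("annotation table:", length(unique(x$terms$accession)), "annotated accessions,",
      nrow(x$terms), "term rows,", length(x$locations), "locations\n")
  print(table(x$terms$term_type))
  invisible(x)
}
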