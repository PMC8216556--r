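#' Define a TMT experiment design
#'
#' Maps reporter-ion channels to biological conditions and replicate indices and
#' fixes the ordered list of pairwise comparisons (numerator/denominator
#' condition) that the quantification and differential stages operate on.
#'
#' @param channels Character vector of channel identifiers (e.g. TMT-10plex
#'   reporter labels such as `"127N"`), in plex order.
#' @param conditions Character vector, parallel to `channels`, giving the
#'   condition label of each channel (e.g. `"T30"`).
#' @param replicates Integer vector, parallel to `channels`, giving the
#'   replicate index of each channel within its condition.
#' @param comparisons List of length-2 character vectors
#'   `c(numerator, denominator)`. Defaults to all ordered pairs of later vs
#'   earlier conditions in first-appearance order.
#'
#' @return An object of class `experiment_design`: a list with `channels`,
#'   `conditions`, `replicates` and a data frame `comparisons` with columns
#'   `numerator`, `denominator`, `label` (label is `"num/den"`).
#' @examples
#' d <- default_design()
#' d$comparisons$label
#' @export
experiment_design <- function(channels, conditions, replicates, comparisons = NULL) {
  channels <- as.character(channels)
  conditions <- as.character(conditions)
  replicates <- as.integer(replicates)
  if (anyDuplicated(channels)) stop("channel identifiers must be unique")
  if (length(conditions) != length(channels) || length(replicates) != length(channels))
    stop("'conditions' and 'replicates' must be parallel to 'channels'")
  if (anyDuplicated(paste(conditions, replicates)))
    stop("each (condition, replicate) pair may map to only one channel")
  tab <- table(conditions)
  if (any(tab < 2))
    stop("each condition needs at least 2 replicate channels; offending: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  cond_levels <- unique(conditions)
  if (is.null(comparisons)) {
    comparisons <- list()
    for (i in seq_along(cond_levels)) for (j in seq_along(cond_levels))
      if (i > j) comparisons[[length(comparisons) + 1L]] <- c(cond_levels[i], cond_levels[j])
  }
  cmp <- do.call(rbind, lapply(comparisons, function(p) {
    if (length(p) != 2L) stop("each comparison must be c(numerator, denominator)")
    if (!all(p %in% cond_levels))
      stop("comparison condition not present in design: ",
           paste(setdiff(p, cond_levels), collapse = ", "))
    data.frame(numerator = p[1L], denominator = p[2L],
               label = paste0(p[1L], "/", p[2L]), stringsAsFactors = FALSE)
  }))
  structure(list(channels = channels, conditions = conditions,
                 replicates = replicates, comparisons = cmp),
            class = "experiment_design")
}

#' Default 3 conditions x 3 replicates TMT-10plex design
#'
#' Nine channels of a TMT-10plex carrying triplicates of cultures grown at
#' 30, 50 and 55 degrees C (conditions T30/T50/T55), with the three canonical
#' comparisons T50/T30, T55/T30 and T55/T50.
#'
#' @return An [experiment_design()] object.
#' @export
default_design <- function() {
  experiment_design(
    channels   = c("126", "127N", "127C", "128N", "128C", "129N", "129C", "130N", "130C"),
    conditions = rep(c("T30", "T50", "T55"), each = 3L),
    replicates = rep(1:3, times = 3L),
    comparisons = list(c("T50", "T30"), c("T55", "T30"), c("T55", "T50")))
}

# channels of one condition, ordered by replicate index
design_channels <- function(design, condition) {
  idx <- which(design$conditions == condition)
  idx[order(design$replicates[idx])]
}

# replicate-paired channel indices for a comparison: matrix with columns
# num, den and one row per replicate index shared by both conditions
comparison_pairs <- function(design, numerator, denominator) {
  ni <- which(design$conditions == numerator)
  di <- which(design$conditions == denominator)
  reps <- sort(intersect(design$replicates[ni], design$replicates[di]))
  cbind(num = ni[match(reps, design$replicates[ni])],
        den = di[match(reps, design$replicates[di])],
        replicate = reps)
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("TMT experiment design:", length(x$channels), "channels,",
      length(unique(x$conditions)), "conditions\n")
  for (cond in unique(x$conditions))
    cat("  ", cond, ": ", paste(x$channels[x$conditions == cond], collapse = ", "), "\n", sep = "")
  cat("comparisons:", paste(x$comparisons$label, collapse = ", "), "\n")
  invisible(x)
}

#' Write / read an experiment design as TSV
#'
#' The channel table is written with columns `channel`, `condition`,
#' `replicate`; comparisons are stored in leading `#comparison` header lines so
#' that one file round-trips the whole design.
#'
#' @param design An [experiment_design()] object.
#' @param path File path.
#' @return `write_design` returns `path` invisibly; `read_design` returns an
#'   [experiment_design()].
#' @export
write_design <- function(design, path) {
  hdr <- sprintf("#comparison\t%s\t%s", design$comparisons$numerator, design$comparisons$denominator)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(
    data.frame(channel = design$channels, condition = design$conditions,
               replicate = design$replicates),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  lines <- readLines(path)
  cmp_lines <- grep("^#comparison\t", lines, value = TRUE)
  cmps <- lapply(strsplit(cmp_lines, "\t", fixed = TRUE), function(x) x[2:3])
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.delim(text = paste(body, collapse = "\n"), stringsAsFactors = FALSE)
  need <- c("channel", "condition", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("design file is missing column(s): ", paste(miss, collapse = ", "))
  experiment_design(df$channel, df$condition, df$replicate,
                    comparisons = if (length(cmps)) cmps else NULL)
}
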