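# End-to-end pipeline: simulate (or load) -> quantify -> differential calling
# -> sequon/motif profiling -> amino-acid composition -> enrichment and
# localization, with a JSON run manifest. Identical configuration and inputs
# yield byte-identical outputs.

stage_wrap <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
}

write_stage_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  path
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order and writes all outputs plus a
#' `manifest.json` recording the configuration, package version, per-output
#' row counts and MD5 checksums. Inputs come either from a seeded synthetic
#' experiment (`config`) or from files on disk (`inputs`, a named list with
#' paths `peptides`, `sites`, `fasta`, `annotations`, `design`). Any stage
#' failure aborts with the stage name and the propagated cause; the
#' annotation table is read lazily at the enrichment stage.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [simulation_config()] used when no `inputs` are given.
#' @param inputs Optional named list of input file paths (see above).
#' @param fold_change,alpha Differential thresholds (defaults 1.5 and 0.05).
#' @param adjust `"none"` (default) or `"BH"` p-value adjustment.
#' @return The manifest, invisibly, as a list.
#' @export
run_all <- function(out_dir, config = simulation_config(), inputs = NULL,
                    fold_change = 1.5, alpha = 0.05, adjust = "none") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "thermoglyco",
                   version = as.character(utils::packageVersion("thermoglyco")),
                   parameters = list(fold_change = fold_change, alpha = alpha,
                                     adjust = adjust),
                   stages = list())
  outputs <- character(0)
  note <- function(stage, ...) {
    paths <- c(...)
    outputs <<- c(outputs, paths)
    manifest$stages[[stage]] <<- lapply(stats::setNames(paths, basename(paths)),
                                        function(p) {
      n <- if (grepl("\\.tsv$", p)) length(readLines(p)) - 1L else NA_integer_
      list(rows = n, md5 = unname(tools::md5sum(p)))
    })
  }

  annotations_path <- NULL
  if (is.null(inputs)) {
    sim <- stage_wrap("simulate", simulate_experiment(config))
    manifest$config <- unclass(config)
    in_dir <- file.path(out_dir, "inputs")
    paths <- stage_wrap("simulate", write_simulation(sim, in_dir))
    note("simulate", paths)
    design <- sim$design
    peptides <- sim$peptides
    sites <- sim$sites
    proteome <- sim$proteome
    annotations_path <- paths[["annotations"]]
    truth <- sim$truth
  } else {
    need <- c("peptides", "sites", "fasta", "annotations", "design")
    miss <- setdiff(need, names(inputs))
    if (length(miss)) stop("missing input path(s): ", paste(miss, collapse = ", "))
    design <- stage_wrap("load", read_design(inputs$design))
    proteome <- stage_wrap("load", read_fasta(inputs$fasta))
    peptides <- stage_wrap("load", read_peptide_table(inputs$peptides, design))
    sites <- stage_wrap("load", read_glycosite_table(inputs$sites, design, proteome))
    annotations_path <- inputs$annotations
    manifest$inputs <- lapply(inputs, function(p) unname(tools::md5sum(p)))
    truth <- NULL
  }

  # quantification
  stage_wrap("quantify", {
    npx <- normalize_by_median_ratio(peptides, design)
    pq <- rollup_protein(npx)
    sq <- quantify_sites(sites, npx, pq)
  })
  note("quantify",
       write_stage_table(pq$table, file.path(out_dir, "protein_quant.tsv")),
       write_stage_table(sq$table, file.path(out_dir, "site_quant.tsv")))

  # differential calling and Venn partitions
  stage_wrap("differential", {
    prot_calls <- call_differential(pq, fold_change, alpha, adjust)
    site_calls <- call_differential(sq, fold_change, alpha, adjust)
  })
  psets <- differential_sets(prot_calls)
  ssets <- differential_sets(site_calls)
  labs <- design$comparisons$label
  venn_files <- character(0)
  if (length(labs) == 3L) {
    for (lvl in c("proteins", "glycoproteins")) {
      sets <- if (lvl == "proteins") psets else ssets
      for (dir in c("up", "down")) {
        v <- venn_partition(sets[[labs[1L]]][[dir]], sets[[labs[2L]]][[dir]],
                            sets[[labs[3L]]][[dir]], names = labs)
        venn_files <- c(venn_files, write_stage_table(
          v, file.path(out_dir, sprintf("venn_%s_%s.tsv", lvl, dir))))
      }
    }
  }
  note("differential",
       write_stage_table(prot_calls, file.path(out_dir, "differential_proteins.tsv")),
       write_stage_table(site_calls, file.path(out_dir, "differential_sites.tsv")),
       venn_files)

  # sequon and motif profiling
  seq_files <- stage_wrap("sequon", {
    cls <- classify_sites(sites[c("accession", "position")], proteome)
    wins <- site_windows(sites, proteome)
    occ <- occupancy_matrix(wins)
    occ_df <- data.frame(position = rownames(occ), occ, check.names = FALSE)
    dist <- site_count_distribution(cls[cls$is_sequon, ])
    c(write_stage_table(sequon_table(proteome), file.path(out_dir, "sequons.tsv")),
      write_stage_table(cls, file.path(out_dir, "site_classification.tsv")),
      write_stage_table(occ_df, file.path(out_dir, "occupancy_matrix.tsv")),
      write_stage_table(dist, file.path(out_dir, "site_count_distribution.tsv")))
  })
  note("sequon", seq_files)

  # amino-acid composition of up vs down sets per comparison
  comp_files <- stage_wrap("composition", {
    files <- character(0)
    for (lab in labs) {
      up <- psets[[lab]]$up; down <- psets[[lab]]$down
      if (length(up) >= 2L && length(down) >= 2L) {
        cmp <- compare_composition(aa_composition(proteome[up]),
                                   aa_composition(proteome[down]))
        names(cmp)[names(cmp) == "mean_a"] <- "mean_up"
        names(cmp)[names(cmp) == "mean_b"] <- "mean_down"
        files <- c(files, write_stage_table(
          cmp, file.path(out_dir, sprintf("composition_%s.tsv", gsub("/", "_vs_", lab)))))
      }
    }
    files
  })
  note("composition", comp_files)

  # enrichment, heatmaps, localization
  enr_files <- stage_wrap("enrich", {
    if (!file.exists(annotations_path))
      stop("missing input: annotation table ", annotations_path)
    annotations <- read_annotation_table(annotations_path)
    background <- pq$table$accession
    all_rows <- list()
    for (ns in c("BP", "MF", "CC", "KEGG", "DOMAIN")) {
      for (lab in labs) for (dir in c("up", "down")) {
        fg <- psets[[lab]][[dir]]
        if (!length(fg)) next
        r <- enrich(fg, background, annotations, ns)
        if (nrow(r)) {
          r$cell <- paste0(lab, ":", dir)
          all_rows[[length(all_rows) + 1L]] <- r
        }
      }
    }
    enr <- do.call(rbind, all_rows)
    files <- write_stage_table(enr, file.path(out_dir, "enrichment.tsv"))
    hm <- cluster_heatmap(enr)
    if (nrow(hm$matrix)) {
      hm_df <- data.frame(term = rownames(hm$matrix)[hm$row_order],
                          hm$matrix[hm$row_order, hm$col_order, drop = FALSE],
                          check.names = FALSE)
      files <- c(files, write_stage_table(hm_df, file.path(out_dir, "heatmap_matrix.tsv")))
    }
    diff_prot <- unique(unlist(lapply(psets, unlist)))
    diff_glyco <- unique(unlist(lapply(ssets, unlist)))
    if (length(diff_prot))
      files <- c(files, write_stage_table(
        localization_summary(diff_prot, annotations),
        file.path(out_dir, "localization_proteins.tsv")))
    if (length(diff_glyco))
      files <- c(files, write_stage_table(
        localization_summary(diff_glyco, annotations),
        file.path(out_dir, "localization_glycoproteins.tsv")))
    files
  })
  note("enrich", enr_files)

  if (!is.null(truth)) {
    rep_files <- stage_wrap("truth", c(
      write_stage_table(truth_report(prot_calls, truth$proteins),
                        file.path(out_dir, "truth_report_proteins.tsv")),
      write_stage_table(truth_report(site_calls, truth$sites),
                        file.path(out_dir, "truth_report_sites.tsv"))))
    note("truth", rep_files)
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
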