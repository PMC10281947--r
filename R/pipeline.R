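PKG_VERSION <- function() as.character(utils::packageVersion("microdialysR"))

# Provenance-stamped TSV: every output table carries its run context in
# comment headers so any number in a report is traceable.
write_table_with_header <- function(df, path, meta) {
  header <- paste0("# ", names(meta), ": ", unlist(meta))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline table written by [run_pipeline()]
#'
#' @param path TSV path with `#` provenance headers.
#' @return data.frame; headers attached as attribute `provenance`.
#' @export
read_pipeline_table <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  df <- utils::read.table(text = lines[!startsWith(lines, "# ")],
                          sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  attr(df, "provenance") <- sub("^# ", "", hdr)
  df
}

pipeline_config_keys <- c("seed", "simulate", "input", "presence_min_fraction",
                          "csf_min_fraction", "set_size", "weighting_exponent",
                          "n_permutations", "alpha", "fc_threshold", "contrasts")

#' Run the full microdialysis metabolomics pipeline
#'
#' Orchestrates every stage from a single declarative configuration:
#' normalization, presence filtering, perfusate exclusions, per-case ranked
#' lists, top/bottom signature sets, cross-case enrichment, paired
#' differential tables for the E/B, E/NE and NE/B contrasts, Spearman
#' correlation and Ward clustering, and (when CSF samples are available)
#' bloodiness lists and plasma-contamination enrichment. Identical
#' configuration and inputs give byte-identical outputs.
#'
#' @param config a YAML file path or an equivalent named list. Keys
#'   (unknown keys abort): `seed` (required, no silent default);
#'   `simulate: true` to draw a synthetic cohort, or `input:` with `matrix`,
#'   `annotation`, optional `csf`, `heme_column`, `orientation`;
#'   `presence_min_fraction` (default 0.9), `csf_min_fraction` (0.85),
#'   `set_size` (35), `weighting_exponent` (1), `n_permutations` (1000),
#'   `alpha` (0.05), `fc_threshold` (2), `contrasts` (default
#'   `E/B`, `E/NE`, `NE/B`).
#' @param out_dir output directory, created if needed; `NULL` skips writing
#'   and returns results in memory only.
#' @return (invisibly) a list with the normalized/filtered matrix, ranked
#'   lists, signature sets, enrichment, differential tables, clustering, and
#'   CSF results, plus `provenance`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  unknown <- setdiff(names(cfg), pipeline_config_keys)
  if (length(unknown))
    validation_error(paste0("unknown configuration key(s): ",
                            paste(unknown, collapse = ", ")))
  if (is.null(cfg$seed))
    validation_error("configuration must set an explicit seed")
  seed <- as.integer(cfg$seed)
  pmf <- cfg$presence_min_fraction %||% 0.9
  cmf <- cfg$csf_min_fraction %||% 0.85
  k <- cfg$set_size %||% 35L
  wexp <- cfg$weighting_exponent %||% 1
  nperm <- cfg$n_permutations %||% 1000L
  alpha <- cfg$alpha %||% 0.05
  fc_threshold <- cfg$fc_threshold %||% 2
  contrasts <- cfg$contrasts %||% c("E/B", "E/NE", "NE/B")

  provenance <- list(package = paste0("microdialysR ", PKG_VERSION()),
                     seed = seed, presence_min_fraction = pmf,
                     set_size = k, weighting_exponent = wexp,
                     n_permutations = nperm, alpha = alpha,
                     fc_threshold = fc_threshold)

  csf <- NULL; heme <- NULL
  if (isTRUE(cfg$simulate)) {
    cohort <- generate_cohort(default_generator_config(seed))
    mat <- cohort$matrix; ann <- cohort$annotation
    csf <- cohort$csf; heme <- cohort$heme
    provenance$input <- "simulated"
  } else {
    if (is.null(cfg$input))
      validation_error("configuration needs either simulate: true or an input block")
    mat <- read_peak_matrix(cfg$input$matrix,
                            orientation = cfg$input$orientation %||%
                              "metabolites_in_rows")
    ann <- read_annotation(cfg$input$annotation)
    if (!is.null(cfg$input$csf)) {
      csf <- read_peak_matrix(cfg$input$csf)
      csf_ann <- ann[ann$location == "CSF", ]
      heme <- stats::setNames(csf_ann$heme, csf_ann$sample_id)
    }
    provenance$input_md5 <- paste(
      tools::md5sum(c(cfg$input$matrix, cfg$input$annotation)),
      collapse = ",")
  }
  check_annotation_covers(mat, ann)
  batch <- stats::setNames(ann$batch[match(sample_ids(mat), ann$sample_id)],
                           sample_ids(mat))
  mat$batch <- batch

  # preprocess
  norm <- median_normalize(mat)
  filt <- presence_filter(norm, min_fraction = pmf)
  provenance$presence_threshold <- filt$threshold
  provenance$n_metabolites_kept <- filt$n_kept
  analysed <- apply_perfusate_exclusions(filt$matrix, ann)

  # per-case ranked lists for each contrast with both catheters
  lists <- list()
  for (ct in contrasts) {
    locs <- strsplit(ct, "/", fixed = TRUE)[[1L]]
    pr <- contrast_pairs(ann[ann$sample_id %in% sample_ids(analysed), ],
                         locs[1L], locs[2L])
    ct_lists <- list()
    for (i in seq_len(nrow(pr))) {
      nm <- paste0(pr$case_id[i], "_", locs[1L], "_vs_", locs[2L])
      ct_lists[[pr$case_id[i]]] <-
        make_ranked_list(analysed, pr$sample_a[i], pr$sample_b[i],
                         annotation = ann, name = nm)
    }
    lists[[gsub("/", "_vs_", ct)]] <- ct_lists
  }

  # cross-case enrichment on the primary tumour-vs-brain contrast
  primary <- lists[[gsub("/", "_vs_", contrasts[1L])]]
  enrich <- NULL; sets <- NULL
  if (length(primary) >= 2L) {
    sets <- lapply(primary, build_sets_from_list, k = k)
    enrich <- cross_case_enrichment_matrix(primary, sets, p = wexp,
                                           n_permutations = nperm,
                                           seed = derive_seed(seed, 11L),
                                           alpha = alpha)
  }

  # differential tables
  differential <- list()
  for (ct in contrasts) {
    locs <- strsplit(ct, "/", fixed = TRUE)[[1L]]
    res <- tryCatch(
      paired_contrast_table(analysed, ann, locs[1L], locs[2L],
                            alpha = alpha, fc_threshold = fc_threshold),
      microdialysR_validation_error = function(e) NULL)
    if (!is.null(res)) differential[[ct]] <- res
  }

  # clustering on catheter samples
  clust <- list(spearman = spearman_matrix(analysed),
                tree = hierarchical_cluster(analysed))

  # CSF / plasma-contamination block
  csf_block <- NULL
  if (!is.null(csf)) {
    csf_norm <- median_normalize(csf)
    universe <- metabolite_ids(analysed)
    paired_ids <- intersect(c("csf_paired_bloody", "csf_paired_clean"),
                            sample_ids(csf_norm))
    bloodiness_paired <- if (length(paired_ids) == 2L)
      paired_bloodiness_list(csf_norm, "csf_paired_bloody",
                             "csf_paired_clean", universe) else NULL
    pooled <- tryCatch(
      pooled_bloodiness_list(csf_norm, heme, exclude = paired_ids,
                             microdialysate_universe = universe,
                             csf_min_fraction = cmf),
      microdialysR_validation_error = function(e) NULL)
    bloodiness <- bloodiness_paired %||% pooled
    plasma <- NULL
    e_ne <- lists[["E_vs_NE"]]
    if (!is.null(bloodiness) && length(e_ne) >= 1L)
      plasma <- plasma_enrichment(e_ne, bloodiness, k = k, p = wexp,
                                  n_permutations = nperm,
                                  seed = derive_seed(seed, 13L),
                                  alpha = alpha)
    csf_block <- list(paired = bloodiness_paired, pooled = pooled,
                      plasma = plasma)
  }

  out <- list(normalized = norm, analysed = analysed, filter = filt,
              annotation = ann, lists = lists, sets = sets,
              enrichment = enrich, differential = differential,
              clustering = clust, csf = csf_block,
              provenance = provenance)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  invisible(out)
}

# Serialize every pipeline surface under out_dir.
write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- out$provenance
  write_peak_matrix(out$normalized, file.path(out_dir, "normalized_matrix.csv"))
  writeLines(metabolite_ids(out$analysed),
             file.path(out_dir, "metabolite_universe.txt"))
  rnk_dir <- file.path(out_dir, "ranked_lists")
  dir.create(rnk_dir, showWarnings = FALSE)
  for (ct in names(out$lists))
    for (l in out$lists[[ct]])
      write_rnk(l, file.path(rnk_dir, paste0(attr(l, "name"), ".rnk")))
  if (!is.null(out$sets))
    write_set_file(unlist(out$sets, recursive = FALSE),
                   file.path(out_dir, "signature_sets.gmt"))
  if (!is.null(out$enrichment))
    write_table_with_header(out$enrichment$table,
                            file.path(out_dir, "enrichment_cross_case.tsv"),
                            meta)
  for (ct in names(out$differential)) {
    safe <- gsub("/", "_vs_", ct)
    write_table_with_header(out$differential[[ct]]$table,
                            file.path(out_dir, paste0("differential_", safe, ".tsv")),
                            meta)
    v <- volcano_table(out$differential[[ct]])
    write_table_with_header(v$table,
                            file.path(out_dir, paste0("volcano_", safe, ".tsv")),
                            c(meta, list(up = v$counts[["up"]],
                                         down = v$counts[["down"]])))
  }
  rho <- out$clustering$spearman$rho
  write_table_with_header(data.frame(sample = rownames(rho), rho,
                                     check.names = FALSE),
                          file.path(out_dir, "spearman.tsv"), meta)
  writeLines(out$clustering$tree$newick,
             file.path(out_dir, "dendrogram.nwk"))
  if (!is.null(out$csf)) {
    if (!is.null(out$csf$paired))
      write_rnk(out$csf$paired, file.path(out_dir, "bloodiness_paired.rnk"))
    if (!is.null(out$csf$pooled))
      write_rnk(out$csf$pooled, file.path(out_dir, "bloodiness_pooled.rnk"))
    if (!is.null(out$csf$plasma)) {
      write_table_with_header(out$csf$plasma$table,
                              file.path(out_dir, "plasma_enrichment.tsv"), meta)
      write_table_with_header(out$csf$plasma$summary,
                              file.path(out_dir, "plasma_summary.tsv"), meta)
    }
  }
  writeLines(paste0(names(meta), ": ", unlist(meta)),
             file.path(out_dir, "provenance.log"))
  invisible(out_dir)
}

#' Render report-style summary tables
#'
#' Produces the three publication-style surfaces from a [run_pipeline()]
#' result: (i) a wide differential table with one fold-change and p-value
#' column pair per contrast, p-values printed to 4 decimals and marked
#' significant at the alpha cut-off; (ii) the cross-case average-rank table
#' of the primary contrast; (iii) the cross-case NES matrix with FDR stars,
#' zero permutation estimates displayed below the `1e-5` floor as
#' `"<1e-05"`. Every rendered number is a formatting of a machine-readable
#' table cell; nothing is recomputed at render time.
#'
#' @param out a [run_pipeline()] result.
#' @return list with `differential_wide`, `average_ranks`, `nes_display`.
#' @export
report_tables <- function(out) {
  wide <- NULL
  for (ct in names(out$differential)) {
    tab <- out$differential[[ct]]$table
    alpha <- out$differential[[ct]]$alpha
    block <- data.frame(metabolite = tab$metabolite,
                        fc = sprintf("%.2f", tab$mean_fc),
                        p = format_p4(tab$p_two_sided),
                        significant = tab$p_two_sided <= alpha,
                        stringsAsFactors = FALSE)
    names(block)[-1L] <- paste0(c("mean_fc_", "p_", "significant_"),
                                gsub("/", "_", ct))
    wide <- if (is.null(wide)) block else
      merge(wide, block, by = "metabolite", all = TRUE, sort = FALSE)
  }
  avg <- if (length(out$lists) && length(out$lists[[1L]]) >= 1L)
    average_rank_table(unname(out$lists[[1L]])) else NULL
  nes_disp <- NULL
  if (!is.null(out$enrichment)) {
    tab <- out$enrichment$table
    nes_disp <- data.frame(
      list = tab$list, set = tab$set,
      nes = sprintf("%.2f", tab$nes),
      fdr_q = vapply(seq_len(nrow(tab)), function(i)
        format_floored(tab$fdr_q[i], tab$fdr_q_raw[i]), character(1L)),
      star = ifelse(tab$fdr_q_raw <= 0.05, "*", ""),
      stringsAsFactors = FALSE)
  }
  list(differential_wide = wide, average_ranks = avg, nes_display = nes_disp)
}

# Report rendering of p-values: 4 decimals, matching the precision of the
# exact-test floors (0.0039, 0.0156).
format_p4 <- function(p) sprintf("%.4f", p)
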