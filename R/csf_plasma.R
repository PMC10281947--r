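#' Bloodiness ranked list from one paired CSF sample
#'
#' A patient's two CSF samples — one visibly blood-contaminated, one clean,
#' drawn minutes apart — define a plasma-contamination signature: the fold
#' change bloody/clean ranks metabolites from most to least blood-derived.
#' The list universe is the metabolites observed in *both* CSF samples
#' intersected with the microdialysate presence-filtered universe, so the
#' signature can be queried against catheter ranked lists.
#'
#' @param csf a `peak_matrix` containing the CSF samples (normalized or raw;
#'   the ratio is scale-free per metabolite after median normalization).
#' @param bloody,clean sample ids of the contaminated and clean CSF samples.
#' @param microdialysate_universe character vector of metabolite ids passing
#'   the microdialysate presence filter.
#' @return a [ranked_list()] named `"bloodiness_paired"`; degenerate (all
#'   fold changes 1) lists carry attribute `degenerate = TRUE`.
#' @export
paired_bloodiness_list <- function(csf, bloody, clean,
                                   microdialysate_universe) {
  stopifnot(inherits(csf, "peak_matrix"))
  for (s in c(bloody, clean))
    if (!s %in% sample_ids(csf))
      validation_error(paste0("CSF sample not in matrix: ", s))
  b <- csf$values[, bloody]
  cl <- csf$values[, clean]
  in_both <- !is.na(b) & !is.na(cl)
  universe <- intersect(metabolite_ids(csf)[in_both],
                        microdialysate_universe)
  if (!length(universe))
    validation_error("no metabolite present in both CSF samples and the microdialysate universe")
  fc <- (b / cl)[universe]
  out <- ranked_list(fc, name = "bloodiness_paired",
                     omitted = setdiff(metabolite_ids(csf), universe))
  if (all(fc == 1)) attr(out, "degenerate") <- TRUE
  out
}

#' Bloodiness ranked list from pooled CSF quartiles
#'
#' CSF samples are ranked by heme content (the blood-contamination
#' surrogate; units are arbitrary, only the order matters). After removing
#' excluded subjects, the top and bottom `ceiling(n/4)` samples form the
#' bloody and clean pools — 7 each from 26 samples, as in a typical
#' intracranial CSF collection. The list ranks metabolites by the ratio of
#' pool means, over metabolites present in more than `csf_min_fraction` of
#' CSF samples and in the microdialysate universe. Heme ties are broken by
#' sample id (deterministic); a tie straddling a pool boundary emits a
#' warning.
#'
#' @param csf a `peak_matrix` of CSF samples.
#' @param heme named non-negative numeric vector of heme content per CSF
#'   sample.
#' @param exclude sample ids removed before pooling (e.g. the subject that
#'   contributed the paired samples).
#' @param microdialysate_universe metabolite ids passing the microdialysate
#'   presence filter.
#' @param csf_min_fraction CSF presence fraction required; default 0.85.
#' @return a [ranked_list()] named `"bloodiness_pooled"`, with attributes
#'   `bloody_pool` and `clean_pool` (the sample ids used).
#' @export
pooled_bloodiness_list <- function(csf, heme, exclude = character(),
                                   microdialysate_universe,
                                   csf_min_fraction = 0.85) {
  stopifnot(inherits(csf, "peak_matrix"))
  keep <- setdiff(sample_ids(csf), exclude)
  missing_heme <- setdiff(keep, names(heme))
  if (length(missing_heme))
    validation_error(paste0("no heme value for CSF sample(s): ",
                            paste(missing_heme, collapse = ", ")))
  heme <- heme[keep]
  n <- length(keep)
  if (n < 8L)
    validation_error("need at least 8 CSF samples with heme values to pool quartiles")
  k <- as.integer(ceiling(n / 4))
  ord <- keep[order(-heme, keep, method = "radix")]
  bloody_pool <- ord[seq_len(k)]
  clean_pool <- ord[seq(n - k + 1L, n)]
  boundary_tie <- (heme[ord[k]] == heme[ord[k + 1L]]) ||
    (heme[ord[n - k]] == heme[ord[n - k + 1L]])
  if (boundary_tie)
    warning("heme tie straddles a quartile boundary; resolved by sample id")
  vals <- csf$values[, keep, drop = FALSE]
  present <- rowMeans(!is.na(vals)) > csf_min_fraction
  universe <- intersect(metabolite_ids(csf)[present],
                        microdialysate_universe)
  if (!length(universe))
    validation_error("no metabolite passes both CSF and microdialysate presence filters")
  mean_b <- rowMeans(csf$values[universe, bloody_pool, drop = FALSE],
                     na.rm = TRUE)
  mean_c <- rowMeans(csf$values[universe, clean_pool, drop = FALSE],
                     na.rm = TRUE)
  ok <- is.finite(mean_b) & is.finite(mean_c) & mean_c > 0
  out <- ranked_list(mean_b[ok] / mean_c[ok], name = "bloodiness_pooled",
                     omitted = setdiff(metabolite_ids(csf), universe[ok]))
  attr(out, "bloody_pool") <- bloody_pool
  attr(out, "clean_pool") <- clean_pool
  out
}

#' Plasma-contamination enrichment of catheter contrasts
#'
#' Queries the bloodiness signature's top-k (plasma/bloody) and bottom-k
#' (clean-CSF) sets against each case's catheter ranked list (typically
#' enhancing vs non-enhancing tumour). Positive NES for the bloody set means
#' the numerator catheter resembles blood-contaminated CSF — the expected
#' pattern where the blood-brain barrier is radiographically disrupted;
#' negative NES for the clean set means the denominator catheter resembles
#' clean CSF. FDR is computed across all cells; the summary counts cases
#' significant for either or both directions.
#'
#' @param case_lists named list of per-case [ranked_list()] objects.
#' @param bloodiness a bloodiness [ranked_list()] (paired or pooled).
#' @param k signature size; default 35.
#' @param p weighting exponent; default 1.
#' @param n_permutations permutations per cell; default 1000.
#' @param seed integer seed.
#' @param alpha FDR significance threshold; default 0.05.
#' @return list with `results` (FDR-adjusted `enrichment_result`s), `table`
#'   (flat data.frame with `direction` = `bloody_top`/`clean_bottom` and
#'   `significant`), `summary` (one row per case with logical columns
#'   `bloody_in_numerator`, `clean_in_denominator`, `either`, `both`), and
#'   the counts `n_significant_either` / `n_significant_both`.
#' @export
plasma_enrichment <- function(case_lists, bloodiness, k = 35L, p = 1,
                              n_permutations = 1000L, seed, alpha = 0.05) {
  if (missing(seed) || is.null(seed)) validation_error("a seed is required")
  stopifnot(inherits(bloodiness, "ranked_list"), length(case_lists) >= 1L,
            !is.null(names(case_lists)))
  sets <- build_sets_from_list(bloodiness, k = k)
  results <- list()
  cell <- 0L
  for (cs in names(case_lists)) {
    for (side in c("top", "bottom")) {
      cell <- cell + 1L
      results[[length(results) + 1L]] <-
        permutation_null(case_lists[[cs]], sets[[side]], p = p,
                         n_permutations = n_permutations,
                         seed = derive_seed(seed, cell))
    }
  }
  if (length(results) > 1L) results <- fdr_across_sets(results)
  tab <- enrichment_table(results)
  tab$direction <- rep(c("bloody_top", "clean_bottom"),
                       times = length(case_lists))
  tab$significant <- tab$fdr_q_raw <= alpha
  cases <- names(case_lists)
  # rows alternate bloody_top / clean_bottom per case, in case order
  bloody_rows <- tab[seq(1L, nrow(tab), by = 2L), ]
  clean_rows <- tab[seq(2L, nrow(tab), by = 2L), ]
  bloody_sig <- bloody_rows$nes > 0 & bloody_rows$significant
  clean_sig <- clean_rows$nes < 0 & clean_rows$significant
  summary <- data.frame(case = cases,
                        bloody_in_numerator = bloody_sig,
                        clean_in_denominator = clean_sig,
                        either = bloody_sig | clean_sig,
                        both = bloody_sig & clean_sig,
                        stringsAsFactors = FALSE)
  list(results = results, table = tab, summary = summary,
       n_significant_either = sum(summary$either),
       n_significant_both = sum(summary$both),
       n_cases = length(cases))
}
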