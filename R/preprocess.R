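#' Median-normalize peak areas within batches
#'
#' Divides every value by the median of its metabolite within its analysis
#' batch, computed over non-missing values only, so each (metabolite, batch)
#' group has median exactly 1 afterwards. The missingness mask is unchanged.
#' Idempotent: normalizing a normalized matrix returns it unchanged.
#'
#' @param x a `peak_matrix` (raw or already normalized).
#' @return a `peak_matrix` with `layer = "normalized"`.
#' @export
median_normalize <- function(x) {
  stopifnot(inherits(x, "peak_matrix"))
  vals <- x$values
  offenders <- character()
  for (b in unique(x$batch)) {
    idx <- which(x$batch == b)
    sub <- vals[, idx, drop = FALSE]
    med <- apply(sub, 1L, median_nonmissing)
    all_missing <- which(is.na(med))
    if (length(all_missing))
      offenders <- c(offenders,
                     paste0(rownames(vals)[all_missing], " (batch ", b, ")"))
    vals[, idx] <- sub / med
  }
  if (length(offenders))
    validation_error(paste0(
      "all values missing for (metabolite, batch) group(s): ",
      paste(utils::head(offenders, 10L), collapse = ", ")))
  peak_matrix(vals, layer = "normalized", batch = x$batch)
}

#' Filter metabolites by presence across samples
#'
#' Keeps metabolites observed (non-missing) in at least
#' `ceiling(min_fraction * n_samples)` samples. With 44 catheters and the
#' default 0.90 the threshold is 40 samples. Surviving metabolites keep their
#' original order.
#'
#' @param x a `peak_matrix`.
#' @param min_fraction required presence fraction in (0, 1]; default 0.90.
#' @return a list with `matrix` (the filtered `peak_matrix`), `n_kept`,
#'   `threshold` (the sample count required), and `dropped` (ids removed).
#' @export
presence_filter <- function(x, min_fraction = 0.90) {
  stopifnot(inherits(x, "peak_matrix"))
  if (!(min_fraction > 0 && min_fraction <= 1))
    validation_error("min_fraction must be in (0, 1]")
  n <- ncol(x$values)
  threshold <- as.integer(ceiling(min_fraction * n - 1e-9))
  present <- rowSums(!is.na(x$values))
  keep <- present >= threshold
  out <- x
  out$values <- x$values[keep, , drop = FALSE]
  list(matrix = out,
       n_kept = sum(keep),
       threshold = threshold,
       dropped = rownames(x$values)[!keep])
}

#' Mask perfusate-contaminated (metabolite, case) values
#'
#' When the microdialysis perfusate itself contains an analyte (e.g. lactate
#' in a lactate-containing perfusion fluid), that metabolite's values are
#' uninterpretable for the affected cases. The flagged values are masked
#' (set missing) rather than the metabolite dropped, so the metabolite
#' universe of ranked lists is preserved and downstream paired statistics
#' simply lose those cases.
#'
#' @param x a `peak_matrix`.
#' @param annotation a `sample_annotation` covering the matrix, whose
#'   `perfusate_excluded` column lists the flagged metabolites per sample's
#'   case.
#' @return a `peak_matrix` with the flagged cells set to `NA`.
#' @export
apply_perfusate_exclusions <- function(x, annotation) {
  stopifnot(inherits(x, "peak_matrix"))
  annotation <- as_sample_annotation(as.data.frame(annotation))
  check_annotation_covers(x, annotation)
  pairs <- perfusate_exclusion_pairs(annotation)
  if (!nrow(pairs)) return(x)
  unknown_m <- setdiff(unique(pairs$metabolite_id), metabolite_ids(x))
  if (length(unknown_m))
    validation_error(paste0("perfusate exclusion references unknown metabolite(s): ",
                            paste(unknown_m, collapse = ", ")))
  unknown_c <- setdiff(unique(pairs$case_id), annotation$case_id)
  if (length(unknown_c))
    validation_error(paste0("perfusate exclusion references unknown case(s): ",
                            paste(unknown_c, collapse = ", ")))
  vals <- x$values
  case_of <- stats::setNames(annotation$case_id, annotation$sample_id)
  for (i in seq_len(nrow(pairs))) {
    cols <- which(case_of[colnames(vals)] == pairs$case_id[i])
    vals[pairs$metabolite_id[i], cols] <- NA_real_
  }
  out <- x
  out$values <- vals
  out
}
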