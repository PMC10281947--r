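#' Exact Wilcoxon signed-rank test
#'
#' The exact paired test used for catheter-location contrasts. Zero
#' differences are discarded (Wilcoxon's original treatment — with n = 9
#' all-positive pairs this yields the attainable minimum two-sided
#' p = 2/2^9 = 0.00390625, and 2/2^7 = 0.015625 at n = 7, matching the
#' per-contrast p-value floors). Tied magnitudes receive midranks. The
#' p-value comes from the exact permutation distribution of the signed-rank
#' sum over all 2^n sign assignments, computed by convolution over the
#' (doubled, hence integer) rank values; two-sided p = min(1, 2 x the
#' smaller tail). No normal approximation is used for n up to `exact_limit`.
#'
#' @param differences numeric vector of paired differences.
#' @param exact_limit maximum n for the exact distribution; default 20.
#'   Larger n falls back to the same convolution (still exact, merely
#'   slower), so the limit only guards pathological inputs.
#' @return list with `w_plus`, `w_minus`, `n` (after zero removal),
#'   `p_two_sided`, and `degenerate` (`TRUE` when all differences are zero,
#'   in which case p = 1).
#' @export
exact_wilcoxon_signed_rank <- function(differences, exact_limit = 20L) {
  d <- differences[!is.na(differences)]
  if (!length(d)) validation_error("no non-missing differences")
  d <- d[d != 0]
  if (!length(d))
    return(list(w_plus = 0, w_minus = 0, n = 0L, p_two_sided = 1,
                degenerate = TRUE))
  n <- length(d)
  r <- rank(abs(d))                       # midranks for ties
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  r2 <- round(2 * r)                      # doubled midranks are integers
  dist <- signed_rank_distribution(r2)
  w2 <- round(2 * w_plus)
  p_upper <- sum(dist$count[dist$sum >= w2 - 1e-9]) / 2^n
  p_lower <- sum(dist$count[dist$sum <= w2 + 1e-9]) / 2^n
  p <- min(1, 2 * min(p_upper, p_lower))
  list(w_plus = w_plus, w_minus = w_minus, n = n, p_two_sided = p,
       degenerate = FALSE)
}

# Exact distribution of the positive-rank sum over all 2^n sign assignments:
# counts over achievable sums of a subset of the integer rank values.
# Polynomial product of (1 + x^r_i), as counts indexed by sum 0..sum(r).
signed_rank_distribution <- function(r_int) {
  total <- sum(r_int)
  counts <- numeric(total + 1L)
  counts[1L] <- 1
  for (r in r_int) {
    shifted <- c(rep(0, r), counts[seq_len(total + 1L - r)])
    counts <- counts + shifted
  }
  list(sum = 0:total, count = counts)
}

#' Paired differential-abundance table for a location contrast
#'
#' For each metabolite, pairs the two catheter locations within every case
#' (e.g. enhancing tumour vs adjacent brain), computes the per-case fold
#' change of normalized peak areas, tests the paired differences with the
#' exact signed-rank test, and classifies each metabolite against the
#' fold-change and p-value cut-offs (default FC >= 2 at p <= 0.05). The
#' reported `mean_fc` is the arithmetic mean of per-case fold changes (a
#' mean of ratios, not a ratio of means; the latter is also emitted as
#' `fc_of_means`). Pairs with a masked member (e.g. perfusate-excluded
#' lactate cases) are dropped with the remaining `n_pairs` reported.
#'
#' @param x a normalized `peak_matrix` (presence-filtered, exclusions
#'   applied).
#' @param annotation a `sample_annotation` covering the matrix.
#' @param location_a,location_b the contrast, numerator first: `"E"`,
#'   `"NE"`, or `"B"`.
#' @param alpha significance level; default 0.05.
#' @param fc_threshold fold-change cut-off; default 2. A metabolite is `up`
#'   when `p <= alpha` and `mean_fc >= fc_threshold`, `down` when
#'   `p <= alpha` and `mean_fc <= 1/fc_threshold`, otherwise `ns`.
#' @param min_pairs metabolites with fewer usable pairs are reported in the
#'   `untestable` component instead of tested; default 2.
#' @return list of class `differential_table`: `table` (data.frame with
#'   `metabolite`, `contrast`, `n_pairs`, `mean_fc`, `fc_of_means`,
#'   `p_two_sided`, `p_bh`, `class`), `untestable` (ids), `contrast`,
#'   `alpha`, `fc_threshold`, and `n_cases` available for the contrast.
#'   `p_bh` is a Benjamini-Hochberg column for reference only; it never
#'   drives the classification.
#' @export
paired_contrast_table <- function(x, annotation, location_a, location_b,
                                  alpha = 0.05, fc_threshold = 2,
                                  min_pairs = 2L) {
  stopifnot(inherits(x, "peak_matrix"))
  annotation <- as_sample_annotation(as.data.frame(annotation))
  check_annotation_covers(x, annotation)
  ann <- annotation[annotation$sample_id %in% sample_ids(x), ]
  pairs <- contrast_pairs(ann, location_a, location_b)
  if (nrow(pairs) < 2L)
    validation_error(sprintf("fewer than 2 cases have both %s and %s catheters",
                             location_a, location_b))
  a_vals <- x$values[, pairs$sample_a, drop = FALSE]
  b_vals <- x$values[, pairs$sample_b, drop = FALSE]
  contrast <- paste0(location_a, "/", location_b)
  rows <- vector("list", nrow(x$values))
  untestable <- character()
  for (i in seq_len(nrow(x$values))) {
    a <- a_vals[i, ]; b <- b_vals[i, ]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < min_pairs) {
      untestable <- c(untestable, metabolite_ids(x)[i])
      next
    }
    fc <- a[ok] / b[ok]
    test <- exact_wilcoxon_signed_rank(a[ok] - b[ok])
    rows[[i]] <- data.frame(metabolite = metabolite_ids(x)[i],
                            contrast = contrast,
                            n_pairs = sum(ok),
                            mean_fc = mean(fc),
                            fc_of_means = mean(a[ok]) / mean(b[ok]),
                            p_two_sided = test$p_two_sided,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(tab))
    validation_error("no testable metabolite for this contrast")
  tab$p_bh <- stats::p.adjust(tab$p_two_sided, method = "BH")
  tab$class <- ifelse(tab$p_two_sided <= alpha & tab$mean_fc >= fc_threshold,
                      "up",
               ifelse(tab$p_two_sided <= alpha & tab$mean_fc <= 1 / fc_threshold,
                      "down", "ns"))
  rownames(tab) <- NULL
  structure(list(table = tab, untestable = untestable, contrast = contrast,
                 alpha = alpha, fc_threshold = fc_threshold,
                 n_cases = nrow(pairs)),
            class = "differential_table")
}

# One (sample_a, sample_b) pair per case having exactly one catheter at each
# location; cases with several catheters at a location are ambiguous and
# rejected.
contrast_pairs <- function(ann, location_a, location_b) {
  ann <- ann[ann$location %in% c(location_a, location_b), ]
  out <- list()
  for (cs in unique(ann$case_id)) {
    sa <- ann$sample_id[ann$case_id == cs & ann$location == location_a]
    sb <- ann$sample_id[ann$case_id == cs & ann$location == location_b]
    if (length(sa) > 1L || length(sb) > 1L)
      validation_error(paste0("case ", cs, " has multiple catheters at one location"))
    if (length(sa) == 1L && length(sb) == 1L)
      out[[length(out) + 1L]] <- data.frame(case_id = cs, sample_a = sa,
                                            sample_b = sb,
                                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(case_id = character(), sample_a = character(),
                      sample_b = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' @export
print.differential_table <- function(x, ...) {
  counts <- table(factor(x$table$class, levels = c("up", "down", "ns")))
  cat(sprintf("differential table %s (n = %d cases): %d up, %d down, %d ns (p <= %g, FC >= %g)\n",
              x$contrast, x$n_cases, counts[["up"]], counts[["down"]],
              counts[["ns"]], x$alpha, x$fc_threshold))
  if (length(x$untestable))
    cat(sprintf("  %d metabolite(s) untestable (fewer than 2 usable pairs)\n",
                length(x$untestable)))
  invisible(x)
}

#' Volcano-plot coordinate table
#'
#' Deterministically ordered (descending mean fold change) coordinates for a
#' volcano plot, with per-class counts.
#'
#' @param x a [paired_contrast_table()] result.
#' @return list with `table` (`metabolite`, `log2_mean_fc`, `neg_log10_p`,
#'   `class`) and `counts` (named up/down/ns vector).
#' @export
volcano_table <- function(x) {
  stopifnot(inherits(x, "differential_table"))
  tab <- x$table
  if (!nrow(tab)) validation_error("empty differential table")
  ord <- order(-tab$mean_fc, tab$metabolite, method = "radix")
  out <- data.frame(metabolite = tab$metabolite[ord],
                    log2_mean_fc = log2(tab$mean_fc[ord]),
                    neg_log10_p = -log10(tab$p_two_sided[ord]),
                    class = tab$class[ord],
                    stringsAsFactors = FALSE)
  counts <- table(factor(tab$class, levels = c("up", "down", "ns")))
  list(table = out, counts = c(up = counts[["up"]], down = counts[["down"]],
                               ns = counts[["ns"]]))
}

#' Cross-platform concordance of paired measurements
#'
#' Ordinary least-squares fit of untargeted peak areas against targeted
#' concentrations for the same samples (e.g. total 2-HG peak area against
#' the sum of targeted D- and L-2-HG), on untransformed values, with the
#' squared Pearson correlation as the concordance measure.
#'
#' @param targeted numeric vector (x, e.g. summed stereoisomer
#'   concentrations).
#' @param untargeted numeric vector (y, peak areas), same length/order.
#' @return list with `slope`, `intercept`, `r_squared`, `n`.
#' @export
cross_platform_concordance <- function(targeted, untargeted) {
  ok <- !is.na(targeted) & !is.na(untargeted)
  x <- targeted[ok]; y <- untargeted[ok]
  if (length(x) < 3L) validation_error("need at least 3 paired observations")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    validation_error("zero variance on one platform; correlation undefined")
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = unname(stats::cor(x, y)^2),
       n = length(x))
}
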