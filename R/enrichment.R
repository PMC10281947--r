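#' Extract top/bottom signature sets from a ranked list
#'
#' Builds the two signature sets used throughout cross-case analyses: the
#' `k` most numerator-associated (ranks 1..k, tumour end) and the `k` most
#' denominator-associated (ranks N-k+1..N, brain end) metabolites.
#'
#' @param x a [ranked_list()].
#' @param k signature size; default 35.
#' @return list with elements `top` and `bottom`, each a [metabolite_set()]
#'   named `<list>_top<k>` / `<list>_bottom<k>`.
#' @export
build_sets_from_list <- function(x, k = 35L) {
  stopifnot(inherits(x, "ranked_list"))
  n <- nrow(x)
  if (2L * k > n)
    validation_error(sprintf(
      "cannot take top/bottom %d from a list of %d metabolites", k, n))
  base <- attr(x, "name") %||% "list"
  list(top = metabolite_set(paste0(base, "_top", k),
                            x$metabolite[seq_len(k)],
                            description = paste0("ranks 1..", k, " of ", base)),
       bottom = metabolite_set(paste0(base, "_bottom", k),
                               x$metabolite[seq(n - k + 1L, n)],
                               description = paste0("ranks ", n - k + 1L, "..",
                                                    n, " of ", base)))
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list from rank 1 to rank N. At each set member ("hit")
#' the running sum increases by `|rank_score|^p / N_R`, where `N_R` is the
#' sum of `|rank_score|^p` over all hits; at each non-member ("miss") it
#' decreases by `1 / (N - N_H)`. The enrichment score is the running sum's
#' maximum-magnitude deviation from zero, signed: positive when the set
#' concentrates at the top (numerator/tumour end), negative at the bottom.
#'
#' With `p = 0` every hit counts equally (the classic Kolmogorov-Smirnov
#' statistic); with the default `p = 1` hits are weighted by the magnitude
#' of their log2 fold change. If every hit has rank score exactly zero the
#' weighted sum is undefined and the score falls back to `p = 0` for that
#' set, recorded in the result.
#'
#' @param x a [ranked_list()].
#' @param set a [metabolite_set()]; members absent from the list are ignored
#'   but counted in the result.
#' @param p weighting exponent, a real `>= 0`; default 1.
#' @return list with `es`, `running_sum` (length-N profile), `hit_positions`,
#'   `n_set_in_list`, `n_set_missing`, `weighting_exponent` (the exponent
#'   actually applied) and `fallback_p0` flag.
#' @export
enrichment_score <- function(x, set, p = 1) {
  stopifnot(inherits(x, "ranked_list"), inherits(set, "metabolite_set"))
  if (p < 0) validation_error("weighting exponent must be >= 0")
  n <- nrow(x)
  hit <- x$metabolite %in% set$members
  n_hit <- sum(hit)
  if (n_hit == 0L)
    validation_error(paste0("no member of set '", set$name,
                            "' appears in the ranked list"))
  fallback <- FALSE
  w <- abs(x$rank_score)^p
  if (p > 0 && sum(w[hit]) == 0) {
    fallback <- TRUE
    p <- 0
    w <- rep(1, n)
  }
  if (p == 0) w <- rep(1, n)
  incr <- numeric(n)
  incr[hit] <- w[hit] / sum(w[hit])
  if (n_hit < n) incr[!hit] <- -1 / (n - n_hit)
  rs <- cumsum(incr)
  i_max <- which.max(abs(rs))
  es <- if (abs(rs[i_max]) == 0) 0 else rs[i_max]
  list(es = es,
       running_sum = rs,
       hit_positions = which(hit),
       n_set_in_list = n_hit,
       n_set_missing = length(set$members) - n_hit,
       weighting_exponent = p,
       fallback_p0 = fallback)
}

# Fast ES for a permuted hit-position vector. `aw` is |rank_score|^p for all
# list positions; extremes of the piecewise-linear running sum occur only
# just before and just after hits (and at 0), so only O(N_H) candidates are
# evaluated.
es_from_positions <- function(idx, aw, n) {
  idx <- sort.int(idx)
  w <- aw[idx]
  nr <- sum(w)
  if (nr == 0) w[] <- 1 / length(idx) else w <- w / nr
  n_hit <- length(idx)
  pen <- if (n_hit < n) 1 / (n - n_hit) else 0
  cw <- cumsum(w)
  gap <- (idx - seq_len(n_hit)) * pen       # misses consumed before each hit
  top <- cw - gap                            # value just after each hit
  bot <- c(0, cw[-n_hit]) - gap              # value just before each hit
  cand <- c(top, bot)
  m <- which.max(abs(cand))
  if (abs(cand[m]) == 0) 0 else cand[m]
}

#' Permutation null, normalized enrichment score, and nominal p
#'
#' Ranked lists here derive from single catheter pairs, so no sample-level
#' (phenotype) permutation exists; the null instead redraws the set's
#' in-list members uniformly without replacement from the list (metabolite
#' permutation). The normalized enrichment score divides the observed score
#' by the mean magnitude of same-sign null scores, calibrating positive and
#' negative enrichment separately; the nominal p is the same-sign null
#' exceedance fraction, floored at `1e-5` for display when the raw estimate
#' is zero (the raw estimate is retained).
#'
#' @inheritParams enrichment_score
#' @param n_permutations number of null draws; default 1000.
#' @param seed integer seed (mandatory; all randomness is derived from it).
#' @return an object of class `enrichment_result`: a list with `list_name`,
#'   `set_name`, `es`, `nes`, `p_nominal`, `p_raw`, `fdr_q` (`NA` until
#'   [fdr_across_sets()]), `n_set_in_list`, `n_set_missing`,
#'   `weighting_exponent`, `n_permutations`, `seed`, `null_es`,
#'   `no_same_sign_null` flag and `fallback_p0` flag.
#' @export
permutation_null <- function(x, set, p = 1, n_permutations = 1000L,
                             seed) {
  if (missing(seed) || is.null(seed))
    validation_error("a seed is required for the permutation null")
  obs <- enrichment_score(x, set, p = p)
  n <- nrow(x)
  n_hit <- obs$n_set_in_list
  aw <- abs(x$rank_score)^obs$weighting_exponent
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  null_es <- vapply(seq_len(n_permutations), function(b) {
    es_from_positions(sample.int(n, n_hit), aw, n)
  }, numeric(1L))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  res <- normalize_against_null(obs$es, null_es)
  structure(list(list_name = attr(x, "name") %||% "list",
                 set_name = set$name,
                 es = obs$es, nes = res$nes,
                 p_nominal = res$p_nominal, p_raw = res$p_raw,
                 fdr_q = NA_real_, fdr_q_raw = NA_real_,
                 n_set_in_list = n_hit,
                 n_set_missing = obs$n_set_missing,
                 weighting_exponent = obs$weighting_exponent,
                 n_permutations = n_permutations,
                 seed = as.integer(seed),
                 null_es = null_es,
                 no_same_sign_null = res$no_same_sign,
                 fallback_p0 = obs$fallback_p0),
            class = "enrichment_result")
}

# Display floor applied to zero permutation estimates.
P_FLOOR <- 1e-5

normalize_against_null <- function(es, null_es) {
  if (es == 0)
    return(list(nes = 0, p_nominal = 1, p_raw = 1, no_same_sign = FALSE))
  same <- null_es[sign(null_es) == sign(es)]
  if (!length(same)) {
    pooled <- mean(abs(null_es))
    nes <- if (pooled > 0) es / pooled else 0
    return(list(nes = nes, p_nominal = P_FLOOR, p_raw = 0,
                no_same_sign = TRUE))
  }
  nes <- es / mean(abs(same))
  p_raw <- mean(abs(same) >= abs(es))
  list(nes = nes,
       p_nominal = if (p_raw == 0) P_FLOOR else p_raw,
       p_raw = p_raw,
       no_same_sign = FALSE)
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment of '%s' in '%s': ES %.3f, NES %.3f, p %s%s\n",
              x$set_name, x$list_name, x$es, x$nes,
              format_floored(x$p_nominal, x$p_raw),
              if (is.na(x$fdr_q)) "" else
                paste0(", FDR q ", format_floored(x$fdr_q, x$fdr_q_raw))))
  invisible(x)
}

format_floored <- function(display, raw) {
  if (!is.na(raw) && raw == 0) paste0("<", format(P_FLOOR)) else format(display)
}

#' Permutation-based FDR across a family of enrichment results
#'
#' The q-value of an observed normalized score is the ratio of two tail
#' fractions in the same sign family: the fraction of pooled *null*
#' normalized scores at least as extreme, over the fraction of *observed*
#' normalized scores at least as extreme. Each result's stored null sample
#' is normalized by that result's own same-sign null means (so pooled nulls
#' are on the NES scale), the ratio is clipped to [0, 1], and q is then
#' monotonized within each sign family so it never decreases as `|NES|`
#' decreases. Zero estimates display at the `1e-5` floor; raw values are
#' kept in `fdr_q_raw`.
#'
#' @param results a list of [permutation_null()] results sharing a null
#'   family (same universe and permutation scheme).
#' @return the same list with `fdr_q` and `fdr_q_raw` filled in.
#' @export
fdr_across_sets <- function(results) {
  stopifnot(all(vapply(results, inherits, logical(1L), "enrichment_result")))
  if (length(results) == 1L) {
    results[[1L]]$fdr_q <- results[[1L]]$p_nominal
    results[[1L]]$fdr_q_raw <- results[[1L]]$p_raw
    results[[1L]]$fdr_single_result <- TRUE
    return(results)
  }
  null_nes <- unlist(lapply(results, function(r) {
    nn <- r$null_es
    pos <- nn[nn > 0]; neg <- nn[nn < 0]
    out <- numeric(length(nn))
    if (length(pos)) out[nn > 0] <- nn[nn > 0] / mean(pos)
    if (length(neg)) out[nn < 0] <- nn[nn < 0] / mean(abs(neg))
    out
  }), use.names = FALSE)
  obs_nes <- vapply(results, `[[`, numeric(1L), "nes")
  q_raw <- vapply(seq_along(results), function(i) {
    nes <- obs_nes[i]
    if (nes == 0) return(1)
    null_same <- null_nes[sign(null_nes) == sign(nes)]
    obs_same <- obs_nes[sign(obs_nes) == sign(nes)]
    num <- if (length(null_same)) mean(abs(null_same) >= abs(nes)) else 0
    den <- mean(abs(obs_same) >= abs(nes))   # includes nes itself, > 0
    min(1, num / den)
  }, numeric(1L))
  # monotonize within sign family: q non-increasing in |NES|
  for (s in c(-1, 1)) {
    idx <- which(sign(obs_nes) == s)
    if (length(idx) < 2L) next
    ord <- idx[order(-abs(obs_nes[idx]))]
    q_raw[ord] <- rev(cummin(rev(q_raw[ord])))
  }
  for (i in seq_along(results)) {
    results[[i]]$fdr_q_raw <- q_raw[i]
    results[[i]]$fdr_q <- if (q_raw[i] == 0) P_FLOOR else q_raw[i]
  }
  results
}

#' Flatten enrichment results into a data.frame
#'
#' @param results a list of `enrichment_result` objects.
#' @return data.frame with one row per (list, set) pair.
#' @export
enrichment_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(list = r$list_name, set = r$set_name,
               size = r$n_set_in_list, es = r$es, nes = r$nes,
               p_nominal = r$p_nominal, p_raw = r$p_raw,
               fdr_q = r$fdr_q, fdr_q_raw = r$fdr_q_raw,
               weighting = r$weighting_exponent,
               n_perm = r$n_permutations, seed = r$seed,
               stringsAsFactors = FALSE)
  }))
}

#' Cross-case enrichment matrix
#'
#' Queries every case's top/bottom signature sets against every *other*
#' case's ranked list (self-vs-self excluded by default): a conserved tumour
#' signature appears as uniformly positive, FDR-significant NES for top sets
#' off the diagonal. FDR is computed across all cells (shared null family).
#'
#' @param lists named list of per-case [ranked_list()] objects.
#' @param sets named list of per-case `list(top=, bottom=)` pairs, as from
#'   [build_sets_from_list()]; names must match `lists`.
#' @param p weighting exponent; default 1.
#' @param n_permutations permutations per cell; default 1000.
#' @param seed integer seed; per-cell substreams are derived from it.
#' @param include_self include the diagonal (a set against its own list).
#' @param alpha significance threshold on FDR q for the star matrix.
#' @return list with `results` (all `enrichment_result`s, FDR-adjusted),
#'   `table` (flat data.frame), `nes` and `significant` matrices (rows
#'   labelled `<case>_top` / `<case>_bottom`, columns = list cases; `NA` on
#'   the excluded diagonal).
#' @export
cross_case_enrichment_matrix <- function(lists, sets, p = 1,
                                         n_permutations = 1000L, seed,
                                         include_self = FALSE,
                                         alpha = 0.05) {
  if (missing(seed) || is.null(seed))
    validation_error("a seed is required")
  stopifnot(length(lists) >= 1L, !is.null(names(lists)),
            identical(sort(names(lists)), sort(names(sets))))
  cases <- names(lists)
  row_names <- as.vector(t(outer(cases, c("top", "bottom"), paste, sep = "_")))
  nes <- matrix(NA_real_, length(row_names), length(cases),
                dimnames = list(row_names, cases))
  sig <- matrix(NA, length(row_names), length(cases),
                dimnames = list(row_names, cases))
  results <- list()
  coord <- list()
  cell <- 0L
  for (sc in cases) {
    for (side in c("top", "bottom")) {
      set <- sets[[sc]][[side]]
      for (lc in cases) {
        cell <- cell + 1L
        if (!include_self && identical(sc, lc)) next
        results[[length(results) + 1L]] <-
          permutation_null(lists[[lc]], set, p = p,
                           n_permutations = n_permutations,
                           seed = derive_seed(seed, cell))
        coord[[length(coord) + 1L]] <- c(paste0(sc, "_", side), lc)
      }
    }
  }
  if (length(results) > 1L) results <- fdr_across_sets(results)
  tab <- if (length(results)) enrichment_table(results) else NULL
  for (i in seq_along(results)) {
    nes[coord[[i]][1L], coord[[i]][2L]] <- results[[i]]$nes
    sig[coord[[i]][1L], coord[[i]][2L]] <- results[[i]]$fdr_q_raw <= alpha
  }
  list(results = results, table = tab, nes = nes, significant = sig)
}
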