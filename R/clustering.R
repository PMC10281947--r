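#' Pairwise Spearman correlation between samples
#'
#' Spearman rank correlation between every pair of samples, computed over
#' the metabolites observed in both (pairwise-complete). Monotone rather
#' than linear association suits peak areas, whose scale is arbitrary. Pairs
#' sharing fewer than `min_shared` metabolites are undefined (`NA`) and
#' flagged.
#'
#' @param x a normalized `peak_matrix`.
#' @param samples sample ids to include; default all.
#' @param min_shared minimum shared observations per pair; default 3.
#' @return list with `rho` (symmetric matrix, unit diagonal), `n_shared`
#'   (shared-observation counts), and `undefined` (data.frame of flagged
#'   pairs).
#' @export
spearman_matrix <- function(x, samples = NULL, min_shared = 3L) {
  stopifnot(inherits(x, "peak_matrix"))
  samples <- samples %||% sample_ids(x)
  unknown <- setdiff(samples, sample_ids(x))
  if (length(unknown))
    validation_error(paste0("unknown sample(s): ", paste(unknown, collapse = ", ")))
  vals <- x$values[, samples, drop = FALSE]
  rho <- suppressWarnings(
    stats::cor(vals, method = "spearman", use = "pairwise.complete.obs"))
  obs <- !is.na(vals)
  n_shared <- t(obs * 1) %*% (obs * 1)
  storage.mode(n_shared) <- "integer"
  undef <- which(n_shared < min_shared & upper.tri(n_shared), arr.ind = TRUE)
  rho[n_shared < min_shared] <- NA_real_
  diag(rho) <- 1
  list(rho = rho, n_shared = n_shared,
       undefined = data.frame(
         sample_1 = rownames(n_shared)[undef[, 1L]],
         sample_2 = colnames(n_shared)[undef[, 2L]],
         stringsAsFactors = FALSE))
}

#' Ward hierarchical clustering of samples
#'
#' Ward-linkage agglomeration on Euclidean distances between samples.
#' Metabolite-wise autoscaling (mean 0, sd 1) is applied by default, the
#' standard display scaling for abundance heat maps; values may additionally
#' be clipped for display via [clip_for_display()], which never affects the
#' distances used here. Remaining missing values are filled with half the
#' metabolite's minimum observed value (a conventional metabolomics
#' non-detect floor), recorded in the result. Samples are ordered
#' lexicographically before clustering so the dendrogram is invariant to
#' input column order.
#'
#' @param x a normalized `peak_matrix`, typically presence-filtered.
#' @param scaling `"autoscale"` (default) or `"none"`.
#' @return list with `hclust` (a `stats::hclust` object, Ward linkage),
#'   `leaf_order` (sample ids in dendrogram order), `newick` (the tree in
#'   Newick text), `dropped` (zero-variance metabolites removed under
#'   autoscaling), and `n_filled` (missing values imputed with the
#'   half-minimum floor).
#' @export
hierarchical_cluster <- function(x, scaling = c("autoscale", "none")) {
  scaling <- match.arg(scaling)
  stopifnot(inherits(x, "peak_matrix"))
  vals <- x$values[, order(colnames(x$values)), drop = FALSE]
  n_filled <- 0L
  for (i in seq_len(nrow(vals))) {
    miss <- is.na(vals[i, ])
    if (any(miss)) {
      if (all(miss))
        validation_error(paste0("metabolite ", rownames(vals)[i],
                                " has no observed value"))
      vals[i, miss] <- min(vals[i, !miss]) / 2
      n_filled <- n_filled + sum(miss)
    }
  }
  dropped <- character()
  if (scaling == "autoscale") {
    sds <- apply(vals, 1L, stats::sd)
    zero <- sds == 0
    if (any(zero)) {
      dropped <- rownames(vals)[zero]
      warning("dropping ", sum(zero), " zero-variance metabolite(s) under autoscaling")
      vals <- vals[!zero, , drop = FALSE]
    }
    vals <- t(scale(t(vals)))
  }
  if (ncol(vals) < 2L) validation_error("need at least 2 samples to cluster")
  d <- stats::dist(t(vals), method = "euclidean")
  hc <- stats::hclust(d, method = "ward.D2")
  phylo <- ape::as.phylo(hc)
  list(hclust = hc,
       leaf_order = hc$labels[hc$order],
       newick = ape::write.tree(phylo),
       dropped = dropped,
       n_filled = n_filled)
}

#' Clip autoscaled values for heat-map display
#'
#' Truncates z-scores to a symmetric display range (default [-6, 6]). Only
#' rendered colours are affected; clustering distances are always computed
#' on unclipped values.
#'
#' @param z numeric matrix of autoscaled values.
#' @param limit clip magnitude; default 6.
#' @return the clipped matrix.
#' @export
clip_for_display <- function(z, limit = 6) {
  pmin(pmax(z, -limit), limit)
}
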