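#' Construct a ranked metabolite list
#'
#' Internal constructor: builds the `ranked_list` data.frame from named fold
#' changes, sorting by descending log2 fold change with ties broken by
#' ascending metabolite name (deterministic, seed-free).
#'
#' @param fold_change named numeric vector of strictly positive fold changes.
#' @param name list label, e.g. `"case3_E_vs_B"`.
#' @param omitted character vector of metabolites excluded (masked/missing in
#'   either member of the pair), recorded for provenance.
#' @return a data.frame of class `ranked_list` with columns `metabolite`,
#'   `fold_change`, `rank_score` (log2 fold change) and `rank` (1..N, rank 1
#'   = most numerator-associated).
#' @export
ranked_list <- function(fold_change, name = "ranked_list",
                        omitted = character()) {
  if (!length(fold_change)) validation_error("ranked list cannot be empty")
  if (is.null(names(fold_change)) || anyNA(fold_change))
    validation_error("fold changes must be a complete named vector")
  if (any(fold_change <= 0))
    validation_error("fold changes must be strictly positive")
  score <- log2(fold_change)
  ord <- order(-score, names(fold_change), method = "radix")
  out <- data.frame(metabolite = names(fold_change)[ord],
                    fold_change = unname(fold_change[ord]),
                    rank_score = unname(score[ord]),
                    rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  attr(out, "name") <- name
  attr(out, "omitted") <- omitted
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' @export
print.ranked_list <- function(x, ...) {
  cat(sprintf("ranked_list '%s': %d metabolites (%d omitted)\n",
              attr(x, "name"), nrow(x), length(attr(x, "omitted"))))
  cat(sprintf("  top:    %s (FC %.3g)\n", x$metabolite[1L], x$fold_change[1L]))
  cat(sprintf("  bottom: %s (FC %.3g)\n",
              x$metabolite[nrow(x)], x$fold_change[nrow(x)]))
  invisible(x)
}

#' Paired fold-change ranked list for one catheter contrast
#'
#' Ranks every analyzable metabolite by its fold change between two catheters
#' of the same case, e.g. enhancing tumour (catheter X) over adjacent brain
#' (catheter Z). Rank 1 is the most numerator-associated (tumour end); rank N
#' the most denominator-associated (brain end). Metabolites masked or missing
#' in either sample are omitted and recorded in the result's provenance.
#'
#' @param x a normalized `peak_matrix` (typically presence-filtered).
#' @param numerator,denominator sample ids of the pair.
#' @param annotation optional `sample_annotation`; when given, the two
#'   samples must belong to the same case unless `allow_cross_case = TRUE`
#'   (the design is paired within-patient).
#' @param name list label; defaults to `"<numerator>_vs_<denominator>"`.
#' @param allow_cross_case set `TRUE` to rank across cases deliberately.
#' @return a [ranked_list()].
#' @export
make_ranked_list <- function(x, numerator, denominator, annotation = NULL,
                             name = NULL, allow_cross_case = FALSE) {
  stopifnot(inherits(x, "peak_matrix"))
  if (numerator == denominator && is.null(name))
    name <- paste0(numerator, "_vs_self")
  for (s in c(numerator, denominator))
    if (!s %in% sample_ids(x))
      validation_error(paste0("sample not in matrix: ", s))
  if (!is.null(annotation) && !allow_cross_case) {
    annotation <- as_sample_annotation(as.data.frame(annotation))
    case <- stats::setNames(annotation$case_id, annotation$sample_id)
    if (!identical(unname(case[numerator]), unname(case[denominator])))
      validation_error(paste0(
        "samples ", numerator, " and ", denominator,
        " belong to different cases; pass allow_cross_case = TRUE to override"))
  }
  num <- x$values[, numerator]
  den <- x$values[, denominator]
  ok <- !is.na(num) & !is.na(den)
  if (!any(ok)) validation_error("no metabolite observed in both samples")
  fc <- num[ok] / den[ok]
  ranked_list(fc,
              name = name %||% paste0(numerator, "_vs_", denominator),
              omitted = metabolite_ids(x)[!ok])
}

#' Group-mean fold change
#'
#' Per-metabolite ratio of arithmetic group means of normalized peak areas,
#' e.g. IDH-mutant tumour catheters over IDH-wild-type tumour catheters.
#'
#' @param x a normalized `peak_matrix`.
#' @param group_a,group_b disjoint, non-empty sample-id vectors; `group_a` is
#'   the numerator.
#' @return named numeric vector of fold changes; `NA` where a metabolite is
#'   unobserved in an entire group.
#' @export
group_fold_change <- function(x, group_a, group_b) {
  stopifnot(inherits(x, "peak_matrix"))
  if (!length(group_a) || !length(group_b))
    validation_error("groups must be non-empty")
  if (length(intersect(group_a, group_b)))
    validation_error("groups must be disjoint")
  unknown <- setdiff(c(group_a, group_b), sample_ids(x))
  if (length(unknown))
    validation_error(paste0("sample(s) not in matrix: ",
                            paste(unknown, collapse = ", ")))
  mean_a <- rowMeans(x$values[, group_a, drop = FALSE], na.rm = TRUE)
  mean_b <- rowMeans(x$values[, group_b, drop = FALSE], na.rm = TRUE)
  fc <- mean_a / mean_b
  fc[is.nan(fc)] <- NA_real_
  fc
}

#' Average-rank table across ranked lists
#'
#' The rank of each metabolite in every per-case list, plus the cross-case
#' mean rank, sorted ascending (most tumour-associated first). This is the
#' table behind rank heat maps: a conserved tumour signature shows as stable
#' small ranks across columns.
#'
#' @param lists a non-empty list of [ranked_list()] objects. Lists sharing
#'   only part of their metabolite universe are intersected with a warning.
#' @return a data.frame with `metabolite`, `mean_rank`, and one rank column
#'   per input list; ties in mean rank broken by metabolite name.
#' @export
average_rank_table <- function(lists) {
  if (!length(lists)) validation_error("need at least one ranked list")
  stopifnot(all(vapply(lists, inherits, logical(1L), "ranked_list")))
  nms <- vapply(seq_along(lists), function(i) {
    attr(lists[[i]], "name") %||% paste0("list", i)
  }, character(1L))
  universe <- Reduce(intersect, lapply(lists, function(l) l$metabolite))
  if (!length(universe))
    validation_error("ranked lists share no metabolites")
  full <- length(lists[[1L]]$metabolite)
  if (any(vapply(lists, nrow, integer(1L)) != length(universe)))
    warning("ranked lists differ in metabolite universe; using the intersection (",
            length(universe), " metabolites)")
  ranks <- vapply(lists, function(l) {
    # re-rank within the shared universe so columns are comparable
    sub <- l[l$metabolite %in% universe, ]
    stats::setNames(rank(sub$rank)[match(universe, sub$metabolite)], universe)
  }, numeric(length(universe)))
  ranks <- matrix(ranks, nrow = length(universe),
                  dimnames = list(universe, nms))
  mean_rank <- rowMeans(ranks)
  ord <- order(mean_rank, universe, method = "radix")
  out <- data.frame(metabolite = universe[ord],
                    mean_rank = unname(mean_rank[ord]),
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- cbind(out, as.data.frame(ranks[ord, , drop = FALSE],
                                  check.names = FALSE))
  rownames(out) <- NULL
  out
}

#' Write a ranked list as a two-column RNK file
#'
#' Tab-separated metabolite and rank score (log2 fold change), the de-facto
#' preranked-enrichment exchange format.
#'
#' @param x a [ranked_list()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rnk <- function(x, path) {
  stopifnot(inherits(x, "ranked_list"))
  writeLines(paste(x$metabolite,
                   formatC(x$rank_score, digits = 17, format = "g"),
                   sep = "\t"),
             path, sep = "\n")
  invisible(path)
}

#' Read a two-column RNK file into a ranked list
#'
#' @param path RNK file path (metabolite, tab, log2 score per line).
#' @param name list label; defaults to the file name.
#' @return a [ranked_list()].
#' @export
read_rnk <- function(path, name = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("metabolite", "score"),
                           colClasses = c("character", "numeric"),
                           quote = "\"", comment.char = "#")
  ranked_list(stats::setNames(2^tab$score, trimws(tab$metabolite)),
              name = name %||% tools::file_path_sans_ext(basename(path)))
}
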