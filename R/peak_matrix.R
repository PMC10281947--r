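#' Construct a peak-area matrix
#'
#' The central container of the package: a metabolites-by-samples matrix of
#' LC-MS peak areas. Present values are strictly positive; non-detects are
#' explicit `NA`s, never zeros (untargeted metabolomics vendors report blanks
#' for non-detects, and normalized peak areas are positive by construction).
#'
#' @param values numeric matrix, metabolites in rows, samples in columns.
#'   Row and column names are required and must be unique after whitespace
#'   trimming. Missing values are `NA`.
#' @param layer `"raw"` or `"normalized"`. A normalized layer promises that
#'   the median of every (metabolite, batch) group of non-missing values is 1.
#' @param batch optional character vector of batch labels, one per sample
#'   (named by sample id or in column order). Defaults to a single batch.
#' @return an object of class `peak_matrix`.
#' @export
peak_matrix <- function(values, layer = c("raw", "normalized"), batch = NULL) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values))
    validation_error("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    validation_error("'values' must have metabolite row names and sample column names")
  rownames(values) <- trimws(rownames(values))
  colnames(values) <- trimws(colnames(values))
  dup_m <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_m))
    validation_error(paste0("duplicate metabolite id(s): ",
                            paste(dup_m, collapse = ", ")))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    validation_error(paste0("duplicate sample id(s): ",
                            paste(dup_s, collapse = ", ")))
  bad <- which(!is.na(values) & values <= 0, arr.ind = TRUE)
  if (nrow(bad))
    validation_error(paste0(
      "peak areas must be strictly positive; offending cell(s): ",
      paste(utils::head(paste0(rownames(values)[bad[, 1]], "/",
                               colnames(values)[bad[, 2]]), 5L),
            collapse = ", ")))
  if (is.null(batch)) {
    batch <- rep("batch1", ncol(values))
    names(batch) <- colnames(values)
  } else {
    batch <- as.character(batch)
    if (is.null(names(batch))) {
      if (length(batch) != ncol(values))
        validation_error("'batch' must have one label per sample")
      names(batch) <- colnames(values)
    }
    if (!setequal(names(batch), colnames(values)))
      validation_error("'batch' names must match sample ids")
    batch <- batch[colnames(values)]
  }
  if (layer == "normalized") {
    dev <- max_median_deviation(values, batch)
    if (dev > 1e-9)
      validation_error(sprintf(
        "layer='normalized' but a (metabolite, batch) median deviates from 1 by %.3g",
        dev))
  }
  structure(list(values = values, layer = layer, batch = batch),
            class = "peak_matrix")
}

# Largest |median - 1| over all (metabolite, batch) groups with data.
max_median_deviation <- function(values, batch) {
  dev <- 0
  for (b in unique(batch)) {
    sub <- values[, batch == b, drop = FALSE]
    med <- apply(sub, 1L, median_nonmissing)
    med <- med[!is.na(med)]
    if (length(med)) dev <- max(dev, max(abs(med - 1)))
  }
  dev
}

#' @export
print.peak_matrix <- function(x, ...) {
  cat(sprintf("peak_matrix: %d metabolites x %d samples (layer=%s, %d batch%s, %.1f%% missing)\n",
              nrow(x$values), ncol(x$values), x$layer,
              length(unique(x$batch)),
              if (length(unique(x$batch)) == 1L) "" else "es",
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.peak_matrix <- function(x) dim(x$values)

#' Metabolite and sample identifiers of a peak matrix
#' @param x a `peak_matrix`.
#' @return character vector of ids.
#' @export
metabolite_ids <- function(x) rownames(x$values)

#' @rdname metabolite_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Read a delimited peak-area table
#'
#' Accepts comma- or tab-delimited text with identifiers in the first row and
#' column. Empty cells, `""` and `"NA"` denote missing values. Zeros are
#' rejected: a zero peak area is an encoding error, not a non-detect.
#'
#' @param path file path.
#' @param orientation `"metabolites_in_rows"` (default) or
#'   `"samples_in_rows"`; the latter is transposed on read.
#' @param batch optional batch label vector passed to [peak_matrix()].
#' @param sep field separator; inferred from the first line when `NULL`.
#' @return a `peak_matrix` with `layer = "raw"`.
#' @export
read_peak_matrix <- function(path,
                             orientation = c("metabolites_in_rows",
                                             "samples_in_rows"),
                             batch = NULL, sep = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) md_stop(paste0("file not found: ", path),
                                  "microdialysR_io_error")
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  ids <- trimws(raw[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    parse_error(paste0("duplicate identifier(s) in first column: ",
                       paste(dup, collapse = ", ")))
  body <- raw[, -1L, drop = FALSE]
  vals <- matrix(NA_real_, nrow(body), ncol(body),
                 dimnames = list(ids, trimws(colnames(body))))
  for (j in seq_len(ncol(body))) {
    cell <- trimws(body[[j]])
    miss <- cell == "" | toupper(cell) == "NA"
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!miss & is.na(num))
    if (length(bad))
      parse_error(sprintf(
        "non-numeric value '%s' at row '%s', column '%s'",
        cell[bad[1L]], ids[bad[1L]], colnames(body)[j]))
    num[miss] <- NA_real_
    vals[, j] <- num
  }
  if (orientation == "samples_in_rows") vals <- t(vals)
  peak_matrix(vals, layer = "raw", batch = batch)
}

#' Write a peak-area table
#'
#' Writes a metabolites-in-rows delimited table that [read_peak_matrix()]
#' re-reads exactly (values at full precision, missing cells empty, `\n`
#' line endings).
#'
#' @param x a `peak_matrix`.
#' @param path output file path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_peak_matrix <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "peak_matrix"))
  vals <- x$values
  fmt <- function(v) ifelse(is.na(v), "", formatC(v, digits = 17, format = "g"))
  lines <- c(paste(c("metabolite", colnames(vals)), collapse = sep),
             vapply(seq_len(nrow(vals)), function(i) {
               paste(c(rownames(vals)[i], fmt(vals[i, ])), collapse = sep)
             }, character(1L)))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Read a sample-annotation table
#'
#' A CSV with one row per sample. Required columns: `sample_id`, `case_id`,
#' `location` (one of `E`, `NE`, `B`, `CSF`). Optional columns: `catheter`
#' (`X`/`Y`/`Z`/`none`), `idh_status` (`mutant`/`wild_type`/`unknown`),
#' `recurrent` (logical), `batch`, `heme` (non-negative, CSF samples only),
#' and `perfusate_excluded` (semicolon-separated metabolite ids whose values
#' are unreliable for that sample's case because the perfusate itself
#' contained the analyte).
#'
#' @param path CSV file path.
#' @return a `data.frame` of class `sample_annotation`.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
  as_sample_annotation(ann)
}

#' Validate a sample-annotation data frame
#'
#' @param ann a data.frame with the columns documented in [read_annotation()].
#' @return the validated, completed `sample_annotation` data.frame.
#' @export
as_sample_annotation <- function(ann) {
  req <- c("sample_id", "case_id", "location")
  missing_cols <- setdiff(req, names(ann))
  if (length(missing_cols))
    validation_error(paste0("annotation missing column(s): ",
                            paste(missing_cols, collapse = ", ")))
  ann$sample_id <- trimws(as.character(ann$sample_id))
  ann$case_id <- trimws(as.character(ann$case_id))
  dup <- unique(ann$sample_id[duplicated(ann$sample_id)])
  if (length(dup))
    validation_error(paste0("duplicate sample_id(s) in annotation: ",
                            paste(dup, collapse = ", ")))
  locs <- c("E", "NE", "B", "CSF")
  bad <- setdiff(unique(ann$location), locs)
  if (length(bad))
    validation_error(paste0("unknown location(s): ", paste(bad, collapse = ", ")))
  if (is.null(ann$catheter)) ann$catheter <- "none"
  if (is.null(ann$idh_status)) ann$idh_status <- "unknown"
  if (is.null(ann$recurrent)) ann$recurrent <- FALSE
  if (is.null(ann$batch)) ann$batch <- "batch1"
  if (is.null(ann$heme)) ann$heme <- NA_real_
  if (is.null(ann$perfusate_excluded)) ann$perfusate_excluded <- ""
  ann$heme <- as.numeric(ann$heme)
  if (any(!is.na(ann$heme) & ann$location != "CSF"))
    validation_error("heme content may only be annotated on CSF samples")
  if (any(!is.na(ann$heme) & ann$heme < 0))
    validation_error("heme content must be non-negative")
  class(ann) <- c("sample_annotation", "data.frame")
  ann
}

# Check every sample of a peak matrix has exactly one annotation row.
check_annotation_covers <- function(x, ann) {
  missing_s <- setdiff(sample_ids(x), ann$sample_id)
  if (length(missing_s))
    validation_error(paste0("sample(s) missing from annotation: ",
                            paste(missing_s, collapse = ", ")))
  invisible(TRUE)
}

# Perfusate exclusions as a data.frame of (case_id, metabolite_id) pairs.
perfusate_exclusion_pairs <- function(ann) {
  out <- list()
  for (i in seq_len(nrow(ann))) {
    f <- ann$perfusate_excluded[i]
    if (is.na(f) || !nzchar(f)) next
    mets <- trimws(strsplit(f, ";", fixed = TRUE)[[1L]])
    mets <- mets[nzchar(mets)]
    if (length(mets))
      out[[length(out) + 1L]] <- data.frame(case_id = ann$case_id[i],
                                            metabolite_id = mets,
                                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(case_id = character(), metabolite_id = character(),
                      stringsAsFactors = FALSE))
  unique(do.call(rbind, out))
}
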