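#' Construct a metabolite set
#'
#' A named, ordered collection of metabolite identifiers, e.g. the top-35
#' tumour-associated extract of a ranked list or an externally supplied
#' plasma signature.
#'
#' @param name set name (non-empty).
#' @param members character vector of metabolite ids; non-empty, no
#'   duplicates, order preserved.
#' @param description free-text description.
#' @return an object of class `metabolite_set`.
#' @export
metabolite_set <- function(name, members, description = "") {
  name <- trimws(name)
  if (!nzchar(name)) validation_error("set name must be non-empty")
  members <- trimws(as.character(members))
  members <- members[nzchar(members)]
  if (!length(members))
    validation_error(paste0("set '", name, "' has zero members"))
  dup <- unique(members[duplicated(members)])
  if (length(dup))
    validation_error(paste0("set '", name, "' has duplicate member(s): ",
                            paste(dup, collapse = ", ")))
  structure(list(name = name, members = members,
                 description = as.character(description)),
            class = "metabolite_set")
}

#' @export
print.metabolite_set <- function(x, ...) {
  cat(sprintf("metabolite_set '%s': %d members\n", x$name, length(x$members)))
  invisible(x)
}

#' @export
length.metabolite_set <- function(x) length(x$members)

#' Read a GMT or GMX metabolite-set file
#'
#' GMT holds one set per *row* (name, description, members...); GMX holds one
#' set per *column* (name in row 1, description in row 2, members below).
#' Both are tab-delimited. The dialect is chosen from the file extension and
#' can be overridden. Blank trailing fields are dropped.
#'
#' @param path file path.
#' @param dialect `"auto"` (default, by extension), `"gmt"`, or `"gmx"`.
#' @return a named list of [metabolite_set()] objects.
#' @export
read_set_file <- function(path, dialect = c("auto", "gmt", "gmx")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) md_stop(paste0("file not found: ", path),
                                  "microdialysR_io_error")
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (ext == "gmx") "gmx" else "gmt"
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) validation_error("set file is empty")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (dialect == "gmt") {
    sets <- lapply(fields, function(f) {
      f <- trimws(f)
      if (length(f) < 3L)
        validation_error(paste0("GMT row for '", f[1L],
                                "' has no members"))
      metabolite_set(f[1L], f[-(1:2)][nzchar(f[-(1:2)])],
                     description = f[2L])
    })
  } else {
    ncolumns <- max(lengths(fields))
    grid <- vapply(fields, function(f) {
      c(trimws(f), rep("", ncolumns - length(f)))
    }, character(ncolumns))
    grid <- matrix(grid, nrow = ncolumns)   # columns of grid = file rows
    if (nrow(grid) < 1L || ncol(grid) < 3L)
      validation_error("GMX file must have name, description, and member rows")
    sets <- lapply(seq_len(nrow(grid)), function(j) {
      col <- grid[j, ]
      members <- col[-(1:2)]
      metabolite_set(col[1L], members[nzchar(members)],
                     description = col[2L])
    })
  }
  nm <- vapply(sets, function(s) s$name, character(1L))
  dup <- unique(nm[duplicated(nm)])
  if (length(dup))
    validation_error(paste0("duplicate set name(s): ",
                            paste(dup, collapse = ", ")))
  names(sets) <- nm
  sets
}

#' Write metabolite sets as GMT or GMX
#'
#' Output is byte-stable for identical inputs: fields are tab-separated in a
#' fixed order (name, description, members) with `\n` line endings.
#'
#' @param sets a list of [metabolite_set()] objects.
#' @param path output file path.
#' @param dialect `"gmt"` (one set per row) or `"gmx"` (one set per column).
#' @return `path`, invisibly.
#' @export
write_set_file <- function(sets, path, dialect = c("gmt", "gmx")) {
  dialect <- match.arg(dialect)
  if (!length(sets)) validation_error("cannot write an empty set list")
  stopifnot(all(vapply(sets, inherits, logical(1L), "metabolite_set")))
  if (dialect == "gmt") {
    lines <- vapply(sets, function(s) {
      paste(c(s$name, s$description, s$members), collapse = "\t")
    }, character(1L))
  } else {
    depth <- 2L + max(vapply(sets, function(s) length(s$members), integer(1L)))
    cols <- lapply(sets, function(s) {
      c(s$name, s$description, s$members,
        rep("", depth - 2L - length(s$members)))
    })
    lines <- vapply(seq_len(depth), function(i) {
      paste(vapply(cols, `[`, character(1L), i), collapse = "\t")
    }, character(1L))
  }
  writeLines(lines, path, sep = "\n")
  invisible(path)
}
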