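test_that("peak matrix parsing handles missing cells and both orientations", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("metabolite,s1,s2", "alanine,1.5,2.25", "proline,,4e2",
               "carnitine,0.125,NA"), path)
  m <- read_peak_matrix(path)
  expect_equal(dim(m), c(3L, 2L))
  expect_identical(m$layer, "raw")
  expect_true(is.na(m$values["proline", "s1"]))
  expect_true(is.na(m$values["carnitine", "s2"]))
  expect_equal(m$values["proline", "s2"], 400)
  expect_equal(m$values["alanine", ], c(s1 = 1.5, s2 = 2.25))

  t_path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,alanine,proline", "s1,1.5,2", "s2,2.25,4"), t_path)
  mt <- read_peak_matrix(t_path, orientation = "samples_in_rows")
  expect_identical(rownames(mt$values), c("alanine", "proline"))
  expect_equal(mt$values["proline", "s2"], 4)
})

test_that("peak matrix validation rejects duplicates, zeros, and bad cells", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("metabolite,s1", "alanine,1", "alanine,2"), path)
  expect_error(read_peak_matrix(path), "alanine",
               class = "microdialysR_parse_error")

  writeLines(c("metabolite,s1", "alanine,-3"), path)
  expect_error(read_peak_matrix(path), "positive",
               class = "microdialysR_validation_error")
  writeLines(c("metabolite,s1", "alanine,0"), path)
  expect_error(read_peak_matrix(path), "positive",
               class = "microdialysR_validation_error")

  writeLines(c("metabolite,s1,s2", "alanine,1,2", "proline,abc,3"), path)
  err <- expect_error(read_peak_matrix(path),
                      class = "microdialysR_parse_error")
  expect_match(conditionMessage(err), "proline")
  expect_match(conditionMessage(err), "s1")

  vals <- matrix(c(1, 2), 1, 2, dimnames = list("a", c("s", "s")))
  expect_error(peak_matrix(vals), "duplicate sample",
               class = "microdialysR_validation_error")
})

test_that("peak matrix write/read round-trips values and missing mask exactly", {
  set.seed(42)
  vals <- matrix(exp(rnorm(60, 3, 2)), 10, 6,
                 dimnames = list(sprintf("m%02d", 1:10), sprintf("s%d", 1:6)))
  vals[sample(60, 9)] <- NA
  m <- peak_matrix(vals)
  for (sep in c(",", "\t")) {
    path <- withr::local_tempfile(fileext = ".txt")
    write_peak_matrix(m, path, sep = sep)
    back <- read_peak_matrix(path)
    expect_identical(is.na(back$values), is.na(m$values))
    expect_equal(back$values, m$values, tolerance = 0)
  }
})

test_that("normalized layer is validated against the per-batch unit-median invariant", {
  vals <- matrix(c(0.5, 1, 1.5, 2, 1, 0.5), 2, 3, byrow = TRUE,
                 dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  expect_s3_class(peak_matrix(vals, layer = "normalized"), "peak_matrix")
  vals["a", ] <- c(1, 2, 3)
  expect_error(peak_matrix(vals, layer = "normalized"), "median",
               class = "microdialysR_validation_error")
})

test_that("GMT and GMX dialects parse identically and preserve member order", {
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("E_top35\tdesc\tproline\tcarnitine",
               "B_top\tbrain\tNAA\tcreatine\tmyo-inositol"), gmt)
  sets <- read_set_file(gmt)
  expect_named(sets, c("E_top35", "B_top"))
  expect_identical(sets$E_top35$members, c("proline", "carnitine"))
  expect_identical(sets$B_top$members, c("NAA", "creatine", "myo-inositol"))

  gmx <- withr::local_tempfile(fileext = ".gmx")
  write_set_file(sets, gmx, dialect = "gmx")
  expect_equal(read_set_file(gmx), sets, ignore_attr = FALSE)

  # trailing blank fields (ragged GMX columns) are dropped silently
  gmx2 <- withr::local_tempfile(fileext = ".gmx")
  writeLines(c("A\tB", "da\tdb", "x\ty", "\tz", "\t"), gmx2)
  sets2 <- read_set_file(gmx2)
  expect_identical(sets2$A$members, "x")
  expect_identical(sets2$B$members, c("y", "z"))
})

test_that("set files round-trip bit-stably and reject invalid sets", {
  sets <- list(a = metabolite_set("a", c("x", "y"), "first"),
               b = metabolite_set("b", "z"))
  for (dialect in c("gmt", "gmx")) {
    p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
    write_set_file(sets, p1, dialect = dialect)
    write_set_file(sets, p2, dialect = dialect)
    expect_identical(readLines(p1), readLines(p2))
    expect_equal(read_set_file(p1, dialect = dialect), sets)
  }
  expect_error(write_set_file(list(), withr::local_tempfile()),
               class = "microdialysR_validation_error")
  expect_error(metabolite_set("empty", character()), "zero members",
               class = "microdialysR_validation_error")
  expect_error(metabolite_set("dup", c("x", "x")), "duplicate",
               class = "microdialysR_validation_error")
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("s1\td\tx", "s1\td\ty"), gmt)
  expect_error(read_set_file(gmt), "duplicate set name",
               class = "microdialysR_validation_error")
})

test_that("annotation validation enforces coverage, heme placement, and uniqueness", {
  ann <- toy_annotation(c("s1", "s2"), c("c1", "c1"), c("E", "B"))
  m <- toy_matrix(1:9)  # samples s1..s3; s3 lacks annotation
  expect_error(microdialysR:::check_annotation_covers(m, ann),
               "s3", class = "microdialysR_validation_error")
  expect_error(toy_annotation("s1", "c1", "E", heme = 2), "CSF",
               class = "microdialysR_validation_error")
  expect_error(toy_annotation(c("s1", "s1"), c("c1", "c1"), c("E", "B")),
               "duplicate", class = "microdialysR_validation_error")
  expect_error(toy_annotation("s1", "c1", "elsewhere"), "location",
               class = "microdialysR_validation_error")
  csf <- toy_annotation("s9", "c9", "CSF", heme = 4.5)
  expect_equal(csf$heme, 4.5)
})

test_that("randomly corrupted tables are always rejected", {
  set.seed(7)
  for (i in 1:20) {
    vals <- matrix(exp(rnorm(12)), 4, 3,
                   dimnames = list(paste0("m", 1:4), paste0("s", 1:3)))
    corruption <- sample(c("zero", "negative", "dup_row"), 1)
    if (corruption == "zero") vals[sample(12, 1)] <- 0
    if (corruption == "negative") vals[sample(12, 1)] <- -runif(1)
    if (corruption == "dup_row") rownames(vals)[2] <- rownames(vals)[1]
    expect_error(peak_matrix(vals), class = "microdialysR_validation_error")
  }
})
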