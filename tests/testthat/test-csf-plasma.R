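test_that("paired bloodiness list filters to the shared universe", {
  vals <- matrix(c(8, 2, 1, 4, NA,   # bloody
                   2, 2, 1, 1, 3),   # clean
                 5, 2, dimnames = list(c("a", "b", "c", "d", "e"),
                                       c("bloody", "clean")))
  csf <- peak_matrix(vals)
  rl <- paired_bloodiness_list(csf, "bloody", "clean",
                               microdialysate_universe = c("a", "b", "c", "e"))
  # 'd' not in the microdialysate universe, 'e' missing in bloody CSF
  expect_setequal(rl$metabolite, c("a", "b", "c"))
  expect_equal(rl$fold_change[rl$metabolite == "a"], 4)
  expect_identical(rl$metabolite[1], "a")

  # bloody == clean: degenerate flat list is flagged
  v2 <- vals[1:4, ]; v2[, 2] <- v2[, 1]
  flat <- paired_bloodiness_list(peak_matrix(v2), "bloody", "clean",
                                 microdialysate_universe = letters[1:4])
  expect_true(isTRUE(attr(flat, "degenerate")))
  expect_error(paired_bloodiness_list(csf, "bloody", "clean",
                                      microdialysate_universe = "zzz"),
               class = "microdialysR_validation_error")
})

test_that("pooled bloodiness list takes ceiling(n/4) quartile pools", {
  set.seed(91)
  make_csf <- function(n) {
    vals <- matrix(exp(rnorm(20 * n)), 20, n,
                   dimnames = list(sprintf("m%02d", 1:20), sprintf("c%02d", 1:n)))
    peak_matrix(vals)
  }
  csf26 <- make_csf(26)
  heme26 <- setNames(runif(26), sample_ids(csf26))
  rl <- pooled_bloodiness_list(csf26, heme26,
                               microdialysate_universe = sprintf("m%02d", 1:20))
  expect_length(attr(rl, "bloody_pool"), 7)
  expect_length(attr(rl, "clean_pool"), 7)
  # brute-force sort-and-slice oracle for pool membership
  ord <- names(sort(heme26, decreasing = TRUE))
  expect_setequal(attr(rl, "bloody_pool"), ord[1:7])
  expect_setequal(attr(rl, "clean_pool"), ord[20:26])

  csf8 <- make_csf(8)
  heme8 <- setNames(runif(8), sample_ids(csf8))
  rl8 <- pooled_bloodiness_list(csf8, heme8,
                                microdialysate_universe = sprintf("m%02d", 1:20))
  expect_length(attr(rl8, "bloody_pool"), 2)
  expect_length(attr(rl8, "clean_pool"), 2)
  expect_error(pooled_bloodiness_list(make_csf(7),
                                      setNames(runif(7), sprintf("c%02d", 1:7)),
                                      microdialysate_universe = sprintf("m%02d", 1:20)),
               "at least 8", class = "microdialysR_validation_error")

  heme_tied <- heme8; heme_tied[] <- c(9, 5, 5, 5, 5, 5, 1, 1)
  expect_warning(pooled_bloodiness_list(csf8, heme_tied,
                                        microdialysate_universe = sprintf("m%02d", 1:20)),
                 "tie")
})

test_that("generator ground truth: plasma metabolites top the bloodiness lists", {
  fx <- get_fixture()
  filt <- get_fixture_filtered()
  csf_norm <- median_normalize(fx$csf)
  universe <- metabolite_ids(filt)
  paired <- paired_bloodiness_list(csf_norm, "csf_paired_bloody",
                                   "csf_paired_clean", universe)
  pooled <- pooled_bloodiness_list(
    csf_norm, fx$heme, exclude = c("csf_paired_bloody", "csf_paired_clean"),
    microdialysate_universe = universe)
  truth <- fx$truth$metabolites
  plasma <- truth$metabolite[truth$class == "plasma_derived"]
  for (rl in list(paired, pooled)) {
    top_decile <- rl$metabolite[seq_len(ceiling(nrow(rl) / 10))]
    # plasma-derived metabolites dominate the bloody end
    expect_gt(mean(top_decile %in% plasma), 0.8)
    in_ranks <- rl$rank[rl$metabolite %in% plasma]
    out_ranks <- rl$rank[!rl$metabolite %in% plasma]
    expect_lt(stats::wilcox.test(in_ranks, out_ranks)$p.value, 1e-6)
  }

  # paired and pooled constructions agree on top-quartile membership
  q <- ceiling(nrow(paired) / 4)
  top_paired <- paired$metabolite[seq_len(q)]
  top_pooled <- pooled$metabolite[seq_len(ceiling(nrow(pooled) / 4))]
  jaccard <- length(intersect(top_paired, top_pooled)) /
    length(union(top_paired, top_pooled))
  expect_gte(jaccard, 0.5)
})

test_that("plasma enrichment flags contaminated numerator catheters", {
  fx <- get_fixture()
  filt <- get_fixture_filtered()
  csf_norm <- median_normalize(fx$csf)
  bloodiness <- paired_bloodiness_list(csf_norm, "csf_paired_bloody",
                                       "csf_paired_clean",
                                       metabolite_ids(filt))
  ann <- fx$annotation
  pr <- microdialysR:::contrast_pairs(ann[ann$sample_id %in% sample_ids(filt), ],
                                      "E", "NE")
  lists <- list()
  for (i in seq_len(nrow(pr)))
    lists[[pr$case_id[i]]] <- make_ranked_list(filt, pr$sample_a[i],
                                               pr$sample_b[i], annotation = ann)
  res <- plasma_enrichment(lists, bloodiness, n_permutations = 300, seed = 17)
  expect_equal(res$n_cases, length(lists))
  expect_equal(res$n_significant_either, res$n_cases)
  expect_true(all(res$table$nes[res$table$direction == "bloody_top"] > 0))

  # single-case input still yields a one-row summary
  single <- plasma_enrichment(lists[1], bloodiness, n_permutations = 200,
                              seed = 18)
  expect_equal(nrow(single$summary), 1L)
  expect_equal(nrow(single$table), 2L)
})

test_that("a shuffled bloodiness signature is not systematically enriched", {
  fx <- get_fixture()
  filt <- get_fixture_filtered()
  ann <- fx$annotation
  pr <- microdialysR:::contrast_pairs(ann[ann$sample_id %in% sample_ids(filt), ],
                                      "E", "NE")
  lists <- list()
  for (i in seq_len(nrow(pr)))
    lists[[pr$case_id[i]]] <- make_ranked_list(filt, pr$sample_a[i],
                                               pr$sample_b[i], annotation = ann)
  set.seed(19)
  shuffled <- ranked_list(setNames(2^rnorm(length(metabolite_ids(filt))),
                                   sample(metabolite_ids(filt))),
                          name = "shuffled")
  res <- plasma_enrichment(lists, shuffled, n_permutations = 300, seed = 20)
  expect_lte(mean(res$table$significant), 0.25)
})
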