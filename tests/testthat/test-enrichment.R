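make_list <- function(n, seed = 1, scores = NULL) {
  set.seed(seed)
  s <- scores %||% sort(rnorm(n, 0, 2), decreasing = TRUE)
  ranked_list(setNames(2^s, sprintf("m%03d", seq_len(n))))
}

test_that("top/bottom signature extraction slices the extremes", {
  rl <- make_list(162)
  sets <- build_sets_from_list(rl, k = 35)
  expect_length(sets$top$members, 35)
  expect_length(sets$bottom$members, 35)
  expect_length(intersect(sets$top$members, sets$bottom$members), 0)
  expect_identical(sets$top$members, rl$metabolite[1:35])
  expect_identical(sets$bottom$members, rl$metabolite[128:162])

  k1 <- build_sets_from_list(rl, k = 1)
  expect_identical(k1$top$members, rl$metabolite[1])
  expect_identical(k1$bottom$members, rl$metabolite[162])
  expect_error(build_sets_from_list(make_list(10), k = 6),
               class = "microdialysR_validation_error")

  # slice oracle: independent sort of fold changes
  set.seed(77)
  fc <- setNames(exp(rnorm(60)), sprintf("x%02d", 1:60))
  rl2 <- ranked_list(fc)
  s2 <- build_sets_from_list(rl2, k = 10)
  ord <- names(sort(fc, decreasing = TRUE))
  expect_setequal(s2$top$members, ord[1:10])
  expect_setequal(s2$bottom$members, ord[51:60])
})

test_that("enrichment score hits +1/-1 at the extremes and the worked example", {
  rl <- make_list(40)
  top5 <- metabolite_set("t", rl$metabolite[1:5])
  bottom5 <- metabolite_set("b", rl$metabolite[36:40])
  expect_equal(enrichment_score(rl, top5, p = 1)$es, 1)
  expect_equal(enrichment_score(rl, bottom5, p = 1)$es, -1)

  # N=10, scores 10..1, p=1, hits {1,5,10}: N_R=16... sum(|10,6,1|)=17,
  # peak right after position 1 at 10/17
  rl10 <- ranked_list(setNames(2^(10:1), paste0("m", 1:10)))
  s <- metabolite_set("s", rl10$metabolite[c(1, 5, 10)])
  r <- enrichment_score(rl10, s, p = 1)
  expect_equal(r$es, 10 / 17)
  expect_equal(r$hit_positions, c(1L, 5L, 10L))
  expect_equal(r$n_set_in_list, 3L)
})

test_that("enrichment score agrees with the O(N) running-sum oracle to 1e-12", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(10:200, 1)
    rl <- make_list(n, seed = 1000 + i)
    n_hit <- sample(2:min(20, n - 1), 1)
    hit <- sort(sample(n, n_hit))
    set <- metabolite_set("s", rl$metabolite[hit])
    for (p in c(0, 1, 1.5)) {
      r <- enrichment_score(rl, set, p = p)
      expect_equal(r$es, oracle_enrichment_score(rl$rank_score, hit, p),
                   tolerance = 1e-12)
      expect_gte(r$es, -1); expect_lte(r$es, 1)
    }
  }
})

test_that("the fast permutation path equals the full profile computation", {
  set.seed(55)
  for (i in 1:50) {
    n <- sample(15:150, 1)
    rl <- make_list(n, seed = 2000 + i)
    aw <- abs(rl$rank_score)
    hit <- sort(sample(n, sample(2:12, 1)))
    expect_equal(microdialysR:::es_from_positions(hit, aw, n),
                 oracle_enrichment_score(rl$rank_score, hit, 1),
                 tolerance = 1e-12)
  }
})

test_that("reversing the list negates the enrichment score exactly", {
  set.seed(33)
  rl <- make_list(80, seed = 33)
  hit <- sort(sample(80, 12))
  set <- metabolite_set("s", rl$metabolite[hit])
  fwd <- enrichment_score(rl, set, p = 1)$es
  rev_rl <- ranked_list(setNames(1 / rl$fold_change, rl$metabolite))
  rev_es <- enrichment_score(rev_rl, set, p = 1)$es
  expect_equal(rev_es, -fwd, tolerance = 1e-12)
})

test_that("with p=0 the score ignores magnitudes; zero-score hits fall back", {
  n <- 50
  s1 <- sort(rnorm(n, 0, 1), decreasing = TRUE)
  rl1 <- ranked_list(setNames(2^s1, sprintf("m%03d", 1:n)))
  rl2 <- ranked_list(setNames(2^(s1 * 10 + sign(s1)), sprintf("m%03d", 1:n)))
  set <- metabolite_set("s", rl1$metabolite[c(2, 9, 20, 44)])
  expect_equal(enrichment_score(rl1, set, p = 0)$es,
               enrichment_score(rl2, set, p = 0)$es)

  # all hit scores zero under p=1: falls back to p=0 and records it
  fc <- c(a = 4, b = 1, c = 1, d = 0.25)
  rl3 <- ranked_list(fc)
  zset <- metabolite_set("z", c("b", "c"))
  r <- enrichment_score(rl3, zset, p = 1)
  expect_true(r$fallback_p0)
  expect_equal(r$weighting_exponent, 0)
  expect_error(enrichment_score(rl3, metabolite_set("none", "zzz")),
               class = "microdialysR_validation_error")
})

test_that("permutation null gives deterministic NES and calibrated p", {
  rl <- make_list(100, seed = 404)
  top <- metabolite_set("top", rl$metabolite[1:10])
  r1 <- permutation_null(rl, top, p = 1, n_permutations = 500, seed = 42)
  r2 <- permutation_null(rl, top, p = 1, n_permutations = 500, seed = 42)
  expect_identical(r1$nes, r2$nes)
  expect_identical(r1$null_es, r2$null_es)
  expect_gt(r1$nes, 1)
  expect_lt(r1$p_nominal, 0.05)
  expect_error(permutation_null(rl, top, p = 1, n_permutations = 10),
               "seed", class = "microdialysR_validation_error")

  # degenerate zero score: symmetric list, set perfectly interleaved
  sc <- c(5, 4, 3, 2, 1, -1, -2, -3, -4, -5)
  rl0 <- ranked_list(setNames(2^sc, paste0("m", 1:10)))
  mirror <- metabolite_set("m", paste0("m", 1:10))  # whole list as set
  r0 <- enrichment_score(rl0, mirror, p = 0)
  expect_equal(r0$es, 1)  # all hits, no misses: sum climbs to 1
})

test_that("a middling random set is not significant", {
  rl <- make_list(120, seed = 500)
  set.seed(9)
  rand <- metabolite_set("r", sample(rl$metabolite, 15))
  r <- permutation_null(rl, rand, p = 1, n_permutations = 500, seed = 11)
  expect_gt(r$p_nominal, 0.05)
  expect_lt(abs(r$nes), 2)
})

test_that("FDR q-values floor, monotonize, and respect symmetry", {
  rl <- make_list(150, seed = 321)
  sets <- c(list(metabolite_set("strong", rl$metabolite[1:20])),
            lapply(1:6, function(i) {
              set.seed(600 + i)
              metabolite_set(paste0("rand", i), sample(rl$metabolite, 20))
            }))
  res <- lapply(seq_along(sets), function(i)
    permutation_null(rl, sets[[i]], p = 1, n_permutations = 400,
                     seed = 1000 + i))
  res <- fdr_across_sets(res)
  tab <- enrichment_table(res)
  strong <- tab[tab$set == "strong", ]
  expect_equal(strong$fdr_q_raw, 0)
  expect_equal(strong$fdr_q, 1e-5)   # display floor for a zero estimate

  # monotone: among same-sign results, larger |NES| never has larger q
  for (s in c(-1, 1)) {
    sub <- tab[sign(tab$nes) == s, ]
    if (nrow(sub) >= 2) {
      sub <- sub[order(-abs(sub$nes)), ]
      expect_true(all(diff(sub$fdr_q_raw) >= -1e-12))
    }
  }

  # duplicated identical result gets the identical q
  dup <- fdr_across_sets(list(res[[1]], res[[1]], res[[2]]))
  expect_equal(dup[[1]]$fdr_q, dup[[2]]$fdr_q)

  # single result falls back to the nominal p
  single <- fdr_across_sets(res[1])
  expect_equal(single[[1]]$fdr_q, single[[1]]$p_nominal)
})

test_that("enrichment matches fgsea on random instances (independent route)", {
  skip_if_not_installed("fgsea")
  set.seed(808)
  for (i in 1:20) {
    n <- sample(50:150, 1)
    rl <- make_list(n, seed = 3000 + i)
    hit <- sort(sample(n, 15))
    set <- metabolite_set("s", rl$metabolite[hit])
    mine <- enrichment_score(rl, set, p = 1)$es
    ref <- fgsea::calcGseaStat(setNames(rl$rank_score, rl$metabolite),
                               selectedStats = hit, gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("cross-case matrix excludes the diagonal by default", {
  lists <- list(c1 = make_list(60, seed = 1), c2 = make_list(60, seed = 2))
  for (nm in names(lists)) attr(lists[[nm]], "name") <- nm
  sets <- lapply(lists, build_sets_from_list, k = 10)
  m <- cross_case_enrichment_matrix(lists, sets, n_permutations = 200, seed = 5)
  expect_equal(nrow(m$table), 4L)  # 2 sets x 1 other case each... 2 cases x 2 sides
  expect_true(all(is.na(m$nes[c("c1_top", "c1_bottom"), "c1"])))
  expect_true(all(is.na(m$nes[c("c2_top", "c2_bottom"), "c2"])))

  single <- cross_case_enrichment_matrix(lists["c1"], sets["c1"],
                                         n_permutations = 100, seed = 5)
  expect_equal(length(single$results), 0L)
})
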