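make_profile_result <- function(pcts, seed = 1L) {
  # minimal bamqc_result-shaped object for feature-matrix tests
  set.seed(seed)
  structure(list(
    categories = tibble::tibble(stratum = "overall", category = names(pcts),
                                n = 100L, pct = unname(pcts)),
    per_cycle = tibble::tibble(stratum = "overall", cycle = 1:4,
                               n_aligned_reads = 10L, n_mismatch = 1L,
                               subst_rate = 1, mean_mm_qual = 20),
    rmc = tibble::tibble(stratum = "overall", bin = c("0", "1"),
                         n = c(6L, 4L), pct = c(60, 40)),
    distributions = list(
      insert_size = tibble::tibble(insert = c(300L, 310L), n = c(8L, 2L)),
      gc_content = tibble::tibble(gc_pct = 50L, n = 10L),
      mapq = tibble::tibble(mapq = 60L, n = 10L))), class = "bamqc_result")
}

uniform_pcts <- setNames(rep(100 / 12, 12),
                         c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T",
                           "G>A", "G>C", "G>T", "T>A", "T>C", "T>G"))

test_that("feature matrix rows are per-sample proportions over unioned bins", {
  r1 <- make_profile_result(uniform_pcts)
  r2 <- make_profile_result(uniform_pcts)
  fm <- build_feature_matrix(list(a = r1, b = r2), "substitution_categories")
  expect_equal(unlist(fm[1, -1]), unlist(fm[2, -1]))
  expect_equal(sum(unlist(fm[1, -1])), 100, tolerance = 1e-9)
  # point-mass insert distribution
  r3 <- make_profile_result(uniform_pcts)
  r3$distributions$insert_size <- tibble::tibble(insert = 300L, n = 50L)
  fm2 <- build_feature_matrix(list(a = r1, b = r3), "insert_size")
  expect_equal(fm2[["300"]][2], 100)
  expect_equal(fm2[["310"]][2], 0)   # absent bin filled with 0
  expect_equal(sum(unlist(fm2[2, -1])), 100, tolerance = 1e-9)
  expect_error(build_feature_matrix(list(a = r1), "insert_size"), "at least 2")
})

test_that("Ward clustering recovers duplicated groups and is permutation-equivariant", {
  r_a <- make_profile_result(uniform_pcts)
  shifted <- uniform_pcts
  shifted["C>A"] <- shifted["C>A"] + 5
  r_b <- make_profile_result(100 * shifted / sum(shifted))
  rs <- list(a1 = r_a, a2 = r_a, b1 = r_b, b2 = r_b)
  fm <- build_feature_matrix(rs, "substitution_categories")
  cl <- hcluster(fm, k = 2)
  a <- setNames(cl$assignments$cluster, cl$assignments$sample)
  expect_equal(a[["a1"]], a[["a2"]])
  expect_equal(a[["b1"]], a[["b2"]])
  expect_false(a[["a1"]] == a[["b1"]])
  # identical rows merge at height zero
  fm0 <- build_feature_matrix(list(x = r_a, y = r_a, z = r_a), "substitution_categories")
  expect_equal(max(hcluster(fm0, k = 1)$hclust$height), 0)
  expect_error(hcluster(fm, k = 10), "exceed")
  # permuting sample order permutes assignments identically
  fm_perm <- fm[c(3, 1, 4, 2), ]
  cl2 <- hcluster(fm_perm, k = 2)
  a2 <- setNames(cl2$assignments$cluster, cl2$assignments$sample)
  expect_true(all((a[names(a2)] == a[["a1"]]) == (a2 == a2[["a1"]])))
})

test_that("pair deviation is the signed complement-pair difference", {
  pd <- pair_deviation(c("C>A" = 6.8, "G>T" = 8.6))
  row <- pd[pd$pair == "C>A:G>T", ]
  expect_equal(row$deviation, -1.8)          # i.e. G>T exceeds C>A by 1.8
  # complement-symmetric profile has all-zero deviations
  pd0 <- pair_deviation(uniform_pcts)
  expect_equal(pd0$deviation, rep(0, 6))
  # swapping a profile with its complement flips every sign
  swapped <- uniform_pcts
  names(swapped) <- complement_category(names(uniform_pcts))
  jitter <- uniform_pcts + seq(-0.6, 0.5, by = 0.1)
  swapped_j <- setNames(jitter, complement_category(names(jitter)))
  expect_equal(pair_deviation(jitter)$deviation,
               -pair_deviation(swapped_j)$deviation)
  # zero-mismatch profile: NA deviations
  na_pd <- pair_deviation(setNames(rep(NA_real_, 12), names(uniform_pcts)))
  expect_true(all(is.na(na_pd$deviation)))
})

test_that("planted strand-specific excess is recovered by the deviation metric", {
  fx <- std_fixture()
  res <- std_bamqc()
  pd <- pair_deviation(res)
  # G>T was injected without a matching C>A source, so deviation(C>A:G>T) < 0
  expect_lt(pd$deviation[pd$pair == "C>A:G>T"], 0)
})

test_that("planted outlier group is recovered across seeded replicates", {
  hits <- vapply(1:25, function(s) {
    prof <- simulate_category_profiles(seed = s)
    cl <- hcluster(pair_deviation_matrix(prof), k = 2)
    truth <- unique(prof[, c("sample", "outlier")])
    a <- cl$assignments$cluster[match(truth$sample, cl$assignments$sample)]
    all(a[truth$outlier] == a[truth$outlier][1]) &&
      all(a[!truth$outlier] == a[!truth$outlier][1]) &&
      a[truth$outlier][1] != a[!truth$outlier][1]
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("Dixon Q matches the hand-computed ratio and published criticals", {
  dt <- dixon_test(c(2.1, 2.2, 2.3, 2.4, 9.9), alpha = 0.05)
  expect_equal(dt$statistic, (9.9 - 2.4) / (9.9 - 2.1), tolerance = 1e-12)
  expect_equal(dt$flagged, 5L)
  expect_equal(dt$variant, "r10")
  # classical two-sided r10 critical values (n = 3..7, alpha 0.05)
  published <- c(`3` = 0.970, `4` = 0.829, `5` = 0.710, `6` = 0.628, `7` = 0.569)
  for (n in names(published)) {
    got <- dixon_test(seq_len(as.integer(n)), alpha = 0.05)$critical
    expect_equal(got, unname(published[n]), tolerance = 0.005)
  }
  expect_true(is.na(dixon_test(rep(1, 5))$flagged))   # zero range
  expect_error(dixon_test(1:2), "at least 3")
  expect_error(dixon_test(1:31), "different test")
  expect_error(dixon_test(1:5, alpha = 0.037), "alpha")
})

test_that("Dixon agrees with a brute-force transcription on random vectors", {
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(3:30, 1)
    x <- rnorm(n)
    if (runif(1) < 0.3) x[sample(n, 1)] <- x[sample(n, 1)] + 5  # plant outlier
    dt <- dixon_test(x, alpha = 0.05)
    expect_equal(dt$statistic, brute_dixon_q(x), tolerance = 1e-12)
    expect_identical(!is.na(dt$flagged), dt$statistic > dt$critical)
  }
})

test_that("cycle-spike detection flags exactly the planted cycles", {
  flat <- tibble::tibble(stratum = "overall", cycle = 1:100,
                         n_aligned_reads = 1000L, n_mismatch = 10L,
                         subst_rate = 1 + 0.001 * sin(1:100),
                         mean_mm_qual = 20)
  expect_length(detect_cycle_spikes(flat), 0L)
  spiked <- flat
  spiked$subst_rate[62] <- 3 * spiked$subst_rate[62]
  expect_equal(detect_cycle_spikes(spiked), 62L)
  multi <- flat
  multi$subst_rate[c(20, 52, 65, 96)] <- multi$subst_rate[c(20, 52, 65, 96)] + 2
  expect_equal(detect_cycle_spikes(multi), c(20L, 52L, 65L, 96L))
})

test_that("batch comparison aligns bin grids and respects identity", {
  r1 <- make_profile_result(uniform_pcts)
  bc <- batch_compare(list(s1 = r1, s2 = r1), list(s1 = r1, s2 = r1))
  ov <- bc$overlays
  a <- dplyr::filter(ov, group == "A") |> dplyr::arrange(sample, feature, bin)
  b <- dplyr::filter(ov, group == "B") |> dplyr::arrange(sample, feature, bin)
  expect_equal(a$value, b$value)
  # singleton groups give two single-series overlays
  bc2 <- batch_compare(list(only = r1), list(other = r1),
                       features = "substitution_categories")
  expect_equal(dplyr::n_distinct(bc2$overlays$sample), 2L)
  expect_error(batch_compare(list(), list(a = r1)), "non-empty")
  expect_s3_class(autoplot(bc), "ggplot")
})

test_that("multisample wrapper flags the Dixon outlier sample", {
  rs <- lapply(1:10, function(i) {
    p <- uniform_pcts + rnorm(12, 0, 0.05)
    if (i == 10) { p["G>T"] <- p["G>T"] + 3; p["C>A"] <- p["C>A"] - 3 }
    make_profile_result(100 * p / sum(p), seed = i)
  })
  names(rs) <- paste0("s", 1:10)
  ms <- multisample_qc(rs, k = 2, alpha = 0.01)
  expect_true("s10" %in% ms$outliers$sample)
  expect_equal(sort(unique(ms$cluster$assignments$cluster)), 1:2)
})
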