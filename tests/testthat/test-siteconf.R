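test_that("homopolymer runs follow the reference definitions", {
  ref <- "GGAAAAAACCT"
  hp <- homopolymer_runs(ref, 5, "C")   # inside the A-run
  expect_equal(hp$ref_run, 6L)
  expect_equal(hp$alt_run, 0L)
  hp2 <- homopolymer_runs(ref, 9, "A")  # C at 9, A-run of 6 to the left
  expect_equal(hp2$ref_run, 2L)
  expect_equal(hp2$alt_run, 6L)
  hp3 <- homopolymer_runs("AAAAAA", 3, "T")
  expect_equal(hp3$ref_run, 6L)
})

test_that("clean and noisy sites yield their planted feature values", {
  fx <- std_fixture()
  truth <- fx$truth$reads
  # pick positions covered only by regular error-free reads
  sites <- tibble::tibble(chrom = "chr1", pos = c(2500L, 12000L),
                          ref = "A", alt = "G",
                          label = c("benchmark", "non_benchmark"),
                          zygosity = c("het", "hom"))
  ft <- extract_site_features(fx$bam, fx$fasta, sites)
  expect_equal(nrow(ft), 2L)
  expect_true(all(ft$covered))
  expect_true(all(ft$mean_mapq == 60))
  expect_true(all(ft$frac_mapq0 == 0))
  # feature values equal direct aggregation over the truth reads at the site
  for (i in 1:2) {
    p <- sites$pos[i]
    over <- truth[truth$chrom == "chr1" & truth$pos <= p &
                    truth$pos + truth$ref_span - 1L >= p, ]
    expect_equal(ft$depth[i], nrow(over))
    expect_equal(ft$mean_mismatch[i], mean(over$n_mismatch), tolerance = 1e-9)
  }
  # zero-coverage site
  ft0 <- extract_site_features(fx$bam, fx$fasta,
                               tibble::tibble(chrom = "chr2", pos = 50L,
                                              ref = "A", alt = "C"))
  expect_false(ft0$covered)
  expect_true(is.na(ft0$mean_mismatch))
})

test_that("shuffled labels give chance-level accuracy", {
  set.seed(2026)
  ft <- simulate_bayes_sites(2000, 0.8, seed = 21)
  ft$label <- sample(ft$label)
  fit <- fit_classifier(ft, seed = 7)
  acc <- fit$accuracy$accuracy[fit$accuracy$class == "overall"]
  expect_gt(acc, 45)
  expect_lt(acc, 55)
})

test_that("separable classes reach perfect test accuracy", {
  n <- 400
  ft <- tibble::tibble(
    mean_mismatch = c(rnorm(n / 2, 0, 0.1), rnorm(n / 2, 10, 0.1)),
    label = rep(c("benchmark", "non_benchmark"), each = n / 2))
  fit <- suppressWarnings(fit_classifier(ft, seed = 3))
  expect_equal(fit$accuracy$accuracy[fit$accuracy$class == "overall"], 100)
})

test_that("planted 80 percent Bayes rate is recovered on held-out data", {
  ft <- simulate_bayes_sites(10000, 0.8, seed = 5)
  fit <- fit_classifier(ft, seed = 7)
  acc <- fit$accuracy$accuracy[fit$accuracy$class == "overall"]
  expect_gt(acc, 77)
  expect_lt(acc, 83)
  # per-zygosity accuracies are reported and consistent
  expect_setequal(fit$accuracy$class, c("overall", "het", "hom"))
  expect_equal(sum(fit$confusion), fit$split$n_test)
})

test_that("known logistic coefficients are recovered within 10 percent", {
  beta <- c(mean_mismatch = 0.9, frac_clipped = -1.3, mean_indel = 0.6)
  ft <- simulate_logistic_sites(20000, beta, intercept = 0.4, seed = 11)
  fit <- fit_classifier(ft, seed = 7)
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  for (nm in names(beta)) {
    expect_lt(abs(est[[nm]] - beta[[nm]]) / abs(beta[[nm]]), 0.10)
  }
  expect_lt(abs(est[["(Intercept)"]] - 0.4), 0.1)
})

test_that("fits are deterministic given inputs and seed", {
  ft <- simulate_bayes_sites(3000, 0.8, seed = 9)
  f1 <- fit_classifier(ft, seed = 13)
  f2 <- fit_classifier(ft, seed = 13)
  expect_equal(f1$coefficients, f2$coefficients)
  expect_equal(f1$accuracy, f2$accuracy)
})

test_that("site scoring is a monotone sigmoid of the linear predictor", {
  ft <- simulate_bayes_sites(3000, 0.85, seed = 4)
  fit <- fit_classifier(ft, seed = 7)
  # all-zero features score exactly sigmoid(intercept)
  zero <- tibble::tibble(signal = 0, noise1 = 0, noise2 = 0)
  sc <- classify_sites(fit, zero)
  expect_equal(sc$p_low_confidence,
               stats::plogis(fit$coefficients$estimate[
                 fit$coefficients$term == "(Intercept)"]))
  # probability is monotone in a positive-coefficient feature
  co <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  grid <- tibble::tibble(signal = seq(-3, 3, length.out = 11),
                         noise1 = 0, noise2 = 0)
  p <- classify_sites(fit, grid)$p_low_confidence
  if (co[["signal"]] > 0) expect_true(all(diff(p) > 0)) else
    expect_true(all(diff(p) < 0))
  expect_error(classify_sites(fit, tibble::tibble(bogus = 1)), "schema")
})

test_that("degenerate label inputs are rejected", {
  ft <- simulate_bayes_sites(200, 0.8, seed = 2)
  ft$label <- "benchmark"
  expect_error(fit_classifier(ft), "two levels")
  small <- simulate_bayes_sites(30, 0.8, seed = 2)
  expect_error(fit_classifier(small), "50")
})
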