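test_that("error-free fixture yields zero error rate and all-zero-mismatch reads", {
  fx <- clean_fixture()
  res <- bamqc(fx$bam, fx$fasta)
  expect_equal(res$summary$error_rate_per_base, 0)
  rmc0 <- dplyr::filter(res$rmc, stratum == "overall", bin == "0")
  expect_equal(rmc0$pct, 100)
  expect_equal(as.numeric(res$counts["kept"]), as.numeric(res$counts["mapped"]))
})

test_that("injected counters are recovered exactly from the truth table", {
  fx <- std_fixture()
  res <- std_bamqc()
  vr <- verify_truth(res, fx)
  expect_true(vr$pass)
  expect_equal(nrow(vr$diffs), 0L)
})

test_that("conservation identities hold across feature families and strata", {
  res <- std_bamqc()
  total <- as.integer(res$summary$total_mismatches)
  per_cycle_total <- sum(res$per_cycle$n_mismatch[res$per_cycle$stratum == "overall"])
  cat_total <- sum(res$categories$n[res$categories$stratum == "overall"])
  rmc_total <- with(dplyr::filter(res$rmc_raw, stratum == "overall"), sum(k * n))
  qb_total <- sum(res$qual_bins$n[res$qual_bins$stratum == "overall"])
  expect_equal(per_cycle_total, total)
  expect_equal(cat_total, total)
  expect_equal(rmc_total, total)
  expect_equal(qb_total, total)   # every mismatch has a binned quality
  # orientation strata partition the overall counts
  by_strat <- res$per_cycle |>
    dplyr::group_by(stratum) |>
    dplyr::summarise(n = sum(n_mismatch))
  expect_equal(sum(by_strat$n[by_strat$stratum != "overall"]),
               by_strat$n[by_strat$stratum == "overall"])
  cov_strat <- res$per_cycle |>
    dplyr::group_by(stratum) |>
    dplyr::summarise(n = sum(n_aligned_reads))
  expect_equal(sum(cov_strat$n[cov_strat$stratum != "overall"]),
               cov_strat$n[cov_strat$stratum == "overall"])
})

test_that("percentage tables sum to 100 where defined", {
  res <- std_bamqc()
  cats <- dplyr::filter(res$categories, stratum == "overall")
  expect_equal(sum(cats$pct), 100, tolerance = 1e-9)
  rmc <- dplyr::filter(res$rmc, stratum == "overall")
  expect_equal(sum(rmc$pct), 100, tolerance = 1e-9)
  ctx_sums <- res$context |>
    dplyr::filter(stratum == "overall") |>
    dplyr::group_by(category) |>
    dplyr::summarise(n = sum(n), pct = sum(pct)) |>
    dplyr::filter(n > 0)
  expect_true(all(abs(ctx_sums$pct - 100) < 1e-9))
  pcc <- res$per_cycle_category |>
    dplyr::filter(stratum == "overall") |>
    dplyr::group_by(cycle) |>
    dplyr::summarise(n = sum(n), pct = sum(pct)) |>
    dplyr::filter(n > 0)
  expect_true(all(abs(pcc$pct - 100) < 1e-9))
})

test_that("planted cycle-10 C>T spike dominates its cycle's spectrum", {
  fx <- std_fixture()
  res <- std_bamqc()
  truth_c10 <- fx$truth$events |>
    dplyr::filter(cycle == 10, category == "C>T") |>
    nrow()
  obs <- res$per_cycle_category |>
    dplyr::filter(stratum == "overall", cycle == 10, category == "C>T")
  expect_equal(obs$n, truth_c10)
  den <- res$per_cycle |>
    dplyr::filter(stratum == "overall", cycle == 10)
  expect_equal(den$subst_rate, 100 * den$n_mismatch / den$n_aligned_reads)
  # C>T carries the bulk of cycle 10 (background G>T is 1%-per-site scale)
  expect_gt(obs$pct, 50)
})

test_that("orientation-restricted context rule lands only in its stratum", {
  res <- std_bamqc()
  ag <- res$per_cycle_category |>
    dplyr::filter(category == "A>G", cycle %in% c(20L, 52L), stratum != "overall")
  expect_true(all(ag$n[ag$stratum != "R2F"] == 0L))
  expect_true(sum(ag$n[ag$stratum == "R2F"]) > 0L)
  ctx <- res$context |>
    dplyr::filter(stratum == "R2F", category == "A>G")
  expect_equal(ctx$context[which.max(ctx$n)], "G_G")
})

test_that("quality bins separate low-quality error bases from the baseline", {
  res <- std_bamqc()
  qb <- res$qual_bins |>
    dplyr::filter(stratum == "overall") |>
    dplyr::group_by(bin) |>
    dplyr::summarise(n = sum(n))
  # injected error bases are drawn around Q12 (bins 0-10 / 11-20)
  low <- sum(qb$n[qb$bin %in% c("0-10", "11-20")])
  expect_gt(low / sum(qb$n), 0.8)
})

test_that("common metrics match fixture construction", {
  fx <- std_fixture()
  res <- std_bamqc()
  truth <- fx$truth
  expect_equal(as.numeric(res$counts["total"]), nrow(truth$reads))
  expect_equal(res$summary$mean_read_length, mean(nchar(truth$reads$seq)))
  # insert-size histogram covers proper-pair read1 |TLEN| values only
  ins <- res$distributions$insert_size
  tr_ins <- truth$reads |>
    dplyr::filter(proper, read1)
  expect_equal(sum(ins$n), nrow(tr_ins))
  expect_equal(sort(unique(ins$insert[ins$n > 0])),
               sort(unique(pmin(abs(tr_ins$tlen), 2001L))))
  # indel length distributions equal the planted ones
  expect_equal(sum(res$distributions$del_len$n),
               sum(truth$indels$type == "del"))
  expect_equal(sum(res$distributions$ins_len$n),
               sum(truth$indels$type == "ins"))
  # strand ratio equals the truth-table forward/reverse split
  expect_equal(res$summary$strand_ratio,
               sum(!truth$reads$reverse) / sum(truth$reads$reverse))
})

test_that("per-cycle quality correlation recovers a planted linear trend", {
  # rate rises and error-base quality falls linearly with cycle
  rules <- lapply(seq(10, 90, by = 10), function(c) {
    error_rule("C>T", rate = 0.01 + 0.002 * c, cycles = c,
               qual_mean = 35 - 0.25 * c)
  })
  spec <- fixture_spec(seed = 33, n_pairs = 4000, ref_length = 60000,
                       read_length = 100, error_rules = rules)
  fx <- simulate_bam(spec, withr::local_tempdir())
  res <- bamqc(fx$bam, fx$fasta)
  r <- per_cycle_quality_correlation(res)
  # closed form from the planted series: rate and quality are both linear
  # in cycle, so the planted correlation is -1; sampling noise perturbs it
  expect_lt(r, -0.9)
  expect_gte(r, -1)
})

test_that("correlation degenerates to NA without variation or cycles", {
  pc <- tibble::tibble(stratum = "overall", cycle = 1:5,
                       n_aligned_reads = 100L, n_mismatch = c(1L, 2L, 0L, 0L, 0L),
                       subst_rate = c(1, 2, 0, 0, 0), mean_mm_qual = 20)
  res <- structure(list(per_cycle = pc), class = "bamqc_result")
  expect_true(is.na(per_cycle_quality_correlation(res)))  # <3 usable cycles
  pc2 <- dplyr::mutate(pc, n_mismatch = 1L, mean_mm_qual = 25)
  res2 <- structure(list(per_cycle = pc2), class = "bamqc_result")
  expect_true(is.na(per_cycle_quality_correlation(res2)))  # zero variance
})

test_that("logs round-trip with exact counter equality", {
  res <- std_bamqc()
  outdir <- withr::local_tempdir()
  write_bamqc_logs(res, outdir)
  back <- read_bamqc_logs(outdir)
  expect_equal(back$per_cycle$n_mismatch, res$per_cycle$n_mismatch)
  expect_equal(back$per_cycle$n_aligned_reads, res$per_cycle$n_aligned_reads)
  expect_equal(back$categories$n, res$categories$n)
  expect_equal(back$qual_bins$n, res$qual_bins$n)
  expect_equal(back$context$n, res$context$n)
  expect_equal(back$rmc_raw$n, res$rmc_raw$n)
  expect_equal(as.numeric(back$counts), as.numeric(res$counts))
  expect_equal(back$distributions$insert_size$n, res$distributions$insert_size$n)
  # per-cycle TSV has one row per cycle and stratum
  pc <- readr::read_tsv(file.path(outdir, "logs", "per_cycle.tsv"),
                        show_col_types = FALSE)
  expect_equal(nrow(pc), 5L * res$meta$read_length)
})

test_that("HTML report is self-contained with one section per family", {
  res <- std_bamqc()
  outdir <- withr::local_tempdir()
  render_bamqc_report(res, outdir)
  html <- readLines(file.path(outdir, "report.html"), warn = FALSE)
  txt <- paste(html, collapse = "\n")
  for (h in c("Summary", "Per-cycle substitution rate",
              "Substitution categories", "Read-mismatch-content",
              "Insert size distribution")) {
    expect_match(txt, h, fixed = TRUE)
  }
  expect_match(txt, "data:image/png;base64", fixed = TRUE)
  # zero-mismatch result gets explicit placeholders
  fx <- clean_fixture()
  res0 <- bamqc(fx$bam, fx$fasta)
  out0 <- withr::local_tempdir()
  render_bamqc_report(res0, out0)
  txt0 <- paste(readLines(file.path(out0, "report.html"), warn = FALSE),
                collapse = "\n")
  expect_match(txt0, "no mismatches observed", fixed = TRUE)
})

test_that("tidy and glance expose the result tables", {
  res <- std_bamqc()
  expect_s3_class(tidy(res, "per_cycle"), "tbl_df")
  expect_s3_class(tidy(res, "dist_insert_size"), "tbl_df")
  expect_error(tidy(res, "nope"), "unknown")
  g <- glance(res)
  expect_equal(nrow(g), 1L)
  expect_equal(g$n_kept, as.numeric(res$counts["kept"]))
})
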