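test_that("reference generation is seeded, GC-targeted and indexed", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  spec <- fixture_spec(seed = 7, ref_length = 10000, gc_target = 0.5)
  make_reference(spec, dir1); make_reference(spec, dir2)
  s1 <- readLines(file.path(dir1, "ref.fa"))
  s2 <- readLines(file.path(dir2, "ref.fa"))
  expect_identical(s1, s2)
  expect_true(file.exists(file.path(dir1, "ref.fa.fai")))
  ref <- read_reference(file.path(dir1, "ref.fa"))
  gc <- mean(strsplit(ref$chr1, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 0.01)
  # boundary GC target
  dir3 <- withr::local_tempdir()
  make_reference(fixture_spec(seed = 1, ref_length = 2000, gc_target = 1), dir3)
  ref3 <- read_reference(file.path(dir3, "ref.fa"))
  expect_true(all(strsplit(ref3$chr1, "")[[1]] %in% c("G", "C")))
})

test_that("fixture specs validate their inputs", {
  expect_error(fixture_spec(ref_length = 50, read_length = 100), "ref_length")
  expect_error(fixture_spec(gc_target = 1.5), "gc_target")
  expect_error(fixture_spec(error_rules = list(error_rule("C>T", 2))), "rate")
  expect_error(fixture_spec(read_length = 100,
                            error_rules = list(error_rule("C>T", 0.1, cycles = 200L))),
               "cycles")
  expect_error(error_rule("C>X", 0.1), "category")
  expect_error(error_rule("C>T", 0.1, context = "GG"), "context")
  expect_error(fixture_spec(n_pairs = 5,
                            anomalies = list(n_long_insert = 10)) |>
                 simulate_bam(withr::local_tempdir()),
               "exceed")
  expect_error(fixture_spec(trap_region = list(start = 100, end = 50,
                                               excess_fold = 2)), "trap")
})

test_that("identical spec and seed reproduce identical record streams", {
  spec <- fixture_spec(seed = 55, n_pairs = 300, ref_length = 20000,
                       error_rules = list(error_rule("C>T", 0.02)),
                       anomalies = list(n_long_insert = 3))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- simulate_bam(spec, d1); f2 <- simulate_bam(spec, d2)
  expect_identical(readLines(file.path(d1, "sim.sam")),
                   readLines(file.path(d2, "sim.sam")))
  expect_equal(f1$truth$events, f2$truth$events)
  expect_equal(f1$truth$reads, f2$truth$reads)
})

test_that("zero error rules produce a mismatch-free BAM", {
  fx <- clean_fixture()
  ref <- read_reference(fx$fasta)
  rd <- fx$truth$reads
  set.seed(1)
  for (i in sample(nrow(rd), 25)) {
    ev <- walk_alignment(list(chrom = rd$chrom[i], pos = rd$pos[i],
                              flag = rd$flag[i], cigar = rd$cigar[i],
                              seq = rd$seq[i], qual = rd$qual[i]), ref)
    expect_equal(ev$n_mismatches, 0L)
  }
  expect_equal(nrow(fx$truth$events), 0L)
})

test_that("truth tables are internally consistent", {
  fx <- std_fixture()
  tr <- fx$truth
  # events aggregate to the per-read mismatch counts
  by_read <- table(tr$events$qname)
  for (qn in names(head(by_read, 20))) {
    rows <- tr$reads[tr$reads$qname == qn, ]
    expect_equal(sum(rows$n_mismatch), unname(by_read[[qn]]))
  }
  # per-cycle denominators sum to total aligned bases over cycles
  total_aligned <- sum(tr$per_cycle$n_aligned)
  span_sum <- sum(vapply(seq_len(nrow(tr$reads)), function(i) {
    cig <- parse_cigar(tr$reads$cigar[i])
    sum(cig$len[cig$op %in% c("M", "=", "X")])
  }, 0))
  expect_equal(total_aligned, span_sum)
  # every event's context matches the reference flanks
  ref <- read_reference(fx$fasta)
  ev <- head(tr$events, 50)
  for (i in seq_len(nrow(ev))) {
    expect_equal(substr(ref$chr1, ev$ref_pos[i] - 1, ev$ref_pos[i] - 1),
                 ev$flank5[i])
    expect_equal(substr(ref$chr1, ev$ref_pos[i] + 1, ev$ref_pos[i] + 1),
                 ev$flank3[i])
    expect_equal(substr(ref$chr1, ev$ref_pos[i], ev$ref_pos[i]), ev$ref_base[i])
  }
})

test_that("verify_truth localises an injected counter fault", {
  fx <- std_fixture()
  res <- std_bamqc()
  expect_true(verify_truth(res, fx)$pass)
  broken <- res
  i <- which(broken$per_cycle$stratum == "overall" & broken$per_cycle$cycle == 10)
  j <- which(broken$per_cycle_category$stratum == "R1F" &
               broken$per_cycle_category$cycle == 10 &
               broken$per_cycle_category$category == "C>T")
  broken$per_cycle_category$n[j] <- broken$per_cycle_category$n[j] + 1L
  vr <- verify_truth(broken, fx)
  expect_false(vr$pass)
  expect_equal(nrow(vr$diffs), 1L)
  expect_match(vr$diffs$counter, "per_cycle_category\\[10,R1F,C>T\\]")
})

test_that("trap region piles reads up at the configured excess", {
  spec <- fixture_spec(seed = 17, n_pairs = 800, ref_length = 40000,
                       trap_region = list(start = 15000, end = 15800,
                                          excess_fold = 25))
  fx <- simulate_bam(spec, withr::local_tempdir())
  inside <- fixture_truth_depth(fx, "chr1", 15200, 15600)
  outside <- fixture_truth_depth(fx, "chr1", 5000, 5400)
  expect_gt(mean(inside$depth), 10 * max(mean(outside$depth), 0.5))
})
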