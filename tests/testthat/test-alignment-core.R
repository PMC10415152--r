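test_that("SAM flags decode to their named bits", {
  fs <- decode_flags(c(99, 4, 83, 147, 256 + 1024))
  expect_true(fs$paired[1] && fs$proper_pair[1] && fs$mate_reverse[1] && fs$read1[1])
  expect_false(fs$reverse[1] || fs$unmapped[1])
  expect_true(fs$unmapped[2])
  expect_true(fs$paired[3] && fs$proper_pair[3] && fs$reverse[3] && fs$read1[3])
  expect_true(fs$read2[4] && fs$reverse[4])
  expect_true(fs$secondary[5] && fs$duplicate[5])
  expect_error(decode_flags(-1), "65536")
  expect_error(decode_flags(70000), "65536")
})

test_that("orientation classes map read-pair and strand bits", {
  expect_equal(classify_orientation(c(99, 147, 83, 163)),
               c("R1F", "R2R", "R1R", "R2F"))
  expect_error(classify_orientation(0), "single-end")
  expect_error(classify_orientation(16), "single-end")
  # read1 and read2 both set is ambiguous
  expect_error(classify_orientation(1 + 64 + 128), "ambiguous")
})

test_that("cycle mapping mirrors reverse-strand reads", {
  expect_equal(cycle_of(0, 100, FALSE), 1L)
  expect_equal(cycle_of(0, 100, TRUE), 100L)
  expect_equal(cycle_of(99, 100, TRUE), 1L)
  expect_equal(cycle_of(0:9, 10, FALSE), 1:10)
  expect_equal(cycle_of(0:9, 10, TRUE), 10:1)
  expect_error(cycle_of(100, 100, FALSE), "out of range")
})

test_that("record filter keeps mapped primary pairs and names skip reasons", {
  #            keep  dup   secondary qcfail unmapped
  flags <- c(99L, 99L + 1024L, 99L + 256L, 99L + 512L, 4L + 1L + 64L)
  flt <- record_filter(flags, rep(60L, 5))
  expect_equal(flt$keep, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(flt$skip_reason[2:5],
               c("duplicate", "secondary", "qcfail", "unmapped"))
  # policy overrides
  flt2 <- record_filter(flags, rep(60L, 5), filter_policy(keep_duplicates = TRUE))
  expect_true(flt2$keep[2])
  flt3 <- record_filter(99L, 5L, filter_policy(min_mapq = 10))
  expect_equal(flt3$skip_reason, "low_mapq")
})

test_that("walk_alignment finds mismatches with cycle, flanks and category", {
  ref <- c(chr = "ACGTACGTAC")
  clean <- walk_alignment(list(chrom = "chr", pos = 1L, flag = 99L,
                               cigar = "10M", seq = "ACGTACGTAC",
                               qual = strrep("I", 10)), ref)
  expect_equal(clean$n_mismatches, 0L)
  expect_equal(clean$aligned_cycles, 1:10)

  one <- walk_alignment(list(chrom = "chr", pos = 1L, flag = 99L,
                             cigar = "10M", seq = "ACGTCCGTAC",
                             qual = strrep("I", 10)), ref)
  expect_equal(one$n_mismatches, 1L)
  mm <- one$mismatches
  expect_equal(mm$ref_pos, 5L)
  expect_equal(mm$cycle, 5L)
  expect_equal(mm$category, "A>C")
  expect_equal(mm$flank5, "T")
  expect_equal(mm$flank3, "C")
  expect_equal(mm$base_qual, 40L)
})

test_that("walk_alignment handles clips, deletions and cycle offsets", {
  ref <- c(chr = paste0(strrep("A", 10), "ACGTACGTA"))
  # 2S6M1D2M starting at pos 11: query = 2 clip + 8 aligned bases
  ev <- walk_alignment(list(chrom = "chr", pos = 11L, flag = 99L,
                            cigar = "2S6M1D2M", seq = "TTACGTACTA",
                            qual = strrep("I", 10)), ref)
  expect_equal(ev$clip5_len, 2L)
  expect_equal(ev$clip3_len, 0L)
  expect_equal(ev$deletions, 1L)
  expect_equal(ev$aligned_cycles, 3:10)
  # soft-clip of a reverse read: record-left clip is the read's 3' end
  ev2 <- walk_alignment(list(chrom = "chr", pos = 11L, flag = 83L,
                             cigar = "2S8M", seq = "TTACGTACGT",
                             qual = strrep("I", 10)), ref)
  expect_equal(ev2$clip3_len, 2L)
  expect_equal(ev2$clip5_len, 0L)
})

test_that("strand flip mirrors mismatch cycles but not genomic annotation", {
  ref <- c(chr = "ACGTACGTACGTACGTACGT")
  rd <- list(chrom = "chr", pos = 3L, flag = 99L, cigar = "12M",
             seq = "GTACCCGTACGT", qual = strrep("I", 12))
  fwd <- walk_alignment(rd, ref)
  rd$flag <- 83L
  rev <- walk_alignment(rd, ref)
  expect_equal(nrow(fwd$mismatches), nrow(rev$mismatches))
  expect_equal(fwd$mismatches$ref_pos, rev$mismatches$ref_pos)
  expect_equal(fwd$mismatches$ref_base, rev$mismatches$ref_base)
  expect_equal(fwd$mismatches$read_base, rev$mismatches$read_base)
  expect_equal(sort(13L - fwd$mismatches$cycle),
               sort(rev$mismatches$cycle))
})

test_that("walk_alignment rejects inconsistent records", {
  ref <- c(chr = "ACGTACGTAC")
  expect_error(walk_alignment(list(chrom = "nope", pos = 1L, flag = 99L,
                                   cigar = "4M", seq = "ACGT", qual = "IIII"),
                              ref), "nope")
  expect_error(walk_alignment(list(chrom = "chr", pos = 1L, flag = 99L,
                                   cigar = "5M", seq = "ACGT", qual = "IIII"),
                              ref), "length")
})

test_that("per-read length bookkeeping is conserved on the fixture", {
  fx <- std_fixture()
  rd <- std_fixture()$truth$reads
  ref <- read_reference(fx$fasta)
  set.seed(5)
  for (i in sample(nrow(rd), 50)) {
    ev <- walk_alignment(list(chrom = rd$chrom[i], pos = rd$pos[i],
                              flag = rd$flag[i], cigar = rd$cigar[i],
                              seq = rd$seq[i], qual = rd$qual[i]), ref)
    ins_bases <- sum(ev$insertions)
    expect_equal(ev$clip5_len + ev$clip3_len + length(ev$aligned_cycles) +
                   ins_bases, nchar(rd$seq[i]))
    expect_equal(ev$n_mismatches, rd$n_mismatch[i])
    expect_true(all(ev$mismatches$cycle %in% ev$aligned_cycles))
  }
})

test_that("mismatch counts agree with the MD-tag oracle per read", {
  fx <- std_fixture()
  md <- md_mismatch_counts(fx$bam, fx$fasta)
  truth <- std_fixture()$truth$reads
  key_md <- paste(md$qname, md$flag)
  key_tr <- paste(truth$qname, truth$flag)
  expect_setequal(key_md, key_tr)
  m <- match(key_tr, key_md)
  expect_equal(md$n_mm[m], truth$n_mismatch)
  # and the accumulated bamqc total equals the MD total
  res <- std_bamqc()
  expect_equal(sum(md$n_mm), as.integer(res$summary$total_mismatches))
})
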