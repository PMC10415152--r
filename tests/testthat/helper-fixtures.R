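# Shared fixtures and independent oracles, built once per test run.

.fx_cache <- new.env(parent = emptyenv())

# the standard mixed fixture used by most module tests
std_fixture <- function() {
  if (!is.null(.fx_cache$std)) return(.fx_cache$std)
  spec <- fixture_spec(
    seed = 101, n_pairs = 1500, ref_length = 50000, read_length = 100,
    error_rules = list(
      error_rule("C>T", 0.05, cycles = 10L),
      error_rule("G>T", 0.01),
      error_rule("A>G", 0.5, cycles = c(20L, 52L), orientations = "R2F",
                 context = "G_G")),
    indel_rules = list(list(type = "del", lengths = 1:3, n_reads = 40),
                       list(type = "ins", lengths = 1:2, n_reads = 25)),
    clip_rule = list(n_reads = 30, len = 10, end = "3p"),
    anomalies = list(n_long_insert = 12, n_interchrom = 5, n_ff = 3,
                     n_rr = 2, n_outward = 4))
  .fx_cache$std <- simulate_bam(spec, file.path(tempdir(), "alnqc-std-fx"))
  .fx_cache$std
}

std_bamqc <- function() {
  if (is.null(.fx_cache$std_res)) {
    fx <- std_fixture()
    .fx_cache$std_res <- bamqc(fx$bam, fx$fasta)
  }
  .fx_cache$std_res
}

# a tiny error-free fixture
clean_fixture <- function() {
  if (is.null(.fx_cache$clean)) {
    spec <- fixture_spec(seed = 7, n_pairs = 500, ref_length = 20000,
                         read_length = 100)
    .fx_cache$clean <- simulate_bam(spec, file.path(tempdir(), "alnqc-clean-fx"))
  }
  .fx_cache$clean
}

# ---- independent MD-tag oracle -------------------------------------------
# samtools calmd recomputes MD tags from the reference; the decoder below
# counts mismatch letters in the MD string without touching the package's
# alignment walker.

md_mismatch_counts <- function(bam, fasta) {
  samtools <- Sys.which("samtools")
  stopifnot(nzchar(samtools))
  out <- tempfile(fileext = ".bam")
  res <- system2(samtools, c("calmd", "-b", bam, fasta),
                 stdout = out, stderr = FALSE)
  stopifnot(res == 0L)
  ch <- Rsamtools::scanBam(out, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag"), tag = "MD"))[[1]]
  n_mm <- vapply(ch$tag$MD, decode_md_count, 0L, USE.NAMES = FALSE)
  data.frame(qname = ch$qname, flag = ch$flag, n_mm = n_mm,
             stringsAsFactors = FALSE)
}

decode_md_count <- function(md) {
  if (is.na(md)) return(NA_integer_)
  toks <- regmatches(md, gregexpr("\\^[ACGTN]+|[ACGTN]|[0-9]+", md))[[1]]
  sum(grepl("^[ACGTN]$", toks))
}

# ---- brute-force Dixon Q (independent transcription of the formulas) -----
brute_dixon_q <- function(x) {
  n <- length(x); s <- sort(x)
  rng <- function(a, b) if (b - a > 0) b - a else NA_real_
  if (n <= 7) {
    qlo <- (s[2] - s[1]) / rng(s[1], s[n])
    qhi <- (s[n] - s[n - 1]) / rng(s[1], s[n])
  } else if (n <= 10) {
    qlo <- (s[2] - s[1]) / rng(s[1], s[n - 1])
    qhi <- (s[n] - s[n - 1]) / rng(s[2], s[n])
  } else if (n <= 13) {
    qlo <- (s[3] - s[1]) / rng(s[1], s[n - 1])
    qhi <- (s[n] - s[n - 2]) / rng(s[2], s[n])
  } else {
    qlo <- (s[3] - s[1]) / rng(s[1], s[n - 2])
    qhi <- (s[n] - s[n - 2]) / rng(s[3], s[n])
  }
  q <- suppressWarnings(max(qlo, qhi, na.rm = TRUE))
  if (!is.finite(q)) 0 else q
}

# ---- brute-force jump-read scan ------------------------------------------
brute_jump_names <- function(fixture, criteria = jump_criteria()) {
  rd <- fixture$truth$reads
  mate <- match(paste0(rd$qname, "|", !rd$read1), paste0(rd$qname, "|", rd$read1))
  left <- rd$pos <= rd$pos[mate]
  left_rev <- ifelse(left, rd$reverse, rd$reverse[mate])
  right_rev <- ifelse(left, rd$reverse[mate], rd$reverse)
  cls <- ifelse(rd$mate_chrom != rd$chrom, "INTERCHROM",
         ifelse(!rd$reverse & !rd$reverse[mate], "ANOM_FF",
         ifelse(rd$reverse & rd$reverse[mate], "ANOM_RR",
         ifelse(left_rev & !right_rev, "ANOM_OUTWARD",
         ifelse(abs(rd$tlen) >= criteria$min_insert, "LONG_INSERT", "NORMAL")))))
  sort(unique(rd$qname[cls != "NORMAL"]))
}
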