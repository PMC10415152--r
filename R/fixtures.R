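#' Specify a synthetic paired-end alignment fixture
#'
#' Builds the specification for a deterministic, seeded synthetic fixture:
#' a reference FASTA plus a coordinate-sorted, indexed BAM of paired-end
#' reads with injected artifact patterns, together with exhaustive truth
#' tables. Reads are emitted pre-aligned (true positions known, CIGAR
#' constructed from the injected events), so every truth value is exact.
#'
#' The defaults emulate a small short-read experiment: 100 bp paired-end
#' reads, FR proper pairs with a normal insert-size distribution
#' (mean 300 bp, sd 30 bp), per-base quality around Q32 for correct bases
#' and Q12 for injected error bases.
#'
#' @param seed Integer seed; every random choice derives from it.
#' @param ref_length Length of the main contig `chr1` (a secondary contig
#'   `chr2` is always present for inter-chromosomal mates).
#' @param gc_target Target GC fraction of the reference.
#' @param read_length Fixed read length (bp).
#' @param n_pairs Number of regular proper pairs on `chr1`.
#' @param insert_mean,insert_sd Insert-size (template length) distribution.
#' @param error_rules List of [error_rule()] objects.
#' @param indel_rules List of lists `list(type = "ins"|"del", lengths =
#'   integer vector to sample from, n_reads = count)`; each affected read
#'   carries exactly one indel, on extra proper pairs.
#' @param clip_rule `NULL` or `list(n_reads =, len =, end = "5p"|"3p")`:
#'   soft-clipped reads (clipped bases are random non-reference sequence).
#' @param anomalies List with counts of atypical pairs:
#'   `n_long_insert`, `n_interchrom`, `n_ff`, `n_rr`, `n_outward`, and
#'   `long_insert_size` (default 5000).
#' @param trap_region `NULL` or `list(start =, end =, excess_fold =)`: an
#'   extra pile-up of error-free pairs inside `chr1:start-end` at
#'   `excess_fold` times the baseline depth, emulating a read-trap segment.
#' @param qual_correct_mean,qual_error_mean Mean Phred quality of correct
#'   and injected-error bases (sd 3, clamped to `[2, 40]`).
#' @param sample Sample name (used for read group and logs).
#' @return A list of class `fixture_spec`.
#' @seealso [error_rule()], [make_reference()], [simulate_bam()]
#' @export
fixture_spec <- function(seed = 1L, ref_length = 20000L, gc_target = 0.5,
                         read_length = 100L, n_pairs = 1000L,
                         insert_mean = 300, insert_sd = 30,
                         error_rules = list(), indel_rules = list(),
                         clip_rule = NULL,
                         anomalies = list(), trap_region = NULL,
                         qual_correct_mean = 32, qual_error_mean = 12,
                         sample = "sim") {
  if (ref_length < 2L * read_length) abort("ref_length must be >= 2 * read_length")
  if (gc_target < 0 || gc_target > 1) abort("gc_target must be in [0, 1]")
  anom <- modifyList(list(n_long_insert = 0L, n_interchrom = 0L, n_ff = 0L,
                          n_rr = 0L, n_outward = 0L, long_insert_size = 5000L),
                     anomalies)
  if (!is.null(trap_region)) {
    if (trap_region$start < 1L || trap_region$end > ref_length ||
        trap_region$start >= trap_region$end) {
      abort("trap_region must lie within chr1")
    }
  }
  for (r in error_rules) {
    if (r$rate < 0 || r$rate > 1) abort("error-rule rates must be in [0, 1]")
    if (!is.null(r$cycles) && any(r$cycles < 1L | r$cycles > read_length)) {
      abort("error-rule cycles must lie within the read length")
    }
  }
  structure(list(seed = as.integer(seed), ref_length = as.integer(ref_length),
                 gc_target = gc_target, read_length = as.integer(read_length),
                 n_pairs = as.integer(n_pairs), insert_mean = insert_mean,
                 insert_sd = insert_sd, error_rules = error_rules,
                 indel_rules = indel_rules, clip_rule = clip_rule,
                 anomalies = anom, trap_region = trap_region,
                 qual_correct_mean = qual_correct_mean,
                 qual_error_mean = qual_error_mean, sample = sample),
            class = "fixture_spec")
}

#' Define a substitution-injection rule
#'
#' A rule plants substitutions of one category (reference orientation, e.g.
#' `"C>A"`) at a given per-eligible-site rate, optionally restricted to
#' specific sequencing cycles, orientation classes and reference flanking
#' context (e.g. `"G_G"` to convert `GAG` motifs with an `"A>G"` rule).
#'
#' @param category Substitution category `"X>Y"`.
#' @param rate Per eligible read/cycle probability of injection.
#' @param cycles `NULL` (all cycles) or an integer vector of cycles.
#' @param orientations `NULL` (all) or a subset of `c("R1F","R1R","R2F","R2R")`.
#' @param context `NULL` or a flank duplet `"F5_F3"` required on the
#'   reference forward strand.
#' @param qual_mean Mean Phred quality assigned to the injected base
#'   (`NULL` uses the spec's `qual_error_mean`).
#' @return A list of class `error_rule`.
#' @export
error_rule <- function(category, rate, cycles = NULL, orientations = NULL,
                       context = NULL, qual_mean = NULL) {
  if (!category %in% SUBST_CATEGORIES) abort("unknown substitution category")
  if (!is.null(orientations) && !all(orientations %in% ORIENT_LEVELS)) {
    abort("orientations must be among R1F, R1R, R2F, R2R")
  }
  if (!is.null(context) && !grepl("^[ACGT]_[ACGT]$", context)) {
    abort('context must look like "G_G"')
  }
  structure(list(category = category, rate = rate,
                 cycles = if (is.null(cycles)) NULL else as.integer(cycles),
                 orientations = orientations, context = context,
                 qual_mean = qual_mean), class = "error_rule")
}

#' Generate the fixture reference FASTA
#'
#' Writes a two-contig reference (`chr1` of `ref_length`, `chr2` of 3000 bp)
#' of seeded pseudo-random sequence hitting `gc_target` (+/- 1% for contigs
#' of a few kb), plus a `.fai` index.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the FASTA path.
#' @export
make_reference <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  p <- c(A = (1 - spec$gc_target) / 2, C = spec$gc_target / 2,
         G = spec$gc_target / 2, T = (1 - spec$gc_target) / 2)
  gen <- function(n) paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
  seqs <- Biostrings::DNAStringSet(c(chr1 = gen(spec$ref_length), chr2 = gen(3000L)))
  fa <- file.path(dir, "ref.fa")
  Biostrings::writeXStringSet(seqs, fa)
  Rsamtools::indexFa(fa)
  invisible(fa)
}

# clamped normal Phred qualities
rqual <- function(n, mean) pmin(40L, pmax(2L, as.integer(round(rnorm(n, mean, 3)))))

#' Simulate the fixture BAM with truth tables
#'
#' Generates the full read set of `spec` (regular pairs, indel/clip reads,
#' atypical pairs, trap-region pile-up), injects the configured substitution
#' rules, and writes a coordinate-sorted, indexed BAM. All randomness
#' derives from `spec$seed`; identical specs produce identical BAM record
#' streams and truth tables.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory; the reference is written there too unless
#'   already present from [make_reference()].
#' @return A list of class `alnqc_fixture`: `bam`, `fasta`, `spec`, and
#'   `truth`, a list of tibbles: `reads` (one row per record with true
#'   CIGAR, orientation, mismatch/indel/clip counts), `events` (every
#'   injected substitution with cycle, category, context, orientation,
#'   quality), `per_cycle` (aligned-read denominators by cycle and
#'   orientation), `anomalies` (atypical pairs and their classes).
#' @export
simulate_bam <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "ref.fa")
  if (!file.exists(fa)) make_reference(spec, dir)
  ref <- read_reference(fa)
  chr1 <- ref$chr1; chr2 <- ref$chr2
  L1 <- nchar(chr1)
  rl <- spec$read_length
  set.seed(spec$seed + 1L)

  an <- spec$anomalies
  n_anom <- an$n_long_insert + an$n_interchrom + an$n_ff + an$n_rr + an$n_outward
  if (n_anom > 0 && n_anom > spec$n_pairs) {
    abort("anomaly pair counts exceed n_pairs")
  }

  ## ---- regular proper pairs (all-M; substitution injection targets these)
  n <- spec$n_pairs
  ins_sz <- pmin(L1 - 4L, pmax(2L * rl, as.integer(round(rnorm(n, spec$insert_mean, spec$insert_sd)))))
  start <- 2L + as.integer(floor(runif(n) * (L1 - ins_sz - 2L)))
  r1_left <- runif(n) < 0.5
  reads <- tibble(
    pair = paste0("p", formatC(seq_len(n), width = 7, flag = "0")),
    kind = "regular",
    left_pos = start, right_pos = start + ins_sz - rl,
    insert = ins_sz, r1_left = r1_left)

  rec <- bind_rows(
    tibble(qname = reads$pair, chrom = "chr1", pos = reads$left_pos,
           reverse = FALSE, read1 = reads$r1_left, proper = TRUE,
           mate_chrom = "chr1", mate_pos = reads$right_pos,
           tlen = reads$insert, kind = "regular"),
    tibble(qname = reads$pair, chrom = "chr1", pos = reads$right_pos,
           reverse = TRUE, read1 = !reads$r1_left, proper = TRUE,
           mate_chrom = "chr1", mate_pos = reads$left_pos,
           tlen = -reads$insert, kind = "regular"))
  rec$cigar <- paste0(rl, "M")
  rec$seq <- substring(chr1, rec$pos, rec$pos + rl - 1L)
  rec$ref_span <- rl

  ## ---- trap-region pile-up (error-free regular-looking pairs)
  if (!is.null(spec$trap_region)) {
    tr <- spec$trap_region
    span <- tr$end - tr$start + 1L
    base_depth <- 2 * n * rl / L1
    n_tr <- max(1L, as.integer(ceiling(tr$excess_fold * base_depth * span / (2 * rl))))
    t_ins <- pmin(span, max(2L * rl, min(span, as.integer(spec$insert_mean))))
    t_start <- tr$start + as.integer(floor(runif(n_tr) * max(1L, span - t_ins + 1L)))
    t_r1l <- runif(n_tr) < 0.5
    qn <- paste0("t", formatC(seq_len(n_tr), width = 7, flag = "0"))
    rec <- bind_rows(rec,
      tibble(qname = qn, chrom = "chr1", pos = t_start, reverse = FALSE,
             read1 = t_r1l, proper = TRUE, mate_chrom = "chr1",
             mate_pos = t_start + t_ins - rl, tlen = t_ins, kind = "trap",
             cigar = paste0(rl, "M"),
             seq = substring(chr1, t_start, t_start + rl - 1L), ref_span = rl),
      tibble(qname = qn, chrom = "chr1", pos = t_start + t_ins - rl,
             reverse = TRUE, read1 = !t_r1l, proper = TRUE, mate_chrom = "chr1",
             mate_pos = t_start, tlen = -t_ins, kind = "trap",
             cigar = paste0(rl, "M"),
             seq = substring(chr1, t_start + t_ins - rl, t_start + t_ins - 1L),
             ref_span = rl))
  }

  ## ---- indel pairs: read1 of an extra proper pair carries one indel
  indel_truth <- list()
  idx_counter <- 0L
  for (rule in spec$indel_rules) {
    n_ev <- as.integer(rule$n_reads)
    if (n_ev == 0L) next
    lens <- sample(rep(as.integer(rule$lengths), length.out = max(n_ev, length(rule$lengths))), n_ev)
    ins_sz <- as.integer(spec$insert_mean) + 60L
    st <- 2L + as.integer(floor(runif(n_ev) * (L1 - ins_sz - max(lens) - 2L)))
    a <- 10L + as.integer(floor(runif(n_ev) * (rl - 20L)))   # indel offset within read
    qn <- paste0("i", rule$type, formatC(idx_counter + seq_len(n_ev), width = 6, flag = "0"))
    idx_counter <- idx_counter + n_ev
    if (rule$type == "del") {
      cig <- paste0(a, "M", lens, "D", rl - a, "M")
      sq <- paste0(substring(chr1, st, st + a - 1L),
                   substring(chr1, st + a + lens, st + a + lens + (rl - a) - 1L))
      span <- rl + lens
    } else {
      b <- pmin(lens, rl - a - 1L)
      cig <- paste0(a, "M", b, "I", rl - a - b, "M")
      insbases <- vapply(b, function(k) paste(sample(BASES, k, replace = TRUE), collapse = ""), "")
      sq <- paste0(substring(chr1, st, st + a - 1L), insbases,
                   substring(chr1, st + a, st + a + (rl - a - b) - 1L))
      span <- rl - b
      lens <- b
    }
    m_pos <- st + ins_sz - rl
    rec <- bind_rows(rec,
      tibble(qname = qn, chrom = "chr1", pos = st, reverse = FALSE, read1 = TRUE,
             proper = TRUE, mate_chrom = "chr1", mate_pos = m_pos,
             tlen = ins_sz, kind = paste0("indel_", rule$type),
             cigar = cig, seq = sq, ref_span = span),
      tibble(qname = qn, chrom = "chr1", pos = m_pos, reverse = TRUE, read1 = FALSE,
             proper = TRUE, mate_chrom = "chr1", mate_pos = st,
             tlen = -ins_sz, kind = "indel_mate", cigar = paste0(rl, "M"),
             seq = substring(chr1, m_pos, m_pos + rl - 1L), ref_span = rl))
    indel_truth[[length(indel_truth) + 1L]] <-
      tibble(qname = qn, type = rule$type, length = as.integer(lens))
  }

  ## ---- soft-clipped reads (clip bases are random sequence)
  if (!is.null(spec$clip_rule)) {
    cr <- spec$clip_rule
    n_ev <- as.integer(cr$n_reads); cl <- as.integer(cr$len)
    ins_sz <- as.integer(spec$insert_mean) + 60L
    st <- 2L + as.integer(floor(runif(n_ev) * (L1 - ins_sz - 2L)))
    clipseq <- vapply(seq_len(n_ev), function(i)
      paste(sample(BASES, cl, replace = TRUE), collapse = ""), "")
    aligned <- substring(chr1, st, st + (rl - cl) - 1L)
    if (identical(cr$end, "3p")) {
      cig <- paste0(rl - cl, "M", cl, "S"); sq <- paste0(aligned, clipseq)
    } else {
      cig <- paste0(cl, "S", rl - cl, "M"); sq <- paste0(clipseq, aligned)
    }
    qn <- paste0("c", formatC(seq_len(n_ev), width = 6, flag = "0"))
    m_pos <- st + ins_sz - rl
    rec <- bind_rows(rec,
      tibble(qname = qn, chrom = "chr1", pos = st, reverse = FALSE, read1 = TRUE,
             proper = TRUE, mate_chrom = "chr1", mate_pos = m_pos, tlen = ins_sz,
             kind = "clip", cigar = cig, seq = sq, ref_span = rl - cl),
      tibble(qname = qn, chrom = "chr1", pos = m_pos, reverse = TRUE, read1 = FALSE,
             proper = TRUE, mate_chrom = "chr1", mate_pos = st, tlen = -ins_sz,
             kind = "clip_mate", cigar = paste0(rl, "M"),
             seq = substring(chr1, m_pos, m_pos + rl - 1L), ref_span = rl))
  }

  ## ---- atypical pairs for jump-read extraction (all error-free, all-M)
  anom_truth <- list()
  add_pair <- function(n_ev, prefix, class, left_rev, right_rev, gap, interchrom = FALSE) {
    if (n_ev == 0L) return(invisible(NULL))
    st <- 2L + as.integer(floor(runif(n_ev) * (L1 - gap - 2L * rl - 2L)))
    qn <- paste0(prefix, formatC(seq_len(n_ev), width = 5, flag = "0"))
    if (interchrom) {
      p2 <- 2L + as.integer(floor(runif(n_ev) * (nchar(chr2) - rl - 2L)))
      rec <<- bind_rows(rec,
        tibble(qname = qn, chrom = "chr1", pos = st, reverse = FALSE, read1 = TRUE,
               proper = FALSE, mate_chrom = "chr2", mate_pos = p2, tlen = 0L,
               kind = "anom", cigar = paste0(rl, "M"),
               seq = substring(chr1, st, st + rl - 1L), ref_span = rl),
        tibble(qname = qn, chrom = "chr2", pos = p2, reverse = TRUE, read1 = FALSE,
               proper = FALSE, mate_chrom = "chr1", mate_pos = st, tlen = 0L,
               kind = "anom", cigar = paste0(rl, "M"),
               seq = substring(chr2, p2, p2 + rl - 1L), ref_span = rl))
    } else {
      rp <- st + gap
      tl <- rp + rl - st
      rec <<- bind_rows(rec,
        tibble(qname = qn, chrom = "chr1", pos = st, reverse = left_rev, read1 = TRUE,
               proper = FALSE, mate_chrom = "chr1", mate_pos = rp, tlen = tl,
               kind = "anom", cigar = paste0(rl, "M"),
               seq = substring(chr1, st, st + rl - 1L), ref_span = rl),
        tibble(qname = qn, chrom = "chr1", pos = rp, reverse = right_rev, read1 = FALSE,
               proper = FALSE, mate_chrom = "chr1", mate_pos = st, tlen = -tl,
               kind = "anom", cigar = paste0(rl, "M"),
               seq = substring(chr1, rp, rp + rl - 1L), ref_span = rl))
    }
    anom_truth[[length(anom_truth) + 1L]] <<- tibble(qname = qn, class = class)
    invisible(NULL)
  }
  add_pair(an$n_long_insert, "jl", "LONG_INSERT", FALSE, TRUE,
           gap = max(an$long_insert_size - rl, 2L * rl))
  add_pair(an$n_interchrom, "jx", "INTERCHROM", FALSE, TRUE, gap = 0L, interchrom = TRUE)
  add_pair(an$n_ff, "jf", "ANOM_FF", FALSE, FALSE, gap = as.integer(spec$insert_mean))
  add_pair(an$n_rr, "jr", "ANOM_RR", TRUE, TRUE, gap = as.integer(spec$insert_mean))
  add_pair(an$n_outward, "jo", "ANOM_OUTWARD", TRUE, FALSE, gap = as.integer(spec$insert_mean))

  ## ---- orientation classes
  rec$orientation <- ifelse(rec$read1,
                            ifelse(rec$reverse, "R1R", "R1F"),
                            ifelse(rec$reverse, "R2R", "R2F"))

  ## ---- substitution injection (regular all-M chr1 reads only)
  events <- list()
  target <- which(rec$kind == "regular")
  flank5_of <- function(p) substring(chr1, p - 1L, p - 1L)
  flank3_of <- function(p) substring(chr1, p + 1L, p + 1L)
  for (rule in spec$error_rules) {
    rb <- substr(rule$category, 1, 1); ab <- substr(rule$category, 3, 3)
    oris <- rule$orientations %||% ORIENT_LEVELS
    cycles <- rule$cycles %||% seq_len(rl)
    cand0 <- target[rec$orientation[target] %in% oris]
    for (cyc in cycles) {
      idx0 <- ifelse(rec$reverse[cand0], rl - cyc, cyc - 1L)  # 0-based query index
      rp <- rec$pos[cand0] + idx0
      ok <- substring(chr1, rp, rp) == rb & rp > 1L & rp < L1
      if (!is.null(rule$context)) {
        f5 <- substr(rule$context, 1, 1); f3 <- substr(rule$context, 3, 3)
        ok <- ok & flank5_of(rp) == f5 & flank3_of(rp) == f3
      }
      # skip bases already altered by an earlier rule
      cur <- substr(rec$seq[cand0], idx0 + 1L, idx0 + 1L)
      ok <- ok & cur == rb
      hit <- cand0[ok & runif(length(cand0)) < rule$rate]
      if (!length(hit)) next
      idxh <- ifelse(rec$reverse[hit], rl - cyc, cyc - 1L)
      rph <- rec$pos[hit] + idxh
      substr(rec$seq[hit], idxh + 1L, idxh + 1L) <- ab
      events[[length(events) + 1L]] <- tibble(
        qname = rec$qname[hit], rec_row = hit, chrom = "chr1",
        ref_pos = rph, cycle = cyc, category = rule$category,
        ref_base = rb, read_base = ab,
        flank5 = flank5_of(rph), flank3 = flank3_of(rph),
        orientation = rec$orientation[hit],
        qual_mean = rule$qual_mean %||% spec$qual_error_mean)
    }
  }
  events <- if (length(events)) bind_rows(events) else tibble(
    qname = character(), rec_row = integer(), chrom = character(),
    ref_pos = integer(), cycle = integer(), category = character(),
    ref_base = character(), read_base = character(), flank5 = character(),
    flank3 = character(), orientation = character(), qual_mean = numeric())

  ## ---- base qualities (error bases drawn low)
  nrec <- nrow(rec)
  seq_lens <- nchar(rec$seq)
  qmat <- rqual(sum(seq_lens), spec$qual_correct_mean)
  offs <- cumsum(c(0L, seq_lens[-nrec]))
  if (nrow(events)) {
    ev_idx0 <- ifelse(rec$reverse[events$rec_row], rl - events$cycle, events$cycle - 1L)
    flat <- offs[events$rec_row] + ev_idx0 + 1L
    qmat[flat] <- rqual(nrow(events), events$qual_mean)
    events$base_qual <- qmat[flat]
  } else {
    events$base_qual <- integer()
  }
  qstr <- vapply(seq_len(nrec), function(i)
    intToUtf8(qmat[(offs[i] + 1L):(offs[i] + seq_lens[i])] + 33L), "")
  rec$qual <- qstr

  ## ---- per-read truth summaries
  nmm <- integer(nrec)
  if (nrow(events)) {
    tb <- table(events$rec_row)
    nmm[as.integer(names(tb))] <- as.integer(tb)
  }
  rec$n_mismatch <- nmm

  ## ---- write SAM, convert to sorted+indexed BAM
  flag <- 1L +
    ifelse(rec$proper, 2L, 0L) +
    ifelse(rec$reverse, 16L, 0L) +
    {
      mate_rev <- rec$reverse[match(paste0(rec$qname, "_", !rec$read1),
                                    paste0(rec$qname, "_", rec$read1))]
      ifelse(mate_rev, 32L, 0L)
    } +
    ifelse(rec$read1, 64L, 128L)
  rec$flag <- flag
  ord <- order(match(rec$chrom, c("chr1", "chr2")), rec$pos, rec$qname)
  rec_s <- rec[ord, ]
  rnext <- ifelse(rec_s$mate_chrom == rec_s$chrom, "=", rec_s$mate_chrom)
  sam_lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    paste0("@SQ\tSN:chr1\tLN:", L1),
    paste0("@SQ\tSN:chr2\tLN:", nchar(chr2)),
    paste0("@RG\tID:", spec$sample, "\tSM:", spec$sample),
    paste(rec_s$qname, rec_s$flag, rec_s$chrom, rec_s$pos, 60L, rec_s$cigar,
          rnext, rec_s$mate_pos, rec_s$tlen, rec_s$seq, rec_s$qual,
          paste0("RG:Z:", spec$sample), sep = "\t"))
  sam <- file.path(dir, "sim.sam")
  writeLines(sam_lines, sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "sim"), overwrite = TRUE,
                          indexDestination = TRUE)

  ## ---- truth tables
  per_cycle_cov <- truth_cycle_coverage(rec, rl)
  truth <- list(
    reads = as_tibble(rec[, c("qname", "flag", "chrom", "pos", "cigar",
                              "orientation", "kind", "n_mismatch", "tlen",
                              "proper", "reverse", "read1", "mate_chrom",
                              "mate_pos", "ref_span", "seq", "qual")]),
    events = select(events, -"rec_row", -"qual_mean"),
    per_cycle = per_cycle_cov,
    anomalies = if (length(anom_truth)) bind_rows(anom_truth) else
      tibble(qname = character(), class = character()),
    indels = if (length(indel_truth)) bind_rows(indel_truth) else
      tibble(qname = character(), type = character(), length = integer()))
  structure(list(bam = bam, fasta = fa, spec = spec, truth = truth),
            class = "alnqc_fixture")
}

# truth denominators: reads with an aligned base at each cycle, by orientation
truth_cycle_coverage <- function(rec, rl) {
  # every generated read is ACGT-only, so aligned cycles are read length minus
  # clipped/inserted cycles; derive the aligned cycle range from the CIGAR
  cyc_count <- matrix(0L, nrow = rl, ncol = 4L,
                      dimnames = list(NULL, ORIENT_LEVELS))
  specs <- unique(rec[, c("cigar", "reverse")])
  for (i in seq_len(nrow(specs))) {
    cig <- parse_cigar(specs$cigar[i])
    qi <- 0L; covered <- integer()
    for (j in seq_len(nrow(cig))) {
      if (cig$op[j] %in% c("M", "=", "X")) covered <- c(covered, qi + seq_len(cig$len[j]))
      if (cig$op[j] %in% c("M", "=", "X", "I", "S")) qi <- qi + cig$len[j]
    }
    L <- qi
    cycles <- if (specs$reverse[i]) L - (covered - 1L) else covered
    sel <- rec$cigar == specs$cigar[i] & rec$reverse == specs$reverse[i]
    per_ori <- table(factor(rec$orientation[sel], levels = ORIENT_LEVELS))
    for (o in seq_len(4L)) cyc_count[cycles, o] <- cyc_count[cycles, o] + as.integer(per_ori[o])
  }
  as_tibble(cyc_count) |>
    mutate(cycle = dplyr::row_number()) |>
    pivot_longer(all_of(ORIENT_LEVELS), names_to = "orientation",
                 values_to = "n_aligned") |>
    select("cycle", "orientation", "n_aligned")
}

#' Brute-force per-position depth from fixture truth
#'
#' Expands every truth read's CIGAR over an interval and counts aligned
#' (M) bases per position, split into reference-matching and mismatching
#' bases, plus deletion-spanning reads. Independent of the BAM path: uses
#' only the truth `reads` table and the reference, so it serves as the
#' oracle for pileup-based depth profiling.
#'
#' @param fixture An `alnqc_fixture`.
#' @param chrom,start,end 1-based closed interval.
#' @return Tibble with `pos`, `depth`, `n_ref`, `n_nonref`, `n_del`.
#' @export
fixture_truth_depth <- function(fixture, chrom, start, end) {
  ref <- read_reference(fixture$fasta)
  rseq <- ref[[chrom]]
  reads <- filter(fixture$truth$reads, .data$chrom == !!chrom,
                  .data$pos <= end, .data$pos + .data$ref_span - 1L >= start)
  np <- end - start + 1L
  depth <- n_ref <- n_del <- integer(np)
  ref_win <- strsplit(toupper(substr(rseq, start, end)), "")[[1]]
  for (i in seq_len(nrow(reads))) {
    cig <- parse_cigar(reads$cigar[i])
    rp <- reads$pos[i]; qi <- 1L
    sq_chars <- strsplit(reads$seq[i], "")[[1]]
    for (j in seq_len(nrow(cig))) {
      op <- cig$op[j]; len <- cig$len[j]
      if (op %in% c("M", "=", "X")) {
        p0 <- max(rp, start); p1 <- min(rp + len - 1L, end)
        if (p0 <= p1) {
          k <- (p0 - start + 1L):(p1 - start + 1L)
          q <- (qi + (p0 - rp)):(qi + (p1 - rp))
          depth[k] <- depth[k] + 1L
          hit_ref <- sq_chars[q] == ref_win[k]
          n_ref[k] <- n_ref[k] + hit_ref
        }
        rp <- rp + len; qi <- qi + len
      } else if (op == "D") {
        p0 <- max(rp, start); p1 <- min(rp + len - 1L, end)
        if (p0 <= p1) {
          k <- (p0 - start + 1L):(p1 - start + 1L)
          n_del[k] <- n_del[k] + 1L
        }
        rp <- rp + len
      } else if (op == "N") {
        rp <- rp + len
      } else if (op %in% c("I", "S")) {
        qi <- qi + len
      }
    }
  }
  tibble(pos = start:end, depth = depth, n_ref = n_ref,
         n_nonref = depth - n_ref, n_del = n_del)
}

#' Compare a QC result against fixture truth
#'
#' Checks the accumulated counters of a [bamqc()] result against the
#' fixture's truth tables: total mismatch events, per-cycle mismatch counts
#' by orientation and category, per-cycle aligned denominators, and the
#' per-read mismatch histogram. Counts must match exactly; derived rates
#' are compared at 1e-9.
#'
#' @param result A `bamqc_result`.
#' @param fixture An `alnqc_fixture` (its `truth` element is used).
#' @return A list of class `truth_report`: `pass` (logical) and `diffs`
#'   (tibble of counter, expected, observed for every disagreement).
#' @export
verify_truth <- function(result, fixture) {
  truth <- fixture$truth
  diffs <- list()
  note <- function(counter, expected, observed) {
    if (!isTRUE(all.equal(expected, observed, tolerance = 1e-12))) {
      diffs[[length(diffs) + 1L]] <<- tibble(counter = counter,
                                             expected = as.numeric(expected),
                                             observed = as.numeric(observed))
    }
  }
  note("total_mismatches", nrow(truth$events), sum(result$per_cycle$n_mismatch[result$per_cycle$stratum == "overall"]))

  ev_cyc <- truth$events |>
    count(.data$cycle, .data$orientation, .data$category, name = "n_true")
  obs <- result$per_cycle_category |>
    filter(.data$stratum != "overall") |>
    select(cycle = "cycle", orientation = "stratum", category = "category", n_obs = "n")
  cmp <- full_join(ev_cyc, obs, by = c("cycle", "orientation", "category")) |>
    mutate(n_true = coalesce(.data$n_true, 0L), n_obs = coalesce(.data$n_obs, 0L)) |>
    filter(.data$n_true != .data$n_obs)
  for (i in seq_len(nrow(cmp))) {
    note(paste0("per_cycle_category[", cmp$cycle[i], ",", cmp$orientation[i],
                ",", cmp$category[i], "]"), cmp$n_true[i], cmp$n_obs[i])
  }

  den <- result$per_cycle |>
    filter(.data$stratum != "overall") |>
    select(cycle = "cycle", orientation = "stratum", n_obs = "n_aligned_reads")
  cmp2 <- full_join(truth$per_cycle, den, by = c("cycle", "orientation")) |>
    mutate(n_aligned = coalesce(.data$n_aligned, 0L), n_obs = coalesce(.data$n_obs, 0L)) |>
    filter(.data$n_aligned != .data$n_obs)
  for (i in seq_len(nrow(cmp2))) {
    note(paste0("per_cycle_denominator[", cmp2$cycle[i], ",", cmp2$orientation[i], "]"),
         cmp2$n_aligned[i], cmp2$n_obs[i])
  }

  rmc_true <- truth$reads |> count(k = .data$n_mismatch)
  rmc_obs <- result$rmc_raw |> filter(.data$stratum == "overall")
  cmp3 <- full_join(rmc_true, select(rmc_obs, k = "k", n_obs = "n"), by = "k") |>
    mutate(n = coalesce(.data$n, 0L), n_obs = coalesce(.data$n_obs, 0L)) |>
    filter(.data$n != .data$n_obs)
  for (i in seq_len(nrow(cmp3))) {
    note(paste0("rmc_raw[k=", cmp3$k[i], "]"), cmp3$n[i], cmp3$n_obs[i])
  }

  diffs <- if (length(diffs)) bind_rows(diffs) else
    tibble(counter = character(), expected = numeric(), observed = numeric())
  structure(list(pass = nrow(diffs) == 0L, diffs = diffs), class = "truth_report")
}

#' @export
print.truth_report <- function(x, ...) {
  cat(if (x$pass) "truth check: PASS (zero diffs)\n"
      else paste0("truth check: FAIL (", nrow(x$diffs), " diffs)\n"))
  if (!x$pass) print(x$diffs, n = 20)
  invisible(x)
}
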