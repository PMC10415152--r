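#' Default adapter sequences for soft-clip matching
#'
#' Common Illumina adapter read-through sequences, matched by exact prefix
#' against 3' soft-clipped tails.
#'
#' @return Named character vector of adapter sequences.
#' @export
default_adapters <- function() {
  c(TruSeq_R1  = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
    TruSeq_R2  = "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGT",
    Nextera    = "CTGTCTCTTATACACATCT")
}

QUAL_BIN_LABELS <- c("0-10", "11-20", "21-30", ">=31")
RMC_BIN_LABELS <- c("0", "1", "2", "3", "4", ">=5")

cat_index <- function(ref_code, read_code) {
  # 12 ordered ref>read categories; offset of read base among the 3 non-ref bases
  (ref_code - 1L) * 3L + read_code - (read_code > ref_code)
}

context_labels <- function() {
  # order matches the linear context index (flank3 varies fastest)
  paste0(rep(BASES, each = 4), "_", rep(BASES, 4))
}

#' Accumulate the full QC result for one BAM
#'
#' Single streaming pass over a coordinate-sorted paired-end BAM. Every kept
#' read (see [record_filter()]) is re-walked against the reference; mismatch,
#' indel and clip events feed the three mismatch-centric feature families —
#' the per-cycle profile, the substitution-category profile (with base
#' quality bins and flanking-context distributions) and the read-mismatch
#' histogram — in an overall and four-way orientation (`R1F`, `R1R`, `R2F`,
#' `R2R`) stratification, alongside the common QC metrics (insert size, GC
#' content, base/mapping quality, nucleotide content, clip and indel length
#' distributions, adapter content, depth and error-rate summaries).
#'
#' @param bam Path to a BAM file (indexed if `region` is used).
#' @param ref Reference FASTA path, named character vector of contigs, or
#'   `DNAStringSet`.
#' @param policy A [filter_policy()].
#' @param region `NULL`, a BED path, or a `GRanges`: restrict accumulation
#'   to reads overlapping the region.
#' @param read_group `NULL` or a read-group ID to restrict to.
#' @param sample Sample label for the result (defaults to the BAM name).
#' @param yield_size Records per streaming chunk.
#' @param adapters Adapter sequences for 3' soft-clip prefix matching.
#' @param insert_cap Insert-size histogram cap (overflow bucket above).
#' @return An object of class `bamqc_result`; see [tidy.bamqc_result()].
#' @export
bamqc <- function(bam, ref, policy = filter_policy(), region = NULL,
                  read_group = NULL, sample = NULL, yield_size = 100000L,
                  adapters = default_adapters(), insert_cap = 2000L) {
  refc <- if (is.character(ref) && length(ref) == 1L && file.exists(ref) &&
              is.null(names(ref))) read_reference(ref) else as_ref_chars(ref)
  ref_label <- if (is.character(ref) && length(ref) == 1L) ref else "<in-memory>"
  sample <- sample %||% sub("\\.bam$", "", basename(bam))

  which_gr <- NULL
  if (!is.null(region)) {
    which_gr <- if (methods::is(region, "GRanges")) region else read_bed(region)
    which_gr <- GenomicRanges::reduce(which_gr)
  }

  acc <- new.env(parent = emptyenv())
  acc$max_len <- 0L
  acc$counts <- c(total = 0, mapped = 0, unmapped = 0, secondary = 0,
                  supplementary = 0, duplicate = 0, qcfail = 0, kept = 0,
                  low_mapq = 0, unpaired = 0)
  acc$cycle_cov <- NULL          # L x 4 aligned-read denominators
  acc$mm_cat_cycle <- NULL       # L x 4 x 12 mismatch counts
  acc$mm_qual_cycle_sum <- NULL  # L x 4
  acc$qual_bins <- array(0, c(12, 4, 4))      # category x bin x orientation
  acc$context <- array(0, c(12, 16, 4))       # category x flank-duplet x orientation
  acc$rmc <- list()              # per-chunk tibbles (k, orientation, n)
  acc$nt_cycle <- NULL           # L x 5
  acc$qual_cycle_sum <- NULL; acc$qual_cycle_n <- NULL
  acc$qual_hist <- numeric(94)
  acc$gc_hist <- numeric(101)
  acc$mapq_hist <- numeric(256)
  acc$insert_hist <- numeric(insert_cap + 1L)  # last slot = overflow
  acc$clip5 <- acc$clip3 <- acc$ins_len <- acc$del_len <- numeric(0)
  acc$read_len_tab <- numeric(0)
  acc$fwd <- acc$rev <- 0
  acc$aligned_bases <- 0; acc$n_n <- 0
  acc$adapter_hits <- 0; acc$clipped_reads <- 0
  acc$read_len_sum <- 0

  grow <- function(cur, L, d2) {
    if (is.null(cur)) return(array(0, c(L, d2)))
    if (nrow(cur) >= L) return(cur)
    out <- array(0, c(L, d2)); out[seq_len(nrow(cur)), ] <- cur; out
  }
  grow3 <- function(cur, L) {
    if (is.null(cur)) return(array(0, c(L, 4, 12)))
    if (dim(cur)[1] >= L) return(cur)
    out <- array(0, c(L, 4, 12)); out[seq_len(dim(cur)[1]), , ] <- cur; out
  }

  tags <- if (!is.null(read_group)) "RG" else character()
  param_fields <- c("flag", "rname", "pos", "mapq", "cigar", "seq", "qual", "isize")
  bf <- Rsamtools::BamFile(bam, yieldSize = if (is.null(which_gr)) yield_size else NA_integer_)
  open(bf); on.exit(close(bf), add = TRUE)

  process_chunk <- function(ch) {
    nrec <- length(ch$flag)
    if (nrec == 0L) return(invisible(NULL))
    if (!is.null(read_group)) {
      keep_rg <- !is.na(ch$tag$RG) & ch$tag$RG == read_group
      ch <- within_chunk(ch, keep_rg)
      nrec <- length(ch$flag)
      if (nrec == 0L) return(invisible(NULL))
    }
    fs <- decode_flags(ch$flag)
    acc$counts["total"] <- acc$counts["total"] + nrec
    acc$counts["unmapped"] <- acc$counts["unmapped"] + sum(fs$unmapped)
    acc$counts["mapped"] <- acc$counts["mapped"] + sum(!fs$unmapped)
    acc$counts["secondary"] <- acc$counts["secondary"] + sum(fs$secondary)
    acc$counts["supplementary"] <- acc$counts["supplementary"] + sum(fs$supplementary)
    acc$counts["duplicate"] <- acc$counts["duplicate"] + sum(fs$duplicate)
    acc$counts["qcfail"] <- acc$counts["qcfail"] + sum(fs$qcfail)

    flt <- record_filter(ch$flag, ch$mapq, policy)
    acc$counts["low_mapq"] <- acc$counts["low_mapq"] +
      sum(flt$skip_reason == "low_mapq", na.rm = TRUE)
    acc$counts["unpaired"] <- acc$counts["unpaired"] +
      sum(flt$skip_reason == "unpaired", na.rm = TRUE)
    keep <- flt$keep
    if (!any(keep)) return(invisible(NULL))
    ch <- within_chunk(ch, keep)
    fs <- fs[keep, ]
    nk <- length(ch$flag)
    acc$counts["kept"] <- acc$counts["kept"] + nk

    contigs <- as.character(ch$rname)
    missing <- setdiff(unique(contigs), names(refc))
    if (length(missing)) {
      abort(paste0("contig absent from reference FASTA: ", missing[1]))
    }
    tid <- match(contigs, names(refc))
    orient <- match(classify_orientation(ch$flag), ORIENT_LEVELS)
    seqs <- as.character(ch$seq)
    quals <- as.character(ch$qual)
    L <- max(nchar(seqs))
    acc$max_len <- max(acc$max_len, L)

    w <- walk_reads_cpp(setNames(unlist(refc, use.names = FALSE), names(refc)),
                        tid, ch$pos, fs$reverse, orient,
                        as.character(ch$cigar), seqs, quals, L)

    acc$cycle_cov <- grow(acc$cycle_cov, L, 4L)
    acc$cycle_cov[seq_len(L), ] <- acc$cycle_cov[seq_len(L), ] + w$cycle_cov
    acc$nt_cycle <- grow(acc$nt_cycle, L, 5L)
    acc$nt_cycle[seq_len(L), ] <- acc$nt_cycle[seq_len(L), ] + w$nt_cycle
    acc$qual_cycle_sum <- grow(acc$qual_cycle_sum, L, 1L)
    acc$qual_cycle_sum[seq_len(L), ] <- acc$qual_cycle_sum[seq_len(L), ] + w$qual_cycle_sum
    acc$qual_cycle_n <- grow(acc$qual_cycle_n, L, 1L)
    acc$qual_cycle_n[seq_len(L), ] <- acc$qual_cycle_n[seq_len(L), ] + w$qual_cycle_n
    acc$qual_hist <- acc$qual_hist + w$qual_hist

    mm <- w$mm
    nmm <- length(mm$cycle)
    if (nmm) {
      cat_i <- cat_index(mm$ref_code, mm$read_code)
      # L x 4 x 12 linear index
      lin <- (cat_i - 1L) * (L * 4L) + (mm$orient - 1L) * L + mm$cycle
      tb <- tabulate(lin, nbins = L * 4L * 12L)
      acc$mm_cat_cycle <- grow3(acc$mm_cat_cycle, L)
      acc$mm_cat_cycle[seq_len(L), , ] <- acc$mm_cat_cycle[seq_len(L), , ] +
        array(tb, c(L, 4L, 12L))
      acc$mm_qual_cycle_sum <- grow(acc$mm_qual_cycle_sum, L, 4L)
      qs <- tapply(mm$qual, list(factor(mm$cycle, levels = seq_len(L)),
                                 factor(mm$orient, levels = 1:4)), sum, default = 0)
      acc$mm_qual_cycle_sum[seq_len(L), ] <- acc$mm_qual_cycle_sum[seq_len(L), ] + qs
      bin_i <- findInterval(mm$qual, c(0, 11, 21, 31))
      lin2 <- (mm$orient - 1L) * (12L * 4L) + (bin_i - 1L) * 12L + cat_i
      acc$qual_bins <- acc$qual_bins + array(tabulate(lin2, 12L * 4L * 4L), c(12, 4, 4))
      ctx_ok <- mm$flank5 > 0L & mm$flank3 > 0L
      if (any(ctx_ok)) {
        ctx_i <- (mm$flank5[ctx_ok] - 1L) * 4L + mm$flank3[ctx_ok]
        lin3 <- (mm$orient[ctx_ok] - 1L) * (12L * 16L) + (ctx_i - 1L) * 12L + cat_i[ctx_ok]
        acc$context <- acc$context + array(tabulate(lin3, 12L * 16L * 4L), c(12, 16, 4))
      }
    }

    rd <- w$reads
    acc$rmc[[length(acc$rmc) + 1L]] <-
      tibble(k = rd$n_mismatch, orient = orient) |> count(.data$k, .data$orient)
    acc$aligned_bases <- acc$aligned_bases + sum(rd$aligned_len)
    acc$n_n <- acc$n_n + sum(rd$n_n_positions)
    acc$fwd <- acc$fwd + sum(!fs$reverse); acc$rev <- acc$rev + sum(fs$reverse)
    acc$read_len_sum <- acc$read_len_sum + sum(nchar(seqs))
    rl_tab <- tabulate(nchar(seqs), nbins = L)
    if (length(acc$read_len_tab) < L) acc$read_len_tab <- c(acc$read_len_tab,
      numeric(L - length(acc$read_len_tab)))
    acc$read_len_tab[seq_len(L)] <- acc$read_len_tab[seq_len(L)] + rl_tab

    addtab <- function(cur, v) {
      v <- v[v > 0L]
      if (!length(v)) return(cur)
      tb <- tabulate(v, nbins = max(v))
      if (length(cur) < length(tb)) cur <- c(cur, numeric(length(tb) - length(cur)))
      cur[seq_along(tb)] <- cur[seq_along(tb)] + tb
      cur
    }
    acc$clip5 <- addtab(acc$clip5, rd$clip5)
    acc$clip3 <- addtab(acc$clip3, rd$clip3)
    acc$ins_len <- addtab(acc$ins_len, w$ins_len)
    acc$del_len <- addtab(acc$del_len, w$del_len)

    gc_pct <- as.integer(round(100 * rd$gc_count / pmax(1L, rd$gc_count + rd$at_count)))
    acc$gc_hist <- acc$gc_hist + tabulate(gc_pct + 1L, nbins = 101L)
    acc$mapq_hist <- acc$mapq_hist + tabulate(pmin(ch$mapq, 255L) + 1L, nbins = 256L)

    # insert sizes: |TLEN| of read1 in proper pairs only
    is_ins <- fs$proper_pair & fs$read1 & !is.na(ch$isize) & ch$isize != 0L
    if (any(is_ins)) {
      iv <- pmin(abs(ch$isize[is_ins]), insert_cap + 1L)
      acc$insert_hist <- acc$insert_hist + tabulate(iv, nbins = insert_cap + 1L)
    }

    # adapter content: exact-prefix match on 3' soft-clipped tails
    has_s3 <- grepl("[0-9]+S$", as.character(ch$cigar))
    acc$clipped_reads <- acc$clipped_reads + sum(rd$clip5 > 0L | rd$clip3 > 0L)
    if (any(has_s3)) {
      s3len <- as.integer(sub("^.*[MIDNSHP=X]([0-9]+)S$", "\\1", as.character(ch$cigar)[has_s3]))
      tails <- substring(seqs[has_s3], nchar(seqs[has_s3]) - s3len + 1L)
      hit <- vapply(tails, function(tl) {
        any(vapply(adapters, function(ad) {
          k <- min(nchar(tl), nchar(ad))
          k >= 5L && substr(tl, 1, k) == substr(ad, 1, k)
        }, TRUE))
      }, TRUE, USE.NAMES = FALSE)
      acc$adapter_hits <- acc$adapter_hits + sum(hit)
    }
    invisible(NULL)
  }

  if (is.null(which_gr)) {
    param <- Rsamtools::ScanBamParam(what = param_fields, tag = tags)
    repeat {
      ch <- Rsamtools::scanBam(bf, param = param)[[1]]
      if (length(ch$flag) == 0L) break
      process_chunk(ch)
    }
  } else {
    param <- Rsamtools::ScanBamParam(what = param_fields, tag = tags, which = which_gr)
    res <- Rsamtools::scanBam(bf, param = param)
    for (ch in res) process_chunk(ch)
  }

  if (acc$counts["total"] == 0) warn("BAM contains no records; returning zero counts")

  build_bamqc_result(acc, sample = sample, bam = bam, ref_label = ref_label,
                     refc = refc, policy = policy, which_gr = which_gr,
                     read_group = read_group, insert_cap = insert_cap)
}

within_chunk <- function(ch, keep) {
  out <- lapply(ch[setdiff(names(ch), "tag")], function(x) x[keep])
  if (!is.null(ch$tag)) out$tag <- lapply(ch$tag, function(x) x[keep])
  out
}

# assemble tibbles from the raw accumulators
build_bamqc_result <- function(acc, sample, bam, ref_label, refc, policy,
                               which_gr, read_group, insert_cap) {
  L <- max(acc$max_len, 1L)
  z2 <- function(x, d2) if (is.null(x)) array(0, c(L, d2)) else x
  cycle_cov <- z2(acc$cycle_cov, 4L)
  mm_cc <- if (is.null(acc$mm_cat_cycle)) array(0, c(L, 4, 12)) else acc$mm_cat_cycle
  mmq <- z2(acc$mm_qual_cycle_sum, 4L)

  strat <- function(m) cbind(m, overall = rowSums(m))  # L x 5
  cov5 <- strat(cycle_cov)
  mm_cyc <- apply(mm_cc, c(1, 2), sum)                 # L x 4
  mm5 <- strat(mm_cyc)
  mmq5 <- strat(mmq)
  strata <- c(ORIENT_LEVELS, "overall")

  per_cycle <- map_dfr(seq_along(strata), function(s) {
    tibble(stratum = strata[s], cycle = seq_len(L),
           n_aligned_reads = as.integer(cov5[, s]),
           n_mismatch = as.integer(mm5[, s]),
           subst_rate = ifelse(cov5[, s] > 0, 100 * mm5[, s] / cov5[, s], NA_real_),
           mean_mm_qual = ifelse(mm5[, s] > 0, mmq5[, s] / mm5[, s], NA_real_))
  })

  # per-cycle category percentages
  per_cycle_category <- map_dfr(seq_len(4L), function(o) {
    m <- mm_cc[, o, , drop = FALSE]
    dimnames(m) <- list(NULL, NULL, SUBST_CATEGORIES)
    as_tibble(as.data.frame.table(m[, 1, ], responseName = "n")) |>
      mutate(stratum = ORIENT_LEVELS[o],
             cycle = as.integer(.data$Var1), category = as.character(.data$Var2)) |>
      select("stratum", "cycle", "category", "n")
  })
  overall_pcc <- per_cycle_category |>
    group_by(.data$cycle, .data$category) |>
    summarise(n = sum(.data$n), .groups = "drop") |>
    mutate(stratum = "overall") |>
    select("stratum", "cycle", "category", "n")
  per_cycle_category <- bind_rows(per_cycle_category, overall_pcc) |>
    mutate(n = as.integer(.data$n)) |>
    group_by(.data$stratum, .data$cycle) |>
    mutate(pct = if (sum(.data$n) > 0) 100 * .data$n / sum(.data$n) else NA_real_) |>
    ungroup()

  cat_tot <- apply(mm_cc, c(2, 3), sum)                # 4 x 12
  cat5 <- rbind(cat_tot, overall = colSums(cat_tot))
  categories <- map_dfr(seq_along(strata), function(s) {
    n <- as.integer(cat5[s, ])
    tibble(stratum = strata[s], category = SUBST_CATEGORIES, n = n,
           pct = if (sum(n) > 0) 100 * n / sum(n) else NA_real_)
  })

  qb <- acc$qual_bins                                   # 12 x 4bin x 4ori
  qb5 <- array(0, c(12, 4, 5)); qb5[, , 1:4] <- qb
  qb5[, , 5] <- apply(qb, c(1, 2), sum)
  qual_bins <- map_dfr(seq_along(strata), function(s) {
    as_tibble(expand.grid(category = SUBST_CATEGORIES, bin = QUAL_BIN_LABELS,
                          stringsAsFactors = FALSE)) |>
      mutate(stratum = strata[s], n = as.integer(as.vector(qb5[, , s]))) |>
      select("stratum", "category", "bin", "n")
  })

  ctx <- acc$context                                    # 12 x 16 x 4
  ctx5 <- array(0, c(12, 16, 5)); ctx5[, , 1:4] <- ctx
  ctx5[, , 5] <- apply(ctx, c(1, 2), sum)
  context <- map_dfr(seq_along(strata), function(s) {
    as_tibble(expand.grid(category = SUBST_CATEGORIES, context = context_labels(),
                          stringsAsFactors = FALSE)) |>
      mutate(stratum = strata[s], n = as.integer(as.vector(ctx5[, , s]))) |>
      group_by(.data$category) |>
      mutate(pct = if (sum(.data$n) > 0) 100 * .data$n / sum(.data$n) else NA_real_) |>
      ungroup() |>
      select("stratum", "category", "context", "n", "pct")
  })

  rmc_all <- if (length(acc$rmc)) bind_rows(acc$rmc) |>
    group_by(.data$k, .data$orient) |>
    summarise(n = sum(.data$n), .groups = "drop") else
      tibble(k = integer(), orient = integer(), n = integer())
  rmc_raw <- bind_rows(
    rmc_all |> mutate(stratum = ORIENT_LEVELS[.data$orient]) |>
      select("stratum", "k", "n"),
    rmc_all |> group_by(.data$k) |> summarise(n = sum(.data$n), .groups = "drop") |>
      mutate(stratum = "overall") |> select("stratum", "k", "n")) |>
    mutate(k = as.integer(.data$k), n = as.integer(.data$n)) |>
    arrange(.data$stratum, .data$k)
  rmc <- rmc_raw |>
    mutate(bin = ifelse(.data$k >= 5L, ">=5", as.character(.data$k))) |>
    group_by(.data$stratum, .data$bin) |>
    summarise(n = sum(.data$n), .groups = "drop") |>
    group_by(.data$stratum) |>
    mutate(pct = if (sum(.data$n) > 0) 100 * .data$n / sum(.data$n) else NA_real_) |>
    ungroup() |>
    mutate(bin = factor(.data$bin, levels = RMC_BIN_LABELS)) |>
    complete(stratum, bin, fill = list(n = 0L, pct = 0)) |>
    mutate(bin = as.character(.data$bin)) |>
    arrange(.data$stratum, match(.data$bin, RMC_BIN_LABELS))

  nt5 <- if (is.null(acc$nt_cycle)) array(0, c(L, 5)) else acc$nt_cycle
  nt_cycle <- as_tibble(nt5, .name_repair = ~c("A", "C", "G", "T", "N")) |>
    mutate(cycle = seq_len(L)) |>
    pivot_longer(c("A", "C", "G", "T", "N"), names_to = "base", values_to = "n") |>
    group_by(.data$cycle) |>
    mutate(pct = if (sum(.data$n) > 0) 100 * .data$n / sum(.data$n) else NA_real_,
           n = as.integer(.data$n)) |>
    ungroup()
  qual_cycle <- tibble(cycle = seq_len(L),
                       mean_qual = ifelse(z2(acc$qual_cycle_n, 1L)[, 1] > 0,
                                          z2(acc$qual_cycle_sum, 1L)[, 1] /
                                            z2(acc$qual_cycle_n, 1L)[, 1], NA_real_))

  hist_tib <- function(v, from = 1L, value = "len") {
    idx <- which(v > 0)
    tibble(!!value := as.integer(idx + from - 1L), n = as.integer(v[idx]))
  }
  distributions <- list(
    insert_size = {
      v <- acc$insert_hist
      tb <- hist_tib(v[-length(v)], from = 1L, value = "insert")
      if (v[length(v)] > 0) tb <- bind_rows(tb,
        tibble(insert = insert_cap + 1L, n = as.integer(v[length(v)])))
      tb
    },
    gc_content = hist_tib(acc$gc_hist, from = 0L, value = "gc_pct"),
    base_qual = hist_tib(acc$qual_hist, from = 0L, value = "qual"),
    mapq = hist_tib(acc$mapq_hist, from = 0L, value = "mapq"),
    read_length = hist_tib(acc$read_len_tab, value = "len"),
    clip5 = hist_tib(acc$clip5), clip3 = hist_tib(acc$clip3),
    ins_len = hist_tib(acc$ins_len), del_len = hist_tib(acc$del_len),
    nt_cycle = nt_cycle, qual_cycle = qual_cycle)

  total_mm <- sum(mm_cyc)
  kept <- as.numeric(acc$counts["kept"])
  ref_length <- if (!is.null(which_gr)) sum(GenomicRanges::width(which_gr)) else
    sum(nchar(unlist(refc)))
  ge5 <- sum(rmc_raw$n[rmc_raw$stratum == "overall" & rmc_raw$k >= 5L])
  summary <- list(
    mean_read_length = if (kept > 0) acc$read_len_sum / kept else NA_real_,
    mean_depth = acc$aligned_bases / max(1, ref_length),
    error_rate_per_base = if (acc$aligned_bases > 0) 100 * total_mm / acc$aligned_bases else NA_real_,
    mean_mismatches_per_read = if (kept > 0) total_mm / kept else NA_real_,
    strand_ratio = if (acc$rev > 0) acc$fwd / acc$rev else NA_real_,
    adapter_content_pct = if (kept > 0) 100 * acc$adapter_hits / kept else NA_real_,
    clipped_reads_pct = if (kept > 0) 100 * acc$clipped_reads / kept else NA_real_,
    pct_reads_ge5_mismatch = if (kept > 0) 100 * ge5 / kept else NA_real_,
    n_positions_with_N = acc$n_n,
    total_mismatches = total_mm,
    total_aligned_bases = acc$aligned_bases)

  structure(list(
    meta = list(sample = sample, bam = bam, reference = ref_label,
                read_length = L, policy = unclass(policy),
                region = if (is.null(which_gr)) NA_character_ else
                  paste(as.character(which_gr), collapse = ","),
                read_group = read_group %||% NA_character_),
    counts = acc$counts,
    per_cycle = per_cycle,
    per_cycle_category = per_cycle_category,
    categories = categories,
    qual_bins = qual_bins,
    context = context,
    rmc = rmc, rmc_raw = rmc_raw,
    distributions = distributions,
    summary = summary), class = "bamqc_result")
}

#' @export
print.bamqc_result <- function(x, ...) {
  cat("<bamqc_result> sample:", x$meta$sample, "\n")
  cat(sprintf("  records: %d total, %d mapped, %d kept\n",
              as.integer(x$counts["total"]), as.integer(x$counts["mapped"]),
              as.integer(x$counts["kept"])))
  cat(sprintf("  error rate: %.4f%% per aligned base; mean depth %.2fx; read length %d\n",
              x$summary$error_rate_per_base, x$summary$mean_depth,
              x$meta$read_length))
  invisible(x)
}

#' Correlation between per-cycle substitution rate and mismatch quality
#'
#' Pearson correlation, over cycles with at least one mismatch, between the
#' per-cycle substitution rate and the mean quality of mismatched bases.
#' Phasing/pre-phasing decay produces a strongly negative value.
#'
#' @param result A `bamqc_result`.
#' @param stratum Stratum to use (default `"overall"`).
#' @return Pearson r in `[-1, 1]`, or `NA` if fewer than 3 usable cycles or
#'   zero variance.
#' @export
per_cycle_quality_correlation <- function(result, stratum = "overall") {
  pc <- filter(result$per_cycle, .data$stratum == !!stratum, .data$n_mismatch > 0L,
               is.finite(.data$subst_rate), is.finite(.data$mean_mm_qual))
  if (nrow(pc) < 3L) return(NA_real_)
  if (sd(pc$subst_rate) == 0 || sd(pc$mean_mm_qual) == 0) return(NA_real_)
  cor(pc$subst_rate, pc$mean_mm_qual)
}

#' Read a BED file into a GRanges
#'
#' BED is 0-based half-open; the returned ranges are 1-based closed. Extra
#' columns 4 and 5 are kept as `gene` and `exon_label` metadata when present.
#'
#' @param path BED path (3+ tab-separated columns, no header).
#' @return A `GRanges`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 3L) abort("BED file needs at least 3 columns")
  gr <- GenomicRanges::GRanges(df[[1]],
                               IRanges::IRanges(start = df[[2]] + 1L, end = df[[3]]))
  if (ncol(df) >= 4L) gr$gene <- as.character(df[[4]])
  if (ncol(df) >= 5L) gr$exon_label <- as.character(df[[5]])
  gr
}
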