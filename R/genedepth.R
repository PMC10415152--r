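DEPTH_THRESHOLDS <- c(1L, 10L, 20L, 30L, 50L, 100L)

policy_scanbam_flag <- function(policy) {
  Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = if (policy$keep_secondary) NA else FALSE,
    isSupplementaryAlignment = if (policy$keep_supplementary) NA else FALSE,
    isDuplicate = if (policy$keep_duplicates) NA else FALSE,
    isNotPassingQualityControls = if (policy$keep_qcfail) NA else FALSE)
}

#' Per-position depth profile of an interval
#'
#' Pileup-derived depth over a genomic interval, with each position's depth
#' split into reference-matching and non-reference aligned bases (they add
#' up to the total depth); reads spanning the position with a deletion are
#' counted separately in `n_del`, not in depth. Interval summaries report
#' length, reference GC%, mean depth and the fraction of positions covered
#' at each depth threshold.
#'
#' @param bam Indexed BAM path.
#' @param ref Reference FASTA path or named contig sequences.
#' @param chrom,start,end 1-based closed interval.
#' @param policy A [filter_policy()] (same defaults as [bamqc()]).
#' @param min_baseq Minimum base quality for a base to be counted (default 0).
#' @param max_depth Pileup depth cap (default 100000).
#' @return A list of class `depth_profile`: `positions` (tibble `pos`,
#'   `depth`, `n_ref`, `n_nonref`, `n_del`) and `summary` (one-row tibble
#'   with `chrom`, `start`, `end`, `length`, `gc_pct`, `mean_depth`, and
#'   `fraction_ge_<t>` columns).
#' @export
interval_depth <- function(bam, ref, chrom, start, end,
                           policy = filter_policy(), min_baseq = 0L,
                           max_depth = 100000L) {
  refc <- if (is.character(ref) && length(ref) == 1L && is.null(names(ref)))
    read_reference(ref) else as_ref_chars(ref)
  if (!chrom %in% names(refc)) abort(paste0("contig not in reference: ", chrom))
  clen <- nchar(refc[[chrom]])
  if (start < 1L) { start <- 1L }
  if (end > clen) {
    warn(paste0("interval extends beyond contig end; clipped to ", clen))
    end <- clen
  }
  if (start > end) abort("empty interval after clipping")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  sbp <- Rsamtools::ScanBamParam(which = gr, flag = policy_scanbam_flag(policy),
                                 mapqFilter = policy$min_mapq)
  pp <- Rsamtools::PileupParam(max_depth = max_depth,
                               min_base_quality = as.integer(min_baseq),
                               min_mapq = policy$min_mapq,
                               min_nucleotide_depth = 1L,
                               distinguish_strands = FALSE,
                               distinguish_nucleotides = TRUE,
                               ignore_query_Ns = TRUE,
                               include_deletions = TRUE,
                               include_insertions = FALSE)
  pu <- Rsamtools::pileup(bam, scanBamParam = sbp, pileupParam = pp)
  np <- end - start + 1L
  refbases <- strsplit(toupper(substr(refc[[chrom]], start, end)), "")[[1]]
  depth <- n_ref <- n_del <- integer(np)
  if (nrow(pu)) {
    k <- pu$pos - start + 1L
    ok <- k >= 1L & k <= np
    pu <- pu[ok, ]; k <- k[ok]
    is_del <- pu$nucleotide == "-"
    for (i in which(is_del)) n_del[k[i]] <- n_del[k[i]] + pu$count[i]
    base_rows <- which(!is_del & pu$nucleotide %in% BASES)
    for (i in base_rows) {
      depth[k[i]] <- depth[k[i]] + pu$count[i]
      if (as.character(pu$nucleotide[i]) == refbases[k[i]]) {
        n_ref[k[i]] <- n_ref[k[i]] + pu$count[i]
      }
    }
  }
  positions <- tibble(pos = start:end, depth = depth, n_ref = n_ref,
                      n_nonref = depth - n_ref, n_del = n_del)
  gc_pct <- 100 * sum(refbases %in% c("G", "C")) / np
  smry <- tibble(chrom = chrom, start = start, end = end, length = np,
                 gc_pct = gc_pct, mean_depth = sum(depth) / np)
  for (t in DEPTH_THRESHOLDS) {
    smry[[paste0("fraction_ge_", t)]] <- mean(depth >= t)
  }
  structure(list(positions = positions, summary = smry),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<depth_profile> %s:%d-%d  mean depth %.2fx, GC %.1f%%\n",
              s$chrom, s$start, s$end, s$mean_depth, s$gc_pct))
  invisible(x)
}

#' Fraction of interval positions covered at a depth threshold
#'
#' @param profile A `depth_profile`.
#' @param t Depth threshold (>= 1).
#' @return Fraction in `[0, 1]`.
#' @export
fraction_at_depth <- function(profile, t) {
  if (t < 1) abort("threshold must be >= 1")
  mean(profile$positions$depth >= t)
}

#' Exon-wise gene depth report
#'
#' Computes a depth profile per exon from a 5-column BED (chrom, start,
#' end, gene, exon label; BED coordinates 0-based half-open), writes a
#' per-exon TSV log and a static HTML report with one depth track per exon.
#' Zero-coverage exons are flagged prominently.
#'
#' @param bam Indexed BAM path.
#' @param ref Reference FASTA path.
#' @param bed BED path or `GRanges` with `gene`/`exon_label` metadata.
#' @param outdir Output directory (`NULL` to skip writing).
#' @param policy A [filter_policy()].
#' @param min_baseq Minimum base quality.
#' @return A list of class `gene_report`: `exons` (tibble: gene, exon,
#'   chrom, start, end, length, gc_pct, mean_depth, fraction_ge_*,
#'   zero_coverage), `profiles` (named list of `depth_profile`).
#' @export
gene_report <- function(bam, ref, bed, outdir = NULL,
                        policy = filter_policy(), min_baseq = 0L) {
  gr <- if (methods::is(bed, "GRanges")) bed else read_bed(bed)
  if (is.null(gr$gene)) abort("BED needs a 4th column with the gene name")
  if (is.null(gr$exon_label)) gr$exon_label <- paste0("exon", seq_along(gr))
  profiles <- list()
  rows <- list()
  for (i in seq_along(gr)) {
    chrom <- as.character(GenomicRanges::seqnames(gr)[i])
    st <- GenomicRanges::start(gr)[i]; en <- GenomicRanges::end(gr)[i]
    dp <- interval_depth(bam, ref, chrom, st, en, policy = policy,
                         min_baseq = min_baseq)
    key <- paste0(gr$gene[i], ":", gr$exon_label[i])
    profiles[[key]] <- dp
    rows[[i]] <- mutate(dp$summary, gene = gr$gene[i], exon = gr$exon_label[i],
                        zero_coverage = .data$mean_depth == 0, .before = 1)
  }
  exons <- bind_rows(rows) |>
    select("gene", "exon", "chrom", "start", "end", "length", "gc_pct",
           "mean_depth", starts_with("fraction_ge_"), "zero_coverage")
  rep <- structure(list(exons = exons, profiles = profiles),
                   class = "gene_report")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(exons, file.path(outdir, "gene_depth.tsv"))
    render_gene_report(rep, outdir)
  }
  rep
}

#' @export
print.gene_report <- function(x, ...) {
  cat("<gene_report>", nrow(x$exons), "exons,",
      sum(x$exons$zero_coverage), "with zero coverage\n")
  invisible(x)
}

#' @export
tidy.gene_report <- function(x, ...) x$exons

#' Plot one exon's depth track
#'
#' @param object A `gene_report`.
#' @param exon Key `"gene:exon"` (default: first exon).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gene_report <- function(object, exon = NULL, ...) {
  exon <- exon %||% names(object$profiles)[1]
  dp <- object$profiles[[exon]]
  ggplot2::ggplot(dp$positions, ggplot2::aes(x = .data$pos, y = .data$depth)) +
    ggplot2::geom_area(fill = "steelblue", alpha = 0.7) +
    ggplot2::labs(title = exon, x = "exonic position", y = "depth")
}

render_gene_report <- function(rep, outdir) {
  sections <- list(list(heading = "Per-exon summary", table = rep$exons))
  zero <- filter(rep$exons, .data$zero_coverage)
  if (nrow(zero)) {
    sections <- c(sections, list(list(
      heading = "Zero-coverage exons",
      note = paste("No reads cover:",
                   paste(paste0(zero$gene, ":", zero$exon), collapse = ", ")))))
  }
  for (key in names(rep$profiles)) {
    sections <- c(sections, list(list(heading = paste0("Depth track - ", key),
                                      plot = autoplot(rep, key), height = 2.5)))
  }
  write_html_report(file.path(outdir, "report.html"), "Gene depth report",
                    sections)
}
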