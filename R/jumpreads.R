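#' Criteria for atypical ("jump") read-pair extraction
#'
#' @param min_insert Minimum |TLEN| for the long-insert class (default 1000).
#' @param include_interchrom Extract pairs whose mates map to different
#'   contigs?
#' @param include_anomalous_orient Extract forward-forward, reverse-reverse
#'   and outward-oriented pairs?
#' @return List of class `jump_criteria`.
#' @export
jump_criteria <- function(min_insert = 1000L, include_interchrom = TRUE,
                          include_anomalous_orient = TRUE) {
  if (min_insert < 1L) abort("min_insert must be >= 1")
  structure(list(min_insert = as.integer(min_insert),
                 include_interchrom = include_interchrom,
                 include_anomalous_orient = include_anomalous_orient),
            class = "jump_criteria")
}

JUMP_CLASSES <- c("LONG_INSERT", "INTERCHROM", "ANOM_FF", "ANOM_RR",
                  "ANOM_OUTWARD", "NORMAL")

#' Classify read pairs by mapping anomaly
#'
#' Vectorised classification of mapped, primary, paired records with mapped
#' mates. Precedence: `INTERCHROM` (mate on a different contig) >
#' orientation anomalies (`ANOM_FF`/`ANOM_RR` when both mates share a
#' strand; `ANOM_OUTWARD` when the leftmost mate is reverse and the
#' rightmost forward) > `LONG_INSERT` (|TLEN| >= `min_insert`) > `NORMAL`.
#' Disabled criteria fall through to the next class.
#'
#' @param chrom,mate_chrom Contig of the record and its mate.
#' @param pos,mate_pos Leftmost positions of the record and its mate.
#' @param reverse,mate_reverse Strand of the record and its mate.
#' @param tlen Signed template length.
#' @param criteria A [jump_criteria()].
#' @return Character vector of `JUMP_CLASSES` values.
#' @export
classify_pair <- function(chrom, mate_chrom, pos, mate_pos, reverse,
                          mate_reverse, tlen, criteria = jump_criteria()) {
  n <- length(chrom)
  out <- rep("NORMAL", n)
  left_rev <- ifelse(pos <= mate_pos, reverse, mate_reverse)
  right_rev <- ifelse(pos <= mate_pos, mate_reverse, reverse)
  out[abs(tlen) >= criteria$min_insert] <- "LONG_INSERT"
  if (criteria$include_anomalous_orient) {
    out[left_rev & !right_rev] <- "ANOM_OUTWARD"
    out[!reverse & !mate_reverse] <- "ANOM_FF"
    out[reverse & mate_reverse] <- "ANOM_RR"
  }
  if (criteria$include_interchrom) {
    out[as.character(chrom) != as.character(mate_chrom)] <- "INTERCHROM"
  }
  out
}

#' Extract atypical read pairs into a BAM
#'
#' Scans a coordinate-sorted BAM, classifies every mapped primary paired
#' record with a mapped mate, and writes the non-`NORMAL` records (under
#' the enabled criteria) to an output BAM preserving header and order.
#' Counts are logged per class and as a fraction of total mapped reads.
#'
#' @param bam Input BAM path.
#' @param out_bam Output BAM path.
#' @param criteria A [jump_criteria()].
#' @param log Optional TSV path for the class-count table.
#' @return A list of class `jump_result`: `counts` (tibble `class`, `n`,
#'   `pct_of_mapped`), `n_mapped`, `n_skipped` (mate-unmapped or
#'   secondary/supplementary), `out_bam`, `reads` (tibble `query_name`,
#'   `class` for selected records).
#' @export
jump_extract <- function(bam, out_bam, criteria = jump_criteria(), log = NULL) {
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mrnm", "mpos", "isize"))
  ch <- Rsamtools::scanBam(bam, param = param)[[1]]
  fs <- decode_flags(ch$flag)
  n_mapped <- sum(!fs$unmapped)
  eligible <- !fs$unmapped & fs$paired & !fs$mate_unmapped &
    !fs$secondary & !fs$supplementary
  n_skipped <- sum(!eligible)
  cls <- rep(NA_character_, length(ch$flag))
  if (any(eligible)) {
    cls[eligible] <- classify_pair(
      chrom = as.character(ch$rname[eligible]),
      mate_chrom = as.character(ch$mrnm[eligible]),
      pos = ch$pos[eligible], mate_pos = ch$mpos[eligible],
      reverse = fs$reverse[eligible], mate_reverse = fs$mate_reverse[eligible],
      tlen = ch$isize[eligible], criteria = criteria)
  }
  selected <- !is.na(cls) & cls != "NORMAL"
  reads <- tibble(query_name = ch$qname[selected], class = cls[selected])

  counts <- tibble(class = factor(cls[selected], levels = setdiff(JUMP_CLASSES, "NORMAL"))) |>
    count(.data$class, .drop = FALSE, name = "n") |>
    mutate(class = as.character(.data$class),
           pct_of_mapped = if (n_mapped > 0) 100 * .data$n / n_mapped else 0)

  rules <- S4Vectors::FilterRules(list(jump = function(x) {
    fl <- decode_flags(x$flag)
    elig <- !fl$unmapped & fl$paired & !fl$mate_unmapped &
      !fl$secondary & !fl$supplementary
    out <- logical(nrow(x))
    if (any(elig)) {
      k <- classify_pair(as.character(x$rname[elig]), as.character(x$mrnm[elig]),
                         x$pos[elig], x$mpos[elig], fl$reverse[elig],
                         fl$mate_reverse[elig], x$isize[elig], criteria)
      out[elig] <- k != "NORMAL"
    }
    out
  }))
  dest <- Rsamtools::filterBam(
    bam, destination = out_bam, filter = rules,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mrnm", "mpos", "isize")))
  if (!is.null(log)) readr::write_tsv(counts, log)
  structure(list(counts = counts, n_mapped = n_mapped, n_skipped = n_skipped,
                 out_bam = dest, reads = reads), class = "jump_result")
}

#' @export
print.jump_result <- function(x, ...) {
  cat("<jump_result>", sum(x$counts$n), "atypical records of",
      x$n_mapped, "mapped\n")
  print(x$counts)
  invisible(x)
}

#' @export
tidy.jump_result <- function(x, ...) x$counts
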