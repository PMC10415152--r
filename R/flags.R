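#' Decode SAM flag integers
#'
#' Expands SAM flag bit fields into named logical columns, one row per flag.
#'
#' @param flag Integer vector of SAM flags (0 <= flag < 65536).
#' @return A tibble with columns `flag`, `paired`, `proper_pair`, `unmapped`,
#'   `mate_unmapped`, `reverse`, `mate_reverse`, `read1`, `read2`,
#'   `secondary`, `qcfail`, `duplicate`, `supplementary`.
#' @export
#' @examples
#' decode_flags(c(99, 147, 83, 163, 4))
decode_flags <- function(flag) {
  flag <- as.integer(flag)
  if (any(is.na(flag)) || any(flag < 0L) || any(flag >= 65536L)) {
    abort("SAM flags must be integers in [0, 65536)")
  }
  bit <- function(b) bitwAnd(flag, b) != 0L
  tibble(
    flag = flag,
    paired        = bit(0x1),
    proper_pair   = bit(0x2),
    unmapped      = bit(0x4),
    mate_unmapped = bit(0x8),
    reverse       = bit(0x10),
    mate_reverse  = bit(0x20),
    read1         = bit(0x40),
    read2         = bit(0x80),
    secondary     = bit(0x100),
    qcfail        = bit(0x200),
    duplicate     = bit(0x400),
    supplementary = bit(0x800)
  )
}

#' Classify paired-end orientation
#'
#' Maps mapped primary paired reads onto the four orientation classes
#' `R1F`, `R1R`, `R2F`, `R2R` (first/second in pair crossed with
#' forward/reverse alignment strand). The toolkit is paired-end only:
#' unpaired records, or records with an ambiguous first/second-in-pair
#' state, are rejected.
#'
#' @param flag Integer vector of SAM flags.
#' @return Character vector of orientation classes (same length as `flag`).
#' @export
#' @examples
#' classify_orientation(c(99, 147, 83, 163))
classify_orientation <- function(flag) {
  fs <- decode_flags(flag)
  if (any(!fs$paired)) {
    abort("single-end unsupported: unpaired record encountered (paired-end-only tool)")
  }
  if (any(fs$read1 == fs$read2)) {
    abort("ambiguous pair membership: read1/read2 flag bits must differ")
  }
  ifelse(fs$read1,
         ifelse(fs$reverse, "R1R", "R1F"),
         ifelse(fs$reverse, "R2R", "R2F"))
}

#' Sequencing cycle of an aligned query position
#'
#' Converts a 0-based query index (position within SEQ as stored, i.e.
#' reference orientation) into the 1-based sequencing cycle. For
#' reverse-strand alignments the stored bases run opposite to sequencing
#' order, so the mapping is mirrored.
#'
#' @param index 0-based query index (vectorised).
#' @param read_len Read length(s).
#' @param is_reverse Logical; reverse-strand alignment?
#' @return Integer cycle in `1..read_len`.
#' @export
#' @examples
#' cycle_of(0, 100, FALSE)  # 1
#' cycle_of(0, 100, TRUE)   # 100
cycle_of <- function(index, read_len, is_reverse) {
  index <- as.integer(index)
  read_len <- as.integer(read_len)
  if (any(index < 0L) || any(index >= read_len)) {
    abort("query index out of range [0, read_len)")
  }
  n <- max(length(index), length(read_len), length(is_reverse))
  index <- rep_len(index, n)
  read_len <- rep_len(read_len, n)
  is_reverse <- rep_len(is_reverse, n)
  as.integer(ifelse(is_reverse, read_len - index, index + 1L))
}

#' Default record-filter policy
#'
#' @param min_mapq Minimum mapping quality for a read to enter profile
#'   accumulation (default 0, i.e. no filter).
#' @param keep_duplicates Keep duplicate-flagged reads? Default `FALSE`.
#' @param keep_qcfail Keep QC-failed reads? Default `FALSE`.
#' @param keep_secondary Keep secondary alignments? Default `FALSE`.
#' @param keep_supplementary Keep supplementary alignments? Default `FALSE`.
#' @return A list of class `alnqc_policy`.
#' @export
filter_policy <- function(min_mapq = 0L, keep_duplicates = FALSE,
                          keep_qcfail = FALSE, keep_secondary = FALSE,
                          keep_supplementary = FALSE) {
  structure(list(min_mapq = as.integer(min_mapq),
                 keep_duplicates = keep_duplicates,
                 keep_qcfail = keep_qcfail,
                 keep_secondary = keep_secondary,
                 keep_supplementary = keep_supplementary),
            class = "alnqc_policy")
}

#' Apply the record-filter policy
#'
#' Decides, per record, whether it enters profile accumulation. Skipped
#' categories are still tallied in the summary counters by the callers.
#' The default policy keeps mapped, primary, non-supplementary,
#' non-duplicate, non-QC-failed paired reads.
#'
#' @param flag Integer vector of SAM flags.
#' @param mapq Integer vector of mapping qualities (same length).
#' @param policy A [filter_policy()] object.
#' @return A tibble with columns `keep` (logical) and `skip_reason`
#'   (`NA` for kept reads; otherwise the first matching reason among
#'   `unmapped`, `unpaired`, `secondary`, `supplementary`, `qcfail`,
#'   `duplicate`, `low_mapq`).
#' @export
record_filter <- function(flag, mapq, policy = filter_policy()) {
  fs <- decode_flags(flag)
  mapq <- as.integer(mapq)
  reason <- rep(NA_character_, nrow(fs))
  set <- function(cond, lab) ifelse(is.na(reason) & cond, lab, reason)
  reason <- set(fs$unmapped, "unmapped")
  reason <- set(!fs$paired, "unpaired")
  if (!policy$keep_secondary)     reason <- set(fs$secondary, "secondary")
  if (!policy$keep_supplementary) reason <- set(fs$supplementary, "supplementary")
  if (!policy$keep_qcfail)        reason <- set(fs$qcfail, "qcfail")
  if (!policy$keep_duplicates)    reason <- set(fs$duplicate, "duplicate")
  if (policy$min_mapq > 0L)       reason <- set(!is.na(mapq) & mapq < policy$min_mapq, "low_mapq")
  tibble(keep = is.na(reason), skip_reason = reason)
}
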