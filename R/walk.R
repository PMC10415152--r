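#' Parse a CIGAR string
#'
#' @param cigar A single CIGAR string (e.g. `"2S6M1D2M"`).
#' @return A tibble with columns `op` and `len` in order.
#' @export
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*") return(tibble(op = character(), len = integer()))
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(lens) != length(ops)) abort(paste0("malformed CIGAR: ", cigar))
  tibble(op = ops, len = lens)
}

#' Walk one alignment record against the reference
#'
#' Re-aligns a single read against the reference sequence using its CIGAR,
#' position and strand, emitting every mismatch with its sequencing cycle,
#' base quality, reference flanking bases and orientation class, together
#' with indel and clip events. This is the reference implementation of the
#' per-read walk; [bamqc()] uses a compiled batch equivalent.
#'
#' Substitution categories and flanking bases are reported in reference
#' (genome forward strand) orientation; strand information is carried by the
#' orientation class. Positions where either the read or the reference base
#' is `N` are never counted as substitutions and are excluded from aligned
#' cycles; they are tallied in `n_n_positions`.
#'
#' @param read A list with elements `chrom`, `pos` (1-based), `flag`,
#'   `cigar`, `seq`, `qual` (Phred+33 string or `"*"`).
#' @param ref A named character vector of contig sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @return A list of class `read_events`: `mismatches` (tibble with columns
#'   `chrom`, `ref_pos`, `cycle`, `ref_base`, `read_base`, `base_qual`,
#'   `flank5`, `flank3`, `category`, `orientation`), `insertions`,
#'   `deletions` (integer length vectors), `clip5_len`, `clip3_len`
#'   (soft+hard clip totals at the read 5'/3' ends in sequencing
#'   orientation), `aligned_cycles` (integer set), `n_mismatches`,
#'   `n_n_positions`.
#' @export
walk_alignment <- function(read, ref) {
  ref <- as_ref_chars(ref)
  if (!read$chrom %in% names(ref)) {
    abort(paste0("contig not found in reference: ", read$chrom))
  }
  rseq <- ref[[read$chrom]]
  rl <- nchar(rseq)
  fs <- decode_flags(read$flag)
  rev <- fs$reverse
  orientation <- classify_orientation(read$flag)
  s <- strsplit(toupper(read$seq), "")[[1]]
  L <- length(s)
  quals <- if (identical(read$qual, "*") || is.null(read$qual)) {
    rep(NA_integer_, L)
  } else {
    utf8ToInt(read$qual) - 33L
  }
  if (!is.na(quals[1]) && length(quals) != L) abort("SEQ and QUAL lengths differ")
  cig <- parse_cigar(read$cigar)
  qlen <- sum(cig$len[cig$op %in% c("M", "I", "S", "=", "X")])
  if (qlen != L) abort("CIGAR query length differs from SEQ length")

  qi <- 0L; rp <- read$pos - 1L  # rp: 0-based ref index
  mm <- list()
  ins <- integer(); del <- integer()
  clip_left <- 0L; clip_right <- 0L
  aligned_cycles <- integer(); n_n <- 0L
  seen_core <- FALSE
  for (j in seq_len(nrow(cig))) {
    op <- cig$op[j]; len <- cig$len[j]
    if (op %in% c("M", "=", "X")) {
      for (t in seq_len(len)) {
        if (rp < 0L || rp >= rl) abort("alignment walks off contig end")
        rb <- toupper(substr(rseq, rp + 1L, rp + 1L))
        qb <- s[qi + 1L]
        cyc <- cycle_of(qi, L, rev)
        if (!(rb %in% BASES) || !(qb %in% BASES)) {
          n_n <- n_n + 1L
        } else {
          aligned_cycles <- c(aligned_cycles, cyc)
          if (rb != qb) {
            mm[[length(mm) + 1L]] <- tibble(
              chrom = read$chrom, ref_pos = rp + 1L, cycle = cyc,
              ref_base = rb, read_base = qb, base_qual = quals[qi + 1L],
              flank5 = if (rp > 0L) toupper(substr(rseq, rp, rp)) else NA_character_,
              flank3 = if (rp + 1L < rl) toupper(substr(rseq, rp + 2L, rp + 2L)) else NA_character_,
              category = paste0(rb, ">", qb), orientation = orientation)
          }
        }
        qi <- qi + 1L; rp <- rp + 1L
      }
      seen_core <- TRUE
    } else if (op == "I") {
      ins <- c(ins, len); qi <- qi + len; seen_core <- TRUE
    } else if (op == "D") {
      del <- c(del, len); rp <- rp + len; seen_core <- TRUE
    } else if (op == "N") {
      rp <- rp + len
    } else if (op %in% c("S", "H")) {
      if (!seen_core) clip_left <- clip_left + len else clip_right <- clip_right + len
      if (op == "S") qi <- qi + len
    }
  }
  mismatches <- if (length(mm)) bind_rows(mm) else tibble(
    chrom = character(), ref_pos = integer(), cycle = integer(),
    ref_base = character(), read_base = character(), base_qual = integer(),
    flank5 = character(), flank3 = character(), category = character(),
    orientation = character())
  # record-left clip is the read's 3' clip on reverse-strand alignments
  structure(list(
    mismatches = mismatches,
    insertions = ins, deletions = del,
    clip5_len = if (rev) clip_right else clip_left,
    clip3_len = if (rev) clip_left else clip_right,
    aligned_cycles = sort(unique(aligned_cycles)),
    n_mismatches = nrow(mismatches),
    n_n_positions = n_n,
    orientation = orientation), class = "read_events")
}

# coerce DNAStringSet / character to a named character list of contigs
as_ref_chars <- function(ref) {
  if (methods::is(ref, "DNAStringSet")) {
    out <- as.list(as.character(ref))
    # FASTA headers may carry descriptions; keep the first word
    names(out) <- sub("\\s.*$", "", names(out))
    return(out)
  }
  if (is.list(ref)) {
    if (is.null(names(ref))) abort("reference list must be named by contig")
    return(ref)
  }
  if (is.character(ref)) {
    if (is.null(names(ref))) abort("character reference must be named by contig")
    return(as.list(ref))
  }
  abort("reference must be a named character vector, list or DNAStringSet")
}

#' Read a reference FASTA into contig strings
#'
#' @param fasta Path to a FASTA file.
#' @return Named list of contig sequences (character).
#' @export
read_reference <- function(fasta) {
  as_ref_chars(Biostrings::readDNAStringSet(fasta))
}
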