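#' Parse a site-query string
#'
#' Accepts `"chr1:100-100"` and `"chr1:100"` forms.
#'
#' @param q Query string.
#' @return List with `chrom` and `pos`.
#' @export
parse_site_query <- function(q) {
  m <- regmatches(q, regexec("^(\\S+):([0-9]+)(?:-([0-9]+))?$", q))[[1]]
  if (!length(m)) abort(paste0("cannot parse site query: ", q))
  pos <- as.integer(m[3])
  if (m[4] != "" && as.integer(m[4]) != pos) {
    abort("site queries address a single coordinate (pos-pos)")
  }
  list(chrom = m[2], pos = pos)
}

# base carried by one read at a reference position (or DEL / REFSKIP / NA)
base_at_position <- function(pos0, cigar, read_pos, seq, qual) {
  cig <- parse_cigar(cigar)
  qi <- 0L; rp <- read_pos - 1L
  for (j in seq_len(nrow(cig))) {
    op <- cig$op[j]; len <- cig$len[j]
    if (op %in% c("M", "=", "X")) {
      if (pos0 >= rp && pos0 < rp + len) {
        k <- qi + (pos0 - rp) + 1L
        bq <- if (identical(qual, "*")) NA_integer_ else utf8ToInt(substr(qual, k, k)) - 33L
        return(list(base = toupper(substr(seq, k, k)), qual = bq))
      }
      qi <- qi + len; rp <- rp + len
    } else if (op == "I") { qi <- qi + len
    } else if (op == "D") {
      if (pos0 >= rp && pos0 < rp + len) return(list(base = "DEL", qual = NA_integer_))
      rp <- rp + len
    } else if (op == "N") {
      if (pos0 >= rp && pos0 < rp + len) return(list(base = "REFSKIP", qual = NA_integer_))
      rp <- rp + len
    } else if (op == "S") { qi <- qi + len }
  }
  list(base = NA_character_, qual = NA_integer_)
}

#' Query one genomic site in a BAM
#'
#' Extracts every kept read overlapping the coordinate and reports, per
#' read, the carried base (or `DEL`/`REFSKIP`), its base quality, strand,
#' pair member, mapping quality, template length (signed TLEN of the
#' record) and read group, plus per-allele aggregates. Deletion- or
#' skip-spanning reads are listed but excluded from base-allele aggregates
#' and depth.
#'
#' @param bam Indexed BAM path.
#' @param ref Reference FASTA path or named contig sequences.
#' @param query Query string (`"chr1:100"` / `"chr1:100-100"`) or a list
#'   with `chrom` and `pos`.
#' @param policy A [filter_policy()].
#' @return A list of class `site_report`: `query`, `ref_base`, `entries`
#'   (tibble, one row per overlapping kept read), `alleles` (tibble with
#'   per-allele count, mean base quality, mean mapq, strand and pair
#'   composition), `depth`.
#' @export
query_site <- function(bam, ref, query, policy = filter_policy()) {
  q <- if (is.character(query)) parse_site_query(query) else query
  refc <- if (is.character(ref) && length(ref) == 1L && is.null(names(ref)))
    read_reference(ref) else as_ref_chars(ref)
  if (!q$chrom %in% names(refc)) abort(paste0("unknown contig: ", q$chrom))
  if (!file.exists(paste0(bam, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam))) {
    abort("BAM is not indexed; index it first (e.g. samtools index)")
  }
  ref_base <- toupper(substr(refc[[q$chrom]], q$pos, q$pos))
  gr <- GenomicRanges::GRanges(q$chrom, IRanges::IRanges(q$pos, q$pos))
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "pos", "mapq", "cigar", "seq", "qual", "isize"),
    tag = "RG", which = gr)
  ch <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(ch$flag)
  entries <- tibble(query_name = character(), base = character(),
                    base_qual = integer(), strand = character(),
                    pair = character(), mapq = integer(), insert = integer(),
                    read_group = character())
  if (n > 0L) {
    keep <- record_filter(ch$flag, ch$mapq, policy)$keep
    fs <- decode_flags(ch$flag)
    rows <- lapply(which(keep), function(i) {
      hit <- base_at_position(q$pos - 1L, as.character(ch$cigar[i]), ch$pos[i],
                              as.character(ch$seq[i]), as.character(ch$qual[i]))
      if (is.na(hit$base)) return(NULL)   # clipped over the locus
      tibble(query_name = ch$qname[i], base = hit$base, base_qual = hit$qual,
             strand = if (fs$reverse[i]) "-" else "+",
             pair = if (fs$read1[i]) "R1" else "R2",
             mapq = ch$mapq[i], insert = ch$isize[i],
             read_group = ch$tag$RG[i] %||% NA_character_)
    })
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (length(rows)) entries <- bind_rows(rows)
  }
  base_entries <- filter(entries, .data$base %in% BASES)
  alleles <- base_entries |>
    group_by(allele = .data$base) |>
    summarise(count = dplyr::n(),
              mean_base_qual = mean(.data$base_qual, na.rm = TRUE),
              mean_mapq = mean(.data$mapq),
              n_forward = sum(.data$strand == "+"),
              n_reverse = sum(.data$strand == "-"),
              n_r1 = sum(.data$pair == "R1"),
              n_r2 = sum(.data$pair == "R2"), .groups = "drop") |>
    arrange(desc(.data$count))
  structure(list(query = q, ref_base = ref_base, entries = entries,
                 alleles = alleles, depth = nrow(base_entries)),
            class = "site_report")
}

#' @export
print.site_report <- function(x, ...) {
  cat(sprintf("<site_report> %s:%d  ref %s, depth %d\n",
              x$query$chrom, x$query$pos, x$ref_base, x$depth))
  if (nrow(x$alleles)) print(x$alleles)
  invisible(x)
}

#' @export
tidy.site_report <- function(x, ...) x$entries

#' @export
glance.site_report <- function(x, ...) {
  alt <- filter(x$alleles, .data$allele != x$ref_base)
  tibble(chrom = x$query$chrom, pos = x$query$pos, ref_base = x$ref_base,
         depth = x$depth,
         n_ref = sum(x$alleles$count[x$alleles$allele == x$ref_base]),
         n_alt = sum(alt$count),
         top_alt = if (nrow(alt)) alt$allele[1] else NA_character_)
}

#' Batch site queries from a coordinate file
#'
#' Each line is `chrom:pos[-pos]` or `chrom<TAB>pos`. Malformed lines are
#' reported as warnings, not fatal. Reports come back in input order.
#'
#' @param bam,ref,policy As in [query_site()].
#' @param file Path to the coordinate list.
#' @param out Optional TSV path for the combined per-read table.
#' @return List of `site_report` (one per valid line), invisibly writing
#'   `out` when given.
#' @export
query_batch <- function(bam, ref, file, policy = filter_policy(), out = NULL) {
  lines <- trimws(readLines(file))
  lines <- lines[lines != ""]
  if (!length(lines)) abort("coordinate file is empty")
  lines <- sub("\t", ":", lines)   # accept chrom<TAB>pos
  reports <- list()
  for (ln in lines) {
    q <- tryCatch(parse_site_query(ln), error = function(e) {
      warn(paste0("skipping malformed line: ", ln)); NULL
    })
    if (is.null(q)) next
    reports[[length(reports) + 1L]] <- query_site(bam, ref, q, policy)
  }
  if (!is.null(out)) {
    combined <- map_dfr(reports, function(r) {
      mutate(r$entries, chrom = r$query$chrom, pos = r$query$pos,
             ref_base = r$ref_base, .before = 1)
    })
    readr::write_tsv(combined, out)
  }
  reports
}
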