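#' Write bamqc logs as plain-text TSV
#'
#' Writes one TSV per feature family plus key-value `summary.tsv`,
#' `counts.tsv` and `meta.tsv`, all parseable and reconstructable with
#' [read_bamqc_logs()] at exact counter equality.
#'
#' @param result A `bamqc_result`.
#' @param outdir Output directory (a `logs/` subdirectory is created).
#' @return Invisibly, the logs directory path.
#' @export
write_bamqc_logs <- function(result, outdir) {
  logdir <- file.path(outdir, "logs")
  dir.create(logdir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(tb, name) readr::write_tsv(tb, file.path(logdir, paste0(name, ".tsv")))
  wr(result$per_cycle, "per_cycle")
  wr(result$per_cycle_category, "per_cycle_category")
  wr(result$categories, "categories")
  wr(result$qual_bins, "qual_bins")
  wr(result$context, "context")
  wr(result$rmc, "rmc")
  wr(result$rmc_raw, "rmc_raw")
  for (nm in names(result$distributions)) {
    wr(result$distributions[[nm]], paste0("dist_", nm))
  }
  kv <- function(x) tibble(key = names(x),
                           value = vapply(x, function(v) as.character(v %||% NA), ""))
  readr::write_tsv(tibble(key = names(result$counts),
                          value = as.numeric(result$counts)),
                   file.path(logdir, "counts.tsv"))
  readr::write_tsv(tibble(key = names(result$summary),
                          value = as.numeric(unlist(result$summary))),
                   file.path(outdir, "summary.tsv"))
  meta <- result$meta
  meta$policy <- paste(names(meta$policy), unlist(meta$policy), sep = "=", collapse = ";")
  readr::write_tsv(kv(meta), file.path(logdir, "meta.tsv"))
  invisible(logdir)
}

#' Reconstruct a bamqc result from its TSV logs
#'
#' @param outdir The directory given to [write_bamqc_logs()] (containing
#'   `logs/` and `summary.tsv`).
#' @return A `bamqc_result` with all counters equal to the written ones.
#' @export
read_bamqc_logs <- function(outdir) {
  logdir <- file.path(outdir, "logs")
  if (!dir.exists(logdir)) abort(paste0("no logs/ directory under ", outdir))
  rd <- function(name) readr::read_tsv(file.path(logdir, paste0(name, ".tsv")),
                                       show_col_types = FALSE, progress = FALSE)
  intify <- function(tb, cols) {
    for (cl in intersect(cols, names(tb))) tb[[cl]] <- as.integer(tb[[cl]])
    tb
  }
  dist_files <- list.files(logdir, pattern = "^dist_.*\\.tsv$")
  distributions <- lapply(dist_files, function(f) {
    intify(readr::read_tsv(file.path(logdir, f), show_col_types = FALSE,
                           progress = FALSE),
           c("n", "insert", "gc_pct", "qual", "mapq", "len", "cycle"))
  })
  names(distributions) <- sub("^dist_(.*)\\.tsv$", "\\1", dist_files)
  counts_tb <- rd("counts")
  summary_tb <- readr::read_tsv(file.path(outdir, "summary.tsv"),
                                show_col_types = FALSE, progress = FALSE)
  meta_tb <- rd("meta")
  meta <- as.list(setNames(meta_tb$value, meta_tb$key))
  meta$read_length <- as.integer(meta$read_length)
  structure(list(
    meta = meta,
    counts = setNames(counts_tb$value, counts_tb$key),
    per_cycle = intify(rd("per_cycle"), c("cycle", "n_aligned_reads", "n_mismatch")),
    per_cycle_category = intify(rd("per_cycle_category"), c("cycle", "n")),
    categories = intify(rd("categories"), "n"),
    qual_bins = intify(rd("qual_bins"), "n"),
    context = intify(rd("context"), "n"),
    rmc = intify(rd("rmc"), "n"),
    rmc_raw = intify(rd("rmc_raw"), c("k", "n")),
    distributions = distributions,
    summary = as.list(setNames(summary_tb$value, summary_tb$key))),
    class = "bamqc_result")
}

#' Tidy a bamqc result
#'
#' @param x A `bamqc_result`.
#' @param what Which table: `"per_cycle"`, `"per_cycle_category"`,
#'   `"categories"`, `"qual_bins"`, `"context"`, `"rmc"`, `"rmc_raw"`, or a
#'   distribution name prefixed `"dist_"` (e.g. `"dist_insert_size"`).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.bamqc_result <- function(x, what = "per_cycle", ...) {
  if (startsWith(what, "dist_")) {
    nm <- sub("^dist_", "", what)
    if (!nm %in% names(x$distributions)) abort(paste0("unknown distribution: ", nm))
    return(as_tibble(x$distributions[[nm]]))
  }
  if (!what %in% c("per_cycle", "per_cycle_category", "categories", "qual_bins",
                   "context", "rmc", "rmc_raw")) {
    abort(paste0("unknown table: ", what))
  }
  as_tibble(x[[what]])
}

#' One-row summary of a bamqc result
#'
#' @param x A `bamqc_result`.
#' @param ... Unused.
#' @return A one-row tibble of headline metrics.
#' @export
glance.bamqc_result <- function(x, ...) {
  tibble(sample = x$meta$sample,
         n_total = as.numeric(x$counts["total"]),
         n_mapped = as.numeric(x$counts["mapped"]),
         n_kept = as.numeric(x$counts["kept"]),
         read_length = x$meta$read_length,
         mean_depth = as.numeric(x$summary$mean_depth),
         error_rate_per_base = as.numeric(x$summary$error_rate_per_base),
         mean_mismatches_per_read = as.numeric(x$summary$mean_mismatches_per_read),
         strand_ratio = as.numeric(x$summary$strand_ratio),
         pct_reads_ge5_mismatch = as.numeric(x$summary$pct_reads_ge5_mismatch),
         cycle_quality_r = per_cycle_quality_correlation_safe(x))
}

per_cycle_quality_correlation_safe <- function(x) {
  tryCatch(per_cycle_quality_correlation(x), error = function(e) NA_real_)
}

#' Plot a bamqc feature family
#'
#' @param object A `bamqc_result`.
#' @param type One of `"per_cycle"` (substitution rate and mismatch quality
#'   by cycle), `"categories"` (substitution spectrum), `"rmc"`
#'   (read-mismatch-content), `"context"` (flanking-context heat map),
#'   `"insert_size"`, `"gc_content"`, `"mapq"`, `"base_qual"`.
#' @param stratum Stratum for mismatch families (default `"overall"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bamqc_result <- function(object, type = "per_cycle",
                                  stratum = "overall", ...) {
  x <- object
  if (type == "per_cycle") {
    pc <- filter(x$per_cycle, .data$stratum == !!stratum)
    return(ggplot2::ggplot(pc, ggplot2::aes(x = .data$cycle, y = .data$subst_rate)) +
      ggplot2::geom_line(colour = "firebrick") +
      ggplot2::labs(x = "sequencing cycle", y = "substitution rate (%)",
                    title = paste0("Per-cycle substitution rate (", stratum, ")")))
  }
  if (type == "per_cycle_quality") {
    pc <- filter(x$per_cycle, .data$stratum == !!stratum)
    return(ggplot2::ggplot(pc, ggplot2::aes(x = .data$cycle, y = .data$mean_mm_qual)) +
      ggplot2::geom_line(colour = "steelblue") +
      ggplot2::labs(x = "sequencing cycle", y = "mean mismatch base quality",
                    title = paste0("Mismatch base quality by cycle (", stratum, ")")))
  }
  if (type == "categories") {
    tb <- filter(x$categories, .data$stratum == !!stratum)
    return(ggplot2::ggplot(tb, ggplot2::aes(x = .data$category, y = .data$pct)) +
      ggplot2::geom_col(fill = "grey35") +
      ggplot2::labs(x = NULL, y = "% of mismatches",
                    title = paste0("Substitution categories (", stratum, ")")))
  }
  if (type == "rmc") {
    tb <- filter(x$rmc, .data$stratum == !!stratum) |>
      mutate(bin = factor(.data$bin, levels = RMC_BIN_LABELS))
    return(ggplot2::ggplot(tb, ggplot2::aes(x = .data$bin, y = .data$pct)) +
      ggplot2::geom_col(fill = "grey35") +
      ggplot2::labs(x = "mismatches per read", y = "% of reads",
                    title = paste0("Read-mismatch-content (", stratum, ")")))
  }
  if (type == "context") {
    tb <- filter(x$context, .data$stratum == !!stratum)
    return(ggplot2::ggplot(tb, ggplot2::aes(x = .data$context, y = .data$category,
                                            fill = .data$pct)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_viridis_c(na.value = "grey90") +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5)) +
      ggplot2::labs(x = "flanking context (5'_3')", y = NULL, fill = "%",
                    title = paste0("Flanking context by category (", stratum, ")")))
  }
  dist_map <- c(insert_size = "insert", gc_content = "gc_pct",
                mapq = "mapq", base_qual = "qual")
  if (type %in% names(dist_map)) {
    tb <- x$distributions[[type]]
    xv <- dist_map[[type]]
    return(ggplot2::ggplot(tb, ggplot2::aes(x = .data[[xv]], y = .data$n)) +
      ggplot2::geom_col(width = 1, fill = "grey35") +
      ggplot2::labs(x = xv, y = "reads", title = type))
  }
  abort(paste0("unknown plot type: ", type))
}
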