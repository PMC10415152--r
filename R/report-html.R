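# Minimal self-contained static HTML report writer shared by the bamqc,
# genedepth and multisample modules. Plots are rendered to PNG and embedded
# as base64 data URIs so the report is a single file.

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

embed_plot <- function(p, width = 7, height = 4) {
  tf <- tempfile(fileext = ".png")
  on.exit(unlink(tf), add = TRUE)
  ok <- tryCatch({
    grDevices::png(tf, width = width * 96, height = height * 96, res = 96)
    print(p)
    grDevices::dev.off()
    TRUE
  }, error = function(e) {
    try(grDevices::dev.off(), silent = TRUE)
    FALSE
  })
  if (!ok || !file.exists(tf)) return(NULL)
  b64 <- jsonlite::base64_enc(readBin(tf, "raw", file.info(tf)$size))
  paste0('<img src="data:image/png;base64,', gsub("\n", "", b64),
         '" style="max-width:100%">')
}

html_table <- function(tb, max_rows = 50L) {
  tb <- utils::head(as.data.frame(tb), max_rows)
  cells <- function(row, tag = "td") paste0("<", tag, ">",
                                     html_escape(as.character(row)),
                                     "</", tag, ">", collapse = "")
  rows <- vapply(seq_len(nrow(tb)), function(i) {
    paste0("<tr>", cells(unlist(format(tb[i, ], digits = 6))), "</tr>")
  }, "")
  paste0("<table><tr>", cells(names(tb), "th"), "</tr>",
         paste(rows, collapse = "\n"), "</table>")
}

write_html_report <- function(path, title, sections) {
  css <- "body{font-family:sans-serif;max-width:960px;margin:auto;padding:1em}
h1{border-bottom:2px solid #444}h2{color:#333;margin-top:1.5em}
table{border-collapse:collapse;font-size:90%}td,th{border:1px solid #bbb;padding:2px 8px}
.note{color:#777;font-style:italic}"
  body <- vapply(sections, function(s) {
    parts <- c(paste0("<h2>", html_escape(s$heading), "</h2>"))
    if (!is.null(s$note)) parts <- c(parts, paste0('<p class="note">',
                                                   html_escape(s$note), "</p>"))
    if (!is.null(s$table)) parts <- c(parts, html_table(s$table))
    if (!is.null(s$plot)) {
      img <- embed_plot(s$plot, width = s$width %||% 7, height = s$height %||% 4)
      if (!is.null(img)) parts <- c(parts, img)
    }
    if (!is.null(s$html)) parts <- c(parts, s$html)
    paste(parts, collapse = "\n")
  }, "")
  writeLines(c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
               paste0("<title>", html_escape(title), "</title>"),
               paste0("<style>", css, "</style></head><body>"),
               paste0("<h1>", html_escape(title), "</h1>"),
               body, "</body></html>"), path)
  invisible(path)
}

#' Render the static HTML report for a bamqc result
#'
#' Writes a single self-contained `report.html` with one section per
#' feature family (summary counters, common distributions, per-cycle
#' profile, substitution-category profile, flanking context,
#' read-mismatch-content). All numbers shown come from the TSV logs'
#' tables; when the result holds no mismatches the substitution panels
#' carry an explicit placeholder note.
#'
#' @param result A `bamqc_result`.
#' @param outdir Output directory.
#' @return Invisibly, the report path.
#' @export
render_bamqc_report <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  no_mm <- sum(result$per_cycle$n_mismatch[result$per_cycle$stratum == "overall"]) == 0
  counts_tb <- tibble(metric = names(result$counts),
                      value = as.numeric(result$counts))
  summary_tb <- tibble(metric = names(result$summary),
                       value = round(as.numeric(unlist(result$summary)), 5))
  sections <- list(
    list(heading = "Summary", table = bind_rows(counts_tb, summary_tb)),
    list(heading = "Insert size distribution",
         plot = autoplot(result, "insert_size")),
    list(heading = "GC content distribution",
         plot = autoplot(result, "gc_content")),
    list(heading = "Mapping quality distribution",
         plot = autoplot(result, "mapq")),
    list(heading = "Base quality distribution",
         plot = autoplot(result, "base_qual")))
  if (no_mm) {
    sections <- c(sections, list(
      list(heading = "Per-cycle profile", note = "no mismatches observed"),
      list(heading = "Substitution categories", note = "no mismatches observed"),
      list(heading = "Read-mismatch-content", note = "no mismatches observed")))
  } else {
    sections <- c(sections, list(
      list(heading = "Per-cycle substitution rate",
           plot = autoplot(result, "per_cycle")),
      list(heading = "Per-cycle mismatch base quality",
           plot = autoplot(result, "per_cycle_quality")),
      list(heading = "Substitution categories",
           plot = autoplot(result, "categories")),
      list(heading = "Flanking context", plot = autoplot(result, "context"),
           height = 5),
      list(heading = "Read-mismatch-content", plot = autoplot(result, "rmc"))))
  }
  write_html_report(file.path(outdir, "report.html"),
                    paste0("Alignment QC report - ", result$meta$sample),
                    sections)
  invisible(file.path(outdir, "report.html"))
}
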