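MS_FEATURES <- c("insert_size", "gc_content", "mapping_quality",
                 "per_cycle_rate", "substitution_categories",
                 "read_mismatch_content", "pair_deviation")

# one sample's feature vector as a named numeric
feature_vector <- function(result, feature_id) {
  switch(feature_id,
    insert_size = {
      tb <- result$distributions$insert_size
      v <- setNames(tb$n, tb$insert); 100 * v / sum(v)
    },
    gc_content = {
      tb <- result$distributions$gc_content
      v <- setNames(tb$n, tb$gc_pct); 100 * v / sum(v)
    },
    mapping_quality = {
      tb <- result$distributions$mapq
      v <- setNames(tb$n, tb$mapq); 100 * v / sum(v)
    },
    per_cycle_rate = {
      pc <- filter(result$per_cycle, .data$stratum == "overall")
      setNames(ifelse(is.finite(pc$subst_rate), pc$subst_rate, 0), pc$cycle)
    },
    substitution_categories = {
      tb <- filter(result$categories, .data$stratum == "overall")
      setNames(ifelse(is.finite(tb$pct), tb$pct, 0), tb$category)
    },
    read_mismatch_content = {
      tb <- filter(result$rmc, .data$stratum == "overall")
      setNames(ifelse(is.finite(tb$pct), tb$pct, 0), tb$bin)
    },
    pair_deviation = {
      pd <- pair_deviation(result)
      setNames(pd$deviation, pd$pair)
    },
    abort(paste0("unknown feature: ", feature_id)))
}

#' Build a samples-by-bins feature matrix
#'
#' Assembles the M x N matrix used for multi-sample comparison: M samples by
#' N feature bins, where each cell is the proportion (in percent) of sample
#' i's reads (or mismatches) in bin j — e.g. the proportion of reads with an
#' insert size of j. Bins are the union across samples; absent bins are 0.
#' The `per_cycle_rate` and `pair_deviation` features are rate/difference
#' valued rather than proportions.
#'
#' @param results Named list of `bamqc_result` objects (>= 2), or a
#'   character vector of log directories readable by [read_bamqc_logs()].
#' @param feature_id One of `insert_size`, `gc_content`, `mapping_quality`,
#'   `per_cycle_rate`, `substitution_categories`, `read_mismatch_content`,
#'   `pair_deviation`.
#' @return A tibble of class `feature_matrix` with a `sample` column and
#'   one numeric column per bin; attribute `feature_id`.
#' @export
build_feature_matrix <- function(results, feature_id = "substitution_categories") {
  feature_id <- match.arg(feature_id, MS_FEATURES)
  if (is.character(results)) {
    nms <- names(results) %||% basename(results)
    results <- lapply(results, read_bamqc_logs)
    names(results) <- nms
  }
  if (length(results) < 2L) abort("need at least 2 samples")
  if (is.null(names(results))) names(results) <- paste0("sample", seq_along(results))
  vecs <- lapply(names(results), function(nm) {
    v <- tryCatch(feature_vector(results[[nm]], feature_id),
                  error = function(e) abort(paste0("sample '", nm, "': ",
                                                   conditionMessage(e))))
    tibble(sample = nm, bin = names(v), value = unname(v))
  })
  wide <- bind_rows(vecs) |>
    pivot_wider(names_from = "bin", values_from = "value", values_fill = 0)
  # keep numeric bin order where bins are numeric
  bins <- setdiff(names(wide), "sample")
  if (!anyNA(suppressWarnings(as.numeric(bins)))) {
    wide <- wide[, c("sample", bins[order(as.numeric(bins))])]
  }
  structure(wide, class = c("feature_matrix", class(wide)),
            feature_id = feature_id)
}

#' Hierarchically cluster a feature matrix
#'
#' Euclidean distances between sample rows followed by Ward linkage
#' (`ward.D2`, the squared-increase Ward objective on Euclidean distances).
#' Deterministic given the matrix; ties are broken by sample order.
#'
#' @param fm A [build_feature_matrix()] result (or any tibble with a
#'   `sample` column and numeric bin columns).
#' @param k Number of clusters for the reported cut.
#' @return A list of class `cluster_result`: `hclust` (the merge tree),
#'   `assignments` (tibble `sample`, `cluster`), `dist` (Euclidean distance
#'   matrix), `k`.
#' @export
hcluster <- function(fm, k = 2L) {
  m <- as.matrix(fm[, setdiff(names(fm), "sample")])
  rownames(m) <- fm$sample
  if (nrow(m) < 2L) abort("need at least 2 samples")
  if (k > nrow(m)) abort("k cannot exceed the number of samples")
  d <- dist(m, method = "euclidean")
  hc <- hclust(d, method = "ward.D2")
  ct <- cutree(hc, k = k)
  structure(list(hclust = hc,
                 assignments = tibble(sample = names(ct), cluster = unname(ct)),
                 dist = as.matrix(d), k = k), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> k =", x$k, "\n")
  print(table(x$assignments$cluster))
  invisible(x)
}

#' @export
tidy.cluster_result <- function(x, ...) x$assignments

#' @export
glance.cluster_result <- function(x, ...) {
  tibble(n_samples = nrow(x$assignments), k = x$k,
         max_height = max(x$hclust$height),
         sizes = paste(sort(table(x$assignments$cluster), decreasing = TRUE),
                       collapse = "/"))
}

SUBST_PAIRS <- c("C>A:G>T", "C>T:G>A", "C>G:G>C", "A>T:T>A", "A>G:T>C", "A>C:T>G")

#' Substitution-pair deviation metric
#'
#' Transition and transversion pairs related by complementation (e.g.
#' `A>T` and `T>A`) are expected to occur in similar proportions under
#' strand-symmetric errors; a large signed difference between a category's
#' percentage and its complement's reflects strand-specific artifact
#' incorporation (oxidative-damage C>A/G>T imbalance being the canonical
#' case). Six signed differences `pct(X>Y) - pct(complement)` are returned,
#' one per complement pair.
#'
#' @param x A `bamqc_result`, its `categories` tibble, or a named numeric
#'   vector of category percentages.
#' @param stratum Stratum (default `"overall"`).
#' @return Tibble with `pair`, `cat1`, `cat2`, `pct1`, `pct2`, `deviation`
#'   (`pct1 - pct2`); deviations are `NA` when there are no mismatches.
#' @export
#' @examples
#' pcts <- c("C>A" = 6.8, "G>T" = 8.6)
#' pair_deviation(pcts)   # deviation for C>A:G>T is -1.8
pair_deviation <- function(x, stratum = "overall") {
  pct <- if (inherits(x, "bamqc_result")) {
    tb <- filter(x$categories, .data$stratum == !!stratum)
    setNames(tb$pct, tb$category)
  } else if (is.data.frame(x)) {
    tb <- if ("stratum" %in% names(x)) filter(x, .data$stratum == !!stratum) else x
    setNames(tb$pct, tb$category)
  } else {
    x
  }
  full <- setNames(rep(NA_real_, 12), SUBST_CATEGORIES)
  full[names(pct)] <- pct
  # absent categories with any observed mismatch are zero-percent
  if (any(is.finite(full))) full[!is.finite(full)] <- 0
  cat1 <- sub(":.*", "", SUBST_PAIRS)
  cat2 <- sub(".*:", "", SUBST_PAIRS)
  tibble(pair = SUBST_PAIRS, cat1 = cat1, cat2 = cat2,
         pct1 = unname(full[cat1]), pct2 = unname(full[cat2]),
         deviation = unname(full[cat1] - full[cat2]))
}

#' Simulate substitution-category profiles with planted outliers
#'
#' Generates per-sample substitution-category percentage profiles around a
#' uniform spectrum with Gaussian within-group noise; a subset of samples
#' carries a planted strand-asymmetric C>A/G>T imbalance (oxidative-damage
#' style): `+delta/2` on C>A and `-delta/2` on G>T, so the planted
#' pair-deviation metric equals `delta` in expectation. `sigma` is the
#' within-group standard deviation of each complement-pair deviation — the
#' quantity the outlier clustering operates on — so the per-category noise
#' sd is `sigma / sqrt(2)`.
#'
#' @param n_samples Total samples (default 30).
#' @param n_outliers Samples carrying the planted imbalance (default 9).
#' @param delta Planted C>A:G>T pair deviation in percentage points
#'   (default 1.5).
#' @param sigma Within-group sd of each pair deviation (default 0.2).
#' @param seed RNG seed.
#' @return Tibble with `sample`, `outlier` (logical truth), `category`,
#'   `pct`.
#' @export
simulate_category_profiles <- function(n_samples = 30L, n_outliers = 9L,
                                       delta = 1.5, sigma = 0.2, seed = 1L) {
  set.seed(seed)
  base <- 100 / 12
  map_dfr(seq_len(n_samples), function(i) {
    pct <- base + rnorm(12, 0, sigma / sqrt(2))
    names(pct) <- SUBST_CATEGORIES
    out <- i > n_samples - n_outliers
    if (out) {
      pct["C>A"] <- pct["C>A"] + delta / 2
      pct["G>T"] <- pct["G>T"] - delta / 2
    }
    tibble(sample = sprintf("s%02d", i), outlier = out,
           category = names(pct), pct = unname(pct))
  })
}

#' Pair-deviation feature matrix from category profiles
#'
#' Converts per-sample category percentages into the samples-by-pairs
#' matrix of signed complement-pair deviations used for outlier clustering.
#'
#' @param profiles Tibble with `sample`, `category`, `pct` (e.g. from
#'   [simulate_category_profiles()]).
#' @return A tibble of class `feature_matrix` (`sample` + six pair columns).
#' @export
pair_deviation_matrix <- function(profiles) {
  wide <- profiles |>
    group_by(.data$sample) |>
    group_modify(function(df, key) {
      pd <- pair_deviation(setNames(df$pct, df$category))
      pivot_wider(select(pd, "pair", "deviation"),
                  names_from = "pair", values_from = "deviation")
    }) |>
    ungroup()
  structure(wide, class = c("feature_matrix", class(wide)),
            feature_id = "pair_deviation")
}

#' Multi-sample QC comparison
#'
#' Builds the feature matrix, clusters it (Euclidean + Ward), computes each
#' sample's substitution-pair deviations, and runs Dixon's Q across samples
#' on every deviation pair (when 3 <= M <= 30) to flag outlier samples.
#'
#' @param results Named list of `bamqc_result`s or log-directory paths.
#' @param feature_id Feature for the cluster analysis.
#' @param k Number of clusters (default 2).
#' @param alpha Dixon significance level for the per-pair outlier scan.
#' @return List of class `multisample_result`: `feature_matrix`, `cluster`,
#'   `pair_deviations` (tibble sample x pair), `outliers` (tibble of
#'   Dixon-flagged sample/pair combinations).
#' @export
multisample_qc <- function(results, feature_id = "substitution_categories",
                           k = 2L, alpha = 0.002) {
  fm <- build_feature_matrix(results, feature_id)
  cl <- hcluster(fm, k = k)
  if (is.character(results)) {
    nms <- names(results) %||% basename(results)
    results <- lapply(results, read_bamqc_logs); names(results) <- nms
  }
  pd <- imap_dfr(results, function(r, nm) {
    mutate(pair_deviation(r), sample = nm, .before = 1)
  })
  outliers <- list()
  m <- length(results)
  if (m >= 3L && m <= 30L) {
    for (p in SUBST_PAIRS) {
      v <- filter(pd, .data$pair == p)
      if (anyNA(v$deviation)) next
      dt <- dixon_test(v$deviation, alpha = alpha)
      if (!is.na(dt$flagged)) {
        outliers[[length(outliers) + 1L]] <-
          tibble(sample = v$sample[dt$flagged], pair = p,
                 deviation = dt$value, Q = dt$statistic, critical = dt$critical)
      }
    }
  }
  outliers <- if (length(outliers)) bind_rows(outliers) else
    tibble(sample = character(), pair = character(), deviation = numeric(),
           Q = numeric(), critical = numeric())
  structure(list(feature_matrix = fm, cluster = cl, pair_deviations = pd,
                 outliers = outliers), class = "multisample_result")
}

#' @export
print.multisample_result <- function(x, ...) {
  cat("<multisample_result>", nrow(x$feature_matrix), "samples, feature:",
      attr(x$feature_matrix, "feature_id"), "\n")
  print(table(x$cluster$assignments$cluster))
  if (nrow(x$outliers)) {
    cat("Dixon-flagged outliers:\n"); print(x$outliers)
  }
  invisible(x)
}

#' Side-by-side batch comparison of two sample groups
#'
#' Aligns the bin grids of the chosen features across two groups and
#' returns per-group per-sample overlay series for visual comparison; no
#' statistics beyond the overlay.
#'
#' @param groupA,groupB Named lists of `bamqc_result`s (each non-empty).
#' @param features Feature ids to overlay (default substitution categories
#'   and pair deviation).
#' @return List of class `batch_compare`: `overlays`, a tibble with columns
#'   `feature`, `group`, `sample`, `bin`, `value`.
#' @export
batch_compare <- function(groupA, groupB,
                          features = c("substitution_categories", "pair_deviation")) {
  if (!length(groupA) || !length(groupB)) abort("both groups must be non-empty")
  features <- match.arg(features, MS_FEATURES, several.ok = TRUE)
  if (is.null(names(groupA))) names(groupA) <- paste0("A", seq_along(groupA))
  if (is.null(names(groupB))) names(groupB) <- paste0("B", seq_along(groupB))
  one <- function(results, gname) {
    imap_dfr(results, function(r, nm) {
      map_dfr(features, function(f) {
        v <- tryCatch(feature_vector(r, f), error = function(e) {
          warn(paste0("sample '", nm, "' lacks feature '", f, "'; skipped"))
          NULL
        })
        if (is.null(v)) return(tibble())
        tibble(feature = f, group = gname, sample = nm,
               bin = names(v), value = unname(v))
      })
    })
  }
  overlays <- bind_rows(one(groupA, "A"), one(groupB, "B"))
  structure(list(overlays = overlays), class = "batch_compare")
}

#' @export
autoplot.batch_compare <- function(object, feature = NULL, ...) {
  ov <- object$overlays
  feature <- feature %||% ov$feature[1]
  tb <- filter(ov, .data$feature == !!feature)
  num_bins <- !anyNA(suppressWarnings(as.numeric(tb$bin)))
  if (num_bins) tb$bin <- as.numeric(tb$bin)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$bin, y = .data$value,
                                   group = .data$sample, colour = .data$group)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(title = paste0("Batch comparison: ", feature),
                  x = "bin", y = "value", colour = "group")
}

#' Rank-sum comparison of two samples' feature values
#'
#' Thin wrapper over the Mann-Whitney U (Wilcoxon rank-sum) test, as used
#' for group comparisons of substitution-pair proportions.
#'
#' @param x,y Numeric vectors.
#' @param ... Passed to [stats::wilcox.test()].
#' @return `htest` object.
#' @export
mwu_test <- function(x, y, ...) stats::wilcox.test(x, y, ...)

#' Z-test of two proportions
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @return List with `z`, `p_value` (two-sided), `p1`, `p2`.
#' @export
prop_ztest <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1; p2 <- x2 / n2; p <- (x1 + x2) / (n1 + n2)
  z <- (p1 - p2) / sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  list(z = z, p_value = 2 * pnorm(-abs(z)), p1 = p1, p2 = p2)
}
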