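#' Homopolymer run lengths at a site
#'
#' `ref_run` is the maximal reference run of the reference base containing
#' the site; `alt_run` is the longest reference run of the alternate base
#' immediately adjacent (either side) to the site (0 when neither neighbour
#' is the alternate base).
#'
#' @param refseq Contig sequence (character scalar).
#' @param pos 1-based site position.
#' @param alt Alternate base.
#' @return List with `ref_run` and `alt_run`.
#' @export
homopolymer_runs <- function(refseq, pos, alt) {
  n <- nchar(refseq)
  b <- substr(refseq, pos, pos)
  run_from <- function(p, base, step) {
    len <- 0L
    while (p >= 1L && p <= n && substr(refseq, p, p) == base) {
      len <- len + 1L; p <- p + step
    }
    len
  }
  ref_run <- run_from(pos, b, -1L) + run_from(pos, b, 1L) - 1L
  alt_left <- run_from(pos - 1L, alt, -1L)
  alt_right <- run_from(pos + 1L, alt, 1L)
  list(ref_run = ref_run, alt_run = max(alt_left, alt_right))
}

#' Extract read-level features at candidate variant sites
#'
#' For each site, aggregates over the kept reads overlapping it: mean and
#' median per-read mismatch count, fraction of clipped reads, mean per-read
#' indel count, mean and fraction-zero mapping quality, mean |TLEN|, plus
#' the reference- and alternate-base homopolymer run lengths at the site.
#' These are the read-level predictors of the site-confidence model.
#'
#' @param bam Indexed BAM path.
#' @param ref Reference FASTA path or named contigs.
#' @param sites Tibble with columns `chrom`, `pos`, `ref`, `alt` and
#'   optionally `label` (`"benchmark"`/`"non_benchmark"`) and `zygosity`
#'   (`"het"`/`"hom"`), carried through.
#' @param policy A [filter_policy()].
#' @return Tibble, one row per site, with feature columns
#'   `mean_mismatch`, `median_mismatch`, `frac_clipped`, `mean_indel`,
#'   `mean_mapq`, `frac_mapq0`, `mean_insert`, `ref_hp_run`, `alt_hp_run`,
#'   `depth`; zero-coverage sites get `NA` features and `covered = FALSE`.
#' @export
extract_site_features <- function(bam, ref, sites, policy = filter_policy()) {
  refc <- if (is.character(ref) && length(ref) == 1L && is.null(names(ref)))
    read_reference(ref) else as_ref_chars(ref)
  param_what <- c("qname", "flag", "pos", "mapq", "cigar", "seq", "qual", "isize")
  out <- map_dfr(seq_len(nrow(sites)), function(i) {
    chrom <- sites$chrom[i]; pos <- as.integer(sites$pos[i])
    alt <- sites$alt[i]
    if (!chrom %in% names(refc)) abort(paste0("unknown contig: ", chrom))
    hp <- homopolymer_runs(refc[[chrom]], pos, alt)
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
    ch <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
      what = param_what, which = gr))[[1]]
    keep <- if (length(ch$flag)) record_filter(ch$flag, ch$mapq, policy)$keep
            else logical()
    idx <- which(keep)
    base <- tibble(chrom = chrom, pos = pos, ref = sites$ref[i], alt = alt,
                   ref_hp_run = hp$ref_run, alt_hp_run = hp$alt_run)
    if ("label" %in% names(sites)) base$label <- sites$label[i]
    if ("zygosity" %in% names(sites)) base$zygosity <- sites$zygosity[i]
    if (!length(idx)) {
      return(mutate(base, depth = 0L, covered = FALSE,
                    mean_mismatch = NA_real_, median_mismatch = NA_real_,
                    frac_clipped = NA_real_, mean_indel = NA_real_,
                    mean_mapq = NA_real_, frac_mapq0 = NA_real_,
                    mean_insert = NA_real_))
    }
    ev <- lapply(idx, function(j) {
      walk_alignment(list(chrom = chrom, pos = ch$pos[j], flag = ch$flag[j],
                          cigar = as.character(ch$cigar[j]),
                          seq = as.character(ch$seq[j]),
                          qual = as.character(ch$qual[j])), refc)
    })
    nmm <- vapply(ev, function(e) e$n_mismatches, 0L)
    nind <- vapply(ev, function(e) length(e$insertions) + length(e$deletions), 0L)
    clipped <- vapply(ev, function(e) e$clip5_len + e$clip3_len > 0L, TRUE)
    mutate(base, depth = length(idx), covered = TRUE,
           mean_mismatch = mean(nmm), median_mismatch = median(nmm),
           frac_clipped = mean(clipped), mean_indel = mean(nind),
           mean_mapq = mean(ch$mapq[idx]),
           frac_mapq0 = mean(ch$mapq[idx] == 0L),
           mean_insert = mean(abs(ch$isize[idx]), na.rm = TRUE))
  })
  out
}

SITECONF_FEATURES <- c("mean_mismatch", "median_mismatch", "frac_clipped",
                       "mean_indel", "mean_mapq", "frac_mapq0", "mean_insert",
                       "ref_hp_run", "alt_hp_run")

#' Fit the logistic site-confidence model
#'
#' Maximum-likelihood logistic regression (no regularisation) of site label
#' (`non_benchmark` = low confidence = 1) on the read-level features, on a
#' seeded stratified 70/30 train/test split. Test accuracy is reported
#' separately per zygosity class when a `zygosity` column is present.
#'
#' @param features Tibble from [extract_site_features()] (or any tibble
#'   with the feature columns), with a `label` column containing exactly
#'   two levels; `"non_benchmark"` (or the second sorted level) is coded 1.
#' @param split_frac Training fraction (default 0.7).
#' @param seed Split seed (default 7).
#' @param predictors Feature columns to use (defaults to the available
#'   subset of the standard set).
#' @return List of class `siteconf_fit`: `model` (a `glm`), `coefficients`
#'   tibble, `accuracy` tibble (overall and per zygosity), `confusion`
#'   (test-set table), `split` description.
#' @export
fit_classifier <- function(features, split_frac = 0.7, seed = 7L,
                           predictors = NULL) {
  if (is.null(predictors)) {
    predictors <- intersect(SITECONF_FEATURES, names(features))
    if (!length(predictors)) {
      # fall back to every numeric column that is not metadata
      num <- names(features)[vapply(features, is.numeric, TRUE)]
      predictors <- setdiff(num, c("pos", "depth"))
    }
  }
  if (!length(predictors)) abort("no predictor columns found")
  if (!"label" %in% names(features)) abort("features need a 'label' column")
  df <- features[stats::complete.cases(features[, c(predictors, "label")]), ]
  dropped <- nrow(features) - nrow(df)
  if (dropped > 0) warn(paste0(dropped, " rows with non-finite features dropped"))
  labs <- sort(unique(df$label))
  if (length(labs) != 2L) abort("label must have exactly two levels")
  if (nrow(df) < 50L) abort("need at least 50 labelled sites")
  pos_lab <- if ("non_benchmark" %in% labs) "non_benchmark" else labs[2]
  df$y <- as.integer(df$label == pos_lab)

  withr_seed <- function(code) {   # localised RNG so callers' streams are untouched
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    code
  }
  idx_train <- withr_seed({
    unlist(lapply(split(seq_len(nrow(df)), df$y), function(ii) {
      sample(ii, size = round(split_frac * length(ii)))
    }), use.names = FALSE)
  })
  train <- df[idx_train, ]; test <- df[-idx_train, ]
  fml <- stats::as.formula(paste("y ~", paste(predictors, collapse = " + ")))
  model <- glm(fml, family = binomial(), data = train)
  p <- predict(model, newdata = test, type = "response")
  pred <- as.integer(p >= 0.5)
  acc_tb <- tibble(class = "overall", n = nrow(test),
                   accuracy = 100 * mean(pred == test$y))
  if ("zygosity" %in% names(test)) {
    acc_tb <- bind_rows(acc_tb, test |>
      mutate(correct = pred == .data$y) |>
      group_by(class = .data$zygosity) |>
      summarise(n = dplyr::n(), accuracy = 100 * mean(.data$correct),
                .groups = "drop"))
  }
  confusion <- table(truth = test$y, predicted = pred)
  structure(list(model = model,
                 coefficients = tibble(term = names(stats::coef(model)),
                                       estimate = unname(stats::coef(model))),
                 accuracy = acc_tb, confusion = confusion,
                 positive_label = pos_lab,
                 split = list(frac = split_frac, seed = seed,
                              n_train = nrow(train), n_test = nrow(test)),
                 predictors = predictors), class = "siteconf_fit")
}

#' @export
print.siteconf_fit <- function(x, ...) {
  cat("<siteconf_fit>", x$split$n_train, "train /", x$split$n_test, "test;",
      "positive =", x$positive_label, "\n")
  print(x$accuracy)
  invisible(x)
}

#' @export
tidy.siteconf_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std_error = s[, 2],
         statistic = s[, 3], p_value = s[, 4])
}

#' @export
glance.siteconf_fit <- function(x, ...) {
  acc <- setNames(x$accuracy$accuracy, x$accuracy$class)
  tibble(n_train = x$split$n_train, n_test = x$split$n_test,
         accuracy_overall = unname(acc["overall"]),
         accuracy_het = unname(acc["het"] %||% NA_real_),
         accuracy_hom = unname(acc["hom"] %||% NA_real_),
         aic = x$model$aic)
}

#' Score sites with a fitted site-confidence model
#'
#' @param fit A `siteconf_fit` (or bare `glm` with matching terms).
#' @param features Tibble containing the model's predictor columns.
#' @param threshold Decision threshold on the low-confidence probability
#'   (default 0.5).
#' @return The input tibble with `p_low_confidence` and `low_confidence`
#'   columns appended.
#' @export
classify_sites <- function(fit, features, threshold = 0.5) {
  model <- if (inherits(fit, "siteconf_fit")) fit$model else fit
  preds <- setdiff(names(stats::coef(model)), "(Intercept)")
  missing <- setdiff(preds, names(features))
  if (length(missing)) {
    abort(paste0("feature schema mismatch; missing: ",
                 paste(missing, collapse = ", ")))
  }
  p <- predict(model, newdata = features, type = "response")
  mutate(features, p_low_confidence = unname(p),
         low_confidence = unname(p) >= threshold)
}

#' Simulate site feature vectors from a known logistic model
#'
#' Draws standard-normal features and Bernoulli labels from
#' `P(y=1) = plogis(intercept + X %*% beta)`; used to validate coefficient
#' recovery of [fit_classifier()].
#'
#' @param n Number of sites.
#' @param beta Named coefficient vector (names become feature columns).
#' @param intercept Intercept.
#' @param seed RNG seed.
#' @return Tibble with the feature columns, `label` and `zygosity`
#'   (assigned at random, independent of the features).
#' @export
simulate_logistic_sites <- function(n, beta, intercept = 0, seed = 1L) {
  set.seed(seed)
  X <- matrix(rnorm(n * length(beta)), n, length(beta),
              dimnames = list(NULL, names(beta)))
  eta <- intercept + as.vector(X %*% beta)
  y <- rbinom(n, 1L, stats::plogis(eta))
  as_tibble(X) |>
    mutate(label = ifelse(y == 1L, "non_benchmark", "benchmark"),
           zygosity = sample(c("het", "hom"), n, replace = TRUE))
}

#' Simulate two-class features with a known Bayes accuracy
#'
#' One-dimensional class-conditional Gaussians `N(0, 1)` and `N(d, 1)` with
#' equal priors have Bayes accuracy `pnorm(d / 2)`; `d` is chosen from the
#' requested accuracy. Extra independent noise features carry no signal.
#'
#' @param n Number of sites.
#' @param bayes_accuracy Target Bayes accuracy in (0.5, 1).
#' @param n_noise Number of uninformative extra features.
#' @param seed RNG seed.
#' @return Tibble with `signal`, noise columns, `label`, `zygosity`.
#' @export
simulate_bayes_sites <- function(n, bayes_accuracy = 0.8, n_noise = 2L,
                                 seed = 1L) {
  set.seed(seed)
  d <- 2 * qnorm(bayes_accuracy)
  y <- rbinom(n, 1L, 0.5)
  tb <- tibble(signal = rnorm(n, mean = d * y, sd = 1))
  for (j in seq_len(n_noise)) tb[[paste0("noise", j)]] <- rnorm(n)
  mutate(tb, label = ifelse(y == 1L, "non_benchmark", "benchmark"),
         zygosity = sample(c("het", "hom"), n, replace = TRUE))
}
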