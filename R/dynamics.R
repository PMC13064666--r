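#' Baseline-relative frequency shifts of mutations
#'
#' Computes, per variant and per target-timepoint sample, the change in
#' population-level frequency relative to the baseline mean (all baseline
#' samples pooled across sites), in percentage points. The first reliable
#' retrieval (3 months by default) serves as the baseline, so shifts read
#' as post-establishment change at each burial site.
#'
#' @param matrix A `mutation_matrix`.
#' @param baseline_timepoint Months defining the baseline samples
#'   (default 3).
#' @param target_timepoint Months of the samples to compare.
#' @param variants Optional character keys to restrict to (e.g. the
#'   shared set).
#' @return data.frame of class `freq_shifts`: `key`, `sample_id`, `site`,
#'   `delta` (percentage points), `baseline_mean` (frequency), and
#'   `baseline_absent` flag (variant undetected in every baseline sample,
#'   baseline taken as 0).
#' @export
baseline_shift <- function(matrix, baseline_timepoint = 3,
                           target_timepoint, variants = NULL) {
  sam <- matrix$samples
  base_cols <- which(sam$timepoint == baseline_timepoint)
  targ_cols <- which(sam$timepoint == target_timepoint)
  if (!length(base_cols)) stop("no samples at baseline timepoint ",
                               baseline_timepoint)
  if (!length(targ_cols)) stop("no samples at target timepoint ",
                               target_timepoint)
  keys <- variants %||% matrix$variants$key
  rows <- match(keys, matrix$variants$key)
  if (anyNA(rows)) stop("unknown variant keys requested")
  base_mean <- rowMeans(matrix$frequency[rows, base_cols, drop = FALSE])
  absent <- rowSums(matrix$detected[rows, base_cols, drop = FALSE]) == 0
  out <- expand.grid(key = keys, sample_id = sam$sample_id[targ_cols],
                     stringsAsFactors = FALSE)
  out$site <- sam$site[match(out$sample_id, sam$sample_id)]
  f <- matrix$frequency[rows, targ_cols, drop = FALSE]
  out$delta <- 100 * (as.vector(f) - rep(base_mean, times = length(targ_cols)))
  out$baseline_mean <- rep(base_mean, times = length(targ_cols))
  out$baseline_absent <- rep(absent, times = length(targ_cols))
  class(out) <- c("freq_shifts", "data.frame")
  out
}

#' Fixed-effects ANOVA table (one- or two-way with interaction)
#'
#' Sequential (Type I) sums of squares via [stats::aov()]; for two
#' factors the model is `y ~ a * b`. Exact for balanced or near-balanced
#' layouts; for unbalanced layouts the sequential decomposition (in the
#' order given) is reported as-is. A data set with zero residual
#' variance is flagged (`F` and `p` are `NaN`).
#'
#' @param values Numeric response vector.
#' @param a First factor (coerced).
#' @param b Optional second factor.
#' @return data.frame of class `anova_table`: `term`, `df`, `sumsq`,
#'   `meansq`, `statistic` (F), `p`. Residual df of zero is an error.
#' @export
anova_table <- function(values, a, b = NULL) {
  a <- factor(a)
  if (nlevels(a) < 2L) stop("factor a needs >= 2 levels")
  if (length(values) < 2L) stop("need >= 2 observations")
  d <- data.frame(y = values, a = a)
  if (is.null(b)) {
    fit <- aov(y ~ a, data = d)
  } else {
    d$b <- factor(b)
    if (nlevels(d$b) < 2L) stop("factor b needs >= 2 levels")
    fit <- aov(y ~ a * b, data = d)
  }
  if (fit$df.residual == 0L) stop("zero residual degrees of freedom")
  tab <- summary(fit)[[1L]]
  if (max(values) == min(values)) {
    # fully degenerate response: every SS is exactly 0, F is undefined
    tab$`Sum Sq`[] <- 0
    tab$`Mean Sq`[] <- 0
    tab$`F value`[] <- NaN
    tab$`Pr(>F)`[] <- NaN
  }
  term <- trimws(rownames(tab))
  term[term == "Residuals"] <- "residual"
  n_term <- length(term)
  pad <- function(x) c(x, rep(NA_real_, n_term - length(x)))
  out <- data.frame(term = term, df = as.integer(tab$Df),
                    sumsq = tab$`Sum Sq`, meansq = tab$`Mean Sq`,
                    statistic = pad(tab$`F value`), p = pad(tab$`Pr(>F)`),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Tukey honestly-significant-difference comparisons
#'
#' Computes, for every group pair, the studentized-range statistic
#' `q = |mean_i - mean_j| / sqrt(MS_res/2 * (1/n_i + 1/n_j))` and its
#' adjusted p-value from the studentized-range distribution with
#' `k` groups and the residual degrees of freedom (Tukey-Kramer for
#' unequal group sizes). For `k = 2` the adjusted p equals the ANOVA p.
#'
#' @param means Named numeric vector of group means.
#' @param ms_residual Residual mean square from the preceding ANOVA.
#' @param df_residual Residual degrees of freedom.
#' @param n Group sizes (scalar or vector aligned with `means`).
#' @return data.frame of class `tukey_result`: `pair`, `diff`, `q`, `p`.
#' @export
tukey_hsd <- function(means, ms_residual, df_residual, n) {
  k <- length(means)
  if (k < 2L) stop("tukey_hsd needs >= 2 groups")
  if (is.null(names(means))) names(means) <- paste0("g", seq_len(k))
  n <- rep_len(n, k)
  idx <- combn(k, 2L)
  diffs <- means[idx[2L, ]] - means[idx[1L, ]]
  se <- sqrt(ms_residual / 2 * (1 / n[idx[1L, ]] + 1 / n[idx[2L, ]]))
  q <- abs(diffs) / se
  p <- ptukey(q, nmeans = k, df = df_residual, lower.tail = FALSE)
  out <- data.frame(
    pair = paste(names(means)[idx[2L, ]], names(means)[idx[1L, ]],
                 sep = "-"),
    diff = unname(diffs), q = unname(q), p = unname(p),
    stringsAsFactors = FALSE
  )
  class(out) <- c("tukey_result", "data.frame")
  out
}

#' Per-variant one-way site ANOVA across a mutation matrix
#'
#' Convenience layer over [anova_table()]: tests, for each variant at one
#' timepoint, whether its frequency differs by burial site.
#'
#' @param matrix A `mutation_matrix`.
#' @param timepoint Timepoint restriction (`NULL` = all samples).
#' @param variants Optional variant keys.
#' @param adjust P-adjustment method passed to [stats::p.adjust()]
#'   (default `"none"`, per-mutation reporting; `"BH"` available).
#' @return data.frame: `key`, `statistic`, `df1`, `df2`, `p`, `p_adj`.
#' @export
site_anova <- function(matrix, timepoint = NULL, variants = NULL,
                       adjust = "none") {
  sam <- matrix$samples
  cols <- if (is.null(timepoint)) seq_len(nrow(sam)) else
    which(sam$timepoint == timepoint)
  keys <- variants %||% matrix$variants$key
  rows <- match(keys, matrix$variants$key)
  site <- factor(sam$site[cols])
  res <- lapply(rows, function(r) {
    y <- matrix$frequency[r, cols]
    na_row <- data.frame(statistic = NA_real_, df1 = NA_integer_,
                         df2 = NA_integer_, p = NA_real_)
    if (var(y) == 0) return(na_row)  # constant frequency: nothing to test
    tab <- tryCatch(anova_table(y, site), error = function(e) NULL)
    if (is.null(tab)) return(na_row)  # degenerate layout (e.g. n per site = 1)
    data.frame(statistic = tab$statistic[1L], df1 = tab$df[1L],
               df2 = tab$df[2L], p = tab$p[1L])
  })
  out <- cbind(data.frame(key = keys, stringsAsFactors = FALSE),
               do.call(rbind, res))
  out$p_adj <- stats::p.adjust(out$p, method = adjust)
  out
}

#' Correlations between mutation frequencies and site abiotic covariates
#'
#' Pearson correlation (with two-sided t-based p) between each variant's
#' per-sample frequency and the abiotic covariate value of the sample's
#' burial site -- e.g. a negative association between soil zinc and the
#' frequency of mutations in a zinc-starvation gene.
#'
#' @param matrix A `mutation_matrix`.
#' @param covariates data.frame with a `site` column plus one numeric
#'   column per covariate (e.g. `zinc_ppm`, `pH`, `organic_matter_pct`).
#' @param timepoint Timepoint restriction (`NULL` = all samples).
#' @param variants Optional variant keys.
#' @return data.frame of class `correlation_results`: `key`, `covariate`,
#'   `r`, `p`, `n`, `flagged` (TRUE when either vector has zero variance;
#'   `r`/`p` are NA there).
#' @export
abiotic_correlation <- function(matrix, covariates, timepoint = NULL,
                                variants = NULL) {
  stopifnot("site" %in% names(covariates))
  cov_names <- setdiff(names(covariates), "site")
  sam <- matrix$samples
  cols <- if (is.null(timepoint)) seq_len(nrow(sam)) else
    which(sam$timepoint == timepoint)
  if (length(unique(sam$site[cols])) < 3L) {
    stop("abiotic_correlation needs samples from >= 3 sites")
  }
  keys <- variants %||% matrix$variants$key
  rows <- match(keys, matrix$variants$key)
  out <- expand.grid(key = keys, covariate = cov_names,
                     stringsAsFactors = FALSE)
  out$r <- NA_real_; out$p <- NA_real_
  out$n <- length(cols); out$flagged <- FALSE
  for (i in seq_len(nrow(out))) {
    y <- matrix$frequency[rows[match(out$key[i], keys)], cols]
    x <- covariates[[out$covariate[i]]][match(sam$site[cols],
                                              covariates$site)]
    if (anyNA(x)) stop("covariate values missing for some sites")
    if (var(x) == 0 || var(y) == 0) {
      out$flagged[i] <- TRUE
      next
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    out$r[i] <- unname(ct$estimate)
    out$p[i] <- ct$p.value
  }
  class(out) <- c("correlation_results", "data.frame")
  out
}
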