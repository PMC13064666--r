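test_that("baseline shifts are percentage-point differences from the
          pooled baseline mean", {
  metas <- make_metas(6, sites = c("S1", "S2"),
                      timepoints = c(3L, 3L, 3L, 10L, 10L, 10L))
  keys <- c("1:A>G", "2:A>G")
  freq <- matrix(c(0.30, 0.28, 0.32, 0.38, 0.25, 0.30,
                   0.00, 0.00, 0.00, 0.05, 0.00, 0.00),
                 nrow = 2, byrow = TRUE,
                 dimnames = list(keys, metas$sample_id))
  det <- freq > 0
  m <- structure(list(variants = data.frame(key = keys, position = 1:2,
                                            ref = "A", alt = "G",
                                            gene_id = NA,
                                            effect = "non-synonymous"),
                      samples = metas, frequency = freq, detected = det,
                      rule = detection_rule()), class = "mutation_matrix")
  sh <- baseline_shift(m, 3, 10)
  # baseline mean of variant 1 = 0.30; sample s04 at 0.38 -> +8 points
  expect_equal(sh$delta[sh$key == "1:A>G" & sh$sample_id == "s04"], 8)
  # variant absent at baseline: baseline 0, flagged
  expect_true(all(sh$baseline_absent[sh$key == "2:A>G"]))
  expect_equal(sh$delta[sh$key == "2:A>G" & sh$sample_id == "s04"], 5)
  # target = baseline sample set -> mean delta 0
  sh0 <- baseline_shift(m, 3, 3)
  expect_equal(mean(sh0$delta[sh0$key == "1:A>G"]), 0)
})

test_that("baseline shifts equal direct spreadsheet recomputation", {
  m <- random_matrix(41, n_var = 15L,
                     metas = make_metas(10, timepoints = rep(c(3L, 24L), 5)))
  sh <- baseline_shift(m, 3, 24)
  base_cols <- m$samples$sample_id[m$samples$timepoint == 3]
  for (i in seq_len(nrow(sh))) {
    oracle <- 100 * (m$frequency[sh$key[i], sh$sample_id[i]] -
                       mean(m$frequency[sh$key[i], base_cols]))
    expect_equal(sh$delta[i], unname(oracle))
  }
  expect_true(all(sh$delta >= -100 & sh$delta <= 100))
})

test_that("one-way ANOVA matches the hand decomposition", {
  # groups {1,2,3} vs {4,5,6}: SSB = 13.5, SSW = 4 -> F = 13.5 on (1,4) df
  tab <- anova_table(c(1, 2, 3, 4, 5, 6), rep(c("g1", "g2"), each = 3))
  expect_equal(tab$sumsq[1], 13.5)
  expect_equal(tab$sumsq[2], 4)
  expect_equal(tab$statistic[1], 13.5)
  expect_identical(tab$df, c(1L, 4L))
  # SS decomposition: total = between + residual
  expect_equal(sum(tab$sumsq), var(c(1:6)) * 5)
})

test_that("two-group one-way F equals the squared pooled t statistic", {
  withr::with_seed(51, {
    for (i in 1:5) {
      y1 <- rnorm(6); y2 <- rnorm(8, mean = 0.5)
      tab <- anova_table(c(y1, y2), rep(c("a", "b"), c(6, 8)))
      tt <- t.test(y1, y2, var.equal = TRUE)
      expect_equal(tab$statistic[1], unname(tt$statistic)^2,
                   tolerance = 1e-10)
      expect_equal(tab$p[1], tt$p.value, tolerance = 1e-10)
    }
  })
})

test_that("two-way ANOVA decomposes sums of squares sequentially", {
  withr::with_seed(52, {
    d <- expand.grid(a = c("a1", "a2"), b = c("b1", "b2", "b3"),
                     rep = 1:4)
    y <- rnorm(nrow(d)) + (d$a == "a2") * 1 + (d$b == "b2") * 0.5
    tab <- anova_table(y, d$a, d$b)
    expect_setequal(tab$term, c("a", "b", "a:b", "residual"))
    expect_equal(sum(tab$df), length(y) - 1)
    expect_equal(sum(tab$sumsq), sum((y - mean(y))^2), tolerance = 1e-8)
    expect_true(all(tab$sumsq >= 0))
    # permutation invariance of the fit
    perm <- sample(length(y))
    tab2 <- anova_table(y[perm], d$a[perm], d$b[perm])
    expect_equal(tab2$sumsq, tab$sumsq, tolerance = 1e-10)
  })
})

test_that("degenerate ANOVA inputs are flagged or rejected", {
  # all observations equal: SS 0, F undefined (NaN)
  tab <- anova_table(rep(1, 6), rep(c("a", "b"), 3))
  expect_equal(tab$sumsq, c(0, 0))
  expect_true(is.nan(tab$statistic[1]))
  # zero residual df
  expect_error(anova_table(c(1, 2), c("a", "b")), "residual")
})

test_that("Tukey HSD with two groups reproduces the ANOVA p-value", {
  withr::with_seed(53, {
    for (i in 1:5) {
      y <- rnorm(12); g <- rep(c("a", "b"), each = 6)
      tab <- anova_table(y, g)
      means <- tapply(y, g, mean)
      tk <- tukey_hsd(means, tab$meansq[2], tab$df[2], 6)
      expect_equal(tk$p, tab$p[1], tolerance = 1e-6)
      # q = sqrt(2) * |t|
      expect_equal(tk$q, sqrt(2 * tab$statistic[1]), tolerance = 1e-10)
    }
  })
})

test_that("identical group means give Tukey p of 1", {
  tk <- tukey_hsd(c(a = 1, b = 1, c = 2), ms_residual = 0.5,
                  df_residual = 12, n = 5)
  expect_equal(tk$p[tk$pair == "b-a"], 1)
  expect_error(tukey_hsd(c(a = 1), 0.5, 10, 5), ">= 2")
})

test_that("Tukey p matches numerical integration of the studentized range
          CDF in a balanced 3-group case", {
  # oracle: P(Q > q) = 1 - int f_s(s) * k int phi(z) [Phi(z) - Phi(z - q s)]^(k-1) dz ds
  # where s ~ (chi_df / sqrt(df)) density
  ptukey_quad <- function(q, k, df) {
    inner <- function(s) {
      vapply(s, function(si) {
        f <- function(z) dnorm(z) * (pnorm(z) - pnorm(z - q * si))^(k - 1)
        k * integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
      }, numeric(1))
    }
    dens <- function(s) {
      # density of sqrt(chi2_df / df)
      2 * s * df * dchisq(s^2 * df, df)
    }
    integrate(function(s) dens(s) * inner(s), 0, Inf,
              rel.tol = 1e-9)$value
  }
  for (q in c(1.5, 3.0, 4.5)) {
    expect_equal(1 - ptukey_quad(q, 3, 12),
                 ptukey(q, nmeans = 3, df = 12, lower.tail = FALSE),
                 tolerance = 1e-4)
  }
})

test_that("abiotic correlations recover exact and degenerate cases", {
  metas <- make_metas(6, sites = c("S1", "S2", "S3"))
  keys <- c("1:A>G", "2:A>G")
  covs <- data.frame(site = c("S1", "S2", "S3"), zinc_ppm = c(1, 5, 9),
                     pH = c(7, 7, 7))
  # variant 1 frequency collinear with zinc; variant 2 constant
  freq <- rbind(covs$zinc_ppm[match(metas$site, covs$site)] / 10,
                rep(0.2, 6))
  dimnames(freq) <- list(keys, metas$sample_id)
  m <- structure(list(variants = data.frame(key = keys, position = 1:2,
                                            ref = "A", alt = "G",
                                            gene_id = NA,
                                            effect = "non-synonymous"),
                      samples = metas, frequency = freq,
                      detected = freq > 0, rule = detection_rule()),
                 class = "mutation_matrix")
  res <- abiotic_correlation(m, covs)
  expect_equal(res$r[res$key == "1:A>G" & res$covariate == "zinc_ppm"], 1)
  expect_true(res$flagged[res$key == "2:A>G" & res$covariate == "zinc_ppm"])
  # zero-variance covariate flagged too
  expect_true(all(res$flagged[res$covariate == "pH"]))
})

test_that("a planted negative zinc effect yields negative correlations", {
  cfg <- tiny_config(n_achips_per_site = 4L, timepoints = 24L,
                     abiotic_slope = c(zinc_ppm = -0.6),
                     generations_burial = 120L, dormancy_fraction = 0.5)
  hits <- vapply(1:20, function(s) {
    ex <- simulate_experiment(cfg, seed = 100 + s, community = FALSE)
    gene <- ex$truth$planted$abiotic_gene[1]
    keys <- ex$truth$planted$key[ex$truth$planted$gene_id == gene]
    keys <- intersect(keys, ex$matrix$variants$key)
    res <- abiotic_correlation(ex$matrix, ex$covariates, variants = keys)
    zr <- res$r[res$covariate == "zinc_ppm"]
    mean(zr < 0, na.rm = TRUE) > 0.5
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("per-variant site ANOVA is permutation-invariant", {
  m <- random_matrix(61, n_var = 10L,
                     metas = make_metas(12, sites = rep(c("S1", "S2",
                                                          "S3"), 4)))
  a1 <- site_anova(m)
  perm <- withr::with_seed(62, sample(12))
  m2 <- m
  m2$samples <- m$samples[perm, ]
  m2$frequency <- m$frequency[, perm]
  m2$detected <- m$detected[, perm]
  a2 <- site_anova(m2)
  expect_equal(a1$p, a2$p, tolerance = 1e-12)
})
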