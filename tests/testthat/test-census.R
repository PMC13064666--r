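test_that("matrix assembly merges per-sample calls like a dictionary", {
  metas <- make_metas(2)
  c1 <- make_calls(c(10L, 20L), "A", "G", c(0.3, 0.4))
  c2 <- make_calls(c(30L, 40L), "A", "G", c(0.5, 0.6))
  m <- build_matrix(list(s01 = c1, s02 = c2), metas)
  expect_identical(dim(m$frequency), c(4L, 2L))
  expect_identical(sum(m$frequency == 0), 4L)
  expect_identical(m$frequency["10:A>G", "s01"], 0.3)
  expect_identical(m$frequency["40:A>G", "s02"], 0.6)

  # single sample, three calls
  m1 <- build_matrix(list(s01 = make_calls(c(1L, 2L, 3L), "A", "C",
                                           rep(0.2, 3))),
                     make_metas(1))
  expect_identical(dim(m1$frequency), c(3L, 1L))

  expect_error(build_matrix(list(c1, c2), make_metas(2)[c(1, 1), ]),
               "duplicate")
})

test_that("matrix equals a brute-force per-sample dictionary merge", {
  withr::with_seed(31, {
    metas <- make_metas(6, sites = c("S1", "S2", "S3"))
    calls <- lapply(metas$sample_id, function(s) {
      n <- sample(0:6, 1)
      pos <- sort(sample.int(100L, n))
      make_calls(pos, "A", "G", runif(n, 0.01, 1))
    })
    names(calls) <- metas$sample_id
    m <- build_matrix(calls, metas)
    # oracle: nested-loop lookup
    for (s in metas$sample_id) {
      for (k in m$variants$key) {
        p <- as.integer(sub(":.*", "", k))
        cl <- calls[[s]]
        f_oracle <- if (p %in% cl$position) cl$frequency[cl$position == p]
                    else 0
        expect_equal(unname(m$frequency[k, s]), f_oracle)
      }
    }
  })
})

test_that("k-of-n shared classification is exact and monotone in k", {
  m <- random_matrix(1, n_var = 30L, metas = make_metas(10))
  n_det <- rowSums(m$detected)
  s54 <- classify_shared(m, shared_criterion(9, 10))
  expect_setequal(s54$shared, m$variants$key[n_det >= 9])
  # detected in 0 samples -> never shared; k = 1 -> every detected variant
  s1 <- classify_shared(m, shared_criterion(1, 10))
  expect_setequal(s1$shared, m$variants$key[n_det >= 1])
  # monotone: shared set never grows as k increases
  sizes <- vapply(1:10, function(k) {
    length(classify_shared(m, shared_criterion(k, 10))$shared)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  # partition exhaustive & exclusive
  expect_setequal(c(s54$shared, s54$non_shared), m$variants$key)
  expect_length(intersect(s54$shared, s54$non_shared), 0)

  expect_error(shared_criterion(11, 10), "exceed")
  expect_error(classify_shared(m, shared_criterion(3, 5)), "equal")
})

test_that("a mutation detected in nearly all chambers passes the 54-of-59 rule", {
  metas <- make_metas(59)
  det <- matrix(FALSE, 2, 59, dimnames = list(c("1:A>G", "2:A>G"),
                                              metas$sample_id))
  det["1:A>G", 1:54] <- TRUE   # in exactly 54 of 59
  det["2:A>G", 1:53] <- TRUE
  freq <- det * 0.3
  m <- structure(list(variants = data.frame(key = rownames(det),
                                            position = 1:2, ref = "A",
                                            alt = "G", gene_id = NA,
                                            effect = "non-synonymous"),
                      samples = metas, frequency = freq, detected = det,
                      rule = detection_rule()), class = "mutation_matrix")
  s <- classify_shared(m, shared_criterion(54, 59))
  expect_identical(s$shared, "1:A>G")
  expect_identical(s$non_shared, "2:A>G")
})

test_that("venn regions match toy expectations and count sites once", {
  metas <- make_metas(4, sites = c("S1", "S1", "S2", "S2"))
  # S1 sees {A, B}, S2 sees {B, C}; B in two chambers of S2 counts once
  keys <- c("1:A>G", "2:A>G", "3:A>G")
  det <- matrix(FALSE, 3, 4, dimnames = list(keys, metas$sample_id))
  det[1, 1] <- TRUE; det[2, c(2, 3, 4)] <- TRUE; det[3, 4] <- TRUE
  m <- structure(list(variants = data.frame(key = keys, position = 1:3,
                                            ref = "A", alt = "G",
                                            gene_id = NA,
                                            effect = "non-synonymous"),
                      samples = metas, frequency = det * 0.5,
                      detected = det, rule = detection_rule()),
                 class = "mutation_matrix")
  v <- venn_partition(m, timepoint = 3)
  expect_identical(v$count[v$subset == "S1"], 1L)
  expect_identical(v$count[v$subset == "S2"], 1L)
  expect_identical(v$count[v$subset == "S1&S2"], 1L)
  expect_identical(sum(v$count), 3L)
})

test_that("venn regions equal power-set enumeration on random matrices", {
  for (seed in c(2, 3, 4)) {
    m <- random_matrix(seed, n_var = 20L,
                       metas = make_metas(9, sites = c("S1", "S2", "S3")))
    v <- venn_partition(m, timepoint = 3, effect = NULL)
    sam <- m$samples
    sites <- sort(unique(sam$site))
    # oracle: per variant, enumerate its exact site subset membership
    region_of <- vapply(seq_len(nrow(m$variants)), function(i) {
      pres <- vapply(sites, function(s) {
        any(m$detected[i, sam$site == s])
      }, logical(1))
      paste(sites[pres], collapse = "&")
    }, character(1))
    for (ss in v$subset) {
      expect_identical(v$count[v$subset == ss], sum(region_of == ss),
                       info = paste("subset", ss, "seed", seed))
    }
    expect_identical(sum(v$count), sum(region_of != ""))
    # invariant to sample ordering
    perm <- sample(nrow(sam))
    m2 <- m
    m2$samples <- sam[perm, ]; m2$detected <- m$detected[, perm]
    m2$frequency <- m$frequency[, perm]
    expect_identical(venn_partition(m2, timepoint = 3, effect = NULL), v)
  }
})

test_that("site-unique genes require majority prevalence and exclusivity", {
  metas <- make_metas(8, sites = rep(c("S1", "S2"), each = 4))
  keys <- sprintf("%d:A>G", 1:3)
  det <- matrix(FALSE, 3, 8, dimnames = list(keys, metas$sample_id))
  det[1, 1:3] <- TRUE              # gene gA: 3/4 at S1, 0 at S2 -> unique
  det[2, c(1, 2, 3, 5)] <- TRUE    # gene gB: 3/4 at S1 but also 1 at S2
  det[3, 1] <- TRUE                # gene gC: 1/4 at S1 -> not a majority
  m <- structure(list(variants = data.frame(key = keys, position = 1:3,
                                            ref = "A", alt = "G",
                                            gene_id = c("gA", "gB", "gC"),
                                            effect = "non-synonymous"),
                      samples = metas, frequency = det * 0.5,
                      detected = det, rule = detection_rule()),
                 class = "mutation_matrix")
  u <- site_unique_genes(m)
  expect_identical(u$S1, "gA")
  expect_length(u$S2, 0)
})

test_that("site-unique genes match an exhaustive scan on random matrices", {
  for (seed in c(5, 6)) {
    m <- random_matrix(seed, n_var = 25L,
                       metas = make_metas(12, sites = rep(c("S1", "S2",
                                                            "S3"), 4)))
    u <- site_unique_genes(m, majority_fraction = 0.5)
    sam <- m$samples; vars <- m$variants
    for (s in unique(sam$site)) {
      oracle <- character()
      for (g in unique(vars$gene_id)) {
        rows <- which(vars$gene_id == g & vars$effect == "non-synonymous")
        if (!length(rows)) next
        hit <- colSums(m$detected[rows, , drop = FALSE]) > 0
        frac_here <- mean(hit[sam$site == s])
        n_elsewhere <- sum(hit[sam$site != s])
        if (frac_here > 0.5 && n_elsewhere == 0) oracle <- c(oracle, g)
      }
      expect_setequal(u[[s]], oracle)
    }
  }
})

test_that("per-chamber counts partition detected non-synonymous mutations", {
  m <- random_matrix(7, n_var = 30L, metas = make_metas(8))
  shared <- classify_shared(m, shared_criterion(5, 8))
  pc <- per_achip_counts(m, shared)
  ns_rows <- m$variants$effect == "non-synonymous"
  for (j in seq_len(8)) {
    tot <- sum(m$detected[ns_rows, j])
    expect_identical(pc$per_sample$n_shared[j] +
                       pc$per_sample$n_non_shared[j], tot)
    # direct recount oracle for the shared part
    expect_identical(
      pc$per_sample$n_shared[j],
      sum(m$detected[ns_rows & m$variants$key %in% shared$shared, j]))
  }
  # empty sample
  m$detected[, 1] <- FALSE
  pc2 <- per_achip_counts(m, shared)
  expect_identical(pc2$per_sample$n_shared[1] +
                     pc2$per_sample$n_non_shared[1], 0L)
})
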