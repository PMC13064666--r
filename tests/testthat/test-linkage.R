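test_that("linkage fractions hit 1 for co-resident and 0 for disjoint
          mutations on error-free reads", {
  cfg <- tiny_config(error_rate = 0)
  a <- simulate_ancestor(cfg)
  p1 <- 1000L; p2 <- 1060L  # within one read length
  refs <- vapply(c(p1, p2), function(p)
    substr(a$genome$sequence, p + 1, p + 1), character(1))
  alts <- vapply(refs, function(r) setdiff(c("A", "C", "G", "T"), r)[1],
                 character(1))
  pairs <- data.frame(key_a = "a", key_b = "b", pos_a = p1, alt_a = alts[1],
                      pos_b = p2, alt_b = alts[2],
                      stringsAsFactors = FALSE)

  # all reads from one double-mutant lineage -> fraction 1
  pop_link <- lineage_pop(data.frame(position = c(p1, p2), ref = refs,
                                     alt = alts),
                          list(1:2), 1)
  rd <- generate_reads(sample_isolate_pool(pop_link, 100L, seed = 1),
                       a$genome, cfg, seed = 2, n_reads = 3000L)
  rec <- pairwise_linkage(rd, pairs)
  expect_gt(rec$reads_spanning_both, 10)
  expect_identical(rec$linkage_fraction, 1.0)

  # mutations on disjoint lineages at 0.5 each -> fraction 0
  pop_disj <- lineage_pop(data.frame(position = c(p1, p2), ref = refs,
                                     alt = alts),
                          list(1L, 2L), c(0.5, 0.5))
  rd2 <- generate_reads(sample_isolate_pool(pop_disj, 100L, seed = 3),
                        a$genome, cfg, seed = 4, n_reads = 3000L)
  rec2 <- pairwise_linkage(rd2, pairs)
  expect_identical(rec2$linkage_fraction, 0.0)

  # counts are consistent: both + exactly-one <= spanning
  for (r in list(rec, rec2)) {
    expect_lte(r$reads_with_both_alts + r$reads_with_exactly_one_alt,
               r$reads_spanning_both)
  }

  # pair farther apart than the read length: zero spanning reads, NA fraction
  far <- data.frame(key_a = "a", key_b = "c", pos_a = p1, alt_a = alts[1],
                    pos_b = p1 + 4000L, alt_b = "A",
                    stringsAsFactors = FALSE)
  rec3 <- pairwise_linkage(rd, far)
  expect_identical(rec3$reads_spanning_both, 0L)
  expect_true(is.na(rec3$linkage_fraction))
})

test_that("linkage is symmetric in pair order", {
  cfg <- tiny_config(error_rate = 0.001)
  a <- simulate_ancestor(cfg)
  p1 <- 2000L; p2 <- 2050L
  refs <- vapply(c(p1, p2), function(p)
    substr(a$genome$sequence, p + 1, p + 1), character(1))
  alts <- vapply(refs, function(r) setdiff(c("A", "C", "G", "T"), r)[1],
                 character(1))
  pop <- lineage_pop(data.frame(position = c(p1, p2), ref = refs,
                                alt = alts),
                     list(1:2, integer()), c(0.4, 0.6))
  rd <- generate_reads(sample_isolate_pool(pop, 100L, seed = 5), a$genome,
                       cfg, seed = 6, n_reads = 2000L)
  fwd <- data.frame(key_a = "a", key_b = "b", pos_a = p1, alt_a = alts[1],
                    pos_b = p2, alt_b = alts[2], stringsAsFactors = FALSE)
  rev <- data.frame(key_a = "b", key_b = "a", pos_a = p2, alt_a = alts[2],
                    pos_b = p1, alt_b = alts[1], stringsAsFactors = FALSE)
  expect_identical(pairwise_linkage(rd, fwd)$linkage_fraction,
                   pairwise_linkage(rd, rev)$linkage_fraction)
})

test_that("independent assortment gives the product-frequency linkage", {
  # lineages carrying A alone (p=0.4), B alone (q=0.3), neither (0.3):
  # among reads spanning both sites, P(both alts) = 0 because no lineage
  # carries both -- linkage distinguishes true co-residence from chance.
  # Build instead lineages mimicking independence: AB at pq, A at p(1-q),
  # B at (1-p)q, wt at (1-p)(1-q); expected fraction = pq.
  cfg <- tiny_config(error_rate = 0)
  a <- simulate_ancestor(cfg)
  p1 <- 3000L; p2 <- 3040L
  refs <- vapply(c(p1, p2), function(p)
    substr(a$genome$sequence, p + 1, p + 1), character(1))
  alts <- vapply(refs, function(r) setdiff(c("A", "C", "G", "T"), r)[1],
                 character(1))
  p <- 0.4; q <- 0.3
  pop <- lineage_pop(data.frame(position = c(p1, p2), ref = refs,
                                alt = alts),
                     list(1:2, 1L, 2L, integer()),
                     c(p * q, p * (1 - q), (1 - p) * q,
                       (1 - p) * (1 - q)))
  pairs <- data.frame(key_a = "a", key_b = "b", pos_a = p1,
                      alt_a = alts[1], pos_b = p2, alt_b = alts[2],
                      stringsAsFactors = FALSE)
  fracs <- withr::with_seed(13, vapply(1:20, function(i) {
    pool <- sample_isolate_pool(pop, 1000L)
    rd <- generate_reads(pool, a$genome, cfg, n_reads = 2000L)
    pairwise_linkage(rd, pairs)$linkage_fraction
  }, numeric(1)))
  se <- sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - p * q), 3 * se + 1e-12)
})

test_that("linked groups form transitive closures over passing edges", {
  rec <- data.frame(key_a = c("A", "B", "C", "D"),
                    key_b = c("B", "C", "D", "E"),
                    reads_spanning_both = c(50L, 50L, 5L, 50L),
                    reads_with_both_alts = c(48L, 49L, 5L, 10L),
                    reads_with_exactly_one_alt = c(2L, 1L, 0L, 40L),
                    linkage_fraction = c(0.96, 0.98, 1.0, 0.2),
                    stringsAsFactors = FALSE)
  g <- linked_groups(rec, min_fraction = 0.9, min_spanning = 10L)
  # A-B-C chain joins; C-D fails min_spanning; D-E fails min_fraction
  has_group <- function(groups, members) {
    any(vapply(groups, identical, logical(1), members))
  }
  expect_true(has_group(g, c("A", "B", "C")))
  expect_true(has_group(g, "D"))
  expect_true(has_group(g, "E"))

  # all fractions below threshold -> all singletons
  rec2 <- rec; rec2$linkage_fraction <- 0.1
  expect_true(all(lengths(linked_groups(rec2)) == 1L))
})

test_that("linked groups equal igraph connected components on random graphs", {
  skip_if_not_installed("igraph")
  for (seed in c(21, 22, 23)) {
    rec <- withr::with_seed(seed, {
      nodes <- LETTERS[1:10]
      pairs <- t(combn(nodes, 2))
      keep <- runif(nrow(pairs)) < 0.25
      data.frame(key_a = pairs[keep, 1], key_b = pairs[keep, 2],
                 reads_spanning_both = sample(5:50, sum(keep), TRUE),
                 reads_with_both_alts = 0L,
                 reads_with_exactly_one_alt = 0L,
                 linkage_fraction = runif(sum(keep)),
                 stringsAsFactors = FALSE)
    })
    g <- linked_groups(rec, min_fraction = 0.5, min_spanning = 10L)
    edges <- rec[rec$linkage_fraction >= 0.5 &
                   rec$reads_spanning_both >= 10L, ]
    ig <- igraph::graph_from_data_frame(
      edges[, c("key_a", "key_b")], directed = FALSE,
      vertices = sort(unique(c(rec$key_a, rec$key_b))))
    comp <- igraph::components(ig)$membership
    oracle <- unname(lapply(split(names(comp), comp), sort))
    expect_setequal(lapply(g, paste, collapse = ","),
                    lapply(oracle, paste, collapse = ","))
  }
})

test_that("reads assign to the correct paralog copy by mismatch count", {
  a <- simulate_ancestor(sim_config(seed = 3L, genome_length = 30000L,
                                    n_genes = 20L, error_rate = 0))
  grp <- a$genes[!is.na(a$genes$paralog_group), ]
  copy2 <- grp[2, ]
  # error-free read drawn straight from copy 2's span
  rd_seq <- substr(a$genome$sequence, copy2$start + 1, copy2$start + 150)
  rd <- make_reads(copy2$start, rd_seq, genome_id = a$genome$genome_id)
  asn <- paralog_best_match(rd[1, ], grp, a$genome)
  expect_identical(asn$assigned_gene_id, copy2$gene_id)
  expect_identical(min(asn$mismatches_per_candidate), 0L)

  # identical copies -> AMBIGUOUS
  g2 <- grp
  seq2 <- a$genome$sequence
  substr(seq2, g2$start[2] + 1, g2$end[2]) <-
    substr(seq2, g2$start[1] + 1, g2$end[1])
  genome2 <- a$genome; genome2$sequence <- seq2
  asn2 <- paralog_best_match(rd[1, ], g2, genome2)
  expect_identical(asn2$assigned_gene_id, "AMBIGUOUS")

  # no overlap with any candidate -> error
  rd_far <- make_reads(0L, substr(a$genome$sequence, 1, 50),
                       genome_id = a$genome$genome_id)
  far_genes <- grp
  if (min(far_genes$start) > 60) {
    expect_error(paralog_best_match(rd_far[1, ], far_genes, a$genome),
                 "overlap")
  }
})

test_that("every read from a 90%-identity paralog assigns to its true copy", {
  cfg <- sim_config(seed = 4L, genome_length = 30000L, n_genes = 20L,
                    error_rate = 0)
  a <- simulate_ancestor(cfg)
  grp <- a$genes[!is.na(a$genes$paralog_group), ]
  pool <- sample_isolate_pool(wildtype_pop(), 100L, seed = 1)
  rd <- generate_reads(pool, a$genome, cfg, seed = 2, n_reads = 4000L)
  w <- nchar(rd$sequence)
  for (ci in 1:2) {
    copy <- grp[ci, ]
    # reads fully inside this copy's span
    inside <- which(rd$start >= copy$start & rd$start + w <= copy$end)
    inside <- head(inside, 25)
    for (i in inside) {
      asn <- paralog_best_match(rd[i, ], grp, a$genome)
      expect_identical(asn$assigned_gene_id, copy$gene_id)
    }
  }
})
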