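# base observed at genome position `pos` (0-based) in each read, NA when
# the read does not cover it
read_base_at <- function(reads, pos) {
  off <- pos - reads$start + 1L
  w <- nchar(reads$sequence)
  b <- rep(NA_character_, nrow(reads))
  cov <- off >= 1L & off <= w
  b[cov] <- substr(reads$sequence[cov], off[cov], off[cov])
  b
}

#' Read-backed pairwise linkage of variants
#'
#' For each variant pair, tallies the reads spanning both positions and
#' how many carry both alternate alleles vs exactly one. Mutations found
#' together on single sequencing reads co-occur within single isolates of
#' the pool -- the evidence for multi-mutation lineages. Pairs farther
#' apart than the read length have no spanning reads and are reported
#' with zero counts.
#'
#' @param reads An `aligned_reads` data.frame.
#' @param variant_pairs data.frame with columns `pos_a`, `alt_a`, `pos_b`,
#'   `alt_b` (positions 0-based). Build with [all_variant_pairs()].
#' @return data.frame of class `linkage_records`: the pair columns plus
#'   `reads_spanning_both`, `reads_with_both_alts`,
#'   `reads_with_exactly_one_alt`, `linkage_fraction` (NA when no read
#'   spans the pair).
#' @export
pairwise_linkage <- function(reads, variant_pairs) {
  n <- nrow(variant_pairs)
  out <- variant_pairs
  out$reads_spanning_both <- 0L
  out$reads_with_both_alts <- 0L
  out$reads_with_exactly_one_alt <- 0L
  out$linkage_fraction <- NA_real_
  for (i in seq_len(n)) {
    ba <- read_base_at(reads, variant_pairs$pos_a[i])
    bb <- read_base_at(reads, variant_pairs$pos_b[i])
    span <- !is.na(ba) & !is.na(bb)
    has_a <- span & ba == variant_pairs$alt_a[i]
    has_b <- span & bb == variant_pairs$alt_b[i]
    out$reads_spanning_both[i] <- sum(span)
    out$reads_with_both_alts[i] <- sum(has_a & has_b)
    out$reads_with_exactly_one_alt[i] <- sum(xor(has_a, has_b))
    if (out$reads_spanning_both[i] > 0L) {
      out$linkage_fraction[i] <-
        out$reads_with_both_alts[i] / out$reads_spanning_both[i]
    }
  }
  class(out) <- c("linkage_records", "data.frame")
  out
}

#' Enumerate variant pairs within possible read span
#'
#' @param calls A `variant_calls` data.frame.
#' @param max_distance Maximum pair distance (typically the read length);
#'   `Inf` enumerates all pairs.
#' @return data.frame `key_a`, `key_b`, `pos_a`, `alt_a`, `pos_b`, `alt_b`.
#' @export
all_variant_pairs <- function(calls, max_distance = Inf) {
  n <- nrow(calls)
  if (n < 2L) {
    return(data.frame(key_a = character(), key_b = character(),
                      pos_a = integer(), alt_a = character(),
                      pos_b = integer(), alt_b = character(),
                      stringsAsFactors = FALSE))
  }
  idx <- combn(n, 2L)
  keep <- abs(calls$position[idx[1L, ]] - calls$position[idx[2L, ]]) <=
    max_distance
  idx <- idx[, keep, drop = FALSE]
  key <- variant_key(calls$position, calls$ref, calls$alt)
  data.frame(key_a = key[idx[1L, ]], key_b = key[idx[2L, ]],
             pos_a = calls$position[idx[1L, ]], alt_a = calls$alt[idx[1L, ]],
             pos_b = calls$position[idx[2L, ]], alt_b = calls$alt[idx[2L, ]],
             stringsAsFactors = FALSE)
}

#' Group mutually linked variants
#'
#' Single-linkage clustering over pairs whose linkage fraction and
#' spanning-read support pass the thresholds: connected components of the
#' linkage graph (transitive closure, so A-B and B-C linked implies one
#' group even if A and C are never spanned by a read).
#'
#' @param records A `linkage_records` data.frame.
#' @param min_fraction Minimum linkage fraction for an edge (default 0.9).
#' @param min_spanning Minimum spanning reads for an edge (default 10).
#' @return List of character vectors (variant keys); singletons included.
#' @export
linked_groups <- function(records, min_fraction = 0.9, min_spanning = 10L) {
  keys <- sort(unique(c(records$key_a, records$key_b)))
  parent <- seq_along(keys)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  edges <- which(!is.na(records$linkage_fraction) &
                   records$linkage_fraction >= min_fraction &
                   records$reads_spanning_both >= min_spanning)
  for (e in edges) {
    i <- find(match(records$key_a[e], keys))
    j <- find(match(records$key_b[e], keys))
    if (i != j) parent[j] <- i
  }
  comp <- vapply(seq_along(keys), find, integer(1))
  unname(lapply(split(keys, comp), sort))
}

#' Assign a read to its best-matching paralogous gene copy
#'
#' Compares the read, gap-free at matched within-gene offsets, against
#' every copy in a paralog group, counting mismatches over the
#' overlapping window. A unique minimum assigns the read; a tie is
#' AMBIGUOUS. Verifying that mutation-bearing reads match their assigned
#' copy best rules out cross-paralog misalignment as the source of
#' apparent linked mutations.
#'
#' @param read One-row `aligned_reads` data.frame (or list with `start`,
#'   `sequence`, `read_id`).
#' @param candidate_genes Gene models of one paralog group (equal-length
#'   copies, same strand).
#' @param genome The `reference_genome`.
#' @return List of class `paralog_assignment`: `read_id`,
#'   `candidate_gene_ids`, `mismatches_per_candidate`, `assigned_gene_id`
#'   (or `"AMBIGUOUS"`).
#' @export
paralog_best_match <- function(read, candidate_genes, genome) {
  rstart <- read$start
  rseq <- read$sequence
  w <- nchar(rseq)
  # anchor: the candidate the read physically overlaps
  ov <- which(candidate_genes$start < rstart + w &
                candidate_genes$end > rstart)
  if (!length(ov)) stop("read overlaps no candidate gene")
  anchor <- candidate_genes[ov[1L], ]
  # within-gene offsets of the overlapping window (strand-agnostic: the
  # copies are co-oriented, so genomic offsets correspond)
  lo <- max(rstart, anchor$start)
  hi <- min(rstart + w, anchor$end)
  off <- (lo - anchor$start):(hi - anchor$start - 1L)
  read_codes <- encode_bases(rseq)[(lo - rstart + 1L):(hi - rstart)]
  genome_codes <- encode_bases(genome$sequence)
  mism <- vapply(seq_len(nrow(candidate_genes)), function(i) {
    g <- candidate_genes[i, ]
    use <- off[g$start + off < g$end]  # clip to this copy's span
    sum(genome_codes[g$start + use + 1L] != read_codes[seq_along(use)]) +
      (length(off) - length(use))      # unalignable bases count as mismatches
  }, integer(1))
  best <- which(mism == min(mism))
  structure(list(read_id = read$read_id %||% NA_character_,
                 candidate_gene_ids = candidate_genes$gene_id,
                 mismatches_per_candidate = mism,
                 assigned_gene_id = if (length(best) == 1L)
                   candidate_genes$gene_id[best] else "AMBIGUOUS"),
            class = "paralog_assignment")
}
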