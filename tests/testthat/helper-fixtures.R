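# small deterministic fixtures shared across test files

tiny_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, genome_length = 9000L, n_genes = 6L,
               population_size = 1000L, mutation_rate = 0.002,
               n_achips_per_site = 3L, n_taxa = 15L,
               community_reads = 20000L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# a 2-gene toy genome with hand-chosen sequence for effect annotation:
# gene fwd  [3, 12): ATG GGA ATT  (+ strand)
# gene rev  [15, 24): on - strand, CDS = reverse complement of genome[15:24)
toy_genome <- function() {
  #            0123456789012345678901234567
  seqn <- paste0("AA", "C", "ATGGGAATT", "TAC",
                 "CATTCCGGT", "ACGT")  # length 28
  structure(list(genome_id = "toy", sequence = seqn, topology = "linear"),
            class = "reference_genome")
}

toy_genes <- function() {
  data.frame(gene_id = c("fwd1", "rev1"),
             start = c(3L, 15L), end = c(12L, 24L),
             strand = c("+", "-"),
             annotation = "toy", paralog_group = NA_character_,
             selection_class = "neutral", stringsAsFactors = FALSE)
}

# aligned_reads frame from explicit fields
make_reads <- function(starts, seqs, sample_id = "s1",
                       lineage = NA_character_, genome_id = "toy") {
  out <- data.frame(read_id = sprintf("r%03d", seq_along(starts)),
                    genome_id = genome_id, start = as.integer(starts),
                    sequence = seqs, sample_id = sample_id,
                    true_lineage = lineage, stringsAsFactors = FALSE)
  class(out) <- c("aligned_reads", "data.frame")
  out
}

# minimal sample metadata frame
make_metas <- function(n, sites = "S1", timepoints = 3L) {
  data.frame(sample_id = sprintf("s%02d", seq_len(n)),
             achip_id = sprintf("a%02d", seq_len(n)),
             site = rep_len(sites, n),
             timepoint = rep_len(timepoints, n),
             species = "sp", pool_size = 100L, stringsAsFactors = FALSE)
}

# variant_calls frame from key fields
make_calls <- function(position, ref, alt, frequency, depth = 100L,
                       effect = "non-synonymous", gene_id = NA_character_) {
  n <- length(position)
  out <- data.frame(position = as.integer(position), ref = ref, alt = alt,
                    alt_count = as.integer(round(frequency * depth)),
                    depth = as.integer(rep_len(depth, n)),
                    frequency = frequency,
                    gene_id = rep_len(gene_id, n),
                    effect = rep_len(effect, n),
                    codon_change = NA_character_,
                    aa_change = NA_character_, stringsAsFactors = FALSE)
  class(out) <- c("variant_calls", "data.frame")
  out
}

# random detected/frequency mutation matrix for property tests
random_matrix <- function(seed, n_var = 20L, metas = make_metas(8),
                          p_detect = 0.3) {
  withr::with_seed(seed, {
    keys <- sprintf("%d:A>G", sample.int(5000L, n_var))
    det <- matrix(runif(n_var * nrow(metas)) < p_detect, n_var,
                  dimnames = list(keys, metas$sample_id))
    freq <- matrix(0, n_var, nrow(metas),
                   dimnames = list(keys, metas$sample_id))
    freq[det] <- runif(sum(det), 0.01, 1)
    pos <- as.integer(sub(":.*", "", keys))
    structure(list(
      variants = data.frame(key = keys, position = pos, ref = "A",
                            alt = "G",
                            gene_id = sample(sprintf("g%d", 1:5), n_var,
                                             replace = TRUE),
                            effect = sample(c("non-synonymous",
                                              "synonymous"), n_var,
                                            replace = TRUE, prob = c(.7, .3)),
                            stringsAsFactors = FALSE),
      samples = metas, frequency = freq, detected = det,
      rule = detection_rule()), class = "mutation_matrix")
  })
}
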