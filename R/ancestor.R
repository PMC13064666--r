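#' Simulate an ancestral reference genome with gene models
#'
#' Generates a random genome and places non-overlapping coding genes on it.
#' At least one paralog group is created by duplicating a gene body
#' elsewhere on the genome and mutating a fixed fraction of its positions,
#' so the two copies share a known high identity (>= 80% by construction) --
#' the substrate for paralog best-match checks. A subset of genes is
#' flagged `selected`; mutations landing in them carry a fitness advantage
#' during evolution.
#'
#' @param config A [sim_config()]; `genome_length` and `n_genes` drive the
#'   layout, `seed` makes the output deterministic.
#' @param mean_gene_length Mean coding length in bases (rounded to a codon
#'   multiple per gene).
#' @param n_paralog_pairs Number of duplicated gene pairs (each pair forms
#'   one paralog group).
#' @param paralog_divergence Fraction of positions mutated in the duplicate
#'   copy (0.1 gives ~90% identity).
#' @param selected_fraction Fraction of genes flagged as selected.
#'
#' @return A list with elements `genome` (class `reference_genome`: list of
#'   `genome_id`, `sequence`, `topology`) and `genes` (a data.frame with
#'   columns `gene_id`, `start`, `end` (0-based half-open), `strand`,
#'   `annotation`, `paralog_group`, `selection_class`).
#' @export
simulate_ancestor <- function(config,
                              mean_gene_length = 900L,
                              n_paralog_pairs = 1L,
                              paralog_divergence = 0.10,
                              selected_fraction = 0.2) {
  validate_sim_config(config)
  L <- config$genome_length
  n_genes <- config$n_genes
  with_seed(config$seed, {
    seq_codes <- sample.int(4L, L, replace = TRUE)

    genes <- data.frame(gene_id = character(), start = integer(),
                        end = integer(), strand = character(),
                        annotation = character(),
                        paralog_group = character(),
                        selection_class = character(),
                        stringsAsFactors = FALSE)
    if (n_genes > 0L) {
      # codon-multiple gene lengths around the requested mean
      lens <- 3L * pmax(50L, round(rnorm(n_genes, mean_gene_length / 3, 60)))
      if (sum(lens) + n_genes >= L) {
        stop("genome too short for ", n_genes, " genes of mean length ",
             mean_gene_length, " (need > ", sum(lens) + n_genes,
             " bases, have ", L, ")")
      }
      # place sequentially with random gaps from the leftover space
      slack <- L - sum(lens)
      gaps <- floor(slack * diff(c(0, sort(runif(n_genes)))))
      starts <- cumsum(gaps) + cumsum(c(0L, lens[-n_genes]))
      strands <- sample(c("+", "-"), n_genes, replace = TRUE)
      n_sel <- max(1L, round(selected_fraction * n_genes))
      sel <- rep("neutral", n_genes)
      sel[sample.int(n_genes, n_sel)] <- "selected"
      genes <- data.frame(
        gene_id = sprintf("gene_%04d", seq_len(n_genes)),
        start = as.integer(starts),
        end = as.integer(starts + lens),
        strand = strands,
        annotation = "hypothetical protein",
        paralog_group = NA_character_,
        selection_class = sel,
        stringsAsFactors = FALSE
      )

      n_paralog_pairs <- min(n_paralog_pairs, floor(n_genes / 2))
      if (n_paralog_pairs > 0L) {
        # pair genes of identical length by rewriting the second copy's
        # body as a mutated duplicate of the first
        free <- seq_len(n_genes)
        for (p in seq_len(n_paralog_pairs)) {
          i <- free[1L]
          len_i <- genes$end[i] - genes$start[i]
          j_pool <- free[free != i]
          j <- j_pool[which.min(abs((genes$end[j_pool] - genes$start[j_pool]) -
                                      len_i))]
          # force equal length: truncate/extend j's span is not possible
          # without moving neighbours, so rewrite j's body over len_i bases
          # only if it fits; otherwise shrink the copy to j's length
          len <- min(len_i, genes$end[j] - genes$start[j])
          len <- 3L * (len %/% 3L)
          genes$end[i] <- genes$start[i] + len
          genes$end[j] <- genes$start[j] + len
          src <- seq_codes[(genes$start[i] + 1L):(genes$start[i] + len)]
          n_mut <- floor(paralog_divergence * len)
          dup <- src
          if (n_mut > 0L) {
            at <- sample.int(len, n_mut)
            dup[at] <- ((dup[at] - 1L + sample.int(3L, n_mut, replace = TRUE)) %% 4L) + 1L
          }
          seq_codes[(genes$start[j] + 1L):(genes$start[j] + len)] <- dup
          grp <- sprintf("paralog_%02d", p)
          genes$paralog_group[c(i, j)] <- grp
          genes$annotation[c(i, j)] <- sprintf("duplicated gene family %s", grp)
          genes$strand[j] <- genes$strand[i]
          free <- setdiff(free, c(i, j))
        }
      }
    }

    genome <- structure(
      list(genome_id = sprintf("ancestor_seed%d", config$seed),
           sequence = decode_bases(seq_codes),
           topology = "linear"),
      class = "reference_genome"
    )
    list(genome = genome, genes = genes)
  })
}

#' @export
print.reference_genome <- function(x, ...) {
  cat("<reference_genome>", x$genome_id, "-", nchar(x$sequence), "bp,",
      x$topology, "\n")
  invisible(x)
}

# extract a gene's coding sequence (strand-aware) as base codes
gene_codes <- function(genome_codes, gene) {
  codes <- genome_codes[(gene$start + 1L):gene$end]
  if (gene$strand == "-") codes <- rev(5L - codes)  # reverse complement
  codes
}
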