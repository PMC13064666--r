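#' Generate error-bearing aligned reads from an isolate pool
#'
#' Emulates shotgun sequencing of a pooled sample: reads start uniformly
#' along the (linear) genome, each read is drawn from a lineage with
#' probability proportional to its isolate count, carries that lineage's
#' mutations within its span, and then accumulates independent per-base
#' substitution errors. Reads are emitted pre-aligned (ungapped, known
#' start); no aligner is involved. Wrapping reads are not produced --
#' circular genomes are sequenced as if linearized at the origin.
#'
#' @param pool An `isolate_pool` from [sample_isolate_pool()].
#' @param genome A `reference_genome`.
#' @param config A [sim_config()] supplying `mean_depth`, `read_length`,
#'   `error_rate`.
#' @param seed Optional seed for a deterministic draw.
#' @param sample_id Sample label recorded on every read.
#' @param n_reads Override the depth-derived read count.
#' @return data.frame of class `aligned_reads` with columns `read_id`,
#'   `genome_id`, `start` (0-based), `sequence`, `sample_id`,
#'   `true_lineage`.
#' @export
generate_reads <- function(pool, genome, config, seed = NULL,
                           sample_id = "sample1", n_reads = NULL) {
  stopifnot(inherits(pool, "isolate_pool"))
  validate_sim_config(config)
  rl <- config$read_length
  genome_codes <- encode_bases(genome$sequence)
  L <- length(genome_codes)
  if (rl > L) stop("read_length exceeds genome length")
  n <- n_reads %||% round(config$mean_depth * L / rl)

  run <- function() {
    starts <- sample.int(L - rl + 1L, n, replace = TRUE) - 1L  # 0-based
    lin_idx <- sample.int(length(pool$counts), n, replace = TRUE,
                          prob = pool$counts)
    mat <- matrix(genome_codes[rep(starts, each = rl) + seq_len(rl)],
                  nrow = n, ncol = rl, byrow = TRUE)
    # install lineage mutations falling inside each read's span
    muts <- pool$pop$mutations
    if (nrow(muts)) {
      alt_code <- match(muts$alt, BASES)
      for (li in seq_along(pool$pop$members)) {
        mset <- pool$pop$members[[li]]
        if (!length(mset)) next
        rd <- which(lin_idx == li)
        if (!length(rd)) next
        for (m in mset) {
          pos <- muts$position[m]
          hit <- rd[starts[rd] <= pos & pos < starts[rd] + rl]
          if (length(hit)) mat[cbind(hit, pos - starts[hit] + 1L)] <- alt_code[m]
        }
      }
    }
    # sequencing errors: substitutions to one of the three other bases
    if (config$error_rate > 0) {
      n_err <- rbinom(1L, n * rl, config$error_rate)
      if (n_err > 0L) {
        at <- sample.int(n * rl, n_err)
        mat[at] <- ((mat[at] - 1L + sample.int(3L, n_err, replace = TRUE)) %% 4L) + 1L
      }
    }
    chr <- matrix(BASES[mat], nrow = n)
    seqs <- do.call(paste0, as.data.frame(chr, stringsAsFactors = FALSE))
    data.frame(
      read_id = sprintf("%s_read_%06d", sample_id, seq_len(n)),
      genome_id = genome$genome_id,
      start = starts,
      sequence = seqs,
      sample_id = sample_id,
      true_lineage = pool$pop$lineage_ids[lin_idx],
      stringsAsFactors = FALSE
    )
  }
  reads <- if (is.null(seed)) run() else with_seed(seed, run())
  class(reads) <- c("aligned_reads", "data.frame")
  reads
}
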