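#' Build a per-position allele-count pileup from aligned reads
#'
#' Counts A/C/G/T read support at every covered position of the reference.
#' Reads must be gap-free, fully-matching alignments (CIGAR `<len>M`);
#' positions with zero coverage are omitted.
#'
#' @param reads An `aligned_reads` data.frame (columns `start` 0-based and
#'   `sequence`), e.g. from [generate_reads()] or [read_sam()].
#' @param genome A `reference_genome`.
#' @return data.frame of class `pileup` with columns `position` (0-based),
#'   `A`, `C`, `G`, `T`, `depth`.
#' @export
build_pileup <- function(reads, genome) {
  L <- nchar(genome$sequence)
  widths <- nchar(reads$sequence)
  if (nrow(reads) == 0L) {
    out <- data.frame(position = integer(), A = integer(), C = integer(),
                      G = integer(), T = integer(), depth = integer())
    class(out) <- c("pileup", "data.frame")
    return(out)
  }
  if (any(reads$start < 0L) || any(reads$start + widths > L)) {
    stop("malformed input: read exceeds genome bounds")
  }
  pos <- sequence(widths) - 1L + rep(reads$start, widths)  # 0-based
  code <- encode_bases(reads$sequence)
  cell <- pos * 4L + code  # 1..4 within each position
  tab <- tabulate(cell, nbins = 4L * L)
  mat <- matrix(tab, ncol = 4L, byrow = TRUE)
  depth <- rowSums(mat)
  covered <- which(depth > 0L)
  out <- data.frame(position = covered - 1L,
                    A = mat[covered, 1L], C = mat[covered, 2L],
                    G = mat[covered, 3L], T = mat[covered, 4L],
                    depth = as.integer(depth[covered]))
  class(out) <- c("pileup", "data.frame")
  out
}

#' Call variants from a pileup with pool-aware thresholds
#'
#' One call is emitted per (position, non-reference base) whose read
#' support passes the [detection_rule()]: at least `min_alt_reads`
#' supporting reads and alternate frequency `alt_count / depth >=
#' min_frequency`. Multi-allelic positions yield one call per alternate
#' base. Frequencies are exact read-count ratios; at the default 1%
#' threshold with 100-isolate pools, variants carried by a single isolate
#' sit exactly on the detection floor.
#'
#' @param pileup A `pileup` from [build_pileup()].
#' @param genome The `reference_genome` the pileup was built against.
#' @param rule A [detection_rule()].
#' @return data.frame of class `variant_calls`: columns `position`
#'   (0-based), `ref`, `alt`, `alt_count`, `depth`, `frequency`, plus
#'   `gene_id`, `effect`, `codon_change`, `aa_change` placeholders filled
#'   by [annotate_effect()].
#' @export
call_variants <- function(pileup, genome, rule = detection_rule()) {
  stopifnot(inherits(rule, "detection_rule"))
  genome_codes <- encode_bases(genome$sequence)
  ref_code <- genome_codes[pileup$position + 1L]
  counts <- as.matrix(pileup[, BASES])
  rows <- list()
  for (b in 1:4) {
    alt_count <- counts[, b]
    ok <- which(ref_code != b &
                  alt_count >= rule$min_alt_reads &
                  alt_count / pileup$depth >= rule$min_frequency &
                  alt_count > 0L)
    if (length(ok)) {
      rows[[b]] <- data.frame(
        position = pileup$position[ok],
        ref = BASES[ref_code[ok]],
        alt = BASES[b],
        alt_count = as.integer(alt_count[ok]),
        depth = pileup$depth[ok],
        frequency = alt_count[ok] / pileup$depth[ok],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = integer(), ref = character(), alt = character(),
               alt_count = integer(), depth = integer(),
               frequency = numeric(), stringsAsFactors = FALSE)
  out <- out[order(out$position, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out$gene_id <- NA_character_
  out$effect <- NA_character_
  out$codon_change <- NA_character_
  out$aa_change <- NA_character_
  class(out) <- c("variant_calls", "data.frame")
  out
}

#' Annotate coding effect of variant calls
#'
#' Classifies each substitution as synonymous, non-synonymous or
#' intergenic using the standard genetic code on the strand-aware codon
#' containing the position (reverse-strand genes are complement-
#' translated). Stop-codon gains are classified as non-synonymous (binary
#' split, no separate nonsense class). Genes whose length is not a codon
#' multiple trigger a warning and their calls fall back to intergenic.
#'
#' @param calls A `variant_calls` data.frame.
#' @param genes Gene models (0-based half-open `start`/`end`, `strand`).
#' @param genome The `reference_genome`.
#' @return `calls` with `gene_id`, `effect`, `codon_change`, `aa_change`
#'   filled.
#' @export
annotate_effect <- function(calls, genes, genome) {
  if (nrow(calls) == 0L) return(calls)
  genome_codes <- encode_bases(genome$sequence)
  code_tab <- Biostrings::GENETIC_CODE
  calls$effect <- "intergenic"
  if (is.null(genes) || nrow(genes) == 0L) return(calls)

  bad_len <- (genes$end - genes$start) %% 3L != 0L
  if (any(bad_len)) {
    warning("gene length not divisible by 3 for: ",
            paste(genes$gene_id[bad_len], collapse = ", "),
            "; calls in these genes left intergenic")
  }
  usable <- genes[!bad_len, , drop = FALSE]
  for (i in seq_len(nrow(calls))) {
    pos <- calls$position[i]
    gi <- which(usable$start <= pos & pos < usable$end)
    if (!length(gi)) next
    g <- usable[gi[1L], ]
    calls$gene_id[i] <- g$gene_id
    # offset within the coding sequence, strand-aware
    off <- if (g$strand == "+") pos - g$start else g$end - 1L - pos
    codon_i <- off %/% 3L
    within <- off %% 3L
    cds <- gene_codes(genome_codes, g)
    codon <- cds[(codon_i * 3L + 1L):(codon_i * 3L + 3L)]
    alt_code <- match(calls$alt[i], BASES)
    if (g$strand == "-") alt_code <- 5L - alt_code  # complement
    codon_mut <- codon
    codon_mut[within + 1L] <- alt_code
    ref_codon <- paste(BASES[codon], collapse = "")
    alt_codon <- paste(BASES[codon_mut], collapse = "")
    aa_ref <- code_tab[[ref_codon]]
    aa_alt <- code_tab[[alt_codon]]
    calls$codon_change[i] <- paste0(ref_codon, ">", alt_codon)
    calls$aa_change[i] <- sprintf("%s%d%s", aa_ref, codon_i + 1L, aa_alt)
    calls$effect[i] <- if (aa_ref == aa_alt) "synonymous" else "non-synonymous"
  }
  calls
}
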