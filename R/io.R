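# standard comment header for every text output: tool version, config
# hash, seed -- so any file can be traced to the run that produced it
output_header <- function(seed = NA, config = NULL, char = "#") {
  hash <- if (is.null(config)) "none" else config_hash(config)
  paste0(char, c(paste0("evopool_version=", as.character(packageVersion("evopool"))),
                 paste0("config_hash=", hash),
                 paste0("seed=", seed)))
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(names(unlist(config)), unlist(config), sep = "="), f)
  unname(tools::md5sum(f))
}

#' Read and write FASTA
#'
#' Thin wrappers over Biostrings keeping the package's plain
#' `reference_genome` representation at the boundary.
#'
#' @param genome A `reference_genome` (for writing).
#' @param path File path.
#' @return `read_fasta()` returns a `reference_genome` (first record).
#' @export
write_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(setNames(genome$sequence, genome$genome_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  structure(list(genome_id = names(x)[1L],
                 sequence = as.character(x[[1L]]),
                 topology = "linear"),
            class = "reference_genome")
}

#' Read and write gene models as GFF3
#'
#' Internal coordinates are 0-based half-open; GFF3 is 1-based inclusive.
#' The conversion happens exactly once, here.
#'
#' @param genes Gene model data.frame (internal coordinates).
#' @param genome The `reference_genome` (sequence id and length).
#' @param path File path.
#' @return `read_gff3()` returns the internal gene model data.frame.
#' @export
write_gff3 <- function(genes, genome, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genome$genome_id,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  gr$annotation <- genes$annotation
  gr$paralog_group <- genes$paralog_group
  gr$selection_class <- genes$selection_class
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  get_chr <- function(col, default = NA_character_) {
    if (col %in% names(md)) as.character(md[[col]]) else
      rep(default, length(gr))
  }
  data.frame(
    gene_id = get_chr("ID"),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    annotation = get_chr("annotation"),
    paralog_group = get_chr("paralog_group"),
    selection_class = get_chr("selection_class", "neutral"),
    stringsAsFactors = FALSE
  )
}

#' Write aligned reads as FASTQ
#'
#' Constant quality (no quality model is simulated).
#'
#' @param reads An `aligned_reads` data.frame.
#' @param path File path.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  q <- Biostrings::BStringSet(strrep("I", nchar(reads$sequence)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Write and read the SAM subset used for simulated alignments
#'
#' Writer emits a standard SAM header (`@HD`, `@SQ`) and the 11 mandatory
#' columns with match-only CIGARs (`<len>M`), POS 1-based. The reader goes
#' through Rsamtools (SAM -> BAM conversion, then `scanBam`) and rejects
#' any CIGAR operation other than a single match run.
#'
#' @param reads An `aligned_reads` data.frame.
#' @param genome The `reference_genome` aligned against.
#' @param path File path.
#' @return `read_sam()` returns an `aligned_reads` data.frame (0-based
#'   `start`).
#' @export
write_sam <- function(reads, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", genome$genome_id,
                       nchar(genome$sequence))), con)
  if (nrow(reads)) {
    w <- nchar(reads$sequence)
    writeLines(sprintf("%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                       reads$read_id, reads$genome_id %||% genome$genome_id,
                       reads$start + 1L, w, reads$sequence,
                       strrep("I", w)), con)
  }
  invisible(path)
}

#' @rdname write_sam
#' @export
read_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam))
  res <- Rsamtools::scanBam(bam)[[1L]]
  cig <- res$cigar
  bad <- !grepl("^[0-9]+M$", cig)
  if (any(bad)) {
    stop("unsupported CIGAR operations (only <len>M accepted): ",
         paste(unique(cig[bad]), collapse = ", "))
  }
  out <- data.frame(read_id = res$qname,
                    genome_id = as.character(res$rname),
                    start = res$pos - 1L,
                    sequence = as.character(res$seq),
                    sample_id = NA_character_,
                    true_lineage = NA_character_,
                    stringsAsFactors = FALSE)
  class(out) <- c("aligned_reads", "data.frame")
  out
}

#' Write and read variant calls as VCF v4.2
#'
#' Writer emits the 8 fixed columns with INFO keys `AF` (alternate
#' frequency), `DP` (depth), `EFF` (effect class), `GENE`; truth files use
#' `TRUEAF`. POS is 1-based (converted from the internal 0-based
#' coordinates exactly once). The reader goes through vcfR.
#'
#' @param calls A `variant_calls` data.frame.
#' @param genome The `reference_genome`.
#' @param path File path.
#' @param sample_id Recorded in the header.
#' @param seed,config Recorded in the header.
#' @param af_key INFO key for the frequency field (`"AF"`, or `"TRUEAF"`
#'   for truth output).
#' @return `read_vcf()` returns a `variant_calls` data.frame.
#' @export
write_vcf <- function(calls, genome, path, sample_id = NA, seed = NA,
                      config = NULL, af_key = "AF") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##source=evopool %s", packageVersion("evopool")),
    sprintf("##evopool_seed=%s", seed),
    sprintf("##evopool_config_hash=%s",
            if (is.null(config)) "none" else config_hash(config)),
    sprintf("##evopool_sample=%s", sample_id),
    sprintf("##contig=<ID=%s,length=%d>", genome$genome_id,
            nchar(genome$sequence)),
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"Alternate allele frequency\">",
            af_key),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Coding effect\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene id\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), con)
  if (nrow(calls)) {
    info <- sprintf("%s=%s;DP=%s;EFF=%s;GENE=%s", af_key,
                    format(calls$frequency, digits = 6, trim = TRUE),
                    calls$depth %||% NA,
                    calls$effect %||% NA, calls$gene_id %||% NA)
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                       genome$genome_id, calls$position + 1L,
                       calls$ref, calls$alt, info), con)
  }
  invisible(path)
}

#' @rdname write_vcf
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  grab <- function(key) {
    m <- regmatches(fix$INFO,
                    regexpr(paste0("(?<=^|;)", key, "=[^;]*"), fix$INFO,
                            perl = TRUE))
    val <- rep(NA_character_, nrow(fix))
    has <- grepl(paste0("(^|;)", key, "="), fix$INFO)
    val[has] <- sub(paste0(key, "="), "", m)
    val
  }
  af <- grab("AF")
  if (all(is.na(af))) af <- grab("TRUEAF")
  dp <- grab("DP")
  out <- data.frame(position = as.integer(fix$POS) - 1L,
                    ref = fix$REF, alt = fix$ALT,
                    alt_count = NA_integer_,
                    depth = suppressWarnings(as.integer(dp)),
                    frequency = suppressWarnings(as.numeric(af)),
                    gene_id = grab("GENE"), effect = grab("EFF"),
                    codon_change = NA_character_,
                    aa_change = NA_character_,
                    stringsAsFactors = FALSE)
  out$gene_id[out$gene_id == "NA"] <- NA_character_
  out$effect[out$effect == "NA"] <- NA_character_
  out$alt_count <- as.integer(round(out$frequency * out$depth))
  class(out) <- c("variant_calls", "data.frame")
  out
}

#' Write and read headered TSV
#'
#' Tab-separated tables with `#key=value` provenance comment lines (tool
#' version, config hash, seed) that the reader skips.
#'
#' @param df data.frame to write.
#' @param path File path.
#' @param seed,config Recorded in the header.
#' @return `read_tsv()` returns the data.frame.
#' @export
write_tsv <- function(df, path, seed = NA, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(seed, config), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}
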