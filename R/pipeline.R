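#' Run the full synthetic-experiment pipeline
#'
#' Executes every stage end to end -- simulate, call, census, linkage,
#' dynamics, community -- and writes all outputs (FASTA/GFF3/VCF/TSV) plus
#' a checksum manifest to `outdir`. Deterministic given `seed`. Stage
#' failures abort with the stage name; stages that a degenerate layout
#' cannot support (e.g. dynamics with a single timepoint) are skipped with
#' a logged notice.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if missing).
#' @param seed Run seed (default `config$seed`).
#' @param observation Passed to [simulate_experiment()].
#' @param quiet Suppress stage logging to stderr.
#' @return Invisibly, a list with the `evo_experiment`, the shared set,
#'   per-stage result objects, and the manifest data.frame.
#' @export
run_pipeline <- function(config = sim_config(), outdir, seed = NULL,
                         observation = "binomial", quiet = FALSE) {
  seed <- as.integer(seed %||% config$seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(outdir, "pipeline.log")
  logs <- character()
  say <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   paste0(...))
    logs <<- c(logs, msg)
    if (!quiet) message(msg)
  }
  stage <- function(name, expr) {
    say("stage ", name, " started")
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  say("run seed=", seed, " config_hash=", config_hash(config))

  exp <- stage("simulate", simulate_experiment(config, seed = seed,
                                               observation = observation))
  write_fasta(exp$genome, file.path(outdir, "reference.fasta"))
  write_gff3(exp$genes, exp$genome, file.path(outdir, "genes.gff3"))
  write_tsv(exp$samples, file.path(outdir, "samples.tsv"), seed, config)
  write_tsv(exp$covariates, file.path(outdir, "site_covariates.tsv"),
            seed, config)
  truth <- exp$truth$planted
  truth_calls <- data.frame(position = truth$position, ref = truth$ref,
                            alt = truth$alt, alt_count = NA, depth = NA,
                            frequency = rowMeans(exp$truth$pool_frequency,
                                                 na.rm = TRUE),
                            gene_id = truth$gene_id, effect = NA,
                            stringsAsFactors = FALSE)
  write_vcf(truth_calls, exp$genome, file.path(outdir, "truth.vcf"),
            sample_id = "truth", seed = seed, config = config,
            af_key = "TRUEAF")
  vcf_dir <- file.path(outdir, "vcf")
  dir.create(vcf_dir, showWarnings = FALSE)
  stage("call", for (s in exp$samples$sample_id) {
    write_vcf(exp$calls[[s]], exp$genome,
              file.path(vcf_dir, paste0(s, ".vcf")), sample_id = s,
              seed = seed, config = config)
  })

  census <- stage("census", {
    shared <- classify_shared(exp$matrix, exp$criterion)
    counts <- per_achip_counts(exp$matrix, shared)
    gsum <- ns_ratio(gene_mutation_counts(exp$matrix))
    venns <- lapply(config$timepoints, function(t) {
      cbind(timepoint = t, venn_partition(exp$matrix, timepoint = t))
    })
    write_tsv(data.frame(key = c(shared$shared, shared$non_shared),
                         shared = rep(c(TRUE, FALSE),
                                      c(length(shared$shared),
                                        length(shared$non_shared)))),
              file.path(outdir, "shared_set.tsv"), seed, config)
    write_tsv(do.call(rbind, venns), file.path(outdir, "venn_regions.tsv"),
              seed, config)
    write_tsv(as.data.frame(gsum), file.path(outdir, "gene_summary.tsv"),
              seed, config)
    write_tsv(counts$per_sample, file.path(outdir, "per_achip_counts.tsv"),
              seed, config)
    mat_df <- cbind(exp$matrix$variants,
                    as.data.frame(exp$matrix$frequency))
    write_tsv(mat_df, file.path(outdir, "mutation_matrix.tsv"), seed,
              config)
    list(shared = shared, counts = counts, gene_summary = gsum,
         venns = venns)
  })

  linkage <- NULL
  if (length(exp$reads)) {
    linkage <- stage("linkage", {
      s1 <- exp$samples$sample_id[1L]
      cl <- exp$calls[[s1]]
      pairs <- all_variant_pairs(cl, max_distance = config$read_length)
      rec <- pairwise_linkage(exp$reads[[s1]], pairs)
      write_tsv(as.data.frame(rec), file.path(outdir, "linkage.tsv"),
                seed, config)
      rec
    })
  } else say("stage linkage skipped: no per-read output (binomial mode)")

  dynamics <- NULL
  tps <- sort(unique(exp$samples$timepoint))
  if (length(tps) >= 2L) {
    dynamics <- stage("dynamics", {
      shared_keys <- intersect(census$shared$shared,
                               exp$matrix$variants$key)
      shifts <- do.call(rbind, lapply(tps[-1L], function(t) {
        cbind(timepoint = t,
              baseline_shift(exp$matrix, baseline_timepoint = tps[1L],
                             target_timepoint = t,
                             variants = shared_keys))
      }))
      an <- site_anova(exp$matrix, timepoint = max(tps),
                       variants = shared_keys)
      corr <- abiotic_correlation(exp$matrix, exp$covariates,
                                  timepoint = max(tps),
                                  variants = shared_keys)
      write_tsv(shifts, file.path(outdir, "freq_shifts.tsv"), seed, config)
      write_tsv(an, file.path(outdir, "site_anova.tsv"), seed, config)
      write_tsv(as.data.frame(corr), file.path(outdir, "correlations.tsv"),
                seed, config)
      list(shifts = shifts, anova = an, correlations = corr)
    })
  } else {
    say("stage dynamics skipped: fewer than 2 timepoints in layout")
  }

  communty <- stage("community", {
    ct <- exp$community
    div <- data.frame(sample_id = names(shannon_diversity(ct)),
                      shannon = unname(shannon_diversity(ct)),
                      stringsAsFactors = FALSE)
    bc <- bray_curtis(ct)
    ord <- pcoa_ordination(bc)
    attr_res <- attribute_sources(ct)
    write_tsv(cbind(taxon = rownames(ct$counts),
                    as.data.frame(ct$counts)),
              file.path(outdir, "community_counts.tsv"), seed, config)
    write_tsv(div, file.path(outdir, "shannon.tsv"), seed, config)
    write_tsv(cbind(sample_id = rownames(bc), as.data.frame(bc)),
              file.path(outdir, "bray_curtis.tsv"), seed, config)
    write_tsv(cbind(sample_id = rownames(ord$coordinates),
                    as.data.frame(ord$coordinates)),
              file.path(outdir, "pcoa.tsv"), seed, config)
    write_tsv(attr_res$site_percentages,
              file.path(outdir, "source_attribution.tsv"), seed, config)
    list(diversity = div, pcoa = ord, attribution = attr_res)
  })

  say("writing manifest")
  files <- setdiff(list.files(outdir, recursive = TRUE),
                   c("manifest.tsv", "pipeline.log"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(outdir, files))),
    stringsAsFactors = FALSE
  )
  write_tsv(manifest, file.path(outdir, "manifest.tsv"), seed, config)
  writeLines(logs, log_file)
  invisible(list(experiment = exp, census = census, linkage = linkage,
                 dynamics = dynamics, community = communty,
                 manifest = manifest))
}
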