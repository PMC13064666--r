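PAPER_SITES <- c("BC", "BT", "CCC", "GH", "PVF")

#' Scale a k-of-n shared criterion to a new sample count
#'
#' Keeps the reference prevalence fraction (default 54/59) while adapting
#' to the layout's actual sampled-chamber count, rounding k up so the
#' rule never loosens.
#'
#' @param n Number of sampled chambers.
#' @param k_ref,n_ref Reference rule (defaults 54 of 59).
#' @return A [shared_criterion()].
#' @export
scale_shared_criterion <- function(n, k_ref = 54L, n_ref = 59L) {
  shared_criterion(min(n, ceiling(n * k_ref / n_ref)), n)
}

experiment_layout <- function(config) {
  sites <- if (config$n_sites == 5L) PAPER_SITES else
    paste0("S", seq_len(config$n_sites))
  grid <- expand.grid(achip = seq_len(config$n_achips_per_site),
                      site = sites, stringsAsFactors = FALSE)
  tp <- rep_len(config$timepoints, config$n_achips_per_site)
  grid$timepoint <- tp[grid$achip]
  data.frame(sample_id = sprintf("%s_a%02d_t%02d", grid$site, grid$achip,
                                 grid$timepoint),
             achip_id = sprintf("%s_a%02d", grid$site, grid$achip),
             site = grid$site,
             timepoint = grid$timepoint,
             species = "focal_sp",
             pool_size = config$pool_size,
             stringsAsFactors = FALSE)
}

default_site_covariates <- function(sites) {
  # abiotic ranges typical of the farm soils profiled in such studies
  data.frame(site = sites,
             zinc_ppm = round(runif(length(sites), 1.0, 9.0), 2),
             pH = round(runif(length(sites), 5.6, 7.2), 2),
             organic_matter_pct = round(runif(length(sites), 2.2, 4.9), 2),
             stringsAsFactors = FALSE)
}

#' Simulate a complete pooled-isolate resequencing experiment
#'
#' Runs the full synthetic study: ancestral genome with gene models and a
#' paralog pair; a pre-deployment carrier-soil population carrying planted
#' mid-frequency (25--50%) linked mutations (the shared set); independent
#' burial-phase Wright-Fisher evolution with dormancy for every chamber;
#' 100-isolate pool sampling; a sequencing observation per chamber; variant
#' calling; and assembly of the cross-sample mutation matrix with effect
#' annotation. Also simulates the contaminant community and site abiotic
#' covariates, and records machine-readable truth.
#'
#' @param config A [sim_config()].
#' @param seed Run seed (default `config$seed`).
#' @param observation `"binomial"` observes each truth mutation's pool
#'   frequency through a Poisson-depth binomial read draw (fast, the
#'   default for multi-chamber layouts); `"reads"` emits full aligned
#'   reads per chamber and runs the pileup caller on them (needed for
#'   linkage and paralog work; use small layouts).
#' @param covariates Optional site covariate data.frame (`site` + numeric
#'   columns); generated from the seed when `NULL`.
#' @param community Simulate the contaminant community table too.
#' @return Object of class `evo_experiment`: list with `genome`, `genes`,
#'   `samples`, `calls` (named list), `matrix` (a `mutation_matrix`),
#'   `criterion` (scaled k-of-n rule), `truth` (list: `planted` data.frame
#'   with `key`, `gene_id`, `lineage`; `pool_frequency` planted x samples
#'   matrix), `pools` (list of `isolate_pool`), `reads` (named list, reads
#'   mode only), `covariates`, `community`, `config`, `seed`.
#' @export
simulate_experiment <- function(config = sim_config(), seed = NULL,
                                observation = c("binomial", "reads"),
                                covariates = NULL, community = TRUE) {
  observation <- match.arg(observation)
  validate_sim_config(config)
  seed <- as.integer(seed %||% config$seed)
  cfg <- config
  cfg$seed <- seed
  anc <- simulate_ancestor(cfg)
  genome <- anc$genome
  genes <- anc$genes
  rule <- detection_rule()
  metas <- experiment_layout(cfg)

  with_seed(seed + 1L, {
    pre_pop <- plant_shared_mutations(genome, genes,
                                      n = cfg$n_shared_mutations)
    if (is.null(covariates)) {
      covariates <- default_site_covariates(unique(metas$site))
    }

    # optional abiotic effect: lineages whose planted mutations sit in the
    # first planted gene respond to one covariate during burial
    ab <- cfg$abiotic_slope
    ab_gene <- NA_character_
    if (!is.null(ab)) {
      ab_cov <- names(ab)
      if (!ab_cov %in% names(covariates)) {
        stop("abiotic_slope names unknown covariate: ", ab_cov)
      }
      ab_gene <- pre_pop$mutations$gene_id[1L]
      z_all <- scale(covariates[[ab_cov]])[, 1L]
    }

    pools <- list()
    calls <- list()
    reads_list <- list()
    for (i in seq_len(nrow(metas))) {
      t <- metas$timepoint[i]
      gens <- round(cfg$generations_burial * t / max(cfg$timepoints))
      extra <- NULL
      if (!is.null(ab)) {
        z <- z_all[match(metas$site[i], covariates$site)]
        mult <- exp(unname(ab) * z)
        extra <- function(pop) {
          resp <- vapply(pop$members, function(m) {
            any(pop$mutations$planted[m] &
                  pop$mutations$gene_id[m] %in% ab_gene)
          }, logical(1))
          ifelse(resp, mult, 1)
        }
      }
      pop_t <- evolve_population(genome, genes, "burial", cfg, pre_pop,
                                 generations = gens, extra_fitness = extra)
      pool <- sample_isolate_pool(pop_t, cfg$pool_size)
      pools[[metas$sample_id[i]]] <- pool

      if (observation == "binomial") {
        calls[[metas$sample_id[i]]] <- observe_pool_binomial(pool, cfg, rule)
      } else {
        rd <- generate_reads(pool, genome, cfg,
                             sample_id = metas$sample_id[i])
        reads_list[[metas$sample_id[i]]] <- rd
        pl <- build_pileup(rd, genome)
        calls[[metas$sample_id[i]]] <- call_variants(pl, genome, rule)
      }
    }

    mat <- build_matrix(calls, metas, rule)
    # annotate the variant union once, then propagate
    if (nrow(mat$variants)) {
      ann <- annotate_effect(as_calls(mat$variants), genes, genome)
      mat$variants$gene_id <- ann$gene_id
      mat$variants$effect <- ann$effect
    }

    planted <- pre_pop$mutations[pre_pop$mutations$planted, , drop = FALSE]
    planted_key <- variant_key(planted$position, planted$ref, planted$alt)
    lin_of <- vapply(seq_len(nrow(planted)), function(m) {
      hit <- which(vapply(pre_pop$members,
                          function(mm) m %in% mm, logical(1)))
      pre_pop$lineage_ids[hit[1L]]
    }, character(1))
    pool_freq <- vapply(metas$sample_id, function(s) {
      pool <- pools[[s]]
      key_s <- variant_key(pool$pop$mutations$position,
                           pool$pop$mutations$ref, pool$pop$mutations$alt)
      pool$mutation_frequencies[match(planted_key, key_s)]
    }, numeric(nrow(planted)))
    pool_freq <- matrix(pool_freq, nrow = nrow(planted),
                        dimnames = list(planted_key, metas$sample_id))

    comm <- if (community) {
      layout <- rbind(
        data.frame(sample_id = "PRE_carrier", site = "PRE", timepoint = 0L,
                   stringsAsFactors = FALSE),
        metas[, c("sample_id", "site", "timepoint")]
      )
      simulate_contaminants(cfg, seed = seed + 2L, metas = layout)
    } else NULL

    structure(list(genome = genome, genes = genes, samples = metas,
                   calls = calls, matrix = mat,
                   criterion = scale_shared_criterion(nrow(metas)),
                   truth = list(planted = data.frame(
                                  key = planted_key,
                                  position = planted$position,
                                  ref = planted$ref, alt = planted$alt,
                                  gene_id = planted$gene_id,
                                  lineage = lin_of,
                                  abiotic_gene = ab_gene,
                                  stringsAsFactors = FALSE),
                                pool_frequency = pool_freq,
                                pre_population = pre_pop),
                   pools = pools, reads = reads_list,
                   covariates = covariates, community = comm,
                   config = cfg, seed = seed),
              class = "evo_experiment")
  })
}

# observe each truth mutation of a pool through Poisson depth + binomial
# alt reads (with substitution error), returning a variant_calls frame
observe_pool_binomial <- function(pool, config, rule) {
  muts <- pool$pop$mutations
  f <- pool$mutation_frequencies
  keep <- which(f > 0)
  e <- config$error_rate
  depth <- rpois(length(keep), config$mean_depth)
  p_obs <- f[keep] * (1 - e) + (1 - f[keep]) * e / 3
  alt <- rbinom(length(keep), depth, p_obs)
  ok <- which(alt >= rule$min_alt_reads & depth > 0 &
                alt / depth >= rule$min_frequency)
  out <- data.frame(position = muts$position[keep][ok],
                    ref = muts$ref[keep][ok],
                    alt = muts$alt[keep][ok],
                    alt_count = alt[ok],
                    depth = depth[ok],
                    frequency = alt[ok] / depth[ok],
                    gene_id = NA_character_, effect = NA_character_,
                    codon_change = NA_character_,
                    aa_change = NA_character_,
                    stringsAsFactors = FALSE)
  out <- out[order(out$position, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("variant_calls", "data.frame")
  out
}

# view a mutation_matrix variants frame as a variant_calls frame so the
# annotator can run on the union once
as_calls <- function(variants) {
  out <- data.frame(position = variants$position, ref = variants$ref,
                    alt = variants$alt, alt_count = NA_integer_,
                    depth = NA_integer_, frequency = NA_real_,
                    gene_id = NA_character_, effect = NA_character_,
                    codon_change = NA_character_, aa_change = NA_character_,
                    stringsAsFactors = FALSE)
  class(out) <- c("variant_calls", "data.frame")
  out
}

#' @export
print.evo_experiment <- function(x, ...) {
  cat("<evo_experiment> seed", x$seed, "-", nrow(x$samples), "chambers,",
      nrow(x$matrix$variants), "variants,",
      nrow(x$truth$planted), "planted shared mutations\n")
  invisible(x)
}
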