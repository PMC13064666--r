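#' Simulation configuration
#'
#' Bundles every tunable of the synthetic experiment: the evolving
#' population, the two growth phases (pre-burial lab incubation and burial
#' with dormancy), the pooled sampling and sequencing model, and the
#' experiment layout (sites x chambers x timepoints).
#'
#' @param seed Integer seed controlling every stochastic step.
#' @param population_size Haploid population size N for Wright-Fisher
#'   resampling.
#' @param mutation_rate Expected new mutations per genome per generation
#'   (Poisson rate per individual).
#' @param generations_pre Generations of pre-burial lab incubation.
#' @param generations_burial Generations spanned by the full burial period
#'   (before dormancy thinning); timepoints realize a proportional share.
#' @param dormancy_fraction Fraction of burial generations skipped by
#'   dormancy, in `[0, 1]`. Only `ceil((1 - dormancy_fraction) * g)`
#'   generations are realized.
#' @param selection_coefficient Per-mutation fitness advantage `s` for
#'   mutations landing in selected genes (multiplier `(1+s)^k`).
#' @param pool_size Isolates per recaptured pool (default 100, giving the
#'   1% frequency detection floor).
#' @param mean_depth Mean sequencing depth per position (reads).
#' @param read_length Read length in bases.
#' @param error_rate Per-base substitution error rate.
#' @param genome_length Ancestral genome length in bases.
#' @param n_genes Number of genes placed on the ancestral genome.
#' @param n_sites Number of burial sites.
#' @param n_achips_per_site Chambers buried (and sampled) per site.
#' @param timepoints Retrieval timepoints in months; each chamber is
#'   destructively sampled at exactly one of them.
#' @param n_shared_mutations Pre-deployment mutations planted at 25--50%
#'   frequency (standing variation shared by every chamber).
#' @param n_taxa Contaminant taxa in the carrier-soil community.
#' @param community_reads Shotgun reads drawn per community sample.
#' @param site_effect_sd Log-scale standard deviation of the per-site,
#'   per-time community perturbation at the final timepoint (scales
#'   linearly with time).
#' @param external_taxon_fraction Fraction of contaminant taxa absent from
#'   the pre-deployment pool (default 0: all contaminants are carrier-soil
#'   residents).
#' @param abiotic_slope Optional named number: per-unit standardized
#'   covariate effect on the burial-phase selection coefficient of planted
#'   mutations in one gene (e.g. `c(zinc_ppm = -0.5)` makes high-zinc sites
#'   select against that gene's variants). `NULL` disables the effect.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       population_size = 10000L,
                       mutation_rate = 0.01,
                       generations_pre = 60L,
                       generations_burial = 120L,
                       dormancy_fraction = 0.9,
                       selection_coefficient = 0.08,
                       pool_size = 100L,
                       mean_depth = 450,
                       read_length = 150L,
                       error_rate = 0.001,
                       genome_length = 50000L,
                       n_genes = 40L,
                       n_sites = 5L,
                       n_achips_per_site = 12L,
                       timepoints = c(3L, 10L, 24L),
                       n_shared_mutations = 12L,
                       n_taxa = 40L,
                       community_reads = 50000L,
                       site_effect_sd = 1.0,
                       external_taxon_fraction = 0,
                       abiotic_slope = NULL) {
  cfg <- list(
    seed = as.integer(seed),
    population_size = as.integer(population_size),
    mutation_rate = mutation_rate,
    generations_pre = as.integer(generations_pre),
    generations_burial = as.integer(generations_burial),
    dormancy_fraction = dormancy_fraction,
    selection_coefficient = selection_coefficient,
    pool_size = as.integer(pool_size),
    mean_depth = mean_depth,
    read_length = as.integer(read_length),
    error_rate = error_rate,
    genome_length = as.integer(genome_length),
    n_genes = as.integer(n_genes),
    n_sites = as.integer(n_sites),
    n_achips_per_site = as.integer(n_achips_per_site),
    timepoints = as.integer(timepoints),
    n_shared_mutations = as.integer(n_shared_mutations),
    n_taxa = as.integer(n_taxa),
    community_reads = as.integer(community_reads),
    site_effect_sd = site_effect_sd,
    external_taxon_fraction = external_taxon_fraction,
    abiotic_slope = abiotic_slope
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  rates <- c(cfg$mutation_rate, cfg$dormancy_fraction, cfg$error_rate,
             cfg$external_taxon_fraction)
  if (any(rates < 0 | rates > 1)) {
    stop("mutation_rate, dormancy_fraction, error_rate and ",
         "external_taxon_fraction must lie in [0, 1]")
  }
  if (cfg$population_size < cfg$pool_size) {
    stop("population_size must be >= pool_size")
  }
  if (cfg$mean_depth <= 0) stop("mean_depth must be positive")
  if (cfg$pool_size < 1L) stop("pool_size must be >= 1")
  if (cfg$genome_length < 1L) stop("genome_length must be positive")
  cfg
}

#' Load a simulation configuration from a flat YAML file
#'
#' Keys mirror the arguments of [sim_config()]; unknown keys are an error so
#' typos do not silently fall back to defaults.
#'
#' @param path Path to a YAML file of scalar keys.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(sim_config, vals)
}

#' Pool-aware variant detection rule
#'
#' A variant is reported when its alternate-allele read support passes both
#' thresholds. The 1% frequency default matches the smallest frequency a
#' 100-isolate pool can represent, below which variants are invisible to the
#' pooling design.
#'
#' @param min_frequency Minimum alternate-allele frequency, in `[0, 1]`.
#' @param min_alt_reads Minimum alternate-supporting reads (suppresses
#'   singleton sequencing errors at typical 400-500x depth).
#' @return An object of class `detection_rule`.
#' @export
detection_rule <- function(min_frequency = 0.01, min_alt_reads = 2L) {
  if (min_frequency < 0 || min_frequency > 1) {
    stop("min_frequency must lie in [0, 1]")
  }
  if (min_alt_reads < 0) stop("min_alt_reads must be >= 0")
  structure(list(min_frequency = min_frequency,
                 min_alt_reads = as.integer(min_alt_reads)),
            class = "detection_rule")
}

#' k-of-n shared-mutation criterion
#'
#' A mutation detected in at least `k` of the `n` sampled chambers is
#' classified as shared, i.e. interpreted as pre-deployment standing
#' variation rather than an independent post-burial event.
#'
#' @param k Minimum number of chambers a mutation must be detected in.
#' @param n Total chambers considered.
#' @return An object of class `shared_criterion`.
#' @export
shared_criterion <- function(k, n) {
  k <- as.integer(k); n <- as.integer(n)
  if (k <= 0L) stop("k must be positive")
  if (k > n) stop("k must not exceed n (", k, " > ", n, ")")
  structure(list(k = k, n = n), class = "shared_criterion")
}
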