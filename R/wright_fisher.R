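#' Construct a lineage population
#'
#' A lineage population is the package's carrier of standing genetic
#' variation: a master mutation table, a list of per-lineage mutation index
#' sets, and a frequency vector summing to 1.
#'
#' @param mutations data.frame with columns `position` (0-based), `ref`,
#'   `alt` (single bases) and optionally `selected` (logical; default
#'   FALSE). May have zero rows.
#' @param members list of integer vectors; `members[[i]]` indexes the rows
#'   of `mutations` carried by lineage `i`.
#' @param frequencies numeric vector of lineage frequencies summing to 1.
#' @param lineage_ids optional character ids; generated when missing.
#' @return An object of class `lineage_pop`.
#' @export
lineage_pop <- function(mutations, members, frequencies, lineage_ids = NULL) {
  if (length(members) != length(frequencies)) {
    stop("members and frequencies must have the same length")
  }
  if (length(frequencies) == 0L) stop("a population needs >= 1 lineage")
  if (abs(sum(frequencies) - 1) > 1e-9) {
    stop("lineage frequencies must sum to 1 (got ", sum(frequencies), ")")
  }
  if (is.null(mutations) || nrow(mutations) == 0L) {
    mutations <- data.frame(position = integer(), ref = character(),
                            alt = character(), selected = logical(),
                            stringsAsFactors = FALSE)
  }
  if (is.null(mutations$selected)) mutations$selected <- FALSE
  if (is.null(lineage_ids)) {
    lineage_ids <- sprintf("lin_%03d", seq_along(frequencies))
  }
  structure(list(mutations = mutations, members = members,
                 frequencies = frequencies, lineage_ids = lineage_ids),
            class = "lineage_pop")
}

#' A single wild-type population (no mutations)
#' @return A `lineage_pop` with one lineage at frequency 1.
#' @export
wildtype_pop <- function() {
  lineage_pop(NULL, list(integer()), 1, "lin_wt")
}

#' @export
print.lineage_pop <- function(x, ...) {
  cat("<lineage_pop>", length(x$frequencies), "lineages,",
      nrow(x$mutations), "segregating mutations\n")
  invisible(x)
}

# per-lineage fitness (1+s)^(number of selected mutations carried);
# s may be a per-mutation vector via mutation-level selection coefficients
lineage_fitness <- function(pop, s) {
  vapply(pop$members, function(m) {
    (1 + s)^sum(pop$mutations$selected[m])
  }, numeric(1))
}

# frequency of each mutation across lineages
mutation_frequencies <- function(pop) {
  if (nrow(pop$mutations) == 0L) return(numeric())
  f <- numeric(nrow(pop$mutations))
  for (i in seq_along(pop$members)) {
    m <- pop$members[[i]]
    if (length(m)) f[m] <- f[m] + pop$frequencies[i]
  }
  f
}

#' Evolve a lineage population by Wright-Fisher resampling
#'
#' Forward simulation of one growth phase. Each realized generation
#' multinomially resamples `N` individuals with selection weighting
#' `(1+s)^k` for lineages carrying `k` mutations in selected genes, then
#' adds `Poisson(mu * N)` new mutations, each founding a new lineage at
#' frequency `1/N` on a parent drawn by frequency. The burial phase models
#' dormancy by realizing only `ceil((1 - dormancy_fraction) *
#' generations_burial)` generations -- spore-dominated populations sit out
#' most of calendar time.
#'
#' @param genome A `reference_genome` (mutation positions and reference
#'   bases are drawn from it).
#' @param genes Gene model data.frame from [simulate_ancestor()]; used to
#'   flag new mutations in `selected` genes.
#' @param phase `"pre"` or `"burial"`.
#' @param config A [sim_config()].
#' @param initial A `lineage_pop` to start from.
#' @param generations Override the phase's generation count (before
#'   dormancy thinning); defaults to the config value for the phase.
#' @param extra_fitness Optional function `(pop) -> numeric` returning a
#'   per-lineage fitness multiplier applied each generation (used to give
#'   site-covariate-dependent selection to particular lineages).
#' @return The evolved `lineage_pop` (frequencies sum to 1).
#' @export
evolve_population <- function(genome, genes, phase = c("pre", "burial"),
                              config, initial,
                              generations = NULL, extra_fitness = NULL) {
  phase <- match.arg(phase)
  validate_sim_config(config)
  stopifnot(inherits(initial, "lineage_pop"))
  g <- generations %||%
    if (phase == "pre") config$generations_pre else config$generations_burial
  if (phase == "burial") {
    g <- ceiling((1 - config$dormancy_fraction) * g)
  }
  if (g <= 0L) return(initial)

  N <- config$population_size
  mu <- config$mutation_rate
  s <- config$selection_coefficient
  genome_codes <- encode_bases(genome$sequence)
  L <- length(genome_codes)
  sel_mask <- rep(FALSE, L)
  if (!is.null(genes) && nrow(genes)) {
    for (i in which(genes$selection_class == "selected")) {
      sel_mask[(genes$start[i] + 1L):genes$end[i]] <- TRUE
    }
  }

  pop <- initial
  next_id <- length(pop$frequencies) + 1L
  for (gen in seq_len(g)) {
    w <- lineage_fitness(pop, s)
    if (!is.null(extra_fitness)) w <- w * extra_fitness(pop)
    p <- pop$frequencies * w
    counts <- as.vector(rmultinom(1L, N, p))
    keep <- counts > 0L
    pop$members <- pop$members[keep]
    pop$lineage_ids <- pop$lineage_ids[keep]
    counts <- counts[keep]

    n_new <- rpois(1L, mu * N)
    if (n_new > 0L) {
      parents <- sample.int(length(counts), n_new, replace = TRUE,
                            prob = counts)
      pos <- sample.int(L, n_new, replace = TRUE) - 1L   # 0-based
      ref <- BASES[genome_codes[pos + 1L]]
      alt <- BASES[((genome_codes[pos + 1L] - 1L +
                       sample.int(3L, n_new, replace = TRUE)) %% 4L) + 1L]
      new_rows <- data.frame(position = pos, ref = ref, alt = alt,
                             selected = sel_mask[pos + 1L],
                             stringsAsFactors = FALSE)
      # keep any extra bookkeeping columns of the master table aligned
      for (cl in setdiff(names(pop$mutations), names(new_rows))) {
        new_rows[[cl]] <- if (is.logical(pop$mutations[[cl]])) FALSE else NA
      }
      new_rows <- new_rows[, names(pop$mutations), drop = FALSE]
      base_idx <- nrow(pop$mutations)
      pop$mutations <- rbind(pop$mutations, new_rows)
      for (k in seq_len(n_new)) {
        par <- parents[k]
        if (counts[par] == 0L) next  # parent exhausted by earlier mutant
        counts[par] <- counts[par] - 1L
        counts <- c(counts, 1L)
        pop$members <- c(pop$members,
                         list(c(pop$members[[par]], base_idx + k)))
        pop$lineage_ids <- c(pop$lineage_ids, sprintf("lin_%05d", next_id))
        next_id <- next_id + 1L
      }
      keep <- counts > 0L
      pop$members <- pop$members[keep]
      pop$lineage_ids <- pop$lineage_ids[keep]
      counts <- counts[keep]
    }
    pop$frequencies <- counts / sum(counts)
  }
  # drop mutations no longer carried by any surviving lineage
  carried <- sort(unique(unlist(pop$members)))
  if (length(carried) < nrow(pop$mutations)) {
    remap <- integer(nrow(pop$mutations))
    remap[carried] <- seq_along(carried)
    pop$mutations <- pop$mutations[carried, , drop = FALSE]
    rownames(pop$mutations) <- NULL
    pop$members <- lapply(pop$members, function(m) remap[m])
  }
  pop
}

#' Sample a pool of isolates from a lineage population
#'
#' Emulates recapturing `pool_size` distinct isolates from one chamber: a
#' multinomial draw over lineage frequencies. Pool-level frequency of any
#' carried mutation is then a multiple of `1/pool_size` -- the origin of
#' the design's 1% detection floor at the default pool size of 100.
#'
#' @param pop A `lineage_pop`.
#' @param pool_size Number of isolates to draw.
#' @param seed Optional seed for a deterministic draw.
#' @return An object of class `isolate_pool`: list with `counts` (named by
#'   lineage id, summing to `pool_size`), `pool_size`, `pop` (the source
#'   population, for mutation lookup) and `mutation_frequencies` (pool-level
#'   frequency per row of `pop$mutations`).
#' @export
sample_isolate_pool <- function(pop, pool_size = 100L, seed = NULL) {
  stopifnot(inherits(pop, "lineage_pop"))
  if (length(pop$frequencies) == 0L) stop("empty lineage list")
  if (pool_size < 1L) stop("pool_size must be >= 1")
  draw <- function() as.vector(rmultinom(1L, pool_size, pop$frequencies))
  counts <- if (is.null(seed)) draw() else with_seed(seed, draw())
  names(counts) <- pop$lineage_ids
  mf <- numeric(nrow(pop$mutations))
  for (i in seq_along(pop$members)) {
    m <- pop$members[[i]]
    if (length(m) && counts[i] > 0L) mf[m] <- mf[m] + counts[i]
  }
  structure(list(counts = counts, pool_size = as.integer(pool_size),
                 pop = pop, mutation_frequencies = mf / pool_size),
            class = "isolate_pool")
}

rexp_norm <- function(n) {
  w <- stats::rexp(n)
  w / sum(w)
}

#' Plant a set of pre-deployment mutations on a wild-type population
#'
#' Builds the carrier-soil population state at burial time: `n` mutations
#' at mid frequencies (default Unif(0.25, 0.50)), grouped onto a small
#' number of co-mutated lineages so that mutations sharing a lineage are
#' physically linked on reads. Positions are drawn inside the supplied
#' genes (selected genes model the lab-incubation sweep).
#'
#' @param genome,genes Ancestor from [simulate_ancestor()].
#' @param n Number of mutations to plant.
#' @param freq_range Frequency band for the planted lineages.
#' @param n_lineages Number of mutant lineages to distribute mutations
#'   over (each lineage's mutations are fully linked).
#' @param target_genes Optional character vector of gene ids to restrict
#'   mutation placement to; default: the selected genes, else all genes.
#' @return A `lineage_pop` whose mutation table carries a logical column
#'   `planted` = TRUE.
#' @export
plant_shared_mutations <- function(genome, genes, n = 12L,
                                   freq_range = c(0.25, 0.50),
                                   n_lineages = 3L,
                                   target_genes = NULL) {
  genome_codes <- encode_bases(genome$sequence)
  if (is.null(target_genes)) {
    target_genes <- genes$gene_id[genes$selection_class == "selected"]
    if (!length(target_genes)) target_genes <- genes$gene_id
  }
  gsub <- genes[genes$gene_id %in% target_genes, , drop = FALSE]
  if (!nrow(gsub)) stop("no target genes available for planting")
  n_lineages <- min(n_lineages, n)
  # each lineage owns one target gene; its mutations cluster there, so a
  # lineage's mutation set is both genetically and physically cohesive
  lin_gene <- rep_len(sample(nrow(gsub)), n_lineages)
  assign_lin <- sort(rep_len(seq_len(n_lineages), n))
  pos <- integer(n)
  for (gi in unique(lin_gene)) {
    g <- gsub[gi, ]
    idx <- which(assign_lin %in% which(lin_gene == gi))
    span <- g$start:(g$end - 1L)
    if (length(span) < length(idx)) stop("target gene too short for planting")
    pos[idx] <- sort(sample(span, length(idx)))  # distinct positions per gene
  }
  ref <- BASES[genome_codes[pos + 1L]]
  alt <- BASES[((genome_codes[pos + 1L] - 1L +
                   sample.int(3L, n, replace = TRUE)) %% 4L) + 1L]
  muts <- data.frame(position = pos, ref = ref, alt = alt,
                     selected = TRUE, planted = TRUE,
                     gene_id = gsub$gene_id[lin_gene[assign_lin]],
                     stringsAsFactors = FALSE)
  members <- c(lapply(seq_len(n_lineages), function(i) which(assign_lin == i)),
               list(integer()))
  # lineages are disjoint, so total mutant mass must stay below 1;
  # partition a random mass so every lineage stays inside freq_range
  lo <- freq_range[1]; hi <- freq_range[2]
  m_max <- min(0.95, n_lineages * hi)
  if (n_lineages * lo >= m_max) {
    stop("freq_range infeasible for ", n_lineages, " disjoint lineages")
  }
  excess <- runif(1, 0, m_max - n_lineages * lo)
  w <- rexp_norm(n_lineages)
  f_mut <- lo + pmin(excess * w, hi - lo)
  freqs <- c(f_mut, 1 - sum(f_mut))
  lineage_pop(muts, members, freqs,
              c(sprintf("lin_planted_%02d", seq_len(n_lineages)), "lin_wt"))
}
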