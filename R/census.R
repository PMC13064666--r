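variant_key <- function(position, ref, alt) {
  sprintf("%d:%s>%s", position, ref, alt)
}

#' Build a cross-sample mutation matrix
#'
#' Takes per-sample variant calls and assembles the central census object:
#' the union of variant keys across samples, a frequency matrix (0 where a
#' variant was not detected in a sample) and the detection indicator under
#' the shared [detection_rule()].
#'
#' @param calls_list Named list of `variant_calls` data.frames, one per
#'   sample; names must match `metas$sample_id`.
#' @param metas Sample metadata data.frame: `sample_id`, `achip_id`,
#'   `site`, `timepoint`, `species`, `pool_size`.
#' @param rule The [detection_rule()] the calls were made under.
#' @return Object of class `mutation_matrix`: list with `variants`
#'   (data.frame `key`, `position`, `ref`, `alt`, `gene_id`, `effect`),
#'   `samples` (metas), `frequency` and `detected` (variants x samples
#'   matrices), `rule`.
#' @export
build_matrix <- function(calls_list, metas, rule = detection_rule()) {
  if (anyDuplicated(metas$sample_id)) {
    stop("duplicate sample_id in metadata")
  }
  if (is.null(names(calls_list))) names(calls_list) <- metas$sample_id
  missing <- setdiff(metas$sample_id, names(calls_list))
  if (length(missing)) stop("calls missing for samples: ",
                            paste(missing, collapse = ", "))
  all_calls <- do.call(rbind, lapply(metas$sample_id, function(s) {
    cl <- calls_list[[s]]
    if (nrow(cl) == 0L) return(NULL)
    cl$sample_id <- s
    cl
  }))
  if (is.null(all_calls)) {
    variants <- data.frame(key = character(), position = integer(),
                           ref = character(), alt = character(),
                           gene_id = character(), effect = character(),
                           stringsAsFactors = FALSE)
    freq <- matrix(0, 0, nrow(metas),
                   dimnames = list(NULL, metas$sample_id))
  } else {
    all_calls$key <- variant_key(all_calls$position, all_calls$ref,
                                 all_calls$alt)
    first <- all_calls[!duplicated(all_calls$key), , drop = FALSE]
    first <- first[order(first$position, first$alt), , drop = FALSE]
    variants <- data.frame(key = first$key, position = first$position,
                           ref = first$ref, alt = first$alt,
                           gene_id = first$gene_id, effect = first$effect,
                           stringsAsFactors = FALSE)
    freq <- matrix(0, nrow(variants), nrow(metas),
                   dimnames = list(variants$key, metas$sample_id))
    freq[cbind(match(all_calls$key, variants$key),
               match(all_calls$sample_id, metas$sample_id))] <-
      all_calls$frequency
  }
  detected <- freq >= rule$min_frequency & freq > 0
  structure(list(variants = variants, samples = metas, frequency = freq,
                 detected = detected, rule = rule),
            class = "mutation_matrix")
}

#' @export
print.mutation_matrix <- function(x, ...) {
  cat("<mutation_matrix>", nrow(x$variants), "variants x",
      nrow(x$samples), "samples\n")
  invisible(x)
}

#' Classify mutations as shared vs non-shared under a k-of-n rule
#'
#' A mutation detected in at least `k` of the `n` sampled chambers is
#' "shared" -- the signature of pre-deployment standing variation, since
#' independent post-burial events are vanishingly unlikely to recur in
#' nearly every chamber. The partition is exhaustive and exclusive.
#'
#' @param matrix A `mutation_matrix`.
#' @param criterion A [shared_criterion()]; `n` must equal the number of
#'   samples in the matrix.
#' @return List of class `shared_set`: `shared`, `non_shared` (character
#'   keys), `n_detected` (named detection counts), `criterion`.
#' @export
classify_shared <- function(matrix, criterion) {
  stopifnot(inherits(matrix, "mutation_matrix"),
            inherits(criterion, "shared_criterion"))
  if (criterion$n != ncol(matrix$detected)) {
    stop("criterion n (", criterion$n, ") must equal the number of samples (",
         ncol(matrix$detected), ")")
  }
  n_det <- rowSums(matrix$detected)
  shared <- matrix$variants$key[n_det >= criterion$k]
  structure(list(shared = shared,
                 non_shared = setdiff(matrix$variants$key, shared),
                 n_detected = setNames(n_det, matrix$variants$key),
                 criterion = criterion),
            class = "shared_set")
}

#' @export
print.shared_set <- function(x, ...) {
  cat("<shared_set>", length(x$shared), "shared /", length(x$non_shared),
      "non-shared (k =", x$criterion$k, "of n =", x$criterion$n, ")\n")
  invisible(x)
}

#' Venn partition of site-level mutation presence
#'
#' For one timepoint, a mutation is marked present at a site if detected
#' in at least one of that site's chambers -- a mutation appearing in
#' several chambers of a site counts once. Returns the count of distinct
#' mutations in each non-empty site subset (the regions of a Venn
#' diagram); region counts sum to the number of distinct site-present
#' mutations.
#'
#' @param matrix A `mutation_matrix`.
#' @param timepoint Timepoint (months) to restrict to; `NULL` uses all
#'   samples.
#' @param effect Restrict to one effect class (default
#'   `"non-synonymous"`); `NULL` keeps all.
#' @return data.frame with columns `subset` (site names joined by `&`),
#'   `n_sites`, `count`.
#' @export
venn_partition <- function(matrix, timepoint = NULL,
                           effect = "non-synonymous") {
  sam <- matrix$samples
  keep_s <- if (is.null(timepoint)) seq_len(nrow(sam)) else
    which(sam$timepoint == timepoint)
  if (!length(keep_s)) stop("no samples at timepoint ", timepoint)
  keep_v <- if (is.null(effect)) seq_len(nrow(matrix$variants)) else
    which(matrix$variants$effect == effect)
  det <- matrix$detected[keep_v, keep_s, drop = FALSE]
  sites <- sort(unique(sam$site[keep_s]))
  # per-site presence: detected in >= 1 chamber of that site
  pres <- vapply(sites, function(s) {
    cols <- which(sam$site[keep_s] == s)
    rowSums(det[, cols, drop = FALSE]) > 0
  }, logical(nrow(det)))
  pres <- matrix(pres, ncol = length(sites),
                 dimnames = list(NULL, sites))
  sig <- apply(pres, 1L, function(r) paste(sites[r], collapse = "&"))
  sig <- sig[sig != ""]
  m <- length(sites)
  subsets <- unlist(lapply(seq_len(m), function(k) {
    apply(combn(sites, k), 2L, paste, collapse = "&")
  }))
  counts <- as.integer(table(factor(sig, levels = subsets)))
  data.frame(subset = subsets,
             n_sites = lengths(strsplit(subsets, "&", fixed = TRUE)),
             count = counts,
             stringsAsFactors = FALSE)
}

#' Site-unique mutated genes (within-site parallelism)
#'
#' Lists, per site, the genes carrying a detected non-synonymous mutation
#' in more than `majority_fraction` of that site's chambers while never
#' being mutated in any chamber at any other site. Such genes are the
#' signature of evolutionary pressures unique to one site.
#'
#' @param matrix A `mutation_matrix`.
#' @param majority_fraction Fraction of a site's chambers that must carry
#'   a mutation in the gene (strictly greater than; default 0.5 = "most").
#' @param timepoint Optional timepoint restriction.
#' @return Named list (by site) of character vectors of gene ids.
#' @export
site_unique_genes <- function(matrix, majority_fraction = 0.5,
                              timepoint = NULL) {
  sam <- matrix$samples
  keep_s <- if (is.null(timepoint)) seq_len(nrow(sam)) else
    which(sam$timepoint == timepoint)
  sites <- sort(unique(sam$site[keep_s]))
  if (length(sites) < 2L) stop("site_unique_genes needs >= 2 sites")
  vars <- matrix$variants
  keep_v <- which(vars$effect == "non-synonymous" & !is.na(vars$gene_id))
  det <- matrix$detected[keep_v, keep_s, drop = FALSE]
  gene_of <- vars$gene_id[keep_v]
  genes <- unique(gene_of)
  # per gene x sample: any detected non-synonymous variant
  gene_hit <- t(vapply(genes, function(g) {
    colSums(det[gene_of == g, , drop = FALSE]) > 0
  }, logical(ncol(det))))
  out <- lapply(sites, function(s) {
    here <- sam$site[keep_s] == s
    n_here <- sum(here)
    frac <- rowSums(gene_hit[, here, drop = FALSE]) / n_here
    elsewhere <- rowSums(gene_hit[, !here, drop = FALSE])
    genes[frac > majority_fraction & elsewhere == 0]
  })
  names(out) <- sites
  out
}

#' Per-gene, per-chamber mutation counts
#'
#' Tallies detected non-synonymous and synonymous mutations per gene in
#' each sample -- the input to [ns_ratio()].
#'
#' @param matrix A `mutation_matrix`.
#' @return data.frame: `sample_id`, `gene_id`, `n_nonsyn`, `n_syn`.
#' @export
gene_mutation_counts <- function(matrix) {
  vars <- matrix$variants
  keep <- which(!is.na(vars$gene_id) &
                  vars$effect %in% c("non-synonymous", "synonymous"))
  out <- expand.grid(sample_id = matrix$samples$sample_id,
                     gene_id = unique(vars$gene_id[keep]),
                     stringsAsFactors = FALSE)
  if (!nrow(out)) {
    return(data.frame(sample_id = character(), gene_id = character(),
                      n_nonsyn = integer(), n_syn = integer()))
  }
  for (cls in c("non-synonymous", "synonymous")) {
    col <- if (cls == "non-synonymous") "n_nonsyn" else "n_syn"
    out[[col]] <- mapply(function(s, g) {
      rows <- keep[vars$gene_id[keep] == g & vars$effect[keep] == cls]
      sum(matrix$detected[rows, s])
    }, out$sample_id, out$gene_id)
  }
  out
}

#' Per-gene N:S mutation summary
#'
#' For each gene, averages the non-synonymous and synonymous detected
#' mutation counts over the chambers that possessed at least one mutation
#' (of either class) in that gene, and reports their ratio N:S =
#' mean_nonsyn / mean_syn. An N:S well below the ~3:1 expected of newly
#' arisen mutations is a heuristic flag that variants may predate the
#' experiment (or arrived by horizontal transfer). The ratio is rounded
#' half-up to 2 decimals for report parity, and is NA when the synonymous
#' mean is zero. Genes with no qualifying chamber are omitted.
#'
#' @param counts data.frame from [gene_mutation_counts()] (or equivalent):
#'   columns `sample_id`, `gene_id`, `n_nonsyn`, `n_syn`.
#' @return data.frame of class `gene_mutation_summary`: `gene_id`,
#'   `mean_nonsyn`, `se_nonsyn`, `mean_syn`, `se_syn`, `ns_ratio`,
#'   `n_achips`.
#' @export
ns_ratio <- function(counts) {
  stopifnot(all(c("sample_id", "gene_id", "n_nonsyn", "n_syn") %in%
                  names(counts)))
  res <- lapply(split(counts, counts$gene_id), function(d) {
    qual <- d[d$n_nonsyn + d$n_syn > 0, , drop = FALSE]
    m <- nrow(qual)
    if (m == 0L) return(NULL)
    se <- function(x) if (m > 1L) sd(x) / sqrt(m) else 0
    mean_n <- mean(qual$n_nonsyn)
    mean_s <- mean(qual$n_syn)
    data.frame(gene_id = d$gene_id[1L],
               mean_nonsyn = mean_n, se_nonsyn = se(qual$n_nonsyn),
               mean_syn = mean_s, se_syn = se(qual$n_syn),
               ns_ratio = if (mean_s == 0) NA_real_ else
                 round_half_up(mean_n / mean_s, 2),
               n_achips = m,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), mean_nonsyn = numeric(),
                      se_nonsyn = numeric(), mean_syn = numeric(),
                      se_syn = numeric(), ns_ratio = numeric(),
                      n_achips = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("gene_mutation_summary", "data.frame")
  out
}

#' Per-chamber counts of shared and non-shared non-synonymous mutations
#'
#' Partitions each sample's detected non-synonymous mutations by the
#' shared classification, and summarizes mean +/- SE per site x timepoint.
#'
#' @param matrix A `mutation_matrix`.
#' @param shared A `shared_set` from [classify_shared()] on the same
#'   matrix.
#' @return List with `per_sample` (data.frame `sample_id`, `site`,
#'   `timepoint`, `n_shared`, `n_non_shared`) and `summary` (site x
#'   timepoint means and SEs).
#' @export
per_achip_counts <- function(matrix, shared) {
  stopifnot(inherits(shared, "shared_set"))
  vars <- matrix$variants
  ns <- vars$effect == "non-synonymous"
  is_shared <- vars$key %in% shared$shared
  det <- matrix$detected
  per_sample <- data.frame(
    sample_id = matrix$samples$sample_id,
    site = matrix$samples$site,
    timepoint = matrix$samples$timepoint,
    n_shared = as.integer(colSums(det[ns & is_shared, , drop = FALSE])),
    n_non_shared = as.integer(colSums(det[ns & !is_shared, , drop = FALSE])),
    stringsAsFactors = FALSE
  )
  rownames(per_sample) <- NULL
  grp <- interaction(per_sample$site, per_sample$timepoint, drop = TRUE)
  summ <- do.call(rbind, lapply(split(per_sample, grp), function(d) {
    m <- nrow(d)
    se <- function(x) if (m > 1L) sd(x) / sqrt(m) else 0
    data.frame(site = d$site[1L], timepoint = d$timepoint[1L], n = m,
               mean_shared = mean(d$n_shared), se_shared = se(d$n_shared),
               mean_non_shared = mean(d$n_non_shared),
               se_non_shared = se(d$n_non_shared),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(per_sample = per_sample, summary = summ)
}
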