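#' Per-sample focal-species read fraction
#'
#' Percentage of each sample's reads classified as the focal (inoculated)
#' species -- the measure of how strongly contaminant taxa dilute the
#' focal signal in whole-soil shotgun data.
#'
#' @param table A `community_table`.
#' @return data.frame: `sample_id`, `focal_reads`, `total_reads`,
#'   `focal_pct` (NA with a `flagged` TRUE for zero-total samples).
#' @export
focal_fraction <- function(table) {
  stopifnot(inherits(table, "community_table"))
  tot <- colSums(table$counts)
  foc <- table$counts[table$focal_taxon, ]
  out <- data.frame(sample_id = colnames(table$counts),
                    focal_reads = as.integer(foc),
                    total_reads = as.integer(tot),
                    focal_pct = ifelse(tot > 0, 100 * foc / tot, NA_real_),
                    flagged = tot == 0,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Shannon alpha diversity of the non-focal community
#'
#' `H = -sum p_i ln p_i` over taxon proportions (natural log), by default
#' excluding the focal species so the index reflects the contaminant
#' community only. Zero-count taxa contribute nothing.
#'
#' @param table A `community_table`, or a numeric count vector.
#' @param exclude_focal Drop the focal taxon before computing (ignored
#'   for plain vectors).
#' @return Named numeric vector of H per sample.
#' @export
shannon_diversity <- function(table, exclude_focal = TRUE) {
  counts <- community_counts(table, exclude_focal)
  if (any(colSums(counts) == 0)) {
    stop("all-zero count vector: Shannon diversity undefined")
  }
  vegan::diversity(t(counts), index = "shannon")
}

#' Bray-Curtis dissimilarity between samples
#'
#' `BC(a, b) = sum|a_i - b_i| / sum(a_i + b_i)` on counts, by default over
#' non-focal taxa only. Pairs of all-zero samples are undefined (NA, with
#' a warning).
#'
#' @param table A `community_table` or a taxa x samples count matrix.
#' @param exclude_focal Drop the focal taxon first.
#' @return A symmetric matrix of class `dist_matrix` with zero diagonal.
#' @export
bray_curtis <- function(table, exclude_focal = TRUE) {
  counts <- community_counts(table, exclude_focal)
  if (ncol(counts) < 2L) stop("bray_curtis needs >= 2 samples")
  zero <- colSums(counts) == 0
  d <- as.matrix(vegan::vegdist(t(counts), method = "bray"))
  if (any(zero)) {
    warning("all-zero samples give undefined Bray-Curtis pairs: ",
            paste(colnames(counts)[zero], collapse = ", "))
    d[zero, zero] <- NA_real_
    diag(d) <- 0
  }
  class(d) <- c("dist_matrix", "matrix", "array")
  d
}

community_counts <- function(table, exclude_focal) {
  if (inherits(table, "community_table")) {
    counts <- table$counts
    if (exclude_focal) {
      counts <- counts[setdiff(rownames(counts), table$focal_taxon), ,
                       drop = FALSE]
    }
    counts
  } else if (is.matrix(table)) {
    table
  } else {
    matrix(table, ncol = 1L, dimnames = list(names(table), "sample1"))
  }
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers `-D^2/2`, eigendecomposes, and returns the top axes by
#' eigenvalue. Negative eigenvalues (non-Euclidean dissimilarities such as
#' Bray-Curtis) are reported but excluded from the variance-explained
#' denominator. Requesting more axes than there are positive eigenvalues
#' truncates with a warning.
#'
#' @param distances A `dist_matrix`, `dist`, or symmetric matrix.
#' @param n_axes Number of ordination axes to keep (default 2).
#' @return List of class `pcoa_result`: `coordinates` (samples x axes),
#'   `eigenvalues` (all), `variance_explained` (per kept axis, as a
#'   fraction of the positive-eigenvalue total).
#' @export
pcoa_ordination <- function(distances, n_axes = 2L) {
  d <- as.dist(distances)
  n <- attr(d, "Size")
  fit <- suppressWarnings(cmdscale(d, k = n - 1L, eig = TRUE))
  eig <- fit$eig
  n_pos <- sum(eig > 1e-12)
  if (n_axes > n_pos) {
    warning("only ", n_pos, " positive eigenvalues; returning ", n_pos,
            " axes")
    n_axes <- n_pos
  }
  coords <- fit$points[, seq_len(n_axes), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(n_axes))
  structure(list(coordinates = coords,
                 eigenvalues = eig,
                 variance_explained = eig[seq_len(n_axes)] /
                   sum(eig[eig > 0])),
            class = "pcoa_result")
}

#' Source attribution of non-focal taxa
#'
#' Classifies every non-focal taxon detected in a site's chambers into
#' exactly one category: `pre_deployment` if also detected in the
#' pre-deployment carrier soil, else `other_site` if detected in at least
#' one other site's chambers, else `site_exclusive`. Read percentages per
#' site are tallied over these categories (read-weighted across the
#' site's chamber set) and sum to 100.
#'
#' @param table A `community_table` whose samples carry `site` metadata.
#' @param pre_sample_ids Sample ids of the pre-deployment carrier-soil
#'   samples (default: samples with site `"PRE"` or timepoint 0).
#' @param min_count Reads required to count a taxon as detected
#'   (default 1).
#' @return List of class `source_attribution`: `taxon_category`
#'   (data.frame `taxon`, `site`, `category`) and `site_percentages`
#'   (data.frame `site`, `pre_deployment`, `other_site`,
#'   `site_exclusive`).
#' @export
attribute_sources <- function(table, pre_sample_ids = NULL,
                              min_count = 1L) {
  stopifnot(inherits(table, "community_table"))
  sam <- table$samples
  if (is.null(pre_sample_ids)) {
    pre_sample_ids <- sam$sample_id[sam$site == "PRE" | sam$timepoint == 0]
  }
  if (!length(pre_sample_ids)) stop("no pre-deployment samples identified")
  counts <- table$counts[setdiff(rownames(table$counts), table$focal_taxon),
                         , drop = FALSE]
  pre_cols <- colnames(counts) %in% pre_sample_ids
  field <- sam[!sam$sample_id %in% pre_sample_ids, , drop = FALSE]
  sites <- sort(unique(field$site))
  in_pre <- rowSums(counts[, pre_cols, drop = FALSE] >= min_count) > 0
  det_site <- vapply(sites, function(s) {
    cols <- field$sample_id[field$site == s]
    rowSums(counts[, cols, drop = FALSE] >= min_count) > 0
  }, logical(nrow(counts)))
  det_site <- matrix(det_site, ncol = length(sites),
                     dimnames = list(rownames(counts), sites))

  cats <- c("pre_deployment", "other_site", "site_exclusive")
  tc <- list(); sp <- list()
  for (s in sites) {
    present <- which(det_site[, s])
    other <- rowSums(det_site[, setdiff(sites, s), drop = FALSE]) > 0
    category <- ifelse(in_pre[present], "pre_deployment",
                       ifelse(other[present], "other_site",
                              "site_exclusive"))
    tc[[s]] <- data.frame(taxon = rownames(counts)[present], site = s,
                          category = category, stringsAsFactors = FALSE)
    cols <- field$sample_id[field$site == s]
    reads <- rowSums(counts[present, cols, drop = FALSE])
    tot <- sum(reads)
    pct <- vapply(cats, function(cc) {
      if (tot == 0) return(NA_real_)
      100 * sum(reads[category == cc]) / tot
    }, numeric(1))
    sp[[s]] <- data.frame(site = s, pre_deployment = pct[1L],
                          other_site = pct[2L], site_exclusive = pct[3L],
                          stringsAsFactors = FALSE)
  }
  structure(list(taxon_category = do.call(rbind, tc),
                 site_percentages = do.call(rbind, sp)),
            class = "source_attribution")
}
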