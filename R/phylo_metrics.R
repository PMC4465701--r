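#' Node-count phylogenetic distance matrix
#'
#' Distance between two tips is the number of edges on the path connecting
#' them — the patristic distance after setting every branch length to 1. This
#' is the appropriate metric when a topology is assembled from literature and
#' branch lengths are unavailable.
#'
#' @param phylogeny A rooted `"phylo"` tree.
#' @return Square symmetric numeric matrix (units: edges), zero diagonal,
#'   species in `tip.label` order.
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' node_count_distances(tr)  # d(A,B)=2, d(A,C)=4
#' @export
node_count_distances <- function(phylogeny) {
  phylogeny <- validate_phylogeny(phylogeny)
  phylogeny$edge.length <- rep(1, nrow(phylogeny$edge))
  D <- ape::cophenetic.phylo(phylogeny)
  D[phylogeny$tip.label, phylogeny$tip.label, drop = FALSE]
}

#' Mean pairwise distance of a species set
#'
#' Arithmetic mean of the phylogenetic distance over all unordered pairs of
#' species present in a community.
#'
#' @param species Character vector (>= 2 species) present at the site.
#' @param D Distance matrix containing all of them.
#' @return Mean pairwise distance, or `NA` for a singleton community.
#' @export
mpd_community <- function(species, D) {
  species <- unique(species)
  if (length(species) < 2) return(NA_real_)
  sub <- D[species, species]
  sum(sub) / (length(species) * (length(species) - 1))
}

#' Mean nearest-taxon distance of a species set
#'
#' Mean, over community members, of each member's distance to its closest
#' relative within the community.
#'
#' @inheritParams mpd_community
#' @return Mean nearest-taxon distance, or `NA` for a singleton.
#' @export
mntd_community <- function(species, D) {
  species <- unique(species)
  if (length(species) < 2) return(NA_real_)
  sub <- D[species, species]
  diag(sub) <- Inf
  mean(apply(sub, 1, min))
}

metric_fun <- function(metric) {
  switch(match.arg(metric, c("mpd", "mntd")),
         mpd = mpd_community, mntd = mntd_community)
}

# integer-index fast paths for the randomization loops
mpd_idx <- function(D, idx) {
  s <- length(idx)
  sum(D[idx, idx]) / (s * (s - 1))
}
mntd_idx <- function(D, idx) {
  sub <- D[idx, idx]
  diag(sub) <- Inf
  mean(apply(sub, 1, min))
}
metric_fun_idx <- function(metric) {
  switch(match.arg(metric, c("mpd", "mntd")), mpd = mpd_idx, mntd = mntd_idx)
}

#' Null distribution of a structure metric under random pool assembly
#'
#' Draws communities of fixed richness uniformly at random from the regional
#' pool and evaluates the metric on each. For presence-only data this is
#' equivalent to shuffling the tip labels of the pool subtree while holding
#' richness constant. With `exhaustive = TRUE` all richness-sized subsets are
#' enumerated instead (feasible for small pools; used as an exact reference).
#'
#' @param metric `"mpd"` or `"mntd"`.
#' @param richness Community size to draw.
#' @param pool_D Distance matrix over the pool species.
#' @param n_rand Number of random draws.
#' @param exhaustive Enumerate all subsets instead of sampling.
#' @return Numeric vector of metric values.
#' @export
null_metric_distribution <- function(metric, richness, pool_D, n_rand = 999,
                                     exhaustive = FALSE) {
  pool <- rownames(pool_D)
  if (richness > length(pool)) stop("richness exceeds pool size")
  f <- metric_fun(metric)
  if (exhaustive) {
    subsets <- utils::combn(pool, richness, simplify = FALSE)
    return(vapply(subsets, f, numeric(1), D = pool_D))
  }
  n <- length(pool)
  fi <- metric_fun_idx(metric)
  vapply(seq_len(n_rand), function(i) fi(pool_D, sample.int(n, richness)),
         numeric(1))
}

#' NRI / NTI for one community against its regional pool
#'
#' Standardized effect size of MPD (net relatedness index, NRI) or MNTD
#' (nearest taxon index, NTI), sign-flipped so that positive values indicate
#' phylogenetic clustering and negative values overdispersion:
#' `index = -(obs - mean_null) / sd_null`. The null holds richness constant
#' and draws species uniformly from the site's regional pool (tip-label
#' randomization on the pool subtree). Two-sided significance is flagged at
#' `|index| > z_threshold` as well as reported as a randomization rank p.
#'
#' @param species Species present at the site.
#' @param pool_D Node-count distance matrix over the site's regional pool.
#' @param metric `"mpd"` (NRI) or `"mntd"` (NTI).
#' @param n_rand Randomizations (ignored when `exhaustive`).
#' @param exhaustive Use the exhaustive subset enumeration (population-sd
#'   convention) instead of Monte Carlo sampling (sample-sd convention).
#' @param z_threshold Two-sided significance threshold (default 1.96).
#' @return One-row data frame: richness, observed metric, null mean/sd,
#'   index (z), rank p, significance flag, pool size, the sd convention used.
#' @export
structure_index <- function(species, pool_D, metric = c("mpd", "mntd"),
                            n_rand = 999, exhaustive = FALSE,
                            z_threshold = 1.96) {
  metric <- match.arg(metric)
  species <- unique(normalize_species(species))
  if (!all(species %in% rownames(pool_D)))
    stop("community species missing from pool: ",
         paste(setdiff(species, rownames(pool_D)), collapse = ", "))
  obs <- metric_fun(metric)(species, pool_D)
  S <- length(species)
  nulls <- null_metric_distribution(metric, S, pool_D, n_rand = n_rand,
                                    exhaustive = exhaustive)
  mu <- mean(nulls)
  # exhaustive enumeration is the full null population -> population sd;
  # Monte Carlo draws use the sample (n-1) form
  sdv <- if (exhaustive) sqrt(mean((nulls - mu)^2)) else stats::sd(nulls)
  z <- if (is.na(sdv) || sdv == 0) NA_real_ else -(obs - mu) / sdv
  p_rank <- (sum(nulls <= obs) + 1) / (length(nulls) + 1)  # rank of observed (low tail)
  data.frame(richness = S, obs = obs, null_mean = mu, null_sd = sdv,
             index = z, p_rank = p_rank,
             significant = !is.na(z) && abs(z) > z_threshold,
             pool_size = nrow(pool_D),
             sd_convention = if (exhaustive) "population" else "sample",
             stringsAsFactors = FALSE)
}

#' NRI and NTI across all sites of a metacommunity
#'
#' Computes, per site, the net relatedness and nearest taxon indices against
#' that site's regional pool (the whole species set of the metacommunity when
#' no pools are supplied), with tip-label randomization nulls.
#'
#' @param mc A [metacommunity()].
#' @param phylogeny Rooted tree containing all pool species.
#' @param config An [analysis_config()]; its seed and randomization count are
#'   used and recorded.
#' @return Data frame, one row per site: richness, MPD/MNTD observed, null
#'   moments, NRI, NTI, significance flags, pool sizes.
#' @export
community_structure <- function(mc, phylogeny, config = analysis_config()) {
  D_all <- node_count_distances(phylogeny)
  set.seed(config$seed)
  rows <- lapply(rownames(mc$presence), function(s) {
    sp <- colnames(mc$presence)[mc$presence[s, ] == 1]
    pool <- if (is.null(mc$pools)) rownames(D_all) else mc$pools[[s]]
    pool_D <- D_all[pool, pool]
    r_mpd <- structure_index(sp, pool_D, "mpd",
                             n_rand = config$n_randomizations_structure,
                             z_threshold = config$z_threshold)
    r_mntd <- structure_index(sp, pool_D, "mntd",
                              n_rand = config$n_randomizations_structure,
                              z_threshold = config$z_threshold)
    data.frame(site = s, richness = r_mpd$richness,
               mpd_obs = r_mpd$obs, mpd_null_mean = r_mpd$null_mean,
               mpd_null_sd = r_mpd$null_sd, NRI = r_mpd$index,
               NRI_significant = r_mpd$significant,
               mntd_obs = r_mntd$obs, mntd_null_mean = r_mntd$null_mean,
               mntd_null_sd = r_mntd$null_sd, NTI = r_mntd$index,
               NTI_significant = r_mntd$significant,
               pool_size = r_mpd$pool_size, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "seed") <- config$seed
  attr(out, "n_randomizations") <- config$n_randomizations_structure
  out
}
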