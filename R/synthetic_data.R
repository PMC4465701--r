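#' Parameters for the synthetic metacommunity generator
#'
#' The generator emulates the structure of a latitudinal survey of snake
#' communities in forest and open (non-forest) habitat: a clade-structured
#' species pool whose major lineages have latitudinally shifted ranges,
#' presence/absence communities assembled with a tunable habitat filter
#' acting on phylogenetically conserved traits, and Brownian-motion
#' morphometric traits with an additive habitat effect.
#'
#' @param n_species Pool size (tree tips).
#' @param n_sites Number of sites.
#' @param habitat Habitat class per site (`"forest"`/`"non_forest"`).
#' @param latitude Site latitudes (absolute decimal degrees south).
#' @param sigma2 Brownian rate per unit-length edge for every trait.
#' @param beta Additive habitat effect: species with non-forest affinity are
#'   shifted by +beta/2 and forest-affine species by -beta/2 on the latent
#'   scale of the filtered traits (TL shifted with opposite sign: forest
#'   species have longer tails).
#' @param phi Habitat filter strength (>= 0): a species whose affinity
#'   mismatches the site's habitat enters with probability weight
#'   `exp(-phi)`; `phi = 0` gives uniform (neutral) sampling from the pool.
#' @param gamma Clade-range turnover (>= 0): major-clade latitudinal range
#'   centres are displaced from the metacommunity midpoint by `gamma` times
#'   half the latitudinal span; `gamma = 0` gives every species a range
#'   covering all sites.
#' @param n_clades Number of major clades whose ranges shift.
#' @param richness_range Target community richness bounds (capped at pool
#'   size, never below 2).
#' @param range_halfwidth Latitudinal half-width of species ranges, degrees;
#'   default 0.8 x the latitudinal span.
#' @param seed RNG seed.
#' @return List of class `"simulation_params"`.
#' @export
simulation_params <- function(n_species = 182, n_sites = 12,
                              habitat = rep(c("forest", "non_forest"),
                                            length.out = n_sites),
                              latitude = seq(3.1, 29.7, length.out = n_sites),
                              sigma2 = 1, beta = 0, phi = 0, gamma = 0,
                              n_clades = 3, richness_range = c(9, 61),
                              range_halfwidth = NULL, seed = 1L) {
  stopifnot(n_species >= 2, n_sites >= 2, length(habitat) == n_sites,
            length(latitude) == n_sites, sigma2 >= 0, phi >= 0, gamma >= 0,
            richness_range[1] >= 2, richness_range[2] >= richness_range[1])
  if (is.null(range_halfwidth))
    range_halfwidth <- 0.8 * diff(range(latitude))
  structure(list(n_species = as.integer(n_species),
                 n_sites = as.integer(n_sites), habitat = habitat,
                 latitude = latitude, sigma2 = sigma2, beta = beta,
                 phi = phi, gamma = gamma, n_clades = as.integer(n_clades),
                 richness_range = as.integer(richness_range),
                 range_halfwidth = range_halfwidth, seed = as.integer(seed)),
            class = "simulation_params")
}

#' The "snakelike" preset
#'
#' Mirrors the shape of the study system the generator emulates: 182 species,
#' 12 sites (6 forest / 6 non-forest) spanning latitudes 3.1-29.7 degrees S,
#' target richness 9-61, 8 morphometric traits.
#'
#' @param ... Overrides passed to [simulation_params()].
#' @export
snakelike_params <- function(...) {
  over <- list(...)
  defaults <- list(n_species = 182, n_sites = 12,
                   habitat = rep(c("forest", "non_forest"), each = 6),
                   latitude = seq(3.1, 29.7, length.out = 12),
                   sigma2 = 1, beta = 1, phi = 1, gamma = 1, seed = 1L)
  # interleave habitats across the latitude gradient so habitat and latitude
  # are not confounded
  defaults$habitat <- rep(c("forest", "non_forest"), length.out = 12)
  do.call(simulation_params, utils::modifyList(defaults, over))
}

#' Simulate a pure-birth (Yule) phylogeny
#'
#' @param n Number of tips.
#' @param seed RNG seed.
#' @return Rooted bifurcating `"phylo"` tree with tips `sp001`, `sp002`, ...
#'   Branch lengths are present but ignored downstream (node counting).
#' @export
simulate_phylogeny <- function(n, seed = 1L) {
  stopifnot(n >= 2)
  set.seed(seed)
  tree <- ape::rphylo(n, birth = 1, death = 0)
  tree$tip.label <- sprintf("sp%03d", seq_len(n))
  validate_phylogeny(tree)
}

# deterministic major-clade assignment: average-linkage clustering of the
# node-count distances
assign_clades <- function(tree, k) {
  D <- node_count_distances(tree)
  cl <- stats::cutree(stats::hclust(stats::as.dist(D), method = "average"), k)
  stats::setNames(as.integer(cl), rownames(D))
}

# scales mapping latent Brownian values onto positive morphometric ranges
TRAIT_SCALES <- c(SVL = 800, TL = 200, CAM = 60, HL = 25, HW = 15, HH = 10,
                  VS = 180, SS = 60)
TRAIT_LOG_SD <- 0.25           # latent-to-log shrinkage
FILTERED_TRAITS <- c("TL", "CAM", "VS")  # traits receiving the habitat effect

#' Simulate Brownian-motion traits with an additive habitat effect
#'
#' Each of the 8 morphometric traits evolves independently by Brownian motion
#' with rate `sigma2` on the unit-edge-length topology. A phylogenetically
#' conserved habitat affinity (a thresholded Brownian liability) splits the
#' pool into forest- and non-forest-affine species; the filtered traits (TL,
#' CAM, VS) are shifted by +/- `beta`/2 on the latent scale according to
#' affinity (non-forest species stouter with more ventral scales, forest
#' species with longer tails). Latent values are exponentiated onto positive
#' morphometric scales, so `sigma2 = 0, beta = 0` makes all species
#' identical.
#'
#' @param tree A `"phylo"` tree.
#' @param sigma2 Brownian rate on unit-length edges.
#' @param beta Habitat effect size on the latent scale.
#' @param seed RNG seed.
#' @return List: `traits` (a [trait_table()]), `ground_truth` (list with
#'   `affinity`, `liability`, `latent` matrix of pre-noise latent values).
#' @export
simulate_traits <- function(tree, sigma2 = 1, beta = 0, seed = 1L) {
  tree <- validate_phylogeny(tree)
  unit <- tree
  unit$edge.length <- rep(1, nrow(unit$edge))
  set.seed(seed)
  n <- length(unit$tip.label)
  liability <- ape::rTraitCont(unit, model = "BM", sigma = 1)
  affinity <- ifelse(liability >= stats::median(liability),
                     "non_forest", "forest")
  latent <- sapply(TRAIT_NAMES, function(tr) {
    if (sigma2 == 0) stats::setNames(rep(0, n), unit$tip.label)
    else ape::rTraitCont(unit, model = "BM", sigma = sqrt(sigma2))
  })
  rownames(latent) <- unit$tip.label
  shift <- ifelse(affinity == "non_forest", beta / 2, -beta / 2)
  latent[, "CAM"] <- latent[, "CAM"] + shift
  latent[, "VS"] <- latent[, "VS"] + shift
  latent[, "TL"] <- latent[, "TL"] - shift
  values <- sweep(exp(TRAIT_LOG_SD * latent), 2, TRAIT_SCALES[TRAIT_NAMES], "*")
  list(traits = trait_table(as.data.frame(values), species = unit$tip.label),
       ground_truth = list(affinity = affinity, liability = liability,
                           latent = latent))
}

#' Assemble a habitat-filtered metacommunity over clade-structured pools
#'
#' Major clades get latitudinally displaced range centres (`gamma` controls
#' the displacement); a site's regional pool is every species whose range
#' covers the site latitude. Communities are then drawn from the pool
#' without replacement at a target richness sampled uniformly from
#' `richness_range` (capped at the pool size), with inclusion probability
#' proportional to `exp(-phi * mismatch)` where mismatch is 1 when the
#' species' habitat affinity differs from the site's habitat. `phi = 0`
#' gives uniform (neutral) draws from the pool.
#'
#' @param tree Phylogeny over the species pool.
#' @param traits Result of [simulate_traits()] (its ground-truth affinity
#'   drives the filter).
#' @param params A [simulation_params()].
#' @return List: `metacommunity` (with pools attached), `ground_truth`
#'   (affinity, range centres, per-site sampling weights).
#' @export
simulate_metacommunity <- function(tree, traits, params) {
  tree <- validate_phylogeny(tree)
  affinity <- traits$ground_truth$affinity
  sp <- tree$tip.label
  stopifnot(all(sp %in% names(affinity)))
  set.seed(params$seed + 1L)
  lat <- params$latitude
  span <- diff(range(lat))
  mid <- mean(range(lat))
  clade <- assign_clades(tree, params$n_clades)
  # clade centres displaced from the midpoint by gamma * span/2, spread evenly
  offsets <- seq(-1, 1, length.out = params$n_clades)
  centres_clade <- mid + params$gamma * offsets[clade[sp]] * span / 2
  centre <- centres_clade + stats::rnorm(length(sp), 0, span / 8)
  names(centre) <- sp
  pools <- lapply(lat, function(l) sp[abs(centre - l) <= params$range_halfwidth])
  names(pools) <- paste0("site", seq_along(lat))
  presence <- matrix(0L, params$n_sites, length(sp),
                     dimnames = list(names(pools), sp))
  weights <- vector("list", params$n_sites)
  for (i in seq_len(params$n_sites)) {
    pool <- pools[[i]]
    if (length(pool) < params$richness_range[1])
      stop("unattainable richness target: site ", i, " pool has only ",
           length(pool), " species")
    mism <- as.numeric(affinity[pool] != params$habitat[i])
    w <- exp(-params$phi * mism)
    S <- sample(params$richness_range[1]:min(params$richness_range[2],
                                             length(pool)), 1)
    chosen <- if (S == length(pool)) pool else sample(pool, S, prob = w)
    presence[i, chosen] <- 1L
    weights[[i]] <- stats::setNames(w / sum(w), pool)
  }
  observed <- colnames(presence)[colSums(presence) > 0]
  mc <- metacommunity(presence[, observed, drop = FALSE],
                      habitat = params$habitat, latitude = lat,
                      pools = pools)
  list(metacommunity = mc,
       ground_truth = list(affinity = affinity, range_centre = centre,
                           clade = clade, sampling_weights = weights))
}

#' Simulate a complete ground-truthed dataset
#'
#' Convenience wrapper: phylogeny, traits and metacommunity from one
#' parameter object, ready for the full pipeline.
#'
#' @param params A [simulation_params()].
#' @return List of class `"synthetic_dataset"`: `phylogeny`, `traits`
#'   (trait_table), `metacommunity`, `ground_truth`, `params`.
#' @export
simulate_dataset <- function(params = snakelike_params()) {
  tree <- simulate_phylogeny(params$n_species, seed = params$seed)
  tr <- simulate_traits(tree, sigma2 = params$sigma2, beta = params$beta,
                        seed = params$seed)
  mcres <- simulate_metacommunity(tree, tr, params)
  structure(list(phylogeny = tree, traits = tr$traits,
                 metacommunity = mcres$metacommunity,
                 ground_truth = c(tr$ground_truth,
                                  mcres$ground_truth[c("range_centre", "clade",
                                                       "sampling_weights")]),
                 params = params),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic dataset:", length(x$phylogeny$tip.label), "species pool;\n")
  print(x$metacommunity)
  cat(sprintf("params: sigma2 = %g, beta = %g, phi = %g, gamma = %g, seed = %d\n",
              x$params$sigma2, x$params$beta, x$params$phi, x$params$gamma,
              x$params$seed))
  invisible(x)
}
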