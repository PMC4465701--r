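test_that("Yule simulation gives the right shape and is seed-reproducible", {
  expect_equal(ape::Ntip(simulate_phylogeny(2, seed = 1)), 2)
  big <- simulate_phylogeny(182, seed = 4)
  expect_equal(big$Nnode, 181)           # fully bifurcating
  expect_equal(big$tip.label[1], "sp001")
  again <- simulate_phylogeny(182, seed = 4)
  expect_true(ape::all.equal.phylo(big, again))
  expect_false(isTRUE(ape::all.equal.phylo(
    ape::unroot(big), ape::unroot(simulate_phylogeny(182, seed = 5)),
    use.edge.length = FALSE)))
})

test_that("zero rate and zero effect collapse all species onto one phenotype", {
  tr <- simulate_phylogeny(12, seed = 2)
  out <- simulate_traits(tr, sigma2 = 0, beta = 0, seed = 2)
  expect_true(all(apply(as.matrix(as.data.frame(out$traits)), 2,
                        function(x) diff(range(x))) == 0))
  expect_true(all(as.matrix(as.data.frame(out$traits)) > 0))
})

test_that("a large habitat effect separates the filtered trait by affinity", {
  seps <- replicate(25, {
    s <- sample.int(1e6, 1)
    tr <- simulate_phylogeny(40, seed = s)
    out <- simulate_traits(tr, sigma2 = 1, beta = 6, seed = s)
    aff <- out$ground_truth$affinity
    lat <- out$ground_truth$latent[, "CAM"]
    mean(lat[aff == "non_forest"]) - mean(lat[aff == "forest"])
  })
  expect_true(all(seps > 0))
  # the imposed shift dominates: mean separation close to beta
  expect_gt(mean(seps), 4)
})

test_that("tip variance grows linearly with node-count depth under BM", {
  tr <- simulate_phylogeny(30, seed = 9)
  unit <- tr; unit$edge.length <- rep(1, nrow(tr$edge))
  depth <- ape::node.depth.edgelength(unit)[seq_len(30)]
  skip_if(diff(range(depth)) < 3)  # need depth contrast for the regression
  set.seed(9)
  lat <- replicate(120, simulate_traits(tr, sigma2 = 1, beta = 0,
                                        seed = sample.int(1e6, 1)
                                        )$ground_truth$latent[, "SVL"])
  v <- apply(lat, 1, var)
  fit <- lm(v ~ depth)
  # BM closed form: Var(tip) = sigma2 * depth -> slope ~ 1, intercept ~ 0
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.35)
  expect_gt(cor(v, depth), 0.6)
})

test_that("assembled metacommunities respect pools, richness and validation", {
  for (s in c(3, 77)) {
    ds <- simulate_dataset(snakelike_params(seed = s, beta = 1, phi = 1,
                                            gamma = 1))
    mc <- ds$metacommunity
    expect_true(all(rowSums(mc$presence) >= 9))
    expect_true(all(rowSums(mc$presence) <= 61))
    rep <- validate_dataset(ds$phylogeny, mc, ds$traits)
    expect_false(any(rep$severity == "fatal"))
    # presence within pools is enforced by construction
    for (site in rownames(mc$presence)) {
      pres <- colnames(mc$presence)[mc$presence[site, ] == 1]
      expect_true(all(pres %in% mc$pools[[site]]))
    }
  }
  # same parameters, same seed: identical realization
  a <- simulate_dataset(snakelike_params(seed = 5))
  b <- simulate_dataset(snakelike_params(seed = 5))
  expect_identical(a$metacommunity$presence, b$metacommunity$presence)
})

test_that("neutral assembly samples the pool uniformly, filter reweights it", {
  tr <- simulate_phylogeny(60, seed = 21)
  out <- simulate_traits(tr, sigma2 = 1, beta = 0, seed = 21)
  p0 <- simulation_params(n_species = 60, n_sites = 4,
                          habitat = rep(c("forest", "non_forest"), 2),
                          latitude = c(5, 10, 20, 28),
                          richness_range = c(5, 20), phi = 0, seed = 21)
  mc0 <- simulate_metacommunity(tr, out, p0)
  w0 <- mc0$ground_truth$sampling_weights[[1]]
  expect_true(all(w0 == w0[1]))          # phi = 0: uniform weights
  p2 <- simulation_params(n_species = 60, n_sites = 4,
                          habitat = rep(c("forest", "non_forest"), 2),
                          latitude = c(5, 10, 20, 28),
                          richness_range = c(5, 20), phi = 2, seed = 21)
  mc2 <- simulate_metacommunity(tr, out, p2)
  w2 <- mc2$ground_truth$sampling_weights[[1]]
  aff <- out$ground_truth$affinity[names(w2)]
  expect_true(all(w2[aff == "forest"] > w2[aff == "non_forest"]))  # forest site
})

test_that("strong filtering on conserved affinity clusters non-forest sites", {
  nri_means <- replicate(8, {
    s <- sample.int(1e6, 1)
    ds <- simulate_dataset(snakelike_params(seed = s, beta = 0, phi = 4,
                                            gamma = 0,
                                            n_species = 120,
                                            richness_range = c(9, 30)))
    res <- community_structure(ds$metacommunity, ds$phylogeny,
                               analysis_config(n_randomizations_structure = 199,
                                               seed = s))
    mean(res$NRI[ds$metacommunity$sites$habitat == "non_forest"])
  })
  expect_gt(mean(nri_means), 0)
  expect_gt(mean(nri_means > 0), 0.6)
})

test_that("clade-range turnover produces the NRI-latitude trend", {
  set.seed(41)
  slopes <- replicate(6, {
    s <- sample.int(1e6, 1)
    ds <- simulate_dataset(snakelike_params(seed = s, beta = 0, phi = 0,
                                            gamma = 2))
    # clustering is relative to the metacommunity-wide pool here, so the
    # null is drawn from the full tree rather than the per-site pools
    mc_global <- metacommunity(ds$metacommunity$presence,
                               ds$metacommunity$sites$habitat,
                               ds$metacommunity$sites$latitude)
    res <- community_structure(mc_global, ds$phylogeny,
                               analysis_config(n_randomizations_structure = 199,
                                               seed = s))
    unname(coef(lm(res$NRI ~ ds$metacommunity$sites$latitude))[2])
  })
  expect_gt(mean(slopes > 0), 0.8)
  expect_gt(mean(slopes), 0)
})

test_that("rho(TE) permutation p is uniform under fully neutral assembly", {
  set.seed(55)
  ps <- replicate(150, {
    s <- sample.int(1e6, 1)
    ds <- simulate_dataset(snakelike_params(seed = s, beta = 0, phi = 0,
                                            gamma = 0, n_species = 60,
                                            richness_range = c(5, 20)))
    B <- standardize_traits(ds$traits)
    permutation_test_TE(B, ds$metacommunity, c("TL", "CAM", "VS"),
                        n_perm = 99)$p
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
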