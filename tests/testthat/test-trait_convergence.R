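test_that("robustness is the log-log allometric residual with the right sign", {
  svl <- c(300, 500, 800, 1200)
  tt <- toy_traits(paste0("sp", 1:4))
  tt$SVL <- svl
  tt$CAM <- 0.1 * svl^0.9          # exactly on the allometric line
  r0 <- derive_robustness(tt)
  expect_equal(unname(r0$robustness), rep(0, 4), tolerance = 1e-12)
  # one species fatter than the line: positive residual
  tt$CAM[2] <- tt$CAM[2] * 1.5
  r1 <- derive_robustness(tt)
  expect_gt(r1$robustness[2], 0)
  # closed-form OLS oracle on the 4-species fixture
  x <- log(tt$SVL); y <- log(tt$CAM)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  expect_equal(unname(r1$robustness), y - (a + b * x))
  # raw-CAM alternative
  expect_equal(derive_robustness(tt, "raw_cam")$robustness, tt$CAM)
  expect_error(derive_robustness(tt[1:2, ]), ">= 3 species")
})

test_that("trait ranging maps to [0,1], drops constants, and is idempotent", {
  B <- cbind(t1 = c(10, 20, 30), t2 = c(5, 5, 5), t3 = c(0, 0.5, 1))
  rownames(B) <- paste0("sp", 1:3)
  expect_warning(Bh <- standardize_traits(B), "constant")
  expect_equal(colnames(Bh), c("t1", "t3"))
  expect_equal(unname(Bh[, "t1"]), c(0, 0.5, 1))
  expect_equal(standardize_traits(Bh), Bh)  # idempotent on ranged columns
})

test_that("matrix T is the community-weighted mean of ranged traits", {
  Bh <- cbind(tr1 = c(a = 0, b = 1), tr2 = c(a = 1, b = 0.5))
  m <- rbind(both = c(a = 1L, b = 1L), only_b = c(a = 0L, b = 1L),
             only_a = c(a = 1L, b = 0L))
  mc <- metacommunity(m, c("forest", "non_forest", "forest"), c(3, 10, 20))
  Tm <- build_matrix_T(Bh, mc)
  expect_equal(unname(Tm["both", "tr1"]), 0.5)
  expect_equal(unname(Tm["only_b", ]), unname(Bh["b", ]))
  # direct matrix-product oracle
  W_rel <- m / rowSums(m)
  expect_equal(unname(Tm), unname(W_rel %*% Bh), ignore_attr = TRUE)
  # subsetting traits
  expect_equal(colnames(build_matrix_T(Bh, mc, "tr2")), "tr2")
  expect_error(build_matrix_T(Bh, mc, "nope"), "unknown trait")
})

test_that("sites without full trait coverage are excluded from matrix T", {
  Bh <- cbind(tr1 = c(a = 0, b = 1))        # species c has no traits
  m <- rbind(s1 = c(a = 1L, b = 1L, c = 0L), s2 = c(a = 1L, b = 0L, c = 1L))
  mc <- metacommunity(m, c("forest", "non_forest"), c(3, 10))
  Tm <- build_matrix_T(Bh, mc)
  expect_equal(attr(Tm, "sites_used"), "s1")
})

test_that("habitat and trait dissimilarities take the stated forms", {
  m <- diag(4); dimnames(m) <- list(paste0("s", 1:4), paste0("sp", 1:4))
  mc <- metacommunity(m, c("forest", "forest", "non_forest", "non_forest"),
                      1:4)
  DE <- as.matrix(env_dissimilarity(mc))
  expect_equal(DE["s1", "s2"], 0)
  expect_equal(DE["s1", "s3"], 1)
  Tm <- rbind(s1 = c(0.2, 0.4), s2 = c(0.2, 0.4), s3 = c(1, 0))
  DT <- as.matrix(trait_dissimilarity(Tm))
  expect_equal(DT["s1", "s2"], 0)
  expect_equal(DT["s1", "s3"], sqrt(0.8^2 + 0.4^2))
  expect_warning(env_dissimilarity(setNames(rep("forest", 3), paste0("s", 1:3))),
                 "single habitat")
})

test_that("matrix correlation is Pearson on lower triangles with exact limits", {
  set.seed(8)
  DX <- as.matrix(dist(matrix(rnorm(8), 4)))
  expect_equal(matrix_correlation(DX, 2 * DX), 1)
  expect_equal(matrix_correlation(DX, max(DX) - DX), -1)
  # hand computation on the 6 pairs of a 4-site fixture
  DY <- as.matrix(dist(matrix(rnorm(8), 4)))
  x <- DX[lower.tri(DX)]; y <- DY[lower.tri(DY)]
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(matrix_correlation(DX, DY), r_hand)
  # affine rescaling of either matrix leaves rho unchanged
  expect_equal(matrix_correlation(0.3 + 2 * DX, DY), r_hand)
  expect_error(matrix_correlation(DX * 0, DY), "zero variance")
})

test_that("rho(TE) hits 1 with p = 1/(n+1) under perfect habitat sorting", {
  # 8 forest species share one trait value, 8 non-forest species another, and
  # sites are pure mixtures of their own group: community means are exactly
  # two-valued and aligned with habitat
  sp <- c(paste0("f", 1:8), paste0("n", 1:8))
  Bh <- cbind(tr = c(rep(0, 8), rep(1, 8)))
  rownames(Bh) <- sp
  m <- rbind(s1 = c(rep(1L, 5), rep(0L, 11)),
             s2 = c(0L, 0L, rep(1L, 6), rep(0L, 8)),
             s3 = c(1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L, rep(0L, 8)),
             s4 = c(rep(0L, 8), rep(1L, 5), rep(0L, 3)),
             s5 = c(rep(0L, 8), 0L, 0L, rep(1L, 6)),
             s6 = c(rep(0L, 8), 1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L))
  colnames(m) <- sp
  mc <- metacommunity(m, c(rep("forest", 3), rep("non_forest", 3)),
                      c(3, 8, 12, 20, 24, 28))
  set.seed(1)
  te <- permutation_test_TE(Bh, mc, n_perm = 199)
  expect_equal(te$rho, 1)
  expect_equal(te$p, 1 / 200)
  set.seed(1)
  te2 <- permutation_test_TE(Bh, mc, n_perm = 199)
  expect_identical(te$p, te2$p)  # seed-reproducible
  # site-shuffle scheme is exposed as an alternative
  set.seed(1)
  te3 <- permutation_test_TE(Bh, mc, n_perm = 199, scheme = "sites")
  expect_equal(te3$rho, 1)
  expect_equal(te3$scheme, "sites")
})

test_that("partial rho(TE.P) follows the closed formula and its limits", {
  tr <- simulate_phylogeny(10, seed = 14)
  mc <- toy_metacommunity(tr$tip.label, n_sites = 6, seed = 14)
  mp <- build_matrix_P(tr, mc)
  set.seed(3)
  n_sp <- ncol(mc$presence)
  Bh <- standardize_traits(matrix(runif(2 * n_sp), ncol = 2,
                                  dimnames = list(colnames(mc$presence),
                                                  c("t1", "t2"))))
  tep <- rho_TE_given_P(mp, Bh, mc, n_perm = 49)
  # independent closed-form check
  Tm <- build_matrix_T(Bh, mc)
  sites <- attr(Tm, "sites_used")
  DT <- dist(Tm)
  DE <- env_dissimilarity(mc, sites)
  DP <- as.dist(as.matrix(bray_curtis(mp))[sites, sites])
  lv <- function(d) { m <- as.matrix(d); m[lower.tri(m)] }
  r_te <- cor(lv(DT), lv(DE)); r_tp <- cor(lv(DT), lv(DP))
  r_ep <- cor(lv(DE), lv(DP))
  expect_equal(tep$rho,
               (r_te - r_tp * r_ep) / sqrt((1 - r_tp^2) * (1 - r_ep^2)))
  # constant D_P: reduces to the plain rho(TE)
  mp0 <- mp; mp0$P <- matrix(1 / nrow(mp$P), nrow(mp$P), ncol(mp$P),
                             dimnames = dimnames(mp$P))
  tep0 <- rho_TE_given_P(mp0, Bh, mc, n_perm = 9)
  expect_equal(tep0$rho, r_te)
})

test_that("traits driven by composition leave no partial habitat signal", {
  # D_T built directly from the community composition (hence from P),
  # habitat assigned independently: partial rho(TE.P) should sit near 0
  tr <- simulate_phylogeny(24, seed = 33)
  set.seed(33)
  reps <- replicate(12, {
    mc <- toy_metacommunity(tr$tip.label, n_sites = 8,
                            habitat = sample(rep(c("forest", "non_forest"), 4)),
                            seed = sample.int(1e6, 1))
    mp <- build_matrix_P(tr, mc)
    # trait = a clade-indicator, so T is a linear readout of composition
    D <- node_count_distances(tr)
    Bh <- cbind(t1 = as.numeric(D[, 1] > median(D[, 1])))
    rownames(Bh) <- rownames(D)
    Bh <- Bh[colnames(mc$presence), , drop = FALSE]
    if (sd(Bh) == 0) return(NA_real_)
    rho_TE_given_P(mp, Bh, mc, n_perm = 9)$rho
  })
  expect_lt(abs(mean(reps, na.rm = TRUE)), 0.25)
})

test_that("exhaustive subset search finds the informative trait and breaks ties", {
  set.seed(9)
  sp <- paste0("sp", 1:8)
  hab <- rep(c("forest", "non_forest"), each = 4)
  m <- diag(8); storage.mode(m) <- "integer"
  dimnames(m) <- list(paste0("s", 1:8), sp)
  mc <- metacommunity(m, hab, 1:8)
  Bh <- cbind(t1 = c(0, 0.05, 0.1, 0.15, 0.85, 0.9, 0.95, 1),  # habitat-sorted
              t2 = runif(8), t3 = runif(8))
  rownames(Bh) <- sp
  best <- optimal_trait_subset(Bh, mc)
  expect_equal(best$subset, "t1")
  expect_equal(best$n_evaluated, 7)
  # independent exhaustive oracle
  DE <- env_dissimilarity(mc)
  subsets <- unlist(lapply(1:3, function(k)
    utils::combn(colnames(Bh), k, simplify = FALSE)), recursive = FALSE)
  rhos <- vapply(subsets, function(s)
    matrix_correlation(dist(build_matrix_T(Bh, mc, s)), DE), numeric(1))
  expect_equal(best$rho, max(rhos))
  expect_equal(best$subset, subsets[[which.max(rhos)]])
  # identical columns tie: first singleton wins
  Bid <- cbind(a = Bh[, 1], b = Bh[, 1], c = Bh[, 1])
  expect_equal(optimal_trait_subset(Bid, mc)$subset, "a")
})

test_that("the d-separation verdict follows the published decision logic", {
  t_sig <- list(p = 0.049); t_marg <- list(p = 0.128)
  t_ns <- list(p = 0.4); t_str <- list(p = 0.01)
  expect_equal(dsep_verdict(t_sig, t_marg), "niche_conservatism_supported")
  expect_equal(dsep_verdict(t_ns, t_str), "no_convergence")
  expect_equal(dsep_verdict(t_str, t_str),
               "convergence_independent_of_phylogeny")
  expect_equal(dsep_verdict(t_sig, t_marg, alpha = 0.2),
               "convergence_independent_of_phylogeny")
})
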