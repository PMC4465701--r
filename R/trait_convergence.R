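#' Add the robustness trait (allometric stoutness residual)
#'
#' Midbody circumference indicates stoutness only after controlling for body
#' size; robustness is defined as the residual of the least-squares fit of
#' log(CAM) on log(SVL) across species. Species fatter than the allometric
#' line get positive values. The raw-CAM alternative (no size control) is
#' selectable for sensitivity checks.
#'
#' @param traits A trait_table with positive SVL and CAM.
#' @param method `"allometric_residual"` (default) or `"raw_cam"`.
#' @return The trait table with a `robustness` column appended.
#' @export
derive_robustness <- function(traits, method = c("allometric_residual",
                                                 "raw_cam")) {
  method <- match.arg(method)
  if (method == "raw_cam") {
    traits$robustness <- traits$CAM
    return(traits)
  }
  if (nrow(traits) < 3) stop("need >= 3 species to fit the allometric line")
  fit <- stats::lm(log(traits$CAM) ~ log(traits$SVL))
  traits$robustness <- stats::resid(fit)
  traits
}

#' Range-standardize traits to [0, 1]
#'
#' Each trait is ranged across species: `(x - min) / (max - min)`. This puts
#' lengths in mm and scale counts on a common scale before community
#' averaging. Constant traits carry no information and are dropped with a
#' warning. Idempotent on already-ranged columns.
#'
#' @param traits Trait table (data frame, species as row names).
#' @return Numeric matrix (species x traits) of ranged values.
#' @export
standardize_traits <- function(traits) {
  B <- as.matrix(as.data.frame(traits))
  if (nrow(B) < 2) stop("need >= 2 species to range traits")
  rng <- apply(B, 2, range)
  const <- rng[2, ] - rng[1, ] == 0
  if (any(const)) {
    warning("dropping constant trait(s): ",
            paste(colnames(B)[const], collapse = ", "))
    B <- B[, !const, drop = FALSE]
    rng <- rng[, !const, drop = FALSE]
  }
  sweep(sweep(B, 2, rng[1, ], "-"), 2, rng[2, ] - rng[1, ], "/")
}

#' Community-weighted mean trait matrix (matrix T)
#'
#' T is the product of the site-standardized composition and the ranged trait
#' matrix: with W_rel the presence matrix divided by site richness,
#' `T = W_rel %*% B_hat`, i.e. each community's entry is the mean ranged
#' trait value of its member species. Sites are restricted to those where
#' every present species has trait data.
#'
#' @param B_hat Species x traits matrix of ranged values
#'   ([standardize_traits()]).
#' @param mc A [metacommunity()].
#' @param trait_subset Optional character vector of trait names to use.
#' @return Sites x traits numeric matrix (class `"matrix"`), attribute
#'   `"sites_used"`.
#' @export
build_matrix_T <- function(B_hat, mc, trait_subset = NULL) {
  if (!is.null(trait_subset)) {
    missing <- setdiff(trait_subset, colnames(B_hat))
    if (length(missing)) stop("unknown trait(s): ", paste(missing, collapse = ", "))
    B_hat <- B_hat[, trait_subset, drop = FALSE]
  }
  W <- mc$presence
  uncovered <- setdiff(colnames(W), rownames(B_hat))
  keep <- rowSums(W[, uncovered, drop = FALSE]) == 0
  if (!any(keep)) stop("no site has complete trait coverage")
  W <- W[keep, colnames(W) %in% rownames(B_hat), drop = FALSE]
  if (any(rowSums(W) == 0)) stop("site with zero trait-covered species")
  W_rel <- sweep(W, 1, rowSums(W), "/")
  Tm <- W_rel %*% B_hat[colnames(W), , drop = FALSE]
  attr(Tm, "sites_used") <- rownames(W)
  Tm
}

#' Habitat (environmental) dissimilarity between sites
#'
#' Simple mismatch on the two-level habitat factor: 0 for sites of the same
#' class, 1 otherwise.
#'
#' @param mc A metacommunity (or a character vector of habitat classes with
#'   names = sites).
#' @param sites Optional site subset/order.
#' @return `dist` object.
#' @export
env_dissimilarity <- function(mc, sites = NULL) {
  hab <- if (inherits(mc, "metacommunity")) {
    stats::setNames(mc$sites$habitat, mc$sites$site)
  } else mc
  if (!is.null(sites)) hab <- hab[sites]
  if (length(unique(hab)) < 2)
    warning("single habitat class: environmental dissimilarity is all zero")
  d <- stats::dist(as.numeric(factor(hab, levels = c("forest", "non_forest"))),
                   method = "manhattan")
  attr(d, "Labels") <- names(hab)
  d
}

#' Euclidean trait dissimilarity between community rows of matrix T
#' @param Tm Sites x traits matrix.
#' @return `dist` object.
#' @export
trait_dissimilarity <- function(Tm) {
  stats::dist(Tm)
}

lower_vec <- function(d) {
  m <- as.matrix(d)
  m[lower.tri(m)]
}

# permutation-loop correlation: a permuted trait matrix can collapse to
# identical community rows; such a draw carries no association and scores 0
perm_cor <- function(D_X, D_Y) {
  x <- lower_vec(D_X); y <- lower_vec(D_Y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

#' Matrix correlation between two dissimilarity structures
#'
#' Pearson correlation over the strictly-lower-triangle entries of two
#' aligned dissimilarity matrices (Mantel-type statistic).
#'
#' @param D_X,D_Y `dist` objects or square matrices over the same sites in
#'   the same order.
#' @return Correlation coefficient.
#' @export
matrix_correlation <- function(D_X, D_Y) {
  x <- lower_vec(D_X); y <- lower_vec(D_Y)
  if (length(x) != length(y)) stop("dissimilarity size mismatch")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in a dissimilarity matrix: correlation undefined")
  stats::cor(x, y)
}

partial_cor <- function(r_xy, r_xz, r_yz) {
  den <- sqrt((1 - r_xz^2) * (1 - r_yz^2))
  if (den == 0) stop("partial correlation undefined (|r| = 1 with control)")
  (r_xy - r_xz * r_yz) / den
}

#' Trait-convergence test rho(TE)
#'
#' Correlates community trait dissimilarity (Euclidean on matrix T) with
#' habitat dissimilarity, and tests it against the null that traits are
#' unrelated to species identity: trait rows are permuted across species,
#' matrix T and the correlation are rebuilt each permutation. One-sided (high
#' rho = convergence), with the +1 correction so p is never 0. An alternative
#' site-permutation (classic Mantel) scheme is available.
#'
#' @param B_hat Ranged species x traits matrix.
#' @param mc Metacommunity.
#' @param trait_subset Optional trait names.
#' @param n_perm Permutations (default 9999).
#' @param scheme `"species"` (default; shuffle trait rows) or `"sites"`.
#' @return List of class `"matrix_correlation_test"`: `rho`, `p`, `n_perm`,
#'   `scheme`, `sites`, `traits`.
#' @export
permutation_test_TE <- function(B_hat, mc, trait_subset = NULL,
                                n_perm = 9999, scheme = c("species", "sites")) {
  scheme <- match.arg(scheme)
  Tm <- build_matrix_T(B_hat, mc, trait_subset)
  sites <- attr(Tm, "sites_used")
  D_E <- env_dissimilarity(mc, sites)
  obs <- matrix_correlation(trait_dissimilarity(Tm), D_E)
  perm_rho <- numeric(n_perm)
  if (scheme == "species") {
    for (i in seq_len(n_perm)) {
      Bp <- B_hat[sample.int(nrow(B_hat)), , drop = FALSE]
      rownames(Bp) <- rownames(B_hat)
      Tp <- build_matrix_T(Bp, mc, trait_subset)
      perm_rho[i] <- perm_cor(trait_dissimilarity(Tp), D_E)
    }
  } else {
    DT <- as.matrix(trait_dissimilarity(Tm))
    n <- nrow(DT)
    for (i in seq_len(n_perm)) {
      idx <- sample.int(n)
      perm_rho[i] <- perm_cor(DT[idx, idx], D_E)
    }
  }
  structure(list(rho = obs, p = (sum(perm_rho >= obs) + 1) / (n_perm + 1),
                 n_perm = n_perm, scheme = scheme, sites = sites,
                 traits = colnames(Tm), conditioned_on = NULL),
            class = "matrix_correlation_test")
}

#' @export
print.matrix_correlation_test <- function(x, ...) {
  cat(sprintf("matrix correlation rho = %.3f, p = %.4g (%d permutations, %s scheme%s)\n",
              x$rho, x$p, x$n_perm, x$scheme,
              if (is.null(x$conditioned_on)) "" else
                paste0(", partial on ", x$conditioned_on)))
  invisible(x)
}

#' Phylogenetic signal at the metacommunity level: rho(PT)
#'
#' Correlates Bray-Curtis dissimilarities of the phylogeny-weighted
#' composition (matrix P, restricted to the trait-covered sites) with the
#' Euclidean dissimilarities of matrix T; significance by the same
#' species-level trait permutation as [permutation_test_TE()].
#'
#' @param matP A `"matrix_P"` object.
#' @param B_hat Ranged trait matrix.
#' @param mc Metacommunity.
#' @param trait_subset Optional trait names.
#' @param n_perm Permutations.
#' @return `"matrix_correlation_test"` object.
#' @export
rho_PT <- function(matP, B_hat, mc, trait_subset = NULL, n_perm = 9999) {
  Tm <- build_matrix_T(B_hat, mc, trait_subset)
  sites <- attr(Tm, "sites_used")
  D_P <- stats::as.dist(as.matrix(bray_curtis(matP))[sites, sites])
  obs <- matrix_correlation(D_P, trait_dissimilarity(Tm))
  perm_rho <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    Bp <- B_hat[sample.int(nrow(B_hat)), , drop = FALSE]
    rownames(Bp) <- rownames(B_hat)
    Tp <- build_matrix_T(Bp, mc, trait_subset)
    perm_rho[i] <- perm_cor(D_P, trait_dissimilarity(Tp))
  }
  structure(list(rho = obs, p = (sum(perm_rho >= obs) + 1) / (n_perm + 1),
                 n_perm = n_perm, scheme = "species", sites = sites,
                 traits = colnames(Tm), conditioned_on = NULL),
            class = "matrix_correlation_test")
}

#' Partial trait-environment correlation rho(TE.P)
#'
#' The d-separation statistic: the correlation between trait and habitat
#' dissimilarities after controlling for phylogeny-weighted composition,
#' `r_TE.P = (r_TE - r_TP r_EP) / sqrt((1 - r_TP^2)(1 - r_EP^2))`. Under
#' phylogenetic niche conservatism the habitat filter acts through whole
#' clades, so this partial correlation should collapse to null. Significance
#' by species-level trait permutation (999 by default), rebuilding T and all
#' dependent terms each draw.
#'
#' @param matP `"matrix_P"` object (for D_P).
#' @param B_hat Ranged trait matrix.
#' @param mc Metacommunity.
#' @param trait_subset Optional trait names.
#' @param n_perm Permutations (default 999).
#' @return `"matrix_correlation_test"` object with `conditioned_on = "P"`.
#' @export
rho_TE_given_P <- function(matP, B_hat, mc, trait_subset = NULL,
                           n_perm = 999) {
  Tm <- build_matrix_T(B_hat, mc, trait_subset)
  sites <- attr(Tm, "sites_used")
  D_E <- env_dissimilarity(mc, sites)
  D_P <- stats::as.dist(as.matrix(bray_curtis(matP))[sites, sites])
  # a constant D_P carries no information: its correlations are taken as 0,
  # so the partial statistic reduces to the plain rho(TE)
  p_const <- stats::sd(lower_vec(D_P)) == 0
  stat <- function(Tmat, strict = FALSE) {
    D_T <- trait_dissimilarity(Tmat)
    r_te <- if (strict) matrix_correlation(D_T, D_E) else perm_cor(D_T, D_E)
    partial_cor(r_te,
                if (p_const) 0 else perm_cor(D_T, D_P),
                if (p_const) 0 else perm_cor(D_E, D_P))
  }
  obs <- stat(Tm, strict = TRUE)
  perm_rho <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    Bp <- B_hat[sample.int(nrow(B_hat)), , drop = FALSE]
    rownames(Bp) <- rownames(B_hat)
    perm_rho[i] <- stat(build_matrix_T(Bp, mc, trait_subset))
  }
  structure(list(rho = obs, p = (sum(perm_rho >= obs) + 1) / (n_perm + 1),
                 n_perm = n_perm, scheme = "species", sites = sites,
                 traits = colnames(Tm), conditioned_on = "P"),
            class = "matrix_correlation_test")
}

#' Exhaustive search for the trait subset maximizing convergence
#'
#' Community trait structure mixes convergence and divergence signals, so the
#' convergence test is run on the trait subset that maximizes rho(TE). All
#' non-empty subsets are scored when the number of candidate traits is at
#' most `max_exhaustive` (2^9 - 1 = 511 subsets for the 8 measured traits
#' plus robustness); ties are broken toward the smaller subset, then
#' lexicographically.
#'
#' @param B_hat Ranged species x traits matrix.
#' @param mc Metacommunity.
#' @param max_exhaustive Exhaustive-search limit on trait count (default 12).
#' @return List: `subset` (character), `rho`, `n_evaluated`.
#' @export
optimal_trait_subset <- function(B_hat, mc, max_exhaustive = 12) {
  traits <- colnames(B_hat)
  if (length(traits) < 1) stop("no candidate traits")
  if (length(traits) > max_exhaustive)
    stop("too many traits for exhaustive search (", length(traits), ")")
  # precompute: D_E fixed; T columns are per-trait, and Euclidean distance on a
  # subset uses only that subset's columns, so compute per-trait T once
  Tm_full <- build_matrix_T(B_hat, mc)
  sites <- attr(Tm_full, "sites_used")
  D_E <- env_dissimilarity(mc, sites)
  best <- list(subset = NULL, rho = -Inf)
  idx_list <- lapply(seq_along(traits), function(k)
    utils::combn(seq_along(traits), k, simplify = FALSE))
  idx_list <- unlist(idx_list, recursive = FALSE)
  # order guarantees the tie-break: smaller subsets first, lexicographic within
  n_eval <- 0L
  for (idx in idx_list) {
    rho <- matrix_correlation(
      stats::dist(Tm_full[, idx, drop = FALSE]), D_E)
    n_eval <- n_eval + 1L
    if (rho > best$rho + 1e-12) best <- list(subset = traits[idx], rho = rho)
  }
  c(best, list(n_evaluated = n_eval))
}

#' D-separation verdict on trait convergence
#'
#' Combines the marginal convergence test rho(TE) and the phylogeny-
#' controlled partial rho(TE.P): a significant marginal correlation that
#' collapses under control indicates the habitat filter acts on
#' phylogenetically conserved traits (niche conservatism); one that survives
#' control indicates convergence independent of phylogeny; a non-significant
#' marginal correlation means no detectable convergence.
#'
#' @param te `"matrix_correlation_test"` for rho(TE).
#' @param te_given_p `"matrix_correlation_test"` for rho(TE.P).
#' @param alpha Significance level (default 0.05).
#' @return One of `"niche_conservatism_supported"`,
#'   `"convergence_independent_of_phylogeny"`, `"no_convergence"`.
#' @export
dsep_verdict <- function(te, te_given_p, alpha = 0.05) {
  if (te$p >= alpha) return("no_convergence")
  if (te_given_p$p >= alpha) return("niche_conservatism_supported")
  "convergence_independent_of_phylogeny"
}
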