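#' Phylogenetic similarity from a distance matrix
#'
#' Node-count distances are bounded, so similarity is taken as
#' `s_ij = 1 - d_ij / max(d)`, mapping the most distant pair to 0 and each
#' species to itself to 1. The result is invariant to uniform rescaling of
#' the distances.
#'
#' @param D Square symmetric distance matrix (zero diagonal).
#' @return Similarity matrix S with unit diagonal and entries in [0, 1].
#' @export
phylo_similarity <- function(D) {
  dmax <- max(D)
  if (dmax <= 0) stop("degenerate distance matrix (max distance 0)")
  S <- 1 - D / dmax
  diag(S) <- 1
  S
}

#' Fuzzy belonging weights from a similarity matrix
#'
#' Each species j distributes one unit of belonging across all species
#' (including itself) in proportion to phylogenetic similarity:
#' `q_ij = s_ij / sum_k s_kj`. Columns therefore sum to exactly 1; on a star
#' phylogeny (no shared internal structure) Q is the identity.
#'
#' @param S Similarity matrix from [phylo_similarity()].
#' @return Column-stochastic matrix Q, same dimnames as S.
#' @export
fuzzy_weights <- function(S) {
  sweep(S, 2, colSums(S), "/")
}

#' Phylogeny-weighted species composition (matrix P)
#'
#' Builds the fuzzy-weighted composition matrix: presence columns are first
#' standardized to relative frequencies (each site sums to 1), then each
#' species' occurrence is spread over phylogenetically similar species
#' through Q: `P = Q %*% W_rel`. Columns of P sum to 1, so sites remain
#' comparable; when the phylogeny carries no structure (star tree) P equals
#' the relative composition itself.
#'
#' @param phylogeny Rooted tree covering all metacommunity species (or a
#'   precomputed Q via the `Q` argument).
#' @param mc A [metacommunity()].
#' @param Q Optional: fuzzy-weight matrix to use directly.
#' @return Object of class `"matrix_P"`: list with `S`, `Q`, `P`
#'   (species x sites), `species`, `sites`.
#' @export
build_matrix_P <- function(phylogeny = NULL, mc, Q = NULL) {
  if (is.null(Q)) {
    D <- node_count_distances(phylogeny)
    S <- phylo_similarity(D)
    Q <- fuzzy_weights(S)
  } else {
    S <- NULL
  }
  sp <- colnames(mc$presence)
  if (!all(sp %in% rownames(Q)))
    stop("metacommunity species missing from phylogeny: ",
         paste(setdiff(sp, rownames(Q)), collapse = ", "))
  Q <- Q[sp, sp]
  if (!is.null(S)) S <- S[sp, sp]
  # renormalize columns after restriction to observed species
  Q <- sweep(Q, 2, colSums(Q), "/")
  W <- t(mc$presence)                      # species x sites
  W_rel <- sweep(W, 2, colSums(W), "/")
  P <- Q %*% W_rel
  structure(list(S = S, Q = Q, P = P, species = sp,
                 sites = colnames(P)), class = "matrix_P")
}

#' @export
print.matrix_P <- function(x, ...) {
  cat("matrix P:", nrow(x$P), "species x", ncol(x$P), "sites;",
      "column sums", paste(format(range(colSums(x$P)), digits = 10),
                           collapse = "-"), "\n")
  invisible(x)
}

#' Bray-Curtis dissimilarity between sites of a matrix P
#'
#' @param P Species x sites non-negative matrix (a `"matrix_P"` object or the
#'   bare matrix).
#' @return `dist` object over sites.
#' @export
bray_curtis <- function(P) {
  if (inherits(P, "matrix_P")) P <- P$P
  vegan::vegdist(t(P), method = "bray")
}

#' Principal coordinates of phylogenetic structure (PCPS)
#'
#' Classical scaling (PCoA) of the Bray-Curtis dissimilarities among the
#' columns of matrix P. Axes with non-positive eigenvalues are dropped
#' (no Cailliez/Lingoes correction) and the fraction of variability per axis
#' is relative to the sum of positive eigenvalues. For reproducible output
#' the sign of each axis is fixed so its first nonzero site score is
#' positive. Species scores, for ordination plots, are the P-weighted
#' averages of site scores (a plotting convenience, not a canonical
#' projection).
#'
#' @param P A `"matrix_P"` object (or species x sites matrix).
#' @param dissimilarity Optional precomputed `dist` over sites; Bray-Curtis
#'   of P's columns by default.
#' @return Object of class `"pcps_result"`: `scores` (sites x axes),
#'   `eigenvalues` (positive ones), `fraction` (per-axis share of positive
#'   eigenvalue total), `n_axes`, `species_scores`, `n_dropped`
#'   (non-positive eigenvalues discarded).
#' @export
pcps <- function(P, dissimilarity = NULL) {
  mat <- if (inherits(P, "matrix_P")) P$P else P
  d <- if (is.null(dissimilarity)) bray_curtis(mat) else dissimilarity
  if (all(as.matrix(d) == 0)) stop("all-zero dissimilarity: no axes")
  pc <- ape::pcoa(d, correction = "none")
  eig <- pc$values$Eigenvalues
  pos <- which(eig > 1e-10)
  scores <- pc$vectors[, pos, drop = FALSE]
  # deterministic axis orientation: first nonzero score positive
  for (k in seq_len(ncol(scores))) {
    nz <- which(abs(scores[, k]) > 1e-12)[1]
    if (!is.na(nz) && scores[nz, k] < 0) scores[, k] <- -scores[, k]
  }
  colnames(scores) <- paste0("PCPS", seq_len(ncol(scores)))
  rownames(scores) <- attr(d, "Labels")
  sp_scores <- NULL
  if (!is.null(mat)) {
    w <- sweep(mat, 1, rowSums(mat), "/")
    sp_scores <- w %*% scores[colnames(mat), , drop = FALSE]
  }
  structure(list(scores = scores, eigenvalues = eig[pos],
                 fraction = eig[pos] / sum(eig[pos]),
                 n_axes = length(pos), species_scores = sp_scores,
                 n_dropped = length(eig) - length(pos)),
            class = "pcps_result")
}

#' @export
print.pcps_result <- function(x, ...) {
  cat("PCPS:", x$n_axes, "positive axes (", x$n_dropped, "dropped );",
      "first axes explain", paste(sprintf("%.1f%%", 100 * utils::head(x$fraction, 3)),
                                  collapse = ", "), "\n")
  invisible(x)
}

#' Distance-based redundancy statistic on a set of ordination axes
#'
#' Regresses the selected axes jointly on a predictor design: explained and
#' total sums of squares are pooled over axes, giving
#' `R2 = SS_explained / SS_total` and
#' `F = (R2/q) / ((1-R2)/(n-q-1))` with q predictors and n sites. A
#' permutation p is obtained by shuffling the site rows of the predictors.
#' With a single axis this reduces exactly to the ordinary regression R2/F.
#'
#' @param axes Sites x axes score matrix.
#' @param predictors Sites x q numeric design matrix (no intercept column).
#' @param n_perm Permutations for the p-value (0 to skip).
#' @return List: `R2`, `F`, `df`, `p_perm` (NA when `n_perm = 0`).
#' @export
db_rda <- function(axes, predictors, n_perm = 999) {
  Y <- as.matrix(axes)
  X <- as.matrix(predictors)
  n <- nrow(Y); q <- ncol(X)
  if (nrow(X) != n) stop("predictor/axis row mismatch")
  if (q >= n - 1) stop("too many predictors for ", n, " sites")
  rda_stat <- function(X) {
    Yc <- scale(Y, center = TRUE, scale = FALSE)
    H <- stats::lm.fit(cbind(1, X), Y)
    ss_res <- sum(H$residuals^2)
    ss_tot <- sum(Yc^2)
    R2 <- 1 - ss_res / ss_tot
    list(R2 = R2, F = (R2 / q) / ((1 - R2) / (n - q - 1)))
  }
  obs <- rda_stat(X)
  p <- NA_real_
  if (n_perm > 0) {
    exceed <- vapply(seq_len(n_perm), function(i)
      rda_stat(X[sample.int(n), , drop = FALSE])$F >= obs$F, logical(1))
    p <- (sum(exceed) + 1) / (n_perm + 1)
  }
  list(R2 = obs$R2, F = obs$F, df = c(q, n - q - 1), p_perm = p)
}

#' Select the number of PCPS axes by F-maximization
#'
#' Evaluates the db-RDA F statistic of the leading k axes against the
#' predictors for k = 1..K and returns the k with the greatest F (i.e. the
#' lowest residual variation relative to model size); ties go to the smaller
#' k.
#'
#' @param pcps_result A [pcps()] result.
#' @param predictors Sites x q design matrix.
#' @return List: `k`, `F_by_k` (named vector), `R2_by_k`.
#' @export
select_pcps <- function(pcps_result, predictors) {
  K <- pcps_result$n_axes
  Fv <- R2v <- numeric(K)
  for (k in seq_len(K)) {
    r <- db_rda(pcps_result$scores[, seq_len(k), drop = FALSE], predictors,
                n_perm = 0)
    Fv[k] <- r$F; R2v[k] <- r$R2
  }
  names(Fv) <- names(R2v) <- seq_len(K)
  # which.max takes the first maximum, so ties resolve toward fewer axes
  list(k = unname(which.max(Fv)), F_by_k = Fv, R2_by_k = R2v)
}
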