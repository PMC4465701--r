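#' Ordinary least squares fit with full-model F test
#'
#' Thin wrapper around [stats::lm()] returning the quantities the structure
#' analyses report: coefficients, raw and adjusted R2, the overall F with
#' exact degrees of freedom, and its parametric p.
#'
#' @param y Numeric response (one value per site).
#' @param design Data frame or matrix of predictors (no intercept column; an
#'   intercept is always included).
#' @return List of class `"ols_fit"`: `coefficients`, `r_squared`,
#'   `adj_r_squared`, `F`, `df` (numerator, denominator), `p`, `n`, `fitted`,
#'   `residuals`.
#' @export
ols_fit <- function(y, design) {
  X <- as.data.frame(design)
  n <- length(y)
  if (nrow(X) != n) stop("response/design length mismatch")
  if (n <= ncol(X) + 1) stop("need n > predictors + 1")
  # reserved response name so predictor columns can never shadow it
  dat <- data.frame(.response. = y, X, check.names = FALSE)
  fit <- stats::lm(.response. ~ ., data = dat)
  if (any(is.na(stats::coef(fit)))) stop("rank-deficient design")
  s <- suppressWarnings(summary(fit))  # "essentially perfect fit" is fine here
  q <- ncol(X)
  R2 <- s$r.squared
  Fv <- if (R2 == 1) Inf else (R2 / q) / ((1 - R2) / (n - q - 1))
  structure(list(coefficients = stats::coef(fit), r_squared = R2,
                 adj_r_squared = s$adj.r.squared, F = Fv,
                 df = c(q, n - q - 1),
                 p = stats::pf(Fv, q, n - q - 1, lower.tail = FALSE),
                 n = n, fitted = stats::fitted(fit),
                 residuals = stats::resid(fit)),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS: R2 = %.4f (adj %.4f), F(%d,%d) = %.3f, p = %.4g\n",
              x$r_squared, x$adj_r_squared, x$df[1], x$df[2], x$F, x$p))
  invisible(x)
}

#' Two-set variation partitioning
#'
#' Decomposes the variance of `y` explained by two predictor sets into the
#' unique fraction of set 1 (`a`), the shared fraction (`b`), the unique
#' fraction of set 2 (`c`) and the residual (`d`), via the three regressions
#' y ~ X1, y ~ X2, y ~ X1 + X2:
#' `a = R2(full) - R2(X2)`, `c = R2(full) - R2(X1)`,
#' `b = R2(full) - a - c`, `d = 1 - R2(full)`.
#' Both the raw-R2 fractions (which sum to 1 exactly) and the adjusted-R2
#' fractions (which can be negative and are reported unclipped) are returned.
#'
#' @param y Numeric response.
#' @param X1,X2 Predictor sets (data frame / matrix / vector). `X2 = NULL`
#'   degenerates to [ols_fit()] on X1.
#' @return List of class `"varpart_result"`: `raw` and `adjusted` named
#'   vectors (a, b, c, d), `fits` (the three ols_fit objects), percent
#'   roundings of both forms.
#' @export
varpart_two <- function(y, X1, X2 = NULL) {
  X1 <- as.data.frame(X1)
  if (is.null(X2)) {
    f <- ols_fit(y, X1)
    raw <- c(a = f$r_squared, b = 0, c = 0, d = 1 - f$r_squared)
    adj <- c(a = f$adj_r_squared, b = 0, c = 0, d = 1 - f$adj_r_squared)
    return(structure(list(raw = raw, adjusted = adj,
                          fits = list(X1 = f, X2 = NULL, full = f),
                          raw_percent = round(100 * raw),
                          adjusted_percent = round(100 * adj)),
                     class = "varpart_result"))
  }
  X2 <- as.data.frame(X2)
  f1 <- ols_fit(y, X1)
  f2 <- ols_fit(y, X2)
  Xf <- cbind(X1, X2)
  # collinear duplicated sets: full model = either submodel
  full_ok <- qr(cbind(1, as.matrix(Xf)))$rank == ncol(Xf) + 1
  ff <- if (full_ok) ols_fit(y, Xf) else f1
  frac <- function(r_full, r1, r2) {
    a <- r_full - r2; c <- r_full - r1
    c(a = a, b = r_full - a - c, c = c, d = 1 - r_full)
  }
  raw <- frac(ff$r_squared, f1$r_squared, f2$r_squared)
  adj <- frac(ff$adj_r_squared, f1$adj_r_squared, f2$adj_r_squared)
  structure(list(raw = raw, adjusted = adj,
                 fits = list(X1 = f1, X2 = f2, full = ff),
                 raw_percent = round(100 * raw),
                 adjusted_percent = round(100 * adj)),
            class = "varpart_result")
}

#' @export
print.varpart_result <- function(x, ...) {
  cat("variation partitioning (a = unique set 1, b = shared, c = unique set 2, d = residual)\n")
  cat("  raw:     ", paste(sprintf("%s = %.3f", names(x$raw), x$raw),
                           collapse = ", "), "\n")
  cat("  adjusted:", paste(sprintf("%s = %.3f", names(x$adjusted), x$adjusted),
                           collapse = ", "), "\n")
  invisible(x)
}
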