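#' The H3K27me3 dependency model
#'
#' The model expresses the mutant H3K27me3 level `z` at a genomic bin as a
#' function of the pre-existing (wild-type) H3K27me3 level `x` and the
#' oncohistone level `y` at the same bin, through a degree-7 Taylor-style
#' polynomial in the single variable `d = x - y`:
#'
#'   `Z = A0 + A1 * sum_{n=1..7} A_{n+1} * d^n`
#'
#' The nine coefficients A0..A8 are stored in order. Evaluation at `x = y`
#' returns exactly `A0`. The (A1, A2..A8) split is not identifiable (only
#' the products `A1 * A_{n+1}` are); fitting therefore uses the reduced form
#' `Z = B0 + sum B_n d^n` and maps back with `A1 = 1`.
#'
#' @param coefficients numeric vector of 9 finite values A0..A8.
#' @return An object of class `DependencyModel`.
#' @export
dependency_model <- function(coefficients) {
  if (length(coefficients) != 9L || !all(is.finite(coefficients)))
    validation_error("a dependency model needs 9 finite coefficients A0..A8")
  structure(list(A = stats::setNames(as.numeric(coefficients),
                                     paste0("A", 0:8))),
            class = "DependencyModel")
}

# Packaged reference coefficients (verbatim copy of the JSON file shipped in
# inst/extdata/dependency_table1.json).
table1_coefficients <- function() {
  path <- system.file("extdata", "dependency_table1.json", package = "oncochrom")
  if (nzchar(path)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(as.numeric(j[paste0("A", 0:8)]))
  }
  # fallback for un-installed use (e.g. sourcing during development)
  c(-0.709110206, 0.689422042, 0.92135143, 0.291658614, -0.153205021,
    -0.049106574, 0.002409524, 0.00175899, 0.000128287)
}

#' The packaged reference dependency model
#'
#' Returns the dependency model with the published reference coefficients
#' (A0 = -0.709110206, ...), read from the JSON file shipped with the
#' package.
#'
#' @return A [dependency_model()].
#' @export
table1_model <- function() dependency_model(table1_coefficients())

#' Evaluate a dependency model
#'
#' Vectorized over bins; `x` and `y` are recycled to a common length.
#' Depends on `(x, y)` only through `d = x - y`, so it is invariant under a
#' common shift of both inputs.
#'
#' @param model a `DependencyModel`.
#' @param x pre-existing (wild-type) H3K27me3 level(s).
#' @param y oncohistone level(s).
#' @return Predicted mutant H3K27me3 level(s) `Z`.
#' @export
evaluate_dependency <- function(model, x, y) {
  stopifnot(inherits(model, "DependencyModel"))
  if (!all(is.finite(x)) || !all(is.finite(y)))
    validation_error("x and y must be finite")
  d <- x - y
  A <- model$A
  # Horner on the inner polynomial sum_{n=1..7} A_{n+1} d^n; d = 0 gives
  # exactly 0 so evaluation at x = y returns A0 with no rounding.
  inner <- A[9]
  for (k in 8:3) inner <- inner * d + A[k]
  inner <- inner * d
  unname(A[1] + A[2] * inner)
}

# Map a polynomial in u = (d - center)/scale, coefficients c_0..c_p, to the
# equivalent polynomial in d.  T[j+1, k+1] = choose(k, j) (-center)^(k-j) /
# scale^k for k >= j; b = T %*% c.
poly_shift_matrix <- function(p, center, scale) {
  T <- matrix(0, p + 1L, p + 1L)
  for (k in 0:p)
    for (j in 0:k)
      T[j + 1L, k + 1L] <- choose(k, j) * (-center)^(k - j) / scale^k
  T
}

#' Fit the dependency model by ordinary least squares
#'
#' Fits the identifiable reduced form `Z = B0 + sum_{n=1..7} B_n d^n` with
#' `d = x - y`. Internally the powers are computed on centered and scaled
#' `d` (a degree-7 raw Vandermonde design is ill-conditioned) and the
#' coefficients are mapped back to the raw-`d` basis. The result is returned
#' in the A parameterization with `A1 = 1`, `A0 = B0`, `A_{n+1} = B_n`.
#'
#' @param x,y,z equal-length finite numeric vectors (length >= 9).
#' @param degree polynomial degree (default 7, the reference form).
#' @return A list of class `FitResult`: `model` (a [dependency_model()] when
#'   `degree = 7`, otherwise the coefficient vector), `coefficients` (B0..),
#'   `se` (OLS standard errors), `r_squared` (1 - SSE/TSS), `sse`, `n_bins`.
#' @export
fit_dependency <- function(x, y, z, degree = 7L) {
  n <- length(z)
  if (length(x) != n || length(y) != n)
    dimension_error("x, y, z must have equal length")
  if (n < degree + 2L) fit_error("too few observations for the requested degree")
  if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(z)))
    validation_error("inputs must be finite")
  d <- x - y
  if (stats::sd(d) == 0)
    fit_error("degenerate design: all d = x - y identical")
  ctr <- mean(d); scl <- stats::sd(d)
  u <- (d - ctr) / scl
  X <- outer(u, 0:degree, `^`)
  qrX <- qr(X)
  if (qrX$rank < degree + 1L)
    fit_error("rank-deficient design: too few distinct d values")
  cf <- qr.coef(qrX, z)
  fitted <- drop(X %*% cf)
  resid <- z - fitted
  sse <- sum(resid^2)
  dof <- n - (degree + 1L)
  sigma2 <- if (dof > 0) sse / dof else 0
  XtXinv <- chol2inv(chol(crossprod(X)))
  T <- poly_shift_matrix(degree, ctr, scl)
  b <- drop(T %*% cf)
  cov_b <- T %*% (sigma2 * XtXinv) %*% t(T)
  se <- sqrt(pmax(diag(cov_b), 0))
  tss <- sum((z - mean(z))^2)
  r2 <- if (tss > 0) 1 - sse / tss else NA_real_
  model <- if (degree == 7L) dependency_model(c(b[1], 1, b[-1])) else NULL
  structure(list(model = model,
                 coefficients = stats::setNames(b, paste0("B", 0:degree)),
                 se = stats::setNames(se, paste0("B", 0:degree)),
                 r_squared = r2, sse = sse, n_bins = n),
            class = "FitResult")
}

#' Goodness of fit of a dependency model on observed data
#'
#' Reports the sum of squared errors `sum (Z_i - z_i)^2` between model
#' predictions `Z` and observations `z`, and two R-squared variants: the
#' squared Pearson correlation between `Z` and `z` (`r_squared`, the primary
#' metric) and the regression variant `1 - SSE/TSS`
#' (`r_squared_regression`). The two coincide for an OLS fit with intercept
#' on its own training data but differ when a model is applied across
#' datasets.
#'
#' @param model a `DependencyModel`.
#' @param x,y,z equal-length finite numeric vectors.
#' @return List with `r_squared`, `r_squared_regression`, `sse`, `n_bins`.
#'   If `Z` or `z` has zero variance, the correlation-based value is `NA`.
#' @export
goodness_of_fit <- function(model, x, y, z) {
  n <- length(z)
  if (length(x) != n || length(y) != n)
    dimension_error("x, y, z must have equal length")
  Z <- evaluate_dependency(model, x, y)
  sse <- sum((Z - z)^2)
  tss <- sum((z - mean(z))^2)
  r2_cor <- if (stats::sd(Z) > 0 && stats::sd(z) > 0)
    stats::cor(Z, z)^2 else NA_real_
  r2_reg <- if (tss > 0) 1 - sse / tss else NA_real_
  list(r_squared = r2_cor, r_squared_regression = r2_reg,
       sse = sse, n_bins = n)
}

#' @export
print.FitResult <- function(x, ...) {
  cat(sprintf("FitResult: n = %d bins, R^2 = %.4f, SSE = %.4g\n",
              x$n_bins, x$r_squared, x$sse))
  print(round(x$coefficients, 6))
  invisible(x)
}
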