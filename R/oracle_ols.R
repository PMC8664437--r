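# Brute-force nested-regression implementation of the same LOD score.
# Deliberately slow and transparent: one least-squares fit per trait-marker
# pair, used as the correctness oracle for the matrix-multiplication engine.

#' Ordinary least squares fit via QR
#'
#' @param y Numeric response vector.
#' @param X Design matrix (full column rank), same number of rows as `y`.
#' @return An `ols_fit`: list with `coefficients`, `residuals`, `rss`,
#'   `sigma2` (`rss/n`) and `n_obs`.
#' @export
fit_ols <- function(y, X) {
  stopifnot(is.numeric(y), is.matrix(X), length(y) == nrow(X))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("design matrix is rank deficient")
  beta <- qr.coef(qrX, y)
  res <- qr.resid(qrX, y)
  rss <- sum(res^2)
  structure(list(coefficients = beta, residuals = res, rss = rss,
                 sigma2 = rss / length(y), n_obs = length(y)),
            class = "ols_fit")
}

#' Single-pair LOD score from nested regressions
#'
#' Fits the null model (intercept, plus covariates if given) and the full
#' model (adding the marker), and returns `(n/2) * log10(rss0 / rss1)`. The
#' perfect-fit edge (`rss1` near 0) is clamped consistently with the scan
#' engine's `r2_clamp` so both paths agree everywhere.
#'
#' @param y Trait vector.
#' @param g Marker dosage vector.
#' @param Z Optional covariate matrix including the intercept; default
#'   intercept only.
#' @param r2_clamp Clamp applied to `1 - rss1/rss0` (default `1 - 1e-12`).
#' @return A `nested_lod`: list with `rss0`, `rss1` and `lod`.
#' @export
lod_ols <- function(y, g, Z = NULL, r2_clamp = 1 - 1e-12) {
  n <- length(y)
  stopifnot(length(g) == n)
  X0 <- if (is.null(Z)) matrix(1, n, 1) else unclass(as.matrix(Z))
  stopifnot(nrow(X0) == n)
  X1 <- cbind(X0, g)
  if (qr(X1)$rank < ncol(X1))
    stop("marker is collinear with the covariates")
  rss0 <- fit_ols(y, X0)$rss
  rss1 <- fit_ols(y, X1)$rss
  if (rss0 <= 0) {
    lod <- 0  # y constant under null model: no variance to explain
  } else {
    # clamp via the partial r2 so the edge matches lod_from_r2
    r2 <- min(max(1 - rss1 / rss0, 0), r2_clamp)
    lod <- -(n / 2) * log10(1 - r2)
  }
  structure(list(rss0 = rss0, rss1 = rss1, lod = lod, n_obs = n),
            class = "nested_lod")
}

#' Brute-force LOD matrix by an explicit double loop
#'
#' Entry `(i, j)` is `lod_ols(y_i, g_j, Z)$lod`. Guarded to small problems
#' (`m * p <= 1e6`): this is the oracle, not the engine.
#'
#' @param traits A `trait_matrix` or plain strains x traits matrix.
#' @param geno A `genotype_matrix` or plain strains x markers matrix.
#' @param Z Optional covariate matrix including the intercept.
#' @param r2_clamp Perfect-fit clamp, matching the scan engine.
#' @return Numeric matrix, traits x markers, of LOD scores.
#' @export
brute_scan <- function(traits, geno, Z = NULL, r2_clamp = 1 - 1e-12) {
  Y <- if (inherits(traits, "trait_matrix")) traits$values else as.matrix(traits)
  G <- if (inherits(geno, "genotype_matrix")) geno$dosage else as.matrix(geno)
  stopifnot(nrow(Y) == nrow(G))
  m <- ncol(Y); p <- ncol(G)
  if (as.double(m) * p > 1e6)
    stop("brute_scan guard: m * p = ", m * p,
         " > 1e6; use scan_eqtl() for problems this size")
  n <- nrow(Y)
  X0 <- if (is.null(Z)) matrix(1, n, 1) else unclass(as.matrix(Z))
  out <- matrix(NA_real_, m, p, dimnames = list(colnames(Y), colnames(G)))
  qr0 <- qr(X0)
  for (i in seq_len(m)) {
    y <- Y[, i]
    rss0 <- fit_ols(y, X0)$rss
    for (j in seq_len(p)) {
      g <- G[, j]
      # a marker collinear with the null design adds nothing: LOD 0,
      # matching the scan engine's zero-correlation convention
      if (sum(qr.resid(qr0, g)^2) <= 1e-20 * sum(g^2)) {
        out[i, j] <- 0
        next
      }
      X1 <- cbind(X0, g)
      rss1 <- fit_ols(y, X1)$rss
      out[i, j] <- if (rss0 <= 0) 0 else {
        r2 <- min(max(1 - rss1 / rss0, 0), r2_clamp)
        -(n / 2) * log10(1 - r2)
      }
    }
  }
  out
}
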