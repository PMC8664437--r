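# Scan engine: standardize -> (project) -> cross-product correlations ->
# element-wise LOD, with per-trait max reduction, MAF filter, trait chunking
# and a selectable floating-point precision.

#' Scan configuration
#'
#' @param precision `"double"` (default) or `"single"`. Single precision runs
#'   the standardize/multiply/LOD kernel in 32-bit floats; see the package
#'   vignette for the accuracy trade-off.
#' @param output_mode `"max"` (default; per-trait peak table, the full LOD
#'   matrix is never materialized) or `"full"` (traits x markers matrix).
#' @param maf_threshold Minor-allele-frequency threshold in `[0, 0.5]`;
#'   markers with MAF below it are removed before scanning. Default 0.05.
#' @param lod_report_threshold Peaks with LOD below this are still reported;
#'   the threshold is carried along for plotting/filtering. Default 0.
#' @param trait_chunk Number of trait columns processed per block; the peak
#'   table is invariant to this. Default 10000.
#' @param r2_clamp Squared correlations are clamped at this value before the
#'   log so perfect fits give a large finite LOD. Default `1 - 1e-12`.
#' @param backend Function `(Ys, Gs) -> crossprod(Ys, Gs)` used for the dense
#'   double-precision cross-product, replaceable so an accelerator backend
#'   can be plugged in. Default [base::crossprod()].
#' @return A `scan_config` list.
#' @export
scan_config <- function(precision = c("double", "single"),
                        output_mode = c("max", "full"),
                        maf_threshold = 0.05,
                        lod_report_threshold = 0,
                        trait_chunk = 10000L,
                        r2_clamp = 1 - 1e-12,
                        backend = crossprod) {
  precision <- match.arg(precision)
  output_mode <- match.arg(output_mode)
  stopifnot(is.numeric(maf_threshold), length(maf_threshold) == 1L,
            maf_threshold >= 0, maf_threshold <= 0.5,
            is.numeric(lod_report_threshold), lod_report_threshold >= 0,
            is.numeric(r2_clamp), r2_clamp > 0, r2_clamp <= 1,
            is.function(backend))
  trait_chunk <- as.integer(trait_chunk)
  if (is.na(trait_chunk) || trait_chunk < 1L) stop("trait_chunk must be >= 1")
  structure(list(precision = precision, output_mode = output_mode,
                 maf_threshold = maf_threshold,
                 lod_report_threshold = lod_report_threshold,
                 trait_chunk = trait_chunk, r2_clamp = r2_clamp,
                 backend = backend),
            class = "scan_config")
}

#' Center and scale matrix columns for correlation by cross-product
#'
#' Columns are centered and scaled so the population variance is 1
#' (`(1/n) * sum(z^2) == 1`); the cross-product of two such matrices divided
#' by `n` is then exactly the Pearson correlation matrix. Constant
#' (zero-variance) columns are set to all zeros and flagged in the mask, so
#' they yield correlation 0 rather than NaN.
#'
#' @param M Numeric matrix (observations x variables), no missing values.
#' @return A `standardized_matrix`: list with `values`, `n_obs`, and
#'   `constant_mask` (logical per column).
#' @export
standardize_columns <- function(M) {
  stopifnot(is.matrix(M), is.numeric(M))
  n <- nrow(M)
  if (n < 3L) stop("need at least 3 observations to standardize")
  if (anyNA(M))
    stop("matrix contains missing values; run drop_incomplete() first")
  mu <- colMeans(M)
  Z <- sweep(M, 2L, mu, "-")
  ss <- colSums(Z^2)
  sd_pop <- sqrt(ss / n)
  const <- sd_pop <= 1e-12 * pmax(abs(mu), 1)
  sd_pop[const] <- 1
  Z <- sweep(Z, 2L, sd_pop, "/")
  Z[, const] <- 0
  structure(list(values = Z, n_obs = n, constant_mask = const),
            class = "standardized_matrix")
}

#' Build a covariate projection context
#'
#' Holds the QR decomposition of the covariate matrix `Z` (intercept
#' included) so that the orthogonal projection `P = I - Z (Z'Z)^{-1} Z'` can
#' be applied to any conformable matrix as least-squares residuals, without
#' ever forming the n x n projector.
#'
#' @param Z A `covariate_matrix` (or plain full-rank numeric matrix whose
#'   first column is the intercept).
#' @return A `projection_context`.
#' @export
new_projection <- function(Z) {
  if (!inherits(Z, "covariate_matrix")) Z <- new_covariate_matrix(as.matrix(Z))
  qrZ <- qr(unclass(Z))
  if (qrZ$rank < ncol(Z)) {
    dep <- setdiff(seq_len(ncol(Z)), qrZ$pivot[seq_len(qrZ$rank)])
    stop("rank-deficient covariates; dependent column(s): ",
         paste(colnames(Z)[dep], collapse = ", "))
  }
  structure(list(Z = Z, qr = qrZ, n_obs = nrow(Z)),
            class = "projection_context")
}

#' Project a matrix onto the orthogonal complement of the covariate space
#'
#' Returns `P %*% M` computed as the residuals of regressing each column of
#' `M` on the covariates.
#'
#' @param M Numeric matrix with as many rows as the covariate matrix.
#' @param ctx A `projection_context` from [new_projection()].
#' @return Numeric matrix of residuals, same shape as `M`.
#' @export
residualize <- function(M, ctx) {
  stopifnot(inherits(ctx, "projection_context"), is.matrix(M))
  if (nrow(M) != ctx$n_obs)
    stop("row count of M (", nrow(M), ") does not match covariates (",
         ctx$n_obs, ")")
  R <- qr.resid(ctx$qr, M)
  dimnames(R) <- dimnames(M)
  R
}

#' Bulk Pearson correlations of two standardized matrices
#'
#' Computes `R = (1/n) * t(Ys) %*% Gs` for column-standardized inputs; in
#' single precision the cross-product runs in 32-bit floats. Masked
#' (constant) columns give exactly 0.
#'
#' @param Ys,Gs `standardized_matrix` objects sharing `n_obs`.
#' @param precision `"double"` or `"single"`.
#' @param backend Cross-product function for the double path (see
#'   [scan_config()]).
#' @return A `correlation_block`: list with `r` (traits x markers matrix) and
#'   `n_obs`.
#' @export
correlation_scan <- function(Ys, Gs, precision = "double",
                             backend = crossprod) {
  stopifnot(inherits(Ys, "standardized_matrix"),
            inherits(Gs, "standardized_matrix"))
  if (Ys$n_obs != Gs$n_obs || nrow(Ys$values) != nrow(Gs$values))
    stop("dimension mismatch: Ys has n = ", Ys$n_obs, ", Gs has n = ", Gs$n_obs)
  n <- Ys$n_obs
  r <- if (precision == "single") {
    crossprod_float(Ys$values, Gs$values) / n
  } else {
    backend(Ys$values, Gs$values) / n
  }
  if (any(Ys$constant_mask)) r[Ys$constant_mask, ] <- 0
  if (any(Gs$constant_mask)) r[, Gs$constant_mask] <- 0
  structure(list(r = r, n_obs = n), class = "correlation_block")
}

#' LOD score from a squared correlation
#'
#' The one-degree-of-freedom LOD for a trait-marker pair with Pearson
#' correlation `r` over `n` observations is `-(n/2) * log10(1 - r^2)`,
#' algebraically identical to `(n/2) * log10(RSS0/RSS1)` for the nested
#' linear models with and without the marker. `r^2` is clamped below 1 so
#' perfect fits stay finite.
#'
#' @param r2 Numeric vector/matrix of squared correlations in `[0, 1]`.
#' @param n Sample size (>= 3).
#' @param r2_clamp Clamp value (default `1 - 1e-12`).
#' @return LOD scores, same shape as `r2`; non-negative and finite.
#' @export
lod_from_r2 <- function(r2, n, r2_clamp = 1 - 1e-12) {
  stopifnot(is.numeric(r2), is.numeric(n), length(n) == 1L, n >= 3)
  if (any(r2 < -1e-8 | r2 > 1 + 1e-8))
    stop("r2 outside [0, 1]: range ", paste(signif(range(r2), 6), collapse = " .. "))
  r2 <- pmin(pmax(r2, 0), r2_clamp)
  -(n / 2) * log10(1 - r2)
}

#' Filter markers by minor allele frequency
#'
#' The allele frequency of a marker is its mean dosage `f`; the marker is
#' kept iff `min(f, 1 - f) >= threshold`.
#'
#' @param geno A `genotype_matrix` with complete dosages in `[0, 1]`.
#' @param threshold MAF threshold in `[0, 0.5]` (default 0.05).
#' @return List with `geno` (filtered) and `kept` (integer indices of the
#'   retained markers in the input order).
#' @export
maf_filter <- function(geno, threshold = 0.05) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 0.5)
    stop("maf threshold must be in [0, 0.5]")
  if (anyNA(geno$dosage))
    stop("genotypes contain missing values; run drop_incomplete() first")
  f <- colMeans(geno$dosage)
  keep <- pmin(f, 1 - f) >= threshold
  if (!any(keep)) stop("no markers survive MAF filter at threshold ", threshold)
  kept <- which(keep)
  geno$dosage <- geno$dosage[, kept, drop = FALSE]
  geno$map <- geno$map[kept, , drop = FALSE]
  list(geno = geno, kept = kept)
}

#' Genome-wide eQTL scan by matrix multiplication
#'
#' The full pipeline: MAF-filter the markers, residualize genotypes and
#' traits on the covariates (if any), standardize the columns of both, then
#' for each chunk of traits take the cross-product to get a block of Pearson
#' correlations and transform it element-wise to LOD scores. In `"max"` mode
#' only each trait's best marker and score are kept and the block is
#' discarded; in `"full"` mode the complete traits x markers matrix is
#' assembled. Results are invariant to the chunk size; argmax ties go to the
#' lowest marker index.
#'
#' The `n` in the LOD formula is the aligned sample size and is not reduced
#' by the number of covariates, matching the correlation-based definition of
#' the score (this differs from an F-test's residual degrees of freedom).
#'
#' @param geno A `genotype_matrix` (aligned, complete).
#' @param traits A `trait_matrix` (aligned, complete).
#' @param covariates Optional `covariate_matrix` (aligned; intercept
#'   included).
#' @param config A [scan_config()].
#' @return A `lod_result`: list with `n_obs`, `config`, `map` (the retained
#'   markers), and either `peaks` (data.frame `trait_id`, `marker_index`,
#'   `marker_id`, `chromosome`, `position_cM`, `lod`) or `lod` (full
#'   matrix).
#' @export
scan_eqtl <- function(geno, traits, covariates = NULL, config = scan_config()) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(traits, "trait_matrix"),
            inherits(config, "scan_config"))
  if (!identical(geno$strain_ids, traits$strain_ids))
    stop("geno and traits are not aligned; run align_strains() first")
  if (anyNA(traits$values))
    stop("traits contain missing values; run drop_incomplete() first")
  n <- nrow(geno$dosage)
  if (n < 3L) stop("need at least 3 strains")

  mf <- maf_filter(geno, config$maf_threshold)
  G <- mf$geno$dosage
  Y <- traits$values
  map <- mf$geno$map

  ctx <- NULL
  if (!is.null(covariates)) {
    if (!identical(rownames(covariates), geno$strain_ids))
      stop("covariates are not aligned; run align_strains() first")
    ctx <- new_projection(covariates)
    G <- residualize(G, ctx)
    Y <- residualize(Y, ctx)
  }

  Gs <- standardize_columns(G)
  m <- ncol(Y)
  p <- ncol(G)
  chunk <- config$trait_chunk
  starts <- seq(1L, m, by = chunk)

  if (config$output_mode == "full") {
    lod <- matrix(NA_real_, m, p, dimnames = list(colnames(Y), colnames(G)))
  } else {
    peak_idx <- integer(m)
    peak_lod <- numeric(m)
  }

  for (s in starts) {
    idx <- s:min(s + chunk - 1L, m)
    Ys <- standardize_columns(Y[, idx, drop = FALSE])
    if (config$precision == "single") {
      block <- lod_block_float(Ys$values, Gs$values, config$r2_clamp)
      if (any(Ys$constant_mask)) block[Ys$constant_mask, ] <- 0
      if (any(Gs$constant_mask)) block[, Gs$constant_mask] <- 0
    } else {
      cb <- correlation_scan(Ys, Gs, precision = "double",
                             backend = config$backend)
      block <- lod_from_r2(cb$r^2, n, config$r2_clamp)
    }
    if (config$output_mode == "full") {
      lod[idx, ] <- block
    } else {
      peak_idx[idx] <- apply(block, 1L, which.max)   # first max: lowest index
      peak_lod[idx] <- block[cbind(seq_len(nrow(block)), peak_idx[idx])]
    }
  }

  out <- list(n_obs = n, config = config, map = map)
  if (config$output_mode == "full") {
    out$lod <- lod
  } else {
    out$peaks <- data.frame(trait_id = colnames(Y),
                            marker_index = peak_idx,
                            marker_id = map$marker[peak_idx],
                            chromosome = map$chr[peak_idx],
                            position_cM = map$cM[peak_idx],
                            lod = peak_lod,
                            stringsAsFactors = FALSE)
  }
  structure(out, class = "lod_result")
}

#' @export
print.lod_result <- function(x, ...) {
  if (!is.null(x$lod)) {
    cat("<lod_result> full LOD matrix: ", nrow(x$lod), " traits x ",
        ncol(x$lod), " markers (n = ", x$n_obs, ")\n", sep = "")
  } else {
    cat("<lod_result> peaks for ", nrow(x$peaks), " traits (n = ", x$n_obs,
        "); max LOD = ", signif(max(x$peaks$lod), 4), "\n", sep = "")
  }
  invisible(x)
}
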