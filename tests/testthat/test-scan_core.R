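# Scan engine: standardization, projection, bulk correlation, LOD transform,
# MAF filter, chunked scan with max reduction.

test_that("standardize_columns centers and scales to population variance 1", {
  M <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  s <- standardize_columns(M)
  expect_equal(unname(s$values[, "a"]), c(-1.224745, 0, 1.224745),
               tolerance = 1e-6)
  expect_equal(unname(s$values[, "b"]), c(0, 0, 0))
  expect_equal(unname(s$constant_mask), c(FALSE, TRUE))
  # invariants on a random matrix
  Z <- standardize_columns(random_matrix(50, 8, seed = 3))$values
  expect_lt(max(abs(colMeans(Z))), 1e-10)
  expect_equal(unname(colSums(Z^2) / 50), rep(1, 8), tolerance = 1e-10)
  # idempotence
  expect_equal(standardize_columns(Z)$values, Z, tolerance = 1e-12)
})

test_that("standardize_columns demands complete data and n >= 3", {
  M <- random_matrix(10, 2)
  M[1, 1] <- NA
  expect_error(standardize_columns(M), "drop_incomplete")
  expect_error(standardize_columns(random_matrix(2, 2)), "at least 3")
})

test_that("residualize equals the explicit projector and annihilates Z", {
  set.seed(42)
  n <- 8
  Z <- new_covariate_matrix(cbind(matrix(rnorm(n), n, 1,
                                         dimnames = list(paste0("s", 1:n), "x"))))
  ctx <- new_projection(Z)
  M <- matrix(rnorm(n * 3), n, 3)
  P <- diag(n) - unclass(Z) %*% solve(crossprod(Z)) %*% t(unclass(Z))
  expect_equal(residualize(M, ctx), P %*% M, tolerance = 1e-10,
               ignore_attr = TRUE)
  # PZ = 0 and idempotence
  expect_lt(max(abs(residualize(unclass(Z), ctx))), 1e-10)
  R1 <- residualize(M, ctx)
  expect_equal(residualize(R1, ctx), R1, tolerance = 1e-10)
})

test_that("projection on the intercept alone is column centering", {
  n <- 12
  Z <- new_covariate_matrix(matrix(numeric(0), n, 0,
                                   dimnames = list(paste0("s", 1:n), NULL)))
  M <- random_matrix(n, 4, seed = 9)
  expect_equal(residualize(M, new_projection(Z)),
               sweep(M, 2, colMeans(M)), tolerance = 1e-10)
})

test_that("rank-deficient covariates are rejected by name", {
  n <- 10
  x <- rnorm(n)
  Z <- cbind(x = x, x2 = 2 * x)
  rownames(Z) <- paste0("s", 1:n)
  expect_error(new_covariate_matrix(Z), "rank deficient.*x2")
})

test_that("correlation_scan reproduces pairwise Pearson correlation", {
  Ys <- standardize_columns(random_matrix(10, 4, seed = 1))
  Gs <- standardize_columns(random_matrix(10, 6, seed = 2))
  cb <- correlation_scan(Ys, Gs)
  oracle <- cor(random_matrix(10, 4, seed = 1), random_matrix(10, 6, seed = 2))
  expect_equal(cb$r, oracle, tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(abs(cb$r) <= 1 + 1e-8))
})

test_that("correlation_scan hits +-1 on (anti)duplicated columns and 0 on masked", {
  g <- c(0, 1, 0, 1, 1, 0)
  M <- cbind(t1 = g, t2 = -g, t3 = rep(2, 6))
  Ys <- standardize_columns(M)
  Gs <- standardize_columns(cbind(m1 = g))
  r <- correlation_scan(Ys, Gs)$r
  expect_equal(unname(r[, 1]), c(1, -1, 0), tolerance = 1e-12)
  expect_error(correlation_scan(Ys, standardize_columns(random_matrix(5, 2))),
               "dimension mismatch")
})

test_that("lod_from_r2 matches closed forms and stays finite", {
  expect_equal(lod_from_r2(0, 10), 0)
  expect_equal(lod_from_r2(0.9, 10), 5)                      # log10(0.1) = -1
  expect_equal(lod_from_r2(0.5, 20), 3.010300, tolerance = 1e-6)
  expect_true(is.finite(lod_from_r2(1, 100)))                # clamped
  expect_error(lod_from_r2(1.1, 10), "outside")
  expect_error(lod_from_r2(-0.2, 10), "outside")
})

test_that("lod_from_r2 is monotone in r2 and in n", {
  r2 <- seq(0, 1 - 1e-12, length.out = 200)
  lods <- lod_from_r2(r2, 30)
  expect_true(all(diff(lods) > 0))
  ns <- c(3, 10, 50, 200, 1000)
  expect_true(all(diff(vapply(ns, function(n) lod_from_r2(0.3, n), 1)) > 0))
})

test_that("maf_filter keeps markers by min(f, 1-f) >= threshold", {
  n <- 79
  d <- cbind(mono = rep(0, n),
             rare = c(rep(1, 3), rep(0, n - 3)),   # f = 3/79 = 0.038 < 0.05
             common = c(rep(1, 40), rep(0, n - 40)))
  g <- geno_from_matrix(d)
  out <- maf_filter(g, 0.05)
  expect_equal(out$kept, 3L, ignore_attr = TRUE)
  expect_equal(colnames(out$geno$dosage), "m3")
  # threshold 0 keeps everything
  expect_equal(maf_filter(g, 0)$kept, 1:3, ignore_attr = TRUE)
  expect_error(maf_filter(g, 0.6), "\\[0, 0.5\\]")
  expect_error(maf_filter(geno_from_matrix(cbind(a = rep(0, 10))), 0.05),
               "no markers survive")
})

test_that("scan_eqtl finds a trait's own marker", {
  panel <- tiny_panel(n_strains = 60, n_traits = 4, prop_with_qtl = 0)
  g <- panel$geno
  set.seed(5)
  y <- g$dosage[, 7] + rnorm(60, sd = 0.01)
  Y <- panel$traits$values
  Y[, 1] <- y
  tm <- new_trait_matrix(Y)
  res <- scan_eqtl(g, tm)
  hit <- res$peaks$marker_index[1]
  # the peak is marker 7 or one effectively collinear with it
  expect_gt(abs(cor(g$dosage[, hit], g$dosage[, 7])), 0.999)
})

test_that("peaks are invariant to trait chunking", {
  panel <- tiny_panel(n_strains = 40, n_traits = 23)
  ref <- scan_eqtl(panel$geno, panel$traits,
                   config = scan_config(trait_chunk = 10000))
  for (chunk in c(1, 7)) {
    alt <- scan_eqtl(panel$geno, panel$traits,
                     config = scan_config(trait_chunk = chunk))
    expect_identical(alt$peaks$marker_index, ref$peaks$marker_index)
    # BLAS kernels differ by block shape, so only last-bit fp wiggle allowed
    expect_lt(max(abs(alt$peaks$lod - ref$peaks$lod)), 1e-10)
  }
})

test_that("max mode equals the row-wise max/argmax of full mode", {
  panel <- tiny_panel(n_strains = 50, n_traits = 30, seed = 3)
  pk <- scan_eqtl(panel$geno, panel$traits)$peaks
  full <- scan_eqtl(panel$geno, panel$traits,
                    config = scan_config(output_mode = "full"))$lod
  expect_equal(pk$lod, unname(apply(full, 1, max)))
  expect_equal(pk$marker_index, unname(apply(full, 1, which.max)))
})

test_that("intercept-only covariates leave the LOD matrix unchanged", {
  panel <- tiny_panel(n_strains = 30, n_traits = 10, seed = 8)
  Z <- new_covariate_matrix(
    matrix(numeric(0), 30, 0, dimnames = list(panel$geno$strain_ids, NULL)))
  plain <- scan_eqtl(panel$geno, panel$traits,
                     config = scan_config(output_mode = "full"))$lod
  withz <- scan_eqtl(panel$geno, panel$traits, covariates = Z,
                     config = scan_config(output_mode = "full"))$lod
  expect_equal(withz, plain, tolerance = 1e-10)
})

test_that("LOD scores are invariant to affine rescaling of traits", {
  panel <- tiny_panel(n_strains = 30, n_traits = 8, seed = 13)
  ref <- scan_eqtl(panel$geno, panel$traits,
                   config = scan_config(output_mode = "full"))$lod
  Y2 <- sweep(panel$traits$values, 2, c(rep(3.7, 4), rep(0.02, 4)), "*") + 11
  alt <- scan_eqtl(panel$geno, new_trait_matrix(Y2),
                   config = scan_config(output_mode = "full"))$lod
  expect_equal(alt, ref, tolerance = 1e-10)
})

test_that("single precision tracks double precision closely", {
  panel <- tiny_panel(n_strains = 80, n_chromosomes = 5, n_traits = 60,
                      seed = 17)
  dbl <- scan_eqtl(panel$geno, panel$traits,
                   config = scan_config(output_mode = "full"))$lod
  sng <- scan_eqtl(panel$geno, panel$traits,
                   config = scan_config(output_mode = "full",
                                        precision = "single"))$lod
  sel <- dbl <= 25
  expect_lt(max(abs(sng[sel] - dbl[sel])), 1e-3)
})

test_that("scan_eqtl validates its inputs", {
  panel <- tiny_panel(n_strains = 20, n_traits = 4)
  Y <- panel$traits$values
  Y[1, 1] <- NA
  expect_error(scan_eqtl(panel$geno, new_trait_matrix(Y)), "drop_incomplete")
  expect_error(scan_config(trait_chunk = 0), "trait_chunk")
  tm2 <- panel$traits
  tm2$values <- tm2$values[c(2, 1, 3:20), ]
  tm2$strain_ids <- rownames(tm2$values)
  expect_error(scan_eqtl(panel$geno, tm2), "not aligned")
})
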