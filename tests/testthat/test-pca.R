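test_that("build_psi matches hand evaluation", {
  # J=2, K=1: w = (0.1/0.05, 0.2/0.1) = (2, 2); rho12 = 0.5
  s <- summary_data(c("a", "b"), matrix(c(0.1, 0.2)), matrix(0.01, 2, 1),
                    c(0, 0), c(0.05, 0.1))
  ld <- ld_matrix(matrix(c(1, 0.5, 0.5, 1), 2, 2), c("a", "b"))
  expect_equal(unname(build_psi(s, ld)), matrix(c(4, 2, 2, 4), 2, 2),
               tolerance = 1e-12)

  # J = 1 scalar case
  s1 <- summary_data("a", matrix(c(0.1, 0.3), 1, 2), matrix(0.01, 1, 2),
                     0, 0.2)
  expect_equal(unname(build_psi(s1)), matrix((0.4 / 0.2)^2), tolerance = 1e-12)

  # identity LD decouples variants: diagonal entries w_j^2
  set.seed(30)
  s <- random_summary(5, 2)
  psi <- build_psi(s)
  w <- rowSums(abs(s$beta_exposures)) / s$se_outcome
  expect_equal(unname(psi), diag(w^2), tolerance = 1e-12)
})

test_that("Psi is PSD whenever rho is PSD", {
  set.seed(31)
  for (i in 1:10) {
    J <- sample(3:12, 1)
    s <- random_summary(J, 2)
    ld <- ld_matrix(random_corr(J), s$variant_ids)
    ev <- eigen(build_psi(s, ld), symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * max(ev))
  }
})

test_that("select_components: threshold rule on the raw spectrum", {
  t1 <- select_components(diag(c(99, 1)), 0.99)
  expect_equal(t1$k, 1L)
  # cumulative proportions 0.6, 0.9, 0.99, 1 -> k = 3 (boundary included)
  t2 <- select_components(diag(c(0.6, 0.3, 0.09, 0.01)), 0.99)
  expect_equal(t2$k, 3L)
  # total variance keeps the complete basis
  psi <- crossprod(matrix(rnorm(25), 5, 5)) + diag(5)
  expect_equal(select_components(psi, 1)$k, 5L)
  expect_error(select_components(matrix(0, 3, 3)), "no signal")
  expect_error(select_components(psi, 0), "var_threshold")
})

test_that("select_components: centered convention and orthonormal loadings", {
  set.seed(32)
  s <- random_summary(10, 2)
  ld <- ld_matrix(random_corr(10), s$variant_ids)
  psi <- build_psi(s, ld)
  for (center in c(FALSE, TRUE)) {
    tr <- select_components(psi, 0.99, center = center)
    W <- tr$loadings
    expect_equal(unname(crossprod(W)), diag(tr$k), tolerance = 1e-10)
    expect_gte(tr$variance_explained, 0.99 - 1e-10)
    # sign convention: largest-magnitude loading positive
    for (j in seq_len(ncol(W)))
      expect_gt(W[which.max(abs(W[, j])), j], 0)
  }
  expect_equal(select_components(psi, 1, center = TRUE)$k, 10L)
})

test_that("retained count is monotone in the variance threshold", {
  set.seed(33)
  psi <- build_psi(random_summary(12, 3),
                   ld_matrix(random_corr(12)))
  for (center in c(FALSE, TRUE)) {
    ks <- vapply(c(0.5, 0.8, 0.9, 0.99, 0.999, 1),
                 function(v) select_components(psi, v, center = center)$k, 1L)
    expect_true(all(diff(ks) >= 0))
  }
})

test_that("transform_summary is the stated matrix algebra", {
  set.seed(34)
  s <- random_summary(6, 2)
  ld <- ld_matrix(random_corr(6), s$variant_ids)
  # identity transform leaves everything unchanged
  id <- structure(list(loadings = diag(6), eigenvalues = rep(1, 6), k = 6L,
                       variance_explained = 1, center = FALSE),
                  class = "pca_transform")
  tr <- transform_summary(s, ld, id)
  expect_equal(unname(tr$beta_exposures), unname(s$beta_exposures))
  expect_equal(unname(tr$beta_outcome), unname(s$beta_outcome))
  expect_equal(tr$sigma, ld$rho * tcrossprod(s$se_outcome),
               ignore_attr = TRUE)

  # k < J projection: direct product oracle + trace contraction
  tr3 <- select_components(build_psi(s, ld), 0.8)
  W <- tr3$loadings
  out <- transform_summary(s, ld, tr3)
  sigma <- ld$rho * tcrossprod(s$se_outcome)
  expect_equal(out$beta_exposures, t(W) %*% s$beta_exposures,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(out$beta_outcome, drop(t(W) %*% s$beta_outcome),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(out$sigma, t(W) %*% sigma %*% W, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_lte(sum(diag(out$sigma)), sum(diag(sigma)) + 1e-12)
})

test_that("PCA estimators with 100% variance equal their counterparts", {
  set.seed(35)
  s <- random_summary(9, 2)
  ld <- ld_matrix(random_corr(9), s$variant_ids)
  ivw <- suppressWarnings(mv_ivw(s, ld))
  liml <- suppressWarnings(mv_liml(s, ld))
  for (center in c(FALSE, TRUE)) {
    fp <- suppressWarnings(mv_ivw_pca(s, ld, var_threshold = 1,
                                      pre_prune = NULL, center = center))
    expect_equal(fp$theta, ivw$theta, tolerance = 1e-8)
    expect_equal(fp$se, ivw$se, tolerance = 1e-8)
    lp <- suppressWarnings(mv_liml_pca(s, ld, var_threshold = 1,
                                       pre_prune = NULL, center = center))
    expect_equal(lp$theta, liml$theta, tolerance = 1e-6)
    expect_equal(lp$se, liml$se, tolerance = 1e-6)
  }
})

test_that("mv_liml_pca recovers noiseless truth with zero objective", {
  set.seed(36)
  theta <- c(0.4, -0.6)
  s <- consistent_summary(10, 2, theta)
  ld <- ld_matrix(random_corr(10), s$variant_ids)
  f <- suppressWarnings(mv_liml_pca(s, ld, pre_prune = NULL))
  expect_equal(unname(f$theta), theta, tolerance = 1e-4)
  expect_lt(f$objective_value, 1e-6)
})

test_that("outcome orthogonal to retained components gives a zero estimate", {
  set.seed(37)
  s <- random_summary(10, 2)
  ld <- ld_matrix(random_corr(10), s$variant_ids)
  tr <- select_components(build_psi(s, ld), 0.8)
  W <- tr$loadings
  stopifnot(tr$k < 10)
  z <- rnorm(10)
  by_perp <- drop(z - W %*% crossprod(W, z))     # in the orthocomplement
  s2 <- summary_data(s$variant_ids, s$beta_exposures, s$se_exposures,
                     by_perp, s$se_outcome, s$trait_names)
  out <- transform_summary(s2, ld, tr)
  expect_lt(max(abs(out$beta_outcome)), 1e-10)
  fit <- mvmrpca:::gls_fit(out$beta_exposures, out$beta_outcome, out$sigma)
  expect_lt(max(abs(fit$theta)), 1e-8)
})

test_that("PCA succeeds where Sigma is beyond the conditioning ceiling", {
  set.seed(38)
  J <- 12
  base <- random_corr(J - 2)
  # append two near-duplicates of variant 1 (|rho| ~ 1 - 1e-14)
  rho <- matrix(0, J, J)
  rho[1:(J - 2), 1:(J - 2)] <- base
  for (d in (J - 1):J) {
    rho[d, ] <- rho[1, ]; rho[, d] <- rho[, 1]
    rho[d, d] <- 1
  }
  rho[J - 1, J] <- rho[J, J - 1] <- 1 - 1e-14
  rho[1, (J - 1):J] <- rho[(J - 1):J, 1] <- 1 - 1e-14
  s <- random_summary(J, 2)
  s$beta_exposures[(J - 1):J, ] <- s$beta_exposures[1, ]  # coherent dupes
  ld <- ld_matrix(rho, s$variant_ids, psd_tol = 1e-4)
  expect_error(suppressWarnings(mv_ivw(s, ld)), "ceiling|singular")
  f <- suppressWarnings(mv_ivw_pca(s, ld))    # pre-prune removes duplicates
  expect_true(is.finite(f$condition_number))
  expect_lt(f$condition_number, 1e12)
})

test_that("too-low variance threshold raises an identification error", {
  set.seed(39)
  s <- random_summary(8, 3)
  ld <- ld_matrix(random_corr(8), s$variant_ids)
  expect_error(mv_ivw_pca(s, ld, var_threshold = 1e-6),
               "increase var_threshold")
})

test_that("write_pca_spectrum emits one row per component", {
  set.seed(40)
  tr <- select_components(build_psi(random_summary(6, 2)), 0.9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pca_spectrum(tr, path)
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(df), 6)
  expect_equal(sum(df$retained), tr$k)
})
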