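test_that("condition_number matches the eigenvalue-ratio oracle", {
  expect_equal(condition_number(diag(5)), 1)
  expect_equal(condition_number(matrix(c(1, 0.8, 0.8, 1), 2, 2)), 9,
               tolerance = 1e-12)
  set.seed(2)
  for (i in 1:5) {
    m <- crossprod(matrix(rnorm(100), 10, 10)) + diag(10)
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(condition_number(m), max(ev) / min(ev), tolerance = 1e-10)
  }
  expect_error(condition_number(matrix(1, 2, 3)), "square")
  expect_equal(condition_number(matrix(c(1, 1, 1, 1), 2, 2)), Inf)
})

test_that("wald_pvalues definition and bounds", {
  expect_equal(wald_pvalues(0, 1), 1)
  expect_equal(wald_pvalues(1.959964, 1), 0.05, tolerance = 1e-6)
  # reported applied-analysis value: estimate 0.254, SE 0.089 -> p 0.004
  expect_equal(round(wald_pvalues(0.254, 0.089), 3), 0.004)
  expect_error(wald_pvalues(1, 0), "positive")
  p <- wald_pvalues(c(0, 50, -50), c(1, 1, 1))
  expect_true(all(p > 0 & p <= 1))
})

test_that("mv_ivw degenerate and noiseless cases", {
  # J = K = 1: ratio estimate through the GLS formula
  s <- summary_data("v1", matrix(2), matrix(0.1), 1, 1)
  f <- mv_ivw(s)
  expect_equal(unname(f$theta), 0.5)
  expect_equal(unname(f$se), 0.5)

  # consistent J=3, K=2 system is solved exactly
  s <- summary_data(paste0("v", 1:3),
                    rbind(c(1, 0), c(0, 1), c(1, 1)),
                    matrix(0.1, 3, 2),
                    c(0.4, -0.6, -0.2), rep(1, 3))
  f <- mv_ivw(s)
  expect_equal(unname(f$theta), c(0.4, -0.6), tolerance = 1e-12)
  expect_equal(f$n_instruments, 3)

  expect_error(mv_ivw(random_summary(2, 3)), "not identified")
})

test_that("mv_ivw agrees with an independent GLS solver to 1e-10", {
  set.seed(13)
  for (i in 1:10) {
    J <- sample(4:10, 1); K <- sample(2:3, 1)
    s <- random_summary(J, K)
    ld <- ld_matrix(random_corr(J), s$variant_ids)
    f <- suppressWarnings(mv_ivw(s, ld))
    sigma <- ld$rho * tcrossprod(s$se_outcome)
    o <- naive_gls(s$beta_exposures, s$beta_outcome, sigma)
    expect_equal(unname(f$theta), o$theta, tolerance = 1e-10)
    expect_equal(unname(f$se), o$se, tolerance = 1e-10)
  }
})

test_that("mv_ivw with identity LD equals weighted least squares", {
  set.seed(14)
  s <- random_summary(8, 2)
  f1 <- mv_ivw(s)                                   # ld = NULL
  f2 <- mv_ivw(s, ld_matrix(diag(8), s$variant_ids))
  w <- 1 / s$se_outcome^2
  xtwx <- t(s$beta_exposures) %*% (w * s$beta_exposures)
  v <- solve(xtwx)
  theta_wls <- unname(drop(v %*% t(s$beta_exposures) %*% (w * s$beta_outcome)))
  expect_equal(unname(f1$theta), theta_wls, tolerance = 1e-10)
  expect_equal(unname(f2$theta), theta_wls, tolerance = 1e-10)
  expect_equal(unname(f1$se), unname(sqrt(diag(v))), tolerance = 1e-10)
})

test_that("mv_ivw is equivariant to simultaneous variant reordering", {
  set.seed(15)
  s <- random_summary(7, 2)
  ld <- ld_matrix(random_corr(7), s$variant_ids)
  perm <- sample(7)
  f1 <- suppressWarnings(mv_ivw(s, ld))
  f2 <- suppressWarnings(mv_ivw(s[perm], ld[perm]))
  expect_equal(f1$theta, f2$theta, tolerance = 1e-10)
  expect_equal(f1$se, f2$se, tolerance = 1e-10)
})

test_that("estimators are scale-equivariant in each exposure column", {
  set.seed(16)
  s <- random_summary(8, 2)
  ld <- ld_matrix(random_corr(8), s$variant_ids)
  cc <- 3.7
  s2 <- summary_data(s$variant_ids,
                     s$beta_exposures %*% diag(c(cc, 1)),
                     s$se_exposures %*% diag(c(cc, 1)),
                     s$beta_outcome, s$se_outcome, s$trait_names)
  for (fit in list(mv_ivw, function(...) mv_liml(...))) {
    f1 <- suppressWarnings(fit(s, ld))
    f2 <- suppressWarnings(fit(s2, ld))
    expect_equal(unname(f2$theta), unname(f1$theta) / c(cc, 1),
                 tolerance = 1e-8)
    expect_equal(unname(f2$se), unname(f1$se) / c(cc, 1), tolerance = 1e-8)
  }
})

test_that("mv_liml: noiseless data gives theta* with Q = 0 (both routes)", {
  set.seed(17)
  theta <- c(0.5, -0.25)
  s <- consistent_summary(8, 2, theta)
  ld <- ld_matrix(random_corr(8), s$variant_ids)
  for (opt in c("irgls", "argmin")) {
    f <- suppressWarnings(mv_liml(s, ld, optimizer = opt))
    expect_equal(unname(f$theta), theta, tolerance = 1e-5)
    expect_lt(f$objective_value, 1e-8)
  }
})

test_that("mv_liml with (numerically) zero exposure SEs equals mv_ivw", {
  set.seed(18)
  s <- random_summary(8, 2)
  # exposure SEs small enough that their squares underflow to zero:
  # Omega(theta) == Sigma for every theta
  s0 <- summary_data(s$variant_ids, s$beta_exposures,
                     matrix(1e-200, 8, 2), s$beta_outcome, s$se_outcome,
                     s$trait_names)
  ld <- ld_matrix(random_corr(8), s$variant_ids)
  ivw <- suppressWarnings(mv_ivw(s0, ld))
  for (opt in c("irgls", "argmin")) {
    f <- suppressWarnings(mv_liml(s0, ld, optimizer = opt))
    expect_equal(f$theta, ivw$theta, tolerance = 1e-6)
    expect_equal(f$se, ivw$se, tolerance = 1e-6)
  }
})

test_that("argmin route never exceeds the IVW objective value", {
  set.seed(19)
  for (i in 1:5) {
    s <- random_summary(7, 2)
    ld <- ld_matrix(random_corr(7), s$variant_ids)
    ivw <- suppressWarnings(mv_ivw(s, ld))
    f <- suppressWarnings(mv_liml(s, ld, optimizer = "argmin"))
    obj <- mvmrpca:::make_liml_objective(
      s$beta_exposures, s$se_exposures, s$beta_outcome, s$se_outcome,
      ld$rho, diag(2), "two")
    expect_lte(f$objective_value, obj$Q(ivw$theta) + 1e-8)
  }
})

test_that("the as-printed four-SE weight matrix collapses LIML onto IVW", {
  set.seed(20)
  # GWAS-realistic magnitudes: exposure SEs of order 5e-3
  s <- random_summary(8, 2, se_scale = 0.005)
  ld <- ld_matrix(random_corr(8), s$variant_ids)
  ivw <- suppressWarnings(mv_ivw(s, ld))
  f4 <- suppressWarnings(mv_liml(s, ld, se_product = "four"))
  f2 <- suppressWarnings(mv_liml(s, ld, se_product = "two"))
  # the four-SE exposure term is ~se^4, numerically invisible next to Sigma
  expect_equal(f4$theta, ivw$theta, tolerance = 5e-3)
  # ... while the two-SE covariance perturbs the fit by far more
  expect_gt(max(abs(f2$se - ivw$se)), 100 * max(abs(f4$se - ivw$se)))
})

test_that("conditioning diagnostics: warning over 100, error over ceiling", {
  set.seed(21)
  s <- random_summary(4, 2)
  rho <- diag(4); rho[1, 2] <- rho[2, 1] <- 0.999
  ld <- ld_matrix(rho, s$variant_ids)
  expect_warning(mv_ivw(s, ld), "condition number")
  rho[1, 2] <- rho[2, 1] <- 1 - 1e-14
  ld2 <- ld_matrix(rho, s$variant_ids)
  expect_error(suppressWarnings(mv_ivw(s, ld2)), "ceiling|singular")
})

test_that("estimate container invariants and export shape", {
  set.seed(22)
  s <- random_summary(9, 3)
  f <- mv_ivw(s)
  expect_true(all(f$se > 0))
  expect_true(all(f$p_values > 0 & f$p_values <= 1))
  expect_gte(f$n_instruments, n_traits(s))
  df <- as.data.frame(f)
  expect_equal(nrow(df), 3)
  expect_named(df, c("trait", "estimate", "se", "p", "method",
                     "n_instruments", "condition_number"))
})
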