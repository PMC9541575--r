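# Programmatic fixtures: everything is generated in code at test time.

# random PSD correlation matrix with moderate off-diagonals
random_corr <- function(J, strength = 0.4) {
  A <- matrix(stats::rnorm(J * (J + 5)), J, J + 5)
  A <- A + strength * matrix(stats::rnorm(J + 5), J, J + 5, byrow = TRUE)
  stats::cov2cor(tcrossprod(A))
}

# random summary_data instance with positive SEs
random_summary <- function(J, K, se_scale = 0.05) {
  summary_data(paste0("v", seq_len(J)),
               matrix(stats::rnorm(J * K, sd = 0.2), J, K),
               matrix(stats::runif(J * K, 0.5, 1.5) * se_scale, J, K),
               stats::rnorm(J, sd = 0.2),
               stats::runif(J, 0.5, 1.5) * se_scale,
               paste0("X", seq_len(K)))
}

# noiseless (consistent) summary_data with beta_Y = beta_X theta
consistent_summary <- function(J, K, theta, se_scale = 0.05) {
  bx <- matrix(stats::rnorm(J * K, sd = 0.3), J, K)
  summary_data(paste0("v", seq_len(J)), bx,
               matrix(se_scale, J, K),
               drop(bx %*% theta),
               rep(se_scale, J))
}

# small, fast simulation configuration for harness-level tests
small_config <- function(alpha_mean = 0.15, ...) {
  sim_config(n_exposure_sample = 1500, n_outcome_sample = 1500,
             J = 20, K = 3, causal_variants_per_trait = 5,
             alpha_mean = alpha_mean, ...)
}

# independently coded generalized least squares (explicit inverses)
naive_gls <- function(bx, by, sigma) {
  w <- solve(unname(sigma))
  bx <- unname(bx)
  v <- solve(t(bx) %*% w %*% bx)
  list(theta = drop(v %*% t(bx) %*% w %*% unname(by)),
       se = unname(sqrt(diag(v))))
}
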