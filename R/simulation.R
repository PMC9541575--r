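# Data-generating model for the Monte-Carlo study.
#
# Each replication draws a fresh variant correlation structure and a fresh
# two-sample dataset:
#   A[j1,j2] ~ Uniform(lo, hi),  B = cor(A A'),  G_i ~ N_J(0, B)
#   alpha_j ~ N(alpha_mean, alpha_sd^2), j = 1..(K * causal_per_trait)
#   X_ik = sum over trait k's causal block of alpha_j G_ij + U_ik + eps_X[ik]
#   Y_i  = sum_k theta_k X_ik + sum_k U_ik + eps_Y[i]
# with all confounders U and noise terms independent standard normal.
# Under the defaults (J = 100 variants, K = 3 traits, 5 causal variants per
# trait, alpha ~ N(0.08, 0.01^2), theta = (+0.4, 0, -0.6), n = 10 000 per
# sample) each trait's causal block explains about 3.5% of its variance.
# "Variants" are continuous Gaussians, not discretized genotypes.

#' Simulation scenario configuration
#'
#' @param n_exposure_sample individuals in the exposure-association sample
#'   (default 10 000).
#' @param n_outcome_sample individuals in the outcome-association sample
#'   (default 10 000).
#' @param J number of variants (default 100).
#' @param K number of exposure traits (default 3).
#' @param causal_variants_per_trait causal variants per trait, in disjoint
#'   consecutive blocks (default 5).
#' @param alpha_mean mean of the variant-trait effect sizes (default 0.08;
#'   0.05 gives the weak-instrument scenario).
#' @param alpha_sd SD of the effect sizes (default 0.01).
#' @param theta_true length-K vector of causal effects of the traits on the
#'   outcome (default `c(0.4, 0, -0.6)`).
#' @param ld_bounds lower/upper bounds of the uniform draws filling the A
#'   matrix whose row covariance defines the variant correlations (default
#'   `c(-0.3, 1)`; `c(0.1, 1)` gives the strong-correlation scenario).
#' @param correlated_exposures if `TRUE`, each trait additionally receives
#'   the next trait's confounder (cyclically: U2 into X1, U3 into X2, U1
#'   into X3), scaled by `confounder_cross_scale`, so the exposures are
#'   correlated beyond their shared genetics.
#' @param confounder_cross_scale coefficient of the cross-assigned
#'   confounders (default 1).
#' @param ld_reference `NULL` to estimate variant correlations in the
#'   exposure sample, or a sample size to estimate them in an independent
#'   reference panel drawn from the same distribution.
#' @param rounding_decimals `NULL`, or an integer: round every summary beta
#'   and SE to this many decimals (3 emulates publicly reported GWAS
#'   estimates).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_exposure_sample = 10000, n_outcome_sample = 10000,
                       J = 100, K = 3, causal_variants_per_trait = 5,
                       alpha_mean = 0.08, alpha_sd = 0.01,
                       theta_true = c(0.4, 0, -0.6),
                       ld_bounds = c(-0.3, 1),
                       correlated_exposures = FALSE,
                       confounder_cross_scale = 1,
                       ld_reference = NULL,
                       rounding_decimals = NULL) {
  stopifnot(n_exposure_sample >= 1, n_outcome_sample >= 1, J >= 1, K >= 1,
            causal_variants_per_trait >= 1, alpha_sd >= 0,
            length(theta_true) == K, length(ld_bounds) == 2,
            ld_bounds[1] < ld_bounds[2])
  if (K * causal_variants_per_trait > J)
    stop("K * causal_variants_per_trait must not exceed J")
  if (!is.null(ld_reference)) stopifnot(ld_reference >= 2)
  if (!is.null(rounding_decimals)) stopifnot(rounding_decimals >= 1)
  structure(list(n_exposure_sample = as.integer(n_exposure_sample),
                 n_outcome_sample = as.integer(n_outcome_sample),
                 J = as.integer(J), K = as.integer(K),
                 causal_variants_per_trait = as.integer(causal_variants_per_trait),
                 alpha_mean = alpha_mean, alpha_sd = alpha_sd,
                 theta_true = theta_true, ld_bounds = ld_bounds,
                 correlated_exposures = isTRUE(correlated_exposures),
                 confounder_cross_scale = confounder_cross_scale,
                 ld_reference = ld_reference,
                 rounding_decimals = rounding_decimals),
            class = "sim_config")
}

#' Draw a random variant correlation structure
#'
#' Fills a J x J matrix A with uniform draws on `ld_bounds` and returns
#' `cor(A A')`: the sample correlation matrix of the columns of the product
#' matrix, treating its J rows as observations (the `cor()` reading, which
#' reproduces the documented correlation ranges; normalizing A A' as a
#' covariance matrix instead gives markedly stronger correlations). Under
#' the default bounds (-0.3, 1) off-diagonal correlations typically range
#' from about -0.1 to +0.6 with an interquartile range around +0.2 to
#' +0.4; bounds (+0.1, +1) push the interquartile range to about +0.65 to
#' +0.75. Note B has rank J - 1 (column centering removes one dimension),
#' so it is PSD but singular; downstream code never inverts B itself.
#'
#' @param config a [sim_config].
#' @return J x J correlation matrix (symmetric PSD, unit diagonal).
#' @export
generate_ld_structure <- function(config) {
  J <- config$J
  A <- matrix(stats::runif(J * J, config$ld_bounds[1], config$ld_bounds[2]),
              J, J)
  B <- stats::cor(tcrossprod(A))
  diag(B) <- 1
  B
}

# Internal: M with M'M = B for a PSD (possibly singular) covariance.
psd_sqrt <- function(B) {
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  diag(sqrt(pmax(e$values, 0))) %*% t(e$vectors)
}

#' Simulate one individual-level dataset
#'
#' Draws the correlation structure, the genotype-like variant matrix, the
#' effect sizes, confounders and noise, and builds the traits and outcome.
#' The returned object carries everything downstream steps need: the true
#' correlation matrix, the causal blocks, and the configuration.
#'
#' @param config a [sim_config].
#' @return An object of class `mvmr_sim`: list with `G`
#'   (n x J, n = exposure + outcome sample), `X` (n x K), `Y` (length n),
#'   `B` (true J x J correlation), `alpha` (causal effect sizes),
#'   `causal_blocks` (list of variant index blocks per trait), `config`.
#' @export
simulate_individual_data <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  J <- config$J; K <- config$K; cpt <- config$causal_variants_per_trait
  n <- config$n_exposure_sample + config$n_outcome_sample
  B <- generate_ld_structure(config)
  G <- matrix(stats::rnorm(n * J), n, J) %*% psd_sqrt(B)
  colnames(G) <- paste0("v", seq_len(J))
  alpha <- stats::rnorm(K * cpt, config$alpha_mean, config$alpha_sd)
  blocks <- split(seq_len(K * cpt), rep(seq_len(K), each = cpt))
  U <- matrix(stats::rnorm(n * K), n, K)
  epsX <- matrix(stats::rnorm(n * K), n, K)
  X <- matrix(0, n, K)
  for (k in seq_len(K)) {
    idx <- blocks[[k]]
    X[, k] <- G[, idx, drop = FALSE] %*% alpha[idx] + U[, k] + epsX[, k]
    if (config$correlated_exposures) {
      cross <- if (k < K) k + 1L else 1L
      X[, k] <- X[, k] + config$confounder_cross_scale * U[, cross]
    }
  }
  colnames(X) <- paste0("X", seq_len(K))
  Y <- drop(X %*% config$theta_true) + rowSums(U) + stats::rnorm(n)
  structure(list(G = G, X = X, Y = Y, B = B, alpha = alpha,
                 causal_blocks = blocks, config = config),
            class = "mvmr_sim")
}

# Vectorized univariable OLS of y on each column of G (with intercept).
# Returns beta and se per column; se uses the n-2 denominator.
uni_ols <- function(G, y) {
  n <- nrow(G)
  Gc <- scale(G, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  sxx <- colSums(Gc^2)
  if (any(sxx <= 0)) stop("degenerate (zero-variance) variant column")
  sxy <- drop(crossprod(Gc, yc))
  beta <- sxy / sxx
  rss <- sum(yc^2) - beta * sxy
  rss[rss < 0] <- 0
  se <- sqrt(rss / (n - 2) / sxx)
  list(beta = beta, se = se)
}

#' Extract two-sample summary statistics from an individual-level dataset
#'
#' Variant-exposure associations (per-variant univariable OLS with an
#' intercept) are estimated on the first `n_exposure_sample` individuals,
#' variant-outcome associations on the subsequent `n_outcome_sample`
#' individuals, so exposure and outcome samples do not overlap. Variant
#' correlations are estimated in the exposure sample, or - when
#' `config$ld_reference` is set - in a freshly drawn independent panel of
#' that size (consuming random numbers). When `config$rounding_decimals`
#' is set, every beta and SE is rounded to that many decimals before being
#' returned.
#'
#' @param dataset an `mvmr_sim` from [simulate_individual_data()].
#' @param config configuration; defaults to the one stored in `dataset`.
#' @return list with `summary` (a [summary_data]) and `ld`
#'   (an [ld_matrix]).
#' @export
summarize_two_sample <- function(dataset, config = dataset$config) {
  stopifnot(inherits(dataset, "mvmr_sim"))
  n1 <- config$n_exposure_sample; n2 <- config$n_outcome_sample
  if (nrow(dataset$G) != n1 + n2)
    stop("dataset rows must equal n_exposure_sample + n_outcome_sample")
  i1 <- seq_len(n1); i2 <- n1 + seq_len(n2)
  G1 <- dataset$G[i1, , drop = FALSE]
  K <- config$K; J <- config$J
  bx <- sx <- matrix(0, J, K)
  for (k in seq_len(K)) {
    f <- uni_ols(G1, dataset$X[i1, k])
    bx[, k] <- f$beta; sx[, k] <- f$se
  }
  fy <- uni_ols(dataset$G[i2, , drop = FALSE], dataset$Y[i2])
  rho <- if (is.null(config$ld_reference)) {
    stats::cor(G1)
  } else {
    Gref <- matrix(stats::rnorm(config$ld_reference * J),
                   config$ld_reference, J) %*% psd_sqrt(dataset$B)
    stats::cor(Gref)
  }
  by <- fy$beta; sy <- fy$se
  if (!is.null(config$rounding_decimals)) {
    d <- config$rounding_decimals
    bx <- round(bx, d); sx <- round(sx, d)
    by <- round(by, d); sy <- round(sy, d)
  }
  ids <- colnames(dataset$G)
  list(summary = summary_data(ids, bx, sx, by, sy,
                              trait_names = colnames(dataset$X)),
       ld = ld_matrix((rho + t(rho)) / 2, ids))
}

#' Instrument-strength diagnostics for the true causal variants
#'
#' Oracle diagnostics that use the known causal blocks: per trait, the R^2
#' and F statistic from regressing the trait on its own causal variants,
#' and a conditional F statistic (Sanderson-Windmeijer construction) that
#' measures the strength of each trait's instruments given the other
#' traits, using all causal variants jointly.
#'
#' @param dataset an `mvmr_sim`.
#' @param sample `"all"` (default) uses every simulated individual, the
#'   scale on which the degrees of freedom of the reported F statistics
#'   are conventionally quoted; `"exposure"` restricts to the exposure
#'   sample.
#' @return data frame with one row per trait: `trait`, `r_squared`,
#'   `f_univariable`, `f_conditional`.
#' @export
instrument_strength <- function(dataset, sample = c("all", "exposure")) {
  stopifnot(inherits(dataset, "mvmr_sim"))
  sample <- match.arg(sample)
  cfg <- dataset$config
  rows <- if (sample == "exposure") seq_len(cfg$n_exposure_sample) else
    seq_len(nrow(dataset$G))
  blocks <- dataset$causal_blocks
  Z <- dataset$G[rows, unlist(blocks), drop = FALSE]
  Zc <- scale(Z, center = TRUE, scale = FALSE)
  X <- dataset$X[rows, , drop = FALSE]
  n <- length(rows); K <- cfg$K; Jz <- ncol(Z)
  r2_of <- function(W, y) {
    yc <- y - mean(y)
    fit <- stats::lm.fit(W, yc)
    1 - sum(fit$residuals^2) / sum(yc^2)
  }
  out <- data.frame(trait = colnames(dataset$X),
                    r_squared = NA_real_, f_univariable = NA_real_,
                    f_conditional = NA_real_, stringsAsFactors = FALSE)
  col_of <- function(k) match(blocks[[k]], unlist(blocks))
  # first-stage fitted values of every trait on all causal variants
  Xhat <- matrix(0, n, K)
  for (k in seq_len(K)) {
    f <- stats::lm.fit(Zc, X[, k] - mean(X[, k]))
    Xhat[, k] <- f$fitted.values
  }
  for (k in seq_len(K)) {
    q <- length(blocks[[k]])
    r2 <- r2_of(Zc[, col_of(k), drop = FALSE], X[, k])
    f_uni <- (r2 / q) / ((1 - r2) / (n - q - 1))
    # Sanderson-Windmeijer conditional F: residualize trait k on the
    # first-stage fitted values of the other traits, then test the joint
    # explanatory power of all instruments on that residual
    other <- Xhat[, -k, drop = FALSE]
    e <- stats::lm.fit(cbind(1, other), X[, k])$residuals
    r2e <- r2_of(Zc, e)
    f_cond <- (r2e / (Jz - K + 1)) / ((1 - r2e) / (n - Jz - 1))
    out$r_squared[k] <- r2
    out$f_univariable[k] <- f_uni
    out$f_conditional[k] <- f_cond
  }
  out
}
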