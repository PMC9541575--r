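# Weighted principal-component reduction of correlated instruments.
#
# Instead of pruning, the J correlated variants are replaced by the top k
# principal components of the weighted matrix
#   Psi[j1,j2] = (sum_k |bX[j1,k]|) (sum_k |bX[j2,k]|)
#                 se(bY[j1])^-1 se(bY[j2])^-1 rho[j1,j2]
# i.e. Psi = diag(w) rho diag(w) with w[j] = sum_k |bX[j,k]| / se(bY[j]).
# The weights upweight variants with large exposure associations and precise
# outcome associations, so the leading components carry the most information
# for the MR estimate. The components are orthogonal, so the transformed
# covariance is well-conditioned even when Sigma itself is near-singular.

#' Weighted variant covariance matrix Psi for PCA reduction
#'
#' @param data a [summary_data] object.
#' @param ld an [ld_matrix] over the same variants (`NULL` = identity).
#' @return J x J symmetric PSD matrix `diag(w) rho diag(w)` with
#'   `w[j] = sum_k |beta_X[j,k]| / se(beta_Y[j])`.
#' @export
build_psi <- function(data, ld = NULL) {
  stopifnot(inherits(data, "summary_data"))
  rho <- align_ld(data, ld)
  if (is.null(rho)) rho <- diag(n_variants(data))
  w <- rowSums(abs(data$beta_exposures)) / data$se_outcome
  psi <- rho * tcrossprod(w)
  dimnames(psi) <- list(data$variant_ids, data$variant_ids)
  psi
}

#' Select principal components of Psi by cumulative variance explained
#'
#' With `center = FALSE` (the default here) this is the plain
#' eigendecomposition of the symmetric matrix `psi`, and the retained
#' count k is the smallest integer whose cumulative eigenvalue proportion
#' reaches `var_threshold` (a cumulative proportion exactly equal to the
#' threshold is included; tiny negative eigenvalues from floating point
#' are clipped at zero for the ratio, since Psi is PSD in exact
#' arithmetic). With `center = TRUE` the components are those of a
#' conventional PCA of the columns of `psi` (column-centered, unscaled,
#' as `prcomp` computes them) and the variance proportions come from the
#' component variances; this is the convention the PCA estimators use by
#' default, because the centered spectrum decays much faster and the
#' retained components carry almost all of the estimator-relevant signal
#' (see the package vignette). `var_threshold = 1` always returns the
#' complete basis, making the transform lossless.
#'
#' Eigenvector signs are fixed so the largest-magnitude loading of each
#' component is positive, which makes the decomposition deterministic;
#' estimates are invariant to the choice.
#'
#' @param psi square symmetric PSD matrix, e.g. from [build_psi()].
#' @param var_threshold proportion of variance to retain (default 0.99).
#' @param center use column-centered (prcomp-style) components instead of
#'   the raw eigenvectors of `psi` (default `FALSE`).
#' @return An object of class `pca_transform` with elements `loadings`
#'   (J x k), `eigenvalues` (length J, descending; component variances
#'   when `center = TRUE`), `k`, `variance_explained` (cumulative
#'   proportion at k) and `center`.
#' @export
select_components <- function(psi, var_threshold = 0.99, center = FALSE) {
  psi <- as.matrix(psi)
  if (nrow(psi) != ncol(psi)) stop("psi must be square")
  if (max(abs(psi - t(psi))) > 1e-8 * max(1, max(abs(psi))))
    stop("psi must be symmetric")
  if (!is.numeric(var_threshold) || var_threshold <= 0 || var_threshold > 1)
    stop("var_threshold must be in (0, 1]")
  if (center) {
    p <- stats::prcomp(psi, center = TRUE, scale. = FALSE)
    W <- p$rotation
    if (ncol(W) < nrow(psi)) {       # pad to a full orthonormal basis
      W <- qr.Q(qr(cbind(W, diag(nrow(psi)))))[, seq_len(nrow(psi)),
                                               drop = FALSE]
    }
    ev <- c(p$sdev^2, rep(0, nrow(psi) - length(p$sdev)))
  } else {
    e <- eigen((psi + t(psi)) / 2, symmetric = TRUE)
    W <- e$vectors
    ev <- e$values
  }
  evc <- pmax(ev, 0)
  total <- sum(evc)
  if (total <= 0)
    stop("psi has no signal to decompose (all eigenvalues are zero)")
  cum <- cumsum(evc) / total
  k <- if (var_threshold >= 1) nrow(psi) else
    which(cum >= var_threshold - 1e-10)[1L]
  for (j in seq_len(ncol(W))) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  structure(list(loadings = W[, seq_len(k), drop = FALSE],
                 eigenvalues = ev, k = k,
                 variance_explained = cum[min(k, length(cum))],
                 center = center),
            class = "pca_transform")
}

#' @export
print.pca_transform <- function(x, ...) {
  cat("PCA transform: ", x$k, " of ", length(x$eigenvalues),
      " components retained (", round(100 * x$variance_explained, 2),
      "% of variance)\n", sep = "")
  invisible(x)
}

#' Project summarized data onto retained principal components
#'
#' @param data a [summary_data] object.
#' @param ld an [ld_matrix] over the same variants (`NULL` = identity).
#' @param transform a `pca_transform` from [select_components()].
#' @return list with `beta_exposures` (k x K, `Wk' bX`), `beta_outcome`
#'   (length k, `Wk' bY`) and `sigma` (k x k, `Wk' Sigma Wk`).
#' @export
transform_summary <- function(data, ld, transform) {
  stopifnot(inherits(data, "summary_data"),
            inherits(transform, "pca_transform"))
  W <- transform$loadings
  if (nrow(W) != n_variants(data))
    stop("transform dimension does not match the number of variants")
  rho <- align_ld(data, ld)
  sigma <- outcome_covariance(data$se_outcome, rho)
  list(beta_exposures = crossprod(W, data$beta_exposures),
       beta_outcome = drop(crossprod(W, data$beta_outcome)),
       sigma = crossprod(W, sigma %*% W))
}

# Internal: shared pre-pruning + component selection for the PCA methods.
pca_reduce <- function(data, ld, var_threshold, pre_prune, center = TRUE) {
  if (!is.null(pre_prune)) {
    pv <- min_pvalue_per_variant(data)
    ld_for_prune <- if (is.null(ld))
      ld_matrix(diag(n_variants(data)), data$variant_ids) else ld
    sel <- prune_variants(pv, ld_for_prune, pre_prune)
    keep <- sort(sel$selected)
    data <- data[keep]
    if (!is.null(ld)) ld <- ld[data$variant_ids]
  }
  K <- n_traits(data)
  if (n_variants(data) <= K)
    stop("not identified after pre-pruning: ", n_variants(data),
         " variant(s) for ", K, " trait(s)", call. = FALSE)
  psi <- build_psi(data, ld)
  tr <- select_components(psi, var_threshold, center = center)
  if (tr$k < K)
    stop("only ", tr$k, " principal component(s) retained for ", K,
         " trait(s); increase var_threshold", call. = FALSE)
  list(data = data, ld = ld, transform = tr)
}

#' MV-IVW with principal-component instrument reduction (MV-IVW-PCA)
#'
#' Replaces the correlated variants by the top k principal components of
#' the weighted matrix Psi (see [build_psi()]), then fits the IVW
#' generalized regression on the transformed data:
#' `theta = (bX~' Sigma~^-1 bX~)^-1 bX~' Sigma~^-1 bY~`, standard errors
#' from the diagonal of `(bX~' Sigma~^-1 bX~)^-1`. Very highly correlated
#' variants are removed first by greedy pruning at `|rho| < pre_prune`
#' (they add no information but can break the eigendecomposition
#' numerically); set `pre_prune = NULL` to disable.
#'
#' With `var_threshold = 1` on full-rank inputs the transform is
#' invertible and the estimate equals [mv_ivw()] exactly.
#'
#' @inheritParams mv_ivw
#' @param var_threshold proportion of Psi variance the retained components
#'   must explain (default 0.99).
#' @param pre_prune correlation threshold for the initial pruning step
#'   (default 0.95); `NULL` disables.
#' @param center component convention passed to [select_components()];
#'   defaults to `TRUE` (prcomp-style centered components), the variant
#'   whose operating characteristics the package documents.
#' @return an `mvmr_estimate`; `n_instruments` is the number of retained
#'   components and `condition_number` refers to the transformed
#'   covariance `Sigma~`.
#' @export
mv_ivw_pca <- function(data, ld = NULL, var_threshold = 0.99,
                       pre_prune = 0.95, center = TRUE, cond_warn = 100,
                       cond_ceiling = 1e12) {
  stopifnot(inherits(data, "summary_data"))
  red <- pca_reduce(data, ld, var_threshold, pre_prune, center)
  tr <- transform_summary(red$data, red$ld, red$transform)
  kappa <- condition_number(tr$sigma)
  check_conditioning(kappa, cond_warn, cond_ceiling, "transformed Sigma")
  fit <- gls_fit(tr$beta_exposures, tr$beta_outcome, tr$sigma)
  new_mvmr_estimate(fit$theta, fit$se, "mv-ivw-pca", kappa,
                    red$transform$k, data$trait_names,
                    extra = list(transform = red$transform))
}

#' MV-LIML with principal-component instrument reduction (MV-LIML-PCA)
#'
#' Minimizes the projected LIML objective
#' `Q~(theta) = g~(theta)' Omega~(theta)^-1 g~(theta)` with
#' `g~ = Wk' g(theta)` and `Omega~ = Wk' Omega(theta) Wk`, where Wk holds
#' the retained components of Psi (as in [mv_ivw_pca()]). Standard errors
#' come from the diagonal of `(bX~' Omega~(theta_hat)^-1 bX~)^-1`.
#'
#' @inheritParams mv_liml
#' @inheritParams mv_ivw_pca
#' @return an `mvmr_estimate` with `objective_value` the minimized
#'   projected Q.
#' @export
mv_liml_pca <- function(data, ld = NULL, phi = NULL, var_threshold = 0.99,
                        pre_prune = 0.95, center = TRUE,
                        optimizer = c("irgls", "argmin"),
                        se_product = c("two", "four"),
                        n_restarts = 5, cond_warn = 100,
                        cond_ceiling = 1e12) {
  stopifnot(inherits(data, "summary_data"))
  se_product <- match.arg(se_product)
  optimizer <- match.arg(optimizer)
  K <- n_traits(data)
  phi_m <- if (is.null(phi)) diag(K) else phi$phi
  if (!all(dim(phi_m) == K)) stop("phi must be K x K")
  red <- pca_reduce(data, ld, var_threshold, pre_prune, center)
  d <- red$data
  rho <- align_ld(d, red$ld)
  W <- red$transform$loadings
  tr0 <- transform_summary(d, red$ld, red$transform)
  start <- gls_fit(tr0$beta_exposures, tr0$beta_outcome, tr0$sigma)
  obj <- make_liml_objective(d$beta_exposures, d$se_exposures,
                             d$beta_outcome, d$se_outcome, rho, phi_m,
                             se_product, W = W)
  best <- if (optimizer == "irgls") liml_irgls(obj, start$theta) else
    liml_minimize(obj, start$theta, start$se, n_restarts)
  theta <- best$par
  om <- obj$omega(theta)
  kappa <- condition_number(om)
  check_conditioning(kappa, cond_warn, cond_ceiling,
                     "transformed Omega(theta)")
  ch <- tryCatch(chol(om), error = function(e)
    stop("transformed Omega is numerically singular at the optimum",
         call. = FALSE))
  a <- backsolve(ch, obj$bx, transpose = TRUE)
  v <- chol2inv(chol(crossprod(a)))
  new_mvmr_estimate(theta, sqrt(diag(v)), "mv-liml-pca", kappa,
                    red$transform$k, data$trait_names,
                    objective_value = best$value,
                    extra = list(transform = red$transform))
}

#' Export the eigenvalue spectrum of a PCA transform as a TSV
#'
#' Diagnostic companion to the PCA estimators: one row per component with
#' its eigenvalue and the cumulative proportion of variance explained.
#'
#' @param transform a `pca_transform`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pca_spectrum <- function(transform, path) {
  ev <- pmax(transform$eigenvalues, 0)
  df <- data.frame(component = seq_along(ev), eigenvalue = transform$eigenvalues,
                   cumulative_variance = cumsum(ev) / sum(ev),
                   retained = seq_along(ev) <= transform$k)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
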