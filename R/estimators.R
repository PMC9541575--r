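# Core multivariable MR estimators for correlated variants.
#
# MV-IVW is generalized weighted linear regression of the variant-outcome
# associations on the variant-exposure associations, with error covariance
#   Sigma[j1,j2] = se(bY[j1]) * se(bY[j2]) * rho[j1,j2].
# MV-LIML minimizes an Anderson-Rubin-type GMM objective whose weight matrix
# Omega(theta) depends on the parameter, which makes it robust with many
# weak instruments at the price of a non-quadratic optimization problem.

#' Condition number of a symmetric positive (semi-)definite matrix
#'
#' The ratio of the largest to the smallest eigenvalue, the standard
#' diagnostic of how ill-conditioned inversion of a covariance matrix is.
#' Values over 100 are conventionally a cause for concern when the inputs
#' are known to limited precision.
#'
#' @param m square symmetric numeric matrix.
#' @param tol relative tolerance: eigenvalues below `tol * lambda_max` are
#'   treated as zero, giving a condition number of `Inf`.
#' @return a scalar; `Inf` when the smallest eigenvalue is non-positive
#'   within tolerance.
#' @export
condition_number <- function(m, tol = 1e-12) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("condition_number requires a square matrix")
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  lo <- min(ev); hi <- max(ev)
  if (lo <= max(tol * hi, 0)) return(Inf)
  hi / lo
}

#' Two-sided Wald p-values from a standard normal reference
#'
#' @param theta estimates.
#' @param se their standard errors (strictly positive).
#' @return vector of p-values in (0, 1]; the 95% confidence interval
#'   excludes the null exactly when p < 0.05, i.e. |theta/se| > 1.959964.
#' @export
wald_pvalues <- function(theta, se) {
  if (any(se <= 0)) stop("standard errors must be strictly positive")
  pmax(2 * stats::pnorm(-abs(theta / se)), .Machine$double.xmin)
}

# Estimate container shared by all four methods -----------------------------

new_mvmr_estimate <- function(theta, se, method, condition_number,
                              n_instruments, trait_names,
                              objective_value = NULL, extra = list()) {
  theta <- as.numeric(theta); se <- as.numeric(se)
  names(theta) <- names(se) <- trait_names
  out <- c(list(theta = theta, se = se,
                p_values = wald_pvalues(theta, se),
                method = method,
                condition_number = condition_number,
                n_instruments = n_instruments,
                objective_value = objective_value,
                trait_names = trait_names),
           extra)
  structure(out, class = "mvmr_estimate")
}

#' @export
print.mvmr_estimate <- function(x, ...) {
  cat("Multivariable MR estimate (", x$method, "), ",
      x$n_instruments, " instrument(s)\n", sep = "")
  print(as.data.frame(x), digits = 4)
  cat("Condition number of working covariance:",
      format(x$condition_number, digits = 4), "\n")
  if (!is.null(x$objective_value))
    cat("Minimized objective Q:", format(x$objective_value, digits = 6), "\n")
  invisible(x)
}

#' Convert a fitted estimate into a one-row-per-trait data frame
#' @param x an `mvmr_estimate`.
#' @param ... unused.
#' @return data frame with columns trait, estimate, se, p, method,
#'   n_instruments, condition_number.
#' @export
as.data.frame.mvmr_estimate <- function(x, ...) {
  data.frame(trait = x$trait_names, estimate = x$theta, se = x$se,
             p = x$p_values, method = x$method,
             n_instruments = x$n_instruments,
             condition_number = x$condition_number,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Internal: Sigma = D rho D with D = diag(se_outcome)
outcome_covariance <- function(se_outcome, rho = NULL) {
  if (is.null(rho)) return(diag(se_outcome^2, nrow = length(se_outcome)))
  rho * tcrossprod(se_outcome)
}

# Internal: GLS solve via Cholesky; returns theta, se, vcov.
gls_fit <- function(bx, by, sigma) {
  ch <- tryCatch(chol(sigma), error = function(e)
    stop("working covariance matrix is numerically singular; consider ",
         "pruning correlated variants or a PCA method", call. = FALSE))
  a <- backsolve(ch, bx, transpose = TRUE)
  b <- backsolve(ch, by, transpose = TRUE)
  xtx <- crossprod(a)
  v <- tryCatch(chol2inv(chol(xtx)), error = function(e)
    stop("exposure associations are collinear after weighting; the model ",
         "is not identified", call. = FALSE))
  theta <- drop(v %*% crossprod(a, b))
  list(theta = theta, se = sqrt(diag(v)), vcov = v)
}

check_conditioning <- function(kappa, cond_warn, cond_ceiling, label) {
  if (is.infinite(kappa) || kappa > cond_ceiling)
    stop(label, " condition number ", format(kappa, digits = 4),
         " exceeds the ceiling (", format(cond_ceiling),
         "); prune correlated variants or use a PCA method", call. = FALSE)
  if (kappa > cond_warn)
    warning(label, " condition number is ", format(kappa, digits = 4),
            "; values over ", cond_warn, " are cause for concern",
            call. = FALSE)
  invisible(kappa)
}

#' Multivariable inverse-variance weighted estimator (MV-IVW)
#'
#' Generalized weighted linear regression of the variant-outcome
#' associations on the variant-exposure associations,
#' `theta = (bX' Sigma^-1 bX)^-1 bX' Sigma^-1 bY`, where
#' `Sigma[j1,j2] = se(bY[j1]) se(bY[j2]) rho[j1,j2]`. With an identity LD
#' matrix this reduces to weighted linear regression with weights
#' `se(bY)^-2`. Standard errors are the square roots of the diagonal of
#' `(bX' Sigma^-1 bX)^-1` (fixed-effect model).
#'
#' @param data a [summary_data] object (J variants, K traits, J >= K).
#' @param ld an [ld_matrix] over the same variants in the same order;
#'   `NULL` means uncorrelated variants (identity).
#' @param cond_warn warn when the condition number of `Sigma` exceeds this
#'   (default 100).
#' @param cond_ceiling hard error above this condition number
#'   (default 1e12).
#' @return an object of class `mvmr_estimate`.
#' @export
mv_ivw <- function(data, ld = NULL, cond_warn = 100, cond_ceiling = 1e12) {
  stopifnot(inherits(data, "summary_data"))
  J <- n_variants(data); K <- n_traits(data)
  if (J < K)
    stop("not identified: ", J, " variant(s) for ", K,
         " trait(s); J >= K is required", call. = FALSE)
  rho <- align_ld(data, ld)
  sigma <- outcome_covariance(data$se_outcome, rho)
  kappa <- condition_number(sigma)
  check_conditioning(kappa, cond_warn, cond_ceiling, "Sigma")
  fit <- gls_fit(data$beta_exposures, data$beta_outcome, sigma)
  new_mvmr_estimate(fit$theta, fit$se, "mv-ivw", kappa, J, data$trait_names)
}

# Internal: check LD matrix matches the data and return its rho (or NULL).
align_ld <- function(data, ld) {
  if (is.null(ld)) return(NULL)
  stopifnot(inherits(ld, "ld_matrix"))
  if (!identical(ld$variant_ids, data$variant_ids)) {
    if (!all(data$variant_ids %in% ld$variant_ids))
      stop("LD matrix is missing variant(s): ",
           paste(setdiff(data$variant_ids, ld$variant_ids), collapse = ", "))
    ld <- ld[data$variant_ids]
  }
  ld$rho
}

# --------------------------------------------------------------------------
# MV-LIML: Q(theta) = g(theta)' Omega(theta)^-1 g(theta),
# g(theta) = bY - bX theta, and
#   Omega[j1,j2](theta) = se(bY[j1]) se(bY[j2]) rho[j1,j2]
#     + sum_{k,l} se(bX[j1,k]) se(bX[j2,k]) se(bX[j1,l]) se(bX[j2,l])
#                 rho[j1,j2] Phi[k,l] theta_k theta_l.
# The exposure term as literally printed in the source derivation carries
# the product of FOUR exposure standard errors per (k,l) summand
# (`se_product = "four"`). That form is dimensionally a variance-squared:
# with typical exposure SEs of order 1e-2 the whole term is ~1e-8 and
# Omega collapses onto Sigma, making LIML numerically identical to IVW.
# The default `se_product = "two"` uses the dimensionally conventional
# covariance se(bX[j1,k]) se(bX[j2,l]) rho[j1,j2] Phi[k,l], i.e.
# Omega = Var(bY) + Var(bX theta), which actually distinguishes the two
# estimators; the four-SE form is kept for comparison.
#
# For fixed (k,l) the four-SE summand factorizes over (j1,j2): with
# w_kl[j] = se_x[j,k] * se_x[j,l], the J x J contribution is
# rho * outer(w_kl, w_kl). These K(K+1)/2 matrices depend only on the data,
# so Omega(theta) is a cheap linear combination at every objective
# evaluation; an optional projection matrix W turns the same machinery into
# the PCA-reduced objective (g~ = W'g, Omega~ = W' Omega W).

make_liml_objective <- function(bx, se_x, by, se_y, rho, phi,
                                se_product = c("two", "four"), W = NULL) {
  se_product <- match.arg(se_product)
  K <- ncol(bx)
  if (is.null(rho)) rho <- diag(nrow(bx))
  sigma <- outcome_covariance(se_y, rho)
  project <- function(m) if (is.null(W)) m else crossprod(W, m %*% W)
  base <- project(sigma)
  bx_t <- if (is.null(W)) bx else crossprod(W, bx)
  by_t <- if (is.null(W)) by else drop(crossprod(W, by))
  pieces <- list()
  coefs <- list()
  for (k in seq_len(K)) for (l in k:K) {
    if (se_product == "four") {
      wkl <- se_x[, k] * se_x[, l]
      m <- rho * tcrossprod(wkl)
    } else {
      m <- rho * tcrossprod(se_x[, k], se_x[, l])
      if (l > k) m <- m + t(m)
    }
    mult <- if (l > k && se_product == "four") 2 else 1
    pieces[[length(pieces) + 1L]] <- project(m)
    coefs[[length(coefs) + 1L]] <- c(k, l, mult * phi[k, l])
  }
  omega <- function(theta) {
    om <- base
    for (i in seq_along(pieces)) {
      cf <- coefs[[i]]
      w <- cf[3L] * theta[cf[1L]] * theta[cf[2L]]
      if (w != 0) om <- om + w * pieces[[i]]
    }
    om
  }
  Q <- function(theta) {
    om <- omega(theta)
    ch <- tryCatch(chol(om), error = function(e) NULL)
    if (is.null(ch)) return(sqrt(.Machine$double.xmax) * (1 + sum(theta^2)))
    r <- by_t - drop(bx_t %*% theta)
    sum(backsolve(ch, r, transpose = TRUE)^2)
  }
  list(Q = Q, omega = omega, bx = bx_t, by = by_t)
}

# Internal: solve the LIML first-order condition by iteratively
# reweighted GLS: theta <- (bX' Omega(theta)^-1 bX)^-1 bX' Omega(theta)^-1
# bY, iterated to a fixed point. This profile solution is stable even when
# direct minimization of Q would escape along its asymptote (see vignette).
liml_irgls <- function(obj, theta0, tol = 1e-10, maxit = 200) {
  theta <- theta0
  for (i in seq_len(maxit)) {
    om <- obj$omega(theta)
    fit <- gls_fit(obj$bx, obj$by, om)
    step <- fit$theta - theta
    theta <- fit$theta
    if (max(abs(step)) < tol * max(1, max(abs(theta))))
      return(list(par = theta, value = obj$Q(theta), convergence = 0L,
                  iterations = i))
  }
  stop("MV-LIML fixed-point iteration did not converge after ", maxit,
       " iterations; last theta = (",
       paste(format(theta, digits = 6), collapse = ", "), ")",
       call. = FALSE)
}

# Internal: minimize Q from the IVW estimate with random restarts.
liml_minimize <- function(obj, theta0, se0, n_restarts = 5,
                          reltol = 1e-10) {
  K <- length(theta0)
  starts <- c(list(theta0),
              lapply(seq_len(n_restarts), function(i)
                theta0 + stats::rnorm(K, sd = 2 * se0)))
  best <- NULL
  any_conv <- FALSE
  for (st in starts) {
    o <- tryCatch(
      stats::optim(st, obj$Q, method = "BFGS",
                   control = list(maxit = 500, reltol = reltol)),
      error = function(e) NULL)
    if (is.null(o)) next
    if (o$convergence == 0) any_conv <- TRUE
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best))
    stop("MV-LIML optimization failed from every start", call. = FALSE)
  if (!any_conv) {
    # one Nelder-Mead polish before giving up
    o <- stats::optim(best$par, obj$Q,
                      control = list(maxit = 2000, reltol = reltol))
    if (o$value <= best$value) best <- o
    if (o$convergence != 0)
      stop("MV-LIML optimizer did not converge after ", length(starts),
           " starts; best objective ", format(best$value),
           " at theta = (", paste(format(best$par, digits = 6),
                                  collapse = ", "), ")", call. = FALSE)
  }
  best
}

#' Multivariable limited-information maximum likelihood estimator (MV-LIML)
#'
#' Minimizes the Anderson-Rubin-type objective
#' `Q(theta) = g(theta)' Omega(theta)^-1 g(theta)` with
#' `g(theta) = bY - bX theta`, where `Omega(theta)` augments the MV-IVW
#' error covariance with a parameter-dependent term built from the exposure
#' standard errors and the exposure correlation matrix `Phi` (see Details
#' in the package vignette). With all exposure standard errors equal to
#' zero, `Omega` is constant and the estimate coincides with [mv_ivw()].
#' Standard errors come from the diagonal of
#' `(bX' Omega(theta_hat)^-1 bX)^-1`.
#'
#' Two solution routes are provided. The default, `optimizer = "irgls"`,
#' solves the LIML first-order condition by iteratively reweighted GLS
#' from the MV-IVW start (`theta <- GLS(Omega(theta))` to a fixed point);
#' it is numerically stable for any number of weak correlated instruments.
#' `optimizer = "argmin"` minimizes Q directly by quasi-Newton descent
#' from the IVW estimate with additional random restarts (perturbation SD
#' twice the IVW standard error). Direct minimization can be badly
#' behaved when many instruments are weak: Q has a finite asymptote as
#' the parameter norm grows, so its deep minima may lie arbitrarily far
#' from the identified region (see the package vignette).
#'
#' @inheritParams mv_ivw
#' @param phi an [exposure_correlation] (K x K); `NULL` means identity.
#' @param optimizer `"irgls"` (default) or `"argmin"`; see Details.
#' @param se_product `"two"` (default) builds `Omega`'s exposure term from
#'   the conventional covariance `se(bX[j1,k]) se(bX[j2,l]) rho Phi[k,l]`;
#'   `"four"` reproduces an alternative form with the product of four
#'   exposure standard errors per summand, which is numerically
#'   indistinguishable from MV-IVW at realistic standard errors (see the
#'   package vignette).
#' @param n_restarts number of random restarts (default 5).
#' @return an `mvmr_estimate` whose `objective_value` is the minimized Q.
#' @export
mv_liml <- function(data, ld = NULL, phi = NULL,
                    optimizer = c("irgls", "argmin"),
                    se_product = c("two", "four"), n_restarts = 5,
                    cond_warn = 100, cond_ceiling = 1e12) {
  stopifnot(inherits(data, "summary_data"))
  se_product <- match.arg(se_product)
  optimizer <- match.arg(optimizer)
  J <- n_variants(data); K <- n_traits(data)
  if (J < K)
    stop("not identified: ", J, " variant(s) for ", K, " trait(s)",
         call. = FALSE)
  phi_m <- if (is.null(phi)) diag(K) else phi$phi
  if (!all(dim(phi_m) == K)) stop("phi must be K x K")
  rho <- align_ld(data, ld)
  ivw <- suppressWarnings(mv_ivw(data, ld, cond_warn = Inf,
                                 cond_ceiling = cond_ceiling))
  obj <- make_liml_objective(data$beta_exposures, data$se_exposures,
                             data$beta_outcome, data$se_outcome, rho,
                             phi_m, se_product)
  best <- if (optimizer == "irgls") liml_irgls(obj, ivw$theta) else
    liml_minimize(obj, ivw$theta, ivw$se, n_restarts)
  theta <- best$par
  om <- obj$omega(theta)
  kappa <- condition_number(om)
  check_conditioning(kappa, cond_warn, cond_ceiling, "Omega(theta)")
  ch <- tryCatch(chol(om), error = function(e)
    stop("Omega is numerically singular at the optimum", call. = FALSE))
  a <- backsolve(ch, obj$bx, transpose = TRUE)
  v <- chol2inv(chol(crossprod(a)))
  new_mvmr_estimate(theta, sqrt(diag(v)), "mv-liml", kappa, J,
                    data$trait_names, objective_value = best$value)
}
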