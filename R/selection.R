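# Instrument selection: greedy p-value-based LD pruning on summarized data,
# and stepwise conditional selection from individual-level data (a COJO-like
# forward selection with an explicit conditional p-value stopping rule).

#' Minimum association p-value per variant across exposure traits
#'
#' For each variant, the minimum over traits of the two-sided Wald p-value
#' of `beta_X / se(beta_X)`. This is the relevance ranking used by the
#' pruning algorithm: instrument relevance is defined by the exposure
#' associations only.
#'
#' @param data a [summary_data] object.
#' @return named numeric vector of J p-values.
#' @export
min_pvalue_per_variant <- function(data) {
  stopifnot(inherits(data, "summary_data"))
  p <- 2 * stats::pnorm(-abs(data$beta_exposures / data$se_exposures))
  out <- apply(p, 1L, min)
  names(out) <- data$variant_ids
  out
}

#' Greedy p-value-based LD pruning
#'
#' Iteratively selects the remaining variant with the lowest p-value and
#' excludes from consideration all remaining variants whose correlation
#' with it reaches the threshold, until every variant is either selected or
#' excluded. Exclusion uses `|rho| >= rho_threshold`, so "pruned at
#' |rho| < t" reads literally: every retained pair satisfies
#' `|rho| < t`. Ties in p-value are broken by the lower variant index, so
#' the algorithm is deterministic.
#'
#' @param pvals length-J vector of per-variant p-values (e.g. from
#'   [min_pvalue_per_variant()]).
#' @param ld an [ld_matrix] over the same J variants.
#' @param rho_threshold correlation threshold in (0, 1].
#' @return An object of class `selection_result`: `selected` (indices in
#'   selection order), `excluded_by` (named integer vector mapping each
#'   excluded index to the selected index that removed it), `threshold`,
#'   and `variant_ids`.
#' @export
prune_variants <- function(pvals, ld, rho_threshold) {
  stopifnot(inherits(ld, "ld_matrix"))
  if (!is.numeric(rho_threshold) || rho_threshold <= 0 || rho_threshold > 1)
    stop("rho_threshold must be in (0, 1]")
  J <- length(pvals)
  if (nrow(ld$rho) != J)
    stop("pvals and LD matrix disagree on the number of variants")
  absr <- abs(ld$rho)
  status <- integer(J)                  # 0 candidate, 1 selected, -1 excluded
  excluded_by <- integer(0)
  selected <- integer(0)
  ord <- order(pvals, seq_len(J))       # ties broken by lowest index
  repeat {
    cand <- ord[status[ord] == 0L]
    if (!length(cand)) break
    pick <- cand[1L]
    status[pick] <- 1L
    selected <- c(selected, pick)
    rest <- cand[-1L]
    drop <- rest[absr[pick, rest] >= rho_threshold]
    if (length(drop)) {
      status[drop] <- -1L
      eb <- rep.int(pick, length(drop))
      names(eb) <- as.character(drop)
      excluded_by <- c(excluded_by, eb)
    }
  }
  structure(list(selected = selected, excluded_by = excluded_by,
                 threshold = rho_threshold,
                 variant_ids = ld$variant_ids[selected]),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Variant selection:", length(x$selected), "selected,",
      length(x$excluded_by), "excluded (threshold ", x$threshold, ")\n")
  invisible(x)
}

#' Stepwise conditional variant selection from individual-level data
#'
#' Forward selection on conditional association p-values. Step 0 selects
#' the variant with the lowest marginal p-value for association with any
#' trait. Each later step regresses every trait on every remaining
#' candidate together with all previously selected variants (ordinary least
#' squares with an intercept), takes the candidate's coefficient p-value,
#' and selects the candidate minimizing it over traits and candidates.
#' Selection stops when the minimum conditional p-value reaches
#' `p_threshold`. Candidates that are (near-)collinear with the selected
#' set have unidentified conditional coefficients and are skipped.
#'
#' All regressions are computed from centered cross-products, so the cost
#' per step is independent of the sample size after a single Gram-matrix
#' computation.
#'
#' @param genotypes n x J numeric matrix of variant values.
#' @param traits n x K numeric matrix of exposure trait values.
#' @param p_threshold stop when no conditional p-value is below this
#'   (default 0.001).
#' @param collinearity_tol skip a candidate when the fraction of its
#'   variance left unexplained by the selected set falls below this
#'   (default 2e-3, i.e. multiple correlation above ~0.999).
#' @return An object of class `selection_result`; `excluded_by` is empty
#'   (conditional selection excludes by stopping, not by pairwise rule).
#' @export
conditional_select <- function(genotypes, traits, p_threshold = 0.001,
                               collinearity_tol = 2e-3) {
  G <- as.matrix(genotypes); X <- as.matrix(traits)
  n <- nrow(G); J <- ncol(G); K <- ncol(X)
  if (nrow(X) != n) stop("genotypes and traits must have the same rows")
  Gc <- scale(G, center = TRUE, scale = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  GG <- crossprod(Gc)
  GX <- crossprod(Gc, Xc)
  XX <- colSums(Xc^2)
  selected <- integer(0)
  candidates <- seq_len(J)
  step <- 0L
  repeat {
    s <- length(selected)
    if (n <= s + 2L) break
    df <- n - s - 2L                    # intercept + selected + candidate
    best_p <- Inf; best_j <- NA_integer_
    for (j in candidates) {
      idx <- c(selected, j)
      M <- GG[idx, idx, drop = FALSE]
      if (s > 0L) {
        # residual variance fraction of candidate given selected set
        Ms <- GG[selected, selected, drop = FALSE]
        gj <- GG[selected, j]
        sol <- tryCatch(solve(Ms, gj), error = function(e) NULL)
        if (is.null(sol)) next
        resid_frac <- (GG[j, j] - sum(gj * sol)) / GG[j, j]
        if (!is.finite(resid_frac) || resid_frac < collinearity_tol) next
      }
      Minv <- tryCatch(solve(M), error = function(e) NULL)
      if (is.null(Minv)) next
      pos <- s + 1L
      for (k in seq_len(K)) {
        rhs <- GX[idx, k]
        b <- Minv %*% rhs
        rss <- XX[k] - sum(b * rhs)
        if (rss <= 0) next
        se_b <- sqrt(rss / df * Minv[pos, pos])
        p <- 2 * stats::pt(-abs(b[pos] / se_b), df)
        if (p < best_p) { best_p <- p; best_j <- j }
      }
    }
    # step 0 (the marginal pick) is always made; the conditional stopping
    # rule applies from step 1 onwards
    if (!is.finite(best_p) || (step > 0L && best_p >= p_threshold)) break
    selected <- c(selected, best_j)
    candidates <- setdiff(candidates, best_j)
    step <- step + 1L
    if (!length(candidates)) break
  }
  ids <- colnames(G)
  if (is.null(ids)) ids <- paste0("v", seq_len(J))
  structure(list(selected = selected, excluded_by = integer(0),
                 threshold = p_threshold, variant_ids = ids[selected]),
            class = "selection_result")
}
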