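# Domain types and text I/O for summarized genetic association data,
# variant correlation (LD) matrices, and exposure correlation matrices.

#' Summarized genetic association data
#'
#' Container for the inputs of every multivariable MR estimator in this
#' package: per-variant association estimates with K exposure traits and one
#' outcome, together with their standard errors. One row per variant; all
#' components share the same variant ordering.
#'
#' @param variant_ids character vector of J unique variant identifiers.
#' @param beta_exposures J x K numeric matrix of variant-exposure association
#'   estimates (per-allele effects from univariable regression).
#' @param se_exposures J x K numeric matrix of their standard errors
#'   (strictly positive).
#' @param beta_outcome length-J numeric vector of variant-outcome association
#'   estimates.
#' @param se_outcome length-J numeric vector of their standard errors
#'   (strictly positive).
#' @param trait_names character vector of K exposure labels; defaults to
#'   the column names of `beta_exposures` or `X1..XK`.
#'
#' @return An object of class `summary_data`.
#' @export
summary_data <- function(variant_ids, beta_exposures, se_exposures,
                         beta_outcome, se_outcome, trait_names = NULL) {
  beta_exposures <- as.matrix(beta_exposures)
  se_exposures <- as.matrix(se_exposures)
  variant_ids <- as.character(variant_ids)
  beta_outcome <- as.numeric(beta_outcome)
  se_outcome <- as.numeric(se_outcome)
  J <- length(variant_ids)
  K <- ncol(beta_exposures)
  if (J < 1L) stop("summary_data needs at least one variant (J >= 1)")
  if (K < 1L) stop("summary_data needs at least one exposure trait (K >= 1)")
  if (anyDuplicated(variant_ids))
    stop("duplicate variant id(s): ",
         paste(unique(variant_ids[duplicated(variant_ids)]), collapse = ", "))
  if (nrow(beta_exposures) != J || !all(dim(se_exposures) == c(J, K)))
    stop("beta_exposures/se_exposures must be J x K with J = length(variant_ids)")
  if (length(beta_outcome) != J || length(se_outcome) != J)
    stop("beta_outcome/se_outcome must have length J")
  vals <- c(beta_exposures, se_exposures, beta_outcome, se_outcome)
  if (anyNA(vals) || any(!is.finite(vals)))
    stop("summary_data does not allow missing or non-finite values")
  bad <- which(se_outcome <= 0)
  if (length(bad))
    stop("non-positive outcome standard error at row(s): ",
         paste(bad, collapse = ", "))
  badx <- which(se_exposures <= 0, arr.ind = TRUE)
  if (nrow(badx))
    stop("non-positive exposure standard error at row ", badx[1L, 1L],
         ", trait ", badx[1L, 2L])
  if (is.null(trait_names)) trait_names <- colnames(beta_exposures)
  if (is.null(trait_names)) trait_names <- paste0("X", seq_len(K))
  trait_names <- as.character(trait_names)
  if (length(trait_names) != K) stop("trait_names must have length K")
  dimnames(beta_exposures) <- list(variant_ids, trait_names)
  dimnames(se_exposures) <- list(variant_ids, trait_names)
  names(beta_outcome) <- names(se_outcome) <- variant_ids
  structure(list(variant_ids = variant_ids,
                 beta_exposures = beta_exposures,
                 se_exposures = se_exposures,
                 beta_outcome = beta_outcome,
                 se_outcome = se_outcome,
                 trait_names = trait_names),
            class = "summary_data")
}

#' @export
print.summary_data <- function(x, ...) {
  cat("Summarized genetic associations:",
      length(x$variant_ids), "variants,",
      length(x$trait_names), "exposure trait(s)\n")
  cat("Traits:", paste(x$trait_names, collapse = ", "), "\n")
  invisible(x)
}

#' Number of variants / traits in a summary_data object
#' @param x a `summary_data` object.
#' @return integer count.
#' @export
n_variants <- function(x) length(x$variant_ids)

#' @rdname n_variants
#' @export
n_traits <- function(x) length(x$trait_names)

#' Subset summarized data to a set of variants
#'
#' @param x a `summary_data` object.
#' @param i integer indices or character variant ids, in the desired order.
#' @param ... unused.
#' @return a `summary_data` with the requested variants in the requested
#'   order.
#' @export
`[.summary_data` <- function(x, i, ...) {
  if (is.character(i)) {
    miss <- setdiff(i, x$variant_ids)
    if (length(miss))
      stop("variant id(s) not present: ", paste(miss, collapse = ", "))
    i <- match(i, x$variant_ids)
  }
  summary_data(x$variant_ids[i],
               x$beta_exposures[i, , drop = FALSE],
               x$se_exposures[i, , drop = FALSE],
               x$beta_outcome[i],
               x$se_outcome[i],
               x$trait_names)
}

# ---------------------------------------------------------------------------

#' Variant correlation (LD) matrix
#'
#' @param rho J x J numeric matrix of pairwise correlations between variants.
#'   Must be symmetric (within `sym_tol`, enforced by averaging with its
#'   transpose), with unit diagonal, entries in \[-1, 1\], and positive
#'   semi-definite down to a smallest eigenvalue of `-psd_tol`.
#' @param variant_ids character vector of J identifiers; defaults to the
#'   row names of `rho` or `v1..vJ`.
#' @param sym_tol maximum tolerated asymmetry `max|rho - t(rho)|`
#'   (default 1e-8).
#' @param psd_tol magnitude of the most negative eigenvalue tolerated
#'   (default 1e-6); below that the matrix is treated as corrupt and an
#'   error advises pruning the variant set.
#'
#' @return An object of class `ld_matrix` with elements `variant_ids` and
#'   `rho`.
#' @export
ld_matrix <- function(rho, variant_ids = NULL, sym_tol = 1e-8,
                      psd_tol = 1e-6) {
  rho <- as.matrix(rho)
  if (nrow(rho) != ncol(rho)) stop("LD matrix must be square")
  J <- nrow(rho)
  if (anyNA(rho)) stop("LD matrix contains missing values")
  asym <- max(abs(rho - t(rho)))
  if (asym > sym_tol)
    stop("LD matrix asymmetric beyond tolerance (max |rho - t(rho)| = ",
         format(asym), ")")
  rho <- (rho + t(rho)) / 2
  if (max(abs(diag(rho) - 1)) > sym_tol)
    stop("LD matrix must have unit diagonal")
  diag(rho) <- 1
  if (max(abs(rho)) > 1 + sym_tol)
    stop("LD matrix entries must lie in [-1, 1]; max |entry| = ",
         format(max(abs(rho))))
  rho[rho > 1] <- 1
  rho[rho < -1] <- -1
  ev_min <- min(eigen(rho, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -psd_tol)
    stop("LD matrix is not positive semi-definite (smallest eigenvalue ",
         format(ev_min), "); the variant set is likely corrupt - prune ",
         "highly correlated variants or re-estimate the matrix")
  if (is.null(variant_ids)) variant_ids <- rownames(rho)
  if (is.null(variant_ids)) variant_ids <- paste0("v", seq_len(J))
  variant_ids <- as.character(variant_ids)
  if (length(variant_ids) != J)
    stop("variant_ids must have length ", J)
  if (anyDuplicated(variant_ids))
    stop("duplicate variant id(s) in LD matrix")
  dimnames(rho) <- list(variant_ids, variant_ids)
  structure(list(variant_ids = variant_ids, rho = rho), class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat("LD matrix:", length(x$variant_ids), "variants\n")
  invisible(x)
}

#' Subset / reorder an LD matrix
#'
#' Subsetting to a set `S` and then to `T` (a subset of `S`) gives the same
#' result as subsetting directly to `T`.
#'
#' @param x an `ld_matrix`.
#' @param i integer indices or character variant ids, in the desired order.
#' @param ... unused.
#' @return an `ld_matrix` over the requested variants.
#' @export
`[.ld_matrix` <- function(x, i, ...) {
  if (is.character(i)) {
    miss <- setdiff(i, x$variant_ids)
    if (length(miss))
      stop("variant id(s) not present in LD matrix: ",
           paste(miss, collapse = ", "))
    i <- match(i, x$variant_ids)
  }
  ld_matrix(x$rho[i, i, drop = FALSE], x$variant_ids[i])
}

# ---------------------------------------------------------------------------

#' Correlation matrix between exposure traits
#'
#' The K x K matrix of correlations between the exposures, used by the
#' MV-LIML objective. Defaults to the identity, which is also the setting
#' used throughout the simulation engine.
#'
#' @param phi K x K correlation matrix, or a single integer K for the
#'   identity.
#' @param trait_names optional K labels.
#' @return An object of class `exposure_correlation`.
#' @export
exposure_correlation <- function(phi, trait_names = NULL) {
  if (length(phi) == 1L && is.numeric(phi) && phi == round(phi) && phi >= 1)
    phi <- diag(as.integer(phi))
  phi <- as.matrix(phi)
  if (nrow(phi) != ncol(phi)) stop("exposure correlation must be square")
  if (max(abs(phi - t(phi))) > 1e-8) stop("exposure correlation must be symmetric")
  phi <- (phi + t(phi)) / 2
  if (max(abs(diag(phi) - 1)) > 1e-8)
    stop("exposure correlation must have unit diagonal")
  diag(phi) <- 1
  if (max(abs(phi)) > 1 + 1e-8)
    stop("exposure correlation entries must lie in [-1, 1]")
  ev_min <- min(eigen(phi, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-6)
    stop("exposure correlation is not positive semi-definite")
  if (!is.null(trait_names)) dimnames(phi) <- list(trait_names, trait_names)
  structure(list(phi = phi), class = "exposure_correlation")
}

# ---------------------------------------------------------------------------
# Text I/O. Summary statistics travel as TSV with one header row and columns
#   variant, beta_<trait>, se_<trait> (per exposure), beta_outcome, se_outcome
# mirroring GWAS summary-statistic conventions without committing to any
# consortium format. Matrices travel as whitespace- or comma-delimited square
# tables with an optional header row of variant ids. No allele harmonization
# is performed: inputs are assumed pre-harmonized to a common effect allele.

#' Read summarized genetic associations from a TSV file
#'
#' Expected columns: `variant`, then `beta_<trait>` and `se_<trait>` for each
#' exposure trait, and `beta_outcome` / `se_outcome`. Row order is preserved.
#'
#' @param path file path.
#' @param trait_names exposure trait labels; if `NULL`, inferred from the
#'   header (`beta_*` columns other than `beta_outcome`).
#' @return a [summary_data] object.
#' @export
read_summary_data <- function(path, trait_names = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"variant" %in% names(df)) stop("missing column 'variant' in ", path)
  if (is.null(trait_names)) {
    bcols <- grep("^beta_", names(df), value = TRUE)
    trait_names <- setdiff(sub("^beta_", "", bcols), "outcome")
    if (!length(trait_names))
      stop("no exposure beta_<trait> columns found in ", path)
  }
  need <- c(paste0("beta_", trait_names), paste0("se_", trait_names),
            "beta_outcome", "se_outcome")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  bad_se <- c(paste0("se_", trait_names), "se_outcome")
  for (cn in bad_se) {
    bad <- which(!is.finite(df[[cn]]) | df[[cn]] <= 0)
    if (length(bad))
      stop("non-positive or missing standard error in column '", cn,
           "' at row ", bad[1L])
  }
  summary_data(df$variant,
               as.matrix(df[paste0("beta_", trait_names)]),
               as.matrix(df[paste0("se_", trait_names)]),
               df$beta_outcome, df$se_outcome, trait_names)
}

#' Write summarized genetic associations to a TSV file
#' @param x a `summary_data` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_data <- function(x, path) {
  df <- data.frame(variant = x$variant_ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (k in seq_along(x$trait_names)) {
    df[[paste0("beta_", x$trait_names[k])]] <- x$beta_exposures[, k]
    df[[paste0("se_", x$trait_names[k])]] <- x$se_exposures[, k]
  }
  df$beta_outcome <- x$beta_outcome
  df$se_outcome <- x$se_outcome
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Read a square numeric matrix with an optional header row of ids.
# Delimiter is any run of whitespace or a comma.
read_square_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  split_row <- function(s) strsplit(trimws(s), "[,[:space:]]+")[[1L]]
  first <- split_row(lines[1L])
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  ids <- NULL
  if (has_header) {
    ids <- first
    lines <- lines[-1L]
  }
  rows <- lapply(lines, function(s) suppressWarnings(as.numeric(split_row(s))))
  n <- length(rows)
  if (!n) stop("empty matrix file: ", path)
  if (any(vapply(rows, length, 1L) != length(rows[[1L]])) ||
      anyNA(unlist(rows)))
    stop("malformed matrix file (ragged rows or non-numeric entries): ", path)
  m <- do.call(rbind, rows)
  if (nrow(m) != ncol(m)) stop("matrix in ", path, " is not square")
  if (!is.null(ids) && length(ids) != nrow(m))
    stop("header id count does not match matrix dimension in ", path)
  list(matrix = m, ids = ids)
}

#' Read a variant correlation (LD) matrix from a text file
#'
#' Accepts a whitespace- or comma-delimited square matrix with an optional
#' single header row of variant ids. When `variant_ids` is supplied the
#' matrix is reordered/subset to that order; ids that are requested but
#' absent raise an error listing them. Mild asymmetry (up to 1e-8) is
#' resolved by averaging with the transpose; anything larger is an error.
#'
#' @param path file path.
#' @param variant_ids optional ids to subset/reorder to.
#' @return an [ld_matrix] object.
#' @export
read_ld_matrix <- function(path, variant_ids = NULL) {
  parsed <- read_square_matrix(path)
  ids <- parsed$ids
  if (is.null(ids)) {
    ids <- if (!is.null(variant_ids) && length(variant_ids) == nrow(parsed$matrix))
      as.character(variant_ids) else paste0("v", seq_len(nrow(parsed$matrix)))
  }
  ld <- ld_matrix(parsed$matrix, ids)
  if (!is.null(variant_ids)) ld <- ld[as.character(variant_ids)]
  ld
}

#' Write an LD matrix to a tab-separated text file with a header of ids
#' @param x an `ld_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(x$variant_ids, collapse = "\t"), con)
  utils::write.table(x$rho, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an exposure correlation matrix from a text file
#'
#' Same square-matrix dialect as [read_ld_matrix()]: whitespace- or
#' comma-delimited, optional header row of trait names.
#'
#' @param path file path.
#' @param trait_names optional trait labels to subset/reorder to.
#' @return an [exposure_correlation] object.
#' @export
read_exposure_correlation <- function(path, trait_names = NULL) {
  parsed <- read_square_matrix(path)
  phi <- parsed$matrix
  labels <- parsed$ids
  if (!is.null(labels)) dimnames(phi) <- list(labels, labels)
  if (!is.null(trait_names) && !is.null(labels)) {
    miss <- setdiff(trait_names, labels)
    if (length(miss))
      stop("trait(s) not present in ", path, ": ", paste(miss, collapse = ", "))
    idx <- match(trait_names, labels)
    phi <- phi[idx, idx, drop = FALSE]
    labels <- trait_names
  }
  exposure_correlation(phi, labels)
}
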