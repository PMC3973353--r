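# Shrinkage estimation of correlation and partial-correlation matrices.
#
# The empirical correlation matrix R is shrunk toward the identity,
# R* = lambda I + (1 - lambda) R, with the analytic shrinkage intensity
#
#   lambda* = sum_{i<j} Var-hat(r_ij) / sum_{i<j} r_ij^2 , clipped to [0,1],
#
# where Var-hat(r_ij) = n / (n-1)^3 * sum_k (w_kij - w-bar_ij)^2 and
# w_kij is the product of the k-th sample's standardized values of
# variables i and j (so r_ij = n/(n-1) * w-bar_ij). Partial correlations
# are read off the inverse of R*:  pcor_ij = -Omega_ij / sqrt(Omega_ii
# Omega_jj), Omega = (R*)^{-1}. Shrinkage keeps R* positive definite and
# invertible even when the sample count is small relative to the number of
# metabolites.

# strip a metab_matrix down to its (complete) numeric matrix
as_values_matrix <- function(X) {
  if (inherits(X, "metab_matrix")) X <- X$values
  X <- as.matrix(X)
  if (anyNA(X)) stop("complete data required; drop incomplete samples first")
  X
}

# standardized data plus the cross-product summaries shared by the
# estimators below; sd uses the n-1 denominator
standardize_stats <- function(X) {
  X <- as_values_matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("at least 3 complete samples required")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("degenerate variance: constant column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  }
  xs <- scale(X, center = TRUE, scale = sds)
  list(xs = xs, n = n)
}

#' Empirical Pearson correlation matrix
#'
#' @param X a [metab_matrix()] or plain numeric matrix with at least 3
#'   complete rows and no constant column.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
empirical_correlation <- function(X) {
  s <- standardize_stats(X)
  r <- crossprod(s$xs) / (s$n - 1)
  diag(r) <- 1
  r[r > 1] <- 1
  r[r < -1] <- -1
  r
}

#' Analytic shrinkage intensity for the correlation matrix
#'
#' Estimates the weight \code{lambda} pulling the empirical correlation
#' matrix toward the identity: the ratio of the summed estimated sampling
#' variances of the off-diagonal correlations to their summed squares,
#' clipped to [0, 1]. When all off-diagonal correlations vanish the
#' convention is \code{lambda = 1}.
#'
#' @inheritParams empirical_correlation
#' @return Scalar \code{lambda} in [0, 1].
#' @export
shrinkage_intensity <- function(X) {
  s <- standardize_stats(X)
  n <- s$n
  wbar <- crossprod(s$xs) / n                 # mean per-sample product
  w2 <- crossprod(s$xs^2)                     # sum of squared products
  var_r <- n / (n - 1)^3 * (w2 - n * wbar^2)  # Var-hat(r_ij)
  r <- wbar * n / (n - 1)
  off <- upper.tri(r)
  denom <- sum(r[off]^2)
  if (denom == 0) return(1)
  min(1, max(0, sum(var_r[off]) / denom))
}

#' Shrinkage estimate of the partial-correlation matrix
#'
#' Computes \code{R* = lambda I + (1 - lambda) R} with \code{lambda} from
#' [shrinkage_intensity()] (re-estimated from the data supplied, unless
#' overridden), inverts it by a symmetric positive-definite factorization
#' (falling back to a pseudo-inverse with a warning if that fails), and
#' standardizes the negated inverse to partial correlations.
#'
#' @inheritParams empirical_correlation
#' @param lambda optional fixed shrinkage intensity in [0, 1]; by default
#'   estimated from \code{X}.
#' @return Object of class \code{pcor_matrix}: list with \code{matrix}
#'   (symmetric, unit diagonal, entries in [-1, 1]), \code{lambda},
#'   \code{n} and \code{metabolite_ids}.
#' @export
shrunk_partial_correlation <- function(X, lambda = NULL) {
  ids <- if (inherits(X, "metab_matrix")) X$metabolite_ids else colnames(X)
  if (is.null(lambda)) lambda <- shrinkage_intensity(X)
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  r <- empirical_correlation(X)
  n <- if (inherits(X, "metab_matrix")) nrow(X$values) else nrow(X)
  rs <- (1 - lambda) * r
  diag(rs) <- 1
  omega <- tryCatch(chol2inv(chol(rs)), error = function(e) {
    if (lambda == 0) {
      warning("singular correlation matrix at lambda = 0; ",
              "using pseudo-inverse (consider a lambda floor)")
      pseudo_inverse(rs)
    } else {
      stop("failed to invert shrunk correlation matrix: ",
           conditionMessage(e))
    }
  })
  d <- sqrt(diag(omega))
  pc <- -omega / tcrossprod(d)
  diag(pc) <- 1
  pc <- (pc + t(pc)) / 2
  pc[pc > 1] <- 1
  pc[pc < -1] <- -1
  dimnames(pc) <- list(ids, ids)
  structure(list(matrix = pc, lambda = lambda, n = n,
                 metabolite_ids = ids),
            class = "pcor_matrix")
}

pseudo_inverse <- function(A, tol = 1e-12) {
  e <- eigen(A, symmetric = TRUE)
  pos <- e$values > tol * max(abs(e$values))
  e$vectors[, pos, drop = FALSE] %*%
    (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
}

#' @export
print.pcor_matrix <- function(x, ...) {
  cat(sprintf("pcor_matrix: %d variables, lambda = %.4f, n = %d\n",
              ncol(x$matrix), x$lambda, x$n))
  invisible(x)
}

# fast internal path used by the permutation engine: standardize once,
# reuse cross-products for both lambda and the correlation matrix
pcor_shrunk_fast <- function(X) {
  n <- nrow(X)
  sds <- sqrt(colSums(scale(X, scale = FALSE)^2) / (n - 1))
  xs <- scale(X, center = TRUE, scale = sds)
  cp <- crossprod(xs)
  r <- cp / (n - 1)
  diag(r) <- 1
  wbar <- cp / n
  w2 <- crossprod(xs^2)
  var_r <- n / (n - 1)^3 * (w2 - n * wbar^2)
  off <- upper.tri(r)
  denom <- sum(r[off]^2)
  lambda <- if (denom == 0) 1 else min(1, max(0, sum(var_r[off]) / denom))
  rs <- (1 - lambda) * r
  diag(rs) <- 1
  omega <- chol2inv(chol(rs))
  d <- sqrt(diag(omega))
  pc <- -omega / tcrossprod(d)
  diag(pc) <- 1
  pc
}
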