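# Differential-network stage: two-sample permutation test on shrinkage
# partial-correlation differences, network construction at an uncorrected
# p < 0.01, and cross-cohort comparison by hypergeometric overlap.

#' Construct a differential network object
#'
#' @param nodes character vector of all metabolite ids (connected or not).
#' @param edges data.frame with columns \code{metabolite_1},
#'   \code{metabolite_2} (canonical order: id1 < id2), \code{delta}
#'   (pcor group2 - pcor group1), \code{p_perm}, \code{sign}.
#' @param threshold p-value threshold used to admit edges.
#' @param B number of permutations behind \code{p_perm}.
#' @return Object of class \code{differential_network}; element \code{D} is
#'   the number of differential connections.
#' @export
differential_network <- function(nodes, edges, threshold = NA_real_,
                                 B = NA_integer_) {
  nodes <- as.character(nodes)
  if (nrow(edges)) {
    swap <- edges$metabolite_1 > edges$metabolite_2
    if (any(swap)) {
      tmp <- edges$metabolite_1[swap]
      edges$metabolite_1[swap] <- edges$metabolite_2[swap]
      edges$metabolite_2[swap] <- tmp
    }
    if (!all(c(edges$metabolite_1, edges$metabolite_2) %in% nodes)) {
      stop("edge endpoint not in node set")
    }
    edges <- edges[order(edges$metabolite_1, edges$metabolite_2), ,
                   drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges, threshold = threshold,
                 B = B, D = nrow(edges)),
            class = "differential_network")
}

#' @export
print.differential_network <- function(x, ...) {
  cat(sprintf(
    "differential_network: %d nodes, D = %d edges (p < %s, B = %s)\n",
    length(x$nodes), x$D, format(x$threshold), format(x$B)))
  invisible(x)
}

#' Difference of shrinkage partial-correlation matrices between two groups
#'
#' @param X1,X2 residualized, complete [metab_matrix()] objects (or plain
#'   matrices) over the same metabolites: group 1 (e.g. non-obese) and
#'   group 2 (e.g. obese). The shrinkage intensity is re-estimated within
#'   each group.
#' @return Symmetric matrix \code{pcor(X2) - pcor(X1)} with zero diagonal.
#' @export
pcorr_difference <- function(X1, X2) {
  ids1 <- if (inherits(X1, "metab_matrix")) X1$metabolite_ids else colnames(X1)
  ids2 <- if (inherits(X2, "metab_matrix")) X2$metabolite_ids else colnames(X2)
  if (!identical(ids1, ids2)) stop("metabolite sets differ between groups")
  d <- shrunk_partial_correlation(X2)$matrix -
    shrunk_partial_correlation(X1)$matrix
  diag(d) <- 0
  d
}

#' Two-sample permutation test on partial-correlation differences
#'
#' Pools the two groups and relabels samples uniformly at random into
#' groups of the original sizes; for every replicate both shrinkage
#' partial-correlation matrices are recomputed (shrinkage intensity
#' re-estimated per group) and the absolute difference compared with the
#' observed one. Two-tailed p-values use the add-one estimator
#' \code{p = (1 + #\{|delta_b| >= |delta_obs|\}) / (B + 1)}, so p is never
#' 0 and lies in [1/(B+1), 1]. One shared permutation ensemble serves all
#' metabolite pairs.
#'
#' @inheritParams pcorr_difference
#' @param B number of permutations (the reference analysis used 100 000;
#'   smaller values are adequate for simulation work).
#' @param seed optional RNG seed for reproducibility.
#' @return list with \code{p} (symmetric matrix of permutation p-values,
#'   diagonal 1), \code{delta} (observed difference), \code{B},
#'   \code{n1}, \code{n2}.
#' @export
permutation_test_diffnet <- function(X1, X2, B = 1000L, seed = NULL) {
  if (B < 1) stop("B must be >= 1")
  M1 <- as_values_matrix(X1)
  M2 <- as_values_matrix(X2)
  ids1 <- if (inherits(X1, "metab_matrix")) X1$metabolite_ids else colnames(M1)
  ids2 <- if (inherits(X2, "metab_matrix")) X2$metabolite_ids else colnames(M2)
  if (!identical(ids1, ids2)) stop("metabolite sets differ between groups")
  n1 <- nrow(M1); n2 <- nrow(M2)
  if (n1 < 4L || n2 < 4L || n1 + n2 < 8L) {
    stop("group sizes too small for the permutation test (need n >= 4 each)")
  }
  if (!is.null(seed)) set.seed(seed)
  pool <- rbind(M1, M2)
  delta_obs <- pcor_shrunk_fast(M2) - pcor_shrunk_fast(M1)
  diag(delta_obs) <- 0
  abs_obs <- abs(delta_obs)
  count <- matrix(0L, nrow(abs_obs), ncol(abs_obs))
  n <- n1 + n2
  for (b in seq_len(B)) {
    idx <- sample.int(n, n1)
    d_b <- pcor_shrunk_fast(pool[-idx, , drop = FALSE]) -
      pcor_shrunk_fast(pool[idx, , drop = FALSE])
    diag(d_b) <- 0
    count <- count + (abs(d_b) >= abs_obs)
  }
  p <- (1 + count) / (B + 1)
  diag(p) <- 1
  dimnames(p) <- dimnames(delta_obs) <- list(ids1, ids1)
  list(p = p, delta = delta_obs, B = as.integer(B), n1 = n1, n2 = n2)
}

#' Build the differential network from p-value and difference matrices
#'
#' Admits an edge for every metabolite pair with \code{p < threshold}
#' (strict inequality; a pair at exactly the threshold is not connected).
#' Edge signs are the signs of the partial-correlation difference.
#'
#' @param p symmetric matrix of (permutation) p-values with metabolite ids
#'   as dimnames, or the list returned by [permutation_test_diffnet()].
#' @param delta symmetric matrix of partial-correlation differences
#'   (ignored when \code{p} is a permutation-test result).
#' @param threshold uncorrected p-value cutoff, default 0.01.
#' @param B number of permutations, recorded in the network.
#' @return A [differential_network()].
#' @export
build_differential_network <- function(p, delta = NULL, threshold = 0.01,
                                       B = NA_integer_) {
  if (is.list(p) && !is.null(p$p)) {
    if (is.na(B)) B <- p$B
    delta <- p$delta
    p <- p$p
  }
  if (is.null(delta)) stop("delta matrix required")
  if (!identical(dim(p), dim(delta))) stop("matrices not conformable")
  ids <- colnames(p)
  if (is.null(ids)) ids <- paste0("V", seq_len(ncol(p)))
  sel <- which(upper.tri(p) & p < threshold, arr.ind = TRUE)
  edges <- data.frame(
    metabolite_1 = ids[sel[, 1L]], metabolite_2 = ids[sel[, 2L]],
    delta = delta[sel], p_perm = p[sel],
    sign = ifelse(delta[sel] >= 0, 1L, -1L),
    stringsAsFactors = FALSE)
  differential_network(nodes = ids, edges = edges, threshold = threshold,
                       B = B)
}

#' Hypergeometric tail probability for network-overlap enrichment
#'
#' For two edge sets of sizes \code{M_edges} and \code{K_edges} drawn from
#' \code{N} candidate pairs, the probability of an overlap larger than
#' (strict, the default) or at least (inclusive) \code{x} under the
#' hypergeometric null. With the worked sizes (703, 36, 19, 5) the strict
#' tail is 1.97e-4.
#'
#' @param N number of candidate pairs in the universe.
#' @param M_edges,K_edges sizes of the two edge sets.
#' @param x observed overlap.
#' @param strict logical; \code{TRUE} for P(X > x), \code{FALSE} for
#'   P(X >= x).
#' @return Tail probability.
#' @export
hypergeometric_tail <- function(N, M_edges, K_edges, x, strict = TRUE) {
  if (N < 0 || M_edges < 0 || K_edges < 0 || M_edges > N || K_edges > N) {
    stop("require 0 <= M_edges, K_edges <= N")
  }
  if (x < 0 || x > min(M_edges, K_edges)) {
    stop("require 0 <= x <= min(M_edges, K_edges)")
  }
  q <- if (strict) x else x - 1
  stats::phyper(q, m = M_edges, n = N - M_edges, k = K_edges,
                lower.tail = FALSE)
}

#' Compare two differential networks across cohorts
#'
#' Intersects the two edge sets on unordered metabolite pairs, reports the
#' sign concordance of the overlapping connections, and tests the overlap
#' against the hypergeometric null on the N = M(M-1)/2 candidate pairs of
#' the shared node set.
#'
#' @param net1,net2 [differential_network()] objects on the same node set.
#' @param strict tail convention passed to [hypergeometric_tail()].
#' @return list of class \code{network_comparison}: \code{N},
#'   \code{M_edges}, \code{K_edges}, \code{x}, \code{overlap} (data.frame
#'   of shared pairs with both signs and \code{concordant} flag),
#'   \code{concordance} (fraction), \code{p_hyper}.
#' @export
compare_networks <- function(net1, net2, strict = TRUE) {
  stopifnot(inherits(net1, "differential_network"),
            inherits(net2, "differential_network"))
  if (!setequal(net1$nodes, net2$nodes)) stop("node sets differ")
  m <- length(net1$nodes)
  N <- m * (m - 1) / 2
  k1 <- pair_key(net1$edges$metabolite_1, net1$edges$metabolite_2)
  k2 <- pair_key(net2$edges$metabolite_1, net2$edges$metabolite_2)
  shared <- intersect(k1, k2)
  i1 <- match(shared, k1); i2 <- match(shared, k2)
  overlap <- data.frame(
    metabolite_1 = net1$edges$metabolite_1[i1],
    metabolite_2 = net1$edges$metabolite_2[i1],
    sign_1 = net1$edges$sign[i1], sign_2 = net2$edges$sign[i2],
    stringsAsFactors = FALSE)
  overlap$concordant <- overlap$sign_1 == overlap$sign_2
  x <- length(shared)
  structure(list(
    N = N, M_edges = nrow(net1$edges), K_edges = nrow(net2$edges),
    x = x, overlap = overlap,
    concordance = if (x > 0) mean(overlap$concordant) else NA_real_,
    p_hyper = hypergeometric_tail(N, nrow(net1$edges), nrow(net2$edges),
                                  x, strict = strict)),
    class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(sprintf(
    "network_comparison: N = %d pairs, M = %d, K = %d, x = %d, p = %.3g\n",
    x$N, x$M_edges, x$K_edges, x$x, x$p_hyper))
  if (x$x > 0) {
    cat(sprintf("sign concordance: %d/%d\n",
                sum(x$overlap$concordant), x$x))
  }
  invisible(x)
}
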