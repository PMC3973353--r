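# Simulation and ROC evaluation of both analysis stages.
#
# Scenarios combine (i) minor allele frequency and (ii) the size of the
# between-group difference in pairwise association. The GWCA arm draws
# genotypes under Hardy-Weinberg proportions and, per SNP, a focal
# bivariate-normal metabolite pair whose correlation depends on carrier
# status for truly associated SNPs. The differential-network arm draws two
# multivariate normal samples whose correlation matrices differ only on
# designated (vertex-disjoint) pairs. Candidates are ranked by each
# stage's p-values and scored by ROC/AUC against the truth labels.

#' Define a simulation scenario
#'
#' @param name scenario label.
#' @param maf minor allele frequency in (0, 0.5].
#' @param r_A,r_B focal-pair correlations in genotype group A (0 copies)
#'   and B (1-2 copies) for the GWCA arm; the differential-network arm
#'   uses the same two values as the group-specific pair correlations.
#' @param n total sample count.
#' @param n_true,n_null counts of truly differential and null candidates
#'   (SNPs in the GWCA arm; designated pairs in the network arm).
#' @param seed RNG seed making the scenario reproducible.
#' @return list of class \code{simulation_scenario}.
#' @export
simulation_scenario <- function(name, maf, r_A, r_B, n = 3000L,
                                n_true = 50L, n_null = 950L, seed = 1L) {
  if (maf <= 0 || maf > 0.5) stop("maf must lie in (0, 0.5]")
  if (abs(r_A) >= 1 || abs(r_B) >= 1) stop("|r| must be < 1")
  if (n_true + n_null < 2L || n_true < 1L || n_null < 1L) {
    stop("need at least one true and one null candidate")
  }
  structure(list(name = name, maf = maf, r_A = r_A, r_B = r_B,
                 n = as.integer(n), n_true = as.integer(n_true),
                 n_null = as.integer(n_null), seed = as.integer(seed)),
            class = "simulation_scenario")
}

#' Default four-scenario grid
#'
#' Crosses two minor allele frequencies (0.30, 0.05) with a large
#' (0.2 -> 0.8) and a small (0.2 -> 0.25) between-group change in the
#' focal-pair correlation, at n = 3000 with 50 true and 950 null
#' candidates, covering strong and weak effects at common and rare
#' variants.
#'
#' @param n,n_true,n_null scenario sizes (see [simulation_scenario()]).
#' @param seed base seed; scenario k uses \code{seed + k - 1}.
#' @return list of four [simulation_scenario()] objects.
#' @export
default_scenarios <- function(n = 3000L, n_true = 50L, n_null = 950L,
                              seed = 1L) {
  grid <- list(
    list(name = "maf0.30_large", maf = 0.30, r_A = 0.2, r_B = 0.8),
    list(name = "maf0.05_large", maf = 0.05, r_A = 0.2, r_B = 0.8),
    list(name = "maf0.30_small", maf = 0.30, r_A = 0.2, r_B = 0.25),
    list(name = "maf0.05_small", maf = 0.05, r_A = 0.2, r_B = 0.25))
  lapply(seq_along(grid), function(k) {
    g <- grid[[k]]
    simulation_scenario(g$name, g$maf, g$r_A, g$r_B, n = n,
                        n_true = n_true, n_null = n_null,
                        seed = seed + k - 1L)
  })
}

# bivariate normal pair with per-sample correlation rho (vectorized)
draw_pair <- function(n, rho) {
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  cbind(z1, rho * z1 + sqrt(1 - rho^2) * z2)
}

#' Simulate a GWCA dataset
#'
#' Each SNP's dosages are Binomial(2, maf) per sample (Hardy-Weinberg).
#' For a truly associated SNP, its focal metabolite pair is bivariate
#' normal with correlation \code{r_A} among samples carrying 0 copies and
#' \code{r_B} among carriers; null SNPs get an independent pair correlated
#' \code{r_A} for everyone. A warning is raised when the expected carrier
#' (or non-carrier) group falls below 8 samples.
#'
#' @param scenario a [simulation_scenario()].
#' @return list with \code{genotypes} ([genotype_matrix()]),
#'   \code{metabolites} ([metab_matrix()], two columns per SNP, flagged
#'   residualized), \code{pairs} (data.frame mapping each SNP to its focal
#'   pair) and logical \code{truth} per SNP.
#' @export
simulate_gwca_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  set.seed(scenario$seed)
  n <- scenario$n
  n_snp <- scenario$n_true + scenario$n_null
  p_carrier <- 1 - (1 - scenario$maf)^2
  exp_small <- n * min(p_carrier, 1 - p_carrier)
  if (exp_small < 8) {
    warning("expected genotype-group size below 8 (n * maf too small)")
  }
  truth <- c(rep(TRUE, scenario$n_true), rep(FALSE, scenario$n_null))
  dos <- matrix(stats::rbinom(n * n_snp, 2L, scenario$maf), nrow = n)
  vals <- matrix(NA_real_, n, 2L * n_snp)
  for (j in seq_len(n_snp)) {
    rho <- if (truth[j]) {
      ifelse(dos[, j] == 0, scenario$r_A, scenario$r_B)
    } else {
      rep(scenario$r_A, n)
    }
    vals[, c(2L * j - 1L, 2L * j)] <- draw_pair(n, rho)
  }
  snp_ids <- sprintf("snp%04d", seq_len(n_snp))
  met_ids <- as.vector(rbind(sprintf("M%04d.a", seq_len(n_snp)),
                             sprintf("M%04d.b", seq_len(n_snp))))
  markers <- data.frame(id = snp_ids, chrom = "1",
                        pos = seq_len(n_snp) * 1000L,
                        ref = "A", alt = "B", minor = "B",
                        stringsAsFactors = FALSE)
  samples <- sprintf("s%05d", seq_len(n))
  list(genotypes = genotype_matrix(dos, markers, sample_ids = samples),
       metabolites = metab_matrix(vals, sample_ids = samples,
                                  metabolite_ids = met_ids,
                                  residualized = TRUE),
       pairs = data.frame(snp = snp_ids,
                          metabolite_1 = sprintf("M%04d.a", seq_len(n_snp)),
                          metabolite_2 = sprintf("M%04d.b", seq_len(n_snp)),
                          stringsAsFactors = FALSE),
       truth = truth)
}

# target correlation matrix with the designated pair correlations
pair_sigma <- function(M, pairs_idx, r) {
  S <- diag(M)
  for (k in seq_len(nrow(pairs_idx))) {
    i <- pairs_idx[k, 1L]; j <- pairs_idx[k, 2L]
    S[i, j] <- S[j, i] <- r[min(k, length(r))]
  }
  S
}

#' Simulate a differential-network dataset
#'
#' Two multivariate normal samples over \code{M = 2 * n_true} variables
#' whose correlation matrices agree everywhere except on \code{n_true}
#' vertex-disjoint designated pairs, correlated \code{r_A} in group 1 and
#' \code{r_B} in group 2. Disjointness keeps both target matrices positive
#' definite for any |r| < 1; a non-positive-definite custom target raises
#' an error suggesting a nearest-positive-definite repair.
#'
#' @param scenario a [simulation_scenario()]; \code{n} samples are split
#'   into two equal groups.
#' @param n1,n2 optional explicit group sizes (default \code{n/2} each).
#' @return list with [metab_matrix()] objects \code{X1}, \code{X2}
#'   (flagged residualized), the canonical \code{pairs} over all
#'   M(M-1)/2 candidates and logical \code{truth} per pair.
#' @export
simulate_diffnet_dataset <- function(scenario,
                                     n1 = scenario$n %/% 2L,
                                     n2 = scenario$n - scenario$n %/% 2L) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  set.seed(scenario$seed)
  M <- 2L * scenario$n_true
  idx <- cbind(seq(1L, M, by = 2L), seq(2L, M, by = 2L))
  S1 <- pair_sigma(M, idx, scenario$r_A)
  S2 <- pair_sigma(M, idx, scenario$r_B)
  ch <- function(S) tryCatch(chol(S), error = function(e) {
    stop("target correlation matrix is not positive definite; ",
         "project it to the nearest positive-definite matrix first")
  })
  C1 <- ch(S1); C2 <- ch(S2)
  ids <- sprintf("V%03d", seq_len(M))
  X1 <- matrix(stats::rnorm(n1 * M), n1, M) %*% C1
  X2 <- matrix(stats::rnorm(n2 * M), n2, M) %*% C2
  colnames(X1) <- colnames(X2) <- ids
  pairs <- canonical_pairs(ids)
  true_keys <- pair_key(ids[idx[, 1L]], ids[idx[, 2L]])
  truth <- pair_key(pairs$metabolite_1, pairs$metabolite_2) %in% true_keys
  list(X1 = metab_matrix(X1, metabolite_ids = ids, residualized = TRUE),
       X2 = metab_matrix(X2, metabolite_ids = ids, residualized = TRUE),
       pairs = pairs, truth = truth)
}

#' ROC curve and area under it
#'
#' Sweeps the score threshold from high to low (ties grouped), recording
#' (false-positive-rate, true-positive-rate) points. The AUC is the
#' normalized Mann-Whitney statistic -- the probability that a random
#' positive outscores a random negative, ties counting one half -- which
#' equals the trapezoidal integral of the curve and is invariant under
#' strictly monotone transforms of the scores.
#'
#' @param scores numeric ranking scores, higher = more positive
#'   (e.g. \code{-log10(p)}).
#' @param truth logical (or 0/1) labels; both classes must be present.
#' @param step label recorded on the result (e.g. \code{"DiffNet"}).
#' @return Object of class \code{roc_result}: list with \code{points}
#'   (data.frame \code{fpr}, \code{tpr}), \code{auc}, \code{step}.
#' @export
roc_auc <- function(scores, truth, step = "") {
  truth <- as.logical(truth)
  if (length(scores) != length(truth)) stop("scores/truth length mismatch")
  if (anyNA(scores) || anyNA(truth)) stop("missing scores or labels")
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present in the truth labels")
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  ts <- scores[ord]; tt <- truth[ord]
  grp_end <- which(c(ts[-1L] != ts[-length(ts)], TRUE))
  tp <- cumsum(tt)[grp_end]; fp <- cumsum(!tt)[grp_end]
  points <- data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  structure(list(points = points, auc = auc, step = step),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result%s: AUC = %.4f (%d points)\n",
              if (nzchar(x$step)) paste0(" [", x$step, "]") else "",
              x$auc, nrow(x$points)))
  invisible(x)
}

#' Evaluate the GWCA stage on a simulated dataset
#'
#' Per SNP: dichotomize, groupwise pair correlation on that SNP's focal
#' pair, Fisher z test; SNPs are then ranked by p-value.
#'
#' @param sim result of [simulate_gwca_dataset()].
#' @return list with per-SNP \code{p}, the [roc_auc()] result \code{roc}
#'   and \code{auc}.
#' @export
evaluate_gwca_step <- function(sim) {
  n_snp <- ncol(sim$genotypes$dosages)
  X <- sim$metabolites$values
  p <- vapply(seq_len(n_snp), function(j) {
    g <- dichotomize_genotype(sim$genotypes$dosages[, j])
    if (g$untestable) return(NA_real_)
    cols <- c(2L * j - 1L, 2L * j)
    a <- X[g$A, cols, drop = FALSE]
    b <- X[g$B, cols, drop = FALSE]
    if (nrow(a) < 4L || nrow(b) < 4L) return(NA_real_)
    z <- fisher_z_test(stats::cor(a[, 1L], a[, 2L]), nrow(a),
                       stats::cor(b[, 1L], b[, 2L]), nrow(b))
    z$p
  }, numeric(1))
  ok <- !is.na(p)
  roc <- roc_auc(-log10(p[ok]), sim$truth[ok], step = "GWCA")
  list(p = p, roc = roc, auc = roc$auc)
}

#' Evaluate the differential-network stage on a simulated dataset
#'
#' Runs the two-sample permutation test and ranks all candidate pairs by
#' their permutation p-value.
#'
#' @param sim result of [simulate_diffnet_dataset()].
#' @param B number of permutations.
#' @param seed RNG seed for the permutation ensemble.
#' @return list with the permutation result \code{perm}, per-pair
#'   \code{p} (aligned with \code{sim$pairs}), the [roc_auc()] result
#'   \code{roc} and \code{auc}.
#' @export
evaluate_diffnet_step <- function(sim, B = 1000L, seed = NULL) {
  perm <- permutation_test_diffnet(sim$X1, sim$X2, B = B, seed = seed)
  p <- perm$p[cbind(match(sim$pairs$metabolite_1, colnames(perm$p)),
                    match(sim$pairs$metabolite_2, colnames(perm$p)))]
  roc <- roc_auc(-log10(p), sim$truth, step = "DiffNet")
  list(perm = perm, p = p, roc = roc, auc = roc$auc)
}

#' Run both stages over a scenario grid
#'
#' For each scenario, simulates and evaluates the differential-network arm
#' (permutation test over all candidate pairs) and the GWCA arm (Fisher z
#' test over all candidate SNPs), returning both AUCs.
#'
#' @param scenarios list of [simulation_scenario()] objects (default the
#'   four-scenario grid of [default_scenarios()]).
#' @param B_perm permutations for the network arm.
#' @param diffnet logical; set \code{FALSE} to skip the (slower)
#'   permutation arm.
#' @return data.frame with one row per scenario: name, maf, r_A, r_B, n,
#'   auc_diffnet, auc_gwca.
#' @export
run_scenario_suite <- function(scenarios = default_scenarios(),
                               B_perm = 1000L, diffnet = TRUE) {
  if (length(scenarios) < 1L) stop("at least one scenario required")
  rows <- lapply(scenarios, function(sc) {
    auc_dn <- NA_real_
    if (diffnet) {
      sim_dn <- simulate_diffnet_dataset(sc)
      auc_dn <- evaluate_diffnet_step(sim_dn, B = B_perm,
                                      seed = sc$seed + 10000L)$auc
    }
    sim_gw <- simulate_gwca_dataset(sc)
    auc_gw <- evaluate_gwca_step(sim_gw)$auc
    data.frame(scenario = sc$name, maf = sc$maf, r_A = sc$r_A,
               r_B = sc$r_B, n = sc$n, auc_diffnet = auc_dn,
               auc_gwca = auc_gw, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
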