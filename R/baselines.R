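# Conventional single-variable baselines: univariate metabolite-BMI
# regression with standardized coefficients and BH q-values, and an
# additive single-SNP GWAS of BMI, both with sex as a covariate.

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: with the p-values sorted
#' ascending, \code{q_(i) = min_\{j >= i\} p_(j) * m / j}, capped at 1 and
#' returned in the input order.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return q-values in the input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Univariate metabolite-BMI regression
#'
#' Fits one ordinary least-squares model per metabolite with sex as a
#' covariate. By default BMI is regressed on the metabolite
#' (\code{direction = "bmi_on_metabolite"}); the opposite direction is
#' available. The standardized coefficient is obtained by z-scoring both
#' BMI and the metabolite before fitting (sex enters as an unstandardized
#' binary code). Significance is flagged at the Bonferroni level
#' \code{alpha / M} and BH q-values are computed across the M tests.
#'
#' @param metabolites a [metab_matrix()] (raw concentrations).
#' @param covariates data.frame with \code{sample_id}, \code{bmi},
#'   \code{sex}.
#' @param alpha Bonferroni family level; default 0.01 so the per-test
#'   cutoff is 0.01/M.
#' @param direction \code{"bmi_on_metabolite"} (default) or
#'   \code{"metabolite_on_bmi"}.
#' @return data.frame with one row per metabolite: \code{variable},
#'   \code{beta_std}, \code{p}, \code{q}, \code{significant} (Bonferroni),
#'   plus the cutoff as attribute \code{"bonferroni_cutoff"}. Zero-variance
#'   metabolites are skipped with a warning.
#' @export
metabolite_bmi_regression <- function(metabolites, covariates, alpha = 0.01,
                                      direction = c("bmi_on_metabolite",
                                                    "metabolite_on_bmi")) {
  direction <- match.arg(direction)
  stopifnot(inherits(metabolites, "metab_matrix"))
  idx <- match(metabolites$sample_ids, covariates$sample_id)
  if (anyNA(idx)) stop("covariates missing for some samples")
  bmi <- covariates$bmi[idx]
  sex <- covariates$sex[idx]
  M <- length(metabolites$metabolite_ids)
  rows <- lapply(seq_len(M), function(j) {
    y <- metabolites$values[, j]
    ok <- !is.na(y) & !is.na(bmi) & !is.na(sex)
    if (sum(ok) < 4L || stats::sd(y[ok]) == 0) {
      warning("skipping zero-variance or undersized metabolite: ",
              metabolites$metabolite_ids[j])
      return(NULL)
    }
    yz <- as.numeric(scale(y[ok]))
    bz <- as.numeric(scale(bmi[ok]))
    fit <- if (direction == "bmi_on_metabolite") {
      stats::lm(bz ~ yz + sex[ok])
    } else {
      stats::lm(yz ~ bz + sex[ok])
    }
    sm <- summary(fit)$coefficients
    data.frame(variable = metabolites$metabolite_ids[j],
               beta_std = sm[2L, 1L], p = sm[2L, 4L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) stop("no testable metabolites")
  out$q <- bh_adjust(out$p)
  cutoff <- alpha / M
  out$significant <- out$p < cutoff
  attr(out, "bonferroni_cutoff") <- cutoff
  rownames(out) <- NULL
  out
}

#' Additive single-SNP GWAS of BMI
#'
#' Per SNP, ordinary least squares of BMI on the minor-allele dosage
#' (additive coding) with sex as a covariate; samples with a missing
#' dosage are dropped per SNP. Monomorphic SNPs (after missing-drop) are
#' skipped. Genome-wide significance is flagged at \code{p < 5e-8}.
#'
#' @param genotypes a QC'd [genotype_matrix()].
#' @param covariates data.frame with \code{sample_id}, \code{bmi},
#'   \code{sex}; matched to the genotype samples by id.
#' @param threshold genome-wide significance threshold, default 5e-8.
#' @return data.frame with one row per tested SNP: \code{variable} (snp
#'   id), \code{beta}, \code{p}, \code{q}, \code{significant}.
#' @export
single_snp_gwas <- function(genotypes, covariates, threshold = 5e-8) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  idx <- match(genotypes$sample_ids, covariates$sample_id)
  if (anyNA(idx)) stop("covariates missing for some samples")
  bmi <- covariates$bmi[idx]
  sex <- covariates$sex[idx]
  rows <- lapply(seq_len(ncol(genotypes$dosages)), function(j) {
    g <- genotypes$dosages[, j]
    ok <- !is.na(g) & !is.na(bmi) & !is.na(sex)
    if (sum(ok) < 4L || stats::var(g[ok]) == 0) return(NULL)
    sm <- summary(stats::lm(bmi[ok] ~ g[ok] + sex[ok]))$coefficients
    data.frame(variable = genotypes$markers$id[j],
               beta = sm[2L, 1L], p = sm[2L, 4L], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) {
    warning("no testable SNPs")
    return(data.frame(variable = character(), beta = numeric(),
                      p = numeric(), q = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  }
  out$q <- bh_adjust(out$p)
  out$significant <- out$p < threshold
  rownames(out) <- NULL
  out
}
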