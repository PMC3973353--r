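# Covariate residualization, BMI group assignment, and marker QC
# (call rate, minor allele frequency, Hardy-Weinberg equilibrium).

#' Residualize metabolites on covariates
#'
#' Replaces each metabolite by the residuals of an ordinary least-squares
#' regression (with intercept) of that metabolite on the named covariates,
#' removing e.g. the confounding effect of sex on serum metabolite levels.
#' The fit uses all samples jointly (before any group split). Samples with a
#' missing covariate are dropped and reported via a warning.
#'
#' @param metabolites a [metab_matrix()].
#' @param covariates data.frame with a \code{sample_id} column and the
#'   covariate columns.
#' @param covariate_names character vector of covariate columns to regress
#'   out; default \code{"sex"}.
#' @return A [metab_matrix()] with \code{residualized = TRUE}; every column
#'   has mean zero and is orthogonal to each covariate.
#' @export
residualize_on_covariates <- function(metabolites, covariates,
                                      covariate_names = "sex") {
  stopifnot(inherits(metabolites, "metab_matrix"))
  if (metabolites$residualized) {
    warning("input is already residualized; residualizing again")
  }
  miss_cov <- setdiff(covariate_names, names(covariates))
  if (length(miss_cov)) {
    stop("covariate(s) not found: ", paste(miss_cov, collapse = ", "))
  }
  cov <- covariates[match(metabolites$sample_ids, covariates$sample_id),
                    covariate_names, drop = FALSE]
  if (any(is.na(match(metabolites$sample_ids, covariates$sample_id)))) {
    stop("covariates missing for some samples")
  }
  keep <- stats::complete.cases(cov)
  if (!all(keep)) {
    warning(sum(!keep), " sample(s) dropped for missing covariates")
  }
  X <- stats::model.matrix(~ ., data = cov[keep, , drop = FALSE])
  for (v in covariate_names) {
    col <- cov[keep, v]
    if (is.numeric(col) && stats::var(col) == 0) {
      stop("degenerate design: covariate '", v, "' is constant")
    }
  }
  Y <- metabolites$values[keep, , drop = FALSE]
  res <- stats::lm.fit(X, Y)$residuals
  if (is.null(dim(res))) res <- matrix(res, ncol = ncol(Y))
  metab_matrix(res, sample_ids = metabolites$sample_ids[keep],
               metabolite_ids = metabolites$metabolite_ids,
               residualized = TRUE)
}

#' Assign samples to BMI groups
#'
#' Classifies each sample as non-obese (\code{group1}), obese
#' (\code{group2}) or \code{excluded}. With the adult defaults, obese means
#' BMI strictly above 30 kg/m^2 and non-obese means BMI in the closed
#' interval [18.5, 25]; everything else (including the 25-30 gap and missing
#' BMI) is excluded. Cutoffs may be sex-specific: pass named vectors with
#' one element per sex code.
#'
#' @param covariates data.frame with \code{sample_id}, \code{bmi} and,
#'   for sex-specific cutoffs, \code{sex}.
#' @param cutoffs list with \code{obese_min}, \code{nonobese_low},
#'   \code{nonobese_high}; each either a scalar or a vector named by sex
#'   code.
#' @return data.frame (class \code{group_assignment}) with columns
#'   \code{sample_id}, \code{label}; the rule used is attached as the
#'   \code{"rule"} attribute.
#' @export
assign_bmi_groups <- function(covariates,
                              cutoffs = list(obese_min = 30,
                                             nonobese_low = 18.5,
                                             nonobese_high = 25)) {
  need <- c("obese_min", "nonobese_low", "nonobese_high")
  if (!all(need %in% names(cutoffs))) {
    stop("cutoffs must provide: ", paste(need, collapse = ", "))
  }
  pick <- function(cut) {
    if (length(cut) == 1L && is.null(names(cut))) {
      rep(as.numeric(cut), nrow(covariates))
    } else {
      if (!"sex" %in% names(covariates)) {
        stop("sex-specific cutoffs require a 'sex' covariate column")
      }
      as.numeric(cut[as.character(covariates$sex)])
    }
  }
  obese_min <- pick(cutoffs$obese_min)
  lo <- pick(cutoffs$nonobese_low)
  hi <- pick(cutoffs$nonobese_high)
  if (any(hi > obese_min, na.rm = TRUE)) {
    stop("configuration error: overlapping cutoff ranges ",
         "(nonobese_high > obese_min)")
  }
  bmi <- covariates$bmi
  label <- rep("excluded", nrow(covariates))
  label[which(bmi > obese_min)] <- "group2"
  label[which(bmi >= lo & bmi <= hi)] <- "group1"
  out <- data.frame(sample_id = as.character(covariates$sample_id),
                    label = label, stringsAsFactors = FALSE)
  attr(out, "rule") <- sprintf(
    "group2 (obese): bmi > %s; group1 (non-obese): %s <= bmi <= %s",
    paste(unique(obese_min), collapse = "/"),
    paste(unique(lo), collapse = "/"), paste(unique(hi), collapse = "/"))
  class(out) <- c("group_assignment", "data.frame")
  out
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' (AA, Aa, aa) against the expected proportions p^2, 2pq, q^2, with the
#' allele frequency estimated from the counts. Monomorphic markers return
#' chi2 = 0, p = 1 by convention.
#'
#' @param n_AA,n_Aa,n_aa non-negative genotype counts.
#' @return list with \code{chi2} and \code{p} (upper tail, 1 df).
#' @examples
#' hwe_chi2_test(25, 50, 25)   # perfect HWE: chi2 = 0, p = 1
#' hwe_chi2_test(0, 100, 0)    # all heterozygotes: chi2 = 100
#' @export
hwe_chi2_test <- function(n_AA, n_Aa, n_aa) {
  obs <- c(n_AA, n_Aa, n_aa)
  if (any(obs < 0) || any(obs != round(obs))) {
    stop("genotype counts must be non-negative integers")
  }
  n <- sum(obs)
  if (n == 0) stop("total genotype count must be positive")
  p_hat <- (2 * n_AA + n_Aa) / (2 * n)
  if (p_hat %in% c(0, 1)) return(list(chi2 = 0, p = 1))
  expct <- n * c(p_hat^2, 2 * p_hat * (1 - p_hat), (1 - p_hat)^2)
  chi2 <- sum((obs - expct)^2 / expct)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Marker quality control
#'
#' Removes markers failing any of: call rate below \code{call_rate_min},
#' minor allele frequency below \code{maf_min}, Hardy-Weinberg equilibrium
#' p-value below \code{hwe_p_min} (defaults: 95\%, 1\%, 1e-4).
#'
#' @param genotypes a [genotype_matrix()] (minor-allele coded).
#' @param call_rate_min minimum fraction of non-missing genotypes.
#' @param maf_min minimum minor allele frequency.
#' @param hwe_p_min minimum HWE p-value.
#' @return list with \code{genotypes} (filtered) and \code{report}, a
#'   data.frame giving all three statistics and pass/fail flags per marker.
#' @export
snp_qc <- function(genotypes, call_rate_min = 0.95, maf_min = 0.01,
                   hwe_p_min = 1e-4) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  dos <- genotypes$dosages
  n <- nrow(dos)
  call_rate <- colSums(!is.na(dos)) / n
  freq <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  maf[is.nan(maf)] <- 0
  hwe <- vapply(seq_len(ncol(dos)), function(j) {
    d <- dos[, j]
    cnt <- c(sum(d == 0, na.rm = TRUE), sum(d == 1, na.rm = TRUE),
             sum(d == 2, na.rm = TRUE))
    if (sum(cnt) == 0) return(c(0, 1))
    h <- hwe_chi2_test(cnt[1L], cnt[2L], cnt[3L])
    c(h$chi2, h$p)
  }, numeric(2))
  report <- data.frame(
    id = genotypes$markers$id,
    call_rate = call_rate, maf = maf,
    hwe_chi2 = hwe[1L, ], hwe_p = hwe[2L, ],
    pass_call_rate = call_rate >= call_rate_min,
    pass_maf = maf >= maf_min,
    pass_hwe = hwe[2L, ] >= hwe_p_min,
    stringsAsFactors = FALSE)
  report$pass <- report$pass_call_rate & report$pass_maf & report$pass_hwe
  keep <- which(report$pass)
  if (length(keep) == 0L) {
    warning("all markers removed by QC; returning empty matrix")
    out <- structure(list(dosages = dos[, 0, drop = FALSE],
                          markers = genotypes$markers[0, , drop = FALSE],
                          sample_ids = genotypes$sample_ids),
                     class = "genotype_matrix")
  } else {
    out <- genotype_matrix(dos[, keep, drop = FALSE],
                           genotypes$markers[keep, , drop = FALSE],
                           genotypes$sample_ids)
  }
  list(genotypes = out, report = report)
}

#' Dichotomize one SNP's dosages into genotype groups A and B
#'
#' Group A carries 0 copies of the minor allele, group B one or two copies;
#' missing genotypes belong to neither. An empty group makes the SNP
#' untestable (flagged, not an error).
#'
#' @param dosages numeric vector of 0/1/2/NA dosages for one SNP.
#' @return list with integer index vectors \code{A} and \code{B},
#'   \code{untestable} flag and \code{reason}.
#' @examples
#' dichotomize_genotype(c(0, 1, 2, 0))  # A = 1,4; B = 2,3
#' @export
dichotomize_genotype <- function(dosages) {
  if (!all(dosages %in% c(0, 1, 2) | is.na(dosages))) {
    stop("dosages must lie in {0, 1, 2, NA}")
  }
  A <- which(!is.na(dosages) & dosages == 0)
  B <- which(!is.na(dosages) & dosages >= 1)
  untestable <- length(A) == 0L || length(B) == 0L
  reason <- if (!untestable) NA_character_
  else if (length(A) == 0L) "no homozygous-major samples"
  else "no minor-allele carriers"
  list(A = A, B = B, untestable = untestable, reason = reason)
}

#' Drop samples with any missing metabolite value
#'
#' Listwise deletion prior to correlation estimation (the shrinkage
#' estimator assumes a complete matrix).
#'
#' @param metabolites a [metab_matrix()].
#' @return A [metab_matrix()] restricted to complete rows.
#' @export
drop_incomplete_samples <- function(metabolites) {
  stopifnot(inherits(metabolites, "metab_matrix"))
  keep <- stats::complete.cases(metabolites$values)
  if (all(keep)) return(metabolites)
  metab_matrix(metabolites$values[keep, , drop = FALSE],
               sample_ids = metabolites$sample_ids[keep],
               metabolite_ids = metabolites$metabolite_ids,
               residualized = metabolites$residualized)
}
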