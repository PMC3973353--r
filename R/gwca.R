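# Genome-wide correlation analysis (GWCA): every SNP is tested for a
# genotype-dependent difference in the correlation of selected metabolite
# pairs, via dichotomization into carriers/non-carriers of the minor allele
# and the Fisher z test for the equality of two correlations.

#' Fisher z test for the equality of two independent correlations
#'
#' Applies the variance-stabilizing transform \code{z = atanh(r)} to each
#' groupwise correlation; the statistic
#' \code{Z = (z_A - z_B) / sqrt(1/(n_A - 3) + 1/(n_B - 3))} is referred to
#' the standard normal, two-tailed. Correlations at exactly +/-1 are
#' clamped to +/-(1 - 1e-15) with a warning.
#'
#' @param r_A,r_B Pearson correlations in the two groups.
#' @param n_A,n_B group sample sizes, both > 3.
#' @return list with \code{Z} and two-tailed \code{p}.
#' @examples
#' fisher_z_test(0.8, 103, 0.2, 103)  # Z ~ 6.335
#' @export
fisher_z_test <- function(r_A, n_A, r_B, n_B) {
  if (n_A <= 3 || n_B <= 3) stop("group sizes must exceed 3")
  if (abs(r_A) > 1 || abs(r_B) > 1) stop("correlations must lie in [-1, 1]")
  if (abs(r_A) == 1 || abs(r_B) == 1) {
    warning("correlation at +/-1 clamped for the z transform")
    lim <- 1 - 1e-15
    r_A <- max(-lim, min(lim, r_A))
    r_B <- max(-lim, min(lim, r_B))
  }
  Z <- (atanh(r_A) - atanh(r_B)) /
    sqrt(1 / (n_A - 3) + 1 / (n_B - 3))
  list(Z = Z, p = 2 * stats::pnorm(-abs(Z)))
}

#' Groupwise Pearson correlation of one metabolite pair
#'
#' Computes the correlation of the two (covariate-residualized) metabolites
#' separately in two disjoint sample groups, dropping rows missing either
#' metabolite. Groups below the minimum size, or with a constant
#' metabolite, are flagged untestable rather than raising an error.
#'
#' @param metabolites a [metab_matrix()] (residualized) or plain matrix.
#' @param pair length-2 character vector (or 2 column indices) naming the
#'   metabolite pair.
#' @param indices_A,indices_B disjoint sample index vectors (genotype
#'   groups A and B).
#' @param min_n minimum per-group size, default 4.
#' @return list with \code{r_A}, \code{n_A}, \code{r_B}, \code{n_B},
#'   \code{untestable}, \code{reason}.
#' @export
groupwise_pair_correlation <- function(metabolites, pair, indices_A,
                                       indices_B, min_n = 4L) {
  X <- if (inherits(metabolites, "metab_matrix")) metabolites$values
  else as.matrix(metabolites)
  if (length(pair) != 2L) stop("pair must name exactly two metabolites")
  if (length(intersect(indices_A, indices_B))) {
    stop("genotype groups must be disjoint")
  }
  sub <- X[, pair, drop = FALSE]
  one_group <- function(idx) {
    v <- sub[idx, , drop = FALSE]
    v <- v[stats::complete.cases(v), , drop = FALSE]
    n <- nrow(v)
    if (n < min_n) return(list(r = NA_real_, n = n, reason = "group too small"))
    if (stats::sd(v[, 1L]) == 0 || stats::sd(v[, 2L]) == 0) {
      return(list(r = NA_real_, n = n, reason = "constant metabolite"))
    }
    list(r = stats::cor(v[, 1L], v[, 2L]), n = n, reason = NA_character_)
  }
  a <- one_group(indices_A)
  b <- one_group(indices_B)
  reason <- stats::na.omit(c(a$reason, b$reason))
  list(r_A = a$r, n_A = a$n, r_B = b$r, n_B = b$n,
       untestable = length(reason) > 0,
       reason = if (length(reason)) reason[1L] else NA_character_)
}

#' Effective GWCA significance threshold
#'
#' The genome-wide threshold 5e-8 Bonferroni-adjusted by the number of
#' differential connections D carried into the analysis: \code{base / D}.
#'
#' @param D number of tested differential connections (>= 1).
#' @param base genome-wide base threshold, default 5e-8.
#' @return list with \code{base}, \code{D}, \code{effective}.
#' @export
gwca_threshold <- function(D, base = 5e-8) {
  if (D < 1 || D != round(D)) stop("D must be a positive integer")
  list(base = base, D = as.integer(D), effective = base / D)
}

#' Run the genome-wide correlation analysis
#'
#' For every (SNP, metabolite pair) combination: dichotomize the SNP into
#' genotype groups A (0 minor-allele copies) and B (1 or 2 copies), compute
#' the groupwise Pearson correlations of the pair on residualized data, and
#' test their equality with the Fisher z method. Significance uses the
#' strict threshold \code{base / D} where D defaults to the number of
#' pairs tested. Untestable SNPs (empty genotype group, tiny group,
#' constant metabolite) are recorded with a reason, not dropped silently.
#'
#' @param genotypes a QC'd [genotype_matrix()]; samples must align with
#'   \code{metabolites} rows (matched by sample id when both are named).
#' @param metabolites a residualized [metab_matrix()].
#' @param pairs data.frame with columns \code{metabolite_1},
#'   \code{metabolite_2} (typically the replicated differential
#'   connections).
#' @param threshold a [gwca_threshold()] list; default uses
#'   \code{D = nrow(pairs)}.
#' @param progress_every log a progress line every this many SNPs
#'   (0 disables).
#' @return data.frame with one row per (SNP, pair): snp, chrom, pos,
#'   metabolite_1, metabolite_2, n_A, n_B, r_A, r_B, Z, p, significant,
#'   status.
#' @export
run_gwca <- function(genotypes, metabolites, pairs,
                     threshold = gwca_threshold(nrow(pairs)),
                     progress_every = 10000L) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(metabolites, "metab_matrix"))
  if (!metabolites$residualized) {
    warning("metabolites are not residualized; GWCA assumes covariate ",
            "effects were removed")
  }
  if (nrow(pairs) == 0L) stop("no metabolite pairs supplied")
  bad <- !(c(pairs$metabolite_1, pairs$metabolite_2) %in%
             metabolites$metabolite_ids)
  if (any(bad)) stop("pair metabolite(s) not in the metabolite matrix")
  # align samples
  idx <- match(metabolites$sample_ids, genotypes$sample_ids)
  if (anyNA(idx)) stop("sample ids of genotypes and metabolites do not match")
  dos <- genotypes$dosages[idx, , drop = FALSE]
  n_snp <- ncol(dos)
  if (n_snp == 0L) stop("empty testable SNP set")
  mk <- genotypes$markers
  res <- vector("list", n_snp)
  for (j in seq_len(n_snp)) {
    g <- dichotomize_genotype(dos[, j])
    rows <- lapply(seq_len(nrow(pairs)), function(k) {
      pr <- c(pairs$metabolite_1[k], pairs$metabolite_2[k])
      if (g$untestable) {
        return(data.frame(
          snp = mk$id[j], chrom = mk$chrom[j], pos = mk$pos[j],
          metabolite_1 = pr[1L], metabolite_2 = pr[2L],
          n_A = length(g$A), n_B = length(g$B),
          r_A = NA_real_, r_B = NA_real_, Z = NA_real_, p = NA_real_,
          significant = FALSE,
          status = paste0("untestable: ", g$reason),
          stringsAsFactors = FALSE))
      }
      gc <- groupwise_pair_correlation(metabolites, pr, g$A, g$B)
      if (gc$untestable) {
        z <- list(Z = NA_real_, p = NA_real_)
        status <- paste0("untestable: ", gc$reason)
      } else {
        z <- fisher_z_test(gc$r_A, gc$n_A, gc$r_B, gc$n_B)
        status <- "ok"
      }
      data.frame(
        snp = mk$id[j], chrom = mk$chrom[j], pos = mk$pos[j],
        metabolite_1 = pr[1L], metabolite_2 = pr[2L],
        n_A = gc$n_A, n_B = gc$n_B, r_A = gc$r_A, r_B = gc$r_B,
        Z = z$Z, p = z$p,
        significant = !is.na(z$p) && z$p < threshold$effective,
        status = status, stringsAsFactors = FALSE)
    })
    res[[j]] <- do.call(rbind, rows)
    if (progress_every > 0 && j %% progress_every == 0) {
      message("GWCA: tested ", j, " / ", n_snp, " SNPs")
    }
  }
  out <- do.call(rbind, res)
  attr(out, "threshold") <- threshold
  out
}

#' Assign records to the nearest annotated gene
#'
#' Distance is 0 when the SNP lies within the gene interval (1-based
#' inclusive), otherwise the distance to the nearest interval boundary.
#' Genes farther than \code{max_distance} (default 1 Mb, inclusive) leave
#' the record unassigned. Equidistant genes are broken lexicographically,
#' with all tied symbols reported in \code{tied_genes}.
#'
#' @param records data.frame with \code{chrom} and \code{pos} columns (as
#'   from [run_gwca()]).
#' @param annotation data.frame from [read_annotation_table()].
#' @param max_distance maximum assignment distance in bases.
#' @return \code{records} with added \code{candidate_gene},
#'   \code{gene_distance}, \code{tied_genes} columns.
#' @export
annotate_nearest_gene <- function(records, annotation,
                                  max_distance = 1e6) {
  records$candidate_gene <- NA_character_
  records$gene_distance <- NA_real_
  records$tied_genes <- NA_character_
  for (i in seq_len(nrow(records))) {
    ann <- annotation[annotation$chrom == records$chrom[i], , drop = FALSE]
    if (nrow(ann) == 0L) next
    pos <- records$pos[i]
    inside <- pos >= ann$start & pos <= ann$end
    dist <- ifelse(inside, 0, pmin(abs(pos - ann$start), abs(pos - ann$end)))
    dmin <- min(dist)
    if (dmin > max_distance) next
    tied <- sort(ann$gene[dist == dmin])
    records$candidate_gene[i] <- tied[1L]
    records$gene_distance[i] <- dmin
    if (length(tied) > 1L) {
      records$tied_genes[i] <- paste(tied, collapse = ",")
    }
  }
  records
}
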