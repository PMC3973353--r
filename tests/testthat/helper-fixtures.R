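# Fixture builders and independent oracles shared across the test files.
# Everything is generated in code; no binary data.

write_metab_tsv <- function(values, ids, sample_ids = NULL,
                            path = tempfile(fileext = ".tsv")) {
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(values)))
  tab <- data.frame(sample_id = sample_ids, values, check.names = FALSE)
  names(tab) <- c("sample_id", ids)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_vcf_fixture <- function(records, samples = c("S1", "S2", "S3"),
                              path = tempfile(fileext = ".vcf")) {
  header <- c("##fileformat=VCFv4.2",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", "FORMAT", samples),
                    collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

vcf_record <- function(chrom, pos, id, ref, alt, gts) {
  paste(c(chrom, pos, id, ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

# brute-force shrinkage-intensity oracle: per-sample products, pair by pair
oracle_lambda <- function(X) {
  n <- nrow(X)
  xs <- scale(X)
  num <- 0
  den <- 0
  for (i in seq_len(ncol(X) - 1)) {
    for (j in seq(i + 1, ncol(X))) {
      w <- xs[, i] * xs[, j]
      num <- num + n / (n - 1)^3 * sum((w - mean(w))^2)
      den <- den + (n / (n - 1) * mean(w))^2
    }
  }
  if (den == 0) return(1)
  min(1, max(0, num / den))
}

# dense-inverse partial-correlation oracle at a given lambda
oracle_pcor <- function(X, lambda) {
  r <- cor(X)
  rs <- lambda * diag(ncol(X)) + (1 - lambda) * r
  om <- solve(rs)
  pc <- -om / sqrt(outer(diag(om), diag(om)))
  diag(pc) <- 1
  pc
}

# hypergeometric upper tail by direct summation of the pmf via choose()
oracle_hyper_inclusive <- function(N, M, K, x) {
  ks <- x:min(M, K)
  sum(choose(M, ks) * choose(N - M, K - ks)) / choose(N, K)
}

# AUC by brute-force pairwise comparison (ties count one half)
oracle_auc <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# small synthetic cohort (metabolites with a sex effect, BMI with obese and
# non-obese strata, additive genotypes) used by the pipeline tests
make_cohort <- function(n = 240, m = 6, n_snp = 12, seed = 99) {
  set.seed(seed)
  sex <- rep(c(0, 1), length.out = n)
  ids <- sprintf("c%04d", seq_len(n))
  vals <- matrix(rnorm(n * m), n, m) + outer(sex, rnorm(m))
  met_ids <- sprintf("met%02d", seq_len(m))
  bmi <- c(runif(n %/% 2, 19, 24.5), runif(n - n %/% 2, 30.5, 38))
  cov <- data.frame(sample_id = ids, sex = sex, bmi = bmi,
                    stringsAsFactors = FALSE)
  dos <- matrix(rbinom(n * n_snp, 2, 0.3), n, n_snp,
                dimnames = list(ids, sprintf("rs%03d", seq_len(n_snp))))
  list(metab_path = write_metab_tsv(vals, met_ids, ids),
       cov_path = {
         p <- tempfile(fileext = ".tsv")
         write.table(cov, p, sep = "\t", quote = FALSE, row.names = FALSE)
         p
       },
       geno_path = {
         p <- tempfile(fileext = ".tsv")
         write.table(data.frame(sample_id = ids, dos, check.names = FALSE),
                     p, sep = "\t", quote = FALSE, row.names = FALSE)
         p
       },
       cov = cov, met_ids = met_ids)
}
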