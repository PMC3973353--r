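test_that("residualization matches the hand-computed two-group OLS", {
  # metabolite [1,2,3,4] on sex [0,0,1,1]: group means 1.5 and 3.5
  m <- metab_matrix(cbind(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1)),
                    sample_ids = paste0("s", 1:4))
  cov <- data.frame(sample_id = paste0("s", 1:4), sex = c(0, 0, 1, 1))
  res <- residualize_on_covariates(m, cov, "sex")
  expect_equal(unname(res$values[, "a"]), c(-0.5, 0.5, -0.5, 0.5))
  expect_true(res$residualized)
  expect_equal(colMeans(res$values), c(a = 0, b = 0))
})

test_that("residuals are orthogonal to every regressed covariate", {
  set.seed(11)
  n <- 120
  cov <- data.frame(sample_id = paste0("s", 1:n),
                    sex = rbinom(n, 1, 0.5), age = runif(n, 20, 60))
  vals <- sapply(1:5, function(j) 2 * cov$sex - 0.1 * cov$age + rnorm(n))
  colnames(vals) <- paste0("m", 1:5)
  m <- metab_matrix(vals, sample_ids = cov$sample_id)
  res <- residualize_on_covariates(m, cov, c("sex", "age"))
  for (v in c("sex", "age")) {
    r <- abs(cor(res$values, cov[[v]]))
    expect_true(all(r < 1e-10))
  }
})

test_that("degenerate and repeated residualization are reported", {
  m <- metab_matrix(cbind(a = rnorm(10), b = rnorm(10)),
                    sample_ids = paste0("s", 1:10))
  cov <- data.frame(sample_id = paste0("s", 1:10), sex = rep(1, 10))
  expect_error(residualize_on_covariates(m, cov, "sex"),
               "degenerate design")

  cov$sex <- rep(c(0, 1), 5)
  res <- residualize_on_covariates(m, cov, "sex")
  expect_warning(residualize_on_covariates(res, cov, "sex"),
                 "already residualized")
})

test_that("BMI groups follow the adult cutoffs with inclusive bounds", {
  cov <- data.frame(sample_id = paste0("s", 1:6), sex = rep(0, 6),
                    bmi = c(31, 27, 18.5, 25, 30, 17))
  g <- assign_bmi_groups(cov)
  expect_identical(g$label,
                   c("group2",    # 31 > 30: obese
                     "excluded",  # 27 in the 25-30 gap
                     "group1",    # 18.5 boundary inclusive
                     "group1",    # 25 boundary inclusive
                     "excluded",  # exactly 30 is not > 30
                     "excluded")) # below 18.5
  expect_error(
    assign_bmi_groups(cov, list(obese_min = 24, nonobese_low = 18.5,
                                nonobese_high = 25)),
    "overlapping")
})

test_that("sex-specific cutoffs select the right thresholds per sample", {
  cov <- data.frame(sample_id = paste0("s", 1:4), sex = c(0, 1, 0, 1),
                    bmi = c(27.8, 27.8, 24.1, 24.1))
  cuts <- list(obese_min = c("0" = 27.5, "1" = 28.2),
               nonobese_low = c("0" = 17.4, "1" = 17.0),
               nonobese_high = c("0" = 24.05, "1" = 24.2))
  g <- assign_bmi_groups(cov, cuts)
  expect_identical(g$label, c("group2", "excluded", "excluded", "group1"))
})

test_that("HWE chi-square reproduces hand-computed statistics", {
  h <- hwe_chi2_test(25, 50, 25)
  expect_equal(h$chi2, 0)
  expect_equal(h$p, 1)
  # expected (25, 50, 25): 25 + 50 + 25 = 100
  expect_equal(hwe_chi2_test(0, 100, 0)$chi2, 100)
  h3 <- hwe_chi2_test(298, 489, 213)
  expect_equal(h3$chi2, 0.2214896, tolerance = 1e-6)
  expect_equal(h3$p, 0.6379073, tolerance = 1e-6)
  # monomorphic convention
  expect_equal(hwe_chi2_test(10, 0, 0), list(chi2 = 0, p = 1))
  expect_error(hwe_chi2_test(0, 0, 0), "positive")
})

test_that("HWE chi-square is non-negative and zero only at exact fit", {
  set.seed(21)
  for (i in 1:25) {
    cnt <- rmultinom(1, 200, c(0.25, 0.5, 0.25))
    h <- hwe_chi2_test(cnt[1], cnt[2], cnt[3])
    expect_gte(h$chi2, 0)
    p_hat <- (2 * cnt[1] + cnt[2]) / 400
    expected <- 200 * c(p_hat^2, 2 * p_hat * (1 - p_hat), (1 - p_hat)^2)
    if (h$chi2 == 0) expect_equal(as.numeric(cnt), expected)
  }
})

test_that("marker QC removes failures on any criterion", {
  # marker 1: call rate 9/10; marker 2: MAF 0.005-ish impossible at n=10,
  # so build explicit columns
  n <- 1000
  set.seed(5)
  good <- rbinom(n, 2, 0.3)
  low_call <- rbinom(n, 2, 0.3)
  low_call[1:60] <- NA                       # call rate 0.94 < 0.95
  rare <- c(rep(1, 10), rep(0, n - 10))      # MAF 0.005 < 0.01
  het_only <- rep(1, n)                      # HWE p << 1e-4
  gm <- genotype_matrix(cbind(good, low_call, rare, het_only),
                        data.frame(id = c("good", "low_call", "rare",
                                          "het_only"),
                                   chrom = "1", pos = 1:4))
  qc <- snp_qc(gm)
  expect_identical(qc$genotypes$markers$id, "good")
  expect_false(qc$report$pass_call_rate[2])
  expect_false(qc$report$pass_maf[3])
  expect_false(qc$report$pass_hwe[4])
  expect_equal(qc$report$maf[3], 0.005)

  expect_warning(snp_qc(gm, call_rate_min = 1.1), "all markers removed")
})

test_that("raising a QC threshold never recovers a removed marker", {
  set.seed(31)
  dos <- matrix(rbinom(3000, 2, runif(30, 0.005, 0.4)), nrow = 100,
                byrow = TRUE)
  dos[sample(length(dos), 150)] <- NA
  gm <- genotype_matrix(dos, data.frame(id = paste0("v", 1:30),
                                        chrom = "1", pos = 1:30))
  loose <- snp_qc(gm, 0.9, 0.005, 1e-6)$report
  strict <- snp_qc(gm, 0.97, 0.05, 1e-2)$report
  expect_true(all(loose$pass | !strict$pass))
})

test_that("genotype dichotomization splits carriers from non-carriers", {
  g <- dichotomize_genotype(c(0, 1, 2, 0))
  expect_identical(g$A, c(1L, 4L))
  expect_identical(g$B, c(2L, 3L))
  expect_false(g$untestable)

  g2 <- dichotomize_genotype(c(0, 0, 0, 0))
  expect_true(g2$untestable)
  expect_match(g2$reason, "carrier")

  g3 <- dichotomize_genotype(c(0, NA, 2))
  expect_identical(g3$A, 1L)
  expect_identical(g3$B, 3L)
  expect_error(dichotomize_genotype(c(0, 3)), "0, 1, 2")
})
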