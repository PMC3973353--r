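test_that("Fisher z test reproduces the hand-computed statistic", {
  z <- fisher_z_test(0.8, 103, 0.2, 103)
  expect_equal(z$Z, (atanh(0.8) - atanh(0.2)) / sqrt(2 / 100))
  expect_equal(z$Z, 6.335, tolerance = 1e-3)

  eq <- fisher_z_test(0.5, 50, 0.5, 200)
  expect_equal(eq$Z, 0)
  expect_equal(eq$p, 1)

  # swapping groups negates Z, p unchanged
  a <- fisher_z_test(0.3, 40, -0.2, 60)
  b <- fisher_z_test(-0.2, 60, 0.3, 40)
  expect_equal(a$Z, -b$Z)
  expect_equal(a$p, b$p)

  expect_error(fisher_z_test(0.5, 3, 0.2, 100), "exceed 3")
  expect_error(fisher_z_test(1.5, 10, 0, 10), "lie in")
  expect_warning(z1 <- fisher_z_test(1, 10, 0, 10), "clamped")
  expect_lt(z1$p, 1e-10)
})

test_that("Fisher z p-values are uniform under the null", {
  set.seed(61)
  p <- replicate(4000, {
    x <- matrix(rnorm(60), 30, 2)
    y <- matrix(rnorm(80), 40, 2)
    fisher_z_test(cor(x[, 1], x[, 2]), 30, cor(y[, 1], y[, 2]), 40)$p
  })
  ks <- ks.test(p, "punif")
  expect_gt(ks$p.value, 0.01)
  # two-tailed rejection rates close to nominal
  for (alpha in c(0.05, 0.01)) {
    bounds <- qbinom(c(0.005, 0.995), 4000, alpha)
    expect_true(sum(p < alpha) >= bounds[1] && sum(p < alpha) <= bounds[2])
  }
})

test_that("groupwise pair correlations are estimated per genotype group", {
  set.seed(63)
  n <- 2000
  rho <- c(rep(0.6, 1500), rep(0.1, 500))
  z1 <- rnorm(n); z2 <- rnorm(n)
  vals <- cbind(a = z1, b = rho * z1 + sqrt(1 - rho^2) * z2)
  m <- metab_matrix(vals, residualized = TRUE)
  gc <- groupwise_pair_correlation(m, c("a", "b"), 1:1500, 1501:2000)
  expect_false(gc$untestable)
  expect_lt(abs(gc$r_A - 0.6), 0.08)
  expect_lt(abs(gc$r_B - 0.1), 0.08)
  expect_identical(c(gc$n_A, gc$n_B), c(1500L, 500L))

  # identical data in both groups
  m2 <- metab_matrix(rbind(vals[1:50, ], vals[1:50, ]), residualized = TRUE)
  gc2 <- groupwise_pair_correlation(m2, c("a", "b"), 1:50, 51:100)
  expect_equal(gc2$r_A, gc2$r_B)

  # constant metabolite within one group is untestable, not an error
  vals3 <- vals[1:100, ]
  vals3[51:100, 1] <- 3
  gc3 <- groupwise_pair_correlation(metab_matrix(vals3, residualized = TRUE),
                                    c("a", "b"), 1:50, 51:100)
  expect_true(gc3$untestable)
  expect_match(gc3$reason, "constant")

  expect_error(groupwise_pair_correlation(m, c("a", "b"), 1:10, 5:20),
               "disjoint")
})

test_that("the effective GWCA threshold divides by D", {
  thr <- gwca_threshold(5)
  expect_equal(thr$effective, 1e-8)
  expect_equal(gwca_threshold(1)$effective, 5e-8)
  expect_error(gwca_threshold(0), "positive")
})

test_that("run_gwca tests every SNP x pair and flags significance", {
  set.seed(67)
  n <- 3000
  # SNP 1 is causal for the pair: carriers correlate 0.8, others 0.2
  dos <- cbind(causal = rbinom(n, 2, 0.3),
               sapply(1:20, function(i) rbinom(n, 2, 0.3)))
  colnames(dos) <- c("causal", paste0("null", 1:20))
  carrier <- dos[, 1] >= 1
  rho <- ifelse(carrier, 0.8, 0.2)
  z1 <- rnorm(n); z2 <- rnorm(n)
  vals <- cbind(a = z1, b = rho * z1 + sqrt(1 - rho^2) * z2,
                c = rnorm(n))
  ids <- sprintf("s%04d", 1:n)
  gm <- genotype_matrix(dos, data.frame(id = colnames(dos), chrom = "1",
                                        pos = seq_len(ncol(dos)) * 100),
                        sample_ids = ids)
  mm <- metab_matrix(vals, sample_ids = ids, residualized = TRUE)
  pairs <- data.frame(metabolite_1 = c("a", "a"),
                      metabolite_2 = c("b", "c"))
  rec <- run_gwca(gm, mm, pairs, progress_every = 0)
  expect_identical(nrow(rec), ncol(dos) * 2L)
  # the causal SNP on its pair attains the smallest p overall
  best <- rec[which.min(rec$p), ]
  expect_identical(best$snp, "causal")
  expect_identical(best$metabolite_2, "b")
  # significance flags consistent with the effective threshold 5e-8 / 2
  thr <- attr(rec, "threshold")
  expect_equal(thr$effective, 2.5e-8)
  expect_identical(rec$significant, !is.na(rec$p) & rec$p < thr$effective)
  expect_true(best$significant)

  # monomorphic SNP is reported untestable, not dropped
  dos2 <- cbind(mono = rep(0, n), poly = dos[, 2])
  gm2 <- genotype_matrix(dos2, data.frame(id = c("mono", "poly"),
                                          chrom = "1", pos = c(1, 2)),
                         sample_ids = ids)
  rec2 <- run_gwca(gm2, mm, pairs[1, ], progress_every = 0)
  expect_match(rec2$status[rec2$snp == "mono"], "untestable")
  expect_false(any(rec2$significant[rec2$snp == "mono"]))
})

test_that("null GWCA p-values are uniform with no spurious hits", {
  set.seed(71)
  n <- 600
  n_snp <- 300
  dos <- matrix(rbinom(n * n_snp, 2, 0.3), n, n_snp,
                dimnames = list(NULL, paste0("v", 1:n_snp)))
  z1 <- rnorm(n); z2 <- rnorm(n)
  vals <- cbind(a = z1, b = 0.3 * z1 + sqrt(0.91) * z2)
  ids <- sprintf("s%04d", 1:n)
  gm <- genotype_matrix(dos, data.frame(id = colnames(dos), chrom = "1",
                                        pos = seq_len(n_snp)),
                        sample_ids = ids)
  mm <- metab_matrix(vals, sample_ids = ids, residualized = TRUE)
  rec <- run_gwca(gm, mm, data.frame(metabolite_1 = "a",
                                     metabolite_2 = "b"),
                  progress_every = 0)
  expect_false(any(rec$significant))
  ks <- ks.test(rec$p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("nearest-gene assignment respects the 1 Mb limit and tie rule", {
  ann <- data.frame(gene = c("BBB", "AAA", "FAR"),
                    chrom = c("1", "1", "1"),
                    start = c(2000, 6000, 5e7),
                    end = c(3000, 7000, 5.1e7), stringsAsFactors = FALSE)
  rec <- data.frame(snp = paste0("r", 1:4), chrom = "1",
                    pos = c(2500,       # inside BBB
                            4500,       # equidistant (1500) to BBB and AAA
                            7000 + 1e6, # exactly 1 Mb from AAA: assigned
                            7001 + 1e6),# 1 Mb + 1: unassigned
                    p = 1e-9, stringsAsFactors = FALSE)
  out <- annotate_nearest_gene(rec, ann)
  expect_identical(out$candidate_gene, c("BBB", "AAA", "AAA", NA))
  expect_equal(out$gene_distance, c(0, 1500, 1e6, NA))
  expect_identical(out$tied_genes[2], "AAA,BBB")
  expect_true(is.na(out$tied_genes[1]))
})
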