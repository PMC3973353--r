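test_that("scenario construction validates its parameters", {
  expect_error(simulation_scenario("s", 0.6, 0.2, 0.8), "maf")
  expect_error(simulation_scenario("s", 0.3, 1, 0.8), "< 1")
  expect_error(simulation_scenario("s", 0.3, 0.2, 0.8, n_true = 0), "one true")
  sc <- simulation_scenario("s", 0.3, 0.2, 0.8, n = 100, n_true = 2,
                            n_null = 8, seed = 5)
  expect_s3_class(sc, "simulation_scenario")
  expect_length(default_scenarios(), 4)
})

test_that("GWCA simulation hits its MAF and per-group correlation targets", {
  sc <- simulation_scenario("t", 0.3, 0.2, 0.8, n = 3000, n_true = 5,
                            n_null = 5, seed = 7)
  sim <- simulate_gwca_dataset(sc)
  expect_identical(dim(sim$genotypes$dosages), c(3000L, 10L))
  expect_identical(dim(sim$metabolites$values), c(3000L, 20L))
  maf <- colMeans(sim$genotypes$dosages) / 2
  expect_true(all(abs(maf - 0.3) < 0.02))
  # per-group correlations of a true SNP's focal pair
  j <- which(sim$truth)[1]
  g <- dichotomize_genotype(sim$genotypes$dosages[, j])
  X <- sim$metabolites$values[, c(2 * j - 1, 2 * j)]
  expect_lt(abs(cor(X[g$A, ])[1, 2] - 0.2), 0.08)
  expect_lt(abs(cor(X[g$B, ])[1, 2] - 0.8), 0.08)
  # a null SNP shows no genotype-dependent difference
  k <- which(!sim$truth)[1]
  gk <- dichotomize_genotype(sim$genotypes$dosages[, k])
  Xk <- sim$metabolites$values[, c(2 * k - 1, 2 * k)]
  expect_lt(abs(cor(Xk[gk$A, ])[1, 2] - cor(Xk[gk$B, ])[1, 2]), 0.1)
})

test_that("simulations are reproducible bit-exactly under a fixed seed", {
  sc <- simulation_scenario("t", 0.2, 0.1, 0.5, n = 200, n_true = 3,
                            n_null = 7, seed = 11)
  a <- simulate_gwca_dataset(sc)
  b <- simulate_gwca_dataset(sc)
  expect_identical(a$genotypes$dosages, b$genotypes$dosages)
  expect_identical(a$metabolites$values, b$metabolites$values)
  d1 <- simulate_diffnet_dataset(sc)
  d2 <- simulate_diffnet_dataset(sc)
  expect_identical(d1$X1$values, d2$X1$values)
  expect_identical(d1$truth, d2$truth)
  expect_warning(
    simulate_gwca_dataset(simulation_scenario("w", 0.01, 0.1, 0.5, n = 100,
                                              n_true = 1, n_null = 1)),
    "below 8")
})

test_that("diffnet simulation plants correlations only on designated pairs", {
  sc <- simulation_scenario("t", 0.3, 0.2, 0.8, n = 4000, n_true = 10,
                            n_null = 180, seed = 13)
  sim <- simulate_diffnet_dataset(sc)
  M <- 2L * sc$n_true
  expect_identical(ncol(sim$X1$values), M)
  expect_identical(sum(sim$truth), 10L)
  expect_identical(length(sim$truth), as.integer(M * (M - 1L) / 2L))
  r1 <- cor(sim$X1$values)
  r2 <- cor(sim$X2$values)
  idx <- cbind(match(sim$pairs$metabolite_1, colnames(r1)),
               match(sim$pairs$metabolite_2, colnames(r1)))
  expect_true(all(abs(r1[idx][sim$truth] - 0.2) < 0.07))
  expect_true(all(abs(r2[idx][sim$truth] - 0.8) < 0.07))
  # null pairs carry no planted correlation (max over 180 estimates)
  expect_true(all(abs(r1[idx][!sim$truth]) < 0.1))
  expect_true(all(abs(r2[idx][!sim$truth]) < 0.1))
})

test_that("ROC/AUC matches a brute-force pairwise oracle", {
  set.seed(17)
  for (rep in 1:5) {
    scores <- sample(rep(seq(0, 1, length.out = 40), 5))  # many ties
    truth <- runif(200) < plogis(6 * scores - 3)
    if (length(unique(truth)) < 2) next
    r <- roc_auc(scores, truth)
    expect_equal(r$auc, oracle_auc(scores, truth), tolerance = 1e-12)
    # trapezoidal integral of the curve equals the Mann-Whitney AUC
    pts <- r$points
    trap <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
    expect_equal(trap, r$auc, tolerance = 1e-12)
    expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
  }
})

test_that("ROC handles separation, ties and monotone transforms", {
  truth <- c(rep(TRUE, 4), rep(FALSE, 4))
  expect_equal(roc_auc(c(5, 6, 7, 8, 1, 2, 3, 4), truth)$auc, 1)
  expect_equal(roc_auc(rep(2, 8), truth)$auc, 0.5)
  set.seed(19)
  s <- rnorm(1000)
  t2 <- c(rep(TRUE, 500), rep(FALSE, 500))
  a1 <- roc_auc(s, t2)$auc
  expect_lt(abs(a1 - 0.5), 0.05)
  # strictly monotone transform leaves the AUC unchanged
  expect_equal(roc_auc(exp(2 * s) - 5, t2)$auc, a1)
  expect_error(roc_auc(s, rep(TRUE, 1000)), "both classes")
})

test_that("strong effects are perfectly ranked at reduced scale", {
  sc <- simulation_scenario("strong-small", 0.3, 0.2, 0.8, n = 800,
                            n_true = 5, n_null = 95, seed = 23)
  expect_equal(evaluate_gwca_step(simulate_gwca_dataset(sc))$auc, 1)
  dn <- evaluate_diffnet_step(simulate_diffnet_dataset(sc), B = 300,
                              seed = 24)
  # the five differential pairs outrank all 40 null pairs
  expect_equal(dn$auc, 1)
})

test_that("zero-effect scenarios give chance-level AUC", {
  # 100/900 candidates keep the Monte Carlo sd of the AUC near 0.03
  sc <- simulation_scenario("null", 0.3, 0.3, 0.3, n = 2000, n_true = 100,
                            n_null = 900, seed = 29)
  expect_lt(abs(evaluate_gwca_step(simulate_gwca_dataset(sc))$auc - 0.5),
            0.06)
})

test_that("GWCA power is monotone in effect size and sample size", {
  aucs <- sapply(c(0.25, 0.5, 0.8), function(rb) {
    sc <- simulation_scenario("g", 0.3, 0.2, rb, n = 1500, n_true = 40,
                              n_null = 160, seed = 31)
    evaluate_gwca_step(simulate_gwca_dataset(sc))$auc
  })
  expect_true(all(diff(aucs) > -0.03))
  expect_gt(aucs[3], aucs[1])

  aucs_n <- sapply(c(400, 1200, 3600), function(n) {
    sc <- simulation_scenario("n", 0.3, 0.2, 0.35, n = n, n_true = 40,
                              n_null = 160, seed = 37)
    evaluate_gwca_step(simulate_gwca_dataset(sc))$auc
  })
  expect_true(all(diff(aucs_n) > -0.03))
  expect_gt(aucs_n[3], aucs_n[1])
})

test_that("the scenario suite reports both AUCs per scenario", {
  scen <- default_scenarios(n = 400, n_true = 4, n_null = 36, seed = 41)
  tab <- run_scenario_suite(scen, B_perm = 100)
  expect_identical(nrow(tab), 4L)
  expect_true(all(tab$auc_diffnet >= 0 & tab$auc_diffnet <= 1))
  expect_true(all(tab$auc_gwca >= 0 & tab$auc_gwca <= 1))
  # large-difference scenarios dominate their small-difference twins
  expect_gt(tab$auc_gwca[1], tab$auc_gwca[3])
})
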