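test_that("REML recovers zero heritability on null data", {
  p <- sim_params(500, 1000, maf_range = c(0.05, 0.5), seed = 100)
  g <- simulate_genotypes(p)
  set.seed(101)
  y <- rnorm(500)
  fit <- reml_fit(y, build_grm(g))
  expect_lt(fit$h2_obs, 2 * max(fit$h2_se, 0.05))
  expect_gt(fit$lrt_p, 0.05)
})

test_that("REML approaches one in the noiseless limit", {
  p <- sim_params(800, 1500, n_causal = 200, h2_trait1 = 0.6, seed = 102)
  g <- simulate_genotypes(p)
  tr <- simulate_liability_pair(g, p)
  fit <- reml_fit(tr$genetic1, build_grm(g))
  expect_gt(fit$h2_obs, 0.9)
})

test_that("REML recovers a moderate observed-scale heritability", {
  ests <- t(vapply(1:8, function(r) {
    p <- sim_params(1000, 2000, n_causal = 300, h2_trait1 = 0.5,
                    seed = 110 + r)
    g <- simulate_genotypes(p)
    tr <- simulate_liability_pair(g, p)
    fit <- reml_fit(tr$liability1, build_grm(g))
    c(fit$h2_obs, fit$h2_se)
  }, numeric(2)))
  expect_lt(abs(mean(ests[, 1]) - 0.5), 0.05)
  expect_gte(mean(abs(ests[, 1] - 0.5) < 2 * ests[, 2]), 7 / 8)
})

test_that("accepted REML iterations never decrease the log-likelihood", {
  p <- sim_params(400, 800, n_causal = 100, h2_trait1 = 0.4,
                  prevalence1 = 0.2, seed = 120)
  g <- simulate_genotypes(p)
  tr <- simulate_liability_pair(g, p)
  fit <- reml_fit(tr$pheno1, build_grm(g))
  expect_false(is.unsorted(fit$logL_history))
  expect_true(fit$converged)
})

test_that("REML estimates are invariant to sample reordering", {
  p <- sim_params(300, 600, n_causal = 100, h2_trait1 = 0.5, seed = 121)
  g <- simulate_genotypes(p)
  tr <- simulate_liability_pair(g, p)
  grm <- build_grm(g)
  fit <- reml_fit(tr$liability1, grm)
  set.seed(122)
  perm <- sample(300)
  grm_p <- grm
  grm_p$K <- grm$K[perm, perm]
  fit_p <- reml_fit(tr$liability1[perm], grm_p)
  expect_equal(fit_p$h2_obs, fit$h2_obs, tolerance = 1e-8)
})

test_that("a two-component fit recovers the MHC block's variance share", {
  p <- sim_params(2000, 5000, n_causal = 500, h2_trait1 = 0.6,
                  mhc_block = list(start = 2301, end = 2700,
                                   var_share = 0.3), seed = 123)
  g <- simulate_genotypes(p)
  tr <- simulate_liability_pair(g, p)
  parts <- partition_snps(g$snp_map)
  fit <- reml_fit(tr$liability1,
                  list(build_grm(g, parts$auto_exMHC, region = "exMHC"),
                       build_grm(g, parts$MHC, region = "MHC")))
  comp <- fit$components
  gen_tot <- sum(comp$variance[comp$component != "residual"])
  mhc_share_of_genetic <- comp$variance[comp$component == "MHC"] / gen_tot
  expect_lt(abs(mhc_share_of_genetic - 0.3), 0.10)
})

test_that("the liability transform matches its closed forms", {
  expect_equal(observed_to_liability(0, 0.1, 0.4)$h2_liab, 0)
  expect_equal(observed_to_liability(0.5, 0.5, 0.5)$h2_liab, 0.5 * pi / 2,
               tolerance = 1e-12)
  # frozen value from a high-precision evaluation of the multiplier
  out <- observed_to_liability(0.2, 0.005, 0.1)
  expect_equal(out$multiplier, 1.31529300637, tolerance = 1e-9)
  expect_equal(out$h2_liab, 0.263058601273, tolerance = 1e-9)
  # the SE scales by the same multiplier
  out2 <- observed_to_liability(0.2, 0.005, 0.1, se = 0.05)
  expect_equal(out2$se_liab, 0.05 * out2$multiplier)
  expect_warning(observed_to_liability(0.7, 0.3, 0.3), "exceeds 1")
  expect_error(observed_to_liability(0.5, 0, 0.5), "lie in")
})

test_that("the MHC percentage follows the report arithmetic", {
  expect_equal(pct_mhc(0.454, 0.447), 1.5418502, tolerance = 1e-6)
  expect_equal(pct_mhc(0.863, 0.581), 32.676709, tolerance = 1e-6)
  expect_equal(pct_mhc(0.5, 0.5), 0)
  expect_true(is.na(pct_mhc(0, 0.1)))
  expect_lt(pct_mhc(0.949, 0.9492), 0)  # slight negative is legitimate
})

test_that("the partition report combines regional fits into one row", {
  p <- sim_params(400, 900, n_causal = 150, h2_trait1 = 0.6,
                  prevalence1 = 0.2,
                  mhc_block = list(start = 400, end = 500, var_share = 0.3),
                  seed = 124)
  g <- simulate_genotypes(p)
  tr <- simulate_liability_pair(g, p)
  parts <- partition_snps(g$snp_map)
  fit_auto <- reml_fit(tr$liability1, build_grm(g, parts$auto))
  fit_ex <- reml_fit(tr$liability1,
                     build_grm(g, parts$auto_exMHC, region = "auto_exMHC"))
  rep_ <- partition_report(fit_auto, fit_ex)
  expect_equal(rep_$h2_auto, fit_auto$h2_obs)
  expect_equal(rep_$pct_mhc,
               100 * (fit_auto$h2_obs - fit_ex$h2_obs) / fit_auto$h2_obs)
  expect_gt(rep_$pct_mhc, 0)   # the block carries real variance
})
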