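test_that("genotype simulation is reproducible and respects the MAF range", {
  p <- sim_params(200, 150, maf_range = c(0.05, 0.5), seed = 7)
  g1 <- simulate_genotypes(p)
  g2 <- simulate_genotypes(p)
  expect_identical(g1$dosage, g2$dosage)

  p2 <- sim_params(2000, 200, maf_range = c(0.05, 0.5), seed = 8)
  g <- simulate_genotypes(p2)
  f <- colMeans(g$dosage) / 2
  expect_true(all(pmin(f, 1 - f) >= 0.01))
})

test_that("empirical allele frequency matches the binomial sampling bound", {
  p <- sim_params(5000, 1, maf_range = c(0.3, 0.3), seed = 9)
  g <- simulate_genotypes(p)
  f_hat <- mean(g$dosage) / 2
  expect_lt(abs(f_hat - 0.3), 3 * sqrt(0.3 * 0.7 / (2 * 5000)))
})

test_that("parameter validation rejects impossible settings", {
  expect_error(sim_params(0, 10), "positive")
  expect_error(sim_params(10, 10, maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_params(10, 10, n_causal = 11), "n_causal")
  expect_error(sim_params(10, 10, rg_true = 1.2), "rg_true")
  expect_error(sim_params(10, 10, mhc_block = list(start = 5, end = 20)),
               "mhc_block")
})

test_that("perfectly correlated traits share one effect vector", {
  p <- sim_params(300, 100, n_causal = 40, h2_trait1 = 0.5,
                  h2_trait2 = 0.5, rg_true = 1, seed = 10)
  g <- simulate_genotypes(p)
  tr <- simulate_liability_pair(g, p)
  expect_equal(tr$effects$beta1, tr$effects$beta2, tolerance = 1e-12)
})

test_that("genetic values of a trait pair realize the target correlation", {
  p <- sim_params(20000, 600, n_causal = 500, h2_trait1 = 0.5,
                  h2_trait2 = 0.5, rg_true = 0.66, seed = 17)
  g <- simulate_genotypes(p)
  tr <- simulate_liability_pair(g, p)
  expect_lt(abs(cor(tr$genetic1, tr$genetic2) - 0.66), 0.05)
})

test_that("case counts follow the configured prevalence", {
  p <- sim_params(20000, 450, n_causal = 400, h2_trait1 = 0.3,
                  prevalence1 = 0.005, seed = 18)
  g <- simulate_genotypes(p)
  tr <- simulate_liability_pair(g, p)
  expected <- 20000 * 0.005
  expect_lt(abs(sum(tr$pheno1) - expected),
            3 * sqrt(20000 * 0.005 * 0.995))
})

test_that("realized genetic variance is h2 by construction", {
  vars <- vapply(1:200, function(r) {
    p <- sim_params(400, 60, n_causal = 50, h2_trait1 = 0.5, seed = 5000 + r)
    g <- simulate_genotypes(p)
    tr <- simulate_liability_pair(g, p)
    var(tr$genetic1)
  }, numeric(1))
  expect_lt(abs(mean(vars) - 0.5), 0.02 * 0.5 / 0.5)  # within 2% of 0.5
  expect_lt(abs(mean(vars) - 0.5), 0.01)
})

test_that("ascertainment returns exact counts, records P, and is seeded", {
  pheno <- c(rep(1L, 150), rep(0L, 1850))
  a <- ascertain_case_control(pheno, 100, 900, seed = 3)
  expect_equal(a$case_proportion, 0.1)
  expect_equal(sum(pheno[a$idx] == 1L), 100)
  expect_equal(sum(pheno[a$idx] == 0L), 900)
  b <- ascertain_case_control(pheno, 100, 900, seed = 3)
  expect_identical(a$idx, b$idx)
  expect_error(ascertain_case_control(pheno, 0, 10), "positive")
  expect_error(ascertain_case_control(pheno, 200, 10), "insufficient cases")
})

test_that("comorbid cases resolve to the smaller cohort, disjointly", {
  sets <- list(BIG = sprintf("id%04d", 1:2000),
               SMALL = c(sprintf("id%04d", 1:5), sprintf("x%03d", 1:95)))
  out <- assign_comorbid_cases(sets)
  expect_true(all(sprintf("id%04d", 1:5) %in% out$SMALL))
  expect_length(intersect(out$BIG, out$SMALL), 0)

  # no overlap: unchanged
  sets2 <- list(A = c("a1", "a2"), B = c("b1"))
  out2 <- assign_comorbid_cases(sets2)
  expect_setequal(out2$A, sets2$A)
  expect_setequal(out2$B, sets2$B)

  # three-way overlap: the individual appears exactly once
  sets3 <- list(A = c("z", "a1", "a2", "a3"), B = c("z", "b1"),
                C = c("z", "c1", "c2"))
  out3 <- assign_comorbid_cases(sets3)
  expect_equal(sum(vapply(out3, function(s) "z" %in% s, logical(1))), 1L)
  expect_true("z" %in% out3$B)  # smallest cohort
})

test_that("artifact injection produces the intended missingness and kinship", {
  p <- sim_params(200, 400, maf_range = c(0.1, 0.5), seed = 20)
  g <- simulate_genotypes(p)
  snp1 <- g$snp_map$id[1]
  ga <- inject_artifacts(g, missing_rate_per_snp = stats::setNames(0.1, snp1),
                         seed = 21)
  cr <- mean(!is.na(ga$dosage[, 1]))
  expect_lt(abs(cr - 0.9), 3 * sqrt(0.1 * 0.9 / 200))
  expect_true(all(!is.na(ga$dosage[, -1])))

  gr <- inject_artifacts(g, n_related_pairs = 1L, seed = 22)
  rel <- attr(gr, "related")
  K <- build_grm(gr, seq_len(400))$K
  expect_gt(K[rel$child, rel$parent1], 0.35)
  expect_gt(K[rel$child, rel$parent2], 0.35)

  # fst = 0: no drift, genotypes untouched
  g0 <- inject_artifacts(g, n_subpops = 2L, fst = 0, seed = 23)
  expect_identical(g0$dosage, g$dosage)
})

test_that("the two-stage ascertained simulator matches its design", {
  p <- sim_params(1, 500, n_causal = 50, h2_trait1 = 0.5,
                  prevalence1 = 0.1, seed = 30)
  sim <- simulate_case_control_study(p, 150, 150)
  expect_equal(sum(sim$pheno == 1L), 150)
  expect_equal(sum(sim$pheno == 0L), 150)
  expect_equal(sim$case_proportion, 0.5)
  expect_false(anyNA(sim$geno$dosage))
  # cases should carry higher mean genetic values
  expect_gt(mean(sim$truth$genetic1[sim$pheno == 1L]),
            mean(sim$truth$genetic1[sim$pheno == 0L]))
})
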