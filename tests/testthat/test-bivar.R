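# helper: simulate a two-cohort design and fit the bivariate model
fit_pair <- function(rg, n_side = 400, m = 800, h2_1 = 0.6, h2_2 = 0.6,
                     seed = 1, grm_subset = NULL) {
  p <- sim_params(1, m, n_causal = round(m / 5), h2_trait1 = h2_1,
                  h2_trait2 = h2_2, rg_true = rg, prevalence1 = 0.1,
                  prevalence2 = 0.1, seed = seed)
  sim <- simulate_case_control_pair(p, n_side / 2, n_side / 2, n_side)
  ids <- sim$geno$sample_table$id
  al <- split_controls(ids[sim$status == 0L], seed = seed + 1)
  i1 <- match(c(ids[sim$status == 1L], al$controls1), ids)
  i2 <- match(c(ids[sim$status == 2L], al$controls2), ids)
  g <- subset_geno(sim$geno, i = c(i1, i2))
  y1 <- as.integer(sim$status[i1] == 1L)
  y2 <- as.integer(sim$status[i2] == 2L)
  grm <- build_grm(g, grm_subset)
  list(fit = bivar_reml(y1, y2, grm), g = g, y1 = y1, y2 = y2, grm = grm)
}

test_that("control pools split evenly, larger half first, reproducibly", {
  s <- split_controls(letters[1:10], seed = 4)
  expect_length(s$controls1, 5)
  expect_length(s$controls2, 5)
  expect_setequal(c(s$controls1, s$controls2), letters[1:10])
  s11 <- split_controls(letters[1:11], seed = 4)
  expect_length(s11$controls1, 6)
  expect_length(s11$controls2, 5)
  expect_identical(split_controls(letters[1:11], seed = 4), s11)
  expect_error(split_controls("a"), "at least 2")
})

test_that("genetically independent traits give a null genetic correlation", {
  out <- fit_pair(rg = 0, seed = 330)
  expect_lt(abs(out$fit$rG), 2 * out$fit$rG_se)
  expect_gt(out$fit$lrt_p, 0.01)
})

test_that("perfectly correlated traits give a near-unit genetic correlation", {
  out <- fit_pair(rg = 1, seed = 131)
  expect_gt(out$fit$rG, 0.8)
  expect_lte(out$fit$rG, 1)
})

test_that("rG is symmetric in the trait labels", {
  out <- fit_pair(rg = 0.5, seed = 132)
  n1 <- length(out$y1)
  # swap cohorts: reorder the combined GRM accordingly
  ord <- c(n1 + seq_along(out$y2), seq_len(n1))
  grm_sw <- out$grm
  grm_sw$K <- out$grm$K[ord, ord]
  fit_sw <- bivar_reml(out$y2, out$y1, grm_sw)
  expect_equal(fit_sw$rG, out$fit$rG, tolerance = 1e-6)
})

test_that("rG is invariant to linear rescaling of a phenotype", {
  out <- fit_pair(rg = 0.5, seed = 133)
  fit_sc <- bivar_reml(out$y1 * 3 + 1, out$y2, out$grm)
  expect_equal(fit_sc$rG, out$fit$rG, tolerance = 1e-4)
})

test_that("excluding the MHC leaves rG unchanged when sharing is genome-wide", {
  # causal architecture has no MHC concentration, so the exMHC estimate
  # must agree within statistical error
  p <- sim_params(1, 800, n_causal = 160, h2_trait1 = 0.6, h2_trait2 = 0.6,
                  rg_true = 0.6, prevalence1 = 0.1, prevalence2 = 0.1,
                  mhc_block = list(start = 350, end = 420, var_share = 0),
                  seed = 134)
  sim <- simulate_case_control_pair(p, 200, 200, 400)
  ids <- sim$geno$sample_table$id
  al <- split_controls(ids[sim$status == 0L], seed = 135)
  i1 <- match(c(ids[sim$status == 1L], al$controls1), ids)
  i2 <- match(c(ids[sim$status == 2L], al$controls2), ids)
  g <- subset_geno(sim$geno, i = c(i1, i2))
  y1 <- as.integer(sim$status[i1] == 1L)
  y2 <- as.integer(sim$status[i2] == 2L)
  parts <- partition_snps(g$snp_map)
  f_auto <- bivar_reml(y1, y2, build_grm(g, parts$auto))
  f_ex <- bivar_reml(y1, y2, build_grm(g, parts$auto_exMHC))
  se <- max(f_auto$rG_se, f_ex$rG_se)
  expect_lt(abs(f_auto$rG - f_ex$rG), 2 * se)
})

test_that("Bonferroni adjustment reproduces printed pairwise corrections", {
  expect_equal(bonferroni_adjust(2.47e-3, 9), 2.223e-2)
  expect_equal(bonferroni_adjust(1.33e-2, 9), 0.1197)
  expect_equal(bonferroni_adjust(0.5, 9), 1.0)
  expect_error(bonferroni_adjust(0, 9), "lie in")
  expect_error(bonferroni_adjust(0.5, 0), "n_tests")
})
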