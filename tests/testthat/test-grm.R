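test_that("single-SNP GRM entries match hand arithmetic", {
  # both individuals het at f = 0.5: centered dosage 0 -> contribution 0
  g <- make_geno(matrix(c(1L, 1L), 2, 1))
  expect_equal(build_grm(g, 1)$K[1, 2], 0)
  # dosages 2 and 0 at f = 0.5: (1)(-1)/0.5 = -2
  g2 <- make_geno(matrix(c(2L, 0L), 2, 1))
  expect_equal(build_grm(g2, 1)$K[1, 2], -2)
})

test_that("GRM equals the brute-force double loop, with missing data", {
  set.seed(90)
  dos <- matrix(rbinom(5 * 4, 2, 0.4), 5, 4)
  dos[2, 3] <- NA
  g <- make_geno(dos)
  K <- build_grm(g, 1:4)$K
  expect_equal(unname(K), brute_grm(dos), tolerance = 1e-10)
  expect_error(build_grm(make_geno(matrix(0L, 4, 2)), 1:2), "monomorphic")
})

test_that("a 2-way SNP partition recombines to the full GRM", {
  set.seed(91)
  dos <- matrix(rbinom(50 * 60, 2, runif(60, 0.1, 0.5)), 50, 60,
                byrow = FALSE)
  g <- make_geno(dos)
  K_all <- build_grm(g, 1:60)
  K_a <- build_grm(g, 1:25)
  K_b <- build_grm(g, 26:60)
  recomb <- (K_a$n_snps * K_a$K + K_b$n_snps * K_b$K) /
    (K_a$n_snps + K_b$n_snps)
  expect_equal(K_all$K, recomb, tolerance = 1e-10)
})

test_that("GRM moments on unrelated samples behave as theory predicts", {
  p <- sim_params(500, 5000, maf_range = c(0.05, 0.5), seed = 92)
  g <- simulate_genotypes(p)
  K <- build_grm(g)$K
  off <- K[upper.tri(K)]
  expect_gt(mean(diag(K)), 0.98); expect_lt(mean(diag(K)), 1.02)
  expect_lt(abs(mean(off)), 0.005)
  expect_lt(abs(sd(off) - 1 / sqrt(5000)) / (1 / sqrt(5000)), 0.20)
})

test_that("X GRM: all-female cohort reduces to the autosomal formula", {
  p <- sim_params(80, 10, n_snps_x = 30, male_fraction = 0, seed = 93)
  g <- simulate_genotypes(p)
  xs <- which(g$snp_map$region == "X")
  Kx <- build_grm_x(g)$K
  Ka <- build_grm(g, xs)$K
  expect_equal(Kx, Ka, tolerance = 1e-12)
})

test_that("X GRM male coding matches a brute-force oracle", {
  sex <- c(1L, 1L, 2L, 2L)
  dos <- matrix(c(2L, 0L, 1L, 2L,
                  0L, 2L, 2L, 1L), 4, 2)
  g <- make_geno(dos, chr = c(23L, 23L), bp = c(1000L, 2000L), sex = sex)
  K <- build_grm_x(g)$K
  # oracle: explicit loops with the stated sex-specific codings
  W <- dos; W[sex == 1L, ] <- W[sex == 1L, ] / 2
  f <- colSums(W) / (sum(sex == 1L) + 2 * sum(sex == 2L))
  Z <- matrix(0, 4, 2)
  for (i in 1:4) for (j in 1:2) {
    Z[i, j] <- if (sex[i] == 1L)
      sqrt(2) * (W[i, j] - f[j]) / sqrt(f[j] * (1 - f[j]))
    else (dos[i, j] - 2 * f[j]) / sqrt(2 * f[j] * (1 - f[j]))
  }
  oracle <- matrix(0, 4, 4)
  for (a in 1:4) for (b in 1:4)
    oracle[a, b] <- mean(Z[a, ] * Z[b, ])
  expect_equal(unname(K), oracle, tolerance = 1e-12)

  g_nox <- make_geno(dos, sex = sex)
  expect_error(build_grm_x(g_nox), "no X-chromosome")
})

test_that("relatedness pruning retains the largest sample", {
  K <- diag(4) * 1.0
  ids <- c("A", "B", "C", "D")
  dimnames(K) <- list(ids, ids)
  grm <- structure(list(K = K, M = matrix(100, 4, 4), ids = ids,
                        n_snps = 100, region = "auto"), class = "grm")
  # single related pair: one of the two removed
  grm$K["A", "B"] <- grm$K["B", "A"] <- 0.5
  kept <- prune_related(grm)
  expect_length(kept, 3)
  expect_equal(sum(c("A", "B") %in% kept), 1L)
  # chain A-B, B-C: removing B keeps both A and C
  grm$K["B", "C"] <- grm$K["C", "B"] <- 0.3
  kept2 <- prune_related(grm)
  expect_setequal(kept2, c("A", "C", "D"))
  # nothing above threshold: no-op
  grm$K[upper.tri(grm$K)] <- 0.01
  grm$K[lower.tri(grm$K)] <- 0.01
  expect_setequal(prune_related(grm), ids)
})

test_that("region partition applies inclusive MHC boundaries", {
  map <- data.frame(
    id = paste0("s", 1:10),
    chr = c(1L, 6L, 6L, 6L, 6L, 6L, 7L, 23L, 6L, 2L),
    bp = c(1e6, 26499999L, 26500000L, 30e6, 34000000L, 34000001L,
           30e6, 5e6, 1e6, 2e6))
  parts <- partition_snps(map)
  expect_setequal(parts$MHC, c(3L, 4L, 5L))
  expect_true(2L %in% parts$auto_exMHC)   # chr6 before the window
  expect_true(6L %in% parts$auto_exMHC)   # chr6 just after the window
  expect_setequal(parts$X, 8L)
  expect_length(parts$auto, 9)
})

test_that("GRM text output round-trips through the triplet format", {
  p <- sim_params(12, 30, maf_range = c(0.1, 0.5), seed = 94)
  g <- simulate_genotypes(p)
  grm <- build_grm(g, 1:30)
  pre <- tempfile()
  write_grm(grm, pre)
  tri <- read.table(gzfile(paste0(pre, ".grm.gz")))
  ids <- read.table(paste0(pre, ".grm.id"))
  expect_equal(nrow(tri), 12 * 13 / 2)
  expect_equal(as.character(ids[[2]]), grm$ids)
  K2 <- matrix(0, 12, 12)
  K2[cbind(tri$V1, tri$V2)] <- tri$V4
  K2[cbind(tri$V2, tri$V1)] <- tri$V4
  expect_equal(unname(grm$K), K2, tolerance = 1e-12)
})
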