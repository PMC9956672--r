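make_counts <- function(p, m) {
  # frequencies p (SNPs x pops) realized exactly with m haplotypes
  allele_counts(round(p * m), matrix(m, nrow(p), ncol(p)),
                populations = colnames(p))
}

test_that("count files parse with totals, missingness and line errors", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("popA popB out", "1,3 2,2 0,4"), p)
  cc <- read_counts(p)
  expect_identical(cc$populations, c("popA", "popB", "out"))
  expect_equal(cc$n_snps, 1L)
  expect_equal(as.numeric(cc$p[1, ]), c(0.25, 0.5, 0))
  expect_equal(as.numeric(cc$m[1, ]), c(4, 4, 4))

  writeLines(c("popA popB out", "1,3 NA 0,4"), p)
  cc <- read_counts(p)
  expect_true(is.na(cc$p[1, "popB"]))

  writeLines(c("popA popB out", "1,3 2,2 0,4", "5,3 1,1"), p)
  expect_error(read_counts(p), "line 3")
  writeLines(c("popA popB out", "1,3 2,x 0,4"), p)
  expect_error(read_counts(p), "malformed")
})

test_that("count files round-trip through write_counts", {
  set.seed(5)
  x <- matrix(rbinom(30, 10, 0.4), 10, 3)
  m <- matrix(10, 10, 3)
  x[3, 2] <- NA; m[3, 2] <- NA
  cc <- allele_counts(x, m, c("a", "b", "out"))
  p <- withr::local_tempfile(fileext = ".txt")
  write_counts(cc, p)
  cc2 <- read_counts(p)
  expect_equal(cc2$x, cc$x)
  expect_equal(cc2$m, cc$m)
})

test_that("empirical covariance averages outgroup-centered products", {
  # two populations identical to the outgroup: zero matrix
  p <- cbind(a = c(0.2, 0.7), b = c(0.2, 0.7), out = c(0.2, 0.7))
  S <- empirical_covariance(make_counts(p, 10), "out")
  expect_equal(max(abs(S)), 0)

  # hand value: deviations +0.1 and -0.3 give (0.01 + 0.09)/2
  p <- cbind(a = c(0.3, 0.1), b = c(0.3, 0.1), out = c(0.2, 0.4))
  cc <- make_counts(p, 10)
  S <- empirical_covariance(cc, "out")
  expect_equal(S["a", "a"], 0.05)

  # excluding the second SNP leaves only the first summand
  cc$p[2, "a"] <- NA
  S2 <- empirical_covariance(cc, "out")
  expect_equal(S2["a", "a"], 0.01)
  # the (a,b) entry now averages over the single complete SNP as well
  expect_equal(S2["a", "b"], 0.01)
  expect_equal(S2["b", "b"], 0.05)
})

test_that("bias correction matches the finite-haplotype formula", {
  # outgroup fixed everywhere: off-diagonal term vanishes
  p <- cbind(a = c(0.5, 0.3), b = c(0.4, 0.6), out = c(0, 1))
  B <- bias_correction(make_counts(p, 5), "out")
  expect_equal(B["a", "b"], 0)

  # single SNP diagonal with p_k = 0.5, p_0 = 0.2, m = 5:
  # 0.25/4 + 0.16/4 = 0.1025
  cc <- allele_counts(matrix(c(2, 2.5, 1), 1), matrix(5, 1, 3),
                      c("a", "b", "out"))
  B <- bias_correction(cc, "out")
  expect_equal(B["b", "b"], 0.1025)

  # vanishes as m grows with frequencies fixed
  big <- make_counts(cbind(a = 0.5, b = 0.5, out = 0.4), 1e6)
  expect_lt(max(abs(bias_correction(big, "out"))), 1e-5)

  tiny <- allele_counts(matrix(c(1, 1, 0), 1), matrix(c(1, 2, 2), 1),
                        c("a", "b", "out"))
  expect_error(bias_correction(tiny, "out"), "m = 1")
})

test_that("heterozygosity normalizer uses complete SNPs only", {
  p <- cbind(a = 0.2, b = 0.4, out = 0.6)
  expect_equal(heterozygosity_norm(make_counts(p, 10)), 0.24)
  # permutation invariance
  expect_equal(heterozygosity_norm(make_counts(p[, c(2, 1, 3),
                                                 drop = FALSE], 10)),
               0.24)
  # SNP with missing entry is dropped
  cc <- make_counts(rbind(p, c(0.9, 0.9, 0.9)), 10)
  cc$p[2, 1] <- NA
  expect_equal(heterozygosity_norm(cc), 0.24)
  mono <- make_counts(cbind(a = 0, b = 0, out = 0), 10)
  expect_error(heterozygosity_norm(mono), "monomorphic")
})

test_that("block bootstrap is deterministic and centered on S/h", {
  set.seed(6)
  p <- matrix(runif(400, 0.2, 0.8), 100, 4,
              dimnames = list(NULL, c("a", "b", "c", "out")))
  cc <- make_counts(p, 50)
  base <- empirical_covariance(cc, "out") / heterozygosity_norm(cc)

  # one block: every replicate is exactly S/h
  reps <- bootstrap_covariances(cc, "out", R = 3, block_size = 100,
                                seed = 1)
  for (r in reps) expect_equal(r, base)

  # fixed seed reproduces the replicate list bit for bit
  r1 <- bootstrap_covariances(cc, "out", R = 5, block_size = 10, seed = 9)
  r2 <- bootstrap_covariances(cc, "out", R = 5, block_size = 10, seed = 9)
  expect_identical(r1, r2)

  # replicate mean approaches S/h
  r3 <- bootstrap_covariances(cc, "out", R = 400, block_size = 5,
                              seed = 2)
  avg <- Reduce(`+`, r3) / length(r3)
  expect_lt(max(abs(avg - base)), 0.05 * max(abs(base)))

  expect_error(bootstrap_covariances(cc, "out", block_size = 1000),
               "block_size")
})

test_that("moment df estimator has its closed form and scale invariance", {
  set.seed(7)
  M <- crossprod(matrix(rnorm(16), 4)) + diag(4)
  reps <- simulate_wishart(M, df = 80, R = 200, seed = 3)
  df_cf <- estimate_df_moment(reps)

  # numeric minimization of the moment objective agrees to 1e-6 relative
  mo <- rjadmix:::.rep_moments(reps)
  obj <- function(df) sum((mo$v - mo$a / df)^2)
  df_num <- optimize(obj, c(1, 1e5), tol = 1e-9)$minimum
  expect_lt(abs(df_cf - df_num) / df_num, 1e-6)

  # scaling all replicates leaves df unchanged
  df_sc <- estimate_df_moment(lapply(reps, function(X) 7.3 * X))
  expect_equal(df_sc, df_cf, tolerance = 1e-12)

  same <- rep(list(M), 5)
  expect_error(estimate_df_moment(same), "degenerate")
})

test_that("ML df estimator finds an interior optimum on Wishart draws", {
  set.seed(8)
  M <- crossprod(matrix(rnorm(9), 3)) + diag(3)
  reps <- simulate_wishart(M, df = 50, R = 300, seed = 4)
  df_ml <- estimate_df_mle(reps)
  expect_gt(df_ml, 50 * 0.8)
  expect_lt(df_ml, 50 * 1.2)
  # optimality against halved and doubled df
  mo <- rjadmix:::.rep_moments(reps)
  ll <- function(df) sum(vapply(reps, function(X)
    rjadmix:::dwishart_mean_log(X, mo$xbar, df), 0))
  expect_gte(ll(df_ml), ll(df_ml / 2))
  expect_gte(ll(df_ml), ll(df_ml * 2))
})

test_that("robustness scale follows the trace normalization", {
  S <- diag(c(3, 1)); h <- 1
  expect_equal(robustness_scale(S, h, 2), (2 * 1 + 2) / 4)
  # halving h halves c_S
  expect_equal(robustness_scale(S, 0.5, 2),
               robustness_scale(S, 1, 2) / 2)
  # c_S * tr(S/h) is the fixed target L log2 L + L
  for (L in 2:5) {
    S <- diag(runif(L, 0.5, 2)); h <- 0.3
    expect_equal(robustness_scale(S, h, L) * sum(diag(S)) / h,
                 L * log2(L) + L)
  }
  expect_error(robustness_scale(matrix(0, 2, 2), 1, 2), "trace")
})

test_that("df of iid-SNP bootstrap tracks the SNP count", {
  set.seed(9)
  g <- oracle_graph_k1(0.01)
  sim <- simulate_dataset(g, n_snps = 3000, m = 30, seed = 10)
  reps <- bootstrap_covariances(sim$counts, "out", R = 120,
                                block_size = 1, seed = 11)
  df <- estimate_df_moment(reps)
  expect_gt(df, 3000 * 0.75)
  expect_lt(df, 3000 * 1.25)
})
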