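test_that("runs are reproducible and degenerate ladders reduce cleanly", {
  cfg <- mc3_config(n_iter = 400L, thin = 4L, seed = 101)
  a <- mc3_run(NULL, leaves = c("A", "B", "C"), config = cfg)
  b <- mc3_run(NULL, leaves = c("A", "B", "C"), config = cfg)
  expect_identical(a$stats, b$stats)
  expect_identical(vapply(a$records, canonical_key, ""),
                   vapply(b$records, canonical_key, ""))
  expect_identical(length(a$records), 100L)
  # a single chain never swaps
  expect_true(is.na(a$swap_rate))
})

test_that("swaps between equal-temperature chains always succeed", {
  cfg <- mc3_config(n_iter = 300L, n_chains = 2L, betas = c(1, 1),
                    thin = 10L, swap_every = 5L, seed = 102)
  expect_error(mc3_config(n_iter = 10, n_chains = 2, betas = c(1, 1)),
               NA)
  ps <- mc3_run(NULL, leaves = c("A", "B"), config = cfg)
  expect_equal(ps$swap_rate, 1)
})

test_that("every recorded graph is valid and caches stay consistent", {
  cfg <- mc3_config(n_iter = 2000L, thin = 20L, seed = 103)
  ps <- mc3_run(NULL, leaves = c("A", "B", "C", "D"), config = cfg)
  for (g in ps$records) expect_length(validate_graph(g), 0)
  # recorded prior matches recomputation from the graph
  lp <- vapply(ps$records, log_prior_graph, 0)
  expect_equal(lp, ps$stats$log_prior, tolerance = 1e-9)
  expect_equal(ps$stats$log_post, ps$stats$log_lik + ps$stats$log_prior,
               tolerance = 1e-9)
  # K trace matches the recorded graphs
  expect_equal(vapply(ps$records, n_admixture, 1L),
               as.integer(ps$stats$K))
})

test_that("branch lengths follow the prior on the fixed 2-leaf topology", {
  # L = 2: a single labeled topology, so the run checks the continuous
  # moves (reflecting walks) against the analytic Exp(1) marginal
  cfg <- mc3_config(n_iter = 20000L, thin = 20L, seed = 104,
                    proposal_weights = c(add = 0, remove = 0, slide = 0,
                                         branch_rw = 0.6, resample_w = 0,
                                         outgroup_rw = 0.4,
                                         nullspace_rw = 0))
  ps <- mc3_run(NULL, leaves = c("A", "B"), config = cfg)
  lens <- vapply(ps$records[500:1000], function(g) g$length[1], 0)
  ks <- suppressWarnings(ks.test(lens, "pexp", 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("posterior event-count probability matches brute-force integration", {
  # data drawn exactly from the Wishart likelihood of a 3-leaf,
  # one-admixture graph; P(K = 1 | data) computed two ways: importance
  # sampling from the prior (enumeration oracle + prior draws, no MCMC)
  # and the reversible-jump chain restricted to K <= 1
  g_true <- rjadmix:::new_graph(
    child  = c("A", "m", "B", "C", "m", "s1", "s2"),
    parent = c("s1", "s1", "m", "s2", "s2", "r", "r"),
    length = c(0.8, 0.5, 0.6, 0.7, 0.4, 0.5, 0.6),
    type   = c("normal", "main", "normal", "normal", "admix", "normal",
               "normal"),
    prop   = c(NA, 0.6, NA, NA, 0.4, NA, NA),
    outgroup = "out", outgroup_length = 0.5)
  Sig <- graph_covariance(g_true)
  df <- 60
  S <- simulate_wishart(Sig, df, 1, seed = 72)[[1]]
  dimnames(S) <- dimnames(Sig)
  cov <- structure(list(S = S, B = matrix(0, 3, 3, dimnames = dimnames(Sig)),
                        h = 1, df = df,
                        c_S = (3 * log2(3) + 3) / sum(diag(S)),
                        populations = rownames(Sig), outgroup = "out"),
                   class = "covariance_estimate")
  lv <- rownames(Sig)
  likfn <- function(g) wishart_loglik(cov, graph_covariance(g)[lv, lv])

  set.seed(73)
  draw_lik <- function(K, n_draw) {
    topos <- enumerate_topologies(3, K, leaves = c("A", "B", "C"))
    mean_len <- 4 / (4 + 3 * K)
    vapply(seq_len(n_draw), function(i) {
      g <- topos[[sample.int(length(topos), 1L)]]
      g$length <- rexp(length(g$length), rate = 1 / mean_len)
      g$outgroup_length <- rexp(1, rate = 1 / mean_len)
      for (e in which(g$type == "admix")) {
        w <- runif(1)
        g$prop[e] <- w
        g$prop[g$child == g$child[e] & g$type == "main"] <- 1 - w
      }
      likfn(g)
    }, 0)
  }
  lme <- function(x) { m <- max(x); m + log(mean(exp(x - m))) }
  ev <- vapply(0:1, function(K) lme(draw_lik(K, 40000L)) + log_prior_K(K),
               0)
  p1_is <- 1 / (1 + exp(ev[1L] - ev[2L]))

  cfg <- mc3_config(n_iter = 50000L, thin = 5L, seed = 81, K_max = 1L)
  ps <- mc3_run(cov, config = cfg)
  p1_chain <- mean(ps$stats$K[2000:10000])
  expect_lt(abs(p1_chain - p1_is), 0.08)
  # and the posterior genuinely prefers one event here
  expect_gt(p1_is, 0.15)
  expect_lt(p1_is, 0.6)
})

test_that("adaptation freezes after the configured horizon", {
  cfg <- mc3_config(n_iter = 500L, thin = 500L, adapt_until = 0L,
                    seed = 105)
  ps <- mc3_run(NULL, leaves = c("A", "B", "C"), config = cfg)
  sc <- ps$scales[[1]]
  expect_equal(sc$lambda, 0.1)
  expect_equal(sc$s, 0.1)
  expect_equal(sc$s_out, 0.1)
  cfg2 <- mc3_config(n_iter = 500L, thin = 500L, adapt_until = 500L,
                     seed = 105)
  sc2 <- mc3_run(NULL, leaves = c("A", "B", "C"), config = cfg2)$scales[[1]]
  expect_false(isTRUE(all.equal(sc2$s, 0.1)))
})

test_that("states with impossible reverse or forbidden moves stay out", {
  # a likelihood wall at K > 0: the kernel must never accept a crossing
  set.seed(106)
  likfn <- function(g) if (n_admixture(g) > 0L) -Inf else 0
  cfg <- mc3_config(n_iter = 1L, seed = NULL)
  pc <- prior_config()
  state <- list(g = random_tree(c("A", "B", "C")), ll = 0, lp = 0)
  state$lp <- log_prior_graph(state$g, pc)
  scales <- rjadmix:::new_scales()
  for (i in 1:500) {
    st <- rjadmix:::mh_step(state, likfn, cfg, scales, adapt = FALSE,
                            pc = pc)
    state <- st$state; scales <- st$scales
    expect_identical(n_admixture(state$g), 0L)
  }
})
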