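test_that("add and remove are exact inverses with reciprocal densities", {
  set.seed(31)
  checked <- 0L
  for (rep in 1:120) {
    g <- random_admixture_graph(L = sample(2:5, 1), K = sample(0:2, 1))
    pr <- rjadmix:::propose_add_admixture(g, 20)
    if (is.null(pr)) next
    g2 <- pr$graph
    expect_true(rjadmix:::graph_is_valid(g2))
    expect_identical(n_admixture(g2), n_admixture(g) + 1L)
    # continuous dimension bookkeeping: +3 lengths, +1 proportion
    expect_identical(length(g2$child), length(g$child) + 3L)
    expect_identical(sum(!is.na(g2$prop)), sum(!is.na(g$prop)) + 2L)

    # removing the branch just added restores the graph and its lengths
    res <- rjadmix:::graph_remove_admixture(g2, length(g2$child))
    expect_false(is.null(res))
    expect_identical(canonical_key(res$graph), canonical_key(g))
    expect_equal(sum(res$graph$length), sum(g$length))

    # the remove bookkeeping reproduces the add density exactly
    g3 <- res$graph
    Dp <- length(rjadmix:::valid_admixture_sources(g3, res$sink))
    log_src <- if (identical(res$source, "root")) -res$u_source
               else -log(g3$length[res$source])
    log_bwd <- -log(length(g3$child)) - log(Dp) -
      log(g3$length[res$sink]) + log_src - res$s_len - log(2)
    expect_equal(log_bwd, pr$log_fwd, tolerance = 1e-9)
    checked <- checked + 1L
  }
  expect_gt(checked, 80L)
})

test_that("fast removal eligibility agrees with performing the removal", {
  set.seed(30)
  for (i in 1:60) {
    g <- random_admixture_graph(L = sample(2:5, 1), K = sample(1:3, 1))
    rem <- rjadmix:::removable_admixture_edges(g)
    tab <- table(g$child)
    admix_nodes <- names(tab)[tab == 2L]
    cand <- which(g$child %in% admix_nodes &
                    !(g$parent %in% admix_nodes))
    slow <- cand[vapply(cand, function(e)
      !is.null(rjadmix:::graph_remove_admixture(g, e)), NA)]
    expect_identical(rem, slow)
  }
})

test_that("remove move handles availability rules", {
  g <- tree_AB_C()
  expect_null(rjadmix:::propose_remove_admixture(g))
  set.seed(32)
  g1 <- random_admixture_graph(3, 1)
  rem <- rjadmix:::removable_admixture_edges(g1)
  expect_gte(length(rem), 1L)
  if (length(rem) == 1L) {
    pr <- rjadmix:::propose_remove_admixture(g1)
    expect_identical(pr$log_fwd, 0)  # -log(1)
  }
  # on K=1 graphs removal always returns to the tree space
  for (i in 1:20) {
    g1 <- random_admixture_graph(sample(3:5, 1), 1)
    pr <- rjadmix:::propose_remove_admixture(g1)
    expect_false(is.null(pr))
    expect_identical(n_admixture(pr$graph), 0L)
  }
})

test_that("node sliding preserves validity and the leaf set", {
  set.seed(33)
  moved <- 0L
  for (i in 1:200) {
    g <- random_admixture_graph(L = sample(3:5, 1), K = sample(0:2, 1))
    pr <- rjadmix:::propose_node_slide(g, lambda = 0.3)
    if (is.null(pr)) next
    expect_true(rjadmix:::graph_is_valid(pr$graph))
    expect_setequal(graph_leaves(pr$graph), graph_leaves(g))
    expect_identical(n_admixture(pr$graph), n_admixture(g))
    expect_true(is.finite(pr$log_fwd) && is.finite(pr$log_bwd))
    moved <- moved + 1L
  }
  expect_gt(moved, 100L)
})

test_that("sliding explores all three labeled 3-leaf trees", {
  set.seed(34)
  g <- tree_AB_C()
  seen <- character(0)
  for (i in 1:400) {
    pr <- rjadmix:::propose_node_slide(g, lambda = 1)
    if (!is.null(pr)) {
      g <- pr$graph   # accept everything: just reachability
      seen <- union(seen, canonical_key(g, topology_only = TRUE))
    }
  }
  expect_length(seen, 3L)
})

test_that("reflecting walks, proportion resampling and null-space moves", {
  g <- example_admixture_graph()
  set.seed(35)
  pr <- rjadmix:::propose_branch_rw(g, s = 0.5)
  expect_true(all(pr$graph$length > 0))
  expect_identical(pr$log_fwd, pr$log_bwd)
  # reflection at zero: proposed lengths are |x + eps|, so with a step
  # scale far above the current length they stay positive and follow the
  # folded-normal law
  tiny <- g; tiny$length[] <- 0.05
  draws <- replicate(300, rjadmix:::propose_branch_rw(tiny, s = 1)$graph$length[1])
  expect_true(all(draws > 0))
  ks <- suppressWarnings(ks.test(draws, function(q)
    pnorm(q, 0.05, 1) - pnorm(-q, 0.05, 1)))
  expect_gt(ks$p.value, 0.001)

  pr <- rjadmix:::propose_outgroup_rw(g, s = 0.2)
  expect_gt(pr$graph$outgroup_length, 0)
  expect_identical(pr$graph$length, g$length)

  # proportion resampling touches only the admixture pair
  pr <- rjadmix:::propose_resample_w(g)
  adm <- pr$graph$type == "admix"
  expect_equal(sum(pr$graph$prop[!is.na(pr$graph$prop)]), 1)
  expect_identical(pr$graph$length, g$length)
  g0 <- tree_AB_C()
  pr0 <- rjadmix:::propose_resample_w(g0)
  expect_identical(canonical_key(pr0$graph), canonical_key(g0))
  expect_identical(pr0$graph$length, g0$length)

  # null-space step leaves the covariance (hence likelihood) unchanged
  set.seed(36)
  changed <- 0L
  for (i in 1:20) {
    gk <- random_admixture_graph(3, 1)
    S0 <- graph_covariance(gk)
    pr <- rjadmix:::propose_nullspace_rw(gk, s = 0.05)
    if (is.null(pr) || isTRUE(pr$no_op)) next
    if (!identical(pr$graph$length, gk$length)) changed <- changed + 1L
    expect_lt(max(abs(graph_covariance(pr$graph) - S0)), 1e-9)
  }
  expect_gt(changed, 5L)
})
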