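test_that("validity rules catch the defining violations", {
  g <- example_admixture_graph()
  expect_length(validate_graph(g), 0)

  # both parent edges of the admixture node attached to the same parent
  eye <- g
  eye$parent[eye$child == "m"] <- "s1"
  expect_true(any(grepl("eye", validate_graph(eye))))

  # two parentless internal nodes
  two_roots <- admixture_graph(data.frame(
    child = c("A", "B", "C", "ab"), parent = c("ab", "ab", "r2", "r1"),
    length = 1), outgroup = "out", outgroup_length = 1, validate = FALSE)
  expect_false(length(validate_graph(two_roots)) == 0)

  # non-positive lengths, bad proportions, branch-count mismatch
  bad <- g; bad$length[1] <- -1
  expect_true(any(grepl("length", validate_graph(bad))))
  bad <- g; bad$prop[bad$type == "admix"] <- 1.2
  expect_true(length(validate_graph(bad)) > 0)

  # fast checker agrees with the detailed one on random graphs
  set.seed(1)
  for (i in 1:25) {
    gg <- random_admixture_graph(L = sample(2:5, 1), K = sample(0:2, 1))
    expect_true(rjadmix:::graph_is_valid(gg))
    expect_length(validate_graph(gg), 0)
  }
})

test_that("edge count is 2L - 2 + 3K on random graphs", {
  set.seed(2)
  for (i in 1:20) {
    L <- sample(2:6, 1); K <- sample(0:3, 1)
    g <- random_admixture_graph(L = L, K = K)
    expect_identical(length(g$child), 2L * L - 2L + 3L * K)
  }
})

test_that("topology sets follow the descendant-set definition", {
  expect_equal(as.character(topology_set(tree_AB_C())), "A,B")
  expect_equal(sort(as.character(topology_set(example_admixture_graph()))),
               c("P1,P2", "P2", "P2,P3"))
  two_leaf <- admixture_graph(
    data.frame(child = c("A", "B"), parent = "r", length = 1),
    outgroup = "out", outgroup_length = 1)
  expect_length(topology_set(two_leaf), 0)
})

test_that("minimal topology extends a topology set by cover relations", {
  # on trees the construction reproduces the tree itself
  mt <- minimal_topology(tree_ABC_D())
  expect_setequal(mt$nodes, c("A,B,C,D", "A,B,C", "A,B", "A", "B", "C",
                              "D"))
  expect_true(all(c("A,B,C>A,B", "A,B>A", "A,B,C,D>D") %in%
                    paste(mt$edges$from, mt$edges$to, sep = ">")))
  expect_false("A,B,C,D>A,B" %in%
                 paste(mt$edges$from, mt$edges$to, sep = ">"))

  # the admixed node {P2} acquires both {P1,P2} and {P2,P3} as parents
  mt2 <- minimal_topology(topology_set(example_admixture_graph()))
  ek <- paste(mt2$edges$from, mt2$edges$to, sep = ">")
  expect_true(all(c("P1,P2>P2", "P2,P3>P2") %in% ek))
  expect_true(all(c("P1,P2,P3>P1,P2", "P1,P2,P3>P2,P3") %in% ek))

  # empty topology set gives the star
  star <- minimal_topology(rjadmix:::new_topology_set(character(0),
                                                      c("A", "B")))
  expect_setequal(paste(star$edges$from, star$edges$to, sep = ">"),
                  c("A,B>A", "A,B>B"))
})

test_that("minimal_topology of a tree's topology set is the tree", {
  set.seed(3)
  for (i in 1:10) {
    L <- sample(3:8, 1)
    g <- random_tree(paste0("t", 1:L))
    mt <- minimal_topology(topology_set(g))
    # every internal tree node corresponds 1:1 to a minimal-topology node
    desc <- rjadmix:::leaf_descendants(g)
    keys <- unique(vapply(desc, function(s) paste(sort(s), collapse = ","),
                          ""))
    expect_setequal(mt$nodes, keys)
    # and each non-root node has exactly one parent edge
    root_key <- paste(sort(graph_leaves(g)), collapse = ",")
    in_deg <- table(factor(mt$edges$to, levels = mt$nodes))
    expect_true(all(in_deg[setdiff(mt$nodes, root_key)] == 1))
    expect_identical(as.integer(in_deg[root_key]), 0L)
  }
})

test_that("set distance is the symmetric difference and a pseudometric", {
  expect_identical(set_distance(tree_AB_C(), tree_AB_C()), 0L)
  expect_identical(set_distance(tree_AB_CD(), tree_ABC_D()), 2L)
  expect_error(set_distance(tree_AB_C(), tree_AB_CD()), "leaf sets")
  set.seed(4)
  for (i in 1:15) {
    g1 <- random_admixture_graph(5, sample(0:2, 1))
    g2 <- random_admixture_graph(5, sample(0:2, 1))
    g3 <- random_admixture_graph(5, sample(0:2, 1))
    d12 <- set_distance(g1, g2); d21 <- set_distance(g2, g1)
    expect_identical(d12, d21)
    expect_gte(d12, 0L)
    expect_lte(set_distance(g1, g3), d12 + set_distance(g2, g3))
  }
})

test_that("covariance distance is the sum of squared differences", {
  expect_equal(covariance_distance(matrix(2), matrix(5)), 9)
  S <- matrix(c(2, 1, 1, 3), 2)
  expect_equal(covariance_distance(S, S), 0)
  perm <- c(2, 1)
  S2 <- matrix(c(4, 0.5, 0.5, 1), 2)
  expect_equal(covariance_distance(S, S2),
               covariance_distance(S[perm, perm], S2[perm, perm]))
  expect_error(covariance_distance(S, matrix(1, 3, 3)), "shape")
})

test_that("subgraph restriction intersects and drops trivial sets", {
  g4 <- tree_graph(list(c("A", "B", "ab", "C", "abc", "D"),
                        c("ab", "ab", "abc", "abc", "r", "r")))
  mt <- restrict_to_subgraph(g4, c("A", "B", "C"))
  expect_setequal(mt$nodes, c("A,B,C", "A,B", "A", "B", "C"))

  # identity on the full leaf set
  g <- example_admixture_graph()
  full <- restrict_to_subgraph(g, graph_leaves(g))
  expect_identical(rjadmix:::minimal_topology_key(full),
                   rjadmix:::minimal_topology_key(
                     minimal_topology(topology_set(g))))

  # {P1,P3}: every intersection is trivial, leaving a star
  star <- restrict_to_subgraph(g, c("P1", "P3"))
  expect_setequal(star$nodes, c("P1,P3", "P1", "P3"))
  expect_error(restrict_to_subgraph(g, "P1"), "two focal")
  expect_error(restrict_to_subgraph(g, c("P1", "nope")), "subset")
})

test_that("canonical keys identify labeled topologies", {
  g <- example_admixture_graph()
  shuf <- sample(seq_along(g$child))
  g2 <- rjadmix:::new_graph(g$child[shuf], g$parent[shuf],
                            g$length[shuf], g$type[shuf], g$prop[shuf],
                            g$outgroup, g$outgroup_length)
  # internal relabeling + edge permutation leaves the key unchanged
  map <- c(m = "zz1", s1 = "zz2", s2 = "zz3", r = "zz4")
  g2$child <- ifelse(g2$child %in% names(map), map[g2$child], g2$child)
  g2$parent <- ifelse(g2$parent %in% names(map), map[g2$parent],
                      g2$parent)
  expect_identical(canonical_key(g), canonical_key(g2))

  expect_false(canonical_key(tree_AB_C()) == canonical_key(tree_AC_B()))

  # branch lengths and proportions do not enter the key
  g3 <- example_admixture_graph(w = 0.9)
  g3$length <- g3$length * 3
  expect_identical(canonical_key(g), canonical_key(g3))

  # swapping the main/admix labels changes the default key only
  g4 <- example_admixture_graph()
  adm <- g4$type == "admix"; mn <- g4$type == "main"
  g4$type[adm] <- "main"; g4$type[mn] <- "admix"
  expect_false(canonical_key(g) == canonical_key(g4))
  expect_identical(canonical_key(g, topology_only = TRUE),
                   canonical_key(g4, topology_only = TRUE))
})

test_that("graph serialization round-trips and rejects malformed files", {
  g <- example_admixture_graph()
  p <- withr::local_tempfile(fileext = ".txt")
  write_graph(g, p)
  g2 <- read_graph(p)
  expect_identical(canonical_key(g), canonical_key(g2))
  expect_equal(g2$length[order(g2$child, g2$parent)],
               g$length[order(g$child, g$parent)])
  expect_equal(g2$outgroup_length, g$outgroup_length)
  expect_identical(g2$outgroup, g$outgroup)

  writeLines(c("@outgroup out 1", "A\tr"), p)
  expect_error(read_graph(p), "fields")
})

test_that("DOT export marks admixture edges dashed", {
  g <- example_admixture_graph()
  p <- withr::local_tempfile(fileext = ".dot")
  write_dot(g, p)
  txt <- readLines(p)
  expect_true(any(grepl("style=dashed", txt)))
  expect_true(any(grepl("digraph", txt)))
  mt <- minimal_topology(topology_set(g))
  attr(mt, "frequencies") <- c("P2" = 0.8)
  write_dot(mt, p)
  expect_true(any(grepl("80%", readLines(p))))
})
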