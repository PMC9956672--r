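# Shared graph fixtures, built in code.

# Three-populations-plus-outgroup graph with one admixed population (P2),
# mirroring the worked design-matrix example: P2 draws a fraction w of its
# ancestry through the P3-side lineage and 1-w through the P1-side one.
example_admixture_graph <- function(w = 0.3) {
  admixture_graph(data.frame(
    child  = c("P1", "m",    "P2", "P3", "m",     "s1", "s2"),
    parent = c("s1", "s1",   "m",  "s2", "s2",    "r",  "r"),
    length = c(2,    3,      7,    4,    6,       1.5,  2.5),
    type   = c("normal", "main", "normal", "normal", "admix", "normal",
               "normal"),
    prop   = c(NA, 1 - w, NA, NA, w, NA, NA)),
    outgroup = "out", outgroup_length = 1)
}

# plain rooted trees from newick-ish nested lists, unit branch lengths
tree_graph <- function(edges, outgroup = "out") {
  admixture_graph(data.frame(child = edges[[1]], parent = edges[[2]],
                             length = 1),
                  outgroup = outgroup, outgroup_length = 1)
}

tree_AB_C <- function() tree_graph(list(c("A", "B", "ab", "C"),
                                        c("ab", "ab", "r", "r")))
tree_AC_B <- function() tree_graph(list(c("A", "C", "ac", "B"),
                                        c("ac", "ac", "r", "r")))
tree_AB_CD <- function() tree_graph(list(
  c("A", "B", "C", "D", "ab", "cd"),
  c("ab", "ab", "cd", "cd", "r", "r")))
tree_ABC_D <- function() tree_graph(list(
  c("A", "B", "ab", "C", "abc", "D"),
  c("ab", "ab", "abc", "abc", "r", "r")))

# 4-leaf, one-admixture graph with drift branch lengths small enough that
# the Gaussian model stays far from the frequency boundaries
oracle_graph_k1 <- function(scale = 0.002) {
  admixture_graph(data.frame(
    child  = c("A", "m", "B", "C", "D", "cd", "m", "ab", "d"),
    parent = c("ab", "ab", "m", "cd", "cd", "d", "d", "r", "r"),
    length = scale * c(2, 0.8, 1.2, 1.8, 2.5, 1.2, 1.5, 1.5, 1),
    type   = c("normal", "main", "normal", "normal", "normal", "normal",
               "admix", "normal", "normal"),
    prop   = c(NA, 0.65, NA, NA, NA, NA, 0.35, NA, NA)),
    outgroup = "out", outgroup_length = scale * 2)
}

# a random valid graph with K admixture events, built through the proposal
# machinery (so tests exercise realistic shapes)
random_admixture_graph <- function(L = 4, K = 1,
                                   leaves = paste0("p", seq_len(L))) {
  g <- random_tree(leaves)
  added <- 0L
  while (added < K) {
    pr <- rjadmix:::propose_add_admixture(g, K_max = K + 2L)
    if (!is.null(pr)) {
      g <- pr$graph
      added <- added + 1L
    }
  }
  g
}
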