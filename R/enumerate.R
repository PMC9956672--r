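## Brute-force enumeration of labeled admixture-graph topologies. This is
## the independent oracle for the counting recurrence and for canonical-key
## uniqueness; it is only meant for small L and K.

## all rooted, leaf-labeled binary trees on the given leaves, as
## admixture_graphs with unit branch lengths
enumerate_trees <- function(leaves, outgroup = "out") {
  stopifnot(length(leaves) >= 2L)
  base <- admixture_graph(
    data.frame(child = leaves[1:2], parent = "n1", length = 1),
    outgroup = outgroup, outgroup_length = 1)
  trees <- list(base)
  nid <- 1L
  for (lf in leaves[-(1:2)]) {
    nid <- nid + 1L
    nn <- paste0("n", nid)
    out <- list()
    for (tr in trees) {
      ## attach to every edge
      for (k in seq_along(tr$child)) {
        child <- c(tr$child, tr$child[k], lf)
        parent <- c(tr$parent, nn, nn)
        child[k] <- nn
        out[[length(out) + 1L]] <- new_graph(
          child, parent, rep(1, length(child)),
          rep("normal", length(child)), rep(NA_real_, length(child)),
          outgroup, 1)
      }
      ## attach above the root
      root <- graph_root(tr)
      child <- c(tr$child, root, lf)
      parent <- c(tr$parent, nn, nn)
      out[[length(out) + 1L]] <- new_graph(
        child, parent, rep(1, length(child)),
        rep("normal", length(child)), rep(NA_real_, length(child)),
        outgroup, 1)
    }
    trees <- out
  }
  trees
}

#' Number of cherries of an admixture graph
#'
#' A cherry is a pair of leaves sharing a common parent node.
#'
#' @param g an `admixture_graph`.
#' @return Integer cherry count.
#' @export
count_cherries <- function(g) {
  leaves <- graph_leaves(g)
  pars <- unique(g$parent)
  sum(vapply(pars, function(v) {
    ch <- g$child[g$parent == v]
    length(ch) == 2L && all(ch %in% leaves)
  }, NA))
}

#' Enumerate all labeled admixture-graph topologies
#'
#' Brute-force oracle: builds every distinct labeled, eye-free topology
#' with `L` leaves and `K` admixture events, deduplicated by
#' [canonical_key()] (which distinguishes the main/admix labeling of
#' admixture parent edges). Trees (K = 0) are enumerated directly; for
#' K >= 1 every discrete add-admixture choice is applied to each topology
#' with K - 1 events. Intended for small problems (L <= 5, K <= 2); the
#' result is complete for K <= 1, where every graph has a removable
#' admixture branch.
#'
#' @param L number of leaves (2 to 5).
#' @param K number of admixture events (0 to 2).
#' @param P optional cherry-count filter.
#' @param max_items guard against combinatorial explosion; error if the
#'   candidate list exceeds it.
#' @param leaves leaf labels, default `l1, ..., lL`.
#' @return List of `admixture_graph` topologies (unit branch lengths,
#'   proportions 0.5).
#' @examples
#' length(enumerate_topologies(3, 0))  # 3 labeled trees
#' @export
enumerate_topologies <- function(L, K, P = NULL, max_items = 100000L,
                                 leaves = paste0("l", seq_len(L))) {
  stopifnot(L >= 2L, L <= 5L, K >= 0L, K <= 2L, length(leaves) == L)
  graphs <- enumerate_trees(leaves)
  if (K > 0L) {
    for (k in seq_len(K)) {
      seen <- new.env(parent = emptyenv())
      out <- list()
      for (g in graphs) {
        D <- length(g$child)
        for (sink in seq_len(D)) {
          for (source in valid_admixture_sources(g, sink)) {
            for (admix_on_new in c(TRUE, FALSE)) {
              g2 <- graph_add_admixture(
                g, sink, source,
                u_sink = g$length[sink] / 2,
                u_source = if (identical(source, "root")) 1
                           else g$length[[source]] / 2,
                s_len = 1, w = 0.5, admix_on_new = admix_on_new)
              key <- canonical_key(g2)
              if (is.null(seen[[key]])) {
                seen[[key]] <- TRUE
                out[[length(out) + 1L]] <- g2
                if (length(out) > max_items)
                  stop("enumerate_topologies: more than max_items topologies")
              }
            }
          }
        }
      }
      graphs <- out
    }
  } else {
    ## trees from sequential attachment are already distinct, but dedupe
    ## anyway so the function is its own check
    keys <- vapply(graphs, canonical_key, "")
    graphs <- graphs[!duplicated(keys)]
  }
  if (!is.null(P))
    graphs <- graphs[vapply(graphs, count_cherries, 1L) == P]
  graphs
}

## relabel the leaves of a topology according to a named mapping
relabel_leaves <- function(g, map) {
  child <- g$child
  hit <- child %in% names(map)
  child[hit] <- unname(map[child[hit]])
  new_graph(child, g$parent, g$length, g$type, g$prop, g$outgroup,
            g$outgroup_length)
}

## canonical key of the unlabeled topology: minimum labeled key over all
## permutations of the leaf labels (respects main/admix edge types)
unlabeled_key <- function(g) {
  leaves <- sort(graph_leaves(g))
  perms <- permutations_of(leaves)
  keys <- vapply(perms, function(p) {
    names(p) <- leaves
    canonical_key(relabel_leaves(g, p))
  }, "")
  min(keys)
}

permutations_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    rest <- permutations_of(x[-i])
    for (r in rest) out[[length(out) + 1L]] <- c(x[i], r)
  }
  out
}

#' Count unlabeled topologies by orbit collapse
#'
#' Groups the labeled topologies from [enumerate_topologies()] into
#' equivalence classes under permutation of the leaf labels (graph
#' isomorphism respecting main/admix edge types) and returns the class
#' sizes, named by a canonical class representative key.
#'
#' @inheritParams enumerate_topologies
#' @return Named integer vector of orbit sizes; its length is the number
#'   of distinct unlabeled topologies.
#' @export
count_unlabeled_topologies <- function(L, K, P = NULL) {
  graphs <- enumerate_topologies(L, K, P)
  keys <- vapply(graphs, unlabeled_key, "")
  tab <- table(keys)
  stats::setNames(as.integer(tab), names(tab))
}
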