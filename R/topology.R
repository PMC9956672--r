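## Topology sets, minimal topologies, graph distances, canonical keys.
##
## A topology set is the set of leaf-descendant sets of all internal
## (non-leaf, non-root) nodes of an admixture graph. It discards the number
## and timing of admixture events and is the basis of every posterior
## summary.

set_key <- function(x) paste(sort(x), collapse = ",")
key_set <- function(k) strsplit(k, ",", fixed = TRUE)[[1L]]

#' Topology set of an admixture graph
#'
#' Returns the set of descendant (leaf) sets of every internal node,
#' excluding the leaves themselves and the root. Admixture and divergence
#' nodes are treated identically. Duplicated descendant sets collapse.
#'
#' @param g an `admixture_graph` (or an existing `topology_set`, returned
#'   unchanged).
#' @return A `topology_set`: a character vector of comma-joined sorted leaf
#'   sets, with attribute `leaves` giving the leaf universe.
#' @examples
#' g <- admixture_graph(
#'   data.frame(child = c("A", "B", "C", "ab"),
#'              parent = c("ab", "ab", "r", "r"),
#'              length = rep(0.1, 4)),
#'   outgroup = "out", outgroup_length = 0.1)
#' topology_set(g)   # {A,B}
#' @export
topology_set <- function(g) {
  if (inherits(g, "topology_set")) return(g)
  stopifnot(inherits(g, "admixture_graph"))
  leaves <- graph_leaves(g)
  root <- graph_root(g)
  desc <- leaf_descendants(g)
  internal <- setdiff(names(desc), c(leaves, root))
  elems <- unique(vapply(desc[internal], set_key, ""))
  structure(sort(elems), leaves = sort(leaves), class = "topology_set")
}

new_topology_set <- function(elems, leaves) {
  structure(sort(unique(elems)), leaves = sort(leaves),
            class = "topology_set")
}

#' @export
print.topology_set <- function(x, ...) {
  cat("topology set over {", paste(attr(x, "leaves"), collapse = ", "),
      "}:\n", sep = "")
  if (!length(x)) cat("  (empty)\n")
  for (e in x) cat("  {", gsub(",", ", ", e), "}\n", sep = "")
  invisible(x)
}

#' Minimal topology of a topology set
#'
#' Extends a topology set to the smallest directed graph consistent with it:
#' nodes are the topology-set elements plus the trivial leaf singletons and
#' the full leaf set (root); there is an edge from set t to set t' exactly
#' when t' is a proper subset of t with no third set strictly between them.
#'
#' @param ts a `topology_set` (or an `admixture_graph`, converted first).
#' @return A `minimal_topology`: list with `nodes` (character vector of set
#'   keys), `edges` (data frame `from`, `to`) and `leaves`.
#' @export
minimal_topology <- function(ts) {
  if (inherits(ts, "admixture_graph")) ts <- topology_set(ts)
  stopifnot(inherits(ts, "topology_set"))
  leaves <- attr(ts, "leaves")
  stopifnot(length(leaves) >= 1L)
  nodes <- unique(c(set_key(leaves), as.character(ts), leaves))
  sets <- lapply(nodes, key_set)
  n <- length(nodes)
  from <- character(0); to <- character(0)
  subset_of <- function(a, b) all(a %in% b)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    t1 <- sets[[i]]; t2 <- sets[[j]]
    if (length(t2) >= length(t1) || !subset_of(t2, t1)) next
    blocked <- FALSE
    for (k in seq_len(n)) {
      if (k == i || k == j) next
      tk <- sets[[k]]
      if (subset_of(t2, tk) && subset_of(tk, t1)) { blocked <- TRUE; break }
    }
    if (!blocked) { from <- c(from, nodes[i]); to <- c(to, nodes[j]) }
  }
  structure(list(nodes = sort(nodes),
                 edges = data.frame(from = from, to = to,
                                    stringsAsFactors = FALSE),
                 leaves = leaves),
            class = "minimal_topology")
}

#' @export
print.minimal_topology <- function(x, ...) {
  cat("minimal topology over {", paste(x$leaves, collapse = ", "), "}, ",
      length(x$nodes), " nodes, ", nrow(x$edges), " edges\n", sep = "")
  e <- x$edges[order(x$edges$from, x$edges$to), , drop = FALSE]
  for (i in seq_len(nrow(e)))
    cat("  {", gsub(",", ", ", e$from[i]), "} -> {",
        gsub(",", ", ", e$to[i]), "}\n", sep = "")
  invisible(x)
}

## deterministic identity key for a minimal topology (nodes are leaf sets,
## so no relabeling is needed)
minimal_topology_key <- function(mt) {
  ek <- paste(mt$edges$from, mt$edges$to, sep = ">")
  paste(c(paste(sort(mt$nodes), collapse = ";"),
          paste(sort(ek), collapse = ";")), collapse = "||")
}

#' Set Distance between two graphs or topology sets
#'
#' The size of the symmetric difference between the two topology sets,
#' |T1 \\ T2| + |T2 \\ T1| — a Robinson-Foulds-style distance that ignores
#' branch lengths, admixture proportions and the number of admixture events.
#'
#' @param g1,g2 `admixture_graph`s or `topology_set`s over the same leaves.
#' @return Non-negative integer.
#' @export
set_distance <- function(g1, g2) {
  t1 <- topology_set(g1); t2 <- topology_set(g2)
  if (!identical(attr(t1, "leaves"), attr(t2, "leaves")))
    stop("set_distance: graphs have different leaf sets")
  length(setdiff(t1, t2)) + length(setdiff(t2, t1))
}

#' Covariance Distance between two covariance matrices
#'
#' Sum of squared entrywise differences between two graph-implied (or
#' empirical) covariance matrices over the same populations, in the same
#' order.
#'
#' @param S1,S2 square symmetric matrices of equal dimension.
#' @return Non-negative scalar.
#' @export
covariance_distance <- function(S1, S2) {
  S1 <- as.matrix(S1); S2 <- as.matrix(S2)
  if (!all(dim(S1) == dim(S2)) || nrow(S1) != ncol(S1))
    stop("covariance_distance: shape mismatch")
  sum((S1 - S2)^2)
}

#' Restrict an admixture graph to a focal leaf subset
#'
#' Intersects every topology-set element with the focal set, drops results
#' that become empty, a singleton, or the whole focal set, and builds the
#' minimal topology over the focal leaves. This is how a sampled graph
#' contributes to subgraph posterior summaries.
#'
#' @param g an `admixture_graph` or `topology_set`.
#' @param focal subset of the leaves, at least two.
#' @return A `minimal_topology` over `focal`.
#' @export
restrict_to_subgraph <- function(g, focal) {
  ts <- topology_set(g)
  leaves <- attr(ts, "leaves")
  focal <- sort(unique(as.character(focal)))
  if (!all(focal %in% leaves)) stop("focal populations not a subset of leaves")
  if (length(focal) < 2L) stop("need at least two focal populations")
  restricted <- character(0)
  for (e in ts) {
    r <- intersect(key_set(e), focal)
    if (length(r) >= 2L && length(r) < length(focal))
      restricted <- c(restricted, set_key(r))
  }
  minimal_topology(new_topology_set(restricted, focal))
}

#' Canonical key of a labeled admixture-graph topology
#'
#' Produces a string such that two valid graphs receive the same key exactly
#' when they share the same labeled topology: same leaves, same wiring of
#' divergence and admixture nodes, and (by default) the same main/admixture
#' labeling of the parent edges of each admixture node. Branch lengths and
#' proportions are ignored. The key is computed by iterative color
#' refinement seeded from the (fixed) leaf labels, with individualization
#' branching on the rare residual symmetric classes, so it is deterministic
#' and invariant under internal node relabeling and edge-list permutation.
#'
#' @param g an `admixture_graph`.
#' @param topology_only if `TRUE`, ignore the main/admix edge labels, so two
#'   graphs differing only in which parent edge of an admixture node is
#'   labeled "main" compare equal.
#' @return A character scalar.
#' @export
canonical_key <- function(g, topology_only = FALSE) {
  stopifnot(inherits(g, "admixture_graph"))
  nodes <- graph_nodes(g)
  leaves <- graph_leaves(g)
  ci <- match(g$child, nodes)
  pi_ <- match(g$parent, nodes)
  ety <- if (topology_only) rep("e", length(g$type)) else g$type
  ## initial colors: leaves are individualized by their labels
  col0 <- ifelse(nodes %in% leaves, paste0("L:", nodes), "I")
  key <- canon_search(ci, pi_, ety, match(col0, sort(unique(col0))),
                      nodes, leaves)
  key
}

## refine colors to a stable partition; returns integer colors
canon_refine <- function(ci, pi_, ety, col) {
  repeat {
    sig <- vapply(seq_along(col), function(v) {
      dn <- which(pi_ == v)   # edges to children
      up <- which(ci == v)    # edges from parents
      paste(col[v],
            paste(sort(paste(ety[dn], col[ci[dn]], sep = "~")), collapse = "|"),
            paste(sort(paste(ety[up], col[pi_[up]], sep = "~")), collapse = "|"),
            sep = "#")
    }, "")
    newcol <- match(sig, sort(unique.default(sig)))
    ## compare partitions, not labels: the signature sort may permute the
    ## labels of an already-stable partition
    if (identical(match(newcol, unique.default(newcol)),
                  match(col, unique.default(col)))) return(newcol)
    col <- newcol
  }
}

## individualization-refinement search returning the lexicographically
## smallest edge-list encoding over all discrete refinements
canon_search <- function(ci, pi_, ety, col, nodes, leaves) {
  col <- canon_refine(ci, pi_, ety, col)
  tab <- tabulate(col)
  amb <- which(tab[col] > 1L)
  if (!length(amb)) {
    ## discrete: emit the canonical edge list (leaves keep their labels)
    name <- ifelse(nodes %in% leaves, nodes, paste0("#", col))
    ek <- paste(name[ci], name[pi_], ety, sep = ">")
    return(paste(sort(ek), collapse = ";"))
  }
  target <- min(col[amb])
  cand <- which(col == target)
  best <- NULL
  for (v in cand) {
    col2 <- col
    col2[v] <- max(col) + 1L
    k <- canon_search(ci, pi_, ety, col2, nodes, leaves)
    if (is.null(best) || k < best) best <- k
  }
  best
}
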