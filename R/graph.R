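#' Admixture graph objects
#'
#' An admixture graph is a rooted directed acyclic graph describing a
#' population history. Leaves are labeled sampled populations; internal nodes
#' are either divergence nodes (one parent, two children) or admixture nodes
#' (two parents, one child). The root has two children and is itself the
#' child of the outgroup, whose branch length `outgroup_length` enters every
#' covariance entry. Branch lengths are in drift units
#' (c = 1 - exp(-t/2N)). Each admixture node carries a proportion w in (0,1):
#' its parent edge labeled `"admix"` contributes w of its ancestry and the
#' edge labeled `"main"` the remaining 1 - w.
#'
#' @param edges data frame with columns `child`, `parent`, `length` and
#'   optionally `type` (`"normal"`, `"main"` or `"admix"`) and `prop`
#'   (ancestry weight; required on `main`/`admix` edges, `NA` otherwise).
#'   The edge set excludes the outgroup branch, which is given separately.
#' @param outgroup label of the outgroup population (must not occur in
#'   `edges`).
#' @param outgroup_length length of the branch between the root and the
#'   outgroup, in drift units.
#' @param validate if `TRUE` (default) stop on an invalid graph.
#'
#' @return An object of class `admixture_graph`.
#' @seealso [validate_graph()], [topology_set()], [read_graph()]
#' @examples
#' g <- admixture_graph(
#'   data.frame(child = c("A", "B", "C", "ab"),
#'              parent = c("ab", "ab", "r", "r"),
#'              length = c(0.05, 0.05, 0.1, 0.02)),
#'   outgroup = "out", outgroup_length = 0.3)
#' graph_leaves(g)
#' @export
admixture_graph <- function(edges, outgroup, outgroup_length,
                            validate = TRUE) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (is.null(edges$type)) edges$type <- "normal"
  edges$type[is.na(edges$type)] <- "normal"
  if (is.null(edges$prop)) edges$prop <- NA_real_
  g <- structure(list(
    child = as.character(edges$child),
    parent = as.character(edges$parent),
    length = as.numeric(edges$length),
    type = as.character(edges$type),
    prop = as.numeric(edges$prop),
    outgroup = as.character(outgroup),
    outgroup_length = as.numeric(outgroup_length)
  ), class = "admixture_graph")
  if (validate) {
    v <- validate_graph(g)
    if (length(v)) stop("invalid admixture graph: ", paste(v, collapse = "; "))
  }
  g
}

## internal constructor used in hot paths; skips coercion and validation
new_graph <- function(child, parent, length, type, prop, outgroup,
                      outgroup_length) {
  structure(list(child = child, parent = parent, length = length,
                 type = type, prop = prop, outgroup = outgroup,
                 outgroup_length = outgroup_length),
            class = "admixture_graph")
}

#' @export
print.admixture_graph <- function(x, ...) {
  L <- length(graph_leaves(x))
  cat(sprintf(
    "admixture graph: %d leaves, %d admixture events, %d branches (+ outgroup '%s', c0 = %.4g)\n",
    L, n_admixture(x), length(x$child), x$outgroup, x$outgroup_length))
  cat("  leaves:", paste(sort(graph_leaves(x)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.admixture_graph <- function(x, ...) {
  data.frame(child = x$child, parent = x$parent, length = x$length,
             type = x$type, prop = x$prop, stringsAsFactors = FALSE)
}

#' Graph accessors
#'
#' `graph_leaves()` returns the leaf labels (excluding the outgroup),
#' `graph_root()` the root node, `graph_nodes()` all node names,
#' `n_admixture()` the number of admixture nodes (K).
#'
#' @param g an `admixture_graph`.
#' @return character vector of labels, or an integer for `n_admixture()`.
#' @export
graph_leaves <- function(g) setdiff(g$child, g$parent)

#' @rdname graph_leaves
#' @export
graph_root <- function(g) setdiff(g$parent, g$child)

#' @rdname graph_leaves
#' @export
graph_nodes <- function(g) unique(c(g$child, g$parent))

#' @rdname graph_leaves
#' @export
n_admixture <- function(g) {
  ## nodes appearing twice as a child have two parents
  ci <- match(g$child, unique.default(g$child))
  sum(tabulate(ci) == 2L)
}

## parent count per node name, as named integer
in_degree <- function(g) table(g$child)

## topological order of nodes, root first; NULL if cyclic
topo_order <- function(g) {
  nodes <- graph_nodes(g)
  indeg <- integer(length(nodes))
  names(indeg) <- nodes
  tab <- table(g$child)
  indeg[names(tab)] <- as.integer(tab)
  order <- character(0)
  frontier <- nodes[indeg == 0L]
  while (length(frontier)) {
    v <- frontier[1L]
    frontier <- frontier[-1L]
    order <- c(order, v)
    for (ch in g$child[g$parent == v]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) frontier <- c(frontier, ch)
    }
  }
  if (length(order) != length(nodes)) return(NULL)
  order
}

## descendant leaf sets for every node: named list of character vectors
leaf_descendants <- function(g) {
  ord <- topo_order(g)
  if (is.null(ord)) stop("graph is cyclic")
  leaves <- graph_leaves(g)
  desc <- vector("list", length(ord))
  names(desc) <- ord
  for (v in rev(ord)) {
    if (v %in% leaves) {
      desc[[v]] <- v
    } else {
      ch <- g$child[g$parent == v]
      desc[[v]] <- sort(unique(unlist(desc[ch], use.names = FALSE)))
    }
  }
  desc
}

## all descendants (nodes, not only leaves) of node v, excluding v
node_descendants <- function(g, v) {
  seen <- character(0)
  frontier <- g$child[g$parent == v]
  while (length(frontier)) {
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    frontier <- g$child[g$parent %in% new]
  }
  seen
}

#' Check the structural validity of an admixture graph
#'
#' Verifies every state-space invariant: a unique root with two children,
#' correct degree structure (divergence nodes 1 parent/2 children, admixture
#' nodes 2 parents/1 child), no eyes (the two parents of an admixture node
#' and the two children of a divergence node must be distinct), acyclicity,
#' strictly positive branch lengths, admixture proportions in (0,1) with a
#' `main`/`admix` edge pair summing to 1, branch count D = 2L - 2 + 3K, and
#' at least two leaves.
#'
#' @param g an `admixture_graph`.
#' @return Character vector of violations; empty when the graph is valid.
#'   Violations are data, not errors.
#' @export
validate_graph <- function(g) {
  bad <- character(0)
  child <- g$child; parent <- g$parent
  if (!length(child)) return("empty edge set")
  nodes <- unique(c(child, parent))
  roots <- setdiff(parent, child)
  if (length(roots) == 0L) bad <- c(bad, "no root (cyclic)")
  if (length(roots) > 1L)
    bad <- c(bad, paste0("multiple roots: ", paste(roots, collapse = ",")))
  if (g$outgroup %in% nodes)
    bad <- c(bad, "outgroup label used as a graph node")
  leaves <- setdiff(child, parent)
  if (length(leaves) < 2L)
    bad <- c(bad, "fewer than 2 leaves")
  ord <- topo_order(g)
  if (is.null(ord)) bad <- c(bad, "cycle detected")

  npar <- vapply(nodes, function(v) sum(child == v), 1L)
  nchl <- vapply(nodes, function(v) sum(parent == v), 1L)
  K <- 0L
  for (i in seq_along(nodes)) {
    v <- nodes[i]
    if (length(roots) && v == roots[1L]) {
      if (nchl[i] != 2L)
        bad <- c(bad, paste0("root ", v, " has ", nchl[i], " children"))
      ch <- child[parent == v]
      if (length(ch) == 2L && ch[1L] == ch[2L])
        bad <- c(bad, paste0("eye: duplicated children of root ", v))
      next
    }
    if (npar[i] == 1L && nchl[i] == 0L) next  # leaf
    if (npar[i] == 1L && nchl[i] == 2L) {     # divergence
      ch <- child[parent == v]
      if (ch[1L] == ch[2L])
        bad <- c(bad, paste0("eye: duplicated children of divergence node ", v))
      next
    }
    if (npar[i] == 2L && nchl[i] == 1L) {     # admixture
      K <- K + 1L
      pa <- parent[child == v]
      ty <- sort(g$type[child == v])
      pr <- g$prop[child == v]
      if (pa[1L] == pa[2L])
        bad <- c(bad, paste0("eye: duplicated parents of admixture node ", v))
      if (!identical(ty, c("admix", "main")))
        bad <- c(bad, paste0("admixture node ", v,
                             " lacks one main and one admix parent edge"))
      if (anyNA(pr) || any(pr <= 0) || any(pr >= 1) ||
          abs(sum(pr) - 1) > 1e-9)
        bad <- c(bad, paste0("admixture node ", v,
                             " proportions not in (0,1) summing to 1"))
      next
    }
    bad <- c(bad, paste0("node ", v, " has ", npar[i], " parents and ",
                         nchl[i], " children"))
  }
  norm_idx <- !(g$type %in% c("main", "admix"))
  if (any(!is.na(g$prop[norm_idx])))
    bad <- c(bad, "ancestry proportion on a non-admixture edge")
  if (any(!(g$type %in% c("normal", "main", "admix"))))
    bad <- c(bad, "unknown edge type")
  if (any(!is.finite(g$length)) || any(g$length <= 0))
    bad <- c(bad, "non-positive or non-finite branch length")
  if (!is.finite(g$outgroup_length) || g$outgroup_length <= 0)
    bad <- c(bad, "non-positive outgroup branch length")
  L <- length(leaves)
  D <- length(child)
  if (L >= 2L && length(roots) == 1L && D != 2L * L - 2L + 3L * K)
    bad <- c(bad, sprintf("branch count %d != 2L-2+3K = %d", D,
                          2L * L - 2L + 3L * K))
  if (!is.null(ord) && length(roots) == 1L) {
    reach <- c(roots[1L], node_descendants(g, roots[1L]))
    if (!all(leaves %in% reach))
      bad <- c(bad, "not all leaves reachable from root")
  }
  bad
}

## edge weight used in ancestry flow: admix edges carry their proportion,
## everything else carries 1
edge_weights <- function(g) ifelse(is.na(g$prop), 1, g$prop)

## fast boolean validity check (same invariants as validate_graph, minus
## the diagnostic messages); used inside proposal hot paths
graph_is_valid <- function(g) {
  child <- g$child; parent <- g$parent
  ne <- length(child)
  if (!ne) return(FALSE)
  nodes <- unique.default(c(child, parent))
  nn <- length(nodes)
  ci <- match(child, nodes); pi_ <- match(parent, nodes)
  npar <- tabulate(ci, nn); nchl <- tabulate(pi_, nn)
  root <- which(npar == 0L)
  if (length(root) != 1L || nchl[root] != 2L) return(FALSE)
  leaf <- npar == 1L & nchl == 0L
  div <- npar == 1L & nchl == 2L
  adm <- npar == 2L & nchl == 1L
  ok <- leaf | div | adm
  ok[root] <- TRUE
  if (!all(ok)) return(FALSE)
  L <- sum(leaf); K <- sum(adm)
  if (L < 2L) return(FALSE)
  if (ne != 2L * L - 2L + 3L * K) return(FALSE)
  ## parallel edges are exactly the eyes
  if (anyDuplicated(pi_ * (nn + 1L) + ci)) return(FALSE)
  if (any(g$length <= 0) || g$outgroup_length <= 0) return(FALSE)
  ## typed parent-edge pairs on admixture nodes
  for (v in which(adm)) {
    e2 <- which(ci == v)
    ty <- g$type[e2]; pr <- g$prop[e2]
    if (!(("main" %in% ty) && ("admix" %in% ty))) return(FALSE)
    if (anyNA(pr) || any(pr <= 0) || any(pr >= 1) ||
        abs(pr[1L] + pr[2L] - 1) > 1e-9) return(FALSE)
  }
  if (any(!is.na(g$prop) & !(g$type %in% c("main", "admix"))))
    return(FALSE)
  ## acyclicity (Kahn); with one root and valid degrees this also implies
  ## every node is reachable from the root
  indeg <- npar
  queue <- root; head <- 1L; done <- 0L
  while (head <= length(queue)) {
    v <- queue[head]; head <- head + 1L; done <- done + 1L
    for (e2 in which(pi_ == v)) {
      w <- ci[e2]
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  done == nn
}

#' Draw a random admixture-free tree
#'
#' Builds a rooted binary tree over the given leaves by sequential random
#' attachment (uniform over labeled topologies), with branch lengths drawn
#' i.i.d. exponential with the given mean. Used to initialize MCMC chains
#' and in property tests.
#'
#' @param leaves character vector of at least two leaf labels.
#' @param outgroup outgroup label.
#' @param mean_length mean of the exponential branch-length draw.
#' @return A valid `admixture_graph` with K = 0.
#' @export
random_tree <- function(leaves, outgroup = "out", mean_length = 1) {
  stopifnot(length(leaves) >= 2L)
  leaves <- sample(leaves)
  nid <- 0L
  newnode <- function() { nid <<- nid + 1L; paste0("n", nid) }
  ## grow by attaching each next leaf to a uniformly chosen existing edge
  ## (or above the current root), which is uniform over labeled topologies
  child <- c(leaves[1L], leaves[2L])
  root <- newnode()
  parent <- c(root, root)
  for (lf in leaves[-(1:2)]) {
    k <- sample.int(length(child) + 1L, 1L)
    nn <- newnode()
    if (k > length(child)) {       # attach above the root
      child <- c(child, root, lf)
      parent <- c(parent, nn, nn)
      root <- nn
    } else {                       # split edge k
      child <- c(child, child[k], lf)
      parent <- c(parent, nn, nn)
      child[k] <- nn
    }
  }
  n_edge <- length(child)
  admixture_graph(
    data.frame(child = child, parent = parent,
               length = stats::rexp(n_edge, rate = 1 / mean_length)),
    outgroup = outgroup,
    outgroup_length = stats::rexp(1, rate = 1 / mean_length))
}
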