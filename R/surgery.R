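## Structural surgery on admixture graphs: adding and removing admixture
## branches. Shared by the brute-force topology enumerator and the
## reversible-jump MCMC proposals, so that the two agree on what the
## discrete neighborhood of a graph is.

## n fresh internal node names not colliding with existing ones
fresh_names <- function(g, n) {
  existing <- c(graph_nodes(g), g$outgroup)
  out <- character(0)
  i <- 0L
  while (length(out) < n) {
    i <- i + 1L
    cand <- paste0("x", i)
    if (!(cand %in% existing)) out <- c(out, cand)
  }
  out
}

## edge indices that may serve as the source of a new admixture branch for
## the given sink edge: any edge other than the sink whose parent endpoint
## is not the sink's child or one of its descendants (which would create a
## cycle). The root/outgroup branch is always an additional valid source,
## appended as the string "root".
valid_admixture_sources <- function(g, sink) {
  c_sink <- g$child[sink]
  below <- c(c_sink, node_descendants(g, c_sink))
  idx <- setdiff(which(!(g$parent %in% below)), sink)
  c(as.list(idx), list("root"))
}

## Add an admixture branch. sink is an edge index; source an edge index or
## "root". u_sink/u_source are attachment distances measured from the child
## endpoint of the respective edge (u_source is the distance above the old
## root when source == "root"). s_len is the new branch's length, w the
## proportion carried by the "admix"-labeled parent edge, admix_on_new
## whether the new branch d->m is the "admix" edge.
graph_add_admixture <- function(g, sink, source, u_sink, u_source, s_len,
                                w, admix_on_new) {
  nm <- fresh_names(g, 2L)
  m <- nm[1L]; d <- nm[2L]
  child <- g$child; parent <- g$parent; len <- g$length
  type <- g$type; prop <- g$prop

  ## split the sink edge p -> c into p -> m -> c
  p <- parent[sink]; cc <- child[sink]; lc <- len[sink]
  ty <- type[sink]; pr <- prop[sink]
  stopifnot(u_sink > 0, u_sink < lc)
  new_type <- if (admix_on_new) "admix" else "main"
  old_type <- if (admix_on_new) "main" else "admix"
  new_prop <- if (admix_on_new) w else 1 - w
  old_prop <- if (admix_on_new) 1 - w else w
  ## upper part p -> m becomes one of m's typed parent edges
  child[sink] <- m; len[sink] <- lc - u_sink
  type[sink] <- old_type; prop[sink] <- old_prop
  child <- c(child, cc); parent <- c(parent, m); len <- c(len, u_sink)
  type <- c(type, ty); prop <- c(prop, pr)

  if (identical(source, "root")) {
    root <- setdiff(parent, child)   # old root (d not yet wired above it)
    stopifnot(length(root) == 1L, u_source > 0)
    child <- c(child, root); parent <- c(parent, d)
    len <- c(len, u_source); type <- c(type, "normal"); prop <- c(prop, NA)
  } else {
    p2 <- parent[source]; c2 <- child[source]; l2 <- len[source]
    ty2 <- type[source]; pr2 <- prop[source]
    stopifnot(u_source > 0, u_source < l2)
    child[source] <- d; len[source] <- l2 - u_source
    type[source] <- "normal"; prop[source] <- NA
    child <- c(child, c2); parent <- c(parent, d); len <- c(len, u_source)
    type <- c(type, ty2); prop <- c(prop, pr2)
  }
  ## the admixture branch itself
  child <- c(child, m); parent <- c(parent, d); len <- c(len, s_len)
  type <- c(type, new_type); prop <- c(prop, new_prop)

  new_graph(child, parent, len, type, prop, g$outgroup, g$outgroup_length)
}

## splice out a degree-2 node v (one parent edge, one child edge): the two
## edges merge with summed length and the child-side type/proportion
splice_node <- function(child, parent, len, type, prop, v) {
  up <- which(child == v)
  dn <- which(parent == v)
  stopifnot(length(up) == 1L, length(dn) == 1L)
  child[up] <- child[dn]
  len[up] <- len[up] + len[dn]
  type[up] <- type[dn]
  prop[up] <- prop[dn]
  list(child = child[-dn], parent = parent[-dn], len = len[-dn],
       type = type[-dn], prop = prop[-dn])
}

## Remove the admixture branch with edge index e (child must be an
## admixture node whose parent is not an admixture node). Returns the new
## graph plus the bookkeeping needed to evaluate the density of the add
## move that would undo the removal, or NULL if the removal leaves an
## invalid graph (ineligible branch).
graph_remove_admixture <- function(g, e) {
  m <- g$child[e]; u <- g$parent[e]
  child <- g$child; parent <- g$parent; len <- g$length
  type <- g$type; prop <- g$prop
  other_par <- setdiff(which(child == m), e)
  stopifnot(length(other_par) == 1L)
  w_admix <- if (type[e] == "admix") prop[e] else prop[other_par]
  admix_on_new <- type[e] == "admix"
  s_len <- len[e]

  ## drop the admixture branch, then splice m
  st <- list(child = child[-e], parent = parent[-e], len = len[-e],
             type = type[-e], prop = prop[-e])
  dn_m <- which(st$parent == m)               # m's child edge (for u_sink)
  u_sink <- st$len[dn_m]
  sink_child <- st$child[dn_m]
  st$type[which(st$child == m)] <- "normal"   # m no longer an admixture node
  st$prop[which(st$child == m)] <- NA
  st <- splice_node(st$child, st$parent, st$len, st$type, st$prop, m)

  root <- setdiff(g$parent, g$child)
  u_parent <- g$parent[g$child == u]   # empty when u is the root
  if (u == root) {
    ## u was the root; its other child becomes the new root and the stub
    ## branch above it is discarded (it is the Exp-distributed attachment
    ## distance of the reverse root-source add)
    dn_u <- which(st$parent == u)
    stopifnot(length(dn_u) == 1L)
    u_source <- st$len[dn_u]
    source_child <- NULL
    st <- list(child = st$child[-dn_u], parent = st$parent[-dn_u],
               len = st$len[-dn_u], type = st$type[-dn_u],
               prop = st$prop[-dn_u])
    source_is_root <- TRUE
  } else {
    dn_u <- which(st$parent == u)
    stopifnot(length(dn_u) == 1L)
    u_source <- st$len[dn_u]
    source_child <- st$child[dn_u]
    st <- splice_node(st$child, st$parent, st$len, st$type, st$prop, u)
    source_is_root <- FALSE
  }
  g2 <- new_graph(st$child, st$parent, st$len, st$type, st$prop,
                  g$outgroup, g$outgroup_length)
  if (!graph_is_valid(g2)) return(NULL)
  ## locate the merged sink/source branches in the new graph by their
  ## (child, parent) endpoints; both endpoints survive the splices (only m
  ## and u are removed, and neither can be an endpoint of the merged edges
  ## in a valid removal)
  p_sink <- g$parent[setdiff(which(g$child == m), e)]
  sink <- which(g2$child == sink_child & g2$parent == p_sink)
  if (length(sink) != 1L) return(NULL)
  if (source_is_root) {
    source <- "root"
  } else {
    source <- which(g2$child == source_child & g2$parent == u_parent)
    if (length(source) != 1L) return(NULL)
  }
  list(graph = g2, sink = sink, source = source, u_sink = u_sink,
       u_source = u_source, s_len = s_len, w = w_admix,
       admix_on_new = admix_on_new)
}

## indices of admixture branches eligible for removal: edges into an
## admixture node whose parent endpoint is not itself an admixture node
## and whose removal yields a valid graph. Removing such a branch from a
## valid graph preserves degrees and acyclicity automatically, so the
## only possible violation is an eye: one of the merged edges duplicating
## an existing (parent, child) pair (or the two merged edges coinciding).
removable_admixture_edges <- function(g) {
  child <- g$child; parent <- g$parent
  tab <- table(child)
  admix_nodes <- names(tab)[tab == 2L]
  if (!length(admix_nodes)) return(integer(0))
  cand <- which(child %in% admix_nodes & !(parent %in% admix_nodes))
  root <- setdiff(parent, child)
  ok <- vapply(cand, function(e) {
    m <- child[e]; u <- parent[e]
    p <- parent[child == m & seq_along(child) != e]
    cc <- child[parent == m]
    dn_u <- which(parent == u & seq_along(child) != e)
    drop <- c(e, which(child == m), which(parent == m), dn_u,
              which(child == u))
    rest <- paste(parent[-drop], child[-drop])
    merged <- paste(p, cc)                      # spliced sink edge
    if (u != root) {
      pu <- parent[child == u]
      merged <- c(merged, paste(pu, child[dn_u]))  # spliced source edge
    }
    !anyDuplicated(c(rest, merged))
  }, NA)
  cand[ok]
}
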