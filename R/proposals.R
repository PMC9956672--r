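## The seven MCMC proposals over admixture graphs, each returning the
## proposed graph together with the log forward and backward proposal
## densities (reversible-jump Jacobian factors are 1 throughout). A NULL
## return means the move is unavailable or immediately rejected; the
## calling kernel counts it as a rejection of that proposal type.

#' Propose adding an admixture branch
#'
#' A sink branch is chosen uniformly among the D internal branches and a
#' source uniformly among the cycle-safe remaining branches plus the
#' root/outgroup branch. Attachment points are uniform on each branch
#' (exponential above the root), the new branch length is Exp(1), the
#' proportion uniform, and the main/admix labeling of the new admixture
#' node's parent edges is a fair coin. The backward density is the uniform
#' removal choice among the new graph's removable admixture branches.
#'
#' @param g a valid `admixture_graph`.
#' @param K_max admixture-event cap.
#' @return List `(graph, log_fwd, log_bwd)`, or NULL when at the cap.
#' @keywords internal
propose_add_admixture <- function(g, K_max = 20L) {
  if (n_admixture(g) >= K_max) return(NULL)
  D <- length(g$child)
  sink <- sample.int(D, 1L)
  sources <- valid_admixture_sources(g, sink)
  Dp <- length(sources)
  src <- sources[[sample.int(Dp, 1L)]]
  len_sink <- g$length[sink]
  u_sink <- stats::runif(1, 0, len_sink)
  if (identical(src, "root")) {
    u_source <- stats::rexp(1)
    log_src <- -u_source            # Exp(1) attachment above the root
  } else {
    len_src <- g$length[src]
    u_source <- stats::runif(1, 0, len_src)
    log_src <- -log(len_src)
  }
  s_len <- stats::rexp(1)
  w <- stats::runif(1)
  admix_on_new <- stats::runif(1) < 0.5
  g2 <- graph_add_admixture(g, sink, src, u_sink, u_source, s_len, w,
                            admix_on_new)
  log_fwd <- -log(D) - log(Dp) - log(len_sink) + log_src - s_len - log(2)
  K2 <- length(removable_admixture_edges(g2))
  if (K2 == 0L) return(NULL)        # must be reversible
  list(graph = g2, log_fwd = log_fwd, log_bwd = -log(K2))
}

#' Propose removing an admixture branch
#'
#' Chooses uniformly among the admixture branches whose removal leaves a
#' valid graph (parent not an admixture node, no eye created). The
#' backward density is the full add-admixture density of re-inserting the
#' removed branch.
#'
#' @param g a valid `admixture_graph`.
#' @return List `(graph, log_fwd, log_bwd)`, or NULL when no branch is
#'   removable.
#' @keywords internal
propose_remove_admixture <- function(g) {
  rem <- removable_admixture_edges(g)
  if (!length(rem)) return(NULL)
  e <- rem[sample.int(length(rem), 1L)]
  res <- graph_remove_admixture(g, e)
  # eligibility and the full removal must agree, or K' would be
  # inconsistent between the forward and backward densities
  if (is.null(res)) stop("internal error: eligible removal failed")
  g2 <- res$graph
  D2 <- length(g2$child)
  sources2 <- valid_admixture_sources(g2, res$sink)
  Dp2 <- length(sources2)
  log_src <- if (identical(res$source, "root")) -res$u_source
             else -log(g2$length[res$source])
  log_bwd <- -log(D2) - log(Dp2) - log(g2$length[res$sink]) + log_src -
    res$s_len - log(2)
  list(graph = g2, log_fwd = -log(length(rem)), log_bwd = log_bwd)
}

## --- node sliding ---------------------------------------------------------

## spliced skeleton: the graph with sliding node u removed (through-edges
## merged) and the slid branch u->x dropped. Returns edge vectors plus the
## start position of u on the merged edge (distance from the parent end).
slide_skeleton <- function(g, e) {
  u <- g$parent[e]
  up <- which(g$child == u)
  dn <- setdiff(which(g$parent == u), e)
  stopifnot(length(up) == 1L, length(dn) == 1L)
  child <- g$child; parent <- g$parent; len <- g$length
  type <- g$type; prop <- g$prop
  ## merged through edge keeps index `up` (child side wins typing)
  child[up] <- child[dn]
  start_t <- len[up]                 # u sat this far below the parent end
  len[up] <- len[up] + len[dn]
  type[up] <- type[dn]; prop[up] <- prop[dn]
  drop <- c(dn, e)
  remap <- up - sum(drop < up)
  list(child = child[-drop], parent = parent[-drop], len = len[-drop],
       type = type[-drop], prop = prop[-drop],
       start_edge = remap, start_t = start_t)
}

## all walk endpoints at exactly distance delta from position (edge,
## offset-from-parent-end), walking both ways with non-backtracking
## branching at junctions; endpoints are (edge, t) pairs. Paths that run
## out of graph (leaf tips, above the root) die. max_out caps pathological
## blow-ups.
slide_destinations <- function(sk, edge, t0, delta, max_work = 1024L) {
  nodes <- unique.default(c(sk$child, sk$parent))
  ci <- match(sk$child, nodes)
  pi_ <- match(sk$parent, nodes)
  ne <- length(ci)
  inc <- vector("list", length(nodes))
  for (e in seq_len(ne)) {
    inc[[ci[e]]] <- c(inc[[ci[e]]], e)
    inc[[pi_[e]]] <- c(inc[[pi_[e]]], e)
  }
  ## preallocated frontier queue of active path segments; direction +1
  ## walks toward the child end
  cap <- 2L * max_work + 8L
  q_edge <- integer(cap); q_pos <- numeric(cap)
  q_dir <- integer(cap); q_rem <- numeric(cap)
  q_edge[1:2] <- edge; q_pos[1:2] <- t0
  q_dir[1:2] <- c(1L, -1L); q_rem[1:2] <- delta
  head <- 1L; tail <- 2L
  out_edge <- integer(0); out_t <- numeric(0)
  work <- 0L
  while (head <= tail) {
    work <- work + 1L
    if (work > max_work) return(NULL)   # pathological walk: reject move
    e1 <- q_edge[head]; pos <- q_pos[head]
    dirn <- q_dir[head]; rem <- q_rem[head]
    head <- head + 1L
    room <- if (dirn > 0L) sk$len[e1] - pos else pos
    if (rem <= room) {
      out_edge <- c(out_edge, e1); out_t <- c(out_t, pos + dirn * rem)
      next
    }
    node <- if (dirn > 0L) ci[e1] else pi_[e1]
    for (e2 in inc[[node]]) {
      if (e2 == e1) next
      down <- pi_[e2] == node
      tail <- tail + 1L
      if (tail > cap) return(NULL)
      q_edge[tail] <- e2
      q_pos[tail] <- if (down) 0 else sk$len[e2]
      q_dir[tail] <- if (down) 1L else -1L
      q_rem[tail] <- rem - room
    }
  }
  list(edge = out_edge, t = out_t)
}

## edges of the spliced skeleton lying inside the subtree of node x
## (attaching there would create a cycle), plus any edge whose child is x
## itself (attaching there would create an eye on x's parents)
forbidden_slide_edges <- function(sk, x) {
  gsk <- new_graph(sk$child, sk$parent, sk$len, sk$type, sk$prop, "·", 1)
  below <- c(x, node_descendants(gsk, x))
  which(sk$parent %in% below | sk$child == x)
}

#' Propose sliding a node
#'
#' A branch whose parent is a divergence node is chosen uniformly; its
#' attachment point moves a distance lambda * x, x ~ chi-squared(1), along
#' the graph, choosing uniformly among the destinations reachable at that
#' distance (branching at junctions; walks that leave the graph die, and
#' if no destination survives the move is rejected). Destinations inside
#' the slid subtree would create a cycle and are rejected if drawn. The
#' forward and backward densities are chi2(delta/lambda)/(lambda * omega)
#' with omega counted from the old and new positions on the common spliced
#' skeleton.
#'
#' @param g a valid `admixture_graph`.
#' @param lambda slide scale (adapted by the kernel).
#' @return List `(graph, log_fwd, log_bwd)`, or NULL.
#' @keywords internal
propose_node_slide <- function(g, lambda = 0.1) {
  nodes <- unique.default(c(g$child, g$parent))
  npar <- tabulate(match(g$child, nodes), length(nodes))
  pidx <- match(g$parent, nodes)
  ## slidable: parent is a divergence node (has a parent itself, i.e. not
  ## the root; exactly one parent, i.e. not an admixture node)
  slidable <- which(npar[pidx] == 1L)
  if (!length(slidable)) return(NULL)
  e <- slidable[sample.int(length(slidable), 1L)]
  x <- g$child[e]
  delta <- lambda * stats::rchisq(1, df = 1)
  sk <- slide_skeleton(g, e)
  dest <- slide_destinations(sk, sk$start_edge, sk$start_t, delta)
  if (is.null(dest) || !length(dest$edge)) return(NULL)
  omega <- length(dest$edge)
  pick <- sample.int(omega, 1L)
  e_star <- dest$edge[pick]; t_star <- dest$t[pick]
  if (e_star %in% forbidden_slide_edges(sk, x)) return(NULL)
  if (t_star <= 0 || t_star >= sk$len[e_star]) return(NULL)
  ## rebuild: split e_star and re-attach u above x
  u <- g$parent[e]
  child <- sk$child; parent <- sk$parent; len <- sk$len
  type <- sk$type; prop <- sk$prop
  c_star <- child[e_star]
  child[e_star] <- u
  lower <- len[e_star] - t_star
  len[e_star] <- t_star
  ty <- type[e_star]; pr <- prop[e_star]
  type[e_star] <- "normal"; prop[e_star] <- NA
  child <- c(child, c_star, x)
  parent <- c(parent, u, u)
  len <- c(len, lower, g$length[e])
  type <- c(type, ty, g$type[e])
  prop <- c(prop, pr, g$prop[e])
  g2 <- new_graph(child, parent, len, type, prop, g$outgroup,
                  g$outgroup_length)
  ## splicing u can merge an admixture node's parent edges into an eye, and
  ## other rare degeneracies exist; any invalid rebuild is a rejection
  if (!graph_is_valid(g2)) return(NULL)
  back <- slide_destinations(sk, e_star, t_star, delta)
  if (is.null(back) || !length(back$edge)) return(NULL)
  list(graph = g2,
       log_fwd = stats::dchisq(delta / lambda, 1, log = TRUE) -
         log(lambda) - log(omega),
       log_bwd = stats::dchisq(delta / lambda, 1, log = TRUE) -
         log(lambda) - log(length(back$edge)))
}

#' Reflecting random walks and proportion resampling
#'
#' `propose_branch_rw()` adds independent Gaussian noise of scale `s` to
#' every internal branch length, reflecting at zero (absolute value), a
#' symmetric proposal. `propose_outgroup_rw()` does the same to the
#' outgroup branch only. `propose_resample_w()` redraws every admixture
#' proportion independently from U(0,1) (an independence sampler with
#' constant density; a no-op on admixture-free graphs).
#' `propose_nullspace_rw()` takes a Gaussian step of scale `s` inside the
#' null space of the linear map from branch lengths to the graph
#' covariance, so the likelihood is unchanged; steps making any length
#' non-positive are rejected.
#'
#' @param g a valid `admixture_graph`.
#' @param s step scale.
#' @return List `(graph, log_fwd, log_bwd)`, or NULL.
#' @keywords internal
propose_branch_rw <- function(g, s = 0.1) {
  lens <- abs(g$length + stats::rnorm(length(g$length), 0, s))
  if (any(lens == 0)) return(NULL)
  g2 <- new_graph(g$child, g$parent, lens, g$type, g$prop, g$outgroup,
                  g$outgroup_length)
  list(graph = g2, log_fwd = 0, log_bwd = 0)
}

#' @rdname propose_branch_rw
#' @keywords internal
propose_outgroup_rw <- function(g, s = 0.1) {
  c0 <- abs(g$outgroup_length + stats::rnorm(1, 0, s))
  if (c0 == 0) return(NULL)
  g2 <- new_graph(g$child, g$parent, g$length, g$type, g$prop, g$outgroup,
                  c0)
  list(graph = g2, log_fwd = 0, log_bwd = 0)
}

#' @rdname propose_branch_rw
#' @keywords internal
propose_resample_w <- function(g) {
  type <- g$type; prop <- g$prop
  adm <- which(type == "admix")
  if (length(adm)) {
    for (e in adm) {
      w <- stats::runif(1)
      prop[e] <- w
      mate <- which(g$child == g$child[e] & type == "main")
      prop[mate] <- 1 - w
    }
  }
  g2 <- new_graph(g$child, g$parent, g$length, type, prop, g$outgroup,
                  g$outgroup_length)
  list(graph = g2, log_fwd = 0, log_bwd = 0)
}

#' @rdname propose_branch_rw
#' @keywords internal
propose_nullspace_rw <- function(g, s = 0.1) {
  A <- design_matrix(g)
  n <- nrow(A); nb <- ncol(A)
  ## rows of the covariance map c -> vech(A diag(c) A')
  idx <- which(upper.tri(diag(n), diag = TRUE), arr.ind = TRUE)
  M <- A[idx[, 1L], , drop = FALSE] * A[idx[, 2L], , drop = FALSE]
  sv <- svd(M, nu = 0, nv = nb)
  tol <- max(dim(M)) * max(sv$d) * .Machine$double.eps
  null_dim <- nb - sum(sv$d > tol)
  if (null_dim == 0L) {
    return(list(graph = g, log_fwd = 0, log_bwd = 0, no_op = TRUE))
  }
  Nb <- sv$v[, (nb - null_dim + 1L):nb, drop = FALSE]
  dc <- as.numeric(Nb %*% stats::rnorm(null_dim, 0, s))
  lens <- c(g$outgroup_length, g$length) + dc
  if (any(lens <= 0)) return(NULL)
  g2 <- new_graph(g$child, g$parent, lens[-1L], g$type, g$prop,
                  g$outgroup, lens[1L])
  list(graph = g2, log_fwd = 0, log_bwd = 0, likelihood_invariant = TRUE)
}
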