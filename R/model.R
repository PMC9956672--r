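## Graph-implied covariance and the Wishart likelihood, plus the full
## prior: geometric on the number of admixture events, uniform over labeled
## topologies via the counting recurrence, exponential branch lengths with
## topology-adaptive mean, uniform admixture proportions.

#' Design matrix of an admixture graph
#'
#' One row per non-outgroup leaf and one column per branch (the outgroup
#' branch first, named `x0`). The entry for leaf l and branch b is the
#' total ancestry flow from the root into l that passes through b: the sum
#' over root-to-leaf paths through b of the product of admixture
#' proportions chosen along the path. For a tree this is the 0/1 indicator
#' of the root-to-leaf path; the `x0` column is always 1.
#'
#' @param g a valid `admixture_graph`.
#' @return Matrix with rownames the leaves (sorted) and one column per
#'   branch; attribute `lengths` holds the matching branch-length vector
#'   (outgroup branch first).
#' @export
design_matrix <- function(g) {
  leaves <- sort(graph_leaves(g))
  nodes <- graph_nodes(g)
  nn <- length(nodes); ne <- length(g$child); nl <- length(leaves)
  ci <- match(g$child, nodes); pi_ <- match(g$parent, nodes)
  ord <- topo_order_idx(ci, pi_, nn)
  if (is.null(ord)) stop("invalid graph: cycle")
  wts <- ifelse(is.na(g$prop), 1, g$prop)
  ## F[v]: total weighted flow from the root into node v
  F <- numeric(nn)
  F[ord[1L]] <- 1
  for (e_ord in order(match(ci, ord)))
    F[ci[e_ord]] <- F[ci[e_ord]] + wts[e_ord] * F[pi_[e_ord]]
  ## G[v, l]: weighted measure of paths from v down to leaf l
  G <- matrix(0, nn, nl)
  li <- match(leaves, nodes)
  G[cbind(li, seq_len(nl))] <- 1
  for (e_ord in order(match(pi_, ord), decreasing = TRUE)) {
    G[pi_[e_ord], ] <- G[pi_[e_ord], ] + wts[e_ord] * G[ci[e_ord], ]
  }
  A <- matrix(0, nl, ne + 1L,
              dimnames = list(leaves, c("x0", paste0("x", seq_len(ne)))))
  A[, 1L] <- 1
  A[, -1L] <- t(G[ci, , drop = FALSE]) *
    rep(F[pi_] * wts, each = nl)
  attr(A, "lengths") <- c(g$outgroup_length, g$length)
  A
}

## topological order on integer-indexed edges; NULL if cyclic
topo_order_idx <- function(ci, pi_, nn) {
  indeg <- tabulate(ci, nn)
  queue <- which(indeg == 0L)
  head <- 1L
  while (head <= length(queue)) {
    v <- queue[head]; head <- head + 1L
    for (e in which(pi_ == v)) {
      w <- ci[e]
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(queue) != nn) return(NULL)
  queue
}

#' Graph-implied covariance matrix
#'
#' Sigma = A diag(c) A' where A is the [design_matrix()] and c the branch
#' lengths (outgroup branch included). Under the Gaussian drift model the
#' outgroup-centered leaf frequencies have covariance p(1-p) Sigma.
#'
#' @param g a valid `admixture_graph`.
#' @return Symmetric positive semi-definite matrix over the sorted leaves;
#'   every entry contains at least the outgroup branch length.
#' @export
graph_covariance <- function(g) {
  A <- design_matrix(g)
  cl <- attr(A, "lengths")
  Sg <- A %*% (cl * t(A))
  (Sg + t(Sg)) / 2
}

## log density of the mean-parameterized Wishart W(mean = M, df) at X:
## scale V = M/df, density per the standard Wishart formula; -Inf when the
## mean is not positive definite (rejected state, not an error)
dwishart_mean_log <- function(X, M, df) {
  n <- nrow(X)
  if (df <= n - 1) return(-Inf)
  V <- M / df
  cV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cV)) return(-Inf)
  cX <- tryCatch(chol(X), error = function(e) NULL)
  if (is.null(cX)) return(-Inf)
  ldX <- 2 * sum(log(diag(cX)))
  ldV <- 2 * sum(log(diag(cV)))
  tr <- sum(chol2inv(cV) * X)   # tr(V^-1 X); both symmetric
  lmg <- (n * (n - 1) / 4) * log(pi) +
    sum(lgamma((df + 1 - seq_len(n)) / 2))
  (df - n - 1) / 2 * ldX - tr / 2 - df * n / 2 * log(2) -
    df / 2 * ldV - lmg
}

#' Wishart log likelihood of a graph covariance
#'
#' Log density of the mean-parameterized Wishart with degrees of freedom
#' `df`, evaluated at the rescaled data covariance c_S S/h with mean
#' Sigma + c_S B/h. The robustness scale c_S puts the data trace at the
#' magnitude the branch-length prior expects (L log2 L + L), so the
#' sampled graph's branch lengths live on that calibrated scale; a graph
#' expressed in raw drift units corresponds to c_S times its covariance.
#' Scaling the data without rescaling the sampled covariance is what
#' makes the correction effective — applying c_S to both sides would
#' cancel out of the density's shape entirely. Non-positive-definite
#' means yield -Inf (a rejected state), not an error.
#'
#' @param cov a `covariance_estimate` (from [covariance_estimate()]).
#' @param Sigma graph covariance matrix over the same populations, in the
#'   order of `cov$S`'s rows, on the c_S-rescaled scale.
#' @return Log likelihood (scalar, possibly -Inf).
#' @export
wishart_loglik <- function(cov, Sigma) {
  n <- nrow(cov$S)
  stopifnot(all(dim(Sigma) == c(n, n)))
  X <- cov$c_S * cov$S / cov$h
  M <- Sigma + cov$c_S * cov$B / cov$h
  dwishart_mean_log(X, M, cov$df)
}

#' Prior configuration
#'
#' Bundles the constants of the graph prior: the geometric parameter for
#' the number of admixture events, its truncation point, and the branch
#' length prior family (exponential with mean (2L-2)/D, D = 2L-2+3K).
#'
#' @param q geometric success parameter (default 0.5).
#' @param K_max truncation of the admixture-event count (default 20).
#' @return A `prior_config` list.
#' @export
prior_config <- function(q = 0.5, K_max = 20L) {
  stopifnot(q > 0, q < 1, K_max >= 0L)
  structure(list(q = q, K_max = as.integer(K_max),
                 lognorm = log(sum(q * (1 - q)^(0:K_max))),
                 branch_prior = "exponential, mean (2L-2)/D"),
            class = "prior_config")
}

#' Log prior of the admixture-event count
#'
#' Geometric with parameter q, truncated at `K_max` and renormalized:
#' P(K) proportional to q (1-q)^K for K = 0..K_max (q = 0.5 by default, so
#' successive counts halve in probability); -Inf above the truncation.
#'
#' @param K number of admixture events (>= 0).
#' @param config a [prior_config()].
#' @return Log probability.
#' @export
log_prior_K <- function(K, config = prior_config()) {
  if (K < 0) return(-Inf)
  if (K > config$K_max) return(-Inf)
  log(config$q) + K * log(1 - config$q) - config$lognorm
}

#' Log prior of a labeled topology given its admixture-event count
#'
#' Uniform over all labeled topologies with L leaves and K admixture
#' events: -log of the total count from the recurrence. Depends only on
#' (L, K).
#'
#' @param g an `admixture_graph`, or NULL when `L` and `K` are given.
#' @param L,K optional explicit leaf and admixture-event counts.
#' @return Log probability.
#' @export
log_prior_topology <- function(g = NULL, L = NULL, K = NULL) {
  if (!is.null(g)) {
    L <- length(graph_leaves(g))
    K <- n_admixture(g)
  }
  -log(count_topologies_total(L, K))
}

#' Log prior density of the continuous parameters
#'
#' All D = 2L-2+3K internal branch lengths, plus the outgroup branch, are
#' i.i.d. exponential with mean (2L-2)/D, so graphs with more admixture
#' events expect shorter branches; admixture proportions are uniform on
#' (0,1) and contribute 0.
#'
#' @param g an `admixture_graph`.
#' @return Log density; -Inf for any non-positive length.
#' @export
log_prior_continuous <- function(g) {
  L <- length(graph_leaves(g))
  K <- n_admixture(g)
  D <- 2L * L - 2L + 3L * K
  lens <- c(g$length, g$outgroup_length)
  if (any(lens <= 0)) return(-Inf)
  rate <- D / (2 * L - 2)
  sum(stats::dexp(lens, rate = rate, log = TRUE))
}

#' Full log prior of an admixture graph
#'
#' Sum of [log_prior_K()], [log_prior_topology()] and
#' [log_prior_continuous()].
#'
#' @param g an `admixture_graph`.
#' @param config a [prior_config()].
#' @return Log density.
#' @export
log_prior_graph <- function(g, config = prior_config()) {
  K <- n_admixture(g)
  log_prior_K(K, config) +
    log_prior_topology(L = length(graph_leaves(g)), K = K) +
    log_prior_continuous(g)
}
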