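## Posterior post-processing: burn-in and thinning, Mode graph,
## descendant-set frequencies, consensus graphs, subgraph posteriors and
## convergence diagnostics.

#' Apply burn-in and equal-spaced thinning to a posterior sample
#'
#' Drops the first `ceiling(fraction * n)` records, then keeps `n_keep`
#' equally spaced records of the remainder (first and last included when
#' `n_keep >= 2`).
#'
#' @param sample a `posterior_sample` from [mc3_run()].
#' @param fraction burn-in fraction in [0, 1); default 0.35.
#' @param n_keep number of records to keep; default 100.
#' @return A `posterior_sample` with the reduced records and stats.
#' @export
apply_burnin_thin <- function(sample, fraction = 0.35, n_keep = 100L) {
  stopifnot(inherits(sample, "posterior_sample"),
            fraction >= 0, fraction < 1, n_keep >= 1L)
  n <- length(sample$records)
  drop <- ceiling(fraction * n)
  if (drop >= n) stop("nothing left after burn-in")
  idx <- (drop + 1L):n
  if (n_keep >= length(idx)) {
    keep <- idx
  } else if (n_keep == 1L) {
    keep <- idx[length(idx)]
  } else {
    keep <- idx[unique(round(seq(1L, length(idx), length.out = n_keep)))]
  }
  sample$records <- sample$records[match(keep, seq_len(n))]
  sample$stats <- sample$stats[keep, , drop = FALSE]
  sample$burnin_applied <- fraction
  sample
}

#' Highest-posterior sampled graph
#'
#' The recorded graph with the highest log posterior; ties are broken by
#' the earliest iteration, deterministically.
#'
#' @param sample a `posterior_sample`.
#' @return An `admixture_graph`.
#' @export
mode_graph <- function(sample) {
  stopifnot(length(sample$records) >= 1L)
  sample$records[[which.max(sample$stats$log_post)]]
}

#' Posterior frequencies of descendant sets
#'
#' For every descendant set t occurring in any sampled graph's topology
#' set, the fraction f(t) of sampled graphs whose topology set contains t.
#'
#' @param sample a `posterior_sample`.
#' @return Named numeric vector (names are comma-joined sorted leaf sets),
#'   sorted by decreasing frequency.
#' @export
node_frequencies <- function(sample) {
  n <- length(sample$records)
  stopifnot(n >= 1L)
  counts <- new.env(parent = emptyenv())
  for (g in sample$records) {
    for (t in topology_set(g)) {
      v <- counts[[t]]
      counts[[t]] <- if (is.null(v)) 1L else v + 1L
    }
  }
  keys <- ls(counts)
  f <- vapply(keys, function(k) counts[[k]], 1L) / n
  sort(f, decreasing = TRUE)
}

#' Consensus graph at threshold alpha
#'
#' The minimal topology built from all descendant sets whose posterior
#' sample frequency strictly exceeds `alpha` (0.75 by default, the
#' conventional display threshold).
#'
#' @param sample a `posterior_sample`.
#' @param alpha frequency threshold in [0, 1).
#' @return A `minimal_topology`; its `frequencies` attribute holds f(t)
#'   for each retained set.
#' @export
consensus_graph <- function(sample, alpha = 0.75) {
  stopifnot(alpha >= 0, alpha < 1)
  f <- node_frequencies(sample)
  leaves <- sort(graph_leaves(sample$records[[1L]]))
  keep <- f[f > alpha]
  mt <- minimal_topology(new_topology_set(names(keep), leaves))
  attr(mt, "frequencies") <- keep
  mt
}

#' Posterior distribution of minimal topologies on a focal subset
#'
#' Each sampled graph is restricted to the focal leaves
#' (via [restrict_to_subgraph()]) and the resulting minimal topologies are
#' tallied. Also reports, per descendant set seen in a restricted
#' topology, its marginal sample frequency.
#'
#' @param sample a `posterior_sample`.
#' @param focal character vector of at least two leaf labels.
#' @return List with `table` (data frame: key, probability, in decreasing
#'   order), `topologies` (named list of `minimal_topology` objects) and
#'   `node_frequencies` (marginal f(t) over the restricted sets).
#' @export
subgraph_posterior <- function(sample, focal) {
  n <- length(sample$records)
  stopifnot(n >= 1L)
  keys <- character(n)
  mts <- list()
  setcount <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    mt <- restrict_to_subgraph(sample$records[[i]], focal)
    k <- minimal_topology_key(mt)
    keys[i] <- k
    if (is.null(mts[[k]])) mts[[k]] <- mt
    inner <- setdiff(mt$nodes, c(focal, set_key(sort(focal))))
    for (t in inner) {
      v <- setcount[[t]]
      setcount[[t]] <- if (is.null(v)) 1L else v + 1L
    }
  }
  tab <- sort(table(keys), decreasing = TRUE) / n
  nf <- vapply(ls(setcount), function(k) setcount[[k]], 1L) / n
  list(table = data.frame(key = names(tab),
                          probability = as.numeric(tab),
                          stringsAsFactors = FALSE),
       topologies = mts[names(tab)],
       node_frequencies = sort(nf, decreasing = TRUE))
}

#' Convergence diagnostics across independent chains
#'
#' Per-statistic (log posterior, log likelihood, admixture-event count,
#' total branch length) trace summaries; a Gelman-Rubin-style potential
#' scale reduction factor when at least two chains are given (computed as
#' sqrt((W + B/n)/W) with W the pooled within-chain variance and B/n the
#' variance of the chain means, so identical chains give exactly 1); and
#' lag autocorrelation of the continuous statistics (the event count is
#' discrete and excluded).
#'
#' @param samples list of `posterior_sample` objects from independent
#'   chains (same length records).
#' @param lags autocorrelation lags to report.
#' @return A `convergence_report` list with `summary`, `rhat` and `acf`.
#' @export
convergence_diagnostics <- function(samples, lags = 0:20) {
  if (inherits(samples, "posterior_sample")) samples <- list(samples)
  stopifnot(length(samples) >= 1L)
  stat_names <- c("log_post", "log_lik", "K", "total_branch")
  cont <- c("log_post", "log_lik", "total_branch")
  traces <- lapply(stat_names, function(s)
    lapply(samples, function(x) x$stats[[s]]))
  names(traces) <- stat_names
  summ <- do.call(rbind, lapply(stat_names, function(s) {
    v <- unlist(traces[[s]])
    data.frame(statistic = s, mean = mean(v), sd = stats::sd(v),
               min = min(v), max = max(v))
  }))
  rhat <- NULL
  if (length(samples) >= 2L) {
    rhat <- vapply(stat_names, function(s) {
      chains <- traces[[s]]
      n <- min(lengths(chains))
      chains <- lapply(chains, function(v) v[seq_len(n)])
      W <- mean(vapply(chains, stats::var, 0))
      Bn <- stats::var(vapply(chains, mean, 0))  # variance of chain means
      if (W == 0) return(1)
      sqrt((W + Bn) / W)
    }, 0)
  } else {
    warning("single chain: Gelman-Rubin diagnostic omitted")
  }
  acfs <- lapply(cont, function(s) {
    v <- traces[[s]][[1L]]
    if (stats::sd(v) == 0) return(rep(NA_real_, length(lags)))
    a <- stats::acf(v, lag.max = max(lags), plot = FALSE)
    as.numeric(a$acf)[lags + 1L]
  })
  names(acfs) <- cont
  structure(list(summary = summ, rhat = rhat,
                 acf = acfs, lags = lags,
                 n_chains = length(samples)),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("convergence report over", x$n_chains, "chain(s)\n")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$rhat)) {
    cat("R-hat:", paste(sprintf("%s %.4f", names(x$rhat), x$rhat),
                        collapse = ", "), "\n")
  }
  invisible(x)
}

#' Mean posterior summary statistics against a reference graph
#'
#' Over the (burned-in, thinned) sample: mean Set Distance, mean
#' Covariance Distance and mean Topology Equality (the fraction of samples
#' whose labeled topology matches the reference).
#'
#' @param sample a `posterior_sample`.
#' @param reference an `admixture_graph` over the same leaves.
#' @param topology_only passed to [canonical_key()] for the equality
#'   tally.
#' @param sigma_scale factor applied to the reference covariance before
#'   comparison. Sampled graphs carry branch lengths on the
#'   c_S-rescaled scale of the likelihood, so a reference in raw drift
#'   units should be scaled by the run's `cov$c_S` (times 1/h if the
#'   reference is in frequency units).
#' @return Named numeric vector.
#' @export
summarize_against <- function(sample, reference, topology_only = TRUE,
                              sigma_scale = 1) {
  ref_ts <- topology_set(reference)
  ref_S <- sigma_scale * graph_covariance(reference)
  ref_key <- canonical_key(reference, topology_only = topology_only)
  lv <- rownames(ref_S)
  sd_ <- vapply(sample$records, function(g) set_distance(g, ref_ts), 0)
  cd <- vapply(sample$records, function(g) {
    covariance_distance(graph_covariance(g)[lv, lv], ref_S)
  }, 0)
  te <- vapply(sample$records, function(g)
    as.numeric(canonical_key(g, topology_only = topology_only) == ref_key),
    0)
  c(set_distance = mean(sd_), covariance_distance = mean(cd),
    topology_equality = mean(te))
}
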