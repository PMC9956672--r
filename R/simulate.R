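## Synthetic data: allele frequencies evolved along a known admixture graph
## under the Gaussian drift model, binomially sampled into finite haplotype
## counts, with optional missingness. Also mean-parameterized Wishart
## replicate draws for the df estimator tests.

#' Simulate population allele frequencies along an admixture graph
#'
#' Per SNP: the ancestral (outgroup) frequency p is drawn from
#' `root_freq()`; each branch adds independent Gaussian drift noise
#' N(0, c p(1-p)), with p the SNP's ancestral draw throughout (the
#' SNP-global simplification of the drift variance); at an admixture node
#' the two parental contributions (including drift on the respective
#' parent branches) mix with weights w and 1-w. Frequencies are clipped to
#' [0,1] after every node; the fraction of clipped values is reported so
#' boundary effects can be checked.
#'
#' @param g a valid `admixture_graph`.
#' @param n_snps number of SNPs.
#' @param root_freq function(n) drawing n ancestral frequencies; default
#'   uniform on (0.1, 0.9), which keeps the Gaussian drift approximation
#'   away from the boundaries.
#' @param seed optional integer seed.
#' @return List with `freq` (SNPs x populations matrix, outgroup first
#'   column), `root_p` (ancestral draws) and `clipped` (fraction of
#'   node-frequency evaluations clipped).
#' @export
simulate_frequencies <- function(g, n_snps,
                                 root_freq = function(n) stats::runif(n, 0.1, 0.9),
                                 seed = NULL) {
  v <- validate_graph(g)
  if (length(v)) stop("invalid graph: ", paste(v, collapse = "; "))
  if (!is.null(seed)) set.seed(seed)
  n_snps <- as.integer(n_snps)
  p <- root_freq(n_snps)
  sdunit <- sqrt(p * (1 - p))
  ord <- topo_order(g)
  root <- ord[1L]
  leaves <- graph_leaves(g)
  wts <- edge_weights(g)
  clip_lo <- 0L; clip_hi <- 0L
  ## outgroup sits above the root: root frequency = p + drift on c0
  P <- list()
  P[[g$outgroup]] <- p
  P[[root]] <- p + stats::rnorm(n_snps, 0, sqrt(g$outgroup_length)) * sdunit
  clipped <- function(x) pmin(1, pmax(0, x))
  P[[root]] <- clipped(P[[root]])
  ## per-edge drift increments, then accumulate down the graph
  drift <- lapply(seq_along(g$child), function(e)
    stats::rnorm(n_snps, 0, sqrt(g$length[e])) * sdunit)
  for (v in ord[-1L]) {
    up <- which(g$child == v)
    x <- 0
    for (e in up) x <- x + wts[e] * (P[[g$parent[e]]] + drift[[e]])
    xc <- clipped(x)
    clip_lo <- clip_lo + sum(x < 0); clip_hi <- clip_hi + sum(x > 1)
    P[[v]] <- xc
  }
  cols <- c(g$outgroup, sort(leaves))
  freq <- do.call(cbind, P[cols])
  colnames(freq) <- cols
  list(freq = freq, root_p = p,
       clipped = (clip_lo + clip_hi) / (n_snps * (length(ord) - 1L)))
}

#' Sample haplotype counts from population frequencies
#'
#' Draws x ~ Binomial(m, P) per SNP and population and masks entries
#' missing independently at `missing_rate`.
#'
#' @param freq SNPs x populations frequency matrix (as from
#'   [simulate_frequencies()]).
#' @param m haplotypes sampled per population (scalar or per-population
#'   vector).
#' @param missing_rate probability an entry is missing.
#' @param seed optional integer seed.
#' @return An [allele_counts()] object.
#' @export
sample_counts <- function(freq, m, missing_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  np <- ncol(freq)
  N <- nrow(freq)
  m <- rep_len(m, np)
  x <- vapply(seq_len(np), function(i) stats::rbinom(N, m[i], freq[, i]),
              numeric(N))
  mm <- matrix(rep(m, each = N), N, np)
  if (missing_rate > 0) {
    mask <- matrix(stats::runif(N * np) < missing_rate, N, np)
    x[mask] <- NA
    mm[mask] <- NA
  }
  allele_counts(x, mm, colnames(freq))
}

#' Simulate a full allele-count dataset from a graph
#'
#' Convenience wrapper: [simulate_frequencies()] then [sample_counts()].
#'
#' @inheritParams simulate_frequencies
#' @inheritParams sample_counts
#' @return List with `counts` (an [allele_counts()]), `freq`, and the
#'   truth graph `graph`.
#' @export
simulate_dataset <- function(g, n_snps, m = 20L, missing_rate = 0,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fr <- simulate_frequencies(g, n_snps)
  counts <- sample_counts(fr$freq, m, missing_rate)
  list(counts = counts, freq = fr$freq, graph = g)
}

#' Named fixture graphs for simulation studies
#'
#' Four small admixture graphs with human-scale drift branch lengths
#' (0.01-0.15 drift units), mirroring the structural classes used in
#' method benchmarking: `g1` has a single admixture event; `g2` is an
#' admixture-free tree; `g3` places its admixture event between deeply
#' diverged lineages so that the best supporting tree differs from the
#' true tree backbone; `g4` holds two nested admixture events. Branch
#' lengths are this package's defaults, not canonical values.
#'
#' @return Named list of `admixture_graph`s.
#' @export
fixture_graphs <- function() {
  ## g1: ((A,B),(C,D)) backbone; B admixed between the (A,B) ancestor and
  ## a lineage branching off above (C,D). The deep source branch and
  ## w = 0.4 make the event statistically identifiable at moderate SNP
  ## counts, matching its role as the benchmark every method recovers.
  g1 <- admixture_graph(data.frame(
    child  = c("A", "m", "B", "C", "D", "cd", "m", "ab", "d"),
    parent = c("ab", "ab", "m", "cd", "cd", "d", "d", "r", "r"),
    length = c(0.02, 0.012, 0.008, 0.012, 0.018, 0.015, 0.02, 0.025,
               0.03),
    type   = c("normal", "main", "normal", "normal", "normal", "normal",
               "admix", "normal", "normal"),
    prop   = c(NA, 0.6, NA, NA, NA, NA, 0.4, NA, NA)),
    outgroup = "out", outgroup_length = 0.02)
  ## g2: admixture-free 5-leaf tree (((A,B),C),(D,E))
  g2 <- admixture_graph(data.frame(
    child  = c("A", "B", "ab", "C", "abc", "D", "E", "de"),
    parent = c("ab", "ab", "abc", "abc", "r", "de", "de", "r"),
    length = c(0.05, 0.04, 0.03, 0.07, 0.04, 0.06, 0.05, 0.08)),
    outgroup = "out", outgroup_length = 0.12)
  ## g3: C draws substantial ancestry from the deep (A,B) ancestral
  ## lineage, so the best-fitting plain tree misplaces C
  g3 <- admixture_graph(data.frame(
    child  = c("A", "B", "ab", "m", "C", "m", "D", "cd", "d1"),
    parent = c("ab", "ab", "d1", "d1", "m", "cd", "cd", "r", "r"),
    length = c(0.10, 0.09, 0.03, 0.02, 0.02, 0.015, 0.09, 0.05, 0.04),
    type   = c("normal", "normal", "normal", "admix", "normal", "main",
               "normal", "normal", "normal"),
    prop   = c(NA, NA, NA, 0.4, NA, 0.6, NA, NA, NA)),
    outgroup = "out", outgroup_length = 0.12)
  ## g4: two admixture events crossing the deep split in both directions
  g4 <- admixture_graph(data.frame(
    child  = c("A", "m1", "B", "C", "m2", "D", "ab", "cd", "m1", "m2",
               "d1", "d2"),
    parent = c("ab", "ab", "m1", "cd", "cd", "m2", "d2", "d1", "d1",
               "d2", "r", "r"),
    length = c(0.07, 0.02, 0.02, 0.03, 0.02, 0.04, 0.05, 0.04, 0.03,
               0.02, 0.03, 0.03),
    type   = c("normal", "main", "normal", "normal", "main", "normal",
               "normal", "normal", "admix", "admix", "normal", "normal"),
    prop   = c(NA, 0.7, NA, NA, 0.55, NA, NA, NA, 0.3, 0.45, NA, NA)),
    outgroup = "out", outgroup_length = 0.12)
  list(g1 = g1, g2 = g2, g3 = g3, g4 = g4)
}

#' Draw mean-parameterized Wishart replicates
#'
#' R draws from the Wishart with expectation `mean_matrix` and degrees of
#' freedom `df` (scale = mean/df). Used to calibrate the df estimators.
#'
#' @param mean_matrix positive-definite expectation matrix.
#' @param df degrees of freedom (> dim - 1).
#' @param R number of draws.
#' @param seed optional integer seed.
#' @return List of R matrices.
#' @export
simulate_wishart <- function(mean_matrix, df, R, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(mean_matrix)
  if (df <= n - 1) stop("df must exceed dim - 1")
  draws <- stats::rWishart(R, df, mean_matrix / df)
  lapply(seq_len(R), function(r) draws[, , r])
}
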