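## Sufficient statistics of the drift model: empirical covariance S, bias
## correction B, heterozygosity normalizer h, block-bootstrap degrees of
## freedom and the robustness scale c_S.

## deviation matrix p_k - p_0 (SNPs x non-outgroup pops) and observation
## indicator; a SNP contributes to entry (k,l) only when p_k, p_l and p_0
## are all present
.deviations <- function(counts, outgroup) {
  pops <- counts$populations
  if (!(outgroup %in% pops)) stop("unknown outgroup label: ", outgroup)
  keep <- setdiff(pops, outgroup)
  p0 <- counts$p[, outgroup]
  d <- counts$p[, keep, drop = FALSE] - p0
  list(d = d, obs = !is.na(d), keep = keep, p0 = p0)
}

#' Empirical covariance of outgroup-centered allele frequencies
#'
#' S[k,l] is the average over SNPs of (p_k - p_0)(p_l - p_0), where p_0 is
#' the outgroup sample frequency. A SNP enters entry (k,l) only if p_k, p_l
#' and p_0 are all non-missing, so per-entry denominators differ under
#' missingness.
#'
#' @param counts an [allele_counts()] object.
#' @param outgroup outgroup population label.
#' @return n x n symmetric matrix over the non-outgroup populations.
#' @export
empirical_covariance <- function(counts, outgroup) {
  dv <- .deviations(counts, outgroup)
  d0 <- dv$d; d0[!dv$obs] <- 0
  cnt <- crossprod(dv$obs)
  if (any(cnt == 0))
    stop("a population pair has no SNP with complete (k, l, outgroup) data")
  S <- crossprod(d0) / cnt
  (S + t(S)) / 2
}

#' Bias correction for the empirical covariance
#'
#' The sampling of finitely many haplotypes inflates the covariance
#' estimate; the correction subtracts, per entry, the average outgroup
#' binomial variance term p_0(1-p_0)/(m_0 - 1), plus on the diagonal the
#' population's own term p_k(1-p_k)/(m_k - 1). SNP sets per entry match
#' [empirical_covariance()].
#'
#' @inheritParams empirical_covariance
#' @return n x n symmetric matrix B.
#' @export
bias_correction <- function(counts, outgroup) {
  dv <- .deviations(counts, outgroup)
  obs <- dv$obs
  p0 <- dv$p0
  m0 <- counts$m[, outgroup]
  pk <- counts$p[, dv$keep, drop = FALSE]
  mk <- counts$m[, dv$keep, drop = FALSE]
  if (any(m0[!is.na(m0)] == 1) || any(mk[!is.na(mk)] == 1)) {
    bad <- which(counts$m == 1, arr.ind = TRUE)[1, ]
    stop(sprintf("m = 1 at SNP %d, population %s: bias term undefined",
                 bad[1], counts$populations[bad[2]]))
  }
  g0 <- p0 * (1 - p0) / (m0 - 1)
  g0[is.na(g0)] <- 0
  cnt <- crossprod(obs)
  if (any(cnt == 0))
    stop("a population pair has no SNP with complete (k, l, outgroup) data")
  B <- crossprod(obs, obs * g0) / cnt
  gk <- pk * (1 - pk) / (mk - 1)
  gk[!obs] <- 0
  diag(B) <- diag(B) + colSums(gk) / diag(cnt)
  (B + t(B)) / 2
}

#' Heterozygosity normalizer
#'
#' h is the average over SNPs of pbar(1 - pbar), where pbar is the mean
#' sample frequency across all n+1 populations (outgroup included). SNPs
#' with any missing population are excluded from the average.
#'
#' @param counts an [allele_counts()] object.
#' @return Positive scalar; error if every retained SNP is monomorphic.
#' @export
heterozygosity_norm <- function(counts) {
  complete <- rowSums(is.na(counts$p)) == 0
  if (!any(complete)) stop("no SNP with complete data for h")
  pbar <- rowMeans(counts$p[complete, , drop = FALSE])
  h <- mean(pbar * (1 - pbar))
  if (h <= 0) stop("h = 0: all complete SNPs are monomorphic")
  h
}

#' Block-bootstrap replicates of the scaled covariance S/h
#'
#' SNPs are partitioned into contiguous blocks of `block_size` (the last
#' block may be shorter); each replicate resamples blocks with replacement
#' to the original number of blocks and recomputes S/h on the resampled
#' SNPs. Contiguous blocks keep linked SNPs together so the replicate
#' spread reflects the effective number of independent markers.
#'
#' @inheritParams empirical_covariance
#' @param R number of replicates (>= 2).
#' @param block_size SNPs per block (1 <= block_size <= N).
#' @param seed optional integer seed for reproducibility.
#' @return List of R matrices.
#' @export
bootstrap_covariances <- function(counts, outgroup, R = 100L,
                                  block_size = 1000L, seed = NULL) {
  N <- counts$n_snps
  if (block_size < 1L || block_size > N)
    stop("block_size must be between 1 and the number of SNPs")
  if (R < 2L) stop("need at least 2 bootstrap replicates")
  if (!is.null(seed)) set.seed(seed)
  blocks <- split(seq_len(N), (seq_len(N) - 1L) %/% block_size)
  nb <- length(blocks)
  lapply(seq_len(R), function(r) {
    idx <- unlist(blocks[sample.int(nb, nb, replace = TRUE)],
                  use.names = FALSE)
    cc <- allele_counts(counts$x[idx, , drop = FALSE],
                        counts$m[idx, , drop = FALSE],
                        counts$populations)
    empirical_covariance(cc, outgroup) / heterozygosity_norm(cc)
  })
}

## entrywise mean, sample variance and Wishart variance weights of a
## replicate list
.rep_moments <- function(reps) {
  R <- length(reps)
  if (R < 2L) stop("need at least 2 replicates")
  arr <- simplify2array(reps)
  xbar <- apply(arr, c(1, 2), mean)
  v <- apply(arr, c(1, 2), stats::var)
  a <- xbar^2 + outer(diag(xbar), diag(xbar))
  list(xbar = xbar, v = v, a = a)
}

#' Moment-based degrees-of-freedom estimator
#'
#' The entrywise variance of a mean-parameterized Wishart with mean Psi and
#' df degrees of freedom is (Psi_kl^2 + Psi_kk Psi_ll)/df. Matching the
#' bootstrap sample variances v_kl to that identity in least squares gives
#' the closed form df = sum(a^2) / sum(v a) with
#' a_kl = Xbar_kl^2 + Xbar_kk Xbar_ll. This is the default estimator used
#' for the likelihood's degrees of freedom.
#'
#' @param reps list of bootstrap replicate matrices
#'   (from [bootstrap_covariances()]).
#' @return Positive scalar df.
#' @export
estimate_df_moment <- function(reps) {
  mo <- .rep_moments(reps)
  if (all(mo$v == 0)) stop("degenerate bootstrap: all replicates identical")
  df <- sum(mo$a^2) / sum(mo$v * mo$a)
  if (!is.finite(df) || df <= 0) stop("degenerate df estimate")
  df
}

#' Maximum-likelihood degrees-of-freedom estimator
#'
#' Maximizes the mean-parameterized Wishart log likelihood of the
#' replicates, with the mean fixed at the replicate average. Provided for
#' comparison; the moment estimator is the default (it is more accurate in
#' simulations).
#'
#' @inheritParams estimate_df_moment
#' @return Positive scalar df.
#' @export
estimate_df_mle <- function(reps) {
  mo <- .rep_moments(reps)
  xbar <- mo$xbar
  n <- nrow(xbar)
  if (inherits(try(chol(xbar), silent = TRUE), "try-error"))
    stop("replicate mean is not positive definite")
  obj <- function(logdf) {
    df <- exp(logdf)
    if (df <= n - 1) return(-Inf)
    sum(vapply(reps, function(X) dwishart_mean_log(X, xbar, df), 0))
  }
  opt <- stats::optimize(obj, interval = log(c(n, 1e8)), maximum = TRUE,
                         tol = 1e-10)
  exp(opt$maximum)
}

#' Robustness scale for the Wishart likelihood
#'
#' c_S = (L log2(L) + L) / tr(S/h): rescales the data covariance so its
#' trace matches the magnitude the branch-length prior expects, making the
#' inference robust to the overall drift scale.
#'
#' @param S empirical covariance matrix.
#' @param h heterozygosity normalizer.
#' @param L number of non-outgroup populations.
#' @return Positive scalar.
#' @export
robustness_scale <- function(S, h, L) {
  tr <- sum(diag(S)) / h
  if (tr <= 0) stop("non-positive trace of S/h")
  (L * log2(L) + L) / tr
}

#' Full covariance-side summary of an allele-count dataset
#'
#' Computes every statistic the Wishart likelihood needs: S, B, h, the
#' block-bootstrap replicates and moment-based df, and c_S.
#'
#' @inheritParams bootstrap_covariances
#' @param df optional override; skips the bootstrap when given.
#' @return A `covariance_estimate` object with fields `S`, `B`, `h`, `df`,
#'   `c_S`, `bootstrap_reps`, `block_size`, `populations`, `outgroup`.
#' @export
covariance_estimate <- function(counts, outgroup, R = 100L,
                                block_size = 1000L, seed = NULL,
                                df = NULL) {
  S <- empirical_covariance(counts, outgroup)
  B <- bias_correction(counts, outgroup)
  h <- heterozygosity_norm(counts)
  reps <- NULL
  if (is.null(df)) {
    reps <- bootstrap_covariances(counts, outgroup,
                                  R = R,
                                  block_size = min(block_size,
                                                   counts$n_snps),
                                  seed = seed)
    df <- estimate_df_moment(reps)
  }
  n <- nrow(S)
  cs <- robustness_scale(S, h, n)
  structure(list(S = S, B = B, h = h, df = df, c_S = cs,
                 bootstrap_reps = reps, block_size = block_size,
                 populations = rownames(S), outgroup = outgroup,
                 n_snps = counts$n_snps),
            class = "covariance_estimate")
}

#' @export
print.covariance_estimate <- function(x, ...) {
  cat(sprintf(
    "covariance estimate: %d populations, %d SNPs, df = %.1f, c_S = %.4g, h = %.4g\n",
    nrow(x$S), x$n_snps, x$df, x$c_S, x$h))
  invisible(x)
}
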