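## Reversible-jump Metropolis-coupled MCMC over admixture graphs.

#' MCMC configuration
#'
#' Bundles every tunable of [mc3_run()]: iteration count, chain count and
#' temperature ladder, proposal mix, thinning, swap cadence, adaptation
#' horizon and seed.
#'
#' @param n_iter iterations per chain.
#' @param n_chains number of coupled chains; the cold chain (beta = 1) is
#'   the one recorded.
#' @param betas temperature ladder (decreasing from 1). Default geometric
#'   with the hottest chain at 0.1.
#' @param proposal_weights named non-negative weights over
#'   `add`, `remove`, `slide`, `branch_rw`, `resample_w`, `outgroup_rw`,
#'   `nullspace_rw`; renormalized.
#' @param thin record every `thin`-th iteration of the cold chain.
#' @param swap_every propose one adjacent-pair state swap every this many
#'   iterations.
#' @param adapt_until freeze proposal-scale adaptation after this many
#'   iterations (default a third of `n_iter`), so the recorded tail is a
#'   valid Markov chain.
#' @param K_max admixture-event cap (prior truncation).
#' @param q geometric prior parameter for the admixture-event count.
#' @param seed integer seed; every random draw of the run derives from it.
#' @return An `mc3_config` list.
#' @export
mc3_config <- function(n_iter = 10000L, n_chains = 1L, betas = NULL,
                       proposal_weights = c(add = 0.15, remove = 0.15,
                                            slide = 0.2, branch_rw = 0.2,
                                            resample_w = 0.1,
                                            outgroup_rw = 0.1,
                                            nullspace_rw = 0.1),
                       thin = 10L, swap_every = 10L, adapt_until = NULL,
                       K_max = 20L, q = 0.5, seed = NULL) {
  if (is.null(betas)) {
    betas <- if (n_chains == 1L) 1
             else 0.1^((seq_len(n_chains) - 1) / (n_chains - 1))
  }
  stopifnot(length(betas) == n_chains, betas[1L] == 1,
            all(diff(betas) <= 0), all(betas > 0))
  w <- proposal_weights[c("add", "remove", "slide", "branch_rw",
                          "resample_w", "outgroup_rw", "nullspace_rw")]
  stopifnot(!anyNA(w), all(w >= 0), sum(w) > 0)
  if (is.null(adapt_until)) adapt_until <- n_iter %/% 3L
  structure(list(n_iter = as.integer(n_iter),
                 n_chains = as.integer(n_chains), betas = betas,
                 proposal_weights = w / sum(w), thin = as.integer(thin),
                 swap_every = as.integer(swap_every),
                 adapt_until = as.integer(adapt_until),
                 K_max = as.integer(K_max), q = q, seed = seed),
            class = "mc3_config")
}

## adaptive scales with Robbins-Monro log-scale updates; target 0.234 for
## multivariate walks, 0.44 for the 1-D outgroup walk
new_scales <- function() {
  list(lambda = 0.1, s = 0.1, s_out = 0.1, s_null = 0.1,
       n = c(slide = 0L, branch_rw = 0L, outgroup_rw = 0L,
             nullspace_rw = 0L))
}

adapt_scale <- function(scales, type, accepted) {
  target <- c(slide = 0.234, branch_rw = 0.234, outgroup_rw = 0.44,
              nullspace_rw = 0.234)[[type]]
  key <- c(slide = "lambda", branch_rw = "s", outgroup_rw = "s_out",
           nullspace_rw = "s_null")[[type]]
  scales$n[type] <- scales$n[type] + 1L
  gamma <- scales$n[type]^(-0.6)
  scales[[key]] <- exp(log(scales[[key]]) +
                         gamma * ((accepted) - target))
  scales[[key]] <- min(max(scales[[key]], 1e-4), 50)
  scales
}

## one reversible-jump Metropolis-Hastings step on a single chain state
## state: list(g, ll, lp); likfn maps graph -> log likelihood
mh_step <- function(state, likfn, config, scales, adapt, beta = 1,
                    pc = prior_config(q = config$q, K_max = config$K_max)) {
  w <- config$proposal_weights
  type <- names(w)[sample.int(length(w), 1L, prob = w)]
  prop <- switch(type,
    add = propose_add_admixture(state$g, config$K_max),
    remove = propose_remove_admixture(state$g),
    slide = propose_node_slide(state$g, scales$lambda),
    branch_rw = propose_branch_rw(state$g, scales$s),
    resample_w = propose_resample_w(state$g),
    outgroup_rw = propose_outgroup_rw(state$g, scales$s_out),
    nullspace_rw = propose_nullspace_rw(state$g, scales$s_null))
  accepted <- FALSE
  if (!is.null(prop)) {
    if (isTRUE(prop$no_op)) {
      accepted <- TRUE
    } else {
      lp2 <- log_prior_graph(prop$graph, pc)
      ll2 <- if (isTRUE(prop$likelihood_invariant)) state$ll
             else likfn(prop$graph)
      log_alpha <- beta * (ll2 - state$ll) + (lp2 - state$lp) +
        prop$log_bwd - prop$log_fwd
      if (is.finite(log_alpha) || log_alpha == Inf) {
        if (log(stats::runif(1)) < log_alpha) {
          state <- list(g = prop$graph, ll = ll2, lp = lp2)
          accepted <- TRUE
        }
      }
    }
  }
  if (adapt && !isTRUE(prop$no_op) &&
      type %in% c("slide", "branch_rw", "outgroup_rw", "nullspace_rw"))
    scales <- adapt_scale(scales, type, accepted)
  list(state = state, scales = scales, type = type, accepted = accepted)
}

#' Run the reversible-jump Metropolis-coupled sampler
#'
#' `n_chains` chains run at the temperatures of the ladder (the likelihood
#' is raised to the power beta; the prior is never tempered). Adjacent
#' chains exchange states at the configured cadence with the standard
#' coupled-MCMC acceptance; only the cold chain is recorded, every `thin`
#' iterations. Passing `cov = NULL` samples from the prior (the
#' likelihood is identically zero), which is how the proposal machinery is
#' validated.
#'
#' @param cov a `covariance_estimate` from [covariance_estimate()], or
#'   NULL for prior-only sampling.
#' @param leaves leaf labels (required when `cov` is NULL; otherwise taken
#'   from the covariance rownames).
#' @param config an [mc3_config()].
#' @param outgroup label used for the outgroup in sampled graphs.
#' @param init optional initial `admixture_graph`; default a random tree
#'   from the prior.
#' @return A `posterior_sample`: list with `records` (sampled graphs),
#'   `stats` (data frame: iteration, log_post, log_lik, log_prior, K,
#'   total_branch), `acceptance` (per-proposal rates), `swap_rate`,
#'   `config` and `scales`.
#' @export
mc3_run <- function(cov = NULL, leaves = NULL, config = mc3_config(),
                    outgroup = "out", init = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(cov)) {
    if (is.null(leaves)) stop("leaves required for prior-only sampling")
    likfn <- function(g) 0
  } else {
    leaves <- rownames(cov$S)
    outgroup <- cov$outgroup
    n <- nrow(cov$S)
    if (cov$df <= n - 1)
      stop(sprintf("df = %.2f <= n-1 = %d: Wishart likelihood undefined",
                   cov$df, n - 1L))
    ## per-run constants of the Wishart density (X never changes)
    X <- cov$c_S * cov$S / cov$h
    Badd <- cov$c_S * cov$B / cov$h
    df <- cov$df
    ldX <- 2 * sum(log(diag(chol(X))))
    lmg <- (n * (n - 1) / 4) * log(pi) +
      sum(lgamma((df + 1 - seq_len(n)) / 2))
    lconst <- (df - n - 1) / 2 * ldX - df * n / 2 * log(2) - lmg +
      df * n / 2 * log(df)          # from scale V = M/df
    perm <- match(leaves, sort(leaves))
    likfn <- function(g) {
      Sg <- graph_covariance(g)[perm, perm, drop = FALSE]
      M <- Sg + Badd
      cM <- tryCatch(chol(M), error = function(e) NULL)
      if (is.null(cM)) return(-Inf)
      lconst - df * sum(log(diag(cM))) - df * sum(chol2inv(cM) * X) / 2
    }
  }
  pc <- prior_config(q = config$q, K_max = config$K_max)
  nch <- config$n_chains
  chains <- vector("list", nch)
  scales <- replicate(nch, new_scales(), simplify = FALSE)
  for (i in seq_len(nch)) {
    g0 <- if (!is.null(init)) init else random_tree(leaves, outgroup)
    ll0 <- likfn(g0); lp0 <- log_prior_graph(g0, pc)
    if (!is.finite(ll0 + lp0))
      stop("non-finite initial posterior; check df and the data")
    chains[[i]] <- list(g = g0, ll = ll0, lp = lp0)
  }
  n_rec <- config$n_iter %/% config$thin
  records <- vector("list", n_rec)
  stats_m <- matrix(NA_real_, n_rec, 5L,
                    dimnames = list(NULL, c("iteration", "log_post",
                                            "log_lik", "K",
                                            "total_branch")))
  lp_col <- numeric(n_rec)
  acc <- rej <- stats::setNames(integer(7L), names(config$proposal_weights))
  swp_try <- 0L; swp_acc <- 0L
  ri <- 0L
  for (it in seq_len(config$n_iter)) {
    adapt <- it <= config$adapt_until
    for (i in seq_len(nch)) {
      st <- mh_step(chains[[i]], likfn, config, scales[[i]], adapt,
                    beta = config$betas[i], pc = pc)
      chains[[i]] <- st$state
      scales[[i]] <- st$scales
      if (i == 1L) {
        if (st$accepted) acc[st$type] <- acc[st$type] + 1L
        else rej[st$type] <- rej[st$type] + 1L
      }
    }
    if (nch > 1L && it %% config$swap_every == 0L) {
      j <- sample.int(nch - 1L, 1L)
      swp_try <- swp_try + 1L
      d <- (config$betas[j] - config$betas[j + 1L]) *
        (chains[[j + 1L]]$ll - chains[[j]]$ll)
      if (log(stats::runif(1)) < d) {
        tmp <- chains[[j]]; chains[[j]] <- chains[[j + 1L]]
        chains[[j + 1L]] <- tmp
        swp_acc <- swp_acc + 1L
      }
    }
    if (it %% config$thin == 0L) {
      ri <- ri + 1L
      cs <- chains[[1L]]
      records[[ri]] <- cs$g
      stats_m[ri, ] <- c(it, cs$ll + cs$lp, cs$ll, n_admixture(cs$g),
                         sum(cs$g$length) + cs$g$outgroup_length)
      lp_col[ri] <- cs$lp
    }
  }
  stats <- as.data.frame(stats_m[seq_len(ri), , drop = FALSE])
  stats$log_prior <- lp_col[seq_len(ri)]
  structure(list(records = records[seq_len(ri)], stats = stats,
                 acceptance = acc / pmax(acc + rej, 1L),
                 proposal_counts = acc + rej,
                 swap_rate = if (swp_try) swp_acc / swp_try else NA_real_,
                 config = config, scales = scales,
                 burnin_applied = 0),
            class = "posterior_sample")
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat(sprintf(
    "posterior sample: %d recorded graphs (thin %d), K range %d-%d\n",
    length(x$records), x$config$thin, min(x$stats$K), max(x$stats$K)))
  cat("  acceptance:",
      paste(sprintf("%s %.2f", names(x$acceptance), x$acceptance),
            collapse = ", "), "\n")
  invisible(x)
}
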