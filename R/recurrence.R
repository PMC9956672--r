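## Exact counting of labeled admixture-graph topologies.
##
## N(L, P, K, E) is the number of unique labeled topologies with L leaves,
## P cherries (leaf pairs sharing a parent), K admixture events and E eyes.
## Eyes are permitted inside the recurrence's state space only; the
## user-facing state space always has E = 0.

.recurrence_memo <- new.env(parent = emptyenv())

#' Count labeled admixture-graph topologies
#'
#' Evaluates the seven-term counting recurrence for the number of unique
#' labeled topologies with `L` leaves, `P` cherries, `K` admixture events
#' and `E` eyes, with memoization. The terms that increase L while removing
#' an admixture event carry a 1/(L(L+1)) factor; computation is in double
#' precision with each memoized value rounded to the nearest integer
#' (counts are integers, so values are exact up to 2^53). Arguments outside
#' the reachable lattice return 0. The recurrence bottoms out at
#' N(1,0,0,0) = 1.
#'
#' The total over P at E = 0 normalizes the uniform prior over labeled
#' topologies with K admixture events; see [log_prior_topology()].
#'
#' @param L number of leaves (>= 1).
#' @param P number of cherries.
#' @param K number of admixture events.
#' @param E number of eyes (0 for every graph in the sampler's state
#'   space).
#' @return A count (numeric, integer-valued).
#' @examples
#' count_topologies_recurrence(5, 2, 0, 0)  # 45
#' count_topologies_recurrence(3, 1, 1, 0)  # 12
#' @export
count_topologies_recurrence <- function(L, P, K, E = 0) {
  L <- as.integer(L); P <- as.integer(P)
  K <- as.integer(K); E <- as.integer(E)
  if (L < 1L || P < 0L || K < 0L || E < 0L) return(0)
  if (P > L %/% 2L) return(0)
  if (L == 1L) {
    if (P == 0L && K == 0L && E == 0L) return(1)
    if (K == 0L) return(0)
  }
  if (K == 0L && E > 0L) return(0)   # eyes require admixture nodes
  key <- paste(L, P, K, E, sep = "_")
  hit <- .recurrence_memo[[key]]
  if (!is.null(hit)) return(hit)
  Nf <- count_topologies_recurrence
  val <-
    2 * (E + 1) * Nf(L - 1L, P, K, E + 1L) +
    (L - 2L * P + 1L) * Nf(L - 1L, P - 1L, K, E) +
    (L + 2L * P + 3L * K - 2L * E - 2L) * Nf(L - 1L, P, K, E) +
    (2 * (P + 1)) / (L * (L + 1)) * Nf(L + 1L, P + 1L, K - 1L, E - 1L) +
    (4 * (P + 1) * (P + 2)) / (L * (L + 1)) *
      Nf(L + 1L, P + 2L, K - 1L, E) +
    (4 * (P + 1) * (L - 2L * P - 1L)) / (L * (L + 1)) *
      Nf(L + 1L, P + 1L, K - 1L, E) +
    ((L - 2L * P) * (L - 2L * P + 1L)) / (L * (L + 1)) *
      Nf(L + 1L, P, K - 1L, E)
  val <- round(val)
  .recurrence_memo[[key]] <- val
  val
}

#' Total number of labeled topologies with K admixture events
#'
#' Sum of `count_topologies_recurrence(L, P, K, 0)` over all cherry counts
#' P = 0, ..., floor(L/2); the normalizer of the uniform topology prior.
#'
#' @inheritParams count_topologies_recurrence
#' @return A count.
#' @examples
#' count_topologies_total(5, 0)  # 105 rooted labeled binary trees
#' @export
count_topologies_total <- function(L, K) {
  key <- paste(L, K, sep = "_")
  v <- .topo_total_memo[[key]]
  if (is.null(v)) {
    v <- sum(vapply(0:(L %/% 2L),
                    function(P) count_topologies_recurrence(L, P, K, 0L),
                    0))
    .topo_total_memo[[key]] <- v
  }
  v
}

.topo_total_memo <- new.env(parent = emptyenv())
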