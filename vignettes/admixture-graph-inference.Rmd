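---
title: "Bayesian admixture-graph inference: model, priors, sampler and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian admixture-graph inference: model, priors, sampler and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rjadmix)
```

## The problem

Given biallelic SNP allele counts for n populations plus an outgroup,
`rjadmix` samples the posterior distribution of *admixture graphs*:
rooted directed acyclic graphs in which divergence nodes (one parent,
two children) describe population splits and admixture nodes (two
parents, one child) describe admixture events with a mixing proportion
w in (0,1). Branch lengths are in drift units, c = 1 - exp(-t/2N), so a
branch's length is the variance of allele-frequency change along it per
unit of heterozygosity. The outgroup is modeled as the parent of the
root; because Gaussian drift is reversible, the placement of the root
along the outgroup branch is unidentifiable and only the total length
c0 enters the model, as a shared term in every covariance entry.

Posterior samples — rather than a single optimized graph — make it
possible to report how confident the data are about individual features:
a clade, an admixture event, or the relationships among a focal subset
of populations.

## Model

### Graph-implied covariance

For a SNP with ancestral frequency p, drift along branch i adds
independent noise with variance c_i p(1-p). Collecting the flow of
ancestry from the root into each leaf gives a design matrix A (one row
per non-outgroup leaf, one column per branch, entries = products of
admixture proportions summed over paths; the outgroup-branch column is
all ones). The outgroup-centered leaf frequencies then have covariance
p(1-p) Sigma with

    Sigma = A diag(c0, c1, ..., cD) A'.

`design_matrix()` and `graph_covariance()` implement this map. Trees
give 0/1 design entries; admixture nodes mix rows.

### Data summaries

From an allele-count table (`read_counts()`; TreeMix-style text format
with explicit `NA` missingness), `covariance_estimate()` computes

* `S` — the empirical covariance of outgroup-centered sample
  frequencies, averaging each (k,l) entry over exactly the SNPs where
  populations k, l and the outgroup are all observed;
* `B` — a bias correction for binomial sampling of finitely many
  haplotypes, p(1-p)/(m-1) terms from the outgroup (all entries) and
  from the population itself (diagonal);
* `h` — the average heterozygosity pbar(1-pbar) across SNPs with
  complete data, which converts Sigma's drift units to frequency units;
* `df` — an effective number of independent SNPs (below);
* `c_S` — the robustness scale (L log2 L + L) / tr(S/h), which puts the
  rescaled data trace at the magnitude the branch-length prior expects.

### Wishart likelihood and the bootstrap degrees of freedom

The likelihood treats the rescaled data covariance c_S S/h as a
mean-parameterized Wishart draw with mean Sigma + c_S B/h and df
degrees of freedom: the *data* are rescaled by c_S, so the sampled
graph's branch lengths live on the c_S-calibrated scale where the
branch-length prior is meaningful. (Rescaling both the data and the
graph covariance would cancel out of the density's shape and neutralize
the correction entirely — and with it the prior's ability to penalize
spurious admixture events, whose extra near-zero branches would sit in
the high-density region of a sharp exponential at no cost.) SNPs are
correlated (linkage) and only
approximately Gaussian, so df is *estimated*, not set to the SNP count:
contiguous blocks of SNPs (default 1000) are resampled with replacement
(`bootstrap_covariances()`), and df is chosen so the entrywise Wishart
variance identity Var(X_kl) = (Psi_kl^2 + Psi_kk Psi_ll)/df matches the
replicate variances in least squares. This moment estimator has the
closed form df = sum(a^2)/sum(v a) with a_kl = Xbar_kl^2 +
Xbar_kk Xbar_ll (`estimate_df_moment()`; the maximum-likelihood
alternative `estimate_df_mle()` is provided for comparison but is less
accurate in simulations). df controls the peakedness of the likelihood
and therefore how strongly the posterior concentrates; a run aborts if
df <= n-1, where the Wishart density does not exist.

### Prior

* Number of admixture events K: geometric(0.5), truncated at 20.
* Topology given K: uniform over all labeled admixture graphs with K
  events. The normalizer is the exact count N(L,P,K,E) evaluated by a
  seven-term recurrence over leaves L, cherries P, events K and eyes E
  (eyes — parallel parent or child edges — are forbidden in the state
  space but appear as intermediate terms of the recurrence);
  `count_topologies_recurrence()` memoizes it, and a brute-force
  enumeration oracle (`enumerate_topologies()`, complete for K <= 1)
  validates every count at L <= 5.
* Branch lengths: i.i.d. exponential with mean (2L-2)/D, D = 2L-2+3K,
  so the expected total branch length is the same for every topology
  and graphs with more events expect shorter branches. The notation
  for this prior is ambiguous in its usual presentation (rate versus
  mean); we adopt the mean reading because it is the one under which
  more branches imply shorter branches, as the motivating argument
  requires. The outgroup branch c0 receives the same law (it has its
  own proposal, so it needs a proper prior; the choice is ours).
* Admixture proportions: uniform on (0,1).

## Sampler

`mc3_run()` is a reversible-jump Metropolis-coupled MCMC. Seven
proposals are mixed (default weights in parentheses):

1. *Add admixture branch* (0.15): sink branch uniform among the D
   internal branches, source uniform among the cycle-safe remainder
   plus the root branch; attachment points uniform on each branch
   (Exp(1) above the root, measured from the root upward — the origin
   is our choice); new branch length Exp(1), proportion U(0,1),
   main/admix labeling a fair coin. The Jacobian is 1.
2. *Remove admixture branch* (0.15): uniform among branches whose
   removal leaves a valid graph (parent not an admixture node, no eye).
   Removal from a valid graph preserves degrees and acyclicity, so
   eligibility reduces to checking that neither merged edge duplicates
   an existing (parent, child) pair; a test asserts this fast check
   agrees with performing the removal outright.
3. *Node slide* (0.2): a branch under a divergence node moves a
   distance lambda x, x ~ chi-squared(1), along the spliced skeleton,
   choosing uniformly among the destinations at that distance. The
   skeleton is identical before and after the move, so the forward and
   backward destination counts are computed on the same metric graph.
   Slides onto the outgroup branch are excluded: the slid node would
   become the root and the reverse move would be impossible. Walks that
   run off a leaf die; if every path dies, the move is rejected.
4. *Branch-length random walk* (0.2): Gaussian noise on every internal
   branch, reflected at zero (absolute value) — symmetric.
5. *Resample proportions* (0.1): all w redrawn U(0,1).
6. *Outgroup random walk* (0.1): as 4, on c0 only, separate scale.
7. *Null-space walk* (0.1): a Gaussian step inside the null space of
   the linear map c -> Sigma, leaving the likelihood exactly unchanged;
   steps that would make a length non-positive are rejected (reflection
   could leave the null space).

Scales (lambda, s, s_out, s_null) adapt by Robbins-Monro updates on the
log scale toward acceptance 0.234 (0.44 for the one-dimensional
outgroup walk) with step i^(-0.6), and freeze after a configurable
burn-in so the recorded chain is a valid Markov chain. When a chosen
move is unavailable (remove at K = 0), the iteration counts as a
rejection of that type; renormalizing the mix instead would change the
kernel.

Chains run at temperatures beta_i (likelihood tempered, prior not; the
default ladder is geometric with the hottest chain at beta = 0.1), and
adjacent chains propose state swaps every 10 iterations. Only the cold
chain is recorded. Runs are reproducible from the seed.

### Validation of the sampler

Because every proposal density enters the acceptance ratio explicitly,
bookkeeping errors bias the posterior silently. Three independent
checks are part of the test suite:

* *Prior recovery*: with the likelihood forced constant, the sampled
  K-marginal must match the truncated geometric(0.5) (chi-squared
  goodness of fit) and, at fixed K = 0 with three leaves, the three
  labeled trees must be equi-occupied. This exercises the add/remove
  pair, the slide, and the topology-prior normalizer jointly.
* *Reciprocity*: every add proposal is immediately inverted by the
  remove bookkeeping and must reproduce the forward density exactly.
* *Posterior recovery against brute force*: on a three-leaf problem
  with data drawn exactly from the Wishart likelihood, the chain's
  P(K | data) is compared with an importance-sampling estimate that
  uses only the enumeration oracle and prior draws — no MCMC.

## Posterior summaries

Each sampled graph reduces to its *topology set* — the set of
leaf-descendant sets of internal non-root nodes, which deliberately
discards how many admixture events produced it and when. On top of it:

* `node_frequencies()` — f(t), the fraction of samples containing
  descendant set t;
* `consensus_graph(alpha)` — the minimal topology over {t : f(t) >
  alpha} (strictly greater, as defined; default alpha 0.75), where the
  *minimal topology* connects t to t' when t' is a proper subset of t
  with no third set strictly between;
* `subgraph_posterior(focal)` — each sample restricted to a focal leaf
  subset (intersect descendant sets, drop empty/singleton/full results)
  and tallied, giving a complete posterior over the small graphs;
* `mode_graph()` — the sampled graph with the highest posterior (ties
  broken by earliest iteration, for determinism);
* `summarize_against()` — mean Set Distance (symmetric difference of
  topology sets), mean Covariance Distance (sum of squared entry
  differences of the implied covariances — implemented exactly as the
  defining sum of squares, without a square root), and Topology
  Equality against a reference graph.
* `apply_burnin_thin()` — burn-in fraction 0.35 and 100 equally spaced
  samples by default, the convention used for mean summaries.
* `convergence_diagnostics()` — trace summaries, a potential scale
  reduction factor across chains, and autocorrelations of the
  continuous statistics (the discrete event count is excluded, where
  autocorrelation is not meaningful). We compute R-hat as
  sqrt((W + B/n)/W) with W the pooled within-chain variance and B/n the
  variance of chain means; unlike the (n-1)/n-weighted classic form it
  equals exactly 1 for identical chains, which makes the degenerate
  case unambiguous.

Topology-equality tallies can include or ignore the main/admix labeling
of admixture parent edges (`canonical_key(topology_only = )`); the
summaries over topology sets are unaffected because the topology-set
map already discards it. Minimal-topology tallies pool over K, since
topology sets do.

## The synthetic-data generator

`simulate_frequencies()` draws a SNP's ancestral frequency p (default
uniform on (0.1, 0.9)), then adds N(0, c_i p(1-p)) drift along each
branch, mixing at admixture nodes with weights (w, 1-w); the drift
variance uses the SNP's ancestral p throughout, the same simplification
the likelihood makes. `sample_counts()` binomially samples m haplotypes
per population and injects missingness. Frequencies are clipped to
[0,1] after every node; the clipped fraction is reported.

What this emulates — and what it does not. The generator produces data
from exactly the Gaussian-drift/binomial model the likelihood assumes,
with independent SNPs. Real data differ in three ways that matter:
allele frequencies are bounded (drift is not Gaussian near 0 and 1),
SNPs are linked (the effective number of independent SNPs is far below
the SNP count), and ascertainment distorts the frequency spectrum.
Consequently passing recovery tests here demonstrates the correctness
of the inference machinery, not robustness to real-data misspecification.
Two regimes of the generator are worth distinguishing:

* With small total drift (roughly <= 0.05 from root to leaf) and the
  default root-frequency law, boundary clipping is negligible and the
  generator agrees with the graph covariance to Monte-Carlo precision —
  this is the regime for oracle tests of the covariance map.
* With larger, human-scale drift and very many independent SNPs the
  estimated df becomes so large that percent-level clipping bias is
  "statistically significant" under the Wishart, and the posterior
  compensates by adding spurious admixture events. Real analyses are
  protected by the bootstrap df (linked SNPs give much smaller df than
  the SNP count); the simulation studies below therefore use moderate
  SNP counts, where the information content is comparable to the
  scaled-down question being asked.

## Study conditions used in the automated experiments

All sizes were chosen to make each question answerable on a single CPU
in minutes; they are stated here as the package's study conditions.

* *Combinatorics*: recurrence and enumeration cross-checks at L <= 5,
  K <= 1, plus the unlabeled-orbit collapse at (3,1,1,0) — exact.
* *Covariance oracle*: 4 leaves + outgroup, one admixture event
  (w = 0.35), branch lengths 0.0016-0.005 drift units, 100,000 SNPs —
  the Gaussian model's validity domain (clipping < 1e-4).
* *Prior recovery*: 100,000 iterations, three leaves; the goodness of
  fit is computed on draws subsampled at three times the chain's
  estimated integrated autocorrelation time (about 200-450 iterations
  for the event count), since the chi-squared test assumes independent
  observations.
* *df estimator*: true mean-parameterized Wishart replicates, df = 100,
  R = 500.
* *Topology recovery*: the `g1` fixture — four leaves + outgroup, one
  admixture event with w = 0.4 and a deep source lineage (0.03 drift
  units) so the event is statistically identifiable, 3000 SNPs, 30
  haplotypes per population, bootstrap df (R = 50, blocks of 100),
  three chains (ladder 1, 0.55, 0.3) of 12,000 iterations with the
  proposal mix re-weighted toward topology moves, every iteration
  recorded so the Mode graph is the exact running maximum; ten seeded
  replicates, requiring the Mode graph to reach Set Distance 0 in at
  least 8. The admixture event must be identifiable by design: the
  benchmark it scales down used graphs whose events every compared
  method recovered perfectly.
* *Haplotype-number effect*: three leaves with a short internal branch
  (0.008 drift units), 1000 SNPs, m = 2 versus m = 20, three seeds per
  condition; the mean posterior probability of the true topology among
  admixture-free samples must increase with m.

## Numerical and degenerate-input choices

* The recurrence is computed in doubles with each memoized value
  rounded to the nearest integer; counts are exact below 2^53, far
  beyond any value the prior needs at practical L and K.
* Non-positive-definite Wishart means are rejected states (-Inf), not
  errors; Cholesky failures are caught.
* Covariance entries with no complete SNP, h = 0 (all monomorphic),
  m = 1 in a bias denominator, and df <= n-1 are hard errors with
  population/SNP identification.
* Graphs with a single leaf are rejected (no covariance signal).
* Slide walks are capped (1024 queue operations) against pathological
  blow-ups around short admixture cycles; a capped walk rejects the
  move, identically in both directions.
* Mode-graph ties break by iteration order; bootstrap blocks are
  contiguous and the last block may be short; all randomness flows from
  the single run seed.

## Known limitations

* Admixture involving the outgroup branch is outside the state space
  (as specified); data generated by such events will be fit by graphs
  that reroute the ancestry elsewhere.
* The enumeration oracle is complete only for K <= 1 (sufficient for
  every count it validates); for K = 2 it enumerates the graphs
  reachable by a single addition, which is how the sampler itself
  moves.
* With extremely informative data (df in the tens of thousands) and a
  misspecified generator, the posterior inflates K; see the generator
  section. This mirrors the role the robustness scaling and bootstrap
  df play for real data rather than contradicting it.
* Posterior probabilities of topologies are Monte-Carlo estimates from
  a finite chain; for small focal subsets they are stable, but
  probabilities of full labeled graphs on many leaves need long runs.
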