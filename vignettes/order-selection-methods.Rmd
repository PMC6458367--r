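---
title: "Closed-form predictive selection of Markov memory order"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-form predictive selection of Markov memory order}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmselect)
```

## The model

A trajectory over a finite alphabet of $M$ states is modelled as an
$h$-step Markov chain: the distribution of the symbol at position $l$
depends on the context $\mathbf{x}$, the $h$ most recent symbols. Writing
$N_{\mathbf{x},m}^{(j)}$ for the number of times trajectory $j$ makes the
transition $\mathbf{x} \to m$, and pooling $N_{\mathbf{x},m} = \sum_j
N_{\mathbf{x},m}^{(j)}$, the likelihood factorizes completely over contexts
and the counts are sufficient. The first $h$ positions of each trajectory
need a boundary convention; `mmselect` left-pads histories with a reserved
boundary marker (`"."` by default), so the first symbols are themselves
modelled through dedicated boundary contexts, and every observed symbol is
counted exactly once at any order.

Each context's transition vector $\mathbf{p}_\mathbf{x}$ gets an independent
conjugate prior $\mathrm{Dirichlet}(\boldsymbol\alpha)$, one
$\boldsymbol\alpha$ shared across contexts, giving the posterior
$\mathrm{Dirichlet}(\boldsymbol\alpha + \mathbf{N}_\mathbf{x})$. This
regularizes the maximum-likelihood pathology that unobserved transitions
receive probability zero. Everything downstream is a finite combination of
log-gamma, digamma and trigamma evaluations of these posterior parameters.

Candidate models are fixed orders $h = 0, 1, 2, \dots$ or *variable-length*
partitions of the order-$h$ context set into blocks sharing one parameter
vector. Blocks are defined over a fixed base order rather than as
arbitrary-depth context trees: this covers the interesting reduced models
(for free throws, the two-parameter error-correction model with blocks
$\{-\}$ and $\{+, .\}$) while keeping model *search* out of scope — the
package evaluates candidate models supplied by the user, it does not
enumerate the exponentially many variable-length models.

## The criteria and their numerical treatment

Eleven criteria are evaluated in closed form and reported on the deviance
scale ($-2\times$ the underlying log-predictive quantity, lower is better),
so that Bayesian criteria are directly comparable with the AIC. The raw
`LML`/`LPD`/`LPPD` values are also exposed. Numerical choices:

* all beta/gamma computations are in log space; $0 \log 0 \equiv 0$ is
  implemented explicitly wherever MLE plug-ins appear;
* the Stirling expansion `stirling_log_beta()` (through the $1/(12x)$
  terms) is provided for asymptotic analysis; it is accurate to better than
  $10^{-6}$ relative once every component is $\ge 100$ and is deliberately
  unguarded below that — it is an analysis tool, not a computational path;
  the criteria always use exact `lgamma`;
* leave-half-out cross-validation splits the trajectories into the first
  $\lceil J/2 \rceil$ and the rest, in input order. The two defining
  summations are treated as a disjoint partition (their bounds nominally
  overlap at the middle index, which would double-count one trajectory);
  trajectory order in the input file is therefore significant;
* ties in `select_model()` go to the simplest model: fewest parameters,
  then lowest order;
* degenerate inputs: an empty count table yields 0 for every marginal
  criterion (and penalty-only AIC); $J = 1$ makes LHO undefined, so it is
  omitted with a warning; an observed transition with zero plug-in
  probability flags a $-\infty$ log-likelihood rather than an error.

Two parameter-counting conventions are supported for AIC/BIC because both
are natural. `"literal"` counts $M^h(M-1)$ — every context of the full
order-$h$ set, boundary contexts excluded — and is the convention used for
the random-network simulations, where the designated start state supplies
the boundary condition. `"contexts"` counts observed contexts (or blocks)
times $(M-1)$, which matches per-season parameter counting for free-throw
data: 3 parameters for the $h = 1$ model (after-make, after-miss,
first-shot), 2 for the error-correction partition, 1 for $h = 0$.
Variable-length models always use context counting; the literal convention
is undefined for them.

The prior default is $\boldsymbol\alpha = \mathbf{1}$ (uniform);
$\boldsymbol\alpha = \mathbf{1}/2$ (Jeffreys) is available through the
`alpha` argument. In the large-count limit posteriors concentrate at the
MLE, and the per-transition difference between the two priors' LOO values
shrinks as counts scale up (a property the test suite checks on a
$\times 1, \times 10, \times 100$ count ladder).

## History padding: boundary marker vs start state

Two padding schemes are implemented because two situations genuinely
differ.

For observational sequence data (free throws), nothing is known about what
precedes a trajectory, and the first outcomes may well have their own
statistics (players shoot differently on the first attempt of a game).
Boundary-marker padding gives those positions dedicated contexts whose
parameters are estimated like any other.

For data simulated from a network with a designated start state, the
boundary condition is *known*: histories are initialized to $h$ copies of
the start state. Fitting candidate models with `pad = start` pools early
transitions with that state's genuine contexts, matching the generating
process exactly and making $M^h(M-1)$ the natural parameter count. The
network experiments use this scheme; the measured effect on selection
frequencies is small but the choice is principled, not tuned.

## What the synthetic-data generators emulate

`generate_network()` draws an $M$-state, order-$h_{\text{true}}$ system:
one transition vector per context, each $\mathrm{Dirichlet}(\mathbf{1})$
over all $M$ states, with the first state designated start and the last
absorbing. Absorption probability is therefore itself random (about $1/M$
per step on average), trajectory length is the first-passage time to the
absorbing state, and revisiting the start state is allowed.
$h_{\text{true}} = 0$ gives a memoryless system with a single shared
vector. Consequences worth knowing: realized mean trajectory lengths — and
with them the information content of a fixed number $J$ of trajectories —
vary severalfold from network to network, so selection frequencies at small
$J$ are strongly network-dependent. The test suite measures this dispersion
explicitly by rerunning the same experiment over ten independently drawn
networks.

`simulate_season()` emulates a season of free-throw games: attempt counts
per game are zero-truncated Poisson (every counted game has at least one
attempt), with the rate calibrated by root-finding so the *truncated* mean
equals the requested mean attempts per game (defaults: 91 games, mean 7.6,
make probability 0.68 — the scale of a high-volume NBA shooter's season).
Outcomes follow an iid, single-step Markov, or error-correction process.
What these generators do *not* emulate about real data: non-stationarity
within or between seasons, shot-level covariates (fatigue, score, venue),
and latent-state ("hot"/"cold") dynamics that are not finite-order
Markovian. Tests passing on these generators show the selection machinery
behaves correctly when the truth is in (or near) the model class; they
cannot show that real free-throw processes are in that class.

`shuffle_within_trajectories()` implements the shuffle control: each game's
outcomes are permuted uniformly, preserving per-game multisets while
destroying serial order. A nuance the test suite documents: shuffled
sequences are exchangeable, but the collection of per-game compositions
still reflects the original process (serially correlated processes are
over- or under-dispersed in their game totals relative to iid binomial), so
at *strong* effect sizes a residual signature survives shuffling. At
realistic effect sizes the shuffled selection frequencies are statistically
indistinguishable from iid seasons of the same make fraction, which is the
regime in which the control is meaningful.

## Verification strategy

Three independent oracles back the closed forms:

1. **Sequential urn.** Under conjugacy, each marginal or cross-validation
   criterion is a product of sequential predictive probabilities
   $(\alpha_m + C_{\mathbf{x},m})/(\alpha_0 + C_{\mathbf{x}\cdot})$ with
   running counts $C$. The tests walk trajectories symbol by symbol — no
   gamma functions — and require agreement with the beta-function forms to
   $10^{-9}$ on hundreds of random small fixtures (LML, LPPD, LOO, LHO).
2. **Posterior Monte Carlo.** The predictive-density criterion nLPD, the
   expectation term of $k_{\text{WAIC}_1}$ and $k_{\text{DIC}_2} = 2\,
   \mathrm{var}_{\text{post}}[\log \Pr(\mathbf{N}\mid\mathbf{p})]$ are
   checked against large Dirichlet-sampling estimates within three Monte
   Carlo standard errors.
3. **Exact small cases.** The two-game worked example is asserted to
   rational-arithmetic precision, and beta functions against factorial
   identities.

## Simulation studies and the problem sizes used

The package reruns the method-evaluation studies at desk scale, chosen to
keep the default test suite in the minutes range while leaving Monte Carlo
noise well below the effects asserted:

* power analysis of the free-throw null (91 games, mean 7.6 attempts, iid
  0.68): 1000 replicate seasons, candidates $h \in \{0,1,2,3\}$;
* selection frequencies on the eight-state network
  ($h_{\text{true}} = 1$, $J = 4$): 2000 replicates on one fixed network
  plus 200 per network across ten networks for the dispersion report;
* sample-size trends at $M = 4$: 300 replicates per
  $(h_{\text{true}}, J)$ cell over $J \in \{4, 16, 64\}$, and 2000
  replicates for the $h_{\text{true}} = 2$, $J = 64$ check that no
  predictive criterion selects $h = 1$;
* experiment drivers default to 2000 replicates, with the count exposed as
  an argument for larger runs.

`selection_experiment()`'s default `fixed_network` mode draws one network
and resamples trajectory sets from it, so the randomness studied is purely
sampling variation around one fixed truth; `fresh_network` redraws the
network each replicate and yields wider frequency dispersion — useful for
sensitivity analysis.

## Known limitations

* No automated search over variable-length partitions; candidates are
  user-supplied.
* No AICc (its exact form is problem-specific), no model-averaging weights,
  no hidden-Markov or importance-sampling machinery.
* Selection frequencies at small $J$ depend materially on the particular
  random network drawn; single-network results should be read together with
  the across-network dispersion.
* On the four-state system the closed-form marginal likelihood behaves as a
  consistent selector in our experiments (its overfit tail is, if
  anything, smaller than LOO's); a complexity bias of Bayes-factor
  selection relative to LOO is visible in our runs only as non-strict
  inequality on the eight-state system. The test suite asserts the
  direction of the comparison where it holds robustly.
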