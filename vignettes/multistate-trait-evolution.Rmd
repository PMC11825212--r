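---
title: "Bayesian multistate trait evolution with reversible-jump rate classes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian multistate trait evolution with reversible-jump rate classes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rjmk)
```

## The scientific problem

Myiasis — the infestation of living vertebrates by fly larvae — has evolved
within blowflies (Calliphoridae) alongside two related larval life-history
axes: the food substrate larvae exploit and the thermal regime they develop
in. Each axis is coded as a three-state categorical character:

* **trophic specialization**: obligatory parasite / saprophagous /
  facultative parasite;
* **larval food substrate**: necrotic / fresh / both;
* **developmental temperature**: constant / variable / both.

"Both" is a genuine third state with its own transition rates, not an
ambiguity code; only the `NA` token denotes missing information, and a
missing tip enters the likelihood as a fully ambiguous observation (an
all-ones tip vector). The package ships a 61-species trait table and a
species/accession metadata table; the time-calibrated phylogeny those
species were originally analysed on cannot be rebuilt without sequence
data, so the bundled tree (`blowfly_tree_synthetic()`) is a clearly
labelled synthetic Yule stand-in over the same taxa.

Two questions drive the analysis. First, do evolutionary transitions to the
derived, parasitism-associated state pass through an intermediate
("stepping-stone") state rather than happening directly? Second, which
state did the blowfly common ancestor most likely occupy?

## The model

Each trait evolves independently along the fixed rooted tree under a
3-state continuous-time Markov (Mk) model with generator $Q$, whose six
off-diagonal entries $q_{ij} \ge 0$ are the instantaneous rates from state
$i$ to state $j$ (0-based indices; $q_{01}, q_{02}, q_{10}, q_{12}, q_{20},
q_{21}$ in fixed order). Branch transition probabilities are
$P(t) = e^{Qt}$, and the likelihood of the tip data is computed by
Felsenstein's pruning algorithm with per-node rescaling. The root state
carries a prior $\pi$, uniform by default (configurable to the stationary
distribution of $Q$; the choice is recorded in run metadata). Marginal
ancestral-state probabilities at internal nodes come from the standard
two-pass (outside–inside) algorithm; the root marginal is
$\pi_s L_{\mathrm{root}}(s) / \sum_{s'} \pi_{s'} L_{\mathrm{root}}(s')$.

### Reversible-jump model space

Rather than fixing six free rates, the sampler averages over *rate-class
partitions*: assignments of the six rate labels into classes that share a
single positive value, optionally with one distinguished *zero class* whose
rates are exactly zero. With the zero class enabled the model space has
$B(7) = 877$ members (partitions of the six labels plus a phantom element
marking the zero block); without it, $B(6) = 203$. Every model receives
equal prior probability. Class values follow a gamma prior whose mean and
shape each carry a uniform hyperprior; by default the mean bounds span the
maximum-likelihood mean rate by a factor of ten either side
(`elicit_priors()`), and the shape bounds are $[0.5, 20]$.

The sampler mixes five move types (defaults 60/15/15/5/5%):

* **rate-scale** — multiply one class value by $e^{\delta(u - 1/2)}$; the
  log-Jacobian $\log m$ enters the Hastings ratio; $\delta$ is auto-tuned
  during burn-in only, toward roughly 30% acceptance;
* **split** — bipartition one class uniformly; the sub-block holding the
  smallest label keeps the value, the other draws a fresh value from the
  gamma prior at the current hyperparameters;
* **merge** — fuse a uniformly chosen pair of classes (merging with the
  zero block zeroes the merged labels);
* **zero-swap** — move a whole class into an empty zero block, or restore
  the zero block as one fresh-valued class;
* **hyperparameter** — random walks on the gamma mean and shape plus an
  independence redraw from the uniform hyperprior (the redraw is what keeps
  the hyperparameters mixing across their full range).

All proposal densities enter the Hastings ratios, so with a flat likelihood
the chain samples the prior exactly — the test suite verifies both the
uniform-over-models partition frequencies (chi-square) and the
gamma-under-hyperprior rate marginal (Kolmogorov–Smirnov) on a no-data run.

### Chain schedule

The production-scale schedule this mirrors is 110 million iterations,
sampling every 1000 with the first 10 million discarded. Desk-scale
defaults (`mcmc_config()`) are 1.1 million iterations, sampling every 100,
10% burn-in; tests and the acceptance script scale further down and say so.
Runs are bit-deterministic given the seed (all randomness flows through R's
RNG; the compiled kernel is deterministic floating point).

## The hypothesis tests

Both tests are *posterior-proportion* Bayes factors,
$$\mathrm{BF}_{ij} = \frac{P(M_i \mid D)}{P(M_j \mid D)} \cdot
  \frac{P(M_j)}{P(M_i)},$$
not marginal-likelihood ratios. Support is classified as positive for
$3 \le \mathrm{BF} \le 12$ and strong above 12.

**Pathway (stepping-stone) test.** For origin $i$, intermediate $j$,
terminal $k$: per posterior sample the six rates are normalized (default:
divided by their arithmetic mean, so a typical rate is 1 and a product of
two normalized rates is comparable with a single one; geometric-mean and
sum-to-one alternatives are selectable and recorded). $M_i$ holds when
$q'_{ik} < q'_{ij} \, q'_{jk}$; ties — including $0$ vs $0$ — count to
$M_j$, and samples with all six rates zero are excluded and logged. The
prior $P(M_i)$ has no closed form: it is estimated by drawing a model
uniformly from the exactly counted space (Stirling/Bell numbers), drawing
class values from the gamma-under-hyperprior, normalizing, and evaluating
the same inequality; the Monte-Carlo standard error is reported. The
defaults test saprophagous → facultative → obligatory,
necrotic → both → fresh, and variable → both → constant.

**Ancestral-dominance test.** $M_i$ holds in a sample when the focal-node
probability of the focal state exceeds the combined probability of the
other two, i.e. exceeds $1/2$; dominance is evaluated per sample, not on
the posterior-mean probabilities (both are computable; the per-sample form
is the default and the one reported). The prior is exact: under a uniform
distribution on the probability simplex, the dominance region is a
half-scaled sub-simplex, so $P(M_i) = (1/2)^{K-1} = 1/4$ for three states.

## Synthetic data: what it emulates and what it does not

`simulate_study()` generates Yule (pure-birth) trees — rescaled to unit
height so rate magnitudes are comparable across runs — and evolves tip
states by exact CTMC simulation (exponential waiting times). Missingness
is injected uniformly at an exact floor fraction. Defaults mirror the
bundled dataset: 61 tips and a 15% missing fraction per trait (the real
table is missing 13–16% per trait). A coupling mode reproduces the
observed cross-trait association (obligatory↔fresh↔constant,
saprophagous↔necrotic↔variable, facultative↔both↔both) with a configurable
flip probability (default 5%).

What a green test on synthetic data establishes: the likelihood is exact
(checked against brute-force enumeration), the sampler targets its prior
and recovers planted rates with calibrated intervals, and the pathway test
separates planted stepping-stone dynamics from equal-rates null data. What
it does not establish: anything about the true blowfly phylogeny or the
published ancestral estimates — the bundled tree is a synthetic stand-in,
and on it the traits genuinely carry little phylogenetic signal, so
maximum-likelihood rates saturate and ancestral probabilities sit near the
stationary distribution. That behaviour is correct, and it is why the
published quantities are not reproduction targets here.

## Numerical choices

* Matrix exponentials use scaling-and-squaring (order-12 Taylor core with
  the scaled norm below 1/4 for the 3×3 fast path; Armadillo's Padé
  implementation otherwise). Equal-rates transition probabilities match the
  closed form $1/3 + (2/3)e^{-3qt}$ to $10^{-10}$.
* Pruning renormalizes conditional likelihoods at internal nodes and
  accumulates the factors in log space; zero branch lengths are allowed
  (identity transition).
* ML rate estimation is box-constrained L-BFGS-B on log-rates with 10
  seeded restarts; bounds default to $[10^{-8}, 100/\bar t]$ with $\bar t$
  the mean branch length. For constant characters the likelihood surface
  has absorbing-state ridges: rates out of the observed state hit the lower
  bound while rates into it are unidentifiable and may run high — this is a
  property of the model, not an optimizer failure.
* Ultrametricity is validated with tolerance $10^{-6} \times$ tree height
  and violations warn rather than stop: the likelihood is defined for any
  branch lengths, and time-calibrated trees often carry numerical slack.
* Species names are matched exactly after trimming and collapsing internal
  whitespace/underscores; no fuzzy matching, because silent mismatches
  corrupt likelihoods. Outgroup tips may be absent from the trait table and
  are either pruned (default; the root becomes the ingroup MRCA) or
  retained as all-missing.

## Worked example

A small simulated study with a planted stepping-stone process
(direct rate zero), analysed end to end:

```{r example, eval = FALSE}
planted <- build_generator(c(q01 = 0.5, q02 = 0.5, q10 = 0,
                             q12 = 2, q20 = 2, q21 = 0.5))
tree <- simulate_yule_tree(150, seed = 9001)
states <- simulate_trait(tree, planted, root_state = 1, seed = 9101)
def <- trait_definition("trophic",
                        c("obligatory parasite", "saprophagous",
                          "facultative parasite"))
tipvec <- t(vapply(def$states[states + 1], tip_likelihood_vector,
                   numeric(3), def = def))
rownames(tipvec) <- names(states)

priors <- elicit_priors(tree, tipvec, seed = 1)
cfg <- mcmc_config(iterations = 8000, sample_interval = 10,
                   burn_in = 2000, seed = 9201)
chain <- run_chain(tree, tipvec, priors, cfg)

h <- pathway_hypothesis(1, 2, 0)     # saprophagous -> facultative -> obligatory
post <- pathway_posterior_proportion(chain, h)
prior <- pathway_prior(h, priors, n_draws = 1e4, seed = 1)
bayes_factor(post$p_Mi_given_D, post$p_Mj_given_D, prior$p_Mi, prior$p_Mj)
```

On this planted dataset the test reports a Bayes factor of 7.0 — positive
support for the stepping-stone pathway — while equal-rates null data keep
the Bayes factor below 3 (the calibration suite repeats this over 20
replicates each way).

## Open design choices made here

* The root prior in the original analyses is unstated; uniform is the
  default and the stationary-distribution alternative is a parameter, with
  the choice recorded in output metadata.
* Exact hyperprior bounds are unstated beyond "ML-guided uniform"; the
  default spans the ML mean tenfold either way.
* Whether the zero class was active in the original runs is unknown; it is
  on by default and toggleable, and the model-space count (877 vs 203) is
  computed, never hard-coded.
* How set-partition counts alone could fix the pathway prior is
  under-determined (counts carry no rate-value distribution), so the prior
  is realized as exact model counting plus Monte-Carlo over values, with
  its standard error reported.

## Known limitations

* Traits are analysed independently; no correlated-trait (dependent) model.
* No covarion or hidden-state extensions; no Metropolis-coupled chains; no
  marginal-likelihood (stepping-stone/harmonic-mean) Bayes factors.
* The R-level chain loop targets desk-scale schedules; production-length
  runs (hundreds of millions of iterations) would want a compiled loop.
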