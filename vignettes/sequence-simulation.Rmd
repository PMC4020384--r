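---
title: "Simulating sequence evolution along time-calibrated phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating sequence evolution along time-calibrated phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evosim)
```

## The simulation model

`evosim` simulates discrete characters down a rooted tree under a
continuous-time Markov chain (CTMC).  The procedure is a pre-order
traversal: the root sequence is drawn site-by-site from the model's
equilibrium frequencies (or supplied explicitly), and each child node's
state at a site is sampled from the row of the branch transition matrix
indexed by the parent's state.  For a branch of duration $t$, clock
multiplier $r$ and site rate $s$, the transition matrix is
$P = \exp(Q\,r\,s\,t)$.

Three assumptions are worth keeping in mind:

* **Site independence.**  Sites evolve independently given their rate
  category; there is no context dependence and no indel process —
  alignments are simulated already aligned, and gaps arise only from
  taxa missing in a partition.
* **Homogeneity within an epoch.**  The process is time-homogeneous
  except where an epoch model explicitly changes $Q$ at fixed heights.
* **Stationarity at the root.**  Unless a root sequence is supplied,
  the chain starts at equilibrium (for epoch models: the equilibrium of
  the *oldest* epoch, since that is the regime the root lives in), so a
  single long branch leaves the state distribution unchanged — one of
  the properties the test suite checks.

### Normalization and what "distance" means

Every generator is rescaled at build time so that
$-\sum_i \pi_i Q_{ii} = 1$, with $\pi$ the frequencies used to build the
model.  One unit of branch distance therefore equals one expected
substitution per site, and the molecular clock alone converts calendar
time into substitutions.  The site-rate mixture is likewise renormalized
to mean rate 1 (see below), so neither rate heterogeneity nor the choice
of substitution model silently rescales time.

## Tunable parameters

| Parameter | Units / range | Default | Why |
|---|---|---|---|
| `kappa` (HKY/TN93/GY94) | rate ratio, $>0$ | — (`2` in the CLI) | transition/transversion bias; 2 is a typical empirical value |
| `omega` (GY94) | dN/dS, $\ge 0$ | — | $\omega \ll 1$ = purifying selection |
| `alpha` (gamma shape) | $>0$ | off | smaller = more rate heterogeneity |
| `categories` | integer $\ge 1$ | 4 | the field-standard discretization size |
| `p_inv` | $[0,1)$ | 0 | proportion of invariant sites |
| clock `rate` | subst/site/time unit | 1 | keeps substitution-unit trees unchanged |
| clock `mean`, `stdev` | real-space mean/spread | 1, 0 | relaxed clocks collapse to strict at `stdev = 0` |
| `theta` | $N_e \tau$, tree time units | — | pairwise coalescent time for two contemporaneous lineages |
| `growth` | per time unit | 0 | $N(h) = \theta e^{-g h}$ looking back in time |

The discrete-gamma categories use the mean of the
$\mathrm{Gamma}(\alpha,\alpha)$ distribution within each equal-probability
quantile bin (the "mean" method), matching the discretization used by
the major Bayesian phylogenetics tools, rather than the median method.
With invariant sites, the gamma rates are divided by $1 - p_{inv}$ so
that the full mixture keeps mean 1.

The lognormal relaxed clock is parameterized by its *real-space* mean
$M$ (log-rate $\sim N(\log M - S^2/2,\, S)$), so that $M$ multiplies
branch lengths interpretably; the inverse-Gaussian clock maps
(mean, stdev) to $(\mu, \lambda = \mu^3/\sigma^2)$.  Both are stated
explicitly because "lognormal with mean M" is ambiguous between real
and log space and the two conventions differ by a factor $e^{S^2/2}$.

## Epoch models and the normalization question

An epoch model assigns a substitution specification to each interval of
a strictly increasing boundary sequence $h_1 < \dots < h_m$ (heights,
i.e. time before the youngest tip).  A branch crossing boundaries is cut
into segments and its transition matrix is the *chronological* product
of segment exponentials, oldest factor leftmost — the composition is
checked in the tests to be invariant under splitting a segment at any
interior height, and order-sensitive for non-commuting generators.

Two normalization conventions are implemented, chosen by
`epoch_model(..., normalize =)`:

* **`"each"` (default).**  Every epoch's generator is normalized to one
  expected substitution per distance unit.  The clock rate then applies
  unchanged in all epochs and only the *character* of substitution
  varies through time.  For a GY94 schedule with $\omega$ decreasing
  into the past this means: the total substitution rate stays constant,
  synonymous changes saturate at depth, and the amino-acid-changing
  fraction of the flux decays with $\omega$ — a process with constant
  overall rate but increasingly invisible deep history.  This is also
  how epoch models behave in frameworks that normalize each constituent
  substitution model independently, which is why it is the default.
* **`"first"`.**  Only the youngest epoch is normalized; older epochs
  reuse its scaling constant.  Here a falling $\omega$ also lowers the
  realized overall rate back in time (the clock is anchored to the
  youngest regime).  This convention makes the *total* rate decline,
  not just the nonsynonymous share.

The difference is not cosmetic.  In the bundled epoch study
(`run_epoch_study()`), `"each"` produces roughly 2.5–3× more amino-acid
divergence than `"first"` at the same tree depth, because under
`"first"` the deep epochs are slowed down wholesale.  We take `"each"`
as the default on the grounds above; users exploring rate-decline
scenarios can flip the switch.

## The coalescent generator: what it emulates, and what it does not

`simulate_genealogy()` implements the standard serial-sample coalescent:
lineages become active at their sampling heights, and among $k$ active
lineages coalescence is proposed at the intensity
$k(k-1)/(2N(h))$; a proposal overshooting the next sampling height is
discarded and the wait restarts there.  Ties in sampling heights are
activated in one batch — order within a batch is irrelevant by
exchangeability.  Constant size and exponential growth
($N(h) = \theta e^{-gh}$, closed-form inversion of the integrated
intensity) are supported; for $g < 0$ the cumulative intensity is
bounded and a lineage pair may never coalesce, which is reported as an
error rather than silently truncated.

The bundled epoch study (`epoch_study_config()` /
`run_epoch_study()`) emulates a rapidly evolving RNA virus sampled over
a 25-year window: 50 taxa with evenly spaced sampling times, constant
population size, 300–500 codons, a strict clock of $3\times10^{-3}$
codon substitutions/site/year, and a GY94 epoch schedule
$\omega = 1.0, 0.2, 0.1, 0.02, 0.01, 0.002, 0.001$ switching at heights
$10, 50, 100, 500, 1000, 5000$ years — purifying selection strengthening
log-linearly into the past.  $\kappa$ is set to 2 (a typical empirical
transition bias; the scenario is not sensitive enough to $\kappa$ for
this to matter qualitatively) and codon frequencies are uniform over the
61 sense codons.  The default of 500 codons trades Monte Carlo noise
against runtime; the acceptance script uses 300 codons and 20
replicates, which keeps the replicate-mean's standard error near 0.01.

What the generator does *not* emulate: recombination (approximable only
by giving partitions different trees), rate variation among lineages
beyond i.i.d. branch scalers, selection on synonymous sites, indels,
and non-equilibrium base composition.  Passing tests therefore show the
simulator agrees with its own generative model — they say nothing about
whether that model fits any particular real data set.

### Conditioning on tree depth

To study divergence at a fixed age of the most recent common ancestor,
replicate genealogies are *rescaled* to the target root height
(`condition_root_height`) rather than obtained by rejection sampling.
Conditional on tree shape the two give identically distributed distance
statistics, and rescaling is faster by orders of magnitude — a root
height of 10,000 years under $\theta = 1000$ is a several-sigma tail
event one would wait a long time to reject-sample.  The realized
pre-scaling root height is kept in the output table (`tmrca_sim`)
alongside the conditioned one (`tmrca`).

A caveat worth recording: with every epoch convention we implemented,
the replicate-mean amino-acid p-distance at root height 10,000 under
the default schedule comes out near 0.27 (`"each"`; `"first"` gives
about 0.10) — run `scripts/acceptance.R` to recompute it.  Even the
upper bound, obtained by forcing every tip pair to coalesce exactly at
the root, is about 0.42 under uniform codon frequencies and
$\kappa = 2$: an exact calculation from the epoch transition matrices,
against which the simulator agrees to three decimals (2-, 3- and
50-taxon checks).  Mean divergence in this regime is thus intrinsically
capped well below saturation (~0.93), and the commonly quoted "about
one half" for such scenarios is only reachable with different unstated
constants (e.g. empirical codon frequencies or a corrected rather than
proportional distance).

## Numerical choices

* **Matrix exponentials.**  Reversible generators (HKY, TN93, GTR,
  GY94, MG94, empirical amino-acid models) are exponentiated through
  the symmetrized eigen-decomposition
  $\Pi^{1/2} Q \Pi^{-1/2}$, which has a guaranteed real spectrum; the
  decomposition is computed once per model and reused for every branch
  and rate category.  General (possibly non-reversible or defective)
  generators, and any build with a zero equilibrium frequency, use the
  dense scaling-and-squaring exponential from the Matrix package.
  Rows of every transition matrix are clipped to $[0,1]$ and
  renormalized; the tests hold Chapman–Kolmogorov to $10^{-8}$ and
  detailed balance to $10^{-10}$.
* **Height/length consistency.**  Node heights are recomputed from
  branch lengths so the youngest tip sits at height 0; user-supplied
  tip dates are cross-checked against path lengths and a discrepancy
  beyond $10^{-6}$ is an error, never a silent rescale.  The
  `timetree` constructor enforces parent–child height differences equal
  to branch lengths within $10^{-6}$.
* **Degenerate inputs.**  Zero-length branches copy the parent sequence
  (`P(0) = I`); invariant sites skip the transition machinery entirely;
  multifurcating parsed trees are simulated as-is (the pre-order
  recursion never needs binarity), while the coalescent always emits
  binary trees; all-zero rows in a general rate table and frequency
  vectors that do not sum to one are rejected at construction.
* **Goodness of fit.**  The validation harness pools χ² classes with
  expected count below 5 (the classical rule) into a single class;
  degrees of freedom are classes − 1.  The 3-taxon validation fixture
  `((A:0.3,B:0.3):0.2,C:0.5)` with HKY $\kappa=4$, $\Gamma_4$
  $\alpha=0.5$ is a package choice of convenient size, not an estimate
  from data.
* **Seeding.**  `simulate_alignment(seed =)` derives per-partition
  seeds by a fixed counter scheme, so adding a partition never perturbs
  the realizations of earlier ones, and identical seeds give
  byte-identical output files.  Site-rate categories are re-drawn on
  every simulate call (they are part of the stochastic model, not of
  the partition definition).

## Known limitations

* No indels, no context-dependent substitution, no covarion/site-switch
  processes.
* Epoch boundaries apply to substitution models only; clocks and state
  spaces cannot change across epochs (periodic processes can be encoded
  manually with repeated boundaries).
* The pruning validator enumerates complete pattern spaces and is
  therefore practical only for few tips (the default cap is $10^6$
  patterns).
* Likelihood computation is provided for validation, not inference: no
  optimization or sampling machinery is included.
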