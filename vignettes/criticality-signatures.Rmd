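---
title: "Testing signatures of criticality: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing signatures of criticality: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(critsig)
```

## The scientific question

Living neural networks produce *neuronal avalanches* — contiguous runs of
time bins with nonzero population activity, bracketed by silent bins —
whose size and duration distributions often follow power laws. The
criticality hypothesis reads this as evidence that the network sits near
a phase transition between damped and amplified activity propagation,
where information processing is optimal. The standing objection is that
power laws are cheap: a reflected random walk, or an Ornstein–Uhlenbeck
(OU) process passed through a threshold, reproduces power laws, the
exponent relation, and even avalanche shape collapse with no interacting
units at all.

`critsig` implements both sides of that argument as testable code:

* the full statistical battery — truncated power-law fits with model
  comparison, the crackling-noise exponent relation
  $(\alpha-1)/(\tau-1)=\gamma$, avalanche shape collapse, windowed-STD
  Hurst exponents, the naive branching ratio
  $\sigma = \langle A_{t+1}/A_t \rangle$, and stimulus–response mutual
  information;
* the null models that fake the signatures (reflected coin flips,
  thresholded OU walks);
* a sparse excitatory/inhibitory integrate-and-fire network in which the
  signatures are *emergent*, i.e. destroyed by cutting connections; and
* the decision flow that separates the two cases (`classify_system()`).

## Avalanche conventions

An avalanche's heights are the per-bin population counts; its size $S$ is
their sum and its duration $T$ the number of bins. Runs touching the
first or last bin of a raster are discarded because bracketing cannot be
verified there. For walk excursions we follow the flip-count convention:
the six-flip run H,H,H,T,T,T has heights $1,2,3,2,1,0$, duration 6
(the step returning to the origin is counted) and size 9. The raster
route necessarily sees only the positive bins, so its durations are
smaller by exactly one; sizes agree. Duration-1 avalanches enter the
distributions but not shape collapse (a one-point profile carries no
shape).

Reflection of the coin-flip walk is implemented as the absolute value of
the cumulative sum, which is equal in distribution to flipping each
negative excursion.

## Power-law fitting

`fit_power_law()` follows the standard discrete maximum-likelihood
recipe: the exponent maximises the truncated discrete likelihood on
$[x_{\min}, x_{\max}]$ (normalised by Hurwitz-zeta differences); when
$x_{\min}$ is not given it is selected by minimising the
Kolmogorov–Smirnov distance over candidate values (capped at 50,
quantile-spaced, each leaving at least 100 tail samples). Goodness of
fit is a semi-parametric bootstrap of the KS statistic (default 200
replicates; the replicate repeats whatever selection the original fit
used). Alternatives — a discrete exponential and a discretised
lognormal — are compared by Vuong-style normalised log-likelihood
ratios. Both CDFs in the KS distance are integer step functions, so the
distance is evaluated at the observed atoms and just below the next
atom; a recovery test demands the true exponent of exact synthetic data
back within $\pm 0.02$ at $n = 10^6$, and geometric data must be
rejected.

The size–duration scaling exponent $\gamma$ is the log–log slope of mean
size per duration class. Classes with fewer than 5 avalanches are
excluded as noise, and durations below 8 are excluded as lattice-bound:
a two-step excursion has mean size exactly 1, and a four-step one
exactly 4, both far off the $cT^{3/2}$ asymptote, so including them
biases the slope upward regardless of sample size.

## Shape collapse

Mean height profiles per duration are interpolated onto a common
50-point grid on $[0,1]$ and divided by $T^{\gamma-1}$; the collapse
error is the across-duration variance averaged over the grid, divided by
the squared mean rescaled height (so it is invariant to uniform scaling
of all shapes). When $\gamma$ is free it is chosen over the grid 1.00 to
2.50 in steps of 0.01. An exactly self-similar parabola family collapses
to numerical noise; the counter-example is a family of tent shapes with
equal peaks whose rise completes at a fixed absolute time, so no single
exponent can align them — the coin-flip shapes at $\gamma = 1.5$ beat it
by well over an order of magnitude.

## Hurst exponents

`hurst_exponent()` partitions the series into disjoint windows for a
geometric ladder of lengths (default powers of two from 8 to $n/8$),
averages the within-window standard deviations, and fits the log–log
slope, following $STD(Lt) = L^H STD(t)$. A memoryless walk gives
$H \approx 0.5$; the worked two-point check (STDs 70.26 and 202.13 a
factor 8 apart) gives $H \approx 0.51$. One caution we document from our
own tests: a *Markov* persistent walk (each step repeats the last with
probability $p$) is diffusive beyond its few-step persistence length, so
its $H$ separates from 0.5 only when the ladder probes crossover windows
($L \le 32$); genuinely long-range-correlated processes separate at all
scales.

## The spiking network

The network is the classic sparse cortical model: $N$ leaky
integrate-and-fire neurons, 80% excitatory, fixed in-degree
$K = 0.1 N$ drawn uniformly without self-connections, inhibitory
efficacy $-g J$, synaptic delay of one 1.8 ms bin, membrane time
constant 20 ms, threshold 20 mV above rest, reset 10 mV, refractory one
bin. The relative inhibition $g$ is the control parameter; the firing
rate is the order parameter. Stimulation forces randomly chosen neurons
to spike; background drive is either independent Bernoulli spontaneous
firing per neuron ($P_s$) or a shared rectified coin-flip drive feeding
$N_d$ designated neurons at `round(3 * height)` forced spikes per bin.

Two deliberate choices matter, because this model family's constants
are implementation-defined once the continuous background drive is
switched off:

* **Initial membranes.** Potentials start uniformly below threshold,
  the residue of background drive before it is switched off. A volley
  delivering $\mu$ mV then recruits a fraction $\mu/\theta$ of its
  targets, so a pulse of $A$ spikes produces on average $\sigma A$
  descendants with
  $\sigma(g) = (JK/\theta)\,(0.8 - 0.2\,g)$ — graded propagation
  instead of an all-or-none threshold response. The uniform spread
  decays with the membrane leak, so propagation is transiently critical;
  stimuli are therefore delivered early in each trial, and experiments
  are organised as many short trials.
* **Efficacy.** The default fixes $J K = 5\theta$ (1 mV at the
  reference in-degree $K = 100$), which places $\sigma = 1$ exactly at
  $g = 3$ and keeps the transition from drifting with network size or
  density. Measured on $N = 1000$ networks, the firing-rate transition
  and the peak of the post-stimulus decay constant both sit at
  $g = 3.0 \pm 0.25$. Sparse-network caveat: inhibition is partially
  rectified away for small volleys (most targets receive zero or one
  synapse), so the effective critical $g$ of *small* cascades sits
  slightly higher (~3.5); the connectivity-ablation experiment collects
  its evoked cascades there.

The decay constant is fitted as $c + A e^{bt}$ (nonlinear least squares
with a non-negative baseline, bins 3–40 after the stimulus); the
baseline lets the same form capture decays to silence and fast rises
onto a saturation plateau, both of which have short time constants,
while near the transition activity decays slowly and $\tau = 1/|b|$
peaks sharply. A pure log-linear exponential would instead assign huge
time constants to the flat saturated phase.

## Information metrics

The stimulus protocol uses eight pulse magnitudes $0, N/8, \dots, 7N/8$
(3 bits of input entropy), 30 trials per level, response = mean
population count over bins 3–5 after the stimulus. Responses are
discretised into 8 equal-width bins over their observed range, and all
entropies are plug-in estimates in bits; the plug-in bias shrinks with
trial count and is bounded by design through the 8-bin ceiling. Two
consequences of the observed-range binning worth knowing: it makes
$H(R)$ invariant to uniform compression of the responses (so strong
uncorrelated noise lowers mutual information long before it lowers
$H(R)$), and it can award high $H(R)$ to a network whose responses vary
over a narrow absolute range. With correlated drive, trials are
presented in randomised level order, because the drive walk drifts
slowly and a level-ordered schedule would confound drive height with
stimulus level.

## Desk-scale experiments and their honest limits

The packaged experiment drivers default to sizes that run in minutes on
one CPU: $N = 1000$ networks, control-parameter grids of 9–17 points on
$[2, 4]$, 3–5 topologies × 15–30 trials. The full-scale protocols (93
grid points, $N = 8000$, five models × 30 trials per size up to
$N = 2000$ with an exponential finite-size fit of the peak location,
`sweep_mi()`'s `asymptote`) are the same code with larger arguments.

At desk scale, two results are weaker than their large-scale
counterparts, and we report them as such rather than smoothing them
over:

* The mutual-information peak sits ~0.5 below the decay-constant peak
  in $g$. The refractory ceiling ($\approx N/2$ active per bin)
  compresses the upper stimulus levels exactly at criticality, and
  critical avalanche fluctuations inflate $H(R|S)$, both favouring the
  slightly amplified side; the displacement shrinks only slowly with
  $N$.
* With every neuron driven by the coin-flip process, the drive accounts
  for essentially all of the response entropy at the $H(R)$ peak
  (~95–105% by the disconnected/connected ratio, versus a ~90/10 split
  at larger recurrent strength): with $JK = 5\theta$, recurrence
  contributes little response entropy beyond the drive at $N = 1000$.

What passing tests show, and what they do not: the synthetic sources
emulate sparse random connectivity, pulse stimulation and rectified
random drives, but not conductance dynamics, plasticity, topography, or
empirical binning of continuous spike times; agreement here supports the
logic of the discrimination battery, not any claim about a particular
biological dataset.

## Numerical details

* All stochastic operations take explicit seeds; equal seeds give
  bit-identical output (the compiled cores draw from R's RNG).
* Seeds split hierarchically: topology seeds are reused across the $g$
  grid and across densities so ablations compare identical wiring.
* `walk_to_raster()` rounds `gain * height` half away from zero and
  clips at `n_neurons` with a warning.
* OU increments are Gaussian (`x <- x - eta*x + (1-eta)*noise`); the
  coin-flip drive provides the ±1 alternative. `eta` defaults to 0.001,
  keeping the process walk-like on avalanche timescales.
* Degenerate inputs raise typed conditions (`critsig_insufficient_data`,
  `critsig_invalid_parameter`, ...) rather than returning silent NAs.

## A worked discrimination

```{r flow, eval = FALSE}
# A reflected fair coin flip passes the avalanche battery...
avs <- coin_flip_avalanches(1e8, seed = 1)
glance(fit_power_law(avs$size, n_boot = 0))    # tau  ~ 1.33
glance(fit_power_law(avs$duration, n_boot = 0)) # alpha ~ 1.49
glance(size_duration_scaling(avs))              # gamma ~ 1.51
# ...but has no temporal memory and, being a single driven variable,
# loses its signatures when the randomness source is blocked:
hurst_exponent(coin_flip_walk(2^20, reflect = FALSE, seed = 1))$H # ~0.5
classify_system(beyond_power_laws = TRUE, survives_noise_block = FALSE,
                survives_connection_cut = FALSE)  # low_dimensional_driven

# The connected network keeps its signatures under drive but loses them
# when connections are cut:
classify_system(TRUE, TRUE, FALSE)                # emergent_critical
```
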