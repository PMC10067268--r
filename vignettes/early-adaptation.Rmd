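---
title: "Early adaptation on rugged fitness landscapes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Early adaptation on rugged fitness landscapes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakwalk)
```

## The question

A microbial population adapting after an environmental change does not, in
general, climb to the global fitness optimum. On a rugged fitness landscape —
one with several local maxima, produced by epistasis — the population gets
stuck at the *first peak it reaches*, because in the weak-mutation regime
every neighbour of a peak is less fit and deleterious mutations fix ever more
rarely as the population grows. `peakwalk` quantifies this first stage of
adaptation: the fitness $\bar h$ of the first peak encountered, how it depends
on the population size $N$, and which structural features of a landscape
predict that dependence.

## Model

**Genotypes and landscapes.** A genotype is a string of $L$ binary sites
(loci, nucleotides or amino acids); genotype space is the $L$-dimensional
hypercube, each genotype having $L$ single-substitution neighbours. A fitness
landscape assigns a strictly positive fitness $f(\sigma)$ (a division rate) to
each of the $2^L$ genotypes. A *peak* is a genotype strictly fitter than all
its neighbours; a genotype with an equal-fitness neighbour is deliberately
*not* a peak, which keeps "first peak hit" well defined (ties have measure
zero in all continuous-valued models, and can only arise in the neutral LKp
variant or a noise-free Eggbox).

**Origin-fixation walks.** In the weak-mutation regime ($N\mu \ll 1$) the
population is monomorphic: each mutation either fixes or is lost before the
next arises, so evolution is a jump chain on the hypercube. Mutations are
proposed uniformly over the $L$ sites, and a proposal from genotype $i$ to
neighbour $j$ with selection coefficient $s_{ij} = f_j/f_i - 1$ fixes with
probability

$$
P^{\mathrm{Moran}}_{ij} = \frac{1 - (1+s_{ij})^{-1}}{1 - (1+s_{ij})^{-N}},
\qquad
P^{\mathrm{WF}}_{ij} = \frac{1 - e^{-2 s_{ij}}}{1 - e^{-2 N s_{ij}}},
$$

with the neutral limit $1/N$ at $s_{ij}=0$. The Wright–Fisher form is the
diffusion approximation and is used, as is conventional, at all $N$ and $s$.
At $N = 1$ both reduce to the pure random walk (every mutation fixes); as
$N \to \infty$ both converge to *adaptive walks* that accept only beneficial
mutations — the natural AW (transition probability $\propto \max(s_{ij}, 0)$),
with the greedy AW (always the fittest neighbour) and random AW (uniform over
fitter neighbours) as companion limits. Numerically the fixation formulas are
evaluated with `log1p()`/`expm1()`; raw powers $(1+s)^{-N}$ overflow already
around $N \sim 10^4$. Selection coefficients below $10^{-12}$ in magnitude are
treated as neutral, and deleterious probabilities that underflow double
precision are returned as exact zeros.

**First-step analysis (FSA).** Conditioning on the first hop of the embedded
chain $\tilde P_{il} = P_{il} / \sum_q P_{iq}$ gives a linear system for the
probability $x_{ij}$ that a walk from $i$ hits peak $j$ before any other
peak, with boundary values 1 at $j$ and 0 at other peaks. We solve one system
of size $2^L - n_M$ with one right-hand side per peak (or a single combined
right-hand side when only $\bar h_i = \sum_j f_j x_{ij}$ is needed) rather
than the literal joint $2^L n_M$ system — mathematically identical, smaller
and better conditioned. The non-peak sub-chain is strictly substochastic, so
the solution is unique. Dense LU is used for small landscapes and a sparse
(Matrix) solve above $2^{11}$ genotypes; FSA is refused beyond
`options(peakwalk.fsa_max_L = 14)` with a pointer to Monte Carlo simulation,
because the solve grows exponentially in $L$.

From the hitting table: $\bar h_i$, its start-uniform average $\bar h$, the
standard deviation $\sigma_h$ over start and walk randomness (from first and
second moments of peak fitness), the mean number of fixations $\bar\ell$, and
the mean number of mutation events $\bar t$. For $\bar t$, each accepted step
from $i$ contributes a geometric number of proposals with success probability
$\frac{1}{L}\sum_q P_{iq}$, giving the source term $L / \sum_q P_{iq}$ in the
first-step equations; at $N = 1$, $\bar t = \bar\ell$ exactly, which the test
suite asserts. Since mutations arrive at a rate proportional to $N$, physical
time scales as $\bar t / N$.

**Steady state.** The non-absorbing per-mutation-event chain (transitions
$P_{ij}/L$, self-loop otherwise) has a unique stationary distribution. For
the Moran walk the chain is exactly reversible and telescoping
$P_{ij}/P_{ji} = (f_j/f_i)^{N-1}$ gives $\pi_i \propto f_i^{N-1}$, evaluated
in log space. A subtlety worth recording: with $s_{ij} = f_j/f_i - 1$ the
Wright–Fisher diffusion kernel does *not* satisfy detailed balance exactly
(the Kolmogorov cycle product deviates from 1 by order $s^2$ per cycle), so a
detailed-balance construction would be path-dependent. The Wright–Fisher
stationary distribution is therefore computed by an exact dense solve of
$\pi P = \pi$, cross-checked in the tests against an eigenvector oracle; it
is capped at $L \le 12$ and at population sizes where deleterious fixation
probabilities have not underflowed to zero (beyond that the chain is no
longer ergodic in double precision). Mean steady-state fitness
$\sum_i \pi_i f_i$ is non-decreasing in $N$ on every test landscape — the
contrast that makes the non-monotone behaviour of $\bar h$ interesting.

## Landscape ensembles

The LK (also called NK) model is the primary ensemble: each site $i$
contributes a fitness term depending on the states of $i$ and of $K$ epistatic
partners, drawn i.i.d. Uniform(0,1) per partner-state combination, and
genotype fitness is the sum over sites. $K = 0$ is additive (a single peak);
$K = L-1$ is the uncorrelated House of Cards limit. Partner sets come in
`random` (default), `adjacent` and `block` schemes. The study conditions used
throughout the acceptance checks are the paper-scale ones: $L = 3$, $K = 1$,
random neighbourhoods, Uniform(0,1) contributions — small landscapes that are
rugged about 46% of the time, almost always with exactly two peaks.

Variant generators cover the robustness checks: **LKp** (each contribution
zeroed with probability $p$, introducing neutrality), **House of Cards**
(i.i.d. uniform fitness), **Rough Mount Fuji** (additive slope towards a
reference genotype plus Gaussian epistatic noise), **Eggbox** (fitness
alternating with bit parity, the maximal-peak-number regime) and **Ising**
(pairwise spin couplings; peaks are the one-flip-stable spin states). Models
whose raw values can be non-positive are shifted additively per landscape so
the minimum equals 1% of the fitness range. The shift preserves rank order,
peaks, accessible paths and basins, but rescales selection coefficients —
this is the least destructive way to honour the positivity requirement, and
it is the one thing to keep in mind when comparing walk quantities across
shifted and unshifted ensembles. Default parameters of the variant models
(`high = 2, low = 1, noise_sd = 0.1`, standard-normal couplings,
`additive_slope = 1`) are package defaults chosen to land in the sparse-peak
versus dense-peak regimes the variants are meant to illustrate; they are not
fitted to any external dataset. Landscapes are materialized as full
genotype-fitness tables up to `options(peakwalk.max_L = 20)` — at the largest
study size this is $2^{20}$ doubles, ~8 MB, and vectorized materialization is
considerably faster in R than lazy per-genotype evaluation; simulation above
the dense-kernel scale switches to an engine that evaluates transition
probabilities on the fly for the visited genotypes only.

Empirical genotype–fitness tables (for example combinatorially complete
$L = 4$ protein landscapes) enter through the same tab-separated format the
generators write, and are analysed identically; a synthetic two-peak $L=4$
example ships in `inst/extdata/`.

## Curves, classes and predictors

`hbar_curve()` evaluates $\bar h$ on a population-size grid. The default grid
is $\sqrt 2$-spaced from 1 to $10^4$ (27 points): geometric spacing resolves
both the small-$N$ extrema, which sit at $N$ of order 10–100, and the
saturation towards the adaptive-walk limit. The value at $N = 10^4$ doubles
as the large-$N$ anchor $\bar h_\infty$; the natural-AW kernel is available
as an independent cross-check of that limit.

`classify_curve()` detects interior extrema from sign changes of successive
differences exceeding a tolerance and labels the curve monotonic
(increasing/decreasing), one maximum, one minimum, max-then-min,
min-then-max, other (three or more extrema), or flat. The tolerance defaults
to $10^{-9}$ of the curve's value scale: FSA curves are deterministic to
solver precision ($\sim 10^{-14}$ relative), while genuinely tiny secondary
extrema occur near that scale, so the tolerance must sit between the two.
(For Monte Carlo curves pass roughly two standard errors instead.) The
classification of a seeded multi-peak test set is stable under doubling the
grid density, which guards both the grid and the tolerance choice; the
printed class frequencies still shift by a point or two under very different
grids, which is why the corresponding checks carry a few points of slack.
Extremum amplitudes follow the averaged-adjacent-segment definition
($N_0 = 1$, final segment to the anchor), and `curve_summary()` reports
$\Delta\bar h = \bar h_\infty - \bar h(1)$ and the overshoot
$\mathrm{Os} = \max_N \bar h - \bar h_\infty$.

For two-peak landscapes, two structural measures predict the sign of
$\Delta\bar h$. The accessible-path count of a peak is the number of
*maximal* strictly-fitness-increasing mutational paths terminating at it —
paths contained in other counted paths (as contiguous subsequences) are not
counted, which the implementation realizes by depth-first descent from the
peak until no fresh downhill extension exists. Since every counted path ends
at the peak, a path is non-maximal exactly when it can be extended at its
start, so the exclusion rule and "number of maximal paths" coincide; this
reading reproduces the published category frequencies, which is how the
convention was fixed. The greedy basin of a peak is the set of genotypes from
which the deterministic fittest-neighbour walk reaches it (ties broken
towards the lowest genotype index, for reproducibility; basins partition
genotype space in tie-free landscapes). With $\Delta AP$ and $\Delta B$ the
high-minus-low-peak differences, `predict_overall()` labels a landscape
increasing when both are non-negative and not both zero, decreasing when both
are non-positive and not both zero, and undetermined otherwise (both zero, or
strictly conflicting signs). Path enumeration is exponential in the worst
case and capped at `options(peakwalk.ap_max_L = 10)`; the study uses it at
$L = 3$ and $4$. Exact fitness ties between the two peaks make high/low
undefined and raise an error rather than an arbitrary choice.

## Ensembles and reproducibility

`run_ensemble()` streams landscapes one at a time (nothing is retained but
the per-landscape record), deriving each landscape's seed from the master
seed by a counter scheme, so results are bit-for-bit reproducible in the
deterministic modes and ensembles can be chunked or extended without
changing earlier records. Modes: `peaks` (peak counting only), `fsa` (exact
curves via first-step analysis) and `simulate` (Monte Carlo, many embedded
walks per starting genotype). `glance()` aggregates the records into the
headline statistics; `sweep_ensemble()` repeats the run across $L$, $K$ or
the size of the restricted high-fitness starting set.

The desk-scale problem sizes used by the bundled checks are $10^5$ landscapes
for peak statistics and $1.2\times 10^4$ multi-peak landscapes (~$1.2\times
10^4$ curves of 27 FSA solves each) for the curve and accessibility
statistics, a few minutes of single-core work; the corresponding binomial
standard errors (≤ 0.5 percentage points) are well inside the tolerances of
the published percentages, which were measured on ensembles a factor 2–50
larger. The test suite uses further-reduced ensembles with tolerances widened
by three binomial standard errors at the reduced size.

## What the generators do and do not emulate

The synthetic ensembles reproduce the statistical structure the study
rests on — tunable epistasis and ruggedness, neutrality (LKp), sparse versus
dense peaks — under idealized assumptions: binary sites, uniform mutation
across sites, no insertions or deletions, fitness constant in time, and
contribution distributions chosen for convenience rather than fitted to data.
Passing the ensemble checks therefore validates the machinery and the
landscape-statistics claims, not any statement about a particular organism;
empirical tables carry all the caveats of their measurement (missing
genotypes are rejected rather than imputed, and measurement noise enters the
peak structure at face value).

## Worked example

```{r example, eval = FALSE}
library(peakwalk)

ls <- lk_landscape(L = 3, K = 1, seed = 42)
find_peaks(ls)

# exact h-bar versus N and its classification
curve <- hbar_curve(ls, walk = "moran")
glance(curve)
autoplot(curve)

# does peak accessibility predict the overall trend?
differential_accessibility(ls)

# a small ensemble
res <- run_ensemble(ensemble_config(n = 2000, L = 3, K = 1, seed = 1))
glance(res)
```

## Known limitations

* FSA is exponential in $L$ (capped at $L \le 14$); beyond that only Monte
  Carlo estimates are available, and the curve classification then needs a
  noise-aware tolerance.
* The Wright–Fisher kernel is a diffusion approximation used outside its
  formal domain of validity at small $N$ or large $|s|$, exactly as in the
  origin-fixation literature; its stationary solve additionally requires
  that no required fixation probability underflows.
* Adaptive walks are undefined on fitness plateaus (no fitter neighbour at a
  non-peak); such landscapes (possible under LKp) raise an explicit error
  rather than an arbitrary continuation.
* Only single-substitution moves are modelled: no indels, no multi-allelic
  sites, no clonal interference or polymorphic populations, no
  frequency-dependent selection.
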