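---
title: "Comparative growth statistics from PSMC demographic histories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative growth statistics from PSMC demographic histories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmcgrowth)
```

## The problem

The pairwise sequentially Markovian coalescent (PSMC) reconstructs a
lineage's effective population size $N_e$ through time from a single
diploid genome: the density of pairwise coalescence events along the genome
is inversely proportional to $N_e$ at the corresponding depth. Applied
uniformly across a clade, this gives one $N_e$ step function per lineage
spanning millions of years — a basis for asking how a life-history trait
(here: long-distance seasonal migration in thrushes) shapes long-term
population size. `psmcgrowth` implements the post-PSMC half of such a
study: scaling, truncation, per-lineage growth statistics, a
phylogenetic-independence screen, and directional group contrasts. It does
not run the PSMC inference itself, align reads, or estimate trees — those
are inputs.

## Scaling PSMC output to natural units

A `psmc` output file holds one block per EM iteration; the block with the
highest `RD` index is the converged estimate and is what `last_round()`
selects (the plotting utilities shipped with `psmc` do the same; an
explicit round override exists). Each block carries $\theta_0$ (the scaled
mutation rate per bin) and segments $(t_k, \lambda_k)$ in coalescent
units. With mutation rate $\mu$ *per site per year*, generation time $g$
and bin size $s$:

$$N_0 = \frac{\theta_0}{4\,(\mu g)\, s}, \qquad
  t^{\mathrm{yr}}_k = 2 N_0 t_k g, \qquad
  N_e(k) = \lambda_k N_0 .$$

The $\mu g$ product deserves a note: mutation rates for birds are usually
reported per year, while psmc's $\theta$ is scaled per generation, so the
per-generation rate used internally is $\mu_{\mathrm{gen}} = \mu g$
($2.3\times10^{-9} \times 2.5 = 5.75\times10^{-9}$ at the defaults). The
defaults — $\mu = 2.3\times10^{-9}$ site$^{-1}$yr$^{-1}$, $g = 2.5$ yr,
$s = 100$ — are the constants used for the thrush system this package was
built around; changing them rescales axes but not curve shapes, so the
group contrasts (rank-based) and CV (scale-free) are insensitive to them.

Estimates more recent than `cutoff_years` (default 50 000) are discarded:
recent PSMC estimates are unreliable and most affected by population
structure. A segment is kept iff its recent boundary $t_k$ is at or above
the cutoff; the straddling segment is dropped rather than interpolated —
the simplest rule consistent with "ignore everything more recent".

## Per-lineage growth statistics

Over the retained steps, `summarize_growth()` computes the mean and SD of
$N_e$ and their ratio CV, and three early-growth variables anchored at two
points: the **trough** — the oldest retained step, the lineage's PSMC
inception — and the **peak** ending the initial growth phase. Then

$$\mathrm{degree} = 1 - N_{\mathrm{trough}}/N_{\mathrm{peak}}, \qquad
  \Delta T = t_{\mathrm{trough}} - t_{\mathrm{peak}}, \qquad
  \mathrm{rate} = \mathrm{degree}/\Delta T .$$

Degree is negative when a lineage initially declined (one resident thrush
lineage does, with degree $-0.75$). If the peak coincides with the trough
($\Delta T = 0$, e.g. a constant trajectory under global peak search), the
rate is reported as missing with a flag rather than $\pm\infty$, so the
downstream rank tests see an explicitly absent value.

Two conventions were genuinely open and both are implemented:

* **Peak location.** `"first_turning"` (default) scans from oldest to most
  recent and takes the first extremum where the running direction of
  change reverses, ignoring reversals while the cumulative relative change
  since the origin is below $\varepsilon$ (default 0.05, a step-noise
  filter); monotone curves peak at the most recent step. `"global"` takes
  the maximum-$N_e$ step (oldest under ties) — unless that maximum *is*
  the origin step, the initial-decline case, where the "peak" becomes the
  minimum step so that degree comes out negative. Both conventions
  reproduce the sign structure of the published thrush table, and the
  group contrasts computed from that table do not depend on the choice.
* **Mean/SD weighting and divisor.** The default is the unweighted mean
  and population-form SD (divisor $n$) over the plotted segments — the
  most plausible reading of statistics "obtained from standard PSMC
  output" — with a time-span-weighted mean/SD and a sample-form divisor
  ($n-1$) behind flags. Group-level descriptive rows always use the
  sample SD, as is standard for summaries across lineages.

One caveat found while validating against the published 14-lineage table:
in its summary rows the "±SD" attached to mean $N_e$ is the *mean of the
per-lineage SD column* (residents: 15.25), not the SD across lineage means
(23.94), whereas for degree, CV and $\Delta T$ the printed ± matches the
cross-lineage sample SD. `group_descriptives()` keeps the standard
definition; the alternative reading is noted here and exercised in tests.

Two published cells do not reproduce from the printed (rounded) columns:
the CV contrast recomputes to $U = 8.5$ (printed: 10) and the rate
contrast to 21 in the min-orientation (printed: 21.5). Both presumably
reflect unrounded source values; they are documented rather than asserted,
and neither affects a significant result's direction.

## The exact Mann–Whitney contrast

The study design predicts migrants larger, so the test is one-tailed with
the direction fixed and echoed in every output row. $U$ counts (resident,
migrant) pairs with resident > migrant, ties counted $1/2$ — small $U$
favors the alternative. The p-value is exact: all
$\binom{n_1+n_2}{n_2}$ assignments of the pooled values to labels are
enumerated (3003 at the 8 + 6 design, trivially cheap) and $p$ is the
fraction with $U^* \le U_{\mathrm{obs}}$. Enumeration on midranks handles
ties without any correction terms. Above 16 observations the
implementation switches to the normal approximation with tie-corrected
variance and continuity correction; the published design never reaches
that branch. No multiple-testing adjustment is applied across the five
variables, matching the analysis the package reproduces.

## The Abouheif–Moran screen

Group tests treat lineages as independent; close relatives are not. Each
variable is therefore screened for phylogenetic signal first, and
variables with signal ($p \le 0.05$ by default) are reported but not
contrast-tested unless forced. The statistic is Moran-type autocorrelation
with the topological Abouheif proximity: for tips $i \ne j$,

$$A_{ij} = \prod_{v \in \mathrm{path}(i,j)} \frac{1}{\mathrm{dd}(v)},$$

over the internal nodes on the $i$–$j$ path (MRCA included), where
$\mathrm{dd}(v)$ is the number of direct children of $v$; the diagonal
holds the row complement so rows sum to 1 (the row-normalized
"oriAbouheif" dialect). Branch lengths are deliberately ignored — the
method is definitionally topological. The trait is standardized (divisor
$n$), the off-diagonal weights are row-normalized, and
$C_{\mathrm{mean}} = \sum_{i\ne j} W_{ij} z_i z_j / n$. Significance is
one-tailed (greater) from seeded tip permutations with the add-one
estimator $p = (1 + \#\{C^* \ge C_{\mathrm{obs}}\})/(B+1)$, which is
reproducible bit-for-bit for a fixed seed and can never return 0. The
default $B = 999$ follows common practice for this test.

## The synthetic-data generator

`make_trajectory()` builds the kind of history the analysis assumes, as a
deterministic piecewise-constant $N_e$ step function on a log-spaced grid
(64 steps by default, first step pinned at time 0 as in real PSMC output):
exponential growth from `origin_ne` at the lineage's origin to `peak_ne`
over `growth_duration`, a plateau modulated by a sinusoid with period
$10^5$ yr — the rough pacing of Late Pleistocene glacial–interglacial
cycles — and a recent decline, reflecting the common pattern that current
populations sit below their historic peaks. The generator inserts its own
phase breakpoints into the grid, so the trajectory represents its knots
exactly and the growth statistics are recoverable to machine precision on
the noise-free path; grid discretization, not the generator, is the only
recovery error for off-grid parameters (tested: median $\Delta T$ error
below one grid step across a parameter sweep).

Stochasticity enters only at emission: `emit_psmc()` writes the trajectory
as a valid single-round PSMC file (inverting the scaling above) with
multiplicative lognormal noise $\exp(\epsilon_k)$,
$\epsilon_k \sim N(0, \sigma^2)$, on $\lambda_k$ — positive-support,
log-symmetric wobble emulating the spread of bootstrap replicate curves.
With $\sigma = 0$ the emit–parse–scale round trip is exact at every grid
resolution.

The default cohort mirrors the published design: 8 migrant-like lineages
(origin 4.5 Myr, growth 3.1 Myr, peak $8\times10^5$, oscillation
amplitude 0.35) and 6 resident-like ones (origin 2.8 Myr, growth 1.7 Myr,
peak $3.2\times10^5$, amplitude 0.15), parameter means taken from the
ranges of the published per-lineage table, with lognormal jitter
(SD 0.25 on the log scale) per taxon and emission noise $\sigma = 0.1$.
Group labels can be assigned cladewise on the simulated Yule tree
(mimicking the real system, where migration clusters phylogenetically) or
at random. All randomness flows from explicit integer seeds.

What the generator does *not* emulate: population structure (which can
masquerade as size change in PSMC), selection, sequencing error, the
inference noise correlations of a real HMM fit, and time-varying
generation times. Passing calibration tests therefore shows the
*post-PSMC pipeline* is correct and well-calibrated on idealized
histories, not that PSMC itself recovers truth on real genomes.

## Numerical choices and degenerate inputs

* Exact-p tolerance: enumeration compares $U^* \le U_{\mathrm{obs}} +
  10^{-9}$ to absorb float error in midrank sums; $U$ itself is a
  half-integer.
* Global-peak ties take the oldest step attaining the maximum, making
  $\Delta T$ the longest defensible growth duration and the tie-break
  deterministic.
* Trajectories must keep $\ge 2$ steps after truncation; otherwise a
  degenerate-trajectory error names the taxon rather than emitting NaNs.
* All-identical contrast inputs return $p = 1$ with a warning; non-finite
  values are excluded with a logged count.
* Zero-variance traits are an error in the signal test (Cmean undefined).
* Trees are used as encoded: the basal node of the `phylo` object is the
  root, and a basal multifurcation is simply a root of higher out-degree.

## Problem sizes used in the shipped checks

The calibration suite uses 100 cohort replicates for contrast power
(migrant-like vs. resident-like archetypes; expected rejection well above
80%), 200 replicates under identical archetypes for the empirical test
size (the exact test at 8 + 6 is conservative-discrete, observed near
0.03–0.04), and 500 trait simulations on a fixed 14-tip Yule tree with 199
permutations each for the screen's type-I error (nominal 0.05). These
sizes put Monte-Carlo error around one percentage point, small against the
acceptance bands, while keeping the whole suite under a minute of compute.

## Limitations

The package post-processes PSMC output; biases upstream (structure,
selection, reference mismapping) pass straight through. The growth
variables summarize one peak and one trough and will under-describe
multi-phase histories. The exact test's discreteness makes it conservative
at small samples. The screen-then-test logic controls phylogenetic
pseudoreplication only variable-by-variable; it is not a phylogenetic
regression.
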