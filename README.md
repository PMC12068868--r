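# psmcgrowth

Comparative paleodemography from PSMC output. The pairwise sequentially
Markovian coalescent (PSMC) infers a lineage's effective population size
(N<sub>e</sub>) back to its origin from a single diploid genome, as a step
function of relative size &lambda;<sub>k</sub> over coalescent-scaled times
t<sub>k</sub>. `psmcgrowth` is for researchers who want to *compare* such
reconstructions across related lineages — for example seasonally migratory
vs. resident songbirds — rather than inspect one curve at a time. It turns
raw `psmc` output files into per-lineage growth statistics, screens those
statistics for phylogenetic signal, and contrasts groups of lineages with an
exact nonparametric test.

## What it computes

**Scaling.** With a per-year mutation rate &mu;, generation time *g* and bin
size *s*, the baseline size is N<sub>0</sub> = &theta;<sub>0</sub> / (4
&mu; g s), each segment maps to N<sub>e</sub> = &lambda;<sub>k</sub>
N<sub>0</sub> at time 2 N<sub>0</sub> t<sub>k</sub> g years before present
(the &mu;g product converts the per-year rate to psmc's per-generation
scale). Estimates more recent than a cutoff (50 kyr by default) are
discarded as unreliable.

**Growth statistics per lineage.** Over the retained steps: mean
N<sub>e</sub>, its coefficient of variation CV = SD/mean, and three
early-growth variables anchored at the trough (the oldest retained step, the
lineage's PSMC inception) and the peak ending the initial growth phase:

- degree of initial growth = 1 &minus; N<sub>trough</sub>/N<sub>peak</sub>
  (negative if the lineage initially declined),
- deltaT = t<sub>trough</sub> &minus; t<sub>peak</sub> (years),
- rate = degree / deltaT (yr<sup>-1</sup>).

**Phylogenetic screen.** The Abouheif–Moran test: Moran-type autocorrelation
of each variable with a topological proximity matrix whose entries are
reciprocals of products of node out-degrees along tip-to-tip paths,
significance by seeded tip permutation. Variables showing signal are not
group-tested (closely related lineages are not independent data points); a
`force` flag overrides.

**Group contrast.** A one-tailed Mann–Whitney U test of migrants > residents.
U counts (resident, migrant) pairs with resident > migrant (ties = 1/2), and
the p-value is exact, from full enumeration of all C(n&#8321;+n&#8322;,
n&#8322;) group labelings of the pooled values.

**Synthetic data.** `make_cohort()` simulates migrant-like (long growth
phase, high peak, high variability) and resident-like archetype trajectories
on a Yule phylogeny and emits them as valid PSMC-format files with
multiplicative lognormal noise, so the entire pipeline can be exercised and
calibrated without any sequence data.

## Worked example

The package ships published growth statistics for 14 thrush lineages
(genus *Catharus* plus *Hylocichla mustelina*; 8 long-distance migrants,
6 Neotropical residents) as its canonical contrast input:

```r
library(psmcgrowth)
d <- thrush_growth_table()
mann_whitney_one_tailed(d$mean_ne_e4[d$group == "migrant"],
                        d$mean_ne_e4[d$group == "resident"])
#> Mann-Whitney U = 7 (n_migrant = 8, n_resident = 6)
#>   one-tailed (migrants > residents), exact_enumeration p = 0.01465
```

U = 7 means only 7 of the 48 resident–migrant pairs have the resident
larger: migrants have significantly larger historic mean N<sub>e</sub>
(exact p &asymp; 0.015). The same call on the `degree` and `deltat_yr`
columns gives U = 9 (p &asymp; 0.027) and U = 9 (p &asymp; 0.030): migrant
lineages also grew proportionally more, over longer initial periods
(group means 3.10 vs. 1.72 Myr).

The full file-based pipeline runs from a manifest of `psmc` output files:

```r
co <- make_cohort(cohort_spec(seed = 1))          # or your own data
cfg <- run_config(co$manifest_path, co$tree_path, output_dir = "out")
res <- run_full(cfg)                              # writes growth_stats.tsv,
res$contrasts                                     # signal.tsv, contrasts.tsv
```

A thin command-line front end with `simulate`, `run-all` and `table-mode`
subcommands is installed at `inst/scripts/psmcgrowth`.

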