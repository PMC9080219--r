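---
title: "Delineating an interconnected core microbiota: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating an interconnected core microbiota: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coremicro)
```

## The problem

Monthly amplicon surveys of marine plankton produce OTU-by-month count
tables for bacteria and small protists, split into picoplankton
(0.2–3 µm) and nanoplankton (3–20 µm) size fractions. A *core microbiota*
defined only by occurrence misses the fact that communities are built from
interacting species. `coremicro` implements the interaction-aware
delineation: the core is the set of *resident* OTUs (present in at least
30% of months) that participate in strong, significant, and
not-environmentally-driven pairwise associations inferred from the decade
of monthly abundances.

The pipeline stages are

1. **Preprocessing** — rarefaction to a common read depth (default 4907
   reads/sample), removal of OTUs present in fewer than 10% of samples, a
   2:1 read-ratio rule resolving DNA leakage between co-occurring size
   fractions, seasonally aware imputation of unsampled months, and
   selection of residents (≥ 36 of 120 months, with a whitelist for OTUs
   whose occurrence straddles the threshold only because of imputation).
2. **Season and niche annotation** — rule-based season labels from water
   temperature and day length, per-OTU seasonal preference by the
   indicator value (IndVal), and abundance-weighted temperature/day-length
   niche means tested against a permutation null.
3. **Association inference** — local similarity analysis (LSA) over all
   OTU–OTU and OTU–environment pairs with a mixed theoretical/permutation
   significance strategy and Bonferroni correction.
4. **Environmentally driven edge removal** — for every (OTU, OTU,
   environmental variable) triplet, four criteria (sign pattern, interval
   overlap, interaction information, data processing inequality) must
   unanimously implicate the variable before the OTU–OTU edge is removed.
5. **Core network** — edges with |LS| > 0.7, Spearman |ρ| > 0.7 and
   Bonferroni-adjusted p < 0.001 define the core; the package computes the
   standard graph statistics, Erdős–Rényi / Watts–Strogatz /
   Barabási–Albert baselines, seasonal subnetworks, MCODE modules,
   edge-betweenness (Girvan–Newman) modularity, and hub/connector
   classification.

A seeded synthetic-community generator with planted ground truth stands in
for the original sequence data, so every stage can be validated end to end.

## Local similarity analysis

For normalized series $x, y$ of length $n$, the local similarity score is
the signed maximal aligned segment sum

$$ P_i = \max(0,\, P_{i-1} + x_i y_i), \qquad
   N_i = \max(0,\, N_{i-1} - x_i y_i), $$

$$ \mathrm{LS} = \frac{1}{n}\,\mathrm{sgn\text{-}max}\Big(\max_i P_i,\ \max_i N_i\Big), $$

optionally maximized over alignment offsets up to `max_delay` (default 0:
the analysis targets contemporaneous associations). Dividing by the full
length $n$ keeps $|\mathrm{LS}| \le 1$ for unit-variance series. Ties are
broken toward the positive sign, the smaller |delay|, then the earlier
start. The dynamic program is implemented in C++ and is verified in the
test suite against an exhaustive all-subintervals oracle.

### Significance

Under independence of unit-variance series, the maximal segment sum of the
product walk converges (Lévy's identity) to the supremum of reflected
Brownian motion, so

$$ p_{\text{theory}} = 1 - F\big(\sqrt{n}\,|\mathrm{LS}|\big)^2, \qquad
   F(x) = \frac{4}{\pi}\sum_{k\ge 0}\frac{(-1)^k}{2k+1}
          e^{-\pi^2 (2k+1)^2 / (8x^2)}, $$

where the square combines the positive and negative segment maxima with an
independence approximation. The discrete walk's maximum sits below the
Brownian supremum by an excess-over-boundary gap of order $1/\sqrt{n}$; a
Monte-Carlo fit at $n = 60$–$480$ (the gap is ≈ $1.45/\sqrt{n}$ across the
5%–0.5% tail) supplies a continuity correction
$x = \sqrt{n}\,|\mathrm{LS}| + 1.45/\sqrt{n}$, after which the theoretical
p at the empirical 5% point of the null is 0.05 at monthly series lengths,
drifting slightly conservative deeper in the tail — the safe direction for
Bonferroni thresholds.

The *mixed* strategy screens every pair with $p_{\text{theory}}$ at
`screen_alpha` (0.05) and runs a seeded permutation test only on screened
pairs. The final p is the theoretical p when the permutation confirms it
($p_{\text{perm}} \le$ `screen_alpha`), otherwise the permutation p. The
permutation test is exact but floor-limited at $1/(n_{\text{perm}}+1)$; a
Bonferroni threshold of $0.001$ over tens of thousands of pairs requires
p-values far below that floor, which only the theoretical tail can
resolve. Treating the permutation as a calibrated veto keeps the
overall type-I error at the nominal level (verified on 2000 independent
Gaussian pairs in the acceptance suite) while preserving tail resolution.

### Normalization

Three options are provided. `median_mad` (the default) is the robust
z-score $(x - \mathrm{median})/\mathrm{MAD}$ with the raw
$\mathrm{MAD} = \mathrm{median}|x - \mathrm{median}|$; `zscore` is the
ordinary population z-score; `rank_normal` maps average ranks through the
standard normal quantile function (the rank-based "F-transform" used by
eLSA-style tools to accommodate non-linear monotone associations). Inside
the association table every normalized series is additionally rescaled to
unit population variance: the LS score is scale-equivariant, and the
asymptotic null above assumes unit-variance increments — without the
rescaling, raw-MAD scaling would inflate $\sqrt{n}\,\mathrm{LS}$ by a
constant (≈ 1.48² for Gaussian data) and destroy deep-tail calibration.
Series whose raw MAD is zero (heavily zero-inflated counts) fall back to
`rank_normal` rather than aborting the run.

A consequence worth knowing: under `median_mad` (a product-moment score on
the abundance scale) a *perfect negative* coupling between log-normally
distributed abundances has Pearson correlation bounded near
$-(1-e^{-s^2})/(e^{s^2}-1)$ (≈ −0.24 at log-scale effect $s = 1.2$), so
strong co-exclusions cannot reach $|\mathrm{LS}| > 0.7$ on that scale.
The `rank_normal` option restores power for negative associations; the
planted-recovery benchmark therefore runs with it.

## Environmentally driven edges

An OTU–OTU association may reflect a shared response to an environmental
variable rather than an interaction. For every triplet in which both OTUs
are also associated with the same environmental variable, four criteria
are evaluated, and the edge is removed only if **all four** agree for at
least one variable:

* **Sign pattern** — $\mathrm{sgn}(AB) = \mathrm{sgn}(AE)\,\mathrm{sgn}(BE)$.
* **Overlap** — the triple intersection of the three LSA-aligned intervals
  covers at least 60% of the OTU–OTU interval (threshold configurable).
* **Interaction information** — $II = MI(A;B\mid E) - MI(A;B) < 0$
  (redundancy) and significantly so under permutation of the
  environmental series (default 100 permutations, α = 0.05).
* **Data processing inequality** —
  $MI(A;B) \le \min\big(MI(A;E), MI(B;E)\big)$, the ordering implied by a
  chain $A \leftarrow E \rightarrow B$.

Mutual informations are plug-in estimates on equal-frequency bins, with
$\lceil 1 + \log_2 n \rceil$ bins by default (8 at $n = 120$). The
criteria are evaluated cheapest-first and stop at the first variable that
removes an edge; the triplet report records every evaluated criterion.
These operational definitions (sign product, triple-intersection overlap,
binning rule, II sign convention) are this package's choices — the
upstream description names the four methods and the unanimity rule but
not their numeric details — and each is exposed in `ended_config()`.

## Seasons, IndVal, and niches

Months are labelled summer (T > 17 °C and day length > 14 h), winter
(T < 17 °C and < 11 h), autumn (T > 17 °C and < 14 h) or spring
(T < 17 °C and > 11 h). Values exactly on a boundary are undefined by
these rules; `assign_season()` raises an error unless the `closed-lower`
tie-break is chosen (boundaries assigned to the lower interval), which is
what the pipeline uses — with measured temperatures the event has
probability zero, but synthetic or rounded data can hit it.

The indicator value of OTU $i$ in season $j$ is
$\mathrm{IndVal}_{ij} = A_{ij} B_{ij} \times 100$ with specificity
$A_{ij}$ (mean abundance in $j$ over the sum of per-season means) and
fidelity $B_{ij}$ (occurrence fraction within $j$); significance of the
maximum comes from label permutations with $p = (r+1)/(n_{\mathrm{perm}}+1)$,
which avoids zero p-values. Niche preference uses the abundance-weighted
mean of an environmental variable against a permutation null, with 2.5%
and 97.5% percentile confidence limits — a percentile band, not a
parametric SD band, so the "above"/"below" calls agree exactly with the
two-sided 5% test. Spring and autumn niches are not expected to separate
from the null by construction (their preferred temperatures sit near the
randomization mean); the null model targets the summer/winter axis.

## Core network analysis

Graphs are `igraph` objects. Conventions chosen and used consistently:
density is $E/\binom{N}{2}$; diameter and average path length are computed
on the largest connected component; the clustering coefficient is the mean
local coefficient with nodes of degree < 2 contributing 0; modularity is
the best partition found by edge-betweenness (Girvan–Newman) removal.
Girvan–Newman is a divisive heuristic restricted to its own dendrogram:
its Q is bounded by, and on structured graphs typically equal to, the
global maximum over all partitions, but exact agreement on arbitrary
graphs is not a property the algorithm has (the tests assert the bound and
the worked examples).

MCODE vertex weights are $k \cdot \mathrm{density}$ of the highest k-core
of the vertex's closed neighborhood; complexes grow from the
highest-weight unassigned seed, admitting the seed's neighbors with weight
at least $(1-\mathrm{vwp})$ times the seed weight (vwp = 0.2), and are
trimmed to their 2-core ("haircut"). The module score is density × size;
modules scoring above 4 are "main" modules. Growing complexes within the
seed's neighborhood keeps modules local and prevents two dense regions
joined by a single high-weight bridge from merging into one module.

Hubs are nodes with degree ≥ 24, betweenness centrality ≥ 0.03 and
closeness centrality > 0.3; connectors have degree ≤ 5, betweenness
≥ 0.03 and closeness > 0.2. The degree and betweenness thresholds are
inclusive: published tables report centralities at two decimals, and
several genuine hubs/connectors sit exactly on 24, 5, or 0.03 — with
strict inequalities those rows would violate their own rule.

## The synthetic community generator

`synth_config()` defaults encode the emulated sampling design: 120 monthly
samples (January 2004 start), two domains × two size fractions, multinomial
read sampling at depth 4907, and missing nanoplankton months (one block of
27 consecutive months plus two isolated months, indices 3, 14 and 77–103).
Day length is deterministic (CBM photoperiod formula, day 15 of each
month, latitude 41.67° N); temperature is an annual sinusoid
(18.5 ± 6 °C, August peak, SD 0.5 noise); thirteen further variables
(nutrients, chlorophyll, Secchi depth, salinity, plankton counts) are
seasonal signals with multiplicative noise, 15 variables in total.

Latent OTU dynamics are log-normal. Seasonal OTUs (fraction 0.6 by
default) get a circular Gaussian bump over month-of-year (SD 1.5 months,
log-normal amplitude around 2); planted *direct* pairs share a smooth
AR(1) latent driver independent of the environment; planted
*environmentally driven* pairs couple two OTUs to the same variable
(temperature or day length) with independent noise and zero direct
coupling, so the indirect-edge stage has unambiguous ground truth. A
fraction of OTUs appears in both size fractions with a leakage factor of
0.1–0.4, exercising the 2:1 ratio rule. Planted OTUs draw their baseline
abundance from a log-normal with meanlog 1.2 (vs 0 for background OTUs):
at depth 4907 spread over tens of OTUs, a low-baseline OTU's counts are
dominated by multinomial noise that bounds any attainable correlation well
below the detection thresholds, so planting associations there would test
the sequencer, not the method.

What the generator does *not* emulate: taxonomic structure, sequence-level
errors, compositional effects beyond the shared multinomial depth,
long-term trends, and regime shifts. Passing the recovery benchmarks
therefore shows that the statistical machinery detects what it is designed
to detect under the stated noise model — not that any real community has
been characterized.

## Problem sizes and numerical choices

The validation suite uses scaled-down community sizes chosen to exercise
every code path with comfortable statistical margins: recovery benchmarks
run 40 OTUs per table (≈ 160 nodes, ≈ 15,000 pairs) with 20 planted direct
and 20 planted environmentally driven pairs at low noise (`noise_sd` 0.1)
over five seeds; null-calibration runs use 2000 independent pairs at
$n = 120$ and twenty 10-OTU-per-table null communities. Benchmarks score
*direct-pair recall* on the Bonferroni-significant (q < 0.001) post-EnDED
network — detection by the association stage — because the 29 imputed
nanoplankton months dilute full-series correlations of affected pairs
below the display cut-offs while leaving their significance intact, which
is the behavior the real imputed data would show too.

Seeds: every stochastic step draws from an explicit seed derived from the
global seed through fixed per-stage offsets, so each stage is
independently reproducible; permutation engines in C++ use their own
64-bit generator, making results independent of R's RNG state and
identical across platforms.

Known limitations: the theoretical LS tail is asymptotic and slightly
conservative at monthly series lengths; plug-in MI estimates are biased
upward at $n = 120$ (the II permutation test absorbs this); the 2:1 ratio
rule uses totals over all samples, not per-sample ratios; and weak
associations are outside the core definition by design.
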