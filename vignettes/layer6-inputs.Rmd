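---
title: "Quantifying the inputs to layer 6 of cat area 17: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the inputs to layer 6 of cat area 17}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corticount)
```

## The measurement model

Retrograde tracer deposited in layer 6 of area 17 labels the somata of
neurons that project to the injection site. The data are therefore point
sets: one record per labeled soma with a tangential coordinate `x`, a depth
from pia `y` (both µm), a serial-section index, and categorical assignments
(area, hemisphere, cortical layer, tracer). The package fixes one explicit
coordinate frame — `x` within a flattened sheet, `y` from the pia,
`z = section index × 80 µm` — because the original measurements are made on
aligned coronal micrographs where no axis convention is inherent. All
distances are Euclidean in this straightened frame; no geodesic correction
along the folded sheet is attempted, so a distance is a lower bound on the
path an axon travels. Layers are half-open depth bands `[top, bottom)`
tiling 0–1900 µm; the defaults (L1 to 150, L2 to 350, L3 to 800, L4 to
1100, L5 to 1400, L6 to 1900 µm) put the L3/4 border at 800 µm, the depth
at which lateral label concentrates.

Counts are sampling-corrected before any ratio is formed: somata are marked
on alternate sections in cortex and on every fourth section subcortically,
so `corrected = counted × factor` with factors 2 and 4 (configurable per
structure class). The fraction of labeled neurons (FLN) of a group is its
corrected count divided by the corrected total, computed **per animal**
after removing tracer-filled somata inside the injection site (local uptake
is not evidence of a projection). Injection-site membership uses the
recorded flag when present; for synthetic data the fallback is a sphere of
radius `(3V/4π)^{1/3}` around each site centre, with the boundary inclusive
(a soma exactly on the radius is dropped). Cohort values are reported as
mean ± sample SD (n − 1), the convention of the anatomical literature; SD
is suppressed for n = 1. Animals with faint label can be flagged
`exclude_from_fln`: they stay in laminar-proportion summaries (ratios
within an area are robust to faint labeling) but not in FLN cohort means.

## Cluster detection

Labeled neurons lateral to the local column concentrate at the layer 3/4
border and group into periodic clusters roughly 400–800 µm wide, 150–250 µm
thick, with centres 400–800 µm apart. The anatomical description is
qualitative, so the detector is deliberately simple and explicit: project
somata in a depth band (default 575–900 µm, lower L3 through upper L4) onto
the tangential axis, estimate a Gaussian kernel density (bandwidth 150 µm),
and accept local maxima as clusters when

1. the **local prominence** — the drop from the peak to the shallower
   adjacent density minimum — is at least a quarter of the peak height,
2. the peak height is at least 15% of the density maximum (rejecting
   isolated far-tail bumps), and
3. the full width at half prominence does not exceed 1500 µm (rejecting
   the single broad mode of an unclustered scatter).

Local prominence, rather than classical topographic prominence, is the
load-bearing choice: the global maximum of *any* bounded sample has nearly
full topographic prominence because the density decays to zero at the data
edges, so a threshold on it cannot distinguish one broad unclustered mode
from a genuine cluster. The drop to the adjacent minima can. Under these
defaults a dense uniform scatter yields zero clusters, while planted
Gaussian clusters separated by at least ~3 bandwidths are recovered
essentially always (the test suite verifies exact cluster-count recovery
with centres within ±60 µm in ≥95 of 100 seeded replicates at 4-bandwidth
separation). Sparse scatters (a few hundred somata in the band) can show
noise ripples that pass the prominence ratio, and clusters closer than ~3
bandwidths merge — both are resolution limits of any density-based
detector at this bandwidth, and both are stated operating bounds rather
than silent failure modes. Width is reported as full width at half
prominence, spacing as successive centre differences.

## The synaptic budget and its inverse

The budget module reproduces the accounting logic of the quantitative
circuit diagram. For cell type *t* with population `N_t` and per-cell
synapse count `s(t, l)` in target layer *l*, the population total is
`S(t, l) = N_t · s(t, l)`. Against an independent estimate `T_l` of all
asymmetric synapses in the layer (defined as 100%), `a_l = Σ_t S(t, l) /
T_l` is assigned and `u_l = 1 − a_l` unassigned. Over-assignment
(`a_l > 1`, which occurs for layers 2/3 in the source diagram) is reported
with a warning, never clamped.

`T_{L6}` is not printed anywhere, but two printed numbers pin it down: the
p2/3 population contributes 6.41·10⁸ synapses to layer 6, and that is 10%
of the 30% assigned. Hence

```{r}
k <- budget_constants()
k$total_L6   # 6.41e8 / (0.10 * 0.30)
```

The baseline budget is reconstructed from the printed laminar split of the
assigned synapses (57% from L6 cells, 20% L5, 11% L4, 10% L2/3). Those
rounded percentages sum to 98; the remaining 2% of assigned synapses is the
X/Y thalamocortical contribution, carried as one aggregate afferent row so
that the assigned fraction is exactly 30% *and* the four cortical origins
carry exactly the printed split. Deep-layer populations are derived from
the printed per-cell counts (p6(L5/6): 2378, p5(L5/6): 3109 synapses per
cell in layer 6); superficial per-cell counts are derived from the printed
populations (8.25·10⁶ spiny L2/3, 8.74·10⁶ spiny L4 cells). This choice —
derive what is not printed from what is — makes the fixture exactly
self-consistent instead of propagating rounding noise.

The inverse solver answers the scenario question: for a population
`N = f · N_layer` to provide the contribution `c` of `T_l`, each cell needs
`s = c · T_l / N` synapses. With `c = 0.300` for a layer-3 type comprising
one third of the spiny L2/3 population, and `c = 0.217` for a layer-4 type
comprising one quarter of the spiny L4 population:

```{r}
solve_per_cell_synapses(0.300, k$total_L6, k$n_spiny_L23 / 3)
solve_per_cell_synapses(0.217, k$total_L6, k$n_spiny_L4 / 4)
```

Because the published chain was computed from unrounded intermediates and
printed rounded ones, these full-precision values differ from the printed
2329 and 2115 by 0.08% and 0.33%; the package always reports full precision
and the tests assert agreement within 0.5%. The same applies to the
residual unassigned fraction: `1 − 0.30 − 0.300 − 0.217 = 0.183` at full
precision, against a printed 19.2% produced by a different rounding chain.
The scenario report keeps the exact identity `Σ shares + unassigned = 1`
(tested to 1e-12).

## The synthetic-data generator

No coordinates or per-animal tables are published, so validation rests on a
seeded generator whose defaults encode the study's stated conditions: 10
animals, 300–30,000 corrected somata each, area weights {A17 0.81, A18
0.12, A19 0.022, contralateral A17 0.02, LGN 0.028}, an A17 laminar profile
{L2 .08, L3 .41, L4 .15, L5 .08, L6 .28}, clusters of width 400–800 µm,
thickness 150–250 µm and spacing 400–800 µm at the L3/4 border holding half
of the lateral L3/L4 label (the clustered fraction is a free parameter —
the anatomy is described only qualitatively — fixed at 0.5), 1–5 layer-6
injection sites of 0.19 mm³, 80 µm sections.

Two generator design points deserve note. First, section sampling is
emulated **systematically**, not by Bernoulli thinning: the drawn structure
totals are divided by the sampling factor and rounded, and the emitted
somata sit on the alternate/every-fourth section grid. Marking every second
section of a large population is a spatially systematic sample whose count
is essentially deterministic, and this choice keeps the corrected counts'
sampling error binomial — which is what makes the "recovered FLN within 3
binomial standard errors of truth" property exact rather than approximate.
Second, each animal and stage draws from its own deterministically derived
seed, so the generator is bit-reproducible from (config, seed) and one
stage's draws cannot reshuffle another's.

What the generator does **not** emulate: gyral curvature (the sheet is
flat, so generated distances lack the folding-induced compression of real
coronal data), tracer-transport biology, soma-size or labeling-intensity
variation, and any retinotopic structure. Passing recovery tests therefore
show that the pipeline's estimators are correct for data with the study's
statistical shape — not that the anatomical conclusions transfer to tissue.

The package also ships a synthetic **reference cohort**
(`reference_cohort()`): a per-cat count table constructed so that the
pipeline's cohort summaries equal the published statistics (A17 FLN 81.1%
over cats 1–7, 92.0% over the four non-border cats, A18 12%, laminar means
41.3/27.5/14.6% for L3/L6/L4, cohort totals 10,249 and 9,493 with and
without injection-site somata). The real per-animal table lives in an
unpublished supplement; this stand-in is labeled synthetic throughout and
exists so that the summary arithmetic — subsetting, exclusion flags,
sampling factors, grid completion — is exercised end to end against known
answers, with per-cat values otherwise invented at a realistic scale.

## Numerical and interface choices

- Fractions are computed in full precision; percentages are rounded to one
  decimal only at print time.
- FLN partitions are completed with zeros: an animal with no label in a
  group contributes 0 to that group's cohort mean, not a missing value.
  Likewise laminar profiles always cover L1–L6.
- Zero denominators (no label outside the injection site) raise errors,
  never NaN.
- Distance ties between equidistant injection sites resolve to the lowest
  site id, making reports deterministic.
- TSV output uses fixed numeric formatting so identical inputs produce
  byte-identical files; report tables carry `#`-prefixed provenance
  headers (version, seed, stage) and contain no timestamps, keeping reruns
  diffable.
- Problem sizes in the test suite: property checks use 100 seeded
  replicates of 10⁴-soma cohorts for weight recovery and 100 replicates of
  360-soma bands for cluster recovery; the end-to-end run uses the default
  10-animal cohort.

## Known limitations

- The cluster detector's resolution floor (~3 bandwidths) means clusters
  spaced below ~450 µm at the default 150 µm bandwidth merge; narrow the
  bandwidth for finer structure at the cost of noise sensitivity.
- Euclidean distances in the straightened frame understate true
  axonal distances, unavoidably so without a geodesic sheet model.
- The budget reconstruction inherits the printed numbers' rounding; exact
  agreement with every printed digit is impossible and not forced.
- Contralateral somata are distinguished by hemisphere label only; no
  second geometric sheet is modeled, so contralateral distances are not
  meaningful and are never reported.
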