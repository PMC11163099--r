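---
title: "Degree-based topological indices and QSPR models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degree-based topological indices and QSPR models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tiqspr)
```

## The model

A hydrogen-suppressed molecular graph encodes a compound's heavy-atom
skeleton: atoms are vertices, covalent bonds are edges, and the degree $d_u$
of an atom is its bonded heavy-atom count (at most 4 for organic skeletons
without hypervalent centres). A *degree-based topological index* is a sum
over bonds of a weight $f(d_u, d_v)$; because $f$ depends only on the
endpoint degrees, the whole index is determined by the *degree-pair edge
partition* — the multiset of unordered pairs $(d_u, d_v)$ with counts. This
package therefore treats the partition, not the graph, as the primary input:
published partitions are directly usable, and `edge_partition()` derives one
from any graph.

Eleven weights are implemented (`edge_weight()`): the first and second Zagreb
indices $\sum (d_u + d_v)$ and $\sum d_u d_v$, the modified second Zagreb,
harmonic $\sum 2/(d_u+d_v)$, hyper-Zagreb $\sum (d_u+d_v)^2$, forgotten
$\sum (d_u^2+d_v^2)$, reciprocal Randić $\sum \sqrt{d_u d_v}$, Randić
$\sum 1/\sqrt{d_u d_v}$, sum-connectivity $\sum 1/\sqrt{d_u+d_v}$,
geometric-arithmetic $\sum 2\sqrt{d_u d_v}/(d_u+d_v)$ and atom-bond
connectivity $\sum \sqrt{(d_u+d_v-2)/(d_u d_v)}$. The ABC weight at
$d_u = d_v = 1$ is defined as 0 (the radicand vanishes), keeping the single
edge graph valid. Useful identities, asserted throughout the test suite:
$HM = F + 2 M_2$ exactly for every partition, and $M_1 = \sum_v d_v^2$
whenever a graph is available.

The QSPR stage fits, for each index $TI$ and each property $P$ (melting
point, formula weight), the univariate linear model
$$P = A + B \cdot TI + \varepsilon, \qquad \varepsilon \sim N(0, \sigma^2),$$
by ordinary least squares in closed form ($B = S_{xy}/S_{xx}$,
$A = \bar y - B \bar x$). Inference follows the classical simple-regression
theory: $r = S_{xy}/\sqrt{S_{xx} S_{yy}}$,
$F = r^2 (n-2) / (1 - r^2)$ referred to the $F(1, n-2)$ distribution, and
the standard error of the estimate $\sqrt{SS_{res}/(n-2)}$. The equivalent
$t$ test on the slope satisfies $t^2 = F$ and is exposed through
`tidy()`. Models are called significant at $p < 0.05$. With 22 models fit
marginally and no multiple-testing correction, significance calls are
descriptive, not confirmatory — a deliberate match to how such tables are
conventionally reported, and a known limitation.

## Conventions and numerical choices

**The mM2 variant.** The study whose tables this package reproduces computes
the modified second Zagreb index as $\sum \mathrm{count}/(d_u+d_v)$ — exactly
half the harmonic index — although the literature defines it as
$\sum \mathrm{count}/(d_u d_v)$. Reproducing the published tables requires
the former, so `mm2_variant = "reported"` is the default and
`"literature"` is available everywhere (one flag, `--mm2-variant`, on the
command line). For the first sulfonamide the two give 5.59 and 5.64.

**Reported-value audit.** Recomputing the descriptor table of the five
packaged sulfonamides from their published edge partitions reproduces every
integer-valued cell (M1, M2, HM, F) exactly, but 13 of the 35 float cells
disagree with the published figures by more than rounding can explain
(threshold 0.015, i.e. half-ULP of a two-decimal print plus slack for
truncation-style rounding; the largest gap is 0.98, on the fourth compound's
reciprocal Randić value). These look like arithmetic slips in the original
calculations: the partitions themselves are internally consistent (the
$HM = F + 2M_2$ identity holds on the published integer cells). The package
never silently picks a side: `reported_deltas()` lists every divergent cell
with both values, the pipeline carries the list in its report bundle and
writes it as `reported_deltas.csv`, and the recomputed value is what all
downstream analysis uses.

A consequence worth knowing: the published regression coefficients for the
non-integer indices were evidently computed from the rounded two-decimal
descriptor table, not from full-precision values — refitting on the published
table reproduces all 22 printed equations to about twelve significant digits,
while full-precision descriptors give slightly different coefficients for
the affected indices. The acceptance tests check both routes; the integer
descriptor models (M1, M2, HM, F) agree either way.

**Degenerate inputs.** Regression requires $n \ge 3$ and a non-constant
predictor and response; violations raise typed errors naming the offending
stage or column, except in `correlation_table()`, where a degenerate column
yields `NA` cells and a single warning so one bad property cannot sink the
whole table. A perfect fit ($r^2 = 1$ within $10^{-12}$) makes the F
statistic undefined; it is reported as `Inf` with $p = 0$ and a `boundary`
flag, keeping the pipeline total.

**Rounding.** All tables are computed and written at full double precision;
two-decimal rounding happens only in `print()` methods. Test comparisons to
published figures use tolerances matched to the printed precision of each
cell, never string equality.

## The synthetic-data generator

`random_molecular_graph()` emulates the structural envelope of the study
compounds: connected simple graphs with every degree in $[1, 4]$ (no
published partition exceeds degree 4). It grows a random spanning tree under
the degree cap — each new vertex attaches to a uniformly chosen existing
vertex with spare valence, which is always possible for a cap of at least
2 — then adds a small random number of chords (up to one fifth of the vertex
count), mimicking the low ring count of drug-like molecules. Determinism is
by explicit seed; the same configuration always returns bit-identical
output.

`synth_compounds()` fills properties according to the same linear model the
analysis assumes: the target property is $A + B \cdot TI + N(0, \sigma^2)$
on a chosen index, while the other property is drawn independently of
structure (normal with mean 350 and SD 35 for formula weight, mean 165 °C
and SD 30 for melting point — the scale of the study compounds). The
defaults mirror the study conditions: five compounds, 22–32 heavy atoms
(the packaged compounds have 27–36 bonds), and the first-Zagreb
melting-point model with the study-scale intercept (401.74), slope (−1.46)
and residual SD (21). Gaussian noise is the right choice here because the
downstream F test and standard error presume it.

What the generator does *not* emulate: chemical validity beyond the degree
cap (no valence rules per element, no realistic ring statistics, no
correlation between the two properties). Passing tests on synthetic data
therefore demonstrate the statistical machinery — parameter recovery,
calibration of the F tail, determinism — not chemical realism.

## Problem sizes used in validation

The test suite exercises: 100 random graphs for the route-equivalence and
identity properties (5–20 vertices each); 500 draws for the
connectivity/degree-cap check; 200 seeded replicates of 10 compounds for
noisy slope recovery, plus 100 replicates at each of three noise levels for
the correlation-monotonicity property; and a 50-compound set for pipeline
determinism. These sizes give stable averages for the stochastic properties
while the five-compound study data itself is, of course, fixed and exact.

## Limitations

* Five compounds give three residual degrees of freedom; the printed
  p-values are exact under the model but the model is unverifiable at this
  $n$. The package reproduces, it does not endorse.
* Univariate models only; no polynomial terms, no multivariate descent,
  no cross-validation or applicability-domain analysis.
* Structure input is a partition or an edge list; no SMILES/SDF parsing,
  aromaticity perception or stereochemistry.
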