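---
title: "Global transcriptional crosstalk: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global transcriptional crosstalk: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xtalknet)
```

## The model and its assumptions

The package treats gene regulation as an equilibrium binding problem. A
cell carries `M` genes, each with a short regulatory binding site and a
dedicated (cognate) transcription factor species. A fraction `p` of the
genes is under positive control (silent unless an activator binds), the
rest under negative control (active unless a repressor binds); a fraction
`q` must be active in the current condition. Only the TF species needed
for the desired activity pattern are present. Because TF-DNA recognition
is imperfect, every present TF also binds similar foreign sites with
Boltzmann weight `exp(-E)`, `E` the mismatch energy in kT units.

A gene is in a *crosstalk* state when its site is wrongly occupied or
wrongly empty. Under the quasi-static thermodynamic occupancy model the
two error probabilities are

$$x_\mathrm{bound} = \frac{e^{-E_a} + c s}{c/t + e^{-E_a} + c s},
\qquad
x_\mathrm{unbound} = \frac{c s}{e^{-E_a} + c s},$$

with rescaled similarity `s` (mean non-cognate Boltzmann weight times
`M`), availability `t` (fraction of TF species present), concentration
`c` (total TF concentration per gene) and cognate energy gap `Ea`. The
global crosstalk is the availability-weighted mixture
`X = t * x_bound + (1 - t) * x_unbound`: the regulatory design (who is an
activator, who a repressor) enters only through `t = 1 - p - q + 2a`,
where `a` is the activator-regulated active fraction.

Key assumptions inherited from the model: equilibrium (no kinetics),
additive position energies within a site, one shared similarity `s` in
the analytic solution, and equal concentrations across available TFs.
The network machinery below relaxes the symmetry assumptions
numerically.

## Minimal crosstalk and regimes

`minimize_crosstalk()` minimizes `X` over `c ∈ [0, ∞]`. Because the gap
`Ea` satisfies the exact identity `(c, Ea) ≡ (c e^{Ea}, 0)`, the package
works internally at `Ea = 0`; the minimum is independent of `Ea`
altogether. Setting the concentration derivative to zero gives
`(1 + c s)/(c/t + 1 + c s) = sqrt(u)` with `u = s (1 - t)`, hence an
interior optimum

$$c^* = \frac{1 - \sqrt{u}}{\sqrt{u}/t - s(1 - \sqrt{u})},
\qquad
X^* = t\,(2\sqrt{u} - u).$$

Three regimes follow. If `u >= 1` the derivative at `c = 0` is already
nonnegative and the optimum is no regulation at all (`c* = 0`,
`X* = t`). If the denominator of `c*` is nonpositive the interior
stationary point has escaped to infinity and the infimum is the limit
value `X* = 1 - t/(1 + s t)` — reported with `c_star = Inf`, never as a
large finite number, since a diverging optimal concentration is
biologically meaningless. Otherwise the interior optimum stands
(the "regulation regime"). This closed-form classification was verified
against brute-force scan-plus-refinement minimization to relative error
below `1e-12` over thousands of random `(s, t)` draws; the numeric route
is retained as `method = "numeric"` and doubles as an independent oracle
in the test suite. `X*(t)` is non-monotone in `t`, with its maximum at
`t >= 2/3` (exactly 2/3 in the `s -> 0` limit, where
`X* ≈ 2 t sqrt(s(1-t))`).

`design_comparison_grid()` evaluates both extreme designs on a `(p, q)`
grid (default 101 × 101; resolution is configurable). Cells whose
relevant design lands in the divergent-concentration regime are flagged
anomalous and excluded from the winner call rather than silently valued;
ties (including the degenerate corners, where both designs coincide) are
reported as ties.

## Stochastic gene activity

When gene `i`'s regulator is present independently with probability
`gamma_i`, the number of available TF species is Poisson-binomial.
`availability_distribution()` computes the exact pmf by iterative
convolution (quadratic in `M`, capped by default at `M = 5000`, above
which it directs the user to the Gaussian or Monte-Carlo method). The
implemented variance is `sum(gamma_i (1 - gamma_i)) / M^2` — the
variance of the count scaled to the fraction `t = T/M`; a printed form
that omits the second `1/M` factor is dimensionally inconsistent with
`t` and is not used.

`xstar_distribution()` pushes the availability distribution through
`X*(t; s)` with one inverse branch per regime: the identity in the
no-regulation regime; `t(x) = (1 - x)/(1 - s + s x)` with derivative
`-(1 - s + s x)^{-2}` in the divergent regime (the derivative follows
from differentiating the inverse directly; `alpha = s` is identified
from the `c -> ∞` limit of the crosstalk); and numerical inversion by
root bracketing on each monotone branch of the regulation regime, split
at the maximizer `t*`, with the derivative from the inverse-function
rule and a centered finite difference (`1e-6` step). With
`method = "exact"` the discrete pmf is pushed through the map directly,
which is the reference used in the distribution tests; the Gaussian
method gives the corresponding continuous density.

`xstar_samples()` draws per-gene availability Bernoullis in memory-bound
chunks and evaluates `X*` through a lookup over the `M + 1` achievable
`t` values. Every stochastic entry point takes an explicit seed and is
bit-reproducible.

## From count matrices to energies

`energy_matrix_from_pcm()` converts a 4 × L position count matrix to
mismatch energies `eps = ln((c_max + delta)/(c + delta))` in natural-log
(kT) units, with the pseudocount `delta = 0.1` added to every entry
before the column maximum is taken, so all energies are finite and each
column's most common base sits exactly at zero. Matrices are admitted
only if all column totals are equal and at least 5
(`load_and_filter_pcms()`); unequal totals would bias the occurrence
statistics. Consensus ties break by the fixed order A < C < G < T.

`binding_energy()` slides the shorter of motif and site along the longer
and keeps the minimum total energy over all full-containment placements.
When the motif overhangs the site, the overhanging columns contribute
their four-base average. Partial overlaps are excluded: the accounting
for positions outside the site only covers motif positions, which
implies full coverage of the shorter sequence. Reverse-complement
matches are not scanned; that is a documented limitation of the sitewise
energy model, not an option.

Per-gene similarity (`network_similarities()`) uses the
concentration-weighted mean convention
`S_k = sum_{l != cognates} C_l e^{-E^{kl}} / sum_l C_l`, which reduces to
the plain `1/T` average at equal concentrations; a printed form mixing a
count normalization with raw concentrations is reconciled this way.
Genes with several cognate TFs average the similarity over their
candidate sites (one per cognate consensus), and their foreign-binding
sum excludes all of the gene's cognates. Similarities can be computed
against all TFs (descriptive histograms) or against an available subset
(crosstalk runs); both variants are exposed through the `available`
argument.

## Network Monte Carlo and the effective similarity

`min_crosstalk_curve()` draws random available subsets at each target
availability, averages the per-gene crosstalk over draws on a log-spaced
concentration grid (default spanning `M * 10^-6` to `M * 10^6`, 97
points), refines the winning concentration by local scalar optimization
between its grid neighbours, and records the draw spread at the optimum.
Defaults are 20 availability values and 100 draws per value; a
concentration optimum pinned to a grid edge is flagged, mirroring the
divergent-concentration anomaly of the analytic model. Availability
values that are not multiples of `1/n_tf` are rounded to the nearest
achievable count, with a message.

`fit_s_effective()` then fits the single similarity whose analytic
`X*(t; s)` best matches the numerical curve by least squares (log-spaced
scan plus local refinement), returning a classed model object with the
usual `coef`/`predict`/`residuals`/`plot` methods. On a fully symmetric
network with all off-diagonal Boltzmann weights `w`, the construction
similarity `(n - 1) w` is recovered to within a few percent; the
residual, deterministic discrepancy is the finite-subset effect — an
available subset of `k` species offers `k - 1` competitors to a bound
site where the analytic law assumes the full complement — bounded by a
relative similarity offset of `1/(n-1) + (n-k)/(k(n-1))` to which `X*`
responds with elasticity at most 1/2.

## Synthetic networks and subnetwork sampling

`generate_network()` fabricates TFs directly as energy matrices: a motif
length, a consensus drawn from the composition distribution, and
off-consensus energies drawn from the energy histogram.
`pcm_from_energy()` provides the inverse step (integer count matrices)
for round-trip testing. The default generator statistics are explicit,
configurable stand-ins for a real fungal motif collection: AT-biased
consensus composition (A = T = 0.35, C = G = 0.15), lengths uniform on
6–15 bp, and mismatch energies from a gamma-shaped histogram (shape 2,
scale 1, truncated to 0.2–8 kT) — magnitudes typical of pseudocounted
count matrices. One gene per TF is the default, matching the analytic
model; a genes-per-TF distribution exercises the multi-cognate pathway.

`sample_subnetwork()` restricts a network either to a uniform random TF
subset or, in ordered mode, to the most promiscuous TFs. Promiscuity is
ranked by the *bidirectional* inter-TF measure — the mean over partners
of `(e^{-E^{il}} + e^{-E^{li}})/2`. The one-directional, site-only
measure (how strongly a TF's own site attracts others) was found to be a
poor ordering criterion under the default generator: site
attractiveness correlates with consensus length while binding
aggressiveness anti-correlates with it, so the top sites belong to TFs
that bind little, and a subnetwork chosen that way is *less* similar
internally than a random one. The inter-TF notion, which treats the
asymmetric energy table symmetrically in its two roles, restores the
intended meaning of "most promiscuous subset" and with it the
characteristic over-estimation of crosstalk by ordered subnetworks.

`seffective_study()` repeats generate → subsample → curve → fit over
many independent full networks, one random and one ordered subnetwork
per size from each (sampling each full network once per size avoids
correlations between subnetworks). The curve seed is derived from the
network and size only, so at full size — where both modes hold the
identical network — the two fits coincide exactly. Every derived seed is
recorded in the result. Because the fitted `s_effective` spans orders of
magnitude and scales with subnetwork size, spreads across sizes are
compared as interquartile ranges of `log10(s_effective)`.

## Problem sizes and numerical choices

The package's own test and study scales are chosen to keep desk runtimes
in minutes: stochastic distribution checks use `M = 3000` genes with
`1e5` realizations (the Kolmogorov–Smirnov distance to the exact
pushforward is then well below 0.01); symmetric-network recovery uses 60
TFs, 20 availability values and 50 draws; the subnetwork study uses 20
full networks of 60 TFs with sizes 5, 15, 30 and 60, 10 availability
values and 30 draws per curve. Full-scale settings (300-TF networks, 100
draws or more per value, `1e6` realizations) are one argument away in
every entry point.

Tolerances and tie-breaks worth knowing: the closed-form/numeric
agreement is asserted at `1e-6` relative; the Gaussian density of the
minimal-crosstalk distribution integrates to one within `1e-6`;
consensus ties break A < C < G < T; regime ties at the concentration
boundaries resolve toward smaller `c`; crosstalk values reported for a
`t` of zero are exactly zero (no TFs, no binding). Degenerate inputs
error early and descriptively: `x_bound` at `t = 0` (undefined cognate
concentration), fits on all-zero or under-determined curves, stochastic
stages without a seed.

## What the synthetic generator does and does not emulate

The generator reproduces three marginal statistics of a motif
collection: consensus composition, length distribution and the
off-consensus energy histogram. It draws energies independently across
positions and TFs, so it does not emulate positional structure within
motifs (information gradients, palindromes), per-TF energy-scale
heterogeneity (every synthetic TF shares one energy distribution),
phylogenetic relatedness between factors, or genomic background
composition. Consequently, passing tests demonstrate the pipeline's
internal consistency and the qualitative sampling phenomena (ordered
versus random subnetwork bias, convergence with subnetwork size), not
organism-specific crosstalk magnitudes — estimating those requires real
count matrices and a real TF-to-gene map, which the motif pipeline
accepts in JASPAR-style PFM and two-column TSV form.

## Known limitations

Equilibrium occupancy only (no kinetics or dynamics); no combinatorial
promoter logic — multi-input genes enter through similarity averaging
only; no reverse-complement scanning; no epistasis between binding-site
positions; orphan genes (no cognate TF) are rejected rather than
modelled; and the analytic design comparison assumes equal activator and
repressor concentrations.
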