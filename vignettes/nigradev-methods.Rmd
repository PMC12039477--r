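---
title: "Methods: morphology, biophysics and statistics of developing nigral dopaminergic neurons"
author: "nigradev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphology, biophysics and statistics of developing nigral dopaminergic neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nigradev)
```

## The biological problem

Substantia nigra pars compacta (SNc) dopaminergic neurons are autonomous
pacemakers with two morphological peculiarities: in roughly 90% of cells the
axon arises not from the soma but from a dendrite — the axon-bearing
dendrite (ABD) — at a highly variable distance from the soma, and the
somatodendritic membrane carries an unusually high sodium-channel density,
so the broad action potential (AP) back-propagates faithfully through the
dendritic tree. Over the first three postnatal weeks (P3 to P21 in the rat)
these cells acquire their mature morphology and AP shape, with the sharpest
changes between P7 and P14: the ABD elongates about three-fold, soma volume
doubles, the AP narrows from ~2.7 to ~1.3 ms, and the somatodendritic (SD)
component of the AP comes to dominate its initial-segment (IS) component.

`nigradev` implements the complete quantitative apparatus for studying this
maturation: dendritic morphometry on reconstructed or synthetic
morphologies, a stage-typed morphology generator, a multicompartment
Hodgkin–Huxley model on the branched cable, AP-waveform decomposition, a
sodium-conductance screening procedure, and the multivariate
developmental-stage statistics.

## Morphometry conventions

A morphology is a rooted tree of labelled sections (`soma`, `dendrite`,
`axon_start`, `ais`, `axon`). All positions are arc lengths in µm; there is
no 0/1-based ambiguity because positions are continuous.

* **Segments.** Dendritic complexity is the number of *segments*: a segment
  separates two branching points, or a branching point (or the soma) and a
  tip. An unbranched dendrite is one segment; a binary tree with $k$
  bifurcations on one stem has $2k+1$ segments. Collinear subdivisions of a
  section — including the node where the axon leaves the ABD — do not
  create segments, which makes every summary invariant to section
  subdivision.
* **ABD vs nABD.** The ABD is the primary dendrite whose subtree contains
  the axon origin. When the axon arises from the soma there is no ABD and
  all ABD-conditional metrics are *missing* (`NA`), not zero; such neurons
  are excluded from ABD statistics (this mirrors the smaller n of the ABD
  rows in the source measurements).
* **Axonal geometry.** The axon-soma distance is the dendritic *path*
  length from the soma to the axon origin (the straight-line reading is
  ruled out by the additive identity below). The axon start is the axonal
  stretch between origin and AIS. Three identities hold exactly for every
  neuron: total length = ABD + nABD length; total segments = ABD + nABD
  segments; AIS–soma distance = axon–soma distance + axon start length.
* **Soma.** The measured soma volume $V$ enters the compartmental model as
  an equivalent cylinder with length equal to diameter,
  $\pi d^3/4 = V$. The aspect ratio is a convention (the single free
  parameter is volume); length = diameter is the common somatic choice in
  compartmental modelling.
* **Taper.** Primary-stem sections keep the primary diameter; beyond the
  first branch point diameters fall linearly with arc length to 0.5 µm,
  reaching it exactly at the tip of the longest path through each section
  (so every terminal section ends at 0.5 µm). Axonal diameter is constant
  at 0.7 µm.

SWC input/output uses the standard 7-column format (type codes 1 soma,
2 axon, 3 dendrite); because SWC has no AIS code, the
axon_start/AIS/distal-axon partition travels in a JSON side-car written and
read automatically.

## The synthetic morphology generator

Because the study's reconstructions are not redistributed with a usable
accession, every downstream stage is exercised on synthetic morphologies
whose population statistics emulate the per-stage summary table
(P3/P7/P14/P21 means and SDs of segment counts, lengths, AIS geometry,
soma volume, and the somatic-axon fractions 2/10, 4/23, 1/13, 4/38).

* **Distributions.** Only means and SDs are published per field (the
  printed ranges are widths, not endpoints), so each drawn field uses a
  *mean-matched truncated normal*: a normal truncated below at a natural
  bound (0 for lengths and volumes, 1 for counts), with its location
  solved numerically so that the *truncated* mean equals the published
  mean. Without this correction, truncation would bias small-mean fields
  (e.g. the P3 axon start, 3.2 ± 2.7 µm) upward by several standard
  errors. The SD of the truncated draw shrinks slightly below the nominal
  SD for strongly truncated fields; means are exact.
* **Drawn vs derived.** Per neuron the generator draws: ABD and nABD
  segment counts, number of primary nABDs, ABD and total nABD length,
  axon-soma distance, axon start length, AIS length, soma volume. Totals,
  averages and the AIS-soma distance are then *derived*, so the additive
  identities hold exactly by construction.
* **Topology.** Each dendrite is a random binary tree grown by bifurcating
  a uniformly chosen terminal segment until the drawn (odd) segment count
  is reached. Lengths are partitioned over dendrites with Dirichlet
  weights proportional to their segment counts — so length and complexity
  co-vary, as they do in the real populations — and over segments within a
  dendrite uniformly at random.
* **Axon placement.** With the stage's somatic-axon probability the axon
  attaches to the soma; otherwise to the ABD stem at the drawn axon-soma
  distance (the stem is extended to hold the origin when a draw would
  overshoot, preserving total ABD length; infeasible axon-distance draws
  beyond 90% of the ABD length are resampled with a bounded retry count).
* **Stage diameters.** Primary-dendrite diameters (P3 1.2, P7 1.5,
  P14 2.0, P21 2.0 µm) are configuration defaults, *not* measured values —
  the source tabulates no per-stage diameters.
* **What is not emulated.** Cross-field correlations other than the
  length–complexity coupling (e.g. soma volume vs dendritic length), real
  3-D embedding, spines, and diameter variability. Tests that pass on
  synthetic populations therefore validate the computational machinery and
  the published summary statistics, not unpublished aspects of the real
  anatomy.

The electrophysiological columns of a synthetic *feature table*
(threshold, amplitude, half-width, IS and SD peaks, SD/IS ratio) are drawn
from the same per-stage table independently of the morphological block;
morpho-electrical correlations within a stage are deliberately not
fabricated.

## The multicompartment model

Each compartment obeys
$$C_m \frac{dV}{dt} = -\sum_i g_i\,(V - E_i) - I_{\text{axial}},$$
with cytoplasmic resistivity 150 Ω·cm, specific capacitance 0.75 µF/cm²,
and specific membrane resistance 100,000 Ω·cm² (leak reversal −50 mV).
Runs start at −70 mV, last 6,000 ms at dt = 0.01 ms by default, and spike
analysis uses the window after pacemaking reaches steady state (default
discard 2,000 ms; the scaled-down test protocol uses 3,000 ms runs at
dt = 0.02 ms with an 1,800 ms discard).

**Channels.** Seven mechanisms: fast Na and delayed-rectifier K (KDR) in
the Migliore/Schild lineage, an A-type K current with a somatic variant
(higher density; inactivation depolarized by 10 mV and 2.5-fold slower
than in dendrites), an L-type Ca current (CaL, fixed reversal +60 mV, no
GHK flux), an SK-type Ca-activated K current activated *solely* by
calcium (Hill coefficient 4, half-activation 350 nM), an H current, and
leak. The exact rate equations of the original cell-type models are not
published as a closed set; the default kinetics here are a *reconstructed*
parameterization (Boltzmann steady states, bell-shaped voltage-dependent
time constants, all exposed as data) tuned against the model's stated
qualitative constraints — spontaneous regular pacemaking at a few Hz, a
broad AP (~1.3 ms at the mature stage), threshold near −45 mV, and AP
initiation always in the AIS — rather than transcribed from a source.
Reversal potentials (Na +60, K −90, Ca +60, H −35 mV) are likewise
conventional values, not printed ones.

**Pacemaking mechanism.** The subthreshold engine is a guaranteed-inward
ramp: leak (E = −50 mV) and the H current depolarize the cell from the
afterhyperpolarization up to about −55 mV, where the Na window and the
foot of CaL take over and trigger the spike; CaL is steep and
depolarized (half-activation −35 mV, squared gate) so that its window
calcium stays well below the SK half-activation — spike-evoked calcium,
decaying with τ = 150 ms, drives the SK afterhyperpolarization that sets
the interspike interval. A 20 ms calcium pool was tried first and cannot
support 1–5 Hz pacemaking through this mechanism (the AHP collapses within
~100 ms); 150 ms is consistent with the slow somatic calcium clearance of
these cells. Calcium influx is proportional to the CaL current over
compartment volume with a dimensionless scaling (default 0.15) standing in
for buffering.

**Conductance schemes.** Densities are in pS/µm² (1 pS/µm² = 10⁻⁴ S/cm²).
The heterogeneous scheme (Model 2, the mature default) enriches the ABD:
gNa 120 vs 50 pS/µm² and gCa 2.2 vs 1 pS/µm² in ABD vs nABDs; the
homogeneous scheme (Model 1, the immature default) sets ABD = nABD
(gNa 50, gCa 1). The soma carries the ABD-level Na density and the somatic
A variant. All dendritic compartments and the axon start carry all seven
currents; the AIS and distal axon carry only Na, KDR and leak. AIS
densities are expressed as multipliers over the somatodendritic maximum
(default 15× Na, 4× KDR — within the 10–15× range required for reliable
AIS initiation); the distal axon uses 3× Na. Absolute AIS densities are
not published; the multipliers are configurable.

## Numerics

Compartments (≤ 10 µm by default, frustum areas and axial resistances from
the tapered diameters, soma as its equivalent cylinder) are Hines-ordered
so the quasi-tridiagonal implicit system is solved exactly in O(n) per
step. The voltage update is backward Euler (robust default) or staggered
Crank–Nicolson (second order, used for the solver-oracle comparisons);
gates follow Rush–Larsen exponential updates with steady states and update
factors pretabulated on a 0.05 mV grid and linearly interpolated. Gates
initialize to steady state at the initial potential, calcium at its
resting concentration; the calcium pool relaxes exponentially toward an
influx-shifted target. Non-finite voltages abort with the time and
compartment of failure. Verified solver properties: the passive fixed
point at −50 mV; RC charging with τ = RmCm = 75 ms within 1%;
steady-state attenuation along a uniform cable within 1% of
$e^{-x/\lambda}$, $\lambda = \sqrt{R_m d / (4 R_a)}$; charge balance
within 0.5%; and, for the full single-compartment model, RMS voltage
deviation from an adaptive-ODE (lsoda) reference below 0.5 mV over 1 s.

## AP-waveform analysis

Spikes are detected at upward crossings of −20 mV with a 2 ms refractory
separation and averaged aligned on the AP peak. Threshold is the voltage
at which dV/dt first crosses 20 mV/ms before the peak (sub-sample linear
interpolation). Amplitude is threshold-to-peak by default (a fixed
baseline reference is available; the published measure does not state its
reference, so the choice is explicit and configurable). Half-width is the
duration at 50% of that amplitude above threshold. The IS and SD
components are the two largest local maxima of d²V/dt² between threshold
and peak, taken in time order (first = IS, second = SD); an optional
moving-average smoothing of the second derivative suppresses sampling
noise. Pairing AIS and somatic spikes for the initiation-lead measure
takes, for each somatic spike, the earliest AIS crossing in a short
window before it — the AIS can fire a second, non-invading spike as the
somatodendritic spike develops, which must not be mistaken for late
initiation.

## The sodium-conductance screen

The screen varies somatodendritic gNa on a grid — 50–150 pS/µm² in steps
of 10 in the ABD only for the mature heterogeneous model; 25–165 pS/µm²
in ABD and nABDs together for the immature homogeneous model — measures
the somatic AP half-width at each point, and inverts the piecewise-linear
half-width–gNa relation at a target ("biological") half-width. Exact grid
hits return the grid value; outside the achieved range the two nearest
points extrapolate linearly; if several intervals bracket the target
(non-monotone sweep) the bracket closest in half-width is used with a
warning. Sensitivity is the coefficient of variation of half-width over a
threefold gNa range (50–150 mature, 55–165 immature), with the sample-SD
(n−1) convention, stated here because the choice is not fixed by the
source. Silent grid points are recorded as missing, not errors.

## Developmental statistics

Per-parameter stage comparisons apply a Shapiro–Wilk normality gate
(α = 0.05 per group): all-normal parameters get one-way ANOVA with Tukey
HSD; otherwise Kruskal–Wallis with a Dunn post hoc (z statistics on mean
ranks with tie correction, Holm-adjusted — implemented in-package).
Pairwise significance bands (ns, <0.05, <0.01, <0.001) stack into a
6-stage-pair × parameter grid. ABD-vs-nABD contrasts are neuron-per-neuron
paired t tests against the averaged nABD value, excluding somatic-axon
neurons. Regressions are Pearson.

Clustering and discriminants run on z-scored complete cases (mixed units
make standardization necessary; the source does not state its scaling).
AHC uses Ward linkage on Euclidean distance with an automatic threshold —
the cut below the largest gap between successive merge heights — to fix
the number of flat classes; on mixed immature/mature synthetic populations
the two classes recover the stage for ≥ 90% of neurons, with class mean
ages straddling the P7→P14 transition. LDA uses nine parameters by
default; the canonical nine-parameter set is not enumerated in print, so
the default drops from the twelve clustering parameters the three most
redundant length measures (total length = ABD + nABD; average nABD length
duplicates the nABD total; AIS–soma distance is an axon-start sum), and
the set is configurable.

## Problem sizes

The test and acceptance runs use deliberately scaled problem sizes: 3 s
simulations at dt = 0.02 ms on ~150–250-compartment synthetic neurons
(the protocol default is 6 s at dt = 0.01 ms), a 9-point screening grid
(55–135 pS/µm²) with two extra target simulations for the recovery
experiment, 500 neurons per stage for generator fidelity, and 50 + 50
neurons for the clustering separation check. The solver-oracle comparison
against lsoda uses a single compartment at dt = 0.0005 ms over 1 s.

## Known limitations

* Channel kinetics are a reconstruction constrained by qualitative
  behavior, not a fitted replica of the original model; quantitative AP
  statistics (e.g. absolute IS/SD peak amplitudes) match the published
  mature-stage values only approximately.
* The AIS can fire non-invading doublet spikes on morphologies with very
  distal axon origins; somatic rate and AP shape are unaffected, and the
  initiation-lead pairing accounts for it.
* Synthetic feature tables carry no morpho-electrical correlations within
  a stage, so regressions of AP shape on morphology (the Figs 6–7-style
  analyses) are meaningful only on simulated, not generated, electro
  columns.
* Somatic-axon neurons contribute a drawn axon-soma distance of zero; the
  published per-stage distance rows pool both morphologies, so the
  generator's parameter is read as describing dendritic-axon cells.
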