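---
title: "Modelling clustered DNA damage from energy-imparted spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling clustered DNA damage from energy-imparted spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clustdamage)
```

## The model

Ionizing radiation deposits energy in nanometre-scale volumes of chromatin.
`clustdamage` models a 5 × 5 nm cylindrical target — a significant fraction
of a nucleosome, spanning about 73 bp of duplex DNA plus histones and
hydration water — and asks: given that a single track imparts energy
$\varepsilon$ to this site, what is the probability distribution over the
resulting DNA lesions, from isolated single-strand breaks (SSBs) to highly
clustered double-strand breaks (DSBs) with co-located base damage (BD)?

The computation has three layers.

**1. Events.** The energy $\varepsilon$ supports
$J_{TOT} = \lfloor \varepsilon / \varepsilon_{th} \rfloor$ elemental
damage-capable events. The threshold $\varepsilon_{th}$ is not a sharp
constant: it is modelled as a normal distribution (mean 17.5 eV, sd 5 eV)
truncated below at 7.5 eV — a single sharp threshold is implausible across
the different molecules involved, and OH-radical production alone requires
about 13 eV. Each event independently lands on one of four outcomes
according to the mass fractions of the site's components:

| symbol | default | event |
|---|---|---|
| $p_A$ | 0.2 | direct sugar–phosphate ionization → SSB |
| $p_B$ | 0.2 | water ionization → OH radical |
| $p_C$ | 0.2 | direct base ionization → BD |
| $p_D$ | 0.4 | energy to histones/other, no lesion |

The numbers of each type obey a multinomial distribution
(`enumerate_compositions()`, `multinomial_weight()`; the weights are
computed with `stats::dmultinom`). An OH radical converts to an SSB with
probability $r_1 = 0.2 \times 0.65 = 0.13$, to a BD with
$r_2 = 0.8 \times 0.65 = 0.52$ (attack-site fractions times a 65%
conversion efficiency, `radical_fates_from_attack()`), else nothing.

**2. Clustering.** Strand breaks interact through proximity: two breaks
within a 10 bp window form one lesion. When the $k$-th break is added to the
segment it starts a new isolated SSB with probability $q_0(k)$ or falls
inside the window of the existing damage with probability $2q_1(k)$,
$q_0 + 2q_1 = 1$, where the factor 2 covers the equally probable same- and
opposite-strand placements. The default ladder $q_0(J)$ for $J = 2..7$ is
0.87, 0.74, 0.60, 0.475, 0.35, 0.12 (Monte-Carlo estimates for a 73 bp
segment; treated here as normative input), with $q_0(1) = 1$ and linear
extrapolation clipped at zero beyond the ladder — with the default values
$q_0 = 0$ from the 8th break on, i.e. a saturated segment captures every
further break.

An attaching break picks one of the $M$ existing lesions **uniformly**
(weight $2q_1/M$ each) and lands on either strand with equal probability,
upgrading that lesion: an isolated SSB becomes SSB(+) (same strand) or a
simple DSB (opposite strand); SSB(+) becomes SSB(++) or DSB(+); a DSB of any
complexity deepens by one grade. We considered the alternative of weighting
attachment by the number of breaks a lesion already contains, but the
equal-per-lesion rule is the one that reproduces the closed-form fourth-order
expansion exactly — its $q_0 q_1^2$ tier has coefficients 6:2:2:1:1 and its
$q_1^3$ tier splits 7:1 between DSB(++) and SSB(+++) — and it is also what
uniform geometric placement implies, since a compact cluster presents
roughly one window footprint regardless of its break count. The
`resolve_composition()` engine propagates a weighted distribution over
lesion multisets through these branchings; with `q0_constant` the symbolic
expansions are recovered for testing.

**3. Folding.** Damage probabilities as a function of $\varepsilon$
(averaged over the threshold quadrature) are folded with the per-event
energy-imparted frequency distribution $dF/d\varepsilon$ of the radiation
quality to give yields per Gy,
$\mathrm{Yield}_j = c \int d\varepsilon\, \frac{dF}{d\varepsilon} P_j(\varepsilon)$,
and action cross-sections per particle versus LET.

## Two readings of "per J"

Two distinct conditional views coexist and the package exposes both:

* `damage_probability_table(model, j_tot)` — the multinomial view: at a
  given number of *events* $J_{TOT}$, sum the resolved lesion spectra of all
  compositions weighted by their multinomial probabilities, indexing
  $q_0(k)$ by each state's running break count. This is the quantity that
  enters the spectral fold.
* `damage_vs_breaks(model, n_breaks)` — the break-conditional view: the
  lesion-class distribution given that $n$ strand *breaks* were induced,
  with the single ladder value $q_0(n)$ applied across the whole order-$n$
  expansion (the structure of the closed-form expansions, where one $q_0$
  appears per order and decreases with the order). This is the view in which
  the model's signature qualitative results live: DSB(++) becomes the
  dominant DSB class from about 7 breaks on, the DSB:SSB ratio crosses 1
  there, and isolated SSBs disappear once the ladder is exhausted.

The distinction matters because with the default event probabilities only
$\approx 0.23 J_{TOT}$ breaks are expected per event, so the multinomial
view reaches high break numbers only far in the tail; the break-conditional
view isolates the clustering physics from the event-type mixture.

## The Monte-Carlo oracle

`simulate_composition()` re-derives lesion spectra by brute force: it places
breaks as (position, strand) pairs, draws radical fates, and classifies the
resulting pattern geometrically — lesions are connected components of the
graph linking breaks within the window, a component is DSB-class iff it
contains an opposite-strand pair within the window, and complexity follows
the break count (`classify_breaks()`). Placement conventions:

* `"q-ladder"` realizes the clustering ladder in position space: a new
  lesion is anchored far from all others, an attaching break lands next to a
  uniformly chosen existing lesion with a fair-coin strand. Classification
  still happens purely geometrically, so agreement with
  `resolve_composition()` (tested to three Monte-Carlo standard errors at
  $10^6$ trials for every composition with $j_A + j_B \le 4$) checks the
  operator algebra's bookkeeping — upgrade rules, branch weights,
  normalization — against an independent positional simulation under matched
  clustering assumptions.
* `"uniform-bp"` / `"site-resolved"` place breaks uniformly on the segment
  (re-hits of an occupied strand site collapse to one break; a strand cannot
  be "more broken"). These test the geometric classifier and drive
  `estimate_q0()`. Note that uniform placement on 73 bp with a 10 bp window
  gives $q_0(2) \approx 0.72$, visibly different from the printed 0.87 —
  the sampling convention behind the printed ladder is not fully specified,
  which is why the printed values are treated as normative input rather than
  re-estimated.
* `"table-calibrated"` keeps uniform placement but uses the integer window
  whose exact two-break no-cluster probability is closest to 0.87 (window 4
  for the default geometry, `calibrated_window()`).

What passing the oracle tests does *not* show: that the ladder itself, or
the equal-per-lesion attachment rule, is an accurate model of real track
structure. Low-energy electrons scatter with distinct angular correlations
that random placement ignores, and the random-clustering assumption likely
overestimates clustering at high break numbers.

## Spectra and units

An `energy_spectrum` stores a normalized density $dF/d\varepsilon$ (per eV)
with radiation metadata. `exponential_spectrum()` provides the parametric
form whose integral spectrum is $F(>\varepsilon) = e^{-\varepsilon/\varepsilon_0}$,
the shape used to represent electron spectra. The frequency-mean specific
energy is $\bar z_F = \langle\varepsilon\rangle \cdot 1.602\times10^{-19} / m$
Gy, with the site mass $m \approx 9.8\times10^{-23}$ kg computed from the
5 × 5 nm unit-density cylinder (the geometry is stated, the mass is not, so
it is derived and configurable).

The per-Gy conversion constant is derived as follows: one Gy corresponds on
average to $1/\bar z_F$ energy-deposition events per site, and a Gbp
contains $10^9 / n_{bp}$ sites, so
$c = 10^9 / (n_{bp}\, \bar z_F)$ and the yield per Gbp per Gy is
$c \int d\varepsilon (dF/d\varepsilon) P_j(\varepsilon)$. Yield tables
report the Table-5-style rows; the `total_ssb` and `total_bd` rows weight
lesions by their constituent break/BD counts, and `total_dsb` is the exact
sum of the three DSB subclass rows.

For action cross-sections the published expression is typographically
ambiguous about operator precedence, and the units of its constant 6.24 are
not stated. The default grouping implements the printed form,
$\sigma_j = 10^9 n_{bp} \bar z_F / (6.24\, \mathrm{LET}) \int (dF/d\varepsilon) P_j\, d\varepsilon$;
an audit grouping derives the factor from the dose–fluence relation
(1 Gy $\leftrightarrow 6.24\times10^8/\mathrm{LET}$ particles/cm²), giving
$10\,\mathrm{LET} / (6.24\, n_{bp} \bar z_F)$ instead. Every report records
which grouping produced it; the two differ by a spectrum-independent factor,
so LET *trends* within one grouping are unaffected.

The bundled `fixture_spectra()` are **synthetic**: exponential spectra with
mean energies (40, 150, 180, 55 eV) chosen to imitate the hardness ordering
of 100 keV electrons, 1 MeV/u ⁴He, 10 MeV/u ¹²C and relativistic ¹²C at the
nanometre scale. They exercise the pipeline and reproduce qualitative LET
behaviour (e.g. the larger with/without-BD gap for harder spectra) but are
not fits to track-structure calculations; quantitative yield predictions
for a real radiation quality require its measured or simulated
$dF/d\varepsilon$ supplied via `read_spectrum()`.

## Approximation mode

`mode = "paper_approx"` mirrors the closed-form truncations used for
higher-order terms: radical-to-break conversion terms are kept only to order
$r_1^2$ (a state holding two radical breaks routes further conversion weight
to the inert branch — with $r_1 = 0.13$, the discarded terms are
$O(r_1^3) \lesssim 10^{-2}$ even at $j_B = 4$), and attachment weight beyond
the $q_1^3$ tier of the binomial expansion is tallied along the complex-DSB
route only. The exact weighted-state propagation is the default; the
approximation exists to quantify the closed forms' accuracy, and the test
suite bounds their total-variation distance at $\le 1\%$ for all
compositions up to fourth order.

## Numerical choices

* Threshold quadrature: 9 Gauss–Hermite nodes (symmetric about the mean),
  truncated below the cut and renormalized; `sd_ev = 0` degenerates to a
  point mass. All $\varepsilon$-dependent probabilities are expectations
  over these nodes — smearing is never sampled per trial, keeping the fold
  deterministic.
* Event cap: energies are clamped at `j_cap = 30` events. Nanometre-site
  spectra carry negligible weight above $\sim 30\,\varepsilon_{th} \approx
  525$ eV, and beyond the exhausted ladder additional events only deepen
  already-terminal classes.
* State pruning: propagated states below $10^{-16}$ probability are dropped;
  with at most a few thousand live states this perturbs totals well below
  the $10^{-10}$ normalization tolerance asserted in the tests.
* The per-J table uses an exact factorization — conditional on the number of
  radical conversions, the lesion part is the pure break chain and the BD
  count an independent binomial — verified against the direct step-wise
  propagation in the suite.
* Spectral folding integrates the density exactly over each interval on
  which the step-function integrand is constant (cumulative-trapezoid
  interpolation at threshold multiples), so refinement error comes only from
  the density representation; with $\ge 400$ grid points per
  $25\,\varepsilon_0$ the tests bound refinement changes below 0.1%.
* The Monte-Carlo loops (`src/oracle.cpp`) use R's RNG, so `seed` gives
  bit-identical results; the test suite runs its $10^6$-trial equivalence
  sweep in well under the stated budgets.

## Limitations

BD positions within the segment are not tracked (only counts), so BD
clustering is summarized by multiplicity classes and co-location is assessed
at segment resolution; DNA–protein crosslinks and repair processes are out
of scope; multi-segment (kbp-scale) DSB multiplets — relevant to
experimental undercounting at high LET — are not modelled beyond counting a
DSB(++) as a single DSB. The ion spectra formalism combining direct and
δ-ray contributions is not reimplemented; spectra are pluggable inputs, with
`mix_spectra()` provided as a generic mixture utility.
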