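---
title: "Quantifying the degree of folding of flexible glycans from SAXS and MD"
author: "glycoSAXS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the degree of folding of flexible glycans from SAXS and MD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoSAXS)
```

## The problem

Synthetic glycan foldamers — oligosaccharides designed around rigid turn
units so that strands pack into hairpin or sheet-like folds — are flexible
molecules. In solution they populate an ensemble of conformations, and the
quantity of interest is not a single structure but the *degree of folding*:
the fraction of the ensemble occupying the compact, folded state. Classical
observables (NMR NOEs, chemical shifts) average over the ensemble and mainly
report short-range contacts, so they cannot resolve how much of the
population is folded.

This package implements a semiautomated protocol that combines
molecular-dynamics (MD) trajectories with small-angle X-ray scattering
(SAXS):

1. **State identification.** The per-frame radius of gyration
   $R_g$ along the trajectory is averaged over fixed time intervals
   (default 1 ns). Each interval is labelled a *folded conformer* (fc,
   compact, low $R_g$) or *unfolded conformer* (uf) by comparison with an
   $R_g$ threshold. Interval averaging suppresses sub-nanosecond
   fluctuations, so each label describes a dynamic ensemble rather than a
   snapshot.
2. **Per-state SAXS prediction.** All frames sharing a label are
   concatenated and a theoretical SAXS profile is computed for each state
   ensemble from atomic form factors, either by the exact Debye sum or by
   Monte-Carlo orientational averaging.
3. **Population fit.** The experimental curve is modelled as
   $s\,[w_{fc} I_{fc}(q) + w_{uf} I_{uf}(q)] + b$ with non-negative weights
   summing to one. The fitted $w_{fc}$ is the degree of folding.

## Models and conventions

**Units.** All internal lengths are nm. Momentum transfer $q$ is
Å$^{-1}$ at every interface ($1\,\mathrm{Å^{-1}} = 10\,\mathrm{nm^{-1}}$,
converted exactly once inside the forward model). Guinier radii are
reported in Å, matching how solution-scattering results are normally
quoted; trajectory $R_g$ values are in nm, matching the MD convention.

**Radius of gyration.**
$R_g^2 = \sum_i w_i |r_i - \bar r|^2 / \sum_i w_i$ with $\bar r$ the
weighted centroid. Mass weights are the default (the MD convention);
electron-count weights are available because SAXS senses electron density,
and the two differ slightly for heteroatomic molecules. The comparison of
trajectory $R_g$ against Guinier $R_g$ should use electron weights.

**Atomic form factors.** The Cromer–Mann four-Gaussian parametrisation
$f(q) = c + \sum_{k=1}^{4} a_k e^{-b_k (q/4\pi)^2}$, with coefficients for
H, C, N, O, Na, P and S shipped as a plain-text table
(`inst/extdata/cromer_mann.tsv`). At $q = 0$, $f$ equals the element's
electron count to within the parametrisation error (< 0.2 e), which the
test suite asserts for every entry.

**Solvent.** The experimental reference treatment of solvent
(explicit-solvent calculations with a solvation envelope and pure-water
subtraction) requires solvated simulation boxes, which this package does
not consume. Instead two implicit modes are provided: `vacuum` (no solvent
term) and `excluded_volume`, which subtracts a Gaussian dummy atom per
site, $f_{\text{eff}}(q) = f(q) - \rho_s V_j e^{-q^2 V_j^{2/3}/4\pi}$,
with the water electron density $\rho_s = 334$ e/nm³ and standard displaced
atomic volumes. For hydrogen $\rho_s V_H$ exceeds $f_H(0)$, so its
effective contrast is negative — expected behaviour, not an error. The
solvent mode is recorded in run manifests. Hydration-shell contrast is
*not* modelled; predicted absolute intensities are therefore approximate,
which is acceptable here because the population fit carries a free global
scale.

**Forward model.** The Debye equation
$I(q) = \sum_i \sum_j f_i f_j \,\mathrm{sinc}(q r_{ij})$ is the exact
orientational average for a rigid atom set and is the default
($O(N^2)$ per $q$; fine up to a few thousand atoms). The Monte-Carlo route
averages $|\sum_j f_j e^{i\vec q\cdot\vec r_j}|^2$ over directions of
$\vec q$ — 500 per $|q|$ by default — and is unbiased for the Debye value;
it exists because the protocol being automated specifies orientational
averaging by $q$-vector sampling, and because it generalises to
direction-dependent extensions. Directions come from a deterministic
Fibonacci lattice by default (lower variance, bit-reproducible); seeded
uniform sampling is available, and `with_se = TRUE` returns the
per-direction standard error so convergence can be checked quantitatively.
Ensemble curves are unweighted means over (optionally strided) frames.

**Guinier analysis.** $\ln I = \ln I_0 - (R_g^2/3) q^2$ is fitted by
weighted least squares over the largest low-$q$ window satisfying
$q R_g \le 1.3$ at convergence (the standard validity limit for globular
particles), with weights $(I/\sigma)^2$ when uncertainties are present.
The window rule is iterative because $R_g$ is not known before the fit.
Two numerical caveats are worth knowing. First, the Guinier
approximation's error grows within its nominal validity window: for an
ideal solid sphere, a least-squares fit spanning the full
$q R_g \le 1.3$ range overestimates $R_g$ by about 2% purely from the
neglected $q^4$ term; near 1% accuracy requires data confined to
$q R_g \lesssim 0.7$, and elongated shapes deviate more. Second, atomic
form factors decay with $q$, which adds a small apparent
$\Delta R_g^2 \approx 0.7$ Å² for carbon-dominated molecules — negligible
for $R_g \gtrsim 10$ Å but visible for very small bodies. Consistency
checks between geometric and Guinier $R_g$ in the test suite are therefore
performed on a large globular reference body in the strict Guinier regime.

**Kratky analysis.** $q^2 I(q)$ distinguishes compact conformers (an
interior maximum followed by decay) from extended ones (monotone rise
through the measured window). For an ideal Guinier-form curve the maximum
sits at $q = \sqrt 3 / R_g$, which the tests assert; for open chain-like
molecules no such closed form applies and only the qualitative signature
is tested.

## State assignment choices

* **Folded = low $R_g$**, and an interval mean exactly at the threshold is
  labelled fc. The tie rule is documented rather than consequential: real
  interval means are continuous.
* **A trailing partial interval is kept** as its own interval (its mean
  uses only its own frames), and the folded fraction weights intervals by
  frame count, so short trajectories remain usable without bias from the
  remainder.
* **The authoritative threshold is user-chosen per molecule.**
  `autoThreshold()` is a convenience: deterministic two-cluster 1D k-means
  on the interval means (initialised at the extremes), threshold at the
  centroid midpoint, with a between/within variance ratio reported as a
  bimodality diagnostic. Values well above 4 indicate a clean two-state
  $R_g$ distribution; for unimodal distributions the function refuses
  (all-equal means) or the diagnostic warns the user off. Exactly two
  states are first-class throughout, matching the hairpin/sheet systems
  the protocol was designed for.

## Population fit

The mixture problem
$\min_{w \ge 0,\ \sum w = 1,\ s > 0,\ b} \sum_k
\left(\frac{s \sum_s w_s I_s(q_k) + b - I^{\text{exp}}_k}{\sigma_k}\right)^2$
is solved exactly: substituting $c_s = s\,w_s$ and $b = b^+ - b^-$ turns
it into ordinary non-negative least squares, solved by a Lawson–Hanson
active-set solver implemented in the package (the reformulation is exact
because the simplex constraint only fixes the split between $s$ and $w$).
This is deterministic and handles the degenerate cases exactly — an
experimental curve equal to one state curve yields weight 1 with zero
residual. Identical state curves (up to scale) make the weights
unidentifiable; this is detected, warned about, and reported as weight
uncertainties spanning [0, 1]. The background term is off by default
(solution SAXS pipelines normally subtract buffer upstream); σ-weighting is
used when the curve carries uncertainties and plain least squares
otherwise. Weight confidence intervals come from a seeded
residual-resampling bootstrap. For large molecules the fit can be
restricted to low $q$ (e.g. $q \le 0.4$ Å$^{-1}$) to focus on the overall
conformation rather than local structure.

## The synthetic two-state generator

Because real deposited trajectories and beamline curves are large external
data, the package ships a generator that emulates exactly the features the
protocol relies on: a bead chain (alternating C/O, 18 beads, 0.5 nm
spacing — the glycosidic virtual-bond scale) whose folded template is a
two-leg antiparallel hairpin at 0.45 nm strand separation and whose
unfolded template is a straight chain; Markov-chain state switching with a
stationary folded occupancy and mean dwell time (2 ns default), so that
1 ns interval averaging is meaningful; and Gaussian coordinate jitter
(0.03 nm). Pseudo-experimental curves are built as
$s\sum w_s I_s + b + \varepsilon$ with $\varepsilon \sim
N(0, \text{noise}\cdot I)$ and a matching σ column. Everything is seeded
and bit-reproducible.

What the generator does *not* emulate: force-field realism, solvent and
hydration-shell scattering, gradual (non-two-state) conformational
exchange, and any mismatch between the states the trajectory visits and
the states present in solution. Passing the synthetic recovery tests
therefore demonstrates that the *pipeline machinery* is correct and
well-conditioned — not that MD force fields or the implicit solvent model
are accurate for a particular real glycan. The generator's one structural
idealisation worth noting is that pseudo-experiments are mixed from the
same predicted state curves used in the fit, so recovery tests probe
noise- and assignment-driven error, not forward-model bias.

## Study conditions used by the validation suite

The end-to-end benchmark (`syntheticFoldingBenchmark()`) uses 8000 frames
at 0.1 ns (800 ns of trajectory) with 2 ns mean dwell, giving the
folded-occupancy estimator a standard error near 0.013 (roughly 200 dwell
periods), and a 240-point $q$ grid over 0.01–0.5 Å$^{-1}$, a typical
beamline binning density, at 2% relative noise — under which the fitted
weight's standard error is also near 0.013. Both choices make the ±0.05
recovery band used in the tests a comfortable margin rather than a coin
flip. Ground-truth occupancies 0.25, 0.40, 0.71 and 0.75 span the
population range the protocol is meant to resolve.

## Known limitations

* Two states only; multi-state mixtures and ensemble-reweighting methods
  (maximum-entropy / Bayesian) are out of scope by design.
* No explicit-solvent scattering: absolute intensities are approximate and
  a compact state whose scattering signature appears only above
  $q \approx 0.5$ Å$^{-1}$ (e.g. one never visited by the trajectory)
  cannot be modelled.
* PDB/GRO carry no reliable time metadata, so the frame time step is
  always user-supplied.
* Element inference from atom names resolves ambiguous two-letter names
  toward the organic set (CA → carbon, NA → nitrogen); genuinely metallic
  atoms need the element column or an explicit override map.
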