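# glycoSAXS

Quantifying the conformational populations of flexible glycan foldamers in
solution, by combining molecular-dynamics (MD) trajectories with small-angle
X-ray scattering (SAXS).

Designed oligosaccharides built around rigid turn units fold into hairpin
and sheet-like architectures, but as flexible molecules they populate an
ensemble of conformations. The question this package answers is *how much*
of that ensemble is folded — the **degree of folding** — which
population-averaged observables such as NMR cannot resolve. It is aimed at
structural bioinformaticians and scattering practitioners who have an MD
trajectory of a (glyco)foldamer and a measured solution SAXS curve.

## Method

1. **Rg-defined conformational states.** The per-frame radius of gyration
   along the trajectory is averaged over 1 ns intervals; each interval is
   labelled folded (fc, compact) or unfolded (uf) against an Rg threshold
   (user-supplied, or suggested by deterministic 1D k-means). All frames
   sharing a label form that state's ensemble.
2. **Theoretical SAXS per state.** Ensemble intensity curves are computed
   from Cromer–Mann atomic form factors
   f(q) = c + Σₖ aₖ exp(−bₖ (q/4π)²), via the exact Debye equation
   I(q) = Σᵢ Σⱼ fᵢ fⱼ sin(q rᵢⱼ)/(q rᵢⱼ)
   or Monte-Carlo orientational averaging (500 q-vectors per |q| by
   default), in vacuum or with an implicit excluded-volume solvent
   correction (ρₛ = 334 e/nm³).
3. **Population fit.** The experimental curve is fitted as
   s·[w_fc I_fc(q) + w_uf I_uf(q)] + b with w ≥ 0, Σw = 1, solved exactly
   by an active-set non-negative least-squares reformulation. The fitted
   w_fc is the degree of folding; a residual bootstrap gives confidence
   intervals.

Guinier fitting (ln I = ln I₀ − Rg²q²/3 over the largest window with
q·Rg ≤ 1.3), Kratky transforms, glycosidic Φ/Ψ torsions and CH···O
hydrogen-bond diagnostics (favorable iff C–O < 0.4 nm **and**
C–H···O > 150°, strict) are included, together with readers/writers for
PDB, GRO and 2–3 column ASCII scattering curves, and a fully seeded
two-state synthetic generator so the entire pipeline is testable with
known ground truth.

## Worked example

A synthetic hairpin-forming bead polymer at 75% folded occupancy,
end to end:

```r
library(glycoSAXS)

spec <- twoStateSpec(occupancy_folded = 0.75, seed = 42)
gen  <- generateTwoStateTrajectory(spec, n_frames = 8000,
                                   frame_time_step = 0.1)  # 800 ns

rg  <- rgSeries(gen$trajectory)                      # nm, per frame
iv  <- partitionIntervals(rg, frame_time_step = 0.1) # 1 ns intervals
thr <- autoThreshold(iv$mean_rg)
asg <- assignStates(iv, thr$threshold)
asg
#> StateAssignment: 800 intervals (fc: 566 , uf: 234 ), threshold 1.884282 nm
round(mdFoldedFraction(asg), 3)
#> [1] 0.708

q      <- seq(0.01, 0.5, length.out = 240)           # A^-1
curves <- lapply(c(fc = "fc", uf = "uf"), function(s)
    ensembleIntensity(concatenateStateFrames(gen$trajectory, asg, s),
                      q, stride = 10))
pe  <- generatePseudoExperiment(curves, c(fc = 0.75, uf = 0.25),
                                noise_fraction = 0.02, seed = 43)
fit <- fitPopulations(pe, curves)
fit
#> Population fit (chi2/N = 1.023 ):
#>   fc     77.6%
#>   uf     22.4%
#>   scale = 0.9951, background = 0, q range [0.01, 0.5] A^-1
reportDegreeOfFolding(fit)$text
#> [1] "78%"
```

The trajectory's own folded frame fraction (70.8%) and the SAXS-fitted
degree of folding (77.6%) both recover the 75% ground truth within the
±5-point band the validation suite enforces; chi²/N ≈ 1 shows the fit
sits at the noise level. `runProtocol()` runs the same stages from a YAML
config and writes Rg tables, state assignments, predicted curves, Guinier
and Kratky results and a JSON fit report;
`inst/scripts/glycosaxs.R` exposes every stage as a shell subcommand
(`simulate`, `rg-series`, `assign-states`, `predict-saxs`, `guinier`,
`kratky`, `fit-populations`, `run-protocol`).

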