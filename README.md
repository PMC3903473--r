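# micniche

**micniche** is a three-dimensional, multi-scale agent-based simulator of
multiple myeloma growth in bone marrow, built around the biophysical niche
hypothesis: myeloma-initiating cells (MICs) secrete SDF-1, stromal cells
contract and stiffen in response, and stiff niches in turn boost MIC
proliferation, self-renewal and drug resistance. It is aimed at
computational-biology users who want to explore how niche-targeted drugs
(the CXCR4 antagonist AMD3100) combine with cytotoxic chemotherapy
(Bortezomib) against stem-cell-driven disease.

## The model in brief

Cells of the myeloma lineage — MIC, progenitor (PC), mature (MM), terminal
(TMM) — live on a cylindrical lattice (one cell per site, 20 µm spacing).
Every 2 h step couples three scales:

* **Tissue:** the SDF-1 field `S` obeys
  `∂S/∂t = D ∇²S + σ·1(MIC sites) − λS` with a Dirichlet sink boundary
  (explicit FTCS, sub-stepped for stability); drug levels are spatially
  uniform on a clinical schedule (onset 200 h, 400 h on, 500 h off).
* **Intracellular:** all transfer functions are Hill responses
  `floor + (ceil − floor)·xⁿ/(Kⁿ + xⁿ)`; AMD3100 competitively rescales
  effective SDF-1 to `S/(1 + A/K_A)`; stromal stiffness `E ∈ [1, 10]`
  relaxes toward `E_base + (E_max − E_base)·hill(S_eff)`.
* **Cellular:** stochastic "dice-roll" decisions per cell per step —
  apoptosis (baseline + BZM hazard, stiffness-shielded for MICs), division
  (MIC fates: self-renewal / asymmetric / differentiation; PC and MM carry
  passage limits), and stiffness-biased migration
  (`weight ∝ exp(β·E)`).

Downstream analysis reproduces the study design: factorial dose sweeps on a
12-level geometric ladder (0, 0.1×…10×), dose–effect surfaces, Gaussian
smoothing, E50/E100 isoboles, and Loewe combination indices
`CI = d_A/D_A(E) + d_B/D_B(E)`.

## Worked example

```r
library(micniche)

cfg <- sim_config("MBMSC", t_end = 600)   # myeloma-associated stroma
sim <- run_sim(cfg, seed = 3)
sim
#> Myeloma niche simulation (MBMSC, seed 3): 600 h simulated
#>   final counts: 434 MIC, 751 PC, 1170 MM, 7090 TMM (total 9445)
summary(sim)
#> MBMSC niche, 600 h: total 400 -> 9445 (23.61-fold)
#>   final: MIC 434, PC 751, MM 1170, TMM 7090; CD138+ fraction 87.5%;
#>   peak stiffness 9.71
infiltration_diameter(sim)    # µm, 95th-percentile frontier diameter
plot(sim)                     # lineage time series
```

The printed numbers read as follows: starting from 400 seeded cells (100
per type), the stiffened MBMSC niche sustains an expanding MIC pool (434 at
600 h) that drives ~24-fold total growth, while the population remains
dominated by CD138⁺ mature/terminal cells; peak niche stiffness sits near
the saturation value 10. Under `"NBMSC"` the same simulation stays close to
baseline stiffness and the MIC pool drifts downward — the fold difference
between the two niches is the model's headline calibration quantity.

Treatment and synergy:

```r
# one treated run: 1x Bortezomib, no niche inhibitor
cfg <- sim_config("MBMSC", t_end = 1000,
                  schedule = dose_schedule(bzm_dose = ladder_level(6)))
run_sim(cfg, seed = 1)        # MICs survive in the stiff core -> relapse

# desk-scale factorial sweep and Loewe analysis
store <- run_sweep(sweep_design("desk"), sim_config("MBMSC", t_end = 600),
                   seed_base = 1)
er <- effect_surface(store, "mic_eradication", "MBMSC")
isobole_ci(er, 0.999)         # E100 combination indices (CI < 1: synergy)
```

A thin command-line wrapper is installed at
`inst/scripts/mmniche` (`simulate`, `sweep`, `synergy`, `metrics`,
`fixtures`).

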