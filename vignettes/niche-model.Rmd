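---
title: "The MIC-niche model: scales, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The MIC-niche model: scales, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micniche)
```

## The biological model

Multiple myeloma is organised as a cellular hierarchy. A small population of
stem-like **myeloma-initiating cells** (MICs; side-population, CD138-negative)
can self-renew indefinitely, re-establish the whole lineage, and resist
chemotherapy. MICs give rise to **progenitor cells** (PCs) with a limited
number of passages, which mature into CD138-positive **myeloma cells** (MMs,
still dividing) and finally **terminal cells** (TMMs, post-mitotic). In
patients the CD138-positive compartment makes up roughly 90–95% of the
myeloma population.

The model's central mechanism is a chemo-physical positive feedback loop
between MICs and bone-marrow stromal cells (BMSCs):

1. MICs secrete the chemokine **SDF-1** (CXCL12) into the marrow.
2. Stromal cells sense SDF-1 through CXCR4 and **contract**, raising the
   local tissue stiffness.
3. Stiff niches **boost MIC proliferation and self-renewal** and **shield
   MICs from cytotoxic drugs**.

Myeloma-associated stroma (MBMSC) is far more sensitive to SDF-1 than normal
stroma (NBMSC), so the loop ignites only in the diseased microenvironment.
Two drugs probe the loop: **Bortezomib** (BZM), a cytotoxic agent modelled as
a dose-dependent apoptosis hazard, and **AMD3100**, a competitive CXCR4
antagonist that does not kill cells but rescales the effective SDF-1 to
`S / (1 + A / K_A)`, starving the niche.

## Three coupled scales

* **Tissue scale.** A cylindrical bone-marrow domain embedded in an
  `nx × ny × nz` site lattice. The SDF-1 field obeys a reaction–diffusion
  equation (secretion at MIC sites, lattice diffusion, first-order decay,
  Dirichlet sink boundary). Drugs are spatially uniform: marrow is well
  vascularised and small-molecule diffusion is fast compared with every
  cellular timescale, so drug fields are replaced by scheduled levels.
* **Intracellular scale.** All transfer functions are Hill responses
  `floor + (ceiling − floor)·x^n/(K^n + x^n)`: stromal activation from
  sensed SDF-1, per-type division probability and MIC self-renewal from
  local stiffness, drug kill from dose, and MIC drug protection from
  stiffness. Baselines and saturations are parameters, never hard-coded.
* **Intercellular scale.** Each cell is an agent on the lattice (one cell
  per site). Per 2 h step and per cell, in order: dying progression,
  apoptosis decision, division attempt, migration. Every stochastic
  decision is one uniform draw against a probability ("dice rolling").
  Division places the daughter on an adjacent free site; a fully
  surrounded cell stays in M-phase and retries. Migration samples a free
  site within the search distance with weight `exp(β·E)`, so MICs (β > 0)
  drift toward and stay on stiff stroma — this retention is what keeps the
  niche ignited.

BMSCs themselves are modelled as a stationary per-site stromal property
(the stiffness field) rather than as mobile agents: the stromal network
only contracts in place, so a scalar field is the natural representation,
and myeloma cells and stroma coexist at a site.

## Parameters that matter

All defaults live in `mm_params()`; the table lists the most consequential
ones (relative units: stiffness in `[E_base, E_max] = [1, 10]`, doses in
multiples of the 1× reference dose).

| Parameter | Default | Units | Role |
|---|---|---|---|
| `spacing` | 20 | µm | one myeloma cell diameter per site |
| geometry | 40×40×40 | sites | 0.8 mm cube; cylinder radius 400 µm |
| `dt` | 2 | h | macro time step |
| `sdf1$D` | 200 | µm²/h | effective SDF-1 diffusivity |
| `sdf1$lambda` | 0.3 | 1/h | decay; gradient length ≈ 26 µm keeps niches local |
| `sdf1$sigma` | 5 | conc/h | secretion per MIC |
| `stiffness_response` (MBMSC) | K=1.2, n=2, ceil=1 | – | stromal activation |
| `stiffness_response` (NBMSC) | K=4, n=2, ceil=0.07 | – | near-inert normal stroma |
| `k_contract` | 0.06 | 1/h | stiffness relaxation (τ ≈ 17 h) |
| `behavior$self` | 0.32→0.43 over E | – | MIC self-renewal; 1/3 is the branching-neutral point |
| `lineage$LGN_PC`, `LGN_MM` | 2, 1 | passages | lineage amplification 2^(LGN_PC+LGN_MM) per PC |
| `K_A` | 0.06 | 1× units | AMD3100 competition constant |
| `drug$bzm` | K=4, n=2 | 1× units | shared kill curve shape, per-type ceilings |
| `drug$mic_resistance` | 0.85 | – | intrinsic MIC resistance multiplier |
| `drug$protection` | K=4, n=2, ceil=0.93 | – | stiffness shielding of MICs |

Why these shapes: the MIC self-renewal floor sits just below 1/3, the
neutral point of the division branching process (`E[ΔMIC]` per division is
`2·p_self + p_asym − 1`), so MIC counts drift slowly downward in normal
marrow and expand only where the niche stiffens. The drug curves share one
Hill shape (K = 4, n = 2) across cell types so that relative resistance is
carried by the MIC multipliers — the intrinsic factor and the
stiffness-dependent shield — keeping the MIC hazard below the bulk hazard at
every dose, while the wide dynamic range (half-max at 4×) separates the
doses that cure normal-stroma disease (1×) from the doses that overwhelm
even protected niches (≈4×–10×).

## Treatment design

Dosing follows the clinical-style schedule: drugs on at 200 h after
seeding, a 400 h treatment window, 500 h rest; levels are constant inside
the window (no pharmacokinetics, a stated simplification) and only the
first cycle is simulated. Doses live on a 12-level ladder: level 0 is the
control and levels 1–11 are a geometric sequence from 0.1× to 10×
(`0.1·10^{0.2(i−1)}`), so level 6 is exactly 1×.

## What the simulations and fixtures emulate — and what they do not

The synthetic scenario generators (`make_fixture()`) produce: tiny lattice
configurations for trace-level tests; Loewe-additive and synergistic
dose–effect surfaces constructed from two Hill curves by dose equivalence
(effective dose `d_A + (K_A/K_B)·d_B`), on which the combination index is
1 (or < 1) *by construction*; an analytic sweep store with
Poisson-replicate counts; and digital balls for the frontier metric. These
fixtures validate the analysis pipeline independently of the simulator.

Passing tests therefore show that the implementation realises this model
faithfully — not that the model captures patient marrow. Real bone marrow
has vasculature, bone remodelling, heterogeneous stroma density,
pharmacokinetics, immune components, and sub-clonal evolution, none of
which are represented. Calibration anchors the model to a handful of
printed summary quantities, not to longitudinal patient data.

## Numerical choices

* **SDF-1 solver.** Explicit forward-time central-space 7-point stencil,
  sub-stepped so `dt_sub·(6D/h² + λ) ≤ 1` (hence `D·dt_sub/h² ≤ 1/6`).
  Secretion, diffusion and decay advance *together* within every sub-step,
  so the scheme's fixed point is exactly the steady discrete
  reaction–diffusion equation; the test suite checks quasi-steady fields
  against an independent sparse direct solve to < 1%. A reflecting
  boundary mode exists purely as a mass-conservation self-check.
* **Determinism.** One R RNG stream per run seeds everything, including
  the C++ core (which draws through R's generator); a (config, seed) pair
  replays bit-for-bit. Candidate sites are enumerated in fixed
  lexicographic order so the uniform draw is the only stochastic element;
  cells are visited in a freshly shuffled order each step to avoid sweep
  bias.
* **Degenerate inputs.** Zero-length runs return the seeding record;
  empty tumours relax fields only; blocked divisions retry next step;
  `t_end` must be a multiple of `dt`; invalid geometry, niche names,
  probabilities and unknown config keys are rejected at construction.
* **Isobole/CI arithmetic.** Single-agent dose–effect curves are
  monotonised by isotonic regression (replicate noise can break
  monotonicity) and inverted on the log-dose axis (the ladder is
  geometric). Combination indices are always computed on raw monotonised
  surfaces; Gaussian smoothing (θ = 2, edge-renormalised kernel) is for
  visualisation only. Contours come from marching squares
  (`grDevices::contourLines`) in grid-index space and are mapped to dose
  space geometrically; the zero-dose axis is anchored at half the lowest
  ladder dose for plotting, never for CI arithmetic.

## Design decisions on genuinely open points

* **Neighbourhood.** Moore (26-connected); migration reach 2 sites,
  daughter placement 1 site ("much smaller migration distance" for
  divisions).
* **Update precedence.** Dying → apoptosis → division → migration, cells
  in shuffled order; fields update before cells within a macro step so
  cells sense the current microenvironment.
* **Daughter clocks reset** to the full cycle length; both PC/MM
  daughters inherit the incremented passage (the stricter reading of
  limited passaging). A PC reaching its passage limit becomes MM at that
  division; an MM reaching its limit becomes TMM.
* **Quiescence** is an emergent label (a live cell that neither divided
  nor migrated), not a state with its own dynamics.
* **Only MICs secrete SDF-1** by default (they over-secrete relative to
  mature cells; the simplification is configurable per type via the
  secretion parameter).
* **E100** is operationalised as the fraction of replicates ending with
  zero MICs reaching 1.0 — complete eradication is a per-run event, and
  the replicate fraction is its estimable surface.
* **CI with an inactive single agent.** Where one drug alone never
  reaches the effect level (AMD3100 never eradicates MICs by itself), its
  dose-equivalence term vanishes (infinite equivalent dose); the index is
  undefined only when no positive-dose component has a finite equivalent
  dose. This is what makes E100 isoboles informative for a niche
  inhibitor.
* **1× calibration.** BZM 1× is the minimal ladder level that eradicates
  MICs in all normal-stroma replicates; AMD 1× deprives the
  myeloma-associated niche (drives its stiffness trajectory back toward
  the normal one). The shipped defaults realise both anchors.

## Problem sizes

The shipped desk-scale geometry is a 40×40×40 lattice (0.8 mm cube) —
large enough that the tumour (frontier radius < 300 µm through 1000 h)
never touches the cylinder wall. Calibration experiments use 20 untreated
replicates per niche to 600 h; the treatment dichotomy uses 10 replicates
per niche to 1000 h; the desk sweep preset covers a 5×5 dose grid
(levels 0, 2, 6, 9, 11) under both niches at 5 replicates to 600 h. The
full published design (12×12×2 conditions × 20 replicates) is available
through `sweep_design("full")` as an opt-in long-running command.

## Known limitations

* Stiffness is a scalar per site; there is no mechanical force balance,
  cell deformation, or off-lattice motion.
* Passage limits are sharp thresholds; real lineage maturation is
  graded.
* The death spiral of a collapsing niche (MIC loss → SDF-1 loss →
  stiffness loss → protection loss) makes high-dose outcomes sharper than
  intermediate-dose ones; replicate counts should be scaled accordingly
  when estimating eradication probabilities near the threshold.
* Single treatment cycle only; no pharmacokinetics, no acquired (genetic)
  resistance.
* On the 5×5 desk dose grid the E50 isobole has only a handful of
  vertices, so isobole-level combination-index summaries are
  coarse-grained; finer dose grids (the full 12×12 design) give smoother
  isoboles at proportionally higher cost.
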