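---
title: "Methods: withdrawal-corrected gas balances and the bottle simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: withdrawal-corrected gas balances and the bottle simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cowgas)
```

## The measurement problem

A thermophilic facultative anaerobe carrying a co-localized anaerobic CO
dehydrogenase and a group 4a [Ni-Fe] hydrogenase can run the water-gas-shift
(WGS) reaction, CO + H₂O → CO₂ + H₂, once oxygen is gone. The experiment that
demonstrates this is a closed serum bottle (250 ml, 50 ml rich medium,
headspace 50 % CO / 50 % air at 1 bar) sampled repeatedly over 84 h: at each
event the operator records pressure, draws ~3 ml of headspace for GC, records
pressure again, and aspirates 1 ml of culture for OD₆₀₀.

Each event therefore removes material. Over ~18 events roughly 25 % of the gas
phase leaves through the syringe, and the headspace volume grows by ~17 ml of
withdrawn liquid. Any statement such as "x mmol CO was consumed" is only
meaningful after that removal is accounted for.

## The balance

Amounts follow the ideal gas law per species $j$ at point $i$:

$$n_j(i) = x_j(i)\, P_\mathrm{before}(i)\, V_h(i) / (R\,T_\mathrm{inc}),$$

with $R = 0.0831446$ ml·bar·mmol⁻¹·K⁻¹ and
$V_h(i) = V_\mathrm{total} - V_\mathrm{liquid,0} + \sum_{k<i} v_\mathrm{liq}(k)$.
GC fractions are renormalized to sum to one before use. The syringe draws
headspace at bottle pressure, so the moles removed at event $k$ follow from
the bracketing pressure pair:

$$\mathrm{removed}_j(k) = x_j(k)\,\bigl(P_\mathrm{before}(k) - P_\mathrm{after}(k)\bigr)\,V_h(k)/(R\,T_\mathrm{inc}).$$

Cumulative net production credits withdrawals back:

$$Q_j(i) = n_j(i) - n_j(0) + \sum_{k<i} \mathrm{removed}_j(k),$$

so $Q_j$ changes only through reaction. $Q_j(0)=0$ by construction, and for an
inert tracer (N₂) $Q$ stays flat — the package's leak screen.

Derived statistics: the molar yield $Y = Q_{\mathrm{H}_2}/(-Q_{\mathrm{CO}})$
at the final point (defined only when CO was net consumed; reported to two
decimals in summaries, full precision internally); the H₂ onset time (first
point with $Q_{\mathrm{H}_2}$ above a detection threshold, default 0.02 mmol —
an invented default representing GC detectability, exposed as an argument and
CLI flag); the O₂ depletion time (first point with headspace O₂ below
0.05 mmol, same caveat); and growth maxima from the OD column (earliest
maximum on ties; missing ODs are skipped).

### Conventions that needed a decision

* **Temperatures.** Bottles are filled at ambient conditions and incubated
  warm. Amounts derived from incubation-phase pressure readings use
  $T_\mathrm{inc}$ (default 333.15 K); the nominal fill state uses
  $T_\mathrm{fill}$ (298.15 K) at 1 bar. The fill convention reproduces the
  observed initial amounts (0.85 mmol O₂ in a 200 ml headspace of 50 % air at
  1 bar/298.15 K); both are configurable in `bottle_spec()`.
* **"Consumed" excludes the syringe.** With ~3.2 mmol CO initially present
  and ~0.6–0.9 mmol leaving via sampling, defining consumption net of
  withdrawals is the only convention under which "CO was consumed completely"
  and a consumed total well below the initial amount can both be true.
* **Withdrawal composition** uses the same point's pre-sampling GC fractions,
  and the pressure drop is taken from the measured pair, never from the
  nominal 3 ml (operators do not draw exactly 3.000 ml).
* **Event ordering.** $P_\mathrm{after}$ is interpreted at the
  *pre-aspiration* headspace volume: gas draw, pressure reading, then liquid
  draw. This makes the removal ledger exact and is why
  `headspace_volume_at()` counts only liquid draws at strictly earlier
  points. Under this convention the null process (no biology, full sampling
  schedule) balances to zero at machine precision.
* **Missing values.** A missing $P_\mathrm{after}$ is imputed as
  $P_\mathrm{before}(1 - v_\mathrm{gas}/V_h)$ with a warning; missing OD is
  skipped in the growth summary.
* **Dissolved gas in the aspirated liquid is ignored** — there is no
  liquid-phase state anywhere in the accounting (see Limitations).

## The simulator

`simulate_wgs()` integrates a deliberately small ODE model whose state is
biomass $X$ (in OD₆₀₀ units), a growth substrate pool $S$, headspace mmol of
H₂/O₂/N₂/CO/CO₂, and a formate pool $F$. With $p_j = n_j R T_\mathrm{inc}/V_h$,
Monod factors $f_j = p_j/(K_j + p_j)$, substrate factor $f_S$, and the O₂
inhibition factor $I = K_{I,\mathrm{O}_2}/(K_{I,\mathrm{O}_2} + p_{\mathrm{O}_2})$:

* growth $\dot X = \mu_\mathrm{max} f_{\mathrm{O}_2} f_S X - k_d (1 - f_{\mathrm{O}_2}) X$,
  with $\dot S = -\mu_\mathrm{max} f_{\mathrm{O}_2} f_S X$;
* respiration consumes O₂ at $q_{\mathrm{O}_2} f_{\mathrm{O}_2} X$ and
  releases $y_{\mathrm{CO}_2/\mathrm{O}_2}$ CO₂ per O₂ (CO₂ dissolution into
  the medium is absorbed into this yield rather than modelled);
* WGS converts CO → CO₂ + H₂ at $q_\mathrm{wgs} f_\mathrm{CO}\, I\, X$;
* optional aerobic CO oxidation ($q_\mathrm{aco} f_\mathrm{CO} f_{\mathrm{O}_2} X$,
  0.5 O₂ per CO) and an unattributed first-order aerobic CO loss
  ($k_\mathrm{co,loss} f_{\mathrm{O}_2} n_\mathrm{CO}$) for control strains;
* a formate-hydrogenlyase term $q_\mathrm{fhl}\, I\, F/(K_F+F)\, X$ producing
  H₂ + CO₂ from the finite pool $F$ — the interpretation adopted here for the
  observed *supra*-equimolar H₂ yield (1.08 > 1); it is a modelling reading
  of the FHL biology, not a measured pathway.

The substrate pool is the one structural addition relative to the minimal
O₂-gated model: in rich-medium batch growth the OD peaks hours *before* O₂ is
exhausted (growth stops on some non-O₂ nutrient while maintenance respiration
keeps drawing down O₂). Without $S$, the biomass maximum would necessarily
coincide with O₂ depletion and the observed growth/onset chronology (OD max
near 6 h, O₂ gone near 22 h, H₂ onset near 36 h) could not be reproduced.
Setting `substrate_pool = Inf` recovers the purely O₂-gated form.

Kinetics act on headspace partial pressures; gas–liquid transfer is lumped
into the apparent rate constants (no kLa, no Henry equilibria), because the
underlying experiments provide no liquid-phase measurements to constrain a
two-film model.

**Integration and observation.** Fixed-step RK4 (`deSolve::ode(method =
"rk4")`, default step 0.01 h) between sampling times, chosen over adaptive
stepping for bit-reproducibility; sampling events are handled exactly at
their times. The observation layer records pressure, GC fractions and OD
(noise: additive Gaussian on pressure and OD, multiplicative Gaussian on
fractions followed by renormalization, all from one seeded generator), then
removes $v_\mathrm{gas}/V_h$ of every species and enlarges the headspace by
$v_\mathrm{liq}$. Negative states are prevented structurally (all rates
saturate through Monod terms); the integrator additionally rejects any state
below $-10^{-9}$ mmol. The simulator keeps per-pathway cumulative integrals,
so `ground_truth_balance()` provides an exact target for the accounting
pipeline.

## Scenario presets and their calibration

The experiments emulated are three strains under 50 % CO / 50 % air: a
WGS-positive *Parageobacillus thermoglucosidasius* culture, a *P. toebii*
control (aerobic CO oxidation only, no H₂) and a *Geobacillus
thermodenitrificans* control (slight unattributed aerobic CO loss, no H₂),
plus an abiotic control. No rate constants are available for any of them, so
every kinetic value in `scenario_preset()` is a **calibration artifact**: the
constants were tuned once so that the full pipeline — simulate, observe with
withdrawals, re-analyze — reproduces the published endpoints (2.28 mmol CO
consumed / 2.47 mmol H₂ / 2.84 mmol CO₂ at 84 h with max OD 0.82 near 6 h and
H₂ onset at the 35.89 h sampling; 0.37 and 0.216 mmol CO for the two
controls), and then frozen. They are plausible in magnitude
(e.g. $\mu_\mathrm{max} = 0.6\,h^{-1}$, $q_{\mathrm{O}_2} \approx 0.06$
mmol·h⁻¹ per OD unit) but should not be quoted as physiology. Initial
amounts derive from the 1 bar / 298.15 K fill (8.068 mmol total in 200 ml)
with CO and O₂ set to the observed initial values — the reported initial CO
(3.20 mmol) corresponds to a GC fraction near 40 %, not the nominal 50 %, and
is taken at face value. Sampling schedules use 2–4 h spacing to 48 h and 12 h
thereafter (~17–18 withdrawals), including the exact published event times
(6.01, 35.89 h, etc.).

What passing the synthetic tests establishes: that the accounting recovers
known reaction totals *exactly* under realistic sampling losses, stays exact
for null and inert-tracer processes, and is unbiased (±0.03 in yield over 20
seeds) under 2 % GC noise. What it does not establish: anything about
gas–liquid transfer limitation, CO₂ speciation in the medium, leaks, or real
GC calibration error — the generator does not emulate those.

## Locus genomics conventions

Pairwise protein comparison is Smith–Waterman local alignment with affine
gaps (BLOSUM62, gap open 11, extend 1 — BLAST-like defaults), computed by
`Biostrings::pairwiseAlignment()`; the test suite verifies the scores against
an independent exhaustive enumeration of all gapped local alignments for
short sequences. Where several alignments are co-optimal the engine's
deterministic choice is used; the score, identity and coverage of the
examples exercised in tests are unaffected. Identity is computed over aligned
residue *pairs* (gap columns excluded from numerator and denominator);
coverage is the fraction of a sequence's residues inside the aligned region,
assessed on the query by default (`require_both = TRUE` demands both) — the
published rule does not say which sequence, and query coverage is the weaker,
more inclusive reading. Orthology requires identity strictly above 30 % *and*
coverage at least 0.70; pairing between loci is by reciprocal best score with
lexicographic id tie-breaks, each protein in at most one pair. AAI is the
plain mean identity over orthologous pairs. G+C content excludes `N` from the
denominator, and locus deviation is reported signed, in percentage points.
`mutate_protein()` generates fixture pairs at controlled identity (±2 points,
verified by re-alignment), seeded for reproducibility.

## Problem sizes and runtime choices

The shipped scenarios integrate 84 h at 0.01 h steps (~8 400 RK4 steps,
13-dimensional state) — well under a second per run. The property suites use
20 noise seeds for the robustness check, 5-point series for the brute-force
ledger oracle, and 200 random pairs of length ≤ 5 for the alignment oracle;
these sizes make every oracle exhaustive or exact while keeping the whole
suite around two minutes.

## Known limitations

* No liquid-phase gas accounting: dissolved CO₂ (and its pH-dependent
  speciation) is folded into the respiratory CO₂ yield; absolute CO₂ balances
  carry that interpretation.
* The formate-pool FHL term is one mechanistic reading of supra-equimolar
  yields; alternative explanations (e.g. endogenous formate production during
  anaerobiosis) are observationally equivalent at this data resolution.
* The N₂ flatness check screens for leaks but the package makes no attempt to
  estimate a leak rate.
* Yield and onset are only as good as the GC fractions: systematic GC
  calibration error propagates directly and is not modelled beyond the
  random-noise robustness checks.
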