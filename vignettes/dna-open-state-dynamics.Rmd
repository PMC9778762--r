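---
title: "Torsional DNA dynamics, deuterium substitution and open-state classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Torsional DNA dynamics, deuterium substitution and open-state classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(dnaos)
```

## The model

`dnaos` studies base-pair *open states* (OS) — transient breaks of the
inter-strand hydrogen bonds — in a coarse-grained angular model of
double-stranded DNA. Each nitrogenous base is a rigid rotor on its
sugar-phosphate backbone; pair `i` on chain `j` has angular deflection
`phi[j,i](t)`. The 2n Newton equations couple each rotor to its backbone
neighbours through a torsion constant `K` (a discrete Laplacian with
one-sided terms at the ends) and to its complementary base through a
transverse spring of stiffness `k12`. Every base also feels viscous
damping `-beta * dphi/dt` (the surrounding water) and a deterministic
periodic torque `F0 * cos(omega * t)`. There is no thermal noise term:
the model is fully deterministic.

The inter-strand coupling of pair `i` derives from a single potential

```
V_i(phi1, phi2) = k12_i * [ (R1+R2)^2 + R1*R2
                            - R1*(R1+R2) * cos(phi1)
                            + R2*(R1+R2) * cos(phi2)
                            + R1*R2 * cos(phi1 - phi2) ]
```

whose negative partial derivatives are the coupling torques on the two
chains. `(phi1, phi2) = (0, pi)` is the global minimum, `V_i(0, pi) = 0`,
so the binding energy is non-negative and the equilibrium configuration
(`phi1 = 0`, `phi2 = pi`, zero velocities) is a stable stationary point.
Deriving both chains' torques from one potential was a deliberate design
choice: the two printed sign conventions floating around for the
cross-chain term are typographically inconsistent, whereas
`torque = -dV/dphi` is self-consistent and directly testable by finite
differences (the suite checks it to 1e-6 relative at 100 random angle
pairs).

### Bond automaton

Each pair carries a binary bond flag `delta[i]`. After every full
integration step the binding energy `V_i` is compared with the pair's
critical energy `Ecr[i]`: the bond *breaks* (`delta = 0`) when
`V_i > Ecr[i]` and is *restored* (`delta = 1`) when `V_i < Ecr[i]`;
exact equality leaves the flag unchanged, because both rules are strict
inequalities. A broken pair loses only its transverse coupling torque —
`V_i` is always evaluated with the full `k12[i]`, since a broken bond
must still be tested for restoration. Flags are frozen within a step
(the automaton is applied once per step, not per RK4 stage), which keeps
the integrator deterministic and the event handling unambiguous.

### Deuterium substitution

Replacing one hydrogen bond of pair `i` by deuterium strengthens the
pair by the factor `kD = 1.05` (a deuterium bond is about 5% stronger):
`k12_D = kD * k12_H` and `Ecr_D = kD * EcrH`. The rule is applied to the
pair as a whole, for A-T (2 bonds) and G-C (3 bonds) alike. `kD = 1`
must — and, by test, does — reproduce the unsubstituted trajectory
bitwise.

## Parameters

Per-base mechanical coefficients (`mech_params()`): rotational inertia
`I` (kg m²), backbone distance `R` (m), torsion constant `K` (N m),
pair stiffness `k12` (N/m), damping `beta` (J s). The shipped defaults
are literature-typical values for Yakushevich-type base rotors
(`I`: A 7.61, T 4.86, G 8.22, C 4.11 ×1e-44 kg m²; `R`: 5.8/4.8/5.7/4.7
×1e-10 m; `K = 0.7 N/m × R²`; `k12` 0.062 N/m for A-T pairs, 0.096 for
G-C). They are a *calibration input*, not measured constants — the
coefficient set used for the published 980-pair interferon-alpha-17
(IFNA17) analysis is cited there from an external source and not
reprinted, so absolute open-state probabilities from this package are
not comparable with the published absolute values (see Limitations).
`beta` is likewise not printed anywhere; the default `beta = I / 1e-10`
gives a damping time of 1e-10 s, the order of the simulated window, and
is flagged as a knob.

Simulation settings (`sim_config()`) default to the study conditions:
`F0 = 0.526e-22` N m, `omega = 0.4e12` 1/s, total time `T = 3e-10` s,
step `dt = 1e-14` s, `m = 1000` sample times `t_j = j T / m` (t = 0,
being the equilibrium start, is not sampled). The open-state probability
is the time average of the broken-pair fraction,
`P = mean(q_j)`, `q_j = #(delta = 0) / n`. `m` is not stated in the
source; 1000 is this package's documented choice.

## Numerical choices

* **Integrator**: classical fixed-step RK4. Simple, deterministic, and
  testable: with damping and forcing off and no bond events, the energy
  drift over 1e4 steps on a uniform (poly-A) 10-pair chain is below
  1e-6 relative (measured: ~1e-11); small-angle eigenfrequencies of the
  single-pair system match the analytic 2×2 generalized-eigenvalue
  oracle to ~1e-9.
* **Step-size guard**: `dt <= 0.5 / omega_char`, with `omega_char` the
  largest pair frequency `sqrt((K + k12 R (R+R'))/I)`. With the default
  coefficients `omega_char ~ 5e12` 1/s, so the default `dt = 1e-14` s
  runs at `omega_char * dt ~ 0.05` — comfortably accurate, and far below
  RK4's stability limit (~2.8/omega). A stricter guard of
  `0.05/omega_char` was considered and rejected: it would contradict
  the default step it is meant to protect.
* **Backbone energy with per-base constants**: the printed equations use
  the *base's* torsion constant on both its neighbour differences, which
  is conservative only when adjacent constants are equal. The energy
  bookkeeping in `system_energy()` uses the segment mean; conservation
  tests use uniform (single-letter) chains where the point is moot.
* **Degenerate inputs**: `V = Ecr` exactly leaves the bond flag
  unchanged; `EcrH = Inf` is accepted as "never breaks"; non-finite
  states abort with the step and pair index.

## Classification (modified Basov–Jimack algorithm)

For each critical energy, the scan yields the baseline probability `P0`
and per-site probabilities `P_i` (site `i` deuterium-substituted). With
`Pimax = max(P_i)`, `Pimin = min(P_i)`, and provided
`Pimax > P0 >= Pimin >= 0`:

* branch 1 — if `Pimax - (Pimax - Pimin)/10 >= P0 + (Pimax - P0)/2`,
  the "Maximum" threshold is `Pimax - (Pimax - Pimin)/10`;
* branch 2 — otherwise it is `Pimax - (Pimax - P0)/4`;
* membership is `P_i >= threshold`; when `Pimax <= P0` or `P0 < Pimin`
  the range is empty (`nmax = 0`), which is exactly what the saturated
  top-energy rows of the published tables show.

A site is a *closed state* (CSNB) when `P_i = 0` — an exact zero, no
tolerance: the estimator is a mean of non-negative rationals, so it is
zero iff no break was ever sampled. The *new-approach weighting*
corrects part-wise CSNB counts for gene-wide saturation:

```
n_CSNB = nx * (1 - ngCSNB/ng)^2
```

with `nx` the part's raw count, `ngCSNB` the whole-gene count at that
energy and `ng` the gene length. Truncation toward zero is applied to
reported sums (it reproduces the published per-part sums 105 and 51);
the continuous values are kept for correlation analyses (they reproduce
the published Spearman coefficient 0.881, with the G-C-restricted count
damped by the same whole-gene factor). Both behaviours are exposed.
The `Q2–Q4` minimum rule
(`P_i <= Pimin + (3/4)(P0 - Pimin)`) is implemented as a separate
operation but unused by default: above the saturation energy `P0 = 0`
makes it coincide with the CSNB rule, and the source leaves its role in
that regime unstated.

## Statistics

The toolkit mirrors the published analysis: the Yates-corrected 2×2
chi-squared in its shortcut form
`N (|ad-bc| - N/2)^2 / (NA NB NS NF)` with the continuity correction
clamped at zero (the raw formula would manufacture positives from null
tables); the 3×2 Pearson chi-squared with caller-supplied Bonferroni
family size (the source does not state `k`; the pipeline uses 3, one per
pairwise part contrast); tie-corrected Kruskal–Wallis (H defined as 0
when all observations are equal); and *two* Spearman variants — the
`d²` formula on mean ranks, and the Pearson correlation of mean ranks —
because the published coefficients require one each (0.994 comes from
the `d²` form, −0.547 and 0.881 from Pearson-on-ranks; the variants
agree exactly on tie-free data and are cross-checked against
`cor(method = "spearman")`). Spearman p-values use the t approximation
on n−2 degrees of freedom, consistent with the printed p = 0.035 at
n = 15.

## Synthetic genes

`synthesize_gene()` emulates the composition of the studied gene, not
its (unpublished) sequence: part lengths 327/326/327 with exact A-T
counts 163/186/236 (A-T fractions 49.8/57.1/72.2%, converted with
round-half-away-from-zero, which reproduces 0.722×327 → 236). Pair
positions and strand orientation (A-T vs T-A) are drawn from a seeded
RNG, so a spec plus seed is bitwise reproducible, and the generator
restores the caller's RNG state. What it does **not** emulate: real
codon structure, dinucleotide correlations, or the actual IFNA17
sequence — so simulation results on synthetic genes show model
behaviour under realistic composition, not gene-specific predictions.

## Problem sizes used in the shipped checks

The packaged end-to-end check scans a 60-pair synthetic gene (20 pairs
per part at the real per-part A-T percentages) over three critical
energies with `m = 500` samples, `T = 3e-11` s, `dt = 1e-14` s — 183
simulations of 3000 steps each, a few tens of seconds on one core. The
three energies are chosen by construction: 2e-25 J sits below the
energies the forced toy system actually reaches (so open states occur),
6e-25 J is marginal, and 1e-18 J exceeds the analytic bound
`V_i <= k12 (2 (R1+R2)^2 + ... )` (~3e-19 J), so above it `P0 = 0`
provably — the qualitative shape of the published
probability-versus-energy curve, at toy scale.

## Limitations

* Absolute reproduction of the published per-energy counts and
  `P0`/`Pimax` columns is out of reach by construction: it requires the
  exact IFNA17 sequence (no accession is printed) and the unreprinted
  coefficient set. Those columns ship as *data* in the fixture tables,
  and every published derived ratio and correlation is recomputed from
  them exactly; the simulator is validated by its physical invariants
  instead.
* The published part-II CSNB column sums to 1365 while the accompanying
  text quotes 1371; the fixtures transcribe the table verbatim and only
  internally consistent derivations are pinned.
* No helical geometry, stacking beyond per-base constants, thermal
  noise, or DNA–protein interactions; fixed-step explicit integration
  only.

## A worked example

```{r example, eval = FALSE}
g <- synthesize_gene(composition_spec(lengths = c(20, 20, 20),
                                      at_pct = c(49.8, 57.1, 72.2),
                                      seed = 42))
cfg <- sim_config(T = 3e-11, dt = 1e-14, m = 500)
sc <- scan_substitutions(g, mech_params(), cfg,
                         energies = c(2e-25, 6e-25, 1e-18))
cls <- classify_scan(sc, g)
print(cls)
part_comparison_stats(cls)
ratio_report()
correlation_report()
```
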