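# dnaos

Coarse-grained torsional DNA dynamics with hydrogen-bond break/restore,
used to ask: *how does a single ²H/¹H (deuterium) substitution change the
probability of base-pair open states at the highest critical bond
energies?*

Each nitrogenous base is a rotor on its sugar-phosphate backbone. For
pair *i* on chain *j* with deflection φ<sub>ji</sub>(t), the 2n Newton
equations are

    I φ'' = K Δφ (backbone)  +  δ_i · (−∂V_i/∂φ) (pair coupling)
            + F0 cos(ωt)  −  β φ'

where V<sub>i</sub>(φ₁, φ₂) is a pair potential with global minimum 0 at
the equilibrium (0, π), and δ<sub>i</sub> ∈ {0, 1} is a bond flag driven
by an automaton: the bond breaks when V<sub>i</sub> > E<sub>cr</sub> and
is restored when V<sub>i</sub> < E<sub>cr</sub>. A deuterium
substitution at pair *i* scales that pair's stiffness and critical
energy by k<sub>D</sub> = 1.05. The open-state probability is the
time-averaged broken-pair fraction, P = m⁻¹ Σ<sub>j</sub> q<sub>j</sub>;
P₀ is the all-protium baseline and P<sub>i</sub> the value with a single
substitution at site *i*. Sites are then classified with the modified
Basov–Jimack algorithm: a branch-dependent high threshold defines the
"Maximum" range (n<sub>max</sub>), sites with P<sub>i</sub> = 0 are
closed states (CSNB), and the new-approach weighting
n<sub>CSNB</sub> = n<sub>x</sub>(1 − n<sub>gCSNB</sub>/n<sub>g</sub>)²
corrects part-wise CSNB counts for gene-wide saturation.

The package provides:

* `gene_sequence()` / `read_gene_sequence()` / `synthesize_gene()` —
  gene representation with the I/II/III tripartition and a seeded
  generator with exact per-part A-T composition;
* `mech_params()`, `sim_config()`, `integrate_dynamics()` — the RK4
  integrator (compiled core) with the bond automaton;
* `scan_substitutions()`, `classify_scan()` — the per-site substitution
  scan and the modified Basov–Jimack classification (including the
  weighted-CSNB correction);
* `yates_chi2()`, `chi2_rx2_bonferroni()`, `kruskal_wallis()`,
  `spearman_d2()`, `spearman_rank_pearson()` — the statistical toolkit;
* `load_fixture_tables()`, `ratio_report()`, `correlation_report()`,
  `run_pipeline()` — packaged reference count tables for the 980-pair
  IFNA17 case and every derived ratio/correlation recomputed from them.

## Worked example

A 60-pair synthetic gene with the real per-part A-T percentages, a full
60-site substitution scan at three critical energies (the top one above
the analytic bound on the pair potential, so nothing can break there):

```r
library(dnaos)
g <- synthesize_gene(composition_spec(lengths = c(20, 20, 20),
                                      at_pct = c(49.8, 57.1, 72.2),
                                      seed = 42))
cfg <- sim_config(T = 3e-11, dt = 1e-14, m = 500)
sc <- scan_substitutions(g, mech_params(), cfg,
                         energies = c(2e-25, 6e-25, 1e-18))
classify_scan(sc, g)
#> bj_classification over 3 critical energies (gene of 60 pairs)
#>   ecrh         P0  Pimax     Pimin  threshold branch nmax
#>  2e-25 0.78746667 0.7876 0.7874667 0.78758667      1    3
#>  6e-25 0.02006667 0.0222 0.0101000 0.02166667      2    2
#>  1e-18 0.00000000 0.0000 0.0000000         NA     NA    0
```

Read: at 2e-25 J bonds break easily (baseline P₀ ≈ 0.787, threshold
branch 1 selects 3 sites); at 6e-25 J opening is rare (P₀ ≈ 0.02,
branch 2, 2 sites); at 1e-18 J no bond ever breaks, P₀ = 0, every site
is a closed state and the Maximum range is empty — the qualitative
collapse to zero seen in the full-scale analysis.

The published derived statistics, recomputed from the packaged tables:

```r
rr <- ratio_report()
rr[rr$label == "weighted_csnb_partII_pct_of_partIII", ]
#>                                  label      value rounded digits
#>    weighted_csnb_partII_pct_of_partIII 205.882353   205.9      1
correlation_report()
#>                  label        rho      p.value  n
#>       csnb_vs_at_ratio -0.5470253 3.482784e-02 15
#>   weighted_total_vs_gc  0.8809524 3.850320e-03  8
#>       nmax_total_vs_gc  0.9941176 6.433997e-15 16
```

i.e. the weighted closed-state sums of parts II and III (105 vs 51
sites) differ by 205.9%, and the three rank correlations (−0.547,
0.881, 0.994) are reproduced exactly from the counts.

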