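# camine

Mining metagenome-derived protein sets for thermostable **carbonic
anhydrases (CAs)** — the enzymes that accelerate CO₂ hydration in biomimetic
hot potassium carbonate (BioHPC) carbon capture — and analysing the
downstream biochemistry of the candidates: stopped-flow CO₂-hydration
kinetics, thermal/alkaline stability, and pressurized batch-reactor CO₂
absorption.

The package is written for computational biologists and biochemical
engineers who have the *standard outputs* of an annotation pipeline (HMMER3
domain tables, tabular BLAST, Phobius topology calls, FASTA, sample
metadata) and want a tested, reproducible implementation of the selection
and analysis logic — not for re-running assembly or profile searches, which
stay in their canonical tools.

## What it implements

**Candidate screen** (`compile_report()`): a two-branch evidence cascade —
any hit against a curated set of CA-related Pfam profiles, or (for proteins
without such hits) a similarity hit at e-value ≤ 1e-50 against a
keyword-filtered CA reference — followed by filters for sampling-site
environment (T ≥ 80–90 °C, alkaline pH), the β-CA active-site motifs
**CxDxR** and **HxxC**, gene start/stop codons, family-plausible length,
and greedy de-duplication at ≥ 90% global identity (Needleman–Wunsch,
match +1 / mismatch 0 / gap −1, identity over the full alignment length).

**Stopped-flow kinetics**: initial absorbance slopes, uncatalyzed-rate
subtraction, conversion to CO₂ hydration rates through the indicator
buffering factor

    Q = [B·f_B(1−f_B) + I·f_I(1−f_I)] / [εℓ·f_I(1−f_I)]   (mol L⁻¹ A.U.⁻¹)

and Michaelis–Menten fitting (v = V·S/(K_M+S), Levenberg–Marquardt with
fixed data-driven starts), with kcat, K_M, kcat/K_M and standard errors.

**Stability**: Wilbur–Anderson units (t₀−t)/t, residual
activity/solubility percentages, and half-life by log-linear interpolation
of the post-maximum decay (robust to the transient "thermal activation"
bump thermophilic enzymes show).

**Reactor**: ideal-gas mass balance converting a closed-vessel pressure
drop into absorbed CO₂ (n = ΔP·V_h/RT), with initial absorption rate,
plateau time, productivity and removal efficiency, plus a pseudo-first-order
forward simulator used to validate the metrics.

**Synthetic data** (`make_screen_fixture()`, `make_stopped_flow_trace()`,
`make_decay_series()`, `make_pressure_curve()`, `make_mm_dataset()`): seeded
generators for every input, with planted ground truth the tests check
against.

## Worked example

```r
library(camine)

# --- screen a synthetic fixture with 4 planted CA-like positives ---------
fx <- make_screen_fixture(12, 4, seed = 7)
report <- compile_report(fx$proteins, fx$domain_table, fx$similarity_table,
                         fx$topology_table, fx$metadata, fx$config)
report
#> Candidate screening report: 12 proteins, 4 selected
#>  protein_id branch env_ok motifs_ok boundary_ok length_ok ... selected
#>    prot_002    fnr   TRUE      TRUE        TRUE      TRUE ...     TRUE
#>    prot_004   scap   TRUE     FALSE        TRUE      TRUE ...    FALSE
#>    prot_008   scap  FALSE      TRUE        TRUE      TRUE ...    FALSE
#>    ...
identical(sort(report$protein_id[report$selected]), fx$truth)
#> TRUE

# --- fit kinetics from a noisy synthetic rate dataset --------------------
d <- make_mm_dataset(kcat = 1.2e3, KM = 4.9e-3, enzyme_conc = 350e-9,
                     noise_cv = 0.03, replicates = 3, seed = 42)
fit_mm(d$substrate, d$rate, enzyme_conc = 350e-9)
#> Michaelis-Menten fit
#>   kcat      = 1.2e+03 1/s  (SE 33)
#>   KM        = 4.7 mM   (SE 0.39 mM)
#>   kcat/KM   = 2.6e+05 1/(M s)
#>   Vmax      = 0.00042 mol/(L s) at [E] = 3.5e-07 M

# --- half-life from a decay series with an early activation bump ---------
ser <- make_decay_series(24, c(0, 1, 2, 3, 6, 24),
                         activation_bump = 0.15, noise_sd = 2, seed = 11)
half_life(ser)
#> [1] 23.20293

# --- batch-reactor metrics from a simulated 210 min pressure run ---------
cfg <- reactor_config(temperature = 363.15)   # 90 degC, 7 bar, 20% CO2
curve <- simulate_pressure(cfg,
  forward_params(kla = 0.03, enhancement = 2, equilibrium_pressure = 0.015e5),
  seq(0, 210, by = 1))
reactor_metrics(curve, cfg)
#> Batch absorption metrics
#>   initial rate       = 4.89 mmol/(L min) over [0, 4] min
#>   plateau time       = 67 min
#>   productivity       = 1.34 mmol/(L min)
#>   removal efficiency = 98.9 %
#>   total absorbed     = 91.7 mmol/L
```

The screening report shows, per protein, which evidence branch it entered
and which criterion removed it (cold sampling site, missing motif, bad
codons, aberrant length, or redundancy with a selected representative); the
kinetic fit recovers the generating constants within the noise; the reactor
metrics quantify how fast and how completely the headspace CO₂ (92.7 mmol/L
of solvent at these settings) is absorbed.

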