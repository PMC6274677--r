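# hydromelt

Quantify protein hydration shells — and classify proteins as ordered or
intrinsically disordered — from wide-line ¹H NMR melting diagrams.

When an aqueous protein solution is frozen and slowly warmed through
equilibrium states, protein-bound water molecules start to rotate at much
lower temperatures than bulk ice melts. Wide-line ¹H NMR sees this as a
slowly decaying component of the free-induction decay (FID): its amplitude
extrapolated to *t* = 0 counts the mobile water protons. Plotting that
mobile fraction *n* against temperature gives a **melting diagram (MD)** —
a fingerprint of the protein's potential-energy surface as felt by its
hydration water.

`hydromelt` is for NMR spectroscopists and protein biophysicists who want to
go from raw two-component FID traces (or already-reduced MD tables) to the
thermodynamic order parameters of hydration heterogeneity.

## The model

Temperatures are carried on the **normalized fundamental temperature**
scale, *T*_fn = *T*/273.15 (thermal energy normalized to the melting point
of ice), and converted to excitation energies by the Waugh–Fedin relation

    E₀ = c · R · T,     c = 6.01 kJ/mol ÷ (R · 273.15 K) = 2.65

calibrated on the latent heat of bulk ice (R = 8.317 J/mol·K), which also
gives a water molecule ≈ 5.3 thermally active degrees of freedom.

The melting diagram itself is described piecewise: a sharp onset step to the
plateau level *A*, a flat plateau between *T*_fno and *T*_fne (the
homogeneously bound first hydration shell), and a power-series rise

    n = A + B·(T_fn − T_fn1) + C·(T_fn − T_fn2)² + …

above the plateau (the heterogeneous binding-energy region). Its derivative,
the **differential melting diagram (DMD)** Δn/ΔT_fn = B + 2C·(T_fn − T_fn2),
is the distribution of potential-energy barriers opposing bound-water
motion. From the fit the package derives:

| quantity | meaning |
|---|---|
| HeR = (1 − T_fne)/(1 − T_fno) | energy-range fraction that is heterogeneous (0 = bulk water, 1 = no plateau, IDP) |
| n_ho, n_he | first-shell and heterogeneous water, as fractions and waters per protein molecule |
| HeRn = n_he/(n_he + n_ho) | bond-count heterogeneity fraction |
| HeM = (B + 2C)/(1 − T_fne) | slope-like heterogeneity measure (tangent-like, not bounded by 1) |

## Worked example

A synthetic globular-protein archetype (ubiquitin-like preset: plateau
0.832–0.961 at A = 0.019), analysed end to end:

```r
library(hydromelt)

cal <- calibrate_c(6.01, 273.15)
#> Waugh-Fedin energy calibration: c = 2.6455 (prints as 2.65), degrees of freedom = 5.29

md  <- generate_md(md_presets("ubiquitin_like", noise_sd = 0.0005), seed = 42)
fit <- fit_melting_model(md)
fit
#> Melting-diagram fit
#>   onset  T_fn = 0.8292 (-46.7 degC)
#>   plateau T_fno = 0.8329, T_fne = 0.9576, A = 0.01881
#>   rise (order 2): B = 1.458e-08, C = 6.6, D = 0 (anchors at T_fne)
#>   rss = 7.13e-06, plateau noise sd = 0.000647

summarize_hydration(fit, md, sample_spec("UBQ", 50, 8565, 76))
#> Hydration parameters: UBQ
#>   T_fno = 0.833 (4)   T_fne = 0.958 (4)   HeR = 0.25 (2)
#>   n_ho = 0.0188 (2) (fraction), 178 waters/protein (2.3 per residue)
#>   n_he > 0.0102 (8) (fraction), > 96 waters/protein (lower bound)
#>   total bound = 275 waters/protein   HeRn = 0.35 (2)   HeM = 311
#>   excitation energies: 5.006 kJ/mol at T_fno, 5.755 kJ/mol at T_fne
```

Reading the output: the hydration shell starts melting near −46 °C; about
1.9 % of all water (≈ 2.3 molecules per residue) is bound homogeneously in
the first shell; a further ≥ 1 % melts between *T*_fne and 0 °C, so roughly
a third of the bound water sits in the heterogeneous region — the signature
of a globular protein (an IDP-like preset, `"erd10_like"`, gives HeR ≈ 0.7
and HeRn ≈ 0.9 instead).

The same pipeline runs from raw FID traces (`from_fid_series()` →
decomposition → Curie 1/T correction → normalization) and from the command
line:

```sh
Rscript inst/cli/hydromelt.R simulate --preset ubiquitin_like --seed 7 --out demo
Rscript inst/cli/hydromelt.R analyze  --md demo/ubiquitin_like_md.csv --spec ubq.json --out demo/out
Rscript inst/cli/hydromelt.R report   --fit demo/out/fit.json --spec ubq.json
```

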