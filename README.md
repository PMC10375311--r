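# pfnr

Geographic access to HIV preexposure prophylaxis (PrEP) in the US remains
starkly uneven: the locations willing to prescribe PrEP concentrate in urban
cores while the burden of new HIV diagnoses is far more dispersed. One policy
lever is letting pharmacies — dense, evenly distributed, and already trusted
for vaccination and medication management — provide PrEP services. `pfnr` is
an R package for quantifying what that expansion could buy, aimed at
HIV-prevention epidemiologists and health-services researchers working with
small-area facility and incidence data.

## The measure

For a spatial unit *i* (a ZIP code tabulation area or county) with facility
count *nᵢ* of a class *c* (PrEP-prescribing location or pharmacy) and 5-year
HIV incidence *Iᵢ* per 100 000 persons, the **PrEP facility-to-need ratio** is

&nbsp;&nbsp;&nbsp;&nbsp;PFNRᵢᶜ = nᵢᶜ / Iᵢ

Lower PFNRs indicate poorer geographic availability relative to need. The
ratio is undefined where incidence is suppressed (not released for privacy)
or zero; such units are excluded from summaries and counted, never imputed.
Per region, the package reports the mean, median and IQR of the unit PFNR
distribution per facility class, counts **facility deserts** (units with zero
facilities of a class), and computes the **fold increase**

&nbsp;&nbsp;&nbsp;&nbsp;fold = mean(PFNRᵖʰᵃʳᵐ) / mean(PFNRᵖʳᵉᵖ)

— the factor by which average availability relative to need would rise if
pharmacies provided PrEP, using full-precision means.

The pipeline around the measure: GeoJSON boundary and CSV facility/need
ingest with validation and an offline gazetteer, even-odd ray-casting
point-in-polygon assignment with deterministic boundary tie-breaks,
per-region reports, SVG choropleths with facility overlays, and a
synthetic-scenario generator (Poisson facility processes, lognormal
incidence, optional suppression) with known ground truth for validation.

## Worked example

Generate a synthetic metropolitan scenario (100 ZCTA-like units, clustered
prescribers, dense pharmacies, right-skewed incidence with 10% suppression)
and run the full pipeline:

```r
library(pfnr)
sc <- scenario_config(suppression_prob = 0.1, seed = 42)
res <- run_synthetic(sc, "demo")
res$pooled
#> Region all_regions: 100 units (93 used, 7 excluded)
#>   prescriber PFNR: 0.002829 (0 [0-0], n=93)
#>   pharmacy PFNR:   0.07734 (0.05759 [0.0276-0.08757], n=93)
#>   fold increase:   27.3
#>   deserts: 78 without a prescriber, 0 without a pharmacy
```

Read: of 100 units, 93 had a released, positive incidence estimate (7 were
suppressed). The median prescriber PFNR is 0 — most units have no
PrEP-prescribing location at all (78 prescriber deserts) — while every unit
has a pharmacy. Expanding PrEP provision to pharmacies would raise the mean
facility-to-need ratio 27.3-fold in this scenario. `demo/` now contains the
generated inputs, `report.csv` (per-region and pooled rows with mean, median,
IQR, fold and desert counts), `map_SYN.svg` (incidence choropleth with
hatched no-data units and both facility layers), and `run.log`.

Real data runs use `run_analysis(run_config(...))` or the YAML-driven CLI:

```sh
Rscript inst/cli/pfnr.R analyze --config run.yaml
Rscript inst/cli/pfnr.R synth --out-dir out --seed 7
```

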