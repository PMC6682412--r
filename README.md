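# redoxtrack

Single-cell quantification of chloroplast redox state with the
ratiometric biosensor roGFP, and the statistics that link early
oxidation to cell fate.

Photosynthetic microbes such as the diatom *Phaeodactylum tricornutum*
respond heterogeneously to oxidative stress: after an H2O2 pulse the
per-cell distribution of chloroplast glutathione oxidation splits into a
resilient 'reduced' subpopulation that oxidizes mildly and recovers, and
a sensitive 'oxidized' subpopulation pinned near 100% oxidation that
later dies. `redoxtrack` implements the full analysis chain for
measuring this, for two data sources:

- **flow cytometry**: event streams of i405/i488/chlorophyll/Sytox
  intensities, with roGFP-positive gating, per-event OxD, automatic
  splitting of the bimodal OxD distribution, dose/time courses of the
  oxidized fraction, Sytox dead fractions, and the linear
  death-versus-early-oxidation model;
- **time-lapse microscopy**: multi-channel stacks from a microfluidics
  chamber, with drift registration (phase cross-correlation), bit-depth
  normalization, background subtraction, masking, pixel-wise OxD,
  watershed segmentation, shape filtering, optimal centroid tracking,
  Sytox fate calling, and a logistic model of death probability versus
  early OxD whose 50% boundary is the OxD "death threshold".

A synthetic-data generator renders both kinds of data with known ground
truth (subpopulation structure, drift, noise, autofluorescence leakage,
threshold-coupled death), so every stage is testable without any raw
microscopy or cytometry files.

## The core quantities

The probe readout is the excitation ratio `R = i405 / i488`, which rises
with oxidation. Against fully reduced (DTT) and fully oxidized
(saturating H2O2) references it maps onto the **oxidation degree**

```
OxD = (R - R_red) / [ (i488_ox / i488_red) (R_ox - R) + (R - R_red) ]
```

so OxD(R_red) = 0 and OxD(R_ox) = 1; the probe's dynamic range is
`R_ox / R_red`. Apparent OxD above 110% (autofluorescence leakage into
i405) is flagged and excluded from all summaries. Cell fate is modelled
as `logit P(death) = b0 + b1 * OxD_40min`; the decision threshold is
`-b0 / b1`.

## Worked example

The `analysis/` directory holds the numbered drivers of the full
workflow (simulate flow experiment -> flow analysis -> death line ->
simulate time-lapse -> image pipeline -> tracking and fate). For
example, `Rscript analysis/03_death_line.R` simulates a 50-200 uM H2O2
dose range, estimates each sample's oxidized fraction 1.5 h post
treatment and its dead fraction at 24 h, and prints:

```
Sytox threshold (99.9% of control): 23.0 a.u.

Linear model over 25 samples:
  dead_fraction = 1.09 * oxidized_fraction -0.14
  R^2 = 0.90, p = 8e-13
```

i.e. the fraction of early-oxidized cells predicts the dead fraction a
day later almost one-to-one, with a negative offset (a small oxidized
fraction survives). `Rscript analysis/06_tracking_fate.R` runs the
imaging side on one simulated field and prints the per-field fate
model:

```
20 tracks (20 resolved, 0 unresolved)
Logistic cell-fate model (n = 20 cells)
  logit P(death) = -10.754 + 15.152 * OxD
  decision threshold: 71.0% OxD  [complete separation: class midpoint]
accuracy 100.0%, FP 0.0%, FN 0.0% (of 20 cells)
```

In a single 20-cell field the classes separate completely; the pooled
multi-field model (below) gives the stable threshold.

## Layout

- `R/` — package code: redox math and calibration, synthetic-data
  generators, flow pipeline, image pipeline, tracking, fate statistics,
  IO and run configuration.
- `analysis/` — numbered workflow drivers writing tables under
  `results/` (large raw artifacts go to `scratch/`).
- `tests/testthat/` — unit, property and acceptance tests, including
  brute-force oracles for the linking and regression steps.
- `vignettes/single_cell_redox.Rmd` — the methods vignette: model
  assumptions, parameter choices, generator realism and limitations.
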