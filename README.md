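# paMRM

Targeted LC-MRM-EPI lipidomics of phosphatidic acid (PA) molecular species,
in R.

PA is a low-abundance glycerophospholipid — the product of phospholipase D
(PLD) acting on phosphatidylcholine — that exists in tissue as a mixture of
molecular species differing in the length and unsaturation of the two fatty
acyl chains and in which chain occupies the *sn*-1 versus *sn*-2 position of
the glycerol backbone. `paMRM` implements the complete computational side of
a targeted, formula-driven workflow to enumerate, identify and quantify
those species from multiple-reaction-monitoring (MRM) data with
MRM-triggered enhanced-product-ion (EPI) spectra, for anyone running PA
panels on a triple-quadrupole / QTRAP instrument — and a synthetic-data
module so the whole pipeline is testable without an instrument.

## The model

Everything starts from the generalized chemical formula of a diacyl PA with
*m* total acyl carbons and *n* total double bonds:

    PA(m:n)  =  C(m+3) H(2m-2n+5) O8 P        (neutral)
    LPA(m:n) =  C(m+3) H(2m-2n+7) O7 P        (lyso form, one chain)

From it the package computes, with pinned monoisotopic atomic masses and
full electron bookkeeping in ions:

* **MS1 database** — per species: formula, neutral mass, and m/z under the
  nine common adducts ([M+H]+, [M+H−H2O]+, [M+NH4]+, [M+Na]+, [M+K]+,
  [M+Li]+, [M−H]−, [M+HCO2]−, [M+CH3CO2]−).
* **MS/MS database** — per acyl chain c:d: the carboxylate anion
  [RCOO]− = C(c)H(2c−2d−1)O2− and the lyso fragments that betray it.
* **MRM transitions** — Q1 = species [M−H]−, Q3 = candidate-chain anion, one
  transition per chain pair {c1:d1, c2:d2} with c1+c2 = m, d1+d2 = n, capped
  at 75 transitions (30 ms dwell, CE 39 eV).
* **Positional isomers** — in an EPI spectrum at CE 39 eV the *sn*-1 chain's
  carboxylate anion is the most intense fragment; a candidate pair is
  accepted when both its fragments are present, the higher intensity fixes
  *sn*-1 (a ≤20 % relative difference is flagged `sn_ambiguous`), and
  co-elution of the two MRM transitions' apexes confirms the call.
* **Quantitation** — single-point internal-standard ratio,
  `amount = area_species / area_IS × pmol_IS` (response factor 1), reported
  as pmol per nmol total lipid phosphate, with the 1 fmol–12 pmol linear
  range flagged.
* **Group statistics** — per-species unpaired two-tailed Student *t* tests
  and the derived calls *restored-to-wild-type* (p ≥ α vs WT) and
  *elevated-over-mutant* (p < α vs mutant and mean above it).

Printed masses use the field's truncation convention (671.4657 → "671.46",
never rounded); full precision is kept internally.

## Worked example

Design the transition panel for PA 34:2 and interpret its EPI spectrum:

```r
library(paMRM)

build_transition_list("PA(34:2)")[, c("species", "q1_display",
                                      "q3_display", "chain")]
#   species q1_display q3_display chain
#  PA(34:2)     671.46     223.17  14:2
#  PA(34:2)     671.46     255.23  16:0
#  PA(34:2)     671.46     253.21  16:1
#  PA(34:2)     671.46     251.20  16:2
#  PA(34:2)     671.46     283.26  18:0
#  PA(34:2)     671.46     281.24  18:1
#  PA(34:2)     671.46     279.23  18:2
#  PA(34:2)     671.46     311.29  20:0
```

Eight transitions: the four chain pairs that can compose 34:2 in the default
design space. Feeding the interpreter an observed EPI spectrum of the 671.46
precursor (fragments at m/z 253.42, 255.28, 279.25, 281.27 with intensities
100, 60, 30, 60 — unit-resolution masses sit up to ~0.2 Da above theory):

```r
sp <- epi_spectrum(c(253.42, 255.28, 279.25, 281.27), c(100, 60, 30, 60),
                   precursor_mz = 671.46)
identify_species(sp, 34, 2)
#        species  sn1  sn2 confidence intensity_sn1 intensity_sn2
#  PA(16:0/18:2) 16:0 18:2   resolved            60            30
#  PA(16:1/18:1) 16:1 18:1   resolved           100            60
```

Two co-existing molecules inside the 34:2 sum composition, each with a
definitive *sn* assignment: 16:1/18:1 (253 > 281) and 16:0/18:2 (255 > 279).
The 14:2, 16:2, 18:0 and 20:0 candidates are absent, so their pairs are
rejected.

End to end on synthetic raw data (39-species panel, WT / PLD-null mutant /
rescue, n = 3, two internal standards):

```r
truth <- ground_truth()
run   <- simulate_run(truth, seed = 7)   # Gaussian XICs + EPI spectra
res   <- run_pipeline(run)               # integrate, identify, quantify
head(res$quant[res$quant$sample_id == "WT_1", ], 4)
#        species amount_pmol amount_per_phosphate flag
#  PA(14:0/14:1)  0.04905318          0.009810637   ok
#  PA(14:2/14:0)  0.07418692          0.014837385   ok
#  PA(14:1/14:2)  0.11113161          0.022226323   ok
#  PA(16:0/14:0)  0.16728358          0.033456717   ok
```

`amount_per_phosphate` is pmol of the species per nmol of total lipid
phosphate in the sample — the normalization used for total and per-species
PA levels. `compare_species()` + `call_restoration()` then classify each
species across genotypes.

## Command line

`inst/cli/pamrm.R` wraps the main operations:

```sh
Rscript inst/cli/pamrm.R ms1 --class PA --carbons 24:44 --db 0:8 -o ms1.csv
Rscript inst/cli/pamrm.R transitions --species "PA(34:2)" -o mrm.csv
Rscript inst/cli/pamrm.R identify --spectra run.mzML --species PA:34:2 -o out.csv
Rscript inst/cli/pamrm.R simulate --seed 7 -o runs/
Rscript inst/cli/pamrm.R compare --quant quant.csv --groups WT,mutant,rescue -o calls.csv
```

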