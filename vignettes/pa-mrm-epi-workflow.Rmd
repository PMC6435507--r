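---
title: "Identifying and quantifying phosphatidic acid molecular species by LC-MRM-EPI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and quantifying phosphatidic acid molecular species by LC-MRM-EPI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paMRM)
```

## The problem

Phosphatidic acid is not one analyte but dozens: molecular species that
share the phosphate head group yet differ in the two fatty acyl chains and
in which chain sits at *sn*-1 versus *sn*-2 of the glycerol backbone. A
targeted triple-quadrupole experiment sees a species first as a sum
composition — PA 34:2 means 34 acyl carbons and 2 double bonds in total —
and that one precursor mass can hide several distinct molecules
(16:0/18:2, 16:1/18:1, ...). `paMRM` computes the theory (which masses to
monitor), interprets the evidence (which molecules are actually there, and
in which *sn* arrangement), and quantifies the result against spiked
internal standards.

## The mass model

All masses derive from one generalized formula. A diacyl PA with *m* total
acyl carbons and *n* total double bonds is C~m+3~H~2m−2n+5~O~8~P; removing
one acyl chain (the lyso form) gives C~m+3~H~2m−2n+7~O~7~P. Other
glycerophospholipid classes (PC, PE, PS, PG, PI and their lyso forms) are
obtained by adding the head-group heteroatoms to the PA skeleton; PA/LPA is
the validated path, the other classes ship as a registry.

```{r}
format_formula(composition_of_species("PA", 34, 2))
monoisotopic_mass(composition_of_species("PA", 34, 2))
```

Three numerical conventions matter and are fixed package-wide:

* **Pinned monoisotopic constants.** One table (`atomic_masses()`): C = 12
  exactly, H = 1.00782503, D = 2.01410178, O = 15.99491462, P = 30.97376151,
  N = 14.00307401, plus Na/K/Li and the electron mass 0.00054858 Da. Every
  derived value in the test suite is reproducible bit-for-bit from it.
* **Electron bookkeeping in ions.** An [M−H]− ion is the neutral minus a
  hydrogen atom plus one electron mass. This is the only convention under
  which the printed two-decimal transition masses (e.g. 223.17 for the 14:2
  carboxylate anion) are reproduced by truncation; it is adopted globally.
* **Truncation, not rounding, for display.** `format_mz(671.4657)` is
  "671.46" (rounding would print "671.47") — matching how unit-resolution
  transition lists are conventionally printed. Full precision is always
  retained internally; truncation is display-only.

Nine adducts are built in ([M+H]+, [M+H−H2O]+, [M+NH4]+, [M+Na]+, [M+K]+,
[M+Li]+, [M−H]−, [M+HCO2]−, [M+CH3CO2]−), all singly charged. Quantitation
transitions are negative-mode only ([M−H]−); the positive adducts exist in
the MS1 table but never generate transitions.

## Chain spaces and transition design

A sum composition is decomposed into unordered candidate chain pairs
{c1:d1, c2:d2} with c1+c2 = m and d1+d2 = n inside a configurable *chain
space*. Two documented defaults exist, and the distinction is deliberate:

* `default_chain_space()` — 12–22 carbons, odd carbons allowed, up to 6
  double bonds per chain. Used for database building; odd carbons are
  needed because the internal standards (PA(12:0/13:0), PA(17:0/14:1))
  contain them.
* `default_transition_space()` — even carbons 14–20, at most 2 double bonds
  per chain, and chains longer than 18 carbons restricted to saturated.
  Used for MRM design and spectrum interpretation.

The second space was chosen as the *minimal* rule set that reproduces the
published eight-transition candidate panel for PA 34:2 (14:2/20:0,
16:0/18:2, 16:1/18:1, 16:2/18:0). Plain enumeration over "even 14–20, ≤2
double bonds" would also admit 14:0/20:2 and 14:1/20:1; the extra
"saturated above 18 carbons" constraint — biologically reasonable for fly
head lipids, where polyunsaturated very-long chains are rare — removes
exactly those. Both spaces are user-overridable, and the decomposition is
verified against a brute-force enumeration oracle in the tests.

```{r}
decompose_sum_composition(34, 2, default_transition_space())
```

`build_transition_list()` caps a panel at 75 transitions (the duty-cycle
limit of unscheduled MRM at 30 ms dwell); an overflow is an error unless a
priority list says what to keep. Within one sum composition a chain
determines its partner, so no fragment can be shared between two candidate
pairs of the same precursor; the `shared_fragment` flag exists for
user-supplied exotic spaces.

## Interpreting EPI spectra

The *sn* rule: at the calibrated collision energy (39 eV) the *sn*-1
chain's carboxylate anion is the most intense fragment and the *sn*-2 anion
the second — established with an *sn*-1-deuterated 16:0D31/18:1 standard
and consistent with earlier work at 25–35 eV. The interpreter applies four
stages:

1. **Match** (`match_fragments`): each candidate chain's theoretical anion
   is matched to the nearest peak within `mz_tol` (default 0.3 Da — a
   unit-resolution Q3 places observed fragments up to ~0.2 Da off theory;
   the interval is closed, so a boundary peak matches). A peak below
   `absence_frac` (1 %) of the base peak counts as absent.
2. **Resolve** (`resolve_pairs`): a pair is accepted iff both chains are
   present; a self-pair (18:1/18:1) needs its single fragment only.
3. **Assign** (`assign_sn_positions`): higher intensity → *sn*-1. If the
   two intensities are within `equality_tol` (20 % relative) the order is
   `sn_ambiguous` — intensities are compared only *within* a pair, never
   across pairs sharing a precursor, because absolute fragment yields
   differ between molecules.
4. **Confirm** (`confirm_by_coelution`): the two transitions of a real
   molecule must have XIC apexes within `rt_tol_min` (0.1 min) of each
   other; distinct co-resident species may elute apart (9.45 vs 9.36 min in
   the motivating data). A contradiction withdraws the pair; absent XICs
   leave the confidence untouched with `rt_evidence = "incomplete"`.

No intensity apportioning is attempted when a fragment would be shared
between two accepted pairs — such pairs stay `pair_ambiguous` unless their
retention times demonstrably separate them. The collision energy is
recorded in the evidence because the *sn* rule is calibrated at 39 eV;
whether it inverts elsewhere is unknown, and the package applies it
unconditionally.

## Quantitation

Single-point internal-standard quantitation with response factor 1.0:
`amount = area_species / area_IS × pmol_IS`, normalized to externally
measured total lipid phosphate (pmol/nmol). Ratios make the result exactly
invariant to global intensity scaling. The default standard is
PA(17:0/14:1) (odd-chain, hence non-endogenous); PA(12:0/13:0) serves as a
cross-check, and in simulation the two agree within noise. Amounts outside
the 1 fmol–12 pmol linear window are flagged, never clipped. A
`response_factors` hook exists for per-species calibration but defaults to
none, matching standard practice for this assay.

Peak integration re-implements the generic vendor behavior: 5-point moving
average for apex detection, auto-window as the widest contiguous region
above 3× the median-absolute-deviation noise, straight-line baseline
between window edges, trapezoidal area. Only two properties are promised —
exact linearity in intensity (with time-shift invariance) and ≤2 % error on
Gaussian peaks — because the commercial algorithm it replaces is
proprietary and unspecified.

## Group statistics and "restoration"

Per-species comparisons use the unpaired two-tailed Student (equal-
variance) *t* test — the common default of spreadsheet/Prism-style
analyses with n = 3; Welch is available via `var_equal = FALSE`. No
multiple-testing correction is applied by default (per-species reporting
across a ~39-species panel); a Bonferroni flag exists.

Two derived calls mirror how rescue experiments are read:

* **restored_to_wt**: p(reconstituted vs WT) ≥ α. This is explicitly an
  *absence-of-evidence* criterion — with n = 3 it has limited power, and a
  truly restored (null) species still fails it with probability α. The α
  (default 0.05) is exposed rather than hidden.
* **elevated_over_mutant**: p(reconstituted vs mutant) < α *and* the
  reconstituted mean exceeds the mutant mean (one-sided reading of a
  two-sided test, so a significant *decrease* never counts as elevation).

A consequence worth stating: across 16 truly-restored species the
probability that *all* escape a type-I error in one experiment is
0.95^16 ≈ 44 %. Whole-table agreement with a designed restoration pattern
is therefore not an achievable benchmark at α = 0.05; the package's
acceptance tests check per-species correctness rates (and report the
whole-table rate for transparency).

## The synthetic world

`ground_truth()` + `simulate_run()` emulate the study design the statistics
are meant for: a 39-species resolved PA panel, three groups (WT, PLD-null
mutant, reconstituted rescue) × 3 replicates, two internal standards at
10 pmol, 5 nmol total lipid phosphate per sample. Fixed defaults, chosen
once:

* **Panel**: 39 diacyl species over the even-carbon 14–20 chain pool, base
  abundances log-spread 0.05–8 pmol (inside the linear range). The panel is
  a *synthetic construct* — the real fly-head species table is not
  reprinted in full anywhere the package can regenerate it from — so
  biological species identities should not be read off it. Self-paired
  species are excluded so every species carries two distinct diagnostic
  transitions (a self-pair funnels both chains into one fragment, which
  would need a response-factor correction the assay does not model).
* **Design**: 30/39 species reduced ×0.25 in the mutant; in the rescue, 16
  of those restored ×1.0 and 14 partially elevated ×0.5; the 9 unreduced
  species unchanged. Restoration analysis is confined to the 30 reduced
  species, where "designed restored" is well defined.
* **Chromatography**: one Gaussian per species per transition, σ =
  0.05 min, species spaced 0.15 min apart from 6 min, apex drawn once per
  species per sample (co-elution is exact up to `rt_jitter_min`, default
  0.02 min). Area = 10^4 counts·min per pmol, split sn-1 : sn-2 as
  `sn_bias` : 1.
* **EPI**: fragment at each chain's theoretical anion m/z (± `mz_sigma_da`,
  default 0.05 Da), *sn*-1 intensity = `sn_bias` × *sn*-2 before noise.
  `sn_bias` defaults to 1.7 — a clear but not extreme dominance of the
  highest peak, loosely calibrated to the deuterated-standard observation.
* **Noise**: one multiplicative factor ~N(1, `intensity_cv`) per transition
  (and per EPI fragment), truncated at zero. This is run-to-run
  measurement noise only.

What the generator does **not** emulate: electrospray matrix effects,
ionization suppression, isotope-envelope overlap between species one
double bond apart, chimeric EPI spectra from co-eluting isobars, baseline
drift, carry-over, saturation. A green end-to-end test therefore
establishes that the *algorithms* are correct and internally consistent —
not that the workflow is robust to every artifact of real
chromatography-MS data.

With all noise terms zero the pipeline recovers the ground truth exactly
(identity and *sn* order) and amounts to within the <2 % integration error;
this is a tested invariant, as is the monotone growth of quantitation error
with `intensity_cv`.

## Degenerate inputs and tie-breaks

* Impossible formulas (hydrogen count 2m−2n+5 ≤ 0) and chains with
  non-positive hydrogen counts are errors, not NA.
* Decomposition of an impossible sum composition returns an empty set; MS1
  rows whose composition admits no chain pair are flagged `valid = FALSE`.
* Equal fragment intensities in a pair: the chain listed first in canonical
  order wins *sn*-1 numerically, but the assignment is `sn_ambiguous`, so
  the tie-break never silently decides.
* Identical groups in `compare_species` give t = 0, p = 1; zero variance
  with different means gives p = 0.
* A flat chromatogram is `not_detected` with area exactly 0; a not-detected
  species quantifies to 0 pmol, flagged.

## Known limitations

* Only |charge| = 1; no isotope patterns or average masses.
* The non-PA head-group registry is shipped but not validated against
  printed values (the validated path is PA/LPA).
* mzML support is a minimal self-contained subset (uncompressed 64-bit
  arrays) sufficient for SRM chromatograms and MS2 peak lists; vendor raw
  formats are out of scope.
* The *sn* intensity rule is applied unconditionally although it is
  calibrated at one collision energy on one standard; the CE is recorded
  with every assignment so downstream users can filter.
* "Restored to wild type" inherits all the caveats of accepting a null
  hypothesis at n = 3.
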