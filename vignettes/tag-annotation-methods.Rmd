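---
title: "Methods: sodiated TAG annotation, MRM planning and mole-fraction quantification"
author: "lipidtag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sodiated TAG annotation, MRM planning and mole-fraction quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidtag)
```

## Scope and model

`lipidtag` implements the computational core of a targeted glycerolipid
workflow for oilseed lipidomes, of the kind used to follow triacylglycerol
(TAG) accumulation across seed maturation in high-erucic Brassicaceae such
as pennycress. Five ordered maturation stages are used throughout: G
(green, 12 days after flowering), GY (19 DAF), YG (26 DAF), Y (33 DAF) and
M (mature, 45 DAF). The package covers four connected pieces:

1. **Mass arithmetic** (`chem_formula`, `monoisotopic_mass`, `ion_mz`):
   elemental formulas as integer count vectors, monoisotopic masses from a
   committed IUPAC table, and adduct m/z with electron-mass correction.
2. **Species grammar and combinatorics** (`parse_species`,
   `species_formula`, `enumerate_compositions`): the C:DB shorthand at
   three resolution levels, neutral formula assembly by esterification
   bookkeeping, and enumeration of acyl multisets compatible with a
   class total.
3. **Acquisition planning and MS2 annotation** (`head_group_diagnostic`,
   `build_transitions`, `annotate`): class-resolved survey scans and MRM
   transitions computed from head-group formulas, and annotation of
   sodiated TAG MS/MS spectra with intensity-based sn-2 assignment.
4. **Quantification and simulation** (`is_normalize`, `class_fractions`,
   `simulate_profile`, `simulate_ms2`): internal-standard normalisation to
   pmol, mole-fraction summaries, and a synthetic-data generator that
   emulates the statistical structure of the instrument output.

## Mass conventions

Atomic monoisotopic masses are committed constants (six or more decimals,
IUPAC/CIAAW); there is no runtime lookup. Ion m/z is

$$ m/z \;=\; \frac{m(\mathrm{M} + \Delta) - s\,z\,m_e}{z} $$

with $s = +1$ for positive ions, $-1$ for negative, and
$m_e = 0.000548580$ Da. The electron correction is on by default and is
what brings sodiated TAG m/z into agreement with high-resolution reference
values at the fourth decimal (e.g. TAG 62:4 `[M+Na]+` at 1017.8821);
omitting it shifts positive ions up by about $5.5 \times 10^{-4}$, which
the tests verify as a detectable failure. Masses are carried at full
double precision; rounding happens only at presentation and matching.

Acyl chains are identified by carbons:double-bonds only; double-bond
position and geometry are not modelled, so e.g. erucic (22:1 n-9) and any
positional isomer are the same object. The free-acid formula is
$\mathrm{C}_c\mathrm{H}_{2c-2db}\mathrm{O}_2$, and a sodium-salt loss
always exceeds the corresponding free-acid loss by the Na$-$H difference,
21.981944 Da.

## Formula assembly

A molecular-level species assembles as

glycerol backbone(s) + head residue + $\sum$ acyl free acids $-$ one
H$_2$O per ester bond (including the head linkage; TAG and DAG have no
head). Cardiolipin is the one two-backbone class: its "head" is the
central glycerol plus two phosphates joined through four phosphodiester
condensations. Because the acid sum depends only on the totals, all
splits of one class total share a neutral formula; `species_formula`
nevertheless refuses class-total input and directs to
`enumerate_compositions`, keeping resolution levels honest.

## MRM scheme

The planner reproduces a triple-quadrupole glycerolipid method: PC by
precursor-ion scanning on phosphocholine (nominal m/z 184, CE 35 eV),
SQDG on the sulfoquinovosyl anion (nominal 225, $-55$ eV), and the other
head-group classes by neutral-loss scans whose nominal losses (PE 141,
PI 277, PS 185, PG 189, PA 115, MGDG 179, DGDG 341 Da) fall out of the
registered head formulas, never a lookup table. Nominals use
round-half-away-from-zero.

The adduct scanned per class is not something the printed scheme states;
it is inferred here as the unique assignment whose arithmetic reproduces
the printed losses: PE and PS lose their full phospho-head from
`[M+H]+`, while PI, PG, PA (full head + NH$_3$) and MGDG, DGDG
(anhydro-glycosyl + NH$_3$) lose from `[M+NH4]+`. This inference is a
deliberate, documented design decision.

DAG and TAG are quantified by MRM as `[M+NH4]+` at 19 and 26 eV with
30 ms dwell; CL as `[M-H]-` at $-45$ eV with 50 ms dwell. Product ions
for molecular-level DAG/TAG rows are the diacyl fragments from loss of
one acyl as acid plus ammonia; class-total rows fall back to the
ammonia-loss pseudo-molecular transition, and CL uses a Q3 = Q1
pseudo-transition, both because no acyl split is available. Transition
tables are sorted, so they are a pure function of the species *set*.

## Sodiated TAG annotation and the sn-2 rule

`[M+Na]+` TAG precursors fragment by losing an acyl as the free fatty
acid (RCOOH) or, much more weakly, as its sodium salt (RCOONa). Loss of
the sn-1/3 substituents is preferred over loss from sn-2, so the
acid-loss ion of the sn-2 chain is the least intense. Enantiomers (an
sn-1 vs sn-3 swap) fragment identically and are never distinguished:
reported triads store an unordered multiset plus the sn-2 designation,
rendered with sn-2 in the middle.

`annotate` proceeds: enumerate all triads over the acyl pool whose
theoretical sodiated m/z is within the precursor tolerance; predict acid
and salt losses per candidate; match each prediction to the nearest peak
within the fragment tolerance (one peak may serve several near-isobaric
predictions, flagged `shared`); score candidates by weighted fragment
coverage (acid losses weight 1, salt losses 0.25 — they corroborate but
are never required); rank by coverage, then summed matched intensity,
then lexicographic label. The deterministic tie-break never hides
ambiguity: whenever more than one candidate reaches the coverage
threshold (default 0.5) the `ambiguous` flag is set and no positional
call is made, reflecting that several isobaric TAG species can
contribute to one precursor ion.

The sn-2 call on an unambiguous top candidate uses two ratios:

* **dominance** `r` (default 1.5): every other acid-loss intensity must
  be at least `r` times the weakest;
* **similarity** `s` (default 3, asymmetric triads only): the two
  stronger acid losses must agree within a factor `s` — the
  characteristic "two ions of similar abundance" from the two flanking
  positions.

The published account says only that flanking losses are "significantly
more abundant"; `r` and `s` quantify that and are configuration keys, not
constants of nature. Anything failing the tests abstains — abstention is
a first-class value. A triad of three identical acyls has no positional
contrast and always abstains, as does one where the designated sn-2 chain
also occupies a flanking position. Positional calls are restricted to
sodiated precursors; `[M+NH4]+` spectra are annotated compositionally
only.

**Tolerances.** Defaults are 0.3 Da for both precursor and fragment
matching, appropriate for nominal-mass ion-trap spectra and wide enough
to absorb inconsistent published rounding of the same ion (the loss of
18:2 from the 62:4 precursor appears in the source material as both
737.62 and 737.7; the prediction, 737.642, is within 0.05 Da of the
former). A 10 ppm mode (`ppm_mode = TRUE`) serves high-resolution data.

## Quantification

`is_normalize` converts raw MRM responses to pmol:

$$ \mathrm{pmol} = \frac{\text{response}}{\text{response of class standard}}
   \times \text{spiked pmol} \times \text{response factor} $$

The default standard set spikes PE 18:0/18:0, DAG 18:0/22:6 and SQDG
16:0/18:0 at 125 pmol each. Classes without their own standard map to a
chemically similar one through an explicit fallback table (phospholipids
to PE, galactolipids to SQDG, TAG to DAG); an unmapped class is an error,
never a silent default. Response factors default to 1 and model the
quality-control correction of a full workflow; no QC values are bundled
because none are published. All summaries are mole percent (amounts are
pmol throughout), scale-invariant and sum-normalised; a missing species
in a sample is 0 pmol, while a missing sample or standard is an error.
Injection-amount renormalisation (extracts prepared to a fixed total
fatty-acid amount) is not applied: mole fractions are invariant to it.

`stage_summary` reports mean, SD and n per stage; SD for a single
replicate is `NA`, never 0. The optional one-way ANOVA column is plain
`oneway.test` and is marked auxiliary — post-hoc letter displays are out
of scope.

## The synthetic generator

The generator exists so every pipeline stage is testable without
instrument output. Its defaults are calibrated to the published stage
measurements and are not tuning knobs:

* **Class fractions.** The full GREEN-stage breakdown (TAG 29.3 %, PA
  28.5 %, PC 10.1 %, DGDG 8.4 %, MGDG 7.1 %, PE 3.4 %, DAG 3.3 %, PG
  2.7 %; the unmeasured residual is split evenly over PI/PS/SQDG), the
  TAG trajectory 79.5 % (GY), 85.6 % (Y), 90.8 % (M), MGDG 0.8 % (Y) and
  0.09 % (M), PC 5.4 % and DAG 0.8 % at M. Remaining mass at each stage
  is spread over unanchored classes in proportion to their GREEN-stage
  shares. YG TAG, unmeasured, is set once to 82.5 % (midway between its
  neighbours); DAG is held at 3 % through YG and 2 % at Y per the
  reported "close to 3 %" plateau and late decline.
* **Within-class fractions.** Every published species value is anchored
  (DAG 34:2 = 22.21 % at G; the DAG 40:3 = 2.6/9.0/8.8/12.7/17.8 %,
  38:3 = 3.2/8.0/7.2/13.6/23.8 % and 40:4 = 7.5/6.4/9.5/21.3 %
  trajectories, with 2 % chosen for the unreported 40:4 at G; the four
  major GREEN-stage PC species at 14.4/14.6/19.3/17.4 %). Remainders are
  spread uniformly over the rest of the species catalog. TAG species
  fractions encode the qualitative published trend (62:4/62:5 and other
  VLCFA species rise, 54:4/54:5 fall) as package defaults; the PC profile
  is held at its GREEN-stage anchors across stages because only that
  stage was reported quantitatively.
* **Noise.** Replicate noise is multiplicative lognormal with mean 1;
  concentrations are positive and spreads in this field are reported as
  CVs, which rules out additive Gaussian noise. No replicate CVs are
  published for the lipid data, so the default CV 0.05 is a package
  choice within the plausible 5–20 % band and is exposed in
  configuration. The per-sample total (2000 pmol) is likewise arbitrary:
  every downstream quantity is a fraction and invariant to it.
* **MS2 model.** One acid-loss peak per distinct acyl (base intensity
  100 for chains occupying sn-1/3, base/`sn13_sn2_ratio` for a chain
  found only at sn-2; default ratio 2.5), salt peaks at 5 % of their acid
  peak, Gaussian m/z jitter (SD 0.05 Da) and lognormal intensity jitter
  (CV 5 %).
* **Determinism.** One global seed; per-stream sub-seeds (profiles,
  responses, spectra) are derived from it so components regenerate
  independently and bit-identically. Generated tables carry their
  parameter record as an attribute, and datasets written by the CLI
  include a `generation.json` provenance file.

At zero noise the generator inverts exactly through `is_normalize`
(responses are amounts divided by spiked pmol, standards at unit
response), which the tests use as a round-trip identity.

### What passing tests do and do not show

The generator emulates compositional structure, replicate noise and the
sn-2 intensity signature. It does not emulate chromatographic
integration error, ion suppression, isotopic interference between
species two double bonds apart, in-source fragmentation or detector
saturation. Recovery results on synthetic data (e.g. the mature-stage
TAG fraction recovered within one percentage point at CV 5 %, or 100 %
sn-2 recovery at dominance ratio 2.5 with no false calls at ratio 1)
therefore validate the computational pipeline, not instrument
performance on real extracts.

## Numerical choices and degenerate inputs

* Formula subtraction that would drive an element negative is an error;
  so is deprotonating a hydrogen-free neutral.
* Unsatisfiable enumeration totals return an empty list, not an error;
  an empty species list yields an empty, correctly-typed transition
  table.
* An empty spectrum annotates to candidates with zero coverage and
  universal abstention; a precursor with no candidate totals returns a
  zero-row result carrying a diagnostic attribute.
* Label validation (`validate_label_consistency`) requires a non-empty
  acyl list; published tables occasionally disagree with their own triad
  (a 22:1/18:2/24:1 assignment labelled 64:5), and the validator flags
  exactly this.
* Problem sizes in the test-suite simulations — 200 spectra per recovery
  condition, 3 replicates per stage, 400 replicates for the
  concentration check — were chosen as the smallest sizes at which the
  Monte-Carlo statements are stable.

## Known limitations

* Ether/plasmalogen lipids, sphingolipids and oxidized acyls are outside
  the grammar; CL is supported structurally and for MRM but excluded
  from MS2 annotation.
* Only singly charged adducts are modelled; no isotope patterns or
  average masses.
* The mapping between the two lightest survey precursors seen in
  ion-trap spectra (m/z 853.8 and 879.8) and composition names is not
  fixed a priori: the annotator reports every candidate within tolerance
  rather than hard-coding an assignment.
* sn-1 vs sn-3 is fundamentally unresolved by this fragmentation; for
  precursors where several isobaric triads co-exist above threshold the
  package reports the ambiguity instead of a call, and such spectra
  should not be used to exclude co-isolated regioisomers.
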