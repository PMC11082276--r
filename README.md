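# lipidtag

Targeted glycerolipid mass spectrometry for oilseed lipidomes:
triacylglycerol (TAG) MS/MS annotation with sn-2 regioisomer assignment,
class-resolved MRM acquisition planning, and internal-standard
quantification to mole-fraction distributions across seed maturation
stages.

## The problem

Seed oils of high-erucic Brassicaceae (pennycress, crambe, rapeseed)
accumulate TAG whose very long chain fatty acids — 20:1 eicosenoic,
22:1 erucic, 24:1 nervonic — rise sharply during maturation, while the
middle (sn-2) glycerol position stays occupied by C18 polyunsaturates.
Following this requires three computational pieces that this package
provides for R users:

1. **Exact-mass and adduct arithmetic.** Ion m/z is computed as
   `(m(M + Δ) − s·z·mₑ)/z`, electron-corrected, from committed
   monoisotopic atomic masses. Sodiated TAG 62:4 (`C65H118O6`) comes out
   at 1017.8821, matching high-resolution reference values to four
   decimals.
2. **sn-2 assignment from [M+Na]⁺ MS/MS.** Sodiated TAG precursors lose
   an acyl as a free fatty acid (RCOOH) or, much more weakly, as its
   sodium salt (RCOONa); losses from the flanking sn-1/3 positions are
   preferred over sn-2. `annotate()` enumerates candidate acyl triads
   over a configurable pool, predicts both loss series, matches peaks,
   and calls the weakest acid loss as sn-2 when a dominance ratio
   (default 1.5) and, for asymmetric triads, a flanking-similarity
   factor (default 3) are satisfied — otherwise it abstains. Co-isolated
   isobaric triads set an `ambiguous` flag instead of being silently
   dropped. Enantiomers (sn-1 vs sn-3) are never claimed.
3. **MRM planning and quantification.** Head-group survey scans
   (precursor-of m/z 184 for PC, 225 for SQDG; neutral losses of 141,
   277, 185, 189, 115, 179, 341 Da for PE, PI, PS, PG, PA, MGDG, DGDG)
   are derived from head-group formulas, not lookup tables, and
   `is_normalize()` converts MRM responses to pmol against internal
   standards (125 pmol each of PE 18:0/18:0, DAG 18:0/22:6,
   SQDG 16:0/18:0 by default) before mole-fraction summaries.

A synthetic-data module generates stage-resolved profiles, raw peak
tables and sodiated TAG spectra with known ground truth, calibrated to
published stage compositions (TAG 29.3 % of lipid moles at the green
stage rising to 90.8 % at maturity), so the entire pipeline is testable
end to end.

## Worked example

Annotate the four-peak MS/MS spectrum of the sodiated precursor at
m/z 1017.9:

```r
library(lipidtag)

sp  <- ms2_spectrum(1017.9,
                    mz        = c(657.6, 679.6, 715.7, 737.6),
                    intensity = c(8,     100,   5,     40))
annotate(sp)[, c("triad", "total", "coverage", "sn2", "ambiguous")]
#>            triad total  coverage  sn2 ambiguous
#> 1 18:2/22:1/22:1  62:4 1.0000000 18:2     FALSE
#> 2 18:2/20:1/24:1  62:4 0.3333333 <NA>     FALSE
#> 3 18:3/20:0/24:1  62:4 0.0000000 <NA>     FALSE
```

All four peaks are explained by the triad 22:1/18:2/22:1 (coverage 1):
the intense 679.6 is loss of erucic acid from sn-1/3, the weaker 737.6
is loss of linoleic acid, and 657.6/715.7 are the corresponding sodium
salt losses, so linoleate is assigned to sn-2, unambiguously — the two
rival 62:4 triads explain at most a third of the weighted fragments.

Plan transitions and quantify a simulated mature-stage batch:

```r
build_transitions(c("TAG 62:4", "PE 34:2", "PC 34:2"))[,
    c("species", "polarity", "Q1_mz", "Q3_mz", "CE_eV", "dwell_ms")]
#>    species polarity     Q1_mz    Q3_mz CE_eV dwell_ms
#> 1  PC 34:2        +  758.5694 184.0733    35       30
#> 2  PE 34:2        +  716.5225 575.5034    29       30
#> 3 TAG 62:4        + 1012.9267 995.9001    26       30

prof <- simulate_profile(default_stage_params(cv = 0.05)["M"],
                         n_replicates = 3, seed = 1)
cf <- class_fractions(is_normalize(simulate_peak_table(prof)))
mean(cf$mol_pct[cf$class == "TAG"])
#> [1] 90.79002
```

The PE row monitors the 141 Da phospho-head neutral loss
(Q1 − Q3 = 141.019), the PC row the phosphocholine diagnostic at
m/z 184.073, and the recovered TAG mole fraction lands within a fraction
of a percentage point of the generator's calibrated 90.8 %.

A thin command-line front end over the same functions ships in
`inst/cli/lipidtag.R` with subcommands `plan-mrm`, `annotate`,
`quantify` and `simulate`.

## Documentation

The methods vignette
(`vignettes/tag-annotation-methods.Rmd`) describes the fragmentation
model and its assumptions, the tunable parameters and their defaults,
what the synthetic generator does and does not emulate, and the
package's numerical conventions.
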