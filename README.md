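# hrmid

In-silico PCR high-resolution melting (HRM) toolkit for DNA-barcode species
identification of necrophilous flies.

Forensic entomologists estimate the postmortem interval from the carrion
flies colonizing a body, which makes fly species identification — adults and
morphologically cryptic larvae alike — a routine need. PCR-HRM identifies
species without sequencing: a short mitochondrial COXI/COXII barcode region
is amplified with a saturating dsDNA dye, fluorescence is recorded over a
fine 65–90 °C ramp, and the peak position(s) of the negative-derivative melt
curve −dF/dT act as a species signature. An unknown sample is assigned by
comparing its melt-peak temperature Tm against a co-amplified reference
panel under the decision rule

> ΔTm ≥ 0.15 °C ⇒ distinct sequences; ΔTm < 0.15 °C ⇒ identical,

with all panel species within the threshold reported as candidates (so
genuinely close species yield an honest `ambiguous` call rather than a
forced assignment).

The package covers:

* **Panel I/O and synthesis** — FASTA barcode records, reference Tm panels
  (TSV/JSON, four published panels bundled), and a seeded generator of
  aligned barcode panels with conserved primer flanks around a variable
  core (`read_fasta()`, `hrm_panel()`, `synth_barcodes()`).
* **Conservation profiling** — per-column modal-residue identity and
  conserved/variable region calls on aligned panels
  (`conservation_profile()`, `find_regions()`).
* **Primer design** — GC/length windows, hairpin and self-dimer screens,
  pair enumeration over conserved flanks, and mismatch-tolerant in-silico
  PCR with exact 3'-end anchoring (`check_primer()`, `enumerate_pairs()`,
  `in_silico_pcr()`).
* **Thermodynamics** — unified nearest-neighbor ΔH/ΔS with salt correction
  and two-state Tm, for rank/ΔTm analysis of amplicon variants
  (`nn_thermo()`, `amplicon_tm()`).
* **Melt curves** — logistic-mixture melt simulation on a 0.01 °C grid,
  Savitzky–Golay derivative curves, prominence-based peak calling with a
  0.1 °C merge radius (`simulate_melt()`, `derivative_curve()`,
  `call_peaks()`).
* **Classification** — the 0.15 °C rule with ambiguity and multi-peak
  signature handling, panel discriminability audits, replicate-drift QC and
  cross-batch warnings (`classify_sample()`, `pairwise_discriminability()`,
  `replicate_error()`).
* **Bench planning** — the ≥10 ng template rule, 20 µL reaction-mix scaling
  and the thermocycler/HRM program (`template_volume()`, `mix_table()`,
  `thermocycler_program()`).

A thin command-line wrapper over these functions ships at
`inst/cli/hrmid.R` (`design`, `melt`, `classify`, `mix` subcommands).

## Worked example

```r
library(hrmid)

panel <- hrm_panel("cox2")          # bundled ten-species COXII Tm panel
classify_sample(76.73, panel, query_id = "unknown_adult")
#> <ClassificationResult> unknown_adult: ambiguous
#>   candidate B. peregrina           delta 0.00
#>   candidate H. ligurriens          delta 0.03
```

The unknown adult's peak sits exactly on *B. peregrina*'s reference Tm, but
*H. ligurriens* lies only 0.03 °C away — inside the 0.15 °C identity
threshold — so both candidates are reported. The audit shows every such
clash in the panel:

```r
pairwise_discriminability(panel)
#>        species_a     species_b delta_tm
#> 1  A. rufifacies     P. misera     0.13
#> 2  A. rufifacies P. ruficornis     0.07
#> 3   B. peregrina H. ligurriens     0.03
#> 4 C. megacephala     P. misera     0.10
#> 5         P. dux    P. sericea     0.13
```

A larval sample run against the co-amplified five-species panel gives a
unique match:

```r
classify_sample(77.50, hrm_panel("cox2_larva"), query_id = "larva")
#> <ClassificationResult> larva: match -> P. dux (delta Tm 0.10 degC)
#>   candidate P. dux                 delta 0.10
```

Simulating a three-transition melt signature and calling its peaks recovers
the planted temperatures within the ±0.02 °C instrument resolution:

```r
call_peaks(derivative_curve(simulate_melt(
  data.frame(tm = c(74.75, 77.65, 80.32), weight = 1), melt_config())))
#>      tm   height prominence
#> 1 74.75 1.607975   1.607185
#> 2 77.65 1.607975   1.607975
#> 3 80.32 1.607975   1.606273
```

And the bench calculator reproduces the template arithmetic for a dilute
(3.83 ng/µL) extract under the ≥10 ng rule:

```r
template_volume(3.83)
#> $template_ul
#> [1] 3
#> $water_ul
#> [1] 4
```

See `vignettes/hrm-species-identification.Rmd` for the models, parameter
rationale, and what the synthetic-data tests do and do not demonstrate.

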