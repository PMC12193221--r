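---
title: "PCR-HRM species identification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PCR-HRM species identification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrmid)
```

## The problem

Forensic entomology estimates the postmortem interval from the succession of
necrophilous (carrion-feeding) flies on a corpse, which requires identifying
the fly species — including larvae, which are morphologically near-identical.
High-resolution melting (HRM) analysis does this without sequencing: a short
mitochondrial barcode region (COXI/COXII) is amplified by PCR in the presence
of a saturating dsDNA dye, and fluorescence is recorded while temperature is
ramped finely from 65 to 90 °C. Because sequence variants change the melting
temperature (Tm) of the duplex, each species produces a characteristic peak
(or multi-peak signature) in the negative-derivative melt curve, and an
unknown sample can be assigned by comparing its peak position against a
co-amplified reference panel.

`hrmid` implements the whole in-silico side of this workflow: conservation
profiling of aligned barcode panels, primer screening and in-silico PCR,
nearest-neighbor duplex thermodynamics, melt-curve simulation and peak
calling, panel classification with a 0.15 °C decision rule, and the bench
calculators for the 20 µL reaction.

## The decision rule

Two amplicons are called **distinct** when their melt-peak separation is at
least 0.15 °C and **identical** when it is smaller. The source rule states
"exceeds → distinct" and "less than → identical" without covering equality;
we resolve equality as *distinct* (`ΔTm ≥ 0.15 °C ⇒ distinct`, compared at
1e-9 tolerance). This keeps the ten-species COXII panel's
*S. princeps*–*B. peregrina* pair, separated by exactly 0.15 °C, species-
specific — consistent with that panel being reported as fully resolvable.
Peak temperatures are stored and compared at 0.01 °C precision, half the
±0.02 °C resolution of the melting instrument.

The classifier (`classify_sample()`) deliberately **surfaces ambiguity**:
every panel species within the threshold is reported as a candidate, and two
or more candidates yield status `ambiguous` rather than a forced nearest
assignment. The ten-species COXII panel contains two species 0.03 °C apart,
so a query at that position is honestly ambiguous under the rule; the audit
function `pairwise_discriminability()` enumerates all such clashes (five
pairs in that panel) instead of hiding them.

Two matching modes exist because references can carry multi-peak signatures:
`nearest_single` (default) compares the query's principal peak against each
species' closest peak; `full_signature` additionally requires equal peak
counts, returning `partial_signature` when a single-peak query falls within
threshold of one peak of a multi-peak species — the situation that arises
when an unknown matches only the first peak of a three-peak signature. The
principal peak of a query is its highest derivative peak; for panel entries,
which carry no heights, it is the first listed peak.

Melt peaks drift slightly between acquisition runs (the bundled replicate
panel shows per-species shifts of 0.02–0.10 °C, all upward), which is why
classification across batches triggers a warning
(`batch_consistency_guard()`) recommending co-amplified references rather
than silently comparing numbers from different runs.

## Thermodynamics

`nn_thermo()` implements two-state nearest-neighbor thermodynamics: ΔH and
ΔS are summed over adjacent base-pair stacks using the unified
oligonucleotide parameter set (`nn_table_id = "unified-oligo-1998"`, pinned
in every result), plus terminal initiation terms and, for self-complementary
sequences, the symmetry entropy. The melting temperature is

Tm(K) = 1000·ΔH / (ΔS + 0.368·(L−1)·ln[Na⁺] + R·ln(Cₜ/x)),

with R = 1.987 cal/(mol·K), x = 4 for non-self-complementary duplexes
(x = 1 otherwise), and defaults Cₜ = 2.5·10⁻⁷ M and [Na⁺] = 0.05 M recorded
in the output. Only **relative** behaviour is contractual: rank ordering and
ΔTm of sequence variants. Absolute instrument Tm values of ~97 bp amplicons
are *not* reproduced by two-state prediction, and the reference panels in
this package are data, not predictions. The classical rule-of-thumb shifts
(≈6 °C for losing a G·C pair, ≈0.6 °C for G·C→A·T, ≈0.15 °C for a
hydrogen-bond-preserving swap) ship as documentation constants
(`hrm_delta_tm_heuristics`) and are exercised only as order-of-magnitude
checks; the 6 °C figure in particular describes short-oligo behaviour and is
far larger than nearest-neighbor predictions for 100 bp products, a tension
we quote but do not reconcile.

## Melt-curve model and peak calling

`simulate_melt()` models fluorescence as total helicity of a mixture of
two-state transitions: each component contributes
`weight / (1 + exp((T − tm)/w))`, passing through half its weight exactly at
its Tm, plus a constant baseline and optional seeded Gaussian noise.
Multi-peak species are represented as mixtures of transitions without
claiming a mechanism (the cause of multi-peak melt curves is an open
question in the field). Numerical choices:

* **Grid** 0.01 °C over 65–90 °C, so the instrument's ±0.02 °C resolution is
  representable (the instrument's 0.1 °C/s is a ramp rate, not a data grid).
* **Transition width** default `w = 0.15 °C`, giving derivative peaks with
  FWHM ≈ 0.53 °C — the scale instrument derivative plots show for ~100 bp
  amplicons. A width of 0.5 °C, superficially plausible, makes transitions
  1 °C apart unresolvable shoulders and is physically too broad for
  amplicons of this length (a two-state van 't Hoff width R·Tm²/|ΔH| for a
  97 bp product is ≈ 0.3 °C, and cooperative melting sharpens real peaks
  further). Van 't Hoff widths per component are available with
  `transition_width = "vantHoff"` when component enthalpies are supplied.
* **Derivative** (`derivative_curve()`): Savitzky–Golay smoothing (window
  51 points = 0.51 °C, degree 3), central differences, then a second
  Savitzky–Golay pass on the derivative. The second pass is essential:
  finite differencing amplifies white noise by the reciprocal grid step, and
  a single 11-point pass leaves derivative noise far above any usable
  prominence floor. Both passes are exact for cubics, so symmetric peak
  positions are unshifted; edge points with incomplete stencils are dropped.
* **Peak calling** (`call_peaks()`): local maxima filtered at 5% of the
  maximum prominence, peaks closer than 0.1 °C merged into the higher one
  (the instrument never reports distinct peaks that close). Prominence-based
  filtering makes the peak set invariant to uniform weight scaling and to
  baseline offsets.

Under these defaults the full round trip
`simulate_melt → derivative_curve → call_peaks` recovers k ≤ 3 planted
components (pairwise separation ≥ 1 °C, weights ≥ 0.2, noise SD ≤ 0.002)
with the exact count and every position within the ±0.02 °C instrument
resolution, across 50 seeded trials; the measured worst-case error at those
conditions is 0.016 °C.

## Synthetic barcode panels

`synth_barcodes()` emulates the structure that makes this assay work: two
conserved flanks (primer landing sites shared across species) bracketing a
variable core that differentiates species. An ancestor core is drawn
uniformly over A/C/G/T; each species mutates each core site independently
with probability `core_divergence` to a uniformly chosen different base —
the simplest scheme with a closed-form pairwise difference probability,
`2d(1−d) + (2/3)d²` (`expected_pairwise_diff()`), used by the tests as an
analytic oracle. Flanks are redrawn until they pass the GC and structural
primer screens, since they stand in for functional primer sites. Defaults
(flank 20 bp, core 57 bp) reproduce the 97 bp two-footprint product geometry
of the COXII assay.

What the generator does **not** emulate: indel polymorphism inside the core
(real COXII products vary in length between species), transition/transversion
bias, base-composition skew of insect mitochondria, heteroplasmy, and any
relationship between core sequence and realistic absolute Tm. Passing
synthetic-recovery tests therefore demonstrates the pipeline's arithmetic
and signal processing, not field performance on real barcode data.

End-to-end identification is tested at principal-peak spacings ≥ 0.3 °C with
query noise SD 0.002 (200 seeded trials, 100% required); real panels are
tighter — the bundled COXII panel has pairs at 0.03 °C — which is precisely
why the discriminability audit exists.

## Primer screening and in-silico PCR

`check_primer()` applies the design windows (length 20 ± 2 bp, GC 40–60%)
and structural screens by longest complementary run: hairpin stems longer
than 3 bp with loops ≥ 3 nt, self-dimer runs longer than 7 bp, and
3'-anchored runs longer than 4 bp all fail, with every failed check reported.
Run-length screening, rather than full secondary-structure folding, mirrors
the qualitative exclusion criteria primer-design tools expose; the cutoffs
are conventional defaults, since no algorithm is prescribed for them.
Degenerate IUPAC bases are rejected — the design pipeline emits only
A/C/G/T. `enumerate_pairs()` ranks passing pairs by ascending product length
and then by summed distance of oligo GC from 0.5 (closest first).

`in_silico_pcr()` finds primer placements with a mismatch budget and an
exact-match requirement over the 3'-terminal bases (polymerase extension
needs a matched 3' end); products span the forward 5' end through the
reverse 5' end inclusive, so a 20 + 57 + 20 arrangement yields the 97 bp
product length of the COXII assay. The bundled template
`synthetic_pmisera_coxii.fasta` is a **synthetic** COXII-like sequence
carrying the published primer footprints at the published spacing; it stands
in for the GenBank record, which cannot be fetched in an offline build, and
is labelled synthetic everywhere it appears.

## Bench calculators

`template_volume()` encodes the template-quantity rule: at least 10 ng of
template DNA per 20 µL reaction, a 2 µL baseline even when less would
suffice, whole-microlitre pipetting, and a 7 µL template-plus-water budget;
infeasibly dilute extracts are rejected with a re-extraction suggestion. The
"≥ 10 ng" requirement is interpreted as total nanograms in the reaction
(the worked arithmetic for a 3.83 ng/µL extract — 3 µL template + 4 µL
water — supports this reading even though the source phrase says
"concentration"). `mix_table()` keeps every reaction at exactly 20 µL with
water absorbing template adjustments, and scales batch volumes with an
overage fraction on everything except the per-tube template.
`thermocycler_program()` fixes the program structure (10 min at 95 °C;
35 cycles of 95 °C/30 s, anneal/30 s, 72 °C/45 s; 72 °C/10 min; HRM stage
with the 65→90 °C ramp at 0.1 °C/s) and validates the annealing temperature
against a 40–72 °C window (the two shipped assays anneal at 48 and 53 °C;
those values are stored protocol metadata, not recomputed).

## Known limitations

* Absolute Tm prediction is out of reach of two-state nearest-neighbor
  models at amplicon length; panels must come from experiment.
* No multiple-sequence alignment is computed; aligned input is consumed.
* No probabilistic assignment: the threshold rule gives match / ambiguous /
  novel / partial_signature, nothing graded.
* Inter-run drift is warned about, not corrected; a co-amplified reference
  ladder is the recommended practice.
* Primer specificity against a sequence database (the Primer-BLAST step of
  assay design) is out of scope, as are raw instrument file formats and
  dye-binding thermodynamics.

## Problem sizes used by the test suite

The suite simulates curves on the 2,501-point analysis grid; property sweeps
use 50 seeds for melt round-trips, 200 trials for end-to-end identification,
1,000 random sequences (lengths 8–200) for the thermodynamic oracle
comparison, and 100 seeds for the divergence monotonicity check. The whole
suite runs in well under a minute on one core.
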