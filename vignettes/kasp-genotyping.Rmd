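---
title: "KASP genotyping, purity testing and assay design: methods"
author: "kaspr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{KASP genotyping, purity testing and assay design: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kaspr)
```

This vignette is the package's own account of the methods it implements:
the normalization and calling model, the pooled-purity statistics, the
primer-design thermodynamics, the synthetic-data generator that stands in
for wet-lab plates, and the numerical and design choices made where the
problem left them open.

## 1. The calling model

KASP chemistry converts a biallelic SNP into two-channel endpoint
fluorescence. Each assay carries two allele-specific forward primers,
identical except for the 3′-terminal base and prefixed with one of two
fixed universal FRET tails (`fretTails()`), plus one common reverse
primer. Amplification through the FAM-tailed primer releases FAM signal,
through the HEX-tailed primer HEX signal; heterozygous templates drive
both.

### Normalization

Raw endpoint readings are only comparable within one plate and one dye,
so each dye channel is rescaled by its plate-wide extremes:

$$\%F = \frac{X - \min F}{\max F - \min F} \times 100 .$$

Two consequences are load-bearing. First, every downstream quantity is
invariant under a positive affine transformation of a single channel
(gain or offset drift of the instrument cancels), which the test suite
checks as a property. Second, the plate must contain wells that span the
range: the minimum is normally supplied by no-template controls (NTCs)
and the maximum by a homozygous cluster in each dye. NTCs are therefore
*included* in the min/max — excluding them would inflate the percent
fluorescence of weak wells — and simulated screening plates carry
maintainer/restorer/hybrid control samples so that both dyes reach full
scale even when the screened material lacks a genotype class. On a plate
missing a homozygous cluster in some dye, the min–max quotient
compresses that channel and angles shift; this is a real property of
min–max normalization, not an implementation artifact, and the control
samples are the standard guard against it.

A constant channel (max = min) is a degenerate-plate error rather than a
silent division by zero.

### Classification

A well below the no-amplification threshold (default 25 %) in **both**
channels is `no_amp`. The joint rule is a deliberate choice: an NTC has
no signal in either channel, whereas a well high in one dye and low in
the other is a clean homozygote, and a per-dye rule would misclassify
it. Amplified wells are classified by the polar angle from the HEX axis,
$\theta = \mathrm{atan2}(\%FAM, \%HEX)$ in degrees:

| region | class |
|---|---|
| $\theta <$ `boundaryLow` (default 30°) | homozygous, HEX allele |
| `boundaryLow` $\le \theta \le$ `boundaryHigh` (default 60°) | heterozygous |
| $\theta >$ `boundaryHigh` (default 60°) | homozygous, FAM allele |

The defaults split the quadrant into three equal 30° segments — the
ideal-assay geometry — and are configurable per assay because real
assays shift clusters off the ideal axes. The three regions plus the
no-amplification zone partition the normalized square: every well gets
exactly one class (property-tested).

Replicates are combined after dropping `no_amp` members; if fewer than
`minAmplifiedReplicates` remain the sample is `no_amp`. The default
consensus policy is *unanimity*: any disagreement among amplified
replicates yields `ambiguous`. This is the conservative choice befitting
purity certification, where a silent wrong genotype is worse than a
repeat; a majority policy is available. Ambiguity and NTC-contamination
warnings never degrade to a genotype class.

Allele rendering goes through the assay's dye→allele map (for marker
621.5: HEX carries C, FAM carries G, so a HEX homozygote renders "CC"
and a heterozygote "GC"). Heterozygotes are written FAM allele first.

## 2. Pooled-sample purity testing

A pool of a HEX-allele main line with a fraction $f$ of FAM-allele
contaminant plants carries contaminant allele dosage $f$. The package
models endpoint signal as linear in dosage with per-dye gains
$g_{FAM}, g_{HEX}$:

$$ S_{FAM} \propto g_{FAM}\, f, \qquad S_{HEX} \propto g_{HEX}(1-f). $$

Endpoint-PCR saturation is deliberately not modelled. The empirical
justification is that half-contaminated pools cluster with F1 hybrids
(dosage one half) at the endpoint, which is what near-symmetric,
dosage-proportional behaviour predicts; residual nonlinearity can be
absorbed by calibrating the gain ratio against the hybrid reference
angle (`gainsFromHybrid()`, $g_{FAM}/g_{HEX} = \tan\theta_{hybrid}$).

The estimator inverts the model per amplified replicate,

$$\hat f = \frac{\%FAM/g_{FAM}}{\%FAM/g_{FAM} + \%HEX/g_{HEX}},$$

clipped to $[0,1]$ and averaged. Exactness at zero noise, strict
monotonicity of the expected angle in $f$, and the line-swap symmetry
$\hat f \mapsto 1-\hat f$ are property-tested. One known bias remains:
after min–max normalization an amplified well retains a small positive
offset from its baseline fluorescence term (the plate minimum is the
*smallest* baseline draw, not the mean), which inflates $\hat f$ at
small $f$ by about 0.01 under the default generator. The Monte-Carlo
accuracy test quantifies this and shows the error vanishing when the
baseline term is negligible. Reference-anchored background subtraction
would remove the bias but is intentionally left out of the estimator to
keep it a pure model inversion.

### Detection rule

Contamination is declared when the pool's mean angle deviates from the
pure main-line reference by more than `multiplier` (default 3) reference
standard deviations. Purity plates carry few reference replicates (four
by default), so the reference SD estimate has roughly three degrees of
freedom and can be arbitrarily small by chance; a raw $z$-test against
it would flag clean pools on plates where the reference happened to
cluster tightly and miss contaminated ones where it happened to spread.
The SD is therefore bounded below by `sdFloor` (default 1.5°, an
instrument-scale angular resolution guard); a zero-spread reference
additionally warns. The floor is what makes the detection pattern across
contamination levels reproducible seed to seed; with the default
generator the smallest reliably flagged level in a 1/3/5/10/50 % leaf
series is 10 %, while 50 % pools cluster with the hybrid reference.
Pools below the detection limit require single-plant assays — pooling
trades sensitivity for throughput by design.

## 3. Primer design

`designAssay()` composes three searches under `designConstraints()`:

* **Allele-specific pair** — for each admissible length (default
  18–30 nt) the pair of forward bodies ending exactly at the SNP,
  differing only in the 3′-terminal base (first listed allele → FAM by
  default). Discrimination relies on the terminal base alone; no
  auxiliary destabilizing mismatch is introduced, matching the structure
  of the validated published trios.
* **Common reverse primer** — exhaustive search over all windows
  strictly downstream of the SNP (templates are short, no heuristics
  needed), under the strict amplicon cap (default < 150 bp, measured
  from the allele-primer 5′ template position to the common primer's 5′
  end).
* **Selection** — candidates are filtered to a melting-temperature
  window (default 62 ± 3 °C) and GC range (default 30–70 %), then scored
  by the summed absolute Tm deviation of the three primers; ties break
  by shorter primer, then lexicographic body, so the design is a pure
  function of template and constraints (property-tested determinism).

If the forward orientation admits no design, the search repeats on the
reverse-complemented template (allele-specific primers on the minus
strand), the standard fallback in KASP design pipelines; the reported
alleles are then minus-strand bases and the result is marked
`strand = "-"`. Genuinely undesignable contexts — e.g. long AT-only
flanks — raise an infeasibility error naming the failing constraint;
not every SNP context converts to a workable KASP assay, and the
designer says so rather than emitting an out-of-spec trio.

### Melting-temperature model

`meltingTemp()` implements the unified nearest-neighbor two-state model:
per-step enthalpy/entropy sums with terminal A:T / G:C initiation
penalties, the symmetry correction and total-strand concentration for
self-complementary sequences, and the entropic salt correction
$\Delta S \mathrel{+}= 0.368\,(N-1)\ln[\mathrm{mon}^+]$. The
implementation agrees with an independent published NN calculator to
below $10^{-3}$ °C on the shipped regression set.

Defaults: 200 nM total oligonucleotide and **75 mM effective monovalent
salt**. The salt convention deserves a note, because NN melting
temperatures shift by several degrees across reasonable conventions
(plain buffer salt at one extreme, magnesium-corrected effective salt at
the other). 75 mM was fixed once so that the 62 °C design target is
reachable within the 18–30 nt length range for mid-GC templates — at
50 mM the same window sits above what most 30-mers can reach, and at
Mg-corrected values (≈200 mM) short GC-rich candidates overshoot it.
The Tm is computed on the allele-specific *body* only: the FRET tail is
single-stranded overhang in early cycles and does not bind the
template. Structural validation of existing trios (`validateAssay()`)
is deliberately Tm-free, since published trios were designed under
unknown thermodynamic conventions.

## 4. The synthetic-data generator

No replicate-level fluorescence data are publicly deposited for this
assay family, so the package ships a generator whose output has the
statistical structure the caller and the purity test assume. Its
defaults *are* the study conditions used by the tests and the
acceptance script.

Per well and dye,

$$ X = \mathrm{gain} \times \mathrm{dosage} \times \varepsilon_1 +
       \mathrm{baseline} \times \varepsilon_2, $$

with $\varepsilon_i$ independent mean-one lognormal factors of
coefficient of variation `noiseCv`, dosage 0 / 0.5 / 1 for the three
genotype classes (the pool fraction for pooled wells), and baseline-only
draws for NTCs and non-amplifying wells. Multiplicative lognormal noise
reflects that fluorescence signals are positive and PCR noise acts
multiplicatively. Baseline wells land near the plate minimum, hence
below the 25 % no-amplification threshold in both axes after
normalization, matching where negative controls are observed to fall.

Calibration choices, made once and documented rather than fitted to
data:

* `noiseCv` 0.04 for leaf tissue and 0.10 for hypocotyl — tissue quality
  is modelled purely as cluster tightness (leaf disrupts better than
  frozen hypocotyl). These values make the pooled leaf series detect
  10 % but not 5 % under the z > 3 rule, and degrade hypocotyl
  sensitivity, the qualitative pattern pooled testing shows in practice.
* `gain` 1000, `baseline` 400 (arbitrary units). The baseline-to-gain
  ratio sets the angular spread of the pure-line reference
  (≈ 0.9° at leaf noise), which, with the 1.5° SD floor, places the
  detection threshold between the 5 % and 10 % angular shifts
  (≈ 2.9° and 6.3°).
* Plates of 4 replicates per sample and pools of 100 plants; 2
  replicates suffice for line differentiation and are used in the
  26-line validation regression.

What the generator does **not** emulate: PCR saturation kinetics,
allele-specific mispriming, cross-plate batch effects, well-position
effects, and dye cross-talk. Passing tests therefore demonstrate the
correctness and calibration of the *analysis* under the stated noise
model, not instrument-level performance on real plates.

`randomSnpTemplate()` draws design templates in 30-nt blocks of 40–60 %
GC. This emulates the mid-GC genic context that real assay targets are
pre-screened for; fully unconstrained iid sequence occasionally admits
no design under the default constraints in either orientation (as some
real SNP contexts do not), which is the designer's documented
infeasibility outcome, exercised separately in the tests.

## 5. Worked panel: the sunflower restorer locus

The shipped fixtures encode the validated four-marker panel spanning the
sunflower fertility-restoration locus *Rf1* (`table1Assays()`,
`rf1Panel()`; markers 621.5, 621.11, 841.38, 861.19 in locus order, the
restorer allele on HEX throughout). `table2Fixture()` carries the
26-line validation matrix, including its two instructive irregularities:
one line non-amplifying at the two distal markers and one line
heterozygous at a single marker — both encoded as genotype classes so
the whole matrix can be regenerated as synthetic plates and re-called.
One printed heterozygous cell uses an allele letter that does not occur
at that marker; the fixture keeps the printed string verbatim and
resolves the genotype *class* (het) from the accompanying description,
and the regression test compares classes.

`emsScreenTruth()` encodes the single-plant screening example: ten
plants whose four-marker calls partition into two hybrids (one carrying
a non-amplifying marker, still classifiable from the remaining three —
the reason `minInformative` defaults to 2), seven maintainer-genotype
contaminants, and one recombinant whose zygosity switches between the
second and third marker. With the screened total of 431 germinated
plants, seven contaminants give `contaminantRate()` of 1.6 %.
Classification uses genotypes only; phenotype is annotation. "Contaminant"
is a report-level interpretation of `category == "maintainer"` within an
expected-hybrid population, not a core genotype state.

## 6. Problem sizes and determinism

Every stochastic computation is seeded: the simulators reseed from
`SimConfig@seed` (multi-plate simulations derive per-plate seeds by
offset), and the template generator uses the caller's RNG state. The
test suite and the acceptance script use 20-seed batches for stochastic
claims, 50 templates for designer-compliance sweeps, and plates of at
most a few hundred wells — sizes chosen so the whole suite runs in well
under a minute per component while keeping Monte-Carlo error far below
the tested margins.

## 7. Known limitations

* Threshold/angle calling only — no model-based cluster fitting; an
  assay whose clusters rotate far off the ideal axes needs per-assay
  boundaries, which the configuration supports but does not learn.
* The purity model is linear in allele dosage; strong endpoint
  saturation would bias fraction estimates beyond what the hybrid-anchor
  gain calibration absorbs.
* The baseline-leakage bias of the fraction estimator (≈ +0.01 at small
  fractions under default calibration) is documented rather than
  corrected.
* The designer screens Tm, GC, length and product size, but not
  secondary structure, primer-dimers or genome-wide specificity; its
  output is a candidate trio, not a wet-lab-validated assay.
* Recombination intervals are reported in marker order (with coordinates
  when the panel provides them); no genetic-map inference is attempted.
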