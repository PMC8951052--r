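# kaspr

Endpoint-fluorescence genotyping, assay design and genetic purity testing
for **Kompetitive Allele-Specific PCR (KASP)** markers, in R.

KASP reads a biallelic SNP from two-channel endpoint fluorescence: two
allele-specific primers share their sequence except for the 3′-terminal
base and carry distinct 5′ tails that recruit a FAM- or HEX-labelled
universal FRET cassette. The dye whose primer matches the template allele
amplifies, so homozygotes light up one channel, heterozygotes both. The
package is aimed at plant breeders and molecular-marker labs that use
KASP panels for marker-assisted selection — the motivating application is
the four-marker panel spanning the sunflower fertility-restorer locus
*Rf1* used to certify hybrid seed purity and to screen mutagenized
populations — but every component is generic.

## What it computes

**Genotype calling.** Raw endpoint readings `X` of each dye are
normalized per plate to percent fluorescence,

```
%F = (X − min F) / (max F − min F) × 100 ,
```

with `min F`/`max F` the plate-wide extremes of that dye (no-template
controls included). A well below the no-amplification threshold (default
25 %) in *both* channels is `no_amp`; otherwise its polar angle
`θ = atan2(%FAM, %HEX)` classifies it — `θ < 30°` homozygous for the HEX
allele, `30° ≤ θ ≤ 60°` heterozygous, `θ > 60°` homozygous for the FAM
allele (boundaries configurable per assay). Replicates are combined by
unanimity (default) or majority; disagreement yields `ambiguous`, never a
silent genotype.

**Assay design.** `designAssay()` builds the full primer trio for a
bracketed SNP template (`...ACCAG[G/C]TTA...`): two tailed allele-specific
forward primers ending exactly at the SNP plus the best common reverse
primer, under a strict product-length cap (default < 150 bp) and a
nearest-neighbor melting-temperature window (default 62 ± 3 °C, unified
NN parameters with salt correction; Tm is computed on the primer body,
excluding the FRET tail). `validateAssay()` runs the structural checks on
any existing trio.

**Purity testing.** A pool of a HEX-allele main line contaminated by a
FAM-allele line mixes linearly in allele dosage: `%FAM ∝ f`,
`%HEX ∝ 1 − f`. `estimateContamination()` inverts this
(`f̂ = gain-corrected FAM share`), and `detectContamination()` flags a
pool when its mean angle deviates from the pure-line reference by more
than 3 reference standard deviations.

**Haplotype screening.** `classifyPlant()` maps multi-marker consensus
calls to restorer / hybrid / maintainer zygosity and classifies single
plants, reporting recombination intervals whenever the zygosity switches
along the marker order; `contaminantRate()` turns a screen into a
percentage of off-type plants.

**Synthetic plates.** A seeded generator (`simulatePlate()`,
`simulatePoolSeries()`, `simulateEmsScreen()`) emulates two-dye endpoint
clusters with multiplicative lognormal noise, baseline wells and
per-plate scaling, and ships the published fixtures (`table1Assays()`,
`table2Fixture()`, `emsScreenTruth()`).

## Worked example

```r
library(kaspr)

sim <- simulatePlate(
  data.frame(sample_id = c("RHA325", "F1_hybrid", "HA342"),
             class     = c("hom_hex", "het", "hom_fam")),
  simConfig(seed = 11), assayName = "621.5")
calls <- callPlate(sim$plate, table1Assays()[["621.5"]])
calls[, c("sample_id", "class", "genotype", "angle_deg", "n_amplified")]
#>   sample_id   class genotype  angle_deg n_amplified
#> 1 F1_hybrid     het       GC 47.3818157           4
#> 2     HA342 hom_fam       GG 88.3116447           4
#> 3    RHA325 hom_hex       CC  0.7257426           4
```

The restorer line RHA325 sits on the HEX axis (angle ≈ 0.7°, genotype CC
via the dye→allele map of marker 621.5), the maintainer HA342 on the FAM
axis, and the F1 hybrid near 45°. Pooled purity testing on the same
marker:

```r
ps  <- simulatePoolSeries(c(0.01, 0.05, 0.10, 0.50), simConfig(seed = 11))
nw  <- normalizePlate(ps$plate)$wells
refs <- referencesFromWells(nw)
res <- lapply(c(1, 5, 10, 50), function(l)
  detectContamination(nw[nw$sample_id == sprintf("pool_%g", l), ], refs,
                      poolId = sprintf("pool_%g", l)))
purityReport(res)
#>   pool_id mean_angle z_score flagged estimated_fraction estimate_sd
#> 1  pool_1       1.83 -0.0478   FALSE             0.0310     0.00577
#> 2 pool_10       8.53  4.4162    TRUE             0.1304     0.00873
#> 3  pool_5       5.09  2.1225   FALSE             0.0814     0.02169
#> 4 pool_50      45.52 29.0761    TRUE             0.5045     0.01528
#>   nearest_reference n_amplified
#> 1              main           4
#> 2              main           4
#> 3              main           4
#> 4            hybrid           4
```

Under leaf-quality noise the 10 % pool is flagged (z > 3) while 5 % and
below are not, and the half-contaminated pool clusters with the F1-hybrid
reference — the behaviour expected of pooled testing at this noise level.
Designing a fresh assay:

```r
set.seed(11)
designAssay(randomSnpTemplate(), name = "demo")
#> DesignedAssay (strand +, product 106 bp, score 1.2)
#> KaspAssay 'demo' (demo)
#>   alleles: FAM=C HEX=T
#>   FAM primer:    GAAGGTGACCAAGTTCATGCTGCCTACGACTAAGGGAGGCTGC
#>   HEX primer:    GAAGGTCGGAGTCAACGGATTGCCTACGACTAAGGGAGGCTGT
#>   common primer: ATGTCTGCCACTAAGTGCCTAATCCC
```

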