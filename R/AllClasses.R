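#' @import methods
NULL

## Universal FRET-cassette tail sequences. Every KASP allele-specific primer
## starts with one of these; the dye is recruited through the tail, so the
## tail sequence itself is invariant across assays.
.FAM_TAIL <- "GAAGGTGACCAAGTTCATGCT"
.HEX_TAIL <- "GAAGGTCGGAGTCAACGGATT"

#' Universal FRET cassette tail sequences
#'
#' The two fixed 5' tail sequences that recruit the FAM- and HEX-labelled
#' FRET cassettes of the universal KASP master mix. Allele-specific primers
#' must begin with the tail matching their dye.
#'
#' @return Named character vector with elements `fam` and `hex`.
#' @examples
#' fretTails()
#' @export
fretTails <- function() c(fam = .FAM_TAIL, hex = .HEX_TAIL)

.GENO_CLASSES <- c("hom_hex", "het", "hom_fam", "no_amp", "ambiguous")

.is_dna <- function(x) {
  length(x) == 1L && !is.na(x) && nzchar(x) &&
    !grepl("[^ACGT]", x)
}

#' KaspAssay: a KASP marker definition
#'
#' An S4 container for one KASP assay: the marker identity, the two SNP
#' alleles, the dye-to-allele mapping and the primer trio (two tailed
#' allele-specific forward primers plus one common reverse primer).
#'
#' Validity enforces the structural rules of the chemistry: the FAM and HEX
#' primers must start with their respective universal FRET tails
#' ([fretTails()]), each allele-specific primer must end in the allele it
#' reports, and the two allele-specific bodies (tail removed) must be
#' identical except for the 3'-terminal base.
#'
#' @slot name Marker identifier, e.g. `"621.5"`.
#' @slot snpId SNP identifier, e.g. `"PPR621.5"`.
#' @slot alleleFam Single base reported by the FAM channel.
#' @slot alleleHex Single base reported by the HEX channel.
#' @slot primerFam Full FAM allele-specific primer (tail + body).
#' @slot primerHex Full HEX allele-specific primer (tail + body).
#' @slot primerCommon Common (reverse) primer.
#' @slot chromosome Optional chromosome number (1-based), `NA` if unknown.
#' @slot position Optional 1-based position used for marker ordering.
#' @seealso [kaspAssay()], [readAssay()], [validateAssay()]
#' @export
setClass("KaspAssay",
  representation(
    name = "character",
    snpId = "character",
    alleleFam = "character",
    alleleHex = "character",
    primerFam = "character",
    primerHex = "character",
    primerCommon = "character",
    chromosome = "integer",
    position = "integer"
  )
)

setValidity("KaspAssay", function(object) {
  msgs <- character()
  for (s in c("name", "snpId")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || !nzchar(v)) {
      msgs <- c(msgs, sprintf("'%s' must be a non-empty string", s))
    }
  }
  for (s in c("alleleFam", "alleleHex")) {
    v <- slot(object, s)
    if (!.is_dna(v) || nchar(v) != 1L) {
      msgs <- c(msgs, sprintf("'%s' must be a single base in ACGT", s))
    }
  }
  for (s in c("primerFam", "primerHex", "primerCommon")) {
    if (!.is_dna(slot(object, s))) {
      msgs <- c(msgs, sprintf("'%s' must be a non-empty ACGT sequence", s))
    }
  }
  if (length(msgs)) return(msgs)

  if (object@alleleFam == object@alleleHex) {
    msgs <- c(msgs, "alleleFam and alleleHex must differ")
  }
  if (!startsWith(object@primerFam, .FAM_TAIL)) {
    msgs <- c(msgs, "primerFam does not start with the FAM FRET tail")
  }
  if (!startsWith(object@primerHex, .HEX_TAIL)) {
    msgs <- c(msgs, "primerHex does not start with the HEX FRET tail")
  }
  last <- function(x) substr(x, nchar(x), nchar(x))
  if (last(object@primerFam) != object@alleleFam) {
    msgs <- c(msgs, sprintf(
      "primerFam 3' base (%s) disagrees with alleleFam (%s)",
      last(object@primerFam), object@alleleFam))
  }
  if (last(object@primerHex) != object@alleleHex) {
    msgs <- c(msgs, sprintf(
      "primerHex 3' base (%s) disagrees with alleleHex (%s)",
      last(object@primerHex), object@alleleHex))
  }
  bf <- substring(object@primerFam, nchar(.FAM_TAIL) + 1L)
  bh <- substring(object@primerHex, nchar(.HEX_TAIL) + 1L)
  if (nchar(bf) < 2L || nchar(bh) < 2L) {
    msgs <- c(msgs, "allele-specific primer bodies are too short")
  } else if (nchar(bf) != nchar(bh) ||
             substr(bf, 1L, nchar(bf) - 1L) != substr(bh, 1L, nchar(bh) - 1L)) {
    msgs <- c(msgs,
      "allele-specific bodies must be identical except the 3'-terminal base")
  }
  if (length(msgs)) msgs else TRUE
})

#' RawPlate: one plate of raw endpoint fluorescence
#'
#' Per-well, per-dye raw endpoint fluorescence readings joined with sample
#' metadata. `wells` is a data.frame with columns `well_id`, `sample_id`,
#' `replicate_index`, `is_ntc`, `fam`, `hex` and `rox` (`NA` when the
#' passive reference was not exported). ROX is stored for completeness but
#' is not used in normalization: percent fluorescence is defined on the raw
#' dye values relative to the plate minimum and maximum.
#'
#' @slot plateId Free-text plate identifier.
#' @slot assayName Name of the [KaspAssay-class] run on the plate.
#' @slot wells data.frame of well-level readings and metadata.
#' @seealso [rawPlate()], [readPlate()], [normalizePlate()]
#' @export
setClass("RawPlate",
  representation(
    plateId = "character",
    assayName = "character",
    wells = "data.frame"
  )
)

setValidity("RawPlate", function(object) {
  msgs <- character()
  w <- object@wells
  need <- c("well_id", "sample_id", "replicate_index", "is_ntc", "fam", "hex")
  miss <- setdiff(need, names(w))
  if (length(miss)) {
    return(sprintf("wells is missing column(s): %s", paste(miss, collapse = ", ")))
  }
  if (nrow(w) < 2L) msgs <- c(msgs, "a plate needs at least 2 wells")
  if (anyDuplicated(w$well_id)) {
    msgs <- c(msgs, sprintf("duplicate well id(s): %s",
      paste(unique(w$well_id[duplicated(w$well_id)]), collapse = ", ")))
  }
  if (!any(!w$is_ntc)) msgs <- c(msgs, "a plate needs at least one non-NTC well")
  for (dye in c("fam", "hex")) {
    v <- w[[dye]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
      msgs <- c(msgs, sprintf("%s readings must be finite numbers", dye))
    } else if (any(v < 0)) {
      msgs <- c(msgs, sprintf("negative %s fluorescence is not allowed", dye))
    }
  }
  if (any(w$replicate_index < 1L)) {
    msgs <- c(msgs, "replicate_index must be a positive integer")
  }
  if (length(msgs)) msgs else TRUE
})

#' CallerConfig: genotype-calling parameters
#'
#' Thresholds of the angular genotype caller. Wells whose percent
#' fluorescence is below `noAmpThreshold` in *both* dye channels fall into
#' the no-amplification zone (no-template controls and failed assays sit
#' there). Amplified wells are classified by the angle of
#' (%HEX, %FAM) from the HEX axis: below `boundaryLow` degrees is
#' homozygous for the HEX allele, above `boundaryHigh` homozygous for the
#' FAM allele, in between heterozygous. The default boundaries split the
#' 90-degree quadrant into three equal 30-degree segments; both are
#' configurable per assay because real assays can shift clusters off the
#' ideal geometry.
#'
#' @slot noAmpThreshold Percent fluorescence below which a channel counts
#'   as non-amplified (default 25).
#' @slot boundaryLow Lower class boundary in degrees (default 30).
#' @slot boundaryHigh Upper class boundary in degrees (default 60).
#' @slot replicatePolicy `"unanimity"` (default) or `"majority"` for
#'   consensus across replicates.
#' @slot minAmplifiedReplicates Minimum amplified replicates required for a
#'   consensus genotype (default 1).
#' @seealso [callerConfig()], [classifyWells()], [consensusCall()]
#' @export
setClass("CallerConfig",
  representation(
    noAmpThreshold = "numeric",
    boundaryLow = "numeric",
    boundaryHigh = "numeric",
    replicatePolicy = "character",
    minAmplifiedReplicates = "integer"
  )
)

setValidity("CallerConfig", function(object) {
  msgs <- character()
  t <- object@noAmpThreshold
  if (length(t) != 1L || !is.finite(t) || t <= 0 || t >= 100) {
    msgs <- c(msgs, "noAmpThreshold must lie strictly between 0 and 100")
  }
  lo <- object@boundaryLow; hi <- object@boundaryHigh
  if (length(lo) != 1L || length(hi) != 1L || !is.finite(lo) || !is.finite(hi) ||
      !(0 < lo && lo < hi && hi < 90)) {
    msgs <- c(msgs, "boundaries must satisfy 0 < boundaryLow < boundaryHigh < 90")
  }
  if (!object@replicatePolicy %in% c("unanimity", "majority")) {
    msgs <- c(msgs, "replicatePolicy must be 'unanimity' or 'majority'")
  }
  if (object@minAmplifiedReplicates < 1L) {
    msgs <- c(msgs, "minAmplifiedReplicates must be >= 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' SnpTemplate: flanking sequence around a biallelic SNP
#'
#' Design template in bracket notation `LEFT[X/Y]RIGHT`. The upstream flank
#' must leave room for an 18-mer allele-specific primer ending at the SNP;
#' the downstream flank must leave room for a common reverse primer.
#'
#' @slot upstream Plus-strand sequence 5' of the SNP (>= 18 nt).
#' @slot alleleA First allele (assigned to FAM by default in design).
#' @slot alleleB Second allele (assigned to HEX by default).
#' @slot downstream Plus-strand sequence 3' of the SNP (>= 40 nt).
#' @slot label Free-text label.
#' @seealso [parseSnpTemplate()], [designAssay()]
#' @export
setClass("SnpTemplate",
  representation(
    upstream = "character",
    alleleA = "character",
    alleleB = "character",
    downstream = "character",
    label = "character"
  )
)

setValidity("SnpTemplate", function(object) {
  msgs <- character()
  if (!.is_dna(object@upstream) || nchar(object@upstream) < 18L) {
    msgs <- c(msgs, "upstream must be an ACGT sequence of at least 18 nt")
  }
  if (!.is_dna(object@downstream) || nchar(object@downstream) < 40L) {
    msgs <- c(msgs, "downstream must be an ACGT sequence of at least 40 nt")
  }
  for (s in c("alleleA", "alleleB")) {
    v <- slot(object, s)
    if (!.is_dna(v) || nchar(v) != 1L) {
      msgs <- c(msgs, sprintf("'%s' must be a single base in ACGT", s))
    }
  }
  if (!length(msgs) && object@alleleA == object@alleleB) {
    msgs <- c(msgs, "the two alleles must differ")
  }
  if (length(msgs)) msgs else TRUE
})

#' DesignConstraints: primer-design parameters
#'
#' Constraints and physical parameters of the KASP primer designer. The
#' product-length cap and the annealing-temperature target follow the
#' validated assay configuration (products under 150 bp, annealing near
#' 62 degrees C). Melting temperatures are nearest-neighbor estimates of
#' the allele-specific primer *body* (the FRET tail does not bind the
#' template in early cycles) under the stated salt and oligonucleotide
#' concentrations.
#'
#' @slot maxProductLen Strict upper bound on amplicon length in bp
#'   (default 150; designs must be strictly shorter).
#' @slot targetTm Target melting temperature in degrees C (default 62).
#' @slot tmTolerance Allowed deviation from `targetTm` in degrees C
#'   (default 3).
#' @slot primerLenMin,primerLenMax Allowed primer lengths in nt
#'   (default 18-30).
#' @slot gcMin,gcMax Allowed GC content in percent (default 30-70).
#' @slot monovalentMM Effective monovalent cation concentration in mM used
#'   by the melting-temperature model (default 75).
#' @slot oligoNM Total oligonucleotide concentration in nM (default 200).
#' @seealso [designConstraints()], [designAssay()], [meltingTemp()]
#' @export
setClass("DesignConstraints",
  representation(
    maxProductLen = "integer",
    targetTm = "numeric",
    tmTolerance = "numeric",
    primerLenMin = "integer",
    primerLenMax = "integer",
    gcMin = "numeric",
    gcMax = "numeric",
    monovalentMM = "numeric",
    oligoNM = "numeric"
  )
)

setValidity("DesignConstraints", function(object) {
  msgs <- character()
  if (object@primerLenMin < 8L || object@primerLenMax < object@primerLenMin) {
    msgs <- c(msgs, "primer length range is invalid")
  }
  if (object@maxProductLen <= 2L * object@primerLenMin) {
    msgs <- c(msgs, "maxProductLen must exceed twice the minimum primer length")
  }
  if (object@tmTolerance <= 0) msgs <- c(msgs, "tmTolerance must be positive")
  if (!(0 <= object@gcMin && object@gcMin < object@gcMax && object@gcMax <= 100)) {
    msgs <- c(msgs, "GC range must satisfy 0 <= gcMin < gcMax <= 100")
  }
  if (object@monovalentMM <= 0 || object@oligoNM <= 0) {
    msgs <- c(msgs, "salt and oligo concentrations must be positive")
  }
  if (length(msgs)) msgs else TRUE
})

#' DesignedAssay: result of a KASP primer design
#'
#' A [KaspAssay-class] plus design metadata: the shared amplicon length of
#' the two allele-specific primers, a dimensionless design penalty (the sum
#' of the absolute deviations of the three primer melting temperatures from
#' the target; lower is better), and the template strand the trio was
#' designed on (`"+"` or `"-"`; on `"-"` the reported alleles are the
#' complement of the template's bracket alleles).
#'
#' @slot assay The designed [KaspAssay-class].
#' @slot productLenFam,productLenHex Amplicon length in bp for each
#'   allele-specific primer (equal by construction: the two bodies share
#'   coordinates).
#' @slot designScore Penalty used for candidate selection.
#' @slot strand `"+"` or `"-"`.
#' @seealso [designAssay()]
#' @export
setClass("DesignedAssay",
  representation(
    assay = "KaspAssay",
    productLenFam = "integer",
    productLenHex = "integer",
    designScore = "numeric",
    strand = "character"
  )
)

setValidity("DesignedAssay", function(object) {
  msgs <- character()
  if (object@productLenFam < 1L || object@productLenHex < 1L) {
    msgs <- c(msgs, "product lengths must be positive")
  }
  if (!object@strand %in% c("+", "-")) msgs <- c(msgs, "strand must be '+' or '-'")
  if (length(msgs)) msgs else TRUE
})

#' ReferenceSet: reference angles for purity testing
#'
#' Replicate angles (degrees from the HEX axis in normalized coordinates)
#' of the three control groups included on a purity-testing plate: the pure
#' main line, the pure contaminant line, and the F1 hybrid.
#'
#' @slot mainAngles Angles of the pure main-line replicates (>= 2).
#' @slot contaminantAngles Angles of the pure contaminant-line replicates.
#' @slot hybridAngles Angles of the F1 hybrid replicates.
#' @seealso [referenceSet()], [detectContamination()]
#' @export
setClass("ReferenceSet",
  representation(
    mainAngles = "numeric",
    contaminantAngles = "numeric",
    hybridAngles = "numeric"
  )
)

setValidity("ReferenceSet", function(object) {
  msgs <- character()
  for (s in c("mainAngles", "contaminantAngles", "hybridAngles")) {
    v <- slot(object, s)
    if (length(v) < 2L || anyNA(v) || any(!is.finite(v))) {
      msgs <- c(msgs, sprintf("'%s' needs >= 2 finite replicate angles", s))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' PurityResult: outcome of a pooled-sample purity test
#'
#' @slot poolId Pool identifier.
#' @slot meanAngle Mean angle of the amplified pool replicates (degrees).
#' @slot zScore Deviation of the pool mean angle from the pure main-line
#'   reference, in units of the reference angle standard deviation.
#' @slot flagged `TRUE` when `zScore` exceeds the detection multiplier.
#' @slot estimatedFraction Estimated contaminant fraction in `[0, 1]`
#'   (`NA` when no pool replicate amplified).
#' @slot estimateSd Replicate standard deviation of the fraction estimate.
#' @slot nearestReference `"main"`, `"hybrid"` or `"contaminant"`.
#' @slot nAmplified Number of amplified pool replicates used.
#' @seealso [detectContamination()], [purityReport()]
#' @export
setClass("PurityResult",
  representation(
    poolId = "character",
    meanAngle = "numeric",
    zScore = "numeric",
    flagged = "logical",
    estimatedFraction = "numeric",
    estimateSd = "numeric",
    nearestReference = "character",
    nAmplified = "integer"
  )
)

#' MarkerPanel: an ordered multi-marker KASP panel
#'
#' Ordered collection of [KaspAssay-class] markers spanning a locus, with
#' the designation of which dye carries the restorer-haplotype allele at
#' each marker. Marker order follows the list order; when chromosome
#' positions are present they must be strictly increasing.
#'
#' @slot assays List of [KaspAssay-class] objects (>= 2), named by marker.
#' @slot restorerDye Character vector (`"fam"`/`"hex"`), one per marker:
#'   the dye whose allele is the restorer haplotype.
#' @seealso [markerPanel()], [classifyPlant()], [rf1Panel()]
#' @export
setClass("MarkerPanel",
  representation(
    assays = "list",
    restorerDye = "character"
  )
)

setValidity("MarkerPanel", function(object) {
  msgs <- character()
  n <- length(object@assays)
  if (n < 2L) msgs <- c(msgs, "a panel needs at least 2 markers")
  if (!all(vapply(object@assays, is, logical(1), "KaspAssay"))) {
    msgs <- c(msgs, "assays must all be KaspAssay objects")
  } else {
    nm <- unname(vapply(object@assays, function(a) a@name, character(1)))
    if (is.null(names(object@assays)) || !identical(names(object@assays), nm)) {
      msgs <- c(msgs, "assays must be named by their marker names")
    }
    if (anyDuplicated(nm)) msgs <- c(msgs, "marker names must be unique")
    pos <- vapply(object@assays, function(a) a@position, integer(1))
    pos <- pos[!is.na(pos)]
    if (length(pos) > 1L && any(diff(pos) <= 0L)) {
      msgs <- c(msgs, "marker positions must be strictly increasing")
    }
  }
  if (length(object@restorerDye) != n ||
      !all(object@restorerDye %in% c("fam", "hex"))) {
    msgs <- c(msgs, "restorerDye must be 'fam' or 'hex', one per marker")
  }
  if (length(msgs)) msgs else TRUE
})

#' PlantClassification: category of a single plant from a marker panel
#'
#' @slot plantId Plant identifier.
#' @slot category One of `"restorer"`, `"hybrid"`, `"maintainer"`,
#'   `"recombinant"`, `"unclassified"`.
#' @slot informativeMarkers Number of amplified, unambiguous markers used.
#' @slot recombinationIntervals Character vector of adjacent-marker
#'   intervals (`"left--right"`) flanking a zygosity switch; empty unless
#'   the plant is recombinant.
#' @slot zygosities Named character vector of per-marker zygosity states
#'   (`"hom_restorer"`, `"het"`, `"hom_maintainer"`, or `NA` for
#'   uninformative markers).
#' @seealso [classifyPlant()], [screenReport()]
#' @export
setClass("PlantClassification",
  representation(
    plantId = "character",
    category = "character",
    informativeMarkers = "integer",
    recombinationIntervals = "character",
    zygosities = "character"
  )
)

setValidity("PlantClassification", function(object) {
  ok <- object@category %in%
    c("restorer", "hybrid", "maintainer", "recombinant", "unclassified")
  if (!ok) return("unknown category")
  if (object@category != "recombinant" && length(object@recombinationIntervals)) {
    return("recombination intervals are only allowed for recombinant plants")
  }
  TRUE
})

#' SimConfig: synthetic-plate generator settings
#'
#' Parameters of the seeded fluorescence simulator. A well's raw signal in
#' each dye channel is `gain x dosage x lognormal(CV) + baseline x
#' lognormal(CV)`, where dosage is the allele fraction seen by the dye
#' (0, 0.5, 1 for the three genotype classes; the pool fraction for pooled
#' samples) and the lognormal factors have mean 1 and coefficient of
#' variation `noiseCv`. Non-amplifying wells and no-template controls draw
#' only the baseline term, which places them near the plate minimum --
#' below the no-amplification threshold after normalization.
#'
#' Tissue quality is modelled purely as noise: leaf preparations
#' (`noiseCv = 0.04`) give tighter clusters than hypocotyl preparations
#' (`noiseCv = 0.10`).
#'
#' @slot seed Integer seed; identical seeds give identical plates.
#' @slot gainFam,gainHex Mean amplified raw signal per unit allele dosage.
#' @slot baseline Mean raw signal of non-amplifying wells.
#' @slot noiseCv Multiplicative lognormal coefficient of variation.
#' @slot replicates Wells per sample (default 4).
#' @slot poolSize Plants per pool (default 100).
#' @slot tissue `"leaf"` or `"hypocotyl"` (label; sets the default CV).
#' @seealso [simConfig()], [simulatePlate()], [simulatePoolSeries()]
#' @export
setClass("SimConfig",
  representation(
    seed = "integer",
    gainFam = "numeric",
    gainHex = "numeric",
    baseline = "numeric",
    noiseCv = "numeric",
    replicates = "integer",
    poolSize = "integer",
    tissue = "character"
  )
)

setValidity("SimConfig", function(object) {
  msgs <- character()
  if (!(object@gainFam > object@baseline && object@gainHex > object@baseline &&
        object@baseline > 0)) {
    msgs <- c(msgs, "gains must exceed baseline and baseline must be positive")
  }
  if (!(object@noiseCv >= 0 && object@noiseCv < 1)) {
    msgs <- c(msgs, "noiseCv must lie in [0, 1)")
  }
  if (object@replicates < 1L) msgs <- c(msgs, "replicates must be >= 1")
  if (object@poolSize < 1L) msgs <- c(msgs, "poolSize must be >= 1")
  if (!object@tissue %in% c("leaf", "hypocotyl")) {
    msgs <- c(msgs, "tissue must be 'leaf' or 'hypocotyl'")
  }
  if (length(msgs)) msgs else TRUE
})
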