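#' Construct a KaspAssay
#'
#' Builds and validates a KASP assay definition from its primer trio. The
#' FRET tails are auto-detected as prefixes of the two allele-specific
#' primers; the reported alleles default to the 3'-terminal bases of the
#' allele-specific primers and may be stated explicitly as a cross-check.
#'
#' @param name Marker name, e.g. `"621.5"`.
#' @param primerFam,primerHex Full tailed allele-specific primers (5'->3').
#' @param primerCommon Common reverse primer (5'->3').
#' @param snpId SNP identifier; defaults to `name`.
#' @param alleleFam,alleleHex Declared alleles; default to the primers'
#'   3'-terminal bases.
#' @param chromosome,position Optional integer coordinates (1-based).
#' @return A validated [KaspAssay-class].
#' @examples
#' a <- kaspAssay("621.5",
#'   primerFam = "GAAGGTGACCAAGTTCATGCTACCAGTAATCTCCACATGAACATTG",
#'   primerHex = "GAAGGTCGGAGTCAACGGATTACCAGTAATCTCCACATGAACATTC",
#'   primerCommon = "GCGATAAAGAAGCGGGAGATTA", snpId = "PPR621.5")
#' famAllele(a); hexAllele(a)
#' @export
kaspAssay <- function(name, primerFam, primerHex, primerCommon,
                      snpId = name, alleleFam = NULL, alleleHex = NULL,
                      chromosome = NA_integer_, position = NA_integer_) {
  up <- function(x) toupper(gsub("[[:space:]]", "", x))
  primerFam <- up(primerFam); primerHex <- up(primerHex)
  primerCommon <- up(primerCommon)
  last <- function(x) substr(x, nchar(x), nchar(x))
  if (is.null(alleleFam)) alleleFam <- last(primerFam)
  if (is.null(alleleHex)) alleleHex <- last(primerHex)
  new("KaspAssay",
      name = as.character(name), snpId = as.character(snpId),
      alleleFam = toupper(alleleFam), alleleHex = toupper(alleleHex),
      primerFam = primerFam, primerHex = primerHex,
      primerCommon = primerCommon,
      chromosome = as.integer(chromosome), position = as.integer(position))
}

#' Construct a RawPlate
#'
#' @param plateId Plate identifier.
#' @param wells data.frame with columns `well_id`, `sample_id`,
#'   `replicate_index`, `is_ntc`, `fam`, `hex` and optionally `rox`.
#' @param assayName Name of the assay run on the plate.
#' @return A validated [RawPlate-class].
#' @seealso [readPlate()] to build a plate from instrument exports.
#' @export
rawPlate <- function(plateId, wells, assayName = NA_character_) {
  if (!"rox" %in% names(wells)) wells$rox <- NA_real_
  wells$well_id <- as.character(wells$well_id)
  wells$sample_id <- as.character(wells$sample_id)
  wells$replicate_index <- as.integer(wells$replicate_index)
  wells$is_ntc <- as.logical(wells$is_ntc)
  rownames(wells) <- NULL
  new("RawPlate", plateId = as.character(plateId),
      assayName = as.character(assayName),
      wells = wells[, c("well_id", "sample_id", "replicate_index",
                        "is_ntc", "fam", "hex", "rox")])
}

#' Construct a CallerConfig
#'
#' @param noAmpThreshold Percent-fluorescence threshold of the
#'   no-amplification zone (default 25); a well must be below it in both
#'   dye channels to be scored `no_amp`.
#' @param boundaryLow,boundaryHigh Class boundaries in degrees
#'   (defaults 30 and 60).
#' @param replicatePolicy `"unanimity"` or `"majority"`.
#' @param minAmplifiedReplicates Minimum amplified replicates for a
#'   consensus genotype.
#' @return A validated [CallerConfig-class].
#' @export
callerConfig <- function(noAmpThreshold = 25, boundaryLow = 30,
                         boundaryHigh = 60,
                         replicatePolicy = c("unanimity", "majority"),
                         minAmplifiedReplicates = 1L) {
  new("CallerConfig",
      noAmpThreshold = as.numeric(noAmpThreshold),
      boundaryLow = as.numeric(boundaryLow),
      boundaryHigh = as.numeric(boundaryHigh),
      replicatePolicy = match.arg(replicatePolicy),
      minAmplifiedReplicates = as.integer(minAmplifiedReplicates))
}

#' Construct DesignConstraints
#'
#' @param maxProductLen Strict amplicon-length cap in bp (default 150).
#' @param targetTm Target primer melting temperature in degrees C
#'   (default 62).
#' @param tmTolerance Allowed Tm deviation in degrees C (default 3).
#' @param primerLenRange Length-2 integer vector of allowed primer lengths
#'   (default `c(18, 30)`).
#' @param gcRange Length-2 numeric vector of allowed GC percentages
#'   (default `c(30, 70)`).
#' @param monovalentMM Effective monovalent salt in mM for the Tm model
#'   (default 75).
#' @param oligoNM Total oligo concentration in nM (default 200).
#' @return A validated [DesignConstraints-class].
#' @export
designConstraints <- function(maxProductLen = 150L, targetTm = 62,
                              tmTolerance = 3, primerLenRange = c(18L, 30L),
                              gcRange = c(30, 70), monovalentMM = 75,
                              oligoNM = 200) {
  new("DesignConstraints",
      maxProductLen = as.integer(maxProductLen),
      targetTm = as.numeric(targetTm), tmTolerance = as.numeric(tmTolerance),
      primerLenMin = as.integer(primerLenRange[1L]),
      primerLenMax = as.integer(primerLenRange[2L]),
      gcMin = as.numeric(gcRange[1L]), gcMax = as.numeric(gcRange[2L]),
      monovalentMM = as.numeric(monovalentMM), oligoNM = as.numeric(oligoNM))
}

#' Construct a ReferenceSet
#'
#' @param mainAngles,contaminantAngles,hybridAngles Numeric vectors of
#'   replicate angles (degrees) of the pure main line, the pure contaminant
#'   line and the F1 hybrid controls; each needs at least two replicates.
#' @return A validated [ReferenceSet-class].
#' @export
referenceSet <- function(mainAngles, contaminantAngles, hybridAngles) {
  new("ReferenceSet",
      mainAngles = as.numeric(mainAngles),
      contaminantAngles = as.numeric(contaminantAngles),
      hybridAngles = as.numeric(hybridAngles))
}

#' Construct a MarkerPanel
#'
#' @param assays List of [KaspAssay-class] objects in locus order.
#' @param restorerDye `"fam"` or `"hex"` per marker: the dye carrying the
#'   restorer-haplotype allele. Recycled if length 1.
#' @return A validated [MarkerPanel-class].
#' @seealso [rf1Panel()] for the built-in four-marker restorer-locus panel.
#' @export
markerPanel <- function(assays, restorerDye) {
  nm <- vapply(assays, function(a) a@name, character(1))
  names(assays) <- nm
  if (length(restorerDye) == 1L) restorerDye <- rep(restorerDye, length(assays))
  names(restorerDye) <- nm
  new("MarkerPanel", assays = assays, restorerDye = restorerDye)
}

#' Construct a SimConfig
#'
#' @param seed Integer seed for reproducibility.
#' @param gainFam,gainHex Mean amplified raw signal per unit allele dosage
#'   (arbitrary fluorescence units; default 1000).
#' @param baseline Mean raw signal of non-amplifying wells (default 400).
#' @param noiseCv Lognormal coefficient of variation; defaults to 0.04 for
#'   `tissue = "leaf"` and 0.10 for `tissue = "hypocotyl"`.
#' @param replicates Wells per sample (default 4).
#' @param poolSize Plants per pool (default 100).
#' @param tissue `"leaf"` (default) or `"hypocotyl"`.
#' @return A validated [SimConfig-class].
#' @export
simConfig <- function(seed = 1L, gainFam = 1000, gainHex = 1000,
                      baseline = 400, noiseCv = NULL, replicates = 4L,
                      poolSize = 100L, tissue = c("leaf", "hypocotyl")) {
  tissue <- match.arg(tissue)
  if (is.null(noiseCv)) noiseCv <- if (tissue == "leaf") 0.04 else 0.10
  new("SimConfig", seed = as.integer(seed),
      gainFam = as.numeric(gainFam), gainHex = as.numeric(gainHex),
      baseline = as.numeric(baseline), noiseCv = as.numeric(noiseCv),
      replicates = as.integer(replicates), poolSize = as.integer(poolSize),
      tissue = tissue)
}
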