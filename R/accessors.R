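#' @name accessors
#' @title Accessors for kaspr S4 classes
#'
#' @description Slot accessors for the core data objects. `famBody()` and
#' `hexBody()` return the allele-specific primer bodies with the universal
#' FRET tail removed.
#'
#' @param x A kaspr S4 object.
#' @return The slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("assayName", function(x) standardGeneric("assayName"))
#' @rdname accessors
#' @export
setGeneric("famAllele", function(x) standardGeneric("famAllele"))
#' @rdname accessors
#' @export
setGeneric("hexAllele", function(x) standardGeneric("hexAllele"))
#' @rdname accessors
#' @export
setGeneric("famPrimer", function(x) standardGeneric("famPrimer"))
#' @rdname accessors
#' @export
setGeneric("hexPrimer", function(x) standardGeneric("hexPrimer"))
#' @rdname accessors
#' @export
setGeneric("commonPrimer", function(x) standardGeneric("commonPrimer"))
#' @rdname accessors
#' @export
setGeneric("famBody", function(x) standardGeneric("famBody"))
#' @rdname accessors
#' @export
setGeneric("hexBody", function(x) standardGeneric("hexBody"))
#' @rdname accessors
#' @export
setGeneric("plateId", function(x) standardGeneric("plateId"))
#' @rdname accessors
#' @export
setGeneric("wells", function(x) standardGeneric("wells"))
#' @rdname accessors
#' @export
setGeneric("designedAssay", function(x) standardGeneric("designedAssay"))
#' @rdname accessors
#' @export
setGeneric("productLength", function(x) standardGeneric("productLength"))
#' @rdname accessors
#' @export
setGeneric("designScore", function(x) standardGeneric("designScore"))
#' @rdname accessors
#' @export
setGeneric("panelAssays", function(x) standardGeneric("panelAssays"))
#' @rdname accessors
#' @export
setGeneric("restorerDye", function(x) standardGeneric("restorerDye"))
#' @rdname accessors
#' @export
setGeneric("plantCategory", function(x) standardGeneric("plantCategory"))
#' @rdname accessors
#' @export
setGeneric("recombinationIntervals",
           function(x) standardGeneric("recombinationIntervals"))

#' @rdname accessors
setMethod("assayName", "KaspAssay", function(x) x@name)
#' @rdname accessors
setMethod("assayName", "RawPlate", function(x) x@assayName)
#' @rdname accessors
setMethod("famAllele", "KaspAssay", function(x) x@alleleFam)
#' @rdname accessors
setMethod("hexAllele", "KaspAssay", function(x) x@alleleHex)
#' @rdname accessors
setMethod("famPrimer", "KaspAssay", function(x) x@primerFam)
#' @rdname accessors
setMethod("hexPrimer", "KaspAssay", function(x) x@primerHex)
#' @rdname accessors
setMethod("commonPrimer", "KaspAssay", function(x) x@primerCommon)
#' @rdname accessors
setMethod("famBody", "KaspAssay",
          function(x) substring(x@primerFam, nchar(.FAM_TAIL) + 1L))
#' @rdname accessors
setMethod("hexBody", "KaspAssay",
          function(x) substring(x@primerHex, nchar(.HEX_TAIL) + 1L))
#' @rdname accessors
setMethod("plateId", "RawPlate", function(x) x@plateId)
#' @rdname accessors
setMethod("wells", "RawPlate", function(x) x@wells)
#' @rdname accessors
setMethod("designedAssay", "DesignedAssay", function(x) x@assay)
#' @rdname accessors
setMethod("productLength", "DesignedAssay", function(x) x@productLenFam)
#' @rdname accessors
setMethod("designScore", "DesignedAssay", function(x) x@designScore)
#' @rdname accessors
setMethod("panelAssays", "MarkerPanel", function(x) x@assays)
#' @rdname accessors
setMethod("restorerDye", "MarkerPanel", function(x) x@restorerDye)
#' @rdname accessors
setMethod("plantCategory", "PlantClassification", function(x) x@category)
#' @rdname accessors
setMethod("recombinationIntervals", "PlantClassification",
          function(x) x@recombinationIntervals)

setMethod("show", "KaspAssay", function(object) {
  cat("KaspAssay '", object@name, "' (", object@snpId, ")\n", sep = "")
  cat("  alleles: FAM=", object@alleleFam, " HEX=", object@alleleHex,
      "\n", sep = "")
  cat("  FAM primer:    ", object@primerFam, "\n", sep = "")
  cat("  HEX primer:    ", object@primerHex, "\n", sep = "")
  cat("  common primer: ", object@primerCommon, "\n", sep = "")
  if (!is.na(object@position)) {
    cat("  position: chr", object@chromosome, ":", object@position,
        "\n", sep = "")
  }
})

setMethod("show", "RawPlate", function(object) {
  w <- object@wells
  cat("RawPlate '", object@plateId, "' (assay ", object@assayName, ")\n",
      sep = "")
  cat("  ", nrow(w), " wells: ", sum(!w$is_ntc), " sample, ",
      sum(w$is_ntc), " NTC; ", length(unique(w$sample_id[!w$is_ntc])),
      " samples\n", sep = "")
})

setMethod("show", "CallerConfig", function(object) {
  cat("CallerConfig: no-amp < ", object@noAmpThreshold, "%, boundaries ",
      object@boundaryLow, "/", object@boundaryHigh, " deg, ",
      object@replicatePolicy, " consensus (min ",
      object@minAmplifiedReplicates, " amplified)\n", sep = "")
})

setMethod("show", "DesignedAssay", function(object) {
  cat("DesignedAssay (strand ", object@strand, ", product ",
      object@productLenFam, " bp, score ",
      format(object@designScore, digits = 3), ")\n", sep = "")
  show(object@assay)
})

setMethod("show", "MarkerPanel", function(object) {
  cat("MarkerPanel of", length(object@assays), "markers:",
      paste(names(object@assays), collapse = " > "), "\n")
  cat("  restorer allele on:",
      paste(object@restorerDye, collapse = ", "), "\n")
})

setMethod("show", "PurityResult", function(object) {
  cat("PurityResult '", object@poolId, "': ", sep = "")
  if (is.na(object@meanAngle)) {
    cat("no amplified replicate\n")
    return(invisible(NULL))
  }
  cat(sprintf("angle %.2f deg, z = %.2f (%s), f-hat = %.3f, nearest %s\n",
              object@meanAngle, object@zScore,
              if (object@flagged) "FLAGGED" else "not flagged",
              object@estimatedFraction, object@nearestReference))
})

setMethod("show", "PlantClassification", function(object) {
  cat("Plant '", object@plantId, "': ", object@category, " (",
      object@informativeMarkers, " informative markers)\n", sep = "")
  if (length(object@recombinationIntervals)) {
    cat("  recombination interval(s):",
        paste(object@recombinationIntervals, collapse = ", "), "\n")
  }
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: seed ", object@seed, ", gains FAM/HEX ", object@gainFam,
      "/", object@gainHex, ", baseline ", object@baseline, ", CV ",
      object@noiseCv, " (", object@tissue, "), ", object@replicates,
      " replicates\n", sep = "")
})
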