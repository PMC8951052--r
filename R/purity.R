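#' Expected normalized coordinates of a pooled sample
#'
#' Linear allele-dosage mixing model for pooled DNA assayed with a KASP
#' marker whose HEX allele belongs to the main (pure) line and whose FAM
#' allele belongs to the contaminant: the FAM signal is proportional to
#' the contaminant allele dosage (`fraction`), the HEX signal to
#' `1 - fraction`, each scaled by its dye gain and mapped to the percent
#' scale on which a dosage of one at the larger gain reads 100. Endpoint
#' saturation is deliberately not modelled; departures from linearity can
#' be absorbed into the gains via [gainsFromHybrid()].
#'
#' @param fraction Contaminant proportion(s) in `[0, 1]`.
#' @param gains Named numeric vector `c(fam = , hex = )` of positive
#'   per-dye signal gains (default equal).
#' @return data.frame with columns `fraction`, `pct_fam`, `pct_hex`,
#'   `angle_deg`.
#' @examples
#' expectedPoolCoordinates(c(0, 0.5, 1))
#' @export
expectedPoolCoordinates <- function(fraction, gains = c(fam = 1, hex = 1)) {
  stopifnot(all(fraction >= 0 & fraction <= 1), all(gains > 0))
  gf <- gains[["fam"]]; gh <- gains[["hex"]]
  scale <- max(gf, gh)
  pf <- 100 * fraction * gf / scale
  ph <- 100 * (1 - fraction) * gh / scale
  data.frame(fraction = fraction, pct_fam = pf, pct_hex = ph,
             angle_deg = atan2(pf, ph) * 180 / pi)
}

#' Calibrate dye gains from the hybrid reference angle
#'
#' At a true allele fraction of one half the FAM/HEX signal ratio equals
#' the gain ratio, so the mean angle of the F1-hybrid (or 50 percent pool)
#' reference identifies the relative gains: `g_fam / g_hex = tan(angle)`.
#'
#' @param hybridAngleDeg Mean hybrid reference angle in degrees.
#' @return Named gain vector `c(fam = , hex = )` normalized to max 1.
#' @examples
#' gainsFromHybrid(45) # equal gains
#' @export
gainsFromHybrid <- function(hybridAngleDeg) {
  stopifnot(is.finite(hybridAngleDeg), hybridAngleDeg > 0,
            hybridAngleDeg < 90)
  r <- tan(hybridAngleDeg * pi / 180)
  g <- c(fam = r, hex = 1)
  g / max(g)
}

#' Estimate the contamination fraction of a pool
#'
#' Inverts the linear mixing model on each amplified pool replicate: the
#' gain-corrected FAM share
#' `f = (pct_fam / g_fam) / (pct_fam / g_fam + pct_hex / g_hex)`
#' estimates the contaminant allele dosage, and replicates are averaged.
#' Replicates in the no-amplification zone (both channels below
#' `noAmpThreshold`) are excluded; if none remains, no estimate is
#' produced. Estimates are clipped to `[0, 1]`.
#'
#' @param poolWells data.frame of normalized pool replicates (columns
#'   `pct_fam`, `pct_hex`), e.g. a subset of [normalizePlate()] output.
#' @param gains Named per-dye gain vector (see
#'   [expectedPoolCoordinates()]).
#' @param noAmpThreshold Percent threshold of the no-amplification zone.
#' @return List with `estimate` (mean fraction, `NA` if no amplified
#'   replicate), `sd` (replicate standard deviation), `nAmplified`, and
#'   `perReplicate` (the individual estimates).
#' @examples
#' w <- expectedPoolCoordinates(0.1)
#' estimateContamination(w)$estimate
#' @export
estimateContamination <- function(poolWells, gains = c(fam = 1, hex = 1),
                                  noAmpThreshold = 25) {
  stopifnot(all(gains > 0), nrow(poolWells) >= 1L)
  pf <- poolWells$pct_fam; ph <- poolWells$pct_hex
  amp <- !(pf < noAmpThreshold & ph < noAmpThreshold)
  if (!any(amp)) {
    return(list(estimate = NA_real_, sd = NA_real_, nAmplified = 0L,
                perReplicate = numeric()))
  }
  xf <- pf[amp] / gains[["fam"]]
  xh <- ph[amp] / gains[["hex"]]
  f <- pmin(pmax(xf / (xf + xh), 0), 1)
  list(estimate = mean(f),
       sd = if (length(f) > 1L) stats::sd(f) else NA_real_,
       nAmplified = sum(amp), perReplicate = f)
}

#' Test a pooled sample for contamination
#'
#' Compares the mean angle of the amplified pool replicates with the pure
#' main-line reference: the z-score is the angular deviation in units of
#' the reference replicate standard deviation, and the pool is flagged
#' when it exceeds `multiplier`. Because the reference standard deviation
#' is estimated from few replicates (four on a typical plate) it can be
#' arbitrarily small by chance; it is therefore bounded below by
#' `sdFloor` degrees, and a degenerate (zero-spread) reference warns and
#' uses the floor. The nearest reference cluster (`main`, `hybrid`,
#' `contaminant`) is reported by smallest angular distance among the three
#' reference means, and the contamination fraction is estimated via
#' [estimateContamination()].
#'
#' @param poolWells data.frame of normalized pool replicates (columns
#'   `pct_fam`, `pct_hex`).
#' @param refs A [ReferenceSet-class].
#' @param gains Named per-dye gain vector.
#' @param multiplier Detection multiplier on the z-score (default 3).
#' @param sdFloor Lower bound on the reference angle standard deviation in
#'   degrees (default 1.5).
#' @param noAmpThreshold Percent threshold of the no-amplification zone.
#' @param poolId Identifier for the pool.
#' @return A [PurityResult-class].
#' @examples
#' refs <- referenceSet(c(0.2, 0.4, 0.1, 0.3), c(89, 90, 89.5, 89.8),
#'                      c(45, 44, 46, 45))
#' pool <- expectedPoolCoordinates(0.10)
#' detectContamination(pool[rep(1, 4), ], refs)
#' @export
detectContamination <- function(poolWells, refs, gains = c(fam = 1, hex = 1),
                                multiplier = 3, sdFloor = 1.5,
                                noAmpThreshold = 25, poolId = "pool") {
  stopifnot(is(refs, "ReferenceSet"), multiplier > 0, sdFloor > 0)
  est <- estimateContamination(poolWells, gains, noAmpThreshold)
  if (est$nAmplified == 0L) {
    return(new("PurityResult", poolId = as.character(poolId),
               meanAngle = NA_real_, zScore = NA_real_, flagged = FALSE,
               estimatedFraction = NA_real_, estimateSd = NA_real_,
               nearestReference = NA_character_, nAmplified = 0L))
  }
  pf <- poolWells$pct_fam; ph <- poolWells$pct_hex
  amp <- !(pf < noAmpThreshold & ph < noAmpThreshold)
  angles <- atan2(pf[amp], ph[amp]) * 180 / pi
  meanAngle <- mean(angles)

  refMean <- mean(refs@mainAngles)
  refSd <- stats::sd(refs@mainAngles)
  if (refSd == 0) {
    warning("pure main-line reference has zero angle spread; ",
            "using the configured floor of ", sdFloor, " degrees",
            call. = FALSE)
  }
  refSd <- max(refSd, sdFloor)
  z <- (meanAngle - refMean) / refSd

  refAngles <- c(main = refMean,
                 hybrid = mean(refs@hybridAngles),
                 contaminant = mean(refs@contaminantAngles))
  nearest <- names(which.min(abs(refAngles - meanAngle)))

  new("PurityResult", poolId = as.character(poolId), meanAngle = meanAngle,
      zScore = z, flagged = z > multiplier,
      estimatedFraction = est$estimate,
      estimateSd = if (is.null(est$sd)) NA_real_ else est$sd,
      nearestReference = nearest, nAmplified = as.integer(est$nAmplified))
}

#' Tabulate purity results
#'
#' @param results List of [PurityResult-class] objects.
#' @return data.frame with one row per pool, sorted by pool id, with
#'   columns `pool_id`, `mean_angle`, `z_score`, `flagged`,
#'   `estimated_fraction`, `estimate_sd`, `nearest_reference`,
#'   `n_amplified`. Empty input yields a zero-row table with the same
#'   columns.
#' @export
purityReport <- function(results) {
  if (!length(results)) {
    return(data.frame(pool_id = character(), mean_angle = numeric(),
                      z_score = numeric(), flagged = logical(),
                      estimated_fraction = numeric(),
                      estimate_sd = numeric(),
                      nearest_reference = character(),
                      n_amplified = integer(), stringsAsFactors = FALSE))
  }
  stopifnot(all(vapply(results, is, logical(1), "PurityResult")))
  out <- do.call(rbind, lapply(results, function(r) {
    data.frame(pool_id = r@poolId, mean_angle = r@meanAngle,
               z_score = r@zScore, flagged = r@flagged,
               estimated_fraction = r@estimatedFraction,
               estimate_sd = r@estimateSd,
               nearest_reference = r@nearestReference,
               n_amplified = r@nAmplified, stringsAsFactors = FALSE)
  }))
  out <- out[order(out$pool_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract a ReferenceSet from normalized wells
#'
#' Convenience helper: pulls the replicate angles of the three reference
#' samples from a normalized-well table (e.g. a [simulatePoolSeries()]
#' plate after [normalizePlate()]).
#'
#' @param normWells Normalized-well data.frame (columns `sample_id`,
#'   `angle_deg`).
#' @param mainId,contaminantId,hybridId Sample ids of the pure main line,
#'   pure contaminant line and F1 hybrid references.
#' @return A [ReferenceSet-class].
#' @export
referencesFromWells <- function(normWells, mainId = "ref_main",
                                contaminantId = "ref_contaminant",
                                hybridId = "ref_hybrid") {
  pick <- function(id) {
    a <- normWells$angle_deg[normWells$sample_id == id]
    a[is.finite(a)]
  }
  referenceSet(pick(mainId), pick(contaminantId), pick(hybridId))
}
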