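#' Normalize a plate to percent fluorescence
#'
#' Transforms each raw dye reading `X` into percent fluorescence
#' `%F = (X - minF) / (maxF - minF) * 100`, where `minF` and `maxF` are the
#' lowest and highest raw values of that dye across *all* wells of the
#' plate (no-template controls included -- they are the natural minimum of
#' the plate, and excluding them would inflate the percent fluorescence of
#' weak wells). The transformation is applied separately per dye, so every
#' quantity downstream of it is invariant under positive affine rescaling
#' of a single dye channel.
#'
#' A polar angle `atan2(%FAM, %HEX)` in degrees from the HEX axis is
#' attached to every well (`NA` when both coordinates are exactly zero);
#' whether a well counts as amplified is decided later by the caller
#' configuration.
#'
#' @param plate A [RawPlate-class].
#' @return A list with elements `normalization` (data.frame with one row
#'   per dye: `dye`, `min`, `max`) and `wells` (data.frame with
#'   `well_id`, `sample_id`, `replicate_index`, `is_ntc`, `pct_fam`,
#'   `pct_hex`, `angle_deg`).
#' @examples
#' sim <- simulatePlate(data.frame(
#'   sample_id = c("A", "B", "C"),
#'   class = c("hom_fam", "het", "hom_hex")), simConfig(seed = 1))
#' norm <- normalizePlate(sim$plate)
#' head(norm$wells)
#' @export
normalizePlate <- function(plate) {
  stopifnot(is(plate, "RawPlate"))
  w <- plate@wells
  norm <- data.frame(dye = c("fam", "hex"), min = NA_real_, max = NA_real_)
  pct <- list()
  for (i in seq_len(2L)) {
    dye <- norm$dye[i]
    x <- w[[dye]]
    mn <- min(x); mx <- max(x)
    if (mx <= mn) {
      stop("degenerate plate: ", toupper(dye),
           " channel is constant (max = min = ", mn, ")", call. = FALSE)
    }
    norm$min[i] <- mn; norm$max[i] <- mx
    pct[[dye]] <- (x - mn) / (mx - mn) * 100
  }
  ang <- atan2(pct$fam, pct$hex) * 180 / pi
  ang[pct$fam == 0 & pct$hex == 0] <- NA_real_
  out <- data.frame(
    well_id = w$well_id, sample_id = w$sample_id,
    replicate_index = w$replicate_index, is_ntc = w$is_ntc,
    pct_fam = pct$fam, pct_hex = pct$hex, angle_deg = ang,
    stringsAsFactors = FALSE)
  list(normalization = norm, wells = out)
}

#' Render a genotype class as alleles of an assay
#'
#' Maps a genotype class to its allele notation through the dye-to-allele
#' map of the assay: homozygous calls repeat the corresponding dye's
#' allele, heterozygous calls are written FAM allele first, `no_amp`
#' renders as `"-"` and `ambiguous` as `"?"`.
#'
#' @param class Character vector of genotype classes.
#' @param assay A [KaspAssay-class].
#' @return Character vector of allele notations.
#' @examples
#' a <- table1Assays()[["621.5"]]
#' genotypeLabel(c("hom_hex", "het", "hom_fam", "no_amp"), a)
#' @export
genotypeLabel <- function(class, assay) {
  stopifnot(is(assay, "KaspAssay"))
  vapply(class, function(cl) {
    switch(cl,
      hom_fam = paste0(assay@alleleFam, assay@alleleFam),
      hom_hex = paste0(assay@alleleHex, assay@alleleHex),
      het = paste0(assay@alleleFam, assay@alleleHex),
      no_amp = "-",
      ambiguous = "?",
      stop("unknown genotype class '", cl, "'", call. = FALSE))
  }, character(1), USE.NAMES = FALSE)
}

#' Parse an allele-notation genotype into a class
#'
#' Inverse of [genotypeLabel()] for printed genotype strings: `"-"` maps to
#' `no_amp`, a doubled FAM (HEX) allele to `hom_fam` (`hom_hex`), and any
#' two differing bases to `het`.
#'
#' @param genotype Character vector of genotype strings.
#' @param assay A [KaspAssay-class].
#' @return Character vector of genotype classes.
#' @export
genotypeClass <- function(genotype, assay) {
  stopifnot(is(assay, "KaspAssay"))
  vapply(genotype, function(g) {
    g <- toupper(trimws(g))
    if (g %in% c("-", "")) return("no_amp")
    if (g == paste0(assay@alleleFam, assay@alleleFam)) return("hom_fam")
    if (g == paste0(assay@alleleHex, assay@alleleHex)) return("hom_hex")
    if (nchar(g) == 2L && substr(g, 1, 1) != substr(g, 2, 2)) return("het")
    stop("cannot interpret genotype '", g, "' for assay ", assay@name,
         call. = FALSE)
  }, character(1), USE.NAMES = FALSE)
}

#' Classify normalized wells into genotype classes
#'
#' Applies the two-stage rule of the endpoint caller. A well whose percent
#' fluorescence is below the no-amplification threshold in *both* dye
#' channels is `no_amp` (a well that is high in one dye and low in the
#' other is a homozygote, not a failure). Otherwise the well's polar angle
#' from the HEX axis decides the class: below `boundaryLow` degrees
#' `hom_hex`, between the boundaries (inclusive) `het`, above
#' `boundaryHigh` `hom_fam`. The class regions plus the no-amplification
#' zone partition the normalized square, so every well receives exactly one
#' class.
#'
#' @param normWells data.frame of normalized wells from [normalizePlate()]
#'   (columns `pct_fam`, `pct_hex`; other columns are carried through).
#' @param cfg A [CallerConfig-class].
#' @param assay Optional [KaspAssay-class]; when supplied, a `genotype`
#'   column with allele notation is added.
#' @return The input data.frame with columns `angle_deg`, `class` and
#'   (with an assay) `genotype`.
#' @examples
#' w <- data.frame(pct_fam = c(10, 50, 80), pct_hex = c(12, 50, 10))
#' classifyWells(w, callerConfig())$class
#' @export
classifyWells <- function(normWells, cfg = callerConfig(), assay = NULL) {
  stopifnot(is(cfg, "CallerConfig"))
  pf <- normWells$pct_fam; ph <- normWells$pct_hex
  ang <- atan2(pf, ph) * 180 / pi
  no_amp <- pf < cfg@noAmpThreshold & ph < cfg@noAmpThreshold
  cls <- ifelse(no_amp, "no_amp",
         ifelse(ang < cfg@boundaryLow, "hom_hex",
         ifelse(ang > cfg@boundaryHigh, "hom_fam", "het")))
  ang[no_amp] <- NA_real_
  normWells$angle_deg <- ang
  normWells$class <- cls
  if (!is.null(assay)) normWells$genotype <- genotypeLabel(cls, assay)
  normWells
}

#' Consensus genotype across replicates
#'
#' Combines replicate genotype calls of one sample. `no_amp` replicates are
#' excluded first; if fewer than `minAmplifiedReplicates` remain, the
#' consensus is `no_amp`. Under the default `unanimity` policy all
#' remaining replicates must agree, otherwise the consensus is
#' `ambiguous`; under `majority` a strict majority wins and ties are
#' `ambiguous`. Ambiguity never silently degrades to a genotype class.
#' The consensus angle is the mean angle of the amplified replicates.
#'
#' @param classes Character vector of replicate genotype classes.
#' @param angles Numeric vector of replicate angles (degrees), same length.
#' @param cfg A [CallerConfig-class].
#' @return List with `class`, `angle`, `nTotal`, `nAmplified`.
#' @examples
#' consensusCall(c("het", "het", "no_amp", "het"), c(44, 46, NA, 45))
#' @export
consensusCall <- function(classes, angles = rep(NA_real_, length(classes)),
                          cfg = callerConfig()) {
  if (length(classes) < 1L) {
    stop("consensusCall needs at least one replicate", call. = FALSE)
  }
  stopifnot(length(angles) == length(classes), is(cfg, "CallerConfig"))
  amp <- classes != "no_amp"
  meanAngle <- if (any(amp)) mean(angles[amp], na.rm = TRUE) else NA_real_
  if (is.nan(meanAngle)) meanAngle <- NA_real_
  if (sum(amp) < cfg@minAmplifiedReplicates) {
    return(list(class = "no_amp", angle = NA_real_,
                nTotal = length(classes), nAmplified = sum(amp)))
  }
  kept <- classes[amp]
  tab <- table(kept)
  cls <- if (cfg@replicatePolicy == "unanimity") {
    if (length(tab) == 1L) names(tab) else "ambiguous"
  } else {
    top <- tab[tab == max(tab)]
    if (length(top) == 1L && max(tab) > sum(tab) / 2) names(top) else "ambiguous"
  }
  list(class = cls, angle = meanAngle,
       nTotal = length(classes), nAmplified = sum(amp))
}

#' Call all samples on a plate
#'
#' Normalizes the plate, classifies every well and forms one consensus call
#' per sample. No-template control wells are checked rather than called:
#' each NTC is expected to fall into the no-amplification zone, and any
#' amplified NTC attaches a master-mix contamination warning to the
#' returned table (attribute `"warnings"`); the result is never silently
#' degraded.
#'
#' @param plate A [RawPlate-class].
#' @param assay A [KaspAssay-class] (used for allele notation); optional.
#' @param cfg A [CallerConfig-class].
#' @return A call-table data.frame with one row per sample and columns
#'   `plate_id`, `sample_id`, `assay`, `class`, `genotype`, `angle_deg`,
#'   `n_total`, `n_amplified`, `replicate_classes`, plus a `"warnings"`
#'   attribute (character vector, possibly empty).
#' @examples
#' sim <- simulatePlate(data.frame(
#'   sample_id = c("A", "B", "C"),
#'   class = c("hom_fam", "het", "hom_hex")), simConfig(seed = 7))
#' calls <- callPlate(sim$plate, table1Assays()[["621.5"]])
#' calls[, c("sample_id", "class", "genotype")]
#' @export
callPlate <- function(plate, assay = NULL, cfg = callerConfig()) {
  stopifnot(is(plate, "RawPlate"))
  norm <- normalizePlate(plate)
  wl <- classifyWells(norm$wells, cfg, assay)
  aname <- if (!is.null(assay)) assay@name else plate@assayName

  warnings <- character()
  ntc <- wl[wl$is_ntc, , drop = FALSE]
  bad <- ntc[ntc$class != "no_amp", , drop = FALSE]
  if (nrow(bad)) {
    warnings <- sprintf(
      "NTC well %s amplified (class %s): possible master-mix contamination",
      bad$well_id, bad$class)
    for (msg in warnings) warning(msg, call. = FALSE)
  }

  smp <- wl[!wl$is_ntc, , drop = FALSE]
  ids <- unique(smp$sample_id)
  rows <- lapply(ids, function(id) {
    sub <- smp[smp$sample_id == id, , drop = FALSE]
    sub <- sub[order(sub$replicate_index), , drop = FALSE]
    cons <- consensusCall(sub$class, sub$angle_deg, cfg)
    data.frame(
      plate_id = plate@plateId, sample_id = id, assay = aname,
      class = cons$class,
      genotype = if (!is.null(assay)) genotypeLabel(cons$class, assay)
                 else NA_character_,
      angle_deg = cons$angle, n_total = cons$nTotal,
      n_amplified = cons$nAmplified,
      replicate_classes = paste(sub$class, collapse = ";"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$plate_id, out$sample_id, out$assay), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "warnings") <- warnings
  out
}
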