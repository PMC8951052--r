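## Mean-one multiplicative lognormal noise with coefficient of variation cv.
.lognorm <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sigma^2 / 2, sdlog = sigma)
}

## Plate well ids A1, A2, ..., filled row-major over 12 columns; rows
## continue AA, AB, ... beyond Z for oversized virtual plates.
.well_ids <- function(n) {
  rows <- ceiling(n / 12L)
  labels <- c(LETTERS, as.vector(t(outer(LETTERS, LETTERS, paste0))))
  ids <- as.vector(t(outer(labels[seq_len(rows)], 1:12, paste0)))
  ids[seq_len(n)]
}

## FAM-allele dosage per genotype class (HEX dosage is the complement,
## except for non-amplifying wells where both are zero).
.dosages <- function(class) {
  df <- switch(class, hom_fam = 1, het = 0.5, hom_hex = 0, no_amp = 0,
               stop("unknown genotype class '", class, "'", call. = FALSE))
  dh <- switch(class, hom_fam = 0, het = 0.5, hom_hex = 1, no_amp = 0)
  c(fam = df, hex = dh)
}

.simulate_wells <- function(samples, cfg, nNtc) {
  nw <- nrow(samples) + nNtc
  ids <- .well_ids(nw)
  sim_channel <- function(gain, dosage) {
    gain * dosage * .lognorm(length(dosage), cfg@noiseCv) +
      cfg@baseline * .lognorm(length(dosage), cfg@noiseCv)
  }
  fam <- sim_channel(cfg@gainFam, samples$dosage_fam)
  hex <- sim_channel(cfg@gainHex, samples$dosage_hex)
  if (nNtc > 0L) {
    fam <- c(fam, cfg@baseline * .lognorm(nNtc, cfg@noiseCv))
    hex <- c(hex, cfg@baseline * .lognorm(nNtc, cfg@noiseCv))
  }
  data.frame(
    well_id = ids,
    sample_id = c(samples$sample_id, if (nNtc > 0L) paste0("NTC", seq_len(nNtc))),
    replicate_index = c(samples$replicate, if (nNtc > 0L) seq_len(nNtc)),
    is_ntc = c(rep(FALSE, nrow(samples)), rep(TRUE, nNtc)),
    fam = fam, hex = hex, rox = NA_real_,
    stringsAsFactors = FALSE)
}

#' Simulate a genotyping plate
#'
#' Generates a seeded synthetic endpoint-fluorescence plate for a set of
#' samples with known genotype classes, following the signal model of
#' [SimConfig-class]: per well and dye,
#' `gain x dosage x lognormal(CV) + baseline x lognormal(CV)`, with FAM
#' allele dosages 0 / 0.5 / 1 for `hom_hex` / `het` / `hom_fam`, both
#' dosages zero for `no_amp`, and baseline-only no-template control wells.
#' With zero noise the three genotype clusters normalize to angles of
#' exactly 0, 45 and 90 degrees.
#'
#' @param genotypes data.frame with columns `sample_id` and `class`
#'   (`hom_fam`, `het`, `hom_hex`, `no_amp`), one row per sample.
#' @param cfg A [SimConfig-class]; `cfg@seed` makes the plate
#'   reproducible bit for bit.
#' @param assayName Assay name recorded on the plate.
#' @param nNtc Number of no-template control wells (default 2).
#' @param plateId Plate identifier.
#' @param replicates Wells per sample; defaults to `cfg@replicates`.
#' @return List with `plate` (a [RawPlate-class]) and `truth` (the input
#'   genotype table).
#' @examples
#' sim <- simulatePlate(data.frame(
#'   sample_id = c("R", "H", "B"),
#'   class = c("hom_hex", "het", "hom_fam")), simConfig(seed = 11))
#' sim$plate
#' @export
simulatePlate <- function(genotypes, cfg = simConfig(), assayName = "sim",
                          nNtc = 2L, plateId = "sim_plate",
                          replicates = NULL) {
  stopifnot(is(cfg, "SimConfig"), nrow(genotypes) >= 1L,
            all(c("sample_id", "class") %in% names(genotypes)))
  if (is.null(replicates)) replicates <- cfg@replicates
  set.seed(cfg@seed)
  samples <- do.call(rbind, lapply(seq_len(nrow(genotypes)), function(i) {
    d <- .dosages(genotypes$class[i])
    data.frame(sample_id = genotypes$sample_id[i],
               replicate = seq_len(replicates),
               dosage_fam = d[["fam"]], dosage_hex = d[["hex"]],
               stringsAsFactors = FALSE)
  }))
  wellsDf <- .simulate_wells(samples, cfg, nNtc)
  list(plate = rawPlate(plateId, wellsDf, assayName = assayName),
       truth = genotypes)
}

#' Simulate a pooled contamination series
#'
#' Generates a purity-testing plate: one pooled sample per contamination
#' fraction (FAM-allele dosage equal to the fraction, emulating a pool of
#' a HEX-allele main line contaminated by a FAM-allele line), together
#' with the three reference groups routinely included on such plates --
#' the pure main line (dosage 0), the pure contaminant line (dosage 1)
#' and the F1 hybrid (dosage 0.5) -- each with `cfg@replicates` wells,
#' plus no-template controls. An empty fraction list yields a
#' references-only plate.
#'
#' @param fractions Numeric vector of contaminant fractions in `[0, 1]`.
#' @param cfg A [SimConfig-class].
#' @param assayName Assay name recorded on the plate.
#' @param nNtc Number of no-template control wells.
#' @param plateId Plate identifier.
#' @return List with `plate` (a [RawPlate-class]) and `truth` (data.frame
#'   `sample_id`, `role`, `fraction`).
#' @examples
#' sim <- simulatePoolSeries(c(0.01, 0.03, 0.05, 0.10, 0.50),
#'                           simConfig(seed = 5))
#' sim$truth
#' @export
simulatePoolSeries <- function(fractions, cfg = simConfig(),
                               assayName = "621.5", nNtc = 2L,
                               plateId = "pool_series") {
  stopifnot(is(cfg, "SimConfig"),
            all(fractions >= 0 & fractions <= 1))
  set.seed(cfg@seed)
  groups <- data.frame(
    sample_id = c(if (length(fractions))
                    sprintf("pool_%g", 100 * fractions),
                  "ref_main", "ref_hybrid", "ref_contaminant"),
    role = c(rep("pool", length(fractions)),
             rep("reference", 3L)),
    fraction = c(fractions, 0, 0.5, 1),
    stringsAsFactors = FALSE)
  samples <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    data.frame(sample_id = groups$sample_id[i],
               replicate = seq_len(cfg@replicates),
               dosage_fam = groups$fraction[i],
               dosage_hex = 1 - groups$fraction[i],
               stringsAsFactors = FALSE)
  }))
  wellsDf <- .simulate_wells(samples, cfg, nNtc)
  list(plate = rawPlate(plateId, wellsDf, assayName = assayName),
       truth = groups)
}

#' Simulate a multi-marker mutant screen
#'
#' Generates one single-marker plate per panel marker for a set of
#' phenotype-selected plants with known per-marker genotype classes (by
#' default the built-in mutant-screen truth of [emsScreenTruth()]). Plate
#' seeds are derived deterministically from `cfg@seed`, so a seeded rerun
#' reproduces every plate.
#'
#' Each plate also carries the three control samples routinely included
#' in single-plant screening -- a maintainer line (`ctrl_maintainer`,
#' homozygous FAM allele), a restorer line (`ctrl_restorer`, homozygous
#' HEX allele) and the untreated F1 hybrid (`ctrl_hybrid`). Besides their
#' role as visual anchors, the controls guarantee that both dye channels
#' span their full range, which the per-plate min-max normalization
#' relies on when the screened plants happen to lack a genotype class.
#'
#' @param truth Wide truth table as returned by [emsScreenTruth()]:
#'   columns `plant_id`, `phenotype`, one genotype-class column per panel
#'   marker, and `true_category`.
#' @param panel A [MarkerPanel-class].
#' @param cfg A [SimConfig-class].
#' @param nNtc No-template control wells per plate.
#' @return List with `plates` (named list of [RawPlate-class], one per
#'   marker) and `truth` (the truth table, covering the screened plants;
#'   control samples are identifiable by their `ctrl_` prefix).
#' @examples
#' screen <- simulateEmsScreen(cfg = simConfig(seed = 2))
#' names(screen$plates)
#' @export
simulateEmsScreen <- function(truth = emsScreenTruth(), panel = rf1Panel(),
                              cfg = simConfig(), nNtc = 2L) {
  stopifnot(is(panel, "MarkerPanel"), is(cfg, "SimConfig"))
  markers <- names(panel@assays)
  miss <- setdiff(markers, names(truth))
  if (length(miss)) {
    stop("truth table is missing marker column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  controls <- data.frame(
    sample_id = c("ctrl_maintainer", "ctrl_restorer", "ctrl_hybrid"),
    class = c("hom_fam", "hom_hex", "het"), stringsAsFactors = FALSE)
  plates <- lapply(seq_along(markers), function(i) {
    m <- markers[i]
    cfg_i <- cfg
    cfg_i@seed <- cfg@seed + i - 1L
    genotypes <- rbind(
      data.frame(sample_id = truth$plant_id, class = truth[[m]],
                 stringsAsFactors = FALSE),
      controls)
    simulatePlate(genotypes, cfg_i, assayName = m, nNtc = nNtc,
                  plateId = paste0("ems_", m))$plate
  })
  names(plates) <- markers
  list(plates = plates, truth = truth)
}

## One 30-nt sequence block with GC content between 40 and 60 percent.
.random_block <- function() {
  k <- sample(12:18, 1L)
  block <- c(sample(c("G", "C"), k, replace = TRUE),
             sample(c("A", "T"), 30L - k, replace = TRUE))
  paste(sample(block), collapse = "")
}

.random_flank <- function(n) {
  out <- ""
  while (nchar(out) < n) out <- paste0(out, .random_block())
  substr(out, 1L, n)
}

#' Generate a random designable SNP template
#'
#' Draws a synthetic biallelic SNP template with a central SNP and flanks
#' generated in 30-nt blocks of 40-60 percent GC. The local GC balance
#' emulates the mid-GC genic context that assay designers target in
#' practice; fully unconstrained random sequence is occasionally
#' undesignable under standard melting-temperature windows (as are some
#' real SNP contexts). Uses the current RNG state -- call `set.seed()`
#' first for reproducibility.
#'
#' @param length Total template length in bp (default 300; the SNP sits at
#'   the centre).
#' @param alleles Two distinct bases; by default a random pair.
#' @return A [SnpTemplate-class].
#' @examples
#' set.seed(1)
#' randomSnpTemplate()
#' @export
randomSnpTemplate <- function(length = 300L, alleles = NULL) {
  stopifnot(length >= 100L)
  if (is.null(alleles)) alleles <- sample(c("A", "C", "G", "T"), 2L)
  stopifnot(length(alleles) == 2L, alleles[1] != alleles[2])
  upLen <- (length - 1L) %/% 2L
  snpTemplate(.random_flank(upLen), alleles[1], alleles[2],
              .random_flank(length - 1L - upLen),
              label = "synthetic")
}
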