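#' Classify a single plant from multi-marker KASP calls
#'
#' Maps each marker's consensus genotype class to a zygosity state for the
#' restorer haplotype (`hom_restorer`, `het`, `hom_maintainer`) through
#' the panel's restorer-dye designation -- the mapping, not the dye,
#' decides zygosity -- and classifies the plant. Non-amplified and
#' ambiguous markers are dropped as uninformative; with fewer than
#' `minInformative` informative markers the plant is `unclassified`.
#' Uniform zygosity across the informative markers yields `restorer`,
#' `hybrid` or `maintainer`; mixed zygosity yields `recombinant`, with a
#' recombination interval reported at every adjacent pair of informative
#' markers (in panel order) whose zygosity differs.
#'
#' Phenotype is carried as annotation only; classification uses the
#' genotypes alone.
#'
#' @param calls Named character vector of consensus genotype classes
#'   (`hom_fam`, `het`, `hom_hex`, `no_amp`, `ambiguous`), one per panel
#'   marker, names matching the panel's marker names.
#' @param panel A [MarkerPanel-class].
#' @param plantId Plant identifier.
#' @param minInformative Minimum informative markers for a classification
#'   (default 2, so a plant with one failed marker remains classifiable).
#' @return A [PlantClassification-class].
#' @examples
#' panel <- rf1Panel()
#' # maintainer haplotype at the proximal markers, heterozygous distally:
#' calls <- c("621.5" = "hom_fam", "621.11" = "hom_fam",
#'            "841.38" = "het", "861.19" = "het")
#' classifyPlant(calls, panel, plantId = "Mut10")
#' @export
classifyPlant <- function(calls, panel, plantId = "plant",
                          minInformative = 2L) {
  stopifnot(is(panel, "MarkerPanel"))
  markers <- names(panel@assays)
  miss <- setdiff(markers, names(calls))
  if (length(miss)) {
    stop("calls are missing panel marker(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(calls), markers)
  if (length(extra)) {
    stop("calls contain marker(s) not in the panel: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  calls <- calls[markers]

  zyg <- vapply(markers, function(m) {
    cl <- calls[[m]]
    rd <- panel@restorerDye[[m]]
    switch(cl,
      het = "het",
      hom_fam = if (rd == "fam") "hom_restorer" else "hom_maintainer",
      hom_hex = if (rd == "hex") "hom_restorer" else "hom_maintainer",
      no_amp = NA_character_,
      ambiguous = NA_character_,
      stop("unknown genotype class '", cl, "' at marker ", m,
           call. = FALSE))
  }, character(1))

  informative <- which(!is.na(zyg))
  nInf <- length(informative)
  if (nInf < minInformative) {
    return(new("PlantClassification", plantId = as.character(plantId),
               category = "unclassified", informativeMarkers = as.integer(nInf),
               recombinationIntervals = character(), zygosities = zyg))
  }
  states <- zyg[informative]
  if (length(unique(states)) == 1L) {
    category <- switch(states[[1L]],
                       hom_restorer = "restorer",
                       het = "hybrid",
                       hom_maintainer = "maintainer")
    intervals <- character()
  } else {
    category <- "recombinant"
    sw <- unname(which(states[-length(states)] != states[-1L]))
    intervals <- vapply(sw, function(i) {
      .interval_label(panel,
                      markers[informative[i]], markers[informative[i + 1L]])
    }, character(1))
  }
  new("PlantClassification", plantId = as.character(plantId),
      category = category, informativeMarkers = as.integer(nInf),
      recombinationIntervals = intervals, zygosities = zyg)
}

## Interval label: marker names, with 1-based chromosome coordinates
## appended when the panel provides positions for both endpoints.
.interval_label <- function(panel, left, right) {
  a <- panel@assays[[left]]; b <- panel@assays[[right]]
  lab <- paste0(left, "--", right)
  if (!is.na(a@position) && !is.na(b@position)) {
    lab <- sprintf("%s(chr%s:%d)--%s(chr%s:%d)", left, a@chromosome,
                   a@position, right, b@chromosome, b@position)
  }
  lab
}

#' Screen a set of plants against a marker panel
#'
#' Classifies every plant of a record table and returns one report row per
#' plant: phenotype annotation, per-marker rendered alleles, category,
#' informative marker count, and recombination intervals. Rows are ordered
#' by plant id, so the report is deterministic.
#'
#' @param records data.frame with columns `plant_id`, optionally
#'   `phenotype`, and one column per panel marker holding the consensus
#'   genotype class of that plant at that marker.
#' @param panel A [MarkerPanel-class].
#' @param minInformative Passed to [classifyPlant()].
#' @return data.frame with columns `plant_id`, `phenotype`, one rendered
#'   genotype column per marker, `category`, `informative_markers`,
#'   `intervals`. Empty input yields a zero-row table with the same
#'   columns.
#' @examples
#' screen <- simulateEmsScreen(cfg = simConfig(seed = 3))
#' records <- recordsFromCalls(
#'   do.call(rbind, lapply(names(screen$plates), function(m)
#'     callPlate(screen$plates[[m]], panelAssays(rf1Panel())[[m]]))),
#'   phenotypes = screen$truth[, c("plant_id", "phenotype")])
#' screenReport(records, rf1Panel())
#' @export
screenReport <- function(records, panel, minInformative = 2L) {
  stopifnot(is(panel, "MarkerPanel"))
  markers <- names(panel@assays)
  cols <- c("plant_id", "phenotype", markers, "category",
            "informative_markers", "intervals")
  if (!nrow(records)) {
    out <- as.data.frame(setNames(
      rep(list(character()), length(cols)), cols),
      stringsAsFactors = FALSE)
    out$informative_markers <- integer()
    return(out)
  }
  miss <- setdiff(c("plant_id", markers), names(records))
  if (length(miss)) {
    stop("records are missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"phenotype" %in% names(records)) records$phenotype <- "unknown"
  rows <- lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    calls <- vapply(markers, function(m) as.character(r[[m]]), character(1))
    names(calls) <- markers
    cls <- classifyPlant(calls, panel, plantId = r$plant_id,
                         minInformative = minInformative)
    geno <- vapply(markers, function(m)
      genotypeLabel(calls[[m]], panel@assays[[m]]), character(1))
    row <- data.frame(plant_id = r$plant_id, phenotype = r$phenotype,
                      t(geno), category = cls@category,
                      informative_markers = cls@informativeMarkers,
                      intervals = paste(cls@recombinationIntervals,
                                        collapse = ";"),
                      stringsAsFactors = FALSE, check.names = FALSE)
    row
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$plant_id), cols, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Contaminant rate among screened plants
#'
#' Percentage of maintainer-genotype plants -- contaminants within an
#' expected-hybrid population -- relative to the total number of plants
#' screened. The numerator counts `category == "maintainer"` rows of a
#' screen report (optionally restricted to given phenotypes); the
#' denominator is supplied by the caller (typically the number of
#' germinated plants the phenotypic screen covered).
#'
#' @param report Screen-report data.frame from [screenReport()] (or any
#'   data.frame with `category` and optionally `phenotype` columns).
#' @param denominator Total number of plants screened; must be positive.
#' @param phenotypes Optional character vector restricting the numerator
#'   to plants with these phenotype annotations.
#' @return Percentage, rounded to one decimal.
#' @examples
#' rep <- data.frame(category = c(rep("maintainer", 7), "hybrid",
#'                                "recombinant", "hybrid"))
#' contaminantRate(rep, denominator = 431)
#' @export
contaminantRate <- function(report, denominator, phenotypes = NULL) {
  if (length(denominator) != 1L || !is.finite(denominator) ||
      denominator <= 0) {
    stop("denominator must be a positive number", call. = FALSE)
  }
  sub <- report
  if (!is.null(phenotypes)) {
    if (!"phenotype" %in% names(report)) {
      stop("report has no phenotype column to filter on", call. = FALSE)
    }
    sub <- report[report$phenotype %in% phenotypes, , drop = FALSE]
  }
  round(100 * sum(sub$category == "maintainer") / denominator, 1)
}

#' Assemble plant records from per-marker call tables
#'
#' Pivots a combined call table (rows = sample x assay, as produced by
#' [callPlate()] on one plate per marker) into the wide per-plant record
#' format consumed by [screenReport()].
#'
#' @param calls Call-table data.frame with columns `sample_id`, `assay`
#'   and `class` (rbind the tables of the individual marker plates).
#' @param phenotypes Optional data.frame with columns `plant_id` and
#'   `phenotype`.
#' @return data.frame with `plant_id`, `phenotype` and one class column
#'   per marker.
#' @export
recordsFromCalls <- function(calls, phenotypes = NULL) {
  need <- c("sample_id", "assay", "class")
  miss <- setdiff(need, names(calls))
  if (length(miss)) {
    stop("calls are missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  plants <- sort(unique(calls$sample_id))
  markers <- unique(calls$assay)
  out <- data.frame(plant_id = plants, stringsAsFactors = FALSE)
  for (m in markers) {
    sub <- calls[calls$assay == m, ]
    if (anyDuplicated(sub$sample_id)) {
      stop("multiple rows for one sample at marker ", m, call. = FALSE)
    }
    out[[m]] <- sub$class[match(plants, sub$sample_id)]
  }
  out$phenotype <- "unknown"
  if (!is.null(phenotypes)) {
    m <- match(out$plant_id, phenotypes$plant_id)
    out$phenotype[!is.na(m)] <- phenotypes$phenotype[m[!is.na(m)]]
  }
  out[, c("plant_id", "phenotype", markers)]
}
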