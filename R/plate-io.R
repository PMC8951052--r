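#' Read a plate fluorescence export and its sample sheet
#'
#' Parses a comma-separated endpoint-fluorescence export in either wide
#' form (`well,fam,hex[,rox]`) or long form (`well,dye,value` with dyes
#' `fam`, `hex` and optionally `rox`), joins it with a sample sheet
#' (`well,sample_id,replicate,is_ntc`), and returns a validated
#' [RawPlate-class]. The two export dialects parse to identical plates.
#'
#' Every well present in the export must be mapped by the sample sheet;
#' unmapped wells are an error naming the offending well. Duplicate wells,
#' missing dye rows and negative fluorescence values are rejected.
#'
#' @param file Path to the plate export CSV.
#' @param sheetFile Path to the sample-sheet CSV.
#' @param plateId Plate identifier; defaults to the export file name.
#' @param assayName Optional assay name to attach.
#' @return A [RawPlate-class].
#' @seealso [writePlate()], [normalizePlate()]
#' @export
readPlate <- function(file, sheetFile, plateId = NULL,
                      assayName = NA_character_) {
  if (is.null(plateId)) plateId <- sub("\\.[^.]*$", "", basename(file))
  raw <- utils::read.csv(file, stringsAsFactors = FALSE)
  names(raw) <- tolower(names(raw))
  if (!"well" %in% names(raw)) {
    stop("plate export '", file, "' has no 'well' column", call. = FALSE)
  }
  raw$well <- toupper(trimws(raw$well))

  if (all(c("dye", "value") %in% names(raw))) {
    wide <- .long_to_wide(raw, file)
  } else if (all(c("fam", "hex") %in% names(raw))) {
    if (anyDuplicated(raw$well)) {
      stop("duplicate well(s) in plate export: ",
           paste(unique(raw$well[duplicated(raw$well)]), collapse = ", "),
           call. = FALSE)
    }
    wide <- raw[, intersect(c("well", "fam", "hex", "rox"), names(raw))]
  } else {
    stop("plate export '", file, "' must have columns well,fam,hex ",
         "(wide form) or well,dye,value (long form)", call. = FALSE)
  }
  if (!"rox" %in% names(wide)) wide$rox <- NA_real_
  for (dye in c("fam", "hex")) {
    v <- suppressWarnings(as.numeric(wide[[dye]]))
    if (anyNA(v)) {
      stop("non-numeric or missing ", toupper(dye), " value(s) in '", file,
           "'", call. = FALSE)
    }
    if (any(v < 0)) {
      stop("negative ", toupper(dye), " fluorescence in well(s): ",
           paste(wide$well[v < 0], collapse = ", "), call. = FALSE)
    }
    wide[[dye]] <- v
  }
  wide$rox <- suppressWarnings(as.numeric(wide$rox))

  wide <- wide[.plate_order(wide$well), , drop = FALSE]

  sheet <- .read_sample_sheet(sheetFile)
  unmapped <- setdiff(wide$well, sheet$well)
  if (length(unmapped)) {
    stop("sample sheet '", sheetFile, "' does not map well(s): ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  m <- match(wide$well, sheet$well)
  wellsDf <- data.frame(
    well_id = wide$well,
    sample_id = sheet$sample_id[m],
    replicate_index = sheet$replicate[m],
    is_ntc = sheet$is_ntc[m],
    fam = wide$fam, hex = wide$hex, rox = wide$rox,
    stringsAsFactors = FALSE)
  rawPlate(plateId, wellsDf, assayName = assayName)
}

## Canonical plate order: row letter(s), then column number, so that the
## same data always parses to the same well sequence regardless of the
## export dialect's row order.
.plate_order <- function(well) {
  row <- sub("[0-9]+$", "", well)
  col <- suppressWarnings(as.integer(sub("^[^0-9]+", "", well)))
  if (anyNA(col) || any(!nzchar(row))) {
    stop("well id(s) not in letter+number form: ",
         paste(well[is.na(col) | !nzchar(row)], collapse = ", "),
         call. = FALSE)
  }
  order(row, col)
}

.long_to_wide <- function(raw, file) {
  raw$dye <- tolower(trimws(raw$dye))
  bad <- setdiff(unique(raw$dye), c("fam", "hex", "rox"))
  if (length(bad)) {
    stop("unknown dye(s) in '", file, "': ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(raw[, c("well", "dye")])) {
    d <- raw[duplicated(raw[, c("well", "dye")]), ]
    stop("duplicate well/dye row(s) in plate export: ",
         paste(unique(d$well), collapse = ", "), call. = FALSE)
  }
  wells <- unique(raw$well)
  out <- data.frame(well = wells, stringsAsFactors = FALSE)
  for (dye in c("fam", "hex", "rox")) {
    sub <- raw[raw$dye == dye, ]
    out[[dye]] <- sub$value[match(wells, sub$well)]
  }
  for (dye in c("fam", "hex")) {
    missing <- wells[is.na(out[[dye]])]
    if (length(missing)) {
      stop("well(s) missing a ", toupper(dye), " reading: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  out
}

.read_sample_sheet <- function(sheetFile) {
  sheet <- utils::read.csv(sheetFile, stringsAsFactors = FALSE)
  names(sheet) <- tolower(names(sheet))
  need <- c("well", "sample_id")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) {
    stop("sample sheet '", sheetFile, "' is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  sheet$well <- toupper(trimws(sheet$well))
  if (anyDuplicated(sheet$well)) {
    stop("duplicate well(s) in sample sheet: ",
         paste(unique(sheet$well[duplicated(sheet$well)]), collapse = ", "),
         call. = FALSE)
  }
  if (!"replicate" %in% names(sheet)) sheet$replicate <- 1L
  if (!"is_ntc" %in% names(sheet)) sheet$is_ntc <- FALSE
  sheet$replicate <- as.integer(sheet$replicate)
  sheet$is_ntc <- as.logical(sheet$is_ntc)
  sheet
}

#' Write a RawPlate back to export + sample-sheet CSVs
#'
#' Writes the wide-form fluorescence export and the matching sample sheet,
#' so that `readPlate()` on the two files reproduces the plate.
#'
#' @param plate A [RawPlate-class].
#' @param file Destination for the plate export CSV.
#' @param sheetFile Destination for the sample-sheet CSV.
#' @return Invisibly, `plate`.
#' @export
writePlate <- function(plate, file, sheetFile) {
  stopifnot(is(plate, "RawPlate"))
  w <- plate@wells
  exp <- data.frame(well = w$well_id, fam = w$fam, hex = w$hex, rox = w$rox)
  if (all(is.na(exp$rox))) exp$rox <- NULL
  utils::write.csv(exp, file, row.names = FALSE, quote = FALSE)
  sheet <- data.frame(well = w$well_id, sample_id = w$sample_id,
                      replicate = w$replicate_index, is_ntc = w$is_ntc)
  utils::write.csv(sheet, sheetFile, row.names = FALSE, quote = FALSE)
  invisible(plate)
}

#' Read a KASP assay definition
#'
#' Reads a flat key-value YAML document with keys `name`, `snp_id`
#' (optional), `primer_fam`, `primer_hex`, `primer_common`, and optionally
#' `allele_fam`, `allele_hex`, `chromosome`, `position`, and builds a
#' validated [KaspAssay-class]. Primer sequences are upper-cased; the FRET
#' tails are recognized by prefix match, and a primer that does not start
#' with the expected universal tail, or whose 3' base disagrees with the
#' declared allele, is rejected.
#'
#' Free-text keys such as `primer_mix` are retained as metadata in the
#' returned object's attributes but are not interpreted.
#'
#' @param file Path to the YAML assay definition.
#' @return A [KaspAssay-class].
#' @seealso [writeAssay()], [table1Assays()]
#' @export
readAssay <- function(file) {
  def <- yaml::read_yaml(file)
  need <- c("name", "primer_fam", "primer_hex", "primer_common")
  miss <- setdiff(need, names(def))
  if (length(miss)) {
    stop("assay definition '", file, "' is missing key(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  a <- tryCatch(
    kaspAssay(
      name = def$name,
      snpId = if (!is.null(def$snp_id)) def$snp_id else def$name,
      primerFam = def$primer_fam, primerHex = def$primer_hex,
      primerCommon = def$primer_common,
      alleleFam = def$allele_fam, alleleHex = def$allele_hex,
      chromosome = if (!is.null(def$chromosome)) def$chromosome else NA,
      position = if (!is.null(def$position)) def$position else NA),
    error = function(e) {
      stop("invalid assay definition '", file, "': ", conditionMessage(e),
           call. = FALSE)
    })
  extra <- setdiff(names(def), c(need, "snp_id", "allele_fam", "allele_hex",
                                 "chromosome", "position"))
  if (length(extra)) attr(a, "metadata") <- def[extra]
  a
}

#' Write a KASP assay definition
#'
#' @param assay A [KaspAssay-class].
#' @param file Destination YAML path.
#' @return Invisibly, `assay`.
#' @export
writeAssay <- function(assay, file) {
  stopifnot(is(assay, "KaspAssay"))
  def <- list(name = assay@name, snp_id = assay@snpId,
              allele_fam = assay@alleleFam, allele_hex = assay@alleleHex,
              primer_fam = assay@primerFam, primer_hex = assay@primerHex,
              primer_common = assay@primerCommon)
  if (!is.na(assay@chromosome)) def$chromosome <- assay@chromosome
  if (!is.na(assay@position)) def$position <- assay@position
  yaml::write_yaml(def, file)
  invisible(assay)
}

#' Write a call table
#'
#' Writes a genotype call table (as produced by [callPlate()]) as CSV with
#' a deterministic column order and rows sorted by plate, sample and assay,
#' so that [readCalls()] round-trips the table.
#'
#' @param table Call-table data.frame; must be non-empty.
#' @param file Destination CSV path.
#' @return Invisibly, the sorted table.
#' @export
writeCalls <- function(table, file) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop("nothing to write: the call table is empty", call. = FALSE)
  }
  cols <- c("plate_id", "sample_id", "assay", "class", "genotype",
            "angle_deg", "n_total", "n_amplified", "replicate_classes")
  miss <- setdiff(cols, names(table))
  if (length(miss)) {
    stop("call table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  table <- table[order(table$plate_id, table$sample_id, table$assay),
                 cols, drop = FALSE]
  rownames(table) <- NULL
  ok <- tryCatch({
    utils::write.csv(table, file, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("failed to write call table to '", file, "': ",
         conditionMessage(ok), call. = FALSE)
  }
  invisible(table)
}

#' Read a call table written by [writeCalls()]
#'
#' @param file CSV path.
#' @return Call-table data.frame.
#' @export
readCalls <- function(file) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE,
                         colClasses = c(
                           plate_id = "character", sample_id = "character",
                           assay = "character", class = "character",
                           genotype = "character", angle_deg = "numeric",
                           n_total = "integer", n_amplified = "integer",
                           replicate_classes = "character"))
  tab
}
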