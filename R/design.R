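#' Construct a SnpTemplate
#'
#' @param upstream Plus-strand flank 5' of the SNP (>= 18 nt).
#' @param alleleA,alleleB The two SNP alleles (single bases; the first
#'   listed allele is assigned to FAM by default during design).
#' @param downstream Plus-strand flank 3' of the SNP (>= 40 nt).
#' @param label Free-text label.
#' @return A validated [SnpTemplate-class].
#' @export
snpTemplate <- function(upstream, alleleA, alleleB, downstream, label = "") {
  up <- function(x) toupper(gsub("[[:space:]]", "", x))
  new("SnpTemplate", upstream = up(upstream), alleleA = up(alleleA),
      alleleB = up(alleleB), downstream = up(downstream),
      label = as.character(label))
}

#' Parse a bracketed SNP template
#'
#' Parses the conventional bracket notation `LEFT[X/Y]RIGHT` (e.g.
#' `"ACCAG[G/C]TTA..."`) into a [SnpTemplate-class]. Input is upper-cased;
#' exactly one bracket group with two single-base alleles is required.
#'
#' @param text Template string in bracket notation.
#' @param label Free-text label for the template.
#' @return A validated [SnpTemplate-class].
#' @examples
#' t <- parseSnpTemplate(paste0(
#'   strrep("ACGT", 10), "[G/C]", strrep("TGCA", 15)))
#' t@alleleA
#' @export
parseSnpTemplate <- function(text, label = "") {
  text <- toupper(gsub("[[:space:]]", "", text))
  nOpen <- lengths(regmatches(text, gregexpr("\\[", text)))
  if (nOpen != 1L) {
    stop("template must contain exactly one [X/Y] bracket group, found ",
         nOpen, call. = FALSE)
  }
  m <- regexec("^([ACGT]+)\\[([ACGT])/([ACGT])\\]([ACGT]+)$", text)[[1]]
  if (m[1] == -1L) {
    stop("malformed SNP template: expected 'LEFT[X/Y]RIGHT' with ",
         "single-base ACGT alleles and ACGT flanks", call. = FALSE)
  }
  g <- regmatches(text, list(m))[[1]]
  snpTemplate(g[2], g[3], g[4], g[5], label = label)
}

.snp_pos <- function(t) nchar(t@upstream) # 0-based template index of the SNP

.template_seq <- function(t, allele = t@alleleA) {
  paste0(t@upstream, allele, t@downstream)
}

## Reverse-orientation view of a template: allele-specific primers designed
## on this view sit on the minus strand of the original; alleles are
## complemented.
.flip_template <- function(t) {
  comp <- function(b) chartr("ACGT", "TGCA", b)
  snpTemplate(.revcomp(t@downstream), comp(t@alleleA), comp(t@alleleB),
              .revcomp(t@upstream),
              label = paste0(t@label, " (reverse orientation)"))
}

#' Enumerate allele-specific primer pairs
#'
#' For every admissible primer length, forms the pair of forward primers
#' ending exactly at the SNP: both bodies share the same upstream suffix
#' and differ only in the 3'-terminal base, which equals `alleleA` for the
#' FAM member and `alleleB` for the HEX member (first listed allele to FAM
#' by default). Pairs are kept when both bodies have a melting temperature
#' within `tmTolerance` of `targetTm` and a GC content within the allowed
#' range. Terminal-base discrimination alone is used; no additional
#' destabilizing mismatch is introduced.
#'
#' @param template A [SnpTemplate-class].
#' @param constraints A [DesignConstraints-class].
#' @return data.frame with one row per admissible pair: `length`,
#'   `body_fam`, `body_hex`, `tm_fam`, `tm_hex`, `gc_fam`, `gc_hex`,
#'   `start`, `end` (0-based half-open template coordinates), `strand`.
#'   Zero rows when no pair is admissible (not an error).
#' @export
enumerateAllelePrimers <- function(template, constraints = designConstraints()) {
  stopifnot(is(template, "SnpTemplate"), is(constraints, "DesignConstraints"))
  up <- template@upstream
  u <- nchar(up)
  rows <- list()
  for (L in seq(constraints@primerLenMin, constraints@primerLenMax)) {
    if (u < L - 1L) next
    stem <- substring(up, u - L + 2L, u)
    bodyF <- paste0(stem, template@alleleA)
    bodyH <- paste0(stem, template@alleleB)
    tmF <- meltingTemp(bodyF, constraints@monovalentMM, constraints@oligoNM)
    tmH <- meltingTemp(bodyH, constraints@monovalentMM, constraints@oligoNM)
    gcF <- .gc_percent(bodyF); gcH <- .gc_percent(bodyH)
    if (abs(tmF - constraints@targetTm) > constraints@tmTolerance) next
    if (abs(tmH - constraints@targetTm) > constraints@tmTolerance) next
    if (gcF < constraints@gcMin || gcF > constraints@gcMax) next
    if (gcH < constraints@gcMin || gcH > constraints@gcMax) next
    rows[[length(rows) + 1L]] <- data.frame(
      length = L, body_fam = bodyF, body_hex = bodyH,
      tm_fam = tmF, tm_hex = tmH, gc_fam = gcF, gc_hex = gcH,
      start = u - (L - 1L), end = u + 1L, strand = "+",
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(length = integer(), body_fam = character(),
                      body_hex = character(), tm_fam = numeric(),
                      tm_hex = numeric(), gc_fam = numeric(),
                      gc_hex = numeric(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Select the common (reverse) primer for an allele-specific candidate
#'
#' Searches exhaustively over all reverse-strand windows strictly
#' downstream of the SNP whose amplicon (from the allele-specific primer's
#' 5' template position to the common primer's 5' end, inclusive) is
#' strictly shorter than `maxProductLen`, keeping candidates with melting
#' temperature within tolerance of the target and GC within range, and
#' returns the best: smallest `|Tm - target|`, then shortest product, then
#' shortest primer, then lexicographic order.
#'
#' @param template A [SnpTemplate-class].
#' @param fwd One row of [enumerateAllelePrimers()] output (or any list
#'   with a 0-based `start` element for a primer ending at the SNP).
#' @param constraints A [DesignConstraints-class].
#' @return One-row data.frame: `body`, `tm`, `gc`, `start`, `end`
#'   (0-based half-open, plus strand), `strand = "-"`, `product_len`.
#' @export
selectCommonPrimer <- function(template, fwd,
                               constraints = designConstraints()) {
  stopifnot(is(template, "SnpTemplate"), is(constraints, "DesignConstraints"))
  cands <- .common_candidates(template, constraints)
  .pick_common(cands, as.integer(fwd$start), constraints)
}

## All admissible common-primer windows of a template, irrespective of the
## chosen allele-specific primer (the product-length cap is applied later).
## Window melting temperatures are screened with a vectorized
## nearest-neighbor sum over cumulative step energies, then confirmed with
## meltingTemp() so the reported values are exact.
.common_candidates <- function(template, constraints) {
  p <- .snp_pos(template)
  tpl <- .template_seq(template)
  n <- nchar(tpl)
  if (n - (p + 1L) < constraints@primerLenMin) {
    return(NULL)
  }
  chars <- strsplit(tpl, "")[[1]]
  steps <- paste0(chars[-n], chars[-1L])
  cumDh <- c(0, cumsum(.NN_DH[steps]))
  cumDs <- c(0, cumsum(.NN_DS[steps]))
  cumGc <- c(0L, cumsum(chars %in% c("G", "C")))

  grid <- expand.grid(
    cs = seq.int(p + 1L, n - constraints@primerLenMin),
    len = seq(constraints@primerLenMin, constraints@primerLenMax))
  grid$ce <- grid$cs + grid$len
  grid <- grid[grid$ce <= n, , drop = FALSE]
  if (!nrow(grid)) return(NULL)

  # duplex thermodynamics of the window (identical for either strand)
  dh <- cumDh[grid$ce] - cumDh[grid$cs + 1L]
  ds <- cumDs[grid$ce] - cumDs[grid$cs + 1L]
  endBases <- cbind(chars[grid$cs + 1L], chars[grid$ce])
  nAT <- rowSums(matrix(endBases %in% c("A", "T"), ncol = 2L))
  dh <- dh + nAT * .NN_TERM_AT_DH + (2L - nAT) * .NN_TERM_GC_DH
  ds <- ds + nAT * .NN_TERM_AT_DS + (2L - nAT) * .NN_TERM_GC_DS
  ds <- ds + 0.368 * (grid$len - 1L) * log(constraints@monovalentMM / 1000)
  k <- constraints@oligoNM * 1e-9 / 4
  tmApprox <- 1000 * dh / (ds + .GAS_R * log(k)) - 273.15

  gc <- 100 * (cumGc[grid$ce + 1L] - cumGc[grid$cs]) / grid$len
  keep <- abs(tmApprox - constraints@targetTm) <= constraints@tmTolerance + 1 &
    gc >= constraints@gcMin & gc <= constraints@gcMax
  grid <- grid[keep, , drop = FALSE]
  if (!nrow(grid)) return(NULL)

  rcTpl <- .revcomp(tpl)
  body <- substring(rcTpl, n - grid$ce + 1L, n - grid$cs)
  tm <- vapply(body, meltingTemp, numeric(1),
               monovalentMM = constraints@monovalentMM,
               oligoNM = constraints@oligoNM, USE.NAMES = FALSE)
  ok <- abs(tm - constraints@targetTm) <= constraints@tmTolerance
  if (!any(ok)) return(NULL)
  data.frame(body = body[ok], tm = tm[ok],
             gc = gc[keep][ok],
             start = grid$cs[ok], end = grid$ce[ok],
             stringsAsFactors = FALSE)
}

.pick_common <- function(cands, fwdStart, constraints) {
  if (!is.null(cands)) {
    prodLen <- cands$end - fwdStart
    cands <- cands[prodLen < constraints@maxProductLen, , drop = FALSE]
  }
  if (is.null(cands) || !nrow(cands)) {
    stop("design infeasible: no common primer with Tm within ",
         constraints@tmTolerance, " degrees C of ", constraints@targetTm,
         " and product < ", constraints@maxProductLen,
         " bp fits downstream of the SNP", call. = FALSE)
  }
  best <- NULL
  for (i in seq_len(nrow(cands))) {
    cand <- list(body = cands$body[i], tm = cands$tm[i], gc = cands$gc[i],
                 start = cands$start[i], end = cands$end[i],
                 product_len = cands$end[i] - fwdStart)
    if (is.null(best) || .better_common(cand, best, constraints@targetTm)) {
      best <- cand
    }
  }
  data.frame(body = best$body, tm = best$tm, gc = best$gc,
             start = best$start, end = best$end, strand = "-",
             product_len = best$product_len, stringsAsFactors = FALSE)
}

.better_common <- function(a, b, target) {
  da <- abs(a$tm - target); db <- abs(b$tm - target)
  if (da != db) return(da < db)
  if (a$product_len != b$product_len) return(a$product_len < b$product_len)
  la <- nchar(a$body); lb <- nchar(b$body)
  if (la != lb) return(la < lb)
  a$body < b$body
}

#' Design a complete KASP assay for a SNP template
#'
#' Designs the full primer trio: both allele-specific forward primers
#' (universal FRET tails prepended verbatim to the selected bodies) plus
#' the best common reverse primer, under the given constraints. All
#' admissible allele-pair lengths are scored by the summed absolute
#' deviation of the three primer melting temperatures from the target;
#' the lowest score wins, with ties broken by shorter allele-specific
#' primer and then lexicographic body order, so the design is
#' deterministic for a given template and constraints.
#'
#' When the forward orientation admits no design and `tryReverse` is
#' `TRUE`, the designer repeats the search on the reverse-complemented
#' template (allele-specific primers on the minus strand, common primer
#' upstream); the reported alleles are then the complements of the
#' template alleles and the result is marked `strand = "-"`. Not every
#' flanking context admits a KASP design -- a genuinely infeasible
#' template raises an error naming the failing constraint.
#'
#' @param template A [SnpTemplate-class].
#' @param constraints A [DesignConstraints-class].
#' @param name Marker name for the designed assay (defaults to the
#'   template label or `"design"`).
#' @param tryReverse Also try the reverse orientation when the forward
#'   orientation fails (default `TRUE`).
#' @return A [DesignedAssay-class].
#' @examples
#' set.seed(42)
#' tpl <- randomSnpTemplate()
#' d <- designAssay(tpl)
#' productLength(d) < 150
#' @export
designAssay <- function(template, constraints = designConstraints(),
                        name = NULL, tryReverse = TRUE) {
  stopifnot(is(template, "SnpTemplate"))
  if (is.null(name)) {
    name <- if (nzchar(template@label)) template@label else "design"
  }
  res <- .design_one_strand(template, constraints, name, strand = "+")
  if (is.null(res) && tryReverse && nchar(template@upstream) >= 40L) {
    res <- .design_one_strand(.flip_template(template), constraints, name,
                              strand = "-")
  }
  if (is.null(res)) {
    stop("design infeasible for template '", template@label,
         "': no allele-specific primer pair of length ",
         constraints@primerLenMin, "-", constraints@primerLenMax,
         " nt has Tm within ", constraints@tmTolerance, " degrees C of ",
         constraints@targetTm,
         " and GC within range, in either orientation", call. = FALSE)
  }
  res
}

.design_one_strand <- function(template, constraints, name, strand) {
  pairs <- enumerateAllelePrimers(template, constraints)
  if (!nrow(pairs)) return(NULL)
  cands <- .common_candidates(template, constraints)
  best <- NULL
  for (i in seq_len(nrow(pairs))) {
    fwd <- pairs[i, ]
    common <- tryCatch(.pick_common(cands, as.integer(fwd$start), constraints),
                       error = function(e) NULL)
    if (is.null(common)) next
    score <- abs(fwd$tm_fam - constraints@targetTm) +
      abs(fwd$tm_hex - constraints@targetTm) +
      abs(common$tm - constraints@targetTm)
    cand <- list(fwd = fwd, common = common, score = score)
    if (is.null(best) || .better_design(cand, best)) best <- cand
  }
  if (is.null(best)) return(NULL)
  assay <- kaspAssay(
    name = name,
    primerFam = paste0(.FAM_TAIL, best$fwd$body_fam),
    primerHex = paste0(.HEX_TAIL, best$fwd$body_hex),
    primerCommon = best$common$body)
  new("DesignedAssay", assay = assay,
      productLenFam = as.integer(best$common$product_len),
      productLenHex = as.integer(best$common$product_len),
      designScore = best$score, strand = strand)
}

.better_design <- function(a, b) {
  if (a$score != b$score) return(a$score < b$score)
  if (a$fwd$length != b$fwd$length) return(a$fwd$length < b$fwd$length)
  a$fwd$body_fam < b$fwd$body_fam
}

#' Validate the structure of a KASP assay
#'
#' Runs the structural checks of the KASP chemistry on a primer trio:
#' correct universal FRET tails, 3'-terminal bases equal to the declared
#' alleles, allele-specific bodies identical except at the 3' end, and
#' distinct alleles. With a template, additionally checks that the
#' allele-specific bodies end at the SNP, that the common primer maps to
#' the opposite strand beyond the SNP, and that the amplicon is strictly
#' shorter than `maxProductLen` (both template orientations are tried, so
#' minus-strand designs validate against the original template).
#'
#' @param assay A [KaspAssay-class], a [DesignedAssay-class], or a plain
#'   list with elements `primerFam`, `primerHex`, `primerCommon` and
#'   optionally `alleleFam`, `alleleHex` (defaulting to the primers'
#'   3' bases) -- the list form allows candidate trios that would fail
#'   construction to be diagnosed.
#' @param template Optional [SnpTemplate-class].
#' @param constraints A [DesignConstraints-class] (for the product cap).
#' @return data.frame with columns `check`, `pass`, `detail`; attribute
#'   `"valid"` is `TRUE` when every check passed. Failures are reported,
#'   not raised.
#' @examples
#' rep <- validateAssay(table1Assays()[["621.5"]])
#' attr(rep, "valid")
#' @export
validateAssay <- function(assay, template = NULL,
                          constraints = designConstraints()) {
  if (is(assay, "DesignedAssay")) assay <- assay@assay
  trio <- if (is(assay, "KaspAssay")) {
    list(primerFam = assay@primerFam, primerHex = assay@primerHex,
         primerCommon = assay@primerCommon,
         alleleFam = assay@alleleFam, alleleHex = assay@alleleHex)
  } else {
    last1 <- function(x) substr(x, nchar(x), nchar(x))
    list(primerFam = toupper(assay$primerFam),
         primerHex = toupper(assay$primerHex),
         primerCommon = toupper(assay$primerCommon),
         alleleFam = toupper(if (is.null(assay$alleleFam))
           last1(assay$primerFam) else assay$alleleFam),
         alleleHex = toupper(if (is.null(assay$alleleHex))
           last1(assay$primerHex) else assay$alleleHex))
  }
  checks <- list()
  add <- function(check, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, pass = pass, detail = detail, stringsAsFactors = FALSE)
  }
  last <- function(x) substr(x, nchar(x), nchar(x))

  add("fam_tail", startsWith(trio$primerFam, .FAM_TAIL),
      "FAM primer starts with the universal FAM FRET tail")
  add("hex_tail", startsWith(trio$primerHex, .HEX_TAIL),
      "HEX primer starts with the universal HEX FRET tail")
  add("alleles_differ", trio$alleleFam != trio$alleleHex,
      sprintf("alleles %s/%s", trio$alleleFam, trio$alleleHex))
  add("fam_3prime_allele", last(trio$primerFam) == trio$alleleFam,
      sprintf("FAM primer ends in %s", last(trio$primerFam)))
  add("hex_3prime_allele", last(trio$primerHex) == trio$alleleHex,
      sprintf("HEX primer ends in %s", last(trio$primerHex)))
  bf <- substring(trio$primerFam, nchar(.FAM_TAIL) + 1L)
  bh <- substring(trio$primerHex, nchar(.HEX_TAIL) + 1L)
  bodiesOk <- nchar(bf) == nchar(bh) && nchar(bf) >= 2L &&
    substr(bf, 1L, nchar(bf) - 1L) == substr(bh, 1L, nchar(bh) - 1L)
  add("bodies_equal_except_3prime", bodiesOk,
      "allele-specific bodies differ only at the 3'-terminal base")

  if (!is.null(template)) {
    placed <- .check_placement(trio, template, constraints)
    if (is.null(placed)) {
      placed <- .check_placement(trio, .flip_template(template), constraints)
      orientation <- "-"
    } else orientation <- "+"
    if (is.null(placed)) {
      add("template_placement", FALSE,
          "allele-specific bodies do not end at the template SNP in either orientation")
    } else {
      add("template_placement", TRUE,
          sprintf("bodies end at the SNP (%s orientation)", orientation))
      add("common_downstream", placed$commonFound,
          "common primer maps to the opposite strand beyond the SNP")
      if (placed$commonFound) {
        add("product_length",
            placed$productLen < constraints@maxProductLen,
            sprintf("product %d bp (< %d required)", placed$productLen,
                    constraints@maxProductLen))
      }
    }
  }
  out <- do.call(rbind, checks)
  attr(out, "valid") <- all(out$pass)
  out
}

## Placement of a trio on one orientation of a template; NULL when the
## allele bodies do not sit at the SNP.
.check_placement <- function(trio, template, constraints) {
  bf <- substring(trio$primerFam, nchar(.FAM_TAIL) + 1L)
  u <- nchar(template@upstream)
  L <- nchar(bf)
  if (u < L - 1L) return(NULL)
  stem <- substring(template@upstream, u - L + 2L, u)
  expectF <- paste0(stem, template@alleleA)
  expectFswap <- paste0(stem, template@alleleB)
  if (bf != expectF && bf != expectFswap) return(NULL)
  tpl <- .template_seq(template)
  target <- .revcomp(trio$primerCommon)
  hits <- gregexpr(target, tpl, fixed = TRUE)[[1]]
  commonFound <- FALSE; productLen <- NA_integer_
  if (hits[1] != -1L) {
    for (h in as.integer(hits)) {
      cs <- h - 1L
      ce <- cs + nchar(target)
      if (cs >= u + 1L) {
        commonFound <- TRUE
        productLen <- ce - (u - (L - 1L))
        break
      }
    }
  }
  list(commonFound = commonFound, productLen = productLen)
}
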