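#' The four published restorer-locus KASP assays
#'
#' The validated primer trios of the four KASP markers covering the
#' sunflower fertility-restorer locus Rf1 (markers 621.5, 621.11, 841.38
#' and 861.19, detecting SNPs in three candidate PPR genes). At every
#' marker the HEX primer carries the restorer-haplotype allele and the FAM
#' primer the maintainer allele. Marker order follows the locus.
#'
#' @return Named list of four [KaspAssay-class] objects.
#' @seealso [rf1Panel()], [validateAssay()]
#' @examples
#' table1Assays()[["621.5"]]
#' @export
table1Assays <- function() {
  fam <- .FAM_TAIL; hex <- .HEX_TAIL
  assays <- list(
    kaspAssay("621.5", snpId = "PPR621.5",
              primerFam = paste0(fam, "ACCAGTAATCTCCACATGAACATTG"),
              primerHex = paste0(hex, "ACCAGTAATCTCCACATGAACATTC"),
              primerCommon = "GCGATAAAGAAGCGGGAGATTA"),
    kaspAssay("621.11", snpId = "PPR621.11",
              primerFam = paste0(fam, "GCGGACGCTTGTATGTTC"),
              primerHex = paste0(hex, "GCGGACGCTTGTATGTTA"),
              primerCommon = "TACGGGTGGACCCACAT"),
    kaspAssay("841.38", snpId = "PPR841.38",
              primerFam = paste0(fam, "GCAAAGCACTTGTTTCGTAG"),
              primerHex = paste0(hex, "GCAAAGCACTTGTTTCGTAA"),
              primerCommon = "ATCCCTGGAGAAGAACATTGT"),
    kaspAssay("861.19", snpId = "PPR861.19",
              primerFam = paste0(fam, "AAAAGAAATGGAGGAGGATG"),
              primerHex = paste0(hex, "AAAAGAAATGGAGGAGGATC"),
              primerCommon = "CTTCATGCACCTTACCTTCC"))
  names(assays) <- vapply(assays, assayName, character(1))
  assays
}

#' The four-marker restorer-locus panel
#'
#' [MarkerPanel-class] of the four published KASP markers in locus order,
#' with the restorer-haplotype allele on the HEX dye at every marker
#' (restorer lines are homozygous for the HEX allele, maintainer lines for
#' the FAM allele, F1 hybrids heterozygous).
#'
#' @return A [MarkerPanel-class].
#' @examples
#' rf1Panel()
#' @export
rf1Panel <- function() {
  markerPanel(table1Assays(), restorerDye = "hex")
}

#' Truth table of the mutant-screen worked example
#'
#' Per-marker genotype classes of the ten plants of the single-plant
#' screening example: nine phenotyped male-sterile or partially
#' male-sterile plants from a mutagenized F1 seed lot plus one
#' male-fertile internal reference. One plant is an F1 hybrid with a
#' non-amplifying first marker, seven are maintainer-genotype
#' contaminants at all four markers, one is a recombinant (maintainer
#' haplotype at the two proximal markers, heterozygous at the two distal
#' ones), and the reference plant is heterozygous throughout.
#'
#' The attribute `"n_germinated"` records the germinated plant counts of
#' the two mutagenesis doses (213 and 218); their sum (431, attribute
#' `"screened_total"`) is the denominator for [contaminantRate()].
#'
#' @return data.frame with columns `plant_id`, `phenotype`, one
#'   genotype-class column per marker, and `true_category`.
#' @examples
#' emsScreenTruth()
#' @export
emsScreenTruth <- function() {
  maintainers <- paste0("Mut", 2:8)
  truth <- rbind(
    data.frame(plant_id = "Mut1", phenotype = "partially_male_sterile",
               `621.5` = "no_amp", `621.11` = "het", `841.38` = "het",
               `861.19` = "het", true_category = "hybrid",
               check.names = FALSE, stringsAsFactors = FALSE),
    data.frame(plant_id = maintainers, phenotype = "male_sterile",
               `621.5` = "hom_fam", `621.11` = "hom_fam",
               `841.38` = "hom_fam", `861.19` = "hom_fam",
               true_category = "maintainer",
               check.names = FALSE, stringsAsFactors = FALSE),
    data.frame(plant_id = "Mut10", phenotype = "partially_male_sterile",
               `621.5` = "hom_fam", `621.11` = "hom_fam",
               `841.38` = "het", `861.19` = "het",
               true_category = "recombinant",
               check.names = FALSE, stringsAsFactors = FALSE),
    data.frame(plant_id = "Mut16", phenotype = "male_fertile",
               `621.5` = "het", `621.11` = "het", `841.38` = "het",
               `861.19` = "het", true_category = "hybrid",
               check.names = FALSE, stringsAsFactors = FALSE))
  rownames(truth) <- NULL
  attr(truth, "n_germinated") <- c(ems_0.8pct = 213L, ems_1.2pct = 218L)
  attr(truth, "screened_total") <- 431L
  truth
}

#' Validation panel of 26 sunflower lines
#'
#' The printed validation matrix comparing sequence-based SNP genotypes
#' with the KASP marker calls for 26 sunflower lines (12 maintainer-panel
#' and 14 restorer-panel lines) at the four restorer-locus markers.
#' `seq_*` columns hold the sequence-based genotypes (`"-"` where a line
#' was not sequenced), `kasp_*` columns the KASP calls as printed,
#' including the two non-amplifying cells of line CM63 at markers 841.38
#' and 861.19 and the heterozygous call of line UGA-SAM1-109 at marker
#' 841.38. Line IH-51 carries a maintainer-type marker haplotype despite
#' its restorer phenotype (its restoration acts through a different
#' locus).
#'
#' `class_*` columns give the genotype class of each printed KASP call
#' under the corresponding assay's dye-to-allele map (via
#' [genotypeClass()]), which is the representation consumed by the
#' simulator and the caller.
#'
#' @return data.frame with 26 rows and columns `line`, `group`,
#'   `seq_<marker>`, `kasp_<marker>`, `class_<marker>`.
#' @examples
#' fx <- table2Fixture()
#' fx[fx$line == "CM63", c("kasp_841.38", "class_841.38")]
#' @export
table2Fixture <- function() {
  maintainer <- c("Armavirsky 3497", "Arrowhead", "CM259", "CM63",
                  "Krasnodaret", "No. 2", "UGA-SAM1-082", "UGA-SAM1-109",
                  "UGA-SAM1-156", "UGA-SAM1-185", "HA342", "HA383")
  restorer <- c("UGA-SAM1-010", "UGA-SAM1-024", "UGA-SAM1-100",
                "UGA-SAM1-101", "UGA-SAM1-121", "UGA-SAM1-136",
                "UGA-SAM1-161", "UGA-SAM1-169", "UGA-SAM1-191",
                "UGA-SAM1-204", "RHA325", "RHA265", "IH-51", "NS-H-27")
  lines <- c(maintainer, restorer)
  n <- length(lines)

  sequenced_m <- setdiff(maintainer, c("HA342", "HA383"))
  sequenced_r <- c("UGA-SAM1-010", "UGA-SAM1-024", "UGA-SAM1-100",
                   "UGA-SAM1-101", "UGA-SAM1-121", "UGA-SAM1-136",
                   "UGA-SAM1-161", "UGA-SAM1-169", "UGA-SAM1-191",
                   "UGA-SAM1-204")
  mPattern <- c("621.5" = "GG", "621.11" = "CC", "841.38" = "GG",
                "861.19" = "GG")
  rPattern <- c("621.5" = "CC", "621.11" = "AA", "841.38" = "AA",
                "861.19" = "CC")

  out <- data.frame(line = lines,
                    group = rep(c("maintainer", "restorer"),
                                c(length(maintainer), length(restorer))),
                    stringsAsFactors = FALSE)
  assays <- table1Assays()
  for (m in names(assays)) {
    seqCol <- ifelse(out$line %in% sequenced_m, mPattern[[m]],
              ifelse(out$line %in% sequenced_r, rPattern[[m]], "-"))
    kaspCol <- ifelse(out$group == "maintainer", mPattern[[m]],
                      rPattern[[m]])
    # IH-51 groups with the maintainer lines at every marker.
    kaspCol[out$line == "IH-51"] <- mPattern[[m]]
    out[[paste0("seq_", m)]] <- seqCol
    out[[paste0("kasp_", m)]] <- kaspCol
  }
  out[out$line == "CM63", c("kasp_841.38", "kasp_861.19")] <- "-"
  out[out$line == "UGA-SAM1-109", "kasp_841.38"] <- "GC"
  for (m in names(assays)) {
    out[[paste0("class_", m)]] <- genotypeClass(out[[paste0("kasp_", m)]],
                                                assays[[m]])
  }
  out
}
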