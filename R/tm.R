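## Unified nearest-neighbor duplex parameters (kcal/mol for dH,
## cal/(mol K) for dS), one entry per plus-strand dinucleotide step.
.NN_DH <- c(
  AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
  CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
  CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
  CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.NN_DS <- c(
  AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
  CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
  CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
  CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
## Duplex-initiation terms per terminal base pair.
.NN_TERM_AT_DH <- 2.3
.NN_TERM_AT_DS <- 4.1
.NN_TERM_GC_DH <- 0.1
.NN_TERM_GC_DS <- -2.8
.NN_SYM_DS <- -1.4
.GAS_R <- 1.987 # cal / (mol K)

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.gc_percent <- function(x) {
  n <- nchar(x)
  100 * (n - nchar(gsub("[GC]", "", x))) / n
}

#' Nearest-neighbor melting temperature of a primer
#'
#' Computes the duplex melting temperature of a DNA oligonucleotide with
#' the unified nearest-neighbor thermodynamic parameter set (two-state
#' model with initiation and terminal A:T penalties), an entropic salt
#' correction of `0.368 (N-1) ln[monovalent]` per phosphate, and the usual
#' non-self-complementary concentration factor `CT/4` (self-complementary
#' sequences get the symmetry entropy correction and `CT`). Deterministic;
#' ambiguity codes are not supported.
#'
#' For allele-specific KASP primers the Tm is computed on the primer
#' *body* only -- the universal FRET tail does not bind the template in
#' early cycles.
#'
#' @param seq ACGT sequence, at least 8 nt.
#' @param monovalentMM Effective monovalent cation concentration in mM
#'   (default 75).
#' @param oligoNM Total oligonucleotide strand concentration in nM
#'   (default 200).
#' @return Melting temperature in degrees Celsius.
#' @examples
#' meltingTemp("ACCAGTAATCTCCACATGAACATTG")
#' meltingTemp("GCGCGCGCGCGCGCGC") > meltingTemp("ATATATATATATATAT")
#' @export
meltingTemp <- function(seq, monovalentMM = 75, oligoNM = 200) {
  seq <- toupper(gsub("[[:space:]]", "", seq))
  if (grepl("[^ACGT]", seq)) {
    stop("unsupported sequence: only A, C, G, T are allowed", call. = FALSE)
  }
  n <- nchar(seq)
  if (n < 8L) stop("sequence must be at least 8 nt", call. = FALSE)

  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  steps <- paste0(chars[-n], chars[-1L])
  dH <- sum(.NN_DH[steps])
  dS <- sum(.NN_DS[steps])

  nAT <- sum(chars[c(1L, n)] %in% c("A", "T"))
  dH <- dH + nAT * .NN_TERM_AT_DH + (2L - nAT) * .NN_TERM_GC_DH
  dS <- dS + nAT * .NN_TERM_AT_DS + (2L - nAT) * .NN_TERM_GC_DS

  selfComp <- identical(
    chars, rev(strsplit(chartr("ACGT", "TGCA", seq), "", fixed = TRUE)[[1]]))
  if (selfComp) dS <- dS + .NN_SYM_DS

  dS <- dS + 0.368 * (n - 1L) * log(monovalentMM / 1000)

  ct <- oligoNM * 1e-9
  k <- if (selfComp) ct else ct / 4
  1000 * dH / (dS + .GAS_R * log(k)) - 273.15
}
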