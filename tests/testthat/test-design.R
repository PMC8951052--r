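test_that("bracket templates parse and malformed ones are rejected", {
  up <- strrep("ACGT", 10); dn <- strrep("TGCA", 15)
  t <- parseSnpTemplate(paste0(up, "[G/C]", dn))
  expect_equal(t@upstream, up)
  expect_equal(t@alleleA, "G")
  expect_equal(t@alleleB, "C")
  expect_equal(t@downstream, dn)

  # lowercase input is normalized to uppercase
  t2 <- parseSnpTemplate(tolower(paste0(up, "[g/c]", dn)))
  expect_equal(t2@upstream, up)

  expect_error(parseSnpTemplate(paste0(up, "[GG/C]", dn)), "malformed")
  expect_error(parseSnpTemplate(paste0(up, "[G/C]", dn, "[A/T]", dn)),
               "exactly one")
  expect_error(parseSnpTemplate(paste0(up, dn)), "exactly one")
  expect_error(parseSnpTemplate(paste0("NNNN", up, "[G/C]", dn)), "malformed")
})

test_that("melting temperatures reproduce independent nearest-neighbor values", {
  # frozen regression values from an independent published NN calculator
  # (unified parameter set, 75 mM monovalent, 200 nM total strands)
  frozen <- c(
    "ACCAGTAATCTCCACATGAACATTG" = 56.9662,
    "ACCAGTAATCTCCACATGAACATTC" = 56.7327,
    "GCGATAAAGAAGCGGGAGATTA"    = 56.2526,
    "GCGGACGCTTGTATGTTC"        = 55.0533,
    "GCGGACGCTTGTATGTTA"        = 53.5807,
    "TACGGGTGGACCCACAT"         = 55.3342,
    "GCAAAGCACTTGTTTCGTAG"      = 54.0677,
    "GCAAAGCACTTGTTTCGTAA"      = 53.5786,
    "ATCCCTGGAGAAGAACATTGT"     = 54.5341,
    "AAAAGAAATGGAGGAGGATG"      = 50.8751,
    "AAAAGAAATGGAGGAGGATC"      = 50.5741,
    "CTTCATGCACCTTACCTTCC"      = 54.2128)
  for (s in names(frozen)) {
    expect_equal(meltingTemp(s), frozen[[s]], tolerance = 1e-3)
  }
  # self-complementary duplexes (symmetry correction, CT concentration)
  expect_equal(meltingTemp("ATATATATATATATAT"), 21.9012, tolerance = 1e-3)
  expect_equal(meltingTemp("GCGCGCGCGCGCGCGC"), 75.1549, tolerance = 1e-3)
})

test_that("melting temperature respects duplex symmetry and GC ordering", {
  expect_lt(meltingTemp("ATATATATATATATAT"), meltingTemp("GCGCGCGCGCGCGCGC"))
  # the duplex is the same molecule read from either strand
  rc <- function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  }
  set.seed(4)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 24, replace = TRUE),
               collapse = "")
    expect_equal(meltingTemp(s), meltingTemp(rc(s)), tolerance = 1e-9)
  }
  # published primer bodies melt in the plausible PCR range
  for (a in table1Assays()) {
    for (s in c(famBody(a), hexBody(a), commonPrimer(a))) {
      tm <- meltingTemp(s)
      expect_gt(tm, 45); expect_lt(tm, 70)
    }
  }
  expect_error(meltingTemp("ACGTACG"), "at least 8")
  expect_error(meltingTemp("ACGTNACGTACGT"), "unsupported")
})

test_that("allele-primer enumeration pairs share bodies and respect filters", {
  set.seed(11)
  tpl <- randomSnpTemplate(alleles = c("G", "C"))
  cands <- enumerateAllelePrimers(tpl)
  expect_gt(nrow(cands), 0L)
  for (i in seq_len(nrow(cands))) {
    bf <- cands$body_fam[i]; bh <- cands$body_hex[i]
    expect_equal(substr(bf, 1, nchar(bf) - 1), substr(bh, 1, nchar(bh) - 1))
    expect_equal(substr(bf, nchar(bf), nchar(bf)), "G")
    expect_equal(substr(bh, nchar(bh), nchar(bh)), "C")
    expect_lte(abs(cands$tm_fam[i] - 62), 3)
    expect_lte(abs(cands$tm_hex[i] - 62), 3)
  }

  # swapping the alleles swaps the pair roles only
  swapped <- snpTemplate(tpl@upstream, "C", "G", tpl@downstream)
  cands2 <- enumerateAllelePrimers(swapped)
  expect_equal(cands2$body_fam, cands$body_hex)
  expect_equal(cands2$body_hex, cands$body_fam)

  # an all-G upstream fails the GC filter: no admissible pair, no error
  polyG <- snpTemplate(strrep("G", 40), "A", "T", tpl@downstream)
  expect_equal(nrow(enumerateAllelePrimers(polyG)), 0L)
})

test_that("common-primer selection respects the product cap and is monotone", {
  set.seed(21)
  tpl <- randomSnpTemplate(length = 200L)
  cands <- enumerateAllelePrimers(tpl)
  expect_gt(nrow(cands), 0L)
  fwd <- cands[1, ]
  common <- selectCommonPrimer(tpl, fwd)
  expect_lt(common$product_len, 150)
  expect_equal(common$strand, "-")
  expect_lte(abs(common$tm - 62), 3)

  # lengthening the downstream flank never removes a feasible design
  longer <- snpTemplate(tpl@upstream, tpl@alleleA, tpl@alleleB,
                        paste0(tpl@downstream, strrep("ACGT", 20)))
  common2 <- selectCommonPrimer(longer, fwd)
  expect_lte(abs(common2$tm - 62), abs(common$tm - 62))

  # a too-short downstream is design-infeasible
  short <- snpTemplate(tpl@upstream, tpl@alleleA, tpl@alleleB,
                       strrep("GGGG", 11))
  expect_error(selectCommonPrimer(short, fwd), "infeasible")
})

test_that("designed assays obey the KASP structure deterministically", {
  set.seed(33)
  tpls <- replicate(12, randomSnpTemplate(), simplify = FALSE)
  tails <- fretTails()
  for (tpl in tpls) {
    d <- designAssay(tpl)
    a <- designedAssay(d)
    # exactly two tailed allele-specific primers and one common primer
    expect_true(startsWith(famPrimer(a), tails[["fam"]]))
    expect_true(startsWith(hexPrimer(a), tails[["hex"]]))
    expect_false(startsWith(commonPrimer(a), tails[["fam"]]) ||
                   startsWith(commonPrimer(a), tails[["hex"]]))
    # bodies end in the declared alleles and differ only there
    bf <- famBody(a); bh <- hexBody(a)
    expect_equal(substr(bf, nchar(bf), nchar(bf)), famAllele(a))
    expect_equal(substr(bh, nchar(bh), nchar(bh)), hexAllele(a))
    expect_equal(substr(bf, 1, nchar(bf) - 1), substr(bh, 1, nchar(bh) - 1))
    expect_lt(productLength(d), 150)
    # design-then-validate round-trips
    expect_true(attr(validateAssay(d, tpl), "valid"))
    # determinism
    d2 <- designAssay(tpl)
    expect_identical(famPrimer(designedAssay(d2)), famPrimer(a))
    expect_identical(commonPrimer(designedAssay(d2)), commonPrimer(a))
  }
})

test_that("an undesignable flanking context raises a named infeasibility", {
  at <- paste(rep(c("A", "T"), 80), collapse = "")
  tpl <- snpTemplate(at, "G", "C", at)
  expect_error(designAssay(tpl), "infeasible")
})

test_that("the published primer trios pass all structural checks", {
  for (a in table1Assays()) {
    rep <- validateAssay(a)
    expect_true(attr(rep, "valid"), label = assayName(a))
  }
  # 841.38 discriminates G (FAM) from A (HEX), matching its allele pair
  a841 <- table1Assays()[["841.38"]]
  expect_equal(famAllele(a841), "G")
  expect_equal(hexAllele(a841), "A")
  b <- famBody(a841)
  expect_equal(substr(b, nchar(b), nchar(b)), "G")

  # a trio with swapped tails fails exactly the tail checks
  bad <- list(primerFam = hexPrimer(a841), primerHex = famPrimer(a841),
              primerCommon = commonPrimer(a841))
  repBad <- validateAssay(bad)
  expect_false(attr(repBad, "valid"))
  expect_false(repBad$pass[repBad$check == "fam_tail"])
  expect_false(repBad$pass[repBad$check == "hex_tail"])
})
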