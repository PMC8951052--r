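test_that("percent fluorescence maps plate extremes to 0, 100 and midpoints to 50", {
  norm <- normalizePlate(tinyPlate())
  w <- norm$wells
  expect_equal(norm$normalization$min, c(100, 80))
  expect_equal(norm$normalization$max, c(1100, 1080))
  expect_equal(w$pct_fam[w$sample_id == "s_fammax"], 100)
  expect_equal(w$pct_hex[w$sample_id == "s_fammax"], 0)
  expect_equal(w$pct_hex[w$sample_id == "s_hexmax"], 100)
  expect_equal(w$pct_fam[w$sample_id == "s_hexmax"], 0)
  expect_equal(w$pct_fam[w$sample_id == "s_mid"], 50)
  expect_equal(w$pct_hex[w$sample_id == "s_mid"], 50)
  # min/max include the NTC wells
  expect_equal(w$pct_fam[w$is_ntc], 0)
})

test_that("a constant dye channel is a degenerate-plate error", {
  wellsDf <- wells(tinyPlate())
  wellsDf$hex <- 500
  expect_error(normalizePlate(rawPlate("flat", wellsDf)), "degenerate")
})

test_that("well classification follows the no-amp zone and angle segments", {
  cfg <- callerConfig()
  a <- table1Assays()[["621.5"]]
  w <- data.frame(
    pct_fam = c(12, 50, 10, 80, 24.9, 30),
    pct_hex = c(10, 50, 80, 10, 24.9, 10))
  out <- classifyWells(w, cfg, a)
  expect_equal(out$class,
               c("no_amp", "het", "hom_hex", "hom_fam", "no_amp", "hom_fam"))
  expect_equal(out$angle_deg[2], 45)
  expect_equal(out$angle_deg[3], atan2(10, 80) * 180 / pi, tolerance = 1e-12)
  expect_equal(round(out$angle_deg[3], 1), 7.1)
  # dye-to-allele rendering: HEX carries the restorer allele C of 621.5
  expect_equal(out$genotype[3], "CC")
  expect_equal(out$genotype[2], "GC")
  expect_true(is.na(out$angle_deg[1]))
})

test_that("class regions plus the no-amp zone partition the normalized square", {
  set.seed(77)
  cfgs <- list(callerConfig(),
               callerConfig(noAmpThreshold = 10, boundaryLow = 20,
                            boundaryHigh = 70))
  for (cfg in cfgs) {
    w <- data.frame(pct_fam = runif(500, 0, 100),
                    pct_hex = runif(500, 0, 100))
    out <- classifyWells(w, cfg)
    expect_true(all(out$class %in% c("no_amp", "hom_hex", "het", "hom_fam")))
    expect_false(anyNA(out$class))
    # exactly one class per well and the rule is deterministic
    expect_identical(out$class, classifyWells(w, cfg)$class)
  }
})

test_that("calls are invariant under positive affine rescaling of one dye", {
  sim <- simulatePlate(
    data.frame(sample_id = sprintf("s%d", 1:9),
               class = rep(c("hom_fam", "het", "hom_hex"), 3)),
    simConfig(seed = 31))
  plate <- sim$plate
  w2 <- wells(plate)
  w2$fam <- 3.7 * w2$fam + 250   # positive affine map on FAM only
  plate2 <- rawPlate(plateId(plate), w2, assayName = assayName(plate))

  n1 <- normalizePlate(plate)$wells
  n2 <- normalizePlate(plate2)$wells
  expect_equal(n2$pct_fam, n1$pct_fam, tolerance = 1e-12)
  expect_equal(n2$pct_hex, n1$pct_hex, tolerance = 1e-12)
  c1 <- callPlate(plate, table1Assays()[["621.5"]])
  c2 <- callPlate(plate2, table1Assays()[["621.5"]])
  expect_equal(c1$class, c2$class)
  expect_equal(c1$angle_deg, c2$angle_deg, tolerance = 1e-12)
})

test_that("classification is invariant under permutation of wells", {
  sim <- simulatePlate(
    data.frame(sample_id = sprintf("s%d", 1:6),
               class = rep(c("hom_fam", "het", "hom_hex"), 2)),
    simConfig(seed = 13))
  plate <- sim$plate
  set.seed(1)
  w <- wells(plate)[sample(nrow(wells(plate))), ]
  shuffled <- rawPlate(plateId(plate), w, assayName = assayName(plate))
  c1 <- callPlate(plate, table1Assays()[["621.5"]])
  c2 <- callPlate(shuffled, table1Assays()[["621.5"]])
  expect_equal(c1$class, c2$class)
  expect_equal(c1$sample_id, c2$sample_id)
})

test_that("replicate consensus follows the exclusion and agreement rules", {
  cfg <- callerConfig()
  expect_equal(consensusCall(rep("het", 4), rep(45, 4), cfg)$class, "het")

  # no_amp replicates are dropped before judging agreement
  r <- consensusCall(c("het", "het", "no_amp", "het"), c(44, 46, NA, 45), cfg)
  expect_equal(r$class, "het")
  expect_equal(r$angle, 45)
  expect_equal(r$nAmplified, 3L)

  # unanimity: any disagreement is ambiguous
  expect_equal(consensusCall(c("hom_hex", "het"), c(10, 45), cfg)$class,
               "ambiguous")

  # majority: strict majority wins, ties are ambiguous
  maj <- callerConfig(replicatePolicy = "majority")
  expect_equal(consensusCall(c("het", "het", "hom_hex"), c(40, 45, 10),
                             maj)$class, "het")
  expect_equal(consensusCall(c("het", "hom_hex"), c(40, 10), maj)$class,
               "ambiguous")

  # all failed, or too few amplified replicates, is no_amp
  expect_equal(consensusCall(rep("no_amp", 4), rep(NA_real_, 4), cfg)$class,
               "no_amp")
  strict <- callerConfig(minAmplifiedReplicates = 2L)
  expect_equal(consensusCall(c("het", "no_amp"), c(45, NA), strict)$class,
               "no_amp")

  expect_error(consensusCall(character(), numeric()), "at least one")
})

test_that("a clean three-cluster plate yields three distinct consensus calls", {
  sim <- simulatePlate(
    data.frame(sample_id = c("restorer", "hybrid", "maintainer"),
               class = c("hom_hex", "het", "hom_fam")),
    simConfig(seed = 1, noiseCv = 0))
  calls <- callPlate(sim$plate, table1Assays()[["621.5"]])
  expect_equal(sort(calls$class), c("het", "hom_fam", "hom_hex"))
  expect_equal(calls$angle_deg[calls$sample_id == "hybrid"], 45)
  expect_length(attr(calls, "warnings"), 0L)
})

test_that("replicates straddling a class boundary give an ambiguous row", {
  # two replicates just on either side of the 30-degree boundary
  wellsDf <- data.frame(
    well_id = c("A1", "A2", "B1", "B2", "C1"),
    sample_id = c("straddle", "straddle", "anchor", "anchor", "NTC1"),
    replicate_index = c(1L, 2L, 1L, 2L, 1L),
    is_ntc = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    fam = c(576, 650, 1000, 1000, 0),
    hex = c(1000, 1000, 0, 10, 0))
  plate <- rawPlate("straddle", wellsDf)
  calls <- callPlate(plate, cfg = callerConfig())
  expect_equal(calls$class[calls$sample_id == "straddle"], "ambiguous")
  expect_equal(calls$class[calls$sample_id == "anchor"], "hom_fam")
})

test_that("non-amplifying samples are called no_amp without warnings", {
  sim <- simulatePlate(
    data.frame(sample_id = c("dead1", "dead2", "alive"),
               class = c("no_amp", "no_amp", "het")),
    simConfig(seed = 9))
  calls <- callPlate(sim$plate, table1Assays()[["621.5"]])
  expect_equal(calls$class[calls$sample_id %in% c("dead1", "dead2")],
               rep("no_amp", 2))
  expect_length(attr(calls, "warnings"), 0L)
})

test_that("an amplified NTC attaches a contamination warning", {
  wellsDf <- wells(tinyPlate())
  wellsDf$fam[wellsDf$is_ntc] <- 1050 # NTC suddenly full of FAM product
  plate <- rawPlate("dirty", wellsDf)
  expect_warning(calls <- callPlate(plate), "master-mix")
  expect_match(attr(calls, "warnings"), "A5")
})

test_that("genotype labels and classes are mutually inverse", {
  for (a in table1Assays()) {
    classes <- c("hom_fam", "het", "hom_hex", "no_amp")
    expect_equal(genotypeClass(genotypeLabel(classes, a), a), classes)
  }
})
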