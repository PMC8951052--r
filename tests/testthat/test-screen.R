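test_that("a proximal/distal zygosity switch is called recombinant", {
  panel <- rf1Panel()
  calls <- c("621.5" = "hom_fam", "621.11" = "hom_fam",
             "841.38" = "het", "861.19" = "het")
  cls <- classifyPlant(calls, panel, plantId = "Mut10")
  expect_equal(plantCategory(cls), "recombinant")
  expect_equal(recombinationIntervals(cls), "621.11--841.38")
  expect_equal(cls@informativeMarkers, 4L)
})

test_that("a failed marker leaves a plant classifiable on the rest", {
  panel <- rf1Panel()
  calls <- c("621.5" = "no_amp", "621.11" = "het",
             "841.38" = "het", "861.19" = "het")
  cls <- classifyPlant(calls, panel, plantId = "Mut1")
  expect_equal(plantCategory(cls), "hybrid")
  expect_equal(cls@informativeMarkers, 3L)
  expect_length(recombinationIntervals(cls), 0L)

  # below the informative-marker floor the plant stays unclassified
  mostlyDead <- c("621.5" = "no_amp", "621.11" = "no_amp",
                  "841.38" = "no_amp", "861.19" = "het")
  expect_equal(plantCategory(classifyPlant(mostlyDead, panel)),
               "unclassified")
})

test_that("uniform zygosity maps to the three pure categories", {
  panel <- rf1Panel()
  allHet <- setNames(rep("het", 4), names(panelAssays(panel)))
  expect_equal(plantCategory(classifyPlant(allHet, panel)), "hybrid")
  allHex <- setNames(rep("hom_hex", 4), names(panelAssays(panel)))
  expect_equal(plantCategory(classifyPlant(allHex, panel)), "restorer")
  allFam <- setNames(rep("hom_fam", 4), names(panelAssays(panel)))
  expect_equal(plantCategory(classifyPlant(allFam, panel)), "maintainer")
})

test_that("uniform plants are never recombinant, whatever the pattern", {
  panel <- rf1Panel()
  markers <- names(panelAssays(panel))
  set.seed(17)
  for (i in 1:30) {
    state <- sample(c("hom_fam", "het", "hom_hex"), 1)
    calls <- setNames(rep(state, 4), markers)
    drop <- sample(c(0L, 1L, 2L), 1)
    if (drop > 0) calls[sample(4, drop)] <- "no_amp"
    cls <- classifyPlant(calls, panel)
    expect_true(plantCategory(cls) != "recombinant")
    expect_length(recombinationIntervals(cls), 0L)
  }
})

test_that("reversing the panel reverses interval endpoints, not the category", {
  fwd <- rf1Panel()
  rev_assays <- rev(panelAssays(fwd))
  revPanel <- markerPanel(rev_assays, restorerDye = "hex")
  calls <- c("621.5" = "hom_fam", "621.11" = "hom_fam",
             "841.38" = "het", "861.19" = "het")
  a <- classifyPlant(calls, fwd)
  b <- classifyPlant(calls, revPanel)
  expect_equal(plantCategory(a), plantCategory(b))
  expect_equal(recombinationIntervals(a), "621.11--841.38")
  expect_equal(recombinationIntervals(b), "841.38--621.11")
})

test_that("zygosity follows the restorer-allele map, not the dye", {
  panel <- rf1Panel()
  flipped <- markerPanel(panelAssays(panel), restorerDye = "fam")
  calls <- setNames(rep("hom_hex", 4), names(panelAssays(panel)))
  expect_equal(plantCategory(classifyPlant(calls, panel)), "restorer")
  expect_equal(plantCategory(classifyPlant(calls, flipped)), "maintainer")
  # complementing both the map and the calls leaves the category fixed
  callsFam <- setNames(rep("hom_fam", 4), names(panelAssays(panel)))
  expect_equal(plantCategory(classifyPlant(callsFam, flipped)), "restorer")
})

test_that("marker mismatches between record and panel are contract errors", {
  panel <- rf1Panel()
  expect_error(classifyPlant(c("621.5" = "het"), panel), "missing")
  calls <- setNames(rep("het", 5),
                    c(names(panelAssays(panel)), "extra_marker"))
  expect_error(classifyPlant(calls, panel), "not in the panel")
})

test_that("the mutant-screen fixture partitions into 1/7/1 plus the control", {
  truth <- emsScreenTruth()
  rep <- screenReport(truth, rf1Panel())
  expect_equal(nrow(rep), 10L)
  expect_equal(sum(rep$category == "maintainer"), 7L)
  expect_equal(sum(rep$category == "hybrid"), 2L)
  expect_equal(sum(rep$category == "recombinant"), 1L)
  expect_equal(rep$intervals[rep$category == "recombinant"],
               "621.11--841.38")
  # the no-amp marker of the hybrid plant renders as "-"
  expect_equal(rep[rep$plant_id == "Mut1", "621.5"], "-")
  expect_equal(rep[rep$plant_id == "Mut1", "category"], "hybrid")
  # empty input gives a header-only report
  expect_equal(nrow(screenReport(truth[0, ], rf1Panel())), 0L)
})

test_that("contaminant rates are percentages of the screened total", {
  rep <- screenReport(emsScreenTruth(), rf1Panel())
  expect_equal(contaminantRate(rep, denominator = 431), 1.6)
  expect_equal(contaminantRate(rep[rep$category == "hybrid", ], 431), 0)
  all431 <- data.frame(category = rep("maintainer", 431))
  expect_equal(contaminantRate(all431, 431), 100)
  expect_error(contaminantRate(rep, 0), "positive")
  # phenotype filtering restricts the numerator
  expect_equal(contaminantRate(rep, 431, phenotypes = "male_sterile"), 1.6)
  expect_equal(contaminantRate(rep, 431, phenotypes = "male_fertile"), 0)
})

test_that("simulated screen plates recover the true plant categories", {
  screen <- simulateEmsScreen(cfg = simConfig(seed = 8))
  panel <- rf1Panel()
  calls <- do.call(rbind, lapply(names(screen$plates), function(m) {
    callPlate(screen$plates[[m]], panelAssays(panel)[[m]])
  }))
  records <- recordsFromCalls(
    calls, phenotypes = screen$truth[, c("plant_id", "phenotype")])
  # reference controls anchor the plates but are not screened plants
  records <- records[records$plant_id %in% screen$truth$plant_id, ]
  rep <- screenReport(records, panel)
  truth <- screen$truth[match(rep$plant_id, screen$truth$plant_id), ]
  expect_equal(rep$category, truth$true_category)
  expect_equal(contaminantRate(rep, 431), 1.6)
})
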