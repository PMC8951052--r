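# Shared test fixtures, all built in code.

# A small hand-built plate with known raw values: per-dye min/max are
# 100/1100 (FAM) and 80/1080 (HEX), so percent fluorescence is exact.
tinyPlate <- function() {
  wellsDf <- data.frame(
    well_id = c("A1", "A2", "A3", "A4", "A5"),
    sample_id = c("s_hexmax", "s_fammax", "s_mid", "s_low", "NTC1"),
    replicate_index = 1L,
    is_ntc = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    fam = c(100, 1100, 600, 150, 100),
    hex = c(1080, 80, 580, 130, 80))
  rawPlate("tiny", wellsDf, assayName = "621.5")
}

# Write a RawPlate as wide-form export + sheet, return the two paths.
writeTempPlate <- function(plate) {
  f <- tempfile(fileext = ".csv"); s <- tempfile(fileext = ".csv")
  writePlate(plate, f, s)
  c(plate = f, sheet = s)
}

expect_identical_plates <- function(a, b) {
  expect_equal(wells(a), wells(b))
}
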