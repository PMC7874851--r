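test_that("melanin extinction is strictly decreasing over the band", {
  lib <- chromophoreLibrary()
  expect_true(all(diff(melaninMua(defaultWavelengths(), lib)) < 0))
  # dense sweep, not only the instrument wavelengths
  expect_true(all(diff(melaninMua(seq(471, 851, by = 5), lib)) < 0))
})

test_that("skin models follow the phenotype and chromophore defaults", {
  lib <- chromophoreLibrary()
  targets <- defaultLocationTargets()
  # zero melanin: epidermis optically matched to the dermis
  ph0 <- subjectPhenotype("Z", "I", melaninFraction = 0)
  tm0 <- skinModelFromPhenotype(ph0, "forehead", 471)
  expect_equal(tm0@layers$mua[1], tm0@layers$mua[2])
  expect_equal(tm0@layers$musp[1], tm0@layers$musp[2])
  # dermal anchor: musp at 851 equals the location target times the scale
  ph <- subjectPhenotype("S", "III",
                         locationScale = c(forehead = 1.1))
  tm851 <- skinModelFromPhenotype(ph, "forehead", 851)
  expect_equal(tm851@layers$musp[2], targets$mean[["forehead"]] * 1.1)
  # epidermal absorption increases with melanin fraction
  muaEpi <- vapply(fitzpatrickMelanin(c("I", "III", "VI")), function(mf) {
    p <- subjectPhenotype("X", "I", melaninFraction = mf)
    skinModelFromPhenotype(p, "forehead", 471)@layers$mua[1]
  }, numeric(1))
  expect_true(all(diff(muaEpi) > 0))
  expect_error(skinModelFromPhenotype(ph0, "elbow", 471), "unknown location")
  expect_error(skinModelFromPhenotype(ph0, "forehead", 300), "band")
})

test_that("Fitzpatrick melanin defaults give the designed spectral contrast", {
  # V/VI vs I epidermal absorption ratio at 471 nm exceeds 5
  epi <- function(type, wl) {
    p <- subjectPhenotype("X", type)
    skinModelFromPhenotype(p, "forehead", wl)@layers$mua[1]
  }
  expect_gt(epi("V", 471) / epi("I", 471), 5)
  expect_gt(epi("VI", 471) / epi("I", 471), 5)
  # at 851 nm epidermal absorption is < 20% of its 471 nm value, every type
  for (t in c("I", "II", "III", "IV", "V", "VI"))
    expect_lt(epi(t, 851) / epi(t, 471), 0.20)
  # melanin fraction non-decreasing with Fitzpatrick type
  expect_true(all(diff(fitzpatrickMelanin(
    c("I", "II", "III", "IV", "V", "VI"))) >= 0))
  expect_error(fitzpatrickMelanin("VII"), "unknown Fitzpatrick")
})

test_that("the palm override suppresses melanin", {
  p <- subjectPhenotype("X", "VI")
  palm <- skinModelFromPhenotype(p, "palm", 471)
  fore <- skinModelFromPhenotype(p, "forehead", 471)
  melPalm <- palm@layers$mua[1] - palm@layers$mua[2]
  melFore <- fore@layers$mua[1] - fore@layers$mua[2]
  expect_lte(melPalm / melFore, 0.10 + 1e-12)
})

test_that("synthesizeCohort reproduces the designed structure", {
  spec <- cohortSpec(seed = 1L)
  expect_identical(spec@nSubjects, 15L)
  expect_identical(length(spec@locations), 10L)
  expect_identical(length(spec@wavelengths), 8L)
  expect_identical(length(spec@fx), 5L)
  expect_identical(length(spec@phases), 3L)
  co <- synthesizeCohort(spec)
  expect_identical(length(co@phenotypes), 15L)
  expect_identical(nrow(cohortTruth(co)), 15L * 10L * 8L)
  # every Fitzpatrick type is present in the default assignment
  expect_setequal(unique(spec@fitzpatrick),
                  c("I", "II", "III", "IV", "V", "VI"))
  # a rendered stack has the full index grid
  st <- renderSubjectLocation(co, 1, "forehead")
  expect_identical(dim(st@data),
                   c(48L, 48L, 8L, 5L, 3L))
  expect_error(cohortSpec(nSubjects = 0), "positive")
})

test_that("the cohort generator is seed-deterministic", {
  s1 <- synthesizeCohort(cohortSpec(nSubjects = 4L, seed = 11L))
  s2 <- synthesizeCohort(cohortSpec(nSubjects = 4L, seed = 11L))
  expect_identical(cohortTruth(s1), cohortTruth(s2))
  st1 <- renderSubjectLocation(s1, 2, "palm")
  st2 <- renderSubjectLocation(s2, 2, "palm")
  expect_identical(st1@data, st2@data)
  s3 <- synthesizeCohort(cohortSpec(nSubjects = 4L, seed = 12L))
  expect_false(identical(cohortTruth(s1), cohortTruth(s3)))
})

test_that("851 nm dermal anchors track the location targets", {
  co <- synthesizeCohort(cohortSpec(seed = 1L))
  tr <- cohortTruth(co)
  fh <- tr$musp851[tr$location == "forehead" & tr$wavelength == 851]
  # sample mean within 2 standard errors of the 1.65 target
  se <- 0.174 / sqrt(15)
  expect_lt(abs(mean(fh) - 1.65), 2 * se)
})

test_that("phantom self-consistency through the full pipeline", {
  lut <- sharedLUT()
  fx <- defaultFrequencies()
  ph <- renderPhantom(defaultPhantom(c(471, 851)), fx = fx, imageSize = 6L,
                      noiseLevel = 0, seed = 2)
  # predicted table equals the forward model on the phantom properties
  props <- defaultPhantom(c(471, 851))
  for (i in 1:2)
    expect_identical(unname(ph$predictedRd[i, ]),
                     rdDiffusion(props$mua[i], props$musp[i], fx))
  # processing the phantom against itself returns its own properties
  m <- demodulate(ph$stack)
  rs <- calibrate(m, m, ph$predictedRd)
  opm <- invertMap(rs, lut)
  gA <- diff(lut@muaAxis)[1]; gS <- diff(lut@muspAxis)[1]
  for (i in 1:2) {
    expect_true(all(abs(opm@muA[, , i] - props$mua[i]) < gA))
    expect_true(all(abs(opm@muSp[, , i] - props$musp[i]) < gS))
  }
})

test_that("noiseless single-layer truth is recovered at every wavelength", {
  # ground-truth recoverability: a dermis-only (single-layer) scene rendered
  # without noise inverts back to the generating coefficients; the scene
  # must lie inside the LUT domain (muSp <= 4), so use mid-range locations
  # whose 471 nm dermal scattering cannot reach the ceiling
  lut <- sharedLUT()
  spec <- cohortSpec(nSubjects = 2L, locations = c("neck", "shin"),
                     wavelengths = c(471, 659, 851), imageSize = 4L,
                     noiseLevel = 0, seed = 21L)
  co <- synthesizeCohort(spec)
  tr <- cohortTruth(co)
  ph <- renderPhantom(defaultPhantom(spec@wavelengths), fx = spec@fx,
                      imageSize = 4L, noiseLevel = 0, seed = 2)
  refMod <- demodulate(ph$stack)
  gA <- diff(lut@muaAxis)[1]; gS <- diff(lut@muspAxis)[1]
  for (i in 1:2) for (loc in spec@locations) {
    rows <- tr[tr$subject == sprintf("S%02d", i) & tr$location == loc, ]
    models <- lapply(seq_len(nrow(rows)), function(r)
      tissueModel(Inf, rows$muaDermis[r], rows$muspDermis[r]))
    st <- renderAcquisition(models = lapply(models, list),
                            wavelengths = spec@wavelengths, fx = spec@fx,
                            imageSize = 4L, noiseLevel = 0, seed = 3)
    rs <- calibrate(demodulate(st), refMod, ph$predictedRd)
    opm <- invertMap(rs, lut)
    for (r in seq_len(nrow(rows))) {
      expect_true(all(abs(opm@muSp[, , r] - rows$muspDermis[r]) < gS))
      expect_true(all(abs(opm@muA[, , r] - rows$muaDermis[r]) < gA))
    }
  }
})
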