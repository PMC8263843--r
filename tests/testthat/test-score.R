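test_that("the default rubric encodes the modality asymmetry", {
  r <- defaultRubric()
  expect_identical(scoreCD("A1", "DWI", r), 10)
  expect_identical(scoreCD("A1", "ADC", r), 8)
  expect_identical(scoreCD("A2", "DWI", r), 8)
  expect_identical(scoreCD("A2", "ADC", r), 10)
  expect_identical(scoreCD("EXACT", "DWI", r), 10)
  expect_identical(scoreCD("EXACT", "ADC", r), 10)
  expect_identical(scoreCD("NONE", "DWI", r), 0)
  expect_error(scoreCD("A9", "DWI", r), "condition")
  expect_error(defaultRubric(unmatchedScore = 12), "\\[0, 10\\]")
  expect_error(defaultRubric(tau = 0.3), "tau")
})

test_that("label scores average CDs with unmatched components penalized", {
  mk <- function(conditions)
    data.frame(label = 1L, condition = conditions, stringsAsFactors = FALSE)
  expect_equal(scoreLabel(mk(c("A1", "A2")), "DWI"), 9)     # (10 + 8) / 2
  expect_equal(scoreLabel(mk(c("EXACT", "NONE")), "DWI"), 5)
  expect_equal(scoreLabel(mk(c("NONE", "NONE")), "ADC"), 0)
  expect_true(is.na(scoreLabel(data.frame(label = integer(0),
                                          condition = character(0)), "DWI")))
  expect_error(scoreLabel(data.frame(label = c(1L, 2L),
                                     condition = c("A1", "A1")), "DWI"),
               "one label")
})

test_that("patient scores aggregate label scores", {
  expect_equal(scorePatient(c(8, 10)), 9)
  expect_equal(scorePatient(7.5), 7.5)
  expect_equal(scorePatient(rep(10, 8)), 10)
  expect_equal(scorePatient(c(NA, 6, 8)), 7)
  expect_error(scorePatient(NA_real_), "no scored labels")
})

test_that("score reports reproduce the canonical perturbation patterns", {
  lab <- deskPhantom(seed = 12)
  perfectD <- scoreReport(lab, lab, "DWI")
  perfectA <- scoreReport(lab, lab, "ADC")
  expect_equal(perfectD@patientScore, 10)
  expect_equal(perfectA@patientScore, 10)
  expect_true(all(perfectD@dscPerLabel == 1))

  dil <- perturbSegmentation(lab, perturbSpec("dilate", 1))
  expect_equal(scoreReport(dil, lab, "DWI")@patientScore, 10)
  expect_equal(scoreReport(dil, lab, "ADC")@patientScore, 8)

  ero <- perturbSegmentation(lab, perturbSpec("erode", 1))
  expect_equal(scoreReport(ero, lab, "DWI")@patientScore, 8)
  expect_equal(scoreReport(ero, lab, "ADC")@patientScore, 10)

  expect_error(scoreReport(lab, deskPhantom(seed = 12,
    dim = c(32, 64, 68))), "geometry")
})

test_that("swapping modality swaps the A1/A2 contributions exactly", {
  lab <- deskPhantom(seed = 15)
  # mixed degradation: dilate the midline bones, erode the femoral heads
  p <- perturbSegmentation(lab, perturbSpec("dilate", 1, target = list(label = 1)))
  p <- perturbSegmentation(p, perturbSpec("dilate", 1, target = list(label = 2)))
  p <- perturbSegmentation(p, perturbSpec("erode", 1, target = list(label = 5)))
  d <- scoreReport(p, lab, "DWI")
  a <- scoreReport(p, lab, "ADC")
  expect_equal(unname(d@labelScores[c("1", "2")]), c(10, 10))
  expect_equal(unname(a@labelScores[c("1", "2")]), c(8, 8))
  expect_equal(unname(d@labelScores["5"]), 8)
  expect_equal(unname(a@labelScores["5"]), 10)
  # untouched labels are EXACT on both modalities
  expect_equal(unname(d@labelScores[c("3", "4", "6", "7", "8")]), rep(10, 5))
  # patient scores are dual because every condition is EXACT, A1 or A2
  expect_equal(d@patientScore + a@patientScore,
               2 * mean(c(10, 10, 10, 10, 10, 9, 9, 9)))
})

test_that("dropping CDs monotonically degrades the patient score", {
  lab <- deskPhantom(seed = 18)
  s0 <- scoreReport(lab, lab, "DWI")@patientScore
  p1 <- perturbSegmentation(lab, perturbSpec("drop_cd",
    target = list(label = 3, component_id = 1)))
  s1 <- scoreReport(p1, lab, "DWI")@patientScore
  p2 <- perturbSegmentation(p1, perturbSpec("drop_cd",
    target = list(label = 5, component_id = 1)))
  s2 <- scoreReport(p2, lab, "DWI")@patientScore
  expect_lt(s1, s0)
  expect_lt(s2, s1)
  # patient score stays within the label score range
  rep2 <- scoreReport(p2, lab, "DWI")
  expect_gte(rep2@patientScore, min(rep2@labelScores))
  expect_lte(rep2@patientScore, max(rep2@labelScores))
})

test_that("spurious predictions enter the label denominator", {
  lab <- deskPhantom(seed = 19)
  sp <- perturbSegmentation(lab, perturbSpec("add_spurious", 2,
    target = list(label = 1), seed = 4))
  r <- scoreReport(sp, lab, "DWI")
  # label 1: one EXACT CD (10) + one spurious NONE (0) -> 5
  expect_equal(unname(r@labelScores["1"]), 5)
  expect_equal(unname(r@labelScores["2"]), 10)
})

test_that("the optional DSC floor caps affected labels only", {
  lab <- deskPhantom(seed = 20)
  ero <- perturbSegmentation(lab, perturbSpec("erode", 1))
  base <- scoreReport(ero, lab, "DWI")
  floored <- scoreReport(ero, lab, "DWI",
                         rubric = defaultRubric(dscFloor = 1.01, cap = 3))
  expect_true(all(floored@labelScores <= 3))
  expect_true(all(base@labelScores == 8))
})

test_that("rubrics and score reports survive their JSON/CSV round trips", {
  tf <- withr::local_tempfile(fileext = ".json")
  r <- defaultRubric(unmatchedScore = 1, tau = 0.9, strict = TRUE)
  writeRubricJSON(r, tf)
  back <- readRubricJSON(tf)
  expect_identical(back@table, r@table)
  expect_identical(back@unmatchedScore, r@unmatchedScore)
  expect_identical(back@tau, r@tau)
  expect_identical(back@strict, r@strict)

  lab <- deskPhantom(seed = 1)
  rep <- scoreReport(lab, lab, "ADC")
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  writeScoreReport(rep, csv, js)
  tab <- read.csv(csv)
  expect_identical(nrow(tab), 14L)
  agg <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(agg$patient_score, 10)
  expect_identical(agg$modality, "ADC")
})
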