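test_that("neutral-loss masses derive from formulas", {
  tab <- neutral_loss_table()
  expect_setequal(tab$label, c("H2O", "CO", "HCOOH", "C5H8O2"))
  for (i in seq_len(nrow(tab)))
    expect_equal(tab$mass[i], monoisotopic_mass(tab$formula[i]),
                 tolerance = 1e-6)
  expect_equal(neutral_loss_table("H2O")$mass, 18.010565, tolerance = 1e-6)
  expect_error(neutral_loss_table("SO2"), "unknown neutral loss")
})

test_that("loss series enumerates combinations and keeps known ions", {
  ls <- loss_series(471.3469, c("H2O", "CO"), max_depth = 2)
  hit <- ls[ls$label == "[M+H-H2O-CO]+", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$mz, 425.3414, tolerance = 1e-4 / 425)
  expect_equal(floor(hit$mz), 425) # the nominal ion reported for ursanes

  single <- loss_series(471.3469, "H2O", max_depth = 1)
  expect_equal(nrow(single), 1L)
  expect_equal(single$mz, 453.3363, tolerance = 1e-4 / 453)

  # water + CO is isobaric with formic acid: parsimony keeps the single loss
  dedup <- loss_series(500, c("H2O", "CO", "HCOOH"), max_depth = 2)
  expect_true("[M+H-HCOOH]+" %in% dedup$label)
  expect_false("[M+H-H2O-CO]+" %in% dedup$label)
})

test_that("loss series size matches the multiset enumeration oracle", {
  masses <- neutral_loss_table()$mass
  for (d in 1:4) {
    got <- loss_series(600, max_depth = d)
    expect_equal(nrow(got), oracle_loss_count(masses, d, 600),
                 label = sprintf("depth %d", d))
  }
  # scan-floor exclusion, not an error
  low <- loss_series(60, "C5H8O2", max_depth = 2)
  expect_equal(nrow(low), 0L)
})

test_that("diagnostic ions follow the skeleton-class rules", {
  ole <- diagnostic_ions("oleanane")
  expect_true(all(c(249.1856, 203.1807, 191.1803) %in% ole$mz))
  expect_true(all(ole$rda))
  urs <- diagnostic_ions("ursane")
  expect_true(205 %in% urs$mz)
  expect_true(all(urs$nominal))
  lup <- diagnostic_ions("lupane")
  expect_true(all(c(191, 203) %in% lup$mz))
  expect_false(any(lup$rda)) # non-RDA pathways for saturated ring C
  fri <- diagnostic_ions("friedelane")
  expect_equal(nrow(fri), 0L)
  expect_true(isTRUE(attr(fri, "documented_gap")))
  expect_error(diagnostic_ions("steroid"), "unknown skeleton class")
})

test_that("annotation labels known fragments of the packaged spectra", {
  lib <- fixture_library()
  ile <- lib$records[["Ilelatifol D"]]
  ann <- annotate_spectrum(ile$spectra[[1]], ile)
  lab <- ann$label[abs(ann$mz - 425.3414) < 1e-3]
  expect_match(lab, "-H2O-CO|HCOOH") # isobaric explanations
  expect_true(all(is.na(ann$delta) | abs(ann$delta) <= 0.5 + 1e-9))

  lan <- lib$records[["Lantanilic acid"]]
  ann_na <- annotate_spectrum(lan$spectra[[1]], lan)
  # sodium-adduct loss of C5H8O2, reported at 491.3195, annotated at the
  # default 0.01 Da tolerance; the HCOOH-loss peak deviates by 0.011 Da and
  # needs a wider setting
  expect_equal(ann_na$label[abs(ann_na$mz - 491.3195) < 1e-3],
               "[M+Na-C5H8O2]+")
  expect_true(is.na(ann_na$label[abs(ann_na$mz - 545.3714) < 1e-3]))
  ann_wide <- annotate_spectrum(lan$spectra[[1]], lan, tol = 0.012)
  expect_match(ann_wide$label[abs(ann_wide$mz - 545.3714) < 1e-3], "HCOOH")
})

test_that("planted ions are recovered and decoys left unlabeled", {
  set.seed(7)
  prec <- adduct_mz("C34H54O4", "[M+H]+")
  theo <- loss_series(prec, max_depth = 2)
  planted <- theo$mz
  repeat {
    decoys <- runif(5, 60, prec - 5)
    d <- vapply(decoys, function(x)
      min(abs(x - c(planted, diagnostic_ions("oleanane")$mz))), numeric(1))
    if (all(d > 1)) break
  }
  mz <- c(planted, decoys)
  s <- new_spectrum(mz, rep(100, length(mz)), precursor_mz = prec,
                    adduct = "[M+H]+")
  ann <- annotate_spectrum(s, skeleton_class = "oleanane", tol = 0.01)
  is_planted <- vapply(ann$mz, function(x)
    min(abs(x - planted)) < 1e-9, logical(1))
  expect_true(all(!is.na(ann$label[is_planted])))
  expect_true(all(is.na(ann$label[!is_planted])))
  # brute-force nearest-ion oracle agrees on every assigned theoretical m/z
  for (i in which(is_planted)) {
    expect_equal(ann$theoretical_mz[i],
                 theo$mz[which.min(abs(theo$mz - ann$mz[i]))],
                 tolerance = 1e-12)
  }
})

test_that("annotation is stable under peak-order permutation", {
  set.seed(8)
  prec <- 471.3469
  mz <- c(453.3363, 425.3414, 403.0, 207.7)
  perm <- sample(length(mz))
  a1 <- annotate_spectrum(new_spectrum(mz, rep(1, 4), precursor_mz = prec),
                          skeleton_class = "ursane")
  a2 <- annotate_spectrum(new_spectrum(mz[perm], rep(1, 4),
                                       precursor_mz = prec),
                          skeleton_class = "ursane")
  expect_equal(a1, a2)
  empty <- annotate_spectrum(new_spectrum(numeric(0), numeric(0),
                                          precursor_mz = prec),
                             skeleton_class = "ursane")
  expect_equal(nrow(empty), 0L)
})
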