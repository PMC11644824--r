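test_that("the packaged standards build into a 43-record library", {
  expect_warning(lib <- build_library(triterpenoid_standards(),
                                      spectra = reference_spectra()),
                 "Oleanoic acid")
  expect_s3_class(lib, "spectral_library")
  expect_length(lib, 43L)
  expect_true("calc_inconsistent" %in% lib$records[["Oleanoic acid"]]$flags)
  # curated class column (input metadata, not computed from structures)
  cls <- vapply(lib$records, `[[`, character(1), "skeleton_class")
  expect_equal(as.vector(table(cls)[c("oleanane", "ursane", "lupane",
                                      "friedelane", "limonoid", "other")]),
               c(18L, 13L, 6L, 1L, 4L, 1L))
  # sodium adducts are available for every record (inferred where unobserved)
  expect_true(all(vapply(lib$records, function(r)
    all(c("[M+H]+", "[M+Na]+") %in% r$adducts$adduct), logical(1))))
  expect_false(
    lib$records[["beta-Neriursate"]]$adducts$observed[
      lib$records[["beta-Neriursate"]]$adducts$adduct == "[M+Na]+"])
})

test_that("build_library rejects duplicates and bad formulas by row", {
  tab <- data.frame(name = c("a", "a"), formula = "C10H16",
                    logp = 1, rt = 5, adduct = "[M+H]+")
  expect_error(build_library(tab), "duplicate")
  tab2 <- data.frame(name = "bad", formula = "C10Qx", logp = 1, rt = 5,
                     adduct = "[M+H]+")
  expect_error(build_library(tab2), "bad")
})

test_that("an empty spectra list yields a usable MS1-only library", {
  lib <- triterpenoid_library(spectra = FALSE, quiet = TRUE)
  expect_true(all(vapply(lib$records, function(r) length(r$spectra) == 0,
                         logical(1))))
  hits <- match_precursor(471.3469, lib, 0.005)
  expect_gte(nrow(hits), 3)
})

test_that("MSP and MGF writers honour their format contracts", {
  rec <- library_record("demo", "C30H48O3", rt = 10.5,
                        adducts = data.frame(adduct = "[M+H]+",
                                             calc_mz = adduct_mz("C30H48O3"),
                                             meas_mz = NA, observed = TRUE),
                        spectra = list(new_spectrum(
                          c(191.18, 203.18, 409.35), c(10, 20, 30),
                          precursor_mz = adduct_mz("C30H48O3"),
                          adduct = "[M+H]+", collision_energy = "20")))
  lib <- spectral_library(list(rec))
  msp <- tempfile(fileext = ".msp")
  write_library(lib, msp, "msp")
  expect_true(any(grepl("^Num Peaks: 3$", readLines(msp))))
  mgf <- tempfile(fileext = ".mgf")
  write_library(lib, mgf, "mgf")
  pep <- grep("^PEPMASS=", readLines(mgf), value = TRUE)
  expect_equal(as.numeric(sub("PEPMASS=", "", pep)),
               round_half_away(rec$adducts$calc_mz[1], 4))
  expect_error(write_library(lib, tempfile(), "library"))
})

test_that("MSP import tolerates missing fields and rejects corrupt files", {
  txt <- c("Name: partial", "PrecursorMZ: 455.3520", "Num Peaks: 2",
           "191.18 10", "203.18 5", "")
  f <- tempfile(fileext = ".msp")
  writeLines(txt, f)
  lib <- read_library(f, "msp")
  expect_true(is.na(lib$records[["partial"]]$rt))
  # still usable for mass-only matching
  expect_equal(nrow(match_precursor(455.3520, lib, 0.005)), 1L)

  writeLines(txt[1:4], f) # truncated peak list
  expect_error(read_library(f, "msp"), "truncated")
  writeLines(c(txt[1:3], "191.18 10", "203.18 5", "205.00 7", ""), f)
  expect_error(read_library(f, "msp"), "more peak lines")
  writeLines(c("Name: x", "Num Peaks: 1", "oops not numbers", ""), f)
  expect_error(read_library(f, "msp"), "malformed peak line")
})

test_that("archive round-trip is lossless for the fixture and random libraries", {
  lib <- fixture_library()
  f <- tempfile(fileext = ".json")
  write_library(lib, f, "archive")
  expect_true(isTRUE(all.equal(read_library(f, "archive"), lib,
                               tolerance = 0)))
  expect_error(read_library(tempfile(fileext = ".json"), "archive"),
               "not found")
  writeLines('{"format": "something-else"}', f)
  expect_error(read_library(f, "archive"), "not a triterpenlib archive")

  set.seed(202)
  for (i in 1:100) {
    rl <- rand_library()
    write_library(rl, f, "archive")
    expect_true(isTRUE(all.equal(read_library(f, "archive"), rl,
                                 tolerance = 0)))
  }
})

test_that("consensus merging matches a brute-force clustering oracle", {
  set.seed(5)
  s <- rand_spectrum(500, n = 5)
  expect_equal(consensus_spectrum(list(s), 0.005)$peaks$mz, s$peaks$mz,
               tolerance = 1e-12)

  a <- new_spectrum(c(425.341, 300.10), c(100, 50), precursor_mz = 471.3469)
  b <- new_spectrum(c(425.343, 180.05), c(400, 20), precursor_mz = 471.3469)
  cons <- consensus_spectrum(list(a, b), 0.005)
  expect_equal(nrow(cons$peaks), 3L)
  merged <- cons$peaks[abs(cons$peaks$mz - 425.342) < 0.01, ]
  expect_equal(merged$intensity, 400) # max across energies
  expect_equal(merged$mz, (425.341 * 100 + 425.343 * 400) / 500,
               tolerance = 1e-9)

  expect_error(consensus_spectrum(list(
    new_spectrum(100, 1, precursor_mz = 400),
    new_spectrum(100, 1, precursor_mz = 401)), 0.005), "precursor")

  # multi-CE spectra from the simulator, peak count vs all-pairs oracle
  lib <- fixture_library()
  run <- simulate_run(spectral_library(lib$records[8:10]),
                      noise = noise_spec(decoy_components = 0), seed = 1)
  ev_one <- run$events[!run$events$decoy, ]
  comp1 <- ev_one$component[1]
  sp <- run$spectra[ev_one$event[ev_one$component == comp1]][1:4]
  sp <- sp[!vapply(sp, is.null, logical(1))]
  cons2 <- consensus_spectrum(sp, 0.005)
  pooled <- unlist(lapply(sp, function(x) x$peaks$mz))
  expect_equal(nrow(cons2$peaks), oracle_cluster_count(pooled, 0.005))

  # idempotence
  again <- consensus_spectrum(list(cons2), 0.005)
  expect_equal(again$peaks, cons2$peaks, tolerance = 1e-12)
})
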