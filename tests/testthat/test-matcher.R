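test_that("precursor candidates match the brute-force scan", {
  lib <- fixture_library()
  hits <- match_precursor(471.3469, lib, 0.005)
  # four standards share C30H46O4 [M+H]+
  expect_gte(sum(hits$adduct == "[M+H]+"), 4)
  expect_true(all(c("11-Oxooleanolic acid", "Ilelatifol D",
                    "Glycyrrhetic acid", "Atriplicin") %in% hits$name))
  expect_equal(nrow(match_precursor(1000.0, lib, 0.005)), 0L)

  set.seed(303)
  for (q in runif(200, 100, 700)) {
    got <- sort(paste(match_precursor(q, lib, 0.005)$name,
                      match_precursor(q, lib, 0.005)$adduct))
    expect_identical(got, oracle_candidates(q, lib, 0.005))
  }
})

test_that("feature matching assigns levels and reproduces the harmala hit", {
  lib <- fixture_library()
  q <- plant_extract_queries()
  res <- match_feature(q[q$source == "Peganum harmala", ], lib)
  expect_equal(res$compound[1], "beta-Neriursate")
  expect_equal(res$level[1], 1L)
  expect_equal(res$rt_drift[1], 10.53 - 10.35, tolerance = 1e-9)
  expect_equal(round_half_away(abs(res$rt_drift[1]), 1), 0.2)

  # outside the RT window the same feature cannot reach level 1
  far <- q[q$source == "Peganum harmala", ]
  far$rt <- far$rt + 10
  res_far <- match_feature(far, lib)
  expect_true(all(res_far$level != 1L))

  # score bounds; score 1 when the query fragments are the consensus peaks
  silymin <- lib$records[["Silymin A"]]
  full <- list(source = "x", rt = 9.9, precursor_mz = 507.3081,
               adduct = "[M+Na]+",
               fragments = silymin$spectra[[1]]$peaks$mz)
  res_full <- match_feature(full, lib)
  expect_equal(res_full$score[res_full$compound == "Silymin A"], 1)
  expect_true(all(res_full$score >= 0 & res_full$score <= 1))
})

test_that("planted features are recovered and decoys rejected", {
  set.seed(11)
  lib <- fixture_library()
  picks <- names(lib$records)[seq(1, 40, length.out = 10)]
  libT <- add_theoretical_spectra(lib)
  feats <- do.call(rbind, lapply(picks, function(nm) {
    r <- libT$records[[nm]]
    sp <- r$spectra[[1]]
    data.frame(source = nm, rt = r$rt + rnorm(1, 0, 0.1),
               precursor_mz = r$adducts$calc_mz[1] + rnorm(1, 0, 0.001),
               adduct = r$adducts$adduct[1],
               fragments = paste(sprintf("%.4f",
                 sp$peaks$mz + rnorm(nrow(sp$peaks), 0, 0.001)),
                 collapse = ";"))
  }))
  rep1 <- screen_run(feats, libT)
  expect_equal(rep1$summary$n_level1, 10L)
  # the planted compound reaches level 1 for its own feature (isobaric
  # standards with close RT may legitimately tie at the top rank)
  for (k in seq_along(picks)) {
    res <- match_feature(feats[k, ], libT)
    expect_true(any(res$compound == picks[k] & res$level == 1L))
  }

  # decoy precursors > 3x tolerance from every library adduct
  idx <- adduct_index(libT)
  decoys <- c()
  while (length(decoys) < 50) {
    x <- runif(1, 100, 700)
    if (min(abs(x - idx$calc_mz)) > 3 * 0.005) decoys <- c(decoys, x)
  }
  dq <- data.frame(source = "decoy", rt = runif(50, 1, 13),
                   precursor_mz = decoys, adduct = NA,
                   fragments = "100.1;200.2")
  rep2 <- screen_run(dq, libT)
  expect_equal(rep2$summary$n_level1, 0L)
  expect_equal(rep2$summary$n_assigned, 0L)
})

test_that("level-1 recall is complete at small jitter over repeated draws", {
  lib <- add_theoretical_spectra(fixture_library())
  picks <- names(lib$records)[1:8]
  tol <- match_parameters()
  for (seed in 1:20) {
    set.seed(seed)
    feats <- do.call(rbind, lapply(picks, function(nm) {
      r <- lib$records[[nm]]
      sp <- r$spectra[[1]]
      data.frame(source = nm,
                 rt = r$rt + runif(1, -tol$rt_window / 2, tol$rt_window / 2),
                 precursor_mz = r$adducts$calc_mz[1] +
                   runif(1, -tol$precursor_tol / 3, tol$precursor_tol / 3),
                 adduct = r$adducts$adduct[1],
                 fragments = paste(sprintf("%.5f", sp$peaks$mz),
                                   collapse = ";"))
    }))
    rep <- screen_run(feats, lib)
    expect_gte(rep$summary$n_level1 / length(picks), 1 - 1e-9)
  }
})

test_that("enlarging tolerance windows never removes a level-1 hit", {
  lib <- fixture_library()
  q <- plant_extract_queries()
  base <- screen_run(q, lib, match_parameters())
  wide <- screen_run(q, lib, match_parameters(precursor_tol = 0.01,
                                              rt_window = 1.0))
  lv1 <- function(r) with(r$assignments[r$assignments$level == 1, ],
                          paste(source, compound))
  expect_true(all(lv1(base) %in% lv1(wide)))
})

test_that("screening the extract panel identifies three compounds", {
  lib <- fixture_library()
  q <- plant_extract_queries()
  rep <- screen_run(q, lib)
  expect_equal(rep$summary$n_compounds, 3L)
  expect_setequal(rep$summary$compounds,
                  c("beta-Neriursate", "Butyl ester of glycyrrhetinic acid",
                    "Silymin A"))
  expect_equal(rep$summary$max_rt_drift, 0.41)
  # every Table-level expectation maps to its parent standard
  expect_identical(rep$assignments$compound, q$expected_compound)

  empty <- screen_run(q[0, ], lib)
  expect_equal(empty$summary$n_compounds, 0L)
  expect_equal(empty$summary$n_features, 0L)

  doubled <- screen_run(rbind(q, q), lib)
  expect_equal(doubled$summary$n_compounds, rep$summary$n_compounds)
})
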