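test_that("relative error uses the observed-value denominator and the
           conventional reporting precision", {
  expect_equal(format_relative_error(relative_error(474, 472)), 0.4)
  expect_equal(format_relative_error(relative_error(595, 586)), 1.5)
  expect_equal(format_relative_error(relative_error(2.71, 5.03)), 46)
  expect_equal(relative_error(100, 100), 0)
  expect_error(relative_error(100, 0), "> 0")
  expect_error(relative_error(100, -3), "> 0")
})

test_that("m/z-only matching hits every isobaric candidate", {
  feats <- example_features()
  lib <- example_library("uplc")

  expect_equal(nrow(match_mz(feats[0, ], lib)), 0L)
  expect_equal(nrow(match_mz(feats, lib[0, ])), 0L)

  # one hydroxybenzoate feature, three C7H6O3 isomers
  hba <- match_mz(feats[feats$feature_id == "F04", ], lib)
  expect_equal(nrow(hba), 3L)
  expect_setequal(hba$compound_id,
                  c("4-hydroxybenzoic acid", "3-hydroxybenzoic acid",
                    "salicylic acid"))
  expect_true(all(abs(hba$delta_mz) <= 0.005))
})

test_that("tolerance boundaries are inclusive and symmetric", {
  lib <- data.frame(compound_id = "C", adduct = "[M+H]+", polarity = "pos",
                    mz = 200.0, mean_ri = 500)
  at_tol <- data.frame(feature_id = c("up", "down"),
                       mz = c(200.005, 199.995), polarity = "pos",
                       ri = c(510, 490))
  expect_equal(nrow(match_mz(at_tol, lib, mz_tol = 0.005)), 2L)
  expect_equal(nrow(match_mz_ri(at_tol, lib, ri_tol = 10)), 2L)
})

test_that("RI filtering reduces the isomer ambiguity to a single hit", {
  feats <- example_features()
  lib <- example_library("uplc")
  f04 <- feats[feats$feature_id == "F04", ]

  hits <- match_mz_ri(f04, lib, mz_tol = 0.005, ri_tol = 10)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$compound_id, "4-hydroxybenzoic acid")
  expect_equal(abs(hits$delta_ri), 2)

  # candidates at RI 561 sit 48 units away and are excluded
  all_hits <- match_mz(f04, lib)
  expect_true(any(abs(all_hits$delta_ri) == 48))

  # removing the filter reproduces m/z-only matching
  loose <- match_mz_ri(f04, lib, ri_tol = 1e9)
  expect_equal(nrow(loose), nrow(all_hits))
})

test_that("features without an index are skipped with a warning", {
  lib <- example_library("uplc")
  f <- example_features()[4, ]
  f$ri <- NA_real_
  expect_warning(hits <- match_mz_ri(f, lib), "without retention index")
  expect_equal(nrow(hits), 0L)
})

test_that("combined matching is a subset of m/z matching and shrinking
           tolerances never adds hits", {
  feats <- example_features()
  lib <- rbind(example_library("uplc"), example_library("hplc"))
  key <- function(h) paste(h$feature_id, h$compound_id, h$adduct, h$delta_ri)
  h_mz <- match_mz(feats, lib)
  h_both <- match_mz_ri(feats, lib)
  expect_true(all(key(h_both) %in% key(h_mz)))
  for (tol in c(20, 10, 5, 2)) {
    h_tight <- match_mz_ri(feats, lib, ri_tol = tol)
    expect_true(all(key(h_tight) %in% key(h_both)) || tol > 10)
    expect_lte(nrow(h_tight), nrow(match_mz_ri(feats, lib, ri_tol = tol * 2)))
  }
})

test_that("ppm and Da tolerances are mutually exclusive", {
  feats <- example_features()
  lib <- example_library("uplc")
  expect_error(match_mz(feats, lib, mz_tol = 0.005, ppm = 5), "not both")
  h <- match_mz(feats, lib, mz_tol = NULL, ppm = 40)
  expect_gt(nrow(h), 0L)
})

test_that("on simulated ground truth the RI filter removes decoys but never
           the true identity", {
  runs <- simulate_standard_runs(replicates = 3, seed = 5)
  lib <- build_ri_library(runs, method = "linear", policy = "average")
  lib$mz <- NA_real_
  # candidate m/z from the panel the runs were generated from
  panel <- attr(runs, "panel")
  if (is.null(panel)) {
    set.seed(5); panel <- simulate_analyte_panel()
  }
  lib$mz <- panel$mz[match(lib$compound_id, panel$compound_id)]
  lib <- lib[lib$usable, ]

  # decoys: same m/z, index shifted by +50
  decoys <- lib
  decoys$compound_id <- paste0(lib$compound_id, "_decoy")
  decoys$mean_ri <- lib$mean_ri + 50
  lib_with_decoys <- rbind(lib, decoys)

  # a fresh indexed run of the same panel
  sys <- reference_system()
  set.seed(99)
  run <- simulate_run(panel, sys)
  naps <- simulate_naps_series(sys)
  cal <- ri_calibration(make_anchors(naps, naps), method = "linear")
  run$ri <- rt_to_ri(cal, run$rt_min)$ri
  run <- run[run$ri > 300 & run$compound_id %in% lib$compound_id, ]
  feats <- data.frame(feature_id = run$feature_id, mz = run$mz,
                      polarity = run$polarity, ri = run$ri,
                      rt_min = run$rt_min)

  h_mz <- match_mz(feats, lib_with_decoys)
  h_ri <- match_mz_ri(feats, lib_with_decoys, ri_tol = 10)
  truth <- run$compound_id[match(h_ri$feature_id, run$feature_id)]
  # precision strictly increases and every retained hit is the truth
  prec_mz <- mean(!grepl("_decoy", h_mz$compound_id))
  expect_true(all(h_ri$compound_id == truth))
  expect_gt(nrow(h_mz), nrow(h_ri))
  expect_gt(mean(!grepl("_decoy", h_ri$compound_id)), prec_mz)
  # and no true identity was lost relative to m/z matching
  true_mz <- h_mz[!grepl("_decoy", h_mz$compound_id), ]
  expect_equal(nrow(h_ri), nrow(true_mz))
})
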