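test_that("pairing identical runs self-pairs every feature at 100%", {
  run <- data.frame(mz = c(150.1, 300.2, 450.3), rt_min = c(1, 5, 9),
                    intensity = c(1e5, 2e5, 3e5))
  p <- pair_runs(run, run)
  expect_equal(nrow(p$pairs), 3L)
  expect_equal(p$pairs$intensity_spiked, p$pairs$intensity_unspiked)
  expect_equal(nrow(p$unpaired_spiked), 0L)

  shifted <- run; shifted$mz <- run$mz + 1
  expect_equal(nrow(pair_runs(shifted, run)$pairs), 0L)
})

test_that("greedy pairing is one-to-one and prefers the closer m/z", {
  unspiked <- data.frame(mz = c(200.000, 200.004), rt_min = c(5, 5),
                         intensity = c(1, 2))
  spiked <- data.frame(mz = 200.001, rt_min = 5, intensity = 10)
  p <- pair_runs(spiked, unspiked)
  expect_equal(nrow(p$pairs), 1L)
  expect_equal(p$pairs$intensity_unspiked, 1)  # nearer m/z wins
  expect_equal(nrow(p$unpaired_unspiked), 1L)
})

test_that("evaluation windows exclude the void-volume homologues", {
  apexes <- data.frame(n_carbons = 1:6, rt_min = c(0.7, 0.71, 0.72, 0.76,
                                                   0.88, 1.26))
  w <- suppression_windows(apexes)
  expect_equal(w$ri, c(400, 500, 600))
  expect_true(all(w$half_width == 0.20))
})

test_that("profiles report percent-of-unspiked with inclusive window
           membership", {
  pairs <- data.frame(mz = c(100, 101, 102, 103),
                      rt_min = c(5.0, 5.20, 5.25, 4.85),
                      intensity_spiked = c(50, 100, 100, 0),
                      intensity_unspiked = c(100, 100, 100, 0))
  windows <- data.frame(ri = 1000, apex_rt = 5.0, half_width = 0.20)
  prof <- suppression_profile(pairs, windows)
  # 5.25 is outside the window; the zero-unspiked pair is undefined
  expect_equal(nrow(prof), 3L)
  expect_equal(prof$pct_of_unspiked[prof$mz == 100], 50)
  expect_equal(prof$pct_of_unspiked[prof$mz == 101], 100)  # edge inclusive
  expect_true(prof$undefined[prof$mz == 103])
  expect_true(all(abs(prof$delta_rt_to_apex) <= 0.20 + 1e-9))
})

test_that("a feature inside two overlapping windows goes to the nearer
           apex and pct is scale-invariant", {
  pairs <- data.frame(mz = 100, rt_min = 5.1, intensity_spiked = 30,
                      intensity_unspiked = 60)
  windows <- data.frame(ri = c(800, 900), apex_rt = c(5.0, 5.15),
                        half_width = c(0.2, 0.2))
  prof <- suppression_profile(pairs, windows)
  expect_equal(prof$window_ri, 900)

  scaled <- pairs
  scaled$intensity_spiked <- pairs$intensity_spiked * 1e3
  scaled$intensity_unspiked <- pairs$intensity_unspiked * 1e3
  expect_equal(suppression_profile(scaled, windows)$pct_of_unspiked,
               prof$pct_of_unspiked)
})

test_that("shrinking the window half-width never adds results", {
  ex <- simulate_suppression_experiment(seed = 2, n_features = 300)
  p <- pair_runs(ex$spiked[["1:20"]], ex$unspiked)
  wide <- suppression_profile(p$pairs, suppression_windows(ex$naps_apexes,
                                                           0.20))
  narrow <- suppression_profile(p$pairs, suppression_windows(ex$naps_apexes,
                                                             0.10))
  expect_lte(nrow(narrow), nrow(wide))
  expect_true(all(narrow$mz %in% wide$mz))
})

test_that("generator-imposed suppression is recovered: minima at apexes and
           medians increasing with dilution", {
  ex <- simulate_suppression_experiment(seed = 4)
  wins <- suppression_windows(ex$naps_apexes)
  profs <- lapply(names(ex$spiked), function(d) {
    p <- pair_runs(ex$spiked[[d]], ex$unspiked)
    suppression_profile(p$pairs, wins, dilution = d)
  })
  names(profs) <- names(ex$spiked)

  tr <- dilution_trend(profs)
  expect_true(all(tr$monotone_increasing, na.rm = TRUE))

  # pooled over windows, the binned median pct is lowest adjacent to the apex
  p20 <- profs[["1:20"]]
  bins <- cut(p20$delta_rt_to_apex, breaks = seq(-0.2, 0.2, by = 0.04))
  med <- tapply(p20$pct_of_unspiked, bins, stats::median, na.rm = TRUE)
  centers <- seq(-0.18, 0.18, by = 0.04)
  expect_lte(abs(centers[which.min(med)]), 0.04)

  # apex suppression depth matches the imposed kernel (50% at 1:20)
  near_apex <- p20$pct_of_unspiked[abs(p20$delta_rt_to_apex) < 0.02]
  expect_lt(abs(stats::median(near_apex) - 50), 10)
})

test_that("dilution summaries flag missing cells instead of guessing", {
  prof <- data.frame(mz = 1, rt_min = 5, window_ri = 1500, apex_rt = 5,
                     delta_rt_to_apex = 0, pct_of_unspiked = 80,
                     undefined = FALSE, dilution = "1:20")
  prof2 <- prof; prof2$dilution <- "1:40"; prof2$window_ri <- 1600
  tr <- dilution_trend(rbind(prof, prof2))
  expect_true(any(is.na(tr$medians$median_pct)))
  expect_true(all(is.na(tr$monotone_increasing)))
})
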