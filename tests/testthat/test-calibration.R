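test_that("bracketing policies average, before and after behave as stated", {
  before <- data.frame(n_carbons = 4:6, rt_min = c(4.0, 5.0, 6.5))
  after <- data.frame(n_carbons = 4:6, rt_min = c(4.2, 5.1, 6.7))

  avg <- make_anchors(before, after, policy = "average")
  expect_equal(avg$rt, c(4.1, 5.05, 6.6))
  expect_equal(avg$ri, c(400, 500, 600))

  expect_equal(make_anchors(before, policy = "before")$rt, before$rt_min)
  expect_equal(make_anchors(before, after, policy = "after")$rt,
               after$rt_min)
  # average of identical runs is the run itself
  expect_equal(make_anchors(before, before, policy = "average")$rt,
               before$rt_min)

  expect_error(make_anchors(before, policy = "average"), "both bracketing")
  bad_after <- data.frame(n_carbons = c(4, 5, 7), rt_min = c(4.2, 5.1, 6.7))
  expect_error(make_anchors(before, bad_after, policy = "average"),
               "different homologues")
})

test_that("near-coeluting anchors collapse to the highest homologue", {
  run <- data.frame(n_carbons = 1:5,
                    rt_min = c(0.700, 0.703, 0.706, 0.95, 1.4))
  a <- make_anchors(run, policy = "before")
  expect_equal(a$n, c(3, 4, 5))          # C1 and C2 folded into C3
  expect_equal(a$rt[1], 0.706)

  # small jitter-induced inversions inside the gap are tolerated
  inv <- data.frame(n_carbons = 1:4, rt_min = c(0.705, 0.701, 0.95, 1.4))
  expect_equal(make_anchors(inv, policy = "before")$n, c(2, 3, 4))
  # larger inversions are a data error
  bad <- data.frame(n_carbons = 1:3, rt_min = c(1.0, 0.5, 2.0))
  expect_error(make_anchors(bad, policy = "before"), "decreases")
})

test_that("all three methods reproduce their anchors exactly", {
  anch <- naps_anchor_fixture()
  for (m in c("linear", "cubic", "akima")) {
    cal <- ri_calibration(anch, method = m)
    expect_equal(rt_to_ri(cal, anch$rt)$ri, anch$ri, tolerance = 1e-12,
                 info = m)
    expect_lt(max(abs(residuals(cal))), 1e-9)
  }
  expect_error(ri_calibration(anch[1, , drop = FALSE]), "at least 2")
  dup <- data.frame(ri = c(400, 500), rt = c(4, 4))
  expect_error(ri_calibration(dup), "strictly increasing")
})

test_that("collinear anchors give the same line for every method", {
  cmp <- compare_methods(collinear_anchors(), seq(4, 10, by = 0.05))
  expect_equal(cmp$ri_cubic, cmp$ri_linear, tolerance = 1e-9)
  expect_equal(cmp$ri_akima, cmp$ri_linear, tolerance = 1e-9)
  expect_equal(cmp$ri_linear, 100 * cmp$rt, tolerance = 1e-12)
})

test_that("linear conversion implements bracketing interpolation with
           flags instead of failures", {
  cal <- ri_calibration(data.frame(ri = c(400, 500), rt = c(4, 6)))
  out <- rt_to_ri(cal, c(4, 4.5, 5, 6))
  expect_equal(out$ri, c(400, 425, 450, 500))
  expect_false(any(out$extrapolated))
  expect_false(any(out$below_usable))

  ext <- rt_to_ri(cal, c(3, 7))
  expect_equal(ext$ri, c(350, 550))       # terminal-segment extension
  expect_true(all(ext$extrapolated))
  expect_false(any(ext$below_usable))     # 350 and 550 both above 300
})

test_that("below_usable marks indices at or below the C3 boundary", {
  cal <- ri_calibration(data.frame(ri = c(100, 1000), rt = c(1, 10)),
                        usable_ri_min = 300)
  out <- rt_to_ri(cal, c(2, 3, 4))        # RI 200, 300, 400
  expect_equal(out$below_usable, c(TRUE, TRUE, FALSE))
})

test_that("linear indexing is affine-invariant and monotone", {
  anch <- naps_anchor_fixture()
  cal <- ri_calibration(anch)
  set.seed(11)
  rts <- runif(25, min(anch$rt), max(anch$rt))
  ri0 <- rt_to_ri(cal, rts)$ri
  for (k in 1:100) {
    a <- runif(1, 0.2, 5); b <- runif(1, 0, 3)
    t_anch <- anch; t_anch$rt <- a * anch$rt + b
    ri1 <- rt_to_ri(ri_calibration(t_anch), a * rts + b)$ri
    expect_lt(max(abs(ri1 - ri0) / abs(ri0)), 1e-9)
  }
  ord <- order(rts)
  expect_true(all(diff(ri0[ord]) > 0))
})

test_that("rt -> ri -> rt round-trips within method tolerance where the
           interpolant is monotone", {
  anch <- naps_anchor_fixture()
  set.seed(7)
  # the cubic spline folds inside the compressed void-volume region (the
  # overshoot pathology), so inversion is only defined from C6 upward
  mono <- anch[anch$ri >= 600, ]
  rts <- runif(60, min(mono$rt), max(mono$rt))
  tol <- c(linear = 1e-6, cubic = 1e-4, akima = 1e-4)
  for (m in names(tol)) {
    cal <- ri_calibration(mono, method = m)
    back <- ri_to_rt(cal, rt_to_ri(cal, rts)$ri)
    expect_lt(max(abs(back - rts)), tol[[m]])
    # anchors invert exactly
    expect_equal(ri_to_rt(cal, mono$ri), mono$rt, tolerance = 1e-12)
  }
  # the linear method is invertible over the full anchor range
  cal_lin <- ri_calibration(anch)
  full <- runif(40, min(anch$rt), max(anch$rt))
  expect_lt(max(abs(ri_to_rt(cal_lin, rt_to_ri(cal_lin, full)$ri) - full)),
            1e-6)
})

test_that("inverse conversion rejects out-of-range and ambiguous queries", {
  cal <- ri_calibration(data.frame(ri = c(400, 500), rt = c(4, 6)))
  expect_error(ri_to_rt(cal, 700), "outside")
  expect_equal(ri_to_rt(cal, 450), 5)

  # a zig-zag anchor pattern makes the cubic spline non-monotone
  zig <- data.frame(ri = c(400, 500, 600, 700, 800),
                    rt = c(1, 1.05, 4, 4.05, 8))
  czig <- ri_calibration(zig, method = "cubic")
  expect_error(ri_to_rt(czig, 550), "segment")
})

test_that("overshoot of the cubic spline exceeds the Akima deviation in the
           compressed early region", {
  anch <- naps_anchor_fixture()
  early <- seq(min(anch$rt), anch$rt[anch$ri == 700], length.out = 400)
  cmp <- compare_methods(anch, early)
  dev_cubic <- max(abs(cmp$ri_cubic - cmp$ri_linear))
  dev_akima <- max(abs(cmp$ri_akima - cmp$ri_linear))
  expect_gt(dev_cubic, dev_akima)
  # at the anchors themselves all methods agree
  at_anchor <- compare_methods(anch, anch$rt)
  expect_equal(at_anchor$ri_cubic, at_anchor$ri_linear, tolerance = 1e-9)
  expect_equal(at_anchor$ri_akima, at_anchor$ri_linear, tolerance = 1e-9)
})

test_that("hand-rolled Akima interpolant agrees with an independent
           implementation away from the endpoints", {
  skip_if_not_installed("pracma")
  anch <- naps_anchor_fixture()
  cal <- ri_calibration(anch, method = "akima")
  grid <- seq(anch$rt[3], anch$rt[nrow(anch) - 2], length.out = 200)
  ours <- rt_to_ri(cal, grid)$ri
  ref <- pracma::akimaInterp(anch$rt, anch$ri, grid)
  expect_equal(ours, as.numeric(ref), tolerance = 1e-8)
})

test_that("calibrations serialise to JSON and back without changing the
           fit", {
  anch <- make_anchors(data.frame(n_carbons = 4:8,
                                  rt_min = c(1, 2.2, 3.1, 4.9, 7.0)),
                       policy = "before")
  cal <- ri_calibration(anch, method = "akima")
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(cal, path)
  cal2 <- read_calibration(path)
  expect_equal(cal2$method, "akima")
  expect_equal(cal2$policy, "before")
  grid <- seq(1, 7, by = 0.1)
  expect_equal(rt_to_ri(cal2, grid)$ri, rt_to_ri(cal, grid)$ri,
               tolerance = 1e-12)
})

test_that("model object methods report the fit", {
  cal <- ri_calibration(collinear_anchors(), method = "cubic")
  expect_equal(unname(coef(cal)[, "ri"]), collinear_anchors()$ri)
  expect_equal(fitted(cal), collinear_anchors()$ri, tolerance = 1e-9)
  p <- predict(cal, data.frame(rt_min = c(4.5, 5.5)))
  expect_equal(p$ri, c(450, 550), tolerance = 1e-9)
  expect_output(print(cal), "cubic")
  expect_output(print(summary(cal)), "anchors")
})
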