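test_that("single-delta spectra map to the expected window", {
  g <- make_t2_grid()
  s <- numeric(60); s[which.min(abs(g - 20))] <- 1
  m <- compute_metrics(s, g)
  expect_equal(m$twc_raw, 1)
  expect_equal(m$mwf, 1)
  expect_equal(m$iewf, 0)
  expect_equal(m$fqfwf, 0)
  expect_true(is.na(m$t2ie))
  # all-zero spectrum: all metrics absent
  mz <- compute_metrics(numeric(60), g)
  expect_true(all(is.na(unlist(mz))))
  expect_error(compute_metrics(c(-1, numeric(59)), g), "non-negative")
})

test_that("three-pool arithmetic and the geometric mean follow the definitions", {
  # a grid carrying the nominal T2 values exactly
  g2 <- structure(c(10, 20, 40, 80, 120, 200, 500, 2000), class = "mct2_grid")
  s2 <- numeric(8); s2[2] <- 0.15; s2[4] <- 0.80; s2[7] <- 0.05
  m <- compute_metrics(s2, g2)
  expect_equal(m$mwf, 0.15)
  expect_equal(m$iewf, 0.80)
  expect_equal(m$fqfwf, 0.05)
  expect_equal(m$t2ie, 80)
  # weighted geometric mean of two equal components
  s3 <- numeric(8); s3[4] <- 0.4; s3[5] <- 0.4
  expect_equal(compute_metrics(s3, g2)$t2ie, sqrt(80 * 120))
})

test_that("window partition is complete and fractions sum to one", {
  g <- make_t2_grid()
  gv <- as.numeric(g)
  w <- metric_windows()
  in_my <- gv < w$myelin_upper
  in_ie <- gv >= w$myelin_upper & gv <= w$ie_upper
  in_fr <- gv > w$ie_upper
  expect_true(all(in_my + in_ie + in_fr == 1))  # exactly one window each
  set.seed(9)
  for (i in 1:200) {
    s <- runif(60) * rbinom(60, 1, 0.3)
    if (sum(s) == 0) next
    m <- compute_metrics(s, g)
    expect_lt(abs(m$mwf + m$iewf + m$fqfwf - 1), 1e-12)
    if (!is.na(m$t2ie)) expect_true(m$t2ie >= 40 && m$t2ie <= 200)
    # scale invariance
    m2 <- compute_metrics(3.7 * s, g)
    expect_equal(m2$mwf, m$mwf, tolerance = 1e-12)
    expect_equal(m2$t2ie, m$t2ie, tolerance = 1e-10)
    expect_equal(m2$twc_raw, 3.7 * m$twc_raw, tolerance = 1e-10)
  }
})

test_that("vectorized metric maps agree with the scalar path", {
  g <- make_t2_grid()
  set.seed(21)
  sp <- array(runif(4 * 3 * 2 * 60), c(4, 3, 2, 60))
  sp[1, 1, 1, ] <- 0           # undefined voxel
  maps <- metric_maps(sp, g)
  expect_true(is.na(maps$mwf[1, 1, 1]))
  m <- compute_metrics(sp[3, 2, 2, ], g)
  expect_equal(maps$mwf[3, 2, 2], m$mwf)
  expect_equal(maps$t2ie[3, 2, 2], m$t2ie)
  expect_equal(maps$twc[3, 2, 2], m$twc_raw)
})

test_that("CSF normalization scales and is idempotent", {
  m <- array(2, c(4, 4, 2))
  csf <- array(FALSE, c(4, 4, 2)); csf[1:2, 1, 1] <- TRUE
  expect_equal(normalize_twc(m, csf), array(1, c(4, 4, 2)))
  m2 <- array(1.4, c(4, 4, 2)); m2[csf] <- 2.0
  out <- normalize_twc(m2, csf)
  expect_equal(out[3, 3, 1], 0.7)
  expect_equal(mean(out[csf]), 1)
  expect_equal(normalize_twc(out, csf), out)   # idempotence
  expect_error(normalize_twc(m, array(FALSE, c(4, 4, 2))), "CSF")
})

test_that("ROI means average defined voxels and flag missing regions", {
  lab <- array(0L, c(4, 4, 1))
  lab[1, 1, 1] <- 1L
  lab[2, 1:2, 1] <- 2L
  map <- array(NA_real_, c(4, 4, 1))
  map[1, 1, 1] <- 0.5
  map[2, 1, 1] <- 0.1; map[2, 2, 1] <- 0.3
  tab <- roi_means(list(mwf = map), lab, c(one = 1, two = 2, ghost = 9),
                   subject = "S1")
  expect_equal(tab$mean[tab$roi == "one"], 0.5)
  expect_equal(tab$mean[tab$roi == "two"], 0.2)
  expect_equal(tab$flag[tab$roi == "ghost"], "missing_roi")
  expect_true(is.na(tab$mean[tab$roi == "ghost"]))
  # region present but entirely undefined
  lab[3, 3, 1] <- 3L
  tab2 <- roi_means(list(mwf = map), lab, c(dead = 3))
  expect_equal(tab2$flag, "all_undefined")
})
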