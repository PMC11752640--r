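test_that("flip-angle search recovers on-grid and off-grid angles", {
  dset <- default_dset()
  g <- dset$grid
  # two-component spectrum synthesized at an on-grid angle
  x <- numeric(60); x[c(20, 35)] <- c(0.3, 0.7)
  y150 <- as.numeric(build_dictionary(g, 150)$entries %*% x)
  expect_equal(estimate_flip_angle(y150, dset), 150)
  # mono-exponential at ideal refocusing
  y180 <- epg_decay(85, 1000, 180, dset$scheme)
  expect_equal(estimate_flip_angle(y180, dset), 180)
  # off-grid angle: lands on the residual-minimizing 2-degree neighbour,
  # verified against a dense 0.1-degree dictionary search
  y151 <- as.numeric(build_dictionary(g, 151)$entries %*% x)
  got <- estimate_flip_angle(y151, dset)
  expect_true(got %in% c(150, 152))
  dense <- seq(149, 153, by = 0.1)
  mse <- vapply(dense, function(fl) {
    D <- build_dictionary(g, fl)$entries
    mean((D %*% nnls_solve(D, y151) - y151)^2)
  }, numeric(1))
  best_dense <- dense[which.min(mse)]
  expect_equal(got, c(150, 152)[which.min(abs(c(150, 152) - best_dense))])
  expect_error(estimate_flip_angle(y151[1:10], dset), "length")
})

test_that("regularized fit degenerates correctly as k approaches 1", {
  dset <- default_dset()
  d <- dset$dictionaries[[which(dset$flip_grid == 160)]]
  set.seed(3)
  y <- as.numeric(d$entries %*% c(numeric(10), 0.2, numeric(15), 0.8,
                                  numeric(33))) + rnorm(32, 0, 0.002)
  f <- fit_spectrum_regularized(d, y, fit_config(k_chi2 = 1 + 1e-9))
  f0 <- nnls_solve(d$entries, y)
  expect_equal(f$spectrum, f0, tolerance = 1e-4)
  expect_lt(f$chi2_reg / f$chi2_min, 1 + 1e-6)
  expect_error(fit_config(k_chi2 = 1), "k_chi2")
})

test_that("noise-free on-grid spectra are recovered exactly with lambda 0", {
  dset <- default_dset()
  d <- dset$dictionaries[[which(dset$flip_grid == 140)]]
  x_true <- numeric(60); x_true[c(12, 31)] <- c(0.15, 0.85)
  y <- as.numeric(d$entries %*% x_true)
  f <- fit_spectrum_regularized(d, y)
  expect_identical(f$lambda_star, 0)
  expect_lt(sum(abs(f$spectrum - x_true)), 1e-6)
  # all-zero signal: all-zero solution, not an error
  fz <- fit_spectrum_regularized(d, numeric(32))
  expect_equal(fz$spectrum, numeric(60))
})

test_that("chi-squared criterion hits its target and behaves monotonically", {
  dset <- default_dset()
  d <- dset$dictionaries[[which(dset$flip_grid == 160)]]
  x_true <- numeric(60); x_true[c(11, 30, 55)] <- c(0.15, 0.8, 0.05)
  y0 <- as.numeric(d$entries %*% x_true)
  set.seed(5)
  for (rep in 1:3) {
    y <- y0 + rnorm(32, 0, max(y0) / 200)   # SNR 200
    f <- fit_spectrum_regularized(d, y)
    ratio <- f$chi2_reg / f$chi2_min
    expect_gte(ratio, 1.018)
    expect_lte(ratio, 1.022)
    # regularization shrinks the solution norm
    x0 <- nnls_solve(d$entries, y)
    expect_lte(sqrt(sum(f$spectrum^2)), sqrt(sum(x0^2)) + 1e-12)
    expect_gte(f$chi2_reg, f$chi2_min)
    # chi^2(lambda) is non-decreasing along a candidate sweep
    lams <- exp(seq(log(1e-4), log(5), length.out = 20)) * norm(d$entries, "F")
    chis <- vapply(lams, function(l) {
      xl <- nnls_solve(rbind(d$entries, l * diag(60)), c(y, numeric(60)))
      sum((d$entries %*% xl - y)^2)
    }, numeric(1))
    expect_true(all(diff(chis) >= -1e-10))
  }
})

test_that("volume fitting reduces to the scalar path for one voxel", {
  dset <- default_dset()
  g <- dset$grid
  sch <- dset$scheme
  tis <- default_tissues()$WM
  y <- tissue_signal(tis, 156, sch)
  vol <- array(0, c(3, 3, 1, 32))
  vol[2, 2, 1, ] <- y
  mask <- array(FALSE, c(3, 3, 1)); mask[2, 2, 1] <- TRUE
  fv <- fit_volume(vol, mask, scheme = sch, grid = g, dset = dset)
  expect_equal(fv$flip_map[2, 2, 1], 156)
  scalar <- fit_spectrum_regularized(
    dset$dictionaries[[which(dset$flip_grid == 156)]], y)
  expect_equal(fv$spectra[2, 2, 1, ], scalar$spectrum)
  expect_true(all(is.na(fv$spectra[1, 1, 1, ])))
  expect_error(fit_volume(vol, mask[, , 1, drop = FALSE][1:2, , , drop = TRUE]),
               regexp = ".")
})

test_that("a noise-free phantom at ideal refocusing round-trips the metrics", {
  sch <- acquisition_scheme()
  g <- make_t2_grid()
  # put every tissue T2 on the grid so recovery can be exact
  tissues <- list(
    WM = tissue_spec("WM", as.numeric(g[c(12, 31, 60)]), c(0.15, 0.83, 0.02), 0.7),
    GM = tissue_spec("GM", as.numeric(g[c(12, 33, 60)]), c(0.03, 0.94, 0.03), 0.82),
    CSF = tissue_spec("CSF", as.numeric(g[60]), 1, 1))
  ph <- generate_phantom(c(12, 12, 2), sch, g, tissues,
                         flip_field = array(180, c(12, 12, 2)), snr = Inf)
  dset <- build_dictionary_set(g, c(170, 175, 180), 1000, sch)
  fit <- fit_volume(ph$volume, ph$truth$labels > 0, scheme = sch, grid = g,
                    dset = dset)
  maps <- metric_maps(fit)
  inside <- ph$truth$labels > 0
  expect_true(all(fit$flip_map[inside] == 180))
  expect_lt(max(abs(maps$mwf[inside] - ph$truth$fraction_maps$mwf[inside])),
            1e-3)
  expect_lt(max(abs(maps$iewf[inside] - ph$truth$fraction_maps$iewf[inside])),
            1e-3)
})
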