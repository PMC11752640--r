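#' Tissue specification for synthetic phantoms
#'
#' A tissue is a small mixture of T2 pools (delta components) plus a
#' relative water density scaling the total signal. Defaults follow the
#' usual three-pool picture of brain water: a fast-relaxing myelin-water
#' pool, a dominant intra-extracellular pool and a small free-water pool.
#' These are generator defaults for validation phantoms, not measurements.
#'
#' @param name Tissue label.
#' @param t2s Component T2 values in ms.
#' @param fractions Component fractions (must sum to 1).
#' @param water_density Relative total water content (CSF = 1).
#' @return An object of class `mct2_tissue`.
#' @export
tissue_spec <- function(name, t2s, fractions, water_density) {
  if (length(t2s) != length(fractions)) stop("t2s and fractions differ in length")
  if (abs(sum(fractions) - 1) > 1e-10) stop("fractions must sum to 1")
  if (any(fractions < 0) || any(t2s <= 0)) stop("invalid tissue components")
  if (water_density <= 0) stop("water_density must be positive")
  structure(list(name = name, t2s = t2s, fractions = fractions,
                 water_density = water_density),
            class = "mct2_tissue")
}

#' Default phantom tissues (white matter, grey matter, CSF)
#'
#' @return Named list of [tissue_spec()] objects with integer labels 1 (WM),
#'   2 (GM), 3 (CSF) in that order.
#' @export
default_tissues <- function() {
  list(
    WM  = tissue_spec("WM",  c(20, 80, 2000), c(0.15, 0.83, 0.02), 0.70),
    GM  = tissue_spec("GM",  c(20, 95, 2000), c(0.03, 0.94, 0.03), 0.82),
    CSF = tissue_spec("CSF", 2000, 1.0, 1.00))
}

#' Block phantom geometry
#'
#' Concentric rectangular regions in a `dim_xyz` volume: a background rim
#' (label 0), a grey-matter shell (2), a white-matter interior (1) and a
#' central CSF block (3, a ventricle stand-in). Large enough for the
#' smoothing kernels, small enough for minutes-scale fitting.
#'
#' @param dim_xyz Volume dimensions (default `c(24, 24, 8)`).
#' @return Integer 3D label array.
#' @export
phantom_geometry <- function(dim_xyz = c(24, 24, 8)) {
  if (any(dim_xyz[1:2] < 12) || dim_xyz[3] < 2)
    stop("phantom needs at least 12 voxels in x and y and 2 in z")
  lab <- array(0L, dim_xyz)
  nx <- dim_xyz[1]; ny <- dim_xyz[2]; nz <- dim_xyz[3]
  lab[3:(nx - 2), 3:(ny - 2), ] <- 2L                       # GM shell
  lab[5:(nx - 4), 5:(ny - 4), ] <- 1L                       # WM interior
  cx <- seq(floor(nx / 2) - 2, floor(nx / 2) + 1)
  cy <- seq(floor(ny / 2) - 2, floor(ny / 2) + 1)
  cz <- seq(max(1, floor(nz / 2) - 1), min(nz, floor(nz / 2) + 2))
  lab[cx, cy, cz] <- 3L                                     # central CSF
  lab
}

#' Smooth refocusing flip-angle field
#'
#' Quadratic ramp from `flip_min` to `flip_max` along x, emulating a smooth
#' B1+ inhomogeneity across the head.
#'
#' @param dim_xyz Volume dimensions.
#' @param flip_min,flip_max Field range in degrees (defaults 120 and 180).
#' @return 3D array of refocusing angles in degrees.
#' @export
flip_angle_field <- function(dim_xyz = c(24, 24, 8), flip_min = 120,
                             flip_max = 180) {
  if (flip_min < 90 || flip_max > 180 || flip_min > flip_max)
    stop("flip field must lie within [90, 180]")
  x <- (seq_len(dim_xyz[1]) - 1) / max(1, dim_xyz[1] - 1)
  ramp <- flip_min + (flip_max - flip_min) * x^2
  array(rep(ramp, times = dim_xyz[2] * dim_xyz[3]), dim_xyz)
}

#' Add Rician noise to magnitude data
#'
#' Magnitude MRI noise: `sqrt((s + g1)^2 + g2^2)` with `g1`, `g2`
#' independent zero-mean Gaussians of standard deviation `sigma` (the
#' single-coil complex noise level). At zero signal this reduces to a
#' Rayleigh distribution.
#'
#' @param signal Numeric vector/array of noise-free magnitudes.
#' @param sigma Gaussian noise standard deviation (>= 0; 0 is the identity).
#' @param seed Optional integer seed for reproducibility.
#' @return Noisy magnitudes, same shape as `signal`.
#' @export
add_rician_noise <- function(signal, sigma, seed = NULL) {
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(signal)
  if (!is.null(seed)) set.seed(seed)
  g1 <- rnorm(length(signal), 0, sigma)
  g2 <- rnorm(length(signal), 0, sigma)
  out <- sqrt((signal + g1)^2 + g2^2)
  if (!is.null(dim(signal))) dim(out) <- dim(signal)
  out
}

#' Generate a multi-echo GRASE phantom with known ground truth
#'
#' The noise-free signal of a voxel with tissue `t` and local refocusing
#' angle `alpha` is
#' `water_density_t * sum_c fraction_c * epg_decay(T2_c, t1, alpha)`,
#' i.e. a known three-pool spectrum seen through the EPG forward model and
#' the smooth flip-angle field. Rician noise is added at a level set by the
#' signal-to-noise ratio `snr`, defined on the mean first-echo white-matter
#' signal; `snr = Inf` yields noise-free data.
#'
#' @param dim_xyz Volume dimensions (default `c(24, 24, 8)`).
#' @param scheme An [acquisition_scheme()].
#' @param grid A [make_t2_grid()]; tissue T2s must lie within its range.
#' @param tissues Named list of [tissue_spec()] (order = labels 1, 2, 3...).
#' @param flip_field 3D array of refocusing angles; default quadratic ramp.
#' @param t1 Assumed T1 in ms.
#' @param snr Signal-to-noise ratio (> 0 or `Inf`).
#' @param seed Integer seed (default 1).
#' @return List of class `mct2_phantom`: `volume` (4D x, y, z, echo),
#'   `truth` (label volume, per-tissue specs, per-metric truth values,
#'   fraction maps, flip field, `sigma`, `seed`), `scheme`, `grid`.
#' @export
generate_phantom <- function(dim_xyz = c(24, 24, 8),
                             scheme = acquisition_scheme(),
                             grid = make_t2_grid(),
                             tissues = default_tissues(),
                             flip_field = NULL, t1 = 1000, snr = 100,
                             seed = 1L) {
  t2_rng <- range(as.numeric(grid))
  for (tis in tissues)
    if (any(tis$t2s < t2_rng[1] | tis$t2s > t2_rng[2]))
      stop("tissue T2 outside the grid range for ", tis$name)
  if (!(snr > 0)) stop("snr must be positive (or Inf)")
  labels <- phantom_geometry(dim_xyz)
  if (is.null(flip_field)) flip_field <- flip_angle_field(dim_xyz)
  if (!identical(dim(flip_field), dim(labels)))
    stop("flip_field shape does not match geometry")

  ne <- scheme$n_echoes
  vol <- array(0, c(dim_xyz, ne))
  vmat <- matrix(0, prod(dim_xyz), ne)
  flips <- sort(unique(as.numeric(flip_field)))
  for (li in seq_along(tissues)) {
    tis <- tissues[[li]]
    sel_t <- labels == li
    for (fl in flips) {
      sel <- which(sel_t & flip_field == fl)
      if (!length(sel)) next
      dec <- numeric(ne)
      for (c in seq_along(tis$t2s))
        dec <- dec + tis$fractions[c] * epg_decay(tis$t2s[c], t1, fl, scheme)
      vmat[sel, ] <- matrix(tis$water_density * dec, length(sel), ne,
                            byrow = TRUE)
    }
  }
  vol <- array(vmat, c(dim_xyz, ne))

  wm_first <- vmat[labels == 1L, 1]
  sigma <- if (is.infinite(snr)) 0 else mean(wm_first) / snr
  noisy <- add_rician_noise(vol, sigma, seed = seed)

  fraction_maps <- truth_fraction_maps(labels, tissues, grid)
  structure(list(
    volume = noisy,
    truth = list(labels = labels, tissues = tissues,
                 metrics = truth_tissue_metrics(tissues),
                 fraction_maps = fraction_maps,
                 flip_field = flip_field, sigma = sigma, seed = seed),
    scheme = scheme, grid = grid),
    class = "mct2_phantom")
}

# ground-truth per-tissue window fractions from the delta components
truth_tissue_metrics <- function(tissues, windows = metric_windows()) {
  out <- lapply(tissues, function(tis) {
    my <- tis$t2s < windows$myelin_upper
    ie <- tis$t2s >= windows$myelin_upper & tis$t2s <= windows$ie_upper
    w_ie <- tis$fractions[ie]
    list(mwf = sum(tis$fractions[my]),
         iewf = sum(w_ie),
         fqfwf = sum(tis$fractions[tis$t2s > windows$ie_upper]),
         t2ie = if (sum(w_ie) > 0)
           exp(sum(w_ie * log(tis$t2s[ie])) / sum(w_ie)) else NA_real_,
         water_density = tis$water_density)
  })
  names(out) <- names(tissues)
  out
}

# per-voxel truth maps of the three window fractions
truth_fraction_maps <- function(labels, tissues, grid,
                                windows = metric_windows()) {
  tm <- truth_tissue_metrics(tissues, windows)
  mk <- function(field) {
    m <- array(NA_real_, dim(labels))
    for (li in seq_along(tissues)) m[labels == li] <- tm[[li]][[field]]
    m
  }
  list(mwf = mk("mwf"), iewf = mk("iewf"), fqfwf = mk("fqfwf"),
       t2ie = mk("t2ie"), water_density = mk("water_density"))
}
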