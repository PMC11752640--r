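#' Multi-echo spin-echo acquisition scheme
#'
#' Describes a GRASE/CPMG echo train: the echo time of echo \eqn{n} is
#' \eqn{n \cdot \Delta TE}. The repetition time is recorded for provenance
#' only; the train is simulated from a fully recovered equilibrium state.
#'
#' @param n_echoes Number of refocusing echoes (default 32).
#' @param delta_te Echo spacing \eqn{\Delta TE} in ms (default 10.24).
#' @param tr Repetition time in ms (default 2000, provenance only).
#' @param excitation_deg Excitation flip angle in degrees; the excitation is
#'   modeled as ideal, so only 90 is supported.
#' @return An object of class `mct2_scheme` with fields `n_echoes`,
#'   `delta_te`, `tr`, `excitation_deg` and the echo-time vector `te`.
#' @examples
#' sch <- acquisition_scheme()
#' sch$te[1:4]
#' @export
acquisition_scheme <- function(n_echoes = 32L, delta_te = 10.24, tr = 2000,
                               excitation_deg = 90) {
  n_echoes <- as.integer(n_echoes)
  if (n_echoes < 1L) stop("n_echoes must be >= 1")
  if (delta_te <= 0) stop("delta_te must be positive")
  if (excitation_deg != 90) stop("only an ideal 90 degree excitation is modeled")
  structure(
    list(n_echoes = n_echoes, delta_te = delta_te, tr = tr,
         excitation_deg = excitation_deg,
         te = seq_len(n_echoes) * delta_te),
    class = "mct2_scheme")
}

#' Logarithmically spaced T2 grid
#'
#' The spectral inverse problem is solved on a fixed grid of T2 values with
#' a constant ratio between neighbours (log spacing), spanning
#' `t2_min` to `t2_max` inclusive.
#'
#' @param n Number of grid points (default 60).
#' @param t2_min,t2_max Grid endpoints in ms (defaults 10 and 2000).
#' @return An object of class `mct2_grid`: numeric vector of T2 values (ms)
#'   with attributes `t2_min`, `t2_max`.
#' @examples
#' g <- make_t2_grid()
#' range(g)          # 10 2000
#' g[2] / g[1]       # constant ratio (2000/10)^(1/59)
#' @export
make_t2_grid <- function(n = 60L, t2_min = 10, t2_max = 2000) {
  n <- as.integer(n)
  if (n < 2L) stop("a T2 grid needs at least 2 points")
  if (t2_min <= 0 || t2_max <= t2_min) stop("need 0 < t2_min < t2_max")
  v <- exp(seq(log(t2_min), log(t2_max), length.out = n))
  v[1] <- t2_min
  v[n] <- t2_max
  structure(v, t2_min = t2_min, t2_max = t2_max, class = "mct2_grid")
}
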