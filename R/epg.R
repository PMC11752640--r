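#' Extended phase graph echo-train simulation
#'
#' Predicts the magnitude of the primary spin-echo coherence at each echo of
#' a CPMG/GRASE train under imperfect refocusing, using the extended phase
#' graph (EPG) formalism: transverse configuration states \eqn{F^+(k)},
#' \eqn{F^-(k)} and longitudinal states \eqn{Z(k)} evolve by relaxation over
#' each \eqn{\Delta TE/2} interval, an integer dephasing shift per crusher
#' (perfect spoiling, only integer orders retained), and RF mixing at each
#' refocusing pulse. Stimulated-echo pathways arising at flip angles below
#' 180 degrees are therefore included. States are truncated at order
#' `n_echoes + 1`; higher orders cannot rephase within the train.
#'
#' The excitation is an ideal 90 degree pulse in quadrature with the
#' refocusing axis (CPMG condition). Longitudinal regrowth during the train
#' is neglected, as is conventional for echo trains much shorter than T1
#' (T1 enters only through the decay of stored longitudinal pathways);
#' recovery between repetitions is assumed complete.
#'
#' @param t2 Transverse relaxation time in ms (> 0).
#' @param t1 Longitudinal relaxation time in ms (>= t2). No T1 map is
#'   typically acquired alongside a GRASE scan; 1000 ms is the conventional
#'   assumption and the echo-train signal depends only weakly on it.
#' @param flip_deg Refocusing flip angle in degrees, in (0, 180].
#' @param scheme An [acquisition_scheme()].
#' @return Numeric vector of `n_echoes` echo amplitudes in `[0, 1]` for unit
#'   initial magnetization. At `flip_deg = 180` this equals
#'   `exp(-te / t2)` exactly.
#' @examples
#' sch <- acquisition_scheme()
#' a <- epg_decay(80, 1000, 150, sch)
#' plot(sch$te, a, type = "b", xlab = "TE (ms)", ylab = "amplitude")
#' @export
epg_decay <- function(t2, t1 = 1000, flip_deg = 180, scheme = acquisition_scheme()) {
  if (!is.finite(t2) || t2 <= 0) stop("t2 must be positive")
  if (!is.finite(t1) || t1 <= 0) stop("t1 must be positive")
  # t1 < t2 is unphysical for tissue but must remain computable: the
  # dictionary spans T2 values (e.g. CSF, 2000 ms) above the assumed T1
  if (flip_deg <= 0 || flip_deg > 180) stop("flip_deg must lie in (0, 180]")

  n <- scheme$n_echoes
  K <- n + 1L                      # highest retained dephasing order
  e2 <- exp(-scheme$delta_te / 2 / t2)
  e1 <- exp(-scheme$delta_te / 2 / t1)

  # refocusing rotation about x by alpha (excitation was 90 about y)
  a <- flip_deg * pi / 180
  ca2 <- cos(a / 2)^2
  sa2 <- sin(a / 2)^2
  sa <- sin(a)
  Rm <- matrix(c(ca2,        sa2,        -1i * sa,
                 sa2,        ca2,         1i * sa,
                 -0.5i * sa, 0.5i * sa,   cos(a)),
               nrow = 3, byrow = TRUE)

  Fp <- complex(K + 1L)
  Fm <- complex(K + 1L)
  Z  <- complex(K + 1L)
  Fp[1] <- 1 + 0i                  # unit magnetization after ideal 90y
  Fm[1] <- 1 + 0i                  # F-(0) = conj(F+(0))

  relax <- function() {
    Fp <<- Fp * e2
    Fm <<- Fm * e2
    Z  <<- Z * e1   # regrowth during the train neglected (train length << T1)
  }
  shift <- function() {
    Fp <<- c(0i, Fp[seq_len(K)])
    Fm <<- c(Fm[-1L], 0i)
    Fp[1] <<- Conj(Fm[1])
  }

  out <- numeric(n)
  for (ech in seq_len(n)) {
    relax(); shift()
    S <- Rm %*% rbind(Fp, Fm, Z)
    Fp <- S[1L, ]
    Fm <- S[2L, ]
    Z  <- S[3L, ]
    relax(); shift()
    out[ech] <- Mod(Fp[1])
  }
  out
}

#' Build an EPG dictionary over a T2 grid
#'
#' Column \eqn{j} holds the echo-train amplitudes predicted by
#' [epg_decay()] for T2 equal to the \eqn{j}-th grid value, at one
#' refocusing flip angle and assumed T1.
#'
#' @param grid A [make_t2_grid()].
#' @param flip_deg Refocusing flip angle in degrees.
#' @param t1 Assumed T1 in ms.
#' @param scheme An [acquisition_scheme()].
#' @return An `mct2_dictionary`: list with `entries` (`n_echoes` x `N`
#'   matrix), `flip_deg`, `t1`, `grid` and `scheme`.
#' @export
build_dictionary <- function(grid, flip_deg, t1 = 1000,
                             scheme = acquisition_scheme()) {
  entries <- vapply(as.numeric(grid), epg_decay, numeric(scheme$n_echoes),
                    t1 = t1, flip_deg = flip_deg, scheme = scheme)
  structure(list(entries = entries, flip_deg = flip_deg, t1 = t1,
                 grid = grid, scheme = scheme),
            class = "mct2_dictionary")
}

#' Build dictionaries for a set of candidate flip angles
#'
#' One dictionary per candidate refocusing angle; used by the per-voxel
#' flip-angle search.
#'
#' @param grid A [make_t2_grid()].
#' @param flip_grid Numeric vector of candidate flip angles in degrees.
#' @param t1 Assumed T1 in ms.
#' @param scheme An [acquisition_scheme()].
#' @return An `mct2_dictionary_set`: list of `mct2_dictionary` keyed by
#'   angle, with `flip_grid`, `grid`, `t1`, `scheme` fields.
#' @export
build_dictionary_set <- function(grid, flip_grid = seq(90, 180, by = 2),
                                 t1 = 1000, scheme = acquisition_scheme()) {
  if (length(flip_grid) == 0) stop("flip_grid must be non-empty")
  if (any(flip_grid <= 0 | flip_grid > 180))
    stop("flip angles must lie in (0, 180]")
  flip_grid <- sort(flip_grid)
  dicts <- lapply(flip_grid, build_dictionary, grid = grid, t1 = t1,
                  scheme = scheme)
  structure(list(dictionaries = dicts, flip_grid = flip_grid, grid = grid,
                 t1 = t1, scheme = scheme),
            class = "mct2_dictionary_set")
}

#' Write / read a dictionary set as JSON
#'
#' On-disk layout: a single JSON object with keys `n_echoes`, `delta_te_ms`,
#' `t1_ms`, `flip_grid`, `t2_grid` and `entries` (one echoes-by-grid matrix
#' per flip angle, row-major).
#'
#' @param dset An `mct2_dictionary_set`.
#' @param path Output file path.
#' @return `path`, invisibly; `read_dictionary_set` returns the set.
#' @export
write_dictionary_set <- function(dset, path) {
  stopifnot(inherits(dset, "mct2_dictionary_set"))
  obj <- list(
    n_echoes = dset$scheme$n_echoes,
    delta_te_ms = dset$scheme$delta_te,
    tr_ms = dset$scheme$tr,
    t1_ms = dset$t1,
    flip_grid = dset$flip_grid,
    t2_grid = as.numeric(dset$grid),
    entries = lapply(dset$dictionaries, function(d) d$entries))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dictionary_set
#' @export
read_dictionary_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid_v <- obj$t2_grid
  grid <- make_t2_grid(length(grid_v), grid_v[1], grid_v[length(grid_v)])
  scheme <- acquisition_scheme(obj$n_echoes, obj$delta_te_ms, obj$tr_ms)
  get_entries <- function(i) {
    e <- obj$entries
    if (is.array(e) && length(dim(e)) == 3) return(e[i, , ])
    m <- e[[i]]
    if (!is.matrix(m)) m <- do.call(rbind, m)
    m
  }
  dicts <- lapply(seq_along(obj$flip_grid), function(i) {
    structure(list(entries = get_entries(i), flip_deg = obj$flip_grid[i],
                   t1 = obj$t1_ms, grid = grid, scheme = scheme),
              class = "mct2_dictionary")
  })
  structure(list(dictionaries = dicts, flip_grid = obj$flip_grid, grid = grid,
                 t1 = obj$t1_ms, scheme = scheme),
            class = "mct2_dictionary_set")
}
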