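# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the isochromat simulator integrates Bloch
# rotations over an explicit spin ensemble, the NNLS oracle enumerates
# active sets, and the TFCE oracle labels components with igraph.

# Brute-force isochromat CPMG simulation: an ensemble of spins uniformly
# dephased by ideal crushers, explicit rotation + relaxation per half
# echo-spacing interval. Deterministic uniform phase grid.
iso_decay <- function(t2, t1, flip_deg, scheme, n_spins = 1e5) {
  e2 <- exp(-scheme$delta_te / 2 / t2)
  e1 <- exp(-scheme$delta_te / 2 / t1)
  del <- 2 * pi * ((seq_len(n_spins) - 0.5) / n_spins)
  cd <- cos(del); sd_ <- sin(del)
  Mx <- rep(1, n_spins); My <- rep(0, n_spins); Mz <- rep(0, n_spins)
  a <- flip_deg * pi / 180
  ca <- cos(a); sa <- sin(a)
  half <- function() {
    Mx <<- Mx * e2; My <<- My * e2; Mz <<- Mz * e1   # no regrowth in-train
    x <- Mx * cd - My * sd_; y <- Mx * sd_ + My * cd
    Mx <<- x; My <<- y
  }
  out <- numeric(scheme$n_echoes)
  for (n in seq_len(scheme$n_echoes)) {
    half()
    y <- My * ca - Mz * sa; z <- My * sa + Mz * ca
    My <- y; Mz <- z
    half()
    out[n] <- Mod(mean(Mx) + 1i * mean(My))
  }
  out
}

# Exhaustive-support NNLS oracle: solve unconstrained least squares on every
# subset of columns, keep the feasible (non-negative) solution with the
# smallest residual.
nnls_bruteforce <- function(A, y) {
  n <- ncol(A)
  best <- rep(0, n)
  best_rss <- sum(y^2)
  for (k in 1:n) {
    for (S in utils::combn(n, k, simplify = FALSE)) {
      z <- tryCatch(qr.solve(A[, S, drop = FALSE], y), error = function(e) NULL)
      if (is.null(z) || any(z < 0)) next
      x <- rep(0, n); x[S] <- z
      rss <- sum((A %*% x - y)^2)
      if (rss < best_rss - 1e-12) { best <- x; best_rss <- rss }
    }
  }
  best
}

# Per-threshold connected-component TFCE oracle built on igraph.
tfce_bruteforce <- function(map, connectivity, H, E, dh) {
  d <- dim(map)
  nv <- prod(d)
  coords <- arrayInd(seq_len(nv), d)
  neigh <- function(i, j) {
    dd <- abs(coords[i, ] - coords[j, ])
    if (all(dd == 0) || any(dd > 1)) return(FALSE)
    s <- sum(dd)
    (connectivity == 26) || (connectivity == 18 && s <= 2) ||
      (connectivity == 6 && s == 1)
  }
  out <- array(0, d)
  hmax <- max(map)
  if (hmax <= 0) return(out)
  for (h in seq(dh, hmax + 1e-12, by = dh)) {
    on <- which(map >= h - 1e-9 * dh)   # tie resolution as in the package
    if (!length(on)) next
    edges <- c()
    if (length(on) > 1) {
      for (a in seq_along(on)) {
        for (b in seq_along(on)) {
          if (a < b && neigh(on[a], on[b])) edges <- c(edges, a, b)
        }
      }
    }
    g <- igraph::make_empty_graph(n = length(on), directed = FALSE)
    if (length(edges)) g <- igraph::add_edges(g, edges)
    comp <- igraph::components(g)
    for (a in seq_along(on))
      out[on[a]] <- out[on[a]] + comp$csize[comp$membership[a]]^E * h^H * dh
  }
  out
}

# Shared fixtures, built lazily once per test run (dictionary construction
# over the full flip grid is the expensive part).
.fixtures <- new.env()

default_dset <- function() {
  if (is.null(.fixtures$dset))
    .fixtures$dset <- build_dictionary_set(make_t2_grid(), seq(90, 180, 2),
                                           1000, acquisition_scheme())
  .fixtures$dset
}

default_phantom_fit <- function() {
  if (is.null(.fixtures$phfit)) {
    ph <- generate_phantom(snr = 100, seed = 7)
    fit <- fit_volume(ph$volume, mask = ph$truth$labels > 0,
                      dset = default_dset())
    .fixtures$phfit <- list(phantom = ph, fit = fit,
                            maps = metric_maps(fit))
  }
  .fixtures$phfit
}

# mixture echo train of a tissue spec through the EPG forward model
tissue_signal <- function(tissue, flip, scheme = acquisition_scheme(),
                          t1 = 1000) {
  dec <- numeric(scheme$n_echoes)
  for (c in seq_along(tissue$t2s))
    dec <- dec + tissue$fractions[c] * epg_decay(tissue$t2s[c], t1, flip, scheme)
  tissue$water_density * dec
}
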