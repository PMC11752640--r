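#' T2 window boundaries for the water-compartment metrics
#'
#' The spectrum is partitioned into three windows: myelin water
#' (`T2 < myelin_upper`, strict), intra-extracellular water
#' (`myelin_upper <= T2 <= ie_upper`, both boundaries inclusive) and
#' free/quasi-free water (`T2 > ie_upper` up to the grid maximum).
#'
#' @param myelin_upper Myelin water cut-off in ms (default 40).
#' @param ie_upper Upper bound of the intra-extracellular window in ms
#'   (default 200).
#' @param free_upper Upper bound of the free-water window in ms (default
#'   2000, the grid maximum).
#' @return An object of class `mct2_windows`.
#' @export
metric_windows <- function(myelin_upper = 40, ie_upper = 200,
                           free_upper = 2000) {
  if (!(0 < myelin_upper && myelin_upper < ie_upper && ie_upper < free_upper))
    stop("need 0 < myelin_upper < ie_upper < free_upper")
  structure(list(myelin_upper = myelin_upper, ie_upper = ie_upper,
                 free_upper = free_upper),
            class = "mct2_windows")
}

#' Water-compartment metrics of a single T2 spectrum
#'
#' Computes, from a non-negative T2 spectrum:
#' \describe{
#'   \item{twc_raw}{total water content: area under the whole distribution.}
#'   \item{mwf}{myelin water fraction: mass at `T2 < 40` ms over `twc_raw`.}
#'   \item{iewf}{intra-extracellular water fraction: mass in 40-200 ms.}
#'   \item{fqfwf}{free/quasi-free water fraction: mass above 200 ms.}
#'   \item{t2ie}{amplitude-weighted geometric mean T2 within 40-200 ms,
#'     `NA` when that window carries no mass.}
#' }
#' Fractions are normalized by `twc_raw` and sum to one; an all-zero
#' spectrum yields all-`NA` metrics.
#'
#' @param spectrum Non-negative amplitude vector (one per grid point).
#' @param grid A [make_t2_grid()] of matching length.
#' @param windows A [metric_windows()].
#' @return Named list with `twc_raw`, `mwf`, `iewf`, `fqfwf`, `t2ie`.
#' @examples
#' g <- make_t2_grid()
#' s <- numeric(60)
#' s[which.min(abs(g - 60))] <- 0.4
#' s[which.min(abs(g - 120))] <- 0.4
#' compute_metrics(s, g)$t2ie   # close to sqrt(60 * 120)
#' @export
compute_metrics <- function(spectrum, grid, windows = metric_windows()) {
  t2 <- as.numeric(grid)
  if (length(spectrum) != length(t2))
    stop("spectrum length does not match grid")
  if (anyNA(spectrum) || any(spectrum < 0))
    stop("spectrum must be non-negative and complete")
  twc <- sum(spectrum)
  if (twc == 0)
    return(list(twc_raw = NA_real_, mwf = NA_real_, iewf = NA_real_,
                fqfwf = NA_real_, t2ie = NA_real_))
  my <- t2 < windows$myelin_upper
  ie <- t2 >= windows$myelin_upper & t2 <= windows$ie_upper
  w_ie <- spectrum[ie]
  t2ie <- if (sum(w_ie) > 0) exp(sum(w_ie * log(t2[ie])) / sum(w_ie))
          else NA_real_
  list(twc_raw = twc,
       mwf = sum(spectrum[my]) / twc,
       iewf = sum(w_ie) / twc,
       fqfwf = sum(spectrum[t2 > windows$ie_upper]) / twc,
       t2ie = t2ie)
}

#' Voxelwise biomarker maps from a fitted volume
#'
#' Vectorized application of [compute_metrics()] to every masked voxel of a
#' [fit_volume()] result (or a plain 4D spectra array).
#'
#' @param fit An `mct2_volume_fit`, or a 4D array of spectra (x, y, z, bin).
#' @param grid Required when `fit` is a plain array.
#' @param windows A [metric_windows()].
#' @return Named list of 3D maps: `twc`, `mwf`, `iewf`, `fqfwf`, `t2ie`
#'   (`NA` outside the mask or where undefined).
#' @export
metric_maps <- function(fit, grid = NULL, windows = metric_windows()) {
  if (inherits(fit, "mct2_volume_fit")) {
    spectra <- fit$spectra
    grid <- fit$grid
  } else spectra <- fit
  if (is.null(grid)) stop("grid must be supplied for a plain spectra array")
  d <- dim(spectra)
  if (length(d) != 4L || d[4] != length(grid))
    stop("spectra must be 4D with trailing axis matching the grid")
  t2 <- as.numeric(grid)
  S <- matrix(spectra, ncol = d[4])
  my <- t2 < windows$myelin_upper
  ie <- t2 >= windows$myelin_upper & t2 <= windows$ie_upper
  fr <- t2 > windows$ie_upper

  twc <- rowSums(S)
  pos <- !is.na(twc) & twc > 0
  mk <- function(num) {
    v <- rep(NA_real_, nrow(S))
    v[pos] <- num[pos] / twc[pos]
    array(v, d[1:3])
  }
  m_ie <- rowSums(S[, ie, drop = FALSE])
  t2ie <- rep(NA_real_, nrow(S))
  ok <- pos & m_ie > 0
  t2ie[ok] <- exp((S[ok, ie, drop = FALSE] %*% log(t2[ie])) / m_ie[ok])
  twc_map <- rep(NA_real_, nrow(S))
  twc_map[pos] <- twc[pos]
  list(twc = array(twc_map, d[1:3]),
       mwf = mk(rowSums(S[, my, drop = FALSE])),
       iewf = mk(m_ie),
       fqfwf = mk(rowSums(S[, fr, drop = FALSE])),
       t2ie = array(t2ie, d[1:3]))
}

#' Normalize a total-water-content map to CSF
#'
#' Divides the raw TWC map by its mean over a cerebrospinal-fluid mask, so
#' CSF averages to exactly 1 and tissue values become relative water
#' contents. Normalizing an already-normalized map with the same mask is the
#' identity.
#'
#' @param twc_map 3D raw TWC map (may contain `NA` outside the brain).
#' @param csf_mask Logical/0-1 3D array; must select at least one voxel with
#'   a defined TWC value.
#' @return Normalized 3D map.
#' @export
normalize_twc <- function(twc_map, csf_mask) {
  if (!identical(dim(twc_map), dim(csf_mask)))
    stop("csf_mask shape does not match map")
  sel <- as.logical(csf_mask) & !is.na(twc_map)
  if (!any(sel)) stop("CSF mask selects no voxels with defined TWC")
  twc_map / mean(twc_map[sel])
}

#' Identify a CSF mask from fitted maps
#'
#' For synthetic phantoms the ground-truth labels should be used instead;
#' this heuristic serves real data, where CSF delineation is not part of the
#' relaxometry output: voxels dominated by free water (`fqfwf` above
#' `fqfwf_min`) with above-median raw TWC.
#'
#' @param maps Output of [metric_maps()].
#' @param fqfwf_min Free-water fraction threshold (default 0.9).
#' @return Logical 3D array.
#' @export
csf_mask_from_maps <- function(maps, fqfwf_min = 0.9) {
  ok <- !is.na(maps$fqfwf) & !is.na(maps$twc)
  med <- median(maps$twc[ok])
  out <- array(FALSE, dim(maps$twc))
  out[ok] <- maps$fqfwf[ok] > fqfwf_min & maps$twc[ok] > med
  out
}

#' Smooth biomarker maps
#'
#' Gaussian smoothing (default 2 mm FWHM) of each metric map, applied after
#' CSF normalization and before statistics. Undefined voxels are handled by
#' kernel renormalization over defined neighbours (see [smooth_gaussian()]).
#'
#' @param maps Named list of 3D maps.
#' @param fwhm_mm Kernel FWHM in mm (default 2).
#' @param voxel_size_mm Voxel dimensions in mm.
#' @return Named list of smoothed maps.
#' @export
smooth_metric_maps <- function(maps, fwhm_mm = 2,
                               voxel_size_mm = c(1.7, 1.7, 4)) {
  lapply(maps, smooth_gaussian, fwhm_mm = fwhm_mm,
         voxel_size_mm = voxel_size_mm)
}

#' Region-of-interest means of metric maps
#'
#' Arithmetic mean of each metric over each labelled region, counting only
#' voxels with defined values. A requested label absent from the label
#' volume, or a region whose voxels are all undefined, yields a flagged row
#' with `NA` mean rather than a silent zero.
#'
#' @param maps Named list of 3D metric maps (or a single 3D map).
#' @param label_volume Integer 3D array of region labels.
#' @param roi_ids Integer labels to extract; optionally named (names become
#'   the `roi` column).
#' @param subject Subject identifier recycled into the output.
#' @return A data.frame with columns `subject`, `roi`, `metric`, `mean`,
#'   `n_voxels`, `flag` (`""`, `"missing_roi"` or `"all_undefined"`).
#' @export
roi_means <- function(maps, label_volume, roi_ids, subject = "subject") {
  if (is.array(maps)) maps <- list(value = maps)
  if (!identical(dim(maps[[1]]), dim(label_volume)))
    stop("label volume shape does not match maps")
  roi_names <- if (!is.null(names(roi_ids))) names(roi_ids)
               else as.character(roi_ids)
  rows <- list()
  for (r in seq_along(roi_ids)) {
    in_roi <- label_volume == roi_ids[r]
    for (m in names(maps)) {
      vals <- maps[[m]][in_roi]
      vals <- vals[!is.na(vals)]
      flag <- if (!any(in_roi)) "missing_roi"
              else if (length(vals) == 0) "all_undefined" else ""
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subject, roi = roi_names[r], metric = m,
        mean = if (length(vals)) mean(vals) else NA_real_,
        n_voxels = length(vals), flag = flag,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
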