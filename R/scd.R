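#' Diagnostic classification by hippocampal Z-score
#'
#' Applies the normative-atrophy rule: a subject with cognitive complaints
#' whose left and/or right hippocampal volume Z-score lies below one
#' standard deviation (`Z < -1`, strict) is SCD+; with complaints and both
#' `Z >= -1`, SCD-. Without complaints, both Z-scores must be within the
#' normal range (`>= -1`) for a CU label; otherwise the subject does not
#' fit any group and is flagged `excluded`.
#'
#' @param records A data.frame with columns `scc` (logical complaints
#'   flag), `z_hip_left` and `z_hip_right`.
#' @return Factor with levels `CU`, `SCD-`, `SCD+`, `excluded`, one per row.
#' @examples
#' classify_scd(data.frame(scc = TRUE, z_hip_left = -1.2, z_hip_right = 0.3))
#' @export
classify_scd <- function(records) {
  need <- c("scc", "z_hip_left", "z_hip_right")
  if (!all(need %in% names(records)))
    stop("records must have columns scc, z_hip_left, z_hip_right")
  zl <- records$z_hip_left
  zr <- records$z_hip_right
  if (anyNA(zl) || anyNA(zr) || anyNA(records$scc))
    stop("missing Z-scores or complaints flag")
  atrophy <- zl < -1 | zr < -1
  out <- ifelse(records$scc,
                ifelse(atrophy, "SCD+", "SCD-"),
                ifelse(atrophy, "excluded", "CU"))
  factor(out, levels = c("CU", "SCD-", "SCD+", "excluded"))
}

#' White-matter hyperintensity load from a lesion-probability map
#'
#' Binarizes a lesion-probability map at 0.5 (a probability of exactly 0.5
#' counts as lesion), converts the lesion voxel count to a volume,
#' normalizes by total intracranial volume (TIV) and log transforms. One
#' voxel volume is added before the logarithm so lesion-free subjects map
#' to a finite floor instead of `-Inf`.
#'
#' @param lesion_probability_map Numeric array with values in `[0, 1]`.
#' @param voxel_volume_mm3 Volume of one voxel in mm^3.
#' @param tiv_mm3 Total intracranial volume in mm^3.
#' @return List with `lesion_map` (0/1 array), `volume_mm3` and `wmh_log`
#'   (`log((volume + voxel_volume) / tiv)`).
#' @export
wmh_load <- function(lesion_probability_map, voxel_volume_mm3, tiv_mm3) {
  p <- lesion_probability_map
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("lesion probabilities must lie in [0, 1]")
  if (!(tiv_mm3 > 0) || !(voxel_volume_mm3 > 0))
    stop("voxel volume and TIV must be positive")
  lesion <- p >= 0.5
  vol <- sum(lesion) * voxel_volume_mm3
  list(lesion_map = array(as.integer(lesion),
                          dim = if (is.null(dim(p))) length(p) else dim(p)),
       volume_mm3 = vol,
       wmh_log = log((vol + voxel_volume_mm3) / tiv_mm3))
}

#' Minimum detectable effect size (two-sample, normal approximation)
#'
#' Smallest standardized mean difference (Cohen's d) detectable with a
#' two-sided two-sample test at significance `alpha` and the stated power:
#' `d = (z_{1-alpha/2} + z_{power}) * sqrt(1/n1 + 1/n2)`.
#'
#' @param n1,n2 Group sizes (>= 2).
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @return Cohen's d.
#' @examples
#' minimum_detectable_effect(53, 70)   # about 0.5 SD
#' @export
minimum_detectable_effect <- function(n1, n2, alpha = 0.05, power = 0.80) {
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2")
  if (!(alpha > 0 && alpha < 1) || !(power > 0 && power < 1))
    stop("alpha and power must lie in (0, 1)")
  (qnorm(1 - alpha / 2) + qnorm(power)) * sqrt(1 / n1 + 1 / n2)
}
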