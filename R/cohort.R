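#' Synthetic cohort specification
#'
#' Describes a three-group ageing cohort — cognitively unimpaired (CU),
#' subjective cognitive decline without (SCD-) and with (SCD+) hippocampal
#' atrophy — with covariate distributions, normative hippocampal Z-score
#' rules and per-metric group effects on regional biomarker means.
#' Default group sizes are 53/70/16 (CU/SCD-/SCD+) and default covariate
#' distributions match a typical 50+ primary-care cohort (ages in the low
#' to high sixties, mild depressive symptom scores). All group effects
#' default to zero (a null cohort).
#'
#' @param n Named group sizes, `c(CU = 53, "SCD-" = 70, "SCD+" = 16)`.
#' @param age_mean,age_sd Per-group age distributions (years).
#' @param gds_mean,gds_sd Per-group geriatric depression scale scores
#'   (0-15; draws are rounded and clamped).
#' @param wmh_log_mean,wmh_log_sd Log TIV-normalized white-matter
#'   hyperintensity load; a mild age slope (`wmh_age_slope` per year) is
#'   added.
#' @param wmh_age_slope Slope of `wmh_log` on centred age.
#' @param effects Named list: per metric, a named vector of group mean
#'   shifts in within-group SD units, e.g.
#'   `list(fqfwf = c("SCD+" = 0.8))`. Metrics/groups omitted default to 0.
#' @param z_slope Named vector: per metric, slope (in SD units per Z unit)
#'   of the hippocampal metric values on the matching hippocampal Z-score;
#'   nonzero values create purely volume-driven group differences.
#' @param baselines,sds Named vectors of metric baselines and within-group
#'   SDs (natural units).
#' @param age_slope_sd,gds_slope_sd Covariate slopes applied to every
#'   metric, in SD units per year (centred age) and per GDS point.
#' @return An object of class `mct2_cohort_spec`.
#' @export
cohort_spec <- function(n = c(CU = 53, "SCD-" = 70, "SCD+" = 16),
                        age_mean = c(CU = 63.3, "SCD-" = 65.9, "SCD+" = 68.4),
                        age_sd = c(CU = 6.6, "SCD-" = 7.8, "SCD+" = 7.5),
                        gds_mean = c(CU = 2.2, "SCD-" = 3.3, "SCD+" = 3.9),
                        gds_sd = c(CU = 3.0, "SCD-" = 2.9, "SCD+" = 2.9),
                        wmh_log_mean = -6.5, wmh_log_sd = 0.8,
                        wmh_age_slope = 0.03,
                        effects = list(), z_slope = c(),
                        baselines = c(mwf = 0.08, iewf = 0.87, t2ie = 85,
                                      fqfwf = 0.05, twc = 0.82),
                        sds = c(mwf = 0.015, iewf = 0.03, t2ie = 4,
                                fqfwf = 0.02, twc = 0.04),
                        age_slope_sd = 0.03, gds_slope_sd = 0.02) {
  groups <- c("CU", "SCD-", "SCD+")
  if (!all(groups %in% names(n)) || any(n < 1))
    stop("n must name all of CU, SCD-, SCD+ with sizes >= 1")
  structure(list(n = n[groups], age_mean = age_mean[groups],
                 age_sd = age_sd[groups], gds_mean = gds_mean[groups],
                 gds_sd = gds_sd[groups], wmh_log_mean = wmh_log_mean,
                 wmh_log_sd = wmh_log_sd, wmh_age_slope = wmh_age_slope,
                 effects = effects, z_slope = z_slope,
                 baselines = baselines, sds = sds,
                 age_slope_sd = age_slope_sd, gds_slope_sd = gds_slope_sd),
            class = "mct2_cohort_spec")
}

# draw n pairs of hippocampal Z-scores subject to the group constraint:
# CU and SCD- require both >= -1, SCD+ requires min < -1
draw_z_pair <- function(n, mean, sd, atrophic) {
  zl <- numeric(n); zr <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      z <- rnorm(2, mean, sd)
      ok <- if (atrophic) min(z) < -1 else all(z >= -1)
      if (ok) break
    }
    zl[i] <- z[1]; zr[i] <- z[2]
  }
  cbind(zl, zr)
}

#' Generate a synthetic subject table with regional biomarker means
#'
#' Subjects are drawn group by group: covariates from the per-group
#' distributions, hippocampal Z-scores satisfying each group's defining
#' constraint by construction (CU and SCD- both `Z >= -1`; SCD+
#' `min(Z_left, Z_right) < -1`), and regional biomarker means as
#' `baseline + covariate effects + group effect (in SD units) + noise`.
#' Cortical signature means are produced for all five metrics; hippocampal
#' per-side means for FQFWF, IEWF and T2IE (the hippocampal follow-up
#' metrics), optionally coupled to the hippocampal Z-score via
#' `spec$z_slope`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return A data.frame with one row per subject: `subject`, `group`,
#'   `scc` (complaints flag), `age`, `gds`, `z_hip_left`, `z_hip_right`,
#'   `wmh_log`, the signature metric columns `mwf`, `iewf`, `t2ie`,
#'   `fqfwf`, `twc`, and `fqfwf_hip_left` etc. for the follow-up metrics.
#' @examples
#' coh <- generate_cohort(cohort_spec(), seed = 1)
#' table(coh$group)
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "mct2_cohort_spec"))
  set.seed(seed)
  groups <- names(spec$n)
  rows <- lapply(groups, function(g) {
    n <- spec$n[[g]]
    age <- rnorm(n, spec$age_mean[[g]], spec$age_sd[[g]])
    gds <- pmin(15, pmax(0, round(rnorm(n, spec$gds_mean[[g]],
                                        spec$gds_sd[[g]]))))
    z <- if (g == "SCD+") draw_z_pair(n, -0.8, 0.6, atrophic = TRUE)
         else if (g == "SCD-") draw_z_pair(n, -0.1, 0.6, atrophic = FALSE)
         else draw_z_pair(n, 0.2, 0.7, atrophic = FALSE)
    data.frame(group = g, scc = g != "CU", age = age, gds = as.numeric(gds),
               z_hip_left = z[, 1], z_hip_right = z[, 2],
               wmh_log = rnorm(n, spec$wmh_log_mean, spec$wmh_log_sd) +
                 spec$wmh_age_slope * (age - 65),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- cbind(subject = sprintf("S%03d", seq_len(nrow(df))), df,
              stringsAsFactors = FALSE)

  metrics <- names(spec$baselines)
  eff <- function(metric, group) {
    e <- spec$effects[[metric]]
    if (is.null(e) || is.na(e[group])) 0 else unname(e[group])
  }
  for (m in metrics) {
    sdm <- spec$sds[[m]]
    shift <- vapply(df$group, eff, numeric(1), metric = m)
    df[[m]] <- spec$baselines[[m]] +
      sdm * (spec$age_slope_sd * (df$age - 65) +
             spec$gds_slope_sd * df$gds + shift) +
      rnorm(nrow(df), 0, sdm)
  }
  zsl <- function(m) if (m %in% names(spec$z_slope)) spec$z_slope[[m]] else 0
  for (m in c("fqfwf", "iewf", "t2ie")) {
    sdm <- spec$sds[[m]]
    shift <- vapply(df$group, eff, numeric(1), metric = m)
    for (side in c("left", "right")) {
      zv <- df[[paste0("z_hip_", side)]]
      df[[paste0(m, "_hip_", side)]] <- spec$baselines[[m]] +
        sdm * (spec$age_slope_sd * (df$age - 65) +
               spec$gds_slope_sd * df$gds + shift + zsl(m) * zv) +
        rnorm(nrow(df), 0, sdm)
    }
  }
  rownames(df) <- NULL
  df
}
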