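# Internal: orthonormal bases of the reduced (covariates) and full
# (covariates + group) design spaces, shared by the permutation routines.
build_designs <- function(group, covariates, n) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2) stop("need at least 2 groups")
  if (any(table(group) < 2)) stop("every group needs n >= 2")
  Xr <- if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0)
    matrix(1, n, 1)
  else model.matrix(~ ., data = as.data.frame(covariates))
  Xf <- cbind(Xr, model.matrix(~ group)[, -1, drop = FALSE])
  qrf <- qr(Xf)
  if (qrf$rank < ncol(Xf))
    stop("singular design: rank ", qrf$rank, " < ", ncol(Xf), " columns")
  list(group = group,
       Qr = qr.Q(qr(Xr)), Qf = qr.Q(qrf),
       df1 = nlevels(group) - 1L, df2 = n - ncol(Xf),
       p_r = ncol(Xr))
}

# residual sums of squares of each column of Y against an orthonormal basis Q
rss_cols <- function(Y, Q) {
  colSums(Y^2) - colSums(crossprod(Q, Y)^2)
}

#' ANCOVA group F-test with Freedman-Lane permutation inference
#'
#' Tests the group factor on top of nuisance covariates by comparing nested
#' linear models (full: covariates + group; reduced: covariates only):
#' `F = [(RSS_r - RSS_f) / df1] / [RSS_f / df2]`. The permutation p-value
#' uses the Freedman-Lane scheme — residuals of the reduced model are
#' permuted and added back to the reduced-model fit, and the full statistic
#' is recomputed — which is the standard scheme for permutation inference
#' with nuisance covariates in neuroimaging. `p = (1 + #[F* >= F]) /
#' (n_perm + 1)`, bounded below by `1/(n_perm + 1)`.
#'
#' @param values Numeric response vector.
#' @param group Factor (or coercible) with >= 2 levels, each of size >= 2.
#' @param covariates Optional data.frame of numeric nuisance covariates.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed for the permutations.
#' @return A list of class `mct2_stat`: `statistic`, `df`, `p_param`,
#'   `p_perm`, `n_perm`, `method`.
#' @export
ancova_f <- function(values, group, covariates = NULL, n_perm = 999L,
                     seed = NULL) {
  y <- as.numeric(values)
  n <- length(y)
  dz <- build_designs(group, covariates, n)
  rss_r <- unname(rss_cols(cbind(y), dz$Qr))
  rss_f <- unname(rss_cols(cbind(y), dz$Qf))
  Fobs <- ((rss_r - rss_f) / dz$df1) / (rss_f / dz$df2)
  p_param <- pf(Fobs, dz$df1, dz$df2, lower.tail = FALSE)

  if (!is.null(seed)) set.seed(seed)
  fit_r <- y - as.numeric(dz$Qr %*% crossprod(dz$Qr, y))  # reduced residuals
  base_r <- y - fit_r
  Yp <- vapply(seq_len(n_perm), function(i) base_r + fit_r[sample.int(n)],
               numeric(n))
  rssr_p <- rss_cols(Yp, dz$Qr)
  rssf_p <- rss_cols(Yp, dz$Qf)
  Fp <- ((rssr_p - rssf_p) / dz$df1) / (rssf_p / dz$df2)
  p_perm <- (1 + sum(Fp >= Fobs)) / (n_perm + 1)

  structure(list(statistic = Fobs, df = c(dz$df1, dz$df2),
                 p_param = p_param, p_perm = p_perm, n_perm = n_perm,
                 method = "ANCOVA F (Freedman-Lane permutation)"),
            class = "mct2_stat")
}

#' Pairwise two-sample t-test with covariates and permutation inference
#'
#' Two-group contrast adjusted for the same nuisance covariates, reported
#' as a signed t statistic for the second level minus the first. Two-sided
#' p-values; the permutation scheme is Freedman-Lane as in [ancova_f()].
#'
#' @inheritParams ancova_f
#' @param group Factor with exactly 2 levels.
#' @return An `mct2_stat` list; `statistic` is the signed t value and
#'   `contrast` names the direction.
#' @export
pairwise_t <- function(values, group, covariates = NULL, n_perm = 999L,
                       seed = NULL) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2) stop("pairwise_t needs exactly 2 groups")
  y <- as.numeric(values)
  n <- length(y)
  dz <- build_designs(group, covariates, n)
  g <- as.numeric(group == levels(group)[2])
  g_res <- g - as.numeric(dz$Qr %*% crossprod(dz$Qr, g))
  gg <- sum(g_res^2)
  if (gg < 1e-12) stop("group indicator collinear with covariates")

  t_of <- function(Y) {
    beta <- as.numeric(crossprod(g_res, Y)) / gg
    rssf <- unname(rss_cols(Y, dz$Qf))
    beta / sqrt(rssf / dz$df2 / gg)
  }
  tobs <- t_of(cbind(y))
  p_param <- 2 * pt(abs(tobs), dz$df2, lower.tail = FALSE)

  if (!is.null(seed)) set.seed(seed)
  fit_r <- y - as.numeric(dz$Qr %*% crossprod(dz$Qr, y))
  base_r <- y - fit_r
  Yp <- vapply(seq_len(n_perm), function(i) base_r + fit_r[sample.int(n)],
               numeric(n))
  tp <- t_of(Yp)
  p_perm <- (1 + sum(abs(tp) >= abs(tobs))) / (n_perm + 1)

  structure(list(statistic = tobs, df = dz$df2, p_param = p_param,
                 p_perm = p_perm, n_perm = n_perm,
                 contrast = paste(levels(group)[2], "-", levels(group)[1]),
                 method = "two-sample t, covariate-adjusted (Freedman-Lane)"),
            class = "mct2_stat")
}

#' Per-metric group models with Bonferroni correction
#'
#' Fits one covariate-adjusted group F-test ([ancova_f()]) per metric
#' column of a subject table and multiplies p-values by the family size
#' (Bonferroni). This is the regional "signature" analysis: Group as fixed
#' factor, age and depressive-symptom scores as covariates; a hippocampal
#' follow-up is obtained by passing the per-side metric columns and adding
#' the matching hippocampal Z-score to `covariate_cols`. Rows with missing
#' values are excluded listwise and the count reported.
#'
#' @param data Subject table (e.g. from [generate_cohort()]).
#' @param metric_cols Metric column names; the Bonferroni family.
#' @param covariate_cols Covariate column names (default `age`, `gds`).
#' @param group_col Group column name.
#' @param n_perm,seed Passed to [ancova_f()].
#' @return data.frame with one row per metric: `metric`, `F`, `df1`, `df2`,
#'   `p_param`, `p_perm`, `p_bonferroni` (permutation p corrected),
#'   `n_used`, `n_excluded`, `n_tests`.
#' @export
signature_models <- function(data, metric_cols = c("mwf", "iewf", "t2ie",
                                                   "fqfwf", "twc"),
                             covariate_cols = c("age", "gds"),
                             group_col = "group", n_perm = 999L,
                             seed = NULL) {
  missing_cols <- setdiff(c(metric_cols, covariate_cols, group_col),
                          names(data))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  m <- length(metric_cols)
  rows <- lapply(metric_cols, function(mc) {
    keep <- stats::complete.cases(data[, c(mc, covariate_cols, group_col)])
    d <- data[keep, ]
    st <- ancova_f(d[[mc]], d[[group_col]],
                   d[covariate_cols], n_perm = n_perm)
    data.frame(metric = mc, F = st$statistic, df1 = st$df[1], df2 = st$df[2],
               p_param = st$p_param, p_perm = st$p_perm,
               p_bonferroni = min(1, st$p_perm * m),
               n_used = nrow(d), n_excluded = sum(!keep), n_tests = m,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
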