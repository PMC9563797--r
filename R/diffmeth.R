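#' Per-set paired M-value differences
#'
#' Collapses each patient/control set to one column of differences:
#' `deltaM = mean(patient samples) - mean(control samples)`. Sets with
#' several patient or control samples (replicates, or two matched controls)
#' are averaged before differencing, so the output always has one column
#' per set.
#'
#' @param m matrix of M-values (probes x samples).
#' @param design data.frame with columns `sample_id`, `set`, `role`
#'   (`"patient"`/`"control"`).
#' @return Matrix (probes x sets) of paired differences; column names are
#'   the set ids.
#' @export
pair_differences <- function(m, design) {
  stopifnot(is.matrix(m),
            all(c("sample_id", "set", "role") %in% names(design)))
  missing <- setdiff(design$sample_id, colnames(m))
  if (length(missing))
    stop("samples absent from the M matrix: ", paste(missing, collapse = ", "))
  sets <- unique(design$set)
  if (length(sets) < 2L) stop("need at least 2 patient/control sets")
  out <- matrix(NA_real_, nrow(m), length(sets),
                dimnames = list(rownames(m), as.character(sets)))
  for (j in seq_along(sets)) {
    d <- design[design$set == sets[j], ]
    pats <- d$sample_id[d$role == "patient"]
    ctls <- d$sample_id[d$role == "control"]
    if (length(pats) == 0L || length(ctls) == 0L)
      stop("set ", sets[j], " lacks a patient or a control sample")
    out[, j] <- rowMeans(m[, pats, drop = FALSE]) -
      rowMeans(m[, ctls, drop = FALSE])
  }
  out
}

#' Empirical-Bayes prior on per-CpG variances
#'
#' Method-of-moments fit of a scaled inverse-chi-squared prior
#' `s^2 ~ s0^2 * chisq(d0) / d0` to the observed per-CpG variances, using
#' the log-variance representation: with
#' `e_g = log s2_g - digamma(d_g/2) + log(d_g/2)`, solve
#' `trigamma(d0/2) = var(e) - trigamma(d_g/2)` for `d0` by monotone
#' root-finding (Newton on the inverse trigamma), then
#' `s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2))`. If the spread of `e`
#' is no larger than the sampling contribution `trigamma(d_g/2)`, the prior
#' is degenerate: `d0 = Inf`, `s0^2 = exp(mean(e))`.
#'
#' @param s2 per-CpG sample variances (finite, positive; zeros are dropped
#'   with a warning, all-zero is an error).
#' @param df residual degrees of freedom (scalar, or per-CpG vector whose
#'   trigamma/digamma terms are averaged).
#' @return List with `d0` (prior df, possibly `Inf`) and `s02` (prior
#'   variance).
#' @export
fit_variance_prior <- function(s2, df) {
  if (all(s2 == 0, na.rm = TRUE)) stop("all variances are zero")
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 100L)
    stop("need at least 100 CpGs with finite positive variance")
  if (any(!ok)) warning(sum(!ok), " non-positive/non-finite variances dropped")
  s2 <- s2[ok]
  df <- if (length(df) == 1L) rep(df, length(s2)) else df[ok]
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e)
  target <- evar - mean(trigamma(df / 2))
  if (!is.finite(target) || target <= 0)
    return(list(d0 = Inf, s02 = exp(emean)))
  d0 <- 2 * trigamma_inverse(target)
  list(d0 = d0, s02 = exp(emean + digamma(d0 / 2) - log(d0 / 2)))
}

## Newton iteration for y = trigamma(x); trigamma is strictly decreasing
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Moderated paired t-statistics per CpG
#'
#' For each CpG, the per-set differences are regressed on an intercept
#' (plus optional set-level covariates) by least squares; the intercept is
#' the paired effect. Residual variances are shrunk towards the
#' empirical-Bayes prior, `s2_post = (d0*s02 + df*s2) / (d0 + df)`, and
#' `t = effect / (s_post * sqrt(v11))` with `v11` the intercept's unscaled
#' variance from `(X'X)^{-1}`. Two-sided p-values use `d0 + df` degrees of
#' freedom (normal when `d0 = Inf`), and are Benjamini-Hochberg adjusted.
#'
#' When every CpG has zero residual variance and zero effect (a noiseless
#' null input) the statistics degenerate: such CpGs are reported with
#' `t = 0`, `p = 1` rather than erroring, so a null input yields a null
#' result.
#'
#' @param delta_m matrix (probes x sets) from [pair_differences()].
#' @param covariates optional data.frame/matrix of set-level covariates
#'   (one row per set, e.g. age difference, sex); must be full rank.
#' @param prior optional list `(d0, s02)`; fitted from the data when `NULL`.
#' @return A data.frame of class `"ranked_stats"` with columns `probe_id`,
#'   `effect`, `s2`, `t`, `df_total`, `p`, `p_adj`, `direction`
#'   (`"hyper"`/`"hypo"` by sign of t, `"none"` at t = 0) and attributes
#'   `d0`, `s02`, `df_residual`.
#' @export
moderated_t <- function(delta_m, covariates = NULL, prior = NULL) {
  stopifnot(is.matrix(delta_m))
  n <- ncol(delta_m)
  X <- matrix(1, n, 1)
  if (!is.null(covariates)) {
    cv <- as.matrix(data.frame(covariates))
    stopifnot(nrow(cv) == n)
    X <- cbind(X, cv)
  }
  q <- ncol(X)
  if (n < q + 1L) stop("need at least ", q + 1L, " sets for ", q, " coefficients")
  if (qr(X)$rank < q) stop("covariate matrix is rank-deficient")

  XtXi <- solve(crossprod(X))
  v11 <- XtXi[1, 1]
  H <- XtXi %*% t(X)                      # coefficients = H %*% y
  coef <- delta_m %*% t(H)                # probes x q
  fitted <- coef %*% t(X)
  res <- delta_m - fitted
  df_res <- n - q
  s2 <- rowSums(res^2) / df_res
  effect <- coef[, 1]

  degenerate <- all(s2 == 0)
  if (is.null(prior)) {
    prior <- if (degenerate) list(d0 = Inf, s02 = 0)
    else fit_variance_prior(s2, df_res)
  }
  d0 <- prior$d0
  s02 <- prior$s02

  if (is.infinite(d0)) {
    s2_post <- rep(s02, length(s2))
    df_total <- rep(Inf, length(s2))
  } else {
    s2_post <- (d0 * s02 + df_res * s2) / (d0 + df_res)
    df_total <- rep(d0 + df_res, length(s2))
  }
  se <- sqrt(s2_post * v11)
  t <- ifelse(se > 0, effect / se, ifelse(effect == 0, 0, sign(effect) * Inf))
  p <- ifelse(is.finite(df_total),
              2 * stats::pt(-abs(t), df_total),
              2 * stats::pnorm(-abs(t)))
  p[t == 0] <- 1
  p <- pmax(p, .Machine$double.xmin)      # p in (0, 1]
  out <- data.frame(
    probe_id = rownames(delta_m), effect = effect, s2 = s2, t = t,
    df_total = df_total, p = p, p_adj = adjust_bh(p),
    direction = ifelse(t > 0, "hyper", ifelse(t < 0, "hypo", "none")),
    row.names = NULL)
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  attr(out, "df_residual") <- df_res
  class(out) <- c("ranked_stats", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control; monotone in rank and capped at 1.
#'
#' @param p vector of p-values in \[0, 1\] (no NAs).
#' @return Adjusted p-values.
#' @export
adjust_bh <- function(p) {
  if (anyNA(p)) stop("NA p-values are not allowed")
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Full paired differential-methylation stage
#'
#' Convenience wrapper: filter probes, compute betas and M-values, paired
#' differences and moderated t-statistics.
#'
#' @param intensities an [intensity_matrix()].
#' @param design paired design data.frame.
#' @param annotation annotation for filtering.
#' @param covariates optional set-level covariates for [moderated_t()].
#' @param detection_threshold,offset,clip_eps see the underlying stages.
#' @param probes optional probe-id subset defining the analysis universe
#'   (e.g. a region-exclusion rerun); applied after filtering.
#' @return List with `stats` (a `ranked_stats`), `m` (M-value matrix on the
#'   retained universe), `beta`, `retained`, `removed`.
#' @export
run_diffmeth <- function(intensities, design, annotation, covariates = NULL,
                         detection_threshold = 0.01, offset = 100,
                         clip_eps = 1e-6, probes = NULL) {
  filt <- filter_probes(intensities, annotation, detection_threshold)
  keep <- filt$retained
  if (!is.null(probes)) keep <- intersect(keep, probes)
  beta <- compute_beta(intensities, offset)[keep, , drop = FALSE]
  m <- compute_m(beta, clip_eps)
  dm <- pair_differences(m, design)
  stats <- moderated_t(dm, covariates)
  list(stats = stats, m = m, beta = beta,
       retained = keep, removed = filt$removed)
}
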