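#' Per-player correlation of sprint velocity with cumulative work
#'
#' Pearson correlation between the per-cycle peak sprint velocity
#' (percentage of the player's overall maximum) and the cumulative positive
#' work of the chosen variant.
#'
#' @param series `player_series` data.frame.
#' @param work_variant one of `"tot"`, `"ext"`, `"int"`, `"pelvis"`, `"bb"`
#'   (positive work) or `"tot_neg"`, `"ext_neg"`.
#' @return list with `r` and `n` (cycle count).
#' @export
player_correlation <- function(series, work_variant = "tot") {
  col <- paste0("cum_", work_variant)
  if (!col %in% names(series)) stop("unknown work variant: ", work_variant)
  x <- series[[col]]
  y <- series$peak_velocity_pct
  n <- length(x)
  if (n < 3L) stop("need at least 3 cycles for a correlation")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance in ",
         if (stats::sd(x) == 0) "cumulative work" else "peak velocity")
  list(r = stats::cor(x, y), n = n)
}

#' Random-effects pooled correlation (Fisher-z scale)
#'
#' Pools per-player Pearson coefficients while accounting for random
#' between-player effects and unequal cycle counts: each r is Fisher-z
#' transformed with sampling variance `1/(n - 3)`; the between-player
#' variance `tau2` is estimated by the DerSimonian-Laird moment estimator
#' (truncated at 0); the pooled z uses weights `1/(1/(n_i - 3) + tau2)`,
#' and the pooled estimate with its 95% CI is back-transformed through
#' `tanh`. A single player returns that player's r with its own
#' large-sample CI.
#'
#' @param r per-player Pearson coefficients.
#' @param n per-player cycle counts (all must exceed 3).
#' @param conf confidence level (default 0.95).
#' @return list of class `pooled_correlation` with `r_pooled`, `ci_low`,
#'   `ci_high`, `tau2`, `k`.
#' @export
pooled_correlation <- function(r, n, conf = 0.95) {
  if (length(r) != length(n)) stop("r and n differ in length")
  if (any(abs(r) > 1)) stop("correlations must lie in [-1, 1]")
  bad <- which(n <= 3L)
  if (length(bad))
    stop("player(s) ", paste(bad, collapse = ", "),
         " have n <= 3 cycles; Fisher-z variance 1/(n-3) undefined")
  zcrit <- stats::qnorm(1 - (1 - conf) / 2)
  # clamp |r| = 1 (noise-free limit) so atanh stays finite
  z <- atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
  vi <- 1 / (n - 3)
  k <- length(z)
  if (k == 1L) {
    se <- sqrt(vi)
    out <- list(r_pooled = tanh(z), ci_low = tanh(z - zcrit * se),
                ci_high = tanh(z + zcrit * se), tau2 = 0, k = 1L)
    class(out) <- "pooled_correlation"
    return(out)
  }
  wi <- 1 / vi
  z_fe <- sum(wi * z) / sum(wi)
  Q <- sum(wi * (z - z_fe)^2)
  c_dl <- sum(wi) - sum(wi^2) / sum(wi)
  tau2 <- max((Q - (k - 1)) / c_dl, 0)
  wr <- 1 / (vi + tau2)
  z_re <- sum(wr * z) / sum(wr)
  se <- sqrt(1 / sum(wr))
  out <- list(r_pooled = tanh(z_re),
              ci_low = tanh(z_re - zcrit * se),
              ci_high = tanh(z_re + zcrit * se),
              tau2 = tau2, k = k)
  class(out) <- "pooled_correlation"
  out
}

#' Qualitative magnitude of a correlation
#'
#' Labels `|r|` against the thresholds 0.5, 0.7 and 0.9 (strictly above):
#' large, very large, extremely large; anything at or below 0.5 is reported
#' as trivial-to-moderate.
#'
#' @param r correlation coefficient in [-1, 1].
#' @return character label.
#' @export
magnitude_label <- function(r) {
  if (abs(r) > 1) stop("|r| must not exceed 1")
  a <- abs(r)
  if (a > 0.9) "extremely large"
  else if (a > 0.7) "very large"
  else if (a > 0.5) "large"
  else "trivial-to-moderate"
}

#' Repeated-measures Bland-Altman agreement
#'
#' Agreement between a reference and a proxy measurement with multiple
#' trials per subject, where the true value varies between trials. Per-pair
#' differences `d = proxy - reference` are decomposed by one-way
#' random-effects ANOVA over subjects into within- and between-subject
#' variance components (unequal trial counts handled via the standard n0
#' coefficient); the 95% limits of agreement are
#' `bias +/- 1.96 sqrt(sd_within^2 + sd_between^2)`.
#'
#' @param reference,proxy numeric vectors of paired work values (J/kg).
#' @param subject subject identifier per pair (>= 2 subjects).
#' @return list of class `agreement_result` with `bias`, `loa_halfwidth`,
#'   `sd_within`, `sd_between`, `loa_low`, `loa_high`.
#' @export
rm_bland_altman <- function(reference, proxy, subject) {
  if (length(reference) != length(proxy) || length(proxy) != length(subject))
    stop("reference, proxy and subject must be the same length")
  d <- proxy - reference
  subject <- factor(subject)
  k <- nlevels(subject)
  if (k < 2L)
    stop("degenerate decomposition: need at least 2 subjects")
  ni <- as.numeric(table(subject))
  N <- length(d)
  grand <- mean(d)
  means <- tapply(d, subject, mean)
  ssb <- sum(ni * (means - grand)^2)
  ssw <- sum((d - means[subject])^2)
  msb <- ssb / (k - 1)
  msw <- if (N - k > 0) ssw / (N - k) else 0
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  var_between <- max((msb - msw) / n0, 0)
  var_within <- msw
  halfwidth <- 1.96 * sqrt(var_within + var_between)
  out <- list(bias = grand, loa_halfwidth = halfwidth,
              sd_within = sqrt(var_within), sd_between = sqrt(var_between),
              loa_low = grand - halfwidth, loa_high = grand + halfwidth)
  class(out) <- "agreement_result"
  out
}

#' Minimal detectable correlation for a given design
#'
#' Smallest population correlation for which a two-sided Fisher-z test at
#' level `alpha` reaches the requested power with `n` paired observations:
#' the solution of `atanh(rho) * sqrt(n - 3) = z_{1-alpha/2} + z_power`.
#'
#' @param n sample size (>= 4).
#' @param alpha two-sided significance level.
#' @param power target power.
#' @return minimal detectable `r`.
#' @export
min_detectable_r <- function(n, alpha = 0.05, power = 0.8) {
  if (n < 4L) stop("need n >= 4")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("alpha and power must lie in (0, 1)")
  tanh((stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) / sqrt(n - 3))
}
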