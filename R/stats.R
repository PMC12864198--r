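#' Winsorise extreme values
#'
#' Values lying more than `z_limit` standard deviations from the mean are
#' replaced by the boundary value `mean +/- z_limit * sd`. Mean and sample
#' sd are computed once from the ORIGINAL vector (single pass, no
#' re-iteration), so re-applying with the same bounds is idempotent. The
#' default limit 3.29 corresponds to the two-sided 0.001 normal quantile.
#'
#' @param values Numeric vector (length >= 3).
#' @param z_limit Threshold in standard deviations.
#' @return Vector of the same length with extremes clamped.
#' @examples
#' winsorize(c(rep(0, 100), 1e6))
#' @export
winsorize <- function(values, z_limit = 3.29) {
  if (length(values) < 3) stop("need at least 3 values")
  m <- mean(values)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    message("winsorize: zero variance, returning input unchanged")
    return(values)
  }
  pmin(pmax(values, m - z_limit * s), m + z_limit * s)
}

#' Paired t test with effect size and Bayes factor
#'
#' Two-tailed paired t test on the differences `x - y`, reporting the mean
#' difference with its 95% CI, Cohen's d_z (mean difference over the sd of
#' differences, identically `t / sqrt(n)`), and the JZS Bayes factor BF10
#' from [jzs_bf_ttest()].
#'
#' @param x,y Paired numeric vectors of equal length (n >= 3).
#' @param cauchy_scale Cauchy prior scale for the Bayes factor.
#' @return A list of class `swi_paired_test`: `n`, `mean_diff`, `ci95`,
#'   `t`, `df`, `p`, `d_z`, `bf10`.
#' @examples
#' paired_t(c(1, 2, 3), c(1, 3, 5))
#' @export
paired_t <- function(x, y, cauchy_scale = 0.707) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- stats::complete.cases(x, y)
  d <- (x - y)[keep]
  n <- length(d)
  if (n < 3) stop("need at least 3 complete pairs")
  sd_d <- stats::sd(d)
  if (!is.finite(sd_d) || sd_d == 0) {
    stop("zero variance in paired differences")
  }
  md <- mean(d)
  se <- sd_d / sqrt(n)
  df <- n - 1
  tval <- md / se
  p <- 2 * stats::pt(-abs(tval), df)
  half <- stats::qt(0.975, df) * se
  structure(
    list(n = n, mean_diff = md, ci95 = c(md - half, md + half),
         t = tval, df = df, p = p, d_z = md / sd_d,
         bf10 = jzs_bf_ttest(tval, n, cauchy_scale)),
    class = "swi_paired_test"
  )
}

#' @export
print.swi_paired_test <- function(x, ...) {
  cat(sprintf(
    "paired t: mean diff = %.4g, 95%% CI [%.4g, %.4g]\n  t(%d) = %.3f, p = %.4g, d_z = %.3f, BF10 = %.4g\n",
    x$mean_diff, x$ci95[1], x$ci95[2], x$df, x$t, x$p, x$d_z, x$bf10))
  invisible(x)
}

#' Wilcoxon signed-rank test for paired data
#'
#' `V` is the sum of the ranks of positive differences among the ranks of
#' `|x - y|` (zero differences dropped, average ranks for ties). The
#' p value is exact when there are at most 25 nonzero differences and no
#' ties; otherwise the normal approximation with continuity correction is
#' used.
#'
#' @param x,y Paired numeric vectors.
#' @return A list with `V`, `p`, `n` (nonzero differences), and `exact`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  d <- x - y
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0) stop("all paired differences are zero")
  ties <- any(duplicated(abs(d)))
  exact <- n <= 25 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(d, exact = exact, correct = TRUE)
  )
  list(V = unname(wt$statistic), p = wt$p.value, n = n, exact = exact)
}

#' Shapiro-Wilk normality gate for paired contrasts
#'
#' Tests the supplied values (typically paired differences) for departure
#' from normality. When the test rejects at `alpha`, the contrast should be
#' routed to [wilcoxon_signed_rank()] instead of [paired_t()].
#'
#' @param values Numeric vector, 3..5000 observations.
#' @param alpha Significance level of the gate.
#' @return A list with `nonnormal` (route to the rank test when `TRUE`),
#'   `W`, and `p`.
#' @export
shapiro_wilk_gate <- function(values, alpha = 0.05) {
  sw <- stats::shapiro.test(values)
  list(nonnormal = sw$p.value < alpha, W = unname(sw$statistic),
       p = sw$p.value)
}

#' Within-subjects ANOVA on z-scored heaviness ratings
#'
#' Aggregates z-scored test-trial ratings to one cell mean per participant
#' in each size x weight x condition cell (2 x 2 x 2), then fits the
#' classical repeated-measures ANOVA in which every effect is tested
#' against its own participant-by-effect interaction stratum. Reports F,
#' numerator/denominator dfs, p, and partial eta squared
#' `SS_effect / (SS_effect + SS_error)` for the three main effects and all
#' interactions.
#'
#' @param ztrials Z-scored test trials from [zscore_ratings()] (columns
#'   `participant_id`, `condition`, `object`, `z_rating`).
#' @return Data frame with one row per term: `term`, `F`, `df_num`,
#'   `df_den`, `p`, `partial_eta_sq`.
#' @export
rm_anova_ratings <- function(ztrials) {
  needed <- c("participant_id", "condition", "object", "z_rating")
  missing <- setdiff(needed, names(ztrials))
  if (length(missing) > 0) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  dat <- ztrials[ztrials$object != "medium_washout", , drop = FALSE]
  dat$size <- factor(ifelse(grepl("^small", dat$object), "small", "large"))
  dat$weight <- factor(ifelse(grepl("heavy$", dat$object), "heavy", "light"))
  dat$condition <- factor(dat$condition)
  dat$pid <- factor(dat$participant_id)

  cells <- stats::aggregate(
    z_rating ~ pid + size + weight + condition, data = dat, FUN = mean
  )
  expected <- nlevels(cells$pid) * 8L
  if (nrow(cells) != expected) {
    full <- expand.grid(pid = levels(cells$pid), size = levels(cells$size),
                        weight = levels(cells$weight),
                        condition = levels(cells$condition))
    key <- function(d) paste(d$pid, d$size, d$weight, d$condition)
    miss <- setdiff(key(full), key(cells))
    stop("missing design cell(s): ", paste(miss, collapse = "; "))
  }

  fit <- stats::aov(
    z_rating ~ size * weight * condition +
      Error(pid / (size * weight * condition)),
    data = cells
  )
  out <- list()
  for (stratum in summary(fit)) {
    tab <- stratum[[1]]
    terms <- trimws(rownames(tab))
    resid_i <- which(terms == "Residuals")
    for (i in setdiff(seq_along(terms), resid_i)) {
      ss_eff <- tab[i, "Sum Sq"]
      ss_err <- tab[resid_i, "Sum Sq"]
      out[[length(out) + 1]] <- data.frame(
        term = terms[i],
        F = tab[i, "F value"],
        df_num = tab[i, "Df"],
        df_den = tab[resid_i, "Df"],
        p = tab[i, "Pr(>F)"],
        partial_eta_sq = ss_eff / (ss_eff + ss_err),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' JZS Bayes factor for a paired / one-sample t test
#'
#' Default Bayes factor BF10 contrasting a Cauchy(0, `cauchy_scale`) prior
#' on the standardised effect against the point null. The Cauchy prior is
#' handled through its scale-mixture representation (a normal prior whose
#' relative variance g follows an inverse-gamma(1/2, 1/2) law): the effect
#' is integrated out analytically and the remaining one-dimensional
#' marginal over g is evaluated by adaptive quadrature after mapping
#' g = u / (1 - u) onto the unit interval, which tames the heavy prior
#' tail. Relative integration tolerance 1e-8.
#'
#' @param t Observed t statistic.
#' @param n Number of (pairs of) observations (>= 2).
#' @param cauchy_scale Prior scale; 0.707 (sqrt(2)/2) is the common default.
#' @return BF10, the marginal-likelihood ratio of alternative to null.
#' @examples
#' jzs_bf_ttest(2.05, 25)   # ~ 1.25
#' @export
jzs_bf_ttest <- function(t, n, cauchy_scale = 0.707) {
  if (!is.finite(t) || !is.finite(n)) stop("t and n must be finite")
  if (n < 2) stop("need n >= 2")
  r2 <- cauchy_scale^2
  nu <- n - 1
  log_lik <- function(g_eff) {
    # marginal likelihood of t with effect integrated out; g_eff = n*g*r^2
    -0.5 * log1p(g_eff) -
      (nu + 1) / 2 * log1p(t^2 / ((1 + g_eff) * nu))
  }
  integrand <- function(u) {
    g <- u / (1 - u)
    dens <- exp(log_lik(n * g * r2)) *
      (2 * pi)^(-0.5) * g^(-1.5) * exp(-1 / (2 * g))
    dens / (1 - u)^2
  }
  num <- stats::integrate(integrand, 0, 1, rel.tol = 1e-8,
                          subdivisions = 500L)$value
  num / exp(log_lik(0))
}

#' Zellner-Siow Bayes factor for a linear regression from R-squared
#'
#' Mixture-of-g-priors Bayes factor BF10 for a linear model with `p`
#' predictors against the intercept-only null, computed from the sample
#' R-squared. The g prior is the Zellner-Siow inverse-gamma
#' (1/2, n * scale^2 / 2), i.e. a Cauchy prior of scale `scale` on the
#' standardised coefficients; the one-dimensional integral over g is
#' evaluated by adaptive quadrature on the unit interval. This reproduces
#' the conventional default-prior regression Bayes factor approximately --
#' exactly up to quadrature error for the same prior scale.
#'
#' @param r_sq R-squared of the fitted model, in \[0, 1).
#' @param n Number of observations (> p + 1).
#' @param n_predictors Number of predictors p.
#' @param scale Prior scale on standardised coefficients; default
#'   sqrt(2)/4, the convention for a single continuous covariate.
#' @return BF10.
#' @examples
#' jzs_bf_regression(0.20, 25)  # ~ 2.7
#' @export
jzs_bf_regression <- function(r_sq, n, n_predictors = 1,
                              scale = sqrt(2) / 4) {
  if (!is.finite(r_sq) || r_sq < 0 || r_sq >= 1) {
    stop("r_sq must lie in [0, 1)")
  }
  if (n <= n_predictors + 1) stop("need n > n_predictors + 1")
  p <- n_predictors
  b <- n * scale^2 / 2
  log_f <- function(g) {
    (n - p - 1) / 2 * log1p(g) - (n - 1) / 2 * log1p(g * (1 - r_sq)) +
      0.5 * log(b) - lgamma(0.5) - 1.5 * log(g) - b / g
  }
  integrand <- function(u) exp(log_f(u / (1 - u))) / (1 - u)^2
  stats::integrate(integrand, 0, 1, rel.tol = 1e-8,
                   subdivisions = 500L)$value
}

#' Sample size for a paired t test via the noncentral t distribution
#'
#' Smallest number of pairs for which a paired t test at level `alpha`
#' reaches the target power against a standardised effect `d_z`, computed
#' by upward search from n = 3 with exact noncentral-t power
#' (noncentrality `d_z * sqrt(n)`, df `n - 1`).
#'
#' @param d_z Standardised paired effect size (> 0).
#' @param alpha Two-sided (or one-sided) significance level.
#' @param power Target power.
#' @param tails `"two"` or `"one"`.
#' @return Required number of pairs (integer >= 3).
#' @examples
#' required_n_paired_t(0.7, 0.05, 0.90)  # 24
#' @export
required_n_paired_t <- function(d_z, alpha = 0.05, power = 0.90,
                                tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (!is.finite(d_z) || d_z <= 0) stop("d_z must be positive")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop("alpha and power must lie in (0, 1)")
  }
  achieved <- function(n) {
    df <- n - 1
    ncp <- d_z * sqrt(n)
    if (tails == "two") {
      tcrit <- stats::qt(1 - alpha / 2, df)
      (1 - stats::pt(tcrit, df, ncp)) + stats::pt(-tcrit, df, ncp)
    } else {
      1 - stats::pt(stats::qt(1 - alpha, df), df, ncp)
    }
  }
  n <- 3L
  while (achieved(n) < power) {
    n <- n + 1L
    if (n > 1e6) stop("required sample size exceeds search bound")
  }
  n
}

#' Simple linear regression with Bayes factor
#'
#' OLS regression of `y` on `x` reporting the slope with 95% CI, the model
#' F test, R-squared, and the Zellner-Siow Bayes factor from
#' [jzs_bf_regression()]. Used both for the level analysis (virtual-block
#' SWI on presence) and for the difference-score variant (real minus
#' virtual SWI on presence).
#'
#' @param x Predictor (e.g. presence scores); must have variance.
#' @param y Response (e.g. SWI scores).
#' @param scale Prior scale for the Bayes factor.
#' @return A list of class `swi_regression`: `n`, `intercept`, `beta`,
#'   `ci95`, `F`, `df`, `p`, `r_sq`, `bf10`.
#' @export
simple_regression <- function(x, y, scale = sqrt(2) / 4) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete observations")
  if (stats::sd(x) == 0) stop("predictor has zero variance")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  beta <- unname(stats::coef(fit)[2])
  ci <- stats::confint(fit)["x", ]
  fstat <- sm$fstatistic
  structure(
    list(
      n = n,
      intercept = unname(stats::coef(fit)[1]),
      beta = beta,
      ci95 = unname(ci),
      F = unname(fstat[1]),
      df = unname(c(fstat[2], fstat[3])),
      p = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                           lower.tail = FALSE)),
      r_sq = sm$r.squared,
      # a numerically perfect fit sends the Bayes factor to infinity
      bf10 = if (sm$r.squared >= 1 - 1e-12) Inf
             else jzs_bf_regression(sm$r.squared, n, 1, scale)
    ),
    class = "swi_regression"
  )
}

#' @export
print.swi_regression <- function(x, ...) {
  cat(sprintf(
    "regression: beta = %.4g, 95%% CI [%.4g, %.4g]\n  F(%d, %d) = %.3f, p = %.4g, R^2 = %.3f, BF10 = %.4g\n",
    x$beta, x$ci95[1], x$ci95[2], x$df[1], x$df[2], x$F, x$p, x$r_sq,
    x$bf10))
  invisible(x)
}
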