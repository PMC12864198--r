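test_that("winsorisation clamps only beyond-threshold values", {
  expect_equal(winsorize(c(1, 2, 3, 4, 5)), c(1, 2, 3, 4, 5))
  x <- c(rep(0, 100), 1e6)
  m <- mean(x); s <- sd(x)
  w <- winsorize(x)
  expect_equal(w[101], m + 3.29 * s)
  expect_equal(w[1:100], rep(0, 100))
  # idempotent under the original-sample bounds
  clamp <- function(v) pmin(pmax(v, m - 3.29 * s), m + 3.29 * s)
  expect_equal(clamp(w), w)
  expect_message(winsorize(rep(2, 5)), "zero variance")
  expect_equal(suppressMessages(winsorize(rep(2, 5))), rep(2, 5))
  expect_error(winsorize(c(1, 2)), "at least 3")
})

test_that("paired t test matches the hand-computed example", {
  res <- paired_t(c(1, 2, 3), c(1, 3, 5))
  expect_equal(res$mean_diff, -1)
  expect_equal(res$t, -sqrt(3))
  expect_equal(res$df, 2)
  expect_equal(res$p, 2 * pt(-sqrt(3), 2))
  expect_equal(res$d_z, -1)
  expect_true(res$ci95[1] <= res$mean_diff & res$mean_diff <= res$ci95[2])
  expect_error(paired_t(1:5, 1:5), "zero variance")
})

test_that("d_z equals t/sqrt(n) and the CI is dual to the p value", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    x <- rnorm(n, 0.2)
    y <- rnorm(n)
    res <- paired_t(x, y)
    expect_equal(res$d_z, res$t / sqrt(res$n))
    excludes0 <- res$ci95[1] > 0 || res$ci95[2] < 0
    expect_equal(excludes0, res$p < 0.05)
    # agreement with stats::t.test
    tt <- t.test(x, y, paired = TRUE)
    expect_equal(res$t, unname(tt$statistic))
    expect_equal(res$p, tt$p.value)
  }
})

test_that("Wilcoxon V and exact p match sign-flip enumeration", {
  res <- wilcoxon_signed_rank(c(2, 3, 4), c(1, 1, 1))  # d = 1, 2, 3
  expect_equal(res$V, 6)
  expect_equal(res$p, 0.25)
  expect_equal(wilcoxon_signed_rank(c(1, 1, 1), c(2, 3, 4))$V, 0)
  expect_error(wilcoxon_signed_rank(1:4, 1:4), "zero")

  set.seed(11)
  for (n in 3:8) {
    d <- round(runif(n, 0.5, 10), 3)          # tie-free magnitudes
    d <- d * sample(c(-1, 1), n, replace = TRUE)
    res <- wilcoxon_signed_rank(d, rep(0, n))
    r <- rank(abs(d))
    v_obs <- sum(r[d > 0])
    # enumerate all 2^n sign assignments
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vs <- signs %*% r
    expect_equal(res$V, v_obs)
    p_lo <- mean(vs <= v_obs)
    p_hi <- mean(vs >= v_obs)
    p_exact <- min(1, 2 * if (v_obs > n * (n + 1) / 4) p_hi else p_lo)
    expect_equal(res$p, p_exact)
  }
})

test_that("large or tied samples use the corrected normal approximation", {
  set.seed(13)
  x <- rnorm(30, 0.5)
  y <- rnorm(30)
  res <- wilcoxon_signed_rank(x, y)
  expect_false(res$exact)
  ref <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = FALSE,
                                      correct = TRUE))
  expect_equal(res$V, unname(ref$statistic))
  expect_equal(res$p, ref$p.value)
})

test_that("the normality gate rejects skewed and passes normal samples", {
  set.seed(17)
  skewed <- mean(vapply(1:300, function(i) {
    shapiro_wilk_gate(rlnorm(24))$nonnormal
  }, logical(1)))
  expect_gt(skewed, 0.6)
  normal <- mean(vapply(1:300, function(i) {
    shapiro_wilk_gate(rnorm(24))$nonnormal
  }, logical(1)))
  expect_gt(normal, 0.005)
  expect_lt(normal, 0.12)
})

test_that("the within-subjects ANOVA matches a hand-computed SS oracle", {
  set.seed(23)
  grid <- expand.grid(participant_id = 1:2,
                      size = c("small", "large"),
                      weight = c("light", "heavy"),
                      condition = c("real", "virtual"))
  grid$object <- paste(grid$size, grid$weight, sep = "_")
  grid$z_rating <- rnorm(16)
  tab <- rm_anova_ratings(grid)

  m <- mean(grid$z_rating)
  cell <- function(...) tapply(grid$z_rating, list(...), mean)
  # main-effect SS: levels x participants x remaining cells
  ss_main <- function(f) 8 * sum((tapply(grid$z_rating, f, mean) - m)^2)
  ss_err_main <- function(f) {
    mp <- tapply(grid$z_rating, grid$participant_id, mean)
    ma <- tapply(grid$z_rating, f, mean)
    mpa <- tapply(grid$z_rating, list(grid$participant_id, f), mean)
    4 * sum((mpa - outer(mp, rep(0, 2), "+") -
               outer(rep(0, 2), ma, "+") + m)^2)
  }
  for (eff in c("size", "weight", "condition")) {
    f <- grid[[eff]]
    F_oracle <- ss_main(f) / ss_err_main(f)  # df 1 over df 1
    row <- tab[tab$term == eff, ]
    expect_equal(row$F, F_oracle, tolerance = 1e-8)
    expect_equal(row$df_num, 1)
    expect_equal(row$df_den, 1)
  }
  # partial eta squared identity for every term
  expect_equal(tab$partial_eta_sq,
               (tab$F * tab$df_num) / (tab$F * tab$df_num + tab$df_den))
  expect_equal(nrow(tab), 7)
})

test_that("the ANOVA table is invariant to adding a constant", {
  cfg <- swi_config(n_participants = 6, seed = 29)
  z <- zscore_ratings(simulate_ratings(cfg))
  t1 <- rm_anova_ratings(z)
  z$z_rating <- z$z_rating + 5
  t2 <- rm_anova_ratings(z)
  expect_equal(t1$F, t2$F)
  expect_equal(t1$partial_eta_sq, t2$partial_eta_sq)
})

test_that("ANOVA detects a weight effect and holds its size at alpha", {
  rej <- matrix(NA, 100, 3,
                dimnames = list(NULL, c("weight", "size", "condition")))
  for (i in 1:100) {
    cfg <- swi_config(
      n_participants = 10, seed = 4000 + i,
      rating_model = list(betaV_mean = 0, betaV_sd = 0,
                          betaV_condition_sd = 0,
                          condition_deltas = c(real = 0, virtual = 0)))
    tab <- rm_anova_ratings(zscore_ratings(simulate_ratings(cfg)))
    for (term in colnames(rej)) {
      rej[i, term] <- tab$p[tab$term == term] < 0.05
    }
  }
  expect_equal(mean(rej[, "weight"]), 1)
  expect_lt(mean(rej[, "size"]), 0.15)
  expect_lt(mean(rej[, "condition"]), 0.15)
})

test_that("missing design cells are reported", {
  grid <- expand.grid(participant_id = 1:3,
                      object = c("small_light", "small_heavy",
                                 "large_light", "large_heavy"),
                      condition = c("real", "virtual"))
  grid$z_rating <- rnorm(nrow(grid))
  grid <- grid[!(grid$participant_id == 2 & grid$object == "large_heavy" &
                   grid$condition == "virtual"), ]
  expect_error(rm_anova_ratings(grid), "missing design cell")
})

test_that("JZS t-test Bayes factors behave like a default Bayes factor", {
  # null-consistent at t = 0, strictly increasing in |t|
  expect_lt(jzs_bf_ttest(0, 20), 1)
  grid <- seq(0, 6, by = 0.5)
  bfs <- vapply(grid, jzs_bf_ttest, numeric(1), n = 24)
  expect_true(all(diff(bfs) > 0))
  expect_equal(jzs_bf_ttest(2, 20), jzs_bf_ttest(-2, 20))
  # Monte-Carlo marginal-likelihood oracle (Cauchy prior draws)
  set.seed(37)
  delta <- rcauchy(2e5, 0, 0.707)
  for (case in list(c(1, 10), c(2.05, 25))) {
    t_obs <- case[1]; n <- case[2]
    lik <- suppressWarnings(dt(t_obs, n - 1, ncp = delta * sqrt(n)))
    est <- mean(lik) / dt(t_obs, n - 1)
    se <- sd(lik) / sqrt(length(lik)) / dt(t_obs, n - 1)
    expect_lt(abs(jzs_bf_ttest(t_obs, n) - est), 3 * se)
  }
  expect_error(jzs_bf_ttest(Inf, 10), "finite")
})

test_that("regression Bayes factors favour the null at R2 = 0 and grow", {
  expect_lt(jzs_bf_regression(0, 25), 1)
  grid <- seq(0, 0.9, by = 0.1)
  bfs <- vapply(grid, jzs_bf_regression, numeric(1), n = 25)
  expect_true(all(diff(bfs) > 0))
  expect_error(jzs_bf_regression(1, 25), "r_sq")
})

test_that("required sample size search matches independent power tools", {
  expect_equal(required_n_paired_t(0.7, 0.05, 0.90), 24)
  expect_equal(required_n_paired_t(10), 3)
  # bracketing: normal-approximation n <= exact n <= approx + 3
  for (d in c(0.3, 0.5, 0.7, 0.9, 1.2)) {
    n <- required_n_paired_t(d)
    approx <- ((qnorm(0.975) + qnorm(0.90)) / d)^2
    expect_gte(n, floor(approx))
    expect_lte(n, ceiling(approx) + 3)
    # independent oracle: stats::power.t.test solves the same model
    cont <- power.t.test(delta = d, sd = 1, sig.level = 0.05, power = 0.90,
                         type = "paired")$n
    expect_equal(n, ceiling(cont))
  }
  expect_error(required_n_paired_t(-1), "positive")
})

test_that("simple regression matches the normal equations", {
  x <- c(1, 2, 4, 5, 9)
  y <- c(2.2, 2.9, 4.5, 4.4, 8.1)
  res <- simple_regression(x, y)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxx <- sum((x - mean(x))^2)
  expect_equal(res$beta, sxy / sxx)
  expect_equal(res$r_sq, cor(x, y)^2)
  perfect <- suppressWarnings(simple_regression(x, 2 * x))
  expect_equal(perfect$r_sq, 1)
  expect_lt(perfect$p, 1e-10)
  expect_error(simple_regression(rep(3, 5), rnorm(5)), "zero variance")
})

test_that("the regression slope test keeps its nominal size", {
  set.seed(41)
  rej <- mean(vapply(1:500, function(i) {
    x <- rnorm(20)
    y <- rnorm(20)
    simple_regression(x, y)$p < 0.05
  }, logical(1)))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.08)
})
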