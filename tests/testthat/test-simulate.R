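test_that("noise-free ratings reproduce the linear model exactly", {
  cfg <- noise_free_config(betaW = 0.01, betaV = -0.5, beta0 = 300)
  r <- simulate_ratings(cfg)
  # 300 + 0.01*430 - 0.5*pi*2.5^2*7.5
  small_light <- unique(round(r$rating[r$object == "small_light"], 6))
  expect_equal(small_light, round(300 + 0.01 * 430 - 0.5 * 147.2622, 6),
               tolerance = 1e-6)
  expect_equal(unique(r$rating[r$object == "small_light"])[1], 230.67,
               tolerance = 1e-4)
})

test_that("without a volume slope, equal-mass objects are rated equally", {
  cfg <- noise_free_config(betaV = 0, betaW = 1, beta0 = 10)
  r <- simulate_ratings(cfg)
  light <- r$rating[r$object %in% c("small_light", "large_light")]
  heavy <- r$rating[r$object %in% c("small_heavy", "large_heavy")]
  expect_equal(length(unique(light)), 1)
  expect_equal(length(unique(heavy)), 1)
  expect_false(unique(light) == unique(heavy))
})

test_that("identical config and seed give identical datasets", {
  cfg <- swi_config(n_participants = 3, seed = 11)
  s1 <- simulate_study(cfg, streams = "none")
  s2 <- simulate_study(cfg, streams = "none")
  expect_identical(s1$ratings, s2$ratings)
  expect_identical(s1$presence, s2$presence)
  s3 <- simulate_study(swi_config(n_participants = 3, seed = 12),
                       streams = "none")
  expect_false(identical(s1$ratings$rating, s3$ratings$rating))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123)
  a <- runif(3)
  set.seed(123)
  invisible(simulate_study(swi_config(n_participants = 2),
                           streams = "none"))
  b <- runif(3)
  expect_identical(a, b)
})

test_that("ratings respect the positive floor and reject bad noise", {
  cfg <- noise_free_config(beta0 = -10000, betaW = 0.01, betaV = 0)
  r <- simulate_ratings(cfg)
  expect_true(all(r$rating > 0))
  expect_equal(min(r$rating), 1e-6)
  expect_error(swi_config(rating_model = list(residual_sd = -1)),
               "residual_sd")
})

test_that("noise-free streams follow the minimum-jerk closed form", {
  cfg <- noiseless_kinematics()
  s <- simulate_stream(cfg, "real")
  d <- differentiate(as.matrix(s[, c("wrist_x_mm", "wrist_y_mm",
                                     "wrist_z_mm")]), s$time_s)
  A <- cfg$kinematic_model$reach_amplitude_mm
  Tr <- cfg$kinematic_model$reach_duration_s[["real"]]
  # peak speed 1.875 * A / T at the reach midpoint (one-sample tolerance)
  expect_equal(max(d$speed), 1.875 * A / Tr, tolerance = 0.005)
  t_peak <- s$time_s[which.max(d$speed)]
  mid <- cfg$kinematic_model$pre_still_s + Tr / 2
  expect_lt(abs(t_peak - mid), 1.5 / cfg$sampling_rate_hz)
})

test_that("the object is stationary until lift onset", {
  cfg <- noiseless_kinematics()
  s <- simulate_stream(cfg, "virtual")
  km <- cfg$kinematic_model
  reach_end <- km$pre_still_s + km$reach_duration_s[["virtual"]]
  during_reach <- s$time_s <= reach_end
  obj <- as.matrix(s[during_reach, c("obj_x_mm", "obj_y_mm", "obj_z_mm")])
  expect_true(all(apply(obj, 2, function(x) diff(range(x))) == 0))
})

test_that("stream length equals rate times duration plus one", {
  cfg <- noiseless_kinematics()
  s <- simulate_stream(cfg, "real")
  km <- cfg$kinematic_model
  total <- km$pre_still_s + km$reach_duration_s[["real"]] +
    km$grasp_pause_s + km$lift_duration_s + cfg$hold_duration_s +
    km$replace_duration_s + km$post_still_s
  expect_equal(nrow(s), length(seq(0, total, by = 1 / 90)))
  expect_lte(abs(nrow(s) - (total * cfg$sampling_rate_hz + 1)), 1)
  expect_equal(median(diff(s$time_s)), 1 / 90)
  expect_error(simulate_stream(cfg, "real", tempo = 0), "tempo")
  expect_error(swi_config(kinematic_model = list(lift_duration_s = -1)),
               "durations")
})

test_that("degenerate presence models hit the scale floor and ceiling", {
  base <- list(latent_sd = 0, item_sd = 0, assoc_slope = 0)
  cfg_hi <- swi_config(n_participants = 3,
                       presence_model = c(base, latent_mean = 7))
  p_hi <- presence_scores(simulate_presence(cfg_hi))
  expect_true(all(p_hi$presence_score == 6))
  cfg_lo <- swi_config(n_participants = 3,
                       presence_model = c(base, latent_mean = 3))
  p_lo <- presence_scores(simulate_presence(cfg_lo))
  expect_true(all(p_lo$presence_score == 0))
})

test_that("zero association slope decouples presence from the SWI", {
  cfg <- swi_config(n_participants = 500, seed = 4,
                    presence_model = list(assoc_slope = 0))
  parts <- draw_participants(cfg)
  pres <- presence_scores(simulate_presence(cfg, parts))
  # u drives the participant-level SWI; with slope 0 the correlation with
  # the presence score should vanish up to Monte-Carlo error at n = 500
  r <- cor(parts$u, pres$presence_score)
  expect_lt(abs(r), 2.5 / sqrt(500))
  # and a positive slope induces a positive u-presence correlation
  cfg2 <- swi_config(n_participants = 500, seed = 4,
                     presence_model = list(assoc_slope = 20))
  pres2 <- presence_scores(simulate_presence(cfg2, parts))
  expect_gt(cor(parts$u, pres2$presence_score), 0.3)
})
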