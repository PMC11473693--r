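test_that("expected-distribution membership requires strictly positive support", {
  phi <- cbind(n1 = c(0.1, -0.05, 0.05, 0.3), n2 = c(0.05, 0.02, -0.05, -0.1),
               t1 = c(-0.2, 0.1, 0.0, -0.1))
  shap <- make_shap(phi, baseline = 0.5)
  E <- expected_distribution(shap, c("n1", "n2"))
  expect_equal(unname(E), c(TRUE, FALSE, FALSE, TRUE)) # row 3 sums to 0
  expect_error(expected_distribution(shap, character(0L)), "empty")
  expect_error(expected_distribution(shap, "missing_var"), "missing_var")
})

test_that("scenario replacement matches hand arithmetic", {
  # site 1: threat -0.2, baseline 0.5, natural sum +0.1, other threat 0
  phi <- cbind(n1 = c(0.1, 0.2), t1 = c(-0.2, 0.4), t2 = c(0, 0))
  shap <- make_shap(phi, baseline = 0.5)
  suppressMessages(
    exp_zero <- expected_suitability(shap, c("t1", "t2"), "zero_negative"))
  expect_equal(exp_zero[[1]], 0.6, tolerance = 1e-12)
  expect_equal(exp_zero[[2]], 0.5 + 0.2 + 0.4, tolerance = 1e-12)
  # mean_positive: t1 recovers to its mean positive value (0.4)
  suppressMessages(
    exp_mean <- expected_suitability(shap, c("t1", "t2"), "mean_positive"))
  expect_equal(exp_mean[[1]], 0.5 + 0.1 + 0.4, tolerance = 1e-12)
  # q95_positive: every site gets the 95th percentile of positives
  q95 <- unname(quantile(0.4, 0.95))
  suppressMessages(
    exp_q95 <- expected_suitability(shap, c("t1", "t2"), "q95_positive"))
  expect_equal(unname(exp_q95), 0.5 + c(0.1, 0.2) + q95, tolerance = 1e-12)
})

test_that("threats with no positive attribution anywhere are logged as zero", {
  phi <- cbind(n1 = c(0.2, 0.1), t1 = c(-0.1, -0.3))
  shap <- make_shap(phi, baseline = 0.4)
  expect_message(e <- expected_suitability(shap, "t1", "q95_positive"),
                 "no positive attribution")
  expect_equal(unname(e), 0.4 + c(0.2, 0.1), tolerance = 1e-12)
})

test_that("unharmed tables leave the observed prediction unchanged", {
  phi <- cbind(n1 = c(0.1, 0.3), t1 = c(0.05, 0.2))
  shap <- make_shap(phi, baseline = 0.4)
  expect_equal(expected_suitability(shap, "t1", "zero_negative"),
               shap$y, tolerance = 1e-12)
  res <- quantitative_shadow(shap, "n1", "t1", "zero_negative")
  expect_equal(res$sites$ratio, c(1, 1), tolerance = 1e-12)
})

test_that("the quantitative shadow ratio is the clamped observed/expected", {
  # observed 0.38 vs expected 0.54 -> ratio 0.7037...
  phi <- cbind(n1 = c(0.1), t1 = c(-0.16), t2 = c(0.04))
  shap <- make_shap(phi, baseline = 0.4) # y = 0.38
  res <- quantitative_shadow(shap, "n1", c("t1", "t2"), "zero_negative")
  expect_equal(res$sites$observed[1L], 0.38, tolerance = 1e-12)
  expect_equal(res$sites$expected[1L], 0.54, tolerance = 1e-12)
  expect_equal(res$sites$ratio[1L], 0.38 / 0.54, tolerance = 1e-12)
})

test_that("ratios are clamped to one and NA outside the expected range", {
  set.seed(1)
  phi <- cbind(n1 = runif(50, -0.3, 0.5), t1 = rnorm(50, 0, 0.2))
  shap <- make_shap(phi, baseline = 0.45)
  res <- quantitative_shadow(shap, "n1", "t1", "q95_positive")
  inE <- res$sites$in_expected
  expect_true(all(is.na(res$sites$ratio[!inE])))
  expect_true(all(res$sites$ratio[inE] >= 0 & res$sites$ratio[inE] <= 1))
  # sites whose own positive attribution beats the q95 replacement exceed
  # their "expected" value and are clamped to exactly 1
  q95 <- quantile(phi[phi[, "t1"] > 0, "t1"], 0.95)
  over <- inE & phi[, "t1"] > q95
  if (any(over)) expect_true(all(res$sites$ratio[over] == 1))
})

test_that("degenerate non-positive expectations are marked undefined", {
  phi <- cbind(n1 = c(0.2), drag = c(-0.9), t1 = c(-0.1))
  shap <- make_shap(phi, baseline = 0.3)
  expect_message(res <- quantitative_shadow(shap, "n1", "t1",
                                            "zero_negative"),
                 "non-positive")
  expect_true(res$sites$in_expected[1L])
  expect_true(is.na(res$sites$ratio[1L]))
})

test_that("binary shadow requires expected membership and net negative threat", {
  phi <- cbind(n1 = c(0.2, 0.2, -0.1, 0.2), t1 = c(0.1, -0.2, -0.2, 0.0))
  shap <- make_shap(phi, baseline = 0.5)
  s <- binary_shadow(shap, "n1", "t1")
  # in E with positive threat; in E with negative threat; outside E; zero
  expect_equal(unname(s), c(FALSE, TRUE, FALSE, FALSE))
  expect_error(binary_shadow(shap, "n1", character(0L)), "empty")
})

test_that("shadow sets nest inside the expected distribution", {
  set.seed(2)
  phi <- cbind(n1 = rnorm(200, 0.05, 0.2), t1 = rnorm(200, 0, 0.1),
               t2 = rnorm(200, 0, 0.1), t3 = rnorm(200, 0, 0.1))
  shap <- make_shap(phi, baseline = 0.5)
  E <- expected_distribution(shap, "n1")
  all_shadow <- binary_shadow(shap, "n1", c("t1", "t2", "t3"))
  singles <- sapply(c("t1", "t2", "t3"),
                    function(t) binary_shadow(shap, "n1", t))
  expect_true(all(!all_shadow | E))
  # net-negative implies at least one negative component
  expect_true(all(!all_shadow | rowSums(singles) > 0))
})

test_that("all-threat shadow equals the single-threat union only for aligned signs", {
  # exhaustive sign patterns over 3 threats at one E-site
  signs <- expand.grid(s1 = c(-1, 1), s2 = c(-1, 1), s3 = c(-1, 1))
  for (r in seq_len(nrow(signs))) {
    mag <- c(0.1, 0.2, 0.4) * unlist(signs[r, ])
    phi <- cbind(n1 = 0.3, t1 = mag[1], t2 = mag[2], t3 = mag[3])
    shap <- make_shap(phi, baseline = 0.5)
    in_union <- any(sapply(c("t1", "t2", "t3"),
                           function(t) binary_shadow(shap, "n1", t)))
    in_all <- unname(binary_shadow(shap, "n1", c("t1", "t2", "t3")))
    expect_equal(in_all, sum(mag) < 0)
    expect_equal(in_union, any(mag < 0))
    if (all(mag < 0) || all(mag > 0)) expect_equal(in_all, in_union)
  }
})

test_that("threat profiles count negative contributions inside E", {
  phi <- cbind(n1 = c(0.2, 0.2, 0.2, 0.2, -0.1),
               t1 = c(-0.1, 0.1, -0.1, 0.1, -0.1),
               t2 = c(-0.1, 0.1, 0.1, 0.1, 0.1),
               t3 = c(-0.1, -0.1, 0.1, 0.1, 0.1),
               t4 = c(0.1, 0.1, 0.1, 0.1, 0.1))
  shap <- make_shap(phi, baseline = 0.5)
  E <- expected_distribution(shap, "n1")
  prof <- threat_profile(shap, E, c("t1", "t2", "t3", "t4"))
  # E covers the first four sites; hand counts per threat: 2,1,2,0 of 4
  expect_equal(unname(prof$percent_negative), c(50, 25, 50, 0))
  expect_equal(unname(prof$n_negative[1L]), 3) # three negative threats
  expect_true(is.na(prof$n_negative[5L]))
  expect_equal(unname(prof$net_threat),
               unname(rowSums(phi[, c("t1", "t2", "t3", "t4")])))
  # an all-positive table has empty profiles
  shap_pos <- make_shap(abs(phi), baseline = 0.5)
  Ep <- expected_distribution(shap_pos, "n1")
  prof_pos <- threat_profile(shap_pos, Ep, c("t1", "t2"))
  expect_true(all(prof_pos$percent_negative == 0))
  expect_true(all(prof_pos$n_negative[Ep] == 0))
})

test_that("feature adjustment is a no-op when threats are already improved", {
  fx <- riverscape_fixture()
  model <- fitted_model_fixture()
  env2 <- fx$env
  meta <- env_metadata(env2)
  for (v in THR_SET) {
    dir <- meta$direction[meta$variable == v]
    q <- if (dir == "high_good") 0.99 else 0.01
    env2[[v]] <- rep(unname(quantile(fx$env[[v]], q)), nrow(env2))
  }
  expected <- feature_adjustment_expected(model, env2, THR_SET)
  expect_equal(expected, predict_suitability(model, env2), tolerance = 1e-12)
  # missing direction metadata is refused
  meta_bad <- meta
  meta_bad$direction[meta_bad$variable == "urbanisation"] <- NA
  env3 <- env_table(as.data.frame(fx$env), meta_bad)
  expect_error(feature_adjustment_expected(model, env3, "urbanisation"),
               "direction_of_benefit")
})

test_that("improving harmful threats does not lower expected suitability", {
  fx <- riverscape_fixture()
  model <- fitted_model_fixture()
  observed <- predict_suitability(model, fx$env)
  expected <- feature_adjustment_expected(model, fx$env, "urbanisation")
  expect_gte(median(expected - observed), 0)
})
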