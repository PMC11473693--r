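test_that("every tree's bootstrap is balanced at the minority-class size", {
  set.seed(1)
  n <- 430
  x <- rnorm(n)
  env <- toy_env(x = x, z = rnorm(n))
  pres <- c(rep(1L, 30), rep(0L, 400)) # 30 presences, 400 absences
  occ <- data.frame(site_id = env$site_id, presence = pres)
  model <- fit_downsampled_rf(env, occ, ntree = 100, seed = 2)
  counts <- inbag_class_counts(model, occ)
  expect_true(all(counts[, "presence"] == 30))
  expect_true(all(counts[, "absence"] == 30))
})

test_that("a perfectly separable gradient is learned on training data", {
  set.seed(2)
  x <- c(rnorm(100, -2), rnorm(100, 2))
  env <- toy_env(x = x)
  occ <- data.frame(site_id = env$site_id,
                    presence = rep(c(0L, 1L), each = 100))
  model <- fit_downsampled_rf(env, occ, ntree = 200, seed = 3)
  score <- predict_suitability(model, env)
  m <- classification_metrics(occ$presence, score, 0.5)
  expect_gte(m[["auc"]], 0.99)
})

test_that("predictions are vote fractions with the stored baseline", {
  fx <- riverscape_fixture()
  model <- fitted_model_fixture()
  p <- predict_suitability(model, fx$env)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(mean(p), model$baseline, tolerance = 1e-12)
  one <- fit_downsampled_rf(fx$env, fx$occ, ntree = 1, seed = 4)
  expect_true(all(predict_suitability(one, fx$env) %in% c(0, 1)))
})

test_that("model fitting validates its inputs", {
  fx <- riverscape_fixture()
  expect_error(fit_downsampled_rf(fx$env, data.frame(
    site_id = fx$occ$site_id, presence = 1L)), "Both presences")
  bad_occ <- fx$occ
  bad_occ$site_id[1L] <- "nowhere"
  expect_error(fit_downsampled_rf(fx$env, bad_occ), "nowhere")
  model <- fitted_model_fixture()
  expect_error(predict_suitability(model, fx$env[
    setdiff(names(fx$env), "discharge")]), "discharge")
})

test_that("spatial blocks keep nearby sites in the same fold", {
  sites <- data.frame(site_id = c("a", "b"), x = c(0, 1), y = c(0, 0.5))
  expect_error(spatial_block_folds(sites, block_size = 10000, k = 2),
               "non-empty tile")
  sites2 <- data.frame(site_id = c("a", "b", "c", "d"),
                       x = c(0, 1, 25000, 25001), y = c(0, 1, 0, 1))
  f <- spatial_block_folds(sites2, block_size = 10000, k = 2, seed = 1)
  expect_equal(f$fold[1L], f$fold[2L])
  expect_equal(f$fold[3L], f$fold[4L])
  expect_equal(f$block_id[1L], f$block_id[2L])
})

test_that("tiles are dealt evenly across folds when counts divide", {
  grid <- expand.grid(x = (0:4) * 10000 + 5000, y = (0:4) * 10000 + 5000)
  sites <- data.frame(site_id = paste0("g", seq_len(25)), grid)
  f <- spatial_block_folds(sites, block_size = 10000, k = 5, seed = 3)
  expect_equal(length(unique(f$block_id)), 25L)
  expect_true(all(table(f$fold) == 5L))
})

test_that("classification metrics match hand arithmetic", {
  # contingency TP=40, FN=10, TN=35, FP=15
  obs <- c(rep(1L, 50), rep(0L, 50))
  score <- c(rep(1, 40), rep(0, 10), rep(0, 35), rep(1, 15))
  m <- classification_metrics(obs, score, 0.5)
  expect_equal(m[["sensitivity"]], 0.8)
  expect_equal(m[["specificity"]], 0.7)
  expect_equal(m[["tss"]], 0.5)
  # perfect classifier
  mp <- classification_metrics(obs, obs, 0.5)
  expect_equal(unname(mp[c("auc", "tss", "mcc", "kappa")]), rep(1, 4))
  # label-independent scores carry no skill
  set.seed(5)
  m0 <- classification_metrics(rbinom(2000, 1, 0.5), runif(2000), 0.5)
  expect_lt(abs(m0[["auc"]] - 0.5), 0.05)
  expect_lt(abs(m0[["tss"]]), 0.1)
})

test_that("metric identities hold on random confusion tables", {
  set.seed(6)
  for (i in seq_len(200)) {
    cnt <- rmultinom(1, sample(20:200, 1), prob = runif(4, 0.05, 1))[, 1]
    obs <- rep(c(1L, 1L, 0L, 0L), cnt)
    score <- rep(c(1, 0, 0, 1), cnt)
    if (length(unique(obs)) < 2L || length(unique(score)) < 2L) next
    m <- classification_metrics(obs, score, 0.5)
    expect_equal(m[["tss"]], m[["sensitivity"]] + m[["specificity"]] - 1,
                 tolerance = 1e-12)
    # MCC equals the Pearson correlation of the two binary vectors
    expect_equal(m[["mcc"]], cor(obs, as.integer(score >= 0.5)),
                 tolerance = 1e-12)
  }
})

test_that("the max-TSS threshold maximizes TSS over observed scores", {
  set.seed(7)
  obs <- rbinom(300, 1, 0.4)
  score <- plogis(rnorm(300) + obs)
  th <- max_tss_threshold(obs, score)
  tss_at <- function(t) classification_metrics(obs, score, t)[["tss"]]
  expect_true(all(tss_at(th) >= vapply(unique(score), tss_at,
                                       numeric(1L)) - 1e-12))
})

test_that("blocked cross-validation evaluates out-of-fold predictions", {
  fx <- riverscape_fixture()
  folds <- spatial_block_folds(fx$net, block_size = 4000, k = 4, seed = 8)
  cv <- evaluate_blocked_cv(fx$env, fx$occ, folds, ntree = 80, seed = 9)
  expect_equal(sort(unique(cv$predictions$site_id)), sort(fx$occ$site_id))
  expect_true(all(cv$per_fold$auc >= 0 & cv$per_fold$auc <= 1))
  expect_equal(cv$pooled[["tss"]],
               cv$pooled[["sensitivity"]] + cv$pooled[["specificity"]] - 1,
               tolerance = 1e-12)
  # a species with real environmental signal is predictable out of fold
  expect_gt(cv$pooled[["auc"]], 0.6)
})

test_that("folds with single-class training data are skipped with warning", {
  set.seed(10)
  sites <- data.frame(site_id = paste0("s", 1:60),
                      x = rep(c(0, 20000, 40000), each = 20),
                      y = runif(60, 0, 5000))
  env <- env_table(
    data.frame(site_id = sites$site_id, v = rnorm(60)),
    data.frame(variable = "v", category = "natural",
               direction = NA_character_))
  # presences only inside one block: training without it is single-class
  occ <- data.frame(site_id = sites$site_id,
                    presence = rep(c(1L, 0L, 0L), each = 20))
  folds <- spatial_block_folds(sites, block_size = 10000, k = 3, seed = 1)
  expect_warning(cv <- evaluate_blocked_cv(env, occ, folds, ntree = 30,
                                           seed = 2), "single-class")
  expect_true(length(cv$skipped) >= 1L)
})
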