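# Build a shadow_result by hand from a ratio vector and E mask.
fake_result <- function(ratio, inE, site_id = NULL, neg = NULL,
                        threats = c("t1", "t2")) {
  n <- length(ratio)
  if (is.null(site_id)) site_id <- paste0("s", seq_len(n))
  if (is.null(neg)) {
    neg <- matrix(FALSE, n, length(threats),
                  dimnames = list(site_id, threats))
  }
  structure(list(
    sites = data.frame(site_id = site_id, in_expected = inE,
                       observed = ifelse(is.na(ratio), 0.5, ratio * 0.6),
                       expected = 0.6,
                       ratio = ifelse(inE, ratio, NA_real_),
                       stringsAsFactors = FALSE),
    threat_negative = neg, natural_set = "n1", threat_set = threats,
    scenario = "zero_negative"), class = "shadow_result")
}

test_that("a single species summarises to its own ratios", {
  r <- fake_result(c(0.8, 0.4, NA), inE = c(TRUE, TRUE, FALSE))
  cs <- community_summary(list(sp = r), min_species = 0L)
  expect_equal(cs$mean_ratio[1:2], c(0.8, 0.4))
  expect_equal(cs$min_ratio[1:2], c(0.8, 0.4))
  expect_equal(cs$sd_ratio[1:2], c(0, 0))
  expect_true(is.na(cs$mean_ratio[3L]))
  expect_false(cs$masked[1L])
  expect_true(cs$masked[3L]) # zero species in E
})

test_that("cross-species statistics match hand arithmetic and masking", {
  rs <- list(a = fake_result(1.0, TRUE), b = fake_result(0.5, TRUE),
             c = fake_result(0.3, TRUE))
  cs <- community_summary(rs, min_species = 2L)
  expect_equal(cs$mean_ratio[1L], 0.6, tolerance = 1e-12)
  expect_equal(cs$min_ratio[1L], 0.3, tolerance = 1e-12)
  expect_equal(cs$sd_ratio[1L], sd(c(1, 0.5, 0.3)), tolerance = 1e-12)
  expect_equal(cs$n_in_expected[1L], 3L)
  expect_false(cs$masked[1L]) # 3 species > 2
  # with only two species in E the site is masked ("more than 2" rule)
  rs2 <- list(a = fake_result(1.0, TRUE), b = fake_result(0.5, TRUE),
              c = fake_result(0.3, FALSE))
  cs2 <- community_summary(rs2, min_species = 2L)
  expect_true(cs2$masked[1L])
  expect_equal(cs2$n_in_expected[1L], 2L)
})

test_that("species outside E are excluded, not imputed", {
  rs <- list(a = fake_result(c(0.9, 0.2), c(TRUE, TRUE)),
             b = fake_result(c(0.1, 0.4), c(FALSE, TRUE)))
  cs <- community_summary(rs, min_species = 0L)
  expect_equal(cs$mean_ratio, c(0.9, 0.3), tolerance = 1e-12)
  # all-species means still cover both species
  expect_equal(cs$mean_observed_all[1L],
               mean(c(rs$a$sites$observed[1L], rs$b$sites$observed[1L])),
               tolerance = 1e-12)
})

test_that("aggregation is invariant to species and site order", {
  set.seed(1)
  n <- 30
  mk <- function(seed, ids) {
    set.seed(seed)
    fake_result(runif(n), runif(n) > 0.3, site_id = ids)
  }
  ids <- paste0("s", sample(n))
  rs <- list(a = mk(1, ids), b = mk(2, ids), c = mk(3, ids))
  cs1 <- community_summary(rs, min_species = 0L)
  cs2 <- community_summary(rev(rs), min_species = 0L)
  expect_equal(cs1$mean_ratio, cs2$mean_ratio, tolerance = 1e-12)
  # reorder the sites of one species' table
  rs3 <- rs
  perm <- sample(n)
  rs3$b$sites <- rs3$b$sites[perm, ]
  rs3$b$threat_negative <- rs3$b$threat_negative[perm, , drop = FALSE]
  cs3 <- community_summary(rs3, min_species = 0L)
  expect_equal(cs3$mean_ratio, cs1$mean_ratio, tolerance = 1e-12)
})

test_that("mismatched site sets across species are rejected", {
  rs <- list(a = fake_result(0.5, TRUE, site_id = "x"),
             b = fake_result(0.5, TRUE, site_id = "y"))
  expect_error(community_summary(rs), "Site ids differ")
  expect_error(community_summary(list()), "at least one")
})

test_that("zero-negative expectations dominate observations at community level", {
  fx <- riverscape_fixture()
  model <- fitted_model_fixture()
  shap <- shap_table(model, fx$env[1:80, ], background = fx$env,
                     n_reps = 30, seed = 3)
  res <- quantitative_shadow(shap, NAT_SET, THR_SET, "zero_negative")
  cs <- community_summary(list(sp = res), min_species = 0L)
  ok <- !is.na(cs$mean_observed_E)
  expect_true(all(cs$mean_observed_E[ok] <= cs$mean_expected_E[ok] + 1e-12))
})

test_that("threat-group counts feed the shadow association", {
  set.seed(4)
  n <- 60
  counts <- sample(0:4, n, replace = TRUE)
  ratio <- 1 - counts / 5 # strictly decreasing in the habitat count
  neg <- matrix(FALSE, n, 5,
                dimnames = list(paste0("s", 1:n),
                                c("h1", "h2", "h3", "h4", "conn")))
  for (i in seq_len(n)) if (counts[i] > 0) neg[i, seq_len(counts[i])] <- TRUE
  r <- fake_result(ratio, rep(TRUE, n), neg = neg,
                   threats = colnames(neg))
  cs <- community_summary(list(sp = r),
                          threat_groups = list(habitat = paste0("h", 1:4),
                                               connectivity = "conn"),
                          min_species = 0L)
  expect_equal(cs$neg_habitat, counts)
  assoc <- shadow_threat_association(cs)
  expect_equal(assoc$rho[assoc$group == "habitat" &
                           assoc$statistic == "mean_ratio"], -1)
  # the constant connectivity column has no defined association
  expect_true(is.na(assoc$rho[assoc$group == "connectivity" &
                                assoc$statistic == "mean_ratio"]))
})

test_that("independent ratios and counts show no spurious association", {
  set.seed(5)
  n <- 1000
  neg <- matrix(runif(n * 4) < 0.5, n, 4,
                dimnames = list(paste0("s", 1:n), paste0("h", 1:4)))
  r <- fake_result(runif(n), rep(TRUE, n), neg = neg,
                   threats = colnames(neg))
  cs <- community_summary(list(sp = r),
                          threat_groups = list(habitat = paste0("h", 1:4)),
                          min_species = 0L)
  assoc <- shadow_threat_association(cs)
  expect_true(all(abs(assoc$rho) < 0.1))
})

test_that("local contribution reports average attributions per region", {
  phi_a <- cbind(v1 = c(0.1, 0.3, -0.2), v2 = c(0, 0.1, 0.1))
  phi_b <- cbind(v1 = c(-0.1, -0.1, -0.1), v2 = c(0.2, 0.2, 0.2))
  shap_a <- make_shap(phi_a, 0.5, site_id = c("r1a", "r1b", "r2a"))
  shap_b <- make_shap(phi_b, 0.4, site_id = c("r1a", "r1b", "r2a"))
  surveys <- data.frame(site_id = c("r1a", "r2a"), species = c("A", "B"),
                        presence = c(1L, 1L))
  rep1 <- local_contribution_report(list(A = shap_a, B = shap_b),
                                    c("r1a", "r1b"), surveys)
  # hand means over the two region sites
  expect_equal(rep1$mean_phi[rep1$species == "A" & rep1$variable == "v1"],
               0.2, tolerance = 1e-12)
  expect_equal(rep1$mean_phi[rep1$species == "B" & rep1$variable == "v2"],
               0.2, tolerance = 1e-12)
  expect_true(rep1$observed_in_surveys[rep1$species == "A"][1L])
  expect_false(rep1$observed_in_surveys[rep1$species == "B"][1L])
  # a one-site region is that site's attribution row
  rep2 <- local_contribution_report(list(A = shap_a), "r2a")
  expect_equal(rep2$mean_phi[rep2$variable == "v1"], -0.2, tolerance = 1e-12)
  # a species with uniform attributions reports identically in any region
  rep3a <- local_contribution_report(list(B = shap_b), c("r1a", "r1b"))
  rep3b <- local_contribution_report(list(B = shap_b), "r2a")
  expect_equal(rep3a$mean_phi, rep3b$mean_phi, tolerance = 1e-12)
  expect_error(local_contribution_report(list(A = shap_a), character(0L)),
               "non-empty")
  expect_error(local_contribution_report(list(A = shap_a), "nowhere"),
               "nowhere")
})
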