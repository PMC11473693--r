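# Scenario replacement of threat contributions. `thr` is a site x threat
# matrix of attributions; each threat column is replaced by:
#   q95_positive  -> the species-level 95th percentile of its positive values
#   zero_negative -> max(value, 0)
#   mean_positive -> value if >= 0, else the species-level mean of positives
# A threat with no positive value anywhere gets replacement 0 (with a message).
.scenario_replace <- function(thr, scenario) {
  out <- thr
  for (j in seq_len(ncol(thr))) {
    v <- thr[, j]
    pos <- v[v > 0]
    if (scenario == "zero_negative") {
      out[, j] <- pmax(v, 0)
      next
    }
    rep_val <- if (length(pos) == 0L) {
      message("Threat `", colnames(thr)[j],
              "` has no positive attribution anywhere; replacement value 0.")
      0
    } else if (scenario == "q95_positive") {
      unname(stats::quantile(pos, 0.95, type = 7))
    } else { # mean_positive
      mean(pos)
    }
    if (scenario == "q95_positive") {
      # best case: every site gets the near-maximal positive contribution
      out[, j] <- rep_val
    } else {
      # recovery of harmed sites only; unharmed sites keep their value
      out[, j] <- ifelse(v >= 0, v, rep_val)
    }
  }
  out
}

.shadow_scenarios <- c("q95_positive", "zero_negative", "mean_positive")

#' Binary expected distribution from Shapley attributions
#'
#' A site belongs to a species' expected distribution (its naturally
#' realised abiotic niche) when the natural variables' attributions sum to
#' a strictly positive contribution to the suitability prediction. A zero
#' sum gives no positive natural support, so such sites fall outside.
#'
#' @param shap A [shap_matrix].
#' @param natural_set Character vector of natural variable names (non-empty,
#'   all present in the attribution matrix).
#' @return Named logical vector over sites.
#' @export
expected_distribution <- function(shap, natural_set) {
  stopifnot(inherits(shap, "shap_matrix"))
  if (length(natural_set) == 0L) {
    stop("`natural_set` must not be empty.", call. = FALSE)
  }
  .check_shap_vars(shap, natural_set)
  rowSums(shap$phi[, natural_set, drop = FALSE]) > 0
}

#' Expected suitability under a threat-alleviation scenario
#'
#' Reconstructs each site's suitability with threats alleviated: the model
#' baseline plus the natural attributions plus scenario-replaced threat
#' attributions. Scenarios, from most to least optimistic:
#' \describe{
#'   \item{q95_positive}{every threat contributes its species-level 95th
#'     percentile of positive attributions (best case; the 95th rather than
#'     the maximum guards against spuriously large values).}
#'   \item{mean_positive}{negative attributions recover to the mean positive
#'     attribution of that threat (the average unthreatened condition).}
#'   \item{zero_negative}{negative attributions are merely zeroed: the
#'     threat stops hurting but does not help.}
#' }
#' Values are reported for every site (interpretation belongs inside the
#' expected distribution) and are not clamped at this stage.
#'
#' @param shap A [shap_matrix].
#' @param threat_set Threat variable names.
#' @param scenario One of `"q95_positive"`, `"zero_negative"`,
#'   `"mean_positive"`.
#' @return Named numeric vector of expected suitability per site.
#' @export
expected_suitability <- function(shap, threat_set,
                                 scenario = .shadow_scenarios) {
  stopifnot(inherits(shap, "shap_matrix"))
  scenario <- match.arg(scenario)
  if (length(threat_set) == 0L) {
    stop("`threat_set` must not be empty.", call. = FALSE)
  }
  .check_shap_vars(shap, threat_set)
  other <- setdiff(colnames(shap$phi), threat_set)
  thr <- .scenario_replace(shap$phi[, threat_set, drop = FALSE], scenario)
  shap$baseline + rowSums(shap$phi[, other, drop = FALSE]) + rowSums(thr)
}

#' Binary shadow distribution
#'
#' Flags sites inside the expected distribution where a chosen subset of
#' threats has a net negative attribution: the species could occur on
#' natural grounds but the threat subset pulls suitability down. Supports
#' single threats, grouped threats (e.g. the habitat-quality group), and
#' the full threat set.
#'
#' @param shap A [shap_matrix].
#' @param natural_set Natural variable names defining the expected
#'   distribution.
#' @param threat_subset Non-empty subset of threat variable names.
#' @return Named logical vector; `TRUE` marks shadow sites.
#' @export
binary_shadow <- function(shap, natural_set, threat_subset) {
  stopifnot(inherits(shap, "shap_matrix"))
  if (length(threat_subset) == 0L) {
    stop("`threat_subset` must not be empty.", call. = FALSE)
  }
  .check_shap_vars(shap, threat_subset)
  E <- expected_distribution(shap, natural_set)
  E & rowSums(shap$phi[, threat_subset, drop = FALSE]) < 0
}

#' Quantitative shadow distribution
#'
#' For every site inside the expected distribution, computes the ratio of
#' observed suitability (baseline plus all attributions; equal to the model
#' prediction by the efficiency property) to the threat-alleviated expected
#' suitability, clamped to `[0, 1]`. The ratio estimates the fraction of
#' environmental suitability retained under human impacts inside the
#' abiotic niche (1 = no loss). Sites outside the expected distribution
#' carry `NA`; the rare degenerate case `expected <= 0` is also `NA` and
#' logged.
#'
#' @param shap A [shap_matrix].
#' @param natural_set,threat_set Variable subsets.
#' @param scenario Alleviation scenario, see [expected_suitability()].
#' @return Object of class `shadow_result`: list with `sites` (data frame
#'   `site_id`, `in_expected`, `observed`, `expected`, `ratio`),
#'   `threat_negative` (site x threat logical matrix of negative
#'   attributions), plus the sets and scenario used.
#' @export
quantitative_shadow <- function(shap, natural_set, threat_set,
                                scenario = .shadow_scenarios) {
  stopifnot(inherits(shap, "shap_matrix"))
  scenario <- match.arg(scenario)
  E <- expected_distribution(shap, natural_set)
  expected <- expected_suitability(shap, threat_set, scenario)
  observed <- shap$baseline + rowSums(shap$phi)
  ratio <- rep(NA_real_, length(E))
  ok <- E & expected > 0
  if (any(E & expected <= 0)) {
    message(sum(E & expected <= 0),
            " site(s) in the expected distribution have non-positive ",
            "expected suitability; their ratio is undefined (NA).")
  }
  ratio[ok] <- pmin(pmax(observed[ok] / expected[ok], 0), 1)
  sites <- data.frame(
    site_id = rownames(shap$phi),
    in_expected = unname(E),
    observed = unname(observed),
    expected = unname(expected),
    ratio = unname(ratio),
    stringsAsFactors = FALSE
  )
  structure(list(
    sites = sites,
    threat_negative = shap$phi[, threat_set, drop = FALSE] < 0,
    natural_set = natural_set,
    threat_set = threat_set,
    scenario = scenario
  ), class = "shadow_result")
}

#' @export
print.shadow_result <- function(x, ...) {
  s <- x$sites
  cat("Shadow distribution (scenario:", x$scenario, ")\n")
  cat("Sites:", nrow(s), "| expected distribution:", sum(s$in_expected),
      sprintf("(%.0f%%)\n", 100 * mean(s$in_expected)))
  inE <- s[s$in_expected, ]
  if (nrow(inE)) {
    cat("Mean observed/expected suitability in E:",
        round(mean(inE$observed), 3), "/", round(mean(inE$expected), 3),
        "| mean ratio:", round(mean(inE$ratio, na.rm = TRUE), 3), "\n")
  }
  invisible(x)
}

#' Expected suitability by direct feature adjustment (Shapley-free)
#'
#' An alternative route to the threat-alleviated expectation that does not
#' use attributions: threat columns of the environmental table are set to
#' their improved state (the 99th percentile of the observed values when a
#' high value is the improved state, e.g. connectivity; the 1st percentile
#' when a low value is improved, e.g. urbanisation) and the model is simply
#' re-applied. Serves as an independent cross-check on the scenario-based
#' expectation.
#'
#' @param model An `sdm_model` from [fit_downsampled_rf()].
#' @param env The [env_table] to adjust and predict on.
#' @param threat_set Threat variables to improve; each needs
#'   direction-of-benefit metadata.
#' @param improve_quantiles Probabilities used for the improved state,
#'   `c(high = 0.99, low = 0.01)`.
#' @return Named numeric vector of expected suitability per site.
#' @export
feature_adjustment_expected <- function(model, env, threat_set,
                                        improve_quantiles = c(high = 0.99,
                                                              low = 0.01)) {
  stopifnot(inherits(env, "env_table"))
  .check_variables(env, threat_set, "threat variable")
  meta <- env_metadata(env)
  adjusted <- env
  for (v in threat_set) {
    dir <- meta$direction[meta$variable == v]
    if (is.na(dir)) {
      stop("Threat `", v, "` has no direction_of_benefit metadata.",
           call. = FALSE)
    }
    q <- if (dir == "high_good") improve_quantiles[["high"]] else
      improve_quantiles[["low"]]
    adjusted[[v]] <- rep(unname(stats::quantile(env[[v]], q, type = 7)),
                         nrow(env))
  }
  predict_suitability(model, adjusted)
}

#' Per-threat impact profile inside the expected distribution
#'
#' @param shap A [shap_matrix].
#' @param E Logical vector of expected-distribution membership, as returned
#'   by [expected_distribution()].
#' @param threat_set Threat variable names.
#' @return List with `percent_negative` (per-threat percentage of E-sites
#'   with a negative attribution), `n_negative` (per-site count of negative
#'   threat attributions, `NA` outside E), and `net_threat` (per-site sum
#'   of threat attributions).
#' @export
threat_profile <- function(shap, E, threat_set) {
  stopifnot(inherits(shap, "shap_matrix"), length(E) == nrow(shap$phi))
  .check_shap_vars(shap, threat_set)
  neg <- shap$phi[, threat_set, drop = FALSE] < 0
  pct <- if (any(E)) 100 * colMeans(neg[E, , drop = FALSE]) else
    stats::setNames(rep(NA_real_, length(threat_set)), threat_set)
  counts <- rowSums(neg)
  counts[!E] <- NA_integer_
  list(
    percent_negative = pct,
    n_negative = counts,
    net_threat = rowSums(shap$phi[, threat_set, drop = FALSE])
  )
}

.check_shap_vars <- function(shap, vars) {
  missing <- setdiff(vars, colnames(shap$phi))
  if (length(missing)) {
    stop("Variable(s) absent from the attribution matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
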