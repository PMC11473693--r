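#' Define a virtual species' response to environmental gradients
#'
#' A response specification maps environmental variables to additive
#' log-odds contributions. Variables are standardized (z-scored over the
#' supplied table) before the response shape is applied, so slopes are
#' comparable across variables with different units. Three shapes are
#' supported:
#' \describe{
#'   \item{linear}{`slope * z`}
#'   \item{gaussian}{`height * exp(-(z - mu)^2 / (2 * sd^2))` — a niche
#'     optimum at `mu` (in standardized units)}
#'   \item{threshold}{`slope * pmax(z - at, 0)` — no effect below the
#'     breakpoint `at`}
#' }
#'
#' Threat responses must be harmful or neutral: for a `low_good` threat
#' (e.g. urbanisation) the linear/threshold slope must be <= 0 in the
#' variable itself; for a `high_good` threat (e.g. connectivity) it must
#' be >= 0, so that degrading the threat never raises suitability.
#'
#' @param natural Named list of response shapes for natural variables, e.g.
#'   `list(discharge = list(shape = "linear", slope = 2))`.
#' @param threats Named list of response shapes for threat variables.
#' @param intercept Intercept on the log-odds scale (controls prevalence).
#' @return An object of class `response_spec`.
#' @export
response_spec <- function(natural = list(), threats = list(), intercept = 0) {
  spec <- list(natural = natural, threats = threats,
               intercept = as.numeric(intercept))
  for (set in c("natural", "threats")) {
    for (nm in names(spec[[set]])) {
      r <- spec[[set]][[nm]]
      if (is.null(r$shape) ||
          !r$shape %in% c("linear", "gaussian", "threshold")) {
        stop("Response for `", nm,
             "` needs shape linear, gaussian or threshold.", call. = FALSE)
      }
    }
  }
  structure(spec, class = "response_spec")
}

.eval_response <- function(r, z) {
  switch(r$shape,
    linear = r$slope * z,
    gaussian = r$height * exp(-(z - r$mu)^2 / (2 * r$sd^2)),
    threshold = r$slope * pmax(z - r$at, 0)
  )
}

#' Sample a virtual species with known per-variable contributions
#'
#' Evaluates the response specification on an environmental table, centers
#' each variable's log-odds contribution over sites (the grand means are
#' absorbed into the effective intercept), converts the additive log-odds
#' to suitability through the inverse logit, and samples presence--absence
#' as independent Bernoulli draws. Because the per-variable contributions
#' are stored, attribution and shadow-distribution estimates can be checked
#' against an exact ground truth.
#'
#' @param env An [env_table].
#' @param spec A [response_spec]; every referenced variable must exist in
#'   `env`, and threat responses must respect the direction-of-benefit
#'   metadata (see [response_spec]).
#' @param seed Integer seed for the Bernoulli presence draws.
#' @return Object of class `virtual_species`: list with `suitability`
#'   (per-site true suitability in `[0, 1]`), `presence` (0/1),
#'   `contributions` (site x variable matrix of centered log-odds
#'   contributions), `intercept` (effective log-odds intercept),
#'   `site_id`, and the variable sets used.
#' @export
generate_virtual_species <- function(env, spec, seed = 1L) {
  stopifnot(inherits(env, "env_table"), inherits(spec, "response_spec"))
  vars <- c(names(spec$natural), names(spec$threats))
  .check_variables(env, vars)
  meta <- env_metadata(env)
  # enforce monotone non-increasing response in threat intensity
  for (nm in names(spec$threats)) {
    r <- spec$threats[[nm]]
    dir <- meta$direction[meta$variable == nm]
    if (r$shape %in% c("linear", "threshold") && !is.na(dir)) {
      ok <- if (dir == "low_good") r$slope <= 0 else r$slope >= 0
      if (!ok) {
        stop("Threat response for `", nm, "` (direction ", dir,
             ") must not reward higher threat intensity.", call. = FALSE)
      }
    }
  }

  n <- nrow(env)
  contrib <- matrix(0, n, length(vars), dimnames = list(env$site_id, vars))
  for (set in c("natural", "threats")) {
    for (nm in names(spec[[set]])) {
      v <- env[[nm]]
      z <- if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
      contrib[, nm] <- .eval_response(spec[[set]][[nm]], z)
    }
  }
  means <- colMeans(contrib)
  contrib <- sweep(contrib, 2L, means)
  intercept <- spec$intercept + sum(means)
  eta <- intercept + rowSums(contrib)
  suitability <- stats::plogis(eta)
  if (stats::sd(suitability) < 1e-12) {
    warning("Response spec produces constant suitability (",
            signif(suitability[1L], 3), ") at every site.", call. = FALSE)
  }
  set.seed(as.integer(seed))
  presence <- stats::rbinom(n, 1L, suitability)
  structure(list(
    site_id = env$site_id,
    suitability = stats::setNames(suitability, env$site_id),
    presence = stats::setNames(presence, env$site_id),
    contributions = contrib,
    intercept = intercept,
    natural_set = names(spec$natural),
    threat_set = names(spec$threats),
    seed = as.integer(seed)
  ), class = "virtual_species")
}

#' @export
print.virtual_species <- function(x, ...) {
  cat("Virtual species:", length(x$site_id), "sites, prevalence",
      round(mean(x$presence), 3), "| mean true suitability",
      round(mean(x$suitability), 3), "\n")
  cat("Natural responses:", paste(x$natural_set, collapse = ", "), "\n")
  cat("Threat responses:", paste(x$threat_set, collapse = ", "), "\n")
  invisible(x)
}

#' Occurrence records of a virtual species
#'
#' @param vs A `virtual_species`.
#' @param species Species label for the occurrence table.
#' @param year Survey year recorded for every row.
#' @return Data frame with columns `site_id`, `species`, `presence`, `year`.
#' @export
occurrence_table <- function(vs, species = "virtual_sp", year = 2020L) {
  stopifnot(inherits(vs, "virtual_species"))
  data.frame(site_id = vs$site_id, species = species,
             presence = as.integer(vs$presence), year = as.integer(year),
             stringsAsFactors = FALSE)
}

#' Exact shadow distribution from true contributions
#'
#' Applies the expected/shadow-distribution partition to the *true*
#' additive log-odds contributions of a virtual species rather than to
#' estimated Shapley values, providing an exact recovery target. Expected
#' membership requires a positive sum of natural contributions; threat
#' alleviation replaces each threat's contribution under the chosen
#' scenario (see [expected_suitability()] for the scenarios); expected
#' suitability is the inverse logit of the alleviated log-odds; and the
#' quantitative shadow is the observed/expected suitability ratio clamped
#' to `[0, 1]` inside the expected distribution.
#'
#' @param vs A `virtual_species`.
#' @param natural_set,threat_set Variable subsets to use; defaults are the
#'   sets stored in `vs`.
#' @param scenario Threat-alleviation scenario: `"q95_positive"`,
#'   `"zero_negative"` or `"mean_positive"`.
#' @return A data frame with `site_id`, `in_expected`, `observed`,
#'   `expected`, `ratio` (NA outside the expected distribution).
#' @export
ground_truth_shadow <- function(vs, natural_set = vs$natural_set,
                                threat_set = vs$threat_set,
                                scenario = c("q95_positive", "zero_negative",
                                             "mean_positive")) {
  stopifnot(inherits(vs, "virtual_species"))
  scenario <- match.arg(scenario)
  contrib <- vs$contributions
  missing <- setdiff(c(natural_set, threat_set), colnames(contrib))
  if (length(missing)) {
    stop("No true contributions for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  nat_sum <- rowSums(contrib[, natural_set, drop = FALSE])
  in_expected <- nat_sum > 0
  thr <- contrib[, threat_set, drop = FALSE]
  thr_allev <- .scenario_replace(thr, scenario)
  expected_eta <- vs$intercept + nat_sum + rowSums(thr_allev)
  expected <- stats::plogis(expected_eta)
  observed <- unname(vs$suitability)
  ratio <- ifelse(in_expected, pmin(pmax(observed / expected, 0), 1), NA_real_)
  data.frame(site_id = vs$site_id, in_expected = in_expected,
             observed = observed, expected = expected, ratio = ratio,
             stringsAsFactors = FALSE)
}
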