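#' Audit pairwise multicollinearity of environmental variables
#'
#' Shapley attributions (like most per-variable explanations) are not
#' robust to strongly correlated covariates, so decoupling is audited
#' before modelling. Computes the pairwise Spearman rank correlation matrix
#' (average ranks on ties) and summarises the off-diagonal absolute values
#' by their median and 95th percentile. Constant columns have undefined
#' correlations; they are reported as `NA` and excluded from the summaries.
#'
#' @param env An [env_table] with at least 2 variables and 3 sites.
#' @return Object of class `collinearity_audit`: list with `rho` (matrix),
#'   `median_abs`, `q95_abs`, `constant` (names of constant columns).
#' @export
collinearity_audit <- function(env) {
  vars <- env_variables(env)
  if (length(vars) < 2L) stop("Need at least 2 variables.", call. = FALSE)
  if (nrow(env) < 3L) stop("Need at least 3 sites.", call. = FALSE)
  x <- as.data.frame(env)[vars]
  constant <- vars[vapply(x, function(v) stats::sd(v) == 0, logical(1L))]
  rho <- suppressWarnings(stats::cor(x, method = "spearman"))
  rho[constant, ] <- NA_real_
  rho[, constant] <- NA_real_
  diag(rho) <- 1
  off <- abs(rho[upper.tri(rho)])
  off <- off[!is.na(off)]
  structure(list(
    rho = rho,
    median_abs = stats::median(off),
    q95_abs = unname(stats::quantile(off, 0.95, type = 7)),
    constant = constant
  ), class = "collinearity_audit")
}

#' @export
print.collinearity_audit <- function(x, ...) {
  cat("Collinearity audit:", nrow(x$rho), "variables | median |rho| =",
      round(x$median_abs, 3), "| 95th percentile |rho| =",
      round(x$q95_abs, 3), "\n")
  if (length(x$constant)) {
    cat("Constant (excluded):", paste(x$constant, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Residualize a variable against confounders with an additive smooth model
#'
#' Threat indicators often track natural gradients (urbanisation is low at
#' high elevation for reasons that have nothing to do with rivers being
#' unsuitable for urbanisation pressure). To attribute effects to the
#' threat itself rather than to its natural correlates, the variable is
#' regressed on the confounders with a penalized additive model (cubic
#' regression splines, default basis size 10 per confounder, smoothness by
#' generalized cross-validation) and replaced by the residuals. The
#' residual reads as "the value of the variable relative to what its
#' confounders predict at that site". Confounders that are constant (or
#' have too few distinct values for a spline) are dropped with a warning.
#'
#' @param env An [env_table].
#' @param target Name of the variable to residualize (must not be listed
#'   among its own confounders).
#' @param confounders Character vector of confounder variable names.
#' @param k Spline basis dimension per confounder.
#' @return The modified [env_table]; the target column now holds residuals
#'   and its `residualized` metadata flag is set.
#' @export
residualize <- function(env, target, confounders, k = 10L) {
  stopifnot(inherits(env, "env_table"))
  .check_variables(env, c(target, confounders))
  if (target %in% confounders) {
    stop("`target` must not be one of its own confounders.", call. = FALSE)
  }
  df <- as.data.frame(env)
  keep <- character(0L)
  terms <- character(0L)
  for (cf in confounders) {
    nuniq <- length(unique(df[[cf]]))
    if (nuniq < 3L) {
      warning("Confounder `", cf, "` dropped: only ", nuniq,
              " distinct value(s).", call. = FALSE)
      next
    }
    kk <- min(as.integer(k), nuniq - 1L)
    terms <- c(terms, sprintf("s(%s, k = %d, bs = \"cr\")", cf, kk))
    keep <- c(keep, cf)
  }
  if (!length(keep)) {
    stop("No usable confounders left after dropping degenerate ones.",
         call. = FALSE)
  }
  form <- stats::as.formula(paste(target, "~", paste(terms, collapse = " + ")))
  fit <- mgcv::gam(form, data = df)
  env[[target]] <- as.numeric(stats::residuals(fit))
  meta <- env_metadata(env)
  meta$residualized[meta$variable == target] <- TRUE
  attr(env, "metadata") <- meta
  env
}

#' Boruta-style shadow-feature selection for a down-sampled random forest
#'
#' Decides which variables carry real signal about occurrence by competing
#' them against their own permuted copies ("shadow features"). Each run
#' appends a shuffled copy of every active variable, fits a down-sampled
#' random forest with permutation importance (normalized to a Z-score),
#' and records a *hit* for every real variable whose importance exceeds
#' the maximum shadow importance. After each run, a two-sided binomial
#' test (p = 0.5, Bonferroni-corrected over the still-active variables)
#' promotes variables with significantly more hits than misses to
#' *confirmed* and demotes those with significantly fewer to *rejected*
#' (rejected variables leave the competition). The loop stops when no
#' variable is left tentative or after `max_runs` runs; with a single run
#' no decision can reach significance, so everything stays tentative.
#'
#' @param env An [env_table].
#' @param occ Occurrence table (`site_id`, `presence`), both classes
#'   present.
#' @param ntree Trees per forest run.
#' @param alpha Significance level of the binomial decision test.
#' @param max_runs Maximum number of runs.
#' @param seed Integer seed; run `r` uses `seed + r`.
#' @param variables Candidate variables; default all in `env`.
#' @return Object of class `boruta_report`: list with `decision` (data
#'   frame `variable`, `decision`, `hits`, `runs`), `history` (per-run
#'   importance of real and max-shadow features), `alpha`, `max_runs`.
#' @export
boruta_select <- function(env, occ, ntree = 500L, alpha = 0.01,
                          max_runs = 100L, seed = 1L, variables = NULL) {
  env_df <- as.data.frame(env)
  if (is.null(variables)) variables <- setdiff(names(env_df), "site_id")
  if (length(unique(occ$presence)) < 2L) {
    stop("Both presences and absences are required.", call. = FALSE)
  }
  x <- env_df[match(occ$site_id, env_df$site_id), variables, drop = FALSE]
  if (anyNA(x)) stop("Occurrence sites missing from `env`.", call. = FALSE)
  y <- factor(occ$presence, levels = c(0L, 1L))
  nmin <- min(table(y))
  decision <- stats::setNames(rep("tentative", length(variables)), variables)
  hits <- stats::setNames(integer(length(variables)), variables)
  runs <- 0L
  history <- list()
  while (any(decision == "tentative") && runs < max_runs) {
    runs <- runs + 1L
    active <- names(decision)[decision != "rejected"]
    set.seed(as.integer(seed) + runs)
    shadows <- as.data.frame(lapply(x[active], sample))
    names(shadows) <- paste0("shadow_", active)
    xx <- cbind(x[active], shadows)
    rf <- randomForest::randomForest(
      x = xx, y = y, ntree = as.integer(ntree),
      mtry = max(1L, floor(sqrt(ncol(xx)))),
      strata = y, sampsize = c(nmin, nmin), replace = TRUE,
      importance = TRUE
    )
    imp <- randomForest::importance(rf, type = 1L, scale = TRUE)[, 1L]
    max_shadow <- max(imp[names(shadows)])
    hit <- imp[active] > max_shadow
    hits[active] <- hits[active] + as.integer(hit)
    history[[runs]] <- c(imp[active], max_shadow = max_shadow)
    tent <- names(decision)[decision == "tentative"]
    p_adj <- stats::p.adjust(vapply(tent, function(v) {
      stats::binom.test(hits[[v]], runs, 0.5)$p.value
    }, numeric(1L)), method = "bonferroni")
    for (i in seq_along(tent)) {
      if (p_adj[i] < alpha) {
        decision[tent[i]] <- if (hits[[tent[i]]] > runs / 2) "confirmed"
        else "rejected"
      }
    }
  }
  structure(list(
    decision = data.frame(variable = variables,
                          decision = unname(decision[variables]),
                          hits = unname(hits[variables]), runs = runs,
                          stringsAsFactors = FALSE),
    history = history,
    alpha = alpha, max_runs = as.integer(max_runs), seed = as.integer(seed)
  ), class = "boruta_report")
}

#' @export
print.boruta_report <- function(x, ...) {
  d <- x$decision
  cat("Shadow-feature selection after", d$runs[1L], "run(s), alpha =",
      x$alpha, "\n")
  for (dec in c("confirmed", "tentative", "rejected")) {
    v <- d$variable[d$decision == dec]
    if (length(v)) cat(sprintf("  %-9s %s\n", dec, paste(v, collapse = ", ")))
  }
  invisible(x)
}

#' Filter occurrence records by survey year
#'
#' Optional reader-side filter dropping records surveyed before a cutoff
#' (useful when older records predate the threats being modelled).
#'
#' @param occ Occurrence data frame with a `year` column.
#' @param min_year Keep records with `year >= min_year`; `NULL` keeps all.
#' @return Filtered occurrence data frame.
#' @export
filter_occurrences_by_year <- function(occ, min_year = NULL) {
  if (is.null(min_year)) return(occ)
  if (!"year" %in% names(occ)) {
    stop("`occ` has no `year` column to filter on.", call. = FALSE)
  }
  occ[occ$year >= min_year, , drop = FALSE]
}
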