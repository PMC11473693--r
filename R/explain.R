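# Resolve a model argument to a vectorized prediction function over a data
# frame of variables. Accepts an sdm_model or any function(newdata) -> numeric
# (plain functions make closed-form oracles and fast property tests possible).
.predict_fun <- function(model) {
  if (inherits(model, "sdm_model")) {
    function(newdata) .predict_rf(model, newdata)
  } else if (is.function(model)) {
    model
  } else {
    stop("`model` must be an sdm_model or a prediction function.",
         call. = FALSE)
  }
}

.as_feature_df <- function(x, variables) {
  x <- as.data.frame(x)
  missing <- setdiff(variables, names(x))
  if (length(missing)) {
    stop("Missing variable(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x[, variables, drop = FALSE]
}

#' Monte-Carlo Shapley attribution for a single site
#'
#' Estimates the per-variable Shapley contributions to a model prediction
#' with the Strumbelj--Kononenko permutation estimator. Each repetition
#' draws one random permutation of the variables and one background row;
#' walking along the permutation, variables flip one at a time from the
#' background value to the instance value, and each variable is credited
#' with the change in prediction caused by its own flip (the prefix rule:
#' one permutation serves every variable, which also reduces variance).
#' After averaging over repetitions, the residual of the efficiency
#' identity `sum(phi) = f(instance) - mean(f(background))` is spread
#' equally over the variables, so efficiency holds exactly while symmetry
#' is preserved.
#'
#' @param model An `sdm_model`, or a function taking a data frame of
#'   variable columns and returning numeric predictions.
#' @param instance A one-row data frame (or coercible) with the variables.
#' @param background Data frame of background rows defining the reference
#'   distribution (for an interventional value function).
#' @param n_reps Number of Monte-Carlo repetitions (>= 1).
#' @param seed Integer seed.
#' @param variables Variable names; defaults to the model's training
#'   variables or, for function models, the background's columns.
#' @return Named numeric vector `phi` with attributes `baseline` (mean
#'   background prediction), `prediction` (`f(instance)`), and `se`
#'   (per-variable Monte-Carlo standard errors, before the efficiency
#'   adjustment).
#' @seealso [shapley_exact()] for an exact oracle at small dimension,
#'   [shap_table()] to explain every site of a table.
#' @export
shapley_mc <- function(model, instance, background, n_reps = 10000L,
                       seed = 1L, variables = NULL) {
  if (n_reps < 1L) stop("`n_reps` must be >= 1.", call. = FALSE)
  f <- .predict_fun(model)
  if (is.null(variables)) {
    variables <- if (inherits(model, "sdm_model")) model$variables else
      setdiff(colnames(as.data.frame(background)), "site_id")
  }
  background <- .as_feature_df(background, variables)
  if (nrow(background) == 0L) {
    stop("`background` must contain at least one row.", call. = FALSE)
  }
  instance <- .as_feature_df(instance, variables)[1L, , drop = FALSE]
  set.seed(as.integer(seed))
  res <- .shapley_mc_core(f, instance, background, as.integer(n_reps))
  baseline <- mean(f(background))
  fx <- f(instance)
  phi <- res$phi
  resid <- (fx - baseline) - sum(phi)
  phi <- phi + resid / length(phi)
  structure(stats::setNames(phi, variables),
            baseline = baseline, prediction = fx,
            se = stats::setNames(res$se, variables))
}

# Core estimator, assumes RNG state is set. Builds all hybrid rows for all
# repetitions and calls the model once (model calls dominate the cost).
.shapley_mc_core <- function(f, instance, background, n_reps) {
  p <- ncol(background)
  perms <- vapply(seq_len(n_reps), function(i) sample.int(p),
                  integer(p)) # p x n_reps
  bg_idx <- sample.int(nrow(background), n_reps, replace = TRUE)
  bg <- as.matrix(background)[bg_idx, , drop = FALSE]
  inst <- matrix(rep(as.numeric(instance[1L, ]), each = n_reps), n_reps, p)
  # chain of p+1 points per repetition, from pure background to pure instance
  blocks <- vector("list", p + 1L)
  mask <- matrix(FALSE, n_reps, p)
  blocks[[1L]] <- bg
  for (k in seq_len(p)) {
    mask[cbind(seq_len(n_reps), perms[k, ])] <- TRUE
    blocks[[k + 1L]] <- ifelse(mask, inst, bg)
  }
  X <- do.call(rbind, blocks)
  colnames(X) <- colnames(background)
  preds <- matrix(f(as.data.frame(X)), n_reps, p + 1L)
  deltas <- preds[, -1L, drop = FALSE] - preds[, -(p + 1L), drop = FALSE]
  phi <- numeric(p)
  se <- numeric(p)
  for (j in seq_len(p)) {
    # repetitions in which variable j was the k-th flip
    d <- deltas[cbind(seq_len(n_reps), apply(perms == j, 2L, which))]
    phi[j] <- mean(d)
    se[j] <- stats::sd(d) / sqrt(n_reps)
  }
  list(phi = phi, se = se)
}

#' Exact Shapley values by coalition enumeration
#'
#' Computes exact interventional Shapley values for one instance by
#' enumerating all `2^p` coalitions, with value function
#' `v(S) = mean over background rows of f(instance on S, background off S)`.
#' Efficiency, symmetry, dummy and additivity hold exactly, making this the
#' test oracle for [shapley_mc()]. Refused above `p = 12` (4096 coalitions
#' times the background size model calls).
#'
#' @inheritParams shapley_mc
#' @return Named numeric vector with `baseline` and `prediction` attributes.
#' @export
shapley_exact <- function(model, instance, background, variables = NULL) {
  f <- .predict_fun(model)
  if (is.null(variables)) {
    variables <- if (inherits(model, "sdm_model")) model$variables else
      setdiff(colnames(as.data.frame(background)), "site_id")
  }
  p <- length(variables)
  if (p > 12L) {
    stop("shapley_exact enumerates 2^p coalitions and is limited to p <= 12; ",
         "use shapley_mc() for ", p, " variables.", call. = FALSE)
  }
  background <- .as_feature_df(background, variables)
  if (nrow(background) == 0L) {
    stop("`background` must contain at least one row.", call. = FALSE)
  }
  instance <- .as_feature_df(instance, variables)[1L, , drop = FALSE]
  nb <- nrow(background)
  n_coal <- 2L^p
  # membership matrix of all coalitions
  member <- t(vapply(seq_len(n_coal) - 1L,
                     function(s) as.logical(bitwAnd(s, 2L^(seq_len(p) - 1L))),
                     logical(p)))
  bg <- as.matrix(background)
  inst <- as.numeric(instance[1L, ])
  rows <- vector("list", n_coal)
  for (s in seq_len(n_coal)) {
    h <- bg
    h[, member[s, ]] <- matrix(rep(inst[member[s, ]], each = nb), nb)
    rows[[s]] <- h
  }
  X <- do.call(rbind, rows)
  colnames(X) <- variables
  v <- colMeans(matrix(f(as.data.frame(X)), nb, n_coal))
  sizes <- rowSums(member)
  # weight |S|! (p-|S|-1)! / p!, defined only for coalitions excluding j
  wt <- ifelse(sizes < p,
               factorial(sizes) * factorial(pmax(p - sizes - 1L, 0L)) /
                 factorial(p), 0)
  phi <- numeric(p)
  for (j in seq_len(p)) {
    without <- which(!member[, j])
    with_j <- without + 2L^(j - 1L)
    phi[j] <- sum(wt[without] * (v[with_j] - v[without]))
  }
  structure(stats::setNames(phi, variables),
            baseline = v[1L], prediction = v[n_coal])
}

#' Shapley attributions for every site of a table
#'
#' Applies [shapley_mc()] to each row of an environmental table. Each site
#' draws from its own random sub-stream (seed plus site index within the
#' table), so results do not depend on execution order and sites can be
#' explained in any batch arrangement. Sites are processed in chunks so the
#' model is called on large blocks of hybrid rows at once.
#'
#' @param model An `sdm_model` or prediction function.
#' @param env [env_table] (or data frame with `site_id`) of sites to explain.
#' @param background Background table; defaults to `env` itself, subsampled
#'   (seeded) to `background_size` rows when larger.
#' @param n_reps Monte-Carlo repetitions per site.
#' @param seed Integer root seed; each site draws from `seed` plus the
#'   site's rank among the table's ids.
#' @param background_size Maximum background rows retained.
#' @param chunk_size Number of sites whose hybrid rows are batched into one
#'   model call.
#' @return Object of class `shap_matrix`: list with `phi` (site x variable
#'   matrix), `baseline` (mean background prediction), `y` (per-site
#'   reconstructed prediction `baseline + rowSums(phi)`, equal to the model
#'   prediction by efficiency), and `meta` (n_reps, seed, background size).
#' @export
shap_table <- function(model, env, background = NULL, n_reps = 10000L,
                       seed = 1L, background_size = 1000L, chunk_size = 32L) {
  f <- .predict_fun(model)
  variables <- if (inherits(model, "sdm_model")) model$variables else
    setdiff(colnames(as.data.frame(if (is.null(background)) env else
      background)), "site_id")
  env_df <- as.data.frame(env)
  site_id <- if ("site_id" %in% names(env_df)) env_df$site_id else
    as.character(seq_len(nrow(env_df)))
  X <- .as_feature_df(env_df, variables)
  # canonical background order so the result is invariant to row order
  if (is.null(background)) background <- X[order(site_id), , drop = FALSE]
  background <- .as_feature_df(background, variables)
  if (nrow(background) > background_size) {
    set.seed(as.integer(seed))
    background <- background[sample.int(nrow(background), background_size), ,
                             drop = FALSE]
  }
  baseline <- mean(f(background))
  n <- nrow(X)
  p <- length(variables)
  phi <- matrix(NA_real_, n, p, dimnames = list(site_id, variables))
  n_reps <- as.integer(n_reps)
  bg <- as.matrix(background)
  nb <- nrow(bg)
  # cap the hybrid-block size at ~4e6 matrix cells to bound memory
  chunk_size <- max(1L, min(as.integer(chunk_size),
                            floor(4e6 / ((p + 1) * n_reps * p))))
  # per-site sub-streams keyed to the site's rank among ids, not its row,
  # so explaining the same sites in any order gives identical rows
  site_rank <- as.integer(rank(site_id, ties.method = "first"))
  chunks <- split(seq_len(n), ceiling(seq_len(n) / chunk_size))
  for (idx in chunks) {
    rows_per_site <- (p + 1L) * n_reps
    Xbig <- matrix(NA_real_, length(idx) * rows_per_site, p)
    perms_all <- vector("list", length(idx))
    for (ii in seq_along(idx)) {
      i <- idx[ii]
      set.seed(as.integer(seed) + site_rank[i])
      perms <- vapply(seq_len(n_reps), function(r) sample.int(p), integer(p))
      bgr <- bg[sample.int(nb, n_reps, replace = TRUE), , drop = FALSE]
      inst <- matrix(rep(as.numeric(X[i, ]), each = n_reps), n_reps, p)
      mask <- matrix(FALSE, n_reps, p)
      off <- (ii - 1L) * rows_per_site
      Xbig[off + seq_len(n_reps), ] <- bgr
      hyb <- bgr
      for (k in seq_len(p)) {
        mask[cbind(seq_len(n_reps), perms[k, ])] <- TRUE
        hyb <- ifelse(mask, inst, bgr)
        Xbig[off + k * n_reps + seq_len(n_reps), ] <- hyb
      }
      perms_all[[ii]] <- perms
    }
    colnames(Xbig) <- variables
    preds_big <- f(as.data.frame(Xbig))
    for (ii in seq_along(idx)) {
      i <- idx[ii]
      off <- (ii - 1L) * rows_per_site
      preds <- matrix(preds_big[off + seq_len(rows_per_site)], n_reps, p + 1L)
      deltas <- preds[, -1L, drop = FALSE] - preds[, -(p + 1L), drop = FALSE]
      perms <- perms_all[[ii]]
      ph <- numeric(p)
      for (j in seq_len(p)) {
        d <- deltas[cbind(seq_len(n_reps), apply(perms == j, 2L, which))]
        ph[j] <- mean(d)
      }
      phi[i, ] <- ph
    }
  }
  fx <- f(X)
  resid <- (fx - baseline) - rowSums(phi)
  phi <- phi + resid / p
  structure(list(
    phi = phi,
    baseline = baseline,
    y = stats::setNames(baseline + rowSums(phi), site_id),
    meta = list(n_reps = n_reps, seed = as.integer(seed),
                background_size = nrow(background))
  ), class = "shap_matrix")
}

#' @export
print.shap_matrix <- function(x, ...) {
  cat("Shapley attribution matrix:", nrow(x$phi), "sites x", ncol(x$phi),
      "variables | baseline", round(x$baseline, 4),
      "| n_reps", x$meta$n_reps, "\n")
  imp <- sort(colMeans(abs(x$phi)), decreasing = TRUE)
  cat("Mean |phi|:",
      paste(names(imp), round(imp, 4), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Global importance and response-direction summaries
#'
#' Aggregates a [shap_matrix] into the two global views used to interpret
#' a fitted model: the mean absolute attribution per variable (overall
#' importance) and the Spearman rank correlation between each variable's
#' raw values and its attributions (the overall response direction and
#' strength; near +1/-1 indicates a tightly coupled monotone response).
#'
#' @param shap A [shap_matrix].
#' @param env The [env_table] (or data frame) holding the raw values, with
#'   sites matching the attribution rows.
#' @return Data frame with `variable`, `mean_abs_phi`, `rho_raw_phi` (`NA`
#'   when an attribution column is constant).
#' @export
global_summaries <- function(shap, env) {
  stopifnot(inherits(shap, "shap_matrix"))
  env_df <- as.data.frame(env)
  vars <- colnames(shap$phi)
  .check_variables_df(env_df, vars)
  if ("site_id" %in% names(env_df)) {
    m <- match(rownames(shap$phi), env_df$site_id)
    if (anyNA(m)) {
      stop("Sites of the attribution matrix are missing from `env`.",
           call. = FALSE)
    }
    env_df <- env_df[m, , drop = FALSE]
  }
  rho <- vapply(vars, function(v) {
    ph <- shap$phi[, v]
    if (stats::sd(ph) == 0 || stats::sd(env_df[[v]]) == 0) return(NA_real_)
    stats::cor(env_df[[v]], ph, method = "spearman")
  }, numeric(1L))
  data.frame(
    variable = vars,
    mean_abs_phi = unname(colMeans(abs(shap$phi))),
    rho_raw_phi = unname(rho),
    stringsAsFactors = FALSE
  )
}

.check_variables_df <- function(df, vars) {
  missing <- setdiff(vars, names(df))
  if (length(missing)) {
    stop("Unknown variable(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}
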