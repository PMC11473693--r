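#' Fit a down-sampled (class-balanced) random forest
#'
#' Fits a presence--absence random forest in which every tree is grown on a
#' balanced bootstrap: the per-tree sample contains equally many presences
#' and absences, each equal to the minority-class size, drawn with
#' replacement within class. This counters the over-prediction of the
#' majority class under strong class imbalance; the resulting predictions
#' (fraction of trees voting presence) are an index of relative occurrence
#' ("environmental suitability"), not a calibrated probability of
#' occurrence. Defaults follow common SDM practice: `ntree = 1000`,
#' `mtry = floor(sqrt(p))`, no further tuning.
#'
#' @param env An [env_table] covering every surveyed site.
#' @param occ Occurrence data frame with `site_id` and `presence` (0/1);
#'   both classes must be present.
#' @param ntree Number of trees.
#' @param mtry Variables tried per split; default `floor(sqrt(p))`.
#' @param seed Integer seed (the fit is deterministic given it).
#' @param variables Variables to use; default all variables of `env`.
#' @return Object of class `sdm_model`: list with the `randomForest` fit
#'   (`rf`), `variables`, `ntree`, `mtry`, `n_minority`, `baseline` (mean
#'   predicted suitability over the training sites), `train_sites`, `seed`.
#' @export
fit_downsampled_rf <- function(env, occ, ntree = 1000L, mtry = NULL,
                               seed = 1L, variables = NULL) {
  stopifnot(is.data.frame(occ))
  if (!all(c("site_id", "presence") %in% names(occ))) {
    stop("`occ` needs columns site_id and presence.", call. = FALSE)
  }
  env_df <- as.data.frame(env)
  if (is.null(variables)) variables <- setdiff(names(env_df), "site_id")
  .check_variables_df(env_df, variables)
  unmatched <- setdiff(occ$site_id, env_df$site_id)
  if (length(unmatched)) {
    stop("Occurrence site(s) absent from the environmental table: ",
         paste(utils::head(unmatched, 10L), collapse = ", "),
         if (length(unmatched) > 10L) ", ...", call. = FALSE)
  }
  y <- factor(occ$presence, levels = c(0L, 1L))
  if (anyNA(y)) stop("`presence` must be 0 or 1.", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("Both presences and absences are required to fit the model.",
         call. = FALSE)
  }
  x <- env_df[match(occ$site_id, env_df$site_id), variables, drop = FALSE]
  nmin <- min(table(y))
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(length(variables))))
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(
    x = x, y = y, ntree = as.integer(ntree), mtry = as.integer(mtry),
    strata = y, sampsize = c(nmin, nmin), replace = TRUE, keep.inbag = TRUE
  )
  model <- structure(list(
    rf = rf, variables = variables, ntree = as.integer(ntree),
    mtry = as.integer(mtry), n_minority = as.integer(nmin),
    train_sites = occ$site_id, seed = as.integer(seed)
  ), class = "sdm_model")
  model$baseline <- mean(.predict_rf(model, x))
  model
}

.predict_rf <- function(model, newdata) {
  as.numeric(stats::predict(model$rf, newdata = newdata,
                            type = "prob")[, "1"])
}

#' Predict environmental suitability
#'
#' Vote-fraction predictions of an `sdm_model` on new sites; values lie in
#' `[0, 1]`.
#'
#' @param model An `sdm_model`.
#' @param env [env_table] or data frame containing all training variables.
#' @return Named numeric vector (named by `site_id` when present).
#' @export
predict_suitability <- function(model, env) {
  stopifnot(inherits(model, "sdm_model"))
  env_df <- as.data.frame(env)
  missing <- setdiff(model$variables, names(env_df))
  if (length(missing)) {
    stop("Missing model variable(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  p <- .predict_rf(model, env_df[, model$variables, drop = FALSE])
  if ("site_id" %in% names(env_df)) names(p) <- env_df$site_id
  p
}

#' @export
print.sdm_model <- function(x, ...) {
  cat("Down-sampled random forest:", x$ntree, "trees, mtry", x$mtry, "\n")
  cat("Training sites:", length(x$train_sites), "| balanced bootstrap:",
      x$n_minority, "per class per tree\n")
  cat("Baseline suitability (mean over training sites):",
      round(x$baseline, 4), "\n")
  invisible(x)
}

#' Per-tree class counts of the balanced bootstrap
#'
#' Audit helper: counts, for every tree, how many presence and absence
#' records entered its bootstrap (with multiplicity). For a down-sampled
#' forest both counts equal the minority-class size in every tree.
#'
#' @param model An `sdm_model` fitted with [fit_downsampled_rf()].
#' @param occ The occurrence table the model was fitted to.
#' @return Matrix `ntree x 2` with columns `absence`, `presence`.
#' @export
inbag_class_counts <- function(model, occ) {
  stopifnot(inherits(model, "sdm_model"))
  inbag <- model$rf$inbag
  pres <- occ$presence[match(model$train_sites, occ$site_id)] == 1L
  t(vapply(seq_len(ncol(inbag)), function(tr) {
    c(absence = sum(inbag[!pres, tr]), presence = sum(inbag[pres, tr]))
  }, numeric(2L)))
}
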