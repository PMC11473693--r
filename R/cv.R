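#' Assign sites to spatially blocked cross-validation folds
#'
#' Overlays a grid of square tiles of edge `block_size` on the site
#' coordinates (half-open tiles `[x0, x0 + w) x [y0, y0 + w)` anchored at
#' the coordinate minima) and randomly assigns whole tiles -- never
#' individual sites -- to `k` folds, so that spatially proximate sites stay
#' on the same side of every train/test split. Tiles are shuffled
#' (seeded) and dealt round-robin, which balances tile counts across folds.
#'
#' @param sites Data frame with `site_id`, `x`, `y` (planar meters), or a
#'   `river_network` (its nodes are used).
#' @param block_size Tile edge length in meters. The default of 10 km
#'   matches the scale of environmental autocorrelation typical of
#'   riverscape covariates.
#' @param k Number of folds (>= 2); there must be at least `k` non-empty
#'   tiles.
#' @param seed Integer seed for the tile shuffle.
#' @return Object of class `fold_assignment`: data frame with `site_id`,
#'   `block_id`, `fold`; `block_size` and `k` stored as attributes.
#' @export
spatial_block_folds <- function(sites, block_size = 10000, k = 5L,
                                seed = 1L) {
  if (inherits(sites, "river_network")) sites <- sites$nodes
  stopifnot(is.data.frame(sites))
  if (!all(c("site_id", "x", "y") %in% names(sites))) {
    stop("`sites` needs columns site_id, x, y.", call. = FALSE)
  }
  if (k < 2L) stop("`k` must be >= 2.", call. = FALSE)
  if (block_size <= 0) stop("`block_size` must be positive.", call. = FALSE)
  ix <- floor((sites$x - min(sites$x)) / block_size)
  iy <- floor((sites$y - min(sites$y)) / block_size)
  block_id <- paste(ix, iy, sep = "_")
  tiles <- unique(block_id)
  if (length(tiles) < k) {
    stop("Only ", length(tiles), " non-empty tile(s) for k = ", k,
         " folds; enlarge the extent or reduce `block_size`/`k`.",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  tiles <- sample(tiles)
  fold_of_tile <- stats::setNames(rep_len(seq_len(k), length(tiles)), tiles)
  out <- data.frame(site_id = sites$site_id, block_id = block_id,
                    fold = unname(fold_of_tile[block_id]),
                    stringsAsFactors = FALSE)
  structure(out, block_size = block_size, k = as.integer(k),
            class = c("fold_assignment", "data.frame"))
}

#' Binary classification metrics from observations and scores
#'
#' Computes the standard SDM evaluation set from presence/absence labels
#' and continuous suitability scores: threshold-free AUC plus, at the given
#' threshold, sensitivity, specificity, TSS (= sensitivity + specificity
#' - 1), MCC, Cohen's kappa, accuracy, F1 and the Brier score (mean squared
#' error of the score against the 0/1 label, threshold-free).
#' A score >= threshold predicts presence.
#'
#' @param obs Integer/logical vector of observed presence (1) / absence (0).
#' @param score Numeric suitability scores in `[0, 1]`.
#' @param threshold Classification threshold.
#' @return Named numeric vector of the 10 metrics (including `threshold`).
#' @export
classification_metrics <- function(obs, score, threshold = 0.5) {
  obs <- as.integer(obs)
  pred <- as.integer(score >= threshold)
  tp <- sum(obs == 1L & pred == 1L)
  fn <- sum(obs == 1L & pred == 0L)
  tn <- sum(obs == 0L & pred == 0L)
  fp <- sum(obs == 0L & pred == 1L)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / length(obs)
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else NA_real_
  pe <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / length(obs)^2
  kappa <- if (pe < 1) (acc - pe) / (1 - pe) else NA_real_
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  auc <- if (length(unique(obs)) == 2L) {
    as.numeric(pROC::auc(pROC::roc(obs, score, quiet = TRUE,
                                   direction = "<", levels = c(0L, 1L))))
  } else NA_real_
  c(auc = auc, sensitivity = sens, specificity = spec,
    tss = sens + spec - 1, mcc = mcc, kappa = kappa, accuracy = acc,
    f1 = f1, brier = mean((score - obs)^2), threshold = threshold)
}

#' Threshold maximizing the True Skill Statistic
#'
#' Sweeps the unique observed scores as candidate thresholds and returns
#' the one maximizing TSS; ties are broken towards the lowest threshold.
#'
#' @param obs Observed presence (1) / absence (0).
#' @param score Suitability scores.
#' @return A single threshold value.
#' @export
max_tss_threshold <- function(obs, score) {
  obs <- as.integer(obs)
  cand <- sort(unique(score))
  np <- sum(obs == 1L)
  na_ <- sum(obs == 0L)
  # sens/spec over all candidate thresholds via cumulative counts
  tss <- vapply(cand, function(th) {
    pred <- score >= th
    sum(obs == 1L & pred) / np + sum(obs == 0L & !pred) / na_ - 1
  }, numeric(1L))
  cand[which.max(tss)]
}

#' Spatially blocked cross-validation of a down-sampled random forest
#'
#' Iteratively holds out each fold, fits the model on the remaining folds,
#' and evaluates on the held-out sites. Binary metrics use the threshold
#' that maximizes TSS on the *training* predictions of that iteration;
#' AUC and Brier are threshold-free. Folds whose training portion lacks a
#' class are skipped with a warning. Pooled rows combine the out-of-fold
#' predictions (binary metrics from the per-fold thresholded predictions;
#' pooled AUC from the pooled scores).
#'
#' @param env [env_table]; `occ` occurrence table (`site_id`, `presence`).
#' @param occ Occurrence data frame.
#' @param folds A `fold_assignment` covering every occurrence site.
#' @param ntree,mtry,variables Passed to [fit_downsampled_rf()].
#' @param seed Integer seed; fold `i` uses `seed + i`.
#' @return Object of class `cv_report`: list with `per_fold` (data frame of
#'   metrics by fold), `pooled` (named metric vector), `predictions`
#'   (out-of-fold site-level scores), `skipped` fold ids.
#' @export
evaluate_blocked_cv <- function(env, occ, folds, ntree = 1000L, mtry = NULL,
                                seed = 1L, variables = NULL) {
  stopifnot(inherits(folds, "fold_assignment"))
  fold_of <- folds$fold[match(occ$site_id, folds$site_id)]
  if (anyNA(fold_of)) {
    stop("Some occurrence sites have no fold assignment.", call. = FALSE)
  }
  ks <- sort(unique(fold_of))
  per_fold <- list()
  pooled_pred <- list()
  skipped <- integer(0L)
  for (kf in ks) {
    train <- occ[fold_of != kf, , drop = FALSE]
    test <- occ[fold_of == kf, , drop = FALSE]
    if (length(unique(train$presence)) < 2L) {
      warning("Fold ", kf, " skipped: single-class training data.",
              call. = FALSE)
      skipped <- c(skipped, kf)
      next
    }
    model <- fit_downsampled_rf(env, train, ntree = ntree, mtry = mtry,
                                seed = as.integer(seed) + kf,
                                variables = variables)
    env_df <- as.data.frame(env)
    train_score <- predict_suitability(
      model, env_df[match(train$site_id, env_df$site_id), , drop = FALSE])
    th <- max_tss_threshold(train$presence, train_score)
    test_score <- predict_suitability(
      model, env_df[match(test$site_id, env_df$site_id), , drop = FALSE])
    per_fold[[as.character(kf)]] <-
      c(fold = kf, classification_metrics(test$presence, test_score, th))
    pooled_pred[[as.character(kf)]] <- data.frame(
      site_id = test$site_id, fold = kf, presence = test$presence,
      score = unname(test_score), predicted = as.integer(test_score >= th),
      stringsAsFactors = FALSE)
  }
  if (!length(per_fold)) {
    stop("All folds were skipped; cross-validation failed.", call. = FALSE)
  }
  preds <- do.call(rbind, pooled_pred)
  rownames(preds) <- NULL
  tp <- sum(preds$presence == 1L & preds$predicted == 1L)
  fn <- sum(preds$presence == 1L & preds$predicted == 0L)
  tn <- sum(preds$presence == 0L & preds$predicted == 0L)
  fp <- sum(preds$presence == 0L & preds$predicted == 1L)
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  pooled <- c(
    auc = if (length(unique(preds$presence)) == 2L) {
      as.numeric(pROC::auc(pROC::roc(preds$presence, preds$score,
                                     quiet = TRUE, direction = "<",
                                     levels = c(0L, 1L))))
    } else NA_real_,
    sensitivity = sens, specificity = spec, tss = sens + spec - 1,
    mcc = if (denom > 0) (tp * tn - fp * fn) / denom else NA_real_,
    accuracy = (tp + tn) / nrow(preds),
    brier = mean((preds$score - preds$presence)^2)
  )
  structure(list(per_fold = as.data.frame(do.call(rbind, per_fold)),
                 pooled = pooled, predictions = preds, skipped = skipped),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Spatially blocked cross-validation (", nrow(x$per_fold), "folds")
  if (length(x$skipped)) cat(",", length(x$skipped), "skipped")
  cat(" )\n")
  cat(sprintf("Pooled: AUC %.3f | TSS %.3f | MCC %.3f | Brier %.3f\n",
              x$pooled["auc"], x$pooled["tss"], x$pooled["mcc"],
              x$pooled["brier"]))
  invisible(x)
}
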