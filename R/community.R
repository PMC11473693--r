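#' Aggregate per-species shadow results into per-site community summaries
#'
#' For each site, summarises the quantitative shadow ratios of the species
#' whose expected distribution contains that site: their count, the mean,
#' minimum and standard deviation of the ratio, the mean observed and
#' expected suitability (both across species in E and across all species),
#' and the mean per-species counts of negative threat attributions within
#' two threat groups (typically the habitat-quality group of four
#' indicators, scored 0--4 per species, and connectivity alone, scored
#' 0--1). Sites whose species-in-E count does not exceed `min_species` are
#' masked (`masked = TRUE`) to avoid summaries built from too few species;
#' with the default of 2, only sites with more than two species in their
#' expected distributions are retained.
#'
#' @param results Named list of `shadow_result` objects (one per species)
#'   from [quantitative_shadow()], all over the same sites.
#' @param threat_groups Named list of threat subsets to count negatives
#'   over, e.g. `list(habitat = c(...), connectivity = "connectivity")`.
#'   Groups must be subsets of every result's threat set.
#' @param min_species Mask sites with `<= min_species` species in E.
#' @return Object of class `community_summary`: data frame with one row per
#'   site (`site_id`, `n_in_expected`, `mean_ratio`, `min_ratio`,
#'   `sd_ratio`, `mean_observed_E`, `mean_expected_E`, `mean_observed_all`,
#'   `mean_expected_all`, one `neg_<group>` column per threat group,
#'   `masked`).
#' @export
community_summary <- function(results, threat_groups = list(),
                              min_species = 2L) {
  if (!length(results)) stop("Need at least one species result.",
                             call. = FALSE)
  if (!all(vapply(results, inherits, logical(1L), "shadow_result"))) {
    stop("`results` must be a list of shadow_result objects.", call. = FALSE)
  }
  ids <- results[[1L]]$sites$site_id
  for (r in results) {
    if (!identical(sort(r$sites$site_id), sort(ids))) {
      stop("Site ids differ between species results.", call. = FALSE)
    }
  }
  n <- length(ids)
  nsp <- length(results)
  inE <- matrix(FALSE, n, nsp)
  ratio <- obs <- exp_ <- matrix(NA_real_, n, nsp)
  grp_counts <- lapply(threat_groups, function(g) matrix(NA_real_, n, nsp))
  for (s in seq_len(nsp)) {
    r <- results[[s]]
    m <- match(ids, r$sites$site_id)
    inE[, s] <- r$sites$in_expected[m]
    ratio[, s] <- r$sites$ratio[m]
    obs[, s] <- r$sites$observed[m]
    exp_[, s] <- r$sites$expected[m]
    for (g in names(threat_groups)) {
      gv <- threat_groups[[g]]
      missing <- setdiff(gv, colnames(r$threat_negative))
      if (length(missing)) {
        stop("Threat group `", g, "` references variables absent from a ",
             "species result: ", paste(missing, collapse = ", "),
             call. = FALSE)
      }
      grp_counts[[g]][, s] <-
        rowSums(r$threat_negative[m, gv, drop = FALSE])
    }
  }
  n_in_E <- rowSums(inE)
  stat_in_E <- function(mat, fun) {
    vapply(seq_len(n), function(i) {
      v <- mat[i, inE[i, ]]
      v <- v[!is.na(v)]
      if (length(v)) fun(v) else NA_real_
    }, numeric(1L))
  }
  out <- data.frame(
    site_id = ids,
    n_in_expected = n_in_E,
    mean_ratio = stat_in_E(ratio, mean),
    min_ratio = stat_in_E(ratio, min),
    sd_ratio = stat_in_E(ratio, function(v)
      if (length(v) > 1L) stats::sd(v) else 0),
    mean_observed_E = stat_in_E(obs, mean),
    mean_expected_E = stat_in_E(exp_, mean),
    mean_observed_all = rowMeans(obs),
    mean_expected_all = rowMeans(exp_),
    stringsAsFactors = FALSE
  )
  for (g in names(threat_groups)) {
    out[[paste0("neg_", g)]] <- stat_in_E(grp_counts[[g]], mean)
  }
  out$masked <- out$n_in_expected <= min_species
  structure(out, min_species = as.integer(min_species),
            threat_groups = threat_groups,
            class = c("community_summary", "data.frame"))
}

#' @export
print.community_summary <- function(x, ...) {
  cat("Community summary:", nrow(x), "sites,", sum(!x$masked),
      "unmasked (more than", attr(x, "min_species"),
      "species in the expected distribution)\n")
  u <- x[!x$masked, ]
  if (nrow(u)) {
    cat(sprintf("Unmasked means: ratio %.3f | min ratio %.3f | observed %.3f | expected %.3f\n",
                mean(u$mean_ratio, na.rm = TRUE),
                mean(u$min_ratio, na.rm = TRUE),
                mean(u$mean_observed_E, na.rm = TRUE),
                mean(u$mean_expected_E, na.rm = TRUE)))
  }
  invisible(x)
}

#' Associate community shadow ratios with threat-negative counts
#'
#' Spearman rank correlations, over unmasked sites only, between the mean
#' and minimum community shadow ratio and each threat-group negative count
#' of a [community_summary()]. Negative correlations indicate that sites
#' where more threats act negatively retain less of their expected
#' suitability.
#'
#' @param summary A `community_summary` with at least 3 unmasked sites.
#' @return Data frame with `group`, `statistic` (`mean_ratio`/`min_ratio`),
#'   `rho` (`NA` when a column is constant).
#' @export
shadow_threat_association <- function(summary) {
  stopifnot(inherits(summary, "community_summary"))
  u <- summary[!summary$masked, , drop = FALSE]
  if (nrow(u) < 3L) stop("Need at least 3 unmasked sites.", call. = FALSE)
  groups <- names(attr(summary, "threat_groups"))
  if (!length(groups)) stop("The summary has no threat groups.", call. = FALSE)
  res <- expand.grid(group = groups, statistic = c("mean_ratio", "min_ratio"),
                     stringsAsFactors = FALSE)
  res$rho <- mapply(function(g, st) {
    a <- u[[st]]; b <- u[[paste0("neg_", g)]]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 3L || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
      return(NA_real_)
    }
    stats::cor(a[ok], b[ok], method = "spearman")
  }, res$group, res$statistic)
  res
}

#' Per-region, per-species mean attribution report
#'
#' Contrasts how each variable contributes to each species' suitability
#' within a chosen region (e.g. one river catchment): the mean attribution
#' of every variable over the region's sites, per species, expressed as
#' deviations from each species' mean prediction, alongside whether the
#' species was actually recorded in surveys within the region. Variables
#' are ordered by their average attribution across species (most positive
#' first).
#'
#' @param shap_set Named list of [shap_matrix] objects, one per species.
#' @param region_sites Non-empty character vector of site ids; each species'
#'   attribution matrix must contain all of them.
#' @param surveys Optional occurrence data frame (`site_id`, `species`,
#'   `presence`) used to flag species observed in the region.
#' @return Object of class `local_contribution_report`: data frame in long
#'   format with `species`, `variable`, `mean_phi`, `baseline`,
#'   `observed_in_surveys`; variables ordered by cross-species mean phi.
#' @export
local_contribution_report <- function(shap_set, region_sites,
                                      surveys = NULL) {
  if (!length(region_sites)) {
    stop("`region_sites` must be non-empty.", call. = FALSE)
  }
  if (!all(vapply(shap_set, inherits, logical(1L), "shap_matrix"))) {
    stop("`shap_set` must be a list of shap_matrix objects.", call. = FALSE)
  }
  rows <- list()
  for (sp in names(shap_set)) {
    shap <- shap_set[[sp]]
    missing <- setdiff(region_sites, rownames(shap$phi))
    if (length(missing)) {
      stop("Species `", sp, "` has no attributions for region site(s): ",
           paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
    }
    mphi <- colMeans(shap$phi[region_sites, , drop = FALSE])
    observed <- if (is.null(surveys)) NA else {
      any(surveys$species == sp & surveys$site_id %in% region_sites &
            surveys$presence == 1L)
    }
    rows[[sp]] <- data.frame(
      species = sp, variable = names(mphi), mean_phi = unname(mphi),
      baseline = shap$baseline, observed_in_surveys = observed,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ord <- names(sort(tapply(out$mean_phi, out$variable, mean),
                    decreasing = TRUE))
  out$variable <- factor(out$variable, levels = ord)
  out <- out[order(out$species, out$variable), ]
  out$variable <- as.character(out$variable)
  rownames(out) <- NULL
  structure(out, class = c("local_contribution_report", "data.frame"))
}
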