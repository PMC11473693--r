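#' Read and validate a run configuration
#'
#' Run configurations are YAML files collecting the variable sets and the
#' run-level constants of the whole pipeline. Validated invariants: the
#' natural and threat sets are disjoint and non-empty, seeds are integers,
#' and numeric settings are positive. Missing settings fall back to the
#' defaults of [default_run_config()].
#'
#' @param path Path to a YAML file, or a list with the same structure.
#' @return Validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  defaults <- default_run_config()
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  errors <- character(0L)
  overlap <- intersect(cfg$natural_set, cfg$threat_set)
  if (length(overlap)) {
    errors <- c(errors, paste0("natural_set and threat_set overlap: ",
                               paste(overlap, collapse = ", ")))
  }
  if (!length(cfg$natural_set)) errors <- c(errors, "natural_set is empty")
  if (!length(cfg$threat_set)) errors <- c(errors, "threat_set is empty")
  for (nm in c("ntree", "n_reps", "k_folds", "min_species", "seed")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v != round(v)) {
      errors <- c(errors, paste0(nm, " must be a single integer"))
    }
  }
  if (!is.numeric(cfg$block_size) || cfg$block_size <= 0) {
    errors <- c(errors, "block_size must be positive")
  }
  if (!cfg$scenario %in% c("q95_positive", "zero_negative", "mean_positive")) {
    errors <- c(errors, paste0("unknown scenario: ", cfg$scenario))
  }
  if (length(errors)) {
    stop("Invalid run configuration:\n  - ",
         paste(errors, collapse = "\n  - "), call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' @rdname read_run_config
#' @export
default_run_config <- function() {
  list(
    natural_set = c("discharge", "slope", "temperature", "velocity",
                    "distance_to_lake"),
    threat_set = c("urbanisation", "morphological_modification",
                   "floodplain", "wetland", "connectivity"),
    ntree = 1000L,
    mtry = NULL,
    n_reps = 10000L,
    background_size = 1000L,
    scenario = "q95_positive",
    block_size = 10000,
    k_folds = 5L,
    min_species = 2L,
    min_year = NULL,
    seed = 1L
  )
}

#' Read and write environmental tables with sidecar metadata
#'
#' The tabular values travel as UTF-8 CSV; the variable metadata (category,
#' direction of benefit, residualized flag) travels in a YAML sidecar named
#' `<path>.yaml` so the CSV stays a plain rectangular file.
#'
#' @param env An [env_table] (for writing).
#' @param path CSV path; the sidecar is `paste0(path, ".yaml")`.
#' @return `read_env_table()` returns an [env_table];
#'   `write_env_table()` returns `path` invisibly.
#' @export
write_env_table <- function(env, path) {
  stopifnot(inherits(env, "env_table"))
  utils::write.csv(as.data.frame(env), path, row.names = FALSE)
  meta <- env_metadata(env)
  yaml::write_yaml(lapply(seq_len(nrow(meta)), function(i) {
    list(variable = meta$variable[i], category = meta$category[i],
         direction = if (is.na(meta$direction[i])) NULL else
           meta$direction[i],
         residualized = meta$residualized[i])
  }), paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_env_table
#' @export
read_env_table <- function(path) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta_raw <- yaml::read_yaml(paste0(path, ".yaml"))
  metadata <- do.call(rbind, lapply(meta_raw, function(m) {
    data.frame(variable = m$variable, category = m$category,
               direction = if (is.null(m$direction)) NA_character_ else
                 m$direction,
               residualized = isTRUE(m$residualized),
               stringsAsFactors = FALSE)
  }))
  env_table(data, metadata)
}

#' Write tabular pipeline artifacts
#'
#' Writers for the remaining pipeline artifacts, all plain CSV with a JSON
#' manifest where provenance matters. [write_shap_matrix()] writes the
#' attribution table in long format (`site_id`, `variable`, `phi`) plus a
#' `<path>.json` manifest holding the baseline, the estimator settings and
#' a config hash; [read_shap_matrix()] reverses it.
#'
#' @param shap A [shap_matrix].
#' @param path Output CSV path.
#' @return The path, invisibly (writers); the object (readers).
#' @export
write_shap_matrix <- function(shap, path) {
  stopifnot(inherits(shap, "shap_matrix"))
  long <- data.frame(
    site_id = rep(rownames(shap$phi), times = ncol(shap$phi)),
    variable = rep(colnames(shap$phi), each = nrow(shap$phi)),
    phi = as.vector(shap$phi),
    stringsAsFactors = FALSE
  )
  utils::write.csv(long, path, row.names = FALSE)
  manifest <- list(baseline = shap$baseline, n_reps = shap$meta$n_reps,
                   seed = shap$meta$seed,
                   background_size = shap$meta$background_size,
                   version = as.character(utils::packageVersion("shadowdist")))
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_shap_matrix
#' @export
read_shap_matrix <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  manifest <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sites <- unique(long$site_id)
  vars <- unique(long$variable)
  phi <- matrix(NA_real_, length(sites), length(vars),
                dimnames = list(sites, vars))
  phi[cbind(match(long$site_id, sites), match(long$variable, vars))] <-
    long$phi
  structure(list(
    phi = phi, baseline = manifest$baseline,
    y = stats::setNames(manifest$baseline + rowSums(phi), sites),
    meta = list(n_reps = manifest$n_reps, seed = manifest$seed,
                background_size = manifest$background_size)
  ), class = "shap_matrix")
}

#' @param result A `shadow_result`.
#' @rdname write_shap_matrix
#' @export
write_shadow_result <- function(result, path) {
  stopifnot(inherits(result, "shadow_result"))
  out <- result$sites
  neg <- as.data.frame(result$threat_negative)
  names(neg) <- paste0("neg_", names(neg))
  out <- cbind(out, neg)
  out$scenario <- result$scenario
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write site points as GeoJSON
#'
#' Minimal GeoJSON point writer for mapping site-level attributes in GIS
#' tools; coordinates are emitted as-is (planar meters), so set the CRS on
#' import.
#'
#' @param sites Data frame with `site_id`, `x`, `y` plus attribute columns.
#' @param path Output path.
#' @export
write_sites_geojson <- function(sites, path) {
  stopifnot(all(c("site_id", "x", "y") %in% names(sites)))
  attrs <- setdiff(names(sites), c("x", "y"))
  features <- lapply(seq_len(nrow(sites)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(sites$x[i], sites$y[i])),
         properties = as.list(sites[i, attrs, drop = FALSE]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Hash a configuration for artifact manifests
#'
#' MD5 of the canonical JSON serialization, so manifests can state exactly
#' which configuration produced an artifact.
#'
#' @param cfg A list.
#' @return Character MD5 hash.
#' @export
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(cfg, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}
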