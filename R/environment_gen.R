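#' Default configuration for the synthetic environment generator
#'
#' Returns the full list of tunable settings used by
#' [generate_environment()]. Natural gradients follow the river continuum
#' (cold, fast, steep, small headwaters to warm, slow, large main stems);
#' threats are spatially autocorrelated fields, some deliberately confounded
#' with elevation so that residualization has something to remove.
#'
#' @return Named list of settings; see Details in [generate_environment()].
#' @export
environment_config <- function() {
  list(
    # natural gradients
    temperature = list(base = 14, lapse = 0.0065, sd = 0.4),  # degC, degC/m
    discharge   = list(q0 = 0.5, exponent = 0.8, sdlog = 0.3), # m3/s
    velocity    = list(v0 = 0.3, coef = 8, sd = 0.08),         # m/s vs slope
    # spatially autocorrelated threat fields
    kernel_range = 10000, # m, Gaussian distance-decay range of threat fields
    threats = list(
      urbanisation = list(confound_elevation = -0.5),
      morphological_modification = list(confound_elevation = -0.4),
      floodplain = list(confound_elevation = 0),
      wetland = list(confound_elevation = 0)
    ),
    # longitudinal connectivity: random barriers on edges
    barrier_prob = 0.08,
    barrier_decay = 0.5 # connectivity = exp(-decay * barriers to outlet)
  )
}

#' Generate synthetic environmental gradients on a river network
#'
#' Builds an [env_table] for a simulated riverscape. Natural variables are
#' monotone functions of network position plus noise: discharge grows with
#' accumulated drainage area, temperature falls with elevation, velocity
#' rises with channel slope, and distance to the lake is the along-channel
#' distance to the outlet. Slope is derived from the elevation drop of the
#' downstream edge. Threat variables (`urbanisation`,
#' `morphological_modification`, `floodplain`, `wetland`) are spatially
#' autocorrelated fields obtained by Gaussian-kernel smoothing of white
#' noise over site coordinates; each can be linearly confounded with
#' elevation through its `confound_elevation` weight in `[-1, 1]` (0 means
#' independent of elevation by construction). Longitudinal `connectivity`
#' decreases with the number of random barriers on the path to the outlet.
#'
#' All randomness flows from `seed`; each component draws from a sub-stream
#' at a fixed offset so that, e.g., changing the temperature noise does not
#' perturb the threat fields.
#'
#' @param network A `river_network` from [generate_network()].
#' @param config Optional list overriding entries of [environment_config()];
#'   unknown entry names (at either level) are an error.
#' @param seed Integer seed.
#' @return An [env_table] with natural variables `elevation`, `discharge`,
#'   `slope`, `temperature`, `velocity`, `distance_to_lake` and threat
#'   variables `urbanisation`, `morphological_modification`, `floodplain`,
#'   `wetland`, `connectivity`.
#' @export
generate_environment <- function(network, config = list(), seed = 1L) {
  if (!inherits(network, "river_network")) {
    stop("`network` must be a river_network.", call. = FALSE)
  }
  cfg <- .merge_config(environment_config(), config)
  nd <- network$nodes
  n <- nrow(nd)
  parent <- .parent_index(network)
  seed <- as.integer(seed)

  # slope of the downstream edge; the outlet inherits its upstream mean
  drop <- nd$elevation - ifelse(parent > 0L, nd$elevation[parent], NA)
  slope <- drop / nd$edge_length
  outlet <- which(parent == 0L)
  slope[outlet] <- mean(slope[parent == outlet]) # inherit from direct tributaries

  set.seed(seed + 1L)
  discharge <- cfg$discharge$q0 * nd$accumulated_area^cfg$discharge$exponent *
    exp(stats::rnorm(n, 0, cfg$discharge$sdlog))
  set.seed(seed + 2L)
  temperature <- cfg$temperature$base - cfg$temperature$lapse * nd$elevation +
    stats::rnorm(n, 0, cfg$temperature$sd)
  set.seed(seed + 3L)
  velocity <- pmax(0.02, cfg$velocity$v0 + cfg$velocity$coef * slope +
                     stats::rnorm(n, 0, cfg$velocity$sd))
  distance_to_lake <- nd$dist_to_outlet

  # spatially autocorrelated threat fields on the node coordinates
  threat_names <- names(cfg$threats)
  dmat <- as.matrix(stats::dist(cbind(nd$x, nd$y)))
  w <- exp(-(dmat / cfg$kernel_range)^2 / 2)
  elev_z <- as.numeric(scale(nd$elevation))
  # basis spanning elevation on both the raw and the rank scale, so that a
  # zero confound weight leaves (rank) correlation with elevation near zero
  # in the realized sample, not merely in expectation
  elev_basis <- cbind(1, elev_z, as.numeric(scale(rank(nd$elevation))))
  threat_vals <- matrix(NA_real_, n, length(threat_names),
                        dimnames = list(NULL, threat_names))
  for (k in seq_along(threat_names)) {
    set.seed(seed + 10L + k)
    field <- as.numeric(w %*% stats::rnorm(n)) / rowSums(w)
    field_z <- as.numeric(scale(field))
    perp <- field_z - elev_basis %*% solve(crossprod(elev_basis),
                                           crossprod(elev_basis, field_z))
    perp <- as.numeric(scale(perp))
    a <- cfg$threats[[k]]$confound_elevation
    if (abs(a) > 1) stop("confound_elevation must be in [-1, 1].", call. = FALSE)
    z <- a * elev_z + sqrt(1 - a^2) * perp
    threat_vals[, k] <- stats::pnorm(z) # map to a (0,1) intensity/proportion
  }

  set.seed(seed + 30L)
  barrier <- stats::rbinom(n, 1L, cfg$barrier_prob)
  barrier[parent == 0L] <- 0L
  n_barriers <- integer(n)
  ord <- order(nd$dist_to_outlet) # outlet first; parents precede children
  for (i in ord) {
    if (parent[i] > 0L) n_barriers[i] <- n_barriers[parent[i]] + barrier[i]
  }
  connectivity <- exp(-cfg$barrier_decay * n_barriers)

  data <- data.frame(
    site_id = nd$site_id,
    elevation = nd$elevation,
    discharge = discharge,
    slope = slope,
    temperature = temperature,
    velocity = velocity,
    distance_to_lake = distance_to_lake,
    urbanisation = threat_vals[, "urbanisation"],
    morphological_modification = threat_vals[, "morphological_modification"],
    floodplain = threat_vals[, "floodplain"],
    wetland = threat_vals[, "wetland"],
    connectivity = connectivity,
    stringsAsFactors = FALSE
  )
  metadata <- data.frame(
    variable = c("elevation", "discharge", "slope", "temperature", "velocity",
                 "distance_to_lake", "urbanisation",
                 "morphological_modification", "floodplain", "wetland",
                 "connectivity"),
    category = c(rep("natural", 6L), rep("threat", 5L)),
    direction = c(rep(NA_character_, 6L), "low_good", "low_good",
                  "high_good", "high_good", "high_good"),
    residualized = FALSE,
    stringsAsFactors = FALSE
  )
  env_table(data, metadata)
}

# recursive merge of a user config into defaults; unknown names are an error
.merge_config <- function(defaults, config, path = "config") {
  if (!length(config)) return(defaults)
  if (is.null(names(config)) || any(names(config) == "")) {
    stop("All entries of ", path, " must be named.", call. = FALSE)
  }
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("Unknown ", path, " entr", if (length(unknown) > 1) "ies: " else "y: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (nm in names(config)) {
    if (is.list(defaults[[nm]]) && is.list(config[[nm]])) {
      defaults[[nm]] <- .merge_config(defaults[[nm]], config[[nm]],
                                      paste(path, nm, sep = "$"))
    } else {
      defaults[[nm]] <- config[[nm]]
    }
  }
  defaults
}
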