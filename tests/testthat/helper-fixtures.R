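# Shared fixtures, built in code at test time.

NAT_SET <- c("discharge", "slope", "temperature", "velocity",
             "distance_to_lake")
THR_SET <- c("urbanisation", "morphological_modification", "floodplain",
             "wetland", "connectivity")

# A 300-site riverscape with one virtual species responding linearly to
# three natural gradients and harmed by urbanisation; cached per test run.
riverscape_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      net <- generate_network(300, branching_prob = 0.3, seed = 11)
      env <- generate_environment(net, seed = 12)
      spec <- response_spec(
        natural = list(
          temperature = list(shape = "linear", slope = 1.5),
          discharge = list(shape = "linear", slope = 1),
          velocity = list(shape = "linear", slope = 1)),
        threats = list(urbanisation = list(shape = "linear", slope = -2)),
        intercept = -0.3)
      vs <- generate_virtual_species(env, spec, seed = 13)
      cache <<- list(net = net, env = env, vs = vs,
                     occ = occurrence_table(vs))
    }
    cache
  }
})

# A fitted model on the fixture, cached (ntree kept small for speed).
fitted_model_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- riverscape_fixture()
      cache <<- fit_downsampled_rf(fx$env, fx$occ, ntree = 150, seed = 21)
    }
    cache
  }
})

# Hand-assembled attribution object for algebra tests.
make_shap <- function(phi, baseline, site_id = NULL) {
  phi <- as.matrix(phi)
  if (is.null(site_id)) site_id <- paste0("s", seq_len(nrow(phi)))
  rownames(phi) <- site_id
  structure(list(
    phi = phi, baseline = baseline,
    y = stats::setNames(baseline + rowSums(phi), site_id),
    meta = list(n_reps = NA_integer_, seed = NA_integer_,
                background_size = NA_integer_)
  ), class = "shap_matrix")
}

# Minimal env_table builder for synthetic columns.
toy_env <- function(..., category = NULL, direction = NULL) {
  cols <- list(...)
  data <- data.frame(site_id = paste0("s", seq_along(cols[[1L]])), cols,
                     stringsAsFactors = FALSE)
  vars <- names(cols)
  if (is.null(category)) category <- rep("natural", length(vars))
  if (is.null(direction)) direction <- rep(NA_character_, length(vars))
  env_table(data, data.frame(variable = vars, category = category,
                             direction = direction,
                             stringsAsFactors = FALSE))
}
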