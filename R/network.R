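#' Simulate a dendritic river network
#'
#' Grows a rooted tree of river sites by iterative upstream attachment.
#' The first node is the outlet (e.g., a lake inflow); each subsequent node
#' is attached upstream of an existing node. With probability
#' `branching_prob` the new node starts a side branch at a node that already
#' has one upstream neighbour (creating a confluence, so branching is at most
#' binary, as in real dendritic networks); otherwise it extends a current
#' headwater tip. Elevation increases strictly along every upstream path, and
#' planar coordinates (meters) follow a meandering heading so that the tree
#' spreads out in space.
#'
#' @param n_sites Number of sites (nodes), an integer >= 2.
#' @param branching_prob Probability that a new node opens a side branch
#'   rather than extending an existing headwater, in `[0, 1]`.
#' @param seed Integer seed; the network is a deterministic function of
#'   `(n_sites, branching_prob, seed)`.
#'
#' @return An object of class `river_network`: a list with
#' \describe{
#'   \item{nodes}{data frame with `site_id`, planar `x`, `y` (m),
#'     `elevation` (m), `accumulated_area` (count of the node itself plus all
#'     upstream nodes), `dist_to_outlet` (m along the channel), `downstream`
#'     (site_id of the next node downstream; `NA` at the outlet) and
#'     `edge_length` (m of the downstream edge; `NA` at the outlet).}
#'   \item{edges}{data frame of directed downstream links `from` -> `to`
#'     with their `length` in meters.}
#' }
#' @examples
#' net <- generate_network(50, branching_prob = 0.3, seed = 1)
#' nrow(net$nodes)
#' @export
generate_network <- function(n_sites, branching_prob = 0.3, seed = 1L) {
  if (!is.numeric(n_sites) || length(n_sites) != 1L || is.na(n_sites) ||
      n_sites != round(n_sites) || n_sites < 2) {
    stop("`n_sites` must be a single integer >= 2.", call. = FALSE)
  }
  if (!is.numeric(branching_prob) || length(branching_prob) != 1L ||
      is.na(branching_prob) || branching_prob < 0 || branching_prob > 1) {
    stop("`branching_prob` must be a probability in [0, 1].", call. = FALSE)
  }
  n <- as.integer(n_sites)
  set.seed(as.integer(seed))

  downstream <- rep(NA_integer_, n)
  edge_len <- rep(NA_real_, n)
  x <- y <- elev <- heading <- numeric(n)
  n_children <- integer(n) # upstream neighbours attached so far
  x[1L] <- 0; y[1L] <- 0; elev[1L] <- 0; heading[1L] <- pi / 2

  for (i in seq_len(n)[-1L]) {
    prev <- seq_len(i - 1L)
    tips <- prev[n_children[prev] == 0L]
    # nodes eligible to become a confluence: already one upstream neighbour
    junctions <- prev[n_children[prev] == 1L]
    branch <- length(junctions) > 0L && stats::runif(1L) < branching_prob
    parent <- if (branch) {
      junctions[sample.int(length(junctions), 1L)]
    } else {
      tips[sample.int(length(tips), 1L)]
    }
    len <- stats::runif(1L, 300, 1200)
    turn <- if (branch) {
      sample(c(-1, 1), 1L) * stats::runif(1L, 0.5, 1.1)
    } else {
      stats::rnorm(1L, 0, 0.35)
    }
    heading[i] <- heading[parent] + turn
    x[i] <- x[parent] + cos(heading[i]) * len
    y[i] <- y[parent] + sin(heading[i]) * len
    # strictly positive elevation gain keeps elevation increasing upstream;
    # channels steepen with altitude, giving alpine-style relief
    grade <- min(stats::runif(1L, 0.01, 0.08) * (1 + elev[parent] / 300),
                 0.3)
    elev[i] <- elev[parent] + grade * len
    downstream[i] <- parent
    edge_len[i] <- len
    n_children[parent] <- n_children[parent] + 1L
  }

  acc <- rep(1L, n)
  for (i in rev(seq_len(n)[-1L])) acc[downstream[i]] <- acc[downstream[i]] + acc[i]
  d_out <- numeric(n)
  for (i in seq_len(n)[-1L]) d_out[i] <- d_out[downstream[i]] + edge_len[i]

  nodes <- data.frame(
    site_id = paste0("s", seq_len(n)),
    x = x, y = y, elevation = elev,
    accumulated_area = acc, dist_to_outlet = d_out,
    downstream = ifelse(is.na(downstream), NA_character_,
                        paste0("s", downstream)),
    edge_length = edge_len,
    stringsAsFactors = FALSE
  )
  edges <- data.frame(
    from = nodes$site_id[!is.na(downstream)],
    to = nodes$downstream[!is.na(downstream)],
    length = edge_len[!is.na(downstream)],
    stringsAsFactors = FALSE
  )
  structure(list(nodes = nodes, edges = edges), class = "river_network")
}

#' @export
print.river_network <- function(x, ...) {
  n <- nrow(x$nodes)
  tips <- sum(!(x$nodes$site_id %in% x$edges$to))
  cat("River network:", n, "sites,", nrow(x$edges), "edges,",
      tips, "headwaters\n")
  cat("Elevation range:", round(min(x$nodes$elevation)), "-",
      round(max(x$nodes$elevation)), "m; outlet:",
      x$nodes$site_id[is.na(x$nodes$downstream)], "\n")
  invisible(x)
}

# parent index vector (0 for the outlet), used by downstream accumulations
.parent_index <- function(network) {
  m <- match(network$nodes$downstream, network$nodes$site_id)
  ifelse(is.na(m), 0L, m)
}
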