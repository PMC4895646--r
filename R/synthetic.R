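#' Specification for a random signaling network
#'
#' Describes the shape of a randomly generated network: node and edge
#' counts, the fraction of activating edges, a weight sampler and the number
#' of designated input nodes. Edges are ordered pairs sampled uniformly
#' without replacement among the `n_nodes * (n_nodes - 1)` non-self pairs.
#'
#' @param n_nodes number of nodes (>= 1).
#' @param n_edges number of edges; at most `n_nodes * (n_nodes - 1)`.
#' @param activating_fraction probability that an edge is activating
#'   (default 0.75: signaling maps are predominantly activating).
#' @param weight_sampler function of `n` returning `n` weights in \[0, 1\]
#'   (default `runif`).
#' @param n_inputs number of input nodes to designate (nodes with no
#'   incoming edges are preferred, then arbitrary nodes).
#' @param seed integer seed making generation bit-reproducible; `NULL` uses
#'   the current RNG stream.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(n_nodes, n_edges, activating_fraction = 0.75,
                         weight_sampler = stats::runif, n_inputs = 1,
                         seed = NULL) {
  assert_scalar_number(n_nodes, "n_nodes", 1)
  assert_scalar_number(n_edges, "n_edges", 0)
  assert_scalar_number(activating_fraction, "activating_fraction", 0, 1)
  assert_scalar_number(n_inputs, "n_inputs", 0)
  stopifnot(is.function(weight_sampler))
  max_edges <- n_nodes * (n_nodes - 1)
  if (n_edges > max_edges) {
    stop(sprintf("n_edges = %d exceeds the %d possible ordered pairs of %d nodes (no self-loops, no duplicates)",
                 n_edges, max_edges, n_nodes), call. = FALSE)
  }
  if (n_inputs > n_nodes) stop("n_inputs must not exceed n_nodes", call. = FALSE)
  structure(list(n_nodes = as.integer(n_nodes), n_edges = as.integer(n_edges),
                 activating_fraction = activating_fraction,
                 weight_sampler = weight_sampler,
                 n_inputs = as.integer(n_inputs), seed = seed),
            class = "network_spec")
}

#' Generate a random signaling network
#'
#' Samples exactly `n_edges` distinct ordered (source, target) pairs
#' uniformly without replacement (self-loops excluded), assigns signs
#' Bernoulli(`activating_fraction`) and weights from the sampler, and
#' designates `n_inputs` input nodes, preferring nodes with in-degree zero.
#' Identical spec and seed give a bit-identical network.
#'
#' @param spec a [network_spec()].
#' @return A validated [signaling_network()] with nodes named `n001`,
#'   `n002`, ...
#' @examples
#' net <- generate_network(network_spec(5, 13, seed = 42))
#' net
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  n <- spec$n_nodes
  width <- max(3L, nchar(as.character(n)))
  nodes <- sprintf(paste0("n%0", width, "d"), seq_len(n))
  with_seed(spec$seed, {
    m <- spec$n_edges
    if (m > 0L) {
      k <- sample.int(n * (n - 1L), m)           # ordered non-self pairs
      i <- (k - 1L) %/% (n - 1L) + 1L            # source
      r <- (k - 1L) %% (n - 1L) + 1L
      j <- r + (r >= i)                          # target, skipping the diagonal
      sign <- ifelse(stats::runif(m) < spec$activating_fraction, "+", "-")
      w <- spec$weight_sampler(m)
      edges <- data.frame(source = nodes[i], target = nodes[j],
                          sign = sign, weight = w, stringsAsFactors = FALSE)
    } else {
      edges <- NULL
    }
    net <- signaling_network(nodes = nodes, edges = edges)
    deg0 <- net$nodes[in_degree(net) == 0L]
    inputs <- c(deg0, setdiff(net$nodes, deg0))[seq_len(spec$n_inputs)]
    net$input_nodes <- inputs
    validate_network(net)
  })
}

#' Generate noisy pseudo-measurements from a simulation
#'
#' Runs a simulation, downsamples it to `T` time points and perturbs every
#' value with i.i.d. Gaussian noise truncated at zero, emulating a measured
#' protein-by-time-point table (e.g. an 8-time-point phosphoproteomics
#' course) on the same \[0, 1\]-ish scale as the simulation. With
#' `noise_sd = 0` the pseudo-measurements reproduce the simulated values
#' exactly, so the goodness-of-fit machinery must recover correlation 1 for
#' every protein with a non-constant trend.
#'
#' @param net a [signaling_network()].
#' @param schedule a [perturbation_schedule()] or `NULL`.
#' @param config a [sim_config()]; `iterations` must be divisible by `T`.
#' @param T number of measurement time points.
#' @param noise_sd standard deviation of the additive Gaussian noise (>= 0).
#' @param seed integer seed for the noise draw (`NULL`: current stream).
#' @return A [measured_time_course()] with one row per network node.
#' @export
generate_pseudo_measurements <- function(net, schedule = NULL, config, T,
                                         noise_sd = 0, seed = NULL) {
  assert_scalar_number(noise_sd, "noise_sd", 0)
  traj <- simulate_network(net, schedule, config)
  sim <- downsample(traj, T)
  noisy <- with_seed(seed, sim + stats::rnorm(length(sim), sd = noise_sd))
  noisy <- pmax(noisy, 0)
  measured_time_course(noisy, proteins = rownames(sim),
                       time_points = colnames(sim))
}
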