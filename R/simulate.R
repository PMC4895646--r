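#' Simulation configuration
#'
#' @param iterations number of synchronous updates to perform (>= 1). The
#'   trajectory then has `iterations + 1` columns, column 0 being the initial
#'   state.
#' @param degradation global per-iteration degradation rate `d` in \[0, 1\]:
#'   the fraction of a node's activated form lost between consecutive
#'   iterations.
#' @param seed integer seed for the random initial state (and only for that);
#'   `NULL` draws from the current RNG stream.
#' @param initial either `"random"` (activities drawn i.i.d. uniform on
#'   \[0, 1\]) or a numeric vector of starting activities, optionally named
#'   by node.
#' @param clamp clamp every updated activity into \[0, 1\] (default `TRUE`).
#'   The raw update rule can leave the unit interval in extreme regimes
#'   (e.g. `d = 1` with active inhibition); clamping enforces the modeled
#'   range. Set `FALSE` only for diagnostics.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(iterations, degradation = 0.2, seed = NULL,
                       initial = "random", clamp = TRUE) {
  assert_scalar_number(iterations, "iterations", 1)
  if (iterations != floor(iterations)) stop("`iterations` must be an integer", call. = FALSE)
  assert_scalar_number(degradation, "degradation", 0, 1)
  if (!is.character(initial) && !is.numeric(initial)) {
    stop("`initial` must be \"random\" or a numeric vector", call. = FALSE)
  }
  if (is.character(initial) && !identical(initial, "random")) {
    stop("character `initial` must be \"random\"", call. = FALSE)
  }
  if (is.numeric(initial) && (anyNA(initial) || any(initial < 0 | initial > 1))) {
    stop("fixed initial activities must be in [0, 1]", call. = FALSE)
  }
  stopifnot(is.logical(clamp), length(clamp) == 1L)
  structure(list(iterations = as.integer(iterations),
                 degradation = degradation, seed = seed,
                 initial = initial, clamp = clamp),
            class = "sim_config")
}

#' Generalized logical update of a single node
#'
#' One application of the update rule
#' \deqn{X_t = (1-d) X_{t-1}
#'   + \left[1 - \prod_i (1-A_i)\right] \prod_j (1-B_j) \, (1 - X_{t-1})
#'   - \prod_i (1-A_i) \left[1 - \prod_j (1-B_j)\right] X_{t-1}}
#' where each \eqn{A_i} (\eqn{B_j}) is an incoming activating (inhibiting)
#' signal, i.e. parent activity times edge weight, including virtual edges
#' from scheduled perturbations. Empty products equal 1, so a node with no
#' activators gains nothing and a node with no inhibitors loses only to
#' degradation; a parentless node decays as \eqn{(1-d) X_{t-1}}.
#'
#' @param x previous activity level in \[0, 1\].
#' @param d degradation rate in \[0, 1\].
#' @param activating numeric vector of activating signals in \[0, 1\]
#'   (possibly empty).
#' @param inhibiting numeric vector of inhibiting signals in \[0, 1\]
#'   (possibly empty).
#' @param clamp clamp the result into \[0, 1\].
#' @return The updated activity level.
#' @examples
#' update_node(0.5, d = 0.2, activating = 0.6, inhibiting = 0.3)  # 0.55
#' update_node(0.5, d = 0)                                        # 0.5
#' @export
update_node <- function(x, d, activating = numeric(), inhibiting = numeric(),
                        clamp = TRUE) {
  assert_scalar_number(x, "x", 0, 1)
  assert_scalar_number(d, "d", 0, 1)
  if (length(activating) && (anyNA(activating) || any(activating < 0 | activating > 1))) {
    stop("activating signals must be in [0, 1]", call. = FALSE)
  }
  if (length(inhibiting) && (anyNA(inhibiting) || any(inhibiting < 0 | inhibiting > 1))) {
    stop("inhibiting signals must be in [0, 1]", call. = FALSE)
  }
  pa <- prod(1 - activating)   # empty product = 1
  pb <- prod(1 - inhibiting)
  out <- (1 - d) * x + (1 - pa) * pb * (1 - x) - pa * (1 - pb) * x
  if (clamp) out <- min(1, max(0, out))
  out
}

# Precompute per-node incoming-edge index lists for fast iteration.
build_sim_index <- function(net) {
  nodes <- net$nodes
  e <- net$edges
  src <- match(e$source, nodes)
  tgt <- match(e$target, nodes)
  act <- e$sign == "+"
  list(
    nodes = nodes,
    n = length(nodes),
    act_src = lapply(seq_along(nodes), function(i) src[tgt == i & act]),
    act_w = lapply(seq_along(nodes), function(i) e$weight[tgt == i & act]),
    inh_src = lapply(seq_along(nodes), function(i) src[tgt == i & !act]),
    inh_w = lapply(seq_along(nodes), function(i) e$weight[tgt == i & !act])
  )
}

# Virtual-edge signal matrix: V[i, t] is the signed level delivered to node i
# during the computation of iteration t (0 = no signal). One event per
# (target, iteration) is guaranteed by schedule validation.
build_virtual_signals <- function(schedule, nodes, iterations) {
  V <- matrix(0, nrow = length(nodes), ncol = iterations)
  if (is.null(schedule)) return(V)
  for (ev in schedule$events) {
    i <- match(ev$target, nodes)
    t0 <- ev$start
    t1 <- min(ev$end, iterations)
    if (t0 <= t1) V[i, t0:t1] <- ev$level
    }
  V
}

# One synchronous update from `state` given precomputed index and the
# virtual-signal column for this iteration. The hot loop of the simulator.
step_state <- function(idx, state, vcol, d, clamp) {
  new <- numeric(idx$n)
  for (i in seq_len(idx$n)) {
    pa <- prod(1 - state[idx$act_src[[i]]] * idx$act_w[[i]])
    pb <- prod(1 - state[idx$inh_src[[i]]] * idx$inh_w[[i]])
    v <- vcol[i]
    if (v > 0) pa <- pa * (1 - v) else if (v < 0) pb <- pb * (1 + v)
    x <- state[i]
    out <- (1 - d) * x + (1 - pa) * pb * (1 - x) - pa * (1 - pb) * x
    new[i] <- if (clamp) min(1, max(0, out)) else out
  }
  new
}

#' One synchronous update step
#'
#' Updates every node from the *same* previous state vector (synchronous
#' semantics), including virtual edges from any perturbation event active at
#' `iteration`.
#'
#' @param net a [signaling_network()].
#' @param state numeric activity vector, one entry per node in `net$nodes`
#'   order (names, if present, are checked).
#' @param schedule a [perturbation_schedule()] or `NULL`.
#' @param iteration 1-based index of the update being computed.
#' @param config a [sim_config()]; only `degradation` and `clamp` are used.
#' @return The updated activity vector, named by node.
#' @export
step <- function(net, state, schedule = NULL, iteration = 1, config) {
  validate_network(net)
  stopifnot(inherits(config, "sim_config"))
  if (length(state) != length(net$nodes)) {
    stop(sprintf("state has length %d but network has %d nodes",
                 length(state), length(net$nodes)), call. = FALSE)
  }
  if (!is.null(names(state)) && !identical(names(state), net$nodes)) {
    stop("names(state) must match net$nodes order", call. = FALSE)
  }
  idx <- build_sim_index(net)
  vcol <- build_virtual_signals(schedule, net$nodes, iteration)[, iteration]
  stats::setNames(step_state(idx, state, vcol, config$degradation, config$clamp),
                  net$nodes)
}

# Resolve config$initial into a numeric vector in node order.
resolve_initial <- function(config, nodes) {
  n <- length(nodes)
  if (identical(config$initial, "random")) {
    return(with_seed(config$seed, stats::runif(n)))
  }
  init <- config$initial
  if (!is.null(names(init))) {
    missing <- setdiff(nodes, names(init))
    if (length(missing)) stop("fixed initial state missing nodes: ",
                              paste(missing, collapse = ", "), call. = FALSE)
    init <- init[nodes]
  } else if (length(init) != n) {
    stop(sprintf("fixed initial state has length %d but network has %d nodes",
                 length(init), n), call. = FALSE)
  }
  unname(init)
}

#' Run a simulation
#'
#' Iterates the generalized logical update rule synchronously for
#' `config$iterations` steps from a random or fixed initial state, applying
#' the perturbation schedule through the virtual input node. Deterministic
#' given `config$seed`.
#'
#' @param net a [signaling_network()].
#' @param schedule a [perturbation_schedule()] or `NULL` for an unperturbed
#'   run. Every event target must be an input node of `net`.
#' @param config a [sim_config()].
#' @return A `glog_trajectory`: a numeric matrix of activities with one row
#'   per node and columns `0:iterations` (column `"0"` is the initial state),
#'   all values in \[0, 1\] when clamping is on.
#' @examples
#' net <- signaling_network(
#'   edges = data.frame(source = "TNFR", target = "JNK", sign = "+", weight = 0.7),
#'   input_nodes = "TNFR")
#' sch <- perturbation_schedule(perturbation_event("TNFR", 0.8, start = 20))
#' traj <- simulate_network(net, sch, sim_config(100, degradation = 0.2, seed = 1))
#' traj["TNFR", "100"]  # 0.8: the plateau equals the input level when A + d = 1
#' @export
simulate_network <- function(net, schedule = NULL, config) {
  validate_network(net)
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(schedule)) {
    stopifnot(inherits(schedule, "perturbation_schedule"))
    targets <- vapply(schedule$events, `[[`, "", "target")
    bad <- setdiff(targets, net$input_nodes)
    if (length(bad)) {
      stop("schedule targets non-input node(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  idx <- build_sim_index(net)
  V <- build_virtual_signals(schedule, net$nodes, config$iterations)
  init <- resolve_initial(config, net$nodes)
  traj <- sim_core(idx, init, V, config$degradation, config$clamp,
                   config$iterations)
  dimnames(traj) <- list(net$nodes, 0:config$iterations)
  structure(traj, class = c("glog_trajectory", "matrix", "array"),
            degradation = config$degradation, clamp = config$clamp)
}

sim_core <- function(idx, init, V, d, clamp, iterations) {
  traj <- matrix(NA_real_, nrow = idx$n, ncol = iterations + 1L)
  state <- init
  traj[, 1L] <- state
  for (t in seq_len(iterations)) {
    state <- step_state(idx, state, V[, t], d, clamp)
    traj[, t + 1L] <- state
  }
  traj
}

#' Detect whether a trajectory has reached a stable state
#'
#' A trajectory is considered stable when the largest per-node change over
#' the last `window` consecutive transitions is below `tol`.
#'
#' @param traj a `glog_trajectory` (or plain node-by-iteration matrix whose
#'   first column is the initial state).
#' @param tol positive convergence tolerance on per-iteration change.
#' @param window number of final transitions that must all be below `tol`.
#' @return A named numeric vector of stable per-node levels (the final
#'   state), or `NULL` if the trajectory has not stabilized.
#' @export
detect_stable_state <- function(traj, tol = 1e-4, window = 10) {
  stopifnot(is.matrix(traj))
  assert_scalar_number(tol, "tol", lower = .Machine$double.xmin)
  assert_scalar_number(window, "window", 1)
  nc <- ncol(traj)
  if (window >= nc) {
    stop(sprintf("window (%d) must be smaller than the number of trajectory columns (%d)",
                 as.integer(window), nc), call. = FALSE)
  }
  cols <- (nc - window):nc
  deltas <- abs(traj[, cols[-1L], drop = FALSE] - traj[, cols[-length(cols)], drop = FALSE])
  if (max(deltas) < tol) traj[, nc] else NULL
}

#' Write a trajectory to CSV
#'
#' @param traj a `glog_trajectory`.
#' @param path output path.
#' @param layout `"wide"` (default): one row per node, header of iteration
#'   indices `0..N`; or `"long"`: columns `node, iteration, activity`.
#' @return `traj`, invisibly.
#' @export
write_trajectory <- function(traj, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  stopifnot(is.matrix(traj))
  if (layout == "wide") {
    df <- data.frame(node = rownames(traj), unclass(traj), check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    df <- expand.grid(node = rownames(traj), iteration = as.integer(colnames(traj)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    df$activity <- as.vector(unclass(traj))
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(traj)
}

#' @export
print.glog_trajectory <- function(x, ...) {
  cat(sprintf("Simulated trajectory: %d nodes x %d iterations (+ initial state)\n",
              nrow(x), ncol(x) - 1L))
  stable <- detect_stable_state(x, tol = 1e-4,
                                window = min(10L, ncol(x) - 1L))
  cat(if (is.null(stable)) "Not stabilized at tol 1e-4\n" else
        "Stable at tol 1e-4 over the final window\n")
  invisible(x)
}

#' Plot simulated trajectories
#'
#' @param x a `glog_trajectory`.
#' @param nodes node identifiers to draw (default: all).
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.glog_trajectory <- function(x, nodes = rownames(x), ...) {
  m <- x[nodes, , drop = FALSE]
  graphics::matplot(as.integer(colnames(m)), t(unclass(m)), type = "l", lty = 1,
                    xlab = "iteration", ylab = "activity level", ylim = c(0, 1), ...)
  graphics::legend("topright", legend = nodes, lty = 1,
                   col = seq_along(nodes), cex = 0.8, bty = "n")
  invisible(x)
}
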