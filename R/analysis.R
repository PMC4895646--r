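#' Measured time-course container
#'
#' Holds a protein-by-time-point table of measured (or pseudo-measured)
#' activity levels, the shape of a phosphoproteomics time course: each row a
#' protein, each column one of T >= 2 measurement time points. Missing cells
#' are not allowed; impute or drop rows before construction.
#'
#' @param values numeric matrix, proteins in rows, time points in columns,
#'   all entries nonnegative.
#' @param proteins character vector of row identifiers (default: rownames).
#' @param time_points numeric/character labels for the columns (default:
#'   colnames, else `1:T`).
#' @return An object of class `measured_time_course` (a matrix with dimnames).
#' @export
measured_time_course <- function(values, proteins = rownames(values),
                                 time_points = colnames(values)) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (ncol(values) < 2L) stop("need at least 2 time points", call. = FALSE)
  if (anyNA(values)) stop("missing cells are not allowed; impute or drop rows first",
                          call. = FALSE)
  if (any(values < 0)) stop("measured values must be nonnegative", call. = FALSE)
  if (is.null(proteins)) stop("protein identifiers are required", call. = FALSE)
  if (anyDuplicated(proteins)) stop("duplicate protein identifiers", call. = FALSE)
  if (is.null(time_points)) time_points <- seq_len(ncol(values))
  dimnames(values) <- list(as.character(proteins), as.character(time_points))
  structure(values, class = c("measured_time_course", "matrix", "array"))
}

#' Read a measured time course from CSV
#'
#' First column: protein identifier; remaining columns: numeric measurements
#' at T time points (column headers are the time-point labels).
#'
#' @param path CSV file path.
#' @return A [measured_time_course()].
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("measurements file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 3L) stop("measurements CSV needs a protein column plus >= 2 time points",
                          call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  measured_time_course(m, proteins = df[[1L]], time_points = colnames(df)[-1L])
}

#' Write a measured time course to CSV
#'
#' @param mtc a [measured_time_course()].
#' @param path output path.
#' @return `mtc`, invisibly.
#' @export
write_measurements <- function(mtc, path) {
  df <- data.frame(protein = rownames(mtc), unclass(mtc), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(mtc)
}

#' Downsample a trajectory to T equally spaced time points
#'
#' Extracts the columns at iterations N/T, 2N/T, ..., N (excluding the
#' initial state), aligning an N-iteration simulation with T experimental
#' measurement time points. For example N = 32, T = 8 keeps iterations
#' 4, 8, ..., 32. N must be divisible by T; no silent interpolation is done.
#'
#' @param traj a `glog_trajectory` (N = `ncol(traj) - 1` iterations).
#' @param T number of time points to keep.
#' @return A numeric matrix \[nodes x T\] with iteration indices as column
#'   names.
#' @export
downsample <- function(traj, T) {
  stopifnot(is.matrix(traj))
  assert_scalar_number(T, "T", 1)
  N <- ncol(traj) - 1L
  if (T != floor(T) || N %% T != 0) {
    stop(sprintf("iteration count N = %d must be divisible by T = %s", N, format(T)),
         call. = FALSE)
  }
  keep <- seq.int(N / T, N, by = N / T)
  out <- traj[, as.character(keep), drop = FALSE]
  class(out) <- c("matrix", "array")
  out
}

#' Spearman goodness of fit between simulated and measured series
#'
#' Spearman rank correlation with average ranks for ties. If either vector
#' is constant the correlation is undefined and `NA` is returned (never a
#' silent 0).
#'
#' @param simulated numeric vector of simulated activities at T time points.
#' @param measured numeric vector of measurements at the same T time points.
#' @return A correlation in \[-1, 1\], or `NA_real_` when undefined.
#' @examples
#' spearman_fit(1:4, c(10, 20, 30, 40))   #  1
#' spearman_fit(1:4, c(40, 30, 20, 10))   # -1
#' spearman_fit(1:3, c(2, 1, 3))          #  0.5
#' @export
spearman_fit <- function(simulated, measured) {
  if (length(simulated) != length(measured)) {
    stop("simulated and measured vectors must have equal length", call. = FALSE)
  }
  if (length(simulated) < 3L) stop("need at least 3 time points", call. = FALSE)
  if (anyNA(simulated) || anyNA(measured)) stop("missing values are not allowed", call. = FALSE)
  if (stats::sd(simulated) == 0 || stats::sd(measured) == 0) return(NA_real_)
  stats::cor(simulated, measured, method = "spearman")
}

#' Sensitivity of a node's dynamics to its initial value
#'
#' Re-runs the same simulation with the chosen node started at each value in
#' `initial_values` while every other node keeps the same seeded random
#' initial activity across runs. Reports, per starting value, the stable
#' level and the time to stability (first iteration from which the activity
#' stays within `stable_tol` of the final stable level).
#'
#' @param net a [signaling_network()].
#' @param schedule a [perturbation_schedule()] or `NULL`.
#' @param config a [sim_config()]; its seed fixes the other nodes' initials.
#' @param node the node whose initial value is swept.
#' @param initial_values numeric vector of starting activities in \[0, 1\].
#' @param stable_tol tolerance used both to declare stability and to measure
#'   time-to-stability (default 0.01).
#' @return A list with `summary` (data frame: initial, stable_level,
#'   time_to_stable) and `trajectories` (list of `glog_trajectory`, one per
#'   initial value).
#' @export
initial_value_sweep <- function(net, schedule = NULL, config, node,
                                initial_values, stable_tol = 0.01) {
  validate_network(net)
  stopifnot(inherits(config, "sim_config"))
  if (!node %in% net$nodes) stop(sprintf("unknown node: '%s'", node), call. = FALSE)
  if (anyNA(initial_values) || any(initial_values < 0 | initial_values > 1)) {
    stop("initial values must be in [0, 1]", call. = FALSE)
  }
  base_init <- resolve_initial(config, net$nodes)
  i <- match(node, net$nodes)
  trajs <- lapply(initial_values, function(v) {
    init <- base_init
    init[i] <- v
    cfg <- config
    cfg$initial <- init
    cfg$seed <- NULL
    simulate_network(net, schedule, cfg)
  })
  stable <- vapply(trajs, function(tr) {
    s <- detect_stable_state(tr, tol = stable_tol,
                             window = min(10L, ncol(tr) - 1L))
    if (is.null(s)) NA_real_ else s[[i]]
  }, 0)
  tts <- vapply(seq_along(trajs), function(k) {
    if (is.na(stable[[k]])) return(NA_real_)
    x <- trajs[[k]][i, ]
    ok <- abs(x - stable[[k]]) < stable_tol
    # first iteration from which the node stays within tol for good
    runs <- rev(cumprod(rev(ok)))
    as.numeric(names(x)[which(runs == 1)[1L]])
  }, 0)
  list(summary = data.frame(initial = initial_values, stable_level = stable,
                            time_to_stable = tts),
       trajectories = trajs)
}

#' Edge-weight robustness analysis
#'
#' Assesses whether the simulated activity trends are robust to the choice
#' of edge weights. First, `n_background` simulations are run, each with
#' freshly sampled edge weights (signs and topology fixed) and random
#' initial states; the per-node mean activity at each iteration is the
#' *background trend*. Then `n_groups` groups of `group_size` such
#' simulations are run; each group's per-node mean trend is correlated
#' (Spearman) with the background trend. Nodes without incoming edges
#' (receptors/inputs) are excluded since their dynamics do not depend on
#' edge weights. All post-initial iterations enter the correlation.
#'
#' Initial states are paired across groups: run `j` of every group (and of
#' the background) starts from the same sub-seeded random initial state, so
#' that edge-weight variation is the only systematic difference between
#' groups. In particular, a degenerate point-mass weight sampler makes every
#' group trend identical to the background trend (correlation exactly 1
#' wherever defined) when `group_size == n_background`.
#'
#' @param net a [signaling_network()].
#' @param schedule a [perturbation_schedule()] or `NULL`.
#' @param config a [sim_config()]; its seed makes the whole analysis
#'   reproducible (background runs and groups draw from one seeded stream).
#' @param n_background number of background simulations (default 100).
#' @param n_groups number of groups (default 50).
#' @param group_size simulations per group (default 100).
#' @param weight_sampler function of `n` returning `n` weights in \[0, 1\]
#'   (default `runif`: i.i.d. uniform per edge).
#' @return A `robustness_result`: list with `correlations` (matrix
#'   \[nodes x n_groups\], `NA` where a trend was constant), `median` (named
#'   vector of per-node medians over defined correlations, sorted
#'   decreasingly), and `excluded` (nodes without incoming edges).
#' @export
robustness_analysis <- function(net, schedule = NULL, config,
                                n_background = 100, n_groups = 50,
                                group_size = 100, weight_sampler = stats::runif) {
  validate_network(net)
  stopifnot(inherits(config, "sim_config"))
  for (nm in c("n_background", "n_groups", "group_size")) {
    assert_scalar_number(get(nm), nm, 1)
  }
  stopifnot(is.function(weight_sampler))

  idx0 <- build_sim_index(net)
  V <- build_virtual_signals(schedule, net$nodes, config$iterations)
  n_edges <- nrow(net$edges)
  keep <- in_degree(net) > 0L
  if (!any(keep)) stop("no node has incoming edges; nothing to analyse", call. = FALSE)

  # Index template re-weighted per run: positions of each edge weight within
  # the per-node weight lists.
  e <- net$edges
  tgt <- match(e$target, net$nodes)
  act <- e$sign == "+"

  init_seeds <- derive_subseeds(config$seed, max(n_background, group_size))

  run_once <- function(j) {
    w <- weight_sampler(n_edges)
    if (length(w) != n_edges || anyNA(w) || any(w < 0 | w > 1)) {
      stop("weight_sampler must return n_edges values in [0, 1]", call. = FALSE)
    }
    idx <- idx0
    for (i in seq_len(idx$n)) {
      idx$act_w[[i]] <- w[tgt == i & act]
      idx$inh_w[[i]] <- w[tgt == i & !act]
    }
    init <- with_seed(init_seeds[[j]], stats::runif(idx$n))
    sim_core(idx, init, V, config$degradation, config$clamp,
             config$iterations)[, -1L, drop = FALSE]
  }
  mean_trend <- function(n_runs) {
    acc <- 0
    for (r in seq_len(n_runs)) acc <- acc + run_once(r)
    acc / n_runs
  }

  with_seed(config$seed, {
    background <- mean_trend(n_background)
    cors <- matrix(NA_real_, nrow = sum(keep), ncol = n_groups,
                   dimnames = list(net$nodes[keep], NULL))
    for (g in seq_len(n_groups)) {
      trend <- mean_trend(group_size)
      for (i in which(keep)) {
        a <- trend[i, ]
        b <- background[i, ]
        cors[net$nodes[i], g] <-
          if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
          else stats::cor(a, b, method = "spearman")
      }
    }
    med <- apply(cors, 1L, stats::median, na.rm = TRUE)
    med[is.nan(med)] <- NA_real_
    structure(list(correlations = cors,
                   median = sort(med, decreasing = TRUE, na.last = TRUE),
                   excluded = net$nodes[!keep],
                   background_trend = background),
              class = "robustness_result")
  })
}

#' @export
print.robustness_result <- function(x, ...) {
  cat(sprintf("Edge-weight robustness: %d node(s), %d correlation(s) per node\n",
              nrow(x$correlations), ncol(x$correlations)))
  cat("Excluded (no incoming edges):",
      if (length(x$excluded)) paste(x$excluded, collapse = ", ") else "(none)", "\n")
  cat("Median correlation with background trend (ranked):\n")
  print(round(x$median, 3))
  invisible(x)
}

#' Goodness-of-fit report across perturbation conditions
#'
#' Simulates each named input condition, downsamples the trajectory to the
#' measured time points and reports the per-protein Spearman correlation with
#' the measurements — a drug-treatment fit table. A condition maps each input
#' node either to a level in \[-1, 1\] (applied from iteration 1 through a
#' virtual edge) or to the string `"random"`, meaning no extracellular
#' signal: the node starts at a seeded random activity and evolves freely.
#'
#' @param net a [signaling_network()].
#' @param designs named list of conditions; each condition is a named list or
#'   vector mapping input-node identifiers to a numeric level or `"random"`.
#' @param measured a [measured_time_course()] used for all conditions, or a
#'   named list of one per condition (names matching `designs`).
#' @param config a [sim_config()]; `iterations` must be divisible by the
#'   number of measured time points.
#' @return A data frame with one row per protein shared between the
#'   measurements and the network and one correlation column per condition.
#'   Proteins measured but absent from the network are listed in the
#'   `skipped` attribute (with a warning), never an error.
#' @export
condition_fit_report <- function(net, designs, measured, config) {
  validate_network(net)
  stopifnot(inherits(config, "sim_config"), is.list(designs),
            !is.null(names(designs)), all(nzchar(names(designs))))
  if (inherits(measured, "measured_time_course")) {
    measured <- stats::setNames(rep(list(measured), length(designs)), names(designs))
  }
  if (!all(names(designs) %in% names(measured))) {
    stop("`measured` must cover every condition in `designs`", call. = FALSE)
  }
  results <- list()
  skipped <- character()
  for (cond in names(designs)) {
    design <- designs[[cond]]
    bad <- setdiff(names(design), net$input_nodes)
    if (length(bad)) stop("condition '", cond, "' assigns non-input node(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    events <- list()
    for (nd in names(design)) {
      lv <- design[[nd]]
      if (identical(lv, "random")) next
      if (!is.numeric(lv)) stop("levels must be numeric or \"random\"", call. = FALSE)
      events[[length(events) + 1L]] <- perturbation_event(nd, lv, start = 1)
    }
    sch <- perturbation_schedule(events)
    mtc <- measured[[cond]]
    stopifnot(inherits(mtc, "measured_time_course"))
    traj <- simulate_network(net, sch, config)
    sim <- downsample(traj, ncol(mtc))
    shared <- intersect(rownames(mtc), net$nodes)
    skipped <- union(skipped, setdiff(rownames(mtc), net$nodes))
    results[[cond]] <- vapply(shared, function(p) {
      spearman_fit(sim[p, ], mtc[p, ])
    }, 0)
  }
  if (length(skipped)) {
    warning("measured proteins absent from the network were skipped: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  proteins <- Reduce(union, lapply(results, names))
  out <- data.frame(protein = proteins, stringsAsFactors = FALSE)
  for (cond in names(results)) {
    out[[cond]] <- unname(results[[cond]][proteins])
  }
  attr(out, "skipped") <- skipped
  out
}
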