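#' Scheduled perturbation events
#'
#' A perturbation event delivers an extracellular signal to one input node of
#' the network over a span of simulation iterations. The signal is modeled as
#' an edge from a virtual extracellular node whose activity is pinned at 1:
#' a positive level `l` becomes an activating virtual edge of weight `l`, a
#' negative level an inhibiting virtual edge of weight `|l|` (full inhibition
#' is level -1). Iterations are 1-based: an event with `start = 10` first
#' affects the 10th synchronous update. Events persist until `end`
#' (default `Inf`: drugs are added, not withdrawn).
#'
#' @param target identifier of the perturbed node (must be an input node of
#'   the network being simulated).
#' @param level perturbation strength in \[-1, 1\]; positive stimulates,
#'   negative inhibits. `0` is legal and transmits no signal.
#' @param start first iteration (>= 1) at which the perturbation acts.
#' @param end last iteration at which it acts; `Inf` for open-ended.
#' @return An object of class `perturbation_event`.
#' @examples
#' ev <- perturbation_event("TNFR", 0.8, start = 20)
#' sch <- perturbation_schedule(list(ev))
#' active_signal(sch, "TNFR", 5)    # NULL: not yet active
#' active_signal(sch, "TNFR", 20)   # 0.8
#' @export
perturbation_event <- function(target, level, start = 1, end = Inf) {
  stopifnot(is.character(target), length(target) == 1L, nzchar(target))
  assert_scalar_number(level, "level", -1, 1)
  assert_scalar_number(start, "start", 1)
  if (start != floor(start)) stop("`start` must be an integer iteration index", call. = FALSE)
  if (is.finite(end)) {
    assert_scalar_number(end, "end", start)
    if (end != floor(end)) stop("`end` must be an integer iteration index", call. = FALSE)
  }
  structure(list(target = target, level = level, start = start, end = end),
            class = "perturbation_event")
}

#' Build a perturbation schedule
#'
#' Collects events and validates that no two events targeting the same node
#' are active at the same iteration.
#'
#' @param events a list of [perturbation_event()] objects (a single event is
#'   also accepted).
#' @return An object of class `perturbation_schedule`.
#' @export
perturbation_schedule <- function(events = list()) {
  if (inherits(events, "perturbation_event")) events <- list(events)
  stopifnot(is.list(events))
  for (ev in events) {
    if (!inherits(ev, "perturbation_event")) {
      stop("all elements must be perturbation_event objects", call. = FALSE)
    }
  }
  by_target <- split(events, vapply(events, `[[`, "", "target"))
  for (evs in by_target) {
    if (length(evs) < 2L) next
    starts <- vapply(evs, `[[`, 0, "start")
    ends <- vapply(evs, `[[`, 0, "end")
    ord <- order(starts)
    starts <- starts[ord]; ends <- ends[ord]
    if (any(starts[-1L] <= ends[-length(ends)])) {
      stop("overlapping events for target '", evs[[1L]]$target,
           "': at most one event may be active per iteration", call. = FALSE)
    }
  }
  structure(list(events = events), class = "perturbation_schedule")
}

#' @export
print.perturbation_schedule <- function(x, ...) {
  cat(sprintf("Perturbation schedule: %d event(s)\n", length(x$events)))
  for (ev in x$events) {
    cat(sprintf("  %s %+g from iteration %g%s\n", ev$target, ev$level, ev$start,
                if (is.finite(ev$end)) sprintf(" to %g", ev$end) else ""))
  }
  invisible(x)
}

#' Signal level active for a target at an iteration
#'
#' @param schedule a [perturbation_schedule()].
#' @param target node identifier.
#' @param iteration 1-based iteration index (>= 1).
#' @return The signed level of the event covering `(target, iteration)`, or
#'   `NULL` if no event is active (the node then evolves freely).
#' @export
active_signal <- function(schedule, target, iteration) {
  stopifnot(inherits(schedule, "perturbation_schedule"))
  assert_scalar_number(iteration, "iteration", 1)
  for (ev in schedule$events) {
    if (ev$target == target && iteration >= ev$start && iteration <= ev$end) {
      return(ev$level)
    }
  }
  NULL
}

#' Virtual edges induced by a schedule at one iteration
#'
#' Translates the active events into edges from the always-on virtual
#' extracellular node. Since the virtual node's activity is constant 1, the
#' transmitted signal equals the edge weight `|level|`. Events with
#' `level == 0` emit no edge.
#'
#' @param schedule a [perturbation_schedule()].
#' @param iteration 1-based iteration index.
#' @return A data frame with columns `target`, `sign` (`"+"`/`"-"`) and
#'   `weight` (= `|level|`), one row per active non-zero event.
#' @export
as_virtual_edges <- function(schedule, iteration) {
  stopifnot(inherits(schedule, "perturbation_schedule"))
  assert_scalar_number(iteration, "iteration", 1)
  rows <- lapply(schedule$events, function(ev) {
    if (iteration < ev$start || iteration > ev$end || ev$level == 0) return(NULL)
    data.frame(target = ev$target,
               sign = if (ev$level > 0) "+" else "-",
               weight = abs(ev$level), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(target = character(), sign = character(),
                      weight = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Read a perturbation schedule from file
#'
#' CSV files need columns `target, level, start` and optionally `end` (empty
#' or `NA` meaning open-ended). JSON files hold an array of objects with the
#' same fields.
#'
#' @param path path to a `.csv` or `.json` schedule file.
#' @return A validated [perturbation_schedule()].
#' @export
read_schedule <- function(path) {
  if (!file.exists(path)) stop("schedule file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rows <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!is.data.frame(rows)) rows <- as.data.frame(rows)
  } else {
    rows <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("target", "level", "start")
  if (!all(need %in% names(rows))) {
    stop("schedule file must have columns target, level, start (optional end): ",
         path, call. = FALSE)
  }
  events <- lapply(seq_len(nrow(rows)), function(i) {
    end <- if ("end" %in% names(rows) && !is.na(rows$end[[i]])) rows$end[[i]] else Inf
    perturbation_event(rows$target[[i]], rows$level[[i]], rows$start[[i]], end)
  })
  perturbation_schedule(events)
}

#' Write a perturbation schedule to CSV
#'
#' @param schedule a [perturbation_schedule()].
#' @param path output path.
#' @return `schedule`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "perturbation_schedule"))
  df <- data.frame(
    target = vapply(schedule$events, `[[`, "", "target"),
    level = vapply(schedule$events, `[[`, 0, "level"),
    start = vapply(schedule$events, `[[`, 0, "start"),
    end = vapply(schedule$events, function(e) if (is.finite(e$end)) e$end else NA_real_, 0)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(schedule)
}
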