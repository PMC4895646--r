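#' Construct a signaling network
#'
#' A signaling network is a directed graph whose nodes are molecular species
#' (proteins, stimuli, cell fates) and whose edges carry a sign (activation
#' `"+"` or inhibition `"-"`) and a weight in \[0, 1\] giving the interaction
#' strength. A subset of nodes may be designated as input nodes (receptors or
#' stimuli); only these can receive scheduled extracellular perturbations
#' (see [perturbation_event()]).
#'
#' Self-loops are rejected: self-dependence is already encoded by the
#' degradation term of the update rule, and a self-edge would double-count it.
#' At most one edge is allowed per ordered (source, target) pair. Node
#' identifiers are case-sensitive, non-empty strings.
#'
#' @param nodes character vector of unique node identifiers. If `NULL`, the
#'   node set is taken as the union of the edge endpoints (in order of first
#'   appearance).
#' @param edges a data frame with columns `source`, `target`, `sign`,
#'   `weight`. `sign` accepts `"+"`, `"-"`, `"activate"`/`"activating"`,
#'   `"inhibit"`/`"inhibiting"` (normalized to `"+"`/`"-"`). May have zero
#'   rows.
#' @param input_nodes character vector, subset of `nodes`, designating the
#'   nodes eligible to receive perturbations.
#' @return An object of class `signaling_network`: a list with elements
#'   `nodes` (character), `edges` (data frame with normalized columns) and
#'   `input_nodes` (character).
#' @examples
#' net <- signaling_network(
#'   edges = data.frame(source = "EGFR", target = "ERK",
#'                      sign = "+", weight = 0.7),
#'   input_nodes = "EGFR"
#' )
#' parents_of(net, "ERK")
#' @export
signaling_network <- function(nodes = NULL, edges = NULL,
                              input_nodes = character()) {
  if (is.null(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        sign = character(), weight = numeric(),
                        stringsAsFactors = FALSE)
  }
  if (!is.data.frame(edges) ||
      !all(c("source", "target", "sign", "weight") %in% names(edges))) {
    stop("`edges` must be a data frame with columns source, target, sign, weight",
         call. = FALSE)
  }
  edges <- data.frame(source = as.character(edges$source),
                      target = as.character(edges$target),
                      sign = vapply(as.character(edges$sign), normalize_sign, ""),
                      weight = as.numeric(edges$weight),
                      stringsAsFactors = FALSE, row.names = NULL)
  if (is.null(nodes)) {
    nodes <- unique(c(rbind(edges$source, edges$target)))
  }
  nodes <- as.character(nodes)
  net <- structure(list(nodes = nodes, edges = edges,
                        input_nodes = as.character(input_nodes)),
                   class = "signaling_network")
  validate_network(net)
}

normalize_sign <- function(sign) {
  switch(tolower(sign),
         "+" = "+", "activate" = "+", "activating" = "+", "activation" = "+",
         "-" = "-", "inhibit" = "-", "inhibiting" = "-", "inhibition" = "-",
         stop(sprintf("unknown edge sign token: '%s'", sign), call. = FALSE))
}

#' Validate a signaling network
#'
#' Checks all structural invariants: unique non-empty node identifiers, edge
#' endpoints declared, input nodes declared, weights in \[0, 1\], no
#' self-loops, no duplicate ordered (source, target) pairs.
#'
#' @param net a `signaling_network`.
#' @return `net`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_network <- function(net) {
  if (!inherits(net, "signaling_network")) {
    stop("`net` must be a signaling_network", call. = FALSE)
  }
  nodes <- net$nodes
  if (length(nodes) < 1L) stop("network must have at least one node", call. = FALSE)
  if (anyNA(nodes) || any(!nzchar(nodes))) {
    stop("node identifiers must be non-empty strings", call. = FALSE)
  }
  if (anyDuplicated(nodes)) {
    stop("duplicate node identifiers: ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "), call. = FALSE)
  }
  e <- net$edges
  missing_nodes <- setdiff(c(e$source, e$target), nodes)
  if (length(missing_nodes)) {
    stop("edge endpoints not declared as nodes: ",
         paste(missing_nodes, collapse = ", "), call. = FALSE)
  }
  if (any(e$source == e$target)) {
    stop("self-loops are not allowed (node ",
         paste(unique(e$source[e$source == e$target]), collapse = ", "), ")",
         call. = FALSE)
  }
  if (anyNA(e$weight) || any(e$weight < 0 | e$weight > 1)) {
    stop("edge weights must be in [0, 1]", call. = FALSE)
  }
  key <- paste(e$source, e$target, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- e[duplicated(key), , drop = FALSE]
    stop("duplicate edge for ordered pair(s): ",
         paste(sprintf("(%s, %s)", dup$source, dup$target), collapse = ", "),
         call. = FALSE)
  }
  bad_inputs <- setdiff(net$input_nodes, nodes)
  if (length(bad_inputs)) {
    stop("input_nodes not declared as nodes: ",
         paste(bad_inputs, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(net$input_nodes)) {
    stop("duplicate input_nodes", call. = FALSE)
  }
  invisible(net)
}

#' Incoming edges of a node, partitioned by sign
#'
#' @param net a `signaling_network`.
#' @param node a node identifier present in `net`.
#' @return A list with components `activating` and `inhibiting`, each a named
#'   numeric vector of edge weights, named by parent node. Empty vectors if
#'   the node has no parents of that sign.
#' @export
parents_of <- function(net, node) {
  validate_network(net)
  if (length(node) != 1L || !node %in% net$nodes) {
    stop(sprintf("unknown node: '%s'", paste(node, collapse = ", ")), call. = FALSE)
  }
  e <- net$edges[net$edges$target == node, , drop = FALSE]
  act <- e[e$sign == "+", , drop = FALSE]
  inh <- e[e$sign == "-", , drop = FALSE]
  list(activating = stats::setNames(act$weight, act$source),
       inhibiting = stats::setNames(inh$weight, inh$source))
}

#' @export
print.signaling_network <- function(x, ...) {
  cat(sprintf("Signaling network: %d nodes, %d edges (%d activating, %d inhibiting)\n",
              length(x$nodes), nrow(x$edges),
              sum(x$edges$sign == "+"), sum(x$edges$sign == "-")))
  cat("Input nodes:",
      if (length(x$input_nodes)) paste(x$input_nodes, collapse = ", ") else "(none)",
      "\n")
  invisible(x)
}

#' Read a signaling network from file
#'
#' Two plain-text formats are supported:
#' \describe{
#'   \item{edge-list}{A SIF-like four-column format, one edge per line:
#'     `source sign weight target`, separated by whitespace or tabs. The sign
#'     token is one of `+`, `-`, `activate`, `inhibit`. Lines starting with
#'     `#` are comments; an optional header line `source sign weight target`
#'     is skipped. Two structured directives are recognized inside comments,
#'     `#! nodes: a b c` and `#! inputs: a b`, which declare the node set
#'     (including isolated nodes) and the input nodes. Without directives the
#'     node set is the union of edge endpoints and the input nodes default to
#'     nodes with no incoming edges.}
#'   \item{json}{An object `{"nodes": [...], "input_nodes": [...],
#'     "edges": [{"source":..., "target":..., "sign":..., "weight":...}]}`.}
#' }
#'
#' @param path path to the network file.
#' @param format `"auto"` (by extension: `.json` vs anything else),
#'   `"edgelist"` or `"json"`.
#' @return A validated [signaling_network()].
#' @seealso [write_network()]
#' @export
read_network <- function(path, format = c("auto", "edgelist", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("network file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "edgelist"
  }
  if (format == "json") read_network_json(path) else read_network_edgelist(path)
}

read_network_edgelist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  declared_nodes <- NULL
  declared_inputs <- NULL
  rows <- list()
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line)) next
    if (startsWith(line, "#")) {
      m <- regmatches(line, regexec("^#!\\s*(nodes|inputs):\\s*(.*)$", line))[[1]]
      if (length(m) == 3L) {
        toks <- strsplit(trimws(m[[3]]), "\\s+")[[1]]
        toks <- toks[nzchar(toks)]
        if (m[[2]] == "nodes") declared_nodes <- toks else declared_inputs <- toks
      }
      next
    }
    tok <- strsplit(line, "\\s+")[[1]]
    if (length(tok) == 4L && i == which(nzchar(trimws(lines)) &
                                        !startsWith(trimws(lines), "#"))[1] &&
        identical(tolower(tok), c("source", "sign", "weight", "target"))) {
      next  # optional header
    }
    if (length(tok) != 4L) {
      stop(sprintf("parse error at line %d of %s: expected 4 columns 'source sign weight target', got %d",
                   i, path, length(tok)), call. = FALSE)
    }
    w <- suppressWarnings(as.numeric(tok[[3]]))
    if (is.na(w)) {
      stop(sprintf("parse error at line %d of %s: weight '%s' is not numeric",
                   i, path, tok[[3]]), call. = FALSE)
    }
    sign <- tryCatch(normalize_sign(tok[[2]]), error = function(e) {
      stop(sprintf("parse error at line %d of %s: %s", i, path, conditionMessage(e)),
           call. = FALSE)
    })
    rows[[length(rows) + 1L]] <- data.frame(source = tok[[1]], target = tok[[4]],
                                            sign = sign, weight = w,
                                            stringsAsFactors = FALSE)
  }
  edges <- if (length(rows)) do.call(rbind, rows) else NULL
  endpoints <- if (is.null(edges)) character() else unique(c(rbind(edges$source, edges$target)))
  nodes <- declared_nodes %||% endpoints
  net_nodes <- union(nodes, endpoints)
  inputs <- declared_inputs %||% {
    targets <- if (is.null(edges)) character() else edges$target
    setdiff(net_nodes, targets)
  }
  signaling_network(nodes = net_nodes, edges = edges, input_nodes = inputs)
}

read_network_json <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("parse error in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  edges <- obj$edges
  if (!is.null(edges) && !is.data.frame(edges)) edges <- as.data.frame(edges)
  signaling_network(nodes = obj$nodes,
                    edges = edges,
                    input_nodes = obj$input_nodes %||% character())
}

#' Write a signaling network to file
#'
#' Writes either the four-column edge-list dialect (with `#!` directives
#' recording the full node set and the input nodes, so that isolated nodes
#' and input designations survive) or the JSON schema. Weights are written to
#' full precision; `read_network(write_network(net))` reproduces `net`
#' exactly.
#'
#' @param net a validated `signaling_network`.
#' @param path output file path.
#' @param format `"auto"`, `"edgelist"` or `"json"` (as [read_network()]).
#' @return `net`, invisibly.
#' @export
write_network <- function(net, path, format = c("auto", "edgelist", "json")) {
  format <- match.arg(format)
  validate_network(net)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "edgelist"
  }
  if (format == "json") {
    jsonlite::write_json(
      list(nodes = net$nodes, input_nodes = net$input_nodes,
           edges = net$edges),
      path, auto_unbox = FALSE, digits = I(17), pretty = TRUE)
  } else {
    lines <- c(
      paste("#! nodes:", paste(net$nodes, collapse = " ")),
      paste("#! inputs:", paste(net$input_nodes, collapse = " ")),
      if (nrow(net$edges)) {
        sprintf("%s\t%s\t%s\t%s", net$edges$source, net$edges$sign,
                vapply(net$edges$weight, function(w) format(w, digits = 17), ""),
                net$edges$target)
      }
    )
    writeLines(lines, path)
  }
  invisible(net)
}

# Number of incoming edges per node, in node order.
in_degree <- function(net) {
  vapply(net$nodes, function(nd) sum(net$edges$target == nd), 0L)
}
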