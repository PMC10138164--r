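#' Construct a dynamic (temporal) network from an event table
#'
#' A dynamic network is an ordered sequence of `T` undirected simple graph
#' snapshots over a shared node universe. It is stored as its event set:
#' triples `(u, v, t)` meaning that the interaction between nodes `u` and `v`
#' is active at the integer time point `t` (0-based). `(u, v, t)` and
#' `(v, u, t)` denote the same event; self-loops are rejected; duplicate
#' events collapse to one.
#'
#' @param events data frame with character columns `u`, `v` and an integer
#'   column `t` (0-based time indices).
#' @param n_timepoints total number of time points `T`. Defaults to
#'   `max(t) + 1`; may be larger to declare trailing empty snapshots.
#' @param nodes optional character vector of node ids; the node universe is
#'   the union of these with every id appearing in `events`. Nodes absent
#'   from all events of a snapshot are kept as isolated vertices there.
#' @param name label for the network.
#' @return An object of class `temporal_network` with fields `name`, `nodes`
#'   (sorted character vector), `events` (canonicalized data frame with
#'   `u < v`, sorted by `(t, u, v)`) and `n_timepoints`.
#' @seealso [read_temporal_edgelist()], [snapshot_at()]
#' @export
temporal_network <- function(events, n_timepoints = NULL, nodes = NULL,
                             name = "") {
  stopifnot(is.data.frame(events), all(c("u", "v", "t") %in% names(events)))
  u <- as.character(events$u)
  v <- as.character(events$v)
  t <- events$t
  if (length(t) > 0 && (any(is.na(t)) || any(t != floor(t)) || any(t < 0)))
    stop("time indices must be non-negative integers")
  t <- as.integer(t)
  if (any(u == v))
    stop("self-loops are not allowed in a temporal network")
  key <- paste(edge_key(u, v), t, sep = "\r")
  keep <- !duplicated(key)
  uk <- split_key(sub("\r[0-9]+$", "", key[keep]))
  ev <- data.frame(u = uk$u, v = uk$v, t = t[keep], stringsAsFactors = FALSE)
  ord <- order(ev$t, ev$u, ev$v, method = "radix")
  ev <- ev[ord, , drop = FALSE]
  rownames(ev) <- NULL
  T_min <- if (nrow(ev) > 0) max(ev$t) + 1L else 1L
  n_timepoints <- as.integer(n_timepoints %||% T_min)
  if (n_timepoints < T_min)
    stop("n_timepoints (", n_timepoints, ") smaller than max event time + 1 (",
         T_min, ")")
  all_nodes <- sort_c(unique(c(as.character(nodes), ev$u, ev$v)))
  structure(
    list(name = name, nodes = all_nodes, events = ev,
         n_timepoints = n_timepoints),
    class = "temporal_network"
  )
}

#' @export
print.temporal_network <- function(x, ...) {
  cat("temporal_network", if (nzchar(x$name)) sQuote(x$name) else "",
      "\n  nodes:", length(x$nodes),
      "\n  time points:", x$n_timepoints,
      "\n  events:", nrow(x$events), "\n")
  invisible(x)
}

#' Number of time points of a dynamic network
#' @param network a `temporal_network`.
#' @return Integer `T`.
#' @export
n_timepoints <- function(network) {
  stopifnot(inherits(network, "temporal_network"))
  network$n_timepoints
}

#' Read a temporal edge list
#'
#' Parses the snapshot-based TSV dialect: one event per line as
#' `u<TAB>v<TAB>t` with `t` a non-negative 0-based integer time index.
#' Comment lines start with `#`. Two directives are honoured:
#' `#T=<n>` declares the total number of time points (preserving trailing
#' empty snapshots) and `#node <id>` declares a node that may otherwise be
#' silent in every snapshot.
#'
#' @param path path to the file.
#' @param name label for the returned network (defaults to the file name).
#' @return A [temporal_network()].
#' @export
read_temporal_edgelist <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  declared_T <- NULL
  declared_nodes <- character(0)
  is_comment <- startsWith(trimws(lines), "#") | !nzchar(trimws(lines))
  for (ln in lines[is_comment]) {
    ln <- trimws(ln)
    if (grepl("^#T=", ln))
      declared_T <- suppressWarnings(as.integer(sub("^#T=", "", ln)))
    else if (grepl("^#node[ \t]+", ln))
      declared_nodes <- c(declared_nodes, sub("^#node[ \t]+", "", ln))
  }
  data_idx <- which(!is_comment)
  if (length(data_idx) == 0) stop("no events in ", path)
  fields <- strsplit(trimws(lines[data_idx]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed line ", data_idx[which(nf < 3)[1]], " in ", path,
         ": expected at least 3 fields 'u v t'")
  u <- vapply(fields, `[[`, "", 1L)
  v <- vapply(fields, `[[`, "", 2L)
  traw <- vapply(fields, `[[`, "", 3L)
  t <- suppressWarnings(as.integer(traw))
  bad <- which(is.na(t) | t < 0)
  if (length(bad) > 0)
    stop("malformed line ", data_idx[bad[1]], " in ", path,
         ": time index ", sQuote(traw[bad[1]]),
         " is not a non-negative integer")
  if (any(u == v))
    stop("malformed line ", data_idx[which(u == v)[1]], " in ", path,
         ": self-loop")
  temporal_network(data.frame(u = u, v = v, t = t, stringsAsFactors = FALSE),
                   n_timepoints = declared_T, nodes = declared_nodes,
                   name = name %||% basename(path))
}

#' Write a temporal edge list
#'
#' Writes one line per event (`u<TAB>v<TAB>t`, sorted by `(t, u, v)`),
#' preceded by a `#T=<n>` header and `#node <id>` directives for nodes that
#' appear in no event, so that reading the file back reconstructs the exact
#' event set, node universe and number of time points.
#'
#' @param network a `temporal_network`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_temporal_edgelist <- function(network, path) {
  stopifnot(inherits(network, "temporal_network"))
  ev <- network$events
  silent <- setdiff(network$nodes, unique(c(ev$u, ev$v)))
  header <- c(sprintf("#T=%d", network$n_timepoints),
              if (length(silent)) paste("#node", silent))
  body <- sprintf("%s\t%s\t%d", ev$u, ev$v, ev$t)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Extract the static snapshot at a time point
#'
#' @param network a `temporal_network`.
#' @param t 0-based time index, `0 <= t < n_timepoints(network)`.
#' @return An undirected simple [igraph::graph] whose vertices are the full
#'   node universe (nodes inactive at `t` are isolated) and whose edges are
#'   the events at time `t`.
#' @export
snapshot_at <- function(network, t) {
  stopifnot(inherits(network, "temporal_network"))
  if (length(t) != 1 || is.na(t) || t != floor(t) || t < 0 ||
      t >= network$n_timepoints)
    stop("time index t = ", t, " out of range [0, ",
         network$n_timepoints - 1, "]")
  ev <- network$events[network$events$t == t, , drop = FALSE]
  igraph::graph_from_data_frame(
    ev[, c("u", "v"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = network$nodes, stringsAsFactors = FALSE)
  )
}

# edge keys of the snapshot at time t (canonical "u\rv" strings)
snapshot_edge_keys <- function(network, t) {
  ev <- network$events[network$events$t == t, , drop = FALSE]
  edge_key(ev$u, ev$v)
}

#' Induce a subnetwork on a node subset
#'
#' Keeps, in every snapshot, exactly the events whose two endpoints both
#' belong to `nodes`; the node universe of the result is `nodes`.
#'
#' @param network a `temporal_network`.
#' @param nodes character vector of node ids to keep.
#' @return A `temporal_network` over `nodes` with the induced events.
#' @export
induce_subnetwork <- function(network, nodes) {
  stopifnot(inherits(network, "temporal_network"))
  missing <- setdiff(nodes, network$nodes)
  if (length(missing) > 0)
    stop("unknown nodes: ", paste(head(missing, 5), collapse = ", "))
  ev <- network$events
  keep <- ev$u %in% nodes & ev$v %in% nodes
  temporal_network(ev[keep, , drop = FALSE],
                   n_timepoints = network$n_timepoints, nodes = nodes,
                   name = network$name)
}
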