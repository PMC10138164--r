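#' Generate a synthetic dynamic network
#'
#' Builds the first snapshot from the Barabasi-Albert (BA) preferential
#' attachment model (every node ends up with at least one link), then evolves
#' it: snapshot `t` is obtained from snapshot `t - 1` by rewiring a uniformly
#' random `e_rate` fraction of its edges to fresh uniformly random endpoints
#' (no self-loops, no duplicate edges). The edge count is therefore conserved
#' across snapshots and consecutive snapshots share an expected `1 - e_rate`
#' fraction of their edges.
#'
#' @param n_nodes number of nodes.
#' @param events_per_node maximum number of edges attached by each new node
#'   during BA growth (default 2).
#' @param n_timepoints number of snapshots `T` (>= 1).
#' @param e_rate evolution rate in `[0, 1]`: fraction of edges rewired
#'   between consecutive snapshots (default 0.05).
#' @param seed integer seed; all randomness of this operation flows from it.
#' @return A [temporal_network()] with `n_timepoints` snapshots of equal
#'   edge count.
#' @examples
#' net <- generate_base_network(50, 2, 5, e_rate = 0.05, seed = 1)
#' mean(consecutive_snapshot_similarity(net, method = "overlap"))
#' @export
generate_base_network <- function(n_nodes, events_per_node = 2,
                                  n_timepoints = 1, e_rate = 0.05,
                                  seed = 1) {
  if (e_rate < 0 || e_rate > 1) stop("e_rate must be in [0, 1]")
  stopifnot(n_nodes > events_per_node, events_per_node >= 1,
            n_timepoints >= 1)
  node_ids <- sprintf("n%d", seq_len(n_nodes))
  with_seed(mix_seed(seed, 1), {
    g0 <- igraph::sample_pa(n_nodes, power = 1, m = events_per_node,
                            directed = FALSE)
    el <- igraph::as_edgelist(g0, names = FALSE)
    edges <- unique(edge_key(node_ids[el[, 1]], node_ids[el[, 2]]))
    snaps <- vector("list", n_timepoints)
    snaps[[1]] <- edges
    if (n_timepoints > 1) {
      for (t in 2:n_timepoints)
        snaps[[t]] <- rewire_edge_keys(snaps[[t - 1]], node_ids, e_rate)
    }
    ev <- do.call(rbind, lapply(seq_along(snaps), function(t) {
      uv <- split_key(snaps[[t]])
      data.frame(u = uv$u, v = uv$v, t = t - 1L, stringsAsFactors = FALSE)
    }))
    temporal_network(ev, n_timepoints = n_timepoints, nodes = node_ids,
                     name = sprintf("ba_n%d_T%d", n_nodes, n_timepoints))
  })
}

# Rewire a `fraction` of the edges in `keys` (canonical edge keys over
# `nodes`): remove k = round(fraction * |keys|) random edges and add k fresh
# uniformly random edges avoiding self-loops and duplicates of surviving or
# newly added edges (a removed edge may be re-drawn by chance). Consumes the
# caller's RNG stream.
rewire_edge_keys <- function(keys, nodes, fraction) {
  m <- length(keys)
  k <- round(fraction * m)
  if (k == 0) return(keys)
  drop_idx <- sample.int(m, k)
  kept <- keys[-drop_idx]
  current <- kept
  added <- character(0)
  n <- length(nodes)
  while (length(added) < k) {
    need <- k - length(added)
    i <- sample.int(n, 2 * need, replace = TRUE)
    j <- sample.int(n, 2 * need, replace = TRUE)
    ok <- i != j
    cand <- unique(edge_key(nodes[i[ok]], nodes[j[ok]]))
    cand <- setdiff(cand, c(current, added))
    if (length(cand) > need) cand <- cand[seq_len(need)]
    added <- c(added, cand)
  }
  c(kept, added)
}

#' Derive the counterpart of a dynamic network with known ground truth
#'
#' Builds the second network of a benchmark pair: `G` is the subnetwork of
#' `H` induced (per snapshot) on `keep_nodes` uniformly sampled nodes, then
#' perturbed by rewiring a `delta` fraction of each snapshot's edges. Kept
#' nodes retain their ids, so the ground-truth alignment is the namesake
#' (identical id) mapping. When all nodes are kept, the per-snapshot
#' conserved-edge fraction between `G` and `H` is `1 - delta` in expectation.
#'
#' @param H the base (target) `temporal_network`.
#' @param keep_nodes number of nodes to keep (`<= |nodes(H)|`).
#' @param delta divergence fraction in `[0, 1]` (default 0.10).
#' @param seed integer seed.
#' @return A `network_pair`: list with elements `G` (source), `H` (target)
#'   and `truth` (named character vector mapping G's node ids to their
#'   namesakes in H).
#' @export
derive_counterpart <- function(H, keep_nodes = NULL, delta = 0.10, seed = 1) {
  stopifnot(inherits(H, "temporal_network"))
  if (delta < 0 || delta > 1) stop("delta must be in [0, 1]")
  keep_nodes <- keep_nodes %||% length(H$nodes)
  if (keep_nodes < 1 || keep_nodes > length(H$nodes))
    stop("keep_nodes must be in [1, ", length(H$nodes), "]")
  with_seed(mix_seed(seed, 2), {
    kept <- sort_c(sample(H$nodes, keep_nodes))
    sub <- induce_subnetwork(H, kept)
    if (nrow(sub$events) == 0) stop("degenerate counterpart: no events left")
    snaps <- lapply(seq_len(sub$n_timepoints) - 1L, function(t)
      snapshot_edge_keys(sub, t))
    snaps <- lapply(snaps, rewire_edge_keys, nodes = kept, fraction = delta)
    ev <- do.call(rbind, lapply(seq_along(snaps), function(t) {
      if (length(snaps[[t]]) == 0) return(NULL)
      uv <- split_key(snaps[[t]])
      data.frame(u = uv$u, v = uv$v, t = t - 1L, stringsAsFactors = FALSE)
    }))
    if (is.null(ev) || nrow(ev) == 0)
      stop("degenerate counterpart: no events left")
    G <- temporal_network(ev, n_timepoints = sub$n_timepoints, nodes = kept,
                          name = paste0(H$name, "_counterpart"))
    truth <- stats::setNames(kept, kept)
    structure(list(G = G, H = H, truth = truth), class = "network_pair")
  })
}

#' @export
print.network_pair <- function(x, ...) {
  cat("network_pair: |V(G)| =", length(x$G$nodes),
      " |U(H)| =", length(x$H$nodes),
      " T =", x$G$n_timepoints, "\n")
  invisible(x)
}

#' Inject noise by random removal of edges or events
#'
#' Two regimes: `mode = "edges"` removes a `level` fraction of the `(u, v, t)`
#' triples uniformly at random (interactions persist, degraded over random
#' time points); `mode = "events"` removes a `level` fraction of the distinct
#' `(u, v)` interaction pairs together with all their occurrences over time
#' (more incisive). The node universe is unchanged.
#'
#' @param network a `temporal_network`.
#' @param level fraction removed, in `[0, 1]`; the removed count is
#'   `round(level * population)` where the population is the triple count
#'   (`"edges"`) or the distinct-pair count (`"events"`).
#' @param mode `"edges"` or `"events"`.
#' @param seed integer seed.
#' @return A new `temporal_network` over the same nodes and time points.
#' @export
inject_noise <- function(network, level, mode = c("edges", "events"),
                         seed = 1) {
  stopifnot(inherits(network, "temporal_network"))
  mode <- match.arg(mode)
  if (level < 0 || level > 1) stop("noise level must be in [0, 1]")
  ev <- network$events
  with_seed(mix_seed(seed, 3), {
    if (mode == "edges") {
      k <- round(level * nrow(ev))
      if (k > 0) ev <- ev[-sample.int(nrow(ev), k), , drop = FALSE]
    } else {
      pairs <- unique(edge_key(ev$u, ev$v))
      k <- round(level * length(pairs))
      if (k > 0) {
        gone <- sample(pairs, k)
        ev <- ev[!(edge_key(ev$u, ev$v) %in% gone), , drop = FALSE]
      }
    }
  })
  temporal_network(ev, n_timepoints = network$n_timepoints,
                   nodes = network$nodes,
                   name = sprintf("%s_noise%g_%s", network$name, level, mode))
}

#' Edge-set similarity of two static snapshots
#'
#' `method = "jaccard"` returns the Jaccard index
#' `|E1 n E2| / |E1 u E2|`; `method = "overlap"` returns the overlap
#' coefficient `|E1 n E2| / min(|E1|, |E2|)`, i.e. the conserved-edge
#' fraction when the two snapshots have equal edge counts (the quantity the
#' generator's `e_rate` and `delta` parameterize directly).
#'
#' @param g1,g2 [igraph::graph] objects over comparable node ids.
#' @param method `"jaccard"` (default) or `"overlap"`.
#' @return A similarity in `[0, 1]`; 1 with a warning if both edge sets are
#'   empty.
#' @export
snapshot_similarity <- function(g1, g2, method = c("jaccard", "overlap")) {
  method <- match.arg(method)
  k1 <- graph_edge_keys(g1)
  k2 <- graph_edge_keys(g2)
  edge_key_similarity(k1, k2, method)
}

graph_edge_keys <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  unique(edge_key(el[, 1], el[, 2]))
}

edge_key_similarity <- function(k1, k2, method) {
  if (length(k1) == 0 && length(k2) == 0) {
    warning("both edge sets empty; similarity defined as 1")
    return(1.0)
  }
  inter <- length(intersect(k1, k2))
  if (method == "jaccard") inter / length(union(k1, k2))
  else inter / min(max(length(k1), 1), max(length(k2), 1))
}

#' Similarity between consecutive snapshots of a dynamic network
#'
#' @param network a `temporal_network` with `T >= 2`.
#' @inheritParams snapshot_similarity
#' @return Numeric vector of length `T - 1`: similarity of snapshots
#'   `(t, t+1)` for `t = 0..T-2`.
#' @export
consecutive_snapshot_similarity <- function(network,
                                            method = c("jaccard", "overlap")) {
  stopifnot(inherits(network, "temporal_network"),
            network$n_timepoints >= 2)
  method <- match.arg(method)
  keys <- lapply(seq_len(network$n_timepoints) - 1L, function(t)
    snapshot_edge_keys(network, t))
  vapply(seq_len(network$n_timepoints - 1L), function(i)
    edge_key_similarity(keys[[i]], keys[[i + 1]], method), numeric(1))
}

#' Per-snapshot similarity between the two networks of a pair
#'
#' Compares each snapshot of `G` with the corresponding snapshot of `H`
#' induced on `G`'s node set, i.e. with the substructure of the target that
#' the counterpart was derived from.
#'
#' @param pair a `network_pair` from [derive_counterpart()], or a list with
#'   elements `G` and `H`.
#' @inheritParams snapshot_similarity
#' @return Numeric vector of length `T`.
#' @export
pair_snapshot_similarity <- function(pair, method = c("jaccard", "overlap")) {
  method <- match.arg(method)
  G <- pair$G
  H <- induce_subnetwork(pair$H, G$nodes)
  stopifnot(G$n_timepoints == H$n_timepoints)
  vapply(seq_len(G$n_timepoints) - 1L, function(t)
    edge_key_similarity(snapshot_edge_keys(G, t), snapshot_edge_keys(H, t),
                        method),
    numeric(1))
}
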