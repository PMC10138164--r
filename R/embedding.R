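#' Random-walk parameters
#'
#' Bundle of node2vec-style second-order walk parameters. With the defaults
#' `p = q = 1` the walks are ordinary uniform random walks.
#'
#' @param walks_per_node walks started from every node (default 10).
#' @param walk_length maximum walk length in nodes (default 80).
#' @param p return parameter: revisiting the previous node is weighted `1/p`.
#' @param q in-out parameter: moving to a node not adjacent to the previous
#'   one is weighted `1/q`.
#' @return A `walk_params` list.
#' @export
walk_params <- function(walks_per_node = 10, walk_length = 80, p = 1, q = 1) {
  stopifnot(walks_per_node >= 1, walk_length >= 1, p > 0, q > 0)
  structure(list(walks_per_node = as.integer(walks_per_node),
                 walk_length = as.integer(walk_length),
                 p = p, q = q),
            class = "walk_params")
}

#' Skip-Gram training parameters
#'
#' @param dim embedding dimension `N` (hidden-layer size, default 128).
#' @param window rolling context window `w` (default 5).
#' @param epochs training passes over the corpus (default 5); `epochs = 0`
#'   performs no updates, so a fully covered initial state is returned
#'   unchanged.
#' @param negative_samples negative samples per positive pair (default 5);
#'   negative sampling is used as the tractable surrogate for the softmax
#'   output layer.
#' @param alpha initial learning rate, linearly decayed (default 0.025).
#' @param seed integer seed driving walk sampling, initialization and
#'   training; training is single-threaded, so runs are reproducible.
#' @return An `sg_params` list.
#' @export
sg_params <- function(dim = 128, window = 5, epochs = 5,
                      negative_samples = 5, alpha = 0.025, seed = 1) {
  stopifnot(dim >= 1, window >= 1, epochs >= 0, negative_samples >= 0,
            alpha > 0)
  structure(list(dim = as.integer(dim), window = as.integer(window),
                 epochs = as.integer(epochs),
                 negative_samples = as.integer(negative_samples),
                 alpha = alpha, seed = as.integer(seed)),
            class = "sg_params")
}

#' Sample a random-walk corpus from a snapshot
#'
#' Starts `walks_per_node` walks from every vertex. Transitions are
#' second-order biased (node2vec semantics): from the edge `(prev, cur)` the
#' next node `x` is drawn with unnormalized weight `1/p` if `x = prev`, `1`
#' if `x` is adjacent to `prev`, and `1/q` otherwise. Isolated vertices
#' yield singleton walks, so every node of the universe enters the
#' vocabulary.
#'
#' @param snapshot an undirected simple [igraph::graph].
#' @param params a [walk_params()] bundle.
#' @param seed integer seed.
#' @return A `walk_corpus`: list with `walks` (list of character vectors of
#'   node names) and `params`.
#' @export
sample_walks <- function(snapshot, params = walk_params(), seed = 1) {
  stopifnot(igraph::is_igraph(snapshot), inherits(params, "walk_params"))
  n <- igraph::vcount(snapshot)
  if (n == 0) {
    warning("empty graph: returning an empty walk corpus")
    return(structure(list(walks = list(), params = params),
                     class = "walk_corpus"))
  }
  names <- igraph::V(snapshot)$name
  adj <- lapply(igraph::as_adj_list(snapshot, mode = "all"), function(x)
    sort.int(unique(as.integer(x))) - 1L)
  walks_idx <- cpp_sample_walks(adj, params$walks_per_node,
                                params$walk_length, params$p, params$q,
                                as.integer(seed))
  walks <- lapply(walks_idx, function(w) names[w + 1L])
  structure(list(walks = walks, params = params), class = "walk_corpus")
}

#' Train the Skip-Gram model, optionally from an initial embedding state
#'
#' Standard one-hidden-layer Skip-Gram with negative sampling, extended to
#' accept an initial state: the input-embedding row of every vocabulary
#' token also present in `initial` is set to its previous vector (the
#' intersection of the old and new feature sets), tokens only in `initial`
#' are discarded, and tokens new to the corpus receive a deterministic
#' id-keyed random initialization. With an empty initial state this is a
#' plain Skip-Gram run.
#'
#' @param corpus a `walk_corpus` from [sample_walks()] (or a list of
#'   character vectors).
#' @param params an [sg_params()] bundle.
#' @param initial an `embedding_state` to integrate, or `NULL` for the first
#'   time point.
#' @param init_keys optional named character vector mapping vocabulary
#'   tokens to the strings that key their fresh initialization; defaults to
#'   the tokens themselves. Joint cross-network training keys prefixed
#'   tokens by their bare node id so namesakes start from identical vectors.
#' @return An `embedding_state`: list with `vectors` (matrix, one named row
#'   of dimension `dim` per vocabulary token), `dim` and `params`.
#' @export
train_skipgram <- function(corpus, params = sg_params(), initial = NULL,
                           init_keys = NULL) {
  walks <- if (inherits(corpus, "walk_corpus")) corpus$walks else corpus
  if (length(walks) == 0) stop("empty corpus: nothing to train on")
  stopifnot(inherits(params, "sg_params"))
  vocab <- sort_c(unique(unlist(walks, use.names = FALSE)))
  counts <- table(factor(unlist(walks, use.names = FALSE), levels = vocab))
  keys <- vocab
  if (!is.null(init_keys)) {
    hit <- vocab %in% names(init_keys)
    keys[hit] <- unname(init_keys[vocab[hit]])
  }
  init <- cpp_hash_init(keys, params$dim, params$seed)
  rownames(init) <- vocab
  if (!is.null(initial)) {
    stopifnot(inherits(initial, "embedding_state"))
    if (ncol(initial$vectors) != params$dim)
      stop("dimension mismatch: initial state has dim ",
           ncol(initial$vectors), ", params request ", params$dim)
    shared <- intersect(vocab, rownames(initial$vectors))
    init[shared, ] <- initial$vectors[shared, , drop = FALSE]
  }
  walks_idx <- lapply(walks, function(w) match(w, vocab) - 1L)
  trained <- cpp_train_sgns(walks_idx, init, as.numeric(counts),
                            params$window, params$epochs,
                            params$negative_samples, params$alpha,
                            params$seed)
  rownames(trained) <- vocab
  embedding_state(trained, params = params)
}

embedding_state <- function(vectors, t = NA_integer_, params = NULL) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)),
            !anyDuplicated(rownames(vectors)))
  structure(list(vectors = vectors, dim = ncol(vectors), t = t,
                 params = params),
            class = "embedding_state")
}

#' @export
print.embedding_state <- function(x, ...) {
  cat("embedding_state:", nrow(x$vectors), "nodes x", x$dim, "dims")
  if (!is.na(x$t)) cat(" (time point", x$t, ")")
  cat("\n")
  invisible(x)
}

#' Temporal embedding of a dynamic network
#'
#' Processes the snapshots in order: at each time point a walk corpus is
#' sampled and a Skip-Gram model is trained with the previous time point's
#' state as initial embeddings (empty at the first time point). The returned
#' final state reflects the entire temporal evolution of the network.
#'
#' @param network a `temporal_network`.
#' @param wparams a [walk_params()] bundle.
#' @param sparams an [sg_params()] bundle; `sparams$seed` drives all
#'   randomness.
#' @return The final `embedding_state` (time point `T - 1`).
#' @export
temporal_embedding <- function(network, wparams = walk_params(),
                               sparams = sg_params()) {
  stopifnot(inherits(network, "temporal_network"))
  if (nrow(network$events) == 0)
    stop("no trainable content: every snapshot is empty")
  state <- NULL
  for (t in seq_len(network$n_timepoints) - 1L) {
    corpus <- sample_walks(snapshot_at(network, t), wparams,
                           seed = mix_seed(sparams$seed, 100 + t))
    step_params <- sparams
    step_params$seed <- mix_seed(sparams$seed, 200 + t)
    state <- train_skipgram(corpus, step_params, initial = state)
    state$t <- t
  }
  state
}

#' Joint temporal embedding of two dynamic networks in a shared space
#'
#' Embeds a source and a target network so that cosine similarity across the
#' two is meaningful. The two temporal embeddings are trained as *twin
#' trajectories*: both networks use the same id-keyed deterministic
#' initialization, the same walk-sampling streams and the same training
#' streams at every time point. Identical networks therefore produce
#' identical vectors (every namesake pair has cosine similarity 1), and the
#' more two networks share structure, the longer their training trajectories
#' stay correlated, so namesake vectors remain close in proportion to the
#' topological agreement of the inputs. Concatenating the two corpora into
#' one model instead (with prefix-disjoint vocabularies) leaves the two
#' halves of the space mutually unconstrained and destroys cross-network
#' comparability after the first epoch; see the methods vignette.
#'
#' @param G source `temporal_network`.
#' @param H target `temporal_network` with the same number of time points.
#' @inheritParams temporal_embedding
#' @return List with elements `G` and `H`: the two final `embedding_state`s,
#'   living in one comparable space.
#' @export
joint_temporal_embedding <- function(G, H, wparams = walk_params(),
                                     sparams = sg_params()) {
  stopifnot(inherits(G, "temporal_network"), inherits(H, "temporal_network"))
  if (G$n_timepoints != H$n_timepoints)
    stop("unequal time points: G has ", G$n_timepoints, ", H has ",
         H$n_timepoints)
  if (nrow(G$events) == 0 || nrow(H$events) == 0)
    stop("no trainable content: a network has no events")
  embed_one <- function(net) {
    state <- NULL
    for (t in seq_len(net$n_timepoints) - 1L) {
      corpus <- sample_walks(snapshot_at(net, t), wparams,
                             seed = mix_seed(sparams$seed, 300 + t))
      step_params <- sparams
      step_params$seed <- mix_seed(sparams$seed, 500 + t)
      state <- train_skipgram(corpus, step_params, initial = state)
      state$t <- t
    }
    state
  }
  list(G = embed_one(G), H = embed_one(H))
}

#' Write an embedding state as TSV
#'
#' One line per node: the id followed by `N` tab-separated coordinates,
#' preceded by a `#dim=<N> #t=<index>` header.
#'
#' @param state an `embedding_state`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_embedding <- function(state, path) {
  stopifnot(inherits(state, "embedding_state"))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("#dim=%d #t=%d", state$dim,
                     if (is.na(state$t)) -1L else state$t), con)
  apply_rows <- vapply(seq_len(nrow(state$vectors)), function(i)
    paste(c(rownames(state$vectors)[i],
            format(state$vectors[i, ], digits = 17, trim = TRUE)),
          collapse = "\t"),
    character(1))
  writeLines(apply_rows, con)
  invisible(path)
}

#' Read an embedding state written by [write_embedding()]
#'
#' @param path input path.
#' @return An `embedding_state`.
#' @export
read_embedding <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  ids <- vapply(fields, `[[`, "", 1L)
  vecs <- t(vapply(fields, function(f) as.numeric(f[-1]),
                   numeric(length(fields[[1]]) - 1L)))
  rownames(vecs) <- ids
  t_idx <- NA_integer_
  if (length(header) > 0 && grepl("#t=", header[1]))
    t_idx <- as.integer(sub(".*#t=(-?[0-9]+).*", "\\1", header[1]))
  if (!is.na(t_idx) && t_idx < 0) t_idx <- NA_integer_
  embedding_state(vecs, t = t_idx)
}
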