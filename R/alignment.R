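#' Cross-network cosine-similarity matrix
#'
#' Entry `(i, j)` is the cosine similarity between the vector of the i-th
#' source node and the vector of the j-th target node. Rows/columns whose
#' vector has zero norm are set to 0 with a warning.
#'
#' @param embG `embedding_state` of the source network (rows, `|V|`).
#' @param embH `embedding_state` of the target network (columns, `|U|`).
#' @return A `similarity_matrix`: list with `scores` (`|V| x |U|` matrix
#'   with dimnames), `rows`, `cols`.
#' @export
similarity_matrix <- function(embG, embH) {
  stopifnot(inherits(embG, "embedding_state"),
            inherits(embH, "embedding_state"))
  if (embG$dim != embH$dim)
    stop("embedding dimensions differ: ", embG$dim, " vs ", embH$dim)
  A <- embG$vectors
  B <- embH$vectors
  if (nrow(A) == 0 || nrow(B) == 0) stop("empty embedding state")
  na <- sqrt(rowSums(A^2))
  nb <- sqrt(rowSums(B^2))
  if (any(na == 0) || any(nb == 0))
    warning("zero-norm embedding vector(s); their similarities set to 0")
  na[na == 0] <- Inf
  nb[nb == 0] <- Inf
  S <- (A %*% t(B)) / outer(na, nb)
  S[] <- pmin(pmax(S, -1), 1)
  structure(list(scores = S, rows = rownames(A), cols = rownames(B)),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("similarity_matrix:", length(x$rows), "x", length(x$cols), "\n")
  invisible(x)
}

#' Per-source-node similarity lists in descending order
#'
#' @param sim a `similarity_matrix`.
#' @return Named list: for each source node, a named numeric vector of
#'   similarities to every target node, sorted in descending order.
#' @export
similarity_lists <- function(sim) {
  stopifnot(inherits(sim, "similarity_matrix"))
  stats::setNames(lapply(sim$rows, function(v) {
    s <- sim$scores[v, ]
    s[order(-s, sim$cols, method = "radix")]
  }), sim$rows)
}

#' Resolve a similarity matrix into an injective node mapping
#'
#' Default `method = "greedy"` performs iterative global score
#' maximization: the globally best still-available pair is assigned, its row
#' and column are retired, and the process repeats until every source node
#' is mapped. No assignment can then exceed the score of an earlier one, so
#' collisions on a shared best target are resolved in favour of the higher
#' score. Ties break lexicographically on `(source, target)`.
#' `method = "optimal"` instead solves the maximum-weight bipartite
#' assignment exactly (Hungarian algorithm); its total score is an upper
#' bound on the greedy total.
#'
#' @param sim a `similarity_matrix` with `|V| <= |U|`.
#' @param method `"greedy"` (default) or `"optimal"`.
#' @return An `alignment`: list with `mapping` (named character vector,
#'   source id -> target id), `pairs` (data frame `g`, `h`, `score` sorted by
#'   descending score) and `total` (sum of pair scores).
#' @export
align <- function(sim, method = c("greedy", "optimal")) {
  stopifnot(inherits(sim, "similarity_matrix"))
  method <- match.arg(method)
  S <- sim$scores
  n <- nrow(S)
  m <- ncol(S)
  if (n > m)
    stop("|V| = ", n, " exceeds |U| = ", m,
         ": swap the source and target networks so that |V| <= |U|")
  if (method == "greedy") {
    i_idx <- rep(seq_len(n), times = m)
    j_idx <- rep(seq_len(m), each = n)
    ord <- order(-as.vector(S), sim$rows[i_idx], sim$cols[j_idx],
                 method = "radix")
    row_free <- rep(TRUE, n)
    col_free <- rep(TRUE, m)
    gi <- integer(n)
    left <- n
    for (k in ord) {
      i <- i_idx[k]
      j <- j_idx[k]
      if (row_free[i] && col_free[j]) {
        row_free[i] <- FALSE
        col_free[j] <- FALSE
        gi[i] <- j
        left <- left - 1L
        if (left == 0L) break
      }
    }
  } else {
    gi <- hungarian_max(S)
  }
  pairs <- data.frame(g = sim$rows, h = sim$cols[gi],
                      score = S[cbind(seq_len(n), gi)],
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(-pairs$score, pairs$g, method = "radix"), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(mapping = stats::setNames(pairs$h, pairs$g), pairs = pairs,
                 total = sum(pairs$score), method = method),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat("alignment (", x$method, "): ", length(x$mapping), " pairs, total score ",
      format(x$total, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Align two dynamic networks end-to-end
#'
#' Composition of [joint_temporal_embedding()], [similarity_matrix()] and
#' [align()]: embeds both networks in one shared space, scores every
#' cross-network node pair by cosine similarity and resolves the matrix into
#' an injective mapping covering all source nodes.
#'
#' @param G source `temporal_network` (`|V| <= |U|`).
#' @param H target `temporal_network` with the same number of time points.
#' @param wparams a [walk_params()] bundle.
#' @param sparams an [sg_params()] bundle.
#' @param method matcher passed to [align()].
#' @return An `alignment`.
#' @export
align_networks <- function(G, H, wparams = walk_params(),
                           sparams = sg_params(),
                           method = c("greedy", "optimal")) {
  stopifnot(inherits(G, "temporal_network"), inherits(H, "temporal_network"))
  if (length(G$nodes) == 0 || nrow(G$events) == 0)
    stop("source network is empty")
  if (length(G$nodes) > length(H$nodes))
    stop("|V| = ", length(G$nodes), " exceeds |U| = ", length(H$nodes),
         ": swap the source and target networks so that |V| <= |U|")
  emb <- joint_temporal_embedding(G, H, wparams, sparams)
  align(similarity_matrix(emb$G, emb$H), method = match.arg(method))
}

#' Write an alignment as TSV
#'
#' One line per aligned pair, `g_node<TAB>h_node<TAB>score`, sorted by
#' descending score.
#'
#' @param alignment an `alignment`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(alignment, path) {
  stopifnot(inherits(alignment, "alignment"))
  write.table(alignment$pairs, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an alignment TSV written by [write_alignment()]
#' @param path input path.
#' @return An `alignment` (method `"file"`).
#' @export
read_alignment <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("g", "h", "score"),
                   colClasses = c("character", "character", "numeric"))
  structure(list(mapping = stats::setNames(df$h, df$g), pairs = df,
                 total = sum(df$score), method = "file"),
            class = "alignment")
}
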