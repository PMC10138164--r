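# Fixture builders and independent oracles used across the suite.

toy_events <- function() {
  data.frame(u = c("a", "b", "a"), v = c("b", "c", "c"), t = c(0L, 0L, 1L),
             stringsAsFactors = FALSE)
}

toy_network <- function() temporal_network(toy_events())

# minimal alignment object from a named mapping (scores optional)
make_alignment <- function(mapping, scores = NULL) {
  scores <- scores %||% rep(1, length(mapping))
  pairs <- data.frame(g = names(mapping), h = unname(mapping),
                      score = scores, stringsAsFactors = FALSE)
  structure(list(mapping = mapping, pairs = pairs, total = sum(scores),
                 method = "fixture"),
            class = "alignment")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sim_from_matrix <- function(S, rows = NULL, cols = NULL) {
  rows <- rows %||% sprintf("v%02d", seq_len(nrow(S)))
  cols <- cols %||% sprintf("u%02d", seq_len(ncol(S)))
  dimnames(S) <- list(rows, cols)
  structure(list(scores = S, rows = rows, cols = cols),
            class = "similarity_matrix")
}

emb_state <- function(M) {
  structure(list(vectors = M, dim = ncol(M), t = NA_integer_, params = NULL),
            class = "embedding_state")
}

# Independent matching oracle: repeatedly scan the whole remaining matrix
# for its global maximum (lexicographic tie-break on row then column name)
# and assign it. Deliberately quadratic and scan-based, unlike align()'s
# single pre-sorted sweep.
greedy_scan_oracle <- function(S, rows, cols) {
  n <- nrow(S)
  m <- ncol(S)
  avail_r <- rep(TRUE, n)
  avail_c <- rep(TRUE, m)
  out <- stats::setNames(character(n), rows)
  pair_lt <- function(r1, c1, r2, c2) {
    k <- c(paste0(r1, "\r", c1), paste0(r2, "\r", c2))
    k[1] != k[2] && order(k, method = "radix")[1] == 1
  }
  for (step in seq_len(n)) {
    best <- -Inf
    bi <- bj <- 0L
    for (i in which(avail_r)) {
      for (j in which(avail_c)) {
        s <- S[i, j]
        better <- s > best ||
          (s == best && bi > 0L && pair_lt(rows[i], cols[j],
                                           rows[bi], cols[bj]))
        if (better) {
          best <- s
          bi <- i
          bj <- j
        }
      }
    }
    out[rows[bi]] <- cols[bj]
    avail_r[bi] <- FALSE
    avail_c[bj] <- FALSE
  }
  out
}

# Exhaustive maximum-weight assignment by enumerating all injections of
# rows into columns (oracle for the Hungarian matcher; small matrices only).
brute_force_assignment <- function(S) {
  n <- nrow(S)
  m <- ncol(S)
  best <- -Inf
  best_assign <- NULL
  rec <- function(i, used, acc, assign) {
    if (i > n) {
      if (acc > best) {
        best <<- acc
        best_assign <<- assign
      }
      return(invisible(NULL))
    }
    for (j in seq_len(m)) {
      if (!used[j]) {
        used[j] <- TRUE
        rec(i + 1L, used, acc + S[i, j], c(assign, j))
        used[j] <- FALSE
      }
    }
  }
  rec(1L, rep(FALSE, m), 0, integer(0))
  list(total = best, assign = best_assign)
}

# light embedding settings for fast unit tests
tiny_wparams <- function() walk_params(walks_per_node = 2, walk_length = 10)
tiny_sparams <- function(seed = 1, epochs = 1)
  sg_params(dim = 16, window = 3, epochs = epochs, seed = seed)
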