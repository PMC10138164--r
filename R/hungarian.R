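# Exact maximum-weight rectangular assignment (Hungarian algorithm with
# potentials, O(n^2 m)). Rows must not outnumber columns. Returns, for each
# row, the index of its assigned column.
hungarian_max <- function(S) {
  n <- nrow(S)
  m <- ncol(S)
  stopifnot(n <= m)
  cost <- max(S) - S   # convert maximization to minimization, non-negative
  INF <- .Machine$double.xmax / 4

  # 1-based with a virtual column 0 (index m + 1 here)
  u <- numeric(n + 1)
  v <- numeric(m + 1)
  p <- integer(m + 1)  # p[j] = row assigned to column j (0 = none)

  for (i in seq_len(n)) {
    p[m + 1] <- i
    j0 <- m + 1L
    minv <- rep(INF, m)
    way <- integer(m)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in seq_len(m + 1)) {
        if (used[j]) {
          if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == m + 1L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(m)) if (p[j] > 0) assign[p[j]] <- j
  assign
}
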