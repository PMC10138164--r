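# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so package operations never disturb the global stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a dedicated sub-stream seed (< 2^31) from a base seed and a stream
# index, so each stochastic operation consumes its own reproducible stream.
mix_seed <- function(seed, k) {
  s <- (abs(as.double(seed)) %% 2147483646) + 1
  as.integer(((s * 48271) + as.double(k) * 7919) %% 2147483647)
}

# Canonical undirected edge keys: "u\rv" with u <= v in C-locale order.
edge_key <- function(u, v) {
  swap <- order_gt(u, v)
  a <- ifelse(swap, v, u)
  b <- ifelse(swap, u, v)
  paste(a, b, sep = "\r")
}

# C-locale string comparison u > v (locale-independent determinism)
order_gt <- function(u, v) {
  n <- length(u)
  if (n == 0) return(logical(0))
  r <- rank_c(c(u, v))
  r[seq_len(n)] > r[n + seq_len(n)]
}

rank_c <- function(x) {
  ux <- sort_c(unique(x))
  match(x, ux)
}

# radix sort = C-locale ordering regardless of the session locale
sort_c <- function(x) x[order(x, method = "radix")]

split_key <- function(key) {
  parts <- strsplit(key, "\r", fixed = TRUE)
  list(u = vapply(parts, `[[`, "", 1L), v = vapply(parts, `[[`, "", 2L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
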