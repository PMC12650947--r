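# Directed horizontal visibility graph (dHVG): arc i -> j for i < j whenever
# every intermediate value is strictly lower than min(x_i, x_j); adjacent
# points are always linked. Built with the standard monotone-stack sweep,
# O(N) amortised.
hvg_edges <- function(x) {
  n <- length(x)
  from <- integer(2L * n)
  to <- integer(2L * n)
  ne <- 0L
  stack <- integer(n)
  top <- 0L
  add_edge <- function(i, j) {
    ne <<- ne + 1L
    if (ne > length(from)) {
      length(from) <<- 2L * length(from)
      length(to) <<- 2L * length(to)
    }
    from[ne] <<- i
    to[ne] <<- j
  }
  for (j in seq_len(n)) {
    while (top > 0L && x[stack[top]] < x[j]) {
      add_edge(stack[top], j)
      top <- top - 1L
    }
    if (top > 0L) {
      add_edge(stack[top], j)
      if (x[stack[top]] == x[j]) top <- top - 1L  # equal value blocks beyond
    }
    top <- top + 1L
    stack[top] <- j
  }
  cbind(from = from[seq_len(ne)], to = to[seq_len(ne)])
}

# In/out degree sequences of the dHVG (out = links departing forwards in
# time, in = links arriving from the past).
hvg_degrees <- function(x) {
  e <- hvg_edges(x)
  n <- length(x)
  list(out = tabulate(e[, 1L], nbins = n),
       `in` = tabulate(e[, 2L], nbins = n))
}

# Retarded and advanced local clustering coefficients: for each node, the
# triangle density among its past (resp. future) neighbours. Nodes with
# fewer than two neighbours on a side yield coefficient 0 on that side.
hvg_clustering <- function(x) {
  e <- hvg_edges(x)
  n <- length(x)
  past <- split(e[, 1L], factor(e[, 2L], levels = seq_len(n)))
  futu <- split(e[, 2L], factor(e[, 1L], levels = seq_len(n)))
  # edge membership lookup via sorted numeric keys
  keys <- sort((e[, 1L] - 1) * n + e[, 2L])
  has_edge <- function(i, j) {  # i < j assumed
    k <- (i - 1) * n + j
    idx <- findInterval(k, keys)
    idx > 0 && keys[idx] == k
  }
  cc_side <- function(nbrs) {
    vapply(nbrs, function(v) {
      k <- length(v)
      if (k < 2L) return(0)
      cnt <- 0L
      v <- sort(v)
      for (a in 1:(k - 1L)) for (b in (a + 1L):k) {
        if (has_edge(v[a], v[b])) cnt <- cnt + 1L
      }
      2 * cnt / (k * (k - 1))
    }, numeric(1))
  }
  list(retarded = unname(cc_side(past)), advanced = unname(cc_side(futu)))
}
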