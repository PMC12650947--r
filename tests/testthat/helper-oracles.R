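# Naive, loop-based oracle implementations, written independently of the
# package internals; the optimised code must match these.

oracle_skewness <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  m2 <- 0; m3 <- 0
  for (v in x) {
    m2 <- m2 + (v - m)^2 / n
    m3 <- m3 + (v - m)^3 / n
  }
  m3 / m2^1.5
}

oracle_casali <- function(x, m = 1) {
  d <- numeric(0)
  for (i in seq_len(length(x) - m)) d <- c(d, x[i + m] - x[i])
  oracle_skewness(d)
}

oracle_costa <- function(x) {
  nu <- 0; nd <- 0
  for (i in seq_len(length(x) - 1)) {
    if (x[i + 1] > x[i]) nu <- nu + 1
    if (x[i + 1] < x[i]) nd <- nd + 1
  }
  (nu - nd) / (nu + nd)
}

oracle_pomeau <- function(x) {
  s <- 0
  for (i in seq_len(length(x) - 1)) {
    s <- s + x[i] * x[i + 1]^2 - x[i]^2 * x[i + 1]
  }
  s / (length(x) - 1)
}

oracle_ramsey_diff <- function(x, k = 1) {
  n <- length(x)
  b21 <- 0; b12 <- 0
  for (i in (k + 1):n) {
    b21 <- b21 + x[i]^2 * x[i - k]
    b12 <- b12 + x[i] * x[i - k]^2
  }
  (b21 - b12) / (n - k)
}

# correlation integrals by brute force (pairs among the n-m+1 delay vectors,
# sup norm, <= eps), and the K triple statistic
oracle_bds_integrals <- function(x, m, eps) {
  M <- length(x) - m + 1
  c1 <- 0; cm <- 0
  for (i in 1:(M - 1)) for (j in (i + 1):M) {
    if (abs(x[i] - x[j]) <= eps) c1 <- c1 + 1
    ok <- TRUE
    for (l in 0:(m - 1)) if (abs(x[i + l] - x[j + l]) > eps) { ok <- FALSE; break }
    if (ok) cm <- cm + 1
  }
  ktrip <- 0
  for (i in 1:M) for (j in 1:M) for (l in 1:M) {
    if (i != j && j != l && i != l &&
        abs(x[i] - x[j]) <= eps && abs(x[j] - x[l]) <= eps) {
      ktrip <- ktrip + 1
    }
  }
  pairs <- M * (M - 1) / 2
  list(C1 = c1 / pairs, Cm = cm / pairs, K = ktrip / (M * (M - 1) * (M - 2)))
}

# dHVG by the definition: arc i -> j (i < j) iff every intermediate value is
# strictly below min(x_i, x_j)
oracle_hvg_edges <- function(x) {
  n <- length(x)
  e <- matrix(0L, 0, 2)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    visible <- TRUE
    if (j > i + 1) {
      for (k in (i + 1):(j - 1)) {
        if (x[k] >= min(x[i], x[j])) { visible <- FALSE; break }
      }
    }
    if (visible) e <- rbind(e, c(i, j))
  }
  e
}

oracle_hvg_degrees <- function(x) {
  e <- oracle_hvg_edges(x)
  n <- length(x)
  list(out = tabulate(e[, 1], nbins = n), `in` = tabulate(e[, 2], nbins = n))
}

oracle_hvg_clustering <- function(x) {
  e <- oracle_hvg_edges(x)
  n <- length(x)
  adj <- matrix(FALSE, n, n)
  for (r in seq_len(nrow(e))) adj[e[r, 1], e[r, 2]] <- TRUE
  ret <- adv <- numeric(n)
  for (v in 1:n) {
    past <- which(adj[, v])
    futu <- which(adj[v, ])
    cc <- function(nbrs) {
      k <- length(nbrs)
      if (k < 2) return(0)
      cnt <- 0
      for (a in 1:(k - 1)) for (b in (a + 1):k) {
        i <- min(nbrs[a], nbrs[b]); j <- max(nbrs[a], nbrs[b])
        if (adj[i, j]) cnt <- cnt + 1
      }
      2 * cnt / (k * (k - 1))
    }
    ret[v] <- cc(past)
    adv[v] <- cc(futu)
  }
  list(retarded = ret, advanced = adv)
}

oracle_slopes <- function(x, window, degree = 1) {
  M <- length(x) - window + 1
  out <- numeric(M)
  tt <- seq_len(window)
  for (i in seq_len(M)) {
    fit <- stats::lm(x[i:(i + window - 1)] ~ stats::poly(tt, degree, raw = TRUE))
    out[i] <- unname(stats::coef(fit)[degree + 1])
  }
  out
}

oracle_ordinal_counts <- function(x, pSize) {
  M <- length(x) - pSize + 1
  pats <- character(M)
  for (i in seq_len(M)) {
    w <- x[i:(i + pSize - 1)]
    pats[i] <- paste(rank(w, ties.method = "first"), collapse = "")
  }
  table(pats)
}

oracle_cop_distance <- function(window, pattern) {
  z <- window - mean(window)
  z <- z / max(abs(z))
  s <- 0
  for (l in seq_along(z)) s <- s + abs(z[l] - pattern[l])
  s / length(z)
}

# kernel U-statistic Q between forward and reversed delay-vector clouds
oracle_diks_q <- function(X, h) {
  M <- nrow(X); m <- ncol(X)
  K <- function(u, v) exp(-sum((u - v)^2) / (2 * h^2))
  tot <- 0
  for (i in 1:(M - 1)) for (j in (i + 1):M) {
    a_i <- X[i, ]; a_j <- X[j, ]
    b_i <- rev(a_i); b_j <- rev(a_j)
    tot <- tot + K(a_i, a_j) + K(b_i, b_j) - K(a_i, b_j) - K(a_j, b_i)
  }
  tot / (M * (M - 1) / 2)
}

oracle_gaspard <- function(codes, K) {
  n <- length(codes)
  cnt <- matrix(0, K, K)
  for (t in 1:(n - 1)) cnt[codes[t], codes[t + 1]] <- cnt[codes[t], codes[t + 1]] + 1
  pi_ <- rowSums(cnt) / sum(cnt)
  P <- cnt / pmax(rowSums(cnt), 1)
  s <- 0
  for (i in 1:K) for (j in 1:K) {
    if (cnt[i, j] > 0) s <- s + pi_[i] * P[i, j] * log(P[i, j] / P[j, i])
  }
  s
}

oracle_costa_discrete <- function(v) {
  d <- diff(v)
  up <- 0; dn <- 0
  for (val in d) {
    if (val > 0) up <- up + val^2
    if (val < 0) dn <- dn + val^2
  }
  (up - dn) / (up + dn)
}

oracle_zumbach_stat <- function(x, window) {
  r <- diff(x)
  nr <- length(r)
  ts_ <- seq(window + 1, nr - window, by = 2 * window + 2)
  g <- h <- f <- numeric(length(ts_))
  for (q in seq_along(ts_)) {
    t <- ts_[q]
    g[q] <- r[t]^2
    h[q] <- sqrt(mean(r[(t - window):(t - 1)]^2))
    f[q] <- sqrt(mean(r[(t + 1):(t + window)]^2))
  }
  stats::cor(g, f) - stats::cor(g, h)
}

# deterministic mildly irreversible test series
fixture_series <- function(n, seed) {
  set.seed(seed)
  generate_logistic(n, x0 = runif(1, 0.1, 0.9), burn_in = 100) + rnorm(n, 0, 0.05)
}
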