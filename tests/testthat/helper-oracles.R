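# Brute-force graph-metric oracles, independent of the package (and of
# igraph): plain-R enumeration over triples, BFS distances and shortest-path
# counting via the distance matrix. Only usable on small graphs.

oracle_clustering <- function(adj) {
  n <- ncol(adj)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    links <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        links <- links + adj[nb[a], nb[b]]
      }
    }
    out[i] <- 2 * links / (k * (k - 1))
  }
  out
}

oracle_transitivity <- function(adj) {
  n <- ncol(adj)
  triangles <- 0
  triples <- 0
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    triples <- triples + choose(k, 2)
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        triangles <- triangles + adj[nb[a], nb[b]]
      }
    }
  }
  if (triples == 0) 0 else triangles / triples # each triangle counted 3x in both
}

oracle_distances <- function(adj) {
  n <- ncol(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n)) { # BFS
    frontier <- s
    depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (u in which(adj[v, ] == 1)) {
          if (d[s, u] == Inf && u != s) {
            d[s, u] <- depth
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  d
}

oracle_charpath <- function(adj) {
  d <- oracle_distances(adj)
  vals <- d[upper.tri(d)]
  vals <- vals[is.finite(vals) & vals > 0]
  if (!length(vals)) 0 else mean(vals)
}

oracle_global_efficiency <- function(adj) {
  n <- ncol(adj)
  if (n < 2) return(0)
  d <- oracle_distances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_local_efficiency <- function(adj) {
  n <- ncol(adj)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) >= 2) {
      out[i] <- oracle_global_efficiency(adj[nb, nb, drop = FALSE])
    }
  }
  out
}

# Shortest-path counting from the distance matrix (independent of Brandes):
# sigma[s,t] by dynamic programming over distance layers, then pair-by-pair
# dependency accumulation.
oracle_betweenness <- function(adj, normalized = TRUE) {
  n <- ncol(adj)
  d <- oracle_distances(adj)
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  for (s in seq_len(n)) {
    ord <- order(d[s, ])
    for (t in ord) {
      if (t == s || !is.finite(d[s, t])) next
      preds <- which(adj[, t] == 1 & d[s, ] == d[s, t] - 1)
      sigma[s, t] <- sum(sigma[s, preds])
    }
  }
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(d[s, t]) || d[s, t] == 0) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
          d[s, v] + d[v, t] == d[s, t]) {
          bc[v] <- bc[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  if (normalized && n > 2) bc <- bc / ((n - 1) * (n - 2) / 2)
  bc
}

# Direct transcription of the percentage-bend correlation algorithm for one
# pair of vectors (independent oracle for bend_connectivity).
oracle_pbcor <- function(x, y, beta) {
  pb_one <- function(v) {
    n <- length(v)
    w <- sort(abs(v - median(v)))
    omega <- w[floor((1 - beta) * n + 0.5)]
    z <- (v - median(v)) / omega
    i1 <- sum(z < -1)
    i2 <- sum(z > 1)
    phi <- (omega * (i2 - i1) + sum(v[abs(z) <= 1])) / (n - i1 - i2)
    u <- (v - phi) / omega
    pmin(1, pmax(-1, u))
  }
  a <- pb_one(x)
  b <- pb_one(y)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# Closed-form Welch t-test (independent oracle).
oracle_welch <- function(a, b) {
  v1 <- var(a) / length(a)
  v2 <- var(b) / length(b)
  t_stat <- (mean(a) - mean(b)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(a) - 1) + v2^2 / (length(b) - 1))
  list(statistic = t_stat, df = df, p.value = 2 * pt(-abs(t_stat), df))
}

# BH step-up (independent transcription).
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}
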