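# Independent oracles used to cross-check the package's implementations.
# These are deliberately naive re-derivations: pure-R kernel MI, all-pairs
# shortest-path enumeration for betweenness, and a coordinate-descent lasso.

# Pure-R Gaussian product-kernel MI (nats), clamped at 0.
oracle_kernel_mi <- function(x, y) {
  n <- length(x)
  hx <- 1.06 * sd(x) * n^(-0.2)
  hy <- 1.06 * sd(y) * n^(-0.2)
  kx <- exp(-outer(x, x, "-")^2 / (2 * hx^2))
  ky <- exp(-outer(y, y, "-")^2 / (2 * hy^2))
  fx <- rowMeans(kx) / (sqrt(2 * pi) * hx)
  fy <- rowMeans(ky) / (sqrt(2 * pi) * hy)
  fxy <- rowMeans(kx * ky) / (2 * pi * hx * hy)
  max(0, mean(log(pmax(fxy, 1e-300)) - log(pmax(fx, 1e-300)) -
                log(pmax(fy, 1e-300))))
}

# Betweenness by explicit all-pairs BFS path counting:
# b(v) = sum over s,t != v of sigma_sv * sigma_vt / sigma_st over pairs with
# d_sv + d_vt = d_st.  For undirected graphs each unordered pair is counted
# once (ordered-pair total halved).
oracle_betweenness <- function(nodes, edges_from, edges_to, directed = TRUE) {
  n <- length(nodes)
  adj <- lapply(seq_len(n), function(i) integer())
  fi <- match(edges_from, nodes)
  ti <- match(edges_to, nodes)
  for (e in seq_along(fi)) {
    adj[[fi[e]]] <- c(adj[[fi[e]]], ti[e])
    if (!directed) adj[[ti[e]]] <- c(adj[[ti[e]]], fi[e])
  }
  dist <- matrix(Inf, n, n)
  sig <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist[s, s] <- 0; sig[s, s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer()
      for (u in frontier) for (v in adj[[u]]) {
        if (!is.finite(dist[s, v])) {
          dist[s, v] <- dist[s, u] + 1
          nxt <- c(nxt, v)
        }
        if (dist[s, v] == dist[s, u] + 1) sig[s, v] <- sig[s, v] + sig[s, u]
      }
      frontier <- unique(nxt)
    }
  }
  b <- numeric(n)
  for (v in seq_len(n)) {
    acc <- 0
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s == t || s == v || t == v) next
      if (is.finite(dist[s, t]) && sig[s, t] > 0 &&
          is.finite(dist[s, v]) && is.finite(dist[v, t]) &&
          dist[s, v] + dist[v, t] == dist[s, t]) {
        acc <- acc + sig[s, v] * sig[v, t] / sig[s, t]
      }
    }
    b[v] <- if (directed) acc else acc / 2
  }
  setNames(b, nodes)
}

# Cyclic coordinate descent for min 1/2 ||X w - y||^2 + mu ||w||_1.
oracle_cd_lasso <- function(X, y, mu, max_iter = 50000, tol = 1e-13) {
  p <- ncol(X)
  w <- numeric(p)
  xx <- colSums(X^2)
  r <- y
  for (it in seq_len(max_iter)) {
    w_old <- w
    for (j in seq_len(p)) {
      r_j <- r + X[, j] * w[j]
      z <- sum(X[, j] * r_j)
      w[j] <- sign(z) * max(abs(z) - mu, 0) / xx[j]
      r <- r_j - X[, j] * w[j]
    }
    if (max(abs(w - w_old)) < tol) break
  }
  w
}

# z-scoring with the sample (n-1) denominator, matching fit_tfa().
zrows <- function(x) {
  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  (x - mu) / s
}

# random directed graph edge list on `n` nodes
random_graph <- function(n, p_edge, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  idx <- which(matrix(runif(n * n) < p_edge, n, n) &
                 !diag(TRUE, n), arr.ind = TRUE)
  list(nodes = nodes,
       from = nodes[idx[, 1]],
       to = nodes[idx[, 2]])
}
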