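# Independent brute-force oracles used to check the package's graph and
# statistics code. These deliberately share no code with the implementation:
# explicit triple-loop Floyd-Warshall, simple-path enumeration for
# betweenness, an ECDF scan for the KS statistic, and numerical integration
# of the t density for correlation p-values.

# all-pairs shortest paths, explicit triple loop on a dense distance matrix
# (Inf = no edge)
oracle_fw <- function(W) {
  n <- nrow(W)
  D <- W
  diag(D) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# global efficiency from a dense edge-distance matrix
oracle_geff <- function(W) {
  n <- nrow(W)
  D <- oracle_fw(W)
  tot <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      if (is.finite(D[i, j]) && D[i, j] > 0) tot <- tot + 1 / D[i, j]
  2 * tot / (n * (n - 1))
}

# mean local efficiency from a dense edge-distance matrix
oracle_mean_leff <- function(W) {
  n <- nrow(W)
  vals <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(is.finite(W[v, ]) & seq_len(n) != v)
    vals[v] <- if (length(nb) < 2) 0
      else oracle_geff(W[nb, nb, drop = FALSE])
  }
  mean(vals)
}

# weighted betweenness by enumerating every simple path between every pair
# and counting shortest ones through each interior node; feasible up to
# ~8 nodes
oracle_betweenness <- function(W) {
  n <- nrow(W)
  bet <- numeric(n)
  paths_between <- function(s, t) {
    out <- list()
    walk <- function(v, visited, len) {
      if (v == t) {
        out[[length(out) + 1]] <<- list(path = visited, len = len)
        return()
      }
      for (u in seq_len(n)) {
        if (is.finite(W[v, u]) && !(u %in% visited))
          walk(u, c(visited, u), len + W[v, u])
      }
    }
    walk(s, s, 0)
    out
  }
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      ps <- paths_between(s, t)
      if (length(ps) == 0) next
      lens <- vapply(ps, function(p) p$len, numeric(1))
      best <- min(lens)
      short <- ps[abs(lens - best) < 1e-12]
      sigma <- length(short)
      through <- integer(n)
      for (p in short) {
        interior <- setdiff(p$path, c(s, t))
        through[interior] <- through[interior] + 1L
      }
      bet <- bet + through / sigma
    }
  }
  bet
}

# two-sample KS statistic by scanning the pooled support
oracle_ks_D <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  gaps <- vapply(grid, function(x) abs(mean(a <= x) - mean(b <= x)), 0)
  max(gaps)
}

# two-tailed correlation p-value by numerical integration of the t density
# written out explicitly
oracle_corr_p <- function(r, n) {
  df <- n - 2
  t_obs <- abs(r) * sqrt(df / (1 - r^2))
  dens <- function(x)
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  2 * stats::integrate(dens, t_obs, Inf, rel.tol = 1e-10)$value
}

# dense edge-distance matrix (Inf off-edges) of a thresholded_network or
# igraph graph, for feeding the oracles
dist_matrix_of <- function(net) {
  g <- if (inherits(net, "thresholded_network")) net$graph else net
  n <- igraph::vcount(g)
  W <- matrix(Inf, n, n)
  if (igraph::ecount(g) > 0) {
    e <- igraph::as_edgelist(g, names = FALSE)
    d <- igraph::E(g)$distance
    if (is.null(d)) d <- 1 - igraph::E(g)$weight
    W[e] <- d
    W[e[, c(2, 1), drop = FALSE]] <- d
  }
  W
}
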