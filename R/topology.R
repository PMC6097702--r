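# Efficiency metrics and small-world assessment against degree-preserving
# rewired null ensembles.

.as_graph <- function(net) {
  if (inherits(net, "thresholded_network")) net$graph
  else if (igraph::is_igraph(net)) net
  else stop("expected a thresholded_network or igraph object")
}

.edge_distances <- function(g) {
  if (igraph::ecount(g) == 0) return(numeric(0))
  d <- igraph::edge_attr(g, "distance")
  if (is.null(d)) {
    w <- igraph::edge_attr(g, "weight")
    d <- if (is.null(w)) rep(1, igraph::ecount(g)) else 1 - w
  }
  d
}

#' Global efficiency
#'
#' Mean of the inverse shortest-path lengths over all unordered node pairs,
#' computed on the distance view of the edges (`1 - |r|`). Unreachable pairs
#' contribute 0 while remaining in the denominator (the harmonic-mean
#' convention), so the measure is defined on fragmented networks.
#'
#' @param net a [threshold_network()] result or an igraph graph (edge
#'   attribute `distance`, falling back to `1 - weight`, then to 1).
#' @return Global efficiency in `[0, Inf)`; 0 for an edgeless graph.
#' @export
#' @examples
#' g <- igraph::make_graph(~ a - b, b - c)  # path, unit distances
#' global_efficiency(g)                     # (1 + 1 + 1/2) / 3
global_efficiency <- function(net) {
  g <- .as_graph(net)
  n <- igraph::vcount(g)
  if (n < 2) stop("global efficiency needs at least 2 nodes")
  if (igraph::ecount(g) == 0) return(0)
  D <- igraph::distances(g, weights = .edge_distances(g))
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency of a node
#'
#' Global efficiency of the subgraph induced by the node's neighbors (the
#' node itself excluded). Nodes with fewer than two neighbors have local
#' efficiency 0.
#'
#' @param net a [threshold_network()] result or igraph graph.
#' @param node node name or index.
#' @return Local efficiency of the node.
#' @export
local_efficiency <- function(net, node) {
  g <- .as_graph(net)
  nb <- igraph::neighbors(g, node)
  if (length(nb) < 2) return(0)
  sub <- igraph::induced_subgraph(g, nb)
  global_efficiency(sub)
}

#' Mean local efficiency
#'
#' Mean of [local_efficiency()] over all nodes of the network; the standard
#' segregation companion to [global_efficiency()].
#'
#' @param net a [threshold_network()] result or igraph graph.
#' @return Mean local efficiency.
#' @export
mean_local_efficiency <- function(net) {
  g <- .as_graph(net)
  n <- igraph::vcount(g)
  if (n == 0) stop("empty graph")
  mean(vapply(seq_len(n), function(v) local_efficiency(g, v), numeric(1)))
}

# internal adjacency-based twins of the efficiency metrics (shared with the
# rewiring loop, where building an igraph object per null would dominate);
# unit-tested for equality against the public igraph-based functions
.geff_adj <- function(A) {
  n <- nrow(A)
  if (all(A == 0)) return(0)
  D <- .fw_distances(A)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

.mleff_adj <- function(A) {
  n <- nrow(A)
  vals <- vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] > 0)
    if (length(nb) < 2) return(0)
    .geff_adj(A[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(vals)
}

# One degree-preserving randomization of an edge list: `nswaps` successful
# double-edge swaps; self-loops and duplicate edges are rejected and
# retried. Weights (and any parallel edge attributes) travel with the
# rewired edges, so the weight multiset is preserved exactly.
.double_edge_swap <- function(ends, nswaps, n_nodes, max_tries) {
  m <- nrow(ends)
  adj <- matrix(FALSE, n_nodes, n_nodes)
  adj[ends] <- TRUE
  adj[ends[, c(2, 1), drop = FALSE]] <- TRUE
  done <- 0L
  tries <- 0L
  while (done < nswaps) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("rewiring failed: no legal swap found within the retry budget")
    ij <- sample.int(m, 2)
    e1 <- ends[ij[1], ]
    e2 <- ends[ij[2], ]
    # swap partners; orientation chosen at random
    if (stats::runif(1) < 0.5) e2 <- e2[c(2, 1)]
    new1 <- c(e1[1], e2[2])
    new2 <- c(e2[1], e1[2])
    if (new1[1] == new1[2] || new2[1] == new2[2]) next
    if (adj[new1[1], new1[2]] || adj[new2[1], new2[2]]) next
    if (all(sort(new1) == sort(new2))) next
    adj[e1[1], e1[2]] <- adj[e1[2], e1[1]] <- FALSE
    adj[e2[1], e2[2]] <- adj[e2[2], e2[1]] <- FALSE
    adj[new1[1], new1[2]] <- adj[new1[2], new1[1]] <- TRUE
    adj[new2[1], new2[2]] <- adj[new2[2], new2[1]] <- TRUE
    ends[ij[1], ] <- new1
    ends[ij[2], ] <- new2
    done <- done + 1L
  }
  ends
}

#' Rewired null ensemble of a network
#'
#' Generates degree-preserving randomizations of a thresholded network and
#' records, for each, the empirical/random ratio of global efficiency and of
#' mean local efficiency. Each null is a copy of the network subjected to
#' `floor(E / 2)` successful double-edge swaps (E = edge count); swaps
#' producing self-loops or multi-edges are rejected and retried, and edge
#' weights travel with the swapped edges so that the degree sequence and
#' weight multiset of every null equal the empirical ones exactly.
#'
#' @param net a [threshold_network()] result or weighted igraph graph with
#'   at least 2 edges.
#' @param n_nets number of null networks (10000 in a full analysis; smaller
#'   ensembles give wider confidence intervals).
#' @param rng_seed integer seed; the ensemble is reproducible bit-for-bit.
#' @return An object of class `null_ensemble`: list with `geff_ratio` and
#'   `leff_ratio` vectors (length `n_nets`), the empirical `geff` and
#'   `leff`, `n_nets` and `rng_seed`.
#' @export
rewire_null <- function(net, n_nets = 10000, rng_seed = 1L) {
  g <- .as_graph(net)
  m <- igraph::ecount(g)
  if (m < 2) stop("rewiring needs at least 2 edges")
  set.seed(as.integer(rng_seed))
  n_nodes <- igraph::vcount(g)
  ends <- igraph::as_edgelist(g, names = FALSE)
  dist_e <- .edge_distances(g)
  w_e <- igraph::edge_attr(g, "weight")
  if (is.null(w_e)) w_e <- 1 - dist_e
  w_dist <- 1 - dist_e  # .fw_distances() recovers each edge distance as 1 - A
  adj_of <- function(e) {
    A <- matrix(0, n_nodes, n_nodes)
    A[e] <- w_dist
    A[e[, c(2, 1), drop = FALSE]] <- w_dist
    A
  }
  geff_emp <- .geff_adj(adj_of(ends))
  leff_emp <- .mleff_adj(adj_of(ends))
  nswaps <- floor(m / 2)
  geff_ratio <- leff_ratio <- numeric(n_nets)
  for (k in seq_len(n_nets)) {
    ends_k <- .double_edge_swap(ends, nswaps, n_nodes,
                                max_tries = 200L * nswaps + 200L)
    A_k <- adj_of(ends_k)
    geff_k <- .geff_adj(A_k)
    if (geff_k <= 0) stop("null network with zero global efficiency")
    leff_k <- .mleff_adj(A_k)
    geff_ratio[k] <- geff_emp / geff_k
    leff_ratio[k] <- if (leff_k > 0) leff_emp / leff_k else NA_real_
  }
  structure(list(geff_ratio = geff_ratio, leff_ratio = leff_ratio,
                 geff = geff_emp, leff = leff_emp,
                 n_nets = n_nets, rng_seed = as.integer(rng_seed)),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat("<null_ensemble> ", x$n_nets, " rewired nulls; Geff ratio mean ",
      round(mean(x$geff_ratio), 3), ", Leff ratio mean ",
      round(mean(x$leff_ratio, na.rm = TRUE), 3), "\n", sep = "")
  invisible(x)
}

#' Small-world assessment of null ensembles
#'
#' Summarizes one or more [rewire_null()] ensembles: percentile 95% CI of
#' the empirical/random Geff and mean-Leff ratios, a small-world call (the
#' Leff-ratio CI lies entirely above 1, with the Geff ratio expected around
#' 1), and pairwise network comparisons by CI overlap (no overlap between
#' two 95% CIs is taken as a significant difference).
#'
#' @param ensembles a single `null_ensemble` or a named list of them
#'   (e.g. one per group and threshold).
#' @param ci_level confidence level of the percentile interval.
#' @return list with `summary` (one row per ensemble and metric:
#'   `network, metric, mean, ci_lo, ci_hi, small_world`) and `differences`
#'   (pairwise CI-overlap calls per metric; NULL for a single ensemble).
#' @export
smallworld_assessment <- function(ensembles, ci_level = 0.95) {
  if (inherits(ensembles, "null_ensemble"))
    ensembles <- list(network = ensembles)
  stopifnot(length(ensembles) >= 1, !is.null(names(ensembles)))
  a <- (1 - ci_level) / 2
  rows <- list()
  ci <- list()
  for (nm in names(ensembles)) {
    e <- ensembles[[nm]]
    stopifnot(inherits(e, "null_ensemble"))
    for (metric in c("geff_ratio", "leff_ratio")) {
      v <- e[[metric]]
      q <- stats::quantile(v, c(a, 1 - a), na.rm = TRUE, names = FALSE)
      ci[[paste(nm, metric)]] <- q
      rows[[length(rows) + 1]] <- data.frame(
        network = nm,
        metric = if (metric == "geff_ratio") "Geff" else "Leff",
        mean = mean(v, na.rm = TRUE), ci_lo = q[1], ci_hi = q[2],
        small_world = NA)
    }
  }
  summary <- do.call(rbind, rows)
  # small-world call attaches to the Leff row: CI entirely above 1
  for (nm in names(ensembles)) {
    i <- summary$network == nm & summary$metric == "Leff"
    summary$small_world[i] <- summary$ci_lo[i] > 1
  }
  differences <- NULL
  if (length(ensembles) > 1) {
    nms <- names(ensembles)
    pairs <- utils::combn(nms, 2)
    drows <- list()
    for (j in seq_len(ncol(pairs))) {
      for (metric in c("geff_ratio", "leff_ratio")) {
        c1 <- ci[[paste(pairs[1, j], metric)]]
        c2 <- ci[[paste(pairs[2, j], metric)]]
        drows[[length(drows) + 1]] <- data.frame(
          network_a = pairs[1, j], network_b = pairs[2, j],
          metric = if (metric == "geff_ratio") "Geff" else "Leff",
          significant = ci_nonoverlap(c1, c2))
      }
    }
    differences <- do.call(rbind, drows)
  }
  list(summary = summary, differences = differences)
}

#' Do two confidence intervals fail to overlap?
#'
#' @param ci1,ci2 numeric length-2 vectors `(lo, hi)`.
#' @return TRUE when the intervals are disjoint (significant difference
#'   under the CI-overlap rule).
#' @export
ci_nonoverlap <- function(ci1, ci2) {
  ci1[2] < ci2[1] || ci2[2] < ci1[1]
}
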