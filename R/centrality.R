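# Node centralities, quartile-intersection hub identification, and the
# label-permutation test comparing centralities between groups.

# all-pairs shortest-path distances on a thresholded weighted adjacency
# (distance = 1 - |r| per edge, floored at a tiny positive value);
# vectorized Floyd-Warshall — the matrices here are a few dozen regions
.fw_distances <- function(A) {
  R <- nrow(A)
  D <- matrix(Inf, R, R)
  pos <- A > 0
  D[pos] <- pmax(1 - A[pos], 1e-12)
  diag(D) <- 0
  for (k in seq_len(R)) {
    Dk <- outer(D[, k], D[k, ], "+")
    upd <- Dk < D
    if (any(upd)) D[upd] <- Dk[upd]
  }
  D
}

# connected components from a finite-distance pattern
.components_from_D <- function(D) {
  R <- nrow(D)
  comp <- integer(R)
  cur <- 0L
  for (i in seq_len(R)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    comp[is.finite(D[i, ])] <- cur
  }
  comp
}

# eigenvector centrality on a weighted adjacency matrix; on disconnected
# graphs the dominant component (largest leading eigenvalue) carries the
# eigenvector and all other nodes score 0; max-normalized to [0, 1]
.evc_adj <- function(A, comp = NULL) {
  R <- nrow(A)
  out <- numeric(R)
  if (all(A == 0)) return(out)
  if (is.null(comp)) comp <- .components_from_D(.fw_distances(A))
  best_val <- -Inf
  best_vec <- NULL
  best_idx <- NULL
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    if (length(idx) < 2) next
    e <- eigen(A[idx, idx, drop = FALSE], symmetric = TRUE)
    if (e$values[1] > best_val) {
      best_val <- e$values[1]
      best_vec <- abs(e$vectors[, 1])
      best_idx <- idx
    }
  }
  if (is.null(best_idx)) return(out)
  out[best_idx] <- best_vec / max(best_vec)
  out
}

# centralities from a thresholded weighted adjacency matrix (weights = |r|,
# zero = no edge); the workhorse shared by centralities() and the
# permutation test
.centralities_from_adj <- function(A, metrics = c("Wdg", "Evc", "Clo", "Bet")) {
  R <- nrow(A)
  out <- matrix(0, R, length(metrics),
                dimnames = list(rownames(A), metrics))
  if ("Wdg" %in% metrics) out[, "Wdg"] <- rowSums(A)
  has_edges <- any(A > 0)
  need_D <- any(c("Evc", "Clo") %in% metrics)
  D <- if (has_edges && need_D) .fw_distances(A) else NULL
  if ("Evc" %in% metrics && has_edges)
    out[, "Evc"] <- .evc_adj(A, comp = .components_from_D(D))
  if ("Clo" %in% metrics && has_edges) {
    fin <- is.finite(D)
    diag(fin) <- FALSE
    k <- rowSums(fin)
    Dz <- D
    Dz[!fin] <- 0
    s <- rowSums(Dz)
    out[, "Clo"] <- ifelse(k == 0, 0, (k / s) * (k / (R - 1)))
  }
  if ("Bet" %in% metrics && has_edges) {
    ut <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
    g <- igraph::make_undirected_graph(as.vector(t(ut)), n = R)
    out[, "Bet"] <- igraph::betweenness(g, weights = pmax(1 - A[ut], 1e-12))
  }
  out
}

# critical |r| for a two-tailed p <= level at n subjects: p(r, n) <= level
# iff |r| >= r_crit (p is strictly decreasing in |r|)
.r_crit <- function(n, level) {
  t_crit <- stats::qt(1 - level / 2, df = n - 2)
  sqrt(t_crit^2 / (t_crit^2 + n - 2))
}

# thresholded weighted adjacency from raw values: cor -> p-threshold -> |r|
.adj_from_values <- function(v, level) {
  r <- stats::cor(v)
  A <- abs(r)
  A[A < .r_crit(nrow(v), level)] <- 0
  diag(A) <- 0
  A[is.na(A)] <- 0
  A
}

#' Node centralities of a thresholded network
#'
#' Four per-region centralities: weighted degree `Wdg` (sum of incident
#' `|r|` weights), eigenvector `Evc` (principal eigenvector of the weighted
#' adjacency, max-normalized; on fragmented networks the dominant component
#' carries the eigenvector and other components score 0), closeness `Clo`
#' and betweenness `Bet` (both on shortest paths over distances `1 - |r|`;
#' closeness of a node is the reachable count divided by the summed
#' distances to reachable nodes, scaled by the reachable fraction so that
#' nodes in small fragments are penalized). Isolates score 0 on all four.
#'
#' @param net a [threshold_network()] result.
#' @return A data.frame of class `centrality_table`: `region`, `Wdg`,
#'   `Evc`, `Clo`, `Bet`.
#' @export
centralities <- function(net) {
  stopifnot(inherits(net, "thresholded_network"))
  A <- igraph::as_adjacency_matrix(net$graph, attr = if (igraph::ecount(net$graph) > 0) "weight" else NULL,
                                   sparse = FALSE)
  rownames(A) <- colnames(A) <- net$regions
  m <- .centralities_from_adj(A)
  out <- data.frame(region = net$regions, m, row.names = NULL)
  class(out) <- c("centrality_table", "data.frame")
  out
}

#' Identify the hubs of one network
#'
#' For each centrality metric, takes the `ceiling(quantile * R)` most
#' central regions (ties at the cutoff value are all included) and calls a
#' region a hub when it appears in at least `min_metrics` of the four top
#' sets. The rule is rank-based, so hub calls are invariant to monotone
#' transformations of any single metric.
#'
#' @param table a [centralities()] result (or data.frame with `region` plus
#'   metric columns).
#' @param quantile upper fraction defining "most central" (0.25 = upper
#'   quartile).
#' @param min_metrics minimum number of metrics.
#' @return list of class `hub_result`: `hubs` (character), `membership`
#'   (logical region x metric matrix), `n_metrics` (named integer).
#' @export
identify_hubs <- function(table, quantile = 0.25, min_metrics = 3) {
  stopifnot(is.data.frame(table), nrow(table) > 0, "region" %in% names(table))
  metrics <- setdiff(names(table), "region")
  R <- nrow(table)
  k <- ceiling(quantile * R)
  membership <- sapply(metrics, function(mt) {
    v <- table[[mt]]
    cutoff <- sort(v, decreasing = TRUE)[k]
    v >= cutoff
  })
  rownames(membership) <- table$region
  n_metrics <- rowSums(membership)
  hubs <- table$region[n_metrics >= min_metrics]
  structure(list(hubs = hubs, membership = membership,
                 n_metrics = n_metrics),
            class = "hub_result")
}

#' @export
print.hub_result <- function(x, ...) {
  cat("<hub_result> hubs:",
      if (length(x$hubs)) paste(x$hubs, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Stable hubs across thresholds
#'
#' Intersects the hub calls obtained at each p-threshold: a stable hub is a
#' region that is a hub at every threshold, and each region's hub score is
#' the number of thresholds at which it was a hub.
#'
#' @param hubsets named list (one element per threshold) of [identify_hubs()]
#'   results or character vectors of hub regions.
#' @return list of class `hub_set`: `stable_hubs` (character), `hub_score`
#'   (named integer over all regions seen), `n_thresholds`.
#' @export
stable_hubs <- function(hubsets) {
  if (length(hubsets) == 0) stop("no thresholds supplied")
  hub_lists <- lapply(hubsets, function(h) {
    if (inherits(h, "hub_result")) h$hubs else as.character(h)
  })
  universe <- unique(unlist(c(
    hub_lists,
    lapply(hubsets, function(h)
      if (inherits(h, "hub_result")) rownames(h$membership) else character(0)))))
  score <- stats::setNames(integer(length(universe)), universe)
  for (h in hub_lists) score[h] <- score[h] + 1L
  structure(list(stable_hubs = names(score)[score == length(hub_lists)],
                 hub_score = score,
                 n_thresholds = length(hub_lists)),
            class = "hub_set")
}

#' @export
print.hub_set <- function(x, ...) {
  cat("<hub_set> over", x$n_thresholds, "thresholds; stable:",
      if (length(x$stable_hubs)) paste(x$stable_hubs, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Label-permutation test of group centrality differences
#'
#' Compares each region's centrality between two groups measured on the
#' identical region set (e.g. a control network restricted to the lesioned
#' group's regions). Group labels are permuted without replacement and the
#' whole correlation -> threshold -> centrality pipeline is recomputed
#' inside every permutation, since group membership enters the analysis only
#' through the correlation matrices. The empirical difference is
#' `Diff = C_A - C_B` per (region, metric).
#'
#' By default the p-value is two-sided, the fraction of permuted `|Diff|`
#' at or above the empirical `|Diff|`; `two_sided = FALSE` gives the
#' one-sided count of permuted `Diff` strictly above the empirical one, and
#' `add_one` switches to the (b + 1)/(m + 1) small-sample convention.
#'
#' @param exprA,exprB [expression_matrix()] objects with identical regions.
#' @param level p-value threshold at which the networks are built.
#' @param n_permutations number of label permutations.
#' @param rng_seed integer seed.
#' @param metrics centralities to compare (default all four).
#' @param two_sided two-sided p via `|Diff|` (default) or the one-sided
#'   resampled-greater count.
#' @param add_one use the add-one p convention.
#' @return An object of class `permutation_result`: list with `diff` and
#'   `p` (region x metric matrices), `n_permutations`, `rng_seed`,
#'   `level`, `metrics`.
#' @export
permutation_centrality_test <- function(exprA, exprB, level,
                                        n_permutations = 10000,
                                        rng_seed = 1L,
                                        metrics = c("Wdg", "Evc", "Clo", "Bet"),
                                        two_sided = TRUE,
                                        add_one = FALSE) {
  stopifnot(inherits(exprA, "expression_matrix"),
            inherits(exprB, "expression_matrix"))
  if (!identical(sort(exprA$regions), sort(exprB$regions)))
    stop("groups must share an identical region set; restrict the larger ",
         "network first (see drop_regions)")
  vA <- exprA$values
  vB <- exprB$values[, exprA$regions, drop = FALSE]
  nA <- nrow(vA)
  nB <- nrow(vB)
  if (nA + nB < 8) stop("need at least 8 subjects in total")
  X <- rbind(vA, vB)
  n <- nA + nB
  cent_of <- function(v) .centralities_from_adj(.adj_from_values(v, level),
                                                metrics)
  diff_emp <- cent_of(vA) - cent_of(vB)
  set.seed(as.integer(rng_seed))
  count <- matrix(0, nrow(diff_emp), ncol(diff_emp))
  for (b in seq_len(n_permutations)) {
    perm <- sample.int(n)
    d_b <- cent_of(X[perm[seq_len(nA)], , drop = FALSE]) -
      cent_of(X[perm[(nA + 1):n], , drop = FALSE])
    count <- count +
      if (two_sided) (abs(d_b) >= abs(diff_emp)) else (d_b > diff_emp)
  }
  p <- if (add_one) (count + 1) / (n_permutations + 1)
       else count / n_permutations
  dimnames(p) <- dimnames(diff_emp) <- list(exprA$regions, metrics)
  structure(list(diff = diff_emp, p = p,
                 n_permutations = n_permutations,
                 rng_seed = as.integer(rng_seed),
                 level = level, metrics = metrics),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("<permutation_result> ", nrow(x$diff), " regions x ",
      ncol(x$diff), " metrics, ", x$n_permutations,
      " permutations at p <= ", format(x$level), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.permutation_result <- function(x, ...) {
  data.frame(region = rep(rownames(x$diff), times = ncol(x$diff)),
             metric = rep(colnames(x$diff), each = nrow(x$diff)),
             diff = as.vector(x$diff),
             p = as.vector(x$p))
}
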