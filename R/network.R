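# Correlation-network construction: inter-regional Pearson coefficients with
# exact two-tailed p-values, p-thresholded weighted undirected graphs, and
# the component census of the resulting networks.

#' Two-tailed p-value of a Pearson correlation
#'
#' Exact t-transform: `t = r * sqrt((n - 2) / (1 - r^2))` referred to the t
#' distribution with `n - 2` degrees of freedom, two-tailed. `|r| = 1` gives
#' `p = 0` by convention.
#'
#' @param r correlation coefficient(s), `|r| <= 1`.
#' @param n number of subjects (`n >= 4`).
#' @return p-value(s) in `[0, 1]`, same shape as `r`.
#' @export
#' @examples
#' two_tailed_p(0.6, 9)
two_tailed_p <- function(r, n) {
  if (n < 4) stop("n must be >= 4")
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| must be <= 1")
  r <- pmin(pmax(r, -1), 1)
  p <- rep(0, length(r))
  ok <- !is.na(r) & abs(r) < 1
  t_stat <- r[ok] * sqrt((n - 2) / (1 - r[ok]^2))
  p[ok] <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  p[is.na(r)] <- NA_real_
  if (!is.null(dim(r))) {
    dim(p) <- dim(r)
    dimnames(p) <- dimnames(r)
  }
  p
}

#' Inter-regional Pearson correlation matrix
#'
#' Computes the Pearson correlation coefficient between all unordered pairs
#' of regions across subjects (R regions give `R * (R - 1) / 2`
#' coefficients), together with exact two-tailed p-values. Co-activation is
#' measured across subjects because each animal contributes a single
#' post-mortem measurement per region.
#'
#' @param expr an [expression_matrix()]; typically a single group (see
#'   [subset_group()]). All subjects present are used.
#' @return An object of class `correlation_result`: list with `r` (region x
#'   region, unit diagonal), `p` (two-tailed, diagonal NA), `n` (subjects)
#'   and `regions`.
#' @export
pearson_matrix <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  v <- expr$values
  v <- v[, colSums(is.na(v)) == 0, drop = FALSE]
  n <- nrow(v)
  if (n < 4) stop("need at least 4 subjects, got ", n)
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance region(s): ",
         paste(colnames(v)[sds == 0], collapse = ", "))
  r <- stats::cor(v)
  p <- two_tailed_p(r, n)
  diag(p) <- NA_real_
  structure(list(r = r, p = p, n = n, regions = colnames(v)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  R <- length(x$regions)
  cat("<correlation_result> ", R, " regions, ", R * (R - 1) / 2,
      " coefficients, n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Threshold a correlation matrix into a weighted network
#'
#' Retains the region pairs whose two-tailed p-value satisfies `p <= level`
#' (non-strict, matching the usual "p <= 0.05" phrasing) and builds a
#' weighted undirected graph. Edge weight is `|r|` (negative correlations
#' enter as absolute values), the signed coefficient is preserved as an edge
#' attribute, and a distance view `1 - |r|` is attached for shortest-path
#' metrics. All regions remain as nodes, so regions with no surviving edge
#' appear as isolates.
#'
#' @param corr a [pearson_matrix()] result.
#' @param level p-value threshold.
#' @param catalogue optional region catalogue; when supplied, the `system`
#'   of each region is attached as a node attribute.
#' @return An object of class `thresholded_network`: list with the igraph
#'   `graph`, the `level`, subject count `n`, the full signed correlation
#'   matrix `r_full` and `regions`.
#' @export
threshold_network <- function(corr, level, catalogue = NULL) {
  stopifnot(inherits(corr, "correlation_result"))
  r <- corr$r
  p <- corr$p
  R <- length(corr$regions)
  keep <- which(upper.tri(p) & !is.na(p) & p <= level, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = R, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = corr$regions)
  if (!is.null(catalogue)) {
    validate_region_catalogue(catalogue)
    sys <- catalogue$system[match(corr$regions, catalogue$abbreviation)]
    g <- igraph::set_vertex_attr(g, "system", value = sys)
  }
  if (nrow(keep) > 0) {
    rv <- r[keep]
    g <- igraph::add_edges(g, t(keep))
    g <- igraph::set_edge_attr(g, "signed_r", value = rv)
    g <- igraph::set_edge_attr(g, "weight", value = abs(rv))
    g <- igraph::set_edge_attr(g, "distance", value = 1 - abs(rv))
  }
  structure(list(graph = g, level = level, n = corr$n,
                 r_full = r, regions = corr$regions),
            class = "thresholded_network")
}

#' @export
print.thresholded_network <- function(x, ...) {
  cat("<thresholded_network> p <= ", format(x$level), ": ",
      length(x$regions), " nodes, ", igraph::ecount(x$graph),
      " edges (n = ", x$n, " subjects)\n", sep = "")
  invisible(x)
}

#' Component census of a thresholded network
#'
#' Counts the connected components with at least two nodes and, separately,
#' the isolated (degree-0) regions.
#'
#' @param net a [threshold_network()] result.
#' @return list with `sizes` (multi-node component sizes, decreasing),
#'   `n_components` and `n_isolates`.
#' @export
component_census <- function(net) {
  stopifnot(inherits(net, "thresholded_network"))
  comp <- igraph::components(net$graph)
  sizes <- sort(comp$csize[comp$csize >= 2], decreasing = TRUE)
  list(sizes = as.integer(sizes),
       n_components = length(sizes),
       n_isolates = as.integer(sum(comp$csize == 1)))
}
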