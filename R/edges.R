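# Edge-level comparison of two same-size networks: Fisher-Z normalization,
# KS test on edge-coefficient distributions, and per-edge difference
# z-scores (dC) with ownership/hub classification.

#' Fisher Z transformation
#'
#' `Z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`; variance-stabilizing
#' transform of a Pearson coefficient. `|r| >= 1` is rejected.
#'
#' @param r correlation coefficient(s), `|r| < 1`.
#' @return transformed value(s).
#' @export
#' @examples
#' fisher_z(0.5)  # 0.5 * log(3)
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) stop("|r| must be < 1")
  atanh(r)
}

#' KS test on the edge distributions of two networks
#'
#' Two-sample Kolmogorov-Smirnov test comparing the Fisher-Z-transformed
#' signed correlation coefficients of the edges surviving the threshold in
#' each network. D is the maximum ECDF gap; the p-value uses the asymptotic
#' two-sample Kolmogorov distribution.
#'
#' @param netA,netB [threshold_network()] results (both nonempty).
#' @return list with `D`, `p`, and the two edge counts `nA`, `nB`.
#' @export
ks_edge_distributions <- function(netA, netB) {
  stopifnot(inherits(netA, "thresholded_network"),
            inherits(netB, "thresholded_network"))
  zA <- fisher_z(igraph::E(netA$graph)$signed_r)
  zB <- fisher_z(igraph::E(netB$graph)$signed_r)
  if (length(zA) == 0 || length(zB) == 0)
    stop("both networks must have at least one edge")
  kt <- suppressWarnings(stats::ks.test(zA, zB, exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value),
       nA = length(zA), nB = length(zB))
}

#' Per-edge difference z-scores between two networks
#'
#' For every region pair retained in at least one of the two networks,
#' computes the z-score of the difference between the groups' Fisher-Z
#' coefficients:
#' `dC = (Z_A - Z_B) / sqrt(1 / (df_A - 3) + 1 / (df_B - 3))`,
#' where `df` is by default the group's subject count n (so that the
#' Fisher-Z variance is the textbook `1 / (n - 3)`); `df = "n-2"` uses the
#' correlation degrees of freedom instead. Cells where an edge survives in
#' one network only take, on the absent side, the unthresholded coefficient
#' by default (`absent = "zero"` treats it as exactly 0 instead; treating a
#' sub-threshold coefficient as 0 inflates dC). Cells with `|dC|` above
#' `z_cutoff` are flagged significant and assigned to the owner group (the
#' larger Z); when hub sets are supplied each significant cell is annotated
#' with whether it touches one of the owner group's hubs.
#'
#' @param netA,netB [threshold_network()] results on identical node sets.
#' @param nA,nB subject counts of the two groups (default: taken from the
#'   networks).
#' @param z_cutoff significance cutoff on `|dC|`.
#' @param absent `"unthresholded"` (default) or `"zero"`; coefficient used
#'   for the network in which the edge did not survive.
#' @param df `"n"` (default) or `"n-2"`.
#' @param hubsA,hubsB optional character vectors of hub regions of each
#'   group at this threshold.
#' @return An object of class `edge_diff_result`: a data.frame with one row
#'   per compared cell (`region_a, region_b, in_A, in_B, rA, rB, zA, zB,
#'   dC, significant, owner, owner_is_hub_edge`), with attributes `nA`,
#'   `nB`, `z_cutoff`, `absent`.
#' @export
edge_diff_zscores <- function(netA, netB, nA = netA$n, nB = netB$n,
                              z_cutoff = 2.0,
                              absent = c("unthresholded", "zero"),
                              df = c("n", "n-2"),
                              hubsA = NULL, hubsB = NULL) {
  stopifnot(inherits(netA, "thresholded_network"),
            inherits(netB, "thresholded_network"))
  absent <- match.arg(absent)
  df <- match.arg(df)
  if (!identical(netA$regions, netB$regions))
    stop("networks must share an identical node set (same regions, same order)")
  dfA <- if (df == "n") nA else nA - 2
  dfB <- if (df == "n") nB else nB - 2
  if (dfA <= 3 || dfB <= 3) stop("df - 3 must be positive in both groups")
  regions <- netA$regions
  R <- length(regions)
  maskA <- igraph::as_adjacency_matrix(netA$graph, sparse = FALSE) > 0
  maskB <- igraph::as_adjacency_matrix(netB$graph, sparse = FALSE) > 0
  support <- which(upper.tri(maskA) & (maskA | maskB), arr.ind = TRUE)
  if (nrow(support) == 0) {
    out <- data.frame(region_a = character(), region_b = character(),
                      in_A = logical(), in_B = logical(),
                      rA = numeric(), rB = numeric(),
                      zA = numeric(), zB = numeric(), dC = numeric(),
                      significant = logical(), owner = character(),
                      owner_is_hub_edge = logical())
  } else {
    in_A <- maskA[support]
    in_B <- maskB[support]
    rA <- ifelse(in_A | absent == "unthresholded", netA$r_full[support], 0)
    rB <- ifelse(in_B | absent == "unthresholded", netB$r_full[support], 0)
    zA <- fisher_z(rA)
    zB <- fisher_z(rB)
    se <- sqrt(1 / (dfA - 3) + 1 / (dfB - 3))
    dC <- (zA - zB) / se
    significant <- abs(dC) > z_cutoff
    owner <- ifelse(zA > zB, "A", "B")
    ra_names <- regions[support[, 1]]
    rb_names <- regions[support[, 2]]
    owner_is_hub_edge <- rep(NA, length(owner))
    if (!is.null(hubsA) || !is.null(hubsB)) {
      hubsA <- as.character(hubsA)
      hubsB <- as.character(hubsB)
      owner_is_hub_edge <- mapply(function(a, b, o) {
        h <- if (o == "A") hubsA else hubsB
        a %in% h || b %in% h
      }, ra_names, rb_names, owner, USE.NAMES = FALSE)
    }
    out <- data.frame(region_a = ra_names, region_b = rb_names,
                      in_A = in_A, in_B = in_B,
                      rA = rA, rB = rB, zA = zA, zB = zB, dC = dC,
                      significant = significant, owner = owner,
                      owner_is_hub_edge = owner_is_hub_edge)
  }
  attr(out, "nA") <- nA
  attr(out, "nB") <- nB
  attr(out, "z_cutoff") <- z_cutoff
  attr(out, "absent") <- absent
  class(out) <- c("edge_diff_result", "data.frame")
  out
}

#' Summarize significant edge differences
#'
#' Counts the significant cells of an [edge_diff_zscores()] result: total,
#' per owner group, and per owner group touching that group's hubs.
#'
#' @param result an `edge_diff_result`.
#' @param hubsA,hubsB character vectors of the two groups' hub regions at
#'   the same threshold (optional if already annotated in `result`).
#' @return list with `n_significant`, `n_owner_A`, `n_owner_B`,
#'   `n_owner_A_hub`, `n_owner_B_hub`.
#' @export
classify_significant <- function(result, hubsA = NULL, hubsB = NULL) {
  stopifnot(inherits(result, "edge_diff_result"))
  sig <- result[result$significant, , drop = FALSE]
  hub_edge <- sig$owner_is_hub_edge
  if ((!is.null(hubsA) || !is.null(hubsB)) || all(is.na(hub_edge))) {
    hubsA <- as.character(hubsA)
    hubsB <- as.character(hubsB)
    hub_edge <- mapply(function(a, b, o) {
      h <- if (o == "A") hubsA else hubsB
      a %in% h || b %in% h
    }, sig$region_a, sig$region_b, sig$owner, USE.NAMES = FALSE)
    if (length(hub_edge) == 0) hub_edge <- logical(0)
  }
  list(n_significant = nrow(sig),
       n_owner_A = sum(sig$owner == "A"),
       n_owner_B = sum(sig$owner == "B"),
       n_owner_A_hub = sum(hub_edge & sig$owner == "A"),
       n_owner_B_hub = sum(hub_edge & sig$owner == "B"))
}
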