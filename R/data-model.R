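#' Construct an expression matrix
#'
#' Container for subject-by-region expression densities (e.g. pCREB-positive
#' nuclei per mm^2) with one group label per subject. Groups may cover
#' different region sets (a lesioned group typically lacks the damaged
#' regions): within a group every region column must be either fully observed
#' or entirely absent (all NA); partially missing cells are rejected — no
#' imputation is performed.
#'
#' @param values numeric matrix, rows = subjects (rownames used as subject
#'   identifiers), columns = regions (colnames required).
#' @param group character or factor, one label per subject (row).
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `group` (character) and `regions`.
#' @export
#' @examples
#' v <- matrix(rexp(24, 1 / 1000), 6, 4,
#'             dimnames = list(paste0("s", 1:6), c("IL", "PrL", "RSC", "Por")))
#' em <- expression_matrix(v, rep(c("SHAM", "dHPC"), each = 3))
expression_matrix <- function(values, group) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(colnames(values)))
    stop("values must have region column names")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("subj", seq_len(nrow(values)))
  group <- as.character(group)
  if (length(group) != nrow(values))
    stop("group must have one label per subject (row)")
  for (g in unique(group)) {
    sub <- values[group == g, , drop = FALSE]
    if (nrow(sub) < 4)
      stop("group ", g, " has fewer than 4 subjects")
    n_na <- colSums(is.na(sub))
    partial <- n_na > 0 & n_na < nrow(sub)
    if (any(partial))
      stop("missing cells in group ", g, " for region(s): ",
           paste(colnames(sub)[partial], collapse = ", "))
    obs <- sub[, n_na == 0, drop = FALSE]
    if (any(!is.finite(obs)))
      stop("non-finite density values in group ", g)
    if (any(obs < 0))
      stop("negative density values in group ", g)
  }
  structure(list(values = values, group = group, regions = colnames(values)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$values), " subjects x ",
      ncol(x$values), " regions\n", sep = "")
  tab <- table(x$group)
  cat("groups:", paste(names(tab), tab, sep = " n=", collapse = ", "), "\n")
  invisible(x)
}

#' Extract one group from an expression matrix
#'
#' Returns the subjects of a single group, with region columns not measured
#' in that group (all-NA columns) removed.
#'
#' @param expr an [expression_matrix()].
#' @param group group label to keep.
#' @return An `expression_matrix` containing only that group.
#' @export
subset_group <- function(expr, group) {
  stopifnot(inherits(expr, "expression_matrix"))
  keep <- expr$group == group
  if (!any(keep)) stop("no subjects in group ", group)
  v <- expr$values[keep, , drop = FALSE]
  v <- v[, colSums(is.na(v)) == 0, drop = FALSE]
  expression_matrix(v, expr$group[keep])
}

#' Drop flagged regions from an expression matrix
#'
#' Restricts an expression matrix to regions not flagged in the catalogue
#' (by default, regions outside the dorsal hippocampus). Used to derive a
#' control network on the lesioned group's node set, e.g. SHAM-nH from SHAM.
#' Pearson correlations among the surviving regions are unaffected because
#' they are computed pairwise.
#'
#' @param expr an [expression_matrix()].
#' @param catalogue region catalogue with an `in_dorsal_hippocampus` flag.
#' @param flag name of the logical catalogue column marking regions to drop.
#' @return An `expression_matrix` on the reduced region set.
#' @export
drop_regions <- function(expr, catalogue = default_region_catalogue(),
                         flag = "in_dorsal_hippocampus") {
  stopifnot(inherits(expr, "expression_matrix"))
  validate_region_catalogue(catalogue)
  flagged <- catalogue$abbreviation[isTRUE_vec(catalogue[[flag]])]
  keep <- !(expr$regions %in% flagged)
  if (all(keep)) return(expr)
  expression_matrix(expr$values[, keep, drop = FALSE], expr$group)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Construct a behavior table
#'
#' One total freezing time (seconds) per subject, with a group label.
#'
#' @param subjects subject identifiers.
#' @param group one label per subject.
#' @param freezing_s freezing time in seconds, all `>= 0`.
#' @return A data.frame of class `behavior_table` with columns `subject`,
#'   `group`, `freezing_s`.
#' @export
behavior_table <- function(subjects, group, freezing_s) {
  if (length(subjects) == 0) stop("no rows")
  freezing_s <- as.numeric(freezing_s)
  if (anyNA(freezing_s)) stop("non-numeric or missing freezing time")
  if (any(freezing_s < 0)) stop("negative freezing time")
  df <- data.frame(subject = as.character(subjects),
                   group = as.character(group),
                   freezing_s = freezing_s,
                   stringsAsFactors = FALSE)
  class(df) <- c("behavior_table", "data.frame")
  df
}

#' Analysis configuration
#'
#' Bundles the tunable parameters of the pipeline: the ordered p-value
#' thresholds applied to the correlation matrices, the number of resamples
#' for bootstrap/permutation/null ensembles, the hub rule (upper quantile and
#' minimum number of metrics), and the edge-difference z-score cutoff.
#'
#' @param thresholds strictly decreasing p-levels in (0, 1).
#' @param n_resamples resamples for bootstrap, permutation and null ensembles.
#' @param rng_seed integer seed.
#' @param hub_quantile fraction defining the "most central" set per metric.
#' @param hub_min_metrics metrics a region must appear in to be called a hub.
#' @param z_cutoff cutoff on `|dC|` for a significant edge difference.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(thresholds = c(0.05, 0.025, 0.01),
                            n_resamples = 10000,
                            rng_seed = 1L,
                            hub_quantile = 0.25,
                            hub_min_metrics = 3,
                            z_cutoff = 2.0) {
  if (any(thresholds <= 0) || any(thresholds >= 1))
    stop("thresholds must lie in (0, 1)")
  if (any(diff(thresholds) >= 0))
    stop("thresholds must be strictly decreasing")
  if (n_resamples < 1) stop("n_resamples must be >= 1")
  if (hub_quantile <= 0 || hub_quantile >= 1)
    stop("hub_quantile must lie in (0, 1)")
  structure(list(thresholds = thresholds, n_resamples = n_resamples,
                 rng_seed = as.integer(rng_seed),
                 hub_quantile = hub_quantile,
                 hub_min_metrics = hub_min_metrics,
                 z_cutoff = z_cutoff),
            class = "analysis_config")
}
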