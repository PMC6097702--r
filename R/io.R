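# Readers for the tabular layouts deposited with co-activation studies
# (CSV exports of the supplementary spreadsheets) and writers for networks
# and result tables. All CSVs are UTF-8, comma-delimited, "." decimal.

.header_match <- function(headers, synonyms) {
  h <- tolower(gsub("[^a-z0-9]", "", tolower(headers)))
  s <- gsub("[^a-z0-9]", "", tolower(synonyms))
  idx <- which(h %in% s)
  if (length(idx) == 0) NA_integer_ else idx[1]
}

#' Read a subject-by-region expression table
#'
#' Accepts both the long layout (`subject, group, region, value`) and the
#' wide layout (`subject, group`, one column per region), auto-detected from
#' the header. Region labels are matched case-insensitively against the
#' catalogue and reported under their canonical abbreviation. Unknown
#' regions, duplicated (subject, region) cells and missing cells are
#' rejected; no imputation is performed.
#'
#' @param path CSV file.
#' @param catalogue region catalogue (see [default_region_catalogue()]).
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, catalogue = default_region_catalogue()) {
  validate_region_catalogue(catalogue)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("no rows in ", path)
  i_subj <- .header_match(names(df), c("subject", "subject_id", "id", "animal"))
  i_grp <- .header_match(names(df), c("group", "condition", "treatment"))
  if (is.na(i_subj) || is.na(i_grp))
    stop("expression file must have subject and group columns")
  i_reg <- .header_match(names(df), c("region", "brain_region", "area"))
  i_val <- .header_match(names(df), c("value", "density", "pcreb",
                                      "nuclei_density", "expression"))
  if (!is.na(i_reg)) {
    # long layout
    if (is.na(i_val)) stop("long layout needs a value/density column")
    region <- match_regions(df[[i_reg]], catalogue)
    val <- suppressWarnings(as.numeric(df[[i_val]]))
    if (anyNA(val)) stop("non-numeric expression value")
    subj <- as.character(df[[i_subj]])
    key <- paste(subj, region, sep = "\r")
    if (anyDuplicated(key))
      stop("duplicate (subject, region) cell(s): ",
           paste(utils::head(unique(sub("\r", "/", key[duplicated(key)])), 3),
                 collapse = ", "))
    subjects <- unique(subj)
    grp_of <- df[[i_grp]][!duplicated(subj)]
    regions <- intersect(catalogue$abbreviation, unique(region))
    m <- matrix(NA_real_, length(subjects), length(regions),
                dimnames = list(subjects, regions))
    m[cbind(match(subj, subjects), match(region, regions))] <- val
    expression_matrix(m, grp_of)
  } else {
    # wide layout: every non-subject, non-group column is a region
    reg_cols <- setdiff(seq_along(df), c(i_subj, i_grp))
    if (length(reg_cols) == 0) stop("no region columns found")
    region <- match_regions(names(df)[reg_cols], catalogue)
    m <- as.matrix(df[reg_cols])
    if (!is.numeric(m)) {
      m <- apply(df[reg_cols], 2, function(x) suppressWarnings(as.numeric(x)))
      if (any(is.na(m) & !is.na(as.matrix(df[reg_cols]))))
        stop("non-numeric expression value")
    }
    dimnames(m) <- list(as.character(df[[i_subj]]), region)
    expression_matrix(m, df[[i_grp]])
  }
}

#' Read a behavior table
#'
#' Expects columns for subject, group and total freezing time (header
#' synonyms such as "Freezing", "Total Freezing Time", "freezing_s" are
#' accepted). Negative or non-numeric freezing values are rejected.
#'
#' @param path CSV file.
#' @return A [behavior_table()].
#' @export
read_behavior <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("no rows in ", path)
  i_subj <- .header_match(names(df), c("subject", "subject_id", "id", "animal"))
  i_grp <- .header_match(names(df), c("group", "condition", "treatment"))
  i_frz <- .header_match(names(df), c("freezing", "freezing_s", "freezing_time",
                                      "total_freezing_time", "totalfreezing",
                                      "freezing (s)"))
  if (is.na(i_subj) || is.na(i_grp) || is.na(i_frz))
    stop("behavior file must have subject, group and freezing columns")
  frz <- suppressWarnings(as.numeric(df[[i_frz]]))
  if (anyNA(frz)) stop("non-numeric freezing time")
  behavior_table(df[[i_subj]], df[[i_grp]], frz)
}

#' Write an expression matrix (long layout)
#'
#' Inverse of [read_expression()]: writes `subject, group, region, value`
#' rows so that reading the file back reproduces the matrix.
#'
#' @param expr an [expression_matrix()].
#' @param path output CSV path.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "expression_matrix"))
  v <- expr$values
  long <- data.frame(
    subject = rep(rownames(v), times = ncol(v)),
    group = rep(expr$group, times = ncol(v)),
    region = rep(colnames(v), each = nrow(v)),
    value = as.vector(v))
  long <- long[!is.na(long$value), ]
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Write a behavior table
#'
#' @param bt a [behavior_table()].
#' @param path output CSV path.
#' @export
write_behavior <- function(bt, path) {
  utils::write.csv(as.data.frame(bt), path, row.names = FALSE)
  invisible(path)
}

#' Write a thresholded network to disk
#'
#' `"edgelist"` writes one CSV row per edge (`region_a, region_b, weight,
#' signed_r`; header-only for an empty graph). `"graphml"` writes GraphML
#' carrying the node attributes (`name`, `system` when available) and the
#' edge attributes (`weight`, `signed_r`, `distance`); re-reading with
#' [igraph::read_graph()] reproduces the graph.
#'
#' @param net a [threshold_network()] result.
#' @param path output file path.
#' @param format `"edgelist"` or `"graphml"`.
#' @export
write_network <- function(net, path, format = c("edgelist", "graphml")) {
  stopifnot(inherits(net, "thresholded_network"))
  format <- match.arg(format)
  if (format == "edgelist") {
    el <- network_edges(net)
    utils::write.csv(el, path, row.names = FALSE)
  } else {
    igraph::write_graph(net$graph, path, format = "graphml")
  }
  invisible(path)
}

#' Edge table of a thresholded network
#'
#' @param net a [threshold_network()] result.
#' @return data.frame with columns `region_a`, `region_b`, `weight`,
#'   `signed_r` (zero rows for an empty graph).
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "thresholded_network"))
  g <- net$graph
  if (igraph::ecount(g) == 0)
    return(data.frame(region_a = character(), region_b = character(),
                      weight = numeric(), signed_r = numeric()))
  ends <- igraph::as_edgelist(g)
  data.frame(region_a = ends[, 1], region_b = ends[, 2],
             weight = igraph::E(g)$weight,
             signed_r = igraph::E(g)$signed_r)
}

#' Write a set of result tables as CSV reports
#'
#' Each element of `tables` (data.frame or coercible) is written to
#' `<dir>/<name>.csv` with its column order preserved.
#'
#' @param tables named list of result tables.
#' @param dir output directory (created if absent).
#' @return invisibly, the written paths.
#' @export
write_report <- function(tables, dir) {
  stopifnot(is.list(tables), !is.null(names(tables)), all(nzchar(names(tables))))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(as.data.frame(tables[[nm]]), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
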