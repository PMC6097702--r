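# End-to-end orchestration: correlations -> thresholded networks ->
# component census -> small-world assessment -> centralities, hubs and
# stable hubs -> permutation comparison -> edge comparison -> behavior
# statistics, with CSV reports and a hash manifest.

# One global seed expands into independent per-stage seeds so that
# disabling a stage does not perturb the randomness of the others.
.stage_seed <- function(seed, stage) {
  offsets <- c(nulls = 101L, permutation = 211L, behavior = 307L,
               expression = 401L, simulate = 503L)
  (as.integer(seed) * 1009L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full co-activation analysis
#'
#' Executes the complete workflow on a control and a lesioned expression
#' group (plus an optional behavior table): inter-regional Pearson
#' correlations; thresholded networks at each configured p-level for the
#' control group, the control group restricted to the lesioned group's
#' region set, and the lesioned group; component census; rewired-null
#' small-world assessment; centralities, per-threshold hubs and stable
#' hubs; label-permutation centrality comparison (restricted control vs
#' lesioned); Fisher-Z edge comparison with KS test and dC z-scores; and
#' bootstrap behavioral statistics. All result tables are written as CSVs
#' into `out_dir` together with an md5 manifest.
#'
#' @param exprA [expression_matrix()] of the control group (full region set).
#' @param exprB [expression_matrix()] of the lesioned group (possibly a
#'   region subset).
#' @param behavior optional [behavior_table()].
#' @param config an [analysis_config()].
#' @param out_dir output directory; NULL skips writing.
#' @param catalogue region catalogue used for node metadata and for
#'   restricting `exprA` to `exprB`'s region set.
#' @param n_null_nets,n_permutations,n_bootstrap override
#'   `config$n_resamples` per stage (e.g. to trade precision for runtime).
#' @return An object of class `pipeline_run`: list with `networks` (per
#'   group and threshold), `census`, `smallworld`, `centralities`, `hubs`,
#'   `stable_hubs`, `permutation`, `edges`, `behavior`, `config`,
#'   `manifest` (data.frame of written files and md5 hashes, when
#'   `out_dir` is used).
#' @export
run_full <- function(exprA, exprB, behavior = NULL,
                     config = analysis_config(), out_dir = NULL,
                     catalogue = default_region_catalogue(),
                     n_null_nets = config$n_resamples,
                     n_permutations = config$n_resamples,
                     n_bootstrap = config$n_resamples) {
  stopifnot(inherits(exprA, "expression_matrix"),
            inherits(exprB, "expression_matrix"),
            inherits(config, "analysis_config"))
  stage <- "correlation"
  res <- tryCatch({
    groupA <- unique(exprA$group)[1]
    groupB <- unique(exprB$group)[1]
    nameAnh <- paste0(groupA, "-nH")
    exprAnh <- expression_matrix(
      exprA$values[, intersect(exprA$regions, exprB$regions), drop = FALSE],
      exprA$group)
    corr <- list(pearson_matrix(exprA), pearson_matrix(exprAnh),
                 pearson_matrix(exprB))
    names(corr) <- c(groupA, nameAnh, groupB)

    stage <- "threshold"
    networks <- list()
    census <- list()
    for (g in names(corr)) {
      for (lv in config$thresholds) {
        key <- paste(g, lv, sep = "@")
        networks[[key]] <- threshold_network(corr[[g]], lv, catalogue)
        census[[key]] <- component_census(networks[[key]])
      }
    }

    stage <- "smallworld"
    ens <- list()
    for (key in names(networks)) {
      # a near-empty network (possible at the strictest threshold) admits
      # no rewiring null; it is reported without a small-world call
      if (igraph::ecount(networks[[key]]$graph) >= 2)
        ens[[key]] <- rewire_null(networks[[key]], n_nets = n_null_nets,
                                  rng_seed = .stage_seed(config$rng_seed,
                                                         "nulls"))
    }
    sw <- if (length(ens) > 0) smallworld_assessment(ens)
          else list(summary = NULL, differences = NULL)

    stage <- "centrality"
    cent <- lapply(networks, centralities)
    hubs <- lapply(cent, identify_hubs, quantile = config$hub_quantile,
                   min_metrics = config$hub_min_metrics)
    stable <- list()
    for (g in names(corr)) {
      keys <- paste(g, config$thresholds, sep = "@")
      stable[[g]] <- stable_hubs(stats::setNames(hubs[keys],
                                                 config$thresholds))
    }

    stage <- "permutation"
    perm <- list()
    for (lv in config$thresholds) {
      perm[[as.character(lv)]] <- permutation_centrality_test(
        exprAnh, exprB, level = lv, n_permutations = n_permutations,
        rng_seed = .stage_seed(config$rng_seed, "permutation"))
    }

    stage <- "edge comparison"
    edges <- list()
    for (lv in config$thresholds) {
      kA <- paste(nameAnh, lv, sep = "@")
      kB <- paste(groupB, lv, sep = "@")
      netA <- networks[[kA]]
      netB <- networks[[kB]]
      ks <- ks_edge_distributions(netA, netB)
      ed <- edge_diff_zscores(netA, netB, z_cutoff = config$z_cutoff,
                              hubsA = hubs[[kA]]$hubs,
                              hubsB = hubs[[kB]]$hubs)
      edges[[as.character(lv)]] <-
        list(ks = ks, diff = ed,
             counts = classify_significant(ed))
    }

    stage <- "behavior"
    behav <- NULL
    if (!is.null(behavior)) {
      seed_b <- .stage_seed(config$rng_seed, "behavior")
      f <- bootstrap_p(oneway_F, behavior, n_resamples = n_bootstrap,
                       rng_seed = seed_b)
      pt <- pairwise_t_bootstrap(behavior, n_resamples = n_bootstrap,
                                 rng_seed = seed_b)
      groups <- unique(behavior$group)
      pairs <- utils::combn(groups, 2)
      eff <- lapply(seq_len(ncol(pairs)), function(j) {
        a <- behavior$freezing_s[behavior$group == pairs[1, j]]
        b <- behavior$freezing_s[behavior$group == pairs[2, j]]
        ks <- ks_two_sample(a, b)
        data.frame(group_a = pairs[1, j], group_b = pairs[2, j],
                   cohens_d = cohens_d(a, b), ks_D = ks$D, ks_p = ks$p)
      })
      behav <- list(anova = f, pairwise = pt, effects = do.call(rbind, eff))
    }

    list(networks = networks, census = census, smallworld = sw,
         centralities = cent, hubs = hubs, stable_hubs = stable,
         permutation = perm, edges = edges, behavior = behav,
         config = config)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(out_dir)) {
    tables <- .run_full_tables(res)
    paths <- write_report(tables, out_dir)
    for (key in names(res$networks))
      write_network(res$networks[[key]],
                    file.path(out_dir, paste0("network_", gsub("@", "_p", key),
                                              ".csv")))
    files <- list.files(out_dir, full.names = TRUE)
    res$manifest <- data.frame(file = basename(files),
                               md5 = unname(tools::md5sum(files)))
  }
  class(res) <- "pipeline_run"
  res
}

# flatten a pipeline_run into the CSV report tables
.run_full_tables <- function(res) {
  census <- do.call(rbind, lapply(names(res$census), function(k) {
    cc <- res$census[[k]]
    data.frame(network = k, n_components = cc$n_components,
               n_isolates = cc$n_isolates,
               component_sizes = paste(cc$sizes, collapse = "+"))
  }))
  cent <- do.call(rbind, lapply(names(res$centralities), function(k)
    cbind(network = k, res$centralities[[k]])))
  hubs <- do.call(rbind, lapply(names(res$hubs), function(k) {
    h <- res$hubs[[k]]
    data.frame(network = k, region = rownames(h$membership),
               n_metrics = h$n_metrics,
               is_hub = rownames(h$membership) %in% h$hubs)
  }))
  stable <- do.call(rbind, lapply(names(res$stable_hubs), function(g) {
    s <- res$stable_hubs[[g]]
    data.frame(group = g, region = names(s$hub_score),
               hub_score = as.integer(s$hub_score),
               stable = names(s$hub_score) %in% s$stable_hubs)
  }))
  perm <- do.call(rbind, lapply(names(res$permutation), function(lv)
    cbind(level = lv, as.data.frame(res$permutation[[lv]]))))
  edge_diff <- do.call(rbind, lapply(names(res$edges), function(lv)
    cbind(level = lv, as.data.frame(res$edges[[lv]]$diff))))
  edge_summary <- do.call(rbind, lapply(names(res$edges), function(lv) {
    e <- res$edges[[lv]]
    data.frame(level = lv, ks_D = e$ks$D, ks_p = e$ks$p,
               n_significant = e$counts$n_significant,
               n_owner_A = e$counts$n_owner_A,
               n_owner_B = e$counts$n_owner_B,
               n_owner_A_hub = e$counts$n_owner_A_hub,
               n_owner_B_hub = e$counts$n_owner_B_hub)
  }))
  out <- list(component_census = census, centralities = cent, hubs = hubs,
              stable_hubs = stable, smallworld = res$smallworld$summary,
              permutation = perm, edge_differences = edge_diff,
              edge_summary = edge_summary)
  if (!is.null(res$smallworld$differences))
    out$smallworld_differences <- res$smallworld$differences
  if (!is.null(res$behavior)) {
    out$behavior_pairwise <- res$behavior$pairwise
    out$behavior_effects <- res$behavior$effects
    out$behavior_anova <- data.frame(F = res$behavior$anova$statistic,
                                     p = res$behavior$anova$p,
                                     n_resamples = res$behavior$anova$n_resamples)
  }
  out
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run> ", length(x$networks), " networks (",
      paste(format(x$config$thresholds), collapse = "/"),
      " thresholds)\n", sep = "")
  for (g in names(x$stable_hubs)) {
    s <- x$stable_hubs[[g]]$stable_hubs
    cat("  stable hubs [", g, "]: ",
        if (length(s)) paste(s, collapse = ", ") else "(none)", "\n", sep = "")
  }
  invisible(x)
}
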