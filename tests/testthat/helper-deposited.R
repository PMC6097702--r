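# Access to CSV exports of the study's deposited supplementary spreadsheets.
# The package does not ship these data; to run the checks that reproduce the
# published numbers, export the deposited sheets to CSV (long or wide
# layout, see read_expression/read_behavior) and place them under
# inst/extdata/ before installing:
#   s2_expression.csv  - pCREB densities by subject, group and region
#   s1_behavior.csv    - conditioning-cohort freezing times
#   s4_behavior.csv    - double-lesion-cohort freezing times
deposited_path <- function(name) {
  p <- system.file("extdata", name, package = "coactnet")
  if (nzchar(p)) p else file.path("inst", "extdata", name)
}

# the three standard networks (control, restricted control, lesioned) from
# a deposited-style expression table
deposited_networks <- function(path, level) {
  expr <- read_expression(path)
  groups <- unique(expr$group)
  ctrl <- subset_group(expr, groups[1])
  les <- subset_group(expr, groups[2])
  ctrl_nh <- drop_regions(ctrl)
  list(ctrl = threshold_network(pearson_matrix(ctrl), level),
       ctrl_nh = threshold_network(pearson_matrix(ctrl_nh), level),
       les = threshold_network(pearson_matrix(les), level))
}
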