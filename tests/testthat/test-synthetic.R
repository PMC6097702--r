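test_that("correlation targets have the block structure of the scenario", {
  regs <- paste0("R", 1:6)
  sc <- sim_scenario(regs, list(regs[1:3], regs[4:6]),
                     base_corr_within = 0.7, base_corr_between = 0.1,
                     group_specs = list(G = list(n_subjects = 5)))
  C <- make_correlation_target(sc, "G")
  expect_equal(diag(C), rep(1, 6), ignore_attr = TRUE)
  within <- rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6))
  expect_equal(unname(C[within]), rep(0.7, 6), tolerance = 1e-8)
  between <- as.matrix(expand.grid(1:3, 4:6))
  expect_equal(unname(C[between]), rep(0.1, 9), tolerance = 1e-8)
  expect_true(min(eigen(C, symmetric = TRUE)$values) > -1e-10)
})

test_that("identical group specs give identical targets and infeasible ones fail", {
  sc <- twelve_region_scenario()
  expect_identical(make_correlation_target(sc, "A"),
                   make_correlation_target(sc, "B"))
  bad <- twelve_region_scenario(
    mods_b = list(list(pair = c("R1", "R2"), delta = 0.5)))
  expect_error(make_correlation_target(bad, "B"), "infeasible")
})

test_that("edge modifications shift the targeted entries and little else", {
  regs <- paste0("R", 1:10)
  comm <- stats::setNames(rep(c("a", "b"), each = 5), regs)
  sc <- sim_scenario(regs, comm, base_corr_within = 0.6,
                     base_corr_between = 0.2,
                     hub_regions = "R1", hub_corr = 0.55,
                     group_specs = list(
                       G0 = list(n_subjects = 5),
                       G1 = list(n_subjects = 5,
                                 edge_modifications = list(
                                   list(region = "R1", delta = -0.5)))))
  C0 <- make_correlation_target(sc, "G0")
  C1 <- make_correlation_target(sc, "G1")
  others <- setdiff(regs, "R1")
  # modified neighborhood drops by at most the delta (PSD repair can only
  # soften it) and by a substantial share of it
  drop <- C0["R1", others] - C1["R1", others]
  expect_true(all(drop <= 0.5 + 0.05))
  expect_true(mean(drop) > 0.25)
  # untouched cells move only through the PSD repair
  untouched <- C1[others, others] - C0[others, others]
  expect_lt(max(abs(untouched)), 0.05)
})

test_that("simulated samples converge to the target correlations", {
  regs <- paste0("R", 1:8)
  comm <- stats::setNames(rep(c("a", "b"), each = 4), regs)
  sc <- sim_scenario(regs, comm, base_corr_within = 0.7,
                     base_corr_between = 0.2,
                     group_specs = list(G = list(n_subjects = 5000)),
                     rng_seed = 7)
  ex <- simulate_expression(sc)
  C_target <- make_correlation_target(sc, "G")
  C_sample <- cor(ex$G$values)
  expect_lt(max(abs(C_sample - C_target)), 0.05)

  # a single strong pair at moderate n stays within the Fisher-Z tolerance
  sc2 <- sim_scenario(c("x", "y"), list(c("x", "y")),
                      base_corr_within = 0.7, base_corr_between = 0,
                      group_specs = list(G = list(n_subjects = 200)),
                      rng_seed = 8)
  r_hat <- cor(simulate_expression(sc2)$G$values)[1, 2]
  expect_lt(abs(r_hat - 0.7), 0.1)
})

test_that("degenerate scales, determinism and truncation behave as declared", {
  regs <- paste0("R", 1:4)
  sc <- sim_scenario(regs, list(regs), base_corr_within = 0.5,
                     group_specs = list(G = list(n_subjects = 6,
                                                 mean_density = 800,
                                                 density_sd = 0)))
  ex <- simulate_expression(sc)
  expect_true(all(ex$G$values == 800))

  sc2 <- twelve_region_scenario(seed = 9)
  expect_identical(simulate_expression(sc2, rng_seed = 33),
                   simulate_expression(sc2, rng_seed = 33))

  expect_error(
    sim_scenario(regs, list(regs), group_specs = list(G = list(n_subjects = 3))),
    "n_subjects")

  # default density parameters put the mean >= 3 sd above zero, so the
  # truncation at 0 removes a negligible share of mass
  sc3 <- sim_scenario(regs, list(regs), base_corr_within = 0.3,
                      group_specs = list(G = list(n_subjects = 2000)),
                      rng_seed = 10)
  vals <- simulate_expression(sc3)$G$values
  expect_true(all(vals >= 0))
  expect_lt(mean(vals == 0), 0.01)
})

test_that("simulated behavior matches its generating moments", {
  bt0 <- simulate_behavior(group_means = c(A = 100, B = 200),
                           group_sds = 0, group_ns = 5, rng_seed = 1)
  expect_equal(bt0$freezing_s, rep(c(100, 200), each = 5))

  bt_cap <- simulate_behavior(group_means = c(A = 500), group_sds = 10,
                              group_ns = 20, session_length = 300,
                              rng_seed = 2)
  expect_true(all(bt_cap$freezing_s == 300))

  bt <- simulate_behavior(group_means = c(A = 150, B = 95),
                          group_sds = c(25, 25), group_ns = 10000,
                          session_length = 1e6, rng_seed = 3)
  d_hat <- cohens_d(bt$freezing_s[bt$group == "A"],
                    bt$freezing_s[bt$group == "B"])
  expect_lt(abs(d_hat - (150 - 95) / 25), 0.05)
})

test_that("null twins strip modifications, idempotently, and kill the contrast", {
  sc <- twelve_region_scenario(
    mods_b = list(list(region = "R1", delta = -0.3),
                  list(pair = c("R2", "R3"), delta = -0.2),
                  list(pair = c("R7", "R8"), delta = 0.1)))
  tw <- null_twin(sc)
  expect_equal(sum(lengths(lapply(tw$group_specs, `[[`,
                                  "edge_modifications"))), 0)
  expect_identical(null_twin(tw), tw)
  expect_identical(make_correlation_target(tw, "A"),
                   make_correlation_target(tw, "B"))
})
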