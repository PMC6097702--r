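test_that("fisher_z is the closed-form arctanh and rejects |r| = 1", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3), tolerance = 1e-12)
  for (r in c(0.1, 0.37, 0.92))
    expect_equal(fisher_z(-r), -fisher_z(r), tolerance = 1e-14)
  expect_error(fisher_z(1), "< 1")
})

test_that("KS edge statistic matches the ECDF-scan oracle", {
  ab <- make_net(c("a", "b", "c"), cbind(c("a", "b"), c("b", "c")),
                 weights = c(0.5, 0.7), signed_r = c(0.5, 0.7))
  expect_equal(ks_edge_distributions(ab, ab)$D, 0)

  lo <- make_net(c("a", "b", "c"), cbind(c("a", "b"), c("b", "c")),
                 weights = c(0.1, 0.2), signed_r = c(0.1, 0.2))
  hi <- make_net(c("a", "b", "c"), cbind(c("a", "b"), c("b", "c")),
                 weights = c(0.8, 0.9), signed_r = c(0.8, 0.9))
  expect_equal(ks_edge_distributions(lo, hi)$D, 1)

  set.seed(8)
  for (i in 1:5) {
    a <- rnorm(sample(5:50, 1))
    b <- rnorm(sample(5:50, 1), mean = 0.3)
    expect_equal(ks_two_sample(a, b)$D, oracle_ks_D(a, b), tolerance = 1e-12)
  }
})

test_that("dC reproduces the hand-computed two-correlation z-score", {
  # Z difference of 0.5 with groups of 9 and 10 (df = n convention):
  # 0.5 / sqrt(1/6 + 1/7) = 0.8987
  rA <- tanh(0.6)
  rB <- tanh(0.1)
  netA <- make_net(c("x", "y"), cbind("x", "y"), weights = abs(rA),
                   signed_r = rA, n = 9)
  netB <- make_net(c("x", "y"), cbind("x", "y"), weights = abs(rB),
                   signed_r = rB, n = 10)
  ed <- edge_diff_zscores(netA, netB)
  expect_equal(ed$dC, 0.5 / sqrt(1 / 6 + 1 / 7), tolerance = 1e-6)
  expect_equal(ed$dC, 0.8987, tolerance = 1e-3)

  # identical matrices: all dC = 0, nothing significant
  ed0 <- edge_diff_zscores(netA, netA, nA = 9, nB = 9)
  expect_equal(ed0$dC, 0)
  expect_false(any(ed0$significant))

  # df - 3 must stay positive
  expect_error(edge_diff_zscores(netA, netB, nA = 3, nB = 10), "df")
})

test_that("dC is antisymmetric and support is order-invariant", {
  sc <- twelve_region_scenario(seed = 61,
    mods_b = list(list(region = "R1", delta = -0.35)))
  ex <- simulate_expression(sc)
  netA <- threshold_network(pearson_matrix(ex$A), 0.05)
  netB <- threshold_network(pearson_matrix(ex$B), 0.05)
  ed_ab <- edge_diff_zscores(netA, netB)
  ed_ba <- edge_diff_zscores(netB, netA)
  key <- function(e) paste(e$region_a, e$region_b)
  expect_identical(key(ed_ab), key(ed_ba))
  expect_equal(ed_ba$dC, -ed_ab$dC, tolerance = 1e-12)
  expect_equal(ed_ba$significant, ed_ab$significant)
  # every compared cell has a surviving edge on at least one side
  expect_true(all(ed_ab$in_A | ed_ab$in_B))
})

test_that("the absent-edge convention changes only one-sided cells", {
  regs <- c("x", "y", "z")
  rf_A <- diag(3); dimnames(rf_A) <- list(regs, regs)
  rf_A["x", "y"] <- rf_A["y", "x"] <- 0.8
  rf_A["x", "z"] <- rf_A["z", "x"] <- 0.5   # below threshold in A
  rf_B <- diag(3); dimnames(rf_B) <- list(regs, regs)
  rf_B["x", "y"] <- rf_B["y", "x"] <- 0.75
  rf_B["x", "z"] <- rf_B["z", "x"] <- 0.85
  netA <- make_net(regs, cbind("x", "y"), weights = 0.8, signed_r = 0.8,
                   n = 10, r_full = rf_A)
  netB <- make_net(regs, cbind(c("x", "x"), c("y", "z")),
                   weights = c(0.75, 0.85), signed_r = c(0.75, 0.85),
                   n = 10, r_full = rf_B)
  ed_u <- edge_diff_zscores(netA, netB, absent = "unthresholded")
  ed_z <- edge_diff_zscores(netA, netB, absent = "zero")
  xz_u <- ed_u[ed_u$region_a == "x" & ed_u$region_b == "z", ]
  xz_z <- ed_z[ed_z$region_a == "x" & ed_z$region_b == "z", ]
  expect_equal(xz_u$rA, 0.5)
  expect_equal(xz_z$rA, 0)
  expect_gt(abs(xz_z$dC), abs(xz_u$dC))   # zeroing inflates the difference
  both_u <- ed_u[ed_u$region_b == "y", "dC"]
  both_z <- ed_z[ed_z$region_b == "y", "dC"]
  expect_equal(both_u, both_z, tolerance = 1e-12)
})

test_that("ownership classification counts planted asymmetries", {
  regs <- paste0("R", 1:6)
  rf <- function(vals) {
    m <- diag(6); dimnames(m) <- list(regs, regs)
    for (k in seq_len(nrow(vals))) {
      i <- vals[k, 1]; j <- vals[k, 2]
      m[i, j] <- m[j, i] <- as.numeric(vals[k, 3])
    }
    m
  }
  # 3 edges much stronger in A, 1 much stronger in B, 1 equal
  spec <- rbind(c(1, 2, 0.9), c(1, 3, 0.9), c(2, 3, 0.9),
                c(4, 5, 0.2), c(5, 6, 0.7))
  spec_b <- rbind(c(1, 2, 0.2), c(1, 3, 0.15), c(2, 3, 0.1),
                  c(4, 5, 0.9), c(5, 6, 0.7))
  mk <- function(sp) {
    keep <- sp[sp[, 3] >= 0.6, , drop = FALSE]
    make_net(regs, cbind(regs[keep[, 1]], regs[keep[, 2]]),
             weights = keep[, 3], signed_r = keep[, 3], n = 12,
             r_full = rf(sp))
  }
  ed <- edge_diff_zscores(mk(spec), mk(spec_b))
  counts <- classify_significant(ed, hubsA = "R1", hubsB = character(0))
  expect_equal(counts$n_significant, 4)
  expect_equal(counts$n_owner_A, 3)
  expect_equal(counts$n_owner_B, 1)
  expect_equal(counts$n_owner_A_hub, 2)  # R1-R2 and R1-R3 touch hub R1
  expect_equal(counts$n_owner_B_hub, 0)

  none <- edge_diff_zscores(mk(spec), mk(spec))
  c0 <- classify_significant(none)
  expect_equal(c0$n_significant, 0)
  expect_equal(c0$n_owner_A + c0$n_owner_B, 0)
})

test_that("under a shared truth the |dC| > 2 rate matches the normal tail", {
  # both groups drawn from one correlation structure at n = 50; every
  # compared cell has equal true coefficients, so dC should be close to
  # standard normal and exceed |2| at about the 4.55% two-sided rate
  regs <- paste0("R", 1:10)
  sc <- sim_scenario(regs, list(regs), base_corr_within = 0.6,
                     group_specs = list(A = list(n_subjects = 50),
                                        B = list(n_subjects = 50)))
  hits <- 0
  cells <- 0
  for (i in 1:200) {
    ex <- simulate_expression(sc, rng_seed = 7000 + i)
    netA <- threshold_network(pearson_matrix(ex$A), 0.05)
    netB <- threshold_network(pearson_matrix(ex$B), 0.05)
    ed <- edge_diff_zscores(netA, netB)
    hits <- hits + sum(ed$significant)
    cells <- cells + nrow(ed)
  }
  expect_lt(abs(hits / cells - 0.0455), 0.02)
})
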