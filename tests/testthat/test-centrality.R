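test_that("the center of a star is maximal on all four centralities", {
  n <- 8
  regs <- c("hub", paste0("leaf", 1:(n - 1)))
  net <- make_net(regs, cbind("hub", regs[-1]), weights = rep(0.6, n - 1))
  ct <- centralities(net)
  for (m in c("Wdg", "Evc", "Clo", "Bet")) {
    expect_equal(which.max(ct[[m]]), 1)
    expect_true(all(ct[[m]][1] > ct[[m]][-1]))
  }
  expect_equal(ct$Evc[1], 1)  # max-normalized
  expect_true(all(ct$Bet[-1] == 0))
})

test_that("a uniform complete graph ties every region on every metric", {
  regs <- paste0("R", 1:6)
  net <- make_net(regs, t(combn(regs, 2)), weights = rep(0.5, 15))
  ct <- centralities(net)
  for (m in c("Wdg", "Evc", "Clo", "Bet"))
    expect_lt(diff(range(ct[[m]])), 1e-10)
})

test_that("betweenness equals a simple-path enumeration oracle", {
  for (seed in 1:5) {
    g <- random_weighted_graph(8, p_edge = 0.45, seed = 100 + seed)
    net <- structure(list(graph = g, level = 0.05, n = 10,
                          r_full = NULL,
                          regions = paste0("n", 1:8)),
                     class = "thresholded_network")
    igraph::V(net$graph)$name <- net$regions
    ct <- centralities(net)
    expect_equal(ct$Bet, oracle_betweenness(dist_matrix_of(g)),
                 tolerance = 1e-10)
  }
})

test_that("isolates score zero and fragmented eigenvectors follow the dominant component", {
  net <- make_net(c("a", "b", "c", "d", "e", "f", "z"),
                  cbind(c("a", "b", "c", "d"), c("b", "c", "a", "e")),
                  weights = c(0.9, 0.9, 0.9, 0.3))
  ct <- centralities(net)
  z <- ct[ct$region == "z", ]
  expect_equal(unlist(z[c("Wdg", "Evc", "Clo", "Bet")]),
               c(Wdg = 0, Evc = 0, Clo = 0, Bet = 0))
  # strong triangle dominates; the weak d-e pair gets Evc 0
  expect_equal(ct$Evc[ct$region == "d"], 0)
  expect_equal(ct$Evc[ct$region == "e"], 0)
  expect_gt(max(ct$Evc[ct$region %in% c("a", "b", "c")]), 0.99)
})

test_that("hub calls take the upper quantile of at least three metrics", {
  set.seed(42)
  tab <- data.frame(region = paste0("R", 1:28),
                    Wdg = runif(28), Evc = runif(28),
                    Clo = runif(28), Bet = runif(28))
  # plant a clear winner of all four metrics
  tab[1, -1] <- 2
  h <- identify_hubs(tab)
  expect_true("R1" %in% h$hubs)
  # a region in the top quartile of only two metrics is not a hub
  tab2 <- tab
  tab2[2, c("Wdg", "Evc")] <- 3
  tab2[2, c("Clo", "Bet")] <- -1
  h2 <- identify_hubs(tab2)
  expect_false("R2" %in% h2$hubs)
  expect_equal(unname(h2$n_metrics["R2"]), 2)
})

test_that("ties at the quantile cutoff are all included", {
  tab <- data.frame(region = paste0("R", 1:8),
                    Wdg = c(5, 5, 5, 5, 1, 1, 1, 1),
                    Evc = (8:1) / 8, Clo = (8:1) / 8, Bet = 8:1)
  h <- identify_hubs(tab, quantile = 0.25, min_metrics = 3)
  # ceiling(0.25 * 8) = 2, but four regions tie on Wdg at the cutoff
  expect_equal(sum(h$membership[, "Wdg"]), 4)
  expect_equal(sum(h$membership[, "Bet"]), 2)
})

test_that("hub calls are invariant to monotone transformations of a metric", {
  sc <- twelve_region_scenario(seed = 31)
  ex <- simulate_expression(sc)
  ct <- centralities(threshold_network(pearson_matrix(ex$A), 0.05))
  h0 <- identify_hubs(ct)
  ct2 <- ct
  ct2$Wdg <- exp(ct2$Wdg)
  ct2$Clo <- rank(ct2$Clo, ties.method = "min")
  expect_identical(identify_hubs(ct2)$hubs, h0$hubs)
})

test_that("stable hubs are the intersection across thresholds", {
  hs <- stable_hubs(list(`0.05` = c("RSC", "IL", "Por"),
                         `0.025` = c("RSC", "IL"),
                         `0.01` = c("RSC", "Per_36")))
  expect_equal(hs$stable_hubs, "RSC")
  expect_equal(unname(hs$hub_score[c("RSC", "IL", "Por", "Per_36")]),
               c(3L, 2L, 1L, 1L))
  expect_error(stable_hubs(list()), "no thresholds")
})

test_that("identical groups give zero empirical differences", {
  sc <- twelve_region_scenario(seed = 51)
  ex <- simulate_expression(sc)
  reord <- ex$A
  reord$values <- reord$values[sample(nrow(reord$values)), , drop = FALSE]
  pr <- permutation_centrality_test(ex$A, reord, 0.05,
                                    n_permutations = 20, rng_seed = 1)
  expect_true(all(abs(pr$diff) < 1e-10))
})

test_that("swapping the groups negates Diff and keeps two-sided p", {
  sc <- twelve_region_scenario(seed = 52,
    mods_b = list(list(region = "R1", delta = -0.3)))
  ex <- simulate_expression(sc)
  pr_ab <- permutation_centrality_test(ex$A, ex$B, 0.05,
                                       n_permutations = 600, rng_seed = 9)
  pr_ba <- permutation_centrality_test(ex$B, ex$A, 0.05,
                                       n_permutations = 600, rng_seed = 9)
  expect_equal(pr_ba$diff, -pr_ab$diff, tolerance = 1e-10)
  # the two-sided p is invariant under the swap over the full permutation
  # group; with sampled permutations the two estimates agree to Monte Carlo
  # error (binomial sd ~ 0.02 at 600 draws)
  expect_lt(max(abs(pr_ba$p - pr_ab$p)), 0.1)
})

test_that("permutation test enforces its preconditions and conventions", {
  sc <- twelve_region_scenario(seed = 53)
  ex <- simulate_expression(sc)
  sub <- expression_matrix(ex$B$values[, 1:6], ex$B$group)
  expect_error(permutation_centrality_test(ex$A, sub, 0.05, 10),
               "region set")
  pr1 <- permutation_centrality_test(ex$A, ex$B, 0.05,
                                     n_permutations = 100, rng_seed = 2)
  pr2 <- permutation_centrality_test(ex$A, ex$B, 0.05,
                                     n_permutations = 100, rng_seed = 2)
  expect_identical(pr1$p, pr2$p)
  pr_add1 <- permutation_centrality_test(ex$A, ex$B, 0.05,
                                         n_permutations = 100, rng_seed = 2,
                                         add_one = TRUE)
  expect_equal(pr_add1$p, (pr1$p * 100 + 1) / 101, tolerance = 1e-12)
})
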