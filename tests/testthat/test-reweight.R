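# Simplex-constrained ensemble reweighting and derived probabilities.

make_problem <- function(K, J, seed) {
  set.seed(seed)
  M <- matrix(stats::rnorm(K * J, mean = 50, sd = 2), K, J)
  colnames(M) <- paste(seq_len(J), "A", "CA", sep = ":")
  structure(M, class = c("shift_matrix", "matrix", "array"))
}

test_that("a single-conformer pool always gets weight one", {
  M <- make_problem(1, 6, 1)
  w <- fit_weights(M, as.numeric(M[1, ]) + stats::rnorm(6))
  expect_equal(as.numeric(w), 1)
})

test_that("a noiseless two-component mixture is recovered exactly", {
  M <- make_problem(2, 12, 2)
  y <- as.numeric(c(0.7, 0.3) %*% M)
  w <- fit_weights(M, y)
  expect_equal(as.numeric(w), c(0.7, 0.3), tolerance = 1e-6)
  g <- grid_search_weights(M, y, step = 1e-4)
  expect_equal(as.numeric(w), g$w, tolerance = 2e-4)
  expect_lte(attr(w, "objective"), g$objective + 1e-6)
})

test_that("an exact single-row match concentrates the weight", {
  M <- make_problem(3, 12, 3)
  y <- as.numeric(M[2, ])
  w <- fit_weights(M, y)
  expect_gte(w[2], 0.999)
  g <- grid_search_weights(M, y, step = 1e-2)
  expect_lte(attr(w, "objective"), g$objective + 1e-6)
})

test_that("fits never do worse than the simplex grid oracle (K <= 3)", {
  set.seed(17)
  for (rep in 1:20) {
    K <- sample(2:3, 1)
    M <- make_problem(K, 10, 100 + rep)
    w_true <- stats::rgamma(K, 1); w_true <- w_true / sum(w_true)
    y <- as.numeric(w_true %*% M) + stats::rnorm(10, sd = 0.2)
    w <- fit_weights(M, y)
    g <- grid_search_weights(M, y, step = 1e-2)
    expect_lte(attr(w, "objective"), g$objective + 1e-6)
  }
})

test_that("fitted weights stay on the simplex and beat uniform weights", {
  set.seed(23)
  for (rep in 1:10) {
    K <- sample(2:20, 1)
    M <- make_problem(K, 30, 200 + rep)
    y <- as.numeric(stats::rnorm(30, 50, 2))
    w <- fit_weights(M, y)
    expect_gte(min(w), 0)
    expect_lt(abs(sum(w) - 1), 1e-8)
    expect_lte(attr(w, "objective"),
               attr(w, "objective_uniform") + 1e-8)
  }
})

test_that("ridge regularisation never increases the weight norm", {
  set.seed(31)
  for (rep in 1:5) {
    M <- make_problem(8, 24, 300 + rep)
    y <- as.numeric(stats::rnorm(24, 50, 2))
    w0 <- fit_weights(M, y, l2 = 0)
    for (l2 in c(0.1, 1, 10)) {
      wl <- fit_weights(M, y, l2 = l2)
      expect_lte(sum(wl^2), sum(w0^2) + 1e-8)
    }
  }
})

test_that("sparse mixtures over a synthetic pool are recovered", {
  sc <- make_scenario("expanded_22Q", seed = 6, pool_size = 40,
                      noise_sd = 0)
  pool <- sample_pool(sc, build_coords = FALSE)
  w0 <- sparse_truth_weights(40, 8, seed = 19)
  col <- collapse_duplicate_conformers(pool, w0)
  exp0 <- synth_experimental_shifts(col$pool, col$weights, noise_sd = 0,
                                    seed = 5)
  w <- fit_weights(attr(exp0, "matrix"), exp0)
  expect_lte(max(abs(as.numeric(w) - col$weights)), 0.02)

  exp1 <- synth_experimental_shifts(col$pool, col$weights, noise_sd = 0.1,
                                    seed = 5)
  w1 <- fit_weights(attr(exp1, "matrix"), exp1)
  expect_lte(max(abs(as.numeric(w1) - col$weights)), 0.10)
})

test_that("duplicate-row pools are flagged as rank deficient", {
  sc <- make_scenario("normal_10Q", seed = 3, pool_size = 4)
  pool <- sample_pool(sc, build_coords = FALSE)
  pool[[4]] <- pool[[1]]
  exp0 <- synth_experimental_shifts(pool, rep(0.25, 4), seed = 2)
  w <- fit_weights(attr(exp0, "matrix"), exp0)
  expect_true(attr(w, "rank_deficient"))
})

test_that("ensemble probabilities are weighted state indicators", {
  n <- 8
  all_h <- state_conformer(rep("H", n))
  all_c <- state_conformer(rep("C", n))
  s <- ensemble_summary(list(all_h, all_c), c(0.5, 0.5))
  expect_equal(s$profile$p_H[2:(n - 1)], rep(0.5, n - 2))
  expect_equal(s$profile$p_H + s$profile$p_E + s$profile$p_C,
               rep(1, n), tolerance = 1e-9)

  s1 <- ensemble_summary(list(all_h, all_c), c(1, 0))
  expect_equal(s1$profile$p_H[2:(n - 1)], rep(1, n - 2))
  expect_equal(s1$effective_size, 1)

  # brute-force weighted count oracle on a random 5-conformer pool
  sc <- make_scenario("normal_10Q", seed = 13, pool_size = 5)
  pool <- sample_pool(sc, build_coords = FALSE)
  set.seed(3)
  w <- stats::rgamma(5, 1); w <- w / sum(w)
  s5 <- ensemble_summary(pool, w)
  ssm <- sapply(pool, function(cf) strsplit(unclass(cf$ss), "")[[1]])
  for (i in c(1, 10, 25, 40, 62))
    expect_equal(s5$profile$p_H[i], sum(w * (ssm[i, ] == "H")))
})

test_that("variant comparison reports signed helix-probability changes", {
  n <- 8
  all_h <- state_conformer(rep("H", n))
  all_c <- state_conformer(rep("C", n))
  a <- ensemble_summary(list(all_h, all_c), c(0.4, 0.6))
  b <- ensemble_summary(list(all_h, all_c), c(0.6, 0.4))
  same <- compare_variants(a, a, region_a = c(2, 7))
  expect_true(all(same$delta$delta_p_H == 0))
  expect_equal(same$region_mean_delta, 0)
  cmp <- compare_variants(a, b, region_a = c(2, 7))
  expect_equal(cmp$region_mean_delta, 0.2, tolerance = 1e-12)
})

test_that("mismatched pools and weights are rejected", {
  cf <- state_conformer(rep("C", 5))
  expect_error(ensemble_summary(list(cf), c(0.5, 0.5)), "pool size")
  expect_error(ensemble_summary(list(cf, cf), c(0.9, 0.4)), "simplex")
})
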