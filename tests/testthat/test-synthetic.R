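# Synthetic scenario generator: sequences, pools, shifts, HDX.

test_that("presets build the expected sequences and propensity shapes", {
  sc10 <- make_scenario("normal_10Q", seed = 1)
  expect_equal(nchar(sc10$sequence), 62L)
  expect_true(grepl("Q{10}", sc10$sequence))
  expect_false(grepl("Q{11}", sc10$sequence))
  a2 <- sc10$arr2_range
  expect_true(all(sc10$helix_propensity[a2[1]:a2[2]] >= 0.6))
  q <- sc10$polyq_range
  expect_true(all(sc10$helix_propensity[q[1]:q[2]] <= 0.2))

  sc33 <- make_scenario("expanded_33Q", seed = 1)
  expect_true(grepl("Q{33}", sc33$sequence))
  expect_equal(nchar(sc33$sequence), 62L + 23L)
  # elevated tract propensity adjacent to the ARR, decaying along it
  pq <- sc33$helix_propensity[sc33$polyq_range[1]:sc33$polyq_range[2]]
  expect_gt(pq[1], 0.5)
  expect_true(all(diff(pq) <= 0))
  expect_lt(pq[33], 0.1)

  hb <- make_scenario("helix_broken", seed = 1)
  a2b <- hb$arr2_range
  expect_true(all(hb$helix_propensity[a2b[1]:a2b[2]] <= 0.1))
  expect_equal(substr(hb$sequence, 26, 26), "P")

  expect_error(make_scenario("expanded_99Q"), "arg")
})

test_that("scenarios and their derived data are seed-deterministic", {
  a <- make_scenario("expanded_22Q", seed = 33, pool_size = 4)
  b <- make_scenario("expanded_22Q", seed = 33, pool_size = 4)
  expect_identical(a, b)
  pa <- sample_pool(a, build_coords = FALSE)
  pb <- sample_pool(b, build_coords = FALSE)
  expect_identical(pa, pb)
  ea <- synth_experimental_shifts(pa, rep(0.25, 4), noise_sd = 0.1,
                                  seed = 9)
  eb <- synth_experimental_shifts(pb, rep(0.25, 4), noise_sd = 0.1,
                                  seed = 9)
  expect_identical(ea$entries, eb$entries)
  ha <- synth_hdx(a)
  hb <- synth_hdx(b)
  expect_identical(ha, hb)
})

test_that("expanded variants map extra glutamines outside the 10Q frame", {
  sc <- make_scenario("expanded_22Q", seed = 1)
  expect_equal(sc$map10q[1:39], 1:39)
  expect_true(all(is.na(sc$map10q[40:51])))
  expect_equal(sc$map10q[52], 40L)
  expect_equal(sc$map10q[nchar(sc$sequence)], 62L)
})

test_that("degenerate propensity profiles give degenerate pools", {
  sc <- make_scenario("normal_10Q", seed = 2, pool_size = 5)
  sc$helix_propensity[] <- 0
  pool0 <- sample_pool(sc, strand_p = 0, build_coords = FALSE)
  for (cf in pool0)
    expect_false(grepl("H", unclass(cf$ss)))

  sc$helix_propensity[] <- 1
  pool1 <- sample_pool(sc, build_coords = FALSE)
  n <- nchar(sc$sequence)
  for (cf in pool1)
    expect_equal(substr(unclass(cf$ss), 2, n - 1), strrep("H", n - 2))
})

test_that("pool helix frequency tracks the generating propensity", {
  sc <- make_scenario("normal_10Q", seed = 11, pool_size = 500)
  pool <- sample_pool(sc, build_coords = FALSE)
  freq <- rowMeans(vapply(pool, function(cf)
    strsplit(unclass(cf$ss), "")[[1]] == "H", logical(nchar(sc$sequence))))
  a2 <- sc$arr2_range
  expect_lt(abs(mean(freq[a2[1]:a2[2]]) -
                  mean(sc$helix_propensity[a2[1]:a2[2]])), 0.05)
  # whole-profile agreement, termini excluded
  n <- nchar(sc$sequence)
  expect_lt(mean(abs(freq - sc$helix_propensity)[3:(n - 2)]), 0.05)
})

test_that("synthetic shifts are the weighted predictions plus noise", {
  sc <- make_scenario("normal_10Q", seed = 3, pool_size = 3)
  pool <- sample_pool(sc, build_coords = FALSE)

  one_hot <- c(0, 1, 0)
  e <- synth_experimental_shifts(pool, one_hot, noise_sd = 0, seed = 1)
  pred <- predict_shifts(pool[[2]])
  key_e <- paste(e$entries$index, e$entries$nucleus)
  key_p <- paste(pred$entries$index, pred$entries$nucleus)
  expect_equal(e$entries$ppm,
               pred$entries$ppm[match(key_e, key_p)], tolerance = 1e-12)

  e2 <- synth_experimental_shifts(pool[1:2], c(0.5, 0.5), noise_sd = 0,
                                  seed = 1)
  M <- attr(e2, "matrix")
  expect_equal(e2$entries$ppm, as.numeric(colMeans(M)), tolerance = 1e-12)
})

test_that("noisy mixtures are reproducible and refittable within 0.10", {
  sc <- make_scenario("expanded_22Q", seed = 21, pool_size = 50,
                      noise_sd = 0)
  pool <- sample_pool(sc, build_coords = FALSE)
  w0 <- sparse_truth_weights(50, 8, seed = 4)
  col <- collapse_duplicate_conformers(pool, w0)
  e1 <- synth_experimental_shifts(col$pool, col$weights, noise_sd = 0.1,
                                  seed = 77)
  e2 <- synth_experimental_shifts(col$pool, col$weights, noise_sd = 0.1,
                                  seed = 77)
  expect_identical(e1$entries, e2$entries)
  w <- fit_weights(attr(e1, "matrix"), e1)
  expect_lte(max(abs(as.numeric(w) - col$weights)), 0.10)
})

test_that("synthetic HDX reflects the helix propensity profile", {
  hb <- make_scenario("helix_broken", seed = 5)
  m_hb <- classify_hdx(synth_hdx(hb))
  a2 <- hb$arr2_range
  in_arr2 <- m_hb$index >= a2[1] & m_hb$index <= a2[2]
  expect_false(any(m_hb$label[in_arr2] %in% c("+", "*")))

  sc10 <- make_scenario("normal_10Q", seed = 5)
  sc33 <- make_scenario("expanded_33Q", seed = 5)
  m10 <- classify_hdx(synth_hdx(sc10))
  m33 <- classify_hdx(synth_hdx(sc33))
  cmp <- compare_hdx(m10, m33, region_a = sc10$polyq_range,
                     region_b = sc33$polyq_range)
  expect_gt(cmp$difference, 0)

  # slow residues persist (ratio >= 0.5), fast ones vanish (<= 0.05)
  s <- synth_hdx(sc10)
  r15 <- s$intensities[, "i15"] / s$data$ctrl
  slow <- sc10$helix_propensity >= 0.5
  ok <- !is.na(r15)
  expect_true(all(r15[slow & ok] >= 0.5))
  expect_true(all(r15[!slow & ok] <= 0.06))
})
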