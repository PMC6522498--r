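# Secondary shifts, the dCa-dCb indicator, and SSP scoring.

rc <- random_coil_table()

test_that("secondary shifts are exactly observed minus random coil", {
  # observed == random coil -> all zero
  t0 <- calibration_table("AQAQAQ", "helix", scale = 0)
  p0 <- secondary_shifts(t0, rc)
  expect_true(all(abs(p0$dCA) < 1e-12))
  expect_true(all(abs(p0$dCaCb) < 1e-12))

  # forced subtraction and dCaCb arithmetic
  tbl <- shift_table(data.frame(index = c(1, 1), aa = "A",
                                nucleus = c("CA", "CB"),
                                ppm = c(52.5 + 2.0, 19.1 - 0.5)))
  p <- secondary_shifts(tbl, rc)
  expect_equal(p$dCA, 2.0)
  expect_equal(p$dCB, -0.5)
  expect_equal(p$dCaCb, 2.5)
})

test_that("adding the random-coil reference back reproduces the input", {
  sc <- make_scenario("normal_10Q", seed = 8, pool_size = 5)
  pool <- sample_pool(sc, build_coords = FALSE)
  tbl <- synth_experimental_shifts(pool, rep(0.2, 5), noise_sd = 0.1,
                                   seed = 3)
  prof <- secondary_shifts(tbl, rc)
  for (r in seq_len(nrow(tbl$entries))) {
    e <- tbl$entries[r, ]
    d <- prof[prof$index == e$index, paste0("d", e$nucleus)]
    expect_equal(d + random_coil_lookup(rc, e$aa, e$nucleus), e$ppm,
                 tolerance = 1e-12)
  }
})

test_that("fully formed helix scores +1, strand -1, zero scores 0", {
  seqs <- strrep("AQ", 10)
  s_h <- ssp_score(secondary_shifts(calibration_table(seqs, "helix"), rc))
  expect_true(all(abs(s_h$ssp[3:18] - 1) < 0.01))
  s_e <- ssp_score(secondary_shifts(calibration_table(seqs, "strand"), rc))
  expect_true(all(abs(s_e$ssp[3:18] + 1) < 0.01))
  s_0 <- ssp_score(secondary_shifts(calibration_table(seqs, "helix",
                                                      scale = 0), rc))
  expect_true(all(abs(s_0$ssp) < 1e-12))
})

test_that("half-strength secondary shifts score 0.5, matching a direct
           single-window evaluation", {
  seqs <- strrep("AQ", 10)
  prof <- secondary_shifts(calibration_table(seqs, "helix", scale = 0.5), rc)
  ssp <- ssp_score(prof)

  # independent single-window evaluation at residue 10: normalise each
  # secondary shift by the appropriate fully-formed offset, weight by
  # nucleus sensitivity, average over the 5-residue window
  off <- ss_reference_offsets()
  wts <- c(H = 0.3, N = 0.3, HA = 0.8, CA = 1.0, CB = 1.0)
  num <- 0; den <- 0
  for (i in 8:12) {
    for (nu in c("H", "N", "HA", "CA", "CB")) {
      d <- prof[prof$index == i, paste0("d", nu)]
      if (is.na(d)) next
      x <- if (sign(d) == sign(off[nu, "helix"])) d / off[nu, "helix"]
           else -d / off[nu, "strand"]
      num <- num + wts[nu] * x
      den <- den + wts[nu]
    }
  }
  expect_equal(ssp$ssp[ssp$index == 10], unname(num / den),
               tolerance = 1e-12)
  expect_true(all(abs(ssp$ssp[3:18] - 0.5) < 1e-9))
})

test_that("SSP is approximately linear in the secondary-shift amplitude", {
  seqs <- strrep("AQ", 10)
  base <- ssp_score(secondary_shifts(calibration_table(seqs, "helix"), rc))
  for (lam in c(0.2, 0.6, 0.9)) {
    s <- ssp_score(secondary_shifts(
      calibration_table(seqs, "helix", scale = lam), rc))
    expect_equal(s$ssp[3:18], lam * base$ssp[3:18], tolerance = 1e-6)
  }
})

test_that("Gly and Pro still receive scores from their remaining nuclei", {
  s <- ssp_score(secondary_shifts(calibration_table("AAGPAAAA", "helix"),
                                  rc))
  expect_true(all(abs(s$ssp - 1) < 0.01))
})

test_that("scores need at least three covered window residues", {
  tbl <- shift_table(data.frame(index = c(1, 2), aa = "A", nucleus = "CA",
                                ppm = c(54, 54)))
  s <- ssp_score(secondary_shifts(tbl, rc))
  expect_true(all(is.na(s$ssp)))
  empty <- structure(
    data.frame(index = 1:4, aa = "A", dH = NA_real_, dN = NA_real_,
               dHA = NA_real_, dCA = NA_real_, dCB = NA_real_,
               dCaCb = NA_real_),
    class = c("secondary_shift_profile", "data.frame"))
  expect_error(ssp_score(empty), "no usable nuclei")
})

test_that("segment calling finds maximal runs above threshold", {
  mk <- function(scores) {
    structure(data.frame(index = seq_along(scores), aa = "A", ssp = scores),
              class = c("ssp_profile", "data.frame"))
  }
  seg <- call_segments(mk(c(0, 0, 0.4, 0.4, 0.4, 0)), threshold = 0.3)
  expect_equal(seg$start, 3)
  expect_equal(seg$end, 5)
  expect_equal(seg$mean_score, 0.4)

  expect_equal(nrow(call_segments(mk(rep(0.1, 6)), threshold = 0.3)), 0L)
  expect_error(call_segments(mk(rep(0.1, 6)), threshold = -1), "> 0")

  # brute-force run enumeration oracle on random profiles
  set.seed(42)
  for (rep in 1:20) {
    sc <- round(stats::runif(30, 0, 0.6), 2)
    thr <- 0.3
    seg <- call_segments(mk(sc), threshold = thr)
    hits <- sc >= thr
    expected <- list()
    i <- 1
    while (i <= 30) {
      if (hits[i]) {
        j <- i
        while (j < 30 && hits[j + 1]) j <- j + 1
        if (j - i + 1 >= 3)
          expected[[length(expected) + 1]] <- c(i, j)
        i <- j + 1
      } else i <- i + 1
    }
    expect_equal(nrow(seg), length(expected))
    for (k in seq_along(expected)) {
      expect_equal(seg$start[k], expected[[k]][1])
      expect_equal(seg$end[k], expected[[k]][2])
      expect_equal(seg$mean_score[k],
                   mean(sc[expected[[k]][1]:expected[[k]][2]]))
    }
  }
})
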