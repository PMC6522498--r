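# Synthetic-data generator: sequences, helix-propensity profiles,
# conformer pools, ensemble-averaged "experimental" shift tables and HDX
# decay series, all seeded and deterministic.
#
# The default construct emulates a 62-residue N-terminal polyQ-protein
# fragment laid out as NT - ARR1 - ARR2 - polyQ(n) - PRR, with the
# alanine-rich ARR2 motif spanning residues 21-28 (so Ala24-Ala28 sit
# inside it), Arg29 between ARR2 and the tract, the polyQ tract starting
# at Gln30 (Q30-Q39 for the normal 10Q length) and a proline-rich tail.
# Residue identities are a documented stand-in; indices follow the
# normal-polyQ (10Q) numbering frame, expanded tracts inserting extra
# glutamines after position 39.

SEQ_BLOCKS_10Q <- list(
  nt = "MSERAADDV",          # 1-9
  linker = "RGEPRR",         # 10-15
  arr1 = "AAAAG",            # 16-20
  arr2 = "AAAAAAAA",         # 21-28
  pre_q = "R",               # 29
  polyq = strrep("Q", 10),   # 30-39
  prr = "PPQPPQPLPQPPPAPQPPSPPAP"  # 40-62
)

#' Build a synthetic study scenario
#'
#' Presets correspond to the normal fragment, two polyQ-expanded
#' variants, and a helix-broken control emulating ARR2-disrupting
#' mutations (an Ala-to-Pro substitution in ARR2 with the ARR helix
#' propensity removed).
#'
#' @param preset one of `"normal_10Q"`, `"expanded_22Q"`,
#'   `"expanded_33Q"`, `"helix_broken"`.
#' @param seed integer seed; fixes all randomness derived from the
#'   scenario (each downstream operation draws from its own fixed
#'   sub-stream so adding one operation never perturbs another).
#' @param pool_size number of conformers sampled by [sample_pool()].
#' @param noise_sd Gaussian noise (ppm) added by
#'   [synth_experimental_shifts()].
#' @return Object of class `scenario`: sequence, per-residue
#'   `helix_propensity` in `[0,1]`, region table, polyQ length, the
#'   mapping of internal indices onto the 10Q numbering frame (`NA` for
#'   inserted glutamines), and the RNG seed.
#' @export
make_scenario <- function(preset = c("normal_10Q", "expanded_22Q",
                                     "expanded_33Q", "helix_broken"),
                          seed = 1L, pool_size = 100L, noise_sd = 0.05) {
  preset <- match.arg(preset)
  n_q <- switch(preset, normal_10Q = 10L, expanded_22Q = 22L,
                expanded_33Q = 33L, helix_broken = 33L)
  b <- SEQ_BLOCKS_10Q
  b$polyq <- strrep("Q", n_q)
  sequence <- paste(unlist(b), collapse = "")
  if (preset == "helix_broken")  # Ala26 -> Pro breaks the ARR2 helix
    substr(sequence, 26, 26) <- "P"
  n <- nchar(sequence)

  lens <- vapply(b, nchar, integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  regions <- data.frame(block = names(b), start = starts, end = ends,
                        row.names = NULL)
  qs <- starts[["polyq"]]; qe <- ends[["polyq"]]

  # 10Q-frame mapping: inserted glutamines (beyond the 10th) are NA
  map10q <- integer(n)
  map10q[seq_len(qs + 9L)] <- seq_len(qs + 9L)
  if (n_q > 10L) map10q[(qs + 10L):qe] <- NA_integer_
  if (qe < n) map10q[(qe + 1L):n] <- seq(qs + 10L, length.out = n - qe)

  p <- rep(0.05, n)
  reg <- function(name) starts[[name]]:ends[[name]]
  if (preset == "helix_broken") {
    p[reg("arr1")] <- 0.08
    p[reg("arr2")] <- 0.05
    p[ends[["pre_q"]]] <- 0.05
    p[qs:qe] <- 0.05
  } else {
    p[reg("arr1")] <- 0.35
    p[reg("arr2")] <- 0.75
    p[ends[["pre_q"]]] <- 0.60
    qi <- seq_len(n_q)
    if (preset == "normal_10Q") {
      p[qs:qe] <- pmax(0.05, 0.18 * exp(-(qi - 1) / 5))
    } else {
      # expansion: helix propagates from the ARR into the tract, decaying
      p[qs:qe] <- 0.05 + 0.65 * exp(-(qi - 1) / 6)
    }
  }
  p[reg("prr")] <- 0.02
  seq1 <- strsplit(sequence, "")[[1]]
  p[seq1 == "P"] <- 0  # proline cannot occupy a helix interior here

  structure(list(preset = preset, sequence = sequence,
                 n_polyq = n_q, regions = regions,
                 polyq_range = c(qs, qe),
                 arr2_range = c(starts[["arr2"]], ends[["arr2"]]),
                 helix_propensity = p, map10q = map10q,
                 pool_size = as.integer(pool_size),
                 ground_truth_weights = NULL,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario> ", x$preset, ": ", nchar(x$sequence), " residues, polyQ ",
      x$polyq_range[1], "-", x$polyq_range[2], " (", x$n_polyq,
      "Q), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# fixed per-operation RNG sub-streams
scenario_seed <- function(scenario, op) {
  offset <- switch(op, pool = 101L, shifts = 211L, hdx = 307L, truth = 401L,
                   stop("unknown op"))
  (scenario$seed * 7919L + offset) %% 2147483647L
}

#' Sample a conformer pool from a scenario
#'
#' Helix states are drawn by thresholding a latent first-order
#' autoregressive Gaussian field, so each residue's marginal helix
#' probability equals the scenario's propensity while helical residues
#' occur in contiguous runs. Runs shorter than `min_run` are repaired
#' mass-neutrally: a run of length L is extended to `min_run` with
#' probability `L / min_run` and deleted otherwise, so in expectation it
#' still contributes L helical residues and the empirical helix
#' frequency over a large pool tracks the propensity profile.
#' A small strand propensity mixes extended segments into the coil
#' background. Dihedrals are drawn inside the corresponding basin with
#' jitter and coordinates are built with ideal geometry.
#'
#' @param scenario a [make_scenario()].
#' @param K pool size (default `scenario$pool_size`).
#' @param rho latent-field autocorrelation controlling run lengths.
#' @param strand_p marginal strand propensity in the coil background.
#' @param min_run minimum helix run length.
#' @param build_coords build backbone coordinates for every conformer
#'   (disable for large pools where only dihedrals/secondary structure
#'   are needed; coordinates are then built lazily on demand).
#' @return List of `conformer` objects with cached secondary structure.
#' @export
sample_pool <- function(scenario, K = scenario$pool_size, rho = 0.9,
                        strand_p = 0.03, min_run = 4L,
                        build_coords = TRUE) {
  stopifnot(inherits(scenario, "scenario"), K >= 1L)
  set.seed(scenario_seed(scenario, "pool"))
  n <- nchar(scenario$sequence)
  p <- scenario$helix_propensity
  thr_h <- stats::qnorm(pmin(pmax(p, 0), 1))
  thr_e <- stats::qnorm(strand_p)
  pool <- vector("list", K)
  for (k in seq_len(K)) {
    zh <- ar1_field(n, rho)
    ze <- ar1_field(n, 0.8)
    h <- repair_short_runs(zh < thr_h, min_run)
    e <- (ze < thr_e) & !h
    e <- runs_at_least(e, 2L)
    dih <- draw_dihedrals(n, h, e)
    cf <- if (build_coords)
      build_chain(scenario$sequence, dih$phi, dih$psi)
    else
      conformer(scenario$sequence, dih$phi, dih$psi)
    cf$ss <- assign_ss(cf)
    pool[[k]] <- cf
  }
  pool
}

# mass-neutral minimum-run repair: extend a short TRUE-run of length L
# to k with probability L/k (into adjacent FALSE positions, preferring
# the right side), delete it otherwise
repair_short_runs <- function(h, k) {
  r <- rle(h)
  n <- length(h)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in seq_along(r$values)) {
    if (r$values[j] && r$lengths[j] < k) {
      s <- starts[j]; e <- ends[j]
      L <- e - s + 1L
      if (stats::runif(1) < L / k) {
        while (e - s + 1L < k) {
          if (e < n && !h[min(e + 1L, n)]) e <- e + 1L
          else if (s > 1L) s <- s - 1L
          else if (e < n) e <- e + 1L
          else break
        }
        h[s:e] <- TRUE
      } else {
        h[s:e] <- FALSE
      }
    }
  }
  h
}

ar1_field <- function(n, rho) {
  z <- numeric(n)
  z[1] <- stats::rnorm(1)
  if (n > 1) {
    eps <- stats::rnorm(n - 1, sd = sqrt(1 - rho^2))
    for (i in 2:n) z[i] <- rho * z[i - 1] + eps[i - 1]
  }
  z
}

# dihedrals inside the basin for the intended state; coil dihedrals are
# drawn from polyproline-II-like and left-handed pockets that lie outside
# both the helical and the extended basin, so the dihedral-basin
# assignment reproduces the intended states exactly (up to terminal
# residues and pruned short runs)
draw_dihedrals <- function(n, h, e) {
  phi <- numeric(n); psi <- numeric(n)
  for (i in seq_len(n)) {
    if (h[i]) {
      phi[i] <- -57 + stats::runif(1, -8, 8)
      psi[i] <- -47 + stats::runif(1, -8, 8)
    } else if (e[i]) {
      phi[i] <- -135 + stats::runif(1, -10, 10)
      psi[i] <- 135 + stats::runif(1, -10, 10)
    } else if (stats::runif(1) < 0.7) {
      phi[i] <- stats::runif(1, -85, -66)
      psi[i] <- stats::runif(1, 140, 165)
    } else {
      phi[i] <- stats::runif(1, 50, 70)
      psi[i] <- stats::runif(1, 30, 60)
    }
  }
  phi[1] <- NA_real_
  psi[n] <- NA_real_
  list(phi = phi, psi = psi)
}

#' Generate ensemble-averaged experimental shifts from a known mixture
#'
#' The "experimental" value of each observable is the ground-truth
#' weighted average of the pool's predicted shifts plus Gaussian noise.
#'
#' @param pool a [sample_pool()] result.
#' @param weights ground-truth simplex weights, length `|pool|`.
#' @param noise_sd Gaussian noise standard deviation in ppm.
#' @param seed integer seed.
#' @param nuclei nuclei to synthesise.
#' @param rc random-coil table used by the forward model.
#' @return A [shift_table()]; the prediction matrix used is attached as
#'   attribute `"matrix"`.
#' @export
synth_experimental_shifts <- function(pool, weights, noise_sd = 0,
                                      seed = 1L,
                                      nuclei = c("H", "N", "HA", "CA", "CB"),
                                      rc = random_coil_table()) {
  if (length(weights) != length(pool))
    stop("weights length != pool size")
  if (any(weights < -1e-12) || abs(sum(weights) - 1) > 1e-8)
    stop("weights must lie on the probability simplex")
  obs <- supported_observables(pool[[1]]$sequence, nuclei)
  M <- pool_matrix(pool, observables = obs, rc = rc)
  set.seed(seed %% 2147483647L)
  y <- as.numeric(weights %*% M)
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), sd = noise_sd)
  parts <- do.call(rbind, strsplit(obs, ":", fixed = TRUE))
  tbl <- shift_table(
    data.frame(index = as.integer(parts[, 1]), aa = parts[, 2],
               nucleus = parts[, 3], ppm = y, stringsAsFactors = FALSE),
    sequence = pool[[1]]$sequence, label = "synthetic experiment")
  attr(tbl, "matrix") <- M
  tbl
}

#' Generate a synthetic HDX intensity series
#'
#' Residues whose helix propensity is at least 0.5 exchange slowly
#' (intensity ratio ~0.7 of control after 15 min), all others quickly
#' (~0.02), with multiplicative log-normal noise. Prolines carry no
#' amide and get no control peak; glutamines inserted beyond the 10Q
#' frame are marked unassigned.
#'
#' @param scenario a [make_scenario()].
#' @param seed integer seed (default: derived from the scenario seed).
#' @param times exchange times in minutes.
#' @return An [hdx_series()].
#' @export
synth_hdx <- function(scenario, seed = NULL, times = c(15, 60, 120)) {
  stopifnot(inherits(scenario, "scenario"))
  if (is.null(seed)) seed <- scenario_seed(scenario, "hdx")
  set.seed(seed %% 2147483647L)
  seq1 <- strsplit(scenario$sequence, "")[[1]]
  n <- length(seq1)
  slow <- scenario$helix_propensity >= 0.5
  k_slow <- log(1 / 0.7) / 15   # ratio 0.7 at 15 min
  k_fast <- log(1 / 0.02) / 15  # ratio 0.02 at 15 min
  k <- ifelse(slow, k_slow, k_fast)
  ctrl <- 100 * exp(stats::rnorm(n, sd = 0.05))
  ctrl[seq1 == "P"] <- NA_real_
  ints <- sapply(times, function(t)
    ctrl * exp(-k * t) * exp(stats::rnorm(n, sd = 0.05)))
  colnames(ints) <- paste0("i", times)
  df <- data.frame(index = seq_len(n), aa = seq1,
                   assigned = !is.na(scenario$map10q),
                   ctrl = ctrl, stringsAsFactors = FALSE)
  hdx_series(cbind(df, as.data.frame(ints)), times = times)
}

#' Draw sparse ground-truth ensemble weights
#'
#' A Dirichlet draw over a random sparse support, used as the generating
#' mixture of recovery experiments.
#'
#' @param K pool size.
#' @param n_active number of non-zero weights.
#' @param seed integer seed.
#' @return Numeric simplex vector of length `K`.
#' @export
sparse_truth_weights <- function(K, n_active = min(10L, K), seed = 1L) {
  set.seed(seed %% 2147483647L)
  idx <- sample.int(K, n_active)
  g <- stats::rgamma(n_active, shape = 1)
  w <- numeric(K)
  w[idx] <- g / sum(g)
  w
}
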