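# Ensemble reweighting: simplex-constrained least squares matching
# ensemble-averaged predicted shifts to experiment, and derived
# per-residue secondary-structure probabilities.

#' Fit ensemble weights against experimental shifts
#'
#' Finds the weight vector w on the probability simplex (w_k >= 0,
#' sum w = 1) minimising
#' \deqn{\sum_j (\sum_k w_k M_{kj} - y_j)^2 + \lambda \|w\|^2}
#' where row k of `M` holds conformer k's predicted shifts and `y` the
#' experimental values. The quadratic program is solved exactly with a
#' dual active-set method; because the equality constraint fixes
#' `sum w = 1`, columns are centred first, which leaves the objective
#' unchanged but conditions the Gram matrix.
#'
#' @param M a [pool_matrix()] (K x J).
#' @param exp a [shift_table()] of experimental shifts, or a numeric
#'   vector of length J in matrix column order.
#' @param l2 ridge penalty lambda (default 0).
#' @param tol feasibility tolerance for the returned weights.
#' @param max_iter kept for interface stability; the exact QP solver does
#'   not iterate in a user-visible way.
#' @param weights_obs optional per-observable weights (e.g. inverse
#'   variance per nucleus), length J or matching the overlap.
#' @return Object of class `weight_vector`: numeric weights with
#'   attributes `objective`, `objective_uniform`, `rank_deficient`,
#'   `effective_size` (1 / sum w^2) and `solver` metadata.
#' @export
fit_weights <- function(M, exp, l2 = 0, tol = 1e-10, max_iter = 1000L,
                        weights_obs = NULL) {
  K <- nrow(M)
  if (K < 1L) stop("empty pool")
  if (inherits(exp, "shift_table")) {
    mo <- match_observables(M, exp)
    A <- M[, mo$columns, drop = FALSE]
    y <- mo$y
  } else {
    if (length(exp) != ncol(M))
      stop("experimental vector length != number of matrix columns")
    A <- M
    y <- as.numeric(exp)
  }
  if (!is.null(weights_obs)) {
    if (length(weights_obs) != ncol(A))
      stop("weights_obs length mismatch")
    s <- sqrt(weights_obs)
    A <- sweep(A, 2L, s, "*")
    y <- y * s
  }

  if (K == 1L) {
    w <- 1
  } else {
    # centring columns is objective-neutral under sum(w) = 1
    cm <- colMeans(A)
    Ac <- sweep(A, 2L, cm)
    yc <- y - cm
    Q <- tcrossprod(Ac) + diag(l2, K)
    cvec <- as.numeric(Ac %*% yc)
    ridge <- 0
    scale_q <- mean(diag(Q))
    if (scale_q <= 0) scale_q <- 1
    sol <- NULL
    for (attempt in 0:6) {
      Dmat <- Q + diag(ridge, K)
      sol <- tryCatch(
        quadprog::solve.QP(
          Dmat = Dmat, dvec = cvec,
          Amat = cbind(rep(1, K), diag(K)),
          bvec = c(1, rep(0, K)), meq = 1L),
        error = function(e) NULL)
      if (!is.null(sol)) break
      ridge <- if (ridge == 0) 1e-10 * scale_q else ridge * 100
    }
    if (is.null(sol))
      stop("weight fit failed: Gram matrix could not be regularised")
    w <- sol$solution
  }

  w[w < 0 & w > -tol] <- 0
  if (any(w < 0)) w[w < 0] <- 0
  w <- w / sum(w)

  obj <- function(wv) sum((as.numeric(wv %*% A) - y)^2) + l2 * sum(wv^2)
  f_w <- obj(w)
  f_u <- obj(rep(1 / K, K))
  if (f_w > f_u + 1e-8 * max(1, f_u)) {  # safeguard, should not trigger
    w <- rep(1 / K, K)
    f_w <- f_u
  }
  rank_def <- qr(sweep(A, 2L, colMeans(A)))$rank < min(K - 1L, ncol(A))

  structure(w,
            class = "weight_vector",
            objective = f_w,
            objective_uniform = f_u,
            rank_deficient = rank_def,
            effective_size = 1 / sum(w^2),
            solver = list(method = "dual active-set QP (quadprog)",
                          l2 = l2, tol = tol, centred = TRUE))
}

#' @export
print.weight_vector <- function(x, ...) {
  cat("<weight_vector> K =", length(x),
      " effective size =", round(attr(x, "effective_size"), 2),
      " objective =", signif(attr(x, "objective"), 4), "\n")
  if (isTRUE(attr(x, "rank_deficient")))
    cat("  note: prediction matrix is rank-deficient;",
        "weights are not uniquely identified\n")
  invisible(x)
}

#' Per-residue secondary-structure probabilities of a weighted ensemble
#'
#' `p_S(i) = sum_k w_k * 1(ss_k(i) == S)` for S in H, E, C. When the
#' experimental table and prediction matrix used in the fit are supplied,
#' per-nucleus RMSD and correlation between fitted and experimental
#' shifts are reported as diagnostics.
#'
#' @param pool list of `conformer` objects.
#' @param w a [fit_weights()] result (or any simplex vector).
#' @param M,exp optional: the prediction matrix and experimental table
#'   used in the fit, for diagnostics.
#' @return Object of class `ensemble_summary`: list with `profile` (data
#'   frame `index`, `aa`, `p_H`, `p_E`, `p_C`), `effective_size`,
#'   `diagnostics` (or NULL) and `weights`.
#' @export
ensemble_summary <- function(pool, w, M = NULL, exp = NULL) {
  if (length(pool) != length(w))
    stop("pool size (", length(pool), ") != weight length (", length(w), ")")
  if (any(w < -1e-10) || abs(sum(w) - 1) > 1e-8)
    stop("weights must lie on the probability simplex")
  n <- nchar(pool[[1]]$sequence)
  seq1 <- strsplit(pool[[1]]$sequence, "")[[1]]
  ssm <- vapply(pool, function(cf) ss_chars(conformer_ss(cf)),
                character(n))
  if (is.null(dim(ssm))) ssm <- matrix(ssm, nrow = n)
  pH <- matrix(as.numeric(ssm == "H"), nrow = n) %*% w
  pE <- matrix(as.numeric(ssm == "E"), nrow = n) %*% w
  prof <- data.frame(index = seq_len(n), aa = seq1,
                     p_H = as.numeric(pH), p_E = as.numeric(pE))
  prof$p_C <- 1 - prof$p_H - prof$p_E

  diags <- NULL
  if (!is.null(M) && !is.null(exp)) {
    mo <- match_observables(M, exp)
    fitted <- as.numeric(w %*% M[, mo$columns, drop = FALSE])
    nucs <- vapply(strsplit(colnames(M)[mo$columns], ":", fixed = TRUE),
                   `[`, character(1), 3L)
    diags <- do.call(rbind, lapply(unique(nucs), function(nu) {
      i <- nucs == nu
      data.frame(nucleus = nu,
                 rmsd = sqrt(mean((fitted[i] - mo$y[i])^2)),
                 correlation = if (sum(i) > 2 &&
                                   stats::sd(mo$y[i]) > 0 &&
                                   stats::sd(fitted[i]) > 0)
                   stats::cor(fitted[i], mo$y[i]) else NA_real_,
                 n = sum(i))
    }))
  }
  structure(list(profile = prof,
                 weights = as.numeric(w),
                 effective_size = 1 / sum(w^2),
                 diagnostics = diags),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat("<ensemble_summary> ", nrow(x$profile), " residues, K = ",
      length(x$weights), ", effective size = ",
      round(x$effective_size, 2), "\n", sep = "")
  if (!is.null(x$diagnostics)) {
    cat("  fit diagnostics (fitted vs experimental):\n")
    print(x$diagnostics, row.names = FALSE)
  }
  invisible(x)
}

#' Compare helix probability between two ensembles
#'
#' Signed per-residue difference (b minus a) of helix probability over
#' the residues shared in the normal-polyQ (10Q) numbering frame, plus
#' the mean difference over a region of interest. For variants of
#' different polyQ length, supply each ensemble's own region (e.g. each
#' variant's polyQ tract); by default `region_b = region_a`.
#'
#' @param a,b `ensemble_summary` objects.
#' @param region_a integer `c(start, end)` in a's residue numbering.
#' @param region_b same for b (default `region_a`).
#' @return List with `delta` (data frame over the shared leading frame)
#'   and `region_mean_delta` = mean p_H(b region) - mean p_H(a region).
#' @export
compare_variants <- function(a, b, region_a, region_b = region_a) {
  pa <- a$profile; pb <- b$profile
  n <- min(nrow(pa), nrow(pb))
  shared <- seq_len(n)
  if (any(pa$aa[shared] != pb$aa[shared]) &&
      sum(pa$aa[shared] != pb$aa[shared]) > n / 2)
    stop("residue frames do not align")
  delta <- data.frame(index = shared,
                      delta_p_H = pb$p_H[shared] - pa$p_H[shared])
  in_rng <- function(p, r) {
    if (r[1] < 1 || r[2] > nrow(p)) stop("region outside residue frame")
    mean(p$p_H[r[1]:r[2]])
  }
  list(delta = delta,
       region_mean_delta = in_rng(pb, region_b) - in_rng(pa, region_a))
}

#' Export the top-weighted conformers as a multi-model PDB
#'
#' @param pool list of `conformer` objects.
#' @param w weight vector.
#' @param m number of structures to export (default 6).
#' @param path output PDB path.
#' @export
export_top_conformers <- function(pool, w, m = 6L, path) {
  ord <- order(w, decreasing = TRUE)[seq_len(min(m, length(w)))]
  write_pool_pdb(pool[ord], path)
}
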