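# Linear forward chemical-shift model for pool conformers.
#
# The predicted shift of nucleus j of residue i in conformer k is
#   delta_pred = delta_random_coil(aa_i, j) + offset(j, ss_k(i))
# with offset(., C) = 0 and offset(., H/E) the bundled fully-formed
# helix/strand secondary-shift references. Being linear in the secondary-
# structure state, ensemble-averaged predictions are linear in the pool
# weights, which preserves the structure of the reweighting problem. A
# precomputed prediction matrix from any external predictor can be
# imported instead (see read_shift_matrix_csv).

#' Predict backbone chemical shifts for one conformer
#'
#' @param cf a `conformer` (secondary structure assigned on demand via
#'   [assign_ss()]).
#' @param rc a [random_coil_table()].
#' @param nuclei nuclei to predict.
#' @return A [shift_table()] of predicted shifts; an all-coil conformer
#'   predicts exactly the random-coil values.
#' @export
predict_shifts <- function(cf, rc = random_coil_table(),
                           nuclei = c("H", "N", "HA", "CA", "CB")) {
  stopifnot(inherits(cf, "conformer"))
  nuclei <- match.arg(nuclei, SUPPORTED_NUCLEI, several.ok = TRUE)
  ss <- ss_chars(conformer_ss(cf))
  seq1 <- strsplit(cf$sequence, "")[[1]]
  off <- ss_reference_offsets()
  rows <- list()
  for (i in seq_along(seq1)) {
    for (nuc in nuclei) {
      if (seq1[i] == "G" && nuc == "CB") next
      if (seq1[i] == "P" && nuc %in% c("H", "N")) next
      base <- random_coil_lookup(rc, seq1[i], nuc,
                                 next_aa = if (i < length(seq1)) seq1[i + 1])
      d <- switch(ss[i], H = off[nuc, "helix"], E = off[nuc, "strand"], 0)
      rows[[length(rows) + 1L]] <-
        data.frame(index = i, aa = seq1[i], nucleus = nuc, ppm = base + d,
                   stringsAsFactors = FALSE)
    }
  }
  shift_table(do.call(rbind, rows), sequence = cf$sequence,
              label = "predicted")
}

#' Observable identifiers supported by the forward model
#'
#' @param sequence one-letter sequence string.
#' @param nuclei nuclei to include.
#' @return Character vector of `index:aa:nucleus` identifiers, excluding
#'   Gly CB and Pro H/N (those nuclei do not exist).
#' @export
supported_observables <- function(sequence,
                                  nuclei = c("H", "N", "HA", "CA", "CB")) {
  seq1 <- strsplit(sequence, "")[[1]]
  out <- character(0)
  for (i in seq_along(seq1)) {
    for (nuc in nuclei) {
      if (seq1[i] == "G" && nuc == "CB") next
      if (seq1[i] == "P" && nuc %in% c("H", "N")) next
      out <- c(out, paste(i, seq1[i], nuc, sep = ":"))
    }
  }
  out
}

#' Build the pool prediction matrix
#'
#' Row k holds conformer k's predicted shifts restricted to the requested
#' observables; the column order is fixed and recorded in `colnames`.
#'
#' @param pool list of `conformer` objects (shared sequence).
#' @param observables character vector of `index:aa:nucleus` ids; default
#'   all supported observables for CA and CB.
#' @param rc a [random_coil_table()].
#' @return A `shift_matrix`: numeric matrix K x J with observable column
#'   names.
#' @export
pool_matrix <- function(pool,
                        observables = supported_observables(
                          pool[[1]]$sequence, c("CA", "CB")),
                        rc = random_coil_table()) {
  stopifnot(length(pool) >= 1L)
  supp <- supported_observables(pool[[1]]$sequence, SUPPORTED_NUCLEI)
  bad <- setdiff(observables, supp)
  if (length(bad))
    stop("unsupported observable(s): ", paste(bad[1:min(3, length(bad))],
                                              collapse = ", "))
  parts <- do.call(rbind, strsplit(observables, ":", fixed = TRUE))
  idx <- as.integer(parts[, 1])
  aa <- parts[, 2]
  nuc <- parts[, 3]
  seq1 <- strsplit(pool[[1]]$sequence, "")[[1]]
  off <- ss_reference_offsets()
  # the forward model is linear in the three-state label, so each row is
  # base + indicator(H) * helix offset + indicator(E) * strand offset
  base <- mapply(function(a, nu, i) {
    random_coil_lookup(rc, a, nu,
                       next_aa = if (i < length(seq1)) seq1[i + 1])
  }, aa, nuc, idx)
  off_h <- off[nuc, "helix"]
  off_e <- off[nuc, "strand"]
  M <- matrix(NA_real_, nrow = length(pool), ncol = length(observables),
              dimnames = list(NULL, observables))
  for (k in seq_along(pool)) {
    ss <- ss_chars(conformer_ss(pool[[k]]))[idx]
    M[k, ] <- base + (ss == "H") * off_h + (ss == "E") * off_e
  }
  if (anyNA(M)) stop("internal error: prediction matrix has missing cells")
  structure(M, class = c("shift_matrix", "matrix", "array"))
}

#' Restrict an experimental shift table to a matrix's observables
#'
#' @param M a [pool_matrix()].
#' @param exp a [shift_table()] of experimental shifts.
#' @return List with `y` (numeric vector of experimental values) and
#'   `columns` (matching column indices of `M`); observables missing from
#'   the experiment are omitted.
#' @export
match_observables <- function(M, exp) {
  key_exp <- paste(exp$entries$index, exp$entries$aa, exp$entries$nucleus,
                   sep = ":")
  hit <- match(colnames(M), key_exp)
  cols <- which(!is.na(hit))
  if (!length(cols))
    stop("no overlap between experimental shifts and matrix observables")
  list(y = exp$entries$ppm[hit[cols]], columns = cols)
}

#' Export / import a prediction matrix as CSV
#'
#' Rows are conformer ids, columns `index:aa:nucleus` observables, so a
#' matrix precomputed by an external shift predictor can be substituted
#' for the built-in model.
#'
#' @param M a `shift_matrix`.
#' @param path file path.
#' @export
write_shift_matrix_csv <- function(M, path) {
  df <- data.frame(conformer = seq_len(nrow(M)), M, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_shift_matrix_csv
#' @export
read_shift_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- NULL
  structure(M, class = c("shift_matrix", "matrix", "array"))
}
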