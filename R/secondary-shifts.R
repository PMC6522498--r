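# Secondary chemical shifts, the (dCa - dCb) helicity indicator, and the
# windowed secondary-structure-propensity (SSP) score.

#' Compute secondary chemical shifts
#'
#' The secondary shift of a nucleus is the observed shift minus the
#' random-coil reference for that residue type. The per-residue
#' difference (delta-delta-Ca minus delta-delta-Cb) is a robust helicity
#' indicator for disordered proteins: sustained positive values signal
#' helical population, negative values extended structure.
#'
#' @param shifts a [shift_table()] of observed (or predicted) shifts.
#' @param rc a [random_coil_table()].
#' @return An object of class `secondary_shift_profile`: a data frame
#'   with one row per residue (`index`, `aa`), one column per nucleus
#'   (`dH`, `dN`, `dHA`, `dCA`, `dCB`, NA when the shift is missing) and
#'   `dCaCb` (NA unless both CA and CB secondary shifts are present).
#' @examples
#' rc <- random_coil_table()
#' tbl <- shift_table(data.frame(index = 1, aa = "A", nucleus = "CA",
#'                               ppm = 54.5))
#' secondary_shifts(tbl, rc)
#' @export
secondary_shifts <- function(shifts, rc) {
  stopifnot(inherits(shifts, "shift_table"))
  if (nrow(shifts$entries) == 0L) stop("empty shift table")
  seq1 <- strsplit(shifts$sequence, "")[[1]]
  idx <- sort(unique(shifts$entries$index))
  prof <- data.frame(index = idx, aa = seq1[idx], stringsAsFactors = FALSE)
  for (nuc in SUPPORTED_NUCLEI)
    prof[[paste0("d", nuc)]] <- NA_real_
  e <- shifts$entries
  for (r in seq_len(nrow(e))) {
    aa <- e$aa[r]; nuc <- e$nucleus[r]
    if (aa == "G" && nuc == "CB") next
    if (aa == "P" && nuc == "H") next
    next_aa <- if (e$index[r] < length(seq1)) seq1[e$index[r] + 1L] else NULL
    ref <- random_coil_lookup(rc, aa, nuc, next_aa = next_aa)
    prof[prof$index == e$index[r], paste0("d", nuc)] <- e$ppm[r] - ref
  }
  prof$dCaCb <- ifelse(is.na(prof$dCA) | is.na(prof$dCB), NA_real_,
                       prof$dCA - prof$dCB)
  structure(prof, class = c("secondary_shift_profile", "data.frame"))
}

#' Secondary-structure-propensity (SSP) score
#'
#' Maps secondary shifts onto a dimensionless propensity scale where +1
#' is a fully formed alpha helix and -1 a fully formed extended strand.
#' Each available secondary shift in a sliding window is normalised by
#' the bundled fully-formed helix offset (when it points in the helix
#' direction) or fully-formed strand offset (when it points the other
#' way), observations are weighted by nucleus sensitivity, and
#' observations more than `outlier_sd` standard deviations from the
#' window consensus are excluded before the final weighted average.
#'
#' @param profile a [secondary_shifts()] result.
#' @param window odd window length in residues (default 5).
#' @param nuclei nuclei to use.
#' @param offsets reference offsets, see [ss_reference_offsets()].
#' @param weights named nucleus sensitivity weights.
#' @param outlier_sd exclusion cutoff in window standard deviations.
#' @param min_coverage minimum number of window residues with at least one
#'   usable nucleus for a score to be reported.
#' @return An object of class `ssp_profile`: data frame with columns
#'   `index`, `aa`, `ssp` (NA where coverage is insufficient), plus the
#'   parameters as attributes.
#' @export
ssp_score <- function(profile, window = 5L,
                      nuclei = c("H", "N", "HA", "CA", "CB"),
                      offsets = ss_reference_offsets(),
                      weights = SSP_NUCLEUS_WEIGHTS,
                      outlier_sd = 1,
                      min_coverage = 3L) {
  stopifnot(inherits(profile, "secondary_shift_profile"))
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  nuclei <- match.arg(nuclei, SUPPORTED_NUCLEI, several.ok = TRUE)

  # normalised propensity of one observation: +1 at the helix offset,
  # -1 at the strand offset, linear in between/beyond
  norm_obs <- function(d, nuc) {
    h <- offsets[nuc, "helix"]; s <- offsets[nuc, "strand"]
    if (is.na(d)) return(NA_real_)
    if (d == 0) return(0)
    if (sign(d) == sign(h)) d / h else -(d / s)
  }

  idx_all <- profile$index
  full_idx <- seq(min(idx_all), max(idx_all))
  row_of <- match(full_idx, idx_all)

  x_mat <- matrix(NA_real_, nrow = length(full_idx), ncol = length(nuclei),
                  dimnames = list(NULL, nuclei))
  for (j in seq_along(nuclei)) {
    col <- profile[[paste0("d", nuclei[j])]]
    x_mat[!is.na(row_of), j] <-
      vapply(col[row_of[!is.na(row_of)]], norm_obs, numeric(1),
             nuc = nuclei[j])
  }
  if (all(is.na(x_mat)))
    stop("no usable nuclei anywhere in the profile")

  half <- (window - 1L) %/% 2L
  w_nuc <- weights[nuclei]
  scores <- rep(NA_real_, length(full_idx))
  for (i in seq_along(full_idx)) {
    lo <- max(1L, i - half); hi <- min(length(full_idx), i + half)
    rows <- lo:hi
    sub <- x_mat[rows, , drop = FALSE]
    covered <- sum(apply(sub, 1L, function(r) any(!is.na(r))))
    if (covered < min_coverage) next
    xs <- as.vector(sub)
    ws <- rep(w_nuc, each = length(rows))
    keep <- !is.na(xs)
    xs <- xs[keep]; ws <- ws[keep]
    if (!length(xs)) next
    if (length(xs) >= 3L) {
      m <- mean(xs); s <- stats::sd(xs)
      inl <- abs(xs - m) <= outlier_sd * s
      if (any(inl)) { xs <- xs[inl]; ws <- ws[inl] }
    }
    scores[i] <- sum(ws * xs) / sum(ws)
  }

  out <- data.frame(index = full_idx,
                    aa = ifelse(is.na(row_of), "X", profile$aa[row_of]),
                    ssp = scores, stringsAsFactors = FALSE)
  structure(out,
            class = c("ssp_profile", "data.frame"),
            window = window, nuclei = nuclei, outlier_sd = outlier_sd)
}

#' Call contiguous high-propensity segments
#'
#' Maximal runs of at least three consecutive residues whose SSP score is
#' at or above `threshold`, reported with each run's mean score. Used to
#' summarise helical stretches such as the ARR2 motif.
#'
#' @param ssp an [ssp_score()] result.
#' @param threshold positive score threshold.
#' @param min_len minimum run length (default 3).
#' @return Data frame with columns `start`, `end`, `mean_score`
#'   (zero rows if no run qualifies).
#' @export
call_segments <- function(ssp, threshold, min_len = 3L) {
  stopifnot(inherits(ssp, "ssp_profile"))
  if (!is.numeric(threshold) || threshold <= 0) stop("threshold must be > 0")
  hit <- !is.na(ssp$ssp) & ssp$ssp >= threshold
  out <- data.frame(start = integer(0), end = integer(0),
                    mean_score = numeric(0))
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] && r$lengths[k] >= min_len) {
      i0 <- starts[k]; i1 <- ends[k]
      out <- rbind(out, data.frame(
        start = ssp$index[i0], end = ssp$index[i1],
        mean_score = mean(ssp$ssp[i0:i1])))
    }
  }
  out
}
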