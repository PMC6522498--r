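# Hydrogen/deuterium exchange: slow/fast amide classification from HSQC
# peak intensities at exchange time points versus an H2O control.

#' Construct an HDX intensity series
#'
#' @param data data frame with columns `index`, `aa`, `assigned`
#'   (logical; FALSE for unassigned polyQ Gln pseudo-residues), `ctrl`
#'   (H2O control intensity) and one `i<t>` column per exchange time
#'   point in minutes (e.g. `i15`, `i60`, `i120`).
#' @param times numeric exchange times in minutes, strictly increasing;
#'   inferred from the column names by default.
#' @return Object of class `hdx_series`.
#' @export
hdx_series <- function(data, times = NULL) {
  data <- as.data.frame(data)
  req <- c("index", "aa", "assigned", "ctrl")
  if (!all(req %in% names(data)))
    stop("HDX data must have columns ", paste(req, collapse = ", "))
  icols <- grep("^i[0-9]+$", names(data), value = TRUE)
  if (is.null(times)) times <- as.numeric(sub("^i", "", icols))
  ord <- order(times)
  times <- times[ord]; icols <- icols[ord]
  if (length(times) == 0L) stop("no exchange time columns (i<minutes>)")
  if (any(diff(times) <= 0)) stop("time points must be strictly increasing")
  ints <- as.matrix(data[icols])
  if (any(ints < 0, na.rm = TRUE) || any(data$ctrl < 0, na.rm = TRUE))
    stop("intensities must be >= 0")
  structure(list(data = data[req], intensities = ints, times = times),
            class = "hdx_series")
}

#' Classify amides as slow or fast exchangers
#'
#' An amide is a slow exchanger when its peak intensity after `t_ref`
#' minutes of exchange is at least `ratio_threshold` of the H2O control
#' (mirroring the presence/absence of peaks in an HSQC recorded after
#' exchange). Prolines (no amide proton) and residues without a control
#' peak are excluded. Optionally the mean log-intensity slope over all
#' time points is used instead of the single-time ratio.
#'
#' @param series an [hdx_series()].
#' @param t_ref reference exchange time in minutes (default 15); must be
#'   one of the series' time points.
#' @param ratio_threshold intensity ratio at or above which an amide
#'   counts as slow (default 0.2).
#' @param method `"ratio"` (default) or `"slope"`; slope classifies as
#'   slow when the fitted exponential decay would still leave
#'   `ratio_threshold` of the signal at `t_ref`.
#' @return Object of class `hdx_map`: data frame `index`, `aa`, `ratio`,
#'   `label` with labels `+` (slow, assigned), `*` (slow, unassigned
#'   polyQ Gln), `fast`, `excluded`.
#' @export
classify_hdx <- function(series, t_ref = 15, ratio_threshold = 0.2,
                         method = c("ratio", "slope")) {
  stopifnot(inherits(series, "hdx_series"))
  method <- match.arg(method)
  it <- which(series$times == t_ref)
  if (!length(it))
    stop("t_ref = ", t_ref, " min is not among the series' time points")
  d <- series$data
  if (all(is.na(d$ctrl) | d$ctrl == 0)) stop("no control intensities")

  ratio <- rep(NA_real_, nrow(d))
  label <- rep("excluded", nrow(d))
  usable <- !is.na(d$ctrl) & d$ctrl > 0 & d$aa != "P"
  if (method == "ratio") {
    ratio[usable] <- series$intensities[usable, it] / d$ctrl[usable]
  } else {
    for (r in which(usable)) {
      y <- series$intensities[r, ] / d$ctrl[r]
      pos <- y > 0
      if (sum(pos) >= 2) {
        fit <- stats::lm(log(y[pos]) ~ series$times[pos])
        ratio[r] <- exp(sum(stats::coef(fit) * c(1, t_ref)))
      } else {
        ratio[r] <- if (y[it] > 0) y[it] else 0
      }
    }
  }
  slow <- usable & !is.na(ratio) & ratio >= ratio_threshold
  label[usable] <- "fast"
  label[slow & d$assigned] <- "+"
  label[slow & !d$assigned] <- "*"
  structure(data.frame(index = d$index, aa = d$aa, ratio = ratio,
                       label = label, stringsAsFactors = FALSE),
            class = c("hdx_map", "data.frame"),
            t_ref = t_ref, ratio_threshold = ratio_threshold,
            method = method)
}

#' Count and compare slow exchangers between two maps
#'
#' @param a,b [classify_hdx()] maps.
#' @param region_a integer `c(start, end)` region in a's numbering.
#' @param region_b same for b (default `region_a`).
#' @return List with `slow_a`, `slow_b` (counts of slow residues, labels
#'   `+` or `*`, inside each region) and `difference` = b - a.
#' @export
compare_hdx <- function(a, b, region_a, region_b = region_a) {
  count_slow <- function(m, r) {
    i <- m$index >= r[1] & m$index <= r[2]
    sum(m$label[i] %in% c("+", "*"))
  }
  na <- count_slow(a, region_a)
  nb <- count_slow(b, region_b)
  list(slow_a = na, slow_b = nb, difference = nb - na)
}

#' Read / write HDX tables as CSV
#'
#' Input layout `index,aa,assigned,ctrl,i15,i60,i120` (time columns may
#' vary); output maps add the classification label column.
#'
#' @param path file path.
#' @return `read_hdx_csv` returns an [hdx_series()].
#' @export
read_hdx_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$assigned <- as.logical(df$assigned)
  hdx_series(df)
}

#' @rdname read_hdx_csv
#' @param map an `hdx_map`.
#' @export
write_hdx_map_csv <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
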