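# Chemical-shift containers and bundled reference tables.

SUPPORTED_NUCLEI <- c("H", "N", "HA", "CA", "CB")

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

# Random-coil backbone chemical shifts (ppm), values after Wishart et al.
# (1995) J Biomol NMR 5:67-81 (pH ~5, 25 C, relative to DSS). Gly has no CB;
# Pro has no amide H (its N is the pyrrolidine nitrogen, retained here for
# completeness of the N column).
RANDOM_COIL_PPM <- local({
  m <- rbind(
    #         H     N      HA    CA    CB
    A = c(8.24, 123.8, 4.32, 52.5, 19.1),
    R = c(8.23, 120.5, 4.34, 56.0, 30.9),
    N = c(8.40, 118.7, 4.74, 53.1, 38.9),
    D = c(8.34, 120.4, 4.64, 54.2, 41.1),
    C = c(8.32, 118.8, 4.55, 58.2, 28.0),
    Q = c(8.32, 119.8, 4.34, 55.7, 29.4),
    E = c(8.42, 120.2, 4.35, 56.6, 29.9),
    G = c(8.33, 108.8, 3.96, 45.1, NA),
    H = c(8.42, 118.2, 4.73, 55.0, 29.0),
    I = c(8.00, 119.9, 4.17, 61.1, 38.8),
    L = c(8.16, 121.8, 4.34, 55.1, 42.4),
    K = c(8.29, 120.4, 4.32, 56.2, 33.1),
    M = c(8.28, 119.6, 4.48, 55.4, 32.9),
    F = c(8.30, 120.3, 4.62, 57.7, 39.6),
    P = c(NA,  135.8, 4.42, 63.3, 32.1),
    S = c(8.31, 115.7, 4.47, 58.3, 63.8),
    T = c(8.15, 113.6, 4.35, 61.8, 69.8),
    W = c(8.09, 121.3, 4.66, 57.5, 29.6),
    Y = c(8.18, 120.3, 4.55, 57.9, 38.8),
    V = c(8.03, 119.2, 4.12, 62.2, 32.9)
  )
  colnames(m) <- SUPPORTED_NUCLEI
  m
})

# Average secondary shifts (ppm) of fully formed secondary structure, used
# both to normalise SSP scores and as the offsets of the linear forward
# shift model. Helix column: expected delta-delta in a well-formed alpha
# helix; strand column: in a well-formed extended strand.
SS_REFERENCE_OFFSETS <- local({
  m <- rbind(
    H  = c(helix = -0.25, strand = 0.35),
    N  = c(helix = -1.50, strand = 2.00),
    HA = c(helix = -0.35, strand = 0.45),
    CA = c(helix =  3.10, strand = -1.50),
    CB = c(helix = -0.50, strand = 2.20)
  )
  m
})

# Relative sensitivity of each nucleus in the SSP weighted average; carbon
# shifts carry most of the information for helix/strand discrimination in
# disordered proteins, amide H/N are down-weighted.
SSP_NUCLEUS_WEIGHTS <- c(H = 0.3, N = 0.3, HA = 0.8, CA = 1.0, CB = 1.0)

#' Bundled random-coil chemical-shift reference table
#'
#' Returns the random-coil backbone chemical shifts bundled with the
#' package, used to turn observed shifts into secondary shifts
#' (observed minus random coil).
#'
#' @param pro_correction logical; if `TRUE`, callers of
#'   [random_coil_lookup()] may apply a correction for residues followed
#'   by proline (the carbonyl-proline contact lowers the preceding
#'   residue's Calpha shift by about 1.9 ppm). Stored as an attribute;
#'   the base table is unchanged.
#' @return An object of class `random_coil_table`: a numeric matrix
#'   (20 amino acids x nuclei H, N, HA, CA, CB) with a `provenance`
#'   attribute. Glycine CB and proline H are `NA` (no such nuclei).
#' @examples
#' rc <- random_coil_table()
#' random_coil_lookup(rc, "A", "CA")
#' @export
random_coil_table <- function(pro_correction = FALSE) {
  structure(
    RANDOM_COIL_PPM,
    provenance = "Random-coil backbone shifts after Wishart et al. (1995) J Biomol NMR 5:67-81",
    pro_correction = isTRUE(pro_correction),
    class = c("random_coil_table", "matrix", "array")
  )
}

#' Look up a random-coil chemical shift
#'
#' @param table a [random_coil_table()].
#' @param aa one-letter amino-acid code.
#' @param nucleus one of `"H"`, `"N"`, `"HA"`, `"CA"`, `"CB"`.
#' @param next_aa optional one-letter code of the following residue; when
#'   the table was built with `pro_correction = TRUE` and `next_aa` is
#'   `"P"`, the CA value is corrected by -1.9 ppm.
#' @return The reference shift in ppm.
#' @export
random_coil_lookup <- function(table, aa, nucleus, next_aa = NULL) {
  stopifnot(inherits(table, "random_coil_table"))
  if (!aa %in% AA1)
    stop("unknown amino-acid code: ", aa)
  if (!nucleus %in% SUPPORTED_NUCLEI)
    stop("unsupported nucleus: ", nucleus)
  v <- table[aa, nucleus]
  if (is.na(v))
    stop("no random-coil value for (", aa, ", ", nucleus, ")")
  if (isTRUE(attr(table, "pro_correction")) &&
      !is.null(next_aa) && identical(next_aa, "P") && nucleus == "CA")
    v <- v - 1.9
  unname(v)
}

#' Reference secondary-shift offsets of fully formed structure
#'
#' Per-nucleus average secondary shifts of a well-formed alpha helix and a
#' well-formed extended strand, used to normalise SSP scores onto the
#' -1..+1 scale and as the offsets of the linear forward shift model.
#'
#' @return Numeric matrix with rows H, N, HA, CA, CB and columns
#'   `helix`, `strand`, with a `provenance` attribute.
#' @export
ss_reference_offsets <- function() {
  structure(SS_REFERENCE_OFFSETS,
            provenance = "Average secondary shifts of fully formed helix/strand, after Wishart & Sykes (1994) Methods Enzymol 239:363-392")
}

#' Construct a chemical-shift table
#'
#' A `shift_table` holds one value per (residue, nucleus) pair for the
#' backbone nuclei H, N, HA, CA and CB, together with the one-letter
#' sequence it refers to. Residue indices are 1-based in the
#' normal-polyQ-length (10Q) numbering frame.
#'
#' @param entries data frame with columns `index` (integer), `aa`
#'   (one-letter code), `nucleus`, `ppm`.
#' @param sequence optional one-letter sequence string; if omitted it is
#'   reconstructed from `entries` (gaps become `"X"`).
#' @param label free-text label (e.g. variant name).
#' @return An object of class `shift_table`.
#' @export
shift_table <- function(entries, sequence = NULL, label = "") {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  req <- c("index", "aa", "nucleus", "ppm")
  if (!all(req %in% names(entries)))
    stop("entries must have columns ", paste(req, collapse = ", "))
  entries <- entries[req]
  entries$index <- as.integer(entries$index)
  entries$ppm <- as.numeric(entries$ppm)
  if (nrow(entries)) {
    if (any(entries$index < 1L)) stop("residue index must be >= 1")
    bad <- !entries$aa %in% AA1
    if (any(bad))
      stop("non-standard amino-acid code(s): ",
           paste(unique(entries$aa[bad]), collapse = ", "))
    if (!all(entries$nucleus %in% SUPPORTED_NUCLEI))
      stop("unsupported nucleus in entries")
    if (any(!is.finite(entries$ppm))) stop("non-finite ppm value")
    gcb <- entries$aa == "G" & entries$nucleus == "CB"
    if (any(gcb))
      stop("glycine has no CB: residue ",
           paste(entries$index[gcb], collapse = ", "))
    key <- paste(entries$index, entries$nucleus)
    if (anyDuplicated(key)) {
      d <- key[duplicated(key)]
      dup <- entries[key %in% d, , drop = FALSE]
      agg <- tapply(dup$ppm, paste(dup$index, dup$nucleus),
                    function(v) diff(range(v)))
      if (any(agg > 1e-9))
        stop("conflicting duplicate shift for residue/nucleus: ",
             paste(names(agg)[agg > 1e-9], collapse = "; "))
      entries <- entries[!duplicated(key), , drop = FALSE]
    }
  }
  if (is.null(sequence)) {
    n <- if (nrow(entries)) max(entries$index) else 0L
    s <- rep("X", n)
    s[entries$index] <- entries$aa
    sequence <- paste(s, collapse = "")
  } else {
    sequence <- as.character(sequence)
    if (nrow(entries)) {
      if (max(entries$index) > nchar(sequence))
        stop("entry index exceeds sequence length")
      seq_aa <- strsplit(sequence, "")[[1]][entries$index]
      if (any(seq_aa != entries$aa))
        stop("entry amino acid disagrees with sequence at index ",
             paste(entries$index[seq_aa != entries$aa], collapse = ", "))
    }
  }
  entries <- entries[order(entries$index,
                           match(entries$nucleus, SUPPORTED_NUCLEI)), ,
                     drop = FALSE]
  rownames(entries) <- NULL
  structure(list(entries = entries, sequence = sequence, label = label),
            class = "shift_table")
}

#' @export
print.shift_table <- function(x, ...) {
  cat("<shift_table>", if (nzchar(x$label)) x$label else NULL, "\n")
  cat("  sequence: ", x$sequence, "\n", sep = "")
  cat("  ", nrow(x$entries), " shifts over ",
      length(unique(x$entries$index)), " residues, nuclei: ",
      paste(sort(unique(x$entries$nucleus)), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
format.shift_table <- function(x, ...) {
  paste0("shift_table[", nrow(x$entries), " entries]")
}

# Numeric lookup helper: ppm for (index, nucleus), NA when absent.
shift_value <- function(x, index, nucleus) {
  i <- x$entries$index == index & x$entries$nucleus == nucleus
  if (any(i)) x$entries$ppm[which(i)[1]] else NA_real_
}

#' Test two shift tables for equality
#'
#' Entries are compared as sets (order-independent) with an absolute
#' tolerance on the ppm values.
#'
#' @param a,b `shift_table` objects.
#' @param tol absolute tolerance in ppm.
#' @return logical.
#' @export
shift_tables_equal <- function(a, b, tol = 1e-3) {
  ea <- a$entries[order(ea_key(a)), , drop = FALSE]
  eb <- b$entries[order(ea_key(b)), , drop = FALSE]
  nrow(ea) == nrow(eb) &&
    all(ea$index == eb$index) &&
    all(ea$aa == eb$aa) &&
    all(ea$nucleus == eb$nucleus) &&
    all(abs(ea$ppm - eb$ppm) <= tol)
}

ea_key <- function(x)
  paste(sprintf("%06d", x$entries$index), x$entries$nucleus)
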