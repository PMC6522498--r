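# Readers and writers for assigned chemical shifts.
#
# NMR-STAR support is deliberately minimal: the single assigned-chemical-
# shift loop of a 2.1 or 3.1 entry, which is all a backbone-shift analysis
# needs. Everything else in the file is ignored.

#' Read assigned chemical shifts from an NMR-STAR file
#'
#' Parses the assigned-chemical-shift loop of an NMR-STAR 2.1 or 3.1
#' entry (the format of BMRB depositions) into a [shift_table()].
#' Nuclei other than H, N, HA, CA, CB are dropped with a message; HA2/HA3
#' of glycine are averaged into a single HA value.
#'
#' @param path path to a `.str` file.
#' @param label label for the resulting table; defaults to the file name.
#' @return A [shift_table()].
#' @export
read_star <- function(path, label = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  toks <- star_tokens(lines)
  loops <- star_loops(toks)

  loop <- NULL
  for (lp in loops) {
    tags <- tolower(lp$tags)
    if (any(grepl("^_atom_chem_shift\\.", tags)) ||
        ("_atom_name" %in% tags && "_chem_shift_value" %in% tags)) {
      loop <- lp
      break
    }
  }
  if (is.null(loop))
    stop("no assigned chemical-shift loop found in ", path)

  tags <- tolower(loop$tags)
  pick <- function(cands) {
    i <- which(tags %in% cands)
    if (!length(i)) stop("shift loop lacks required tag (", cands[1], ")")
    i[1]
  }
  i_seq <- pick(c("_atom_chem_shift.seq_id", "_atom_chem_shift.comp_index_id",
                  "_residue_seq_code"))
  i_comp <- pick(c("_atom_chem_shift.comp_id", "_residue_label"))
  i_atom <- pick(c("_atom_chem_shift.atom_id", "_atom_name"))
  i_val <- pick(c("_atom_chem_shift.val", "_chem_shift_value"))

  nt <- length(loop$tags)
  vals <- loop$values
  if (length(vals) %% nt != 0)
    stop("malformed shift loop: ", length(vals),
         " values for ", nt, " tags")
  m <- matrix(vals, ncol = nt, byrow = TRUE)

  idx <- suppressWarnings(as.integer(m[, i_seq]))
  comp <- toupper(m[, i_comp])
  aa <- unname(AA3TO1[comp])
  one <- nchar(comp) == 1 & comp %in% AA1
  aa[one] <- comp[one]
  atom <- toupper(m[, i_atom])
  ppm <- suppressWarnings(as.numeric(m[, i_val]))

  bad <- is.na(idx) | is.na(aa) | is.na(ppm)
  if (any(bad))
    stop("unparseable shift row(s) in ", path, ": ",
         paste(which(bad)[seq_len(min(3, sum(bad)))], collapse = ", "))

  atom[atom == "HN"] <- "H"
  is_ha23 <- atom %in% c("HA2", "HA3")
  n_drop <- sum(!(atom %in% SUPPORTED_NUCLEI | is_ha23))
  keep <- atom %in% SUPPORTED_NUCLEI | is_ha23
  if (n_drop > 0)
    message("read_star: dropped ", n_drop, " shift(s) on unsupported nuclei")
  idx <- idx[keep]; aa <- aa[keep]; atom <- atom[keep]; ppm <- ppm[keep]

  # Gly HA2/HA3 -> single averaged HA
  if (any(atom %in% c("HA2", "HA3"))) {
    ha <- atom %in% c("HA2", "HA3")
    key <- paste(idx[ha], aa[ha])
    avg <- tapply(ppm[ha], key, mean)
    first <- !duplicated(key)
    idx2 <- idx[ha][first]; aa2 <- aa[ha][first]
    ppm2 <- as.numeric(avg[paste(idx2, aa2)])
    idx <- c(idx[!ha], idx2); aa <- c(aa[!ha], aa2)
    atom <- c(atom[!ha], rep("HA", length(idx2)))
    ppm <- c(ppm[!ha], ppm2)
  }

  shift_table(data.frame(index = idx, aa = aa, nucleus = atom, ppm = ppm,
                         stringsAsFactors = FALSE),
              label = label)
}

# Tokenize STAR text: whitespace-separated fields; quoted strings and
# semicolon text blocks become single tokens.
star_tokens <- function(lines) {
  out <- character(0)
  in_text <- FALSE
  for (ln in lines) {
    if (in_text) {
      if (grepl("^;", ln)) in_text <- FALSE
      next
    }
    if (grepl("^;", ln)) { in_text <- TRUE; next }
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    out <- c(out, scan(text = ln, what = character(), quiet = TRUE))
  }
  out
}

star_loops <- function(toks) {
  loops <- list()
  i <- 1L
  n <- length(toks)
  while (i <= n) {
    if (toks[i] == "loop_") {
      j <- i + 1L
      tags <- character(0)
      while (j <= n && startsWith(toks[j], "_")) {
        tags <- c(tags, toks[j]); j <- j + 1L
      }
      vals <- character(0)
      while (j <= n && !(toks[j] %in% c("loop_", "stop_")) &&
             !startsWith(toks[j], "_") &&
             !startsWith(toks[j], "save_") &&
             !startsWith(toks[j], "data_")) {
        vals <- c(vals, toks[j]); j <- j + 1L
      }
      loops[[length(loops) + 1L]] <- list(tags = tags, values = vals)
      i <- j
      if (i <= n && toks[i] == "stop_") i <- i + 1L
    } else i <- i + 1L
  }
  loops
}

#' Read / write chemical shifts as CSV
#'
#' CSV layout is `index,aa,nucleus,ppm`, one row per assigned shift.
#' `read_csv_shifts(write_csv_shifts(t, f))` reproduces `t`.
#'
#' @param path file path.
#' @param label label for the resulting table.
#' @return `read_csv_shifts` returns a [shift_table()];
#'   `write_csv_shifts` returns `path` invisibly.
#' @export
read_csv_shifts <- function(path, label = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(NA, "character", "character", NA))
  req <- c("index", "aa", "nucleus", "ppm")
  if (!all(req %in% names(df)))
    stop("shift CSV must have header index,aa,nucleus,ppm: ", path)
  if (nrow(df)) {
    idx <- suppressWarnings(as.integer(df$index))
    ppm <- suppressWarnings(as.numeric(df$ppm))
    bad <- which(is.na(idx) | is.na(ppm))
    if (length(bad))
      stop("malformed shift row at line ", bad[1] + 1L, " of ", path)
    df$index <- idx; df$ppm <- ppm
  }
  shift_table(df, label = label)
}

#' @rdname read_csv_shifts
#' @param table a [shift_table()].
#' @export
write_csv_shifts <- function(table, path) {
  stopifnot(inherits(table, "shift_table"))
  utils::write.csv(table$entries, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
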