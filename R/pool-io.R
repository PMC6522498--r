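# Conformer-pool I/O: multi-model backbone PDB and dihedral CSV tables.

#' Write a conformer pool as a multi-model PDB file
#'
#' Backbone atoms only (N, CA, C, O), chain A, MODEL/ENDMDL delimited,
#' residues numbered 1-based.
#'
#' @param pool list of `conformer` objects (coordinates built on demand).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pool_pdb <- function(pool, path) {
  con <- file(path, "w")
  on.exit(close(con))
  aa3 <- stats::setNames(names(AA3TO1), AA3TO1)
  for (k in seq_along(pool)) {
    cf <- pool[[k]]
    if (is.null(cf$xyz)) cf <- build_chain(cf$sequence, cf$phi, cf$psi)
    writeLines(sprintf("MODEL     %4d", k), con)
    seq1 <- strsplit(cf$sequence, "")[[1]]
    serial <- 0L
    for (i in seq_along(seq1)) {
      for (at in c("N", "CA", "C", "O")) {
        serial <- serial + 1L
        p <- cf$xyz[[at]][i, ]
        el <- substr(at, 1, 1)
        writeLines(sprintf(
          "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, paste0(" ", at), aa3[seq1[i]], i, p[1], p[2], p[3], el),
          con)
      }
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a conformer pool from a multi-model PDB file
#'
#' Uses `bio3d` to parse the file; backbone dihedrals are recomputed from
#' the coordinates so that secondary structure can be assigned.
#'
#' @param path PDB file path.
#' @return List of `conformer` objects.
#' @export
read_pool_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  sel <- bio3d::atom.select(pdb, elety = c("N", "CA", "C", "O"),
                            verbose = FALSE)
  atoms <- pdb$atom[sel$atom, , drop = FALSE]
  resno <- sort(unique(atoms$resno))
  n <- length(resno)
  aa <- vapply(resno, function(r) {
    unname(AA3TO1[atoms$resid[atoms$resno == r][1]])
  }, character(1))
  sequence <- paste(aa, collapse = "")
  nmod <- nrow(pdb$xyz)
  pool <- vector("list", nmod)
  for (k in seq_len(nmod)) {
    xyz <- matrix(pdb$xyz[k, sel$xyz], ncol = 3, byrow = TRUE)
    get <- function(elety) {
      rows <- which(atoms$elety == elety)
      m <- matrix(NA_real_, n, 3)
      m[match(atoms$resno[rows], resno), ] <- xyz[rows, , drop = FALSE]
      m
    }
    co <- list(N = get("N"), CA = get("CA"), C = get("C"), O = get("O"))
    dh <- backbone_dihedrals(co)
    cf <- conformer(sequence, dh$phi, dh$psi, xyz = co)
    pool[[k]] <- cf
  }
  pool
}

# phi/psi (degrees) from backbone coordinates
backbone_dihedrals <- function(co) {
  n <- nrow(co$N)
  phi <- rep(NA_real_, n)
  psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1)
      phi[i] <- dihedral4(co$C[i - 1, ], co$N[i, ], co$CA[i, ], co$C[i, ])
    if (i < n)
      psi[i] <- dihedral4(co$N[i, ], co$CA[i, ], co$C[i, ], co$N[i + 1, ])
  }
  list(phi = phi, psi = psi)
}

dihedral4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

#' Read / write dihedral tables
#'
#' CSV with columns `model,index,phi,psi`; one row per residue per pool
#' member, `NA` for the undefined terminal dihedrals.
#'
#' @param pool list of `conformer` objects.
#' @param sequence sequence string the dihedrals refer to (reading).
#' @param path file path.
#' @return `read_dihedral_csv` returns a list of `conformer`s.
#' @export
write_dihedral_csv <- function(pool, path) {
  rows <- do.call(rbind, lapply(seq_along(pool), function(k) {
    cf <- pool[[k]]
    data.frame(model = k, index = seq_len(nchar(cf$sequence)),
               phi = cf$phi, psi = cf$psi)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dihedral_csv
#' @export
read_dihedral_csv <- function(path, sequence) {
  df <- utils::read.csv(path)
  lapply(split(df, df$model), function(d) {
    d <- d[order(d$index), ]
    conformer(sequence, d$phi, d$psi)
  })
}
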