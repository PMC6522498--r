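# Backbone conformer model: build coordinates from (phi, psi), assign
# three-state secondary structure from dihedral basins, summarise helix
# content.
#
# Ideal geometry (fixed): N-CA 1.46 A, CA-C 1.52 A, C-N 1.33 A, C=O 1.23 A;
# angles N-CA-C 111, CA-C-N 116, C-N-CA 121, CA-C-O 120.5 degrees; trans
# peptide bond (omega = 180).

BOND_N_CA <- 1.46
BOND_CA_C <- 1.52
BOND_C_N <- 1.33
BOND_C_O <- 1.23
ANGLE_N_CA_C <- 111.0
ANGLE_CA_C_N <- 116.0
ANGLE_C_N_CA <- 121.0
ANGLE_CA_C_O <- 120.5

# Dihedral basins of the simplified three-state assignment (degrees).
HELIX_BASIN <- list(phi = c(-100, -30), psi = c(-80, 0))
STRAND_BASIN <- list(phi = c(-180, -90), psi = c(90, 180))

#' Construct a conformer
#'
#' @param sequence one-letter sequence string.
#' @param phi,psi backbone dihedrals in degrees, one per residue;
#'   `phi[1]` and `psi[n]` are `NA` (undefined at the termini).
#' @param xyz optional backbone coordinates (built on demand otherwise).
#' @return Object of class `conformer`.
#' @export
conformer <- function(sequence, phi, psi, xyz = NULL) {
  n <- nchar(sequence)
  if (length(phi) != n || length(psi) != n)
    stop("sequence (", n, ") and dihedral (", length(phi), "/",
         length(psi), ") lengths differ")
  structure(list(sequence = sequence, phi = phi, psi = psi, xyz = xyz,
                 ss = NULL),
            class = "conformer")
}

#' Build backbone coordinates from dihedrals
#'
#' Places N, CA, C and O atoms for every residue with ideal bond lengths
#' and angles and trans peptide bonds, by sequential natural-extension
#' (torsion-driven) placement. Deterministic: identical inputs give
#' bitwise-identical coordinates.
#'
#' @param sequence one-letter sequence string.
#' @param phi,psi dihedrals in degrees (`phi[1]`, `psi[n]` ignored/NA).
#' @return A `conformer` whose `xyz` is a list of `n x 3` matrices
#'   (`N`, `CA`, `C`, `O`), rows = residues.
#' @export
build_chain <- function(sequence, phi, psi) {
  cf <- conformer(sequence, phi, psi)
  n <- nchar(sequence)

  # seed atoms of residue 1
  N1 <- c(0, 0, 0)
  CA1 <- c(BOND_N_CA, 0, 0)
  a <- ANGLE_N_CA_C * pi / 180
  C1 <- CA1 + BOND_CA_C * c(-cos(a), sin(a), 0)

  Nm <- matrix(NA_real_, n, 3)
  CAm <- matrix(NA_real_, n, 3)
  Cm <- matrix(NA_real_, n, 3)
  Om <- matrix(NA_real_, n, 3)
  Nm[1, ] <- N1; CAm[1, ] <- CA1; Cm[1, ] <- C1

  for (i in seq_len(n)) {
    if (i > 1) {
      # N(i): torsion psi(i-1) about CA(i-1)-C(i-1)
      Nm[i, ] <- place_atom(Nm[i - 1, ], CAm[i - 1, ], Cm[i - 1, ],
                            BOND_C_N, ANGLE_CA_C_N, psi[i - 1])
      # CA(i): torsion omega = 180 about C(i-1)-N(i)
      CAm[i, ] <- place_atom(CAm[i - 1, ], Cm[i - 1, ], Nm[i, ],
                             BOND_N_CA, ANGLE_C_N_CA, 180)
      # C(i): torsion phi(i) about N(i)-CA(i)
      Cm[i, ] <- place_atom(Cm[i - 1, ], Nm[i, ], CAm[i, ],
                            BOND_CA_C, ANGLE_N_CA_C, phi[i])
    }
    # carbonyl O: in the peptide plane, torsion psi(i)+180 about
    # N(i)-CA(i)-C(i); terminal residue uses a trans-like placement
    psi_i <- if (is.na(psi[i])) 180 else psi[i]
    Om[i, ] <- place_atom(Nm[i, ], CAm[i, ], Cm[i, ],
                          BOND_C_O, ANGLE_CA_C_O, psi_i + 180)
  }
  cf$xyz <- list(N = Nm, CA = CAm, C = Cm, O = Om)
  cf
}

# Place atom D given positions A, B, C, bond |CD|, angle B-C-D (deg) and
# torsion A-B-C-D (deg). Standard internal-to-Cartesian conversion.
place_atom <- function(A, B, C, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  nv <- pracma_cross(ab, bc)
  nv <- nv / sqrt(sum(nv^2))
  m <- pracma_cross(nv, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          -bond * sin(ang) * sin(tor))
  C + d2[1] * bc + d2[2] * m + d2[3] * nv
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

in_basin <- function(phi, psi, basin) {
  !is.na(phi) & !is.na(psi) &
    phi >= basin$phi[1] & phi <= basin$phi[2] &
    psi >= basin$psi[1] & psi <= basin$psi[2]
}

#' Assign three-state secondary structure from dihedrals
#'
#' A simplified dihedral-basin assignment standing in for a hydrogen-bond
#' based method: a residue is helical (H) when its (phi, psi) lies in the
#' helical basin as part of a run of at least `min_h` consecutive such
#' residues, extended (E) for runs of at least `min_e` residues in the
#' extended basin, otherwise coil (C). Residues lacking a dihedral
#' (chain termini) are coil.
#'
#' @param cf a `conformer`.
#' @param min_h,min_e minimum run lengths for H and E.
#' @return Character scalar over `{H,E,C}`, one letter per residue
#'   (class `ss_assignment`).
#' @export
assign_ss <- function(cf, min_h = 3L, min_e = 2L) {
  stopifnot(inherits(cf, "conformer"))
  n <- nchar(cf$sequence)
  h <- in_basin(cf$phi, cf$psi, HELIX_BASIN)
  e <- in_basin(cf$phi, cf$psi, STRAND_BASIN)
  ss <- rep("C", n)
  ss[runs_at_least(h, min_h)] <- "H"
  ss[runs_at_least(e, min_e)] <- "E"
  structure(paste(ss, collapse = ""), class = "ss_assignment")
}

# logical positions that belong to a TRUE-run of length >= k
runs_at_least <- function(x, k) {
  r <- rle(x)
  keep <- r$values & r$lengths >= k
  inverse.rle(list(values = keep, lengths = r$lengths))
}

ss_chars <- function(ss) strsplit(unclass(ss), "")[[1]]

#' Helix content of a region
#'
#' @param ss an [assign_ss()] result.
#' @param region integer vector `c(start, end)` (1-based, inclusive).
#' @return Fraction of H residues in the region, in `[0, 1]`.
#' @export
helix_content <- function(ss, region) {
  ch <- ss_chars(ss)
  if (region[1] < 1 || region[2] > length(ch) || region[1] > region[2])
    stop("empty or out-of-range region")
  mean(ch[region[1]:region[2]] == "H")
}

# cached SS: compute once per conformer
conformer_ss <- function(cf) {
  if (is.null(cf$ss)) assign_ss(cf) else cf$ss
}
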