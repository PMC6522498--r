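# Shared fixtures, built in code at test time.

# minimal NMR-STAR 3.1 assigned-chemical-shift loop
write_star_fixture <- function(path, rows) {
  lines <- c(
    "data_test_entry",
    "save_assigned_chemical_shifts",
    "loop_",
    "  _Atom_chem_shift.ID",
    "  _Atom_chem_shift.Seq_ID",
    "  _Atom_chem_shift.Comp_ID",
    "  _Atom_chem_shift.Atom_ID",
    "  _Atom_chem_shift.Val",
    vapply(seq_len(nrow(rows)), function(r)
      sprintf("  %d %d %s %s %.3f", r, rows$index[r], rows$comp[r],
              rows$atom[r], rows$ppm[r]), character(1)),
    "stop_",
    "save_"
  )
  writeLines(lines, path)
  path
}

# shift table whose secondary shifts are `scale` times the fully formed
# helix (or strand) offsets, for every nucleus of every residue
calibration_table <- function(sequence, mode = c("helix", "strand"),
                              scale = 1) {
  mode <- match.arg(mode)
  rc <- random_coil_table()
  off <- ss_reference_offsets()
  seq1 <- strsplit(sequence, "")[[1]]
  rows <- list()
  for (i in seq_along(seq1)) {
    for (nu in c("H", "N", "HA", "CA", "CB")) {
      if (seq1[i] == "G" && nu == "CB") next
      if (seq1[i] == "P" && nu %in% c("H", "N")) next
      rows[[length(rows) + 1L]] <- data.frame(
        index = i, aa = seq1[i], nucleus = nu,
        ppm = random_coil_lookup(rc, seq1[i], nu) + scale * off[nu, mode])
    }
  }
  shift_table(do.call(rbind, rows), sequence = sequence)
}

# conformer with prescribed per-residue states drawn at basin centres
state_conformer <- function(states) {
  n <- length(states)
  phi <- ifelse(states == "H", -57, ifelse(states == "E", -135, -75))
  psi <- ifelse(states == "H", -47, ifelse(states == "E", 135, 150))
  phi[1] <- NA; psi[n] <- NA
  conformer(strrep("A", n), phi, psi)
}

# brute-force simplex grid search over the fit objective
grid_search_weights <- function(M, y, step, l2 = 0) {
  K <- nrow(M)
  obj <- function(w) sum((as.numeric(w %*% M) - y)^2) + l2 * sum(w^2)
  best <- NULL; best_f <- Inf
  if (K == 2) {
    for (a in seq(0, 1, by = step)) {
      f <- obj(c(a, 1 - a))
      if (f < best_f) { best_f <- f; best <- c(a, 1 - a) }
    }
  } else if (K == 3) {
    for (a in seq(0, 1, by = step)) {
      for (b in seq(0, 1 - a, by = step)) {
        f <- obj(c(a, b, 1 - a - b))
        if (f < best_f) { best_f <- f; best <- c(a, b, 1 - a - b) }
      }
    }
  } else stop("grid oracle supports K <= 3")
  list(w = best, objective = best_f)
}
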