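# Bonded-term derivation: conformers are mapped to bead (CG) resolution and
# bond lengths / angles are averaged over the ensemble.

#' Map conformers to coarse-grained resolution
#'
#' Bead positions are mass-weighted centres of their atoms, with implicit
#' hydrogen masses folded onto the parent heavy atoms; bead masses are the
#' summed atomic masses (hydrogens included).
#'
#' @param mapping a `cg_mapping`.
#' @param conformers a `cg_conformers` ensemble for the same molecule.
#' @return list with `xyz` (array `n x nbeads x 3`, nm) and `masses` (u).
#' @export
map_to_cg <- function(mapping, conformers) {
  mol <- mapping$molecule
  atom_mass <- mol$atoms$mass + mol$atoms$nH * .ATOMIC_MASS[["H"]]
  nb <- length(mapping$beads)
  n <- conformers$n
  xyz <- array(NA_real_, dim = c(n, nb, 3))
  masses <- numeric(nb)
  for (b in seq_len(nb)) {
    atoms <- mapping$beads[[b]]$atoms
    w <- atom_mass[atoms]
    masses[b] <- sum(w)
    w <- w / sum(w)
    for (k in seq_len(n)) {
      m <- matrix(conformers$xyz[k, atoms, ], nrow = length(atoms))
      xyz[k, b, ] <- colSums(m * w)
    }
  }
  list(xyz = xyz, masses = masses)
}

#' Derive harmonic bonds and angles from a CG conformer ensemble
#'
#' A bond is emitted for every bead pair joined by at least one atomistic
#' bond and an angle for every connected bead triplet, excluding pairs and
#' triplets whose beads all belong to the same ring system (those are
#' handled by the rigid-ring framework).  Equilibrium values are arithmetic
#' means across the ensemble; force constants are the standard Martini
#' values from the configuration.
#'
#' @param mapping a `cg_mapping`.
#' @param cg output of [map_to_cg()].
#' @param config pipeline configuration (force constants).
#' @return list of class `cg_bonded` with data frames `bonds`
#'   (`i`,`j`,`length_nm`,`sd_nm`,`fc`) and `angles`
#'   (`i`,`j`,`k`,`angle_deg`,`sd_deg`,`fc`).
#' @export
derive_bonds_angles <- function(mapping, cg, config = autocg_config()) {
  mol <- mapping$molecule
  beads <- mapping$beads
  nb <- length(beads)
  adjacency <- matrix(FALSE, nb, nb)
  for (k in seq_len(nrow(mol$bonds))) {
    gi <- mapping$atom2bead[mol$bonds$i[k]]
    gj <- mapping$atom2bead[mol$bonds$j[k]]
    if (gi != gj) adjacency[gi, gj] <- adjacency[gj, gi] <- TRUE
  }
  same_ring <- function(ids) {
    rs <- vapply(beads[ids], function(b)
      if (isTRUE(b$ring)) b$ring_system else NA_integer_, integer(1))
    !anyNA(rs) && length(unique(rs)) == 1
  }

  bonds <- data.frame(i = integer(0), j = integer(0), length_nm = numeric(0),
                      sd_nm = numeric(0), fc = numeric(0))
  for (i in seq_len(nb)) for (j in seq_len(nb)) {
    if (j <= i || !adjacency[i, j] || same_ring(c(i, j))) next
    di <- matrix(cg$xyz[, i, ], ncol = 3)
    dj <- matrix(cg$xyz[, j, ], ncol = 3)
    d <- sqrt(rowSums((di - dj)^2))
    sdd <- if (length(d) > 1) stats::sd(d) else 0
    bonds <- rbind(bonds, data.frame(i = i, j = j, length_nm = mean(d),
                                     sd_nm = sdd,
                                     fc = config$bond_fc))
  }

  angles <- data.frame(i = integer(0), j = integer(0), k = integer(0),
                       angle_deg = numeric(0), sd_deg = numeric(0),
                       fc = numeric(0))
  for (j in seq_len(nb)) {
    nbrs <- which(adjacency[j, ])
    if (length(nbrs) < 2) next
    for (a_i in seq_along(nbrs)) for (b_i in seq_along(nbrs)) {
      if (b_i <= a_i) next
      i <- nbrs[a_i]; k <- nbrs[b_i]
      if (same_ring(c(i, j, k))) next
      th <- vapply(seq_len(dim(cg$xyz)[1]), function(t) {
        v1 <- cg$xyz[t, i, ] - cg$xyz[t, j, ]
        v2 <- cg$xyz[t, k, ] - cg$xyz[t, j, ]
        cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      }, numeric(1))
      sdth <- if (length(th) > 1) stats::sd(th) else 0
      angles <- rbind(angles, data.frame(i = i, j = j, k = k,
                                         angle_deg = mean(th),
                                         sd_deg = sdth,
                                         fc = config$angle_fc))
    }
  }
  structure(list(bonds = bonds, angles = angles), class = "cg_bonded")
}
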