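# Conformer ensembles.  A single reference geometry is built
# deterministically from the graph (idealized bond lengths and angles,
# planar ring templates; see build_reference_geometry); the ensemble is then
# generated by a knowledge-based torsion driver that resamples every
# rotatable bond from standard rotamer states with angular jitter and
# rejects sterically clashed structures.  Internal bond lengths, angles and
# ring geometries are held fixed, which is what the coarse-grained averages
# are sensitive to.

#' Generate a conformer ensemble
#'
#' @param mol a `cg_molecule`.
#' @param n number of conformers (default 200).
#' @param seed RNG seed; the ensemble is fully deterministic given the seed.
#' @param clash_dist_nm minimum allowed distance between heavy atoms more
#'   than two bonds apart; clashed torsion draws are rejected and resampled.
#' @return object of class `cg_conformers`: list with `xyz` (array
#'   `n x natoms x 3`, nm, heavy atoms in canonical order), `n`, `seed`.
#' @export
generate_conformers <- function(mol, n = 200, seed = 42,
                                clash_dist_nm = 0.16) {
  stopifnot(n >= 1)
  ref <- build_reference_geometry(mol)
  rot <- rotatable_bonds(mol)
  xyz <- array(NA_real_, dim = c(n, mol$natoms, 3))
  set.seed(as.integer(seed) %% .Machine$integer.max)

  if (nrow(rot) == 0) {
    for (k in seq_len(n)) xyz[k, , ] <- ref
  } else {
    sides <- lapply(seq_len(nrow(rot)), function(r) {
      moving_side(mol, rot$i[r], rot$j[r])
    })
    far <- far_pairs(mol)
    for (k in seq_len(n)) {
      best <- NULL
      best_sep <- -Inf
      for (attempt in 1:25) {
        cand <- ref
        for (r in seq_len(nrow(rot))) {
          target <- sample_torsion(rot$sp2[r])
          cand <- set_torsion(cand, mol, rot$i[r], rot$j[r], sides[[r]],
                              target)
        }
        sep <- min_far_distance(cand, far)
        if (sep > best_sep) { best_sep <- sep; best <- cand }
        if (sep >= clash_dist_nm) break
      }
      xyz[k, , ] <- best
    }
  }
  structure(list(xyz = xyz, n = n, seed = seed), class = "cg_conformers")
}

# Rotatable: single, acyclic, both ends with >= 2 heavy neighbours.
rotatable_bonds <- function(mol) {
  deg <- lengths(mol$adj)
  keep <- vapply(seq_len(nrow(mol$bonds)), function(k) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    mol$bonds$order[k] == 1 &&
      length(intersect(mol$ring_ids[[i]], mol$ring_ids[[j]])) == 0 &&
      deg[i] >= 2 && deg[j] >= 2
  }, logical(1))
  b <- mol$bonds[keep, , drop = FALSE]
  if (!nrow(b)) return(cbind(b, sp2 = logical(0)))
  # sp2-flanked bonds prefer planar rotamers (0/180 deg)
  has_pi <- function(a) {
    ks <- which(mol$bonds$i == a | mol$bonds$j == a)
    any(mol$bonds$order[ks] >= 2) || mol$atoms$aromatic[a]
  }
  b$sp2 <- vapply(seq_len(nrow(b)), function(r) {
    has_pi(b$i[r]) || has_pi(b$j[r])
  }, logical(1))
  b
}

sample_torsion <- function(sp2) {
  base <- if (sp2) sample(c(0, 180), 1) else
    sample(c(-60, 60, 180), 1, prob = c(0.25, 0.25, 0.5))
  (base + rnorm(1, sd = 8)) * pi / 180
}

# Atoms on the j-side of bond i-j (the side that rotates).
moving_side <- function(mol, i, j) {
  seen <- logical(mol$natoms)
  seen[i] <- TRUE
  seen[j] <- TRUE
  queue <- j
  side <- j
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in mol$adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        side <- c(side, w)
        queue <- c(queue, w)
      }
    }
  }
  setdiff(side, j)
}

# Set the torsion a-i-j-b to `target` (radians) by rotating `side` about the
# i->j axis; reference atoms a, b are the lowest-index heavy neighbours.
set_torsion <- function(xyz, mol, i, j, side, target) {
  a <- setdiff(mol$adj[[i]], j)[1]
  b <- setdiff(mol$adj[[j]], i)[1]
  if (is.na(a) || is.na(b) || !length(side)) return(xyz)
  cur <- dihedral_angle(xyz[a, ], xyz[i, ], xyz[j, ], xyz[b, ])
  rotate_about_axis(xyz, side, xyz[i, ], xyz[j, ] - xyz[i, ], target - cur)
}

dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

rotate_about_axis <- function(xyz, atoms, origin, axis, angle) {
  k <- axis / sqrt(sum(axis^2))
  ct <- cos(angle); st <- sin(angle)
  for (a in atoms) {
    v <- xyz[a, ] - origin
    xyz[a, ] <- origin + v * ct + cross3(k, v) * st +
      k * sum(k * v) * (1 - ct)
  }
  xyz
}

# Pairs of heavy atoms separated by more than two bonds (checked for
# clashes after torsion resampling).
far_pairs <- function(mol) {
  n <- mol$natoms
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (k in seq_len(nrow(mol$bonds))) {
    d[mol$bonds$i[k], mol$bonds$j[k]] <- 1
    d[mol$bonds$j[k], mol$bonds$i[k]] <- 1
  }
  for (v in seq_len(n)) d <- pmin(d, outer(d[, v], d[v, ], `+`))
  which(upper.tri(d) & d > 2, arr.ind = TRUE)
}

min_far_distance <- function(xyz, far) {
  if (!nrow(far)) return(Inf)
  diffs <- xyz[far[, 1], , drop = FALSE] - xyz[far[, 2], , drop = FALSE]
  sqrt(min(rowSums(diffs^2)))
}
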