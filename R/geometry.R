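# Deterministic reference geometry from the molecular graph.  Bond lengths
# come from covalent radii with bond-order factors, bond angles from
# hybridization (sp3 tetrahedral, sp2 trigonal, sp linear) and fused ring
# systems are laid out as planar regular polygons sharing edges.  The
# resulting geometry is idealized rather than force-field minimized; the
# torsion driver in generate_conformers() supplies the conformational
# freedom, and coarse-grained averages are insensitive to the sub-percent
# bond-length differences from a minimized structure.

.COVALENT_RADIUS <- c(  # Angstrom
  H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39
)

bond_length_nm <- function(el1, el2, order, aromatic = FALSE) {
  r <- .COVALENT_RADIUS[el1] + .COVALENT_RADIUS[el2]
  f <- if (aromatic) 0.93 else switch(order, `1` = 1.0, `2` = 0.87,
                                      `3` = 0.78, 1.0)
  unname(r * f / 10)   # Angstrom -> nm
}

atom_hybridization <- function(mol) {
  vapply(seq_len(mol$natoms), function(i) {
    ks <- which(mol$bonds$i == i | mol$bonds$j == i)
    ords <- mol$bonds$order[ks]
    if (any(ords == 3) || sum(ords == 2) >= 2) "sp"
    else if (any(ords == 2) || mol$atoms$aromatic[i]) "sp2"
    else "sp3"
  }, character(1))
}

# Planar layout of one ring system: rings are placed as regular polygons,
# breadth-first over the ring-fusion graph, each new ring reflected to the
# free side of its shared edge.  Returns 3D coordinates (z = 0 plane).
layout_ring_system <- function(mol, sys_atoms) {
  rings <- mol$rings[vapply(mol$rings, function(r) all(r %in% sys_atoms),
                            logical(1))]
  stopifnot(length(rings) >= 1)
  pos <- matrix(NA_real_, mol$natoms, 2)
  centers <- list()

  edge_len <- function(a, b) {
    k <- which((mol$bonds$i == a & mol$bonds$j == b) |
                 (mol$bonds$i == b & mol$bonds$j == a))[1]
    bond_length_nm(mol$atoms$element[a], mol$atoms$element[b],
                   mol$bonds$order[k],
                   mol$atoms$aromatic[a] && mol$atoms$aromatic[b])
  }
  place_ring <- function(ring, anchor = NULL) {
    k <- length(ring)
    side <- mean(vapply(seq_len(k), function(t)
      edge_len(ring[t], ring[t %% k + 1]), numeric(1)))
    radius <- side / (2 * sin(pi / k))
    if (is.null(anchor)) {
      ang <- 2 * pi * (seq_len(k) - 1) / k
      pos[ring, ] <<- cbind(radius * cos(ang), radius * sin(ang))
      centers[[length(centers) + 1]] <<- c(0, 0)
      return(invisible())
    }
    # anchor: shared, already-placed edge (a, b); build polygon on the
    # side away from the anchoring ring's centre
    a <- anchor$a; b <- anchor$b
    pa <- pos[a, ]; pb <- pos[b, ]
    mid <- (pa + pb) / 2
    e <- pb - pa
    elen <- sqrt(sum(e^2))
    perp <- c(-e[2], e[1]) / elen
    apothem <- sqrt(max(radius^2 - (elen / 2)^2, 0))
    c1 <- mid + perp * apothem
    c2 <- mid - perp * apothem
    dist_old <- function(cc) min(vapply(centers, function(o)
      sum((cc - o)^2), numeric(1)))
    centre <- if (dist_old(c1) >= dist_old(c2)) c1 else c2
    centers[[length(centers) + 1]] <<- centre
    # order ring so it starts at a and proceeds towards b
    ia <- which(ring == a)
    ring_rot <- ring[c(ia:length(ring), seq_len(ia - 1))]
    if (ring_rot[2] != b) ring_rot <- c(ring_rot[1], rev(ring_rot[-1]))
    ang0 <- atan2(pa[2] - centre[2], pa[1] - centre[1])
    ang1 <- atan2(pb[2] - centre[2], pb[1] - centre[1])
    dang <- (ang1 - ang0) %% (2 * pi)
    if (dang > pi) dang <- dang - 2 * pi     # shortest way round
    step <- if (dang > 0) 2 * pi / k else -2 * pi / k
    for (t in seq_along(ring_rot)) {
      atom <- ring_rot[t]
      if (is.na(pos[atom, 1])) {
        aa <- ang0 + (t - 1) * step
        pos[atom, ] <<- centre + radius * c(cos(aa), sin(aa))
      }
    }
    invisible()
  }

  placed <- logical(length(rings))
  place_ring(rings[[1]])
  placed[1] <- TRUE
  repeat {
    advanced <- FALSE
    for (r in which(!placed)) {
      shared <- rings[[r]][!is.na(pos[rings[[r]], 1])]
      if (length(shared) >= 2) {
        # pick a shared edge (two adjacent placed atoms in this ring)
        k <- length(rings[[r]])
        edge <- NULL
        for (t in seq_len(k)) {
          a <- rings[[r]][t]; b <- rings[[r]][t %% k + 1]
          if (!is.na(pos[a, 1]) && !is.na(pos[b, 1])) {
            edge <- list(a = a, b = b)
            break
          }
        }
        if (!is.null(edge)) {
          place_ring(rings[[r]], edge)
          placed[r] <- TRUE
          advanced <- TRUE
        }
      }
    }
    if (all(placed) || !advanced) break
  }
  if (any(!placed)) {
    # disconnected or spiro-linked rings within one system: place the rest
    # offset along x (best effort; such systems are flagged upstream)
    for (r in which(!placed)) {
      shift <- max(pos[, 1], na.rm = TRUE) + 0.3
      k <- length(rings[[r]])
      side <- 0.15
      radius <- side / (2 * sin(pi / k))
      ang <- 2 * pi * (seq_len(k) - 1) / k
      todo <- rings[[r]][is.na(pos[rings[[r]], 1])]
      ang <- ang[seq_along(todo)]
      pos[todo, ] <- cbind(shift + radius * cos(ang), radius * sin(ang))
      placed[r] <- TRUE
    }
  }
  cbind(pos, 0)[sys_atoms, , drop = FALSE]
}

#' Deterministic reference 3D structure
#'
#' Builds idealized coordinates for the heavy-atom graph: planar regular
#' polygons for (fused) rings, covalent-radius bond lengths, tetrahedral /
#' trigonal / linear angles by hybridization, anti torsions for chains.
#' Fully deterministic for a given canonical graph.
#'
#' @param mol a `cg_molecule`.
#' @return matrix `natoms x 3` of coordinates in nm.
#' @export
build_reference_geometry <- function(mol) {
  n <- mol$natoms
  pos <- matrix(NA_real_, n, 3)
  hyb <- atom_hybridization(mol)
  systems <- ring_systems(mol)
  sys_of <- rep(NA_integer_, n)
  for (s in seq_along(systems)) sys_of[systems[[s]]] <- s
  sys_layout <- lapply(systems, function(sa) layout_ring_system(mol, sa))
  sys_placed <- rep(FALSE, length(systems))

  blen <- function(a, b) {
    k <- which((mol$bonds$i == a & mol$bonds$j == b) |
                 (mol$bonds$i == b & mol$bonds$j == a))[1]
    bond_length_nm(mol$atoms$element[a], mol$atoms$element[b],
                   mol$bonds$order[k],
                   mol$atoms$aromatic[a] && mol$atoms$aromatic[b])
  }
  unit <- function(v) v / sqrt(sum(v^2))
  any_perp <- function(u) {
    v <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    unit(cross3(u, v))
  }

  # rigid-place a ring system template given an anchor atom position and an
  # approach direction (from the atom that leads into the system)
  place_system <- function(s, anchor_atom, target_pos, approach_dir) {
    local <- sys_layout[[s]]
    atoms <- systems[[s]]
    ia <- match(anchor_atom, atoms)
    ctr <- colMeans(local)
    out_dir2 <- local[ia, ] - ctr
    if (sqrt(sum(out_dir2^2)) < 1e-9) out_dir2 <- c(1, 0, 0)
    out_dir2 <- unit(out_dir2)
    if (is.null(approach_dir)) {
      R <- diag(3)
    } else {
      # rotate so the centre->anchor direction aligns with -approach
      tgt <- unit(-approach_dir)
      v <- cross3(out_dir2, tgt)
      sv <- sqrt(sum(v^2)); cv <- sum(out_dir2 * tgt)
      R <- if (sv < 1e-12) {
        if (cv > 0) diag(3) else {
          p <- any_perp(out_dir2)
          2 * outer(p, p) - diag(3)
        }
      } else {
        vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
        diag(3) + vx + vx %*% vx * ((1 - cv) / sv^2)
      }
    }
    moved <- t(R %*% t(sweep(local, 2, local[ia, ])))
    pos[atoms, ] <<- sweep(moved, 2, target_pos, `+`)
    sys_placed[s] <<- TRUE
  }

  start <- if (length(systems)) systems[[1]][1] else 1L
  if (!is.na(sys_of[start])) {
    place_system(sys_of[start], start, c(0, 0, 0), NULL)
  } else {
    pos[start, ] <- 0
  }

  # BFS placement of the remaining atoms
  queue <- start
  visited <- logical(n)
  visited[start] <- TRUE
  if (!is.na(sys_of[start])) {
    visited[systems[[sys_of[start]]]] <- TRUE
    queue <- systems[[sys_of[start]]]
  }
  while (length(queue)) {
    p <- queue[1]; queue <- queue[-1]
    for (child in mol$adj[[p]]) {
      if (visited[child]) next
      used <- mol$adj[[p]][!is.na(pos[mol$adj[[p]], 1])]
      U <- lapply(used, function(u) unit(pos[u, ] - pos[p, ]))
      L <- blen(p, child)
      dir <- if (!length(U)) {
        c(1, 0, 0)
      } else if (length(U) == 1) {
        u <- U[[1]]
        theta <- switch(hyb[p], sp = pi,
                        sp2 = 2 * pi / 3, 109.47 * pi / 180)
        # azimuth reference: trans to the grandparent's other neighbour
        gp <- used[1]
        ref <- NULL
        for (g in mol$adj[[gp]]) {
          if (g != p && !is.na(pos[g, 1])) { ref <- pos[g, ]; break }
        }
        perp <- if (is.null(ref)) any_perp(u) else {
          w <- pos[gp, ] - ref
          w <- w - sum(w * u) * u
          if (sqrt(sum(w^2)) < 1e-9) any_perp(u) else unit(w)
        }
        unit(u * cos(theta) + perp * sin(theta))
      } else if (length(U) == 2) {
        b <- -(U[[1]] + U[[2]])
        nrm <- cross3(U[[1]], U[[2]])
        if (hyb[p] == "sp3" && sqrt(sum(nrm^2)) > 1e-9) {
          gamma <- 54.735 * pi / 180
          unit(unit(b) * cos(gamma) + unit(nrm) * sin(gamma))
        } else {
          if (sqrt(sum(b^2)) < 1e-9) any_perp(U[[1]]) else unit(b)
        }
      } else {
        b <- -Reduce(`+`, U)
        if (sqrt(sum(b^2)) < 1e-9) any_perp(U[[1]]) else unit(b)
      }
      if (!is.na(sys_of[child]) && !sys_placed[sys_of[child]]) {
        place_system(sys_of[child], child, pos[p, ] + dir * L, dir)
        newly <- systems[[sys_of[child]]]
        visited[newly] <- TRUE
        queue <- c(queue, newly)
      } else {
        pos[child, ] <- pos[p, ] + dir * L
        visited[child] <- TRUE
        queue <- c(queue, child)
      }
    }
  }
  if (anyNA(pos)) stop("reference geometry construction left atoms unplaced")
  pos
}
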