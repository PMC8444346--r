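# Rigid-ring frameworks.  Each (near-planar) ring system is projected onto
# its plane; convex-hull beads become real interaction sites and interior
# beads become virtual sites whose positions are weighted combinations of
# neighbouring real sites.  The real sites are rigidified by a minimal
# triangulated constraint network with one harmonic dihedral per hinge.

#' In-plane basis of a ring system
#'
#' Diagonalizes the inertia tensor of the bead positions; the eigenvectors
#' of the two smallest eigenvalues span the ring plane (for a planar body
#' the normal carries the largest moment).  Bead positions are projected
#' onto this basis.
#'
#' @param coords matrix (nbeads x 3) of bead positions (nm).
#' @return list with `center`, `basis` (3 x 2, orthonormal), `proj`
#'   (nbeads x 2 in-plane coordinates).
#' @export
ring_plane_basis <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3) stop("need at least 3 beads to define a ring plane")
  center <- colMeans(coords)
  x <- sweep(coords, 2, center)
  r2 <- rowSums(x^2)
  inertia <- diag(sum(r2), 3) - t(x) %*% x
  es <- eigen(inertia, symmetric = TRUE)
  # eigen() sorts decreasing; the two smallest eigenvalues are columns 2:3
  basis <- es$vectors[, c(3, 2)]
  if (es$values[2] / max(es$values[1], .Machine$double.eps) > 1 - 1e-9 &&
      es$values[3] < 1e-12 * max(r2, 1)) {
    stop("degenerate (collinear) ring geometry")
  }
  proj <- x %*% basis
  list(center = center, basis = basis, proj = proj)
}

#' Split ring beads into real and virtual sites
#'
#' Convex-hull vertices of the projected ring system are real sites; the
#' interior beads are virtual.  Any interior bead bonded to a non-ring
#' substituent bead is promoted back to a real site so that bonds never
#' attach to virtual sites.
#'
#' @param frame output of [ring_plane_basis()].
#' @param substituent_bonded logical vector: is each ring bead bonded to a
#'   bead outside the ring system?
#' @return list with integer vectors `real` and `virtual` (row indices).
#' @export
classify_real_virtual <- function(frame, substituent_bonded = NULL) {
  n <- nrow(frame$proj)
  if (is.null(substituent_bonded)) substituent_bonded <- rep(FALSE, n)
  hull <- sort(unique(grDevices::chull(frame$proj[, 1], frame$proj[, 2])))
  real <- sort(unique(c(hull, which(substituent_bonded))))
  list(real = real, virtual = setdiff(seq_len(n), real))
}

#' Solve virtual-site weights
#'
#' Computes weights `w` with `sum(w) = 1` and `sum(w_i r_i) = v` for a
#' virtual site `v` constructed from 3 or 4 real sites.  With three sites
#' the solution is the unique barycentric one.  With four sites the weights
#' are chosen to balance the redistributed force: `v` is written as the
#' intersection of two lines spanning the quadrilateral, parameterized by
#' the edge fractions `beta_h` and `beta_v`, giving bilinear weights
#' `((1-bh)(1-bv), bh(1-bv), bh bv, (1-bh) bv)` for the corners in cyclic
#' order.  `beta_v` solves a quadratic; the root with both fractions in
#' `[0, 1]` is taken (if both qualify, the one minimizing the largest
#' weight).
#'
#' @param v length-2 in-plane position of the virtual site.
#' @param neighbors matrix (3-4 x 2) of real-site positions.  For n = 4
#'   they are sorted into cyclic order internally.
#' @return numeric weight vector aligned with the input row order.
#' @export
solve_virtual_weights <- function(v, neighbors) {
  nb <- as.matrix(neighbors)
  n <- nrow(nb)
  if (!n %in% c(3, 4)) stop("virtual sites use 3 or 4 constructing sites")
  if (n == 3) {
    A <- cbind(nb[2, ] - nb[1, ], nb[3, ] - nb[1, ])
    if (abs(det(A)) < 1e-14) stop("degenerate constructing triangle")
    w23 <- solve(A, v - nb[1, ])
    w <- c(1 - sum(w23), w23)
  } else {
    ord <- order(atan2(nb[, 2] - mean(nb[, 2]), nb[, 1] - mean(nb[, 1])))
    q <- nb[ord, , drop = FALSE]
    w_cyc <- bilinear_weights(v, q)
    w <- numeric(4)
    w[ord] <- w_cyc
  }
  if (any(w < -1e-9)) {
    stop("virtual site lies outside the hull of its constructing sites; ",
         "negative weights would unbalance the redistributed forces")
  }
  if (max(abs(drop(t(nb) %*% w) - v)) > 1e-7 ||
      abs(sum(w) - 1) > 1e-12) {
    stop("virtual-site weight reconstruction failed")
  }
  w
}

# Inverse bilinear interpolation on an ordered quadrilateral q1..q4:
# v = (1-bh)(1-bv) q1 + bh (1-bv) q2 + bh bv q3 + (1-bh) bv q4.
bilinear_weights <- function(v, q) {
  A <- q[2, ] - q[1, ]
  B <- q[4, ] - q[1, ]
  D <- q[3, ] - q[2, ] - q[4, ] + q[1, ]
  p <- v - q[1, ]
  cross2 <- function(u, w) u[1] * w[2] - u[2] * w[1]
  a2 <- -cross2(B, D)
  a1 <- cross2(p, D) - cross2(B, A)
  a0 <- cross2(p, A)
  roots <- if (abs(a2) < 1e-14) {
    if (abs(a1) < 1e-14) stop("degenerate quadrilateral") else -a0 / a1
  } else {
    disc <- a1^2 - 4 * a2 * a0
    scale <- max(a1^2, abs(4 * a2 * a0), .Machine$double.xmin)
    if (disc < -1e-9 * scale) {
      stop("no real solution for quadrilateral weights")
    }
    disc <- max(disc, 0)
    c((-a1 + sqrt(disc)) / (2 * a2), (-a1 - sqrt(disc)) / (2 * a2))
  }
  cand <- list()
  for (bv in roots) {
    if (bv < -1e-9 || bv > 1 + 1e-9) next
    E <- A + bv * D
    denom <- sum(E^2)
    if (denom < 1e-14) next
    bh <- sum((p - bv * B) * E) / denom
    if (bh < -1e-9 || bh > 1 + 1e-9) next
    w <- c((1 - bh) * (1 - bv), bh * (1 - bv), bh * bv, (1 - bh) * bv)
    cand[[length(cand) + 1]] <- w
  }
  if (!length(cand)) {
    stop("virtual site cannot be expressed with balanced in-range weights")
  }
  cand[[which.min(vapply(cand, max, numeric(1)))]]
}

#' Build the minimal constraint and hinge-dihedral framework
#'
#' Real sites are joined by a closed ring of distance constraints following
#' their cyclic (angular) order; chords added in a zig-zag pattern
#' triangulate the polygon, creating hinges.  Each hinge (pair of triangles
#' sharing a chord) is held at its reference fold angle by a single
#' harmonic dihedral on the two off-edge vertices and the shared edge.  For
#' `n` real sites this gives `2n - 3` constraints and `n - 3` dihedrals,
#' the minimum for a rigid planar framework.
#'
#' @param coords matrix (n_real x 3) of real-site reference positions (nm).
#' @param ids integer bead ids of the real sites (labels carried through).
#' @param dihedral_fc hinge dihedral force constant (kJ/mol/rad^2).
#' @return list of class `cg_framework` with data frames `constraints`
#'   (`i`,`j`,`length_nm`) and `dihedrals` (`i`,`j`,`k`,`l`,`angle_deg`,
#'   `fc`), using the supplied ids.
#' @export
build_constraints_and_dihedrals <- function(coords, ids = seq_len(nrow(coords)),
                                            dihedral_fc = 500) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 3) stop("need at least 3 real sites to rigidify a ring system")
  if (ncol(coords) == 2) coords <- cbind(coords, 0)
  frame <- ring_plane_basis(coords)
  ang <- atan2(frame$proj[, 2], frame$proj[, 1])
  cyc <- order(ang)
  # deterministic start at the lowest bead id; orientation normalized so
  # the neighbour following the start has the smaller id of the two
  # (the in-plane basis orientation from the inertia tensor is arbitrary)
  start <- which(cyc == which.min(ids))
  cyc <- cyc[c(start:n, seq_len(start - 1))]
  if (n > 2 && ids[cyc[2]] > ids[cyc[n]]) {
    cyc <- c(cyc[1], rev(cyc[-1]))
  }

  edges <- cbind(cyc, c(cyc[-1], cyc[1]))
  # zig-zag chords: walk inwards from both ends of the cyclic order
  lo <- 1; hi <- n
  strip <- integer(0)
  while (lo <= hi) {
    strip <- c(strip, cyc[lo])
    if (hi > lo) strip <- c(strip, cyc[hi])
    lo <- lo + 1; hi <- hi - 1
  }
  chords <- if (n > 3) {
    t(vapply(seq_len(n - 3), function(t) c(strip[t + 1], strip[t + 2]),
             integer(2)))
  } else {
    matrix(integer(0), ncol = 2)
  }
  all_edges <- rbind(edges, chords)
  dist3 <- function(a, b) sqrt(sum((coords[a, ] - coords[b, ])^2))
  constraints <- data.frame(
    i = ids[pmin(all_edges[, 1], all_edges[, 2])],
    j = ids[pmax(all_edges[, 1], all_edges[, 2])],
    length_nm = vapply(seq_len(nrow(all_edges)), function(t)
      dist3(all_edges[t, 1], all_edges[t, 2]), numeric(1))
  )

  # triangles of the strip; hinge t shares chord (strip[t+1], strip[t+2])
  dihedrals <- data.frame(i = integer(0), j = integer(0), k = integer(0),
                          l = integer(0), angle_deg = numeric(0),
                          fc = numeric(0))
  if (n >= 4) {
    for (t in seq_len(n - 3)) {
      a <- strip[t]; b <- strip[t + 1]; c_ <- strip[t + 2]; d <- strip[t + 3]
      phi <- dihedral_angle(coords[a, ], coords[b, ], coords[c_, ],
                            coords[d, ]) * 180 / pi
      dihedrals <- rbind(dihedrals, data.frame(
        i = ids[a], j = ids[b], k = ids[c_], l = ids[d],
        angle_deg = phi, fc = dihedral_fc))
    }
  }
  structure(list(constraints = constraints, dihedrals = dihedrals),
            class = "cg_framework")
}

#' Rigidify every ring system of a mapping
#'
#' Runs plane projection, real/virtual classification, virtual-site weight
#' solving and constraint/dihedral generation for each ring system with at
#' least three beads.  Ring systems of one or two beads contribute no
#' framework (their geometry is carried by ordinary bonds).
#'
#' @param mapping a `cg_mapping`.
#' @param cg output of [map_to_cg()].
#' @param config pipeline configuration.
#' @return list of class `cg_rigid` with `constraints`, `dihedrals`,
#'   `virtual_sites` (list of `site`, `constructors`, `weights`), and
#'   `ring_pairs` (all intra-ring bead pairs, for exclusions).
#' @export
rigidify_rings <- function(mapping, cg, config = autocg_config()) {
  beads <- mapping$beads
  nb <- length(beads)
  # conformer-averaged bead coordinates
  ref <- apply(cg$xyz, c(2, 3), mean)

  ring_sys <- vapply(beads, function(b)
    if (isTRUE(b$ring)) b$ring_system else NA_integer_, integer(1))
  mol <- mapping$molecule
  bead_adj <- matrix(FALSE, nb, nb)
  for (k in seq_len(nrow(mol$bonds))) {
    gi <- mapping$atom2bead[mol$bonds$i[k]]
    gj <- mapping$atom2bead[mol$bonds$j[k]]
    if (gi != gj) bead_adj[gi, gj] <- bead_adj[gj, gi] <- TRUE
  }

  constraints <- data.frame(i = integer(0), j = integer(0),
                            length_nm = numeric(0))
  dihedrals <- data.frame(i = integer(0), j = integer(0), k = integer(0),
                          l = integer(0), angle_deg = numeric(0),
                          fc = numeric(0))
  virtual_sites <- list()
  ring_pairs <- data.frame(i = integer(0), j = integer(0))

  for (sys in unique(ring_sys[!is.na(ring_sys)])) {
    members <- which(ring_sys == sys)
    if (length(members) >= 2) {
      prs <- t(utils::combn(members, 2))
      ring_pairs <- rbind(ring_pairs, data.frame(i = prs[, 1], j = prs[, 2]))
    }
    if (length(members) < 3) {
      # too small for a framework: constrain the pair instead
      if (length(members) == 2) {
        d <- sqrt(sum((ref[members[1], ] - ref[members[2], ])^2))
        constraints <- rbind(constraints, data.frame(
          i = members[1], j = members[2], length_nm = d))
      }
      next
    }
    frame <- ring_plane_basis(ref[members, , drop = FALSE])
    subst <- vapply(members, function(b)
      any(bead_adj[b, setdiff(seq_len(nb), members)]), logical(1))
    cls <- classify_real_virtual(frame, subst)
    real_ids <- members[cls$real]
    virt_ids <- members[cls$virtual]

    fw <- build_constraints_and_dihedrals(
      ref[real_ids, , drop = FALSE], ids = real_ids,
      dihedral_fc = config$dihedral_fc)
    constraints <- rbind(constraints, fw$constraints)
    dihedrals <- rbind(dihedrals, fw$dihedrals)

    for (vb in virt_ids) {
      vpos <- frame$proj[match(vb, members), ]
      rp <- frame$proj[match(real_ids, members), , drop = FALSE]
      d <- sqrt(rowSums(sweep(rp, 2, vpos)^2))
      nuse <- min(4, length(real_ids))
      near <- order(d, real_ids)[seq_len(nuse)]
      w <- solve_virtual_weights(vpos, rp[near, , drop = FALSE])
      virtual_sites[[length(virtual_sites) + 1]] <- list(
        site = vb, constructors = real_ids[near], weights = w)
    }
  }
  structure(list(constraints = constraints, dihedrals = dihedrals,
                 virtual_sites = virtual_sites, ring_pairs = ring_pairs),
            class = "cg_rigid")
}
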