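# Pattern-based mapping of fused ring systems: outer single-ring chains are
# split into 2-3 atom beads; the inner remainder is mapped by one spectral
# pass limited to a path length of two bonds.

# Ring systems: connected components of the subgraph induced by ring atoms
# and ring bonds.  Two rings joined only by a non-ring bond (biphenyl) are
# separate systems.
ring_systems <- function(mol) {
  ring_atoms <- which(lengths(mol$ring_ids) > 0)
  if (!length(ring_atoms)) return(list())
  ring_edge <- vapply(seq_len(nrow(mol$bonds)), function(k) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    length(intersect(mol$ring_ids[[i]], mol$ring_ids[[j]])) > 0
  }, logical(1))
  adj <- vector("list", mol$natoms)
  for (k in which(ring_edge)) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  comp <- graph_components(adj, mol$natoms)
  split(ring_atoms, comp[ring_atoms])
}

# Split a chain of k ring atoms into beads of 2-3 atoms.  `bead_atoms` is
# the preferred size (2 at trimer ring resolution, 3 at dimer resolution).
# For linear chains the odd-size bead is centred when the flanks come out
# even, otherwise placed at the canonical (low-index) end.
split_chain <- function(chain, bead_atoms = 2, cyclic = FALSE) {
  k <- length(chain)
  if (k <= 3) return(list(chain))
  sizes <- if (bead_atoms == 2) {
    if (k %% 2 == 0) rep(2L, k / 2) else c(3L, rep(2L, (k - 3) / 2))
  } else {
    r <- k %% 3
    if (r == 0) rep(3L, k / 3)
    else if (r == 2) c(rep(3L, (k - 2) / 3), 2L)
    else c(rep(3L, (k - 4) / 3), 2L, 2L)
  }
  if (!cyclic && length(sizes) > 1 && any(sizes != sizes[1])) {
    # centre a unique odd bead when the two flanks split evenly
    odd <- which(sizes != sizes[1])
    if (length(odd) == 1 && (k - sizes[odd]) %% (2 * sizes[1]) == 0) {
      half <- (k - sizes[odd]) / (2 * sizes[1])
      sizes <- c(rep(sizes[1], half), sizes[odd], rep(sizes[1], half))
    }
  }
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  lapply(seq_along(sizes), function(t) chain[starts[t]:ends[t]])
}

# Maximal runs of atoms belonging to only one active ring, in ring order.
single_ring_chains <- function(ring, multi) {
  m <- length(ring)
  is_single <- !multi[ring]
  if (!any(is_single)) return(list())
  if (all(is_single)) {
    i0 <- which.min(ring)
    return(list(list(atoms = ring[c(i0:m, seq_len(i0 - 1))[seq_len(m)]],
                     cyclic = TRUE)))
  }
  # rotate so position 1 is a multi-ring atom, then collect runs
  start <- which(!is_single)[1]
  idx <- c(start:m, seq_len(start - 1))
  runs <- list()
  current <- integer(0)
  for (p in idx) {
    if (is_single[p]) {
      current <- c(current, ring[p])
    } else if (length(current)) {
      runs[[length(runs) + 1]] <- list(atoms = current, cyclic = FALSE)
      current <- integer(0)
    }
  }
  if (length(current)) runs[[length(runs) + 1]] <- list(atoms = current,
                                                       cyclic = FALSE)
  runs
}

#' Map ring systems onto beads
#'
#' Outer chains of atoms belonging to a single ring are split into 2-3-atom
#' beads using predefined patterns; mapped atoms are removed and the step
#' repeats on the remaining rings.  When no intact ring remains, the leftover
#' inner atoms are mapped with one spectral pass limited to a maximum path
#' length of two bonds.  Ring systems containing rings of a size other than
#' five or six are handled best-effort with a warning.
#'
#' @param mol a `cg_molecule`.
#' @param resolution `"trimer"` (2 ring atoms per bead, three beads per
#'   six-ring) or `"dimer"` (3 ring atoms per bead).
#' @return list of ring beads (possibly empty).
#' @export
map_ring_systems <- function(mol, resolution = c("trimer", "dimer")) {
  resolution <- match.arg(resolution)
  bead_atoms <- if (resolution == "trimer") 2L else 3L
  systems <- ring_systems(mol)
  beads <- list()
  sizes <- lengths(mol$rings)
  if (length(systems) && any(!(sizes %in% c(5L, 6L)))) {
    warning("ring system contains rings of size other than 5 or 6; ",
            "chain splitting is best-effort and should be reviewed manually")
  }
  for (sys_id in seq_along(systems)) {
    sys_atoms <- systems[[sys_id]]
    rings_here <- which(vapply(mol$rings, function(r)
      all(r %in% sys_atoms), logical(1)))
    unmapped <- rep(FALSE, mol$natoms)
    unmapped[sys_atoms] <- TRUE
    sys_beads <- list()
    repeat {
      active <- rings_here[vapply(rings_here, function(r)
        all(unmapped[mol$rings[[r]]]), logical(1))]
      if (!length(active)) break
      ring_count <- integer(mol$natoms)
      for (r in active) {
        ring_count[mol$rings[[r]]] <- ring_count[mol$rings[[r]]] + 1L
      }
      multi <- ring_count > 1L
      new_this_round <- list()
      for (r in active[order(vapply(active, function(r)
        min(mol$rings[[r]]), integer(1)))]) {
        ring <- mol$rings[[r]]
        if (!all(unmapped[ring])) next    # partially consumed this round
        chains <- single_ring_chains(ring, multi)
        for (ch in chains) {
          if (!all(unmapped[ch$atoms])) next
          pieces <- split_chain(ch$atoms, bead_atoms, ch$cyclic)
          for (p in pieces) {
            new_this_round[[length(new_this_round) + 1]] <- p
            unmapped[p] <- FALSE
          }
        }
      }
      if (!length(new_this_round)) break
      for (p in new_this_round) {
        sys_beads[[length(sys_beads) + 1]] <- new_bead(
          p, origin = "ring-outer", ring = TRUE,
          aromatic = all(mol$atoms$aromatic[p]), ring_system = sys_id)
      }
    }
    rest <- sys_atoms[unmapped[sys_atoms]]
    if (length(rest)) {
      singles <- lapply(rest, function(a) new_bead(
        a, origin = "ring-inner", ring = TRUE,
        aromatic = mol$atoms$aromatic[a], ring_system = sys_id))
      merged <- spectral_ring_remainder(mol, singles, sys_beads)
      for (b in merged) {
        b$origin <- "ring-inner"
        b$ring <- TRUE
        b$ring_system <- sys_id
        b$aromatic <- all(mol$atoms$aromatic[b$atoms])
        sys_beads[[length(sys_beads) + 1]] <- b
      }
    }
    beads <- c(beads, sys_beads)
  }
  order_beads(beads)
}

# One spectral iteration over the inner remainder (l <= 2), carried out in
# the context of the already-mapped outer beads so that centrality reflects
# the whole ring system.
spectral_ring_remainder <- function(mol, singles, outer_beads) {
  if (length(singles) <= 1) return(singles)
  groups <- c(outer_beads, singles)
  exclude <- c(rep(TRUE, length(outer_beads)), rep(FALSE, length(singles)))
  res <- spectral_iteration(mol, groups, exclude = exclude, max_l = 2)
  outer_atoms <- unlist(lapply(outer_beads, function(g) g$atoms))
  res[vapply(res, function(g) !any(g$atoms %in% outer_atoms), logical(1))]
}
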