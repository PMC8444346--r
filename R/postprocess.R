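# Postprocessing stage: eliminate single-atom beads left over by spectral
# grouping by transferring atoms from neighbouring beads, merging with
# terminal beads, or absorbing lone atoms into ring beads.

#' Resolve single-atom beads
#'
#' Iteratively removes single-atom beads: each takes one heavy atom from its
#' highest-ranked non-ring neighbour bead (from all equal-rank neighbours
#' simultaneously, preserving symmetry).  Beads containing atoms that were
#' single atoms, or bonded to past single atoms, are tagged and skipped in
#' favour of the next-ranked neighbour, which prevents atoms being passed
#' back and forth.  A single atom bonded to a terminal bead of path length 1
#' merges with it, and one whose only suitable neighbour is a ring bead is
#' absorbed into that ring bead (the highest-centrality ring bead when there
#' is a choice).  Iteration continues until every bead has internal path
#' length between 1 and `max_l`.
#'
#' @param mol a `cg_molecule`.
#' @param groups list of beads (with `origin`, `ring` flags).
#' @param max_l maximum allowed internal path length.
#' @param tie_tol relative score tolerance for rank ties.
#' @return list of beads without single-atom members.
#' @export
resolve_single_atom_beads <- function(mol, groups, max_l = 3,
                                      tie_tol = 1e-8) {
  if (mol$natoms < 2) {
    stop("no appropriate Martini representation for a single heavy atom")
  }
  tagged_atoms <- rep(FALSE, mol$natoms)
  max_iter <- mol$natoms + length(groups) + 2L
  fixed <- vapply(groups, function(g) g$origin == "ionic-predefined",
                  logical(1))

  for (iter in seq_len(max_iter)) {
    sizes <- lengths(lapply(groups, function(g) g$atoms))
    singles <- which(sizes == 1 &
                       !vapply(groups, function(g) isTRUE(g$ring), logical(1)) &
                       !fixed)
    if (!length(singles)) break

    A <- build_weighted_adjacency(mol, groups)
    cs <- centrality_scores(A, tie_tol)
    n <- length(groups)
    nbrs <- apply(A > 0 & !diag(TRUE, n), 1, which, simplify = FALSE)
    is_ring <- vapply(groups, function(g) isTRUE(g$ring), logical(1))
    tagged_bead <- vapply(groups, function(g) any(tagged_atoms[g$atoms]),
                          logical(1))
    min_atom <- vapply(groups, function(g) min(g$atoms), integer(1))

    # order single-atom beads by ascending rank for deterministic handling
    singles <- singles[order(cs$scores[singles], min_atom[singles])]
    s <- singles[1]
    s_atom <- groups[[s]]$atoms
    nb <- nbrs[[s]]

    terminals <- nb[!is_ring[nb] & !fixed[nb] &
                      lengths(nbrs[nb]) == 1 & sizes[nb] == 2]
    # never take an atom from a terminal two-atom bead: doing so would spawn
    # a terminal single atom with no way to combine (merge with it instead)
    donors <- setdiff(
      nb[!is_ring[nb] & !tagged_bead[nb] & !fixed[nb] & sizes[nb] > 1],
      terminals)
    ring_nb <- nb[is_ring[nb]]

    if (length(donors)) {
      top <- cs$tie_group[donors] == max(cs$tie_group[donors])
      take_from <- donors[top]
      moved <- integer(0)
      for (d in take_from) {
        cand <- intersect(groups[[d]]$atoms, mol$adj[[s_atom]])
        cand <- cand[vapply(cand, function(a) {
          rest <- setdiff(groups[[d]]$atoms, a)
          length(rest) == 0 || connected_subset(mol, rest)
        }, logical(1))]
        if (!length(cand)) next
        a <- min(cand)
        groups[[d]]$atoms <- setdiff(groups[[d]]$atoms, a)
        moved <- c(moved, a)
      }
      if (length(moved)) {
        neighbours_of_single <- intersect(mol$adj[[s_atom]],
                                          seq_len(mol$natoms))
        tagged_atoms[c(s_atom, neighbours_of_single)] <- TRUE
        groups[[s]]$atoms <- sort(c(groups[[s]]$atoms, moved))
        groups[[s]]$origin <- "postprocess"
        groups <- groups[lengths(lapply(groups, `[[`, "atoms")) > 0]
        next
      }
    }

    if (length(terminals)) {
      t_scores <- cs$scores[terminals]
      t <- terminals[order(-t_scores, min_atom[terminals])][1]
      groups[[s]]$atoms <- sort(c(groups[[s]]$atoms, groups[[t]]$atoms))
      groups[[s]]$origin <- "postprocess"
      tagged_atoms[groups[[s]]$atoms] <- TRUE
      groups[[t]]$atoms <- integer(0)
      groups <- groups[lengths(lapply(groups, `[[`, "atoms")) > 0]
      fixed <- vapply(groups, function(g) g$origin == "ionic-predefined",
                      logical(1))
      next
    }

    if (length(ring_nb)) {
      r <- ring_nb[order(-cs$scores[ring_nb], min_atom[ring_nb])][1]
      groups[[r]]$atoms <- sort(c(groups[[r]]$atoms, groups[[s]]$atoms))
      groups[[s]]$atoms <- integer(0)
      groups <- groups[lengths(lapply(groups, `[[`, "atoms")) > 0]
      fixed <- vapply(groups, function(g) g$origin == "ionic-predefined",
                      logical(1))
      next
    }

    # no neighbour can donate a connected atom: merge the lone atom into
    # the highest-ranked non-ring neighbour if the size limit allows it
    mergeable <- nb[!is_ring[nb] & !fixed[nb]]
    mergeable <- mergeable[vapply(mergeable, function(d) {
      heavy_atom_path_length(mol, c(groups[[d]]$atoms, s_atom)) <= max_l
    }, logical(1))]
    if (length(mergeable)) {
      d <- mergeable[order(-cs$scores[mergeable], min_atom[mergeable])][1]
      groups[[d]]$atoms <- sort(c(groups[[d]]$atoms, s_atom))
      groups[[d]]$origin <- "postprocess"
      tagged_atoms[groups[[d]]$atoms] <- TRUE
      groups[[s]]$atoms <- integer(0)
      groups <- groups[lengths(lapply(groups, `[[`, "atoms")) > 0]
      fixed <- vapply(groups, function(g) g$origin == "ionic-predefined",
                      logical(1))
      next
    }
    # last resort: take a connectivity-preserving atom from any neighbour
    donors <- nb[!is_ring[nb] & !fixed[nb] & sizes[nb] > 1]
    moved <- FALSE
    for (d in donors[order(-cs$scores[donors], min_atom[donors])]) {
      cand <- intersect(groups[[d]]$atoms, mol$adj[[s_atom]])
      cand <- cand[vapply(cand, function(a) {
        rest <- setdiff(groups[[d]]$atoms, a)
        length(rest) == 0 || connected_subset(mol, rest)
      }, logical(1))]
      if (!length(cand)) next
      a <- min(cand)
      groups[[d]]$atoms <- setdiff(groups[[d]]$atoms, a)
      groups[[s]]$atoms <- sort(c(groups[[s]]$atoms, a))
      groups[[s]]$origin <- "postprocess"
      moved <- TRUE
      break
    }
    if (!moved) stop("cannot resolve single-atom bead at atom ", s_atom)
    groups <- groups[lengths(lapply(groups, `[[`, "atoms")) > 0]
  }
  order_beads(groups)
}

connected_subset <- function(mol, atoms) {
  if (length(atoms) <= 1) return(TRUE)
  in_set <- logical(mol$natoms)
  in_set[atoms] <- TRUE
  seen <- logical(mol$natoms)
  queue <- atoms[1]
  seen[atoms[1]] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in mol$adj[[v]]) {
      if (in_set[w] && !seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
  }
  all(seen[atoms])
}
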