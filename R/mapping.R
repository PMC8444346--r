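# Spectral graph grouping: beads are nodes of a weighted adjacency structure
# whose leading eigenvector ranks them for merging.

new_bead <- function(atoms, origin = "spectral", ring = FALSE,
                     aromatic = FALSE, ring_system = NA_integer_,
                     type = NA_character_) {
  list(atoms = sort(unique(as.integer(atoms))), origin = origin,
       ring = ring, aromatic = aromatic, ring_system = ring_system,
       type = type)
}

#' Spectral node weight of a bead
#'
#' The diagonal weight of a bead node is the product `l * mbar` of its
#' internal maximum path length (bond count) and the mean heavy-atom mass.
#' Path length favours compact, branched beads over extended ones; mean mass
#' breaks ties between chemically distinct beads of equal shape.  Single
#' atoms have `l = 0` and therefore weight 0.
#'
#' @param mol a `cg_molecule`.
#' @param bead a bead (list with an `atoms` field) or an atom index vector.
#' @return numeric weight (u * bonds).
#' @export
node_weight <- function(mol, bead) {
  atoms <- if (is.list(bead)) bead$atoms else as.integer(bead)
  l <- heavy_atom_path_length(mol, atoms)
  l * mean(mol$atoms$mass[atoms])
}

#' Weighted adjacency structure over bead nodes
#'
#' Off-diagonal entries are 1 when any atomistic bond crosses between two
#' beads and 0 otherwise; diagonal entries carry the [node_weight()] of each
#' bead.
#'
#' @param mol a `cg_molecule`.
#' @param groups list of beads partitioning a subset of the atoms.
#' @return symmetric numeric matrix.
#' @export
build_weighted_adjacency <- function(mol, groups) {
  n <- length(groups)
  atom2grp <- rep(NA_integer_, mol$natoms)
  for (g in seq_len(n)) {
    a <- groups[[g]]$atoms
    if (any(!is.na(atom2grp[a]))) stop("overlapping groups in adjacency build")
    atom2grp[a] <- g
  }
  A <- matrix(0, n, n)
  for (k in seq_len(nrow(mol$bonds))) {
    gi <- atom2grp[mol$bonds$i[k]]
    gj <- atom2grp[mol$bonds$j[k]]
    if (!is.na(gi) && !is.na(gj) && gi != gj) {
      A[gi, gj] <- 1
      A[gj, gi] <- 1
    }
  }
  diag(A) <- vapply(groups, function(g) node_weight(mol, g), numeric(1))
  A
}

#' Centrality scores of bead nodes
#'
#' Scores are the components of the eigenvector of the weighted adjacency
#' matrix belonging to its largest eigenvalue, normalized to unit Euclidean
#' norm with signs fixed positive.  For a connected node graph the matrix is
#' irreducible and non-negative, so by Perron-Frobenius the leading
#' eigenvalue is simple and the eigenvector can be taken strictly positive.
#' Scores closer than `tie_tol` (relative) form one tie group.
#'
#' @param A symmetric weighted adjacency matrix.
#' @param tie_tol relative tolerance declaring two scores tied.
#' @return list with `scores`, `rank` (1 = lowest score) and `tie_group`
#'   (integer id; equal ids are tied).
#' @export
centrality_scores <- function(A, tie_tol = 1e-8) {
  n <- nrow(A)
  if (n == 1) {
    return(list(scores = 1, rank = 1L, tie_group = 1L))
  }
  B <- (A > 0) * 1
  diag(B) <- 0
  comp <- graph_components(apply(B, 1, function(r) which(r > 0),
                                 simplify = FALSE), n)
  if (max(comp) > 1) stop("node graph is disconnected; cannot rank globally")
  es <- eigen(A, symmetric = TRUE)
  v <- es$vectors[, 1]
  if (sum(v) < 0) v <- -v
  v <- abs(v)             # Perron vector is positive; abs() removes -0 noise
  v <- v / sqrt(sum(v^2))
  scale <- max(v)
  ord <- order(v)
  tie_group <- integer(n)
  gid <- 0L
  last <- -Inf
  for (i in ord) {
    if (v[i] - last > tie_tol * scale) gid <- gid + 1L
    tie_group[i] <- gid
    last <- v[i]
  }
  list(scores = v, rank = rank(v, ties.method = "min"), tie_group = tie_group)
}

#' One pass of spectral grouping
#'
#' Nodes are visited in ascending centrality.  Each unconsumed, non-ring node
#' picks among its unconsumed non-ring neighbours of equal or higher score
#' the one closest in score; all tied nodes that simultaneously pick the same
#' neighbour merge together with it.  A merge whose combined bead would have
#' internal path length greater than `max_l` is rejected and its constituents
#' stay separate for this pass.  Ring beads never merge.
#'
#' @param mol a `cg_molecule`.
#' @param groups list of beads.
#' @param exclude logical vector marking ring beads excluded from merging
#'   (defaults to each bead's `ring` flag).
#' @param max_l maximum allowed internal path length (bonds).
#' @param tie_tol relative score tolerance for ties.
#' @return new list of beads (unchanged if no merge is possible).
#' @export
spectral_iteration <- function(mol, groups, exclude = NULL, max_l = 3,
                               tie_tol = 1e-8) {
  n <- length(groups)
  if (n <= 1) return(groups)
  if (is.null(exclude)) {
    exclude <- vapply(groups, function(g) isTRUE(g$ring), logical(1))
  }
  A <- build_weighted_adjacency(mol, groups)
  cs <- centrality_scores(A, tie_tol)
  nbrs <- apply(A > 0 & !diag(TRUE, n), 1, which, simplify = FALSE)

  min_atom <- vapply(groups, function(g) min(g$atoms), integer(1))
  score <- cs$scores
  tieg <- cs$tie_group
  consumed <- rep(FALSE, n)
  merged_into <- rep(NA_integer_, n)   # cluster labels
  visit_order <- order(score, min_atom)

  # closest-ranked eligible higher-or-equal neighbours of node i; several
  # neighbours tied at the closest rank are all returned (a merge must
  # treat symmetrically equivalent neighbours together or not at all)
  pick_targets <- function(i) {
    cand <- nbrs[[i]]
    cand <- cand[!exclude[cand] & !consumed[cand] &
                   (tieg[cand] >= tieg[i])]
    if (!length(cand)) return(integer(0))
    d <- abs(score[cand] - score[i])
    sort(cand[tieg[cand] == tieg[cand[which.min(d)]]])
  }

  clusters <- list()
  for (i in visit_order) {
    if (consumed[i] || exclude[i]) next
    targets <- pick_targets(i)
    if (!length(targets)) next
    # all unconsumed tied peers of i with the same target set
    peers <- which(!consumed & !exclude & tieg == tieg[i])
    peers <- setdiff(peers, targets)
    peers <- peers[vapply(peers, function(k)
      identical(pick_targets(k), targets), logical(1))]
    members <- sort(unique(c(i, peers, targets)))
    atoms <- sort(unique(unlist(lapply(groups[members],
                                       function(g) g$atoms))))
    l <- heavy_atom_path_length(mol, atoms)
    if (l > max_l) next                 # rejected: constituents stay separate
    consumed[members] <- TRUE
    clusters[[length(clusters) + 1]] <- members
  }

  if (!length(clusters)) return(groups)
  out <- list()
  done <- rep(FALSE, n)
  for (cl in clusters) {
    atoms <- sort(unique(unlist(lapply(groups[cl], function(g) g$atoms))))
    out[[length(out) + 1]] <- new_bead(atoms, origin = "spectral")
    done[cl] <- TRUE
  }
  for (i in which(!done)) out[[length(out) + 1]] <- groups[[i]]
  order_beads(out)
}

order_beads <- function(groups) {
  groups[order(vapply(groups, function(g) min(g$atoms), integer(1)))]
}
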