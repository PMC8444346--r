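#' Molecular heavy-atom graph from a SMILES string
#'
#' Parses a SMILES string into a heavy-atom graph.  Hydrogens are implicit:
#' they are never graph nodes, but each atom records how many it carries so
#' that fragment capping and bead masses can account for them.  Atom order is
#' canonical (derived from the OpenBabel canonical SMILES), so the same
#' molecule written with any atom ordering yields an identical graph.
#'
#' @param smiles SMILES string of a single covalently connected molecule.
#' @param name optional molecule name carried through to output files.
#' @return an object of class `cg_molecule` with components:
#'   \describe{
#'     \item{atoms}{data frame with `element`, `mass` (u), `aromatic`,
#'       `charge`, `nH` (implicit hydrogens), `donor`, `acceptor`.}
#'     \item{bonds}{data frame of heavy-atom bonds `i`, `j`, `order`
#'       (kekulized orders).}
#'     \item{rings}{list of integer vectors, the smallest set of smallest
#'       rings (SSSR).}
#'     \item{ring_ids}{per-atom list of SSSR ring indices.}
#'     \item{adj}{adjacency list over heavy atoms.}
#'   }
#' @examples
#' \dontrun{
#' mol <- parse_smiles("CCO", name = "ethanol")
#' mol$atoms
#' }
#' @export
parse_smiles <- function(smiles, name = NULL) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  s <- trimws(smiles)
  if (grepl("\\.", s)) {
    frags <- strsplit(s, ".", fixed = TRUE)[[1]]
    stop("disconnected input is not supported (fragments: ",
         paste(frags, collapse = ", "), ")", call. = FALSE)
  }
  canon <- ob_canonical_smiles(s)
  mol_text <- suppressWarnings(ChemmineOB::convertFormat("SMI", "SDF", canon))
  n_atoms <- as.integer(substr(strsplit(mol_text, "\n")[[1]][4], 1, 3))
  mol <- if (n_atoms <= 1) {
    single_atom_molecule(mol_text, canon, name)
  } else {
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(canon))[[1]]
    molecule_from_sdf(sdf, canonical_smiles = canon, name = name)
  }
  if (mol$natoms < 1) stop("no heavy atoms in input: ", smiles, call. = FALSE)
  comp <- graph_components(mol$adj, mol$natoms)
  if (max(comp) > 1) {
    stop("parsed structure is disconnected: ", smiles, call. = FALSE)
  }
  mol
}

# Single heavy atoms never pass through ChemmineR (its SDF validator
# requires a bond block); the molfile text is read directly instead.
single_atom_molecule <- function(mol_text, canon, name = NULL) {
  lines <- strsplit(mol_text, "\n")[[1]]
  el <- trimws(substr(lines[5], 32, 34))
  charge <- 0L
  chg <- grep("^M  CHG", lines, value = TRUE)
  if (length(chg)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", chg[1])),
                             " +")[[1]])
    charge <- f[3]
  }
  nH <- implicit_hydrogens(el, 0, charge)
  atoms <- data.frame(
    element = el, mass = atomic_mass(el), aromatic = FALSE,
    charge = charge, nH = nH,
    donor = el %in% c("N", "O") && nH >= 1 && charge >= 0,
    acceptor = el %in% c("N", "O") && charge <= 0,
    stringsAsFactors = FALSE
  )
  structure(list(
    name = if (is.null(name)) canon else name,
    smiles = canon, natoms = 1L, atoms = atoms,
    bonds = data.frame(i = integer(0), j = integer(0), order = integer(0)),
    adj = list(integer(0)),
    rings = list(), ring_ids = list(integer(0))
  ), class = "cg_molecule")
}

# Build the cg_molecule from a ChemmineR SDF object.  Atom order in the SDF
# follows the canonical SMILES, which is what makes the ordering canonical.
molecule_from_sdf <- function(sdf, canonical_smiles, name = NULL) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- gsub("_.*$", "", rownames(ab))
  n <- length(elements)
  # V2000 charge codes: 1..3 -> +3..+1, 5..7 -> -1..-3
  code <- if (ncol(ab) >= 5) ab[, 5] else rep(0, n)
  charge <- integer(n)
  charge[code >= 1 & code <= 3] <- 4L - as.integer(code[code >= 1 & code <= 3])
  charge[code >= 5 & code <= 7] <- 4L - as.integer(code[code >= 5 & code <= 7])

  if (is.null(dim(bb))) bb <- matrix(bb, nrow = if (length(bb)) 1 else 0,
                                     ncol = max(3, length(bb)))
  bonds <- if (nrow(bb) > 0) {
    data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  } else {
    data.frame(i = integer(0), j = integer(0), order = integer(0))
  }

  adj <- adjacency_list(bonds, n)
  ring_info <- perceive_rings(sdf, elements, n)

  bond_order_sum <- numeric(n)
  for (k in seq_len(nrow(bonds))) {
    bond_order_sum[bonds$i[k]] <- bond_order_sum[bonds$i[k]] + bonds$order[k]
    bond_order_sum[bonds$j[k]] <- bond_order_sum[bonds$j[k]] + bonds$order[k]
  }
  nH <- vapply(seq_len(n), function(i) {
    implicit_hydrogens(elements[i], bond_order_sum[i], charge[i])
  }, integer(1))

  aromatic <- ring_info$aromatic_atoms
  # Pharmacophore-style hydrogen-bond roles on N/O: any N-H or O-H donates;
  # oxygens and nitrogens accept unless the lone pair is tied up in the
  # aromatic pi system (pyrrole-type N-H) or the atom is cationic.
  donor <- elements %in% c("N", "O") & nH >= 1 & charge >= 0
  acceptor <- (elements == "O" & charge <= 0) |
    (elements == "N" & charge <= 0 & !(aromatic & nH >= 1))

  atoms <- data.frame(
    element = elements,
    mass = atomic_mass(elements),
    aromatic = aromatic,
    charge = charge,
    nH = nH,
    donor = donor,
    acceptor = acceptor,
    stringsAsFactors = FALSE
  )

  structure(list(
    name = if (is.null(name)) canonical_smiles else name,
    smiles = canonical_smiles,
    natoms = n,
    atoms = atoms,
    bonds = bonds,
    adj = adj,
    rings = ring_info$rings,
    ring_ids = ring_info$ring_ids
  ), class = "cg_molecule")
}

adjacency_list <- function(bonds, n) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    adj[[bonds$i[k]]] <- c(adj[[bonds$i[k]]], bonds$j[k])
    adj[[bonds$j[k]]] <- c(adj[[bonds$j[k]]], bonds$i[k])
  }
  lapply(adj, function(x) sort(unique(x)))
}

# SSSR from the full cycle list reported by ChemmineR: scan rings by
# increasing size and keep those covering at least one uncovered ring bond.
perceive_rings <- function(sdf, elements, n) {
  empty <- list(rings = list(), ring_ids = rep(list(integer(0)), n),
                aromatic_atoms = rep(FALSE, n))
  rng <- tryCatch(
    suppressWarnings(ChemmineR::rings(sdf, type = "all", arom = TRUE)),
    error = function(e) NULL
  )
  if (is.null(rng) || length(rng$RINGS) == 0) return(empty)
  to_idx <- function(labels) as.integer(gsub("^[A-Za-z]+_", "", labels))
  all_rings <- lapply(rng$RINGS, to_idx)
  arom <- as.logical(rng$AROMATIC)
  ord <- order(vapply(all_rings, length, integer(1)))
  covered <- character(0)
  keep <- integer(0)
  for (k in ord) {
    ring <- all_rings[[k]]
    m <- length(ring)
    edges <- vapply(seq_len(m), function(t) {
      a <- ring[t]; b <- ring[t %% m + 1]
      paste(min(a, b), max(a, b))
    }, character(1))
    if (any(!(edges %in% covered))) {
      keep <- c(keep, k)
      covered <- union(covered, edges)
    }
  }
  rings <- all_rings[keep]
  arom <- arom[keep]
  ring_ids <- rep(list(integer(0)), n)
  aromatic_atoms <- rep(FALSE, n)
  for (r in seq_along(rings)) {
    for (a in rings[[r]]) ring_ids[[a]] <- c(ring_ids[[a]], r)
    if (arom[r]) aromatic_atoms[rings[[r]]] <- TRUE
  }
  list(rings = rings, ring_ids = ring_ids, aromatic_atoms = aromatic_atoms)
}

graph_components <- function(adj, n) {
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
      }
    }
  }
  comp
}

#' @export
print.cg_molecule <- function(x, ...) {
  cat("<cg_molecule> ", x$name, "\n", sep = "")
  cat("  SMILES: ", x$smiles, "\n", sep = "")
  cat("  ", x$natoms, " heavy atoms, ", nrow(x$bonds), " bonds, ",
      length(x$rings), " rings\n", sep = "")
  invisible(x)
}

#' Maximum internal path length of an atom set
#'
#' Returns the maximum number of bonds between any two heavy atoms of
#' `atom_set`, measured by shortest paths within the induced subgraph.  This
#' is the quantity `l` that limits bead size (beads must satisfy `l <= 3`)
#' and enters the spectral node weight.
#'
#' @param mol a `cg_molecule`.
#' @param atom_set integer vector of atom indices inducing a connected
#'   subgraph.
#' @return integer bond count (0 for a single atom).
#' @export
heavy_atom_path_length <- function(mol, atom_set) {
  atom_set <- sort(unique(as.integer(atom_set)))
  if (length(atom_set) == 0) stop("empty atom set")
  if (length(atom_set) == 1) return(0L)
  in_set <- logical(mol$natoms)
  in_set[atom_set] <- TRUE
  lmax <- 0L
  for (src in atom_set) {
    dist <- rep(NA_integer_, mol$natoms)
    dist[src] <- 0L
    queue <- src
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in mol$adj[[v]]) {
        if (in_set[w] && is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
      }
    }
    if (anyNA(dist[atom_set])) {
      stop("atom set does not induce a connected subgraph")
    }
    lmax <- max(lmax, max(dist[atom_set]))
  }
  as.integer(lmax)
}

#' Atom equivalence classes under iterated neighbourhood refinement
#'
#' Weisfeiler-Lehman style colour refinement: atoms start from a colour
#' combining element, aromaticity, charge and hydrogen count, and are
#' iteratively split by the multiset of (bond order, neighbour colour) pairs
#' until a fixpoint.  Used to verify that mappings respect molecular
#' symmetry.
#'
#' @param mol a `cg_molecule`.
#' @return integer vector of class ids (numbered by first occurrence in
#'   canonical atom order).
#' @export
symmetry_classes <- function(mol) {
  n <- mol$natoms
  order_of <- matrix(0L, n, n)
  for (k in seq_len(nrow(mol$bonds))) {
    order_of[mol$bonds$i[k], mol$bonds$j[k]] <- mol$bonds$order[k]
    order_of[mol$bonds$j[k], mol$bonds$i[k]] <- mol$bonds$order[k]
  }
  col <- paste(mol$atoms$element, mol$atoms$aromatic, mol$atoms$charge,
               mol$atoms$nH)
  for (iter in seq_len(n)) {
    sig <- vapply(seq_len(n), function(i) {
      nb <- mol$adj[[i]]
      # aromatic bonds are treated as a single order class so that the
      # kekule phase does not split symmetric aromatic atoms
      ords <- ifelse(mol$atoms$aromatic[i] & mol$atoms$aromatic[nb] &
                       order_of[i, nb] %in% c(1L, 2L), "ar",
                     as.character(order_of[i, nb]))
      paste(col[i], paste(sort(paste(ords, col[nb])), collapse = "|"))
    }, character(1))
    new_col <- sig
    if (length(unique(new_col)) == length(unique(col))) {
      col <- new_col
      break
    }
    col <- new_col
  }
  match(col, unique(col))
}

#' Read a SMILES file
#'
#' One record per line, `SMILES<TAB>name` (name optional); `#` starts a
#' comment.
#'
#' @param path file path.
#' @return data frame with columns `smiles`, `name`.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[\t ]+")
  data.frame(
    smiles = vapply(parts, `[`, character(1), 1),
    name = vapply(parts, function(p) if (length(p) > 1) p[2] else p[1],
                  character(1)),
    stringsAsFactors = FALSE
  )
}
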