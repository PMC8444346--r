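# Nonbonded bead-type assignment: each bead's capped fragment is scored by
# its octanol-water transfer free energy (bundled fragment table first,
# Wildman-Crippen atom contributions as fallback) and matched to the closest
# Martini 2 reference type; hydrogen bonding refines N- and Q-class choices,
# and aromatic fragments are typed through standardized test rings.

GAS_CONSTANT_KJ <- 8.314462618e-3   # kJ/mol/K

#' Convert logP to an octanol-water transfer free energy
#'
#' Sign convention: a hydrophobic fragment (positive logP) has a negative
#' water-to-octanol transfer free energy.  `dgow_to_logp` is the inverse.
#'
#' @param logp base-10 octanol-water partition coefficient.
#' @param temperature_K temperature in kelvin.
#' @return free energy in kJ/mol.
#' @export
logp_to_dgow <- function(logp, temperature_K = 300) {
  -GAS_CONSTANT_KJ * temperature_K * log(10) * logp
}

#' @rdname logp_to_dgow
#' @param dgow transfer free energy in kJ/mol.
#' @export
dgow_to_logp <- function(dgow, temperature_K = 300) {
  -dgow / (GAS_CONSTANT_KJ * temperature_K * log(10))
}

.table_cache <- new.env(parent = emptyenv())

#' Bundled Martini 2 bead-type reference table
#'
#' @param path optional path to a user table (CSV with columns `type`,
#'   `dgow_kj`, `hbond`, `charge`, `window_only`).
#' @return data frame of bead types.
#' @export
load_bead_type_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "martini2_bead_types.csv",
                        package = "autocg")
  }
  tab <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("type", "dgow_kj", "hbond", "charge", "window_only")
                %in% names(tab)))
  if (anyDuplicated(tab$type)) stop("bead type names must be unique")
  tab
}

#' Bundled fragment free-energy lookup table
#'
#' Canonical-SMILES-keyed table of octanol-water logP values for common
#' capped fragments (the shipped values are curated experimental logP data).
#'
#' @param path optional path to a user table (CSV with columns `smiles`,
#'   `name`, `logp`).
#' @return data frame.
#' @export
load_fragment_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "fragment_dgow.csv", package = "autocg")
  }
  key <- paste0("frag:", path)
  if (!is.null(.table_cache[[key]])) return(.table_cache[[key]])
  tab <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("smiles", "name", "logp") %in% names(tab)))
  .table_cache[[key]] <- tab
  tab
}

#' Cap a bead's fragment with hydrogens
#'
#' Builds the standalone neutral-valence fragment of a bead: the induced
#' heavy-atom subgraph with every cut bond replaced by an implicit hydrogen,
#' canonicalized.  Aromatic beads are flagged so the test-ring constructor
#' can rebuild the full ring instead.
#'
#' @param mol a `cg_molecule`.
#' @param bead a bead (or atom index vector).
#' @return list with `smiles` (canonical), `charge`, `donor`, `acceptor`,
#'   `aromatic`, `attachment_count`.
#' @export
cap_fragment <- function(mol, bead) {
  atoms <- if (is.list(bead)) bead$atoms else sort(unique(as.integer(bead)))
  idx <- match(seq_len(mol$natoms), atoms)
  sub_bonds <- mol$bonds[mol$bonds$i %in% atoms & mol$bonds$j %in% atoms, ,
                         drop = FALSE]
  attach <- sum(mol$bonds$i %in% atoms != mol$bonds$j %in% atoms)
  frag_bonds <- data.frame(i = idx[sub_bonds$i], j = idx[sub_bonds$j],
                           order = sub_bonds$order)
  mf <- graph_to_molfile(mol$atoms$element[atoms], frag_bonds,
                         mol$atoms$charge[atoms])
  smi <- ob_to_canonical_or_na(mf, from = "SDF")
  if (is.na(smi)) {
    stop("fragment capping failed for bead with atoms ",
         paste(atoms, collapse = ","))
  }
  arom <- any(mol$atoms$aromatic[atoms])
  list(
    smiles = smi,
    charge = sum(mol$atoms$charge[atoms]),
    donor = any(mol$atoms$donor[atoms]),
    acceptor = any(mol$atoms$acceptor[atoms]),
    aromatic = arom,
    attachment_count = attach
  )
}

#' Octanol-water free energy of a fragment
#'
#' Looks the canonical fragment SMILES up in the fragment table; on a miss
#' the Wildman-Crippen atom-contribution estimate is used.
#'
#' @param smiles fragment SMILES (neutral).
#' @param table fragment table from [load_fragment_table()].
#' @param temperature_K conversion temperature.
#' @return list with `smiles`, `logp`, `dgow` (kJ/mol), `source`.
#' @export
lookup_dgow <- function(smiles, table = load_fragment_table(),
                        temperature_K = 300) {
  canon <- ob_canonical_smiles(smiles)
  hit <- match(canon, table$smiles)
  if (!is.na(hit)) {
    logp <- table$logp[hit]
    src <- "lookup-table"
  } else {
    logp <- wildman_crippen_logp(canon)
    src <- "atom-contribution"
  }
  list(smiles = canon, logp = logp,
       dgow = logp_to_dgow(logp, temperature_K), source = src)
}

#' Assign a neutral bead type
#'
#' The Martini type with reference free energy closest to the fragment's
#' value wins.  If the fragment lies within `nda_window_kj` of the Nda
#' reference, hydrogen-bond roles refine the choice to Na (acceptor only),
#' Nd (donor only) or Nda (both); with neither role the plain distance rule
#' applies.  Ring beads receive the S-variant of the chosen type.
#'
#' @param record fragment record (needs `dgow`, `donor`, `acceptor`).
#' @param table bead-type table.
#' @param ring is the bead part of a ring?
#' @param nda_window_kj window half-width in kJ/mol.
#' @return bead type name.
#' @export
assign_neutral_bead <- function(record, table = load_bead_type_table(),
                                ring = FALSE, nda_window_kj = 1.0) {
  neutral <- table[table$charge == 0 & !table$window_only, , drop = FALSE]
  if (!nrow(neutral)) stop("bead type table has no neutral entries")
  nda_ref <- table$dgow_kj[table$type == "Nda"]
  type <- NULL
  if (length(nda_ref) == 1 &&
      abs(record$dgow - nda_ref) <= nda_window_kj &&
      (record$donor || record$acceptor)) {
    type <- if (record$donor && record$acceptor) "Nda"
            else if (record$donor) "Nd" else "Na"
  }
  if (is.null(type)) {
    d <- abs(neutral$dgow_kj - record$dgow)
    type <- neutral$type[which.min(d)]
  }
  if (ring) paste0("S", type) else type
}

#' Assign a charged bead type
#'
#' Charged fragments are typed purely from hydrogen bonding: Qda (donor and
#' acceptor), Qd (donor), Qa (acceptor), Q0 (neither).
#'
#' @param record fragment record (needs `donor`, `acceptor`).
#' @return bead type name.
#' @export
assign_charged_bead <- function(record) {
  if (record$donor && record$acceptor) "Qda"
  else if (record$donor) "Qd"
  else if (record$acceptor) "Qa"
  else "Q0"
}

# Aromatic-token rendering of one ring atom plus its absorbed single-atom
# substituents, used to assemble test-ring SMILES.
aromatic_atom_token <- function(mol, a, bead_atoms) {
  el <- tolower(mol$atoms$element[a])
  tok <- if (mol$atoms$element[a] == "N" && mol$atoms$nH[a] >= 1) "[nH]"
         else el
  subs <- setdiff(intersect(mol$adj[[a]], bead_atoms),
                  which(mol$atoms$aromatic))
  branch <- ""
  for (s in subs) {
    k <- which((mol$bonds$i == a & mol$bonds$j == s) |
                 (mol$bonds$i == s & mol$bonds$j == a))[1]
    bsym <- if (mol$bonds$order[k] == 2) "=" else ""
    sel <- mol$atoms$element[s]
    satom <- if (mol$atoms$charge[s] != 0) {
      sprintf("[%s%s]", sel, ifelse(mol$atoms$charge[s] > 0, "+", "-"))
    } else sel
    branch <- paste0(branch, "(", bsym, satom, ")")
  }
  paste0(tok, branch)
}

#' Assign an aromatic bead type via a standardized test ring
#'
#' The bead's aromatic ring atoms are completed to a six-membered aromatic
#' test molecule (five-membered when six is not chemically valid, as for
#' some N-heteroaromatics).  The test molecule's free energy is predicted
#' and the candidate type minimizing
#' `|dG(test) - (dG(candidate) + n_filler * dG(filler))|` is chosen, where
#' the filler bead type represents the added carbons (N0 at trimer
#' resolution, C5 at dimer resolution).  The S-variant is returned.
#'
#' @param mol a `cg_molecule`.
#' @param bead an aromatic ring bead.
#' @param table bead-type table.
#' @param fragment_table fragment free-energy table.
#' @param config pipeline configuration.
#' @return bead type name (S-variant).
#' @export
assign_aromatic_bead <- function(mol, bead, table = load_bead_type_table(),
                                 fragment_table = load_fragment_table(),
                                 config = autocg_config()) {
  ring_atoms <- bead$atoms[mol$atoms$aromatic[bead$atoms]]
  if (!length(ring_atoms)) stop("bead has no aromatic atoms")
  ring_atoms <- order_along_path(mol, ring_atoms)
  toks <- vapply(ring_atoms, aromatic_atom_token, character(1),
                 mol = mol, bead_atoms = bead$atoms)
  k <- length(ring_atoms)
  build_ring <- function(size) {
    fill <- size - k
    if (fill < 0) return(NA_character_)
    fills <- rep("c", fill)
    body <- paste0(c(paste0(toks[1], "1"), toks[-1], fills), collapse = "")
    paste0(body, "1")
  }
  test <- NA_character_
  for (size in c(6L, 5L)) {
    cand <- build_ring(size)
    if (is.na(cand)) next
    canon <- ob_to_canonical_or_na(cand, from = "SMI")
    # require a genuinely aromatic parse (ring intact, kekulizable)
    if (!is.na(canon) && grepl("1", canon)) {
      test <- canon
      ring_size <- size
      break
    }
  }
  if (is.na(test)) {
    stop("no valid aromatic test ring for bead with atoms ",
         paste(bead$atoms, collapse = ","), "; manual typing required")
  }
  rec <- lookup_dgow(test, fragment_table, config$temperature_K)
  filler_type <- if (config$resolution == "trimer") config$filler_trimer
                 else config$filler_dimer
  filler_atoms <- if (config$resolution == "trimer") 2L else 3L
  n_filler <- ceiling((ring_size - k) / filler_atoms)
  dg_filler <- table$dgow_kj[table$type == filler_type]
  neutral <- table[table$charge == 0 & !table$window_only, , drop = FALSE]
  resid <- abs(rec$dgow - (neutral$dgow_kj + n_filler * dg_filler))
  paste0("S", neutral$type[which.min(resid)])
}

# Order 2-3 atoms along their induced path (beads are connected chains).
order_along_path <- function(mol, atoms) {
  if (length(atoms) <= 2) return(sort(atoms))
  deg_in <- vapply(atoms, function(a)
    length(intersect(mol$adj[[a]], atoms)), integer(1))
  ends <- atoms[deg_in == 1]
  if (!length(ends)) return(sort(atoms))          # cycle: canonical order
  start <- min(ends)
  path <- start
  while (length(path) < length(atoms)) {
    nxt <- setdiff(intersect(mol$adj[[path[length(path)]]], atoms), path)
    if (!length(nxt)) break
    path <- c(path, min(nxt))
  }
  path
}

#' Assign bead types for a whole mapping
#'
#' Routes each bead through the charged, aromatic or neutral assignment
#' path.  Beads from predefined ionic patterns keep their preassigned type.
#'
#' @param mapping a `cg_mapping`.
#' @param config pipeline configuration.
#' @return the mapping with `type`, `fragment` and `dgow` fields filled in
#'   on each bead.
#' @export
assign_bead_types <- function(mapping, config = autocg_config()) {
  mol <- mapping$molecule
  table <- load_bead_type_table(config$bead_type_table)
  frag_table <- load_fragment_table(config$fragment_table)
  for (b in seq_along(mapping$beads)) {
    bead <- mapping$beads[[b]]
    if (!is.na(bead$type)) next
    frag <- cap_fragment(mol, bead)
    mapping$beads[[b]]$fragment <- frag$smiles
    if (frag$charge != 0) {
      mapping$beads[[b]]$type <- assign_charged_bead(frag)
      next
    }
    if (isTRUE(bead$ring) && frag$aromatic) {
      mapping$beads[[b]]$type <- assign_aromatic_bead(
        mol, bead, table, frag_table, config)
      next
    }
    rec <- lookup_dgow(frag$smiles, frag_table, config$temperature_K)
    rec$donor <- frag$donor
    rec$acceptor <- frag$acceptor
    mapping$beads[[b]]$dgow <- rec$dgow
    mapping$beads[[b]]$type <- assign_neutral_bead(
      rec, table, ring = isTRUE(bead$ring),
      nda_window_kj = config$nda_window_kj)
  }
  mapping
}
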