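#' Map a molecule's heavy atoms onto coarse-grained beads
#'
#' Runs the full mapping pipeline: predefined ionic fragments, ring-system
#' patterns, iterated spectral grouping until no new beads form, and
#' single-atom postprocessing.  The result is a deterministic partition of
#' the heavy atoms into beads with internal path lengths between 1 and
#' `config$max_path_length`.
#'
#' @param mol a `cg_molecule` (at least 2 heavy atoms).
#' @param config pipeline configuration from [autocg_config()].
#' @return object of class `cg_mapping`: list with `beads` (list of beads),
#'   `atom2bead` (integer vector) and `molecule`.
#' @examples
#' \dontrun{
#' run_mapping(parse_smiles("CCCCCCCCCCCC"))
#' }
#' @export
run_mapping <- function(mol, config = autocg_config()) {
  if (mol$natoms < 2) {
    stop("no appropriate Martini representation for a single heavy atom")
  }
  ionic <- match_ionic_fragments(mol, config$ionic_patterns)
  ring <- map_ring_systems(mol, config$resolution)
  ionic_atoms <- unlist(lapply(ionic, `[[`, "atoms"))
  ring <- lapply(ring, function(b) {
    b$atoms <- setdiff(b$atoms, ionic_atoms)
    b
  })
  ring <- ring[lengths(lapply(ring, `[[`, "atoms")) > 0]

  mapped <- c(ionic_atoms, unlist(lapply(ring, `[[`, "atoms")))
  free <- setdiff(seq_len(mol$natoms), mapped)
  singles <- lapply(free, function(a) new_bead(a, origin = "spectral"))

  groups <- order_beads(c(ionic, ring, singles))
  exclude <- vapply(groups, function(g) {
    isTRUE(g$ring) || g$origin == "ionic-predefined"
  }, logical(1))

  repeat {
    new_groups <- spectral_iteration(mol, groups, exclude = exclude,
                                     max_l = config$max_path_length,
                                     tie_tol = config$tie_tol)
    if (length(new_groups) == length(groups)) break
    groups <- new_groups
    exclude <- vapply(groups, function(g) {
      isTRUE(g$ring) || g$origin == "ionic-predefined"
    }, logical(1))
  }

  groups <- resolve_single_atom_beads(mol, groups,
                                      max_l = config$max_path_length,
                                      tie_tol = config$tie_tol)

  beads <- order_beads(groups)
  atom2bead <- rep(NA_integer_, mol$natoms)
  for (b in seq_along(beads)) {
    if (any(!is.na(atom2bead[beads[[b]]$atoms]))) {
      stop("internal error: beads overlap")
    }
    atom2bead[beads[[b]]$atoms] <- b
  }
  if (anyNA(atom2bead)) stop("internal error: unmapped atoms remain")
  for (b in seq_along(beads)) {
    beads[[b]]$l <- heavy_atom_path_length(mol, beads[[b]]$atoms)
    beads[[b]]$aromatic <- all(mol$atoms$aromatic[beads[[b]]$atoms]) &&
      isTRUE(beads[[b]]$ring)
  }
  structure(list(beads = beads, atom2bead = atom2bead, molecule = mol),
            class = "cg_mapping")
}

#' @export
print.cg_mapping <- function(x, ...) {
  cat("<cg_mapping> ", x$molecule$name, ": ", length(x$beads), " beads\n",
      sep = "")
  for (b in seq_along(x$beads)) {
    bead <- x$beads[[b]]
    cat(sprintf("  %2d [%s%s] l=%d atoms: %s\n", b, bead$origin,
                if (isTRUE(bead$ring)) ", ring" else "", bead$l,
                paste(bead$atoms, collapse = ",")))
  }
  invisible(x)
}

#' Write a mapping file
#'
#' Plain-text dialect: one line per bead,
#' `bead_index  bead_name  atom_indices` (1-based canonical order), or a
#' GROMACS index-group (`.ndx`) dialect with one group per bead.
#'
#' @param mapping a `cg_mapping`.
#' @param path output file.
#' @param format `"map"` or `"ndx"`.
#' @return invisibly, the path.
#' @export
write_mapping <- function(mapping, path, format = c("map", "ndx")) {
  format <- match.arg(format)
  beads <- mapping$beads
  names <- bead_names(mapping)
  lines <- if (format == "map") {
    c(sprintf("; autocg mapping for %s", mapping$molecule$name),
      vapply(seq_along(beads), function(b) {
        sprintf("%d  %s  %s", b, names[b],
                paste(beads[[b]]$atoms, collapse = " "))
      }, character(1)))
  } else {
    unlist(lapply(seq_along(beads), function(b) {
      c(sprintf("[ %s ]", names[b]),
        paste(beads[[b]]$atoms, collapse = " "))
    }))
  }
  writeLines(lines, path)
  invisible(path)
}

bead_names <- function(mapping) {
  vapply(seq_along(mapping$beads), function(b) {
    els <- mapping$molecule$atoms$element[mapping$beads[[b]]$atoms]
    tab <- table(els)
    paste0(paste0(names(tab), ifelse(tab > 1, tab, ""), collapse = ""),
           "_", b)
  }, character(1))
}
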