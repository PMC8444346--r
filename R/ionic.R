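# Predefined ionic fragments are mapped before any other stage, with fixed
# bead types.  The shipped set covers the organic sulfate (SO4-, Qa) and
# sulfonate (CSO3-, Q0) head groups; users can extend the set via the
# pipeline configuration.

default_ionic_patterns <- function() {
  list(
    list(name = "sulfate", type = "Qa", match = match_sulfate),
    list(name = "sulfonate", type = "Q0", match = match_sulfonate)
  )
}

# S bonded to four O, one of them anionic: bead = S + 4 O (the ester oxygen
# linking to carbon is included in the head-group bead).
match_sulfate <- function(mol) {
  out <- list()
  for (s in which(mol$atoms$element == "S")) {
    nb <- mol$adj[[s]]
    ox <- nb[mol$atoms$element[nb] == "O"]
    if (length(nb) == 4 && length(ox) == 4 &&
        any(mol$atoms$charge[ox] == -1)) {
      out[[length(out) + 1]] <- c(s, ox)
    }
  }
  out
}

# S bonded to three O (one anionic) and one C: bead = C + S + 3 O.
match_sulfonate <- function(mol) {
  out <- list()
  for (s in which(mol$atoms$element == "S")) {
    nb <- mol$adj[[s]]
    ox <- nb[mol$atoms$element[nb] == "O"]
    cc <- nb[mol$atoms$element[nb] == "C"]
    if (length(nb) == 4 && length(ox) == 3 && length(cc) == 1 &&
        any(mol$atoms$charge[ox] == -1)) {
      out[[length(out) + 1]] <- c(cc, s, ox)
    }
  }
  out
}

#' Match predefined ionic fragments
#'
#' Scans the molecule for predefined charged substructures and maps each
#' non-overlapping match to a bead with a fixed, pre-assigned bead type
#' (excluded from all later mapping and typing stages).  Overlapping matches
#' keep the earlier pattern in the configured priority order.
#'
#' @param mol a `cg_molecule`.
#' @param patterns list of patterns (`name`, `type`, `match` function);
#'   defaults to the shipped sulfate/sulfonate set.
#' @return list of beads with `type` pre-assigned (possibly empty).
#' @export
match_ionic_fragments <- function(mol, patterns = default_ionic_patterns()) {
  taken <- rep(FALSE, mol$natoms)
  beads <- list()
  for (p in patterns) {
    for (atoms in p$match(mol)) {
      if (any(taken[atoms])) {
        message("ionic pattern '", p$name,
                "' overlaps an earlier match; keeping the earlier pattern")
        next
      }
      taken[atoms] <- TRUE
      b <- new_bead(atoms, origin = "ionic-predefined", type = p$type)
      beads[[length(beads) + 1]] <- b
    }
  }
  order_beads(beads)
}
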