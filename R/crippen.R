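# Wildman-Crippen atom-contribution logP.  Atom classes and contribution
# values follow the published parameterization (Wildman & Crippen, J. Chem.
# Inf. Comput. Sci. 1999, 39, 868-873); the classifier below encodes the
# published atom-type definitions as rules over the heavy-atom graph, with
# hydrogens typed from the environment of their parent atom.

.CRIPPEN <- c(
  C1 = 0.1441, C2 = 0.0000, C3 = -0.2035, C4 = -0.2051, C5 = -0.2783,
  C6 = 0.1551, C7 = 0.0017, C8 = 0.08452, C9 = -0.1444, C10 = -0.0516,
  C11 = 0.1193, C12 = -0.0967, C13 = -0.5443, C14 = 0.0, C15 = 0.245,
  C16 = 0.198, C17 = 0.0, C18 = 0.1581, C19 = 0.2955, C20 = 0.2713,
  C21 = 0.136, C22 = 0.4619, C23 = 0.5437, C24 = 0.1893, C25 = -0.8186,
  C26 = 0.264, C27 = 0.2148, CS = 0.08129,
  H1 = 0.123, H2 = -0.2677, H3 = 0.2142, H4 = 0.298, HS = 0.1125,
  N1 = -1.019, N2 = -0.7096, N3 = -1.027, N4 = -0.5188, N5 = 0.08387,
  N6 = 0.1836, N7 = -0.3187, N8 = -0.4458, N9 = 0.01508, N10 = -1.95,
  N11 = -0.3239, N12 = -1.119, N13 = -0.3396, N14 = 0.2887, NS = -0.4806,
  O1 = 0.1552, O2 = -0.2893, O3 = -0.0684, O4 = -0.4195, O5 = 0.0335,
  O6 = -0.3339, O7 = -1.189, O8 = 0.1788, O9 = -0.1526, O10 = 0.1129,
  O11 = 0.4833, O12 = -1.326, OS = -0.1188,
  F = 0.4202, Cl = 0.6895, Br = 0.8456, I = 0.8857, Hal = -2.996,
  P = 0.8612, S1 = 0.6482, S2 = -0.0024, S3 = 0.6237, Me1 = -0.3808
)

# Per-atom feature bundle used by the classifier.
crippen_features <- function(mol, i) {
  nb <- mol$adj[[i]]
  orders <- vapply(nb, function(j) {
    k <- which((mol$bonds$i == i & mol$bonds$j == j) |
                 (mol$bonds$i == j & mol$bonds$j == i))[1]
    mol$bonds$order[k]
  }, integer(1))
  arom_bond <- vapply(seq_along(nb), function(t) {
    mol$atoms$aromatic[i] && mol$atoms$aromatic[nb[t]] &&
      length(intersect(mol$ring_ids[[i]], mol$ring_ids[[nb[t]]])) > 0
  }, logical(1))
  list(
    el = mol$atoms$element[i],
    arom = mol$atoms$aromatic[i],
    charge = mol$atoms$charge[i],
    nH = mol$atoms$nH[i],
    nb = nb,
    nb_el = mol$atoms$element[nb],
    nb_arom = mol$atoms$aromatic[nb],
    orders = orders,
    arom_bond = arom_bond
  )
}

.HET_SET <- c("N", "O", "P", "S", "F", "Cl", "Br", "I")

classify_carbon <- function(f) {
  deg <- length(f$nb)
  sp3 <- all(f$orders == 1) && !f$arom
  nb_alC <- f$nb_el == "C" & !f$nb_arom
  nb_alHet <- f$nb_el %in% .HET_SET & !f$nb_arom
  if (f$arom) {
    subst <- which(!f$arom_bond)
    sub_el <- f$nb_el[subst]
    sub_arom <- f$nb_arom[subst]
    sub_ord <- f$orders[subst]
    weird <- sub_el[!sub_arom &
                      !(sub_el %in% c("C", "N", "O", "S", .HET_SET))]
    if (length(weird)) return("C13")
    if (any(sub_el == "F")) return("C14")
    if (any(sub_el == "Cl")) return("C15")
    if (any(sub_el == "Br")) return("C16")
    if (any(sub_el == "I")) return("C17")
    if (f$nH == 1) return("C18")
    if (sum(f$arom_bond) == 3) return("C19")
    if (any(sub_arom & sub_ord == 1)) return("C20")
    if (any(sub_ord == 2 & sub_el %in% c("C", "N", "O"))) return("C25")
    if (any(sub_el == "C" & !sub_arom)) return("C21")
    if (any(sub_el == "N" & !sub_arom)) return("C22")
    if (any(sub_el == "O" & !sub_arom)) return("C23")
    if (any(sub_el == "S" & !sub_arom)) return("C24")
    return("CS")
  }
  # aliphatic carbon
  if (sp3 && !any(f$nb_arom)) {
    if (all(f$nb_el == "C")) {
      if (f$nH >= 2) return("C1")
      return("C2")
    }
    if (any(nb_alHet)) {
      if (f$nH >= 2 || deg <= 1) return(if (f$nH >= 2) "C3" else "C4")
      return("C4")
    }
  }
  dbl <- which(f$orders == 2)
  trp <- which(f$orders == 3)
  if (length(dbl) && any(f$nb_el[dbl] != "C" & !f$nb_arom[dbl])) return("C5")
  if (length(trp)) return("C7")
  if (length(dbl) && any(f$nb_el[dbl] == "C")) {
    others <- setdiff(seq_along(f$nb), dbl[f$nb_el[dbl] == "C"][1])
    if (any(f$nb_arom[others])) return("C26")
    if (all(!f$nb_arom[others])) return("C6")
  }
  if (length(dbl) && any(f$nb_arom[dbl])) return("C26")
  if (sp3 && any(f$nb_arom)) {
    if (f$nH == 3) {
      return(if (f$nb_el[f$nb_arom][1] == "C") "C8" else "C9")
    }
    if (f$nH == 2) return("C10")
    if (f$nH == 1) return("C11")
    return("C12")
  }
  if (sp3 && any(!(f$nb_el %in% c("C", .HET_SET)))) return("C27")
  "CS"
}

classify_nitrogen <- function(f) {
  deg <- length(f$nb)
  if (f$arom) return(if (f$charge > 0) "N12" else "N11")
  if (f$charge > 0) {
    if (f$nH >= 1) return("N10")
    if (any(f$orders == 3)) return("N14")
    return("N13")
  }
  if (f$charge < 0) return("N14")
  if (any(f$orders == 3)) return("N9")
  dbl <- any(f$orders == 2)
  if (f$nH == 2 && deg == 1) return(if (f$nb_arom[1]) "N3" else "N1")
  if (f$nH == 1) {
    if (dbl) return("N5")
    if (deg == 2 && any(f$nb_arom)) return("N4")
    if (deg == 2) return("N2")
  }
  if (f$nH == 0) {
    if (dbl) return("N6")
    if (deg == 3) return(if (any(f$nb_arom)) "N8" else "N7")
  }
  "NS"
}

classify_oxygen <- function(f) {
  if (f$arom) return("O1")
  if (f$nH >= 1) return("O2")
  deg <- length(f$nb)
  if (f$charge < 0) {
    if (any(f$nb_el == "N")) return("O5")
    if (any(f$nb_el == "S")) return("O6")
    carboxylate <- any(f$nb_el == "C")    # O- on C: carboxylate-like
    if (carboxylate) return("O12")
    return("O7")
  }
  dbl <- which(f$orders == 2)
  if (length(dbl)) {
    partner_el <- f$nb_el[dbl[1]]
    if (partner_el %in% c("N", "O")) return("O5")
    if (partner_el == "S") return("O6")
    if (f$nb_arom[dbl[1]]) return("O8")
  }
  if (deg == 2 && !length(dbl)) {
    if (any(f$nb_arom)) return("O4")
    return("O3")
  }
  if (length(dbl)) return(NA_character_)  # carbonyl: resolved by caller
  "OS"
}

# Carbonyl oxygens need the substitution pattern of the carbonyl carbon.
classify_carbonyl_oxygen <- function(mol, i, f) {
  c_idx <- f$nb[which(f$orders == 2)[1]]
  fc <- crippen_features(mol, c_idx)
  others <- which(fc$nb != i)
  if (!length(others)) return("O9")                   # formaldehyde-like
  if (any(fc$nb_arom[others])) return("O10")
  other_el <- fc$nb_el[others]
  if (all(other_el != "C")) {
    if (length(others) >= 2) return("O11")
    return("O9")                                      # formamide-like
  }
  "O9"
}

classify_hydrogens <- function(mol, i, f) {
  if (f$nH == 0) return(character(0))
  parent <- f$el
  type <- if (parent == "C") {
    "H1"
  } else if (parent == "N") {
    "H3"
  } else if (parent == "O") {
    y <- f$nb
    if (!length(y)) {
      "HS"                                            # water
    } else {
      yel <- f$nb_el
      yarom <- f$nb_arom
      sp3C <- vapply(seq_along(y), function(t) {
        yel[t] == "C" && !yarom[t] &&
          all(crippen_features(mol, y[t])$orders == 1)
      }, logical(1))
      acid <- vapply(seq_along(y), function(t) {
        if (yel[t] != "C" || yarom[t]) return(FALSE)
        fy <- crippen_features(mol, y[t])
        any(fy$orders == 2 & fy$nb_el %in% c("C", "N", "O", "S"))
      }, logical(1))
      if (any(sp3C) || any(yarom)) "H2"
      else if (any(!(yel %in% c("C", "N", "O", "S")))) "H2"
      else if (any(yel == "N")) "H3"
      else if (any(acid) || any(yel %in% c("O", "S"))) "H4"
      else "HS"
    }
  } else {
    "H2"                                              # S-H, P-H, ...
  }
  rep(type, f$nH)
}

classify_atom <- function(mol, i) {
  f <- crippen_features(mol, i)
  heavy <- switch(
    f$el,
    C = classify_carbon(f),
    N = classify_nitrogen(f),
    O = {
      cls <- classify_oxygen(f)
      if (is.na(cls)) classify_carbonyl_oxygen(mol, i, f) else cls
    },
    S = {
      if (f$arom) "S3"
      else if (f$charge != 0) "S2"
      else if (any(f$orders == 2 & f$nb_el %in% c("N", "O", "P", "S"))) "S2"
      else "S1"
    },
    P = "P",
    F = if (f$charge < 0) "Hal" else "F",
    Cl = if (f$charge < 0) "Hal" else "Cl",
    Br = if (f$charge < 0) "Hal" else "Br",
    I = if (f$charge < 0) "Hal" else "I",
    B = "Me1",
    Si = "Me1",
    stop("Wildman-Crippen classification: unparameterized element '",
         f$el, "' at atom ", i)
  )
  c(heavy, classify_hydrogens(mol, i, f))
}

#' Wildman-Crippen atom-contribution logP
#'
#' Sums published per-atom contributions over all heavy atoms and their
#' implicit hydrogens.  Used as the fallback octanol-water estimator when a
#' fragment is missing from the bundled free-energy table.
#'
#' @param x a SMILES string or a `cg_molecule`.  The empty string gives 0.
#' @return logP (dimensionless, base-10).
#' @export
wildman_crippen_logp <- function(x) {
  if (is.character(x)) {
    if (!nzchar(trimws(x))) return(0)
    x <- parse_smiles(x)
  }
  stopifnot(inherits(x, "cg_molecule"))
  types <- unlist(lapply(seq_len(x$natoms), function(i) classify_atom(x, i)))
  contribs <- .CRIPPEN[types]
  if (anyNA(contribs)) {
    stop("unmatched Wildman-Crippen types: ",
         paste(unique(types[is.na(contribs)]), collapse = ", "))
  }
  sum(contribs)
}

#' Per-atom Wildman-Crippen type assignment
#'
#' @param mol a `cg_molecule`.
#' @return character vector of heavy-atom type labels (hydrogens excluded).
#' @keywords internal
crippen_atom_types <- function(mol) {
  vapply(seq_len(mol$natoms), function(i) classify_atom(mol, i)[1],
         character(1))
}
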