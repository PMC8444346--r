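# CG model assembly and GROMACS-dialect file output.

#' Assemble a coarse-grained model
#'
#' Combines mapping, bead types, bonded terms and the rigid-ring framework
#' into one consistent model.  Virtual sites carry zero mass; their mass is
#' redistributed onto the constructing real sites in proportion to the
#' construction weights, so total mass is conserved.  All intra-ring bead
#' pairs are excluded from nonbonded interactions.
#'
#' @param mapping a `cg_mapping` with types assigned
#'   (see [assign_bead_types()]).
#' @param cg output of [map_to_cg()].
#' @param bonded a `cg_bonded` object.
#' @param rigid a `cg_rigid` object.
#' @param name molecule name for the topology.
#' @return object of class `cg_model`.
#' @export
assemble_model <- function(mapping, cg, bonded, rigid,
                           name = mapping$molecule$name) {
  beads <- mapping$beads
  nb <- length(beads)
  types <- vapply(beads, function(b) b$type, character(1))
  if (anyNA(types)) {
    stop("bead(s) without type: ", paste(which(is.na(types)), collapse = ","))
  }
  charges <- vapply(beads, function(b)
    sum(mapping$molecule$atoms$charge[b$atoms]), numeric(1))
  masses <- cg$masses
  for (vs in rigid$virtual_sites) {
    masses[vs$constructors] <- masses[vs$constructors] +
      masses[vs$site] * vs$weights
    masses[vs$site] <- 0
  }
  # no bond may duplicate a constraint on the same pair
  if (nrow(bonded$bonds) && nrow(rigid$constraints)) {
    keyb <- paste(bonded$bonds$i, bonded$bonds$j)
    keyc <- paste(rigid$constraints$i, rigid$constraints$j)
    bonded$bonds <- bonded$bonds[!(keyb %in% keyc), , drop = FALSE]
  }
  structure(list(
    name = name,
    smiles = mapping$molecule$smiles,
    bead_names = bead_names(mapping),
    types = types,
    masses = masses,
    charges = charges,
    coords = apply(cg$xyz, c(2, 3), mean),
    bonds = bonded$bonds,
    angles = bonded$angles,
    constraints = rigid$constraints,
    dihedrals = rigid$dihedrals,
    virtual_sites = rigid$virtual_sites,
    exclusions = rigid$ring_pairs,
    mapping = mapping
  ), class = "cg_model")
}

#' @export
print.cg_model <- function(x, ...) {
  cat("<cg_model> ", x$name, "\n", sep = "")
  cat("  beads: ", length(x$types), " (",
      paste(x$types, collapse = " "), ")\n", sep = "")
  cat("  bonds: ", nrow(x$bonds), ", angles: ", nrow(x$angles),
      ", constraints: ", nrow(x$constraints), ", dihedrals: ",
      nrow(x$dihedrals), ", virtual sites: ", length(x$virtual_sites),
      "\n", sep = "")
  invisible(x)
}

fmt_header <- function(model, config = NULL) {
  c(sprintf("; %s topology generated by autocg %s", model$name,
            as.character(utils::packageVersion("autocg"))),
    sprintf("; SMILES: %s", model$smiles),
    if (!is.null(config)) sprintf("; config hash: %s", config_hash(config)))
}

#' Write a GROMACS molecule topology (.itp)
#'
#' Sections: moleculetype, atoms, bonds, angles, constraints, dihedrals
#' (harmonic, function type 2), virtual_sitesn (function type 3, explicit
#' normalized weights) and exclusions.  Indices are 1-based; lengths in nm
#' with fixed 5-decimal precision.
#'
#' @param model a `cg_model`.
#' @param path output path.
#' @param config optional configuration included in the provenance header.
#' @return invisibly, the path.
#' @export
write_itp <- function(model, path, config = NULL) {
  nb <- length(model$types)
  lines <- c(fmt_header(model, config), "",
             "[ moleculetype ]",
             "; name  nrexcl",
             sprintf("%-8s 1", sanitize_name(model$name)), "",
             "[ atoms ]",
             "; nr  type  resnr  residue  atom  cgnr  charge  mass")
  for (b in seq_len(nb)) {
    lines <- c(lines, sprintf("%4d %-5s %5d %-6s %-5s %4d %8.3f %9.4f",
                              b, model$types[b], 1,
                              substr(sanitize_name(model$name), 1, 5),
                              model$bead_names[b], b, model$charges[b],
                              model$masses[b]))
  }
  if (nrow(model$bonds)) {
    lines <- c(lines, "", "[ bonds ]", ";  i   j  funct  length  fc")
    for (r in seq_len(nrow(model$bonds))) {
      lines <- c(lines, sprintf("%4d %3d   1  %9.5f %9.1f",
                                model$bonds$i[r], model$bonds$j[r],
                                model$bonds$length_nm[r], model$bonds$fc[r]))
    }
  }
  if (nrow(model$angles)) {
    lines <- c(lines, "", "[ angles ]", ";  i   j   k  funct  angle  fc")
    for (r in seq_len(nrow(model$angles))) {
      lines <- c(lines, sprintf("%4d %3d %3d   2  %9.3f %9.1f",
                                model$angles$i[r], model$angles$j[r],
                                model$angles$k[r], model$angles$angle_deg[r],
                                model$angles$fc[r]))
    }
  }
  if (nrow(model$constraints)) {
    lines <- c(lines, "", "[ constraints ]", ";  i   j  funct  length")
    for (r in seq_len(nrow(model$constraints))) {
      lines <- c(lines, sprintf("%4d %3d   1  %9.5f",
                                model$constraints$i[r],
                                model$constraints$j[r],
                                model$constraints$length_nm[r]))
    }
  }
  if (nrow(model$dihedrals)) {
    lines <- c(lines, "", "[ dihedrals ]",
               ";  i   j   k   l  funct  angle  fc  (harmonic hinge)")
    for (r in seq_len(nrow(model$dihedrals))) {
      lines <- c(lines, sprintf("%4d %3d %3d %3d   2  %9.3f %9.1f",
                                model$dihedrals$i[r], model$dihedrals$j[r],
                                model$dihedrals$k[r], model$dihedrals$l[r],
                                model$dihedrals$angle_deg[r],
                                model$dihedrals$fc[r]))
    }
  }
  if (length(model$virtual_sites)) {
    lines <- c(lines, "", "[ virtual_sitesn ]",
               "; site  funct  constructing sites ... weights ...")
    for (vs in model$virtual_sites) {
      lines <- c(lines, sprintf("%4d   3  %s  %s", vs$site,
                                paste(sprintf("%d", vs$constructors),
                                      collapse = " "),
                                paste(sprintf("%.5f", vs$weights),
                                      collapse = " ")))
    }
  }
  if (nrow(model$exclusions)) {
    lines <- c(lines, "", "[ exclusions ]")
    for (i in sort(unique(model$exclusions$i))) {
      js <- sort(model$exclusions$j[model$exclusions$i == i])
      lines <- c(lines, sprintf("%4d  %s", i, paste(js, collapse = " ")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

sanitize_name <- function(x) gsub("[^A-Za-z0-9_-]", "_", x)

#' Read back an autocg topology (.itp)
#'
#' Parses the topology dialect written by [write_itp()]; used for
#' round-trip validation.
#'
#' @param path file path.
#' @return list with the model components found in the file.
#' @export
read_itp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub(";.*$", "", lines))
  section <- NA_character_
  out <- list(atoms = NULL, bonds = NULL, angles = NULL, constraints = NULL,
              dihedrals = NULL, virtual_sites = list(), exclusions = NULL,
              name = NA_character_)
  for (ln in lines) {
    if (!nzchar(ln)) next
    m <- regmatches(ln, regexec("^\\[ *([a-z_]+) *\\]$", ln))[[1]]
    if (length(m)) { section <- m[2]; next }
    f <- strsplit(ln, "[ \t]+")[[1]]
    if (is.na(section)) next
    if (section == "moleculetype") {
      out$name <- f[1]
    } else if (section == "atoms") {
      out$atoms <- rbind(out$atoms, data.frame(
        nr = as.integer(f[1]), type = f[2], bead = f[5],
        charge = as.numeric(f[7]), mass = as.numeric(f[8])))
    } else if (section == "bonds") {
      out$bonds <- rbind(out$bonds, data.frame(
        i = as.integer(f[1]), j = as.integer(f[2]),
        length_nm = as.numeric(f[4]), fc = as.numeric(f[5])))
    } else if (section == "angles") {
      out$angles <- rbind(out$angles, data.frame(
        i = as.integer(f[1]), j = as.integer(f[2]), k = as.integer(f[3]),
        angle_deg = as.numeric(f[5]), fc = as.numeric(f[6])))
    } else if (section == "constraints") {
      out$constraints <- rbind(out$constraints, data.frame(
        i = as.integer(f[1]), j = as.integer(f[2]),
        length_nm = as.numeric(f[4])))
    } else if (section == "dihedrals") {
      out$dihedrals <- rbind(out$dihedrals, data.frame(
        i = as.integer(f[1]), j = as.integer(f[2]), k = as.integer(f[3]),
        l = as.integer(f[4]), angle_deg = as.numeric(f[6]),
        fc = as.numeric(f[7])))
    } else if (section == "virtual_sitesn") {
      vals <- as.numeric(f[-(1:2)])
      ncon <- length(vals) / 2
      out$virtual_sites[[length(out$virtual_sites) + 1]] <- list(
        site = as.integer(f[1]),
        constructors = as.integer(vals[seq_len(ncon)]),
        weights = vals[ncon + seq_len(ncon)])
    } else if (section == "exclusions") {
      i <- as.integer(f[1])
      for (j in as.integer(f[-1])) {
        out$exclusions <- rbind(out$exclusions,
                                data.frame(i = min(i, j), j = max(i, j)))
      }
    }
  }
  out
}

#' Write CG coordinates as a .gro file
#'
#' @param model a `cg_model`.
#' @param path output path.
#' @param xyz optional bead coordinate matrix (nm); defaults to the
#'   conformer-averaged coordinates stored in the model.
#' @param box box vector lengths (nm).
#' @return invisibly, the path.
#' @export
write_gro <- function(model, path, xyz = NULL, box = NULL) {
  if (is.null(xyz)) xyz <- model$coords
  nb <- nrow(xyz)
  if (is.null(box)) {
    span <- apply(xyz, 2, function(v) diff(range(v)))
    box <- span + 2
  }
  lines <- c(sprintf("%s (autocg CG coordinates)", model$name),
             sprintf("%5d", nb))
  for (b in seq_len(nb)) {
    lines <- c(lines, sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                              1, substr(sanitize_name(model$name), 1, 5),
                              substr(model$bead_names[b], 1, 5), b,
                              xyz[b, 1], xyz[b, 2], xyz[b, 3]))
  }
  lines <- c(lines, sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a .gro coordinate file
#'
#' @param path file path.
#' @return list with `names`, `xyz` (nm), `box`.
#' @export
read_gro <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(lines[2]))
  rec <- lines[3:(2 + n)]
  xyz <- t(vapply(rec, function(l) {
    c(as.numeric(substr(l, 21, 28)), as.numeric(substr(l, 29, 36)),
      as.numeric(substr(l, 37, 44)))
  }, numeric(3)))
  rownames(xyz) <- NULL
  list(names = trimws(substr(rec, 11, 15)), xyz = xyz,
       box = as.numeric(strsplit(trimws(lines[3 + n]), " +")[[1]]))
}
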