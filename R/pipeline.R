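#' Run the full coarse-graining pipeline for one molecule
#'
#' Executes graph parsing, mapping, bead typing, conformer generation,
#' bonded-term derivation and ring rigidification, and optionally writes
#' the topology (.itp), coordinate (.gro) and mapping files.
#'
#' @param smiles SMILES string.
#' @param name molecule name.
#' @param config pipeline configuration.
#' @param out_dir output directory, or `NULL` to skip file output.
#' @param verbose log stage decisions with `message()`.
#' @return a `cg_model` (invisibly when files are written).
#' @examples
#' \dontrun{
#' model <- run_pipeline("CCCCCCCCCCCC", name = "dodecane",
#'                       config = autocg_config(conformers = 50))
#' }
#' @export
run_pipeline <- function(smiles, name = NULL, config = autocg_config(),
                         out_dir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  mol <- parse_smiles(smiles, name = name)
  say("parsed ", mol$name, ": ", mol$natoms, " heavy atoms")
  mapping <- run_mapping(mol, config)
  say("mapped onto ", length(mapping$beads), " beads (",
      paste(vapply(mapping$beads, `[[`, character(1), "origin"),
            collapse = ", "), ")")
  mapping <- assign_bead_types(mapping, config)
  for (b in seq_along(mapping$beads)) {
    bd <- mapping$beads[[b]]
    say(sprintf("bead %d [%s] -> %s%s", b,
                paste(bd$atoms, collapse = ","), bd$type,
                if (!is.null(bd$dgow))
                  sprintf(" (dG_OW %.1f kJ/mol)", bd$dgow) else ""))
  }
  conf <- generate_conformers(mol, n = config$conformers, seed = config$seed,
                              clash_dist_nm = config$clash_dist_nm)
  cg <- map_to_cg(mapping, conf)
  bonded <- derive_bonds_angles(mapping, cg, config)
  rigid <- rigidify_rings(mapping, cg, config)
  say(nrow(bonded$bonds), " bonds, ", nrow(bonded$angles), " angles, ",
      nrow(rigid$constraints), " constraints, ", nrow(rigid$dihedrals),
      " dihedrals, ", length(rigid$virtual_sites), " virtual sites")
  model <- assemble_model(mapping, cg, bonded, rigid)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    base <- file.path(out_dir, sanitize_name(model$name))
    write_itp(model, paste0(base, ".itp"), config = config)
    write_gro(model, paste0(base, ".gro"))
    write_mapping(mapping, paste0(base, ".map"))
    return(invisible(model))
  }
  model
}

#' Batch coarse-graining over a SMILES file
#'
#' Processes every record of a SMILES file (see [read_smiles_file()]);
#' failures are collected rather than aborting the batch.
#'
#' @param path SMILES file (`SMILES<TAB>name` per line).
#' @param config pipeline configuration.
#' @param out_dir output directory for the per-molecule file triples.
#' @param verbose forwarded to [run_pipeline()].
#' @return data frame summary with columns `name`, `smiles`, `status`,
#'   `beads`, `message`.
#' @export
run_batch <- function(path, config = autocg_config(), out_dir = NULL,
                      verbose = FALSE) {
  records <- read_smiles_file(path)
  rows <- lapply(seq_len(nrow(records)), function(r) {
    res <- tryCatch({
      model <- run_pipeline(records$smiles[r], name = records$name[r],
                            config = config, out_dir = out_dir,
                            verbose = verbose)
      data.frame(name = records$name[r], smiles = records$smiles[r],
                 status = "ok", beads = length(model$types), message = "")
    }, error = function(e) {
      data.frame(name = records$name[r], smiles = records$smiles[r],
                 status = "error", beads = NA_integer_,
                 message = conditionMessage(e))
    })
    res
  })
  do.call(rbind, rows)
}
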