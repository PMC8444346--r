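#' Pipeline configuration
#'
#' Collects every tunable of the coarse-graining pipeline with its default.
#' Defaults reproduce the reference settings of the method: bead size limit
#' of three bonds internal path length (two for ring-inner mapping), a
#' +-1.0 kJ/mol window around the Nda reference for hydrogen-bond-refined
#' typing, 200 conformers, trimer ring resolution (three beads per six-ring),
#' standard Martini force constants, a free-energy RMSD threshold of 0.1 for
#' the membrane cutoff and 100 profile layers.
#'
#' @param ... named overrides of any default.
#' @return a list of class `autocg_config`.
#' @examples
#' cfg <- autocg_config(conformers = 50, resolution = "dimer")
#' @export
autocg_config <- function(...) {
  cfg <- list(
    max_path_length = 3L,        # bonds, bead size limit
    ring_inner_max_path = 2L,    # bonds, inner-ring spectral pass
    tie_tol = 1e-8,              # relative centrality tie tolerance
    resolution = "trimer",       # ring resolution: trimer | dimer
    nda_window_kj = 1.0,         # kJ/mol, Nda hydrogen-bond window
    temperature_K = 300,         # K, logP <-> free-energy conversion
    filler_trimer = "N0",        # aromatic test-ring filler bead types
    filler_dimer = "C5",
    conformers = 200L,           # conformer ensemble size
    seed = 42L,
    bond_fc = 1250,              # kJ/mol/nm^2, standard Martini bond
    angle_fc = 25,               # kJ/mol, standard Martini angle
    dihedral_fc = 500,           # kJ/mol/rad^2, ring hinge dihedral
    clash_dist_nm = 0.16,        # conformer steric rejection threshold
    rmsd_threshold = 0.1,        # kJ/mol, adaptive membrane cutoff
    layers = 100L,               # free-energy profile resolution
    ionic_patterns = default_ionic_patterns(),
    bead_type_table = NULL,      # path override; NULL = bundled table
    fragment_table = NULL        # path override; NULL = bundled table
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration option(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  if (!cfg$resolution %in% c("trimer", "dimer")) {
    stop("resolution must be 'trimer' or 'dimer'")
  }
  class(cfg) <- "autocg_config"
  cfg
}

config_hash <- function(config) {
  flat <- config[!vapply(config, is.function, logical(1))]
  flat$ionic_patterns <- vapply(
    config$ionic_patterns, function(p) paste(p$name, p$type), character(1))
  txt <- paste(names(flat), vapply(flat, function(x)
    paste(format(x), collapse = ","), character(1)), collapse = ";")
  # small stable polynomial hash; only used for provenance headers
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 131 + b) %% 268435399
  sprintf("%07x", as.integer(h))
}
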