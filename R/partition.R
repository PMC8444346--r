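# Membrane-water partition coefficients from free-energy profiles.  The
# profile is divided into notional layers from the membrane centre (i = 0)
# to the outermost water layer (i = n); the membrane/water boundary R is
# placed adaptively where the free-energy RMSD from the bulk value first
# exceeds a threshold, scanning from the water side inwards.

#' Construct a free-energy profile object
#'
#' @param z layer centres in nm, strictly increasing from the membrane
#'   centre outwards.
#' @param G free energy per layer (kJ/mol); optional if `P` given.
#' @param P solute probability per layer; optional if `G` given.
#' @param V_layer volume of the outermost water layer (dm^3).
#' @param M leaflet mass (kg).
#' @param temperature_K temperature.
#' @return object of class `fe_profile`.
#' @export
fe_profile <- function(z, G = NULL, P = NULL, V_layer = NA_real_,
                       M = NA_real_, temperature_K = 303) {
  stopifnot(length(z) >= 2, all(diff(z) > 0))
  if (is.null(G) && is.null(P)) stop("need G or P")
  if (!is.null(P) && any(P < 0)) stop("probabilities must be >= 0")
  structure(list(z = z, G = G, P = P, V_layer = V_layer, M = M,
                 temperature_K = temperature_K), class = "fe_profile")
}

#' Fill probabilities from the free energy
#'
#' Boltzmann inversion `P(z) = exp(-G(z)/RT)`, normalized so that the
#' outermost (bulk water) layer has `P = 1`.
#'
#' @param profile an `fe_profile` with `G` present.
#' @return the profile with `P` filled in.
#' @export
probability_from_free_energy <- function(profile) {
  stopifnot(!is.null(profile$G), profile$temperature_K > 0)
  RT <- GAS_CONSTANT_KJ * profile$temperature_K
  n <- length(profile$z)
  P <- exp(-(profile$G - profile$G[n]) / RT)
  profile$P <- P
  profile
}

#' Free energy from probabilities
#'
#' Inverse of [probability_from_free_energy()] up to the additive constant
#' (bulk layer pinned at zero).
#'
#' @param profile an `fe_profile` with `P` present.
#' @return the profile with `G` filled in.
#' @export
free_energy_from_probability <- function(profile) {
  stopifnot(!is.null(profile$P))
  RT <- GAS_CONSTANT_KJ * profile$temperature_K
  n <- length(profile$z)
  G <- -RT * log(profile$P / profile$P[n])
  profile$G <- G
  profile
}

#' Adaptive membrane/water cutoff
#'
#' For each candidate layer `j` (scanned from the outermost layer `n`
#' towards the membrane centre), the RMSD of the free-energy profile over
#' layers `j..n` relative to the bulk value `G(z_n)` is computed.  The
#' cutoff `R` is the first layer at which the RMSD exceeds `threshold`.
#' A profile that never deviates gives `R = NA` (no membrane association).
#'
#' @param profile an `fe_profile` with `G` (computed from `P` if absent).
#' @param threshold RMSD threshold in kJ/mol (default 0.1).
#' @return list of class `cutoff_result` with `R` (layer index, 0-based as
#'   in the layer convention, or `NA`), `rmsd` (trace over `j = n..0`,
#'   stored in layer order), `threshold`.
#' @export
adaptive_cutoff <- function(profile, threshold = 0.1) {
  if (is.null(profile$G)) profile <- free_energy_from_probability(profile)
  G <- profile$G
  n <- length(G)
  if (n < 2) stop("profile needs at least 2 layers")
  dev2 <- (G - G[n])^2
  rmsd <- sqrt(rev(cumsum(rev(dev2))) / (n - seq_len(n) + 1))
  R <- NA_integer_
  for (j in seq(n, 1)) {
    if (rmsd[j] > threshold) { R <- j; break }
  }
  structure(list(R = R, rmsd = rmsd, threshold = threshold,
                 n_layers = n), class = "cutoff_result")
}

#' Membrane-water partition coefficient from a profile
#'
#' Evaluates
#' `K_MW = (sum_{i=0}^{R} P(z_i) / M) / (P(z_n) / V(z_n))`,
#' the amount of solute per leaflet mass divided by the water-phase
#' concentration, in dm^3/kg.  `R = NA` (no deviation from bulk anywhere)
#' gives `K_MW = 0` with `no_association = TRUE`.
#'
#' @param profile an `fe_profile` with `P` (computed from `G` if absent),
#'   `V_layer` (dm^3) and `M` (kg).
#' @param cutoff a `cutoff_result`, or `NULL` to compute one.
#' @param threshold RMSD threshold used when `cutoff` is `NULL`.
#' @return list with `kmw` (dm^3/kg), `log_kmw`, `R`, `no_association`.
#' @export
compute_kmw <- function(profile, cutoff = NULL, threshold = 0.1) {
  if (is.null(profile$P)) profile <- probability_from_free_energy(profile)
  if (is.null(cutoff)) cutoff <- adaptive_cutoff(profile, threshold)
  if (!is.na(profile$M) && profile$M <= 0) stop("leaflet mass must be > 0")
  if (!is.na(profile$V_layer) && profile$V_layer <= 0) {
    stop("layer volume must be > 0")
  }
  n <- length(profile$z)
  if (is.na(cutoff$R)) {
    return(list(kmw = 0, log_kmw = -Inf, R = NA_integer_,
                no_association = TRUE))
  }
  membrane <- sum(profile$P[seq_len(cutoff$R)]) / profile$M
  water <- profile$P[n] / profile$V_layer
  kmw <- membrane / water
  list(kmw = kmw, log_kmw = log10(kmw), R = cutoff$R, no_association = FALSE)
}

#' Octanol-water partition coefficient from solvation free energies
#'
#' `log10 K = -dG / (RT ln 10)` with
#' `dG = dG_solv(octanol) - dG_solv(water)`: a more favourable (more
#' negative) octanol solvation gives `log K > 0`.  `logk_to_dg` is the
#' inverse.
#'
#' @param delta_g free-energy difference in kJ/mol.
#' @param temperature_K temperature.
#' @return base-10 log of the partition coefficient.
#' @export
dg_to_logk <- function(delta_g, temperature_K = 300) {
  -delta_g / (GAS_CONSTANT_KJ * temperature_K * log(10))
}

#' @rdname dg_to_logk
#' @param logk base-10 log partition coefficient.
#' @export
logk_to_dg <- function(logk, temperature_K = 300) {
  -logk * GAS_CONSTANT_KJ * temperature_K * log(10)
}

#' Generate a synthetic free-energy profile
#'
#' Builds a smooth membrane-water profile: a flat bulk-water plateau at
#' zero, an optional attractive interfacial dip, and a membrane-core well
#' (negative depth) or barrier, with optional seeded Gaussian noise.  Layer
#' volume and leaflet mass metadata are attached so the profile can be run
#' straight through [compute_kmw()].  The default geometry emulates a
#' 128-lipid POPC bilayer patch (6.5 nm box, 5 nm half-box profile).
#'
#' @param depth_kj well depth (kJ/mol, positive = attractive well of that
#'   depth in the core).
#' @param well_halfwidth_nm extent of the core well.
#' @param interface_dip_kj depth of an additional interfacial minimum.
#' @param interface_z_nm position of the interfacial minimum.
#' @param noise_sd_kj Gaussian noise amplitude.
#' @param layers number of layers (default 100).
#' @param z_max_nm outermost layer position.
#' @param seed RNG seed.
#' @param box_xy_nm lateral box length (sets the layer volume).
#' @param leaflet_mass_kg leaflet mass.
#' @param temperature_K temperature.
#' @return an `fe_profile`.
#' @export
generate_synthetic_profile <- function(depth_kj = 25,
                                       well_halfwidth_nm = 1.5,
                                       interface_dip_kj = 0,
                                       interface_z_nm = 2.0,
                                       noise_sd_kj = 0,
                                       layers = 100,
                                       z_max_nm = 5,
                                       seed = 1,
                                       box_xy_nm = 6.5,
                                       leaflet_mass_kg = 8.1e-23,
                                       temperature_K = 303) {
  stopifnot(layers >= 10)
  z <- seq(0, z_max_nm, length.out = layers)
  G <- -depth_kj * 0.5 * (1 - tanh((z - well_halfwidth_nm) / 0.25))
  if (interface_dip_kj != 0) {
    G <- G - interface_dip_kj * exp(-(z - interface_z_nm)^2 / (2 * 0.09))
  }
  if (noise_sd_kj > 0) {
    set.seed(as.integer(seed) %% .Machine$integer.max)
    G <- G + rnorm(layers, sd = noise_sd_kj)
    G[layers] <- 0    # bulk reference layer stays noise-free
  }
  dz <- z[2] - z[1]
  V_layer <- box_xy_nm^2 * dz * 1e-24    # nm^3 -> dm^3
  fe_profile(z, G = G, V_layer = V_layer, M = leaflet_mass_kg,
             temperature_K = temperature_K)
}

#' Read an .xvg-style two-column profile
#'
#' Tolerates `#` and `@` comment lines.  Column 1 is z (nm), column 2 the
#' free energy (kJ/mol).
#'
#' @param path file path.
#' @param meta optional YAML metadata file with `M_kg`, `V_layer_dm3`,
#'   `temperature_K`.
#' @return an `fe_profile`.
#' @export
read_profile_xvg <- function(path, meta = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^[#@;]", trimws(lines))]
  lines <- lines[nzchar(trimws(lines))]
  vals <- do.call(rbind, lapply(strsplit(trimws(lines), "[ \t]+"),
                                function(f) as.numeric(f[1:2])))
  V <- NA_real_; M <- NA_real_; T_K <- 303
  if (!is.null(meta)) {
    y <- yaml::read_yaml(meta)
    if (!is.null(y$V_layer_dm3)) V <- y$V_layer_dm3
    if (!is.null(y$M_kg)) M <- y$M_kg
    if (!is.null(y$temperature_K)) T_K <- y$temperature_K
  }
  fe_profile(vals[, 1], G = vals[, 2], V_layer = V, M = M,
             temperature_K = T_K)
}

#' Convergence of log K_MW with the cutoff threshold
#'
#' Recomputes `log K_MW` across a grid of RMSD thresholds; used to audit
#' the sensitivity of a result to the adaptive-cutoff threshold.
#'
#' @param profile an `fe_profile`.
#' @param thresholds numeric vector of thresholds (kJ/mol).
#' @return data frame with `threshold`, `R`, `log_kmw`.
#' @export
kmw_convergence <- function(profile, thresholds = seq(0.05, 0.5, by = 0.05)) {
  do.call(rbind, lapply(thresholds, function(th) {
    res <- compute_kmw(profile, threshold = th)
    data.frame(threshold = th,
               R = if (is.na(res$R)) NA_integer_ else res$R,
               log_kmw = res$log_kmw)
  }))
}
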