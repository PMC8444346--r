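# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: shortest paths by Floyd-Warshall, symmetry by
# graph automorphisms (BLISS via igraph, with bond orders encoded as
# coloured subdivision vertices).

# All-pairs shortest path matrix by Floyd-Warshall over the heavy-atom graph.
oracle_distance_matrix <- function(mol) {
  n <- mol$natoms
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (k in seq_len(nrow(mol$bonds))) {
    d[mol$bonds$i[k], mol$bonds$j[k]] <- 1
    d[mol$bonds$j[k], mol$bonds$i[k]] <- 1
  }
  for (v in seq_len(n)) d <- pmin(d, outer(d[, v], d[v, ], `+`))
  d
}

oracle_path_length <- function(mol, atoms) {
  # brute force within the induced subgraph
  atoms <- sort(atoms)
  n <- length(atoms)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (k in seq_len(nrow(mol$bonds))) {
    i <- match(mol$bonds$i[k], atoms)
    j <- match(mol$bonds$j[k], atoms)
    if (!is.na(i) && !is.na(j)) d[i, j] <- d[j, i] <- 1
  }
  for (v in seq_len(n)) d <- pmin(d, outer(d[, v], d[v, ], `+`))
  max(d)
}

# Automorphism orbits of the heavy-atom graph.  Bond orders and aromatic
# bonds are encoded by subdividing each edge with a vertex coloured by the
# bond class, so BLISS sees an equivalent vertex-coloured simple graph.
oracle_symmetry_orbits <- function(mol) {
  n <- mol$natoms
  atom_col <- match(
    paste(mol$atoms$element, mol$atoms$charge, mol$atoms$nH,
          mol$atoms$aromatic),
    unique(paste(mol$atoms$element, mol$atoms$charge, mol$atoms$nH,
                 mol$atoms$aromatic)))
  edges <- integer(0)
  edge_col <- integer(0)
  extra <- 0L
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    arom <- mol$atoms$aromatic[i] && mol$atoms$aromatic[j] &&
      length(intersect(mol$ring_ids[[i]], mol$ring_ids[[j]])) > 0
    cls <- if (arom) 9L else mol$bonds$order[k]
    mid <- n + extra + 1L
    extra <- extra + 1L
    edges <- c(edges, i, mid, mid, j)
    edge_col <- c(edge_col, cls)
  }
  g <- igraph::make_graph(edges, n = n + extra, directed = FALSE)
  colors <- c(atom_col, max(atom_col) + edge_col)
  gens <- igraph::automorphism_group(g, colors = colors)
  # orbit closure over the generator set
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (p in gens) {
    pv <- as.integer(p)
    for (v in seq_len(n)) {
      a <- find(v); b <- find(pv[v])
      if (a != b) parent[b] <- a
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Does a bead partition respect the automorphism orbits?  Atoms in one
# orbit must sit in beads with identical orbit-composition signatures.
respects_symmetry <- function(mol, mapping) {
  orbits <- oracle_symmetry_orbits(mol)
  sig <- vapply(mapping$beads, function(b)
    paste(sort(orbits[b$atoms]), collapse = ","), character(1))
  atom_sig <- sig[mapping$atom2bead]
  all(vapply(unique(orbits), function(o) {
    length(unique(atom_sig[orbits == o])) == 1
  }, logical(1)))
}

# A reasonably diverse fixture set (>= 30 molecules) exercising chains,
# branches, heteroatoms, charges and ring systems.
fixture_smiles <- function() {
  c(
    ethane = "CC",
    propane = "CCC",
    butane = "CCCC",
    isobutane = "CC(C)C",
    neopentane = "CC(C)(C)C",
    hexane = "CCCCCC",
    decane = "CCCCCCCCCC",
    isooctane = "CC(C)CC(C)(C)C",
    ethanol = "CCO",
    glycol = "OCCO",
    glycerol = "OCC(O)CO",
    diethyl_ether = "CCOCC",
    acetone = "CC(C)=O",
    acetic_acid = "CC(=O)O",
    ethyl_acetate = "CCOC(C)=O",
    triethylamine = "CCN(CC)CC",
    trihexylamine = "CCCCCCN(CCCCCC)CCCCCC",
    acetonitrile = "CC#N",
    chloroform = "ClC(Cl)Cl",
    dichloroethane = "ClCCCl",
    dimethyl_sulfide = "CSC",
    benzene = "c1ccccc1",
    toluene = "Cc1ccccc1",
    ethylbenzene = "CCc1ccccc1",
    phenol = "Oc1ccccc1",
    aniline = "Nc1ccccc1",
    chlorobenzene = "Clc1ccccc1",
    pyridine = "c1ccncc1",
    furan = "c1ccoc1",
    naphthalene = "c1ccc2ccccc2c1",
    biphenyl = "c1ccc(-c2ccccc2)cc1",
    triphenylene = "c1ccc2c(c1)ccc3c2ccc4c3cccc4",
    warfarin = "CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O",
    dodecyl_sulfate = "CCCCCCCCCCCCOS([O-])(=O)=O",
    decane_sulfonate = "CCCCCCCCCCS([O-])(=O)=O",
    choline_like = "CC[N+](C)(C)C"
  )
}

# Nonlinear-solve oracle for the n = 4 bilinear virtual-site construction:
# numerically find (beta_h, beta_v) whose bilinear combination reproduces v.
oracle_bilinear_weights <- function(v, quad) {
  bil <- function(b) {
    bh <- b[1]; bv <- b[2]
    w <- c((1 - bh) * (1 - bv), bh * (1 - bv), bh * bv, (1 - bh) * bv)
    drop(t(quad) %*% w)
  }
  obj <- function(b) sum((bil(b) - v)^2)
  best <- NULL
  for (s1 in c(0.25, 0.5, 0.75)) for (s2 in c(0.25, 0.5, 0.75)) {
    o <- stats::optim(c(s1, s2), obj, method = "L-BFGS-B",
                      lower = c(0, 0), upper = c(1, 1),
                      control = list(factr = 1e3))
    if (is.null(best) || o$value < best$value) best <- o
  }
  bh <- best$par[1]; bv <- best$par[2]
  c((1 - bh) * (1 - bv), bh * (1 - bv), bh * bv, (1 - bh) * bv)
}

# Random convex quadrilateral in cyclic order (rejection sampled: all
# consecutive-edge cross products must share a sign).
random_convex_quad <- function() {
  repeat {
    ang <- sort(stats::runif(4, 0, 2 * pi))
    if (min(diff(c(ang, ang[1] + 2 * pi))) <= 0.3) next
    r <- stats::runif(4, 0.7, 1.3)
    q <- cbind(r * cos(ang), r * sin(ang))
    cr <- vapply(1:4, function(t) {
      a <- q[t %% 4 + 1, ] - q[t, ]
      b <- q[(t + 1) %% 4 + 1, ] - q[t %% 4 + 1, ]
      a[1] * b[2] - a[2] * b[1]
    }, numeric(1))
    if (all(cr > 0.05) || all(cr < -0.05)) return(q)
  }
}

random_interior_point <- function(poly) {
  w <- stats::runif(nrow(poly))
  w <- w / sum(w)
  drop(t(poly) %*% w)
}
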