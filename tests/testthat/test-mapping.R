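test_that("node weights are the path-length / mean-mass product", {
  mol <- parse_smiles("CCO")
  expect_equal(node_weight(mol, c(1, 2)), 12.011)
  expect_equal(node_weight(mol, c(2, 3)), (12.011 + 15.999) / 2)
  expect_equal(node_weight(mol, 1), 0)
})

test_that("weighted adjacency has crossing-bond structure and Eq-1 diagonal", {
  eth <- parse_smiles("CC")
  A <- build_weighted_adjacency(eth, list(list(atoms = 1), list(atoms = 2)))
  expect_equal(A, matrix(c(0, 1, 1, 0), 2))

  hex <- parse_smiles("CCCCCC")
  grp <- list(list(atoms = 1:2), list(atoms = 3:4), list(atoms = 5:6))
  A <- build_weighted_adjacency(hex, grp)
  expect_equal(diag(A), rep(12.011, 3))
  expect_equal(A[1, 2], 1)
  expect_equal(A[1, 3], 0)   # non-bonded groups
  expect_equal(A, t(A))

  expect_error(
    build_weighted_adjacency(hex, list(list(atoms = 1:3),
                                       list(atoms = 3:4))),
    "overlapping")
})

test_that("centrality scores match closed-form spectra", {
  # 2-node edge: equal scores, one tie group
  cs <- centrality_scores(matrix(c(0, 1, 1, 0), 2))
  expect_equal(cs$scores, rep(1 / sqrt(2), 2), tolerance = 1e-10)
  expect_equal(length(unique(cs$tie_group)), 1)

  # 3-node path: leading eigenvector proportional to (1, sqrt(2), 1)
  A3 <- matrix(0, 3, 3)
  A3[1, 2] <- A3[2, 1] <- A3[2, 3] <- A3[3, 2] <- 1
  cs <- centrality_scores(A3)
  expect_equal(cs$scores, c(1, sqrt(2), 1) / 2, tolerance = 1e-10)
  expect_equal(which.max(cs$scores), 2)

  # 4-leaf star: centre 2/sqrt(8), leaves 1/sqrt(8)
  A5 <- matrix(0, 5, 5)
  A5[1, 2:5] <- A5[2:5, 1] <- 1
  cs <- centrality_scores(A5)
  expect_equal(cs$scores, c(2, 1, 1, 1, 1) / sqrt(8), tolerance = 1e-10)

  disc <- matrix(0, 4, 4)
  disc[1, 2] <- disc[2, 1] <- disc[3, 4] <- disc[4, 3] <- 1
  expect_error(centrality_scores(disc), "disconnected")
})

test_that("spectral iteration merges by rank with the size guard", {
  neo <- parse_smiles("CC(C)(C)C")
  singles <- lapply(1:5, function(a) list(atoms = a, origin = "spectral",
                                          ring = FALSE))
  out <- spectral_iteration(neo, singles)
  expect_length(out, 1)
  expect_equal(out[[1]]$atoms, 1:5)
  expect_equal(heavy_atom_path_length(neo, out[[1]]$atoms), 2)

  eth <- parse_smiles("CC")
  out <- spectral_iteration(eth, lapply(1:2, function(a)
    list(atoms = a, origin = "spectral", ring = FALSE)))
  expect_length(out, 1)

  # a merge that would exceed l = 3 is rejected: three ethane-sized nodes
  # of hexane with tied ends stay as they are
  hex <- parse_smiles("CCCCCC")
  grp <- list(list(atoms = 1:2, origin = "spectral", ring = FALSE),
              list(atoms = 3:4, origin = "spectral", ring = FALSE),
              list(atoms = 5:6, origin = "spectral", ring = FALSE))
  out <- spectral_iteration(hex, grp)
  expect_length(out, 3)
})

test_that("ring systems map to the predefined 2-3 atom patterns", {
  ben <- map_ring_systems(parse_smiles("c1ccccc1"), "trimer")
  expect_length(ben, 3)
  expect_true(all(vapply(ben, function(b) length(b$atoms) == 2, logical(1))))
  expect_true(all(vapply(ben, function(b) b$aromatic, logical(1))))

  bend <- map_ring_systems(parse_smiles("c1ccccc1"), "dimer")
  expect_length(bend, 2)
  expect_true(all(vapply(bend, function(b) length(b$atoms) == 3,
                         logical(1))))

  nap <- map_ring_systems(parse_smiles("c1ccc2ccccc2c1"), "trimer")
  expect_length(nap, 5)
  sizes <- sort(vapply(nap, function(b) length(b$atoms), integer(1)))
  expect_equal(sizes, rep(2L, 5))
  expect_equal(sum(vapply(nap, function(b) b$origin == "ring-inner",
                          logical(1))), 1)

  tri3 <- map_ring_systems(parse_smiles("c1ccc2c(c1)ccc3c2ccc4c3cccc4"),
                          "trimer")
  expect_length(tri3, 9)
  expect_true(all(vapply(tri3, function(b) length(b$atoms) == 2,
                         logical(1))))

  expect_warning(map_ring_systems(parse_smiles("C1CCCCCCC1")),
                 "best-effort")
})

test_that("predefined ionic fragments map with fixed types", {
  sds <- parse_smiles("CCCCCCCCCCCCOS([O-])(=O)=O")
  hits <- match_ionic_fragments(sds)
  expect_length(hits, 1)
  expect_equal(hits[[1]]$type, "Qa")
  expect_equal(sort(sds$atoms$element[hits[[1]]$atoms]),
               c("O", "O", "O", "O", "S"))

  son <- parse_smiles("CCCCCCCCCCS([O-])(=O)=O")
  hits <- match_ionic_fragments(son)
  expect_length(hits, 1)
  expect_equal(hits[[1]]$type, "Q0")
  expect_equal(sum(son$atoms$element[hits[[1]]$atoms] == "C"), 1)

  expect_length(match_ionic_fragments(parse_smiles("CCCC")), 0)
})

test_that("single-atom postprocessing resolves, merges and absorbs", {
  # trihexylamine needs the postprocessing path and stays 3-fold symmetric
  tha <- parse_smiles("CCCCCCN(CCCCCC)CCCCCC")
  m <- run_mapping(tha)
  expect_true(any(vapply(m$beads, function(b) b$origin == "postprocess",
                         logical(1))))
  nbead <- m$beads[[m$atom2bead[which(tha$atoms$element == "N")]]]
  expect_equal(length(nbead$atoms), 4)   # N plus one carbon from each chain
  expect_true(respects_symmetry(tha, m))

  # a lone substituent atom next to a ring is absorbed into the ring bead
  tol <- parse_smiles("Cc1ccccc1")
  m <- run_mapping(tol)
  methyl <- which(!tol$atoms$aromatic)
  expect_true(isTRUE(m$beads[[m$atom2bead[methyl]]]$ring))

  # an already valid mapping passes through unchanged
  hex <- parse_smiles("CCCCCC")
  grp <- lapply(list(1:2, 3:4, 5:6), function(a)
    list(atoms = a, origin = "spectral", ring = FALSE))
  expect_equal(lapply(resolve_single_atom_beads(hex, grp), `[[`, "atoms"),
               list(1:2, 3:4, 5:6))

  expect_error(run_mapping(parse_smiles("C")), "single heavy atom")
  expect_error(run_mapping(parse_smiles("O")), "single heavy atom")
})

test_that("full mapping satisfies partition, size and symmetry invariants", {
  # molecules whose symmetry CAN be respected by a 2-4 atom bead partition;
  # for e.g. pyridine or toluene any ring dimerization must break a mirror,
  # and the method only promises symmetry preservation where attainable
  symmetric_fixtures <- c("benzene", "neopentane", "trihexylamine",
                          "triphenylene", "naphthalene", "hexane", "butane",
                          "glycol", "dodecyl_sulfate")
  for (nm in names(fixture_smiles())) {
    mol <- parse_smiles(fixture_smiles()[[nm]], name = nm)
    m <- run_mapping(mol)
    atoms <- sort(unlist(lapply(m$beads, `[[`, "atoms")))
    expect_equal(atoms, seq_len(mol$natoms), info = nm)   # exact partition
    for (b in m$beads) {
      l <- heavy_atom_path_length(mol, b$atoms)           # connected + size
      expect_true(l >= 1 && l <= 3, info = nm)
    }
    if (nm %in% symmetric_fixtures) {
      expect_true(respects_symmetry(mol, m), info = nm)
    }
    # determinism: byte-identical reruns
    expect_identical(m, run_mapping(mol))
  }
})

test_that("mapping is invariant under SMILES rewrites", {
  variants <- list(
    c("CCO", "OCC"),
    c("c1ccccc1", "C1=CC=CC=C1"),
    c("CC(C)(C)C", "C(C)(C)(C)C"),
    c("CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O",
      "O=c1oc2ccccc2c(O)c1C(CC(C)=O)c1ccccc1")
  )
  for (v in variants) {
    m1 <- run_mapping(parse_smiles(v[1]))
    m2 <- run_mapping(parse_smiles(v[2]))
    expect_identical(lapply(m1$beads, `[[`, "atoms"),
                     lapply(m2$beads, `[[`, "atoms"))
  }
})

test_that("mapping export formats are stable", {
  m <- run_mapping(parse_smiles("CCCCCC", name = "hexane"))
  f1 <- tempfile(fileext = ".map")
  write_mapping(m, f1)
  lines <- readLines(f1)
  expect_match(lines[2], "^1  C2_1  1 2$")
  f2 <- tempfile(fileext = ".ndx")
  write_mapping(m, f2, format = "ndx")
  expect_match(readLines(f2)[1], "^\\[ C2_1 \\]$")
})
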