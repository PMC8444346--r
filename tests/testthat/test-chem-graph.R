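test_that("SMILES parsing builds correct heavy-atom graphs", {
  eth <- parse_smiles("CC")
  expect_equal(eth$natoms, 2)
  expect_equal(nrow(eth$bonds), 1)
  expect_length(eth$rings, 0)

  ben <- parse_smiles("c1ccccc1")
  expect_equal(ben$natoms, 6)
  expect_true(all(ben$atoms$aromatic))
  expect_length(ben$rings, 1)
  # every aromatic atom is in a ring
  expect_true(all(lengths(ben$ring_ids[ben$atoms$aromatic]) >= 1))

  # canonicalization: input atom order does not matter
  a <- parse_smiles("CCO")
  b <- parse_smiles("OCC")
  expect_identical(a$smiles, b$smiles)
  expect_identical(a$atoms, b$atoms)
  expect_identical(a$bonds, b$bonds)

  kek <- parse_smiles("C1=CC=CC=C1")
  expect_identical(kek$smiles, ben$smiles)

  expect_error(parse_smiles("C((("), "invalid SMILES")
  expect_error(parse_smiles("C1CC"), "unclosed ring")
  expect_error(parse_smiles("[Na+].[Cl-]"), "disconnected")
})

test_that("charges, implicit hydrogens and H-bond roles are perceived", {
  sds <- parse_smiles("CCCCCCCCCCCCOS([O-])(=O)=O")
  expect_equal(sum(sds$atoms$charge), -1)
  tma <- parse_smiles("C[N+](C)(C)C")
  expect_equal(tma$atoms$charge[tma$atoms$element == "N"], 1)
  expect_false(any(tma$atoms$donor))

  etoh <- parse_smiles("CCO")
  o <- which(etoh$atoms$element == "O")
  expect_equal(etoh$atoms$nH[o], 1)
  expect_true(etoh$atoms$donor[o])
  expect_true(etoh$atoms$acceptor[o])
  expect_equal(etoh$atoms$nH[1], 3)

  # pyrrole NH donates but does not accept; pyridine N accepts only
  pyr <- parse_smiles("c1cc[nH]c1")
  n1 <- which(pyr$atoms$element == "N")
  expect_true(pyr$atoms$donor[n1])
  expect_false(pyr$atoms$acceptor[n1])
  pyd <- parse_smiles("c1ccncc1")
  n2 <- which(pyd$atoms$element == "N")
  expect_false(pyd$atoms$donor[n2])
  expect_true(pyd$atoms$acceptor[n2])
})

test_that("heavy-atom path length matches the brute-force oracle", {
  mol <- parse_smiles("CCCC")
  expect_equal(heavy_atom_path_length(mol, 1), 0)
  expect_equal(heavy_atom_path_length(mol, 1:4), 3)
  neo <- parse_smiles("CC(C)(C)C")
  expect_equal(heavy_atom_path_length(neo, 1:5), 2)
  expect_equal(heavy_atom_path_length(neo, 1:5), oracle_path_length(neo, 1:5))
  expect_error(heavy_atom_path_length(neo, c(1, 3)), "connected")

  # random connected subsets across fixtures vs Floyd-Warshall oracle
  set.seed(11)
  for (smi in c("CCCCCCCCCC", "CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O",
                "c1ccc2ccccc2c1")) {
    mol <- parse_smiles(smi)
    for (rep in 1:20) {
      start <- sample(mol$natoms, 1)
      atoms <- start
      while (length(atoms) < min(6, mol$natoms)) {
        nbr <- setdiff(unique(unlist(mol$adj[atoms])), atoms)
        if (!length(nbr)) break
        atoms <- c(atoms, sample(rep(nbr, 2), 1))
      }
      expect_equal(heavy_atom_path_length(mol, atoms),
                   oracle_path_length(mol, atoms))
    }
  }
})

test_that("symmetry classes refine elements and agree with automorphisms", {
  ben <- parse_smiles("c1ccccc1")
  expect_equal(length(unique(symmetry_classes(ben))), 1)

  tha <- parse_smiles("CCCCCCN(CCCCCC)CCCCCC")
  cls <- symmetry_classes(tha)
  tab <- table(cls)
  expect_equal(sum(tab == 1), 1)       # the nitrogen
  expect_equal(sum(tab == 3), 6)       # six equivalent chain positions

  for (smi in c("c1ccccc1", "CC(C)(C)C", "CCCCCCN(CCCCCC)CCCCCC",
                "Cc1ccccc1", "CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O")) {
    mol <- parse_smiles(smi)
    cls <- symmetry_classes(mol)
    orb <- oracle_symmetry_orbits(mol)
    # classes refine the element partition
    for (cl in unique(cls)) {
      expect_equal(length(unique(mol$atoms$element[cls == cl])), 1)
    }
    # refinement classes must not merge distinct automorphism orbits more
    # coarsely than the oracle: orbit-equivalent atoms share a class
    for (o in unique(orb)) {
      expect_equal(length(unique(cls[orb == o])), 1)
    }
  }
})

test_that("SMILES files are read with names and comments", {
  f <- tempfile()
  writeLines(c("# fixtures", "CCO\tethanol", "c1ccccc1\tbenzene", "CC"), f)
  rec <- read_smiles_file(f)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$name[1:2], c("ethanol", "benzene"))
  expect_equal(rec$smiles[3], "CC")
})
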