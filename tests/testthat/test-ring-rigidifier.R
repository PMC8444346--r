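test_that("ring plane projection preserves in-plane structure", {
  hexagon <- cbind(cos(2 * pi * (0:5) / 6), sin(2 * pi * (0:5) / 6), 0)
  frame <- ring_plane_basis(hexagon)
  expect_equal(crossprod(frame$basis), diag(2), tolerance = 1e-12)
  d0 <- as.matrix(dist(hexagon))
  dp <- as.matrix(dist(frame$proj))
  expect_equal(dp, d0, tolerance = 1e-10)

  # a rotated copy projects to the same shape up to a 2D rotation
  ax <- c(1, 2, 3) / sqrt(14)
  th <- 1.1
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  frame2 <- ring_plane_basis(hexagon %*% t(R))
  expect_equal(as.matrix(dist(frame2$proj)), d0, tolerance = 1e-10)

  # puckered ring: in-plane distances within the pucker amplitude
  puck <- hexagon
  puck[, 3] <- 0.05 * c(1, -1, 1, -1, 1, -1)
  framep <- ring_plane_basis(puck)
  expect_lt(max(abs(as.matrix(dist(framep$proj)) - d0)), 0.05)

  expect_error(ring_plane_basis(cbind(0:3, 0, 0)), "collinear")
})

test_that("convex hull splits real and virtual sites with promotion", {
  tri <- ring_plane_basis(cbind(c(0, 1, 0.5), c(0, 0, 1), 0))
  cls <- classify_real_virtual(tri)
  expect_equal(cls$real, 1:3)
  expect_length(cls$virtual, 0)

  # centre point of a square is interior -> virtual
  sq <- ring_plane_basis(rbind(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0),
                               c(0.5, 0.5, 0)))
  cls <- classify_real_virtual(sq)
  expect_equal(cls$virtual, 5)
  # ... unless it carries a substituent bond
  cls2 <- classify_real_virtual(sq, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_length(cls2$virtual, 0)

  # triphenylene's inner beads are virtual
  tri3 <- parse_smiles("c1ccc2c(c1)ccc3c2ccc4c3cccc4")
  m <- run_mapping(tri3)
  conf <- generate_conformers(tri3, n = 1, seed = 1)
  cg <- map_to_cg(m, conf)
  rigid <- rigidify_rings(m, cg)
  expect_length(rigid$virtual_sites, 3)
  inner <- which(vapply(m$beads, function(b) b$origin == "ring-inner",
                        logical(1)))
  expect_setequal(vapply(rigid$virtual_sites, `[[`, integer(1), "site"),
                  inner)
})

test_that("virtual-site weights solve the balanced construction exactly", {
  # unit square centre: all weights 1/4
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  w <- solve_virtual_weights(c(0.5, 0.5), sq)
  expect_equal(w, rep(0.25, 4), tolerance = 1e-12)

  # n = 3 vertex case
  tri <- cbind(c(0, 1, 0), c(0, 0, 1))
  expect_equal(solve_virtual_weights(c(0, 0), tri), c(1, 0, 0),
               tolerance = 1e-12)

  expect_error(solve_virtual_weights(c(2, 2), tri), "outside")
})

test_that("weights agree with the nonlinear-solve oracle on 1000 cases", {
  set.seed(2024)
  for (trial in seq_len(500)) {    # quadrilaterals
    q <- random_convex_quad()
    v <- random_interior_point(q)
    w <- solve_virtual_weights(v, q)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_lt(max(abs(drop(t(q) %*% w) - v)), 1e-9)
    # independent numerical solve of the same bilinear construction,
    # on the cyclically ordered quadrilateral
    ord <- order(atan2(q[, 2] - mean(q[, 2]), q[, 1] - mean(q[, 1])))
    w_orc <- numeric(4)
    w_orc[ord] <- oracle_bilinear_weights(v, q[ord, ])
    expect_equal(w, w_orc, tolerance = 1e-5)
  }
  for (trial in seq_len(500)) {    # triangles, vs exact linear solve
    tri <- random_convex_quad()[1:3, ]
    v <- random_interior_point(tri)
    w <- solve_virtual_weights(v, tri)
    expect_lt(max(abs(drop(t(tri) %*% w) - v)), 1e-9)
    w_lin <- solve(rbind(t(tri), 1), c(v, 1))
    expect_equal(w, w_lin, tolerance = 1e-9)
  }
})

test_that("constraint networks have Laman counts and full rigidity rank", {
  set.seed(77)
  for (n in 3:8) {
    ang <- sort(runif(n, 0, 2 * pi))
    coords <- cbind(cos(ang) * runif(n, 0.9, 1.1),
                    sin(ang) * runif(n, 0.9, 1.1), 0)
    fw <- build_constraints_and_dihedrals(coords)
    expect_equal(nrow(fw$constraints), 2 * n - 3)
    expect_equal(nrow(fw$dihedrals), max(0, n - 3))

    # rigidity matrix over the 2D positions has rank 2n - 3
    Rm <- matrix(0, nrow(fw$constraints), 2 * n)
    for (r in seq_len(nrow(fw$constraints))) {
      i <- fw$constraints$i[r]; j <- fw$constraints$j[r]
      d <- coords[i, 1:2] - coords[j, 1:2]
      Rm[r, c(2 * i - 1, 2 * i)] <- d
      Rm[r, c(2 * j - 1, 2 * j)] <- -d
    }
    expect_equal(qr(Rm)$rank, 2 * n - 3)

    # every chord (internal edge) appears in at most two triangles: each
    # dihedral's central edge is a distinct chord
    chords <- paste(fw$dihedrals$j, fw$dihedrals$k)
    expect_equal(anyDuplicated(chords), 0)

    # invariance of the network under rigid motion (as an edge set: the
    # in-plane basis orientation, and hence listing order, is arbitrary)
    th <- 0.4
    R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    fw2 <- build_constraints_and_dihedrals(coords %*% R + 2)
    key <- function(fw) {
      o <- order(fw$constraints$i, fw$constraints$j)
      cbind(fw$constraints$i, fw$constraints$j,
            round(fw$constraints$length_nm, 9))[o, ]
    }
    expect_equal(key(fw), key(fw2))
  }
  expect_error(build_constraints_and_dihedrals(cbind(0:1, 0, 0)),
               "at least 3")
})

test_that("warfarin's fused bicyclic gets exactly one hinge dihedral", {
  mol <- parse_smiles("CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O")
  m <- run_mapping(mol)
  systems <- unique(na.omit(vapply(m$beads, function(b)
    if (isTRUE(b$ring)) b$ring_system else NA_integer_, integer(1))))
  expect_gte(length(systems), 2)
  cg <- map_to_cg(m, generate_conformers(mol, n = 5, seed = 1))
  rigid <- rigidify_rings(m, cg)
  expect_equal(nrow(rigid$dihedrals), 1)
  expect_gte(length(rigid$virtual_sites), 1)
})
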