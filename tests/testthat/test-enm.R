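# Minimal hand-built structures: single-atom "residues" at given CA points.
point_structure <- function(coords, aa = rep("G", nrow(coords)),
                            chain = rep("A", nrow(coords))) {
  n <- nrow(coords)
  at <- data.frame(type = "ATOM", eleno = seq_len(n), elety = "CA",
                   resid = cgnma:::aa1to3(aa), chain = chain,
                   resno = seq_len(n), insert = "",
                   x = coords[, 1], y = coords[, 2], z = coords[, 3],
                   o = 1, elesy = "C", is_hetero = FALSE,
                   stringsAsFactors = FALSE)
  structure(list(atom = at, source_id = "points", preprocessed = TRUE),
            class = "cg_structure")
}

test_that("contact weight is symmetric, short-ranged, and matches the ramp", {
  s <- point_structure(rbind(c(0, 0, 0), c(50, 0, 0)))
  m <- build_coarse_model(s)
  ra <- cgnma:::split_residue_atoms(s, m)
  expect_equal(contact_weight(ra[[1]], ra[[2]]), 0)

  # two carbon atoms at vdW contact: s(d) = (1.7 + 1.7 + 1.4 - d) / 1.4
  d <- 3.9
  s2 <- point_structure(rbind(c(0, 0, 0), c(d, 0, 0)))
  ra2 <- cgnma:::split_residue_atoms(s2, build_coarse_model(s2))
  expect_equal(contact_weight(ra2[[1]], ra2[[2]]), (1.7 + 1.7 + 1.4 - d) / 1.4)
  expect_equal(contact_weight(ra2[[2]], ra2[[1]]),
               contact_weight(ra2[[1]], ra2[[2]]))

  # full overlap clamps the ramp at 1
  s3 <- point_structure(rbind(c(0, 0, 0), c(3.0, 0, 0)))
  ra3 <- cgnma:::split_residue_atoms(s3, build_coarse_model(s3))
  expect_equal(contact_weight(ra3[[1]], ra3[[2]]), 1)
})

test_that("ANM network respects the distance cutoff", {
  s <- point_structure(rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0)))
  m <- build_coarse_model(s)
  net18 <- build_network(m, s, potential_params("anm", anm_cutoff = 18))
  expect_equal(nrow(net18$springs), 3L)
  net4 <- build_network(m, s, potential_params("anm", anm_cutoff = 4))
  expect_equal(nrow(net4$springs), 2L)
  expect_true(all(net4$springs$d0 <= 4))
})

test_that("sequence-aware springs include inter-chain contacts matching the oracle", {
  dimer <- make_dimer(6, separation = 7)
  m <- build_coarse_model(dimer)
  p <- potential_params(anm_cutoff = 5, base_spring = 0.5)
  net <- build_network(m, dimer, p)
  ra <- cgnma:::split_residue_atoms(dimer, m)
  inter <- net$springs[m$chain[net$springs$i] != m$chain[net$springs$j], ]
  expect_gt(nrow(inter), 0L)
  for (r in seq_len(nrow(inter))) {
    i <- inter$i[r]; j <- inter$j[r]
    w <- contact_weight(ra[[i]], ra[[j]], p$im, p$contact_tol)
    expected <- p$base_spring * (inter$d0[r] <= p$anm_cutoff) +
      p$contact_scale * w
    expect_equal(inter$k[r], expected, tolerance = 1e-12)
  }
})

test_that("potential energy is zero at equilibrium and quadratic nearby", {
  expect_equal(potential_energy(net20, model20$coords), 0)

  # one spring, k = 2, stretched by 1 A
  s <- point_structure(rbind(c(0, 0, 0), c(3.8, 0, 0)))
  m <- build_coarse_model(s)
  net <- build_network(m, s, potential_params("anm", base_spring = 2))
  stretched <- rbind(c(0, 0, 0), c(4.8, 0, 0))
  expect_equal(potential_energy(net, stretched), 0.5 * 2 * 1^2)

  expect_error(potential_energy(net, numeric(5)), "length")

  # V(x0 + dx) agrees with the quadratic form to third order
  set.seed(11)
  H <- build_hessian(net20)
  x0 <- as.vector(t(model20$coords))
  eps <- 1e-3
  dx <- stats::rnorm(length(x0)); dx <- eps * dx / sqrt(sum(dx^2))
  V <- potential_energy(net20, x0 + dx)
  quad <- 0.5 * as.numeric(t(dx) %*% H %*% dx)
  expect_lt(abs(V - quad), 10 * eps^3)
})

test_that("analytic Hessian matches the closed form, symmetry and the numeric oracle", {
  # two nodes along x, k = 1: off-diagonal block is diag(-1, 0, 0)
  s <- point_structure(rbind(c(0, 0, 0), c(1, 0, 0)))
  m <- build_coarse_model(s)
  net <- build_network(m, s, potential_params("anm", base_spring = 1,
                                              contact_scale = 0))
  H <- build_hessian(net)
  expect_equal(H[1:3, 4:6], diag(c(-1, 0, 0)), tolerance = 1e-12)

  expect_lt(max(abs(hess20 - t(hess20))), 1e-10)
  small_net <- build_network(build_coarse_model(make_helix(8)), make_helix(8),
                             params_encom)
  Hs <- build_hessian(small_net)
  expect_lt(max(abs(Hs - build_hessian_numeric(small_net))), 1e-5)
})

test_that("Hessian annihilates rigid translations and rotations", {
  for (H_and_m in list(list(hess20, model20))) {
    H <- H_and_m[[1]]; m <- H_and_m[[2]]
    n <- m$n
    for (ax in 1:3) {
      t_vec <- as.vector(t(matrix(rep(diag(3)[ax, ], n), n, 3, byrow = TRUE)))
      expect_lt(max(abs(H %*% t_vec)), 1e-8)
    }
    ctr <- colMeans(m$coords)
    xc <- sweep(m$coords, 2, ctr)
    for (ax in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
      rot <- t(vapply(seq_len(n), function(i) {
        p <- xc[i, ]
        c(ax[2] * p[3] - ax[3] * p[2],
          ax[3] * p[1] - ax[1] * p[3],
          ax[1] * p[2] - ax[2] * p[1])
      }, numeric(3)))
      expect_lt(max(abs(H %*% as.vector(t(rot)))), 1e-8)
    }
  }
})

test_that("uniform-spring model ignores residue identities bit-exactly", {
  h1 <- make_helix(10, seed = 1)
  h2 <- make_helix(10, seed = 5)   # different sequence, same geometry
  expect_false(identical(h1$atom$resid, h2$atom$resid))
  p <- potential_params("anm")
  H1 <- build_hessian(build_network(build_coarse_model(h1), h1, p))
  H2 <- build_hessian(build_network(build_coarse_model(h2), h2, p))
  expect_identical(H1, H2)
})

test_that("interaction matrix and atom-class table validate", {
  expect_equal(dim(interaction_matrix()), c(8L, 8L))
  expect_error(interaction_matrix(matrix(c(1, 2, 3, 4), 2)))
  expect_error(interaction_matrix(matrix(-1, 2, 2)))
  cls <- atom_classes(c("PHE", "ALA", "ASP", "LYS"),
                      c("CG", "CB", "OD1", "NZ"))
  expect_equal(cls, c(2L, 1L, 7L, 5L))
})
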