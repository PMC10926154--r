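test_that("pigments load from a synthetic PDB with correct typing", {
  # one CLA residue with the five ring atoms
  p1 <- pigment("CLA401", "chl_a",
                atoms = list(MG = c(0, 0, 0), "NA" = c(0, 2, 0),
                             NB = c(-2, 0, 0), NC = c(0, -2, 0),
                             ND = c(2, 0, 0)),
                mu = c(0, 4, 0))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pigments_pdb(list(p1), f)
  got <- load_pigments(f)
  expect_length(got, 1)
  expect_equal(got[[1]]$ptype, "chl_a")
  expect_equal(got[[1]]$atoms[["MG"]], c(0, 0, 0))

  # FCP-like file: residues 401-410 slots, two CLC -> 7 a / 2 c pools
  net <- toy_fcp()
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_pigments_pdb(net$pigments, f2)
  pigs <- load_pigments(f2)
  expect_length(pigs, 9)
  ptypes <- vapply(pigs, `[[`, "", "ptype")
  expect_equal(sum(ptypes == "chl_a"), 7)
  expect_equal(sum(ptypes != "chl_a"), 2)
  # residue-number map assigns c1 vs c2
  labs <- vapply(pigs, `[[`, "", "label")
  expect_equal(unname(ptypes[labs == "CLC403"]), "chl_c2")
  expect_equal(unname(ptypes[labs == "CLC408"]), "chl_c1")

  expect_error(load_pigments(f2, resid = "XYZ"), "zero matches")
})

test_that("point-dipole coupling follows the orientation factor and R^-3", {
  mk <- function(center, mu) pigment("p", "chl_a", atoms = list(MG = center),
                                     mu = mu)
  # both dipoles perpendicular to each other and to R: kappa = 0
  expect_equal(point_dipole_coupling(mk(c(0, 0, 0), c(0, 1, 0)),
                                     mk(c(5, 0, 0), c(0, 0, 1))), 0)
  # collinear head-to-tail: kappa = -2
  v <- point_dipole_coupling(mk(c(0, 0, 0), c(1, 0, 0)),
                             mk(c(5, 0, 0), c(1, 0, 0)))
  expect_equal(v, exc_const$dipole_coupling_cm1 * (-2) / 125)
  # 1 D each, parallel, perpendicular to R, R = 10 A: V = f/1000, f from
  # CODATA constants (derived independently: 1e-19 J / hc = 5034.12 cm^-1)
  v10 <- point_dipole_coupling(mk(c(0, 0, 0), c(0, 1, 0)),
                               mk(c(10, 0, 0), c(0, 1, 0)))
  expect_equal(v10, 5034.12 / 1000, tolerance = 1e-5)

  # properties over random geometries: symmetry and R^-3 decay
  withr::with_seed(7, {
    for (rep in 1:25) {
      c1 <- rnorm(3); m1 <- rnorm(3); m2 <- rnorm(3)
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      p1 <- mk(c1, m1)
      pa <- mk(c1 + 6 * u, m2); pb <- mk(c1 + 12 * u, m2)
      expect_equal(point_dipole_coupling(p1, pa),
                   point_dipole_coupling(pa, p1))
      expect_equal(point_dipole_coupling(p1, pa),
                   8 * point_dipole_coupling(p1, pb), tolerance = 1e-10)
    }
  })
  expect_error(point_dipole_coupling(mk(c(0, 0, 0), c(1, 0, 0)),
                                     mk(c(0, 0, 0), c(1, 0, 0))),
               "coincident")
})

test_that("energy ladder ranks ascending with label tie-breaks", {
  lad <- energy_ladder(c(`Chl-a` = 1.910, `Chl-c1` = 2.023,
                         `Chl-c2` = 1.987))
  expect_equal(lad$label, c("Chl-a", "Chl-c2", "Chl-c1"))
  expect_equal(lad$rank, 1:3)

  tie <- energy_ladder(c(b = 1, a = 1, c = 1))
  expect_equal(tie$label, c("a", "b", "c"))

  withr::with_seed(1, {
    e <- rnorm(20)
    lad2 <- energy_ladder(e, labels = sprintf("s%02d", 1:20))
    expect_equal(lad2$energy, sort(e))                  # sort oracle
    expect_setequal(lad2$energy, e)                     # permutation
  })
})

test_that("diagonalization gives orthonormal states that rebuild H", {
  # diagonal H: energies sorted, coefficients a permutation of identity
  H0 <- exciton_hamiltonian(E = c(5, 3, 9))
  st0 <- diagonalize(H0)
  expect_equal(st0$energies, c(3, 5, 9))
  expect_equal(abs(st0$coeffs), diag(3)[, c(2, 1, 3)], tolerance = 1e-12)

  # resonant dimer closed form
  Hd <- exciton_hamiltonian(E = c(0, 0), J = matrix(c(0, 100, 100, 0), 2))
  expect_equal(diagonalize(Hd)$energies, c(-100, 100))

  # random 9x9 vs brute-force Jacobi oracle
  withr::with_seed(42, {
    M <- matrix(rnorm(81, sd = 50), 9); M <- (M + t(M)) / 2
    H <- exciton_hamiltonian(E = diag(M) + 15000, J = M - diag(diag(M)),
                             mu = matrix(rnorm(27), 9))
    st <- diagonalize(H)
    expect_equal(st$energies, jacobi_eigenvalues(as_matrix_H(H)),
                 tolerance = 1e-8)
    expect_equal(crossprod(st$coeffs), diag(9), tolerance = 1e-8)
    rebuilt <- st$coeffs %*% diag(st$energies) %*% t(st$coeffs)
    expect_lt(max(abs(rebuilt - as_matrix_H(H))), 1e-6)
    # exciton dipoles mu_k = sum_n c_nk mu_n
    expect_equal(st$dipoles[3, ], as.numeric(crossprod(st$coeffs[, 3], H$mu)))
  })
  expect_error(exciton_hamiltonian(E = c(0, 0),
                                   J = matrix(c(0, 1, 2, 0), 2)),
               "not symmetric")
})

test_that("max inter-pool coupling matches exhaustive search", {
  H0 <- exciton_hamiltonian(E = rep(0, 4), pools = c("a_pool", "a_pool",
                                                     "c_pool", "c_pool"))
  expect_equal(max_interpool_coupling(H0)$value, 0)

  J <- matrix(0, 3, 3); J[1, 3] <- J[3, 1] <- -25
  H1 <- exciton_hamiltonian(E = rep(0, 3), J = J,
                            pools = c("a_pool", "a_pool", "c_pool"))
  got <- max_interpool_coupling(H1)
  expect_equal(got$value, 25)
  expect_setequal(got$pair, c(1, 3))

  withr::with_seed(5, {
    J <- matrix(rnorm(81), 9); J <- (J + t(J)) / 2; diag(J) <- 0
    pools <- c(rep("a_pool", 6), rep("c_pool", 3))
    H <- exciton_hamiltonian(rep(0, 9), J, pools = pools)
    best <- 0
    for (i in 1:6) for (j in 7:9) best <- max(best, abs(J[i, j]))
    expect_equal(max_interpool_coupling(H)$value, best)
  })
  expect_error(max_interpool_coupling(H0, 1:3, 3:4), "overlap")
})

test_that("two-exciton manifold obeys hard-core pair structure", {
  H2 <- exciton_hamiltonian(E = c(10, 20), J = matrix(c(0, 5, 5, 0), 2))
  man2 <- two_exciton_expand(H2)
  expect_equal(dim(man2$H2), c(1, 1))
  expect_equal(man2$H2[1, 1], 30)

  H3 <- exciton_hamiltonian(E = c(1, 2, 4))
  man3 <- two_exciton_expand(H3)
  expect_equal(diag(man3$H2), c(3, 5, 6))
  expect_true(all(man3$H2[upper.tri(man3$H2)] == 0))
  # J = 0: eigenvalues exactly the pairwise sums
  expect_equal(sort(eigen(man3$H2)$values), c(3, 5, 6))

  withr::with_seed(9, {
    M <- matrix(rnorm(16), 4); M <- (M + t(M)) / 2
    H4 <- exciton_hamiltonian(diag(M), M - diag(diag(M)),
                              mu = matrix(rnorm(12), 4))
    man <- two_exciton_expand(H4)
    # index-looping oracle
    pairs <- man$pairs
    for (p in seq_len(nrow(pairs))) for (q in seq_len(nrow(pairs))) {
      i <- pairs[p, 1]; j <- pairs[p, 2]
      k <- pairs[q, 1]; l <- pairs[q, 2]
      expected <- if (p == q) H4$E[i] + H4$E[j]
      else {
        shared <- intersect(c(i, j), c(k, l))
        if (length(shared) == 1)
          H4$J[setdiff(c(i, j), shared), setdiff(c(k, l), shared)]
        else 0
      }
      expect_equal(man$H2[p, q], expected)
    }
    # lifting dipoles: nonzero only from member sites, equal to added site
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1]; j <- pairs[p, 2]
      expect_equal(man$dip[p, i, ], H4$mu[j, ])
      expect_equal(man$dip[p, j, ], H4$mu[i, ])
      off <- setdiff(1:4, c(i, j))
      expect_true(all(man$dip[p, off, ] == 0))
    }
  })
  expect_error(two_exciton_expand(exciton_hamiltonian(E = 1)), "n >= 2")
})
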