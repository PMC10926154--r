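test_that("g(t) matches an adaptive quadrature oracle and its invariants", {
  T0 <- 300
  # dense grid so the trapezoid integration is converged to the oracle level
  sdd <- model_sd("drude", 40, 40, grid = sd_grid(1e-4, 12800, 32768))
  tg <- c(0.5, 1, 2, 5, 10, 20, 50, 100, 200, 500)
  g <- lineshape_g(sdd, T0, tgrid = c(0, tg))
  expect_equal(g$g[1], 0 + 0i)
  for (i in seq_along(tg)) {
    want <- oracle_g(sdd, T0, tg[i])
    expect_equal(Re(g$g[i + 1]), Re(want), tolerance = 1e-6)
    expect_equal(Im(g$g[i + 1]), Im(want), tolerance = 1e-6)
  }
  # short-time limit: Re g quadratic in t
  expect_equal(Re(g$g[g$t == 1]) / Re(g$g[g$t == 0.5]), 4,
               tolerance = 0.01)
  # Re g nondecreasing at early times
  expect_true(all(diff(Re(g$g)) > 0))

  # Im g(t)/t -> -2 pi c lambda within 2% at t = 10/(2 pi c gamma)
  tinf <- 10 / (exc_const$twopic * 40)
  gl <- lineshape_g(sdd, T0, tgrid = c(0, tinf))
  lam <- attr(gl, "lambda_eff")
  expect_equal(Im(gl$g[2]) / tinf, -exc_const$twopic * lam,
               tolerance = 0.02)
  expect_equal(lam, 40, tolerance = 0.01)

  # zero spectral density: g identically zero
  zero <- spectral_density(1:100, rep(0, 100))
  expect_true(all(lineshape_g(zero, T0, 0:10)$g == 0))
  expect_error(lineshape_g(sdd, -5), "positive")
})

test_that("single-site cumulant spectrum obeys the first-moment sum rule", {
  T0 <- 300
  sdd <- model_sd("drude", 40, 40)
  H1 <- exciton_hamiltonian(E = 15000, mu = matrix(c(4, 0, 0), 1))
  spec <- absorption_cumulant(H1, sdd, T0)
  expect_true(all(spec$intensity >= 0))
  Aw <- attr(spec, "lineshape_per_omega")
  m1 <- sum(spec$omega * Aw) / sum(Aw)
  expect_equal(m1, 15000, tolerance = 1e-3)     # within 1 cm^-1 of E1

  # zero bath + apodization: single sharp peak at E1
  zero <- spectral_density(1:100, rep(0, 100))
  s0 <- absorption_cumulant(H1, zero, T0, apodization = 200)
  expect_equal(s0$omega[which.max(s0$intensity)], 15000, tolerance = 2)
  expect_error(absorption_cumulant(H1, list(c_pool = sdd), T0), "missing")
})

test_that("secular cumulant is exact for uncoupled aggregates", {
  T0 <- 300
  sda <- model_sd("drude", 40, 40)
  sdb <- model_sd("drude", 60, 80)
  H <- exciton_hamiltonian(E = c(14700, 15300),
                           mu = rbind(c(4, 0, 0), c(0, 2, 0)))
  both <- absorption_cumulant(H, list(sda, sdb), T0)
  s1 <- absorption_cumulant(exciton_hamiltonian(14700, mu = matrix(c(4, 0, 0), 1)),
                            sda, T0)
  s2 <- absorption_cumulant(exciton_hamiltonian(15300, mu = matrix(c(0, 2, 0), 1)),
                            sdb, T0)
  expect_equal(both$intensity, s1$intensity + s2$intensity, tolerance = 1e-8)
})

test_that("removing high-frequency bath modes deletes the vibronic sideband", {
  T0 <- 300
  net <- toy_fcp()
  sds <- fcp_default_sds()
  full <- absorption_cumulant(net$H, sds, T0)
  tr <- absorption_cumulant(net$H, lapply(sds, truncate_sd, cutoff = 800), T0)

  main <- full$omega[which.max(full$intensity)]
  win <- full$omega >= main + 900 & full$omega <= main + 1700
  w_full <- sum(full$intensity[win])
  w_tr <- sum(tr$intensity[win])
  expect_gt(w_full, 0)
  expect_lt(w_tr, 0.10 * w_full)   # >= 90% of the sideband weight removed

  # oscillator strength is conserved under truncation to within 2%
  expect_equal(sum(tr$intensity) / sum(full$intensity), 1, tolerance = 0.02)

  # smaller total reorganization moves the truncated line up in energy (the
  # same effect that makes the truncated spectrum need a larger alignment
  # shift against experiment)
  expect_gte(tr$omega[which.max(tr$intensity)], main)
})

test_that("pool decomposition attributes the spectrum to the a-pool", {
  T0 <- 300
  net <- toy_fcp()
  sds <- fcp_default_sds()
  dec <- pool_decomposition(net$H, sds, T0)
  expect_true(all(c("a_pool", "c_pool") %in% names(dec)))
  frac_a <- sum(dec$a_pool) / (sum(dec$a_pool) + sum(dec$c_pool))
  expect_gt(frac_a, 0.80)

  # single-pool partition reproduces the full spectrum
  one <- pool_decomposition(net$H, sds, T0,
                            pools = list(all = seq_len(net$H$n)))
  expect_equal(one$all, one$intensity, tolerance = 1e-10)

  # zero c-pool dipoles: c component identically zero
  H0 <- net$H
  H0$mu[unname(H0$pools) == "c_pool", ] <- 0
  dec0 <- pool_decomposition(H0, sds, T0)
  expect_true(all(dec0$c_pool == 0))
  expect_error(pool_decomposition(net$H, sds, T0, pools = list(a = 1:3)),
               "partition")
})

test_that("alignment shift moves the computed maximum onto the reference", {
  w <- seq(12000, 16000, 2)
  sp <- tibble::tibble(omega = w,
                       intensity = exp(-(w - 14000)^2 / (2 * 150^2)))
  expect_equal(align_shift(sp, sp), 0)
  ref <- tibble::tibble(omega = w,
                        intensity = exp(-(w - 14250)^2 / (2 * 150^2)))
  expect_equal(align_shift(sp, ref), 250)
  # quantized to the grid step
  expect_equal(align_shift(sp, ref) %% 2, 0)
  flat <- tibble::tibble(omega = w, intensity = rep(0, length(w)))
  expect_error(align_shift(flat, ref), "flat")
})

test_that("cumulant and NISE absorption agree for a fast-bath dimer", {
  T0 <- 300
  g <- sd_grid(1e-3, 6000, 2048)
  sdd <- model_sd("drude", lambda = 6, gamma = 160, grid = g)
  H <- exciton_hamiltonian(E = c(14900, 15100),
                           J = matrix(c(0, 50, 50, 0), 2),
                           mu = rbind(c(4, 0, 0), c(3, 1, 0)))
  wgrid <- seq(14200, 15800, by = 2)
  cum <- absorption_cumulant(H, sdd, T0, omega = wgrid)
  ens <- lapply(1:24, function(s)
    stochastic_hamiltonian(H, sample_trajectory(sdd, T0, 2, 2048, 2,
                                                seed = 100 + s)))
  nise <- linear_response(ens, tmax = 2048, omega = wgrid,
                          apodization = 700)
  pk_c <- wgrid[which.max(cum$intensity)]
  pk_n <- wgrid[which.max(nise$intensity)]
  expect_lt(abs(pk_c - pk_n), 20)
})
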