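test_that("Kabsch alignment recovers rigid transforms and is optimal", {
  withr::with_seed(21, {
    P <- matrix(rnorm(15), 5)
    # identical sets
    id <- kabsch_align(P, P)
    expect_equal(id$rotation, diag(3), tolerance = 1e-10)
    expect_equal(id$translation, rep(0, 3), tolerance = 1e-10)
    expect_equal(id$rmsd, 0, tolerance = 1e-10)

    # apply a known rotation + translation, then recover it
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    R0 <- excitonic:::quat_rotation(q)
    t0 <- c(3, -2, 7)
    Q <- sweep(P %*% t(R0), 2, t0, `+`)
    fit <- kabsch_align(P, Q)
    expect_equal(fit$rotation, R0, tolerance = 1e-8)
    expect_equal(fit$translation, t0, tolerance = 1e-8)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
    expect_lt(fit$rmsd, 1e-10)

    # global optimality: no random rotation beats the Kabsch RMSD
    Qn <- Q + matrix(rnorm(15, sd = 0.3), 5)
    fitn <- kabsch_align(P, Qn)
    cq <- colMeans(P); cqn <- colMeans(Qn)
    for (k in 1:1000) {
      qq <- rnorm(4); qq <- qq / sqrt(sum(qq^2))
      Rr <- excitonic:::quat_rotation(qq)
      moved <- sweep(sweep(P, 2, cq) %*% t(Rr), 2, cqn, `+`)
      expect_gte(sqrt(mean(rowSums((moved - Qn)^2))), fitn$rmsd - 1e-12)
    }
  })
  expect_error(kabsch_align(matrix(0, 2, 3), matrix(0, 2, 3)), "3 paired")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(kabsch_align(line, line + 1), "collinear")
})

test_that("ring frame puts nitrogens at z=0 with NA on +y", {
  sq <- list(MG = c(0, 0, 0), "NA" = c(0, 2, 0), NB = c(-2, 0, 0),
             NC = c(0, -2, 0), ND = c(2, 0, 0))
  p <- pigment("CLC403", "chl_c2", atoms = sq, mu = c(0, 2.4, 0))
  rf <- ring_frame(p)
  aligned <- do.call(rbind, rf$pigment$atoms[c("NA", "NB", "NC", "ND")])
  expect_lt(max(abs(aligned[, 3])), 1e-10)
  expect_equal(rf$pigment$atoms[["NA"]], c(0, 2, 0), tolerance = 1e-10)

  withr::with_seed(31, {
    for (rep in 1:100) {
      q <- rnorm(4); q <- q / sqrt(sum(q^2))
      R0 <- excitonic:::quat_rotation(q)
      shift <- rnorm(3, sd = 20)
      atoms <- lapply(sq, function(a) as.numeric(R0 %*% a) + shift)
      pr <- pigment("X", "chl_a", atoms = atoms, mu = as.numeric(R0 %*% c(0, 4, 0)))
      rfr <- ring_frame(pr)
      Nmat <- do.call(rbind, rfr$pigment$atoms[c("NA", "NB", "NC", "ND")])
      expect_lt(max(abs(Nmat[, 3])), 1e-8)
      expect_gt(rfr$pigment$atoms[["NA"]][2], 0)      # NA lands on +y
      # circulation NA->NB->NC->ND counterclockwise from +z
      ang <- atan2(Nmat[, 2], Nmat[, 1])
      expect_true(all(diff(unwrap_steps(ang)) > 0))
      # vectors rotate with the frame: dipole stays along NA-NC axis
      expect_equal(abs(sum(rfr$pigment$mu * c(0, 1, 0))),
                   sqrt(sum(pr$mu^2)), tolerance = 1e-8)
    }
  })
  expect_error(ring_frame(pigment("X", "chl_a",
                                  atoms = list(MG = c(0, 0, 0)))),
               "lacks ring atoms")
})

test_that("Coulomb fields superpose exactly and match a direct oracle", {
  b <- exc_const$bohr_A
  # +1 e at origin, point at 2 bohr on x: F = 1/4 au along +x
  env1 <- charge_environment(1, matrix(c(0, 0, 0), 1))
  expect_equal(as.numeric(coulomb_field(env1, matrix(c(2 * b, 0, 0), 1))),
               c(0.25, 0, 0))
  # two equal charges symmetric about the midpoint: zero field there
  env2 <- charge_environment(c(0.7, 0.7),
                             rbind(c(-3, 1, 2), c(5, 1, 2)))
  expect_equal(max(abs(coulomb_field(env2, matrix(c(1, 1, 2), 1)))), 0)

  withr::with_seed(13, {
    q <- runif(50, -1, 1)
    pos <- matrix(rnorm(150, sd = 8), 50)
    pts <- matrix(rnorm(15, sd = 2), 5)
    env <- charge_environment(q, pos)
    got <- coulomb_field(env, pts)
    # direct pairwise-sum oracle, independent loop arithmetic
    want <- matrix(0, 5, 3)
    for (k in 1:5) for (i in 1:50) {
      d <- (pts[k, ] - pos[i, ]) / b
      want[k, ] <- want[k, ] + q[i] * d / sum(d^2)^1.5
    }
    expect_lt(max(abs(got - want)), 1e-12)
    # linearity in charges
    env_h <- charge_environment(q / 2, pos)
    expect_equal(coulomb_field(env_h, pts) * 2, got, tolerance = 1e-12)
    # superposition over split environments
    e1 <- charge_environment(q[1:20], pos[1:20, ])
    e2 <- charge_environment(q[21:50], pos[21:50, ])
    expect_equal(coulomb_field(e1, pts) + coulomb_field(e2, pts), got,
                 tolerance = 1e-12)
  })
  expect_error(coulomb_field(env1, matrix(c(0, 0, 0), 1)), "coincides")
})

test_that("field reports flag positive-y components", {
  sq <- list(MG = c(0, 0, 0), "NA" = c(0, 2, 0), NB = c(-2, 0, 0),
             NC = c(0, -2, 0), ND = c(2, 0, 0))
  p <- pigment("CLC403", "chl_c2", atoms = sq, mu = c(0, 2.4, 0))

  rep0 <- field_report(charge_environment(numeric(), matrix(0, 0, 3)), p)
  expect_equal(nrow(rep0), 5)
  expect_true(all(rep0$Fx == 0 & rep0$Fy == 0 & rep0$Fz == 0))
  expect_false(any(rep0$y_positive))

  # positive charge far below the ring on -y pushes +y at all five atoms
  envy <- charge_environment(1, matrix(c(0, -30, 0), 1))
  repy <- field_report(envy, p)
  expect_true(all(repy$Fy > 0))
  expect_true(all(repy$y_positive))

  # generator-targeted field at NA flags the NA row
  env <- make_environment(c(0, 0.022, 0), probe = c(0, 2, 0), seed = 4)
  repNA <- field_report(env, p)
  expect_true(repNA$y_positive[repNA$atom == "NA"])
  expect_equal(repNA$Fy[repNA$atom == "NA"], 0.022, tolerance = 1e-4)

  # literature protein fields: boldface (positive y) pattern is MG, NA, ND
  tab <- chl_protein_fields()
  for (pg in unique(tab$pigment))
    expect_setequal(tab$atom[tab$pigment == pg & tab$y_positive],
                    c("MG", "NA", "ND"))
})

test_that("Stark scan shifts reproduce the printed parentheticals", {
  scan <- chl_field_scan()
  sh <- scan_shifts(scan)
  g <- function(pig, d) sh$shift_ev[sh$pigment == pig & sh$direction == d]
  expect_equal(g("Chl-a", "+x"), -0.051, tolerance = 1e-12)
  expect_equal(g("Chl-c1", "+y"), -0.252, tolerance = 1e-12)
  # max-|shift| direction for Chl-c1 is +y
  expect_equal(sh$direction[sh$pigment == "Chl-c1" & sh$max_abs], "+y")

  flat <- field_scan(tibble::tibble(
    pigment = "p", direction = c("none", "+x", "-x", "+y", "-y", "+z", "-z"),
    energy_ev = 2))
  expect_true(all(scan_shifts(flat)$shift_ev == 0))
  expect_error(field_scan(tibble::tibble(pigment = "p", direction = "+x",
                                         energy_ev = 1)),
               "'none'")
})

test_that("susceptibility ratio compares pool maxima", {
  sh <- scan_shifts(chl_field_scan())
  r <- susceptibility_ratio(sh, "Chl-a", c("Chl-c1", "Chl-c2"))
  expect_equal(r$ratio, 0.252 / 0.051, tolerance = 1e-12)
  expect_equal(r$fold, 5)

  same <- susceptibility_ratio(sh, "Chl-c1", "Chl-c1")
  expect_equal(same$ratio, 1)

  # scaled construction: group B shifts are exactly 3x group A
  base <- sh[sh$pigment == "Chl-a", ]
  b3 <- base; b3$pigment <- "B"; b3$shift_ev <- 3 * base$shift_ev
  expect_equal(susceptibility_ratio(rbind(base, b3), "Chl-a", "B")$ratio, 3)
})

test_that("difference-dipole fit captures the linear Stark response", {
  F0 <- 0.01
  dmu_true <- c(2, -11, 0.5)
  dirs <- list("+x" = c(1, 0, 0), "-x" = c(-1, 0, 0), "+y" = c(0, 1, 0),
               "-y" = c(0, -1, 0), "+z" = c(0, 0, 1), "-z" = c(0, 0, -1))
  e0 <- 2.25
  lin <- tibble::tibble(
    pigment = "syn",
    direction = c("none", names(dirs)),
    energy_ev = c(e0, vapply(dirs, function(d)
      e0 - sum(dmu_true * d) * F0, 1)))
  fit <- difference_dipole_fit(field_scan(lin, F0))
  expect_equal(unname(fit$dmu), dmu_true, tolerance = 1e-10)
  expect_lt(max(abs(fit$residuals$residual_ev)), 1e-12)

  # printed scan, Chl-c1: dmu_y = -(2.037 - 2.285)/0.02 = +12.4 eV/au and
  # large residuals (strongly asymmetric response)
  fitc1 <- difference_dipole_fit(chl_field_scan(), pigment = "Chl-c1")
  expect_equal(unname(fitc1$dmu[["y"]]), 12.4, tolerance = 1e-9)
  expect_gt(fitc1$rms_residual_ev, 0.05)

  # quadratic (even) response: odd differences vanish, residuals remain
  quad <- tibble::tibble(
    pigment = "q", direction = c("none", names(dirs)),
    energy_ev = c(e0, vapply(dirs, function(d) e0 + 0.05 * sum(d * d), 1)))
  fitq <- difference_dipole_fit(field_scan(quad, F0))
  expect_equal(max(abs(fitq$dmu)), 0)
  expect_gt(max(abs(fitq$residuals$residual_ev)), 0.01)
  expect_error(difference_dipole_fit(
    field_scan(lin[lin$direction != "-y", ], F0)), "missing")
})
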