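#' Specification of a synthetic FCP-like pigment network
#'
#' Defaults describe the chlorophyll network of one FCP monomer: seven Chl-a
#' and two Chl-c sites with labels CLA401..CLA410 minus the two CLC slots
#' (CLC403 as Chl-c2 and CLC408 as Chl-c1), the c-pool red-shifted below the
#' a-pool as in the protein-embedded energy ladder, c-pool dipoles 0.6x the
#' a-pool, and the largest coupling between the pools clamped to 25 cm^-1.
#'
#' @param n_a,n_c pool sizes.
#' @param e_mean_a,e_mean_c pool mean site energies (cm^-1).
#' @param e_sd_a,e_sd_c pool site-energy spreads (cm^-1).
#' @param coupling_scale_cm1 the |J| the largest a-c coupling is clamped to.
#' @param mu_a_D,mu_c_D dipole magnitudes (Debye).
#' @param min_dist_A minimal center-center distance (Angstrom).
#' @param box_A cubic placement box edge (Angstrom).
#' @return a `network_spec` list.
#' @export
network_spec <- function(n_a = 7, n_c = 2,
                         e_mean_a = 14950, e_sd_a = 60,
                         e_mean_c = 14800, e_sd_c = 60,
                         coupling_scale_cm1 = 25,
                         mu_a_D = 4.0, mu_c_D = 2.4,
                         min_dist_A = 8, box_A = 40) {
  stopifnot(n_a >= 0, n_c >= 0, n_a + n_c >= 1, coupling_scale_cm1 >= 0,
            min_dist_A > 0)
  structure(list(n_a = n_a, n_c = n_c, e_mean_a = e_mean_a, e_sd_a = e_sd_a,
                 e_mean_c = e_mean_c, e_sd_c = e_sd_c,
                 coupling_scale_cm1 = coupling_scale_cm1,
                 mu_a_D = mu_a_D, mu_c_D = mu_c_D,
                 min_dist_A = min_dist_A, box_A = box_A),
            class = "network_spec")
}

#' Generate a synthetic FCP-like pigment network
#'
#' Places pigments without overlap (rejection sampling, minimum distance
#' `min_dist_A`), gives each a random ring orientation (MG plus a square of
#' ring nitrogens), draws pool-wise Gaussian site energies, builds couplings
#' with [point_dipole_coupling()] and, when both pools are present, rescales
#' J so the largest |a-c coupling| equals `coupling_scale_cm1` exactly.
#' Deterministic for a given (spec, seed).
#'
#' @param spec a [network_spec()].
#' @param seed integer seed.
#' @return list with `pigments` and `H` (an [exciton_hamiltonian()]).
#' @export
make_network <- function(spec = network_spec(), seed = 1) {
  n <- spec$n_a + spec$n_c
  with_local_seed(seed, {
    centers <- matrix(NA_real_, n, 3)
    placed <- 0
    for (tries in seq_len(20000)) {
      cand <- stats::runif(3, 0, spec$box_A)
      if (placed == 0 ||
          min(sqrt(rowSums(sweep(centers[seq_len(placed), , drop = FALSE],
                                 2, cand)^2))) >= spec$min_dist_A) {
        placed <- placed + 1
        centers[placed, ] <- cand
        if (placed == n) break
      }
    }
    if (placed < n) stop("impossible packing: could not place ", n,
                         " pigments at min distance ", spec$min_dist_A,
                         " A in a ", spec$box_A, " A box")
    # c sites at FCP-like slots 403 (c2) and 408 (c1)
    c_slots <- if (spec$n_c >= 1) c(3L, 8L)[seq_len(min(spec$n_c, 2))] else integer()
    if (spec$n_c > 2) c_slots <- c(c_slots, sample(setdiff(1:n, c(3L, 8L)),
                                                   spec$n_c - 2))
    pigs <- vector("list", n)
    E <- numeric(n)
    for (i in seq_len(n)) {
      is_c <- i %in% c_slots
      ptype <- if (!is_c) "chl_a" else if (i == 8L) "chl_c1" else "chl_c2"
      label <- sprintf("%s%d", if (is_c) "CLC" else "CLA", 400 + i)
      # random ring orientation: orthonormal frame from a random rotation
      q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
      R <- quat_rotation(q)
      ringr <- 2.05    # Mg-N distance, Angstrom
      Nloc <- rbind(c(0, ringr, 0), c(-ringr, 0, 0),
                    c(0, -ringr, 0), c(ringr, 0, 0))  # NA, NB, NC, ND ccw
      atoms <- c(list(MG = centers[i, ]),
                 stats::setNames(lapply(1:4, function(k)
                   centers[i, ] + as.numeric(R %*% Nloc[k, ])),
                   c("NA", "NB", "NC", "ND")))
      mu_mag <- if (is_c) spec$mu_c_D else spec$mu_a_D
      qy <- atoms[["NA"]] - atoms[["NC"]]
      mu <- qy / sqrt(sum(qy^2)) * mu_mag
      E[i] <- if (is_c) stats::rnorm(1, spec$e_mean_c, spec$e_sd_c)
              else stats::rnorm(1, spec$e_mean_a, spec$e_sd_a)
      pigs[[i]] <- pigment(label, ptype, atoms = atoms, mu = mu)
    }
    H <- hamiltonian_from_pigments(pigs, E)
    if (spec$n_a >= 1 && spec$n_c >= 1 && spec$coupling_scale_cm1 > 0 && n > 1) {
      mx <- max_interpool_coupling(H)$value
      if (mx > 0) H$J <- H$J * (spec$coupling_scale_cm1 / mx)
    }
    list(pigments = pigs, H = H)
  })
}

quat_rotation <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

#' Default synthetic spectral densities for an FCP-like network
#'
#' Stand-ins for protein-extracted spectral densities: both pools share a
#' Drude term (lambda = 40 cm^-1, gamma = 40 cm^-1); Chl-a adds underdamped
#' intramolecular modes at 750, 1150 and 1520 cm^-1 (lambda 25/35/35 cm^-1,
#' gamma 100 cm^-1) while Chl-c carries the same modes at 0.3x intensity, so
#' the vibronic sideband of the absorption spectrum is Chl-a dominated.
#' All parameters are arguments, not constants.
#'
#' @param lambda_drude,gamma_drude Drude parameters (cm^-1).
#' @param mode_omega,mode_lambda,mode_gamma underdamped mode parameters
#'   (cm^-1), vectorized over modes.
#' @param c_scale intensity factor for the c-pool modes.
#' @param grid common frequency grid.
#' @return named list `list(a_pool = , c_pool = )` of [spectral_density()].
#' @export
fcp_default_sds <- function(lambda_drude = 40, gamma_drude = 40,
                            mode_omega = c(750, 1150, 1520),
                            mode_lambda = c(25, 35, 35),
                            mode_gamma = rep(100, 3),
                            c_scale = 0.3,
                            grid = sd_grid(1e-3, 12000, 4096)) {
  dr <- model_sd("drude", lambda_drude, gamma_drude, grid = grid)
  modes <- function(scale) {
    parts <- lapply(seq_along(mode_omega), function(j)
      model_sd("underdamped", mode_lambda[j] * scale, mode_gamma[j],
               mode_omega[j], grid = grid))
    Reduce(sd_sum, parts)
  }
  list(a_pool = sd_sum(dr, modes(1)), c_pool = sd_sum(dr, modes(c_scale)))
}

#' Synthetic charge environment producing a prescribed field
#'
#' Builds a point-charge shell whose Coulomb field at `probe` equals `target`
#' (atomic units) to better than 1e-6 au: a primary charge along the target
#' direction, a few decoy charges elsewhere, and one corrector charge that
#' cancels the decoys' residual at the probe.  Self-verifies with
#' [coulomb_field()].
#'
#' @param target field 3-vector at the probe (au); must be nonzero.
#' @param probe probe point (Angstrom).
#' @param n_decoys number of decoy charges.
#' @param seed integer seed.
#' @return a [charge_environment()].
#' @export
make_environment <- function(target, probe = c(0, 0, 0), n_decoys = 6,
                             seed = 1) {
  target <- as.numeric(target)
  if (sqrt(sum(target^2)) <= 0) stop("target field must be nonzero")
  probe <- as.numeric(probe)
  with_local_seed(seed, {
    b <- exc_const$bohr_A
    dirs <- target / sqrt(sum(target^2))
    d1 <- 5                                   # A
    q1 <- sqrt(sum(target^2)) * (d1 / b)^2    # F = q/r^2 along +dirs
    pos <- matrix(probe - dirs * d1, 1)
    qs <- q1
    for (k in seq_len(n_decoys)) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      pos <- rbind(pos, probe + u * stats::runif(1, 8, 15))
      qs <- c(qs, stats::runif(1, -0.5, 0.5))
    }
    env <- charge_environment(qs, pos)
    resid <- target - as.numeric(coulomb_field(env, matrix(probe, 1)))
    rn <- sqrt(sum(resid^2))
    if (rn > 0) {
      u <- resid / rn
      d2 <- 6
      qc <- rn * (d2 / b)^2
      env <- charge_environment(c(qs, qc), rbind(pos, probe - u * d2))
    }
    err <- sqrt(sum((as.numeric(coulomb_field(env, matrix(probe, 1))) -
                       target)^2))
    if (err > 1e-6) stop("environment construction failed to converge")
    env
  })
}

#' Ensemble of fluctuating Hamiltonians
#'
#' Draws `n_real` independent site-energy trajectories from the per-pool
#' spectral densities and wraps each with the base Hamiltonian.
#'
#' @param H an [exciton_hamiltonian()].
#' @param sds `list(a_pool=, c_pool=)` (or a single [spectral_density()]).
#' @param temperature K.
#' @param n_real ensemble size.
#' @param dt time step (fs).
#' @param n_steps samples per trajectory.
#' @param seed master seed; realization k uses `seed * 1000 + k`.
#' @return list of [stochastic_hamiltonian()].
#' @export
make_ensemble <- function(H, sds, temperature = 300, n_real = 10, dt = 2,
                          n_steps = 2048, seed = 1) {
  if (n_real == 0) return(list())
  persite <- broadcast_sds(sds, H)
  lapply(seq_len(n_real), function(k) {
    s <- seed * 1000 + k
    cols <- lapply(seq_len(H$n), function(j)
      sample_trajectory(persite[[j]], temperature, dt, n_steps, 1,
                        seed = s * 10 + j)$series[, 1])
    stochastic_hamiltonian(H, gap_trajectory(do.call(cbind, cols), dt))
  })
}

#' Analytic dimer fixture
#'
#' Closed forms for a two-site system with detuning `delta` and coupling `J`
#' about a mean energy of zero: eigenvalues +/- sqrt(delta^2/4 + J^2), Rabi
#' period, and the transfer probability
#' \deqn{P_2(t)=\frac{J^2}{J^2+\delta^2/4}\sin^2(2\pi c\sqrt{J^2+\delta^2/4}\,t)}
#' sampled on request.  The bundle self-verifies its eigenvalues against
#' [diagonalize()] at construction.
#'
#' @param delta site-energy difference (cm^-1).
#' @param J coupling (cm^-1).
#' @return list with `eigenvalues`, `rabi_period_fs`, `transfer_amplitude`,
#'   `population2(t_fs)` and the `hamiltonian`.
#' @export
dimer_fixture <- function(delta, J) {
  Om <- sqrt(delta^2 / 4 + J^2)
  H <- exciton_hamiltonian(E = c(delta / 2, -delta / 2),
                           J = matrix(c(0, J, J, 0), 2),
                           pools = c("a_pool", "c_pool"))
  ev <- c(-Om, Om)
  chk <- diagonalize(H)$energies
  if (max(abs(chk - ev)) > 1e-8 * max(1, Om))
    stop("dimer fixture failed self-verification")
  amp <- if (Om > 0) J^2 / Om^2 else 0
  list(eigenvalues = ev,
       rabi_period_fs = if (Om > 0) 1 / (2 * exc_const$c_cmfs * Om) else Inf,
       transfer_amplitude = amp,
       population2 = function(t_fs)
         amp * sin(pi * exc_const$c_cmfs * 2 * Om * t_fs)^2,
       hamiltonian = H)
}

#' Write a synthetic PDB file for a pigment list
#'
#' Standard fixed-column PDB HETATM records (one residue per pigment), so
#' [load_pigments()] can be exercised end to end without external downloads.
#'
#' @param pigments list of [pigment()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pigments_pdb <- function(pigments, path) {
  lines <- character()
  serial <- 0
  for (i in seq_along(pigments)) {
    p <- pigments[[i]]
    resname <- substr(p$label, 1, 3)
    resno <- suppressWarnings(as.integer(gsub("\\D", "", p$label)))
    if (is.na(resno)) resno <- i
    for (an in names(p$atoms)) {
      serial <- serial + 1
      a <- p$atoms[[an]]
      el <- if (an == "MG") "MG" else substr(an, 1, 1)
      lines <- c(lines, sprintf(
        "HETATM%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, an, "", resname, "A", resno, "", a[1], a[2], a[3], 1, 0, el))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
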