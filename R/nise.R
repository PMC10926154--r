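#' Stochastic (fluctuating) exciton Hamiltonian
#'
#' Pairs a base [exciton_hamiltonian()] with a site-diagonal fluctuation
#' trajectory: \eqn{H(t_i)} has diagonal \eqn{E_n+\delta E_n(t_i)} and
#' time-independent couplings.  This is the input to NISE propagation, where
#' the classical bath enters through the trajectory only.
#'
#' @param base an [exciton_hamiltonian()].
#' @param fluctuations a [gap_trajectory()] with one column per site (or NULL
#'   for a static Hamiltonian).
#' @param dt time step (fs) when `fluctuations` is NULL.
#' @return object of class `stochastic_hamiltonian`.
#' @export
stochastic_hamiltonian <- function(base, fluctuations = NULL, dt = 2) {
  stopifnot(inherits(base, "exciton_hamiltonian"))
  if (!is.null(fluctuations)) {
    stopifnot(inherits(fluctuations, "gap_trajectory"),
              ncol(fluctuations$series) == base$n)
    dt <- fluctuations$dt
  }
  structure(list(base = base, fluctuations = fluctuations, dt = dt),
            class = "stochastic_hamiltonian")
}

#' @export
print.stochastic_hamiltonian <- function(x, ...) {
  cat(sprintf("<stochastic_hamiltonian: %d sites, dt = %g fs, %s>\n",
              x$base$n, x$dt,
              if (is.null(x$fluctuations)) "static"
              else paste0(nrow(x$fluctuations$series), " steps")))
  invisible(x)
}

# diagonal fluctuation at step i (1-based); recycles periodically if the
# trajectory is exhausted (tests keep horizons within the trajectory).
fluct_at <- function(sh, i) {
  if (is.null(sh$fluctuations)) return(rep(0, sh$base$n))
  X <- sh$fluctuations$series
  sh$fluctuations$series[(i - 1L) %% nrow(X) + 1L, ]
}

# one-step propagator exp(-i 2 pi c H dt) via symmetric eigendecomposition
step_propagator <- function(M, dt) {
  e <- eigen(M, symmetric = TRUE)
  ph <- exp(-1i * exc_const$twopic * e$values * dt)
  e$vectors %*% (ph * Conj(t(e$vectors)))
}

#' Propagate wavefunctions over a fluctuating Hamiltonian (NISE)
#'
#' Numerical integration of the Schroedinger equation: per trajectory step the
#' instantaneous Hamiltonian is held fixed and applied through its exact
#' eigendecomposition propagator \eqn{\exp(-i 2\pi c H(t_i)\,dt)}, which is
#' unitary to machine precision, so the norm is conserved to ~1e-10 per ns;
#' drift beyond 1e-6 is a hard error.
#'
#' @param sh a [stochastic_hamiltonian()].
#' @param psi0 initial amplitude vector (length n) or matrix (n x k, k states
#'   propagated simultaneously); a site index is also accepted.
#' @param n_steps number of dt steps.
#' @param keep `"all"` returns every step (array n x k x (n_steps+1));
#'   `"last"` only the final amplitudes.
#' @return complex array of amplitudes (with `keep = "all"`, time along the
#'   third dimension, starting at t = 0).
#' @export
propagate <- function(sh, psi0, n_steps, keep = c("all", "last")) {
  keep <- match.arg(keep)
  n <- sh$base$n
  if (length(psi0) == 1 && is.numeric(psi0) && psi0 == round(psi0) && psi0 >= 1) {
    v <- rep(0, n); v[psi0] <- 1; psi0 <- v
  }
  psi <- as.matrix(psi0)
  stopifnot(nrow(psi) == n)
  psi <- psi * (1 + 0i)
  norm0 <- sqrt(colSums(Mod(psi)^2))
  J <- sh$base$J
  out <- if (keep == "all")
    array(0i, dim = c(n, ncol(psi), n_steps + 1)) else NULL
  if (keep == "all") out[, , 1] <- psi
  for (i in seq_len(n_steps)) {
    M <- J
    diag(M) <- sh$base$E + fluct_at(sh, i)
    psi <- step_propagator(M, sh$dt) %*% psi
    if (keep == "all") out[, , i + 1] <- psi
  }
  drift <- max(abs(sqrt(colSums(Mod(psi)^2)) - norm0))
  if (drift > 1e-6)
    stop("propagation norm drift ", format(drift), " exceeds 1e-6")
  if (keep == "all") out else psi
}

#' Pool-to-pool population transfer
#'
#' Averages NISE site populations over an ensemble of fluctuating
#' Hamiltonians and over all initial excitations placed on the donor pool
#' (one run per donor site, uniformly weighted).  Reports the probability of
#' staying on the donor pool and of arriving on the acceptor pool, plus the
#' per-site breakdown; populations sum to 1 at every step.
#'
#' @param ensemble list of [stochastic_hamiltonian()] objects (>= 1).
#' @param horizon_fs time horizon (fs).
#' @param donor,acceptor pool names.
#' @return tibble of class `pool_populations`: `t`, `P_stay_donor`,
#'   `P_acceptor` and one `P_<label>` column per site.
#' @export
pool_transfer <- function(ensemble, horizon_fs, donor = "a_pool",
                          acceptor = "c_pool") {
  if (!length(ensemble)) stop("ensemble must contain at least one trajectory")
  base <- ensemble[[1]]$base
  idx_d <- which(base$pools == donor)
  idx_a <- which(base$pools == acceptor)
  if (!length(idx_d) || !length(idx_a)) stop("empty donor or acceptor pool")
  dt <- ensemble[[1]]$dt
  n_steps <- ceiling(horizon_fs / dt)
  psi0 <- matrix(0, base$n, length(idx_d))
  for (j in seq_along(idx_d)) psi0[idx_d[j], j] <- 1
  P <- matrix(0, n_steps + 1, base$n)
  for (sh in ensemble) {
    amp <- propagate(sh, psi0, n_steps, keep = "all")
    # average over initial donor sites: mean over k of |psi_n|^2
    for (ti in seq_len(n_steps + 1)) {
      m <- matrix(amp[, , ti], nrow = base$n)
      P[ti, ] <- P[ti, ] + rowMeans(Mod(m)^2)
    }
  }
  P <- P / length(ensemble)
  out <- tibble::tibble(t = seq(0, by = dt, length.out = n_steps + 1),
                        P_stay_donor = rowSums(P[, idx_d, drop = FALSE]),
                        P_acceptor = rowSums(P[, idx_a, drop = FALSE]))
  for (j in seq_len(base$n)) out[[paste0("P_", base$labels[j])]] <- P[, j]
  class(out) <- c("pool_populations", class(out))
  out
}

#' NISE linear absorption
#'
#' Ensemble-averaged dipole autocorrelation
#' \eqn{I(t)=\langle\mu(t)\cdot\mu(0)\rangle/3} computed with NISE
#' propagators in a rotating frame at the mean site energy, apodized and
#' half-Fourier transformed.  This is an independent absorption engine used
#' to cross-check the cumulant route.
#'
#' @param ensemble list of [stochastic_hamiltonian()].
#' @param tmax correlation time window (fs).
#' @param omega output grid (cm^-1).
#' @param apodization exponential damping time (fs).
#' @return an `exciton_spectrum` tibble (`omega`, `intensity`).
#' @export
linear_response <- function(ensemble, tmax = 1024,
                            omega = seq(12000, 20000, by = 1),
                            apodization = tmax / 4) {
  base <- ensemble[[1]]$base
  dt <- ensemble[[1]]$dt
  n_steps <- ceiling(tmax / dt)
  w0 <- mean(base$E)
  mu <- base$mu
  acc <- complex(length.out = n_steps + 1)
  for (sh in ensemble) {
    shr <- sh
    shr$base$E <- sh$base$E - w0
    amp <- propagate(shr, mu, n_steps, keep = "all")   # n x 3 x t
    for (ti in seq_len(n_steps + 1))
      acc[ti] <- acc[ti] + sum(matrix(amp[, , ti], nrow = base$n) * mu) / 3
  }
  acc <- acc / length(ensemble)
  tg <- seq(0, by = dt, length.out = n_steps + 1)
  acc <- acc * exp(-tg / apodization)
  intensity <- halfft_line_cplx(acc, dt, center = w0, omega = omega)
  out <- tibble::tibble(omega = omega, intensity = pmax(intensity, 0))
  class(out) <- c("exciton_spectrum", class(out))
  out
}

# like halfft_line but for complex input signals
halfft_line_cplx <- function(f, dt, center, omega) {
  n <- length(f)
  M <- 2^ceiling(log2(max(4 * n, 64)))
  f[1] <- f[1] / 2
  Fv <- stats::fft(c(f, rep(0i, M - n)), inverse = TRUE) * dt
  k <- seq_len(M) - 1
  wrel <- ifelse(k <= M / 2, k, k - M) / (M * dt) / exc_const$c_cmfs
  ord <- order(wrel)
  stats::approx(wrel[ord] + center, Re(Fv)[ord], xout = omega,
                yleft = 0, yright = 0)$y
}

#' Foerster transfer time from a coupling and lineshape overlap
#'
#' \deqn{k = 2\pi\,(2\pi c)\,J^2\int L_D(\omega)L_A(\omega)\,d\omega}
#' in fs^-1, with J in cm^-1 and donor emission / acceptor absorption
#' lineshapes normalized to unit area on their common cm^-1 grid (so the
#' overlap integral has units of cm).  The transfer time is 1/k, reported in
#' ps; zero overlap gives `Inf` with a warning.
#'
#' @param J electronic coupling (cm^-1).
#' @param donor,acceptor tibbles with `omega`, `intensity`; normalized
#'   internally is an error - they must integrate to 1 within 1e-6.
#' @return time in ps.
#' @export
forster_transfer_time <- function(J, donor, acceptor) {
  grid <- donor$omega
  if (!isTRUE(all.equal(grid, acceptor$omega)))
    stop("donor and acceptor lineshapes must share a frequency grid")
  for (s in list(donor, acceptor)) {
    a <- trapz(s$omega, s$intensity)
    if (abs(a - 1) > 1e-6)
      stop("lineshapes must be normalized to unit area (got ", format(a), ")")
  }
  ov <- trapz(grid, donor$intensity * acceptor$intensity)
  k <- 2 * pi * exc_const$twopic * J^2 * ov   # fs^-1
  if (k <= 0) {
    warning("zero spectral overlap: transfer time is infinite")
    return(Inf)
  }
  (1 / k) / 1000
}

#' Normalize a spectrum to unit area
#' @param spec tibble with `omega`, `intensity`.
#' @return same tibble with intensity scaled so the trapezoid integral is 1.
#' @export
normalize_area <- function(spec) {
  a <- trapz(spec$omega, spec$intensity)
  if (a <= 0) stop("cannot normalize a non-positive spectrum")
  spec$intensity <- spec$intensity / a
  spec
}
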