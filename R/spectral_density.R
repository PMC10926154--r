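#' Spectral densities on a frequency grid
#'
#' A `spectral_density` holds J(omega) >= 0 (cm^-1) on an ascending positive
#' frequency grid (cm^-1).  It drives both cumulant lineshapes and the
#' synthesis of Gaussian site-energy trajectories.
#'
#' @param omega ascending positive frequency grid (cm^-1).
#' @param J values (cm^-1), non-negative.
#' @return object of class `spectral_density` (also a tibble with columns
#'   `omega`, `J`).
#' @export
spectral_density <- function(omega, J) {
  omega <- as.numeric(omega); J <- as.numeric(J)
  stopifnot(length(omega) == length(J), all(is.finite(omega)),
            all(is.finite(J)))
  if (any(diff(omega) <= 0)) stop("omega grid must be strictly ascending")
  if (any(omega <= 0)) stop("omega grid must be positive")
  if (any(J < -1e-12 * max(abs(J), 1))) stop("J(omega) must be non-negative")
  J[J < 0] <- 0
  out <- tibble::tibble(omega = omega, J = J)
  class(out) <- c("spectral_density", class(out))
  out
}

#' Logarithmic frequency grid for spectral densities
#'
#' Drude spectral densities have a 1/omega tail whose reorganization-energy
#' integral converges slowly, and J(omega) -> 0 linearly at small omega; a
#' log-spaced grid resolves both ends cheaply.  All model components meant to
#' be summed should share one grid.
#'
#' @param wmin,wmax grid limits (cm^-1).
#' @param n number of points.
#' @return numeric vector, ascending.
#' @export
sd_grid <- function(wmin = 1e-3, wmax = 12000, n = 4096) {
  exp(seq(log(wmin), log(wmax), length.out = n))
}

#' Model spectral densities (Drude + underdamped modes)
#'
#' Drude (overdamped Brownian oscillator):
#' \deqn{J(\omega)=2\lambda\gamma\omega/(\omega^2+\gamma^2)}
#' Underdamped intramolecular mode (antisymmetrized Lorentzian pair):
#' \deqn{J(\omega)=2\lambda_j\omega_j^2\gamma_j\omega/((\omega^2-\omega_j^2)^2+\gamma_j^2\omega^2)}
#' Both integrate to their lambda under [reorganization_energy()].  Sums of
#' components are pointwise sums (`sd_sum()` or `+`).
#'
#' @param kind `"drude"` or `"underdamped"`.
#' @param lambda reorganization energy of the component (cm^-1, > 0).
#' @param gamma damping (cm^-1, > 0).
#' @param omega0 mode frequency (cm^-1, underdamped only).
#' @param grid frequency grid (cm^-1); defaults to a [sd_grid()] wide enough
#'   for the component's reorganization integral to converge to ~0.2%.
#' @return a [spectral_density()].
#' @examples
#' sd <- model_sd("drude", lambda = 100, gamma = 50)
#' reorganization_energy(sd)  # ~100
#' @export
model_sd <- function(kind = c("drude", "underdamped"), lambda, gamma,
                     omega0 = NULL, grid = NULL) {
  kind <- match.arg(kind)
  if (lambda <= 0 || gamma <= 0) stop("lambda and gamma must be positive")
  if (is.null(grid)) {
    top <- if (kind == "drude") 320 * gamma else max(6 * omega0, 2200)
    grid <- sd_grid(wmax = top)
  }
  w <- grid
  J <- switch(kind,
    drude = 2 * lambda * gamma * w / (w^2 + gamma^2),
    underdamped = {
      if (is.null(omega0) || omega0 <= 0)
        stop("underdamped mode needs a positive omega0")
      2 * lambda * omega0^2 * gamma * w / ((w^2 - omega0^2)^2 + gamma^2 * w^2)
    })
  spectral_density(w, J)
}

#' Sum spectral densities pointwise
#' @param ... [spectral_density()] objects on identical grids.
#' @return a [spectral_density()].
#' @export
sd_sum <- function(...) {
  parts <- list(...)
  w <- parts[[1]]$omega
  for (p in parts[-1]) if (!isTRUE(all.equal(p$omega, w)))
    stop("spectral densities must share a grid to be summed")
  spectral_density(w, Reduce(`+`, lapply(parts, `[[`, "J")))
}

#' @export
`+.spectral_density` <- function(e1, e2) sd_sum(e1, e2)

#' Reorganization energy of a spectral density
#'
#' \deqn{\lambda=(1/\pi)\int_0^\infty J(\omega)/\omega\,d\omega} by
#' trapezoidal rule on the stored grid.  Warns when fewer than 10 grid points
#' lie under the main peak (half maximum).
#'
#' @param sd a [spectral_density()].
#' @return lambda in cm^-1.
#' @export
reorganization_energy <- function(sd) {
  w <- sd$omega; J <- sd$J
  if (max(J) > 0 && sum(J >= max(J) / 2) < 10)
    warning("grid is coarse: fewer than 10 points under the main peak")
  trapz(w, J / w) / pi
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Truncate a spectral density above a cutoff
#'
#' Sets J(omega) = 0 for omega > cutoff (used to remove intramolecular modes,
#' e.g. everything above 800 cm^-1, and watch the vibronic sideband vanish).
#'
#' @param sd a [spectral_density()].
#' @param cutoff cm^-1.
#' @return a [spectral_density()].
#' @export
truncate_sd <- function(sd, cutoff) {
  spectral_density(sd$omega, ifelse(sd$omega > cutoff, 0, sd$J))
}

#' Site-energy gap trajectories
#'
#' Zero-mean fluctuation time series delta E_n(t) per site (cm^-1) on a
#' uniform grid of step `dt` fs, plus the mean site energies they fluctuate
#' about.
#'
#' @param series n_steps x n_sites numeric matrix of fluctuations (cm^-1).
#' @param dt time step (fs).
#' @param mean_energy per-site mean energies (cm^-1).
#' @return object of class `gap_trajectory`.
#' @export
gap_trajectory <- function(series, dt, mean_energy = NULL) {
  series <- as.matrix(series)
  stopifnot(is.finite(dt), dt > 0, all(is.finite(series)))
  if (is.null(mean_energy)) mean_energy <- rep(0, ncol(series))
  stopifnot(length(mean_energy) == ncol(series))
  structure(list(series = series, dt = dt,
                 mean_energy = as.numeric(mean_energy)),
            class = "gap_trajectory")
}

#' @export
print.gap_trajectory <- function(x, ...) {
  cat(sprintf("<gap_trajectory: %d sites x %d steps, dt = %g fs, sd = %.1f cm^-1>\n",
              ncol(x$series), nrow(x$series), x$dt, stats::sd(as.numeric(x$series))))
  invisible(x)
}

#' Synthesize Gaussian trajectories from a spectral density
#'
#' Draws stationary, zero-mean Gaussian fluctuations whose correlation
#' function matches the classical fluctuation-dissipation form of the target
#' spectral density,
#' \deqn{C(t)=\frac{2k_BT}{\pi}\int_0^\infty \frac{J(\omega)}{\omega}
#'       \cos(2\pi c\,\omega t)\,d\omega,}
#' so the sample variance is \eqn{2k_BT\lambda}.  Synthesis is the
#' random-phase Fourier method: independent complex-Gaussian amplitudes with
#' the target power spectrum, one independent realization per site, fully
#' reproducible from `seed`.
#'
#' The step must resolve the fastest bath motion: `dt < 1/(4 c omega_max)`
#' (about 4.2 fs for a spectral density reaching 2000 cm^-1), where
#' `omega_max` is the frequency below which 99% of the reorganization
#' integral lies; larger steps are a hard error naming the bound.
#'
#' @param sd a [spectral_density()].
#' @param temperature K.
#' @param dt time step (fs).
#' @param n_steps samples per site.
#' @param n_sites number of independent site trajectories.
#' @param seed integer seed.
#' @return a [gap_trajectory()].
#' @export
sample_trajectory <- function(sd, temperature, dt, n_steps, n_sites = 1,
                              seed = 1) {
  # effective bandwidth: 99% quantile of the reorganization integral J/w dw
  wmax <- if (max(sd$J) > 0) {
    cum <- cumsum(c(0, diff(sd$omega) *
                      (utils::head(sd$J / sd$omega, -1) +
                       utils::tail(sd$J / sd$omega, -1)) / 2))
    sd$omega[which(cum >= 0.99 * cum[length(cum)])[1]]
  } else 0
  if (wmax > 0) {
    dt_max <- 1 / (4 * exc_const$c_cmfs * wmax)
    if (dt >= dt_max)
      stop(sprintf(
        "dt = %g fs does not resolve the spectral density: need dt < %.3f fs (Nyquist bound for omega_max = %g cm^-1)",
        dt, dt_max, wmax))
  }
  if (max(sd$J) == 0)
    return(gap_trajectory(matrix(0, n_steps, n_sites), dt))
  N <- 2^ceiling(log2(max(2 * n_steps, 64)))
  dnu <- 1 / (N * dt)                       # fs^-1
  k <- seq_len(N / 2 - 1)
  # one-sided PSD over nu (cm^-2 fs) is P(nu) = 2 kB T J(w)/(pi w c), w = nu/c.
  # Integrate it over each frequency bin (first bin absorbs the sub-grid band)
  # so the total variance equals 2 kB T lambda exactly on the stored grid.
  wfine <- c(1e-9, sd$omega)
  cumP <- c(0, cumsum(diff(wfine) *
                        (utils::head(c(0, sd$J / sd$omega), -1) +
                         utils::tail(c(0, sd$J / sd$omega), -1)) / 2)) *
    2 * exc_const$kB_cm1 * temperature / pi
  bandint <- function(wlo, whi) {
    lo <- stats::approx(wfine, cumP, xout = pmin(pmax(wlo, wfine[1]), max(wfine)),
                        rule = 2)$y
    hi <- stats::approx(wfine, cumP, xout = pmin(pmax(whi, wfine[1]), max(wfine)),
                        rule = 2)$y
    hi - lo
  }
  w_edges_lo <- (k - 0.5) * dnu / exc_const$c_cmfs
  w_edges_lo[1] <- 0
  w_edges_hi <- (k + 0.5) * dnu / exc_const$c_cmfs
  sig <- sqrt(bandint(w_edges_lo, w_edges_hi) / 2)
  series <- with_local_seed(seed, {
    vapply(seq_len(n_sites), function(s) {
      a <- stats::rnorm(length(k), sd = sqrt(0.5))
      b <- stats::rnorm(length(k), sd = sqrt(0.5))
      Z <- complex(real = 0, imaginary = 0)
      Z <- rep(Z, N)
      Z[k + 1] <- sig * complex(real = a, imaginary = b)
      Z[N + 1 - k] <- Conj(Z[k + 1])
      Re(stats::fft(Z, inverse = TRUE))[seq_len(n_steps)]
    }, numeric(n_steps))
  })
  gap_trajectory(matrix(series, ncol = n_sites), dt)
}

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Extract spectral densities from gap trajectories
#'
#' Computes the unbiased autocorrelation C(t) of each site's fluctuations,
#' applies a Hann window, zero-pads fourfold and cosine-transforms:
#' \deqn{J(\omega)=2\pi c\,\beta\,\omega\int_0^\infty C(t)\cos(2\pi c\,\omega t)\,dt,}
#' the inverse of the synthesis convention in [sample_trajectory()], so
#' extraction then synthesis is an identity in expectation.  Negative values
#' (estimator noise) are clipped to zero and the clipped fraction reported as
#' attribute `clip_fraction`.
#'
#' @param traj a [gap_trajectory()].
#' @param temperature K.
#' @param sites which site columns to use (default all); their estimates are
#'   averaged (`average = TRUE`) or returned as a list.
#' @param average average over sites?
#' @param max_lag_frac use lags up to this fraction of the series (default
#'   1/4; shorter windows trade resolution for variance).
#' @param grid optional output frequency grid (cm^-1); defaults to the
#'   transform's own grid up to 2200 cm^-1.
#' @return a [spectral_density()] (or list of them when `average = FALSE`).
#' @export
sd_from_trajectory <- function(traj, temperature, sites = NULL,
                               average = TRUE, max_lag_frac = 0.25,
                               grid = NULL) {
  X <- traj$series
  if (is.null(sites)) sites <- seq_len(ncol(X))
  dt <- traj$dt
  if (all(X[, sites] == 0)) {
    w <- if (is.null(grid)) seq(1, 2200, by = 1) else grid
    out <- spectral_density(w, rep(0, length(w)))
    attr(out, "clip_fraction") <- 0
    return(if (average) out else rep(list(out), length(sites)))
  }
  n <- nrow(X)
  L <- floor(n * max_lag_frac)
  beta <- 1 / (exc_const$kB_cm1 * temperature)
  hann <- 0.5 * (1 + cos(pi * (0:L) / L))
  M <- 2^ceiling(log2(4 * (L + 1)))
  one <- function(x) {
    x <- x - mean(x)
    # unbiased autocovariance via FFT
    xp <- c(x, rep(0, n))
    s <- stats::fft(Mod(stats::fft(xp))^2, inverse = TRUE) / (2 * n)
    C <- Re(s[1:(L + 1)]) / (n - 0:L)
    Cw <- C * hann
    padded <- c(Cw, rep(0, M - L - 1))
    I <- Re(stats::fft(padded)) - Cw[1] / 2      # trapezoid at t = 0
    I <- I * dt                                  # integral_0^inf C cos dt
    w <- (seq_len(M) - 1) / (M * dt) / exc_const$c_cmfs
    J <- 2 * pi * exc_const$c_cmfs * beta * w * I
    list(w = w, J = J)
  }
  res <- lapply(sites, function(s) one(X[, s]))
  w <- res[[1]]$w
  keepmax <- if (is.null(grid)) 2200 else max(grid) * 1.05
  keep <- w > 0 & w <= keepmax
  build <- function(J) {
    J <- pmax(J, 0)
    out <- spectral_density(w[keep], J[keep])
    if (!is.null(grid)) {
      out <- spectral_density(grid, pmax(stats::approx(w[keep], J[keep],
        xout = grid, yleft = 0, yright = 0, rule = 2)$y, 0))
    }
    out
  }
  if (average) {
    Jm <- Reduce(`+`, lapply(res, `[[`, "J")) / length(res)
    clip <- mean(Jm[keep] < 0)
    out <- build(Jm)
    attr(out, "clip_fraction") <- clip
    out
  } else {
    lapply(res, function(r) build(r$J))
  }
}
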