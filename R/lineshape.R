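#' Second-order cumulant lineshape function g(t)
#'
#' \deqn{g(t)=\frac{1}{\pi}\int_0^\infty d\omega\,\frac{J(\omega)}{\omega^2}
#'   \left[\coth(\beta\omega/2)(1-\cos 2\pi c\omega t)
#'   + i(\sin 2\pi c\omega t - 2\pi c\omega t)\right]}
#' evaluated by trapezoid on the spectral-density grid; time in fs, all
#' frequencies cm^-1.  `g(0) = 0`, `Re g` is non-decreasing at early times and
#' `Im g(t)/t` tends to \eqn{-2\pi c\lambda}.
#'
#' @param sd a [spectral_density()].
#' @param temperature K (> 0).
#' @param tgrid time grid (fs), starting at 0.
#' @return object of class `lineshape_function`: tibble with columns `t`,
#'   `g` (complex), attributes `lambda_eff` (cm^-1) and `temperature`.
#' @export
lineshape_g <- function(sd, temperature, tgrid = seq(0, 2047, by = 1)) {
  if (temperature <= 0) stop("temperature must be positive")
  w <- sd$omega; J <- sd$J
  beta <- 1 / (exc_const$kB_cm1 * temperature)
  coth <- 1 / tanh(beta * w / 2)
  wt <- exc_const$twopic * w                 # rad/fs per grid point
  dw <- diff(w)
  trap <- function(y) sum(dw * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  base_re <- J / w^2 * coth
  base_im <- J / w^2
  g <- vapply(tgrid, function(t) {
    re <- trap(base_re * (1 - cos(wt * t)))
    im <- trap(base_im * (sin(wt * t) - wt * t))
    complex(real = re, imaginary = im) / pi
  }, complex(1))
  out <- tibble::tibble(t = tgrid, g = g)
  attr(out, "lambda_eff") <- trapz(w, J / w) / pi
  attr(out, "temperature") <- temperature
  class(out) <- c("lineshape_function", class(out))
  out
}

#' Cumulant linear absorption of an exciton system
#'
#' Secular second-order cumulant: each exciton k gets
#' \eqn{g_k(t)=\sum_n |c_{nk}|^4 g_n(t)} and
#' \eqn{\lambda_k=\sum_n |c_{nk}|^4\lambda_n}, and contributes a line
#' \deqn{A(\omega)\propto\omega\,|\mu_k|^2\,
#'   \mathrm{Re}\int_0^\infty dt\, e^{i2\pi c(\omega-E_k)t}\,e^{-g_k(t)}}
#' centred at the vertical exciton energy \eqn{E_k} (so the first moment of
#' \eqn{A(\omega)/\omega} is \eqn{E_k}; with a fast bath the peak maximum
#' relaxes towards \eqn{E_k-\lambda_k}).  No static disorder is added.
#'
#' @param H an [exciton_hamiltonian()].
#' @param sds one [spectral_density()], or a list of length n (per site), or a
#'   named list `list(a_pool = ..., c_pool = ...)` broadcast by pool.
#' @param temperature K.
#' @param omega output frequency grid (cm^-1).
#' @param tmax,dt time integration window (fs).
#' @param apodization optional exponential damping time (fs); `Inf` = off.
#' @return a `exciton_spectrum` tibble with columns `omega`, `intensity`;
#'   attribute `excitons` holds the per-exciton stick data.
#' @export
absorption_cumulant <- function(H, sds, temperature,
                                omega = seq(12000, 20000, by = 1),
                                tmax = 2048, dt = 1, apodization = Inf) {
  sds <- broadcast_sds(sds, H)
  st <- diagonalize(H)
  tg <- seq(0, tmax - dt, by = dt)
  gsite <- site_lineshapes(sds, temperature, tg)
  C4 <- st$coeffs^4
  lam_site <- vapply(gsite, function(g) attr(g, "lambda_eff"), 1)
  gmat <- vapply(gsite, function(g) g$g, complex(length(tg)))  # t x n
  mu2 <- rowSums(st$dipoles^2)
  apod <- if (is.finite(apodization)) exp(-tg / apodization) else rep(1, length(tg))
  acc <- numeric(length(omega))
  comp <- matrix(0, length(omega), H$n,
                 dimnames = list(NULL, paste0("exciton", seq_len(H$n))))
  for (k in seq_len(H$n)) {
    gk <- as.vector(gmat %*% C4[, k])
    line <- halfft_line(exp(-gk) * apod, dt, center = st$energies[k],
                        omega = omega)
    comp[, k] <- mu2[k] * line
    acc <- acc + comp[, k]
  }
  intensity <- pmax(omega * acc, 0)
  out <- tibble::tibble(omega = omega, intensity = intensity)
  attr(out, "excitons") <- tibble::tibble(
    exciton = seq_len(H$n), energy = st$energies,
    lambda_eff = as.vector(crossprod(C4, lam_site)), dipole_strength = mu2)
  attr(out, "lineshape_per_omega") <- acc   # A(omega)/omega, for moment checks
  class(out) <- c("exciton_spectrum", class(out))
  out
}

broadcast_sds <- function(sds, H) {
  if (inherits(sds, "spectral_density")) return(rep(list(sds), H$n))
  if (is.list(sds) && !is.null(names(sds)) &&
      all(names(sds) %in% c("a_pool", "c_pool"))) {
    return(lapply(unname(H$pools), function(p) {
      if (is.null(sds[[p]])) stop("missing spectral density for ", p)
      sds[[p]]
    }))
  }
  if (is.list(sds)) {
    if (length(sds) != H$n) stop("need one spectral density per site")
    return(sds)
  }
  stop("unrecognized spectral-density specification")
}

# one lineshape per *unique* spectral density, reused across sites
site_lineshapes <- function(sds, temperature, tg) {
  keys <- vapply(sds, function(s) digest_sd(s), "")
  uk <- unique(keys)
  gs <- lapply(uk, function(k)
    lineshape_g(sds[[match(k, keys)]], temperature, tg))
  gs[match(keys, uk)]
}

digest_sd <- function(s) paste(length(s$omega), sum(s$omega), sum(s$J),
                               sum(s$J * s$omega), collapse = "|")

# Re int_0^inf e^{i 2 pi c (omega - center) t} f(t) dt on an arbitrary grid,
# via zero-padded FFT in a rotating frame.
halfft_line <- function(f, dt, center, omega) {
  n <- length(f)
  M <- 2^ceiling(log2(max(4 * n, 1 / (exc_const$c_cmfs * 0.5 * dt), 64)))
  f[1] <- f[1] / 2                      # trapezoid at t = 0
  Fv <- stats::fft(c(f, rep(0, M - n)), inverse = TRUE) * dt  # e^{+i 2 pi k j/M}
  k <- seq_len(M) - 1
  wrel <- ifelse(k <= M / 2, k, k - M) / (M * dt) / exc_const$c_cmfs
  ord <- order(wrel)
  stats::approx(wrel[ord] + center, Re(Fv)[ord], xout = omega,
                yleft = 0, yright = 0)$y
}

#' Pool-decomposed absorption spectrum
#'
#' Computes the full cumulant spectrum plus one component per pigment pool,
#' each from the pool-restricted sub-Hamiltonian (sub-block of J, pool
#' energies, dipoles and spectral densities), mirroring the decomposition of
#' an antenna spectrum into its Chl-a and Chl-c contributions.
#'
#' @inheritParams absorption_cumulant
#' @param pools optional named list `pool name -> site indices/labels`;
#'   defaults to the Hamiltonian's own pool map.  Must partition the sites.
#' @return an `exciton_spectrum` tibble with columns `omega`, `intensity` and
#'   one column per pool.
#' @export
pool_decomposition <- function(H, sds, temperature,
                               omega = seq(12000, 20000, by = 1),
                               pools = NULL, ...) {
  if (is.null(pools)) {
    pools <- split(seq_len(H$n), unname(H$pools))
  } else {
    pools <- lapply(pools, function(p)
      if (is.character(p)) match(p, H$labels) else as.integer(p))
  }
  idx <- sort(unlist(pools, use.names = FALSE))
  if (!identical(idx, seq_len(H$n)))
    stop("pools must partition the sites exactly")
  sds <- broadcast_sds(sds, H)
  full <- absorption_cumulant(H, sds, temperature, omega = omega, ...)
  out <- tibble::tibble(omega = omega, intensity = full$intensity)
  for (nm in names(pools)) {
    p <- pools[[nm]]
    Hs <- exciton_hamiltonian(H$E[p], H$J[p, p, drop = FALSE], H$labels[p],
                              H$mu[p, , drop = FALSE], unname(H$pools)[p])
    if (all(rowSums(Hs$mu^2) == 0)) {
      out[[nm]] <- 0
    } else {
      out[[nm]] <- absorption_cumulant(Hs, sds[p], temperature,
                                       omega = omega, ...)$intensity
    }
  }
  attr(out, "excitons") <- attr(full, "excitons")
  class(out) <- c("exciton_spectrum", class(out))
  out
}

#' Rigid shift aligning a computed spectrum to a reference
#'
#' `shift = argmax(reference) - argmax(spec)`: adding `shift` to the computed
#' frequency axis moves its global maximum onto the reference maximum (up to
#' the grid resolution, to which the result is quantized).
#'
#' @param spec,reference spectra (tibbles with `omega`, `intensity`), each
#'   with a single global maximum.
#' @return shift in cm^-1.
#' @export
align_shift <- function(spec, reference) {
  pk <- function(s) {
    if (max(s$intensity) <= 0 || !any(is.finite(s$intensity)))
      stop("flat spectrum has no maximum to align")
    s$omega[which.max(s$intensity)]
  }
  pk(reference) - pk(spec)
}
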