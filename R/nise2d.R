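#' Two-dimensional electronic spectra by NISE propagation
#'
#' Accumulates the six impulsive third-order pathways (ground-state bleach,
#' stimulated emission and excited-state absorption, each in rephasing and
#' non-rephasing phase-matching) with NISE propagators in the one- and
#' two-exciton manifolds, isotropically averaged for parallel (xxxx)
#' polarization, and 2D-Fourier transforms t1/t3 into excitation/detection
#' frequency with a rotating-frame carrier at the mean site energy.
#'
#' Conventions: bleach-positive (GSB and SE positive, induced absorption
#' negative); the rephasing and non-rephasing halves are combined into the
#' purely absorptive real signal.  The two-exciton manifold is the hard-core
#' boson expansion of [two_exciton_expand()]; for a single two-level site the
#' ESA component is identically zero, and for uncoupled sites the ESA exactly
#' cancels the GSB/SE cross peaks.
#'
#' @param ensemble list of [stochastic_hamiltonian()] objects to average.
#' @param t2_fs waiting times (fs); multiples of the trajectory dt.
#' @param tmax_fs coherence-time span for t1 and t3 (fs).
#' @param omega1,omega3 output excitation/detection grids (cm^-1).
#' @param pathways which pathway families to accumulate.
#' @param apodization_fs Gaussian window time constant (fs) applied along t1
#'   and t3 before the 2D transform (`exp(-(t/tau)^2)`); suppresses
#'   truncation sidelobes far below any physical feature.  `Inf` disables.
#' @param rotating_frame_cm1 carrier frequency of the rotating frame;
#'   defaults to the mean site energy.
#' @return object of class `spectrum2d`: list with `omega1`, `omega3`,
#'   `t2_fs`, `signal` (list of matrices omega1 x omega3 per waiting time) and
#'   `components` (per pathway family, same layout).
#' @export
response_2d <- function(ensemble, t2_fs = 0, tmax_fs = 256,
                        omega1 = seq(13800, 17000, by = 10),
                        omega3 = seq(13800, 17000, by = 10),
                        pathways = c("GSB", "SE", "ESA"),
                        apodization_fs = tmax_fs / 5,
                        rotating_frame_cm1 = NULL) {
  base <- ensemble[[1]]$base
  dt <- ensemble[[1]]$dt
  n <- base$n
  nt <- floor(tmax_fs / dt)
  if (nt < 4) stop("t1/t3 grid too coarse: fewer than 4 steps")
  band <- 1 / (2 * exc_const$c_cmfs * dt)
  if (diff(range(base$E)) + 6 * max(abs(base$J)) > band)
    warning("dt may not resolve the exciton band in the rotating frame")
  n2steps <- round(t2_fs / dt)
  if (max(abs(n2steps * dt - t2_fs)) > 1e-9)
    warning("waiting times rounded to multiples of dt = ", dt, " fs")
  w0 <- if (is.null(rotating_frame_cm1)) mean(base$E) else rotating_frame_cm1
  use_esa <- "ESA" %in% pathways && n >= 2
  man <- if (use_esa) two_exciton_expand(base) else NULL
  fam <- intersect(c("GSB", "SE", if (use_esa) "ESA"), pathways)
  acc <- lapply(stats::setNames(fam, fam), function(f)
    lapply(seq_along(n2steps), function(i)
      matrix(0, length(omega1), length(omega3))))
  for (sh in ensemble) {
    res <- response_2d_one(sh, n2steps, nt, w0, man, fam)
    apod <- if (is.finite(apodization_fs))
      exp(-(seq(0, by = dt, length.out = nt) / apodization_fs)^2) else rep(1, nt)
    W <- outer(apod, apod)
    for (f in fam) for (i in seq_along(n2steps)) {
      sp <- r2d_transform(W * res[[f]]$r[[i]], W * res[[f]]$nr[[i]], dt, w0,
                          omega1, omega3)
      acc[[f]][[i]] <- acc[[f]][[i]] + sp / length(ensemble)
    }
  }
  signal <- lapply(seq_along(n2steps), function(i)
    Reduce(`+`, lapply(fam, function(f) acc[[f]][[i]])))
  structure(list(omega1 = omega1, omega3 = omega3, t2_fs = n2steps * dt,
                 signal = signal, components = acc),
            class = "spectrum2d")
}

#' @export
print.spectrum2d <- function(x, ...) {
  cat(sprintf("<spectrum2d: %d x %d grid, t2 = %s fs>\n",
              length(x$omega1), length(x$omega3),
              paste(x$t2_fs, collapse = ", ")))
  invisible(x)
}

# --- internal machinery -----------------------------------------------------

# cumulative propagators G[[k+1]] = U(t_k, 0) in the rotating frame
cumulative_props <- function(sh, n_total, w0, man) {
  n <- sh$base$n
  J <- sh$base$J
  G1 <- vector("list", n_total + 1)
  G1[[1]] <- diag(1 + 0i, n)
  G2 <- NULL
  m <- 0
  if (!is.null(man)) {
    m <- nrow(man$pairs)
    G2 <- vector("list", n_total + 1)
    G2[[1]] <- diag(1 + 0i, m)
    J2 <- man$H2
    diag(J2) <- 0
  }
  for (i in seq_len(n_total)) {
    dE <- fluct_at(sh, i)
    M <- J
    diag(M) <- sh$base$E + dE - w0
    G1[[i + 1]] <- step_propagator(M, sh$dt) %*% G1[[i]]
    if (!is.null(man)) {
      M2 <- J2
      diag(M2) <- man$H2[cbind(seq_len(m), seq_len(m))] +
        dE[man$pairs[, 1]] + dE[man$pairs[, 2]] - 2 * w0
      G2[[i + 1]] <- step_propagator(M2, sh$dt) %*% G2[[i]]
    }
  }
  list(G1 = G1, G2 = G2)
}

# isotropic <xxxx> average for a pathway factorizing into 3x3 blocks M, N:
# (1/15)[tr(M)tr(N) + tr(MN) + tr(M t(N))]
iso_pair <- function(M, N) {
  (sum(diag(M)) * sum(diag(N)) + sum(M * t(N)) + sum(M * N)) / 15
}

# ESA chain: P[[dg]] = 3x3 matrix over (alpha, beta) for Cartesian gamma,
# delta; pairings (ab)(gd), (ag)(bd), (ad)(bg)
iso_esa <- function(P) {
  s <- 0
  for (d in 1:3) for (g in 1:3) {
    V <- P[[(d - 1) * 3 + g]]
    if (d == g) s <- s + sum(diag(V))                    # (alpha=beta)(gamma=delta)
  }
  s1 <- 0; s2 <- 0
  for (d in 1:3) for (g in 1:3) {
    V <- P[[(d - 1) * 3 + g]]
    s1 <- s1 + V[g, d]                                   # alpha=gamma, beta=delta
    s2 <- s2 + V[d, g]                                   # alpha=delta, beta=gamma
  }
  (s + s1 + s2) / 15
}

response_2d_one <- function(sh, n2steps, nt, w0, man, fam) {
  n <- sh$base$n
  mu <- sh$base$mu                       # n x 3 (real)
  n_total <- nt - 1 + max(n2steps) + nt - 1
  cp <- cumulative_props(sh, n_total, w0, man)
  G1 <- cp$G1; G2 <- cp$G2
  Dg <- NULL
  if (!is.null(man) && "ESA" %in% fam) {
    m <- nrow(man$pairs)
    Dg <- lapply(1:3, function(a) man$dip[, , a, drop = TRUE])
    if (m == 1) Dg <- lapply(Dg, function(d) matrix(d, nrow = 1))
  }
  out <- lapply(stats::setNames(fam, fam), function(f)
    list(r = vector("list", length(n2steps)),
         nr = vector("list", length(n2steps))))
  do_gsb <- "GSB" %in% fam; do_se <- "SE" %in% fam; do_esa <- !is.null(Dg)
  for (i2 in seq_along(n2steps)) {
    n2 <- n2steps[i2]
    gsb_r <- matrix(0i, nt, nt); gsb_nr <- matrix(0i, nt, nt)
    se_r <- matrix(0i, nt, nt);  se_nr <- matrix(0i, nt, nt)
    esa_r <- matrix(0i, nt, nt); esa_nr <- matrix(0i, nt, nt)
    for (i1 in 0:(nt - 1)) {
      t2i <- i1 + n2                      # index of tau3 (0-based)
      Gt2 <- G1[[i1 + 1]]                 # U(tau2, 0)
      Gt3 <- G1[[t2i + 1]]                # U(tau3, 0)
      Gt3h <- Conj(t(Gt3))
      V2 <- Conj(t(Gt2)) %*% mu           # n x 3
      S12 <- crossprod(mu, Gt2 %*% mu)    # 3x3; rows = slot 2, cols = slot 1
      S13 <- crossprod(mu, Gt3 %*% mu)    # rows 3, cols 1
      S23 <- crossprod(mu, Gt3 %*% V2)    # rows 3, cols 2
      U32mu <- Gt3 %*% V2                 # U(tau3, tau2) mu
      G3mu <- Gt3 %*% mu                  # U(tau3, tau1) mu
      V3 <- Gt3h %*% mu
      if (do_esa) {
        G2h <- Conj(t(G2[[t2i + 1]]))
        Er  <- lapply(Dg, function(D) G2h %*% (D %*% U32mu))   # m x 3
        Enr <- lapply(Dg, function(D) G2h %*% (D %*% G3mu))
      }
      for (i3 in 0:(nt - 1)) {
        t4i <- t2i + i3
        G4 <- G1[[t4i + 1]]
        G4mu <- G4 %*% mu
        G4V2 <- G4 %*% V2
        if (do_gsb) {
          S34 <- crossprod(mu, G4 %*% V3)  # rows 4, cols 3
          gsb_r[i1 + 1, i3 + 1] <- iso_pair(Conj(S12), S34)
          gsb_nr[i1 + 1, i3 + 1] <- iso_pair(S12, S34)
        }
        if (do_se) {
          S24 <- crossprod(mu, G4V2)       # rows 4, cols 2
          S14 <- crossprod(mu, G4mu)       # rows 4, cols 1
          se_r[i1 + 1, i3 + 1] <- iso_pair(S24, Conj(S13))
          se_nr[i1 + 1, i3 + 1] <- iso_pair(S14, Conj(S23))
        }
        if (do_esa) {
          G24 <- G2[[t4i + 1]]
          A_r <- Conj(G4mu)               # bra side, rephasing
          A_nr <- Conj(G4V2)              # bra side, non-rephasing
          Pr <- vector("list", 9); Pnr <- vector("list", 9)
          for (d in 1:3) {
            tD <- t(Dg[[d]])
            for (g in 1:3) {
              Pr[[(d - 1) * 3 + g]] <- t(A_r) %*% (tD %*% (G24 %*% Er[[g]]))
              Pnr[[(d - 1) * 3 + g]] <- t(A_nr) %*% (tD %*% (G24 %*% Enr[[g]]))
            }
          }
          esa_r[i1 + 1, i3 + 1] <- -iso_esa(Pr)
          esa_nr[i1 + 1, i3 + 1] <- -iso_esa(Pnr)
        }
      }
    }
    if (do_gsb) { out$GSB$r[[i2]] <- gsb_r; out$GSB$nr[[i2]] <- gsb_nr }
    if (do_se)  { out$SE$r[[i2]] <- se_r;   out$SE$nr[[i2]] <- se_nr }
    if (do_esa) { out$ESA$r[[i2]] <- esa_r; out$ESA$nr[[i2]] <- esa_nr }
  }
  out
}

# 2D FFT of rephasing + non-rephasing halves into the absorptive spectrum
r2d_transform <- function(Rr, Rnr, dt, w0, omega1, omega3) {
  nt <- nrow(Rr)
  M <- 2^ceiling(log2(4 * nt))
  pad <- function(X) {
    Y <- matrix(0i, M, M)
    Y[1:nt, 1:nt] <- X
    Y[1, ] <- Y[1, ] / 2; Y[, 1] <- Y[, 1] / 2   # trapezoid at t = 0
    Y
  }
  # non-rephasing ~ e^{-i w1 t1 - i w3 t3}: transform with e^{+i...} both axes
  Snr <- stats::fft(pad(Rnr), inverse = TRUE)
  # rephasing ~ e^{+i w1 t1 - i w3 t3}: conjugate transform over t1
  Sr <- fft_mixed(pad(Rr))
  k <- seq_len(M) - 1
  wrel <- ifelse(k <= M / 2, k, k - M) / (M * dt) / exc_const$c_cmfs
  ord <- order(wrel)
  wabs <- wrel[ord] + w0
  Stot <- Re(Snr + Sr) * dt^2
  Stot <- Stot[ord, ord]
  # bilinear interpolation onto the requested grids
  ix <- findInterval(omega1, wabs, all.inside = TRUE)
  iy <- findInterval(omega3, wabs, all.inside = TRUE)
  fx <- (omega1 - wabs[ix]) / (wabs[ix + 1] - wabs[ix])
  fy <- (omega3 - wabs[iy]) / (wabs[iy + 1] - wabs[iy])
  S11 <- Stot[ix, iy, drop = FALSE]
  S21 <- Stot[ix + 1, iy, drop = FALSE]
  S12 <- Stot[ix, iy + 1, drop = FALSE]
  S22 <- Stot[ix + 1, iy + 1, drop = FALSE]
  W11 <- outer(1 - fx, 1 - fy); W21 <- outer(fx, 1 - fy)
  W12 <- outer(1 - fx, fy);     W22 <- outer(fx, fy)
  W11 * S11 + W21 * S21 + W12 * S12 + W22 * S22
}

# FFT with e^{-i} over rows (t1) and e^{+i} over columns (t3)
fft_mixed <- function(X) {
  Y <- stats::mvfft(X)                      # e^{-i 2 pi k j / M} over rows
  t(stats::mvfft(t(Y), inverse = TRUE))     # e^{+i ...} over columns
}

#' Diagonal waiting-time trace of a 2D spectrum
#'
#' Mean signal over a square diagonal region per waiting time, normalized to
#' its value at the earliest waiting time (which must be t2 = 0 for the
#' conventional normalization).
#'
#' @param s2d a [response_2d()] result.
#' @param region length-2 numeric: diagonal band limits (cm^-1) applied to
#'   both axes, e.g. `c(14800, 15000)` for a main-peak region or
#'   `c(16100, 16400)` for a vibronic region.
#' @return tibble with columns `t2_fs`, `value`, `trace` (normalized).
#' @export
diagonal_trace <- function(s2d, region) {
  i1 <- which(s2d$omega1 >= region[1] & s2d$omega1 <= region[2])
  i3 <- which(s2d$omega3 >= region[1] & s2d$omega3 <= region[2])
  if (!length(i1) || !length(i3)) stop("region lies outside the 2D grids")
  vals <- vapply(s2d$signal, function(S) mean(S[i1, i3]), 1)
  if (max(abs(vals)) == 0) stop("region outside signal support (all zero)")
  tibble::tibble(t2_fs = s2d$t2_fs, value = vals, trace = vals / vals[1])
}
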