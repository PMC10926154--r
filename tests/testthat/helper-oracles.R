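# independent numerical oracles used across test files

# matrix exponential by Taylor series with scaling and squaring (complex-safe);
# independent of the eigendecomposition route used by the package
taylor_expm <- function(A) {
  nrm <- max(Mod(A)) * nrow(A)
  s <- max(0L, ceiling(log2(nrm + 1)) + 4L)
  B <- A / 2^s
  X <- diag(1 + 0i, nrow(A))
  term <- diag(1 + 0i, nrow(A))
  for (k in 1:30) {
    term <- term %*% B / k
    X <- X + term
  }
  for (k in seq_len(s)) X <- X %*% X
  X
}

# time-ordered product of step propagators for a piecewise-constant H(t)
oracle_propagate <- function(E_of_step, J, psi0, dt, n_steps, substeps = 100) {
  psi <- psi0 * (1 + 0i)
  for (i in seq_len(n_steps)) {
    M <- J
    diag(M) <- E_of_step(i)
    U <- taylor_expm(-1i * exc_const$twopic * M * dt / substeps)
    for (k in seq_len(substeps)) psi <- U %*% psi
    psi
  }
  psi
}

# Jacobi eigenvalue sweep for real symmetric matrices (brute-force oracle)
jacobi_eigenvalues <- function(A, tol = 1e-12, max_sweeps = 50) {
  A <- as.matrix(A)
  n <- nrow(A)
  for (sweep in seq_len(max_sweeps)) {
    off <- 0
    for (p in 1:(n - 1)) for (q in (p + 1):n) {
      off <- max(off, abs(A[p, q]))
      if (abs(A[p, q]) > tol) {
        theta <- 0.5 * atan2(2 * A[p, q], A[q, q] - A[p, p])
        c0 <- cos(theta); s0 <- sin(theta)
        G <- diag(n); G[p, p] <- c0; G[q, q] <- c0
        G[p, q] <- s0; G[q, p] <- -s0
        A <- t(G) %*% A %*% G
      }
    }
    if (off < tol) break
  }
  sort(diag(A))
}

# brute-force lineshape integrand via adaptive quadrature over the same
# tabulated spectral density
oracle_g <- function(sd, temperature, t_fs) {
  beta <- 1 / (exc_const$kB_cm1 * temperature)
  Jf <- stats::approxfun(sd$omega, sd$J, yleft = 0, yright = 0)
  edges <- unique(c(min(sd$omega), 1, 10, 100, 1000, max(sd$omega)))
  piece <- function(f) sum(vapply(seq_len(length(edges) - 1), function(i)
    stats::integrate(f, edges[i], edges[i + 1], rel.tol = 1e-9,
                     subdivisions = 5000L)$value, 1))
  re <- piece(function(w) Jf(w) / w^2 / tanh(beta * w / 2) *
                (1 - cos(exc_const$twopic * w * t_fs)))
  im <- piece(function(w) Jf(w) / w^2 *
                (sin(exc_const$twopic * w * t_fs) -
                   exc_const$twopic * w * t_fs))
  complex(real = re, imaginary = im) / pi
}

# rolling mean used to smooth stochastic population traces
roll_mean <- function(x, k) {
  stats::filter(x, rep(1 / k, k), sides = 2) |> as.numeric()
}

# quick toy networks shared by several files
toy_fcp <- function(seed = 11) make_network(network_spec(), seed = seed)

# unwrap a cyclic angle sequence so monotone circulation shows as increase
unwrap_steps <- function(a) {
  d <- diff(a)
  d[d < -pi] <- d[d < -pi] + 2 * pi
  d[d > pi] <- d[d > pi] - 2 * pi
  cumsum(c(a[1], d))
}
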