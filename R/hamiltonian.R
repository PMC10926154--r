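#' Frenkel exciton Hamiltonian of a pigment network
#'
#' Bundles site energies E (diagonal, cm\eqn{^{-1}}), the symmetric coupling
#' matrix J (off-diagonal, cm\eqn{^{-1}}, zero diagonal), site labels,
#' transition dipoles (n x 3, Debye) and a pool assignment (`"a_pool"` /
#' `"c_pool"`) per site.
#'
#' @param E numeric vector of site energies (cm^-1).
#' @param J n x n coupling matrix (cm^-1); must be symmetric to 1e-9 and is
#'   stored symmetrized with an exactly zero diagonal.
#' @param labels site labels; defaults to `site1..siteN`.
#' @param mu n x 3 matrix of transition dipoles (Debye).
#' @param pools character vector (`"a_pool"`/`"c_pool"`) or named map
#'   label -> pool; defaults to all `"a_pool"`.
#' @return object of class `exciton_hamiltonian`.
#' @examples
#' H <- exciton_hamiltonian(E = c(0, 0), J = matrix(c(0, 100, 100, 0), 2))
#' diagonalize(H)$energies
#' @export
exciton_hamiltonian <- function(E, J = NULL, labels = NULL, mu = NULL,
                                pools = NULL) {
  E <- as.numeric(E)
  n <- length(E)
  if (!all(is.finite(E))) stop("site energies must be finite")
  if (is.null(J)) J <- matrix(0, n, n)
  J <- as.matrix(J)
  stopifnot(nrow(J) == n, ncol(J) == n)
  if (max(abs(J - t(J))) > 1e-9)
    stop("coupling matrix not symmetric (max asymmetry ",
         format(max(abs(J - t(J)))), " cm^-1)")
  J <- (J + t(J)) / 2
  diag(J) <- 0
  if (is.null(labels)) labels <- paste0("site", seq_len(n))
  labels <- as.character(labels)
  stopifnot(length(labels) == n)
  if (is.null(mu)) mu <- matrix(0, n, 3)
  mu <- as.matrix(mu)
  stopifnot(nrow(mu) == n, ncol(mu) == 3)
  if (is.null(pools)) pools <- rep("a_pool", n)
  if (!is.null(names(pools))) pools <- unname(pools[labels])
  pools <- as.character(pools)
  stopifnot(length(pools) == n, all(pools %in% c("a_pool", "c_pool")))
  structure(list(n = n, labels = labels, E = E, J = J, mu = mu,
                 pools = stats::setNames(pools, labels)),
            class = "exciton_hamiltonian")
}

#' @export
print.exciton_hamiltonian <- function(x, ...) {
  cat(sprintf("<exciton_hamiltonian: %d sites (%d a_pool, %d c_pool)>\n",
              x$n, sum(x$pools == "a_pool"), sum(x$pools == "c_pool")))
  cat(sprintf("  site energies %.1f .. %.1f cm^-1, max |J| = %.2f cm^-1\n",
              min(x$E), max(x$E), if (x$n > 1) max(abs(x$J)) else 0))
  invisible(x)
}

#' Dense matrix of an exciton Hamiltonian
#' @param H an [exciton_hamiltonian()].
#' @return n x n numeric matrix `diag(E) + J`.
#' @export
as_matrix_H <- function(H) {
  M <- H$J
  diag(M) <- H$E
  dimnames(M) <- list(H$labels, H$labels)
  M
}

#' Build an exciton Hamiltonian from pigments
#'
#' Site energies are supplied per pigment (or per type); couplings come from
#' [point_dipole_coupling()].
#'
#' @param pigments list of [pigment()] objects.
#' @param E site energies (cm^-1), one per pigment, or a named vector by type.
#' @return an [exciton_hamiltonian()].
#' @export
hamiltonian_from_pigments <- function(pigments, E) {
  n <- length(pigments)
  labels <- vapply(pigments, `[[`, "", "label")
  ptypes <- vapply(pigments, `[[`, "", "ptype")
  if (!is.null(names(E))) E <- unname(E[ptypes])
  stopifnot(length(E) == n)
  J <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j)
    J[i, j] <- J[j, i] <- point_dipole_coupling(pigments[[i]], pigments[[j]])
  mu <- do.call(rbind, lapply(pigments, `[[`, "mu"))
  pools <- ifelse(ptypes == "chl_a", "a_pool", "c_pool")
  exciton_hamiltonian(E, J, labels, mu, pools)
}

#' Rank site energies into an energy ladder
#'
#' Sorts energies ascending (the funnel order: rank 1 receives the excitation
#' last); ties are broken by lexicographic label order so the ladder is
#' deterministic.
#'
#' @param E numeric energies, or a data frame with columns `label`, `energy`.
#' @param labels labels when `E` is a bare vector.
#' @return tibble with columns `label`, `energy`, `rank` in ascending order.
#' @examples
#' energy_ladder(c(`Chl-a` = 1.910, `Chl-c1` = 2.023, `Chl-c2` = 1.987))
#' @export
energy_ladder <- function(E, labels = NULL) {
  if (is.data.frame(E)) {
    labels <- E$label
    E <- E$energy
  }
  E <- as.numeric(if (!is.null(names(E)) && is.null(labels)) {
    labels <- names(E); unname(E)
  } else E)
  if (is.null(labels)) labels <- paste0("site", seq_along(E))
  stopifnot(all(is.finite(E)), length(labels) == length(E))
  ord <- order(E, labels, method = "radix")
  tibble::tibble(label = as.character(labels)[ord], energy = E[ord],
                 rank = seq_along(E))
}

#' Diagonalize an exciton Hamiltonian
#'
#' Returns the one-exciton eigenstates: ascending energies, site-basis
#' coefficient columns, and exciton transition dipoles
#' \eqn{\mu_k=\sum_n c_{nk}\mu_n}.
#'
#' @param H an [exciton_hamiltonian()].
#' @return object of class `exciton_states` with fields `energies`, `coeffs`
#'   (n x n, column k = exciton k), `dipoles` (n x 3), `labels`.
#' @export
diagonalize <- function(H) {
  M <- as_matrix_H(H)
  if (max(abs(M - t(M))) > 1e-9) stop("Hamiltonian matrix not symmetric")
  eig <- eigen(M, symmetric = TRUE)
  ord <- order(eig$values)
  C <- eig$vectors[, ord, drop = FALSE]
  # fix sign: largest-|c| entry positive, for reproducibility
  for (k in seq_len(ncol(C))) {
    i <- which.max(abs(C[, k]))
    if (C[i, k] < 0) C[, k] <- -C[, k]
  }
  structure(list(energies = eig$values[ord], coeffs = C,
                 dipoles = crossprod(C, H$mu), labels = H$labels),
            class = "exciton_states")
}

#' @export
print.exciton_states <- function(x, ...) {
  cat(sprintf("<exciton_states: %d states, %.1f .. %.1f cm^-1>\n",
              length(x$energies), min(x$energies), max(x$energies)))
  invisible(x)
}

#' Largest coupling between two pigment pools
#'
#' @param H an [exciton_hamiltonian()].
#' @param poolA,poolB site indices, labels, or pool names (`"a_pool"`,
#'   `"c_pool"`); must be disjoint and nonempty.
#' @return list with `value` (max |J| in cm^-1, unsigned), `pair` (site
#'   indices), `labels`.
#' @export
max_interpool_coupling <- function(H, poolA = "a_pool", poolB = "c_pool") {
  resolve <- function(p) {
    if (is.character(p) && length(p) == 1 && p %in% c("a_pool", "c_pool"))
      return(which(H$pools == p))
    if (is.character(p)) return(match(p, H$labels))
    as.integer(p)
  }
  ia <- resolve(poolA); ib <- resolve(poolB)
  if (!length(ia) || !length(ib)) stop("both pools must be nonempty")
  if (length(intersect(ia, ib))) stop("pools overlap")
  sub <- abs(H$J[ia, ib, drop = FALSE])
  k <- arrayInd(which.max(sub), dim(sub))
  pair <- c(ia[k[1]], ib[k[2]])
  list(value = sub[k], pair = pair, labels = H$labels[pair])
}

#' Two-exciton manifold of an exciton Hamiltonian
#'
#' Hard-core boson double excitations: one basis state per site pair i<j, no
#' doubly excited single site and no anharmonicity.
#' `H2[(i,j),(i,j)] = E_i + E_j`; pairs sharing one site couple through the
#' coupling of the differing sites; disjoint pairs do not couple.  The
#' one- to two-exciton transition dipole from state i to pair (j,k) is nonzero
#' only when `i` belongs to the pair and then equals the dipole of the added
#' site.
#'
#' @param H an [exciton_hamiltonian()] with at least two sites.
#' @return list with `pairs` (m x 2 matrix, i<j), `H2` (m x m, cm^-1) and
#'   `dip` (m x n x 3 array of lifting dipoles), class `two_exciton_manifold`.
#' @export
two_exciton_expand <- function(H) {
  n <- H$n
  if (n < 2) stop("two-exciton manifold needs n >= 2 sites")
  pairs <- t(utils::combn(n, 2))
  m <- nrow(pairs)
  H2 <- matrix(0, m, m)
  for (p in seq_len(m)) {
    H2[p, p] <- H$E[pairs[p, 1]] + H$E[pairs[p, 2]]
    if (p < m) for (q in (p + 1):m) {
      shared <- intersect(pairs[p, ], pairs[q, ])
      if (length(shared) == 1) {
        a <- setdiff(pairs[p, ], shared)
        b <- setdiff(pairs[q, ], shared)
        H2[p, q] <- H2[q, p] <- H$J[a, b]
      }
    }
  }
  dip <- array(0, dim = c(m, n, 3))
  for (p in seq_len(m)) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    dip[p, i, ] <- H$mu[j, ]  # from |i>, add j
    dip[p, j, ] <- H$mu[i, ]
  }
  structure(list(pairs = pairs, H2 = H2, dip = dip, n = n),
            class = "two_exciton_manifold")
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.exciton_hamiltonian <- function(x, ...) {
  tibble::tibble(label = x$labels, pool = unname(x$pools), energy = x$E,
                 mu_D = sqrt(rowSums(x$mu^2)))
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.exciton_states <- function(x, ...) {
  tibble::tibble(
    exciton = seq_along(x$energies),
    energy = x$energies,
    dipole_strength = rowSums(x$dipoles^2),
    participation = 1 / colSums(x$coeffs^4),
    dominant_site = x$labels[apply(abs(x$coeffs), 2, which.max)])
}

#' Tidiers for exciton objects
#'
#' `tidy()` returns one row per site (`exciton_hamiltonian`) or per eigenstate
#' (`exciton_states`); `glance()` gives one-row summaries.
#'
#' @param x object to tidy.
#' @param ... unused.
#' @name tidiers
#' @rdname tidiers
#' @exportS3Method generics::glance
glance.exciton_hamiltonian <- function(x, ...) {
  inter <- if (all(c("a_pool", "c_pool") %in% x$pools))
    max_interpool_coupling(x)$value else NA_real_
  tibble::tibble(n_sites = x$n, n_a = sum(x$pools == "a_pool"),
                 n_c = sum(x$pools == "c_pool"),
                 e_min = min(x$E), e_max = max(x$E),
                 max_J = if (x$n > 1) max(abs(x$J)) else 0,
                 max_interpool_J = inter)
}
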