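#' Pigment objects
#'
#' A `pigment` represents one chromophore: a residue label, a type
#' (`"chl_a"`, `"chl_c1"` or `"chl_c2"`), the coordinates of its named atoms
#' (at least the central magnesium MG and the four ring nitrogens NA, NB, NC,
#' ND when loaded from a structure), a Qy transition-dipole vector in Debye and
#' a center (defaults to the MG position).
#'
#' @param label residue label, e.g. `"CLA409"`.
#' @param ptype one of `"chl_a"`, `"chl_c1"`, `"chl_c2"`.
#' @param atoms named list (or 3-column matrix with rownames) of atom
#'   coordinates in Angstrom.
#' @param mu transition-dipole 3-vector in Debye.
#' @param center optional 3-vector; defaults to the MG coordinate if present,
#'   otherwise the centroid of `atoms`.
#' @return an object of class `pigment`.
#' @examples
#' p <- pigment("CLA401", "chl_a",
#'              atoms = list(MG = c(0, 0, 0), NA. = c(2, 0, 0)),
#'              mu = c(4, 0, 0))
#' p$center
#' @export
pigment <- function(label, ptype = c("chl_a", "chl_c1", "chl_c2"),
                    atoms = list(), mu = c(0, 0, 0), center = NULL) {
  ptype <- match.arg(ptype)
  if (is.matrix(atoms)) {
    atoms <- stats::setNames(lapply(seq_len(nrow(atoms)), function(i) atoms[i, ]),
                             rownames(atoms))
  }
  names(atoms) <- sub("\\.$", "", names(atoms))  # allow NA. for the reserved word
  atoms <- lapply(atoms, as.numeric)
  stopifnot(all(vapply(atoms, length, 1L) == 3L))
  if (!all(vapply(atoms, function(a) all(is.finite(a)), TRUE)))
    stop("pigment '", label, "': non-finite atom coordinates")
  mu <- as.numeric(mu)
  stopifnot(length(mu) == 3L, all(is.finite(mu)))
  if (is.null(center)) {
    center <- if ("MG" %in% names(atoms)) atoms[["MG"]]
              else if (length(atoms)) colMeans(do.call(rbind, atoms))
              else c(NA_real_, NA_real_, NA_real_)
  }
  structure(list(label = as.character(label), ptype = ptype, atoms = atoms,
                 mu = mu, center = as.numeric(center)),
            class = "pigment")
}

#' @export
print.pigment <- function(x, ...) {
  cat(sprintf("<pigment %s (%s): %d atoms, |mu| = %.2f D>\n",
              x$label, x$ptype, length(x$atoms), sqrt(sum(x$mu^2))))
  invisible(x)
}

ring_atom_names <- c("MG", "NA", "NB", "NC", "ND")

#' Load chlorophyll pigments from a PDB structure
#'
#' Reads a PDB file and extracts one [pigment()] per matching chlorophyll
#' residue.  Residue names starting with `CLA`/`CHL` map to `chl_a`; `CLC`
#' residues map to `chl_c2` by default because PDB residue names do not
#' distinguish the c1 and c2 variants - use `c_map` to assign specific residue
#' numbers (in FCP, residue 403 is Chl-c2 and 408 is Chl-c1).
#'
#' Transition dipoles are placed along the NC-to-NA direction (the Qy axis runs
#' through the NA/NC nitrogen pair) with magnitude `mu_scale[ptype]`.
#' Pigments missing any of MG, NA-ND get a warning and a zero dipole; they
#' only become a hard error if a ring frame is requested later
#' (see [ring_frame()]).
#'
#' @param path PDB file.
#' @param resid residue names treated as chlorophylls.
#' @param c_map named character vector mapping residue numbers to `"chl_c1"` /
#'   `"chl_c2"` for CLC residues, e.g. `c("403" = "chl_c2", "408" = "chl_c1")`.
#' @param mu_scale named numeric: dipole magnitude (D) per pigment type.
#' @return list of [pigment()] objects, ordered by residue number.
#' @export
load_pigments <- function(path, resid = c("CLA", "CHL", "CLC"),
                          c_map = c("403" = "chl_c2", "408" = "chl_c1"),
                          mu_scale = c(chl_a = 4.0, chl_c1 = 2.4, chl_c2 = 2.4)) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("cannot parse PDB file '", path, "': ",
                                           conditionMessage(e)))
  at <- pdb$atom
  keep <- at$resid %in% resid
  if (!any(keep)) stop("zero matches: no residues named ",
                       paste(resid, collapse = "/"), " in ", path)
  at <- at[keep, , drop = FALSE]
  split_key <- paste(at$resid, at$resno, at$chain, sep = "|")
  groups <- split(seq_len(nrow(at)), split_key)
  ord <- order(vapply(groups, function(i) at$resno[i[1]], 1))
  pigs <- lapply(groups[ord], function(idx) {
    a <- at[idx, , drop = FALSE]
    rn <- a$resid[1]
    resno <- a$resno[1]
    ptype <- if (startsWith(rn, "CLC")) {
      pt <- unname(c_map[as.character(resno)])
      if (is.na(pt) || is.null(pt)) "chl_c2" else pt
    } else "chl_a"
    atoms <- stats::setNames(
      lapply(seq_len(nrow(a)), function(i) c(a$x[i], a$y[i], a$z[i])),
      trimws(a$elety))
    missing_ring <- setdiff(ring_atom_names, names(atoms))
    label <- sprintf("%s%d", rn, resno)
    mu <- c(0, 0, 0)
    if (length(missing_ring)) {
      warning("pigment ", label, " lacks atoms: ",
              paste(missing_ring, collapse = ", "))
    } else {
      qy <- atoms[["NA"]] - atoms[["NC"]]
      mu <- qy / sqrt(sum(qy^2)) * mu_scale[[ptype]]
    }
    pigment(label, ptype, atoms = atoms, mu = mu)
  })
  unname(pigs)
}

#' Point-dipole excitonic coupling between two pigments
#'
#' \deqn{V = f\,\kappa\,|\mu_1||\mu_2|/R^3,\qquad
#'       \kappa=\hat\mu_1\cdot\hat\mu_2-3(\hat\mu_1\cdot\hat R)(\hat\mu_2\cdot\hat R)}
#' with \eqn{f} the dipole-dipole constant in cm\eqn{^{-1}\AA^3}/D\eqn{^2}
#' computed from CODATA values (`exc_const$dipole_coupling_cm1`, about 5034).
#' No screening factor is applied.
#'
#' @param p1,p2 [pigment()] objects with distinct centers.
#' @return coupling in cm\eqn{^{-1}}; zero if either dipole vanishes.
#' @export
point_dipole_coupling <- function(p1, p2) {
  R <- p2$center - p1$center
  r <- sqrt(sum(R^2))
  if (!is.finite(r) || r < 1e-9) stop("pigments have coincident centers")
  m1 <- sqrt(sum(p1$mu^2)); m2 <- sqrt(sum(p2$mu^2))
  if (m1 == 0 || m2 == 0) return(0)
  u1 <- p1$mu / m1; u2 <- p2$mu / m2; ur <- R / r
  kappa <- sum(u1 * u2) - 3 * sum(u1 * ur) * sum(u2 * ur)
  exc_const$dipole_coupling_cm1 * kappa * m1 * m2 / r^3
}
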