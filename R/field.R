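#' Point-charge environments
#'
#' @param charges numeric vector of charges (elementary charge units).
#' @param positions k x 3 matrix of positions (Angstrom).
#' @return object of class `charge_environment`.
#' @export
charge_environment <- function(charges, positions) {
  charges <- as.numeric(charges)
  positions <- matrix(as.numeric(positions), ncol = 3)
  stopifnot(length(charges) == nrow(positions),
            all(is.finite(charges)), all(is.finite(positions)))
  structure(list(charges = charges, positions = positions),
            class = "charge_environment")
}

#' @export
print.charge_environment <- function(x, ...) {
  cat(sprintf("<charge_environment: %d charges, net %.3f e>\n",
              length(x$charges), sum(x$charges)))
  invisible(x)
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rotation + translation taking `mobile` onto `reference`,
#' with `det(R) = +1` enforced (no reflection).  The same transform can be
#' applied to any other point set (e.g. a charge environment moved together
#' with its pigment).
#'
#' @param mobile,reference paired n x 3 coordinate matrices, n >= 3,
#'   non-collinear.
#' @return list with `rotation` (3 x 3), `translation` (length 3), `rmsd`, and
#'   `apply(points)`; points map as `points %*% t(rotation) + translation`.
#' @export
kabsch_align <- function(mobile, reference) {
  P <- matrix(as.numeric(mobile), ncol = 3)
  Q <- matrix(as.numeric(reference), ncol = 3)
  stopifnot(nrow(P) == nrow(Q))
  if (nrow(P) < 3) stop("need at least 3 paired points")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv <- svd(crossprod(Pc, Qc))   # 3x3 = t(Pc) %*% Qc
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1))
    stop("point set is (near-)collinear; rotation not determined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  translation <- cq - as.numeric(R %*% cp)
  apply_fun <- function(points) {
    pts <- matrix(as.numeric(points), ncol = 3)
    sweep(pts %*% t(R), 2, translation, `+`)
  }
  moved <- apply_fun(P)
  list(rotation = R, translation = translation,
       rmsd = sqrt(mean(rowSums((moved - Q)^2))), apply = apply_fun)
}

#' Canonical ring frame of a chlorophyll
#'
#' Rigid transform that puts the best-fit plane of the four ring nitrogens
#' into z = 0 with their centroid at the origin.  The +z normal is chosen so
#' that NA -> NB -> NC -> ND circulate counterclockwise seen from +z, and the
#' in-plane y axis points along the NC -> NA direction projected into the
#' plane (the Qy axis through the NA/NC pair), so NA ends up at positive y.
#' This is a deterministic geometric convention; analyses that instead rotate
#' for maximal field response along y may differ by an in-plane rotation, so
#' comparisons of absolute field components between conventions are
#' qualitative (sign patterns), not element-wise.
#'
#' @param p a [pigment()] with atoms MG and NA-ND.
#' @return list with `rotation`, `translation`, `apply(points)` and `pigment`
#'   (the input pigment with all atoms, center and dipole transformed).
#' @export
ring_frame <- function(p) {
  need <- ring_atom_names
  if (!all(need %in% names(p$atoms)))
    stop("pigment ", p$label, " lacks ring atoms: ",
         paste(setdiff(need, names(p$atoms)), collapse = ", "))
  N <- do.call(rbind, p$atoms[c("NA", "NB", "NC", "ND")])
  ctr <- colMeans(N)
  Nc <- sweep(N, 2, ctr)
  sv <- svd(Nc)
  if (sv$d[2] < 1e-8) stop("ring nitrogens are collinear")
  zhat <- sv$v[, 3]
  # signed circulation NA->NB->NC->ND about zhat
  circ <- 0
  for (i in 1:4) {
    j <- i %% 4 + 1
    circ <- circ + sum(pracma_cross(Nc[i, ], Nc[j, ]) * zhat)
  }
  if (circ < 0) zhat <- -zhat
  yax <- Nc[1, ] - Nc[3, ]                       # NC -> NA
  yax <- yax - sum(yax * zhat) * zhat            # project into plane
  yhat <- yax / sqrt(sum(yax^2))
  xhat <- pracma_cross(yhat, zhat)
  R <- rbind(xhat, yhat, zhat)
  rownames(R) <- NULL
  apply_fun <- function(points) {
    pts <- matrix(as.numeric(points), ncol = 3)
    sweep(pts, 2, ctr) %*% t(R)
  }
  q <- p
  q$atoms <- lapply(p$atoms, function(a) as.numeric(apply_fun(a)))
  q$center <- as.numeric(apply_fun(p$center))
  q$mu <- as.numeric(p$mu %*% t(R))              # vectors rotate only
  list(rotation = R, translation = -as.numeric(R %*% ctr),
       apply = apply_fun, pigment = q)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Coulomb field of a point-charge environment
#'
#' \deqn{F(r)=\sum_i q_i (r-r_i)/|r-r_i|^3} with coordinates converted to
#' bohr internally; the result is in atomic units (e/a0^2).  Superposition is
#' exact; an evaluation point within 1e-6 A of a charge is an error.
#'
#' @param env a [charge_environment()] (positions in Angstrom).
#' @param points q x 3 matrix of evaluation points (Angstrom).
#' @return q x 3 matrix of field vectors (au).
#' @export
coulomb_field <- function(env, points) {
  pts <- matrix(as.numeric(points), ncol = 3) / exc_const$bohr_A
  pos <- env$positions / exc_const$bohr_A
  out <- matrix(0, nrow(pts), 3)
  for (k in seq_len(nrow(pts))) {
    d <- sweep(-pos, 2, pts[k, ], `+`)           # r - r_i
    r2 <- rowSums(d^2)
    if (any(r2 < (1e-6 / exc_const$bohr_A)^2))
      stop("evaluation point ", k, " coincides with a charge")
    out[k, ] <- colSums(env$charges * d / r2^1.5)
  }
  out
}

#' Electric-field report at chlorophyll probe atoms
#'
#' Evaluates the Coulomb field of `env` at the MG and NA-ND atoms of a
#' pigment that is already in its canonical ring frame (transform the
#' environment with the same [ring_frame()] transform first).  Rows with a
#' positive y component - the direction chlorophyll-c excitation energies are
#' most susceptible to - are flagged.
#'
#' @param env [charge_environment()] in the pigment frame.
#' @param p [pigment()] in the canonical frame.
#' @param atoms probe atom names.
#' @return tibble with columns `atom`, `Fx`, `Fy`, `Fz` (au), `y_positive`.
#' @export
field_report <- function(env, p, atoms = ring_atom_names) {
  missing <- setdiff(atoms, names(p$atoms))
  if (length(missing)) stop("pigment lacks probe atoms: ",
                            paste(missing, collapse = ", "))
  pts <- do.call(rbind, p$atoms[atoms])
  f <- coulomb_field(env, pts)
  tibble::tibble(atom = atoms, Fx = f[, 1], Fy = f[, 2], Fz = f[, 3],
                 y_positive = f[, 2] > 0)
}

#' Field-scan container
#'
#' Excitation energies of pigments under homogeneous electric fields along
#' +/-x, +/-y, +/-z plus the zero-field baseline, as in a Stark scan.
#'
#' @param data data frame with columns `pigment`, `direction` (one of
#'   `none, +x, -x, +y, -y, +z, -z`) and `energy_ev`.
#' @param field_au field magnitude in atomic units (> 0).
#' @return tibble of class `field_scan` (attribute `field_au`).
#' @export
field_scan <- function(data, field_au = 0.01) {
  stopifnot(all(c("pigment", "direction", "energy_ev") %in% names(data)),
            field_au > 0)
  dirs <- c("none", "+x", "-x", "+y", "-y", "+z", "-z")
  if (!all(data$direction %in% dirs))
    stop("direction must be one of: ", paste(dirs, collapse = ", "))
  if (!all(tapply(data$direction == "none", data$pigment, any)))
    stop("every pigment needs a 'none' (zero-field) row")
  out <- tibble::as_tibble(data[c("pigment", "direction", "energy_ev")])
  attr(out, "field_au") <- field_au
  class(out) <- c("field_scan", class(out))
  out
}

#' Stark shifts from a field scan
#'
#' Subtracts the zero-field energy per pigment:
#' `shift = E(direction) - E(none)`, reproducing the parenthetical entries of
#' a scan table, and reports the direction of maximal |shift| per pigment.
#'
#' @param scan a [field_scan()].
#' @return tibble with columns `pigment`, `direction`, `energy_ev`,
#'   `shift_ev`, `max_abs` (TRUE on the row with the largest |shift| for that
#'   pigment).
#' @export
scan_shifts <- function(scan) {
  if (!inherits(scan, "field_scan")) scan <- field_scan(scan)
  base <- scan[scan$direction == "none", c("pigment", "energy_ev")]
  names(base)[2] <- "e0"
  out <- dplyr::left_join(
    scan[scan$direction != "none", , drop = FALSE],
    base, by = "pigment")
  out$shift_ev <- out$energy_ev - out$e0
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$pigment),
    max_abs = abs(.data$shift_ev) == max(abs(.data$shift_ev)))
  out <- dplyr::ungroup(out)
  out$e0 <- NULL
  tibble::as_tibble(out)
}

#' Field-susceptibility ratio between pigment groups
#'
#' Ratio of the largest |Stark shift| found in group B to that in group A
#' (e.g. Chl-c vs Chl-a: the shifts of a scan table give 0.252/0.051 = 4.94,
#' a 5-fold larger susceptibility).
#'
#' @param shifts output of [scan_shifts()] (or a [field_scan()], converted).
#' @param groupA,groupB character vectors of pigment names.
#' @return list with `ratio`, `fold` (nearest integer), `maxA`, `maxB`.
#' @export
susceptibility_ratio <- function(shifts, groupA, groupB) {
  if (inherits(shifts, "field_scan")) shifts <- scan_shifts(shifts)
  stopifnot(length(groupA) > 0, length(groupB) > 0)
  maxA <- max(abs(shifts$shift_ev[shifts$pigment %in% groupA]))
  maxB <- max(abs(shifts$shift_ev[shifts$pigment %in% groupB]))
  if (!is.finite(maxA) || maxA == 0) stop("zero maximal shift in group A")
  list(ratio = maxB / maxA, fold = round(maxB / maxA),
       maxA = maxA, maxB = maxB)
}

#' Linear Stark (difference-dipole) fit of a field scan
#'
#' Models the shift as \eqn{\Delta E=-\Delta\mu\cdot F}.  From the +/- pairs
#' along each axis, \eqn{\Delta\mu_\alpha=-(E(+\alpha)-E(-\alpha))/(2F)} in
#' eV per au of field; residuals (observed - predicted over the six scan
#' points) quantify how nonlinear/asymmetric the true response is.
#'
#' @param scan a [field_scan()] restricted to one pigment, or with `pigment`
#'   given.
#' @param pigment which pigment to fit when the scan holds several.
#' @return list with `dmu` (3-vector, eV/au), `residuals` (tibble per
#'   direction), `rms_residual_ev`.
#' @export
difference_dipole_fit <- function(scan, pigment = NULL) {
  if (!inherits(scan, "field_scan")) scan <- field_scan(scan)
  F0 <- attr(scan, "field_au")
  if (!is.null(pigment)) scan <- scan[scan$pigment %in% pigment, , drop = FALSE]
  if (length(unique(scan$pigment)) != 1)
    stop("scan must contain exactly one pigment (use the 'pigment' argument)")
  e <- stats::setNames(scan$energy_ev, scan$direction)
  axes <- c("x", "y", "z")
  for (a in axes) if (!all(c(paste0("+", a), paste0("-", a)) %in% names(e)))
    stop("missing +/- pair for axis ", a)
  dmu <- vapply(axes, function(a)
    -(e[[paste0("+", a)]] - e[[paste0("-", a)]]) / (2 * F0), 1)
  dirvec <- list("+x" = c(1, 0, 0), "-x" = c(-1, 0, 0),
                 "+y" = c(0, 1, 0), "-y" = c(0, -1, 0),
                 "+z" = c(0, 0, 1), "-z" = c(0, 0, -1))
  res <- tibble::tibble(
    direction = names(dirvec),
    observed_ev = vapply(names(dirvec), function(d) e[[d]] - e[["none"]], 1),
    predicted_ev = vapply(names(dirvec), function(d)
      -sum(dmu * dirvec[[d]]) * F0, 1))
  res$residual_ev <- res$observed_ev - res$predicted_ev
  list(dmu = dmu, residuals = res,
       rms_residual_ev = sqrt(mean(res$residual_ev^2)))
}
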