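#' Read / write exciton Hamiltonians as plain text
#'
#' Format: line 1 the site count N; N label lines; N lines of N whitespace-
#' separated values in cm^-1 (site energies on the diagonal); N lines
#' `label mux muy muz` in Debye.  Values are rendered with 12 significant
#' digits so write-then-read round-trips bit-identically at that precision.
#' Asymmetry beyond 1e-6 cm^-1 on read is a hard error.
#'
#' @param path file path.
#' @param pools optional pool map for [exciton_hamiltonian()] on read.
#' @return an [exciton_hamiltonian()].
#' @export
read_hamiltonian <- function(path, pools = NULL) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  n <- suppressWarnings(as.integer(trimws(ln[1])))
  if (is.na(n) || n < 1) stop("malformed header: first line must be the site count")
  if (length(ln) < 1 + n + n + n) stop("truncated Hamiltonian file")
  labels <- trimws(ln[2:(n + 1)])
  M <- t(vapply(ln[(n + 2):(2 * n + 1)], function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]]), numeric(n)))
  if (any(is.na(M))) stop("non-numeric or non-square coupling block")
  if (max(abs(M - t(M))) > 1e-6)
    stop("Hamiltonian asymmetric beyond 1e-6 cm^-1 (max ",
         format(max(abs(M - t(M)))), ")")
  mu <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(ln[2 * n + 1 + i]), "\\s+")[[1]]
    if (f[1] != labels[i]) stop("dipole block label mismatch at site ", i)
    mu[i, ] <- as.numeric(f[2:4])
  }
  if (any(is.na(mu))) stop("malformed dipole block")
  E <- diag(M)
  J <- M
  diag(J) <- 0
  J <- (J + t(J)) / 2
  exciton_hamiltonian(E, J, labels, mu, pools)
}

#' @rdname read_hamiltonian
#' @param H an [exciton_hamiltonian()] to write.
#' @export
write_hamiltonian <- function(H, path) {
  M <- as_matrix_H(H)
  fmt <- function(x) format(x, digits = 12, scientific = TRUE, trim = TRUE)
  lines <- c(as.character(H$n), H$labels,
             apply(M, 1, function(r) paste(fmt(r), collapse = " ")),
             vapply(seq_len(H$n), function(i)
               paste(H$labels[i], paste(fmt(H$mu[i, ]), collapse = " ")), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write spectral densities as two-column text
#'
#' `omega_cm-1  J_cm-1` per line; `#` comments allowed.
#' @param path file path.
#' @return a [spectral_density()].
#' @export
read_sd <- function(path) {
  d <- utils::read.table(path, comment.char = "#",
                         col.names = c("omega", "J"))
  spectral_density(d$omega, d$J)
}

#' @rdname read_sd
#' @param sd a [spectral_density()] to write.
#' @export
write_sd <- function(sd, path) {
  writeLines(c("# omega_cm-1 J_cm-1",
               paste(format(sd$omega, digits = 12, trim = TRUE),
                     format(sd$J, digits = 12, trim = TRUE))), path)
  invisible(path)
}

#' Read / write gap trajectories as plain text
#'
#' Header `dt_fs N_sites N_steps`, then one row of N_sites values per step.
#' @param path file path.
#' @return a [gap_trajectory()].
#' @export
read_trajectory <- function(path) {
  con <- file(path, "r"); on.exit(close(con))
  hd <- as.numeric(strsplit(trimws(readLines(con, 1)), "\\s+")[[1]])
  if (length(hd) != 3 || any(is.na(hd))) stop("malformed trajectory header")
  d <- utils::read.table(con, nrows = hd[3])
  if (ncol(d) != hd[2] || nrow(d) != hd[3]) stop("trajectory shape mismatch")
  gap_trajectory(as.matrix(d), dt = hd[1])
}

#' @rdname read_trajectory
#' @param traj a [gap_trajectory()] to write.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(format(traj$dt, digits = 12),
                   ncol(traj$series), nrow(traj$series)), con)
  utils::write.table(format(traj$series, digits = 12, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read point charges from a whitespace-separated file
#'
#' Lines of `q x y z` (charge in e, coordinates in Angstrom), `#` comments.
#' @param path file path.
#' @return a [charge_environment()].
#' @export
read_charges <- function(path) {
  d <- utils::read.table(path, comment.char = "#",
                         col.names = c("q", "x", "y", "z"))
  charge_environment(d$q, as.matrix(d[, c("x", "y", "z")]))
}

#' @rdname read_charges
#' @param env a [charge_environment()] to write.
#' @export
write_charges <- function(env, path) {
  writeLines(c("# q_e x_A y_A z_A",
               apply(cbind(env$charges, env$positions), 1, function(r)
                 paste(format(r, digits = 12, trim = TRUE), collapse = " "))),
             path)
  invisible(path)
}

#' Gas-phase and solution Qy energies of Chl-a/c1/c2 (literature table)
#'
#' Qy excitation energies (eV) of isolated chlorophyll a, c1 and c2 from a
#' hierarchy of electronic-structure methods and from solution experiments,
#' as tabulated in the FCP literature; the package only consumes these
#' numbers (difference arithmetic, ladder ranking), it never computes them.
#'
#' @return tibble with columns `method`, `pigment`, `energy_ev`.
#' @export
chl_gasphase_energies <- function() {
  tibble::tribble(
    ~method,                ~pigment,  ~energy_ev,
    "TD-LC-DFTB (gas phase)", "Chl-a",  2.197,
    "TD-LC-DFTB (gas phase)", "Chl-c1", 2.249,
    "TD-LC-DFTB (gas phase)", "Chl-c2", 2.224,
    "TD-LC-DFT (gas phase)",  "Chl-a",  2.239,
    "TD-LC-DFT (gas phase)",  "Chl-c1", 2.291,
    "TD-LC-DFT (gas phase)",  "Chl-c2", 2.262,
    "DFT/MRCI (gas phase)",   "Chl-a",  1.910,
    "DFT/MRCI (gas phase)",   "Chl-c1", 2.023,
    "DFT/MRCI (gas phase)",   "Chl-c2", 1.987,
    "QM/MM MD (ether)",       "Chl-a",  2.065,
    "QM/MM MD (ether)",       "Chl-c1", 2.082,
    "QM/MM MD (ether)",       "Chl-c2", 2.073,
    "QM/MM MD (acetone)",     "Chl-a",  2.049,
    "QM/MM MD (acetone)",     "Chl-c1", 2.060,
    "QM/MM MD (acetone)",     "Chl-c2", 2.050,
    "experiment (ether)",     "Chl-a",  1.873,
    "experiment (ether)",     "Chl-c1", 1.981,
    "experiment (ether)",     "Chl-c2", 1.977)
}

#' Homogeneous-field Stark scan of Chl-a/c1/c2 (literature table)
#'
#' Qy energies (eV) of the gas-phase-optimized pigments without a field and
#' with 0.01 au homogeneous fields along +/-x, +/-y, +/-z, as tabulated in
#' the FCP literature (TD-DFT values; consumed, not computed, here).
#'
#' @return a [field_scan()] with `field_au = 0.01`.
#' @export
chl_field_scan <- function() {
  d <- tibble::tribble(
    ~direction, ~`Chl-a`, ~`Chl-c1`, ~`Chl-c2`,
    "none", 2.243, 2.289, 2.263,
    "+x",   2.192, 2.252, 2.248,
    "+y",   2.268, 2.037, 2.035,
    "+z",   2.243, 2.287, 2.241,
    "-x",   2.249, 2.295, 2.243,
    "-y",   2.220, 2.285, 2.242,
    "-z",   2.239, 2.287, 2.278)
  long <- tidyr::pivot_longer(d, -"direction", names_to = "pigment",
                              values_to = "energy_ev")
  field_scan(long, field_au = 0.01)
}

#' Protein electric fields at Chl-c ring atoms (literature table)
#'
#' Electric-field components (au) produced by the protein environment at the
#' MG and NA-ND atoms of the Chl-c1 and Chl-c2 pigments of FCP, in the
#' pigment frame.  The positive-y components (boldface in the source table)
#' are the direction the Chl-c energies are most susceptible to.
#'
#' @return tibble with columns `pigment`, `atom`, `Fx`, `Fy`, `Fz`,
#'   `y_positive`.
#' @export
chl_protein_fields <- function() {
  d <- tibble::tribble(
    ~pigment, ~atom, ~Fx, ~Fy, ~Fz,
    "Chl-c1", "MG", -0.0056, 0.0003, 0.0354,
    "Chl-c2", "MG", -0.0016, 0.0031, -0.0102,
    "Chl-c1", "NA", -0.0020, 0.0115, 0.0049,
    "Chl-c2", "NA", 0.0032, 0.0220, 0.0011,
    "Chl-c1", "NB", 0.0055, -0.0002, 0.0056,
    "Chl-c2", "NB", 0.0178, -0.0055, -0.0044,
    "Chl-c1", "NC", -0.0085, -0.0057, 0.0054,
    "Chl-c2", "NC", -0.0075, -0.0170, -0.0034,
    "Chl-c1", "ND", -0.0108, 0.0021, 0.0033,
    "Chl-c2", "ND", -0.0193, 0.0103, 0.0003)
  d$y_positive <- d$Fy > 0
  d
}

#' Run the full synthetic analysis pipeline
#'
#' Generates an FCP-like network, evaluates the stages of the analysis chain
#' (energy ladder, field report at the first c-pool pigment, cumulant
#' absorption with pool decomposition and 800 cm^-1 truncation, pool-to-pool
#' population transfer) and writes CSV artifacts plus a log to `out_dir`.
#' Identical `(config, seed)` give byte-identical outputs.
#'
#' @param out_dir output directory (created if missing).
#' @param seed master seed.
#' @param temperature K.
#' @param truncation_cm1 spectral-density truncation cutoff (NULL = off).
#' @param n_real ensemble size for population transfer.
#' @param horizon_fs population-transfer horizon (fs).
#' @param spec a [network_spec()].
#' @return named list of file paths, invisibly.
#' @export
run_pipeline <- function(out_dir, seed = 1, temperature = 300,
                         truncation_cm1 = 800, n_real = 10,
                         horizon_fs = 1000, spec = network_spec()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  logcon <- file(logf, "w"); on.exit(close(logcon))
  say <- function(...) writeLines(paste0(format(Sys.time(), "%H:%M:%S "), ...),
                                  logcon)
  say("pipeline start: seed=", seed, " T=", temperature, "K")
  net <- make_network(spec, seed = seed)
  H <- net$H
  paths <- list()
  wr <- function(x, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(x, p, row.names = FALSE)
    paths[[name]] <<- p
    say("wrote ", name)
  }
  wr(energy_ladder(H$E, H$labels), "ladder.csv")
  cpig <- net$pigments[[which(unname(H$pools) == "c_pool")[1]]]
  rf <- ring_frame(cpig)
  env <- make_environment(c(0, 0.022, 0),
                          probe = rf$pigment$atoms[["NA"]], seed = seed)
  wr(field_report(env, rf$pigment), "field_report.csv")
  sds <- fcp_default_sds()
  spec_full <- pool_decomposition(H, sds, temperature)
  wr(as.data.frame(spec_full), "absorption.csv")
  if (!is.null(truncation_cm1)) {
    sds_tr <- lapply(sds, truncate_sd, cutoff = truncation_cm1)
    wr(as.data.frame(absorption_cumulant(H, sds_tr, temperature)),
       "absorption_truncated.csv")
  }
  ens <- make_ensemble(H, sds, temperature, n_real = n_real, seed = seed)
  wr(as.data.frame(pool_transfer(ens, horizon_fs)), "populations.csv")
  say("pipeline done")
  invisible(paths)
}
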