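# Fixture builders: internal-to-Cartesian backbone construction (NeRF chain
# extension with ideal peptide geometry) and rigid-motion/noise trajectories.

# Ideal backbone geometry (Angstrom / degrees), standard peptide values.
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N <- 1.329
BOND_C_O <- 1.231
BOND_CA_CB <- 1.521
ANGLE_N_CA_C <- 111.0
ANGLE_CA_C_N <- 116.6
ANGLE_C_N_CA <- 121.7
ANGLE_CA_C_O <- 120.8
ANGLE_C_CA_CB <- 110.1

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

new_structure <- function(df) {
  out <- as_tibble(df)
  class(out) <- c("structure_tbl", class(out))
  out
}

#' Build an ideal-geometry backbone from dihedral angles
#'
#' Extends a peptide chain atom by atom (natural-extension reference frame)
#' using ideal bond lengths and angles, so that the built coordinates
#' reproduce the requested phi/psi/omega exactly (round-trip within 1
#' degree). Atoms N, CA, C, O are placed for every residue, plus CB for
#' non-glycine. Omega defaults to 180 (trans); use omega = 0 for a cis
#' peptide bond (e.g. cis-proline).
#'
#' @param residues Data frame with columns `name` (3-letter residue code),
#'   `phi`, `psi` and optionally `omega` (degrees in (-180, 180]). `phi` of
#'   the first residue and `psi` of the last are not structurally determined
#'   but `psi` of the last residue still orients its carbonyl oxygen.
#' @param chain Chain id for the output. Default `"A"`.
#' @return A `structure_tbl` tibble with columns `chain`, `resno`,
#'   `resname`, `atom`, `element`, `x`, `y`, `z` (Angstrom).
#' @examples
#' helix <- build_backbone_from_dihedrals(
#'   data.frame(name = "ALA", phi = -57, psi = -47)[rep(1, 12), ])
#' @export
build_backbone_from_dihedrals <- function(residues, chain = "A") {
  residues <- as_tibble(residues)
  stop_if_not(nrow(residues) >= 2, "need at least 2 residues")
  residues$name <- toupper(residues$name)
  bad <- setdiff(unique(residues$name), AA3)
  stop_if_not(length(bad) == 0, "unknown residue name(s): %s",
              paste(bad, collapse = ", "))
  if (!"omega" %in% names(residues)) residues$omega <- 180
  residues$omega[is.na(residues$omega)] <- 180
  ang <- c(residues$phi, residues$psi, residues$omega)
  stop_if_not(all(is.na(ang) | (ang > -180 & ang <= 180)),
              "angles must lie in (-180, 180]")

  n <- nrow(residues)
  N <- CA <- C <- O <- vector("list", n)
  # residue 1 in a canonical frame
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(BOND_N_CA, 0, 0)
  th <- ANGLE_N_CA_C * pi / 180
  C[[1]] <- CA[[1]] + BOND_CA_C * c(cos(pi - th), sin(pi - th), 0)

  phi <- residues$phi
  psi <- residues$psi
  omg <- residues$omega
  for (i in seq_len(n - 1)) {
    N[[i + 1]] <- nerf_place(N[[i]], CA[[i]], C[[i]], BOND_C_N,
                             ANGLE_CA_C_N, psi[i])
    CA[[i + 1]] <- nerf_place(CA[[i]], C[[i]], N[[i + 1]], BOND_N_CA,
                              ANGLE_C_N_CA, omg[i + 1])
    C[[i + 1]] <- nerf_place(C[[i]], N[[i + 1]], CA[[i + 1]], BOND_CA_C,
                             ANGLE_N_CA_C, phi[i + 1])
  }
  for (i in seq_len(n)) {
    # carbonyl O lies opposite the next N across the C; for the final
    # residue the supplied psi orients it the same way
    psi_i <- if (is.na(psi[i])) 180 else psi[i]
    O[[i]] <- nerf_place(N[[i]], CA[[i]], C[[i]], BOND_C_O, ANGLE_CA_C_O,
                         wrap_angle(psi_i + 180))
  }

  rows <- list()
  for (i in seq_len(n)) {
    atoms <- list(N = N[[i]], CA = CA[[i]], C = C[[i]], O = O[[i]])
    if (residues$name[i] != "GLY") {
      # improper torsion N-C-CA-CB ~ +122.6 deg selects the L-configuration
      atoms$CB <- nerf_place(N[[i]], C[[i]], CA[[i]], BOND_CA_CB,
                             ANGLE_C_CA_CB, 122.6)
    }
    rows[[i]] <- tibble(
      chain = chain, resno = i, resname = residues$name[i],
      atom = names(atoms),
      element = substr(names(atoms), 1, 1),
      x = unname(map_dbl(atoms, 1)), y = unname(map_dbl(atoms, 2)),
      z = unname(map_dbl(atoms, 3))
    )
  }
  new_structure(dplyr::bind_rows(rows))
}

euler_rotation <- function(angles_deg) {
  a <- angles_deg * pi / 180
  rz <- matrix(c(cos(a[1]), -sin(a[1]), 0, sin(a[1]), cos(a[1]), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  ry <- matrix(c(cos(a[2]), 0, sin(a[2]), 0, 1, 0, -sin(a[2]), 0, cos(a[2])),
               3, 3, byrow = TRUE)
  rx <- matrix(c(1, 0, 0, 0, cos(a[3]), -sin(a[3]), 0, sin(a[3]), cos(a[3])),
               3, 3, byrow = TRUE)
  rz %*% ry %*% rx
}

new_trajectory <- function(topology, frames, times) {
  stop_if_not(length(frames) == length(times), "one time per frame")
  stop_if_not(all(diff(times) >= 0), "frame times must be non-decreasing")
  nat <- nrow(topology)
  ok <- vapply(frames, function(f) nrow(f) == nat, TRUE)
  stop_if_not(all(ok), "frame atom counts inconsistent with topology")
  structure(list(topology = topology, frames = frames,
                 times = as.double(times)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms, %g-%g ns\n",
              length(x$frames), nrow(x$topology),
              min(x$times), max(x$times)))
  invisible(x)
}

structure_coords <- function(s) as.matrix(s[, c("x", "y", "z")])

set_coords <- function(s, m) {
  s$x <- m[, 1]; s$y <- m[, 2]; s$z <- m[, 3]
  s
}

#' Generate a trajectory by rigid motion plus coordinate noise
#'
#' Each frame is the input structure under a fixed rotation/translation, with
#' isotropic Gaussian noise added per atom coordinate. The first frame is
#' noise-free, so it equals the rigid transform of the input exactly.
#'
#' @param s A `structure_tbl`.
#' @param rotation Euler angles (z, y, x) in degrees.
#' @param translation Length-3 translation in Angstrom.
#' @param noise_sigma Per-coordinate Gaussian sigma in Angstrom (>= 0).
#' @param n_frames Number of frames (>= 1).
#' @param dt_ns Time step between frames in ns.
#' @param seed Integer seed.
#' @return A `trajectory`.
#' @export
perturb_structure <- function(s, rotation = c(0, 0, 0),
                              translation = c(0, 0, 0), noise_sigma = 0,
                              n_frames = 1, dt_ns = 1, seed = 1L) {
  stop_if_not(n_frames >= 1, "n_frames must be >= 1")
  stop_if_not(noise_sigma >= 0, "noise_sigma must be >= 0")
  seed_rng(seed)
  rot <- euler_rotation(rotation)
  base <- structure_coords(s) %*% t(rot) +
    matrix(translation, nrow(s), 3, byrow = TRUE)
  frames <- lapply(seq_len(n_frames), function(k) {
    if (k == 1 || noise_sigma == 0) base
    else base + matrix(rnorm(length(base), 0, noise_sigma), nrow(base), 3)
  })
  new_trajectory(s, frames, times = (seq_len(n_frames) - 1) * dt_ns)
}
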