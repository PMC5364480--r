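# Geometry engine: selections, Kabsch superposition, trajectory RMSD,
# Shrake-Rupley solvent accessibility, and backbone dihedrals.

#' Select atoms of a structure
#'
#' @param structure A `structure_tbl`.
#' @param chain Optional chain id(s).
#' @param resno Optional residue numbers (author numbering; use e.g.
#'   `98:111` for a closed range).
#' @param atoms Optional atom names (e.g. `"CA"` for C-alpha only).
#' @return Integer row indices into `structure`.
#' @export
atom_select <- function(structure, chain = NULL, resno = NULL, atoms = NULL) {
  keep <- rep(TRUE, nrow(structure))
  if (!is.null(chain)) keep <- keep & structure$chain %in% chain
  if (!is.null(resno)) keep <- keep & structure$resno %in% resno
  if (!is.null(atoms)) keep <- keep & structure$atom %in% atoms
  which(keep)
}

as_coords <- function(x) {
  if (is.matrix(x)) x else structure_coords(x)
}

#' Kabsch superposition
#'
#' Least-squares optimal rigid alignment of a mobile atom set onto a
#' reference: the returned proper rotation (det = +1) and translation
#' minimise the RMSD over the selected atom pairs, and the reported RMSD is
#' measured after applying them.
#'
#' @param mobile,reference `structure_tbl` objects or N x 3 coordinate
#'   matrices with matching atom order.
#' @param selection Optional list of [atom_select()] arguments (`chain`,
#'   `resno`, `atoms`) applied to both structures; requires equal selected
#'   counts.
#' @return List with `rotation` (3 x 3), `translation` (length 3; the
#'   superposed mobile coordinates are `mobile %*% t(rotation) +
#'   translation`), and `rmsd` in Angstrom.
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  sel_m <- sel_r <- NULL
  if (!is.null(selection)) {
    stop_if_not(!is.matrix(mobile) && !is.matrix(reference),
                "selections need structure tables, not bare matrices")
    sel_m <- do.call(atom_select, c(list(mobile), selection))
    sel_r <- do.call(atom_select, c(list(reference), selection))
  }
  P <- as_coords(mobile); Q <- as_coords(reference)
  if (!is.null(sel_m)) { P <- P[sel_m, , drop = FALSE] }
  if (!is.null(sel_r)) { Q <- Q[sel_r, , drop = FALSE] }
  stop_if_not(nrow(P) == nrow(Q),
              "selection yields unequal atom counts (%d vs %d)",
              nrow(P), nrow(Q))
  stop_if_not(nrow(P) >= 3, "need at least 3 atom pairs, got %d", nrow(P))
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  sv_ref <- svd(Q0)$d
  stop_if_not(sv_ref[2] > 1e-8 * max(sv_ref[1], 1),
              "selected reference atoms are collinear")
  H <- t(P0) %*% Q0
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  translation <- unname(cq - as.vector(R %*% cp))
  P_fit <- P %*% t(R) + matrix(translation, nrow(P), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((P_fit - Q)^2)))
  list(rotation = R, translation = translation, rmsd = rmsd)
}

#' RMSD of each atom-pair set without fitting
#' @param a,b Coordinate matrices or structures with matching atom order.
#' @return RMSD in Angstrom.
#' @export
coord_rmsd <- function(a, b) {
  A <- as_coords(a); B <- as_coords(b)
  stop_if_not(nrow(A) == nrow(B), "atom counts differ")
  sqrt(mean(rowSums((A - B)^2)))
}

#' Per-frame RMSD of a trajectory against a reference
#'
#' Reports one RMSD value per frame over the selected atoms (e.g. C-alpha
#' atoms of a subdomain residue range), optionally after Kabsch superposition
#' of each frame onto the reference.
#'
#' @param traj A `trajectory`.
#' @param reference Frame index (default 1) or a `structure_tbl` with the
#'   same atom order as the topology.
#' @param selection Optional list of [atom_select()] arguments.
#' @param superpose Superpose each frame on the reference over the selection
#'   before measuring? Default `TRUE`.
#' @return A tibble (class `trajectory_rmsd`) with `frame`, `time_ns`,
#'   `rmsd`.
#' @export
trajectory_rmsd <- function(traj, reference = 1, selection = NULL,
                            superpose = TRUE) {
  topo <- traj$topology
  sel <- if (is.null(selection)) seq_len(nrow(topo)) else
    do.call(atom_select, c(list(topo), selection))
  stop_if_not(length(sel) > 0, "empty selection")
  ref_coords <- if (is.numeric(reference) && length(reference) == 1) {
    traj$frames[[reference]]
  } else {
    as_coords(reference)
  }
  Q <- ref_coords[sel, , drop = FALSE]
  vals <- map_dbl(traj$frames, function(f) {
    P <- f[sel, , drop = FALSE]
    if (superpose) kabsch_superpose(P, Q)$rmsd else coord_rmsd(P, Q)
  })
  out <- tibble(frame = seq_along(traj$frames), time_ns = traj$times,
                rmsd = vals)
  class(out) <- c("trajectory_rmsd", class(out))
  out
}

# van der Waals radii (Angstrom) by element; overridable in sasa().
DEFAULT_VDW <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8, H = 1.2, P = 1.8)

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over the structure using a deterministic
#' golden-spiral point quadrature on each atom sphere: a surface point is
#' accessible if it lies outside every neighbouring atom's probe-expanded
#' sphere.
#'
#' @param structure A `structure_tbl`. Only the atoms present occlude; to
#'   compute the SASA of a chain alone, subset the structure first.
#' @param probe_radius Probe radius in Angstrom (water: 1.4).
#' @param n_points Quadrature points per atom (>= 100; 960 gives ~1%
#'   accuracy).
#' @param selection Optional [atom_select()] argument list restricting which
#'   atoms' areas are reported (all atoms still occlude).
#' @param radii Named vector of van der Waals radii by element, merged over
#'   the built-in table (C 1.7, N 1.55, O 1.52, S 1.8, H 1.2, P 1.8).
#'   Unknown elements without an override are an error.
#' @return Object of class `sasa_result`: list with `total` (Angstrom^2),
#'   `per_residue` and `per_atom` tibbles.
#' @export
sasa <- function(structure, probe_radius = 1.4, n_points = 960,
                 selection = NULL, radii = NULL) {
  stop_if_not(n_points >= 100, "n_points must be >= 100")
  rad_table <- DEFAULT_VDW
  if (!is.null(radii)) rad_table[names(radii)] <- radii
  elem <- toupper(structure$element)
  unknown <- setdiff(unique(elem), names(rad_table))
  stop_if_not(length(unknown) == 0,
              "no radius for element(s): %s (supply `radii`)",
              paste(unknown, collapse = ", "))
  r <- unname(rad_table[elem]) + probe_radius
  xyz <- structure_coords(structure)
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  report <- if (is.null(selection)) seq_len(n) else
    do.call(atom_select, c(list(structure), selection))

  d2 <- as.matrix(stats::dist(xyz))^2
  area <- numeric(n)
  for (i in report) {
    neigh <- which(d2[i, ] < (r[i] + r)^2 & seq_len(n) != i)
    sp <- pts * r[i] + matrix(xyz[i, ], n_points, 3, byrow = TRUE)
    acc <- rep(TRUE, n_points)
    for (j in neigh) {
      if (!any(acc)) break
      if (d2[i, j] < 1e-12 && r[j] == r[i]) {
        # coincident equal spheres: the lower-index atom owns the surface
        if (j < i) acc[] <- FALSE
        next
      }
      dj2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
        (sp[, 3] - xyz[j, 3])^2
      acc <- acc & dj2 >= r[j]^2 - 1e-9
    }
    area[i] <- 4 * pi * r[i]^2 * mean(acc)
  }
  per_atom <- tibble(
    chain = structure$chain[report], resno = structure$resno[report],
    resname = structure$resname[report], atom = structure$atom[report],
    area = area[report]
  )
  per_residue <- per_atom %>%
    group_by(.data$chain, .data$resno, .data$resname) %>%
    summarise(area = sum(.data$area), .groups = "drop")
  out <- list(total = sum(per_atom$area), per_residue = per_residue,
              per_atom = per_atom,
              probe_radius = probe_radius, n_points = n_points)
  class(out) <- "sasa_result"
  out
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> total %.2f A^2 over %d atoms (probe %.2f A, %d points)\n",
              x$total, nrow(x$per_atom), x$probe_radius, x$n_points))
  invisible(x)
}

#' @export
tidy.sasa_result <- function(x, ...) x$per_residue

#' @export
glance.sasa_result <- function(x, ...) {
  tibble(total = x$total, n_atoms = nrow(x$per_atom),
         probe_radius = x$probe_radius, n_points = x$n_points)
}

#' Backbone dihedral angles
#'
#' Computes phi, psi and omega per residue (IUPAC sign convention, degrees).
#' Phi of the first residue, psi of the last, and any angle spanning a chain
#' gap (peptide C-N distance > 1.8 Angstrom) are reported `NA` rather than
#' interpolated. Omega of residue i describes its preceding peptide bond
#' (CA(i-1), C(i-1), N(i), CA(i)); values near 0 indicate a cis bond.
#'
#' @param structure A `structure_tbl`.
#' @param chain Chain id; default the first chain present.
#' @return A tibble with `chain`, `resno`, `resname`, `phi`, `psi`, `omega`.
#' @export
backbone_dihedrals <- function(structure, chain = NULL) {
  chain <- chain %||% structure$chain[1]
  s <- structure[structure$chain == chain, , drop = FALSE]
  resnos <- sort(unique(s$resno))
  getat <- function(resno, atom) {
    i <- which(s$resno == resno & s$atom == atom)
    if (length(i) == 0) return(NULL)
    c(s$x[i[1]], s$y[i[1]], s$z[i[1]])
  }
  bonded <- function(r1, r2) {
    # consecutive numbering and a peptide-bond-length C-N link
    c1 <- getat(r1, "C"); n2 <- getat(r2, "N")
    !is.null(c1) && !is.null(n2) && r2 == r1 + 1 && vnorm(n2 - c1) < 1.8
  }
  rows <- lapply(seq_along(resnos), function(k) {
    r <- resnos[k]
    rp <- if (k > 1) resnos[k - 1] else NA
    rn <- if (k < length(resnos)) resnos[k + 1] else NA
    Np <- getat(r, "N"); CAp <- getat(r, "CA"); Cp <- getat(r, "C")
    phi <- psi <- omega <- NA_real_
    if (!is.null(Np) && !is.null(CAp) && !is.null(Cp)) {
      if (!is.na(rp) && bonded(rp, r)) {
        Cm <- getat(rp, "C")
        phi <- dihedral_angle(Cm, Np, CAp, Cp)
        CAm <- getat(rp, "CA")
        if (!is.null(CAm)) omega <- dihedral_angle(CAm, Cm, Np, CAp)
      }
      if (!is.na(rn) && bonded(r, rn)) {
        Nn <- getat(rn, "N")
        psi <- dihedral_angle(Np, CAp, Cp, Nn)
      }
    }
    tibble(chain = chain, resno = r,
           resname = s$resname[match(r, s$resno)],
           phi = phi, psi = psi, omega = omega)
  })
  dplyr::bind_rows(rows)
}
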