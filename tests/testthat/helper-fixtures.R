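# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

# small deterministic network with a loop
toy_pin <- function() {
  pin(
    data.frame(node_a = c("SEP3", "SEP3", "AP1", "AG"),
               node_b = c("AP1", "AG", "SVP", "AG")),
    nodes = c("SEP3", "AP1", "AG", "SVP", "AP3"),
    epoch_label = "toy", time_mya = 10
  )
}

# ideal helix fixture
helix_fixture <- function(n = 12) {
  build_backbone_from_dihedrals(
    data.frame(name = "ALA", phi = -57, psi = -47)[rep(1, n), ]
  )
}

# four-residue window embedded in extended flanks, with given inner
# dihedrals (phi1, psi1, phi2, psi2) and optional cis bond at i+2
turn_fixture <- function(phi1, psi1, phi2, psi2, cis_i2 = FALSE,
                         res = c("ALA", "ALA", "ALA", "ALA")) {
  build_backbone_from_dihedrals(data.frame(
    name = res,
    phi = c(NA, phi1, phi2, -120),
    psi = c(130, psi1, psi2, NA),
    omega = c(180, 180, if (cis_i2) 0 else 180, 180)
  ))
}

# place single atoms at explicit coordinates
atoms_at <- function(df) {
  defaults <- list(chain = "A", resno = 1L, resname = "ALA", atom = "X",
                   element = "C")
  for (nm in names(defaults)) {
    if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  }
  pinflex:::new_structure(tibble::as_tibble(
    df[, c("chain", "resno", "resname", "atom", "element", "x", "y", "z")]))
}

# uniform random rotation matrix (quaternion method)
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# rmsd over rotations of centered clouds, with optimal translation:
# rmsd^2(R) = (sum|P0|^2 + sum|Q0|^2 - 2 tr(R H)) / N, H = sum p q^T
brute_force_min_rmsd <- function(P, Q, n_rot = 10000) {
  P0 <- sweep(P, 2, colMeans(P))
  Q0 <- sweep(Q, 2, colMeans(Q))
  H <- t(P0) %*% Q0
  cc <- sum(P0^2) + sum(Q0^2)
  n <- nrow(P)
  vals <- vapply(seq_len(n_rot), function(i) {
    R <- random_rotation()
    sqrt(max(0, (cc - 2 * sum(diag(R %*% H))) / n))
  }, 0)
  min(vals)
}
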