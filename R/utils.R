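# Shared helpers: edge canonicalisation, argument checks, 3D geometry.

# Gas constant in cal mol^-1 K^-1 (entropies are molar).
GAS_CONSTANT_CAL <- 1.98720

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Canonicalise an unordered edge table
#'
#' Orders each pair lexicographically so that `(a, b)` and `(b, a)` denote the
#' same undirected edge, then drops duplicates. Self-pairs (homodimer loops)
#' are kept.
#'
#' @param edges A data frame with columns `node_a`, `node_b` (and optionally
#'   `weight`).
#' @return A tibble with canonical `node_a <= node_b` ordering, deduplicated.
#' @export
canonical_edges <- function(edges) {
  if (nrow(edges) == 0) {
    return(tibble(node_a = character(), node_b = character(),
                  weight = double()))
  }
  a <- as.character(edges$node_a)
  b <- as.character(edges$node_b)
  swap <- a > b
  out <- tibble(
    node_a = ifelse(swap, b, a),
    node_b = ifelse(swap, a, b),
    weight = if ("weight" %in% names(edges)) as.double(edges$weight) else
      NA_real_
  )
  out %>%
    dplyr::group_by(.data$node_a, .data$node_b) %>%
    dplyr::summarise(weight = .data$weight[1], .groups = "drop") %>%
    dplyr::arrange(.data$node_a, .data$node_b)
}

edge_key <- function(edges) paste(edges$node_a, edges$node_b, sep = "\r")

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) abort(sprintf(msg, ...))
}

# ---- 3D geometry -----------------------------------------------------------

vcross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

vnorm <- function(u) sqrt(sum(u^2))

unit <- function(u) u / vnorm(u)

#' Dihedral angle of four points
#'
#' IUPAC sign convention: looking from `p2` to `p3`, the angle is positive for
#' a clockwise rotation of the far bond.
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors (Angstrom).
#' @return Angle in degrees in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- -atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

bond_angle <- function(p1, p2, p3) {
  u <- unit(p1 - p2)
  v <- unit(p3 - p2)
  acos(pmin(1, pmax(-1, sum(u * v)))) * 180 / pi
}

# Natural-extension (NeRF) placement: position a fourth atom D given A-B-C,
# the C-D bond length, the B-C-D angle and the A-B-C-D torsion (degrees).
nerf_place <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d2 <- c(bond * cos(pi - ang),
          bond * cos(tor) * sin(pi - ang),
          bond * sin(tor) * sin(pi - ang))
  bc <- unit(c - b)
  n <- unit(vcross(b - a, bc))
  m <- cbind(bc, vcross(n, bc), n)
  as.vector(m %*% d2 + c)
}

# Deterministic quasi-uniform points on the unit sphere (golden-spiral /
# Fibonacci lattice); used by the SASA quadrature.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  ifelse(y <= -180, y + 360, y)
}

# Smallest absolute circular difference between two angles in degrees.
angle_diff <- function(a, b) abs(wrap_angle(a - b))
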