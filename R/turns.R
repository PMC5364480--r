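# Turn classification and polar-contact detection.
#
# Beta-turns follow the Hutchinson-Thornton convention: a four-residue window
# with CA(i)-CA(i+3) < 7 A that is not part of an alpha-helix is a turn; the
# inner-residue (phi, psi) pairs are matched against the canonical type table
# within a tolerance (one angle may deviate up to 45 degrees), a cis peptide
# bond at i+2 restricting candidates to the type VI classes. Windows passing
# the gate but matching no canonical type are type IV. Gamma (3-residue) and
# alpha (5-residue) turns use analogous distance gates; their "pseudo"
# variants (gate passes, no canonical angle match) are implementation
# definitions.

# canonical (phi1, psi1, phi2, psi2) by beta-turn type; VI types need a cis
# bond at i+2
BETA_TURN_TABLE <- list(
  "I"    = c(-60, -30, -90, 0),
  "I'"   = c(60, 30, 90, 0),
  "II"   = c(-60, 120, 80, 0),
  "II'"  = c(60, -120, -80, 0),
  "VIa1" = c(-60, 120, -90, 0),
  "VIa2" = c(-120, 120, -60, 0),
  "VIb"  = c(-135, 135, -75, 160)
)
CIS_TYPES <- c("VIa1", "VIa2", "VIb")

# classic gamma-turn and inverse gamma-turn inner-residue angles
GAMMA_TABLE <- list("classic" = c(75, -64), "inverse" = c(-79, 69))

is_helical <- function(phi, psi) {
  !is.na(phi) & !is.na(psi) & phi > -100 & phi < -30 & psi > -70 & psi < -25
}

# canonical-angle match: all deviations <= tol, allowing a single angle up
# to relax (Hutchinson-Thornton one-angle relaxation)
angles_match <- function(obs, canon, tol, relax = 45) {
  d <- angle_diff(obs, canon)
  if (any(is.na(d))) return(FALSE)
  sum(d > tol) <= 1 && all(d <= relax)
}

#' Classify backbone turns
#'
#' Scans a chain for beta-turns (4 residues), gamma-turns (3 residues) and
#' alpha-turns (5 residues). Beta-turns require CA(i)-CA(i+3) < 7 Angstrom
#' and a window not lying in an alpha-helix; inner dihedrals are matched
#' against the canonical type table (I, I', II, II', and the cis-proline
#' types VIa1/VIa2/VIb when the i+1 to i+2 peptide bond is cis) within
#' `tolerance` degrees (one angle may deviate up to 45); unmatched windows
#' are type IV. The stabilizing i to i+3 hydrogen bond (N(i+3)-O(i)
#' heavy-atom distance) is attached when below `hbond_cutoff`. Gamma turns
#' gate on CA(i)-CA(i+2) < 5.4 A, alpha turns on CA(i)-CA(i+4) < 6.5 A with
#' non-helical flanks; canonical-angle failures are labelled pseudo-gamma /
#' pseudo-alpha.
#'
#' @param struct A `structure_tbl`.
#' @param chain Chain id; default the first chain.
#' @param tolerance Canonical-angle tolerance in degrees (> 0).
#' @param hbond_cutoff Heavy-atom H-bond distance cutoff in Angstrom.
#' @return A tibble (class `turn_assignments`): `chain`, `start_resno`,
#'   `length`, `type`, inner dihedrals `phi1`, `psi1`, `phi2`, `psi2` (and
#'   `phi3`, `psi3` for alpha-turns), `hbond_dist`.
#' @export
classify_turns <- function(struct, chain = NULL, tolerance = 30,
                           hbond_cutoff = 3.5) {
  stop_if_not(tolerance > 0, "tolerance must be > 0")
  chain <- chain %||% struct$chain[1]
  dh <- backbone_dihedrals(struct, chain)
  s <- struct[struct$chain == chain, , drop = FALSE]
  resnos <- dh$resno
  coord_of <- function(resno, atom) {
    i <- which(s$resno == resno & s$atom == atom)
    if (length(i) == 0) return(NULL)
    c(s$x[i[1]], s$y[i[1]], s$z[i[1]])
  }
  ca_dist <- function(r1, r2) {
    a <- coord_of(r1, "CA"); b <- coord_of(r2, "CA")
    if (is.null(a) || is.null(b)) return(NA_real_)
    vnorm(a - b)
  }
  hel <- is_helical(dh$phi, dh$psi)
  consecutive <- function(idx) all(diff(resnos[idx]) == 1)

  out <- list()
  n <- length(resnos)

  # beta-turns (i .. i+3)
  for (k in seq_len(max(0, n - 3))) {
    idx <- k:(k + 3)
    if (!consecutive(idx)) next
    d <- ca_dist(resnos[k], resnos[k + 3])
    if (is.na(d) || d >= 7) next
    # helix exclusion on the inner residues: a window inside an alpha-helix
    # is not a turn
    if (hel[k + 1] && hel[k + 2]) next
    phi1 <- dh$phi[k + 1]; psi1 <- dh$psi[k + 1]
    phi2 <- dh$phi[k + 2]; psi2 <- dh$psi[k + 2]
    if (any(is.na(c(phi1, psi1, phi2, psi2)))) next
    cis2 <- !is.na(dh$omega[k + 2]) && abs(dh$omega[k + 2]) < 30
    cands <- if (cis2) CIS_TYPES else setdiff(names(BETA_TURN_TABLE),
                                              CIS_TYPES)
    obs <- c(phi1, psi1, phi2, psi2)
    scores <- map_dbl(cands, function(ty)
      sum(angle_diff(obs, BETA_TURN_TABLE[[ty]])))
    hits <- vapply(cands, function(ty)
      angles_match(obs, BETA_TURN_TABLE[[ty]], tolerance), TRUE)
    type <- if (any(hits)) cands[hits][which.min(scores[hits])] else "IV"
    hb <- {
      nO <- coord_of(resnos[k], "O"); nN <- coord_of(resnos[k + 3], "N")
      if (!is.null(nO) && !is.null(nN)) vnorm(nN - nO) else NA_real_
    }
    out[[length(out) + 1]] <- tibble(
      chain = chain, start_resno = resnos[k], length = 4L, type = type,
      phi1 = phi1, psi1 = psi1, phi2 = phi2, psi2 = psi2,
      phi3 = NA_real_, psi3 = NA_real_,
      hbond_dist = if (!is.na(hb) && hb < hbond_cutoff) hb else NA_real_
    )
  }

  beta_windows <- if (length(out))
    dplyr::bind_rows(out)[, c("start_resno", "length")] else NULL

  # gamma-turns (i .. i+2): distance gate plus the stabilizing i -> i+2
  # H-bond; windows lying inside a reported beta-turn are suppressed
  for (k in seq_len(max(0, n - 2))) {
    idx <- k:(k + 2)
    if (!consecutive(idx)) next
    d <- ca_dist(resnos[k], resnos[k + 2])
    if (is.na(d) || d >= 6.0) next
    if (any(hel[idx])) next
    phi1 <- dh$phi[k + 1]; psi1 <- dh$psi[k + 1]
    if (any(is.na(c(phi1, psi1)))) next
    if (!is.null(beta_windows) &&
        any(resnos[k] >= beta_windows$start_resno &
              resnos[k + 2] <= beta_windows$start_resno +
              beta_windows$length - 1)) next
    hb <- {
      nO <- coord_of(resnos[k], "O"); nN <- coord_of(resnos[k + 2], "N")
      if (!is.null(nO) && !is.null(nN)) vnorm(nN - nO) else NA_real_
    }
    if (is.na(hb) || hb >= hbond_cutoff) next
    hits <- vapply(GAMMA_TABLE, function(canon)
      angles_match(c(phi1, psi1), canon, tolerance, relax = 45), TRUE)
    type <- if (any(hits)) "\u03b3" else "pseudo-\u03b3"
    out[[length(out) + 1]] <- tibble(
      chain = chain, start_resno = resnos[k], length = 3L, type = type,
      phi1 = phi1, psi1 = psi1, phi2 = NA_real_, psi2 = NA_real_,
      phi3 = NA_real_, psi3 = NA_real_,
      hbond_dist = if (!is.na(hb) && hb < hbond_cutoff) hb else NA_real_
    )
  }

  # alpha-turns (i .. i+4); skip windows continuing a longer helix
  for (k in seq_len(max(0, n - 4))) {
    idx <- k:(k + 4)
    if (!consecutive(idx)) next
    d <- ca_dist(resnos[k], resnos[k + 4])
    if (is.na(d) || d >= 6.5) next
    flank_hel <- (k > 1 && hel[k - 1] && resnos[k] - resnos[k - 1] == 1) ||
      (k + 5 <= n && hel[k + 5] && resnos[k + 5] - resnos[k + 4] == 1)
    if (flank_hel) next
    inner <- c(dh$phi[k + 1], dh$psi[k + 1], dh$phi[k + 2], dh$psi[k + 2],
               dh$phi[k + 3], dh$psi[k + 3])
    if (any(is.na(inner))) next
    canon <- rep(c(-60, -30), 3)
    type <- if (angles_match(inner, canon, tolerance, relax = 45))
      "\u03b1" else "pseudo-\u03b1"
    hb <- {
      nO <- coord_of(resnos[k], "O"); nN <- coord_of(resnos[k + 4], "N")
      if (!is.null(nO) && !is.null(nN)) vnorm(nN - nO) else NA_real_
    }
    out[[length(out) + 1]] <- tibble(
      chain = chain, start_resno = resnos[k], length = 5L, type = type,
      phi1 = inner[1], psi1 = inner[2], phi2 = inner[3], psi2 = inner[4],
      phi3 = inner[5], psi3 = inner[6],
      hbond_dist = if (!is.na(hb) && hb < hbond_cutoff) hb else NA_real_
    )
  }

  res <- if (length(out)) dplyr::bind_rows(out) else
    tibble(chain = character(), start_resno = integer(), length = integer(),
           type = character(), phi1 = double(), psi1 = double(),
           phi2 = double(), psi2 = double(), phi3 = double(),
           psi3 = double(), hbond_dist = double())
  res <- arrange(res, .data$start_resno, .data$length)
  class(res) <- c("turn_assignments", class(res))
  res
}

# side-chain charge centers
ACIDIC_O <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
BASIC_N <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                HIS = c("ND1", "NE2"))

#' Detect salt bridges and hydrogen bonds
#'
#' A salt bridge is recorded for each Asp/Glu - Arg/Lys/His residue pair
#' whose closest carboxylate-oxygen to side-chain-nitrogen distance is below
#' `salt_bridge_cutoff`; the minimal distance and its atom pair are
#' reported. Hydrogen bonds are heavy-atom N/O-N/O pairs from different,
#' non-adjacent-backbone residues below `hbond_cutoff` (no angle term;
#' distances are what the underlying experiments report).
#'
#' @param struct A `structure_tbl` with side-chain atoms present for the
#'   charged residues.
#' @param salt_bridge_cutoff Angstrom; default 4.0.
#' @param hbond_cutoff Angstrom; default 3.5.
#' @param include_hbonds Also report hydrogen bonds? Default `TRUE`.
#' @return A tibble (class `contact_records`) with partner atom identifiers,
#'   `distance` and `kind`.
#' @export
detect_polar_contacts <- function(struct, salt_bridge_cutoff = 4.0,
                                  hbond_cutoff = 3.5,
                                  include_hbonds = TRUE) {
  xyz <- structure_coords(struct)
  res_id <- paste(struct$chain, struct$resno)

  acid <- which(mapply(function(rn, at)
    rn %in% names(ACIDIC_O) && at %in% ACIDIC_O[[rn]],
    struct$resname, struct$atom))
  base <- which(mapply(function(rn, at)
    rn %in% names(BASIC_N) && at %in% BASIC_N[[rn]],
    struct$resname, struct$atom))

  records <- list()
  sb_pairs <- character()
  if (length(acid) > 0 && length(base) > 0) {
    grid <- expand.grid(i = acid, j = base)
    grid$dist <- sqrt(rowSums((xyz[grid$i, , drop = FALSE] -
                                 xyz[grid$j, , drop = FALSE])^2))
    grid$pair <- paste(res_id[grid$i], res_id[grid$j])
    grid <- grid[order(grid$dist), , drop = FALSE]
    grid <- grid[!duplicated(grid$pair), , drop = FALSE]
    grid <- grid[grid$dist < salt_bridge_cutoff, , drop = FALSE]
    if (nrow(grid) > 0) {
      records[[1]] <- contact_row(struct, grid$i, grid$j, grid$dist,
                                  "salt_bridge")
      sb_pairs <- c(grid$pair, paste(res_id[grid$j], res_id[grid$i]))
    }
  }

  if (include_hbonds) {
    polar <- which(toupper(struct$element) %in% c("N", "O"))
    if (length(polar) >= 2) {
      grid <- t(utils::combn(polar, 2))
      i <- grid[, 1]; j <- grid[, 2]
      dist <- sqrt(rowSums((xyz[i, , drop = FALSE] -
                              xyz[j, , drop = FALSE])^2))
      same_res <- res_id[i] == res_id[j]
      backbone <- c("N", "CA", "C", "O")
      adj_bb <- struct$chain[i] == struct$chain[j] &
        abs(struct$resno[i] - struct$resno[j]) <= 1 &
        struct$atom[i] %in% backbone & struct$atom[j] %in% backbone
      in_sb <- paste(res_id[i], res_id[j]) %in% sb_pairs &
        (toupper(struct$element[i]) != toupper(struct$element[j]))
      keep <- dist < hbond_cutoff & !same_res & !adj_bb & !in_sb
      if (any(keep)) {
        records[[length(records) + 1]] <-
          contact_row(struct, i[keep], j[keep], dist[keep], "hydrogen_bond")
      }
    }
  }

  res <- if (length(records)) dplyr::bind_rows(records) else
    contact_row(struct, integer(), integer(), double(), character())
  res <- arrange(res, .data$kind, .data$chain_a, .data$resno_a,
                 .data$chain_b, .data$resno_b, .data$distance)
  class(res) <- c("contact_records", class(res))
  res
}

contact_row <- function(struct, i, j, dist, kind) {
  # canonical partner order: lower (chain, resno, atom) first
  swap <- paste(struct$chain[i], sprintf("%06d", struct$resno[i]),
                struct$atom[i]) >
    paste(struct$chain[j], sprintf("%06d", struct$resno[j]), struct$atom[j])
  a <- ifelse(swap, j, i); b <- ifelse(swap, i, j)
  tibble(
    chain_a = struct$chain[a], resno_a = struct$resno[a],
    resname_a = struct$resname[a], atom_a = struct$atom[a],
    chain_b = struct$chain[b], resno_b = struct$resno[b],
    resname_b = struct$resname[b], atom_b = struct$atom[b],
    distance = dist, kind = if (length(a)) kind else character()
  )
}
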